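test_that("biplot factors reconstruct the rank-2 cross-product for any alpha", {
  uz <- normalize_trajectories(random_ts(8, 12, seed = SEED))
  b1 <- biplot_layout(uz, alpha_scaling = 1)
  b0 <- biplot_layout(uz, alpha_scaling = 0)
  bh <- biplot_layout(uz, alpha_scaling = 0.5)
  r1 <- b1$scores %*% t(b1$coefficients)
  expect_equal(r1, b0$scores %*% t(b0$coefficients), tolerance = 1e-8)
  expect_equal(r1, bh$scores %*% t(bh$coefficients), tolerance = 1e-8)
  # rank-2 truncation of Z via SVD, computed independently
  s <- svd(uz$X)
  z2 <- s$u[, 1:2] %*% diag(s$d[1:2]) %*% t(s$v[, 1:2])
  expect_equal(unname(r1), z2, tolerance = 1e-8)
  expect_error(biplot_layout(uz, alpha_scaling = 1.2), "alpha")
})

test_that("biplot degenerates correctly for orthonormal and rank-1 inputs", {
  # orthonormal rows: all singular values 1, so alpha = 0 coefficients are
  # orthonormal and score norms equal the independent SVD projection norms
  uo <- normalize_trajectories(trajectory_set(diag(5)[1:3, ]))
  bo <- biplot_layout(uo, alpha_scaling = 0)
  expect_equal(unname(crossprod(bo$coefficients)), diag(2), tolerance = 1e-10)
  sv <- svd(uo$X)
  expect_equal(unname(rowSums(bo$scores^2)),
               unname(rowSums((uo$X %*% sv$v[, 1:2])^2)), tolerance = 1e-10)
  # identical rows: all lineages collapse to one point on component 1
  ur <- normalize_trajectories(trajectory_set(matrix(rep(c(1, 2), each = 4),
                                                     4, 2)))
  br <- biplot_layout(ur, alpha_scaling = 1)
  expect_equal(diff(range(br$scores[, 1])), 0, tolerance = 1e-10)
  expect_equal(br$proportion[1], 1, tolerance = 1e-10)
})

test_that("bootstrap clouds shrink to points at sd = 0 and grow with noise", {
  anc <- matrix(0, 3, 6)
  des <- matrix(rnorm(18, sd = 2), 3, 6)
  # sd = 0: all replicates identical, degenerate point ellipses
  st0 <- sample_specimens(specimen_model(anc, des, sd = 0, n_per_group = 5),
                          seed = SEED)
  ref <- eigen_A(normalize_trajectories(change_vectors(st0)))
  bc0 <- bootstrap_directions(st0, ref, replicates = 150, seed = SEED)
  expect_equal(max(bc0$ellipses$semi_major), 0, tolerance = 1e-10)
  # ellipse area grows monotonically over an sd grid
  areas <- vapply(c(0.05, 0.2, 0.8), function(s) {
    st <- sample_specimens(specimen_model(anc, des, sd = s, n_per_group = 5),
                           seed = SEED + 1)
    bc <- bootstrap_directions(st, ref, replicates = 150, seed = SEED + 2)
    mean(pi * bc$ellipses$semi_major * bc$ellipses$semi_minor)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
  # reproducible under fixed seed
  st <- sample_specimens(specimen_model(anc, des, sd = 0.3, n_per_group = 5),
                         seed = SEED)
  b1 <- bootstrap_directions(st, ref, replicates = 120, seed = 7)
  b2 <- bootstrap_directions(st, ref, replicates = 120, seed = 7)
  expect_identical(b1$scores, b2$scores)
})

test_that("short trajectories have larger directional uncertainty", {
  # same noise, same direction; one lineage's change is 10x shorter
  dirs <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  des <- dirs * c(5, 0.5)
  st <- sample_specimens(
    specimen_model(matrix(0, 2, 4), des, sd = 0.3, n_per_group = 8),
    seed = SEED)
  ref <- eigen_A(normalize_trajectories(change_vectors(st)))
  bc <- bootstrap_directions(st, ref, replicates = 200, seed = SEED + 1)
  area <- pi * bc$ellipses$semi_major * bc$ellipses$semi_minor
  long_lineage <- which(bc$ellipses$lineage_id == "lineage_1")
  expect_gt(area[-long_lineage], 5 * area[long_lineage])
})

test_that("bootstrap warns on degenerate cells and checks its reference", {
  st <- tiny_specimens()  # lineage B has single-specimen cells
  ref <- eigen_A(normalize_trajectories(change_vectors(st)))
  bc <- bootstrap_directions(st, ref, replicates = 100, seed = 1)
  expect_match(bc$notes, "cell size < 2")
  badref <- eigen_C(correlation_matrix(change_vectors(st)))
  expect_error(bootstrap_directions(st, badref, replicates = 100), "eigen_A")
})

test_that("k-means recovers planted clusters and hits the WSS boundary cases", {
  # two tight antipodal-ish bundles, well separated
  mu1 <- c(1, rep(0, 7)); mu2 <- c(0, 1, rep(0, 6))
  s1 <- sample_directions(direction_model("vmf", k = 8, mu = mu1,
                                          kappa = 200), 10, seed = SEED)
  s2 <- sample_directions(direction_model("vmf", k = 8, mu = mu2,
                                          kappa = 200), 10, seed = SEED + 1)
  Z <- rbind(s1$X, s2$X)
  rownames(Z) <- paste0("L", 1:20)
  uz <- normalize_trajectories(trajectory_set(Z))
  km <- kmeans_grouping(uz, k_range = c(1, 2, 20), seed = SEED + 2)
  lab <- km$labels$k2
  expect_identical(length(unique(lab[1:10])), 1L)
  expect_identical(length(unique(lab[11:20])), 1L)
  expect_false(lab[1] == lab[11])
  # k = 1: WSS equals total SS about the grand centroid
  tot <- sum(scale(Z, scale = FALSE)^2)
  expect_equal(unname(km$wss["k1"]), tot, tolerance = 1e-8)
  # k = n: zero WSS
  expect_equal(unname(km$wss["k20"]), 0)
  expect_error(kmeans_grouping(uz, k_range = 21), "k_range")
})
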