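test_that("change vectors are descendant-minus-ancestor means, input order kept", {
  st <- tiny_specimens()
  ts <- change_vectors(st)
  # A: ancestor mean (2, 2), descendant mean (3, 1) -> (1, -1)
  expect_equal(unname(ts$X["A", ]), c(1, -1))
  # B: single specimens (0,0) -> (3,4)
  expect_equal(unname(ts$X["B", ]), c(3, 4))
  expect_identical(ts$lineage_ids, c("A", "B"))
  # structural errors name the offender
  bad <- tiny_specimens()
  expect_error(specimen_table(bad[bad$role == "ancestor", ]), "lineage 'A'")
  bad2 <- tiny_specimens(); bad2$t2[3] <- NA
  expect_error(specimen_table(bad2), "missing value in trait 't2', row 3")
})

test_that("zero-noise synthetic specimens round-trip the programmed differences", {
  anc <- matrix(c(0, 0, 1, 2, -1, 3), 3, 2, byrow = TRUE)
  des <- anc + matrix(c(3, 4, -1, 1, 2, 2), 3, 2, byrow = TRUE)
  sm <- specimen_model(anc, des, sd = 0, n_per_group = 4)
  ts <- change_vectors(sample_specimens(sm, seed = SEED))
  expect_equal(unname(ts$X), des - anc)
})

test_that("normalization yields unit rows, preserves direction, rejects zero rows", {
  ts <- trajectory_set(rbind(c(3, 4), c(0.6, 0.8)),
                       lineage_ids = c("a", "b"))
  uz <- normalize_trajectories(ts)
  expect_equal(unname(uz$X[1, ]), c(0.6, 0.8))
  expect_equal(unname(uz$X[2, ]), c(0.6, 0.8))  # already unit: unchanged
  expect_equal(normalize_trajectories(uz), uz)  # idempotent
  ts2 <- random_ts(8, 15)
  expect_equal(unname(rowSums(normalize_trajectories(ts2)$X^2)),
               rep(1, 8), tolerance = 1e-10)
  tz <- trajectory_set(rbind(c(1, 1), c(0, 0)), lineage_ids = c("ok", "dead"))
  expect_error(normalize_trajectories(tz), "dead")
})

test_that("correlation matrix is the cosine matrix with clean structure", {
  # orthogonal rows (first two standard basis vectors) -> identity
  C0 <- correlation_matrix(trajectory_set(diag(3)[1:2, ]))
  expect_equal(unclass(C0), diag(2), ignore_attr = TRUE)
  # identical rows -> all ones
  C1 <- correlation_matrix(trajectory_set(rbind(c(1, 2), c(2, 4))))
  expect_equal(unclass(C1), matrix(1, 2, 2), ignore_attr = TRUE)
  # random rows: entries equal cosines computed from the inner-product
  # definition, diag exactly 1, symmetric, PSD, trace n
  ts <- random_ts(6, 9)
  C <- correlation_matrix(ts)
  X <- ts$X
  for (i in 1:5) for (j in (i + 1):6) {
    cos_ij <- sum(X[i, ] * X[j, ]) / sqrt(sum(X[i, ]^2) * sum(X[j, ]^2))
    expect_equal(C[i, j], cos_ij, tolerance = 1e-12)
  }
  expect_identical(unname(diag(C)), rep(1, 6))
  expect_equal(unclass(C), t(unclass(C)))
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_equal(sum(diag(C)), 6)
})

test_that("correlations depend on directions only (positive rescaling invariance)", {
  ts <- random_ts(5, 7, seed = SEED + 2)
  C1 <- correlation_matrix(ts)
  ts$X <- ts$X * c(10, 0.01, 3, 1, 500)
  expect_equal(unclass(correlation_matrix(ts)), unclass(C1),
               tolerance = 1e-12)
})

test_that("angle matrix is elementwise arccosine with zero diagonal", {
  C <- correlation_matrix(trajectory_set(diag(3)[1:2, ]))
  th <- angle_matrix(C)
  expect_equal(th[1, 2], pi / 2)
  expect_equal(diag(th), c(0, 0), ignore_attr = TRUE)
  expect_equal(angle_matrix(C, "degrees")[1, 2], 90)
  Cm <- correlation_matrix(trajectory_set(rbind(c(1, 0), c(-1, 0))))
  expect_equal(angle_matrix(Cm)[1, 2], pi)
  # two-vector angle agrees with the geometric definition
  ts <- random_ts(2, 5, seed = SEED + 3)
  geo <- acos(sum(ts$X[1, ] * ts$X[2, ]) /
                sqrt(sum(ts$X[1, ]^2) * sum(ts$X[2, ]^2)))
  expect_equal(angle_matrix(correlation_matrix(ts))[1, 2], geo,
               tolerance = 1e-12)
})

test_that("pairwise report flags extremes against the k-dimensional null", {
  # orthogonal pair: null-consistent
  rep0 <- pairwise_angle_report(trajectory_set(diag(3)[1:2, ]), k = 5)
  expect_identical(rep0$flag, "null-consistent")
  # identical vectors: parallel-extreme with p = 0
  rep1 <- pairwise_angle_report(trajectory_set(rbind(c(1, 2), c(2, 4))),
                                k = 10)
  expect_identical(rep1$flag, "parallel-extreme")
  expect_equal(rep1$p_value, 0)
  # 13 lineages -> 78 pairs; columns and caveat present
  rep2 <- pairwise_angle_report(random_ts(13, 20), alpha = 0.05)
  expect_identical(nrow(rep2), 78L)
  expect_true(all(c("angle_rad", "angle_deg", "r", "p_value", "flag") %in%
                    names(rep2)))
  expect_match(attr(rep2, "caveat"), "not independent")
  # flags match the quantile definition of extremeness
  k <- attr(rep2, "k")
  lo <- qangle(0.025, k); hi <- qangle(0.975, k)
  expect_identical(rep2$flag == "parallel-extreme", rep2$angle_rad < lo)
  expect_identical(rep2$flag == "antiparallel-extreme", rep2$angle_rad > hi)
  # bonferroni never flags more than unadjusted
  rep3 <- pairwise_angle_report(random_ts(13, 20), p_adjust = "bonferroni")
  expect_lte(sum(rep3$flag != "null-consistent"),
             sum(rep2$flag != "null-consistent"))
})

test_that("uniform directions are flagged at close to the nominal rate", {
  # n = 4 lineages at k = 76: expected extreme flags per replicate set is
  # 0.05 * 6 pairs; average over seeded replicates should be close
  counts <- parevo:::with_seed(SEED + 4, {
    vapply(1:300, function(i) {
      uz <- sample_uniform_directions(4, 76)
      sum(pairwise_angle_report(uz)$flag != "null-consistent")
    }, numeric(1))
  })
  rate <- mean(counts) / 6
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
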