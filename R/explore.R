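#' Biplot layout for an ordination of change-vector directions
#'
#' Computes a two-component biplot of the unit change vectors from the
#' singular value decomposition \eqn{Z = U D V^T} (equivalently the
#' eigendecomposition of the inter-trait cross-product \eqn{A}). With
#' scaling parameter \eqn{\alpha \in [0, 1]}, lineage scores are
#' \eqn{U_2 D_2^{1-\alpha}} and trait coefficients \eqn{V_2 D_2^\alpha},
#' so that scores times transposed coefficients reconstructs the rank-2
#' truncation of \eqn{Z} for every \eqn{\alpha}; \eqn{\alpha} only
#' reallocates the singular values between the two factors. The default
#' \eqn{\alpha = 1} puts the full singular values on the trait
#' coefficients.
#'
#' @param x a `unit_trajectory_set` (or anything [normalize_trajectories()]
#'   accepts).
#' @param alpha_scaling scaling parameter in \eqn{[0, 1]}, default 1.
#' @param ncomp number of components retained (default 2).
#' @return An object of class `trajectory_biplot`: `scores` (lineage x
#'   ncomp), `coefficients` (trait x ncomp), `singular_values`,
#'   `alpha_scaling`, and the variance `proportion` per component.
#' @seealso [eigen_A()]; [plot.trajectory_biplot()].
#' @export
biplot_layout <- function(x, alpha_scaling = 1, ncomp = 2) {
  uz <- as_unit(x)
  if (alpha_scaling < 0 || alpha_scaling > 1)
    stop("'alpha_scaling' must lie in [0, 1]")
  s <- svd(uz$X)
  V <- fix_signs(s$v)
  # re-apply the same sign flips to U so that U D V' still reconstructs Z
  flips <- colSums(V * s$v) # +1 or -1 per column
  U <- sweep(s$u, 2, flips, `*`)
  d <- s$d
  ncomp <- min(ncomp, length(d))
  idx <- seq_len(ncomp)
  scores <- U[, idx, drop = FALSE] %*% diag(d[idx]^(1 - alpha_scaling),
                                            ncomp)
  coeff <- V[, idx, drop = FALSE] %*% diag(d[idx]^alpha_scaling, ncomp)
  dimnames(scores) <- list(uz$lineage_ids, paste0("PC", idx))
  dimnames(coeff) <- list(uz$trait_names, paste0("PC", idx))
  structure(list(scores = scores, coefficients = coeff,
                 singular_values = d, alpha_scaling = alpha_scaling,
                 proportion = d^2 / sum(d^2)),
            class = "trajectory_biplot")
}

#' Plot a trajectory biplot
#'
#' Base-graphics display of lineage scores (points) and trait coefficients
#' (arrows) on the first two components.
#'
#' @param x a `trajectory_biplot`.
#' @param arrow_scale multiplier applied to coefficient arrows for
#'   legibility (default 1).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.trajectory_biplot <- function(x, arrow_scale = 1, ...) {
  sc <- x$scores; cf <- x$coefficients * arrow_scale
  lim <- range(c(sc, cf, 0))
  graphics::plot(sc, xlim = lim, ylim = lim, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$proportion[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$proportion[2]), ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::arrows(0, 0, cf[, 1], cf[, 2], length = 0.06, col = "tomato")
  graphics::text(sc, labels = rownames(sc), pos = 3, cex = 0.7)
  invisible(x)
}

#' Bootstrap uncertainty of change-vector directions in ordination space
#'
#' Quantifies sampling error of each lineage's direction by nonparametric
#' bootstrap of the specimen-level data: specimens are resampled with
#' replacement within each lineage x role cell, change vectors are
#' recomputed, renormalized to unit length, and projected onto the *fixed*
#' leading eigenvectors of the observed data ([eigen_A()]). A 95%
#' normal-theory confidence ellipse (replicate covariance, chi-square
#' 2-df quantile) summarizes each lineage's replicate cloud in the plane of
#' the first two components.
#'
#' Lineages with short change vectors relative to the within-group noise
#' show large directional ellipses: direction is poorly determined when the
#' trajectory is short.
#'
#' @param specimens a [specimen_table()].
#' @param reference a `direction_eigen` from [eigen_A()] on the observed
#'   data (its eigenvectors define the fixed projection plane).
#' @param replicates number of bootstrap replicates, at least 100.
#' @param seed RNG seed.
#' @param level ellipse coverage, default 0.95.
#' @return An object of class `bootstrap_cloud`: `scores` (long data frame
#'   of replicate score pairs per lineage), `ellipses` (per lineage:
#'   center, semi-axes, orientation), `replicates`, `seed`, `notes`.
#' @export
bootstrap_directions <- function(specimens, reference, replicates = 1000,
                                 seed = NULL, level = 0.95) {
  specimens <- specimen_table(specimens)
  stopifnot(inherits(reference, "direction_eigen"))
  if (reference$source != "trait_crossproduct_A")
    stop("'reference' must come from eigen_A() on the observed data")
  if (replicates < 100) stop("'replicates' must be at least 100")
  traits <- attr(specimens, "trait_names")
  lineages <- unique(specimens$lineage_id)
  Vref <- reference$vectors[, 1:2, drop = FALSE]
  notes <- character()
  cells <- split(seq_len(nrow(specimens)),
                 list(specimens$lineage_id, specimens$role), drop = TRUE)
  small <- names(cells)[vapply(cells, length, 1L) < 2L]
  if (length(small))
    notes <- c(notes, paste0("degenerate resampling (cell size < 2): ",
                             paste(small, collapse = ", ")))
  if (is.null(seed)) seed <- draw_seed()
  M <- as.matrix(specimens[, traits, drop = FALSE])
  reps <- with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      t(vapply(lineages, function(lin) {
        ia <- cells[[paste(lin, "ancestor", sep = ".")]]
        id <- cells[[paste(lin, "descendant", sep = ".")]]
        anc <- colMeans(M[sample(ia, length(ia), replace = TRUE), ,
                          drop = FALSE])
        des <- colMeans(M[sample(id, length(id), replace = TRUE), ,
                          drop = FALSE])
        d <- des - anc
        nd <- sqrt(sum(d^2))
        if (nd <= 1e-12) return(c(NA_real_, NA_real_))
        drop((d / nd) %*% Vref)
      }, numeric(2)))
    })
  })
  scores <- do.call(rbind, lapply(seq_along(reps), function(b) {
    data.frame(lineage_id = lineages, replicate = b,
               PC1 = reps[[b]][, 1], PC2 = reps[[b]][, 2],
               stringsAsFactors = FALSE)
  }))
  q <- stats::qchisq(level, df = 2)
  ellipses <- do.call(rbind, lapply(lineages, function(lin) {
    s <- scores[scores$lineage_id == lin & !is.na(scores$PC1),
                c("PC1", "PC2")]
    ctr <- colMeans(s)
    cv <- stats::cov(s)
    e <- eigen(cv, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    data.frame(lineage_id = lin, center1 = ctr[1], center2 = ctr[2],
               semi_major = sqrt(ev[1] * q), semi_minor = sqrt(ev[2] * q),
               angle_rad = atan2(e$vectors[2, 1], e$vectors[1, 1]),
               stringsAsFactors = FALSE)
  }))
  rownames(ellipses) <- NULL
  structure(list(scores = scores, ellipses = ellipses,
                 replicates = as.integer(replicates), seed = seed,
                 level = level, notes = notes),
            class = "bootstrap_cloud")
}

#' Plot a bootstrap cloud with confidence ellipses
#'
#' @param x a `bootstrap_cloud`.
#' @param max_points replicate points drawn per lineage (default 200; all
#'   ellipses are always drawn).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bootstrap_cloud <- function(x, max_points = 200, ...) {
  sc <- x$scores[!is.na(x$scores$PC1), ]
  lineages <- unique(sc$lineage_id)
  cols <- grDevices::hcl.colors(length(lineages), "Dark 3")
  names(cols) <- lineages
  keep <- unlist(lapply(split(seq_len(nrow(sc)), sc$lineage_id),
                        function(ii) utils::head(ii, max_points)))
  graphics::plot(sc$PC1[keep], sc$PC2[keep],
                 col = grDevices::adjustcolor(cols[sc$lineage_id[keep]], 0.3),
                 pch = 16, cex = 0.4, xlab = "PC1", ylab = "PC2", ...)
  tt <- seq(0, 2 * pi, length.out = 181)
  for (i in seq_len(nrow(x$ellipses))) {
    el <- x$ellipses[i, ]
    xy <- cbind(el$semi_major * cos(tt), el$semi_minor * sin(tt))
    rot <- matrix(c(cos(el$angle_rad), sin(el$angle_rad),
                    -sin(el$angle_rad), cos(el$angle_rad)), 2)
    xy <- xy %*% t(rot)
    graphics::lines(el$center1 + xy[, 1], el$center2 + xy[, 2],
                    col = cols[el$lineage_id], lwd = 1.5)
  }
  invisible(x)
}

#' k-means clustering of change-vector directions
#'
#' Standard k-means on the unit change vectors for each requested number of
#' clusters, with multiple random restarts (best within-group sum of
#' squares kept). No automatic selection of the number of clusters is
#' attempted; the within-group sum of squares per `k` is reported for the
#' analyst to inspect.
#'
#' @param x a `unit_trajectory_set` (or anything [normalize_trajectories()]
#'   accepts).
#' @param k_range integer vector of cluster counts, each in \eqn{[1, n]}.
#' @param restarts random restarts per `k` (default 50).
#' @param seed RNG seed.
#' @return A list of class `direction_kmeans`: `labels` (data frame,
#'   lineages x one column per `k`), `wss` (named total within-group sum of
#'   squares per `k`), `centroids` (list of centroid matrices), `restarts`,
#'   `seed`.
#' @export
kmeans_grouping <- function(x, k_range, restarts = 50, seed = NULL) {
  uz <- as_unit(x)
  n <- nrow(uz$X)
  k_range <- as.integer(k_range)
  if (any(k_range < 1L) || any(k_range > n))
    stop("every k in 'k_range' must lie in [1, n]")
  if (is.null(seed)) seed <- draw_seed()
  fits <- with_seed(seed, {
    lapply(k_range, function(kk) {
      if (kk == n) # every lineage its own cluster; kmeans() refuses k = n
        return(list(cluster = seq_len(n), centers = uz$X,
                    tot.withinss = 0))
      stats::kmeans(uz$X, centers = kk, nstart = restarts, iter.max = 100)
    })
  })
  labels <- as.data.frame(lapply(fits, function(f) f$cluster))
  names(labels) <- paste0("k", k_range)
  rownames(labels) <- uz$lineage_ids
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  names(wss) <- paste0("k", k_range)
  structure(list(labels = labels, wss = wss,
                 centroids = lapply(fits, function(f) f$centers),
                 restarts = restarts, seed = seed),
            class = "direction_kmeans")
}
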