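#' Eigendecomposition of the inter-lineage correlation matrix
#'
#' Spectral decomposition \eqn{C = U L U^T} of the \eqn{n \times n}
#' vector correlation matrix. Eigenvalues are returned nonincreasing, tiny
#' negative values (numerical noise) clipped to zero. Eigenvector polarity
#' is arbitrary; the convention here makes the largest-magnitude element of
#' each eigenvector positive, which affects plot orientation only.
#'
#' @param cm a `vector_cor` matrix from [correlation_matrix()].
#' @return An object of class `direction_eigen` with elements `source`
#'   (`"lineage_correlation_C"`), `values`, `vectors`, `n`, `p`.
#' @seealso [eigen_A()] for the trait-space decomposition, which shares the
#'   nonzero eigenvalues of `C` and is usually more interpretable for
#'   trait-space variation.
#' @export
eigen_C <- function(cm) {
  stopifnot(inherits(cm, "vector_cor"))
  e <- eigen(unclass(cm), symmetric = TRUE)
  direction_eigen("lineage_correlation_C", e$values, fix_signs(e$vectors),
                  n = nrow(cm), p = NA_integer_,
                  labels = rownames(cm))
}

#' Eigendecomposition of the inter-trait cross-product matrix
#'
#' Decomposes \eqn{A = Z^T Z = V K V^T}, the \eqn{p \times p} cross-product
#' of the unit change vectors. The nonzero eigenvalues of \eqn{A} equal
#' those of \eqn{C}; \eqn{V} and \eqn{K} live in the trait space, making
#' them the natural basis for ordination of phenotypic change vectors. The
#' row scores \eqn{Z V} are returned for that purpose; their total sum of
#' squares equals \eqn{n} (trace conservation).
#'
#' @param x a `unit_trajectory_set` (or anything [normalize_trajectories()]
#'   accepts).
#' @return A `direction_eigen` with `source = "trait_crossproduct_A"`,
#'   eigen`values`, eigen`vectors` (columns, trait space), and `scores`
#'   (\eqn{n \times p} projections of lineages).
#' @export
eigen_A <- function(x) {
  uz <- as_unit(x)
  A <- crossprod(uz$X)
  e <- eigen(A, symmetric = TRUE)
  V <- fix_signs(e$vectors)
  out <- direction_eigen("trait_crossproduct_A", e$values, V,
                         n = nrow(uz$X), p = ncol(uz$X),
                         labels = uz$trait_names)
  out$scores <- uz$X %*% V
  dimnames(out$scores) <- list(uz$lineage_ids,
                               paste0("PC", seq_len(ncol(V))))
  out
}

direction_eigen <- function(source, values, vectors, n, p, labels = NULL) {
  if (any(values < -1e-8 * max(1, abs(values[1]))))
    warning("markedly negative eigenvalue clipped to zero")
  values <- pmax(values, 0)
  ord <- order(values, decreasing = TRUE)
  values <- values[ord]
  vectors <- vectors[, ord, drop = FALSE]
  if (!is.null(labels)) rownames(vectors) <- labels
  colnames(vectors) <- paste0("PC", seq_along(values))
  structure(list(source = source, values = values, vectors = vectors,
                 scores = NULL, n = n, p = p),
            class = "direction_eigen")
}

#' @export
print.direction_eigen <- function(x, ...) {
  cat(sprintf("Eigendecomposition of %s (%d eigenvalues)\n",
              x$source, length(x$values)))
  cat("leading eigenvalues:",
      paste(signif(utils::head(x$values, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

# make the largest-magnitude element of each eigenvector column positive
fix_signs <- function(V) {
  s <- apply(V, 2, function(v) {
    sg <- sign(v[which.max(abs(v))])
    if (sg == 0) 1 else sg
  })
  sweep(V, 2, s, `*`)
}

#' Eigenvalue dispersion
#'
#' Sum of squared deviations of the eigenvalues from their mean,
#' \eqn{\sum_i (\lambda_i - \bar\lambda)^2}. For the lineage correlation
#' matrix \eqn{C} the mean is over its \eqn{n} eigenvalues; for the trait
#' cross-product \eqn{A}, over its \eqn{p}. Uniformly spread directions
#' give low dispersion; concentration of directions inflates it. The
#' dispersions of \eqn{C} and \eqn{A} and the summed squared correlations
#' are linked by the identity
#' \deqn{\sum_i (l_i - \bar l)^2 = \sum_i (k_i - \bar k)^2 + n^2/p - n
#'       = 2 \sum_{i<j} r_{ij}^2.}
#'
#' @param er a `direction_eigen` from [eigen_C()] or [eigen_A()].
#' @return Scalar dispersion.
#' @seealso [sum_squared_correlations()], [schott_test()].
#' @export
eigenvalue_dispersion <- function(er) {
  stopifnot(inherits(er, "direction_eigen"))
  sum((er$values - mean(er$values))^2)
}

#' Sum of squared pairwise vector correlations
#'
#' \eqn{\sum_{i<j} r_{ij}^2} over the \eqn{n(n-1)/2} unordered lineage
#' pairs; equals half the eigenvalue dispersion of \eqn{C}. This is the
#' statistic of the high-dimensional uniformity test ([schott_test()]).
#'
#' @param cm a `vector_cor` matrix.
#' @return Scalar sum of squared off-diagonal correlations.
#' @export
sum_squared_correlations <- function(cm) {
  stopifnot(inherits(cm, "vector_cor"))
  C <- unclass(cm)
  sum(C[upper.tri(C)]^2)
}
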