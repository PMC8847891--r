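#' Construct a set of phenotypic change vectors
#'
#' A trajectory set holds the \eqn{n \times p} matrix \eqn{X} whose rows are
#' phenotypic change vectors (descendant minus ancestor trait means) of
#' \eqn{p} traits for \eqn{n} lineages, together with lineage and trait
#' labels and the effective dimensionality `k_effective` of the trait space.
#' `k_effective` defaults to \eqn{p} but should be lowered when the traits
#' are linearly dependent (see [effective_dim()]).
#'
#' @param X numeric matrix, one row per lineage, one column per trait.
#' @param lineage_ids character vector of unique lineage labels (defaults to
#'   rownames of `X`).
#' @param trait_names character vector of unique trait labels (defaults to
#'   colnames of `X`).
#' @param k_effective effective dimensionality, integer in \eqn{[2, p]}.
#' @return An object of class `trajectory_set`.
#' @seealso [change_vectors()] to build one from specimen-level data,
#'   [normalize_trajectories()], [pairwise_angle_report()].
#' @export
trajectory_set <- function(X, lineage_ids = rownames(X),
                           trait_names = colnames(X),
                           k_effective = ncol(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) stop("need at least 2 traits")
  if (n < 1L) stop("need at least 1 lineage")
  if (anyNA(X)) stop("missing trait values are not allowed")
  if (is.null(lineage_ids)) lineage_ids <- paste0("lineage_", seq_len(n))
  if (is.null(trait_names)) trait_names <- paste0("trait_", seq_len(p))
  if (anyDuplicated(lineage_ids)) stop("duplicate lineage ids")
  if (anyDuplicated(trait_names)) stop("duplicate trait names")
  k_effective <- as.integer(k_effective)
  if (k_effective < 2L || k_effective > p)
    stop("'k_effective' must be an integer in [2, p]")
  dimnames(X) <- list(lineage_ids, trait_names)
  structure(list(X = X, lineage_ids = as.character(lineage_ids),
                 trait_names = as.character(trait_names),
                 k_effective = k_effective),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  unit <- inherits(x, "unit_trajectory_set")
  cat(sprintf("%s: %d lineages x %d traits (k_effective = %d)\n",
              if (unit) "Unit trajectory set" else "Trajectory set",
              nrow(x$X), ncol(x$X), x$k_effective))
  invisible(x)
}

#' Specimen-level trait table
#'
#' Validates a data frame of individual specimens with columns
#' `specimen_id`, `lineage_id`, `role` (literal `"ancestor"` or
#' `"descendant"`) followed by numeric trait columns. Every lineage must have
#' at least one specimen in each role, and no trait value may be missing.
#'
#' @param df a data frame in the layout above.
#' @return The validated data frame with class `specimen_table`.
#' @seealso [change_vectors()], [sample_specimens()], [bootstrap_directions()].
#' @export
specimen_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("specimen_id", "lineage_id", "role")
  if (!all(need %in% names(df)))
    stop("specimen table needs columns: ", paste(need, collapse = ", "))
  traits <- setdiff(names(df), need)
  if (length(traits) < 2L) stop("need at least 2 trait columns")
  bad_role <- setdiff(unique(df$role), c("ancestor", "descendant"))
  if (length(bad_role))
    stop("role must be 'ancestor' or 'descendant'; found: ",
         paste(bad_role, collapse = ", "))
  for (tr in traits) {
    if (!is.numeric(df[[tr]]))
      stop(sprintf("trait column '%s' is not numeric", tr))
    if (anyNA(df[[tr]])) {
      row <- which(is.na(df[[tr]]))[1]
      stop(sprintf("missing value in trait '%s', row %d", tr, row))
    }
  }
  for (lin in unique(df$lineage_id)) {
    roles <- df$role[df$lineage_id == lin]
    if (!all(c("ancestor", "descendant") %in% roles))
      stop(sprintf("lineage '%s' lacks specimens in both roles", lin))
  }
  df$lineage_id <- as.character(df$lineage_id)
  df$role <- as.character(df$role)
  attr(df, "trait_names") <- traits
  class(df) <- c("specimen_table", "data.frame")
  df
}

#' Phenotypic change vectors from specimen-level data
#'
#' For each lineage, computes the change vector as the descendant trait mean
#' minus the ancestor trait mean. Lineages appear in the output in their
#' order of first appearance in the input.
#'
#' @param specimens a [specimen_table()].
#' @param k_effective effective dimensionality passed to [trajectory_set()].
#' @return A `trajectory_set` with one row per lineage.
#' @export
change_vectors <- function(specimens, k_effective = NULL) {
  specimens <- specimen_table(specimens)
  traits <- attr(specimens, "trait_names")
  lineages <- unique(specimens$lineage_id)
  X <- t(vapply(lineages, function(lin) {
    anc <- specimens$lineage_id == lin & specimens$role == "ancestor"
    des <- specimens$lineage_id == lin & specimens$role == "descendant"
    colMeans(as.matrix(specimens[des, traits, drop = FALSE])) -
      colMeans(as.matrix(specimens[anc, traits, drop = FALSE]))
  }, numeric(length(traits))))
  if (is.null(k_effective)) k_effective <- length(traits)
  trajectory_set(X, lineage_ids = lineages, trait_names = traits,
                 k_effective = k_effective)
}

#' Standardize change vectors to unit length
#'
#' Rescales each row of \eqn{X} to unit norm, \eqn{Z = diag(\|x_i\|^{-1}) X},
#' discarding trajectory magnitudes and retaining directions only. A row of
#' (numerically) zero norm has no direction and is an error.
#'
#' @param ts a `trajectory_set` (a unit set passes through unchanged).
#' @return An object of class `unit_trajectory_set` (also a
#'   `trajectory_set`) whose rows have unit norm.
#' @export
normalize_trajectories <- function(ts) {
  if (inherits(ts, "unit_trajectory_set")) return(ts)
  stopifnot(inherits(ts, "trajectory_set"))
  norms <- sqrt(rowSums(ts$X^2))
  if (any(norms <= 1e-12)) {
    bad <- ts$lineage_ids[norms <= 1e-12]
    stop("zero-length change vector (no direction) for lineage(s): ",
         paste(bad, collapse = ", "))
  }
  ts$X <- ts$X / norms
  class(ts) <- c("unit_trajectory_set", "trajectory_set")
  ts
}

# coerce to unit set; accepts trajectory_set or bare matrix
as_unit <- function(x) {
  if (inherits(x, "unit_trajectory_set")) return(x)
  if (inherits(x, "trajectory_set")) return(normalize_trajectories(x))
  if (is.matrix(x)) return(normalize_trajectories(trajectory_set(x)))
  stop("expected a trajectory_set, unit_trajectory_set or matrix")
}

#' Inter-lineage vector correlation matrix
#'
#' Computes \eqn{C = Z Z^T}, the \eqn{n \times n} matrix whose
#' \eqn{(i, j)}th element is the vector correlation (cosine of the angle)
#' between the change vectors of lineages \eqn{i} and \eqn{j}. The diagonal
#' is set exactly to 1 and off-diagonal entries are clipped into
#' \eqn{[-1, 1]} (tolerance `1e-12`) to absorb floating-point overshoot.
#'
#' @param x a `unit_trajectory_set` (or anything [normalize_trajectories()]
#'   accepts).
#' @return A symmetric matrix of class `vector_cor` with lineage ids as
#'   dimnames and the source `k_effective` in attribute `"k_effective"`.
#' @seealso [angle_matrix()], [eigen_C()], [schott_test()].
#' @export
correlation_matrix <- function(x) {
  uz <- as_unit(x)
  C <- tcrossprod(uz$X)
  C <- clip_cor(C)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  structure(C, k_effective = uz$k_effective, class = c("vector_cor", "matrix"))
}

#' @export
print.vector_cor <- function(x, ...) {
  cat(sprintf("Inter-lineage vector correlation matrix (%d lineages)\n",
              nrow(x)))
  print(unclass(x)[seq_len(nrow(x)), seq_len(ncol(x))], ...)
  invisible(x)
}

#' Pairwise angle matrix
#'
#' Element-wise arccosine of a vector correlation matrix, giving the
#' \eqn{n \times n} symmetric matrix of pairwise angles (zero diagonal).
#'
#' @param cm a `vector_cor` matrix from [correlation_matrix()].
#' @param units `"radians"` (default) or `"degrees"`.
#' @return A symmetric numeric matrix of angles.
#' @export
angle_matrix <- function(cm, units = c("radians", "degrees")) {
  units <- match.arg(units)
  stopifnot(inherits(cm, "vector_cor"))
  th <- acos(clip_cor(unclass(cm)))
  diag(th) <- 0
  if (units == "degrees") th <- th * 180 / pi
  th
}

#' Pairwise angle report with extremeness flags
#'
#' Tests each of the \eqn{n(n-1)/2} pairwise angles against the
#' no-preferred-direction null at effective dimensionality `k`
#' (two-sided [angle_test()]), and flags each pair as
#' `"parallel-extreme"` (angle below the \eqn{\alpha/2} null quantile),
#' `"antiparallel-extreme"` (above the \eqn{1 - \alpha/2} quantile), or
#' `"null-consistent"`. A pair exactly on a quantile boundary is
#' non-extreme.
#'
#' The pairwise p-values are *not* independent of one another: off-diagonal
#' correlations covary except under exact uniformity, so the flags are a
#' descriptive screen, not a family of independent tests. No multiplicity
#' control is applied by default; `p_adjust = "bonferroni"` is available and
#' is conservative (but not exact) under that dependence.
#'
#' @param ts a `trajectory_set` or `unit_trajectory_set`.
#' @param k effective dimensionality (defaults to the set's `k_effective`).
#' @param alpha flagging level in (0, 1), default 0.05.
#' @param p_adjust `"none"` (default) or `"bonferroni"`.
#' @return A data frame with one row per unordered pair: lineage labels,
#'   angle in radians and degrees, vector correlation `r`, two-sided
#'   `p_value` and `flag`. Attributes: `k`, `alpha`, `caveat`.
#' @export
pairwise_angle_report <- function(ts, k = NULL, alpha = 0.05,
                                  p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  uz <- as_unit(ts)
  if (is.null(k)) k <- uz$k_effective
  k <- check_k(k)
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must be in (0, 1)")
  n <- nrow(uz$X)
  if (n < 2L) stop("need at least 2 lineages for pairwise angles")
  cm <- correlation_matrix(uz)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  r <- unclass(cm)[idx]
  theta <- acos(clip_cor(r))
  lo <- pangle_vec(theta, k)
  p <- pmin(1, 2 * pmin(lo, 1 - lo))
  if (p_adjust == "bonferroni") p <- stats::p.adjust(p, "bonferroni")
  flag <- rep("null-consistent", length(p))
  flag[p < alpha & theta < pi / 2] <- "parallel-extreme"
  flag[p < alpha & theta > pi / 2] <- "antiparallel-extreme"
  out <- data.frame(
    lineage_i = uz$lineage_ids[idx[, 1]],
    lineage_j = uz$lineage_ids[idx[, 2]],
    angle_rad = theta, angle_deg = theta * 180 / pi,
    r = r, p_value = p, flag = flag,
    stringsAsFactors = FALSE)
  attr(out, "k") <- k
  attr(out, "alpha") <- alpha
  attr(out, "p_adjust") <- p_adjust
  attr(out, "caveat") <-
    "pairwise p-values are not independent: off-diagonal vector correlations covary unless the population correlation matrix is the identity"
  out
}

# vectorized pangle for internal use (pangle itself is vectorized in theta)
pangle_vec <- function(theta, k) pangle(theta, k)
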