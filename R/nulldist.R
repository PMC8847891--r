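#' Density of the angle between random directions
#'
#' Probability density of the angle \eqn{\theta} between two independent
#' directions with no preferred orientation (uniform on the unit hypersphere)
#' in a \eqn{k}-dimensional space,
#' \deqn{f(\theta) = \sin^{k-2}(\theta) / B(1/2, (k-1)/2), \quad 0 \le \theta \le \pi.}
#' For \eqn{k = 2} the density is uniform on \eqn{[0, \pi]}; for larger
#' \eqn{k} it peaks increasingly sharply at the right angle
#' \eqn{\theta = \pi/2}. This concentration of random angles around
#' orthogonality is the reason observed angles cannot be interpreted at face
#' value across trait spaces of different dimensionality.
#'
#' @param theta numeric vector of angles in radians, in \eqn{[0, \pi]}.
#' @param k effective dimensionality of the trait space (integer, \eqn{\ge 2}).
#'   This is the number of dimensions of free variation, which can be lower
#'   than the nominal trait count; see [effective_dim()].
#' @return Numeric vector of densities.
#' @seealso [dveccor()] for the density of the vector correlation
#'   \eqn{r = \cos\theta}; [pangle()] and [qangle()] for the distribution
#'   function and quantiles; [angle_test()] for hypothesis tests.
#' @examples
#' dangle(pi / 2, k = 3)       # 0.5, the equatorial peak on the 2-sphere
#' dangle(1.234, k = 2)        # 1/pi, uniform on the circle
#' integrate(dangle, 0, pi, k = 10)$value  # 1
#' @export
dangle <- function(theta, k) {
  k <- check_k(k)
  if (any(theta < 0 | theta > pi, na.rm = TRUE))
    stop("'theta' must lie in [0, pi] (radians)")
  exp((k - 2) * log(sin(theta)) - lbeta(0.5, (k - 1) / 2))
}

#' Density of the vector correlation between random directions
#'
#' Probability density of \eqn{r = \cos\theta}, the vector correlation
#' between two independent uniformly distributed directions in \eqn{k}
#' dimensions:
#' \deqn{f(r) = (1 - r^2)^{(k-3)/2} / B(1/2, (k-1)/2), \quad -1 \le r \le 1.}
#' The squared correlation \eqn{r^2} follows a Beta\eqn{(1/2, (k-1)/2)}
#' distribution, and \eqn{\sqrt{k-1}\, r / \sqrt{1-r^2}} follows a
#' t-distribution with \eqn{k - 1} degrees of freedom.
#'
#' For \eqn{k = 2} the density diverges at \eqn{|r| = 1}; there the function
#' returns `Inf` (the distribution function remains proper).
#'
#' @inheritParams dangle
#' @param r numeric vector of correlations in \eqn{[-1, 1]}.
#' @return Numeric vector of densities (possibly `Inf` at the boundary for
#'   `k = 2`).
#' @examples
#' dveccor(0.7, k = 3)  # 0.5: the k = 3 law of r is uniform on [-1, 1]
#' dveccor(0, k = 5)    # 3/4
#' @export
dveccor <- function(r, k) {
  k <- check_k(k)
  if (any(abs(r) > 1, na.rm = TRUE))
    stop("'r' must lie in [-1, 1]")
  out <- exp(((k - 3) / 2) * log1p(-r^2) - lbeta(0.5, (k - 1) / 2))
  if (k == 2) out[abs(r) == 1] <- Inf
  out
}

#' Distribution function of the random angle
#'
#' \eqn{P(\Theta \le \theta)} for the angle between two independent uniform
#' directions in \eqn{k} dimensions, computed through the monotone map
#' \eqn{t = \sqrt{k-1}\cot\theta} and the t-distribution with \eqn{k - 1}
#' degrees of freedom. Small angles (near-parallel directions) correspond to
#' large \eqn{t}, so the lower tail in \eqn{\theta} is the upper tail in
#' \eqn{t}.
#'
#' @inheritParams dangle
#' @return Numeric vector of probabilities.
#' @examples
#' pangle(pi / 2, k = 10)   # 0.5 for any k, by symmetry
#' pangle(1, k = 2)         # 1/pi: uniform law on [0, pi]
#' pangle(pi / 3, k = 3)    # (1 - cos(pi/3))/2 = 0.25
#' @export
pangle <- function(theta, k) {
  k <- check_k(k)
  if (any(theta < 0 | theta > pi, na.rm = TRUE))
    stop("'theta' must lie in [0, pi] (radians)")
  t <- sqrt(k - 1) * cos(theta) / sin(theta)  # Inf at the endpoints is fine
  p <- stats::pt(t, df = k - 1, lower.tail = FALSE)
  p[theta == 0] <- 0
  p[theta == pi] <- 1
  p
}

#' Quantile function of the random angle
#'
#' Inverse of [pangle()].
#'
#' @param p numeric vector of probabilities.
#' @inheritParams dangle
#' @return Angles in radians.
#' @examples
#' qangle(0.5, k = 76)             # pi/2
#' qangle(pangle(1.2, k = 5), 5)   # 1.2
#' @export
qangle <- function(p, k) {
  k <- check_k(k)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("'p' must lie in [0, 1]")
  t <- stats::qt(p, df = k - 1, lower.tail = FALSE)
  theta <- pi / 2 - atan(t / sqrt(k - 1))
  theta[p == 0] <- 0
  theta[p == 1] <- pi
  theta
}

#' Test an observed angle against the no-preferred-direction null
#'
#' Tests the null hypothesis that two phenotypic change vectors are
#' independent with no preferred directions in a \eqn{k}-dimensional trait
#' space, under which the angle between them follows the density of
#' [dangle()]. The p-value is computed from the equivalent t-statistic
#' \eqn{t = \sqrt{k-1}\, r/\sqrt{1-r^2}} with \eqn{k - 1} degrees of freedom.
#'
#' Alternatives:
#' \describe{
#'   \item{`two_sided`}{both unusually small (parallel) and unusually large
#'     (antiparallel) angles count as extreme (default).}
#'   \item{`parallel`}{small angles are extreme.}
#'   \item{`antiparallel`}{large angles are extreme.}
#'   \item{`axial`}{polarity is ignored (e.g. angles between eigenvectors);
#'     the p-value is the upper tail of \eqn{r^2} under
#'     Beta\eqn{(1/2, (k-1)/2)}.}
#' }
#'
#' Exactly one of `theta` and `r` must be supplied. `r` is clipped into
#' \eqn{[-1, 1]} with tolerance `1e-12` to absorb floating-point overshoot
#' from inner products; larger excursions are errors.
#'
#' @param theta observed angle in radians, in \eqn{[0, \pi]}.
#' @param r observed vector correlation (cosine of the angle).
#' @inheritParams dangle
#' @param alternative one of `"two_sided"`, `"parallel"`, `"antiparallel"`,
#'   `"axial"`.
#' @return A `direction_test` object; see [print.direction_test()].
#' @examples
#' angle_test(theta = pi / 3, k = 76)
#' angle_test(r = 0.9, k = 10, alternative = "parallel")
#' @export
angle_test <- function(theta = NULL, r = NULL, k,
                       alternative = c("two_sided", "parallel",
                                       "antiparallel", "axial")) {
  k <- check_k(k)
  alternative <- match.arg(alternative)
  if (is.null(theta) == is.null(r))
    stop("supply exactly one of 'theta' and 'r'")
  if (is.null(theta)) {
    r <- clip_cor(r)
    theta <- acos(r)
  } else {
    if (length(theta) != 1L || theta < 0 || theta > pi)
      stop("'theta' must be a single angle in [0, pi] (radians)")
    r <- cos(theta)
  }
  lo <- pangle(theta, k)
  p <- switch(alternative,
    two_sided    = min(1, 2 * min(lo, 1 - lo)),
    parallel     = lo,
    antiparallel = 1 - lo,
    axial        = stats::pbeta(r^2, 0.5, (k - 1) / 2, lower.tail = FALSE))
  tstat <- if (abs(r) < 1) sqrt(k - 1) * r / sqrt(1 - r^2) else sign(r) * Inf
  direction_test(
    method = sprintf("angle test (%s), t null with %d df", alternative, k - 1),
    statistic = theta, p_value = p,
    null_mean = pi / 2, null_sd = sqrt(null_angle_var(k)),
    n = 2L, k = k,
    details = list(theta_rad = theta, theta_deg = theta * 180 / pi,
                   r = r, t = tstat, alternative = alternative))
}

# Var(theta) under the null, by quadrature (E(theta) = pi/2 by symmetry)
null_angle_var <- function(k) {
  stats::integrate(function(th) (th - pi / 2)^2 * dangle(th, k),
                   0, pi, rel.tol = 1e-10)$value
}

#' Dimension-standardized effect size for an angle
#'
#' Returns \eqn{\sqrt{k-2}\,(\pi/2 - \theta)}, a standardization of the
#' deviation of an observed angle from orthogonality whose null distribution
#' converges to the standard normal as \eqn{k \to \infty}. Positive values
#' indicate angles closer to parallel than orthogonal; negative values,
#' closer to antiparallel. Unlike raw angles, this quantity is comparable
#' across trait spaces of different (large) dimensionality.
#'
#' @inheritParams dangle
#' @param theta angle(s) in radians.
#' @return Numeric vector of effect sizes.
#' @examples
#' angle_effect_size(pi / 2, k = 100)  # 0: orthogonality
#' angle_effect_size(pi / 4, k = 3)    # pi/4
#' @export
angle_effect_size <- function(theta, k) {
  k <- check_k(k, min = 3L)
  if (any(theta < 0 | theta > pi, na.rm = TRUE))
    stop("'theta' must lie in [0, pi] (radians)")
  sqrt(k - 2) * (pi / 2 - theta)
}

#' Null moments of the squared vector correlation
#'
#' Under the uniform-direction null, the squared correlation \eqn{r^2}
#' between two independent directions in \eqn{k} dimensions follows
#' Beta\eqn{(1/2, (k-1)/2)}, with mean \eqn{1/k} and variance
#' \eqn{2(k-1)/\{k^2(k+2)\}}. These per-pair moments are the building blocks
#' of the high-dimensional uniformity test moments in [schott_moments()].
#'
#' @inheritParams dangle
#' @return Named numeric vector with elements `mean` and `variance`.
#' @examples
#' sqcor_moments(76)
#' sqcor_moments(2)  # arcsine law: mean 1/2, variance 1/8
#' @export
sqcor_moments <- function(k) {
  k <- check_k(k)
  c(mean = 1 / k, variance = 2 * (k - 1) / (k^2 * (k + 2)))
}

#' Effective dimensionality of a trait space
#'
#' Phenotypic traits are often linearly dependent: Procrustes-aligned shape
#' coordinates from a two-dimensional landmark analysis lose 4 degrees of
#' freedom to alignment (translation, rotation, scale), and tangent-space
#' projection preserves this. The null distributions of angles depend on the
#' number of dimensions of free variation, not the nominal trait count, so
#' the effective dimensionality \eqn{k = p - d} must be supplied by the
#' analyst who knows how the traits were constructed.
#'
#' @param p nominal trait count.
#' @param lost_df degrees of freedom lost to linear constraints (default 0).
#' @return Integer effective dimensionality.
#' @examples
#' effective_dim(80, lost_df = 4)  # 76
#' @export
effective_dim <- function(p, lost_df = 0) {
  p <- as.integer(p); d <- as.integer(lost_df)
  if (is.na(p) || p < 2L) stop("'p' must be an integer >= 2")
  if (is.na(d) || d < 0L || p - d < 2L)
    stop("'lost_df' must be a nonnegative integer with p - lost_df >= 2")
  p - d
}

# --- internal helpers -------------------------------------------------------

check_k <- function(k, min = 2L) {
  if (length(k) != 1L || is.na(k) || k != round(k) || k < min)
    stop(sprintf("'k' must be a single integer >= %d (effective dimensionality)",
                 min))
  as.integer(k)
}

# clip correlations into [-1, 1]; tolerance absorbs floating-point overshoot.
# In-place assignment (not pmin/pmax) so matrix dims survive.
clip_cor <- function(r, tol = 1e-12) {
  if (any(abs(r) > 1 + tol, na.rm = TRUE))
    stop("correlation outside [-1, 1] beyond numerical tolerance")
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}
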