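#' Null moments of the summed squared correlations
#'
#' Expectation and variance of \eqn{\sum_{i<j} r_{ij}^2} over \eqn{n}
#' independent uniformly distributed directions in a \eqn{p}-dimensional
#' space:
#' \deqn{E = \frac{n(n-1)}{2p}, \qquad
#'       Var = \frac{n(n-1)(p-1)}{p^2(p+2)}.}
#' Each squared pairwise correlation is Beta\eqn{(1/2, (p-1)/2)} with mean
#' \eqn{1/p} and variance \eqn{2(p-1)/\{p^2(p+2)\}}, and the squared
#' correlations are mutually uncorrelated under this null, so the moments
#' are the per-pair moments times the number of pairs.
#'
#' @param n number of lineages (directions), integer \eqn{\ge 2}.
#' @param p effective dimensionality of the trait space, integer \eqn{\ge 2}.
#' @return Named numeric vector with elements `expectation` and `variance`.
#' @examples
#' schott_moments(13, 76)  # expectation 1.03, sd 0.16 (2 dp)
#' @export
schott_moments <- function(n, p) {
  if (length(n) != 1L || is.na(n) || n != round(n) || n < 2)
    stop("'n' must be a single integer >= 2")
  if (length(p) != 1L || is.na(p) || p != round(p) || p < 2)
    stop("'p' must be a single integer >= 2")
  n <- as.integer(n); p <- as.integer(p)
  c(expectation = n * (n - 1) / (2 * p),
    variance = n * (n - 1) * (p - 1) / (p^2 * (p + 2)))
}

#' High-dimensional test of no preferred directions (Schott)
#'
#' Tests the null hypothesis that the \eqn{n} change-vector directions are
#' independent with no preferred direction (population correlation matrix
#' \eqn{\Gamma = I_n}) using the statistic
#' \eqn{S = \sum_{i<j} r_{ij}^2}. Under the null and a high-dimensional
#' asymptotic regime (\eqn{n, p \to \infty} with \eqn{n/p} convergent),
#' \eqn{Z = (S - E)/\sqrt{Var}} with the moments of [schott_moments()] is
#' standard normal; a large positive deviation indicates concentration of
#' directions. The p-value is one-sided upper by default. Because \eqn{S}
#' ignores the signs of correlations, the test detects unimodal, antipodal
#' and girdle departures alike but does not distinguish them — inspect the
#' correlation matrix or ordination scores to see which is present.
#'
#' The asymptotic approximation is slightly liberal when \eqn{n} or the
#' dimensionality is small (below about 16); `mode = "auto"` switches to a
#' Monte Carlo null in that regime. Two interchangeable Monte Carlo null
#' generators are available: `"gaussian"` simulates \eqn{n} uniform
#' directions directly (normalized Gaussian vectors); `"wishart"` draws an
#' \eqn{n \times n} Wishart matrix with `k` degrees of freedom and rescales
#' it to a correlation matrix. The two are distributionally equivalent and
#' must agree within Monte Carlo error.
#'
#' @param x a `vector_cor` matrix, or any input [correlation_matrix()]
#'   accepts.
#' @param k effective dimensionality of the trait space (defaults to the
#'   `k_effective` carried by the input).
#' @param mode `"auto"` (default), `"asymptotic"` or `"monte_carlo"`.
#' @param two_sided if `TRUE`, also count unusually *small* `S` as extreme;
#'   not the standard usage (concentration alternative), default `FALSE`.
#' @param reps Monte Carlo replicates (default 10000).
#' @param seed RNG seed for Monte Carlo; drawn and recorded if missing.
#' @param null_generator `"gaussian"` (default) or `"wishart"`.
#' @return A `direction_test` with the statistic `S`, the standardized `Z`
#'   in `details`, null moments, and Monte Carlo provenance when used.
#' @references Schott, J. R. (2005). Testing for complete independence in
#'   high dimensions. *Biometrika* 92, 951-956.
#' @examples
#' uz <- sample_uniform_directions(10, k = 20, seed = 1)
#' schott_test(uz, mode = "asymptotic")
#' @export
schott_test <- function(x, k = NULL,
                        mode = c("auto", "asymptotic", "monte_carlo"),
                        two_sided = FALSE, reps = 10000, seed = NULL,
                        null_generator = c("gaussian", "wishart")) {
  mode <- match.arg(mode)
  null_generator <- match.arg(null_generator)
  cm <- if (inherits(x, "vector_cor")) x else correlation_matrix(x)
  if (is.null(k)) k <- attr(cm, "k_effective")
  if (is.null(k)) stop("'k' (effective dimensionality) must be supplied")
  k <- check_k(k)
  n <- nrow(cm)
  if (n < 2L) stop("need at least 2 lineages")
  S <- sum_squared_correlations(cm)
  mom <- schott_moments(n, k)
  Z <- (S - mom[["expectation"]]) / sqrt(mom[["variance"]])
  notes <- character()
  if (mode == "auto")
    mode <- if (min(n, k) < 16L) "monte_carlo" else "asymptotic"
  if (mode == "asymptotic") {
    if (min(n, k) < 16L)
      notes <- c(notes,
        "small-sample regime (min(n, k) < 16): asymptotic p-value may be liberal; consider mode = 'monte_carlo'")
    p <- stats::pnorm(Z, lower.tail = FALSE)
    if (two_sided) p <- min(1, 2 * min(p, 1 - p))
    return(direction_test(
      method = "Schott test of uniform directions (asymptotic)",
      statistic = S, p_value = p,
      null_mean = mom[["expectation"]], null_sd = sqrt(mom[["variance"]]),
      n = n, k = k, notes = notes,
      details = list(Z = Z, two_sided = two_sided)))
  }
  if (reps < 100) stop("'reps' must be at least 100")
  if (is.null(seed)) seed <- draw_seed()
  sims <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      Cs <- switch(null_generator,
        gaussian = {
          Zm <- matrix(stats::rnorm(n * k), n, k)
          tcrossprod(Zm / sqrt(rowSums(Zm^2)))
        },
        wishart = stats::cov2cor(stats::rWishart(1, df = k,
                                                 Sigma = diag(n))[, , 1]))
      (sum(Cs^2) - n) / 2
    }, numeric(1))
  })
  p_up <- (1 + sum(sims >= S)) / (1 + reps)
  p <- if (two_sided) {
    p_lo <- (1 + sum(sims <= S)) / (1 + reps)
    min(1, 2 * min(p_up, p_lo))
  } else p_up
  direction_test(
    method = sprintf("Schott test of uniform directions (Monte Carlo, %s null)",
                     null_generator),
    statistic = S, p_value = p,
    null_mean = mean(sims), null_sd = stats::sd(sims),
    n = n, k = k, mc_iterations = as.integer(reps), seed = seed,
    notes = notes,
    details = list(Z = Z, two_sided = two_sided,
                   analytic_mean = mom[["expectation"]],
                   analytic_sd = sqrt(mom[["variance"]])))
}

#' Rayleigh test of uniform directions
#'
#' Classical directional-statistics test for unimodal concentration: the
#' statistic is \eqn{T = n k \|\bar z\|^2} where \eqn{\bar z} is the mean of
#' the \eqn{n} unit direction vectors (mean resultant vector) and \eqn{k}
#' the effective dimensionality. Under uniformity \eqn{T} is asymptotically
#' chi-squared with \eqn{k} degrees of freedom. The test is powerful against
#' a single preferred direction but blind to antipodal (axial) and
#' girdle-like departures, whose mean resultant vanishes — use
#' [schott_test()] for those.
#'
#' @param x a `unit_trajectory_set` (or anything [normalize_trajectories()]
#'   accepts).
#' @param k effective dimensionality (defaults to the set's `k_effective`).
#' @param mode `"asymptotic"` (default) or `"monte_carlo"`.
#' @param reps,seed Monte Carlo controls, as in [schott_test()].
#' @return A `direction_test`.
#' @references Mardia, K. V. & Jupp, P. E. (2000). *Directional Statistics*.
#'   Wiley.
#' @export
rayleigh_test <- function(x, k = NULL, mode = c("asymptotic", "monte_carlo"),
                          reps = 10000, seed = NULL) {
  mode <- match.arg(mode)
  uz <- as_unit(x)
  if (is.null(k)) k <- uz$k_effective
  k <- check_k(k)
  n <- nrow(uz$X)
  if (n < 2L) stop("need at least 2 directions")
  rbar2 <- sum(colMeans(uz$X)^2)
  T <- n * k * rbar2
  if (mode == "asymptotic") {
    p <- stats::pchisq(T, df = k, lower.tail = FALSE)
    return(direction_test(
      method = "Rayleigh test of uniform directions (asymptotic chi-square)",
      statistic = T, p_value = p, null_mean = k, null_sd = sqrt(2 * k),
      n = n, k = k,
      details = list(mean_resultant_length = sqrt(rbar2))))
  }
  if (reps < 100) stop("'reps' must be at least 100")
  if (is.null(seed)) seed <- draw_seed()
  sims <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      Zm <- matrix(stats::rnorm(n * k), n, k)
      Zm <- Zm / sqrt(rowSums(Zm^2))
      n * k * sum(colMeans(Zm)^2)
    }, numeric(1))
  })
  p <- (1 + sum(sims >= T)) / (1 + reps)
  direction_test(
    method = "Rayleigh test of uniform directions (Monte Carlo)",
    statistic = T, p_value = p,
    null_mean = mean(sims), null_sd = stats::sd(sims),
    n = n, k = k, mc_iterations = as.integer(reps), seed = seed,
    details = list(mean_resultant_length = sqrt(rbar2)))
}

#' Monte Carlo test of the mean pairwise angle
#'
#' Compares the observed mean of the \eqn{n(n-1)/2} pairwise angles with its
#' distribution over replicate sets of \eqn{n} independent uniform
#' directions in `k` dimensions. The p-value uses tail counting with the
#' add-one correction, \eqn{p = (1 + \#\{sim \le obs\})/(1 + iterations)}
#' for the parallel alternative (and correspondingly for the others).
#'
#' The mean pairwise angle has no clear interpretation beyond this specific
#' null: pairwise angles are mutually dependent, and departures from
#' uniformity do not translate into particular mean values. The result
#' carries a note to that effect; prefer [schott_test()] or
#' [rayleigh_test()] for inference.
#'
#' @param ts a `trajectory_set` or `unit_trajectory_set`.
#' @param k effective dimensionality (defaults to the set's `k_effective`).
#' @param iterations Monte Carlo iterations, at least 1000.
#' @param seed RNG seed; drawn and recorded if missing.
#' @param alternative `"two_sided"` (default), `"parallel"` (small mean
#'   angle extreme) or `"antiparallel"`.
#' @return A `direction_test`; the statistic is the observed mean pairwise
#'   angle in radians (degrees in `details`).
#' @export
mean_pairwise_angle_test <- function(ts, k = NULL, iterations = 10000,
                                     seed = NULL,
                                     alternative = c("two_sided", "parallel",
                                                     "antiparallel")) {
  alternative <- match.arg(alternative)
  if (iterations < 1000) stop("'iterations' must be at least 1000")
  uz <- as_unit(ts)
  if (is.null(k)) k <- uz$k_effective
  k <- check_k(k)
  n <- nrow(uz$X)
  if (n < 2L) stop("need at least 2 lineages")
  obs <- mean_angle_stat(uz$X)
  if (is.null(seed)) seed <- draw_seed()
  sims <- with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      Zm <- matrix(stats::rnorm(n * k), n, k)
      mean_angle_stat(Zm / sqrt(rowSums(Zm^2)))
    }, numeric(1))
  })
  p_par <- (1 + sum(sims <= obs)) / (1 + iterations)
  p_anti <- (1 + sum(sims >= obs)) / (1 + iterations)
  p <- switch(alternative,
    parallel = p_par, antiparallel = p_anti,
    two_sided = min(1, 2 * min(p_par, p_anti)))
  direction_test(
    method = sprintf("Monte Carlo test of the mean pairwise angle (%s)",
                     alternative),
    statistic = obs, p_value = p,
    null_mean = mean(sims), null_sd = stats::sd(sims),
    n = n, k = k, mc_iterations = as.integer(iterations), seed = seed,
    notes = "the mean pairwise angle lacks clear interpretability beyond the uniform-direction null; pairwise angles are mutually dependent",
    details = list(mean_angle_deg = obs * 180 / pi,
                   alternative = alternative))
}

mean_angle_stat <- function(Z) {
  C <- tcrossprod(Z)
  mean(acos(pmin(1, pmax(-1, C[upper.tri(C)]))))
}
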