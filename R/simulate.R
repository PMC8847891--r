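#' Sample uniform random directions on the hypersphere
#'
#' Draws `n` independent directions uniformly distributed on the unit
#' hypersphere in `k` dimensions, by normalizing independent standard
#' Gaussian vectors. This is the null model of "no preferred direction"
#' used throughout the uniformity tests.
#'
#' @param n number of directions.
#' @param k dimensionality (\eqn{\ge 2}).
#' @param seed RNG seed; with a seed the draw is reproducible and the
#'   caller's random stream is left untouched.
#' @return A `unit_trajectory_set` with `k_effective = k` and lineage ids
#'   `sim_1 ... sim_n`.
#' @examples
#' uz <- sample_uniform_directions(5, k = 10, seed = 42)
#' rowSums(uz$X^2)  # all 1
#' @export
sample_uniform_directions <- function(n, k, seed = NULL) {
  k <- check_k(k)
  if (n < 1) stop("'n' must be at least 1")
  X <- with_seed(seed, matrix(stats::rnorm(n * k), n, k))
  X <- X / sqrt(rowSums(X^2))
  rownames(X) <- paste0("sim_", seq_len(n))
  colnames(X) <- paste0("dim_", seq_len(k))
  normalize_trajectories(trajectory_set(X, k_effective = k))
}

#' Specify a direction-generating model
#'
#' Describes one of four regimes of directions on the unit hypersphere:
#' \describe{
#'   \item{`uniform`}{no preferred direction (the uniformity null).}
#'   \item{`vmf`}{von Mises-Fisher: unimodal concentration around mean
#'     direction `mu` with concentration `kappa` (`kappa = 0` is uniform).}
#'   \item{`antipodal_vmf`}{an axial, two-mode pattern: vMF draws around
#'     `mu` with half the sample flipped to `-mu`. By default
#'     (`balanced = TRUE`) exactly half of the vectors (rounding down) are
#'     flipped, giving a sample with (near-)zero mean resultant by
#'     construction; with `balanced = FALSE` each vector flips
#'     independently with probability 1/2, so small samples carry a
#'     binomial imbalance and a nonzero residual resultant.}
#'   \item{`girdle`}{directions concentrated near the great circle
#'     (hyperplane) orthogonal to `girdle_normal`. This is a package
#'     convention: a uniform draw is projected into the hyperplane and
#'     perturbed along the normal by Gaussian noise with standard deviation
#'     \eqn{1/\sqrt{1 + 2\kappa}}, then renormalized; larger `kappa` gives a
#'     tighter girdle.}
#' }
#' The vMF and antipodal regimes emulate parallel and axially-parallel
#' evolution; the girdle regime emulates change confined to a subspace.
#'
#' @param kind one of `"uniform"`, `"vmf"`, `"antipodal_vmf"`, `"girdle"`.
#' @param k dimensionality.
#' @param mu mean direction (unit vector, required for vMF regimes;
#'   normalized if near-unit).
#' @param kappa nonnegative concentration (vMF and girdle regimes).
#' @param girdle_normal unit normal of the girdle hyperplane.
#' @param balanced for `antipodal_vmf`: flip exactly half the sample
#'   (default) rather than each vector independently.
#' @return An object of class `direction_model`.
#' @seealso [sample_directions()], [power_study()].
#' @export
direction_model <- function(kind = c("uniform", "vmf", "antipodal_vmf",
                                     "girdle"),
                            k, mu = NULL, kappa = 0, girdle_normal = NULL,
                            balanced = TRUE) {
  kind <- match.arg(kind)
  k <- check_k(k)
  if (kappa < 0) stop("'kappa' must be nonnegative")
  unitize <- function(v, what) {
    if (length(v) != k) stop(sprintf("'%s' must have length k = %d", what, k))
    nv <- sqrt(sum(v^2))
    if (abs(nv - 1) > 1e-6)
      stop(sprintf("'%s' must be a unit vector", what))
    v / nv
  }
  if (kind %in% c("vmf", "antipodal_vmf")) {
    if (is.null(mu)) stop("'mu' is required for vMF models")
    mu <- unitize(mu, "mu")
  }
  if (kind == "girdle") {
    if (is.null(girdle_normal)) stop("'girdle_normal' is required")
    girdle_normal <- unitize(girdle_normal, "girdle_normal")
  }
  structure(list(kind = kind, k = k, mu = mu, kappa = kappa,
                 girdle_normal = girdle_normal,
                 balanced = isTRUE(balanced)),
            class = "direction_model")
}

#' Sample directions from a direction model
#'
#' @param model a [direction_model()].
#' @param n number of directions.
#' @param seed RNG seed (reproducible, stream-preserving).
#' @return A `unit_trajectory_set`. The sampling algorithm (for vMF,
#'   Wood-style rejection sampling of the cosine component) is recorded in
#'   attribute `"sampler"`.
#' @export
sample_directions <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "direction_model"))
  if (n < 1) stop("'n' must be at least 1")
  k <- model$k
  X <- with_seed(seed, switch(model$kind,
    uniform = {
      Z <- matrix(stats::rnorm(n * k), n, k)
      Z / sqrt(rowSums(Z^2))
    },
    vmf = rvmf(n, model$mu, model$kappa),
    antipodal_vmf = {
      Z <- rvmf(n, model$mu, model$kappa)
      sign_flip <- if (model$balanced) {
        # exactly half the sample (rounding down) points to -mu
        flip <- sample.int(n, n %/% 2)
        ifelse(seq_len(n) %in% flip, -1, 1)
      } else ifelse(stats::runif(n) < 0.5, -1, 1)
      Z * sign_flip
    },
    girdle = {
      g <- model$girdle_normal
      sd_normal <- 1 / sqrt(1 + 2 * model$kappa)
      t(vapply(seq_len(n), function(i) {
        repeat {
          u <- stats::rnorm(k)
          u_perp <- u - sum(u * g) * g
          nu <- sqrt(sum(u_perp^2))
          if (nu > 1e-12) break
        }
        v <- u_perp / nu + stats::rnorm(1, 0, sd_normal) * g
        v / sqrt(sum(v^2))
      }, numeric(k)))
    }))
  rownames(X) <- paste0("sim_", seq_len(n))
  colnames(X) <- paste0("dim_", seq_len(k))
  out <- normalize_trajectories(trajectory_set(X, k_effective = k))
  attr(out, "sampler") <- switch(model$kind,
    vmf = , antipodal_vmf = "vMF via Wood (1994) rejection sampling",
    model$kind)
  out
}

# von Mises-Fisher sampler, Wood (1994): rejection sampling of the cosine
# component w = mu'x, then a uniform tangent direction. kappa = 0 accepts
# every proposal and reduces to the uniform law of w.
rvmf <- function(n, mu, kappa) {
  k <- length(mu)
  b <- (-2 * kappa + sqrt(4 * kappa^2 + (k - 1)^2)) / (k - 1)
  x0 <- (1 - b) / (1 + b)
  c0 <- kappa * x0 + (k - 1) * log(1 - x0^2)
  w <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- stats::rbeta(1, (k - 1) / 2, (k - 1) / 2)
    wc <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
    if (kappa * wc + (k - 1) * log(1 - x0 * wc) - c0 >= log(stats::runif(1))) {
      i <- i + 1L
      w[i] <- wc
    }
  }
  t(vapply(seq_len(n), function(i) {
    repeat {
      v <- stats::rnorm(k)
      v_perp <- v - sum(v * mu) * mu
      nv <- sqrt(sum(v_perp^2))
      if (nv > 1e-12) break
    }
    w[i] * mu + sqrt(max(0, 1 - w[i]^2)) * v_perp / nv
  }, numeric(k)))
}

#' Specify a specimen-level generating model
#'
#' Describes lineage-wise ancestor and descendant population means with
#' independent Gaussian within-group noise — the sampling situation behind
#' specimen-level bootstrap analyses. Change vectors computed from a
#' noise-free draw equal the programmed mean differences exactly.
#'
#' @param ancestor_means,descendant_means numeric matrices (lineage x trait)
#'   of group means, identical dimensions.
#' @param sd within-group standard deviation (common across traits and
#'   groups), nonnegative.
#' @param n_per_group specimens per lineage x role cell, at least 1.
#' @param lineage_ids,trait_names optional labels.
#' @return An object of class `specimen_model`.
#' @export
specimen_model <- function(ancestor_means, descendant_means, sd = 0.1,
                           n_per_group = 10,
                           lineage_ids = rownames(ancestor_means),
                           trait_names = colnames(ancestor_means)) {
  ancestor_means <- as.matrix(ancestor_means)
  descendant_means <- as.matrix(descendant_means)
  if (!all(dim(ancestor_means) == dim(descendant_means)))
    stop("mean matrices must have identical dimensions")
  if (sd < 0) stop("'sd' must be nonnegative")
  if (n_per_group < 1) stop("'n_per_group' must be at least 1")
  n <- nrow(ancestor_means); p <- ncol(ancestor_means)
  if (is.null(lineage_ids)) lineage_ids <- paste0("lineage_", seq_len(n))
  if (is.null(trait_names)) trait_names <- paste0("trait_", seq_len(p))
  structure(list(ancestor_means = ancestor_means,
                 descendant_means = descendant_means,
                 sd = sd, n_per_group = as.integer(n_per_group),
                 lineage_ids = lineage_ids, trait_names = trait_names),
            class = "specimen_model")
}

#' Sample a specimen table from a specimen model
#'
#' @param model a [specimen_model()].
#' @param seed RNG seed; a fixed seed yields a byte-identical table.
#' @return A [specimen_table()] with `n_per_group` specimens per lineage and
#'   role.
#' @export
sample_specimens <- function(model, seed = NULL) {
  stopifnot(inherits(model, "specimen_model"))
  n <- nrow(model$ancestor_means)
  p <- ncol(model$ancestor_means)
  m <- model$n_per_group
  rows <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n), function(i) {
      do.call(rbind, lapply(c("ancestor", "descendant"), function(role) {
        mu <- if (role == "ancestor") model$ancestor_means[i, ]
              else model$descendant_means[i, ]
        vals <- matrix(stats::rnorm(m * p, mean = rep(mu, each = m),
                                    sd = model$sd), m, p)
        data.frame(specimen_id = paste(model$lineage_ids[i], role,
                                       seq_len(m), sep = "_"),
                   lineage_id = model$lineage_ids[i], role = role,
                   stats::setNames(as.data.frame(vals), model$trait_names),
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  specimen_table(rows)
}

#' Power study for the uniformity tests
#'
#' Estimates rejection rates of the Schott and/or Rayleigh tests at level
#' `alpha` over replicate datasets drawn from a direction model. Under the
#' uniform model this recovers the type-I error rate; under concentrated
#' models it measures power. The qualitative contrast between the two tests
#' — Rayleigh powerful only against unimodal concentration, Schott against
#' antipodal and girdle patterns too — is directly visible here.
#'
#' @param model a [direction_model()].
#' @param n directions per replicate dataset.
#' @param replicates number of replicate datasets, at least 100.
#' @param alpha nominal level.
#' @param tests character subset of `c("schott", "rayleigh")`.
#' @param mode test mode passed to the tests (default `"asymptotic"`,
#'   keeping the study fast; use `"monte_carlo"` for small `n` or `k`).
#' @param seed RNG seed for the whole study.
#' @return A data frame with one row per test: rejection `power`, binomial
#'   standard error, `replicates`, `alpha`.
#' @export
power_study <- function(model, n, replicates = 1000, alpha = 0.05,
                        tests = c("schott", "rayleigh"),
                        mode = "asymptotic", seed = NULL) {
  stopifnot(inherits(model, "direction_model"))
  tests <- match.arg(tests, several.ok = TRUE)
  if (replicates < 100) stop("'replicates' must be at least 100")
  rej <- with_seed(seed, {
    counts <- stats::setNames(numeric(length(tests)), tests)
    for (r in seq_len(replicates)) {
      uz <- sample_directions(model, n)
      for (tst in tests) {
        p <- switch(tst,
          schott = schott_test(uz, mode = mode,
                               seed = if (mode == "monte_carlo") draw_seed(),
                               reps = 500)$p_value,
          rayleigh = rayleigh_test(uz, mode = mode,
                                   seed = if (mode == "monte_carlo") draw_seed(),
                                   reps = 500)$p_value)
        if (p < alpha) counts[tst] <- counts[tst] + 1
      }
    }
    counts / replicates
  })
  data.frame(test = tests, power = unname(rej[tests]),
             se = sqrt(unname(rej[tests]) * (1 - unname(rej[tests])) /
                         replicates),
             replicates = replicates, alpha = alpha,
             stringsAsFactors = FALSE)
}
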