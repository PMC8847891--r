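# Shared fixtures, built in code at test time.

# base seed for all stochastic tests (publication-date convention)
SEED <- 20220216L

# random trajectory set with rows of varying magnitude
random_ts <- function(n, p, seed = SEED, k_effective = p) {
  X <- parevo:::with_seed(seed, {
    matrix(rnorm(n * p), n, p) * runif(n, 0.5, 3)
  })
  trajectory_set(X, k_effective = k_effective)
}

# two-lineage specimen table with hand-computable means
tiny_specimens <- function() {
  specimen_table(data.frame(
    specimen_id = paste0("s", 1:6),
    lineage_id = c("A", "A", "A", "A", "B", "B"),
    role = c("ancestor", "ancestor", "descendant", "descendant",
             "ancestor", "descendant"),
    t1 = c(1, 3, 2, 4, 0, 3),
    t2 = c(1, 3, 0, 2, 0, 4),
    stringsAsFactors = FALSE))
}

# path for a scratch file under the session temp dir
temp_path <- function(name) file.path(tempdir(), paste0("parevo-", name))

# draw m independent cosines of uniform random angles in k dims without
# using package samplers (independent oracle): w = 1 - 2B with
# B ~ Beta((k-1)/2, (k-1)/2)
oracle_cosines <- function(m, k) 1 - 2 * rbeta(m, (k - 1) / 2, (k - 1) / 2)
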