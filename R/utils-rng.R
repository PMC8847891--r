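# Run code under a local RNG state. With a seed, the global .Random.seed is
# saved, the seed applied, and the state restored afterwards, so seeded calls
# never disturb the caller's random stream. With seed = NULL the current
# stream is used (and advanced) as usual.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (length(seed) != 1L || is.na(seed) || seed != round(seed))
    stop("'seed' must be a single integer")
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Draw a seed to record when the user supplied none but reproducibility of a
# Monte Carlo result must be reportable.
draw_seed <- function() sample.int(.Machine$integer.max, 1L)
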