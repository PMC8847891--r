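#' Read trajectory or specimen data from delimited text
#'
#' Reads either a lineage-level table (one row per lineage: first column the
#' lineage id, remaining columns numeric traits) or a specimen-level table
#' (columns `specimen_id`, `lineage_id`, `role`, then traits). The delimiter
#' is auto-detected from the header line (tab if present, otherwise comma)
#' and can be overridden.
#'
#' The effective dimensionality can be given directly (`k_effective`) or as
#' degrees of freedom lost to linear constraints (`lost_df`, so that
#' \eqn{k = p - d}); supply at most one.
#'
#' @param path path to a delimited text file with a header row.
#' @param specimen_level logical; read as specimen-level data?
#' @param delim field delimiter; `NULL` (default) auto-detects.
#' @param k_effective effective dimensionality of the trait space.
#' @param lost_df degrees of freedom lost (alternative to `k_effective`).
#' @return A `trajectory_set`, or a `specimen_table` when
#'   `specimen_level = TRUE` (pass it to [change_vectors()]).
#' @export
read_trajectories <- function(path, specimen_level = FALSE, delim = NULL,
                              k_effective = NULL, lost_df = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(k_effective) && !is.null(lost_df))
    stop("supply at most one of 'k_effective' and 'lost_df'")
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (specimen_level) {
    st <- specimen_table(df)
    attr(st, "k_effective") <-
      resolve_k(length(attr(st, "trait_names")), k_effective, lost_df)
    return(st)
  }
  if (ncol(df) < 3L) stop("need a lineage id column plus at least 2 traits")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate lineage ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  traits <- names(df)[-1]
  for (j in seq_along(traits)) {
    col <- df[[j + 1]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d",
                   traits[j], if (is.na(bad)) 1L else bad))
    }
    if (anyNA(col))
      stop(sprintf("missing value in column '%s', row %d",
                   traits[j], which(is.na(col))[1]))
  }
  X <- as.matrix(df[, -1, drop = FALSE])
  trajectory_set(X, lineage_ids = ids, trait_names = traits,
                 k_effective = resolve_k(ncol(X), k_effective, lost_df))
}

resolve_k <- function(p, k_effective, lost_df) {
  if (!is.null(k_effective)) return(check_k(k_effective))
  if (!is.null(lost_df)) return(effective_dim(p, lost_df))
  p
}

#' Write a trajectory set or data frame to delimited text
#'
#' Writes in the same layout [read_trajectories()] consumes, so write
#' followed by read is the identity on values and labels.
#'
#' @param x a `trajectory_set`, `specimen_table`, or data frame.
#' @param path output path.
#' @param delim field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(x, path, delim = "\t") {
  df <- if (inherits(x, "trajectory_set")) {
    data.frame(lineage_id = x$lineage_ids,
               as.data.frame(x$X, check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  } else as.data.frame(x)
  utils::write.table(df, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full parallelism analysis pipeline
#'
#' One call reproduces the standard workflow on a trajectory set: pairwise
#' angle report with extremeness flags, Monte Carlo test of the mean
#' pairwise angle, ordination of the unit change vectors (eigenanalysis of
#' the inter-trait cross-product), and the Schott uniformity test. A JSON
#' manifest records the configuration, seeds and package version so the run
#' is reproducible; given the same seed the report is deterministic.
#'
#' Stage seeds are derived from `seed` (`seed` for the mean-angle Monte
#' Carlo, `seed + 1` for a Schott Monte Carlo null when the small-sample
#' regime requires one).
#'
#' @param x a `trajectory_set`, or a path passed to [read_trajectories()].
#' @param k effective dimensionality (defaults to the set's `k_effective`).
#' @param alpha flagging level for the pairwise report.
#' @param iterations Monte Carlo iterations for the mean-angle test.
#' @param seed integer seed for all stochastic stages.
#' @param outdir optional directory; when given, TSV tables (pairwise
#'   report, eigenvalues, scores, loadings) and the JSON manifest are
#'   written there.
#' @param ... passed to [read_trajectories()] when `x` is a path.
#' @return A list of class `parevo_report`: `pairwise`, `mean_angle`,
#'   `ordination`, `schott`, `manifest`.
#' @export
full_report <- function(x, k = NULL, alpha = 0.05, iterations = 10000,
                        seed = 1, outdir = NULL, ...) {
  ts <- if (is.character(x)) read_trajectories(x, ...) else x
  stopifnot(inherits(ts, "trajectory_set"))
  uz <- normalize_trajectories(ts)
  if (is.null(k)) k <- uz$k_effective
  k <- check_k(k)
  n <- nrow(uz$X)
  seed <- as.integer(seed)

  pairwise <- pairwise_angle_report(uz, k = k, alpha = alpha)
  mean_angle <- mean_pairwise_angle_test(uz, k = k, iterations = iterations,
                                         seed = seed)
  ordination <- eigen_A(uz)
  schott <- schott_test(uz, k = k, mode = "auto", seed = seed + 1L)

  manifest <- list(
    package = "parevo",
    version = as.character(utils::packageVersion("parevo")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = list(n = n, p = ncol(uz$X), k_effective = k, alpha = alpha,
                  iterations = iterations, seed = seed),
    stage_seeds = list(mean_angle = seed, schott = schott$seed),
    results = list(
      n_pairs = nrow(pairwise),
      n_parallel_extreme = sum(pairwise$flag == "parallel-extreme"),
      n_antiparallel_extreme = sum(pairwise$flag == "antiparallel-extreme"),
      mean_angle_rad = mean_angle$statistic,
      mean_angle_p = mean_angle$p_value,
      schott_S = schott$statistic,
      schott_p = schott$p_value))

  out <- structure(list(pairwise = pairwise, mean_angle = mean_angle,
                        ordination = ordination, schott = schott,
                        manifest = manifest),
                   class = "parevo_report")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(pairwise, file.path(outdir, "pairwise_angles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(component = paste0("PC", seq_along(ordination$values)),
                 eigenvalue = ordination$values),
      file.path(outdir, "eigenvalues.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(lineage_id = rownames(ordination$scores),
                 ordination$scores, check.names = FALSE),
      file.path(outdir, "scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(trait = rownames(ordination$vectors),
                 ordination$vectors, check.names = FALSE),
      file.path(outdir, "loadings.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.parevo_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("parevo full report: n = %d lineages, p = %d traits, k = %d\n",
              m$config$n, m$config$p, m$config$k_effective))
  cat(sprintf("pairwise: %d pairs, %d parallel-extreme, %d antiparallel-extreme (alpha = %g)\n",
              m$results$n_pairs, m$results$n_parallel_extreme,
              m$results$n_antiparallel_extreme, m$config$alpha))
  cat(sprintf("mean pairwise angle: %.4g rad (%.4g deg), p %s\n",
              m$results$mean_angle_rad,
              m$results$mean_angle_rad * 180 / pi,
              format.pval(m$results$mean_angle_p)))
  cat(sprintf("Schott: S = %.4g, p %s\n", m$results$schott_S,
              format.pval(m$results$schott_p)))
  invisible(x)
}
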