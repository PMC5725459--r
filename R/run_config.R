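#' Pipeline run configuration
#'
#' Collects the tunable constants of the pipeline in one validated list.
#' Defaults follow the published analysis protocol: restart probability 0.95
#' for the random walk, top 5% of propagated proteins, STRING-style score
#' threshold 0.7 (inclusive), 10,000 randomization replicates, Bonferroni
#' alpha 0.05, and the GATK-style hard-filter thresholds QD < 5.0, MQ < 40.0,
#' FS > 200.0, QUAL < 30.0.
#'
#' @param restart_probability Restart probability of the random walk, in (0, 1].
#' @param top_fraction Fraction of nonzero-score proteins kept as the extended
#'   set, in (0, 1].
#' @param string_score_threshold Minimum interaction score for the
#'   interaction-evolution analysis, in \[0, 1\]; the bound is inclusive.
#' @param n_randomizations Number of resampling replicates for the
#'   randomization test.
#' @param bonferroni_alpha Significance cutoff applied to Bonferroni-adjusted
#'   enrichment p-values.
#' @param filter_thresholds Named list with elements `QD`, `MQ`, `FS`, `QUAL`;
#'   a variant is removed when QD < 5.0, MQ < 40.0, FS > 200.0 or QUAL < 30.0
#'   (all inequalities strict, missing fields never fire).
#' @param rng_seed Integer seed driving every randomized step.
#' @param weighted_adjacency Use edge scores as walk weights (`TRUE`, default)
#'   or a binary adjacency (`FALSE`).
#' @param threshold_before_rwr Apply `string_score_threshold` to the network
#'   before propagation (default `FALSE`: the threshold belongs to the
#'   interaction-evolution stage only).
#' @param resolve Ambiguity resolution for the parsimony top-down pass:
#'   `"deltran"` (default, child keeps the parent state on ties) or
#'   `"acctran"` (ties resolved toward a change on the earlier branch).
#' @return A list of class `run_config`.
#' @export
run_config <- function(restart_probability = 0.95,
                       top_fraction = 0.05,
                       string_score_threshold = 0.7,
                       n_randomizations = 10000L,
                       bonferroni_alpha = 0.05,
                       filter_thresholds = list(QD = 5.0, MQ = 40.0,
                                                FS = 200.0, QUAL = 30.0),
                       rng_seed = 1L,
                       weighted_adjacency = TRUE,
                       threshold_before_rwr = FALSE,
                       resolve = c("deltran", "acctran")) {
  resolve <- match.arg(resolve)
  stopifnot(
    is.numeric(restart_probability), length(restart_probability) == 1L,
    restart_probability > 0, restart_probability <= 1,
    is.numeric(top_fraction), top_fraction > 0, top_fraction <= 1,
    is.numeric(string_score_threshold),
    string_score_threshold >= 0, string_score_threshold <= 1,
    is.numeric(n_randomizations), n_randomizations >= 1,
    is.numeric(bonferroni_alpha), bonferroni_alpha > 0, bonferroni_alpha <= 1
  )
  needed <- c("QD", "MQ", "FS", "QUAL")
  if (!all(needed %in% names(filter_thresholds))) {
    stop("filter_thresholds must name QD, MQ, FS and QUAL")
  }
  if (any(unlist(filter_thresholds[needed]) < 0)) {
    stop("filter thresholds must be non-negative")
  }
  structure(list(
    restart_probability = restart_probability,
    top_fraction = top_fraction,
    string_score_threshold = string_score_threshold,
    n_randomizations = as.integer(n_randomizations),
    bonferroni_alpha = bonferroni_alpha,
    filter_thresholds = filter_thresholds[needed],
    rng_seed = as.integer(rng_seed),
    weighted_adjacency = isTRUE(weighted_adjacency),
    threshold_before_rwr = isTRUE(threshold_before_rwr),
    resolve = resolve
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file keep their [run_config()] defaults.
#'
#' @param path YAML file whose top-level keys match [run_config()] arguments.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  cat(sprintf("  restart_probability: %g, top_fraction: %g\n",
              x$restart_probability, x$top_fraction))
  cat(sprintf("  score threshold: %g, randomizations: %d, alpha: %g\n",
              x$string_score_threshold, x$n_randomizations, x$bonferroni_alpha))
  cat(sprintf("  hard filter: QD<%g MQ<%g FS>%g QUAL<%g\n",
              x$filter_thresholds$QD, x$filter_thresholds$MQ,
              x$filter_thresholds$FS, x$filter_thresholds$QUAL))
  invisible(x)
}
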