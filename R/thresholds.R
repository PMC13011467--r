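#' Numeric gates of the staged salt-stress analysis
#'
#' Bundles every threshold used by the pipeline. Defaults are the values
#' used throughout the original study design; any of them can be
#' overridden, e.g. to explore sensitivity.
#'
#' @param signal_floor MS signal units; a feature is dropped when its
#'   signal is below this floor in every non-blank sample (default 1e7).
#' @param pseudocount MS signal units added to every signal before
#'   log-transformation and fold-change computation (default 1e4).
#' @param prefilter_fold minimum max/min ratio of the six
#'   condition-by-time group means for a feature to enter ANOVA
#'   (default 10).
#' @param fdr_alpha Benjamini-Hochberg adjusted-P cutoff used for the
#'   one-way ANOVA stage and the two-way interaction term (default 0.05).
#' @param interaction_fold minimum max/min ratio of the six group means
#'   for a feature to be called differential after the interaction test
#'   (default 100).
#' @param blank_ratio a feature must be at least this many times more
#'   abundant in some non-blank sample than in the strongest blank
#'   (default 3).
#' @param rt_min,rt_max retention-time window in minutes, inclusive
#'   (defaults 0.5 and 8).
#' @param cluster_window nt; TSS positions within this distance are
#'   chained into one cluster (default 5).
#' @param upstream_window nt; a TSS at most this far 5' of a same-strand
#'   gene start is classified upstream (default 400).
#' @param de_fold fold-change span across conditions required to call a
#'   gene differentially expressed, and the max-of-max fold for
#'   salt-responsiveness (default 5).
#' @param de_alpha adjusted-P cutoff below which a log2 fold change is
#'   considered significant (default 0.05).
#' @param enrichment_fdr adjusted-P cutoff used when flagging enriched
#'   categories (default 0.1).
#'
#' @return A list of class `salt_thresholds`.
#' @export
#' @examples
#' th <- salt_thresholds()
#' th$interaction_fold
salt_thresholds <- function(signal_floor = 1e7,
                            pseudocount = 1e4,
                            prefilter_fold = 10,
                            fdr_alpha = 0.05,
                            interaction_fold = 100,
                            blank_ratio = 3,
                            rt_min = 0.5,
                            rt_max = 8,
                            cluster_window = 5,
                            upstream_window = 400,
                            de_fold = 5,
                            de_alpha = 0.05,
                            enrichment_fdr = 0.1) {
  th <- list(
    signal_floor = signal_floor, pseudocount = pseudocount,
    prefilter_fold = prefilter_fold, fdr_alpha = fdr_alpha,
    interaction_fold = interaction_fold, blank_ratio = blank_ratio,
    rt_min = rt_min, rt_max = rt_max,
    cluster_window = cluster_window, upstream_window = upstream_window,
    de_fold = de_fold, de_alpha = de_alpha,
    enrichment_fdr = enrichment_fdr
  )
  bad <- vapply(th, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad)) {
    stop_saltomics(
      paste0("thresholds must be positive finite scalars; offending: ",
             paste(names(th)[bad], collapse = ", ")),
      "saltomics_config_error"
    )
  }
  if (th$rt_min >= th$rt_max) {
    stop_saltomics("rt_min must be smaller than rt_max",
                   "saltomics_config_error")
  }
  if (!(th$fdr_alpha < 1 && th$de_alpha < 1 && th$enrichment_fdr <= 1)) {
    stop_saltomics("alpha levels must lie in (0, 1)",
                   "saltomics_config_error")
  }
  structure(th, class = "salt_thresholds")
}

#' Read thresholds from a YAML file
#'
#' Keys absent from the file keep their defaults; unknown keys are
#' rejected so typos in a config cannot silently revert a gate to its
#' default.
#'
#' @param path YAML file with a flat mapping of threshold names to
#'   numbers (any subset of the arguments of [salt_thresholds()]).
#' @return A `salt_thresholds` list.
#' @export
thresholds_from_yaml <- function(path) {
  if (!file.exists(path)) {
    stop_saltomics(paste0("threshold file not found: ", path),
                   "saltomics_config_error")
  }
  vals <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop_saltomics(
      paste0("invalid YAML thresholds: ", conditionMessage(e)),
      "saltomics_config_error"
    )
  )
  if (is.null(vals)) vals <- list()
  known <- names(formals(salt_thresholds))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_saltomics(
      paste0("unknown threshold keys in ", path, ": ",
             paste(unknown, collapse = ", ")),
      "saltomics_config_error"
    )
  }
  do.call(salt_thresholds, vals)
}

#' @export
print.salt_thresholds <- function(x, ...) {
  cat("salt-stress pipeline thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}
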