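#' Configuration for the synthetic multi-omics generator
#'
#' Describes one simulated experiment mirroring the study design:
#' 2 salinity conditions x 3 time points x 3 biological replicates for
#' LC-MS and expression tables, and 4 growth conditions (2 time points
#' under 2 salinity conditions) x 3 replicates for Cappable-seq TSS
#' reads, all on one linear chromosome.
#'
#' @param seed integer seed; all randomness is derived deterministically
#'   from it, so identical configs give byte-identical outputs.
#' @param n_features number of LC-MS features to simulate.
#' @param n_planted_diff number of features carrying a planted
#'   condition-by-time interaction effect.
#' @param baseline_log10_mean mean of the per-feature baseline on the
#'   log10 signal scale.
#' @param baseline_log10_sd between-feature spread of the baseline on
#'   the log10 scale.
#' @param replicate_cv coefficient of variation of replicate signals
#'   around their group mean (log-normal noise).
#' @param planted_interaction_fold multiplicative effect applied to one
#'   (salinity, time) cell of each planted feature; the default 200
#'   clears both the 10x prefilter and the 100x interaction gate.
#' @param n_blanks number of medium-blank samples (>= 2).
#' @param n_genes number of non-overlapping genes on the chromosome.
#' @param chromosome_length length of the linear chromosome in nt.
#' @param n_true_tss number of true transcription start sites.
#' @param tss_mean_count mean fragment count per true TSS per replicate
#'   (Poisson).
#' @param tss_jitter_sd standard deviation, in nt, of the normal jitter
#'   applied to each fragment 5' end around its TSS.
#' @param background_end_rate background 5' ends per nt per strand per
#'   library (uniform noise floor).
#' @param fragment_length simulated fragment length in nt.
#' @param n_planted_de number of genes planted as differentially
#'   expressed in the synthetic expression table.
#' @param n_planted_salt_up,n_planted_salt_down of the planted DE genes,
#'   how many are made salt-induced / salt-repressed (their sum must not
#'   exceed `n_planted_de`).
#' @param n_replicates biological replicates per condition (fixed at 3
#'   in the emulated design; configurable for degenerate tests).
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_features = 100, n_planted_diff = 10)
#' cfg$n_features
sim_config <- function(seed = 1L,
                       n_features = 2000L,
                       n_planted_diff = 50L,
                       baseline_log10_mean = 7.5,
                       baseline_log10_sd = 0.4,
                       replicate_cv = 0.2,
                       planted_interaction_fold = 200,
                       n_blanks = 3L,
                       n_genes = 200L,
                       chromosome_length = 1e6,
                       n_true_tss = 300L,
                       tss_mean_count = 50,
                       tss_jitter_sd = 1,
                       background_end_rate = 1e-4,
                       fragment_length = 150L,
                       n_planted_de = 60L,
                       n_planted_salt_up = 20L,
                       n_planted_salt_down = 5L,
                       n_replicates = 3L) {
  cfg <- list(
    seed = as.integer(seed),
    n_features = as.integer(n_features),
    n_planted_diff = as.integer(n_planted_diff),
    baseline_log10_mean = baseline_log10_mean,
    baseline_log10_sd = baseline_log10_sd,
    replicate_cv = replicate_cv,
    planted_interaction_fold = planted_interaction_fold,
    n_blanks = as.integer(n_blanks),
    n_genes = as.integer(n_genes),
    chromosome_length = as.numeric(chromosome_length),
    n_true_tss = as.integer(n_true_tss),
    tss_mean_count = tss_mean_count,
    tss_jitter_sd = tss_jitter_sd,
    background_end_rate = background_end_rate,
    fragment_length = as.integer(fragment_length),
    n_planted_de = as.integer(n_planted_de),
    n_planted_salt_up = as.integer(n_planted_salt_up),
    n_planted_salt_down = as.integer(n_planted_salt_down),
    n_replicates = as.integer(n_replicates)
  )
  positive <- c("n_features", "baseline_log10_mean", "baseline_log10_sd",
                "replicate_cv", "planted_interaction_fold",
                "chromosome_length", "tss_mean_count", "fragment_length",
                "n_replicates")
  nonneg <- c("n_planted_diff", "n_genes", "n_true_tss", "tss_jitter_sd",
              "background_end_rate", "n_planted_de", "n_planted_salt_up",
              "n_planted_salt_down")
  for (nm in c(positive, nonneg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || !is.finite(v)) {
      stop_saltomics(paste0("invalid sim_config field: ", nm),
                     "saltomics_config_error")
    }
  }
  if (any(vapply(cfg[positive], function(v) v <= 0, logical(1)))) {
    stop_saltomics("sim_config dimensions and rates must be positive",
                   "saltomics_config_error")
  }
  if (any(vapply(cfg[nonneg], function(v) v < 0, logical(1)))) {
    stop_saltomics("sim_config counts must be non-negative",
                   "saltomics_config_error")
  }
  if (cfg$n_blanks < 2L) {
    stop_saltomics("at least 2 blank samples are required",
                   "saltomics_config_error")
  }
  if (cfg$n_planted_diff > cfg$n_features) {
    stop_saltomics("n_planted_diff cannot exceed n_features",
                   "saltomics_config_error")
  }
  if (cfg$n_planted_de > cfg$n_genes ||
      cfg$n_planted_salt_up + cfg$n_planted_salt_down > cfg$n_planted_de) {
    stop_saltomics(
      "planted DE gene counts inconsistent: need salt_up + salt_down <= n_planted_de <= n_genes",
      "saltomics_config_error"
    )
  }
  if (cfg$n_genes > 0 && cfg$chromosome_length / cfg$n_genes < 100) {
    stop_saltomics(
      "n_genes too large for chromosome_length (need >= 100 nt per gene slot)",
      "saltomics_config_error"
    )
  }
  structure(cfg, class = "sim_config")
}

# Deterministic sub-seed per dataset so generating one data type never
# perturbs the draws of another. Kept below 2^31 - 1.
sub_seed <- function(cfg, offset) {
  as.integer((abs(as.numeric(cfg$seed)) * 31L + offset) %% 2147483647)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("synthetic salt-stress study configuration\n")
  cat(sprintf("  seed %d | %d LC-MS features (%d planted, fold %g, CV %g)\n",
              x$seed, x$n_features, x$n_planted_diff,
              x$planted_interaction_fold, x$replicate_cv))
  cat(sprintf("  chromosome %g nt | %d genes | %d true TSSs\n",
              x$chromosome_length, x$n_genes, x$n_true_tss))
  cat(sprintf("  %d genes in expression table (%d DE, %d salt-up, %d salt-down)\n",
              x$n_genes, x$n_planted_de, x$n_planted_salt_up,
              x$n_planted_salt_down))
  invisible(x)
}
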