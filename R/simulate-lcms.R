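#' Simulate an untargeted LC-MS feature table with planted effects
#'
#' Emulates the study's metabolomics design: 2 salinity conditions
#' (`salt`, `no_salt`) x 3 time points (0.5, 48, 96 h) x 3 biological
#' replicates, plus medium blanks. Signals are log-normal: each feature
#' draws a baseline on the log10 scale, every group shares that baseline
#' except that planted features have one randomly chosen
#' (salinity, time) cell multiplied by `planted_interaction_fold`.
#' Replicate noise is log-normal with coefficient of variation
#' `replicate_cv`; blanks sit at one tenth of the feature baseline so
#' that ordinary features clear the 3x blank filter.
#'
#' @param cfg a [sim_config()].
#' @return list with `table` (a [feature_table()]) and `truth` (list
#'   with `differential_feature_ids` and `planted_cells`, a data.frame
#'   naming the perturbed (condition, time) cell per planted feature).
#' @export
#' @examples
#' sim <- simulate_lcms(sim_config(seed = 1, n_features = 50,
#'                                 n_planted_diff = 5))
#' dim(sim$table)
simulate_lcms <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(sub_seed(cfg, 1L), {
    conditions <- c("no_salt", "salt")
    times <- c(0.5, 48, 96)
    reps <- seq_len(cfg$n_replicates)

    design <- expand.grid(replicate = reps, time_h = times,
                          condition = conditions,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    design <- design[, c("condition", "time_h", "replicate")]
    design$sample_id <- sprintf("%s_t%g_r%d", design$condition,
                                design$time_h, design$replicate)
    design$is_blank <- FALSE
    blanks <- data.frame(
      condition = "blank", time_h = NA_real_,
      replicate = seq_len(cfg$n_blanks),
      sample_id = sprintf("blank_r%d", seq_len(cfg$n_blanks)),
      is_blank = TRUE
    )
    samples <- rbind(design, blanks)[, c("sample_id", "condition",
                                         "time_h", "replicate", "is_blank")]

    fid <- sprintf("F%05d", seq_len(cfg$n_features))
    features <- data.frame(
      feature_id = fid,
      mz = round(runif(cfg$n_features, 100, 1200), 4),
      rt = round(runif(cfg$n_features, 0.6, 7.9), 3),
      mode = sample(c("positive", "negative"), cfg$n_features,
                    replace = TRUE)
    )

    # per-feature baseline and planted interaction cell, on log10 scale
    base10 <- rnorm(cfg$n_features, cfg$baseline_log10_mean,
                    cfg$baseline_log10_sd)
    groups <- expand.grid(time_h = times, condition = conditions,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    mu10 <- matrix(base10, nrow = cfg$n_features, ncol = nrow(groups))

    planted_id <- sort(sample(cfg$n_features, cfg$n_planted_diff))
    planted_cell <- if (cfg$n_planted_diff > 0) {
      sample(nrow(groups), cfg$n_planted_diff, replace = TRUE)
    } else integer(0)
    for (j in seq_along(planted_id)) {
      mu10[planted_id[j], planted_cell[j]] <-
        mu10[planted_id[j], planted_cell[j]] +
        log10(cfg$planted_interaction_fold)
    }

    # log-normal replicate noise with the requested CV
    sd10 <- sqrt(log(1 + cfg$replicate_cv^2)) / log(10)
    signal <- matrix(0, cfg$n_features, nrow(samples),
                     dimnames = list(fid, samples$sample_id))
    for (i in seq_len(nrow(design))) {
      g <- which(groups$condition == design$condition[i] &
                   groups$time_h == design$time_h[i])
      signal[, design$sample_id[i]] <-
        10^(mu10[, g] + rnorm(cfg$n_features, 0, sd10))
    }
    for (b in blanks$sample_id) {
      signal[, b] <- 10^(base10 - 1 + rnorm(cfg$n_features, 0, sd10))
    }

    truth <- list(
      differential_feature_ids = fid[planted_id],
      planted_cells = data.frame(
        feature_id = fid[planted_id],
        condition = groups$condition[planted_cell],
        time_h = groups$time_h[planted_cell]
      )
    )
    list(table = feature_table(signal, features, samples), truth = truth)
  })
}
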