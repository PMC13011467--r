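#' Blank filter: drop features not above medium background
#'
#' A feature is retained only when its strongest non-blank signal is at
#' least `blank_ratio` (default 3) times its strongest blank signal.
#' Blank columns are kept in the returned table for audit.
#'
#' @param ft a [feature_table()] containing at least one blank sample.
#' @param thresholds a [salt_thresholds()].
#' @return filtered `feature_table`.
#' @export
filter_blank <- function(ft, thresholds = salt_thresholds()) {
  stopifnot(inherits(ft, "feature_table"))
  bl <- blank_ids(ft)
  if (length(bl) == 0L) {
    stop_saltomics("blank filtering requires at least one blank sample",
                   "saltomics_config_error")
  }
  max_nb <- row_max(ft$signal[, nonblank_ids(ft), drop = FALSE])
  max_bl <- row_max(ft$signal[, bl, drop = FALSE])
  subset_features(ft, max_nb >= thresholds$blank_ratio * max_bl)
}

#' Retention-time window filter
#'
#' Keeps features whose retention time lies inside the analytical
#' window, boundaries inclusive (default 0.5-8 min).
#'
#' @inheritParams filter_blank
#' @return filtered `feature_table`.
#' @export
filter_retention_time <- function(ft, thresholds = salt_thresholds()) {
  stopifnot(inherits(ft, "feature_table"))
  rt <- ft$features$rt
  if (anyNA(rt)) {
    stop_saltomics("retention time missing for some features",
                   "saltomics_input_error")
  }
  subset_features(ft, rt >= thresholds$rt_min & rt <= thresholds$rt_max)
}

#' Signal-floor filter
#'
#' Removes a feature only when its signal is below the floor (default
#' 1e7) in every non-blank sample; one sample at or above the floor
#' keeps the feature.
#'
#' @inheritParams filter_blank
#' @return filtered `feature_table`.
#' @export
filter_low_signal <- function(ft, thresholds = salt_thresholds()) {
  stopifnot(inherits(ft, "feature_table"))
  max_nb <- row_max(ft$signal[, nonblank_ids(ft), drop = FALSE])
  subset_features(ft, max_nb >= thresholds$signal_floor)
}

#' Add the pseudocount to every signal
#'
#' Increments all signals (blanks included) by `pseudocount` (default
#' 1e4) so that log-transformation and fold changes are defined for
#' zero signals. Guarded against double application.
#'
#' @inheritParams filter_blank
#' @return `feature_table` with incremented signals and the pseudocount
#'   recorded.
#' @export
add_pseudocount <- function(ft, thresholds = salt_thresholds()) {
  stopifnot(inherits(ft, "feature_table"))
  if (!is.na(ft$pseudocount)) {
    stop_saltomics("pseudocount already applied to this table",
                   "saltomics_state_error")
  }
  feature_table(ft$signal + thresholds$pseudocount, ft$features,
                ft$samples, pseudocount = thresholds$pseudocount)
}

#' Per-feature means over the condition-by-time groups
#'
#' Arithmetic mean of the replicate signals within each
#' (condition, time) cell of the non-blank design. Requires the
#' pseudocount to have been applied, so all means are strictly
#' positive and fold ratios are defined.
#'
#' @param ft a pseudocounted [feature_table()].
#' @return numeric matrix, features x groups; group columns are named
#'   `<condition>.<time_h>` in column-sorted order.
#' @export
group_means <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.na(ft$pseudocount)) {
    stop_saltomics("apply the pseudocount before computing group means",
                   "saltomics_state_error")
  }
  sm <- ft$samples[!ft$samples$is_blank, , drop = FALSE]
  key <- paste(sm$condition, sm$time_h, sep = ".")
  groups <- sort(unique(key))
  sizes <- table(key)
  if (length(unique(as.vector(sizes))) != 1L) {
    stop_saltomics("incomplete design: unequal replicate counts per group",
                   "saltomics_design_error")
  }
  out <- matrix(NA_real_, nrow(ft$signal), length(groups),
                dimnames = list(rownames(ft$signal), groups))
  for (g in groups) {
    out[, g] <- rowMeans(ft$signal[, sm$sample_id[key == g], drop = FALSE])
  }
  out
}

#' Fold-change prefilter over group means
#'
#' A feature passes when the ratio of its largest to smallest
#' (condition, time) group mean is at least `prefilter_fold` (default
#' 10), boundary inclusive.
#'
#' @param means group-mean matrix from [group_means()].
#' @param thresholds a [salt_thresholds()].
#' @return named logical vector, one element per feature.
#' @export
prefilter_fold_change <- function(means, thresholds = salt_thresholds()) {
  fold <- row_max(means) / row_min(means)
  stats::setNames(fold >= thresholds$prefilter_fold, rownames(means))
}

#' 100-fold interaction gate over group means
#'
#' After the interaction test, a feature is only called when its signal
#' spans at least `interaction_fold` (default 100) between the extreme
#' (condition, time) group means, boundary inclusive.
#'
#' @inheritParams prefilter_fold_change
#' @return named logical vector, one element per feature.
#' @export
interaction_fold_gate <- function(means, thresholds = salt_thresholds()) {
  fold <- row_max(means) / row_min(means)
  stats::setNames(fold >= thresholds$interaction_fold, rownames(means))
}

#' Staged differential calling of LC-MS features
#'
#' Runs the full workflow on a raw feature table, in order: blank
#' filter, retention-time window, signal floor, pseudocount, 10x
#' fold-change prefilter on group means, one-way ANOVA of log10 signals
#' over the 6 condition-by-time groups with BH control (q < alpha
#' retained), Brown-Forsythe variance check (reported, not filtered
#' on), balanced two-way ANOVA with BH control on the interaction term
#' (q_int < alpha retained), and the 100x interaction fold gate. BH is
#' applied across the features entering each testing stage, separately
#' per ionization mode (positive and negative tables are independent
#' analyses sharing one call).
#'
#' @param ft a raw [feature_table()] (no pseudocount yet).
#' @param thresholds a [salt_thresholds()].
#' @return list with
#'   `results` — data.frame, one row per input feature: stage flags
#'   (`blank_pass`, `rt_pass`, `floor_pass`, `prefilter_pass`), one-way
#'   `F1`/`p1`/`q1`, `levene_w`/`levene_p`, two-way `p_sal`/`p_time`/
#'   `p_int` and `q_sal`/`q_time`/`q_int`, `max_fold` (extreme
#'   group-mean ratio) and `final_call`; flags are NA for features
#'   eliminated before the stage; and
#'   `audit` — data.frame (`stage`, `n_in`, `n_out`) with one row per
#'   stage in execution order.
#' @export
#' @examples
#' sim <- simulate_lcms(sim_config(seed = 1, n_features = 60,
#'                                 n_planted_diff = 6))
#' res <- call_differential_features(sim$table)
#' res$audit
call_differential_features <- function(ft, thresholds = salt_thresholds()) {
  stopifnot(inherits(ft, "feature_table"))
  if (!is.na(ft$pseudocount)) {
    stop_saltomics("expected a raw table; pseudocount already applied",
                   "saltomics_state_error")
  }
  fid <- ft$features$feature_id
  res <- data.frame(
    feature_id = fid, mode = ft$features$mode,
    blank_pass = NA, rt_pass = NA, floor_pass = NA, prefilter_pass = NA,
    F1 = NA_real_, p1 = NA_real_, q1 = NA_real_,
    levene_w = NA_real_, levene_p = NA_real_,
    p_sal = NA_real_, p_time = NA_real_, p_int = NA_real_,
    q_sal = NA_real_, q_time = NA_real_, q_int = NA_real_,
    max_fold = NA_real_, final_call = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(res) <- fid
  audit <- data.frame(stage = character(0), n_in = integer(0),
                      n_out = integer(0))
  note <- function(stage, n_in, n_out) {
    audit[nrow(audit) + 1L, ] <<- list(stage, n_in, n_out)
    message(sprintf("[saltomics] %-18s %5d -> %5d features",
                    stage, n_in, n_out))
  }

  s1 <- filter_blank(ft, thresholds)
  res$blank_pass <- fid %in% s1$features$feature_id
  note("blank_filter", nrow(ft$signal), nrow(s1$signal))

  s2 <- filter_retention_time(s1, thresholds)
  res[s1$features$feature_id, "rt_pass"] <-
    s1$features$feature_id %in% s2$features$feature_id
  note("rt_window", nrow(s1$signal), nrow(s2$signal))

  s3 <- filter_low_signal(s2, thresholds)
  res[s2$features$feature_id, "floor_pass"] <-
    s2$features$feature_id %in% s3$features$feature_id
  note("signal_floor", nrow(s2$signal), nrow(s3$signal))

  s4 <- add_pseudocount(s3, thresholds)
  gm <- group_means(s4)
  res[rownames(gm), "max_fold"] <- row_max(gm) / row_min(gm)

  pre <- prefilter_fold_change(gm, thresholds)
  res[names(pre), "prefilter_pass"] <- pre
  s5 <- subset_features(s4, names(pre)[pre])
  note("prefilter_fold", nrow(s4$signal), nrow(s5$signal))

  sm <- s5$samples[!s5$samples$is_blank, , drop = FALSE]
  logsig <- log10(s5$signal[, sm$sample_id, drop = FALSE])
  grp <- paste(sm$condition, sm$time_h, sep = ".")

  ids5 <- s5$features$feature_id
  if (length(ids5)) {
    ow <- lapply(ids5, function(i) one_way_anova(logsig[i, ], grp))
    res[ids5, "F1"] <- vapply(ow, `[[`, numeric(1), "statistic")
    res[ids5, "p1"] <- vapply(ow, `[[`, numeric(1), "p.value")
    for (m in unique(s5$features$mode)) {
      im <- ids5[s5$features$mode == m]
      res[im, "q1"] <- bh_adjust(res[im, "p1"])
    }
  }
  keep1 <- ids5[!is.na(res[ids5, "q1"]) &
                  res[ids5, "q1"] < thresholds$fdr_alpha]
  s6 <- subset_features(s5, keep1)
  note("oneway_fdr", length(ids5), length(keep1))

  ids6 <- s6$features$feature_id
  if (length(ids6)) {
    lv <- lapply(ids6, function(i) levene_test(logsig[i, ], grp))
    res[ids6, "levene_w"] <- vapply(lv, `[[`, numeric(1), "statistic")
    res[ids6, "levene_p"] <- vapply(lv, `[[`, numeric(1), "p.value")

    tw <- lapply(ids6, function(i)
      two_way_anova(logsig[i, ], sm$condition, sm$time_h))
    res[ids6, "p_sal"] <- vapply(tw, `[[`, numeric(1), "p_sal")
    res[ids6, "p_time"] <- vapply(tw, `[[`, numeric(1), "p_time")
    res[ids6, "p_int"] <- vapply(tw, `[[`, numeric(1), "p_int")
    for (m in unique(s6$features$mode)) {
      im <- ids6[s6$features$mode == m]
      res[im, "q_sal"] <- bh_adjust(res[im, "p_sal"])
      res[im, "q_time"] <- bh_adjust(res[im, "p_time"])
      res[im, "q_int"] <- bh_adjust(res[im, "p_int"])
    }
  }
  keep2 <- ids6[!is.na(res[ids6, "q_int"]) &
                  res[ids6, "q_int"] < thresholds$fdr_alpha]
  note("interaction_fdr", length(ids6), length(keep2))

  gate <- interaction_fold_gate(gm[keep2, , drop = FALSE], thresholds)
  final <- keep2[gate]
  res[final, "final_call"] <- TRUE
  note("interaction_fold", length(keep2), length(final))

  rownames(res) <- NULL
  list(results = res, audit = audit)
}
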