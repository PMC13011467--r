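#' An LC-MS feature table with its sample design
#'
#' Container pairing a feature-by-sample signal matrix with feature
#' metadata (m/z, retention time, ionization mode) and the sample design
#' (salinity condition, time point, replicate, blank flag). All stage
#' filters of the metabolomics workflow consume and return this class.
#'
#' @param signal numeric matrix, features in rows, samples in columns;
#'   dimnames must carry feature and sample ids; all values finite and
#'   non-negative.
#' @param features data.frame with columns `feature_id`, `mz`, `rt`
#'   (minutes) and `mode` (`"positive"`/`"negative"`), one row per
#'   signal row.
#' @param samples data.frame with columns `sample_id`, `condition`,
#'   `time_h`, `replicate`, `is_blank`, one row per signal column.
#' @param pseudocount numeric or NA; the pseudocount already added to
#'   the signals (NA until [add_pseudocount()] is applied).
#'
#' @return An object of class `feature_table`: a list with elements
#'   `signal`, `features`, `samples`, `pseudocount`.
#' @export
feature_table <- function(signal, features, samples, pseudocount = NA_real_) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop_saltomics("signal must be a numeric matrix",
                   "saltomics_input_error")
  }
  need_f <- c("feature_id", "mz", "rt", "mode")
  need_s <- c("sample_id", "condition", "time_h", "replicate", "is_blank")
  if (!all(need_f %in% names(features))) {
    stop_saltomics(paste0("features must have columns: ",
                          paste(need_f, collapse = ", ")),
                   "saltomics_input_error")
  }
  if (!all(need_s %in% names(samples))) {
    stop_saltomics(paste0("samples must have columns: ",
                          paste(need_s, collapse = ", ")),
                   "saltomics_input_error")
  }
  if (nrow(features) != nrow(signal) || nrow(samples) != ncol(signal)) {
    stop_saltomics("signal dimensions do not match features/samples",
                   "saltomics_input_error")
  }
  if (anyDuplicated(features$feature_id) || anyDuplicated(samples$sample_id)) {
    stop_saltomics("feature_id and sample_id must be unique",
                   "saltomics_input_error")
  }
  if (anyNA(signal) || any(!is.finite(signal)) || any(signal < 0)) {
    stop_saltomics("signals must be finite and non-negative",
                   "saltomics_input_error")
  }
  rownames(signal) <- features$feature_id
  colnames(signal) <- samples$sample_id
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  rownames(features) <- NULL
  rownames(samples) <- NULL
  structure(
    list(signal = signal, features = features, samples = samples,
         pseudocount = pseudocount),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  nb <- sum(!x$samples$is_blank)
  cat(sprintf(
    "feature_table: %d features x %d samples (%d blank)%s\n",
    nrow(x$signal), ncol(x$signal), ncol(x$signal) - nb,
    if (is.na(x$pseudocount)) "" else
      sprintf(", pseudocount %g applied", x$pseudocount)
  ))
  cat(sprintf("  ionization modes: %s\n",
              paste(sort(unique(x$features$mode)), collapse = ", ")))
  cat(sprintf("  conditions: %s; times (h): %s\n",
              paste(sort(unique(x$samples$condition[!x$samples$is_blank])),
                    collapse = ", "),
              paste(sort(unique(x$samples$time_h[!x$samples$is_blank])),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$signal)

# Subset a feature table to a logical/character/integer feature index,
# keeping all samples. Internal: stage filters use this.
subset_features <- function(ft, idx) {
  if (is.logical(idx)) idx <- which(idx)
  if (is.character(idx)) idx <- match(idx, ft$features$feature_id)
  feature_table(
    ft$signal[idx, , drop = FALSE],
    ft$features[idx, , drop = FALSE],
    ft$samples,
    pseudocount = ft$pseudocount
  )
}

# Ids of non-blank / blank sample columns.
nonblank_ids <- function(ft) ft$samples$sample_id[!ft$samples$is_blank]
blank_ids <- function(ft) ft$samples$sample_id[ft$samples$is_blank]
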