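# Deterministic table writers: no quotes unless needed, no row names,
# so identical inputs give byte-identical files.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Write / read an LC-MS feature table as CSV
#'
#' Two files: a feature CSV with columns `feature_id`, `mz`, `rt`,
#' `mode` followed by one signal column per sample, and a sample
#' metadata CSV with columns `sample_id`, `condition`, `time_h`,
#' `replicate`, `is_blank`.
#'
#' @param ft a [feature_table()].
#' @param features_csv,samples_csv output/input paths.
#' @return `write_feature_table` returns the paths invisibly;
#'   `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(ft, features_csv, samples_csv) {
  stopifnot(inherits(ft, "feature_table"))
  df <- cbind(ft$features, as.data.frame(ft$signal, check.names = FALSE))
  write.table(df, features_csv, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  write.table(ft$samples, samples_csv, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(c(features_csv, samples_csv))
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(features_csv, samples_csv) {
  fdf <- read.table(features_csv, sep = ",", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
  samples <- read.table(samples_csv, sep = ",", header = TRUE,
                        stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("feature_id", "mz", "rt", "mode")
  if (!all(meta %in% names(fdf))) {
    stop_saltomics("feature CSV must start with feature_id, mz, rt, mode",
                   "saltomics_input_error")
  }
  sig_cols <- setdiff(names(fdf), meta)
  if (!setequal(sig_cols, samples$sample_id)) {
    stop_saltomics("signal columns do not match sample metadata",
                   "saltomics_input_error")
  }
  signal <- as.matrix(fdf[, samples$sample_id, drop = FALSE])
  samples$is_blank <- as.logical(samples$is_blank)
  feature_table(signal, fdf[, meta], samples)
}

#' Write / read gene models as GFF3
#'
#' Genes are written as `gene` features with their `gene_id` as the
#' GFF3 `ID` attribute; coordinates are 1-based inclusive.
#'
#' @param genes data.frame `gene_id`, `chrom` (optional), `start`,
#'   `end`, `strand`.
#' @param path GFF3 file path.
#' @return `write_gene_models` returns the path invisibly;
#'   `read_gene_models` returns the gene data.frame sorted by start.
#' @export
write_gene_models <- function(genes, path) {
  chrom <- genes$chrom %||% rep("chr", nrow(genes))
  gr <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "saltomics"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$Name <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% "gene"]
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
  df <- data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write / read Cappable-seq fragments as per-library BED6 files
#'
#' One BED6 file per (condition, replicate) library plus a manifest TSV
#' (`file`, `condition`, `replicate`). BED is 0-based half-open on
#' disk; fragments are 1-based inclusive in memory (the conversion
#' happens at this boundary). Each fragment is one record with score 1
#' and a sequential read id as name.
#'
#' @param fragments data.frame `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `condition`, `replicate`.
#' @param dir output directory (created if missing).
#' @param manifest manifest TSV path; default `manifest.tsv` in `dir`.
#' @return `write_fragment_beds` returns the manifest path invisibly;
#'   `read_fragment_beds` returns the fragments data.frame.
#' @export
write_fragment_beds <- function(fragments, dir,
                                manifest = file.path(dir, "manifest.tsv")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  combos <- unique(fragments[, c("condition", "replicate")])
  combos <- combos[order(combos$condition, combos$replicate), ,
                   drop = FALSE]
  man <- data.frame(file = character(0), condition = character(0),
                    replicate = integer(0))
  for (i in seq_len(nrow(combos))) {
    cn <- combos$condition[i]
    r <- combos$replicate[i]
    fr <- fragments[fragments$condition == cn & fragments$replicate == r, ,
                    drop = FALSE]
    gr <- GenomicRanges::GRanges(
      fr$chrom, IRanges::IRanges(fr$start, fr$end), strand = fr$strand
    )
    S4Vectors::mcols(gr)$name <- sprintf("read_%06d", seq_len(nrow(fr)))
    S4Vectors::mcols(gr)$score <- rep(1L, nrow(fr))
    fn <- sprintf("%s_rep%d.bed", cn, r)
    rtracklayer::export(gr, file.path(dir, fn), format = "BED")
    man[nrow(man) + 1L, ] <- list(fn, cn, as.integer(r))
  }
  write_tsv(man, manifest)
  invisible(manifest)
}

#' @rdname write_fragment_beds
#' @export
read_fragment_beds <- function(manifest, dir = dirname(manifest)) {
  man <- read_tsv(manifest)
  if (!all(c("file", "condition", "replicate") %in% names(man))) {
    stop_saltomics("manifest needs file, condition, replicate columns",
                   "saltomics_input_error")
  }
  parts <- lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(dir, man$file[i])
    if (!file.exists(path)) {
      stop_saltomics(paste0("fragment BED not found: ", path),
                     "saltomics_input_error")
    }
    gr <- rtracklayer::import(path, format = "BED")
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      condition = man$condition[i],
      replicate = as.integer(man$replicate[i])
    )
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write / read a gene expression table as TSV
#'
#' Schema: `gene_id` followed by paired `<cond>_lfc` / `<cond>_padj`
#' columns, one pair per condition.
#'
#' @param expr expression data.frame.
#' @param path TSV path.
#' @export
write_expression_table <- function(expr, path) {
  expr_conditions(expr)  # validates the schema
  write_tsv(expr, path)
}

#' @rdname write_expression_table
#' @export
read_expression_table <- function(path) {
  expr <- read_tsv(path)
  expr_conditions(expr)
  expr
}

#' Structural validation of pipeline input files
#'
#' Reports (instead of failing on) structural problems: BED intervals
#' with start >= end or negative start, GFF3 genes with end < start,
#' and missing schema columns in feature / sample / expression tables.
#'
#' @param paths named list with any of `bed`, `gff3`, `features_csv`,
#'   `samples_csv`, `expression_tsv` (each a path or vector of paths).
#' @return data.frame `file`, `check`, `ok`, `message`.
#' @export
validate_formats <- function(paths) {
  rep_df <- data.frame(file = character(0), check = character(0),
                       ok = logical(0), message = character(0))
  note <- function(file, check, ok, message = "") {
    rep_df[nrow(rep_df) + 1L, ] <<- list(file, check, ok, message)
  }
  for (p in paths$bed %||% character(0)) {
    raw <- tryCatch(
      read.table(p, sep = "\t", stringsAsFactors = FALSE),
      error = function(e) NULL
    )
    if (is.null(raw)) { note(p, "bed_readable", FALSE, "unreadable"); next }
    bad <- raw[[2]] >= raw[[3]] | raw[[2]] < 0
    note(p, "bed_half_open", !any(bad),
         if (any(bad)) sprintf("%d records with start >= end or start < 0",
                               sum(bad)) else "")
  }
  for (p in paths$gff3 %||% character(0)) {
    g <- tryCatch(read_gene_models(p), error = function(e) NULL)
    if (is.null(g)) { note(p, "gff3_readable", FALSE, "unreadable"); next }
    bad <- g$end < g$start | g$start < 1
    note(p, "gff3_coordinates", !any(bad),
         if (any(bad)) sprintf("%d genes with invalid coordinates",
                               sum(bad)) else "")
  }
  if (!is.null(paths$features_csv) && !is.null(paths$samples_csv)) {
    ok <- tryCatch({
      read_feature_table(paths$features_csv, paths$samples_csv)
      TRUE
    }, error = function(e) FALSE)
    note(paths$features_csv, "feature_table_schema", ok,
         if (ok) "" else "schema mismatch")
  }
  for (p in paths$expression_tsv %||% character(0)) {
    ok <- tryCatch({ read_expression_table(p); TRUE },
                   error = function(e) FALSE)
    note(p, "expression_schema", ok, if (ok) "" else "schema mismatch")
  }
  rep_df
}
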