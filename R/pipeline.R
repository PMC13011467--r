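# Run manifest written next to every driver's outputs: the exact
# parameters and input checksums needed to reproduce the run. No
# timestamps, so reruns are byte-identical.
write_run_manifest <- function(outdir, step, params, inputs = character(0)) {
  manifest <- list(
    tool = "saltomics",
    version = as.character(packageVersion("saltomics")),
    step = step,
    parameters = params
  )
  if (length(inputs)) {
    sums <- tools::md5sum(inputs)
    manifest$inputs <- as.list(stats::setNames(unname(sums),
                                               basename(names(sums))))
  }
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Generate a full synthetic dataset on disk
#'
#' Writes every input the pipeline consumes: the LC-MS feature and
#' sample CSVs, gene models (GFF3), per-library fragment BEDs with a
#' manifest, the expression and annotation TSVs, and the ground-truth
#' tables (`truth_*.tsv`) for each component.
#'
#' @param cfg a [sim_config()], or a YAML file of `sim_config`
#'   arguments.
#' @param outdir output directory (created if missing).
#' @return invisibly, the list from [simulate_dataset()].
#' @export
run_simulate <- function(cfg = sim_config(), outdir) {
  if (is.character(cfg)) {
    vals <- tryCatch(
      yaml::read_yaml(cfg),
      error = function(e) stop_saltomics(
        paste0("invalid YAML config: ", conditionMessage(e)),
        "saltomics_config_error"
      )
    ) %||% list()
    unknown <- setdiff(names(vals), names(formals(sim_config)))
    if (length(unknown)) {
      stop_saltomics(paste0("unknown sim_config keys: ",
                            paste(unknown, collapse = ", ")),
                     "saltomics_config_error")
    }
    cfg <- do.call(sim_config, vals)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(cfg)

  write_feature_table(sim$lcms$table,
                      file.path(outdir, "features.csv"),
                      file.path(outdir, "samples.csv"))
  write_tsv(data.frame(feature_id = sim$lcms$truth$differential_feature_ids),
            file.path(outdir, "truth_features.tsv"))
  write_tsv(sim$lcms$truth$planted_cells,
            file.path(outdir, "truth_planted_cells.tsv"))

  write_gene_models(sim$annotation, file.path(outdir, "genes.gff3"))
  write_fragment_beds(sim$tss$fragments, file.path(outdir, "fragments"))
  write_tsv(sim$tss$truth, file.path(outdir, "truth_tss.tsv"))

  write_expression_table(sim$expression$expression,
                         file.path(outdir, "expression.tsv"))
  write_tsv(sim$expression$annotation,
            file.path(outdir, "gene_annotation.tsv"))
  tr <- sim$expression$truth
  write_tsv(data.frame(
    gene_id = c(tr$de_gene_ids),
    salt_class = ifelse(tr$de_gene_ids %in% tr$salt_up_gene_ids, "salt_up",
                        ifelse(tr$de_gene_ids %in% tr$salt_down_gene_ids,
                               "salt_down", "neither"))
  ), file.path(outdir, "truth_de_genes.tsv"))

  write_run_manifest(outdir, "simulate", unclass(cfg))
  invisible(sim)
}

#' Run the LC-MS differential-feature workflow on files
#'
#' @param features_csv,samples_csv feature table inputs (schema of
#'   [write_feature_table()]).
#' @param outdir output directory; writes `diff_results.tsv` (one row
#'   per feature with all stage flags and statistics) and `audit.tsv`
#'   (per-stage feature counts).
#' @param thresholds a [salt_thresholds()] or a YAML file for
#'   [thresholds_from_yaml()].
#' @return invisibly, the list from [call_differential_features()].
#' @export
run_metabolomics <- function(features_csv, samples_csv, outdir,
                             thresholds = salt_thresholds()) {
  if (is.character(thresholds)) thresholds <- thresholds_from_yaml(thresholds)
  ft <- read_feature_table(features_csv, samples_csv)
  res <- call_differential_features(ft, thresholds)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(res$results, file.path(outdir, "diff_results.tsv"))
  write_tsv(res$audit, file.path(outdir, "audit.tsv"))
  write_run_manifest(outdir, "metabolomics", unclass(thresholds),
                     c(features_csv, samples_csv))
  invisible(res)
}

#' Run the TSS calling pipeline on files
#'
#' @param manifest fragment-BED manifest TSV from
#'   [write_fragment_beds()].
#' @param genes_gff3 gene models (GFF3).
#' @param outdir output directory; writes `tss_unique.bed` (unique
#'   catalogue, score = total count), `tss_detail.tsv` (classification,
#'   assigned gene, distance, condition set) and `upset_tally.tsv`.
#' @param window,upstream_window clustering / upstream windows in nt.
#' @return invisibly, the list from [call_tss()].
#' @export
run_tss <- function(manifest, genes_gff3, outdir, window = 5,
                    upstream_window = 400) {
  fragments <- read_fragment_beds(manifest)
  genes <- read_gene_models(genes_gff3)
  res <- call_tss(fragments, genes, window, upstream_window)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  tss <- res$tss
  gr <- GenomicRanges::GRanges(
    tss$chrom %||% rep("chr", nrow(tss)),
    IRanges::IRanges(tss$representative, tss$representative),
    strand = tss$strand
  )
  S4Vectors::mcols(gr)$name <- sprintf("TSS_%05d", seq_len(nrow(tss)))
  S4Vectors::mcols(gr)$score <- tss$total_count
  rtracklayer::export(gr, file.path(outdir, "tss_unique.bed"),
                      format = "BED")
  detail <- cbind(tss_id = sprintf("TSS_%05d", seq_len(nrow(tss))), tss)
  write_tsv(detail, file.path(outdir, "tss_detail.tsv"))
  write_tsv(res$tally, file.path(outdir, "upset_tally.tsv"))
  write_run_manifest(outdir, "tss",
                     list(window = window,
                          upstream_window = upstream_window),
                     c(manifest, genes_gff3))
  invisible(res)
}

#' Run the DE / salt-responsiveness / enrichment rules on files
#'
#' @param expression_tsv expression table (schema of
#'   [write_expression_table()]).
#' @param annotation_tsv gene annotation TSV (`gene_id`, `category`,
#'   `conservation`).
#' @param outdir output directory; writes `de_calls.tsv`,
#'   `enrichment.tsv` and `conservation_bins.tsv` (bins for all genes,
#'   the DE set, and each salt class).
#' @param fold,alpha thresholds of the DE rules.
#' @return invisibly, a list with `calls`, `enrichment`, `bins`.
#' @export
run_de <- function(expression_tsv, annotation_tsv, outdir, fold = 5,
                   alpha = 0.05) {
  expr <- read_expression_table(expression_tsv)
  annot <- read_tsv(annotation_tsv)
  calls <- classify_genes(expr, fold = fold, alpha = alpha)
  de_genes <- calls$gene_id[calls$is_de]
  enr <- enrichment_test(de_genes, annot)

  subsets <- list(
    all = annot$gene_id,
    de = de_genes,
    salt_up = calls$gene_id[!is.na(calls$salt_class) &
                              calls$salt_class == "salt_up"],
    salt_down = calls$gene_id[!is.na(calls$salt_class) &
                                calls$salt_class == "salt_down"]
  )
  cons <- stats::setNames(annot$conservation, annot$gene_id)
  bins <- do.call(rbind, lapply(names(subsets), function(nm) {
    b <- bin_conservation(unname(cons[subsets[[nm]]]))
    cbind(subset = nm, b)
  }))

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(calls, file.path(outdir, "de_calls.tsv"))
  write_tsv(enr, file.path(outdir, "enrichment.tsv"))
  write_tsv(bins, file.path(outdir, "conservation_bins.tsv"))
  write_run_manifest(outdir, "de", list(fold = fold, alpha = alpha),
                     c(expression_tsv, annotation_tsv))
  invisible(list(calls = calls, enrichment = enr, bins = bins))
}
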