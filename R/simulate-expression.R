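#' Simulate a gene-level log2 fold-change table with planted DE genes
#'
#' Emulates the transcriptomics output consumed by the DE classifier:
#' per gene, a log2 fold change versus the preculture reference and a
#' BH-adjusted P value for each of 6 conditions (2 salinity x 3 time
#' points; the reference itself is implicit at lfc 0). Null genes have
#' adjusted P >= 0.05 everywhere, so the zeroing rule wipes their fold
#' changes. Planted DE genes carry one significant cell with
#' |log2FC| >= log2(5); planted salt-up (salt-down) genes carry it in a
#' salt (no-salt) column with all opposite-salinity cells left
#' non-significant, so the max-of-max rule classifies them by
#' construction. The remaining planted DE genes get the same significant
#' fold change in one salt and one no-salt column, making them DE but
#' not salt-responsive.
#'
#' A category/conservation annotation table is generated alongside:
#' each gene gets one functional category (DE genes biased towards an
#' ion-transport category so enrichment is detectable) and an ortholog
#' conservation fraction in \[0, 1\] (DE genes drawn less conserved, as
#' observed for salt-responsive genes).
#'
#' @param cfg a [sim_config()].
#' @return list with `expression` (data.frame `gene_id` plus
#'   `<cond>_lfc`/`<cond>_padj` pairs), `annotation` (data.frame
#'   `gene_id`, `category`, `conservation`) and `truth` (list with
#'   `de_gene_ids`, `salt_up_gene_ids`, `salt_down_gene_ids`).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  conds <- c("salt_t1", "salt_t2", "salt_t3",
             "no_salt_t1", "no_salt_t2", "no_salt_t3")
  salt_cols <- conds[1:3]
  no_salt_cols <- conds[4:6]
  withr::with_seed(sub_seed(cfg, 4L), {
    n <- cfg$n_genes
    gid <- sprintf("gene_%04d", seq_len(n))

    lfc <- matrix(rnorm(n * 6, 0, 0.5), n, 6, dimnames = list(gid, conds))
    padj <- matrix(runif(n * 6, 0.05, 1), n, 6, dimnames = list(gid, conds))

    planted <- sample(n, cfg$n_planted_de)
    up <- planted[seq_len(cfg$n_planted_salt_up)]
    down <- planted[cfg$n_planted_salt_up +
                      seq_len(cfg$n_planted_salt_down)]
    other <- setdiff(planted, c(up, down))

    sig_p <- function(k) runif(k, 1e-8, 0.04)
    eff <- function(k) runif(k, 2.5, 6)

    for (g in up) {
      j <- sample(salt_cols, 1L)
      lfc[g, j] <- eff(1L)
      padj[g, j] <- sig_p(1L)
    }
    for (g in down) {
      j <- sample(no_salt_cols, 1L)
      lfc[g, j] <- eff(1L)
      padj[g, j] <- sig_p(1L)
    }
    for (g in other) {
      e <- eff(1L) * sample(c(-1, 1), 1L)
      js <- sample(salt_cols, 1L)
      jn <- sample(no_salt_cols, 1L)
      lfc[g, c(js, jn)] <- e
      padj[g, c(js, jn)] <- sig_p(2L)
    }

    expression <- data.frame(gene_id = gid)
    for (cn in conds) {
      expression[[paste0(cn, "_lfc")]] <- round(lfc[, cn], 6)
      expression[[paste0(cn, "_padj")]] <- signif(padj[, cn], 6)
    }

    categories <- c(
      "Energy production and conversion", "Defense mechanisms",
      "Inorganic ion transport and metabolism",
      "Secondary metabolite biosynthesis", "Cell wall biogenesis",
      "Transcription", "Translation", "Amino acid metabolism"
    )
    category <- sample(categories, n, replace = TRUE)
    de_bias <- planted[runif(length(planted)) < 0.5]
    category[de_bias] <- "Inorganic ion transport and metabolism"
    conservation <- stats::rbeta(n, 5, 2)
    conservation[planted] <- stats::rbeta(length(planted), 2, 2)
    annotation <- data.frame(gene_id = gid, category = category,
                             conservation = round(conservation, 6))

    list(
      expression = expression,
      annotation = annotation,
      truth = list(
        de_gene_ids = sort(gid[planted]),
        salt_up_gene_ids = sort(gid[up]),
        salt_down_gene_ids = sort(gid[down])
      )
    )
  })
}

#' Simulate every input of the pipeline at once
#'
#' Convenience wrapper calling [simulate_lcms()],
#' [simulate_annotation()], [simulate_tss_reads()] and
#' [simulate_expression()] with one configuration. Each component uses
#' its own deterministic sub-seed, so regenerating one piece never
#' changes another.
#'
#' @param cfg a [sim_config()].
#' @return list with `lcms`, `annotation`, `tss`, `expression`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 7, n_features = 50,
#'                                    n_planted_diff = 5, n_genes = 20,
#'                                    n_true_tss = 10))
#' names(sim)
simulate_dataset <- function(cfg = sim_config()) {
  annotation <- simulate_annotation(cfg)
  list(
    lcms = simulate_lcms(cfg),
    annotation = annotation,
    tss = simulate_tss_reads(cfg, annotation),
    expression = simulate_expression(cfg)
  )
}
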