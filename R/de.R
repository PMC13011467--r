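# Condition names of an expression table: every column "<cond>_lfc"
# must have a matching "<cond>_padj".
expr_conditions <- function(expr) {
  conds <- sub("_lfc$", "", grep("_lfc$", names(expr), value = TRUE))
  missing_p <- setdiff(paste0(conds, "_padj"), names(expr))
  if (!length(conds) || length(missing_p)) {
    stop_saltomics(
      "expression table needs paired <cond>_lfc / <cond>_padj columns",
      "saltomics_input_error"
    )
  }
  conds
}

lfc_matrix <- function(expr, conds = expr_conditions(expr)) {
  m <- as.matrix(expr[, paste0(conds, "_lfc"), drop = FALSE])
  dimnames(m) <- list(expr$gene_id, conds)
  m
}

padj_matrix <- function(expr, conds = expr_conditions(expr)) {
  m <- as.matrix(expr[, paste0(conds, "_padj"), drop = FALSE])
  dimnames(m) <- list(expr$gene_id, conds)
  m
}

#' Zero out non-significant log2 fold changes
#'
#' Sets a gene's log2 fold change to 0 in every condition where the
#' adjusted P value is greater than or equal to `alpha` (default 0.05;
#' boundary inclusive, so padj exactly 0.05 is zeroed). A missing
#' adjusted P — as produced by independent filtering in upstream DE
#' tools — is treated as non-significant and the fold change is zeroed.
#'
#' @param expr expression data.frame with `gene_id` and paired
#'   `<cond>_lfc`/`<cond>_padj` columns.
#' @param alpha significance cutoff on the adjusted P value.
#' @return the expression data.frame with zeroed `_lfc` columns
#'   (`_padj` columns untouched).
#' @export
zero_nonsignificant <- function(expr, alpha = 0.05) {
  conds <- expr_conditions(expr)
  for (cn in conds) {
    p <- expr[[paste0(cn, "_padj")]]
    if (any(p < 0 | p > 1, na.rm = TRUE)) {
      stop_saltomics("adjusted P values must lie in [0, 1]",
                     "saltomics_input_error")
    }
    zero <- is.na(p) | p >= alpha
    expr[[paste0(cn, "_lfc")]][zero] <- 0
  }
  expr
}

#' Call differentially expressed genes by fold-change span
#'
#' A gene is differentially expressed when the fold change between its
#' highest and lowest expression levels across the 7 conditions (the 6
#' table columns plus the reference, which contributes log2FC = 0) is
#' at least `fold` (default 5), i.e. max - min >= log2(fold) on the
#' zeroed log2 scale, boundary inclusive.
#'
#' @param zeroed expression data.frame after [zero_nonsignificant()].
#' @param fold fold-change threshold (linear scale).
#' @return named logical vector, one element per gene.
#' @export
call_differential_genes <- function(zeroed, fold = 5) {
  m <- lfc_matrix(zeroed)
  hi <- pmax(row_max(m), 0)
  lo <- pmin(row_min(m), 0)
  stats::setNames((hi - lo) >= log2(fold), zeroed$gene_id)
}

#' Classify DE genes as salt-induced or salt-repressed
#'
#' For each differentially expressed gene, the maximum zeroed log2 fold
#' change across the three salt-supplemented conditions (M+) is
#' compared to the maximum across the three no-salt conditions (M-):
#' `salt_up` when M+ - M- >= log2(fold), `salt_down` when
#' M- - M+ >= log2(fold), otherwise `neither`. Genes not called DE get
#' NA — salt-responsiveness is only evaluated within the DE set.
#'
#' @param zeroed expression data.frame after [zero_nonsignificant()];
#'   salt conditions are the columns whose name starts with `salt`,
#'   no-salt those starting with `no_salt`.
#' @param de_flags logical vector from [call_differential_genes()].
#' @param fold fold-change threshold (linear scale).
#' @return character vector (`salt_up`/`salt_down`/`neither`/NA), one
#'   element per gene.
#' @export
call_salinity_responsive <- function(zeroed, de_flags, fold = 5) {
  conds <- expr_conditions(zeroed)
  is_no_salt <- grepl("^no_salt", conds)
  is_salt <- grepl("^salt", conds)
  if (!any(is_salt) || !any(is_no_salt)) {
    stop_saltomics("need both salt_* and no_salt_* condition columns",
                   "saltomics_input_error")
  }
  m <- lfc_matrix(zeroed, conds)
  m_plus <- row_max(m[, is_salt, drop = FALSE])
  m_minus <- row_max(m[, is_no_salt, drop = FALSE])
  cls <- rep(NA_character_, nrow(zeroed))
  thr <- log2(fold)
  cls[de_flags] <- "neither"
  cls[de_flags & (m_plus - m_minus >= thr)] <- "salt_up"
  cls[de_flags & (m_minus - m_plus >= thr)] <- "salt_down"
  stats::setNames(cls, zeroed$gene_id)
}

#' Zeroing, DE calling and salt classification in one pass
#'
#' @param expr raw expression data.frame (`gene_id`,
#'   `<cond>_lfc`/`<cond>_padj` pairs).
#' @param fold fold-change threshold for both rules (default 5).
#' @param alpha adjusted-P cutoff for the zeroing rule (default 0.05).
#' @return data.frame with `gene_id`, the zeroed `_lfc` columns,
#'   `is_de` and `salt_class`.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(seed = 3, n_genes = 40,
#'                                       n_planted_de = 8,
#'                                       n_planted_salt_up = 3,
#'                                       n_planted_salt_down = 1))
#' calls <- classify_genes(sim$expression)
#' table(calls$salt_class, useNA = "ifany")
classify_genes <- function(expr, fold = 5, alpha = 0.05) {
  zeroed <- zero_nonsignificant(expr, alpha)
  de <- call_differential_genes(zeroed, fold)
  cls <- call_salinity_responsive(zeroed, de, fold)
  conds <- expr_conditions(zeroed)
  out <- zeroed[, c("gene_id", paste0(conds, "_lfc"))]
  out$is_de <- unname(de)
  out$salt_class <- unname(cls)
  out
}

#' Fisher's exact gene-set enrichment of a gene list
#'
#' For each functional category, a two-sided Fisher's exact test on the
#' 2x2 table (genes in the list and category, list outside category,
#' background in category outside the list, remainder), with BH
#' adjustment across categories. Fold enrichment is
#' (k/n) / (K/N): the category's share of the list over its share of
#' the background.
#'
#' @param gene_set character vector of gene ids (e.g. the DE genes);
#'   every id must appear in the background.
#' @param annotation data.frame with `gene_id` and `category` columns
#'   (a gene may appear under several categories).
#' @param background character vector of background gene ids; defaults
#'   to all genes in `annotation`.
#' @return data.frame `category`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `p`, `q`, sorted by `p`.
#' @export
enrichment_test <- function(gene_set, annotation,
                            background = unique(annotation$gene_id)) {
  if (!all(c("gene_id", "category") %in% names(annotation))) {
    stop_saltomics("annotation needs gene_id and category columns",
                   "saltomics_input_error")
  }
  gene_set <- unique(gene_set)
  background <- unique(background)
  if (!length(gene_set)) {
    warning("empty gene set: no enrichment computed")
    return(data.frame(category = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      fold_enrichment = numeric(0), p = numeric(0),
                      q = numeric(0)))
  }
  if (!all(gene_set %in% background)) {
    stop_saltomics("every gene in the set must be in the background",
                   "saltomics_input_error")
  }
  annotation <- annotation[annotation$gene_id %in% background, ,
                           drop = FALSE]
  n <- length(gene_set)
  N <- length(background)
  cats <- sort(unique(annotation$category))
  rows <- lapply(cats, function(ct) {
    members <- unique(annotation$gene_id[annotation$category == ct])
    K <- length(members)
    k <- sum(gene_set %in% members)
    p <- fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2L, 2L),
                     alternative = "two.sided")$p.value
    p <- min(1, p)  # guard against p = 1 + eps from fisher.test
    data.frame(category = ct, k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N), p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram of ortholog conservation over equal-width bins
#'
#' Bins conservation fractions (share of pangenome species carrying an
#' ortholog, in \[0, 1\]) into `n_bins` equal-width bins; bins are
#' left-inclusive and the last bin also includes 1.
#'
#' @param values numeric vector of conservation fractions in \[0, 1\].
#' @param n_bins number of bins (default 10).
#' @return data.frame `bin_lower`, `bin_upper`, `count`; counts sum to
#'   `length(values)`.
#' @export
bin_conservation <- function(values, n_bins = 10) {
  if (length(values) && (anyNA(values) || any(values < 0 | values > 1))) {
    stop_saltomics("conservation values must lie in [0, 1]",
                   "saltomics_input_error")
  }
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  data.frame(
    bin_lower = edges[-length(edges)],
    bin_upper = edges[-1L],
    count = tabulate(idx, nbins = n_bins)
  )
}
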