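#' Classify unique TSSs against gene models
#'
#' Each TSS receives exactly one class, in priority order:
#' \describe{
#'   \item{upstream}{within `upstream_window` nt (default 400,
#'     inclusive) 5' of the start of a same-strand gene, i.e. the
#'     strand-aware distance to the gene start lies in 1..400;}
#'   \item{internal}{inside a same-strand gene;}
#'   \item{antisense}{inside an opposite-strand gene;}
#'   \item{orphan}{none of the above.}
#' }
#' The assigned gene is the qualifying gene at the smallest strand-aware
#' distance (ties towards the smaller gene start). For upstream TSSs
#' `distance_to_start` is the distance to the gene start (1..window);
#' for internal/antisense TSSs it is the offset of the TSS from the
#' (sense) gene's 5' end (0-based, non-negative).
#'
#' @param tss data.frame with columns `representative` (or `position`)
#'   and `strand`; extra columns are carried through.
#' @param genes data.frame with `gene_id`, `start`, `end` (1-based
#'   inclusive) and `strand`.
#' @param upstream_window upstream window in nt, boundary inclusive.
#' @return the `tss` data.frame with `classification`, `assigned_gene`
#'   and `distance_to_start` columns appended.
#' @export
#' @examples
#' genes <- data.frame(gene_id = "g1", start = 1000, end = 2000,
#'                     strand = "+")
#' tss <- data.frame(representative = c(700, 1500, 599), strand = "+")
#' classify_tss(tss, genes)[, c("representative", "classification")]
classify_tss <- function(tss, genes, upstream_window = 400) {
  pos <- tss$representative %||% tss$position
  if (is.null(pos)) {
    stop_saltomics("tss needs a representative or position column",
                   "saltomics_input_error")
  }
  if (nrow(genes)) {
    if (any(genes$end < genes$start) || any(genes$start < 1)) {
      stop_saltomics("malformed gene interval (end < start or start < 1)",
                     "saltomics_annotation_error")
    }
    if (!all(genes$strand %in% c("+", "-"))) {
      stop_saltomics("gene strand must be '+' or '-'",
                     "saltomics_annotation_error")
    }
  }
  n <- nrow(tss)
  classification <- rep("orphan", n)
  assigned_gene <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  if (n == 0L || nrow(genes) == 0L) {
    tss$classification <- classification
    tss$assigned_gene <- assigned_gene
    tss$distance_to_start <- distance
    return(tss)
  }

  chrom <- genes$chrom %||% rep("chr", nrow(genes))
  g <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(genes$start, genes$end), strand = genes$strand
  )
  tchrom <- tss$chrom %||% rep(chrom[1L], n)
  tq <- GenomicRanges::GRanges(
    tchrom, IRanges::IRanges(pos, pos), strand = tss$strand
  )
  gene5 <- ifelse(genes$strand == "+", genes$start, genes$end)

  # pick, per TSS, the hit with smallest distance; ties to smaller start
  pick <- function(hits, dist) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    sel <- vapply(split(seq_along(qi), qi), function(k) {
      k[order(dist[k], genes$start[si[k]])][1L]
    }, integer(1))
    data.frame(tss = qi[sel], gene = si[sel], distance = dist[sel])
  }
  assign_class <- function(chosen, label) {
    todo <- chosen$tss[classification[chosen$tss] == "orphan"]
    keep <- chosen$tss %in% todo
    classification[chosen$tss[keep]] <<- label
    assigned_gene[chosen$tss[keep]] <<- genes$gene_id[chosen$gene[keep]]
    distance[chosen$tss[keep]] <<- as.integer(chosen$distance[keep])
  }

  # upstream: promoter windows [start-w, start-1] / [end+1, end+w]
  up <- GenomicRanges::promoters(g, upstream = upstream_window,
                                 downstream = 0)
  up <- GenomicRanges::trim(up)
  hit_up <- GenomicRanges::findOverlaps(tq, up)
  if (length(hit_up)) {
    si <- S4Vectors::subjectHits(hit_up)
    qi <- S4Vectors::queryHits(hit_up)
    d <- ifelse(genes$strand[si] == "+",
                gene5[si] - pos[qi], pos[qi] - gene5[si])
    assign_class(pick(hit_up, d), "upstream")
  }

  # internal: same-strand overlap with the gene body
  hit_in <- GenomicRanges::findOverlaps(tq, g)
  if (length(hit_in)) {
    si <- S4Vectors::subjectHits(hit_in)
    qi <- S4Vectors::queryHits(hit_in)
    d <- ifelse(genes$strand[si] == "+",
                pos[qi] - gene5[si], gene5[si] - pos[qi])
    assign_class(pick(hit_in, d), "internal")
  }

  # antisense: opposite-strand overlap with the gene body
  g_inv <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(genes$start, genes$end),
    strand = ifelse(genes$strand == "+", "-", "+")
  )
  hit_as <- GenomicRanges::findOverlaps(tq, g_inv)
  if (length(hit_as)) {
    si <- S4Vectors::subjectHits(hit_as)
    qi <- S4Vectors::queryHits(hit_as)
    d <- ifelse(genes$strand[si] == "+",
                pos[qi] - gene5[si], gene5[si] - pos[qi])
    assign_class(pick(hit_as, d), "antisense")
  }

  tss$classification <- classification
  tss$assigned_gene <- assigned_gene
  tss$distance_to_start <- distance
  tss
}
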