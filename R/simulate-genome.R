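#' Simulate non-overlapping gene models on a linear chromosome
#'
#' Genes are placed one per equal-width slot along the chromosome with
#' randomized offset, length and strand, which guarantees disjoint,
#' sorted intervals with intergenic gaps wide enough to host upstream
#' promoter windows. Coordinates are 1-based inclusive (GFF3
#' convention).
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, sorted by `start`.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes == 0L) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  slot <- floor(cfg$chromosome_length / cfg$n_genes)
  if (slot < 100) {
    stop_saltomics("n_genes too large for chromosome_length",
                   "saltomics_config_error")
  }
  withr::with_seed(sub_seed(cfg, 2L), {
    n <- cfg$n_genes
    slot_start <- (seq_len(n) - 1L) * slot
    offset <- floor(runif(n, 0.30, 0.45) * slot)
    len <- pmax(60L, floor(runif(n, 0.20, 0.40) * slot))
    start <- as.integer(slot_start + offset + 1L)
    end <- as.integer(pmin(start + len - 1L, slot_start + slot - 10L))
    data.frame(
      gene_id = sprintf("gene_%04d", seq_len(n)),
      chrom = "chr",
      start = start,
      end = end,
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
  })
}

#' Simulate Cappable-seq fragment alignments around true TSSs
#'
#' Emulates the TSS-mapping design: 4 growth conditions (2 time points
#' under 2 salinity conditions) x 3 replicates. True TSSs are placed on
#' the chromosome at least 100 nt apart; each is active in a random
#' non-empty subset of the conditions (subset sizes weighted to mirror
#' the roughly half-multi-condition overlap structure of the original
#' catalogue). In every active condition and replicate a TSS emits a
#' Poisson(`tss_mean_count`) number of fragments whose 5' ends are
#' jittered by a rounded normal of sd `tss_jitter_sd` nt; a uniform
#' background of `background_end_rate` ends per nt per strand is added
#' per library. Fragments are `fragment_length` nt, clamped to the
#' chromosome.
#'
#' @param cfg a [sim_config()].
#' @param annotation gene models from [simulate_annotation()]; used only
#'   to name the chromosome consistently (TSS placement is uniform).
#' @return list with `fragments` (data.frame `chrom`, `start`, `end`
#'   1-based inclusive, `strand`, `condition`, `replicate`) and `truth`
#'   (data.frame `position`, `strand`, `conditions`
#'   semicolon-separated).
#' @export
simulate_tss_reads <- function(cfg, annotation = simulate_annotation(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  conditions <- c("no_salt_t24", "no_salt_t48", "salt_t24", "salt_t48")
  chrom_len <- as.integer(cfg$chromosome_length)
  withr::with_seed(sub_seed(cfg, 3L), {
    n <- cfg$n_true_tss
    # one TSS per slot keeps true sites >= ~100 nt apart
    slot <- floor(chrom_len / max(n, 1L))
    if (n > 0 && slot < 100) {
      stop_saltomics("n_true_tss too large for chromosome_length",
                     "saltomics_config_error")
    }
    pos <- if (n > 0) {
      as.integer((seq_len(n) - 1L) * slot +
                   floor(runif(n, 0.25, 0.75) * slot) + 1L)
    } else integer(0)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    set_size <- sample(1:4, n, replace = TRUE,
                       prob = c(0.51, 0.20, 0.16, 0.13))
    cond_sets <- lapply(set_size, function(k) sort(sample(conditions, k)))

    frags <- vector("list", 0L)
    add <- function(end5, strand, condition, replicate) {
      if (!length(end5)) return()
      end5 <- pmin(pmax(end5, 1L), chrom_len)
      if (strand == "+") {
        st <- end5
        en <- pmin(end5 + cfg$fragment_length - 1L, chrom_len)
      } else {
        st <- pmax(end5 - cfg$fragment_length + 1L, 1L)
        en <- end5
      }
      frags[[length(frags) + 1L]] <<- data.frame(
        chrom = "chr", start = as.integer(st), end = as.integer(en),
        strand = strand, condition = condition,
        replicate = as.integer(replicate)
      )
    }
    for (cond in conditions) {
      active <- which(vapply(cond_sets, function(s) cond %in% s, logical(1)))
      for (r in seq_len(cfg$n_replicates)) {
        for (i in active) {
          k <- rpois(1L, cfg$tss_mean_count)
          if (k > 0) {
            ends <- pos[i] + as.integer(round(rnorm(k, 0, cfg$tss_jitter_sd)))
            add(ends, strand[i], cond, r)
          }
        }
        for (s in c("+", "-")) {
          nbg <- rpois(1L, cfg$background_end_rate * chrom_len)
          if (nbg > 0) add(sample.int(chrom_len, nbg, replace = TRUE),
                           s, cond, r)
        }
      }
    }
    fragments <- if (length(frags)) do.call(rbind, frags) else
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 condition = character(0), replicate = integer(0))
    ord <- order(fragments$condition, fragments$replicate,
                 fragments$strand, fragments$start, fragments$end)
    fragments <- fragments[ord, , drop = FALSE]
    rownames(fragments) <- NULL
    truth <- data.frame(
      position = pos, strand = strand,
      conditions = vapply(cond_sets, paste, character(1), collapse = ";")
    )
    list(fragments = fragments, truth = truth)
  })
}
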