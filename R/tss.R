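#' Count fragment 5' ends per genomic position
#'
#' For every (condition, replicate, strand) library, counts how many
#' aligned fragments start at each position: for `+` strand fragments
#' the 5' end is the leftmost coordinate, for `-` strand fragments the
#' rightmost. Coordinates are 1-based inclusive.
#'
#' @param fragments data.frame with columns `start`, `end` (1-based
#'   inclusive), `strand` (`"+"`/`"-"`), and optionally `condition` and
#'   `replicate` (defaulted to a single library when absent).
#' @return data.frame with columns `condition`, `replicate`, `strand`,
#'   `position`, `count`, sorted by library, strand, position.
#' @export
#' @examples
#' fr <- data.frame(start = c(101, 101, 120), end = c(150, 150, 170),
#'                  strand = c("+", "+", "-"))
#' count_five_prime_ends(fr)
count_five_prime_ends <- function(fragments) {
  need <- c("start", "end", "strand")
  if (!all(need %in% names(fragments))) {
    stop_saltomics("fragments must have start, end, strand columns",
                   "saltomics_input_error")
  }
  if (!all(fragments$strand %in% c("+", "-"))) {
    stop_saltomics("fragment strand must be '+' or '-'",
                   "saltomics_record_error")
  }
  if (any(fragments$end < fragments$start)) {
    stop_saltomics("fragment end before start", "saltomics_record_error")
  }
  condition <- fragments$condition %||% rep("all", nrow(fragments))
  replicate <- fragments$replicate %||% rep(1L, nrow(fragments))
  pos <- ifelse(fragments$strand == "+", fragments$start, fragments$end)
  if (!length(pos)) {
    return(data.frame(condition = character(0), replicate = integer(0),
                      strand = character(0), position = integer(0),
                      count = integer(0)))
  }
  agg <- aggregate(
    list(count = rep(1L, length(pos))),
    by = list(condition = condition, replicate = replicate,
              strand = fragments$strand, position = as.integer(pos)),
    FUN = sum
  )
  agg <- agg[order(agg$condition, agg$replicate, agg$strand,
                   agg$position), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# Single-linkage chaining of sorted positions on one strand: positions
# join one cluster while the gap to the previous position is <= window.
# Equivalent to connected components of the "within window" graph on a
# line, since consecutive gaps dominate all pairwise distances.
chain_ids <- function(position, window) {
  if (!length(position)) return(integer(0))
  ord <- order(position)
  gap_break <- c(FALSE, diff(position[ord]) > window)
  res <- integer(length(position))
  res[ord] <- cumsum(gap_break) + 1L
  res
}

#' Cluster 5' end positions into candidate TSSs
#'
#' Single-linkage chaining per strand: positions whose gap to the
#' nearest cluster member is at most `window` nt (default 5) join that
#' cluster. The representative is the member with the greatest count
#' (ties broken towards the smallest coordinate); the cluster weight is
#' the sum of member counts.
#'
#' @param ends data.frame with columns `position`, `strand`, `count`
#'   for one library (one replicate of one condition).
#' @param window maximum gap, in nt, joining positions into a cluster.
#' @return data.frame `representative`, `strand`, `total_count`,
#'   `n_members`, plus a list column `members` of member positions.
#' @export
#' @examples
#' e <- data.frame(position = c(100, 103, 109), strand = "+",
#'                 count = c(5, 8, 2))
#' cluster_positions(e)[, 1:4]
cluster_positions <- function(ends, window = 5) {
  if (!all(c("position", "strand", "count") %in% names(ends))) {
    stop_saltomics("ends must have position, strand, count columns",
                   "saltomics_input_error")
  }
  if (!nrow(ends)) {
    return(data.frame(representative = integer(0), strand = character(0),
                      total_count = integer(0), n_members = integer(0),
                      members = I(list())))
  }
  out <- lapply(split(ends, ends$strand), function(e) {
    cl <- chain_ids(e$position, window)
    reps <- vapply(split(seq_len(nrow(e)), cl), function(i) {
      # greatest count first, smallest coordinate on ties
      i[order(-e$count[i], e$position[i])][1L]
    }, integer(1))
    data.frame(
      representative = e$position[reps],
      strand = e$strand[1L],
      total_count = as.vector(tapply(e$count, cl, sum)),
      n_members = as.vector(tapply(e$count, cl, length)),
      members = I(unname(split(e$position, cl)))
    )
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(representative = integer(0), strand = character(0),
                      total_count = integer(0), n_members = integer(0),
                      members = I(list()))
  }
  out <- out[order(out$strand, out$representative), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' All-replicate consensus of clustered TSSs
#'
#' Representatives from the per-replicate cluster lists are chained
#' within `window` nt per strand; a chain becomes a consensus TSS only
#' when it contains a representative from every replicate. The
#' consensus position is the member representative with the greatest
#' per-replicate total count (ties towards the smallest coordinate);
#' the consensus count is the sum across replicates.
#'
#' @param clusters_by_replicate named list of data.frames as returned
#'   by [cluster_positions()], one per replicate.
#' @param window chaining window in nt.
#' @param require_all if TRUE (default), demand detection in every
#'   replicate of the list.
#' @return data.frame `representative`, `strand`, `total_count`,
#'   `n_replicates`.
#' @export
replicate_consensus <- function(clusters_by_replicate, window = 5,
                                require_all = TRUE) {
  if (!length(clusters_by_replicate)) {
    stop_saltomics("need at least one replicate cluster list",
                   "saltomics_input_error")
  }
  if (is.null(names(clusters_by_replicate))) {
    names(clusters_by_replicate) <-
      paste0("rep", seq_along(clusters_by_replicate))
  }
  n_rep <- length(clusters_by_replicate)
  pooled <- do.call(rbind, lapply(names(clusters_by_replicate), function(r) {
    x <- clusters_by_replicate[[r]]
    if (!nrow(x)) return(NULL)
    data.frame(representative = x$representative, strand = x$strand,
               total_count = x$total_count, replicate = r)
  }))
  empty <- data.frame(representative = integer(0), strand = character(0),
                      total_count = integer(0), n_replicates = integer(0))
  if (is.null(pooled) || !nrow(pooled)) return(empty)
  out <- lapply(split(pooled, pooled$strand), function(e) {
    cl <- chain_ids(e$representative, window)
    keep <- vapply(split(seq_len(nrow(e)), cl), function(i) {
      if (require_all && length(unique(e$replicate[i])) < n_rep) return(NA_integer_)
      i[order(-e$total_count[i], e$representative[i])][1L]
    }, integer(1))
    counts <- as.vector(tapply(e$total_count, cl, sum))
    nreps <- as.vector(tapply(e$replicate, cl,
                              function(r) length(unique(r))))
    ok <- !is.na(keep)
    data.frame(representative = e$representative[keep[ok]],
               strand = rep(e$strand[1L], sum(ok)),
               total_count = counts[ok],
               n_replicates = nreps[ok])
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(out) || !nrow(out)) return(empty)
  out <- out[order(out$strand, out$representative), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-condition consensus TSSs into a unique catalogue
#'
#' Consensus TSSs from up to 4 growth conditions are chained within
#' `window` nt per strand. Each unique TSS records the set of
#' conditions in which it was detected and the number of per-condition
#' entries merged (`n_detections`; the two coincide unless one
#' condition contributes two entries to a chain). A tally of TSS counts
#' per exact condition subset (UpSet-style input) is returned
#' alongside.
#'
#' @param consensus_by_condition named list of data.frames from
#'   [replicate_consensus()], one per condition.
#' @param window chaining window in nt.
#' @return list with `tss` (data.frame `representative`, `strand`,
#'   `total_count`, `condition_set` semicolon-joined, `n_conditions`,
#'   `n_detections`) and `tally` (data.frame `condition_set`, `n`).
#' @export
merge_conditions <- function(consensus_by_condition, window = 5) {
  if (!length(consensus_by_condition)) {
    stop_saltomics("need at least one condition consensus list",
                   "saltomics_input_error")
  }
  if (is.null(names(consensus_by_condition))) {
    names(consensus_by_condition) <-
      paste0("cond", seq_along(consensus_by_condition))
  }
  pooled <- do.call(rbind, lapply(names(consensus_by_condition), function(cn) {
    x <- consensus_by_condition[[cn]]
    if (!nrow(x)) return(NULL)
    data.frame(representative = x$representative, strand = x$strand,
               total_count = x$total_count, condition = cn)
  }))
  if (is.null(pooled) || !nrow(pooled)) {
    tss <- data.frame(representative = integer(0), strand = character(0),
                      total_count = integer(0),
                      condition_set = character(0),
                      n_conditions = integer(0), n_detections = integer(0))
    return(list(tss = tss,
                tally = data.frame(condition_set = character(0),
                                   n = integer(0))))
  }
  out <- lapply(split(pooled, pooled$strand), function(e) {
    cl <- chain_ids(e$representative, window)
    idx <- split(seq_len(nrow(e)), cl)
    reps <- vapply(idx, function(i)
      i[order(-e$total_count[i], e$representative[i])][1L], integer(1))
    data.frame(
      representative = e$representative[reps],
      strand = e$strand[1L],
      total_count = as.vector(tapply(e$total_count, cl, sum)),
      condition_set = vapply(idx, function(i)
        paste(sort(unique(e$condition[i])), collapse = ";"), character(1)),
      n_conditions = vapply(idx, function(i)
        length(unique(e$condition[i])), integer(1)),
      n_detections = lengths(idx)
    )
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out <- out[order(out$strand, out$representative), , drop = FALSE]
  rownames(out) <- NULL
  tal <- aggregate(list(n = rep(1L, nrow(out))),
                   by = list(condition_set = out$condition_set), FUN = sum)
  tal <- tal[order(-tal$n, tal$condition_set), , drop = FALSE]
  rownames(tal) <- NULL
  list(tss = out, tally = tal)
}

#' Match two TSS catalogues within a positional window
#'
#' Strand-aware one-to-one matching: candidate pairs within `window` nt
#' are taken greedily by ascending distance (ties towards the smaller
#' coordinate in set A, then in set B); each TSS matches at most once.
#' Used to compare a called catalogue with a previously published one
#' or with planted ground truth.
#'
#' @param a,b data.frames with columns `position` (or `representative`)
#'   and `strand`.
#' @param window maximum |position difference| counted as a match.
#' @return list with `n_matched`, `matched` (data.frame `a_position`,
#'   `b_position`, `strand`, `distance`), `a_only`, `b_only`.
#' @export
compare_tss_sets <- function(a, b, window = 5) {
  getpos <- function(x) {
    p <- x$position %||% x$representative
    if (is.null(p)) {
      stop_saltomics("TSS sets need a position or representative column",
                     "saltomics_input_error")
    }
    data.frame(position = as.integer(p), strand = x$strand)
  }
  a <- getpos(a)
  b <- getpos(b)
  pairs <- NULL
  for (s in intersect(unique(a$strand), unique(b$strand))) {
    ia <- which(a$strand == s)
    ib <- which(b$strand == s)
    if (!length(ia) || !length(ib)) next
    d <- abs(outer(a$position[ia], b$position[ib], "-"))
    hit <- which(d <= window, arr.ind = TRUE)
    if (nrow(hit)) {
      pairs <- rbind(pairs, data.frame(
        ia = ia[hit[, 1L]], ib = ib[hit[, 2L]],
        distance = d[hit], strand = s
      ))
    }
  }
  matched <- data.frame(a_position = integer(0), b_position = integer(0),
                        strand = character(0), distance = integer(0))
  used_a <- logical(nrow(a))
  used_b <- logical(nrow(b))
  if (!is.null(pairs) && nrow(pairs)) {
    pairs <- pairs[order(pairs$distance, a$position[pairs$ia],
                         b$position[pairs$ib]), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$ia[k]; j <- pairs$ib[k]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      matched[nrow(matched) + 1L, ] <-
        list(a$position[i], b$position[j], pairs$strand[k],
             pairs$distance[k])
    }
  }
  list(n_matched = nrow(matched), matched = matched,
       a_only = a[!used_a, , drop = FALSE],
       b_only = b[!used_b, , drop = FALSE])
}

#' Full TSS calling pipeline from fragment alignments
#'
#' Counts fragment 5' ends per (condition, replicate) library, clusters
#' them per replicate, takes the all-replicate consensus per condition,
#' merges conditions into a unique catalogue with detection sets, and
#' classifies every unique TSS against the gene models.
#'
#' @param fragments data.frame of fragment records (`chrom`, `start`,
#'   `end` 1-based inclusive, `strand`, `condition`, `replicate`).
#' @param genes gene models (`gene_id`, `start`, `end`, `strand`), as
#'   from [simulate_annotation()] or [read_gene_models()].
#' @param window clustering window in nt (default 5).
#' @param upstream_window upstream classification window in nt
#'   (default 400).
#' @return list with `tss` (classified unique catalogue), `tally`
#'   (condition-subset counts), `per_condition` (named integer vector
#'   of consensus TSS counts per condition), and `n_detections_total`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 2, n_genes = 20, n_true_tss = 15,
#'                   chromosome_length = 1e5)
#' ann <- simulate_annotation(cfg)
#' reads <- simulate_tss_reads(cfg, ann)
#' called <- call_tss(reads$fragments, ann)
#' table(called$tss$classification)
call_tss <- function(fragments, genes, window = 5, upstream_window = 400) {
  ends <- count_five_prime_ends(fragments)
  conditions <- sort(unique(ends$condition))
  consensus <- lapply(conditions, function(cn) {
    e <- ends[ends$condition == cn, , drop = FALSE]
    reps <- sort(unique(e$replicate))
    clustered <- lapply(reps, function(r) {
      cluster_positions(e[e$replicate == r, , drop = FALSE], window)
    })
    names(clustered) <- paste0("rep", reps)
    replicate_consensus(clustered, window)
  })
  names(consensus) <- conditions
  merged <- merge_conditions(consensus, window)
  tss <- classify_tss(merged$tss, genes, upstream_window)
  list(
    tss = tss,
    tally = merged$tally,
    per_condition = vapply(consensus, nrow, integer(1)),
    n_detections_total = sum(merged$tss$n_detections)
  )
}
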