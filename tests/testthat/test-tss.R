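test_that("5' end counting is strand-aware and aggregates duplicates", {
  fr <- data.frame(
    chrom = "chr",
    start = c(101, 101, 101, 150),
    end = c(150, 150, 150, 199),
    strand = c("+", "+", "-", "-")
  )
  ends <- count_five_prime_ends(fr)
  plus <- ends[ends$strand == "+", ]
  minus <- ends[ends$strand == "-", ]
  expect_equal(plus$position, 101)
  expect_equal(plus$count, 2)
  expect_equal(minus$position, c(150, 199))
  expect_equal(minus$count, c(1, 1))
  expect_error(
    count_five_prime_ends(data.frame(start = 1, end = 5, strand = "*")),
    class = "saltomics_record_error"
  )
})

test_that("BED fragment round-trip preserves 1-based ends", {
  fr <- data.frame(chrom = "chr", start = c(101, 200), end = c(150, 260),
                   strand = c("+", "-"), condition = "salt_t24",
                   replicate = 1L)
  dir <- tempfile()
  man <- write_fragment_beds(fr, dir)
  # on disk: 0-based half-open
  raw <- read.table(file.path(dir, "salt_t24_rep1.bed"), sep = "\t")
  expect_equal(raw[[2]], c(100, 199))
  expect_equal(raw[[3]], c(150, 260))
  back <- read_fragment_beds(man)
  expect_equal(back[, c("start", "end", "strand")],
               fr[, c("start", "end", "strand")])
  unlink(dir, recursive = TRUE)
})

test_that("position clustering matches spec examples and tie rules", {
  e <- data.frame(position = c(100, 103, 109), strand = "+",
                  count = c(5, 8, 2))
  cl <- cluster_positions(e, window = 5)
  expect_equal(cl$representative, c(103, 109))
  expect_equal(cl$total_count, c(13, 2))

  tie <- cluster_positions(
    data.frame(position = c(100, 105), strand = "+", count = c(5, 5)),
    window = 5
  )
  expect_equal(tie$representative, 100)  # tie -> smallest coordinate

  both <- cluster_positions(
    data.frame(position = c(100, 100), strand = c("+", "-"),
               count = c(3, 3)), window = 5
  )
  expect_equal(nrow(both), 2)  # strands never mix

  expect_equal(nrow(cluster_positions(
    data.frame(position = integer(0), strand = character(0),
               count = integer(0)))), 0)
})

test_that("clustering equals the O(n^2) single-linkage oracle", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(1:100, 1)
    w <- sample(1:10, 1)
    pos <- sort(sample(1:500, n))
    cnt <- sample(1:50, n, replace = TRUE)
    e <- data.frame(position = pos, strand = "+", count = cnt)
    got <- cluster_positions(e, window = w)
    comp <- oracle_single_linkage(pos, w)
    # same number of clusters, same membership partition
    expect_equal(nrow(got), length(unique(comp)))
    want_members <- unname(lapply(split(pos, comp), sort))
    got_members <- unname(lapply(got$members, sort))
    expect_setequal(
      vapply(got_members, paste, character(1), collapse = ","),
      vapply(want_members, paste, character(1), collapse = ",")
    )
    # counts conserved at the cluster stage
    expect_equal(sum(got$total_count), sum(cnt))
    # representative is the max-count member (smallest position on tie)
    for (k in seq_len(nrow(got))) {
      m <- got$members[[k]]
      mc <- cnt[match(m, pos)]
      expect_equal(got$representative[k], min(m[mc == max(mc)]))
    }
  }
})

test_that("enlarging the window never increases the cluster count", {
  set.seed(32)
  pos <- sort(sample(1:300, 60))
  e <- data.frame(position = pos, strand = "+",
                  count = sample(1:9, 60, replace = TRUE))
  n_cl <- vapply(1:10, function(w) nrow(cluster_positions(e, w)),
                 integer(1))
  expect_true(all(diff(n_cl) <= 0))
})

test_that("re-clustering well-separated representatives is idempotent", {
  e <- data.frame(position = c(100, 120, 150), strand = "+",
                  count = c(5, 7, 2))
  cl <- cluster_positions(e, window = 5)
  again <- cluster_positions(
    data.frame(position = cl$representative, strand = cl$strand,
               count = cl$total_count), window = 5)
  expect_equal(again$representative, cl$representative)
  expect_equal(again$total_count, cl$total_count)
})

test_that("replicate consensus demands detection in every replicate", {
  mk <- function(pos, cnt) data.frame(
    representative = pos, strand = rep("+", length(pos)),
    total_count = cnt, n_members = 1,
    members = I(as.list(pos))
  )
  cons <- replicate_consensus(
    list(r1 = mk(100, 10), r2 = mk(102, 20), r3 = mk(104, 5)), window = 5)
  expect_equal(cons$representative, 102)  # greatest count wins
  expect_equal(cons$total_count, 35)

  # no chain contains all three replicates -> nothing is emitted
  dropped <- replicate_consensus(
    list(r1 = mk(100, 10), r2 = mk(100, 10), r3 = mk(500, 1)), window = 5)
  expect_equal(nrow(dropped), 0)
})

test_that("consensus keeps only chains covering all replicates", {
  mk <- function(pos, cnt) data.frame(
    representative = pos, strand = rep("+", length(pos)),
    total_count = cnt, n_members = 1, members = I(as.list(pos))
  )
  cons <- replicate_consensus(
    list(r1 = mk(c(100, 120), c(10, 4)), r2 = mk(c(102, 121), c(8, 6)),
         r3 = mk(100, 7)),
    window = 5
  )
  # the 120-chain lacks replicate 3
  expect_equal(cons$representative, 100)
  expect_equal(cons$total_count, 25)
  expect_equal(cons$n_replicates, 3)

  relaxed <- replicate_consensus(
    list(r1 = mk(c(100, 120), c(10, 4)), r2 = mk(c(102, 121), c(8, 6)),
         r3 = mk(100, 7)),
    window = 5, require_all = FALSE
  )
  expect_equal(relaxed$representative, c(100, 121))
})

test_that("condition merging records detection sets and the UpSet tally", {
  mk <- function(pos, cnt) data.frame(
    representative = pos, strand = rep("+", length(pos)),
    total_count = cnt, n_replicates = rep(3L, length(pos))
  )
  merged <- merge_conditions(
    list(A = mk(100, 30), B = mk(103, 10), C = mk(numeric(0), numeric(0)),
         D = mk(200, 5)),
    window = 5
  )
  expect_equal(nrow(merged$tss), 2)
  expect_equal(merged$tss$condition_set, c("A;B", "D"))
  expect_equal(merged$tss$representative, c(100, 200))
  expect_equal(sum(merged$tss$n_detections), 3)  # conservation: 1+1+0+1
  expect_equal(merged$tally$n[merged$tally$condition_set == "A;B"], 1)

  all4 <- merge_conditions(
    list(A = mk(100, 1), B = mk(100, 1), C = mk(100, 1), D = mk(100, 1)))
  expect_equal(all4$tss$n_conditions, 4)
})

test_that("TSS classification follows the upstream/internal/antisense priority", {
  genes <- data.frame(gene_id = c("g1", "g2"),
                      start = c(1000, 5000), end = c(2000, 6000),
                      strand = c("+", "-"))
  tss <- data.frame(
    representative = c(700, 1500, 1500, 599, 600, 6200, 5500, 300),
    strand = c("+", "+", "-", "+", "+", "-", "+", "-")
  )
  got <- classify_tss(tss, genes, upstream_window = 400)
  expect_equal(got$classification,
               c("upstream", "internal", "antisense", "orphan",
                 "upstream", "upstream", "antisense", "orphan"))
  expect_equal(got$assigned_gene[1], "g1")
  expect_equal(got$distance_to_start[1], 300)
  expect_equal(got$distance_to_start[5], 400)  # inclusive boundary
  expect_equal(got$assigned_gene[6], "g2")
  expect_equal(got$distance_to_start[6], 200)

  # malformed annotation
  expect_error(
    classify_tss(tss, data.frame(gene_id = "bad", start = 10, end = 5,
                                 strand = "+")),
    class = "saltomics_annotation_error"
  )

  # every TSS gets exactly one class; categories partition the set
  expect_equal(sum(table(got$classification)), nrow(tss))
})

test_that("upstream beats internal when both apply", {
  # TSS inside g0 but within 400 nt upstream of g1 on the same strand
  genes <- data.frame(gene_id = c("g0", "g1"),
                      start = c(100, 1000), end = c(900, 2000),
                      strand = c("+", "+"))
  got <- classify_tss(data.frame(representative = 850, strand = "+"),
                      genes)
  expect_equal(got$classification, "upstream")
  expect_equal(got$assigned_gene, "g1")
})

test_that("catalogue comparison matches greedily by distance with tie rules", {
  a <- data.frame(position = c(100, 106), strand = "+")
  b <- data.frame(position = 103, strand = "+")
  res <- compare_tss_sets(a, b, window = 5)
  expect_equal(res$n_matched, 1)
  expect_equal(res$matched$a_position, 100)  # tie at distance 3 -> smaller
  expect_equal(res$a_only$position, 106)

  expect_equal(compare_tss_sets(
    data.frame(position = 100, strand = "+"),
    data.frame(position = 104, strand = "+"))$n_matched, 1)
  expect_equal(compare_tss_sets(
    data.frame(position = 100, strand = "+"),
    data.frame(position = 100, strand = "-"))$n_matched, 0)
})

test_that("full caller conserves counts from raw ends to the catalogue", {
  cfg <- sim_config(seed = 33, n_genes = 30, n_true_tss = 40,
                    chromosome_length = 2e5, n_planted_de = 10,
                    n_planted_salt_up = 3, n_planted_salt_down = 1)
  reads <- simulate_tss_reads(cfg)
  called <- call_tss(reads$fragments, simulate_annotation(cfg))

  # detection-set sizes sum to total detections across conditions
  expect_equal(sum(called$tss$n_detections), called$n_detections_total)
  expect_equal(called$n_detections_total, sum(called$per_condition))
  expect_equal(sum(called$tally$n), nrow(called$tss))
  # classification partitions the catalogue
  expect_equal(sum(table(called$tss$classification)), nrow(called$tss))
  expect_true(all(called$tss$classification %in%
                    c("upstream", "internal", "antisense", "orphan")))
})
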