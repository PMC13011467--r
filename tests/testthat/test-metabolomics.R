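test_that("blank filter keeps features 3x above the strongest blank", {
  ft <- make_tiny_table(function(nf, ns, samples) {
    sig <- matrix(1e3, nf, ns)
    nb <- !samples$is_blank
    sig[1, nb] <- 9e6;  sig[1, !nb] <- 4e6   # 9e6 < 3 * 4e6: removed
    sig[2, nb] <- 1.3e7; sig[2, !nb] <- 4e6  # 1.3e7 >= 1.2e7: kept
    sig[3, nb] <- 5;    sig[3, !nb] <- 0     # zero blank: kept
    sig[4, nb] <- 1.2e7; sig[4, !nb] <- 4e6  # boundary: kept
    sig
  })
  kept <- filter_blank(ft)$features$feature_id
  expect_setequal(kept, c("F002", "F003", "F004"))

  no_blanks <- feature_table(
    ft$signal[, !ft$samples$is_blank, drop = FALSE],
    ft$features, ft$samples[!ft$samples$is_blank, ]
  )
  expect_error(filter_blank(no_blanks), class = "saltomics_config_error")
})

test_that("retention-time window is inclusive at both boundaries", {
  ft <- make_tiny_table(flat_signal(1e8), rt = c(0.49, 0.5, 8.0, 8.01))
  kept <- filter_retention_time(ft)$features$feature_id
  expect_setequal(kept, c("F002", "F003"))
})

test_that("signal floor removes only features below 1e7 everywhere", {
  ft <- make_tiny_table(function(nf, ns, samples) {
    sig <- matrix(5e6, nf, ns)
    sig[2, 1] <- 2e7          # one strong sample rescues the feature
    sig[3, ] <- 1e3; sig[3, 2] <- 1e7  # exactly at floor: kept
    sig
  })
  kept <- filter_low_signal(ft)$features$feature_id
  expect_setequal(kept, c("F002", "F003"))
})

test_that("pseudocount adds 1e4 once and refuses double application", {
  ft <- make_tiny_table(flat_signal(0))
  ft2 <- add_pseudocount(ft)
  expect_true(all(ft2$signal == 1e4))
  expect_error(add_pseudocount(ft2), class = "saltomics_state_error")
  ft3 <- make_tiny_table(flat_signal(1e7))
  expect_equal(unique(as.vector(add_pseudocount(ft3)$signal)), 1.001e7)
})

test_that("group means equal the brute-force replicate average", {
  set.seed(101)
  vals <- NULL
  ft <- make_tiny_table(function(nf, ns, samples) {
    vals <<- matrix(10^runif(nf * ns, 4, 8), nf, ns)
    vals
  })
  expect_error(group_means(ft), class = "saltomics_state_error")
  gm <- group_means(add_pseudocount(ft))
  expect_equal(dim(gm), c(4, 6))
  key <- paste(ft$samples$condition, ft$samples$time_h, sep = ".")
  for (g in colnames(gm)) {
    cols <- which(!ft$samples$is_blank & key == g)
    expect_length(cols, 3)
    manual <- rowSums(vals[, cols] + 1e4) / 3
    expect_equal(unname(gm[, g]), unname(manual), tolerance = 1e-12)
  }
})

test_that("prefilter and interaction gates use inclusive fold boundaries", {
  means <- rbind(F1 = c(1e4, 1e4, 1e4, 1e4, 1e4, 9.9e4),
                 F2 = c(1e4, 1e4, 1e4, 1e4, 1e4, 1e5),
                 F3 = rep(2e4, 6),
                 F4 = c(1e4, 2e4, 5e4, 8e4, 9e4, 1e6),
                 F5 = c(1e4, 2e4, 5e4, 8e4, 9e4, 9.9e5))
  expect_equal(unname(prefilter_fold_change(means)),
               c(FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(unname(interaction_fold_gate(means)),
               c(FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("one-way ANOVA handles separation and constant data by convention", {
  sep <- one_way_anova(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3))
  expect_lt(sep$p.value, 1e-12)
  expect_false(sep$degenerate)

  const <- one_way_anova(rep(5, 18), rep(1:6, each = 3))
  expect_true(const$degenerate)
  expect_equal(const$p.value, 1)

  expect_error(one_way_anova(1:4, c("a", "a", "a", "b")),
               class = "saltomics_input_error")
})

test_that("one-way F and p match the explicit sum-of-squares oracle", {
  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(18, sd = runif(1, 0.1, 2))
    g <- rep(1:6, each = 3)
    got <- one_way_anova(x, g)
    want <- oracle_oneway_F(x, g)
    expect_equal(got$statistic, want$F, tolerance = 1e-9)
    expect_equal(got$p.value, want$p, tolerance = 1e-9)
  }
})

test_that("Brown-Forsythe test matches the deviation-ANOVA oracle and car", {
  # equal spread around different centers: no variance heterogeneity
  x <- c(10.1, 10.0, 9.9, 0.1, 0.0, -0.1)
  g <- rep(c("a", "b"), each = 3)
  lv <- levene_test(x, g)
  dev <- abs(x - ave(x, g, FUN = median))
  want <- oracle_oneway_F(dev, g)
  expect_equal(lv$statistic, want$F, tolerance = 1e-9)
  expect_gt(lv$p.value, 0.9)

  # heterogeneous spread: deviations (0,0,0) vs (5,0,5) give F = 4
  x2 <- c(0, 0, 0, -5, 0, 5)
  lv2 <- levene_test(x2, g)
  want2 <- oracle_oneway_F(abs(x2 - ave(x2, g, FUN = median)), g)
  expect_equal(lv2$statistic, want2$F, tolerance = 1e-9)
  expect_lt(lv2$p.value, lv$p.value)  # heterogeneity lowers the p value

  expect_equal(levene_test(rep(1, 6), g)$p.value, 1)

  skip_if_not_installed("car")
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(18, sd = rep(runif(6, 0.2, 2), each = 3))
    gf <- factor(rep(1:6, each = 3))
    got <- levene_test(x, gf)
    ref <- car::leveneTest(x, gf, center = median)
    expect_equal(got$statistic, ref[1, "F value"], tolerance = 1e-9)
    expect_equal(got$p.value, ref[1, "Pr(>F)"], tolerance = 1e-9)
  }
})

test_that("two-way ANOVA matches the factorial oracle and handles degeneracy", {
  set.seed(13)
  sal <- rep(c("s", "n"), each = 9)
  tim <- rep(rep(1:3, each = 3), 2)
  for (i in 1:25) {
    x <- rnorm(18)
    got <- two_way_anova(x, sal, tim)
    want <- oracle_twoway(x, sal, tim)
    expect_equal(unname(got$ss), unname(want$ss), tolerance = 1e-9)
    expect_equal(c(got$p_sal, got$p_time, got$p_int), unname(want$p),
                 tolerance = 1e-9)
    # balanced-design identity
    expect_equal(sum(got$ss), want$ss_total, tolerance = 1e-6)
  }

  # pure salinity effect, noiseless: interaction empty, salinity saturated
  x <- ifelse(sal == "s", 1, 0)
  got <- two_way_anova(x, sal, tim)
  expect_lt(got$p_sal, 1e-12)
  expect_equal(got$p_int, 1)

  # pure interaction in one cell, noiseless
  x <- ifelse(sal == "s" & tim == 2, 1, 0)
  got <- two_way_anova(x, sal, tim)
  expect_lt(got$p_int, 1e-12)

  expect_equal(two_way_anova(rep(3, 18), sal, tim)$p_int, 1)
  expect_error(two_way_anova(rnorm(17), sal[-1], tim[-1]),
               class = "saltomics_input_error")
})

test_that("BH adjustment equals the naive min-over-tail computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "saltomics_input_error")
  set.seed(14)
  for (i in 1:50) {
    p <- sample(seq(0, 1, by = 0.05), sample(1:12, 1), replace = TRUE)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("staged workflow conserves features and recovers planted effects", {
  cfg <- sim_config(seed = 21, n_features = 300, n_planted_diff = 20,
                    replicate_cv = 0.1, n_planted_de = 10,
                    n_planted_salt_up = 3, n_planted_salt_down = 1,
                    n_genes = 20, chromosome_length = 1e5, n_true_tss = 10)
  sim <- simulate_lcms(cfg)
  res <- suppressMessages(call_differential_features(sim$table))

  # audit conservation: stage k input equals stage k-1 output
  expect_equal(res$audit$n_in[-1], res$audit$n_out[-nrow(res$audit)])
  expect_equal(res$audit$n_in[1], 300)
  expect_equal(sum(res$results$final_call), res$audit$n_out[nrow(res$audit)])

  called <- res$results$feature_id[res$results$final_call]
  truth <- sim$truth$differential_feature_ids
  expect_gte(mean(truth %in% called), 0.9)
  expect_equal(length(setdiff(called, truth)), 0)

  # q >= p wherever both are defined
  r <- res$results
  expect_true(all(r$q1 >= r$p1, na.rm = TRUE))
  expect_true(all(r$q_int >= r$p_int, na.rm = TRUE))
  # final calls imply every stage flag and gate
  fin <- r[r$final_call, ]
  expect_true(all(fin$blank_pass & fin$rt_pass & fin$floor_pass &
                    fin$prefilter_pass))
  expect_true(all(fin$q1 < 0.05 & fin$q_int < 0.05 & fin$max_fold >= 100))
  expect_error(call_differential_features(add_pseudocount(sim$table)),
               class = "saltomics_state_error")
})

test_that("tightening thresholds never increases the number of calls", {
  cfg <- sim_config(seed = 22, n_features = 200, n_planted_diff = 15,
                    replicate_cv = 0.3, planted_interaction_fold = 120,
                    n_planted_de = 10, n_planted_salt_up = 3,
                    n_planted_salt_down = 1, n_genes = 20,
                    chromosome_length = 1e5, n_true_tss = 10)
  sim <- simulate_lcms(cfg)
  n_calls <- function(fold, alpha) {
    th <- salt_thresholds(interaction_fold = fold, fdr_alpha = alpha)
    sum(suppressMessages(
      call_differential_features(sim$table, th)
    )$results$final_call)
  }
  by_fold <- vapply(c(50, 100, 150, 300), n_calls, numeric(1),
                    alpha = 0.05)
  expect_true(all(diff(by_fold) <= 0))
  by_alpha <- vapply(c(0.1, 0.05, 0.01), n_calls, numeric(1),
                     fold = 100)
  expect_true(all(diff(by_alpha) <= 0))
})
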