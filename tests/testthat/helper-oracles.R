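# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Single-linkage clustering as connected components of the graph with
# an edge between positions at distance <= window. O(n^2) closure.
oracle_single_linkage <- function(positions, window) {
  n <- length(positions)
  if (n == 0L) return(integer(0))
  adj <- abs(outer(positions, positions, "-")) <= window
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      m <- min(comp[nb])
      if (any(comp[nb] != m)) {
        comp[nb] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# One-way ANOVA from explicit sums of squares.
oracle_oneway_F <- function(x, g) {
  g <- factor(g)
  grand <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(unlist(tapply(x, g, function(v) (v - mean(v))^2)))
  k <- nlevels(g)
  df1 <- k - 1L
  df2 <- length(x) - k
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE),
       ssb = ssb, ssw = ssw)
}

# Balanced two-way factorial decomposition from explicit cell means.
oracle_twoway <- function(x, a, b) {
  a <- factor(a)
  b <- factor(b)
  grand <- mean(x)
  n <- length(x)
  r <- n / (nlevels(a) * nlevels(b))
  ma <- tapply(x, a, mean)
  mb <- tapply(x, b, mean)
  mab <- tapply(x, list(a, b), mean)
  ss_a <- sum((ma - grand)^2) * n / nlevels(a)
  ss_b <- sum((mb - grand)^2) * n / nlevels(b)
  ss_ab <- 0
  ss_e <- 0
  for (i in levels(a)) for (j in levels(b)) {
    dev <- mab[i, j] - ma[[i]] - mb[[j]] + grand
    ss_ab <- ss_ab + r * dev^2
    ss_e <- ss_e + sum((x[a == i & b == j] - mab[i, j])^2)
  }
  df <- c(nlevels(a) - 1L, nlevels(b) - 1L,
          (nlevels(a) - 1L) * (nlevels(b) - 1L),
          n - nlevels(a) * nlevels(b))
  ms_e <- ss_e / df[4L]
  Fv <- c(ss_a / df[1L], ss_b / df[2L], ss_ab / df[3L]) / ms_e
  p <- stats::pf(Fv, df[1:3], df[4L], lower.tail = FALSE)
  list(ss = c(ss_a, ss_b, ss_ab, ss_e), F = Fv, p = p,
       ss_total = sum((x - grand)^2))
}

# Benjamini-Hochberg by its printed definition: q for the i-th order
# statistic is min over j >= i of p_(j) * n / j, capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(n)
  qs <- numeric(n)
  for (i in seq_len(n)) {
    qs[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  q[ord] <- qs
  q
}

# Two-sided Fisher p by enumerating all 2x2 tables with fixed margins:
# sum of hypergeometric probabilities not exceeding the observed one
# (with the same relative tolerance R's fisher.test uses).
oracle_fisher_two_sided <- function(k, K, n, N) {
  lo <- max(0L, n - (N - K))
  hi <- min(n, K)
  probs <- stats::dhyper(lo:hi, K, N - K, n)
  obs <- stats::dhyper(k, K, N - K, n)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# DE rules evaluated directly from their definitions, one gene at a
# time: span over the 6 zeroed lfcs plus the implicit reference 0;
# salt classification from the max over each salinity arm.
oracle_de_rules <- function(lfc_salt, lfc_no_salt, fold = 5) {
  v <- c(lfc_salt, lfc_no_salt, 0)
  is_de <- (max(v) - min(v)) >= log2(fold)
  cls <- NA_character_
  if (is_de) {
    d <- max(lfc_salt) - max(lfc_no_salt)
    cls <- if (d >= log2(fold)) "salt_up"
    else if (-d >= log2(fold)) "salt_down"
    else "neither"
  }
  list(is_de = is_de, salt_class = cls)
}

# Small raw feature table built by hand for filter unit tests: signal
# values are chosen per test; design is 2 conditions x 3 times x 3
# replicates plus 2 blanks.
make_tiny_table <- function(signal_fun, n_features = 4,
                            rt = rep(2, n_features),
                            mode = rep("positive", n_features)) {
  conditions <- c("no_salt", "salt")
  times <- c(0.5, 48, 96)
  design <- expand.grid(replicate = 1:3, time_h = times,
                        condition = conditions, stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_t%g_r%d", design$condition,
                              design$time_h, design$replicate)
  design$is_blank <- FALSE
  blanks <- data.frame(replicate = 1:2, time_h = NA_real_,
                       condition = "blank",
                       sample_id = c("blank_r1", "blank_r2"),
                       is_blank = TRUE)
  samples <- rbind(design, blanks)[, c("sample_id", "condition", "time_h",
                                       "replicate", "is_blank")]
  sig <- signal_fun(n_features, nrow(samples), samples)
  features <- data.frame(
    feature_id = sprintf("F%03d", seq_len(n_features)),
    mz = seq(100, by = 10, length.out = n_features),
    rt = rt, mode = mode
  )
  feature_table(sig, features, samples)
}

# Uniform signal matrix helper.
flat_signal <- function(value) {
  function(nf, ns, samples) matrix(value, nf, ns)
}
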