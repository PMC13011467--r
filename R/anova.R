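#' One-way ANOVA with explicit degenerate-case conventions
#'
#' Classical between/within F test via [stats::lm()]/[stats::anova()],
#' with two conventions needed when screening thousands of LC-MS
#' features: (i) a feature whose values are all (numerically) identical
#' carries no information and is flagged degenerate with p = 1;
#' (ii) complete separation (zero within-group variance but nonzero
#' between-group variance) yields a finite reported p of 1e-15 rather
#' than an exact 0, keeping -log10(p) displays finite.
#'
#' @param x numeric vector (here: log10-transformed pseudocounted
#'   signals).
#' @param g grouping vector, coerced to factor; at least 2 groups and
#'   2 observations per group.
#' @return list with `statistic` (F), `p.value`, `df`, `degenerate`.
#' @export
#' @examples
#' one_way_anova(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
one_way_anova <- function(x, g) {
  g <- factor(g)
  if (length(x) != length(g)) {
    stop_saltomics("x and g lengths differ", "saltomics_input_error")
  }
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    stop_saltomics("need >= 2 groups with >= 2 observations each",
                   "saltomics_input_error")
  }
  ss_tot <- sum((x - mean(x))^2)
  if (ss_tot <= 1e-12 * max(1, mean(x)^2)) {
    return(list(statistic = NA_real_, p.value = 1,
                df = c(nlevels(g) - 1L, length(x) - nlevels(g)),
                degenerate = TRUE))
  }
  # lm warns on numerically perfect fits; separation is handled below
  tab <- suppressWarnings(anova(lm(x ~ g)))
  p <- tab[["Pr(>F)"]][1L]
  if (tab[["Sum Sq"]][2L] <= 1e-12 * ss_tot) p <- 1e-15
  list(statistic = tab[["F value"]][1L], p.value = p,
       df = tab[["Df"]], degenerate = FALSE)
}

#' Brown-Forsythe test for homogeneity of group variances
#'
#' Levene's test in its median-centered (Brown-Forsythe) variant:
#' absolute deviations from the group medians are submitted to
#' [one_way_anova()]. Reported per feature as an assumption check; the
#' pipeline never filters on it. Inherits the degenerate conventions of
#' [one_way_anova()] (all-equal values give p = 1).
#'
#' @inheritParams one_way_anova
#' @return list with `statistic` (W), `p.value`, `df`, `degenerate`.
#' @export
levene_test <- function(x, g) {
  g <- factor(g)
  if (length(x) != length(g)) {
    stop_saltomics("x and g lengths differ", "saltomics_input_error")
  }
  dev <- abs(x - ave(x, g, FUN = median))
  res <- one_way_anova(dev, g)
  names(res)[1] <- "statistic"
  res
}

#' Balanced two-way ANOVA for the salinity x time design
#'
#' Full factorial decomposition of log10 signals into salinity, time,
#' interaction and error sums of squares via [stats::lm()]; the design
#' must be complete and balanced (as in the emulated 2 x 3 x 3 study),
#' where type I/II/III sums of squares coincide. Degenerate cases follow
#' the conventions of [one_way_anova()]: with zero residual variance,
#' terms carrying signal report p = 1e-15 and empty terms p = 1; a
#' constant response reports p = 1 for every term.
#'
#' @param x numeric vector of log10-transformed pseudocounted signals.
#' @param salinity,time grouping vectors, coerced to factors.
#' @return list with per-term statistics `F_sal`, `F_time`, `F_int`,
#'   p values `p_sal`, `p_time`, `p_int`, the sums of squares `ss`
#'   (named: salinity, time, interaction, error), and `degenerate`.
#' @export
two_way_anova <- function(x, salinity, time) {
  salinity <- factor(salinity)
  time <- factor(time)
  if (length(unique(c(length(x), length(salinity), length(time)))) != 1L) {
    stop_saltomics("x, salinity and time lengths differ",
                   "saltomics_input_error")
  }
  tab <- table(salinity, time)
  if (nlevels(salinity) < 2L || nlevels(time) < 2L ||
      any(tab == 0L) || length(unique(as.vector(tab))) != 1L ||
      tab[1L] < 2L) {
    stop_saltomics(
      "two_way_anova requires a complete balanced design with replicates",
      "saltomics_input_error"
    )
  }
  out <- list(F_sal = NA_real_, F_time = NA_real_, F_int = NA_real_,
              p_sal = 1, p_time = 1, p_int = 1,
              ss = c(salinity = 0, time = 0, interaction = 0, error = 0),
              degenerate = FALSE)
  ss_tot <- sum((x - mean(x))^2)
  if (ss_tot <= 1e-12 * max(1, mean(x)^2)) {
    out$degenerate <- TRUE
    return(out)
  }
  fit <- suppressWarnings(anova(lm(x ~ salinity * time)))
  ss <- fit[["Sum Sq"]]
  names(ss) <- c("salinity", "time", "interaction", "error")
  out$ss <- ss
  out$F_sal <- fit[["F value"]][1L]
  out$F_time <- fit[["F value"]][2L]
  out$F_int <- fit[["F value"]][3L]
  p <- fit[["Pr(>F)"]][1:3]
  if (ss[["error"]] <= 1e-12 * ss_tot) {
    # complete separation: terms with mass get 1e-15, empty terms p = 1
    p <- ifelse(ss[1:3] > 1e-12 * ss_tot, 1e-15, 1)
  }
  out$p_sal <- unname(p[1L])
  out$p_time <- unname(p[2L])
  out$p_int <- unname(p[3L])
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control via [stats::p.adjust()], with
#' input validation (raw p values must lie in \[0, 1\]). In the LC-MS
#' workflow the adjustment is applied across the features that survive
#' the preceding stage, separately per ionization mode and per ANOVA
#' term.
#'
#' @param p numeric vector of raw p values.
#' @return numeric vector of adjusted p values (q values).
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_saltomics("p values must lie in [0, 1]", "saltomics_input_error")
  }
  p.adjust(p, method = "BH")
}
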