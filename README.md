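# saltomics

Staged differential analysis for salt-stress multi-omics in
*Streptomyces coelicolor*.

Moderate salt supplementation activates secondary metabolism in
*S. coelicolor*. Measuring that response combines untargeted LC-MS
metabolomics, RNA-seq and Cappable-seq TSS mapping — and each of those
needs a bespoke downstream procedure that standard tools do not
provide. `saltomics` implements the three, plus a seeded synthetic-data
generator with known ground truth so that every stage is verifiable end
to end:

* **`call_differential_features()`** — the staged LC-MS workflow over a
  2 salinity x 3 time x 3 replicate design: blank filter (3x over
  medium blanks), retention-time window (0.5–8 min), signal floor
  (10^7, dropped only when below it in every sample), pseudocount
  (10^4), 10x fold-change prefilter on the six (condition, time) group
  means, one-way ANOVA on log10 signals with Benjamini–Hochberg control
  (q < 0.05), a Brown–Forsythe variance check (reported, not filtered
  on), a balanced two-way ANOVA keeping features with interaction
  q < 0.05, and a final 100x fold gate. A feature is called iff it
  clears every stage; a per-stage audit table is emitted.
* **`call_tss()`** — Cappable-seq TSS calling: strand-aware fragment
  5'-end counting, single-linkage clustering within 5 nt (representative
  = greatest count, ties to the smaller coordinate), all-replicate
  consensus per condition, cross-condition merging with detection sets
  (UpSet tally), and classification against gene models with priority
  upstream (<= 400 nt 5' of a same-strand gene start) > internal >
  antisense > orphan. `compare_tss_sets()` matches catalogues one-to-one
  within 5 nt.
* **`classify_genes()`** — DE rules over log2 fold-change tables versus
  the preculture reference: lfc set to 0 where adjusted P >= 0.05; DE
  iff max − min >= log2 5 across the 7 conditions (reference included at
  0); among DE genes, salt_up iff max(salt lfc) − max(no-salt lfc) >=
  log2 5 (salt_down symmetric). `enrichment_test()` runs two-sided
  Fisher's exact gene-set enrichment with BH control;
  `bin_conservation()` histograms ortholog conservation.
* **`simulate_dataset()`** — log-normal LC-MS signals with planted
  interaction effects (fold 200), disjoint gene models on a 1 Mb linear
  chromosome, Poisson TSS reads with 1 nt 5'-end jitter over a uniform
  background, and expression tables with planted DE/salt-responsive
  genes. Deterministic per seed.

File-level drivers (`run_simulate()`, `run_metabolomics()`,
`run_tss()`, `run_de()`) read and write CSV/TSV/BED6/GFF3, and a thin
CLI wraps them (`inst/scripts/salt-omics`).

## Worked example

```r
library(saltomics)
cfg <- sim_config(seed = 42, n_features = 500, n_planted_diff = 25,
                  n_genes = 100, chromosome_length = 5e5, n_true_tss = 80,
                  n_planted_de = 30, n_planted_salt_up = 10,
                  n_planted_salt_down = 3)
sim <- simulate_dataset(cfg)

res <- call_differential_features(sim$lcms$table)
#> [saltomics] blank_filter         500 ->   500 features
#> [saltomics] rt_window            500 ->   500 features
#> [saltomics] signal_floor         500 ->   472 features
#> [saltomics] prefilter_fold       472 ->    25 features
#> [saltomics] oneway_fdr            25 ->    25 features
#> [saltomics] interaction_fdr       25 ->    25 features
#> [saltomics] interaction_fold      25 ->    25 features
head(subset(res$results, final_call)[, c("feature_id", "mode", "q1",
                                         "q_int", "max_fold")], 3)
#>    feature_id     mode       q1    q_int max_fold
#> 4      F00004 positive 1.19e-12 2.97e-11      262
#> 12     F00012 positive 4.18e-12 8.78e-11      318
#> 15     F00015 positive 1.19e-12 2.60e-11      219
```

28 features fall below the 10^7 floor in every sample; of the 472
remaining, exactly the 25 planted interaction features clear the 10x
prefilter, both ANOVA FDR stages and the 100x gate (`max_fold` is the
ratio between the extreme group means; the planted fold was 200).

```r
tss <- call_tss(sim$tss$fragments, sim$annotation)
table(tss$tss$classification)
#> antisense  internal    orphan  upstream
#>        14        12        52         2

calls <- classify_genes(sim$expression$expression)
sum(calls$is_de); table(calls$salt_class)
#> [1] 30
#> neither  salt_down  salt_up
#>      17          3       10
head(enrichment_test(calls$gene_id[calls$is_de],
                     sim$expression$annotation)[, c("category", "k", "K",
                                                    "fold_enrichment", "q")], 1)
#>                                 category  k  K fold_enrichment        q
#> 1 Inorganic ion transport and metabolism 18 27            2.22 2.58e-05
```

All 80 planted TSSs are recovered (the classification mix reflects the
random placement of TSSs relative to genes), all 30 planted DE genes
are called with their planted salt classes, and the category the
generator biases DE genes towards comes out enriched 2.2-fold at
q ≈ 3e-5.

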