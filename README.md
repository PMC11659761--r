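# agingscreen

An integrated pipeline for studying transcriptome aging in multi-tissue
bulk expression cohorts, written for analysts working with GTEx-style
tissue panels and GEO case/control or intervention series.

The questions it answers, stage by stage:

1. **Which genes change with age?** Per tissue, each gene's log2
   expression is correlated with donor age (Pearson). With the exact t
   transform `t = r·sqrt((n-2)/(1-r²)) ~ t(n-2)` giving a two-sided p,
   genes are called **up** aging genes when `r > 0, p < 0.05` and
   **down** aging genes under the stricter `r < 0, p < 0.01`.
2. **Which tissues age alike?** Tissues are compared by the Pearson
   correlation of their *aging signatures* (the per-gene r-vectors) and
   grouped by average-linkage hierarchical clustering on `1 − r`;
   per-group aging genes are the intersection of calls across a group's
   member tissues, with cross-cohort validation (called in ≥ k tissues
   and confirmed in ≥ 1 independent cohort).
3. **Does disease push aging genes further?** In an age-matched
   case/control cohort, the proportion of aging genes moved *further in
   their aging direction* (same-signed log2FC, Welch p < 0.05) is the
   **syntropy** of the disease with aging.
4. **Does an intervention reverse them?** In cohorts stratified by
   actigraphy (high > 2.1×10⁵ counts/day, moderate (1, 2.1]×10⁵), the
   proportion of aging genes significantly moved *opposite* to their
   aging direction in the high-vs-low contrast is the **rescue**
   proportion.
5. **Which cell types drive the change?** Bulk profiles are deconvolved
   into cell-type fractions by non-negative least squares against a
   signature matrix built from labeled single-cell profiles, and
   fractions compared between age bins (split at 60 years) or activity
   arms.
6. **What are the hits doing?** Any resulting gene set is tested for
   hypergeometric over-representation against a user-supplied GMT
   collection with BH adjustment.

A synthetic-data module generates multi-tissue aging cohorts, disease
and intervention cohorts, and cell mixtures with planted,
machine-readable ground truth, so the whole pipeline is testable
end-to-end without any downloads. See the methods vignette
(`vignettes/aging-transcriptome-pipeline.Rmd`) for the models,
parameter defaults and limitations.

## Worked example

```r
library(agingscreen)

# a 2000-gene hippocampus cohort, 150 donors aged 40-69, with 10% of
# genes planted as declining (-0.05 log2/yr) and 5% rising
cfg    <- sim_config(seed = 42, tissues = c(hippocampus = "group_i"))
cohort <- simulate_aging_cohort(cfg)

calls <- screen_tissue(cohort$expr$hippocampus, cohort$samples)
table(calls$call)
#> down none   up
#>  203 1655  142
head(subset(calls, call == "down"), 3)
#>          gene          r            p   n call
#> G00013 G00013 -0.4273167 4.936095e-08 150 down
#> G00016 G00016 -0.2193996 6.985061e-03 150 down
#> G00022 G00022 -0.5185194 1.070775e-11 150 down
```

203 down calls against 200 planted decliners: sensitivity is high at
this effect size (|r| ≈ 0.4) and the 0.5% null call rate contributes a
handful of false positives. An age-matched disease cohort with 40% of
aging genes planted as further deregulated, and an intervention cohort
with 40% of down genes rescued in the high-activity arm, are then scored
against the calls:

```r
dis  <- simulate_disease_cohort(cohort$truth, "group_i",
                                frac_syntropic = 0.4, n_per_arm = 50,
                                seed = 43)
case <- dis$samples$sample_id[dis$samples$condition == "case"]
ctrl <- dis$samples$sample_id[dis$samples$condition == "control"]
syntropy(calls, two_group_diff(dis$expr, case, ctrl), "down")
#> SyntropyReport [down]: 71 / 203 aging genes further downregulated (35.0%)

iv  <- simulate_intervention_cohort(cohort$truth, "group_i",
                                    frac_rescued = 0.4, n_per_arm = 50,
                                    seed = 44)
arm <- stratify_activity(iv$samples)
rescue(calls, two_group_diff(iv$expr, names(arm)[arm == "high"],
                             names(arm)[arm == "low"]), "down")
#> RescueReport [down aging genes]: 80 / 203 rescued (39.4%)
```

Both estimates sit within sampling error of the planted 40%. The full
pipeline (simulate → screen → group → validate → syntropy → rescue →
deconvolve → enrich) runs from one seeded config and writes every
intermediate table plus a checksummed manifest:

```r
m <- run_pipeline(pipeline_config(seed = 1), "out")
m$results$grouping_agreement   # adjusted Rand index vs planted groups: 1
```

A thin command-line wrapper with the same subcommands lives at
`inst/scripts/agingscreen.R`.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "agingscreen",
                               load_package = "installed")'
```

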