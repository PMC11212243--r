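# netrecur

Rare-variant recurrence + network-propagation gene prioritization for
sequenced disease cohorts **without a matched control population**.

Many rare-disease sequencing studies — the motivating case is a
whole-genome cohort of Ménière's disease, an inner-ear disorder of
episodic vertigo and fluctuating hearing loss — cannot run classical
gene burden tests because no control cohort exists. netrecur implements
the alternative: compare the cohort against public reference-panel
allele frequencies at the variant level, aggregate per gene, and
amplify the gene-level signal through a protein-interaction network.

## The method

1. **Unusually frequent variants (UFVs).** From an annotated cohort
   variant table, keep rare (reference AF ≤ 5% in every panel),
   damaging (not labelled benign by any predictor), protein-altering
   variants whose cohort allele frequency `AC/(2N)` exceeds 1.3× their
   reference frequency — or which are absent from the panel (novel).
2. **Recurrence.** Count distinct UFVs per gene; genes with ≥ 4 are
   "highly recurrent".
3. **Network propagation.** Seed a confidence-weighted interaction
   network with per-gene UFV counts and iterate the
   random-walk-with-restart fixed point
   `F = alpha * W F + (1 - alpha) * S` (symmetric degree-normalized
   `W`, `alpha = 0.5`). Calibrate each gene's score against an
   empirical null ensemble in which every patient keeps their mutation
   count but each mutation lands on a uniformly random gene:
   `z = (F - mean_null) / sd_null`.
4. **Prioritization.** Three gene sets: recurrence (`n_ufv >= 4`),
   network (`z > 3`), and their intersection — the high-priority set.
5. **Downstream.** Hypergeometric gene-set enrichment with BH control;
   diagnostic-panel curves (cumulative cohort recovery of the top-k
   ranked genes versus the Hardy–Weinberg expectation
   `1 - prod (1 - q_v)^2` for a general-population control); and
   cell-type expression-percentile comparison by Wilcoxon rank-sum
   tests.

A fully synthetic study generator (`simulate_study()`) with planted
disease genes, network module, gene sets and expression shifts supports
end-to-end validation against known truth.

## Worked example

```r
library(netrecur)

sim <- simulate_study(sim_config(n_samples = 300, n_genes = 500,
                                 n_disease_genes = 20, edge_prob = 0.02,
                                 module_factor = 15, rng_seed = 42))
fit <- netrecur(sim$variants, sim$network, n_samples = 300,
                n_null = 500, rng_seed = 42)
fit
#> Recurrence + network gene prioritization
#>   cohort: 300 samples, 1326 input variants
#>   rare damaging: 771; UFVs: 455 (59.0%) in 300 genes
#>   null ensemble: 500 replicates (seed 42, alpha 0.50)
#>   gene sets: recurrence (n_ufv >= 4) 10 | network (z > 3) 60 | intersection 8
```

Of 1326 observed variants, 771 survive the rare/damaging reduction and
455 (59.0%) are unusually frequent. Ten genes have ≥ 4 distinct UFVs, 60
have propagation z > 3, and 8 satisfy both. The high-priority genes with
their recurrence and z-scores:

```r
head(predict(fit, genes = fit$sets$intersection)[,
     c("gene", "n_ufv", "n_samples", "z")], 5)
#>     gene n_ufv n_samples         z
#> 1 G00244     5        21  8.372657
#> 2 G00165     4        58 28.737332
#> 3 G00247     4        42 20.354645
#> 4 G00321     4        30 15.123285
#> 5 G00450     4        29 13.034112

mean(fit$sets$intersection %in% sim$truth$disease_genes)  # precision
#> [1] 0.375
```

37.5% of the intersection set are true planted disease genes — against a
4% (20/500) random expectation. As a candidate diagnostic panel:

```r
ranked <- rank_genes_by_recurrence(fit$recurrence,
                                   genes = fit$sets$intersection)
panel_report(list(intersection = ranked), fit$ufv, sim$truth$samples)
#> Panel evaluation (cohort recovery vs Hardy-Weinberg control expectation)
#>   intersection: 8 genes; recovery 55.7% (control 23.9%) at k=8; reaches 50% at k=6
```

Six genes suffice to explain half the cohort, while the same variants
would flag an expected 24% of a general-population control — the gap is
the panel's discriminative value.

`coef()`, `residuals()`, `plot()` and `summary()` work as for other
fitted-model objects; `run_pipeline()` drives all stages from one YAML
config and writes every artifact plus a JSON run manifest. See
`vignettes/netrecur-methods.Rmd` for the model, parameter and generator
details.

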