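# paleosize

Body-size turnover analysis for regional extinction–recovery events.

`paleosize` is written for paleobiologists asking whether the species of a
clade that live in a region *after* an extinction event are larger, smaller,
or no different in body size than expected under unbiased turnover — and
whether individual survivor lineages changed size from their fossil
populations to today. The motivating setting is the Plio-Pleistocene
turnover of western Atlantic marine gastropods (~2 Ma, following closure of
the Central American Seaway), where ~70% of gastropod species went extinct
and origination later restored much of the lost richness, but the machinery
applies to any specimen-level size dataset with pre-extinction and modern
faunas.

## The method

Specimen shell lengths (mm, measured parallel to the coiling axis) are
aggregated into species-level size descriptors (mean, maximum, or a
pluggable "typical" size). For a clade with `N_f` pre-extinction and `N_m`
modern species, three bootstrap distributions of species-mean **log** sizes
are built with `B` draws each:

- **fossil resampled** — means of `N_f` species resampled with replacement
  from the pre-extinction pool;
- **test distribution** — means of `N_m` species resampled from the *same*
  pre-extinction pool: the **non-selective turnover null**, i.e. what the
  modern fauna would look like if extinction and origination were unbiased
  with respect to size while diversity changed as observed;
- **modern resampled** — means of `N_m` species resampled from the modern
  pool.

The mean of the modern resampled distribution is compared with the central
50% confidence window (25th–75th percentiles, linear-interpolation
quantiles) of the test distribution: inside → `no_change`, above →
`larger`, below → `smaller`. The rule is a descriptor with a ~50% null
flag rate by construction, not a significance test; the package's
synthetic-fauna module exists precisely to characterise its operating
behaviour (calibration, power, selectivity response).

Survivor lineages are compared population-vs-population on raw lengths with
pooled and Welch two-sample t-tests and a permutation t-test (exhaustive
when all label assignments are enumerable, Monte-Carlo otherwise), with
Bonferroni correction across the battery.

## Worked example

```r
library(paleosize)

# a turnover in which post-extinction origination skews large
scenario <- sim_scenario(n_species_pre = 20, base_survival = 0.3,
                         n_origination = 6, origination_shift = 0.6,
                         seed = 42)
fauna <- generate_fauna(scenario)
summaries <- summarize_species(fauna$records, typical_clades = character())
tab <- build_fauna(summaries, "SimClade", metric = "mean")
classify_turnover(tab, resample_plan(n_boot = 1000, seed = 1))
#> Non-selective turnover classification: SimClade (metric: mean size)
#>   N_f = 20 pre-extinction species, N_m = 9 modern species, B = 1000
#>   null 50% window: [3.3645, 3.6585] log units  (28.9 to 38.8 mm)
#>   modern resampled center: 3.7868 log units  (44.1 mm)
#>   decision: larger
```

The window says that under size-unbiased turnover, a 9-species modern
fauna drawn from this clade's fossil pool would have a mean size between
28.9 and 38.8 mm half the time; the observed modern fauna centers at
44.1 mm, above the window, so it is classified as larger than chance
expectation. Replicating the whole pipeline shows how often this scenario
is detected:

```r
decision_rates(scenario, resample_plan(seed = 1), n_reps = 200)
#> Turnover decision rates over 200 replicates
#>   larger     0.930
#>   smaller    0.000
#>   no_change  0.070
```

A survivor-lineage comparison on raw specimen lengths:

```r
pair <- lineage_pair("survivor",
                     fossil_lengths = c(21, 24, 26, 23, 25, 22, 27),
                     modern_lengths = c(18, 20, 17, 21, 19, 16))
run_lineage_battery(pair, alpha = 0.05, seed = 1)
#>   lineage  mean_fossil_mm mean_modern_mm t_pooled p_pooled  p_welch  p_perm
#> 1 survivor             24           18.5     4.86 0.000502 0.000458 0.00175
```

The modern population averages 5.5 mm shorter; all three tests agree the
change is real, and it stays significant after Bonferroni correction.

For real data, point the orchestration layer at a measurement CSV
(columns: species, clade, time bin, length in mm; mapping configurable via
`measurement_dialect()`):

```r
cfg <- ppwa_study_config("measurements.csv", outdir = "results")
cmd_all(cfg)   # species_summary.csv, turnover_results.csv, lineage_results.csv, ...
```

A thin command-line wrapper with the same verbs lives at
`inst/cli/paleosize.R`
(`Rscript paleosize.R turnover --input measurements.csv --outdir out --seed 1`).

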