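# galkinetics

Kinetic and single-cell modelling of *GAL1* induction in budding yeast.

When yeast cells are shifted from raffinose to galactose, the *GAL1* gene
switches from silence to strong expression. Comparing strains — say a
wild type against a chromatin mutant — requires separating three
phenotypes that a bulk induction curve confounds: the lag before
transcription begins, the speed of accumulation once it begins, and the
final expression level. At the single-cell level, a slow bulk response can
mean either that every cell responds slowly or that fewer cells respond
at all. `galkinetics` provides a matched pair of models that pull these
apart:

- **Bulk kinetics.** Relative mRNA follows `dM/dt = α − δM` after an
  onset time `x` (and is zero before it). Fitting this three-parameter
  model to a time course yields the activation time `x`, the steady-state
  level `α/δ`, the time to half steady state `x + ln2/δ`, and the
  activation-to-half interval `ln2/δ`, which isolates post-onset speed
  from lag.
- **Single-cell accumulation.** Each cell stays at a Normal background
  level until its own Gamma-distributed activation time, then accumulates
  reporter (Gal1-GFP) linearly at a Gamma-distributed per-cell rate. The
  six parameters are fitted to flow-cytometry snapshot distributions; the
  headline summaries are the mean activation time and the mean per-cell
  expression rate.

Everything is tidyverse-native: time courses and snapshots are tibbles,
fits have `tidy()` / `glance()` / `augment()` methods and `autoplot()`
ggplot output, and the pipeline composes with `dplyr`.

## Worked example

Simulate a wild-type-like strain, fit the kinetic model, and derive its
phenotypes:

```r
library(galkinetics)

presets <- strain_presets(seed = 1)
wt <- presets$wildtype

tc  <- make_mrna_dataset(wt)          # noisy synthetic induction course
fit <- fit_kinetics(tc, seed = 1)
fit
#> Induction-kinetics fit
#>   onset_time       3.67516
#>   production_rate  2.35897
#>   degradation_rate 2.61951
#>   RMSD 0.00861832 over 50 starts (seed 1)

derive_phenotypes(fit, strain = "wildtype", condition = "primary")
#> # A tibble: 1 × 6
#>   strain   condition activation_time steady_state_level time_to_half activation_to_half
#>   <chr>    <chr>               <dbl>              <dbl>        <dbl>              <dbl>
#> 1 wildtype primary              3.68              0.901         3.94              0.265
```

The preset's stated truth is activation at 3.41 h, steady state 0.9 and
half steady state at 3.90 h. The fit recovers the steady state and
time-to-half within a percent or two; the onset/degradation split is
only weakly identified at two-hour sampling with 5% noise (curves with a
slightly later onset and faster approach agree at the sampled points),
which is exactly the kind of design limitation the synthetic generator
makes visible. Comparison tables work on any set of phenotype rows:

```r
ref <- gal1_reference_phenotypes()    # bundled published strain metrics
relative_to_reference(ref[ref$condition == "primary", ], "HTZ1") |>
  dplyr::filter(metric == "time_to_half")
#>   htz1_delta        154.7   (i.e. 54.7% longer than wild type)
#>   htz1_K3.8.10.14R  160.2
percent_change(ref[ref$condition == "primary", ],
               ref[ref$condition == "secondary", ])
#>   time_to_half drops by 93.7% (HTZ1), 89.3% (htz1_delta), ... on reinduction
```

Single-cell side — simulate snapshots, fit the six-parameter model, and
gate:

```r
obs <- make_flow_dataset(wt)                        # 0/2/4/6 h snapshots
ffit <- fit_flow_model(obs, flow_fit_config(profile = "reduced", seed = 2))
ffit$mean_activation_time   # ~4.2 h
ffit$mean_expression_rate   # ~2.2 counts/h
ffit$param_ranges           # min–max over the top-k restarts

thr <- set_gate_threshold(obs$intensity[obs$time == 0])
gate_summary(obs, thr)      # induced fraction + geometric mean per time
```

A full batch run — generate, fit, derive, write artefacts — is one call:

```r
run_pipeline(list(out_dir = "out", seed = 1, reference = "wildtype",
                  scenarios = strain_presets(seed = 1)))
```

which writes the datasets, fits (flat JSON), phenotype and comparison
tables (CSV), and a `run_log.json`; reruns with the same seed are
byte-identical.

## License

MIT.
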