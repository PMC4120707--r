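# gazecue

Analysis tools for trinomial gaze-categorization experiments in which head
orientation biases the perceived direction of another person's gaze.

When observers judge eye gaze as "left", "direct" or "right", a rotated
head pulls the judgment in two opposing ways: the changed iris/sclera
geometry of the visible eye region *repels* perceived gaze away from the
head, while the head itself acts as a direct cue that *attracts* perceived
gaze toward its orientation (the Wollaston effect).  `gazecue` implements
the dual-route analysis that separates these effects, together with a
generative observer for simulation and parameter-recovery studies.  It is
aimed at visual psychophysicists running (or reanalysing) gaze
categorization experiments and at anyone who wants a tested reference
implementation of the cue-weight algebra.

## The model in brief

With eye deviation `E` and head orientation `H` (degrees, positive =
observer's right), responses recoded left = 0, direct = 0.5, right = 1 are
fitted per head orientation with a logistic; its 50% point is the eye
deviation of subjectively direct gaze.  The slope `m` of those points
against `H`, with the two cue weights constrained to sum to one, gives

    G = (1 / (1 - m)) E + (m / (m - 1)) H

A negative head weight is repulsion.  Fitting `m` separately with the
whole head visible (`m_WH`) and with only the eye region visible (`m_ER`)
decomposes the whole-head percept into the two routes:

    G_WH = ((1 - m_ER) / (1 - m_WH)) G_ER + ((m_WH - m_ER) / (m_WH - 1)) H

so the direct (attractive) route weight is positive exactly when hiding
the head context strengthens the repulsion.  A two-criterion Gaussian
categorization model (criteria `b_L < b_R`, sensory noise `sigma_rep`) is
fitted to the same counts by maximum likelihood, yielding the peak and
width of the "cone of direct gaze" plus the data-side centroid of direct
responses.

## Worked example

Simulate 20 observers in the default regime (eye-route head weight
−0.25 ± 0.05, direct head weight 0.15 ± 0.05, bias −1°, σ = 3°, criteria
±4°) through the full 1,080-trial blocked design, then run the whole
analysis chain:

```r
library(gazecue)
cfg <- pipeline_config(
  design = design_spec(seed = 42),
  population = population_spec(n_observers = 20, seed = 42))
report <- run_pipeline(cfg)
report$decomposition_group
#> <dual_route_decomposition> m_WH = 0.0647, m_ER = 0.1938
#>   eye-region route weight: 0.8620
#>   direct head route weight: 0.1380
report$t_tests
#>   weight        mean t_statistic    df  p_value cohen_d     n
#> 1 whole_head -0.0789       -2.89    19 9.29e- 3  -0.647    20
#> 2 eye_region -0.241       -15.4     19 3.40e-12  -3.45     20
#> 3 direct_cue  0.132         8.42    19 7.80e- 8   1.88     20
```

Reading the output: the group-average direct-gaze points shift with head
orientation about three times more steeply when the head context is hidden
(`m_ER = 0.194` vs `m_WH = 0.065`), i.e. the head weight is negative
(repulsive) in both conditions and larger in magnitude for the eye-region
condition (−0.241 vs −0.079).  The decomposition attributes the difference
to a positive direct route with weight 0.138 — close to the generative
population mean of 0.15, which is exactly what the recovery study is
checking.  `report$recovery` tabulates bias and RMSE per parameter, and
`plot_direct_gaze(report$psychometric_subject)` shows the fitted points
with their regression lines.

A thin command-line wrapper over the same functions lives in
`inst/scripts/gazecue-cli.R` (subcommands `design`, `simulate`, `run`).

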