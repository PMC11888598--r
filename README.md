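# socattn

Analysis pipeline linking **multi-dimensional social relationships** to
**social attention** in a small primate group, written for behavioral
neuroscientists and social-network researchers who want the full chain — raw
interaction logs and eye traces in, fitted engagement weights and robustness
statistics out — as tested, reproducible code.

## The science in brief

A group of macaques housed together develops differentiated relationships
along three dimensions: aggression, grooming, and proximity. Each dyad and
dimension is scored dichotomously: the animal that approaches more, receives
more grooming, or initiates aggression more scores **+1**, its partner
**−1**, and both score 0 with no (or tied) interactions. The scores form
antisymmetric matrices *A*, *G*, *P*, combined by weighted linear indices:

- **SEI** (social engagement index), per subject *s*:
  `SEI(s) = ω_a ΣA_si + ω_g ΣG_si + ω_p ΣP_si` — general social tendency;
- **IEI** (individual engagement index), per directed dyad:
  `IEI_s(p) = ω_a A_sp + ω_g G_sp + ω_p P_sp` — engagement with one partner.

Attention is measured in a visual orienting task with face distractors.
Saccades are detected on 1 kHz eye traces by joint velocity/acceleration
thresholds (50 °/s, 500 °/s²). Per cell, **drifting time** is
`DT = RT_face − RT_scrambled`; per subject-day, **distractor bias** is
`DT_incongruent − DT_congruent` — the scalar measure of attentional capture.
The weights ω are fitted by exhaustive grid search over {0, 0.02, …, 1}³,
choosing the extreme Pearson correlation between bias and index (most
negative for SEI, most positive for IEI). Robustness comes from re-analyzing
all 3⁴ × 3⁴ = 6561 ways of withdrawing one in-group and one out-group face
per subject (Wilcoxon signed-rank per combination), and a saline/oxytocin
contrast compares paired biases, weights, and slopes across conditions.

Because the underlying colony video and eye recordings are not distributed,
the package ships a **synthetic-study generator** with known ground truth
(weights ω*, coupling slope *b*, condition multipliers); every stage is
validated by parameter recovery. See the methods vignette
(`vignettes/social-attention-engagement.Rmd`) for the generative model and
all numerical choices.

## Worked example

```r
library(socattn)

cfg   <- study_config()                       # default study conditions
study <- gen_full_study(cfg, seed = 1, conditions = FALSE)

study$matrices$aggression
#> Interaction score matrix (aggression, mode=count)
#>    MA MK ML MC
#> MA  0 -1 -1 -1
#> MK  1  0 -1 -1
#> ML  1  1  0 -1
#> MC  1  1  1  0

compute_sei(study$matrices, c(1, 1, 1))       # equal-weight SEI, sums to 0
#> MA MK ML MC
#> -1  1 -5  5

dt   <- drifting_time_table(study$trials)     # DT per (subject, day, face, congruency)
bias <- distractor_bias_table(dt, group = "in")
head(bias, 3)
#>   subject day group  bias_ms
#> 1      MA   1    in 19.95256
#> 2      MA   2    in 26.78452
#> 3      MA   3    in 26.58814

grid_search_weights(bias, study$matrices, "sei", step = 0.02)
#> grid search (SEI, most_negative_r, step 0.02): best r = -0.9770 at
#>   (0.54, 0.16, 0.92); 1 tie(s), 132650 grid points (0 screened)
#> linear fit: slope -19.52, intercept 40.19, r = -0.9770, p = 1.6e-32, n = 48

withdrawal_robustness(distractor_bias_by_face(dt), alpha = 0.05)
#> image-withdrawal robustness: 6561/6561 evaluable combinations significant
#>   at alpha=0.05 (100.00%); 0 unevaluable
```

The recovered weight triple (0.54, 0.16, 0.92) is closely aligned with the
generator's ground-truth direction ω* = (0.5, 0.25, 1.0) (cosine ≈ 0.995):
distractor bias decreases with engagement at about the configured −26 ms per
index unit, scaled by the in-group effect. The robustness report says the
simulated in-group < out-group gap survives every stimulus-withdrawal
combination.

## Repository layout

- `R/` — the package: interaction scoring, gaze metrics, engagement models
  and grid search, robustness/condition statistics, the synthetic-study
  generator, and `run_pipeline()`.
- `analysis/01_simulate.R … 06_condition_contrast.R` — numbered drivers that
  run the full analysis on a simulated study and write tables under
  `results/` (run them from the repository root, in order).
- `tests/testthat/` — unit, property, and acceptance suites.
- `scripts/acceptance.R` — see below.

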