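---
title: "Linking multi-dimensional social relationships to social attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking multi-dimensional social relationships to social attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socattn)
```

## The problem and the model

A small group of rhesus macaques living together develops a differentiated
social structure along (at least) three behavioral dimensions: **aggression**,
**grooming**, and **proximity**. `socattn` implements a quantitative pipeline
that (i) reduces directed interaction logs to dichotomous per-dyad scores,
(ii) measures each animal's attentional capture by conspecific face images in
a visual orienting task, and (iii) links the two with linear engagement
indices whose dimension weights are fitted by exhaustive grid search.

### Interaction scoring

For each unordered dyad and each dimension, the member on the "winning" side
of the directed comparison scores $+1$ and the other $-1$; no interactions, or
a tie, scores $0/0$. Direction semantics differ by dimension: the +1 goes to
the animal that *approaches* more (proximity), *receives* more grooming
(groomee), or *initiates* aggression more. In the event-log representation the
actor is always the initiator — for grooming the actor is the groomer — so the
grooming credit runs against the actor direction; `score_dyad()` encodes this
explicitly because it inverts the convention of the other two dimensions.
Scores per dimension assemble into an antisymmetric matrix $S$ with
$S_{ij} \in \{-1, 0, 1\}$, $S_{ii} = 0$, $S = -S^\top$, so every score matrix
sums to zero.

Two comparators are supported: event **counts** (default) and total
**durations** (`mode = "duration"`), because field practice mixes both —
approaches are naturally counted while aggressive engagements are naturally
timed. The choice is a per-dimension switch in `build_score_matrices()`; the
package does not claim either as canonical, and ties score $0/0$ under both
(a tie satisfies neither strict direction).

### Engagement indices

With weights $\omega_a, \omega_g, \omega_p \in [0, 1]$,

$$\mathrm{SEI}(s) = \omega_a \sum_i A_{si} + \omega_g \sum_i G_{si}
  + \omega_p \sum_i P_{si},$$

the weighted sum of subject $s$'s score row-sums over all partners — a
summary of *general* social tendency; and for a directed dyad,

$$\mathrm{IEI}_{s}(p) = \omega_a A_{sp} + \omega_g G_{sp} + \omega_p P_{sp},$$

the same combination of the single dyadic scores — *individual* engagement
with a specific partner. Antisymmetry makes the SEIs sum to zero over the
group for any weights, and makes IEI antisymmetric in its arguments under
equal weights; both properties are exercised in the test suite.

### Attention statistics

In the orienting task a central fixation target jumps to $\pm 14^\circ$,
preceded 50 ms earlier by a 100 ms distractor flash at $\pm 18^\circ$ —
congruent (same hemifield) or incongruent. Within a (subject, day, face,
congruency) cell the **drifting time** is
$\mathrm{DT} = \overline{RT}_f - \overline{RT}_s$, the mean response time with
the intact face minus that with its scrambled counterpart, and the
**distractor bias** for a subject-day is
$\mathrm{DT}_{\mathrm{incon}} - \mathrm{DT}_{\mathrm{con}}$, averaging DTs
over the faces of the requested group (in/out/all). A worked numerical
example: cell means of 125.25/142.80 ms (congruent intact/scrambled) and
228.19/213.97 ms (incongruent) give $\mathrm{DT_{con}} = -17.55$,
$\mathrm{DT_{incon}} = +14.22$, bias $= 31.77$ ms; the test suite asserts this
arithmetic exactly.

Saccades are detected on 1 kHz traces by joint thresholds: velocity
$\ge 50^\circ/\mathrm{s}$ **and** acceleration
$\ge 500^\circ/\mathrm{s}^2$ at the onset sample, with the offset at the
first sample back below the velocity threshold. Trials with a saccade in the
500 ms before distractor onset are discarded (half-open interval
$[\mathrm{onset} - 500, \mathrm{onset})$; a saccade exactly at the reference
counts as post-onset). Response time is measured from target relocation to
the onset of the first saccade landing within $\pm 2^\circ$ of the target —
the same half-width as the fixation window. Trials slower than the 300 ms
reward deadline are flagged unrewarded and, by default, excluded from RT
averages; `exclude_unrewarded = FALSE` retains them. Both behaviors are
supported deliberately: deadline handling is an analysis choice, and with
strong simulated effects the deadline can censor the slow tail (the
acceptance script retains such trials in its oxytocin contrast for exactly
that reason).

### Weight grid search

`grid_search_weights()` evaluates the Pearson correlation between bias and
index at every weight vector on the grid $\{0, 0.02, \dots, 1\}^3$ (132,650
points after dropping the all-zero vector) and reports the extreme under the
stated objective — most negative $r$ for SEI, most positive for IEI, the two
conventions used in this analysis; both are overridable. Because a linear
index rescales without changing $r$, exact positive scalings of a grid point
are exact ties: ties (within $10^{-9}$ on $r$) are collected and a canonical
representative is chosen as the member with the largest component sum,
breaking residual ties lexicographically on
$(\omega_a, \omega_g, \omega_p)$ descending. This makes the reported triple
reproducible; its overall scale is a convention, so recovery is judged by
*direction* (cosine similarity). Weight vectors whose index is constant
across the paired observations have no defined correlation and are screened
from the surface.

The vectorized search reduces each grid column to per-unit sufficient
statistics (there is one SEI per subject and one IEI per dyad, repeated over
days), which makes the full 0.02 grid cost a few hundredths of a second; a
naive triple-loop oracle in the test suite must agree with it to $10^{-12}$.

Correlations are computed at the (subject $\times$ day) level — biases are
defined per experimental day, giving $4 \times 12 = 48$ points per condition
— and $p$-values come from the $t$ distribution with $n - 2$ degrees of
freedom at that unit. We note that with $n = 48$ a correlation of
$|r| \approx 0.87$ cannot produce $p$-values as small as some reported in
this literature ($\sim 10^{-88}$), which would require trial-level units;
this package computes and reports $p$ at the subject-day level only.

## Robustness and condition contrasts

The in-group/out-group bias gap could be driven by single images, so the
pipeline re-analyzes after withdrawing one in-group and one out-group face
per subject in every combination — $3^4 \times 3^4 = 6561$ for four subjects
with three faces per side. Per combination, subject-day biases are recomputed
from the retained faces and the in/out difference is tested with a two-sided
Wilcoxon signed-rank test paired by (subject, day), pooled across subjects
(the pairing unit is an analysis choice; pooling uses all 48 pairs and is the
default here). The summary statistic is the fraction of combinations with
$p < \alpha$; no multiplicity correction is applied because that fraction is
itself the quantity of interest. Combinations with fewer than two evaluable
pairs are excluded from the denominator and counted. The signed-rank test is
computed directly (exact via the signed-rank distribution for $n \le 25$
without ties; normal approximation with continuity and tie correction above,
matching `stats::wilcox.test`) so that thousands of combinations run in
seconds; equivalence with `wilcox.test` is verified in the tests. Under
`alpha = 1` every evaluable combination counts as significant, including
those whose $p$ is exactly 1.

The saline/oxytocin contrast pairs subject-day biases across conditions
(paired two-tailed $t$), and compares grid-search results via per-dimension
weight change ratios $(\omega_{OT} - \omega_{sal})/\omega_{sal}$ (undefined
where the saline weight is zero) and the slope pair. Because fitted slopes
scale with the norm of the weight vector, a *scale-free* slope ratio should
be computed with both conditions fitted at a common weight vector (e.g. the
saline canonical weights); `condition_contrast()` accepts either grid-search
results or plain `fit_line()` results for this purpose.

## The synthetic-study generator

No raw colony video or eye data are distributed, so the generator produces
complete studies from a known generative model; every pipeline stage is
validated by parameter recovery against that ground truth. The defaults are
fixed study conditions, chosen once:

* **Colony**: 4 subjects, 3 out-group faces, dominance orders per dimension
  chosen so the three score row-sum vectors are linearly independent (rank 3
  — otherwise weights are unidentifiable even in principle; the rank is
  asserted in the tests). Directed interaction rates 6/h (dominant direction)
  vs 2/h over 20 two-hour observation sessions: Poisson counts at this
  separation resolve every dyad's direction with near certainty.
* **Task**: 12 experimental days, 15 sessions/day of 50 trials (48
  interference + 2 visuomotor, the 96%/4% mixture), distractors drawn with
  equal chances from the subject's 12 stimuli (3 in-group + 3 out-group
  faces, intact or scrambled).
* **RT model**: scrambled-trial means 143 ms (congruent) and 214 ms
  (incongruent) — the worked example's scrambled cell means — with trial
  noise SD 40 ms, in the 30–49 ms range of the example cells. Intact-face
  trials shift by $\mp F/2$ (congruent faster, incongruent slower), so the
  bias pipeline recovers exactly $F$.
* **Coupling**: $F = a + b \cdot \mathrm{Index} + \varepsilon_{day}$ with
  $a = 55$ ms, $b = -26$ ms per index unit, ground truth
  $\omega^* = (0.5, 0.25, 1.0)$, and day jitter $\varepsilon_{day}$ scaled as
  a fraction (default 0.1) of the SD of the signal component. The coupling
  index is SEI by default; `coupling_index = "iei"` couples each in-group
  face's effect to $\mathrm{IEI}(s \to \mathrm{depicted})$, leaving out-group
  faces at the intercept — the configuration used for IEI recovery tests.
  The full dominance orders make the synthetic SEIs span a wider range than
  a real colony's, so default biases span roughly $-15$ to $140$ ms rather
  than the few-tens-of-ms range typical of real data; the linear coupling,
  which is what the fits estimate, is unaffected.
* **Groups and conditions**: in/out-group effect multipliers 0.8/1.2 (the
  out-group gap), and oxytocin modeled as multiplicative changes: slope
  $\times 2.3$ and weight multipliers $(2, 0.5, 1)$ — amplified aggression,
  blunted grooming — mirroring how condition effects are reported (slopes
  and weight change ratios), not a mechanistic RT model.
* **Eye traces**: fixation noise SD $0.02^\circ$ (search-coil grade),
  minimum-jerk saccades with duration $21 + 2.2 A$ ms so peak velocity
  scales with amplitude (main-sequence-like), capture probabilities 0.4
  (intact) / 0.15 (scrambled), 2% fixation-break rate.

What the generator does **not** emulate: sequential/fatigue effects within a
day, non-Gaussian RT tails, anticipatory or express saccades, vertical or
torsional eye movements, blink artifacts, and any nonlinearity in the
engagement–attention coupling. Passing recovery tests therefore demonstrates
that the pipeline is correct and well calibrated under its own model class,
not that real data satisfy that model.

## Numerical choices

* **Velocity filtering**: the 25 Hz first-order low-pass (the analog
  differentiator's characteristic) is applied with `signal::filtfilt`, i.e.
  forwards and backwards. Zero-phase filtering is the standard for offline
  saccade analysis because a causal first-order filter delays the velocity
  signal by $\sim 6$ ms and would bias every onset; the filter order is a
  parameter so a second-order variant can be swapped in.
* **Onset ground truth**: a minimum-jerk saccade crosses the
  $50^\circ/\mathrm{s}$ threshold a few ms after movement onset by
  construction, so detector accuracy is measured against detection on the
  paired noiseless trace; at the default noise the noise-induced onset error
  stays within 2 ms (and in practice within 1 ms), with zero false positives
  on fixation-only traces.
* **Degenerate inputs**: empty analysis cells raise errors naming the cell;
  grid points with zero index variance are screened; an all-screened grid
  (e.g. all-zero matrices) is a hard error; exact zero-variance paired
  differences in the condition contrast return $t = 0, p = 1$ (no
  difference) or $p = 0$ (exact nonzero shift) rather than `NaN`.
* **Determinism**: all generators take a seed, restore the caller's RNG
  state, and are byte-identical across runs; the pipeline manifest records
  MD5 hashes of every output so reproducibility is checkable.

## Problem sizes used in the checks

The test suite and the acceptance script regenerate everything they measure:
weight recovery uses 200 (tests) or 50 (script) replicate studies of 48
subject-day biases each at the full 0.02 grid; saccade-onset accuracy uses
1,000 synthetic saccades plus 1,000 fixation-only traces; the withdrawal
analysis always enumerates all 6,561 combinations, with 10 replicate null
studies for the calibration check. These sizes were chosen so the complete
suite runs in a few minutes on one core while leaving the binomial/Monte
Carlo tolerances meaningful.

## Known limitations

* Weights are only identified up to positive scale; reported triples are
  grid conventions, and comparisons across fits must be direction-based or
  use a common weight vector.
* With four subjects the SEI takes four distinct values; the subject-day
  correlation therefore mixes between-subject structure with day-level
  noise, and its $p$-values should be read accordingly.
* The Wilcoxon pairing unit (days within subject vs pooled) is not uniquely
  determined by the design; the package pools and documents the choice.
* The IEI analysis pairs biases toward in-group faces only; out-group faces
  have no dyadic interaction history, so no IEI is defined for them.
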