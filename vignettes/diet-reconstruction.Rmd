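---
title: "Reconstructing herbivore diets from fatty acid signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing herbivore diets from fatty acid signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qfasadiet)
```

## The problem

Quantitative fatty acid signature analysis (QFASA) estimates what an animal
has been eating from the fatty-acid composition of its stored triglycerides.
Because interconverting fatty acids is energetically costly, animals tend to
deposit dietary fatty acids with limited modification, so stored fat carries
a time-integrated record of diet. `qfasadiet` implements the approach for a
terrestrial study system: plateau pika on the Qinghai-Tibetan plateau in
winter, with three candidate foods (grass, roots and yak feces) sampled at
three elevation sites, and laboratory mice as a negative control. The
headline ecological question is coprophagy: what fraction of the pika's
stored fatty acids derives from yak feces.

## The model

A fatty-acid *signature* is a vector of concentrations in ug fatty acid per
mg sample. Let $\mu_k$ be the mean signature of food $k$ and $y$ the
consumer's stored-fat signature, both restricted to a fitting subset of
fatty acids. For diet proportions $p$ on the simplex the predicted stored
fat is, per fatty acid $i$,

$$\hat{y}_i(p) = c_i \sum_k p_k \mu_{ki},$$

where $c_i$ is a per-fatty-acid *calibration coefficient* absorbing
differential digestion, interconversion and deposition ($c_i = 1$ means no
discrimination). The fitted diet minimizes the summed absolute deviation

$$D(p) = \sum_i |\hat{y}_i(p) - y_i|,$$

and the minimum is the *best model deviation* (BMD, ug/mg). The model
assumes (i) no discrimination between absorbed and excreted fatty acids,
(ii) no post-absorption interconversion and (iii) no discrimination between
storage and oxidation; the calibration stage exists precisely because these
assumptions are violated in practice.

The optimizer is an exhaustive enumeration of every grid diet whose
proportions are multiples of a step (default 0.01, i.e. 1% resolution —
5151 candidate diets for three foods). Exhaustive search is deliberate: the
objective is piecewise linear and cheap, the grid matches the integer
percentages a field study reports, and the full scan yields the
*uniqueness profile* for free (below). The enumeration kernel is written in
C++ so that fine grids (down to step 0.001) and repeated simulation remain
fast. Ties are broken toward the lexicographically smallest proportion
vector in canonical source order, and the tie count is reported.

## Fatty-acid subset and comparability scaling

Stored fat concentrates a subset of the dietary fatty acids, so fitting is
restricted to acids that are well represented in fat. The rule implemented
in `select_shared_fas()` keeps every acid whose unweighted mean across the
consumer species' mean signatures strictly exceeds 5.0 ug/mg; on the
bundled pika and mouse fat means this selects ten acids (12:0, 14:0, 15:0,
16:0, 16:1, 17:0, 18:0, 18:1, 18:2, 18:3n3).

Food subset totals differ across foods (roughly 850-1050 ug/mg here) while
deviations are reported in ug/mg, so by default every signature is compared
on a common subset total: foods are rescaled to the observed fat's subset
total and the mixture prediction is rescaled again after the calibration
coefficients are applied. The rescaling makes calibration vectors
identifiable only up to a common positive factor, which is the natural
identifiability class for coefficients derived as observed/predicted
ratios. Raw-units fitting (`rescale = FALSE`) is available; for signatures
already on a common total the two modes coincide.

## Calibration coefficients as outputs

Feeding trials to measure calibration coefficients were not feasible for
this system, so coefficients are derived from the data: one randomly
selected *index animal* per site (seeded, reproducible) is fitted with all
coefficients at 1; the coefficient vector $c_i = y_i / \hat{y}_i$ that
would make that fit perfect is computed; and the unlogged vectors are
averaged arithmetically across index animals (geometric averaging is
offered as an option). The cohort is then refitted with the averaged
vector — the package's two-pass pipeline.

Two caveats are intrinsic to this construction and documented rather than
hidden. First, a judicious coefficient vector can make *any* diet fit
perfectly, which is why the derivation is anchored to unity-coefficient
fits and a negative control. Second, the derivation is only *locally*
identifiable: the unity fit's discrete argmin is stable under small
distortions, and in that regime the derived vector is proportional to the
true one (our recovery tests use coefficient distortions on the same 2-5%
scale as the within-site food variability, and verify recovery within the
effect of a few grid steps). Under strong discrimination the unity-fit
diet itself shifts, biasing the derived coefficients; simulations with
paper-scale distortions show the refit still reduces mean BMD sharply, but
per-coefficient recovery degrades. Validation of the refined diets
therefore leans on the BMD reduction and the negative control, not on
coefficient point values.

## Negative control

Because the fit is unconstrained, it produces *some* diet for any
consumer, including one that never ate the candidate foods. The package
compares BMD distributions between target consumers and controls with a
two-sample t-test (Welch by default, as the conservative choice for groups
of 5-8; Student's pooled-variance test by flag). Credibility requires
control deviations to be much larger; in the bundled system the mouse
control is separated mainly by its 18:1-rich, 18:3n3-free fat. On
synthetic cohorts at 2% consumer noise, control mean BMDs (~780 ug/mg on a
1000 ug/mg subset total) exceed target mean BMDs (~110) several-fold,
reproducing the direction and rough magnitude of the real contrast.

## Uniqueness diagnostics

For each source the profile curve reports the minimal deviation attainable
with that source's proportion fixed at each grid value. A well-posed fit
shows a single sharp valley; a near-optimal proportion (within 1% of the
global minimum, with an absolute floor for exact fits) lying farther than
10% of the axis from the best proportion flags a non-unique solution.
Exactly collinear sources produce a fully flat exchange direction and are
always flagged; synthetic pika-like cohorts are not flagged, matching the
absence of multiple solutions in the real analysis.

## The synthetic-data generator

`scenario_config()` fixes the study conditions: three sites; mean food
signatures seeded from the bundled reference table; 8 field replicates per
source and site; replicate coefficients of variation drawn uniformly from
2-5% per fatty acid (the consistency observed for real food sources);
structural zeros (e.g. 13:0 outside feces) preserved exactly; 20 consumers
in site blocks of 8/7/5 whose default diets are the per-site mean diets of
the calibrated analysis; a true calibration vector (all 1 unless
configured); and 2% multiplicative consumer noise. The consumer noise
default is an assumption — no within-animal adipose variance is reported
for the real system — chosen at the low end of the food-replicate
variability scale. Noise is Gaussian, multiplicative and truncated at
zero, chosen because replicate sds scale roughly with means in the
reference table.

Generated consumers live on the fitting subset directly: each food mean is
restricted to the subset and rescaled to a common total before mixing, so
a zero-noise cohort is an exact grid mixture and recovery is testable
against ground truth. What the generator does *not* emulate: real adipose
signatures carry mass outside the ten fitting acids, true physiological
discrimination is not a static multiplicative vector, and food replicates
in the field can covary within a site. Passing recovery tests therefore
demonstrate correctness of the estimator under its own model, not field
accuracy.

## Numerical choices

* Grid step 0.01 by default; any step that divides 1 exactly is accepted.
* Tie tolerance $10^{-9}$ ug/mg on deviations; tie counts reported.
* Signature validation rejects negative or non-finite concentrations and
  duplicate labels; absent acids are zero-filled (true structural zeros).
* Canonical fatty-acid order (carbon, then double bonds, then omega
  series) makes all tabular output deterministic.
* All generators take explicit seeds, restore the caller's RNG state, and
  are bit-reproducible; index-animal selection requires a seed.

## Validation problem sizes

The shipped checks run, among others: exact reproduction of the two-food
worked examples; equivalence of the grid minimum with an exact
least-absolute-deviation linear program on 100 random instances (2-3
sources at step 0.001, 4 sources at step 0.004, 6-10 fatty acids) within
the deviation change achievable by rounding the LP optimum onto the grid;
zero-noise cohort recovery within one grid step; calibration-vector
recovery at 2%-scale distortions; noise-degradation monotonicity over
three noise levels with 50 paired replicates; and bit-identical reruns of
the full pipeline under a fixed seed.

## Limitations

Diet proportions are reported without sampling uncertainty (no bootstrap
over food replicates); the uniqueness profile is the only per-animal
diagnostic. Calibration coefficients carry no uncertainty intervals and,
as discussed, are biased under strong discrimination. The package starts
from concentration tables; chromatogram processing, peak integration and
FAME identification are out of scope.
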