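---
title: "Methods: quantifying dimorphic courtship, calcium responses, oviposition preference and input budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying dimorphic courtship, calcium responses, oviposition preference and input budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flydimorph)
```

`flydimorph` packages four analysis pipelines used to characterize
sexually dimorphic behavior and circuitry in *Drosophila melanogaster*:
rule-based courtship quantification from two-fly pose tracks,
stimulus-aligned calcium-trace analysis, two-choice oviposition
preference scoring, and synaptic input-budget analysis of connectome
synapse tables. Each pipeline is paired with a seeded synthetic
generator that plants known ground truth, so every stage can be
validated end to end without raw videos or database downloads. This
vignette documents the models, the parameters that matter, the numerical
choices, and what the synthetic validation does and does not show.

## Courtship quantification

### Geometry

Pose tracks arrive as one row per (frame, fly): centroid position in mm,
heading in rad (counter-clockwise from +x), and the two wing angles in
rad measured from the body axis. From a frame-aligned male/female pair,
`pair_features()` derives:

* **facing angle** — the angle between the male's heading vector and the
  centroid-to-centroid displacement, in $[0, \pi]$;
* **distance to other** — the Euclidean centroid distance;
* **egocentric position** — the female's position rotated into the
  male's frame (`rel_x` forward, `rel_y` to his left), with
  `other_side` given by the sign of `rel_y`;
* **wing extrema** — the lesser and greater of the two wing angles.

All features are frame-local; frames with a missing partner, or
coincident centroids (undefined bearing), propagate `NA` rather than
erroring, and are excluded from every downstream denominator. The
facing angle is computed from the centroid, which is the definition
video trackers export; a head-point variant would differ only at very
short distances.

### Wing-state rules

Wing extension states are classified by fixed thresholds at
$15^\circ = 0.26$ rad and $35^\circ = 0.61$ rad, all inequalities
strict:

* *bilateral*: lesser wing angle $> 0.26$;
* *unilateral*: greater wing angle $> 0.61$ while the lesser is
  $< 0.26$;
* *ipsilateral*: the wing on the female's side of the body axis is
  $> 0.61$ (left wing while she is left, right wing while she is
  right); *contralateral* is the crossed case.

Bilateral and unilateral are mutually exclusive by construction; frames
satisfying neither are "no extension". A female exactly on the body
axis (`rel_y == 0`, a measure-zero event) counts as neither ipsi- nor
contralateral. The **wing choice index** is
$(t_{ipsi} - t_{contra}) / (t_{ipsi} + t_{contra})$, undefined when no
wing extension occurred.

### Initiation, masking and summaries

Copulating frames carry no courtship information, so the label table is
truncated at the first copulation frame (`mask_copulation()`).
**Courtship initiation** is the first frame at which the male has shown
any courtship behavior other than facing for a cumulative 3 s within a
6 s sliding window; window lengths are converted to frames with
`round()` (ties to even). The rule pins down a qualifying *window*, not
a frame; we report the first positive frame inside the earliest
qualifying window, the earliest defensible onset. Recordings shorter
than one window are evaluated over the available frames and flagged.

All summary metrics (`courtship_summary()`) are computed over the
courtship period — post-initiation, pre-copulation frames: the
courtship index (percent of frames showing *any* courtship behavior,
facing included — the exclusion of facing applies only to the
initiation rule), per-behavior indices, bilateral/unilateral indices,
bilateral bout rate and mean bout length (bouts are maximal runs of the
per-frame state, found by run-length encoding; missing frames break a
run), wing choice index, mean facing angle, mean and minimum distance.
Males that never initiate are returned with missing metrics and an
`initiated = FALSE` flag so they can be excluded rather than silently
zeroed. The 60-minute assay horizon is a configuration default of the
survival analysis, not hard-coded anywhere.

`relative_position_heatmap()` bins the female's egocentric position
over frames with a given wing flag into occurrence counts (not
densities); out-of-range or missing positions accumulate in a separate
overflow count so that counts + overflow always equals the number of
flagged frames.

### Synthetic courtship pairs

`sim_courtship_pair()` emulates tracker output: the female walks at
constant speed with a wrapped-random-walk heading; the male does the
same, plus a proportional steering term toward the female
(`pursuit_gain`, 1/s) during scheduled bouts. Confinement uses specular
reflection at the arena wall — position folded across the wall normal
and heading reflected — because that rule preserves the uniform
position-by-heading invariant measure of the confined walk: with
pursuit off, the male's facing angle is uniform and he faces the female
at chance (0.5), a property the tests verify by simulation. (The
simpler "refuse the step" rule was rejected: it traps flies at the wall
facing outward and biases the facing angle.)

The bout schedule is the planted ground truth: labels mirror it
exactly, and wing-extension bouts raise the scheduled wing(s) to
`wing_extended_level` while all other wings sit at `wing_rest_level`,
with Gaussian noise everywhere. Defaults are
`wing_rest_level = 0.08` rad, `wing_extended_level = 0.80` rad and
`wing_noise_sd = 0.03` rad (about 1.7 degrees of tracker jitter):
realistic levels chosen once so the planted states sit 6 or more noise
SDs away from both classification thresholds, making per-frame
misclassification essentially impossible — which is what lets the
recovery suite demand exact planted bout counts rather than
approximate ones. Copulation is a single terminal interval, matching
assay semantics. A conflict check rejects overlapping bouts of the same
behavior (or overlapping wing-extension bouts with different wings).
All bouts belong to the focal male; the assay has a single courter, so
no per-bout target-fly field is carried.

What the generator does **not** emulate: classifier error on real
video (the behavior labels are exact), identity swaps, occlusion,
grooming/locomotion structure, or biomechanically realistic wing
kinematics. Passing recovery tests therefore validates the *analysis
rules*, not the upstream tracker or annotator.

## Group statistics

`group_stats` wraps the standard machinery behind one consistent
surface, and the tests pin each wrapper to an independent oracle:

* `mean_density()` — one Gaussian KDE per individual with the
  rule-of-thumb bandwidth (the `density()` default), evaluated on a
  common 512-point grid spanning the pooled range plus 3 bandwidths,
  then averaged pointwise with a normal-approximation 95% CI across
  individuals. The mean curve integrates to 1 within $10^{-3}$
  (verified by trapezoid quadrature in the tests).
* `ks_2sample()` — two-sided two-sample Kolmogorov–Smirnov with
  default settings, i.e. exact p at small n without ties (checked
  against full enumeration of pooled-rank assignments at n = m = 5).
* `km_logrank()` — Kaplan–Meier product-limit curves with
  Greenwood-based 95% CIs, global and pairwise log-rank tests with Holm
  adjustment. Subjects without an event (or beyond the horizon) are
  censored at the assay horizon (default 60 min). The CI method is the
  survival-package default; checked against hand observed-minus-
  expected arithmetic and the no-censoring identity
  $S(t) = 1 - \mathrm{ECDF}(t)$.
* `anova_pairwise_t()` — one-way ANOVA plus pooled-variance two-sided
  pairwise t tests (the conventional default; the pooled choice is a
  documented policy, swappable by calling `t.test` directly), Holm
  adjusted. Checked against brute-force sums of squares and the
  two-group identity $F = t^2$.
* `kruskal_mwu()` — Kruskal–Wallis with tie correction plus pairwise
  two-sided Mann–Whitney U (exact at small n without ties), Holm
  adjusted; checked against full enumeration at $n = m \le 4$.
* `holm_adjust()` — step-down Holm with monotonicity enforcement.
  Adjustment is applied within one family (one metric across genotype
  comparisons); callers group p-values per metric.

## Calcium-trace analysis

Recordings are (time, F) samples, by default at 5.92 frames/s, with a
stimulus protocol of four onsets at a 20 s inter-stimulus interval and
5 s stimulus duration. The pipeline:

1. `dff()` — per epoch, $F_0$ is the mean raw fluorescence from 10 s to
   200 ms before onset; the trace becomes $(F - F_0)/F_0$ with time
   re-zeroed to the onset. $F_0 \le 0$ is a hard error (non-physical).
2. `within_fly_average()` — each usable epoch is resampled onto a
   common relative-time grid at the native sample spacing by linear
   interpolation and averaged pointwise; epochs truncated by the
   recording edges are excluded and counted. Within-fly averages are
   the unit of all further analysis (n = flies).
3. `auc_dff()` — the mean dF/F over the 1 s immediately before the
   stimulus is subtracted, then the trace is trapezoid-integrated from
   onset to 1 s after stimulus end (non-uniform sample times are safe).
   The baseline subtraction is the reading under which a flat trace
   yields AUC exactly 0; the alternative reading (integrating from
   $-1$ s without subtracting) can be had by passing `baseline_s = 0`
   and shifting the window, but is deliberately not the default.
4. `calcium_group_summary()` — mean ± SE per condition with
   Kruskal–Wallis / Mann–Whitney / Holm tests delegated to
   `group_stats`.

The synthetic generator plants a difference-of-exponentials kernel
$(1 - e^{-t/\tau_r})\,e^{-t/\tau_d}$ normalized to unit peak
($\tau_r = 0.8$ s, $\tau_d = 2.5$ s by default — a GCaMP6f-like shape),
so the planted `amplitude` *is* the true peak dF/F:
$F(t) = f_0 + \text{drift}\cdot t + \text{amplitude}\cdot f_0 \cdot
\sum_i k(t - t_i) + \varepsilon$. At zero noise the pipeline recovers
the planted amplitude within 5% (the residual error is grid
quantization at 5.92 frames/s, about 1%, plus the small decay tail of
the previous epoch leaking into later baselines at a 20 s interval).
Movement-artifact exclusion is upstream manual QC and out of scope; an
exclusion list can simply be applied to the input files.

## Oviposition preference

The per-female index is
$(\text{eggs}_A - \text{eggs}_B)/(\text{eggs}_A + \text{eggs}_B)$, side
A the pheromone-treated zone, so +1.0 is full preference and −1.0 full
aversion. Zero-egg females have an undefined index and are excluded
from preference scoring but retained in fecundity totals (the assay
description is silent on this; excluding an undefined ratio is the only
consistent choice).

Statistics follow three contracts:

* `ovi_signed_rank()` — two-tailed Wilcoxon signed-rank against mu = 0.
  Zero differences are dropped (the conventional default); the exact
  null distribution is used up to 25 nonzero differences without ties,
  else the normal approximation with continuity correction. The exact
  branch is pinned to a $2^n$ sign-pattern enumeration in the tests.
* `preference_glm()` — quasibinomial GLM (logit link, IRLS with
  tolerance $10^{-8}$, 50 iterations max) on
  `cbind(eggs_a, eggs_b) ~ genotype`, genotype tested by an F test with
  Pearson-based dispersion. For this factor-only design the fitted
  per-genotype proportion equals the pooled $A/(A+B)$, an identity the
  tests verify numerically; complete separation is flagged.
* `fecundity_glm()` — negative-binomial GLM (log link, dispersion by
  maximum likelihood) on total eggs, genotype tested by a chi-squared
  likelihood ratio against the intercept-only model.

The egg generator draws totals from a negative binomial and side-A
counts from a binomial with the planted `preference_p`; simulation
tests confirm the GLM recovers planted dispersion within 25% at
n = 100 and detects a 0.7-vs-0.5 preference split at n = 25 per
genotype in most seeded runs.

## Connectome input budgets

Synapse tables are neuPrint-style edge lists: presynaptic and
postsynaptic body ids, synapse weight, the postsynaptic (and optionally
presynaptic) compartment — dendrite, axon or unassigned — and neuropil.
Compartment assignment is consumed as input metadata; no
skeleton-splitting is implemented.

* `input_budget()` — each partner's fraction of the target's total
  input weight, overall or restricted to one postsynaptic compartment
  (the dendritic and axonal input budgets); fractions sum to 1 per
  target by construction.
* `cluster_median_budget()` — for neuron types comprising several
  single neurons, the median of single-neuron contributions, with the
  cluster size reported.
* `compartment_restriction()` — percent of input weight on dendrites
  and output weight from axons, with unassigned weight reported
  separately; quantifies how polarized a neuron's connectivity is.
* `classify_neuron()` — the rule hierarchy: a neuron with dendrites in
  the antennal lobe is a putative olfactory PN (tested first); else a
  neuron with dendritic projections inside the lateral horn, at least
  one synapse from a listed olfactory PN, and output neuropils beyond
  the LH is LH-associated; else other. Any annotated dendritic overlap
  counts — no numeric cutoff exists for "projections inside the LH",
  so one synapse (or the listed neuropil) suffices, documented here as
  a deliberate choice. Missing annotation means unclassifiable, never
  silently "other".
* `top_partners()` — ranking by total synapse weight ("synaptic
  connections" in the budget sense), ties broken by id for determinism.

The generator plants expected budget fractions via a multinomial over
partners and a binomial dendrite/axon split per partner; at $10^4$
input synapses the recovered fractions are within ±0.02 of the planted
values. Morphology-based clustering of ascending-tract neurons is not
algorithmically specified anywhere and is excluded rather than guessed.
An optional external check against the hemibrain v1.1 dataset (aDN body
ids 541347811/604070433 and the egg-laying neurons) requires network
access and is not part of the test suite.

## Problem sizes and determinism

Every generator draws all randomness under the seed in its parameter
object via `withr::with_seed`, leaving the caller's RNG untouched;
identical parameters give byte-identical output, and all CSV writers
emit a fixed column order with floats at 6 significant digits. The
validation suite uses problem sizes chosen to exercise the contracts
tightly while staying quick on a laptop: 50 seeded 60-s pairs at 25
frames/s for courtship recovery, 1000 random 10,000-frame label series
for the initiation rule-equivalence check, a 41 × 41 wing-angle lattice
for the classifier truth table, 20-seed grids for calcium rank-order
recovery, and 10–20k-synapse tables for budget recovery.

## Known limitations

* Behavior labels are consumed as given; the package neither trains nor
  emulates per-frame behavior classifiers, so classifier error on real
  video propagates into the indices untouched.
* The trajectory model is a steered random walk — adequate for
  validating geometric rules, far from fly locomotor dynamics.
* The calcium kernel is phenomenological; indicator nonlinearity,
  bleaching (beyond linear drift) and motion artifacts are not modeled.
* `mean_density()` assumes each individual contributes enough samples
  for a stable KDE; individuals with fewer than two finite values are
  dropped with a warning, which slightly changes the averaging
  population.
* Statistical wrappers inherit the small-sample behavior of their
  underlying routines (e.g. tie handling switching exact tests to
  approximations).
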