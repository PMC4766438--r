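---
title: "Methods: merging heterogeneous odorant-response data into a consensus matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: merging heterogeneous odorant-response data into a consensus matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Odorant-response profiles of olfactory receptors and sensory neurons are
measured in many laboratories with incompatible techniques: single-sensillum
electrophysiology reports spikes per second, calcium imaging reports percent
fluorescence change, heterologous expression systems report yet other units.
Each study covers a different, partially overlapping panel of odorants.
`odorfuse` implements a complete pipeline for fusing such datasets into a
single consensus response matrix (odorants x responding units, scaled
globally to [0, 1]), together with the analysis tools that operate on such a
matrix: tuning-breadth statistics, profile matching, private-odorant search,
and the calcium-imaging response extraction used to produce new datasets in
the first place.

The central modelling assumption is *monotonicity*: for a given responding
unit, a better ligand elicits a stronger response than a weaker ligand
regardless of recording technique. Two studies of the same unit are therefore
related by some unknown monotone transformation, and merging amounts to
estimating that transformation and reading responses off it.

A "responding unit" is deliberately flexible: an unambiguous
receptor/OSN/glomerulus combination where one exists, otherwise a sensillum-
or glomerulus-level aggregate (e.g. `ab4B`, which houses two co-expressed
receptors). The bundled `responding_unit_info()` table records these
relationships.

## Identifiers

Odorants are keyed by InChIKey, the 27-character hash of the structure-derived
InChI (pattern: 14 letters, hyphen, 10 letters, hyphen, 1 letter). Unlike CAS
registry numbers, which are assigned to substances and can duplicate a
compound, an InChIKey is unique per structure; duplicate rows created by
synonym confusion are collapsed to their mean response at load time and
logged. Identifier translation (`trans_id()`) is a purely local lookup against
a bundled table -- no network service is consulted, so results are
reproducible offline. The spontaneous firing rate (SFR) is stored as the
reserved pseudo-odorant key `"SFR"`, so the merge treats baseline activity
like any other stimulus; studies that already subtracted baseline get SFR 0.

## The merge algorithm

For one responding unit with several datasets:

1. **Unit scaling.** Every dataset is rescaled to [0, 1] by
   `(x - min)/(max - min)`. A constant dataset is an error by default
   (`allow_flat = TRUE` downgrades it to a warning and zeros): a flat profile
   carries no rank information and cannot constrain a monotone fit.
2. **Pairwise merging.** For two datasets with at least `overlap_min = 5`
   odorants in common, ten candidate monotone curves are fitted by least
   squares to the common points: five families -- linear `a + b*u`,
   exponential `a*exp(b*u) + c`, sigmoid
   `vmin + (vmax - vmin)/(1 + exp(-(u - x0)/k))`, asymptotic
   `Asym*(1 - exp(-exp(lrc)*u))` and asymptotic-with-offset
   `Asym*(1 - exp(-exp(lrc)*(u - c0)))` -- each fitted both ways round
   (the "inverse" fits swap which dataset is the abscissa). Nonlinear fits
   start from 8 fixed initializations per family; non-convergent starts are
   dropped and a family is rejected only if every start fails. A fitted curve
   must be non-decreasing at 1001 equispaced points of the overlap range;
   violators are rejected with a logged reason.
3. **Scoring.** Each surviving fit is scored by its *mean orthogonal
   distance* (MD): the mean Euclidean distance of the common points to their
   nearest point on the curve. The fit with the lowest MD wins (ties broken
   by a fixed family order, then lexicographic ids). A best MD above
   `0.1*sqrt(2)` -- 10% of the diagonal of the unit response square --
   excludes the pair.
4. **Projection.** Within the overlap range the curve is the fitted family;
   beyond it, the curve continues as a straight line with slope 1. Odorants
   measured in both datasets move to the nearest point of this extended
   curve; odorants unique to one dataset are placed directly onto it
   (vertically given an abscissa value, by curve inversion given an
   ordinate). The merged scalar for each odorant is the *arc length* of its
   projected point along the extended curve, rescaled to [0, 1].
5. **Iteration and ordering.** Merging two sets leaves one fewer set; the
   procedure repeats until one remains. Because the outcome depends on merge
   order, the `exhaustive` strategy replays every permutation and keeps the
   one whose final consensus has the lowest average best-fit MD against the
   original datasets; the `greedy` strategy repeatedly merges the lowest-MD
   pair. `auto` picks exhaustive whenever the permutation count is at most
   `permutation_cap = 10000` (up to 7 datasets).
6. **Global normalization.** Per-unit consensus profiles each span [0, 1],
   hiding absolute sensitivity differences between units. Studies that
   recorded several units simultaneously carry that information: each such
   study is rescaled to [0, 1] jointly across its units, each unit's factor
   is the maximum response it reaches in any such study, factors are
   normalized to a maximum of 1, and unit columns are multiplied by their
   factor. Units never measured alongside others keep factor 1 and are
   flagged.
7. **SFR reset.** Finally each unit's SFR value is subtracted from all its
   responses (`reset_sfr()`), restoring negative values for inhibitory
   odorants; the SFR row becomes exactly 0.

Exclusions (too few shared odorants, MD above the cap) never abort a unit's
merge: they are recorded per study in the consensus provenance and surfaced
in the merge log, because knowing *why* a dataset is absent matters when a
consensus profile misses a known strong ligand. When nothing can merge, the
dataset covering the most odorants is kept.

### Design choices in the merge that were genuinely open

* **The merged scalar.** A projected point is two-dimensional; some single
  number must represent it. We use arc length along the extended curve from
  the lower end of its (padded) domain. Arc length is strictly increasing
  along any monotone curve (the integrand `sqrt(1 + f'(u)^2)` is at least 1),
  so ranks are preserved exactly, and it treats the two datasets
  symmetrically -- `merge_pair(a, b)` and `merge_pair(b, a)` give
  rank-identical output. Alternatives (the x-coordinate, the mean of x and
  y) privilege one axis or compress steep curve segments.
* **Orthogonal projection numerics.** The nearest point on the extended
  curve is found by seeding from a 4001-point discretization and refining
  with golden-section/parabolic search to tolerance 1e-12. Tests verify
  agreement within 1e-6 against a brute-force oracle that discretizes the
  curve at 1e-5 resolution, across all ten candidate families.
* **Ordering score.** Permutations are scored by the mean over datasets of
  the best candidate-fit MD between the final consensus and each dataset.
  Permutations that share a prefix (or differ only in the order of the first
  pair, which is symmetric) are memoized, and identical consensus profiles
  are scored once.

## Tuning-breadth statistics

Lifetime kurtosis (LTK) quantifies how narrowly a unit is tuned:

    LTK = (1/M) * sum_i ((r_i - mean(r)) / sd_pop(r))^4  -  3

with `M` the number of measured stimuli and the *population* standard
deviation (divide by `M`), matching the `(1/M) * sum(...) - 3` form; a
sample-sd variant is available behind `sd_type = "sample"` for sensitivity
checks. LTK is 0 for a Gaussian response distribution, high for a profile
dominated by a few strong ligands, and meaningful for profiles containing
negative (inhibitory) responses -- the reason it is preferred over
sparseness indices that require non-negativity. Population kurtosis (PK) is
the same formula applied to one odorant's row across units; a high PK marks
"labeled-line" candidates such as CO2. Lifetime sparseness (LTS), included
for completeness, is the Rolls-Tovee index
`(1 - (sum r / M)^2 / (sum r^2 / M)) / (1 - 1/M)`, the standard form in the
sparseness literature; it requires non-negative input, so negative responses
are rectified to zero and counted.

Convention thresholds: profile rankings (`rank_profiles_by_ltk()`) consider
only units with at least 50 measured odorants, and PK tables
(`rank_odorants_by_pk()`) only odorants measured in at least half the units
(default 39), because kurtosis estimated from few values is unstable. The
SFR pseudo-odorant is excluded from these statistics: after `reset_sfr()` it
is 0 by construction and would only dilute the estimate.

## Profile matching

`map_receptor()` correlates a query profile against every consensus column
over the odorants they share (Pearson; Spearman behind a flag), with
two-sided p-values from `t = r*sqrt((n-2)/(1-r^2))`. The conventional screen
keeps units that are both significant (`p < 0.05`) and relevant
(`r > 0.75`). No multiple-testing correction is applied by default,
mirroring how such screens are conventionally reported; Benjamini-Hochberg
is available via `adjust = "BH"`. The default `min_overlap = 10` reflects
the overlap sizes (n = 12-24) at which such screens are typically read.

`identify_sensillum()` scores each sensillum by the best one-to-one
assignment of the recorded profiles to that sensillum's units (exhaustive
search; sensilla house at most 4 neurons), maximizing mean correlation or
minimizing mean Euclidean distance on rescaled profiles. Several scoring
conventions are conceivable for this task; the assignment formulation is
stated here precisely so users know exactly what is computed.

`private_odorant()` ranks odorants by the margin between the target unit's
response and the strongest response of any other unit -- the operational
definition of a "private" stimulus.

## Calcium-imaging response extraction

Traces are 20 s recordings at 4 Hz (80 frames); frame `i` spans
`[(i-1)/4, i/4)` s and a window `[t1, t2)` contains frames whose start time
falls in it. Stimuli arrive at 6.75 s and 9.75 s (injection at 6 s and 9 s
plus 750 ms transit delay).

1. **dF/F**: `100*(F_i - F0)/F0`, `F0` = mean fluorescence of the 5 s before
   the first onset.
2. **Bleach correction**: indicator bleaching is modelled as
   `A*exp(-t/B) + C`. Because odorant responses can outlast the trace, `B`
   is estimated once per animal from the framewise *median* of its
   solvent-control traces; `A` and `C` are then refit per trace by weighted
   linear least squares with `B` fixed, and the fitted decay subtracted.
   Weights: pre-stimulus frames 100, the first 750 ms and the 11 s after
   each onset 0 (the fit must see bleaching, not response), other frames 1.
   For the *control* fit the post-onset exclusions are dropped: a solvent
   trace contains no odorant response, and restricting the fit to the
   pre-stimulus segment (24 frames spanning less than one decay constant)
   leaves `B` badly underdetermined. If the fitted amplitude is not
   distinguishable from zero (flat control), correction is skipped and
   logged rather than producing an unstable `B -> Inf` subtraction.
3. **Response magnitude**: mean over the 5 s after onset minus mean over the
   2.5 s before it (frames 28-47 minus 18-27 for the first onset). The first
   injection defines the default analysis; the second is available via
   `onset_index = 2`; the two injections are not silently averaged.
4. **Drift correction**: a line is regressed through the reference-odorant
   responses against measurement index within each animal, and every
   response at index `t` is multiplied by `L(t1)/L(t)` with `t1` the first
   reference presentation. A session whose fitted reference line crosses
   zero is rejected (`drift model invalid`).

Movement-artifact registration and ROI segmentation are out of scope; input
traces are assumed registered and averaged over an area of interest.

## The synthetic-data generators

`simulate_ground_truth()` draws a latent [0, 1] profile (one-hot,
exponential-tailed, or uniform tuning). `simulate_studies()` inverts the
merge's generative assumption: each study sees a subset of odorants through
its own monotone distortion (drawn from the same five families, normalized
to [0, 1]) plus additive Gaussian noise on the transformed scale -- the
noise model matching the least-squares fitting -- plus an optional SFR
offset. Subsets are a shared core of `round(overlap_fraction * n)` odorants
plus disjoint per-study remainders, so every pair overlaps in exactly the
core; configurations in which some pair would share fewer than 5 odorants
are flagged, not hidden. `simulate_traces()` builds raw fluorescence as
baseline + exponential decay + boxcar response + noise, with a linear
within-session decline multiplying the injected magnitudes and interspersed
reference/solvent presentations.

Defaults are chosen to represent a realistic multi-study setting: 3 studies,
60 odorants, 60% pairwise overlap, noise sd 0.05 on the unit scale for the
merge; 8 animals, decay amplitude 10% of baseline with an 8 s time constant,
0.5% frame noise, and a decline to 0.8 of the initial sensitivity for the
traces. Injected trace magnitudes are drawn from a continuous uniform
distribution on [0, 20]% dF/F: odorant panels span a continuum of response
strengths, and a continuous distribution keeps rank-based recovery scores
meaningful (a small discrete set of magnitudes makes Spearman correlations
measure tie-breaking noise instead of recovery; with perfect recovery and a
five-level pool the ceiling is about 0.98). Discrete level designs remain
available through the `magnitudes` argument.

What the generators do *not* emulate: concentration-response relationships,
saturation and adaptation of strong ligands, correlated (non-Gaussian) noise,
spike-sorting ambiguity, and odorant-panel biases of real studies. Passing
the simulation-based tests therefore demonstrates that the algorithms invert
their own generative model at realistic noise levels -- not that every
published dataset merges this cleanly.

## Numerical conventions and degenerate inputs

* Curve padding for projection/arc length: 2 units beyond the overlap range
  per side, enough that every point in the unit response square projects
  into the interior.
* Curve inversion (placing a `y`-only odorant) solves `f_ext(u) = v` by
  bisection to 1e-12; a solution on a flat segment of the curve is an error
  in strict mode (`non-invertible segment`) because the preimage is an
  interval.
* Tie-breaks are deterministic everywhere: (MD, fixed family order,
  lexicographic ids) for fits and pairs, lexicographic permutation order for
  equal-scoring merge orders, lexicographic odorant order for equal
  responses. Identical inputs and configuration give byte-identical outputs;
  file output uses a canonical number format (6 significant digits, `NA`
  for missing).
* Problem sizes in the shipped test-suite: merge-recovery checks use 20
  replicates of the 3-study default; geometry oracle checks use 50 fit
  instances at 1e-5 grid resolution; ordering checks enumerate instances
  with up to 4 datasets against full permutation enumeration.

## Known limitations

* Global normalization requires a convention for turning multi-unit-study
  evidence into per-unit scale factors; ours (documented above) is one
  consistent choice, and the factors it produces are exposed for
  inspection.
* Responses to good ligands that fall outside the overlap of two studies are
  systematically underestimated by the slope-1 extension -- an inherent
  property of the method, visible when a narrowly tuned unit's best ligand
  is known to only one study. Lowering `overlap_min` can pull such a dataset
  into the merge at the cost of a weaker fit.
* Concentration series, temporal response dynamics and mixtures are out of
  scope by design; the consensus matrix stores one scalar per
  odorant-unit pair.
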