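# odorfuse

Odorant-response profiles of olfactory receptors and sensory neurons are
published by many laboratories using incompatible techniques — single
sensillum recordings in spikes/s, calcium imaging in % dF/F, heterologous
expression in yet other units — each covering a different, partially
overlapping odorant panel. `odorfuse` fuses such datasets into a single
consensus response matrix (odorants × responding units, globally scaled to
[0, 1]) and provides the analysis tools that operate on it. It is aimed at
olfaction researchers who want to combine published response data, locate
their own recordings within it, or quantify tuning breadth.

## The method in brief

Merging rests on one assumption: for a given responding unit, a better
ligand elicits a stronger response than a weaker one regardless of
technique, so two studies of the same unit are related by an unknown
monotone transform. For each pair of unit-scaled datasets with ≥ 5 shared
odorants, ten candidate monotone curves are fitted by least squares (linear,
exponential, sigmoid, asymptotic, asymptotic-with-offset — each in both
orientations). Fit quality is the **mean orthogonal distance**

    MD = (1/n) Σ_i  dist( (x_i, y_i), nearest point on the fitted curve )

and the lowest-MD fit wins; a best MD above `0.1·√2` (10 % of the unit
square's diagonal) excludes the pair. Shared odorants are projected to the
nearest point of the curve, unique odorants directly onto it (the curve
continues outside the overlap as a slope-1 line), and each odorant's merged
value is the arc length of its projected point, rescaled to [0, 1]. Merging
iterates pairwise; since order matters, all permutations are replayed where
feasible and the one with the lowest average MD against the original
datasets wins (greedy fallback otherwise). Multi-unit studies then set the
relative scale of the units (global normalization), and subtracting each
unit's spontaneous firing rate (stored as the pseudo-odorant `"SFR"`)
restores negative values for inhibitory odorants.

Tuning breadth is quantified by lifetime kurtosis,

    LTK = (1/M) Σ_i ((r_i − r̄)/σ_r)⁴ − 3     (population σ)

which is 0 for a Gaussian response distribution and large for narrowly tuned
units, plus lifetime sparseness and the odorant-wise population kurtosis.
`map_receptor()` (Pearson screen with t-transform p-values),
`identify_sensillum()` (optimal assignment of recordings to a sensillum's
units) and `private_odorant()` (largest response margin over all other
units) query the consensus matrix. A calcium-imaging pipeline (dF/F,
weighted exponential bleach correction, windowed response magnitudes,
reference-odorant drift correction) turns raw 4 Hz traces into response
values, and seeded generators simulate multi-study data and imaging traces
with known ground truth.

## Worked example

Three bundled toy datasets record the same fictitious receptor: two
electrophysiology studies reporting spikes/s (with spontaneous firing rates
12 and 8) and one imaging study reporting % dF/F, overlapping in 6 of 10
odorants.

```r
library(odorfuse)

dir <- system.file("extdata", "example_studies", package = "odorfuse")
datasets <- lapply(list.files(dir, full.names = TRUE), read_study_dataset)
names(datasets) <- sapply(datasets, function(d) d$study_id[[1]])

consensus <- merge_unit(datasets, unit_id = "exampleOr")
glance(consensus)
#>   unit_id   n_odorants n_included n_excluded strategy    score
#> 1 exampleOr         10          3          0 exhaustive 0.0103
consensus$merge_log[, c("step", "left", "right", "family", "md", "decision")]
#>    step left          right family          md decision
#> 1     1 imagingB      ssrC  asymptotic  0.0227 merged
#> 2     2 imagingB+ssrC ssrA  exponential 0.0187 merged
```

All six permutations of the three studies were scored; the winning order
first maps the imaging study onto one SSR study through an asymptotic curve
(MD 0.023, i.e. common odorants sit ~2 % of the response square away from
the curve), then merges the remaining study. The consensus covers all 10
odorants even though no single study measured them all. Its best ligands,
translated through the bundled local identifier table:

```r
top <- dplyr::slice_max(tidy(consensus), response, n = 3)
trans_id(top$inchikey)
#>   query                       match             ambiguous
#> 1 SHZIWNPUGXLXDT-UHFFFAOYSA-N ethyl hexanoate   FALSE
#> 2 MLFHJEHSLIIPHL-UHFFFAOYSA-N isopentyl acetate FALSE
#> 3 PGMYKACGEOXYJE-UHFFFAOYSA-N pentyl acetate    FALSE

matrix <- reset_sfr(build_response_matrix(list(consensus)))
lifetime_kurtosis(matrix$exampleOr[matrix$inchikey != "SFR"])
#> [1] -0.9200418
```

The negative lifetime kurtosis says this toy receptor is broadly tuned —
its responses spread across the odorant panel instead of concentrating on
one ligand.

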