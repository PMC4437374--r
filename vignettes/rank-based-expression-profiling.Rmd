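---
title: "Rank-based expression profiling: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based expression profiling: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunorank)
```

## The problem and the model

Expression compendia assembled from many laboratories mix scanner
settings, normalization pipelines and batch effects, so raw intensities are
only comparable within an array. `immunorank` adopts the rank-score model:
each array is reduced to the *relative position* of every probe set within
that array. All probe sets are ranked ascending by signal and the rank
order is cut into `n_bins` nearly equal blocks; the block index (1 =
lowest, `n_bins` = highest) is the probe set's rank score. A rank score is
thus a within-array expression percentile, and percentiles — unlike
signals — can be pooled across arrays.

The model's central assumption is that the *shape* of an array's signal
distribution carries no information the analysis needs: only order
matters. This buys robustness to monotone distortions (scaling,
log-transformation, many normalization differences) at the cost of
discarding absolute signal levels; two arrays with genuinely different
global expression activity are forced onto the same percentile scale.

All downstream quantities are functionals of the score distribution of one
probe set *j* in one cell group *i* (scores `M_ij`) or across all groups
(background `M_bj`):

* the **RBE curve**, the probability mass function of `M_ij` over scores
  (ordinates sum to 1 by construction);
* **GPL** `= Q3 − Q1` of `M_ij`, an interquartile range measuring
  expression plasticity across conditions;
* **ARS**, the mean of `M_ij`;
* **MES** `= sign · |log10 p|`, where `p` is a two-sided Wilcoxon rank-sum
  p-value of `M_ij` against `M_bj` and the sign is `+` when
  `median(M_ij) ≥ median(M_bj)`.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_bins` | 100 | score groups | makes scores read as percentiles; small compendia and toy examples may use fewer bins |
| `target_fraction` | 0.99 | fraction of absent calls | the stringency of the "undetectable" calibration |
| `detect_threshold` | 25 | rank score | marker-QC detectability cutoff; sensible to set from `calibrate_detection()` |
| `exact_limit` (`mes_score`) | 20 | pooled sample size | below this the exact permutation null is enumerated; above it the normal approximation is used |

## Numerical and procedural choices

**Block remainder placement.** With `n = q·n_bins + r` probes the `r`
oversized blocks are the *first* (lowest-signal) score groups. Any
placement satisfying the ≤1 block-size difference would do; fixing it makes
scores reproducible to the bit.

**Tie-breaking.** Equal signals are ordered by probe-set ID with a radix
(C-locale) sort. Ties straddling a block boundary must be resolved
somehow; a deterministic, locale-independent rule keeps results identical
across platforms. Consequently a constant array yields scores determined
entirely by probe ID order — the score *multiset* is always the no-tie one.

**Quantile convention.** Q1/Q3 use linear interpolation between order
statistics with the p-th quantile at position `1 + (n−1)p`
(`stats::quantile` type 7, R's default). The choice changes GPL by at most
one score unit at small group sizes; it is stated so independent
reimplementations can match exactly.

**Wilcoxon p-values.** For pooled sizes ≤ 20 the package enumerates the
exact conditional permutation distribution of the rank-sum statistic
(midranks, so ties are handled; the two-sided p is the probability of a
deviation from the null mean at least as large as observed). Larger
problems use the normal approximation with tie correction and continuity
correction. The group is *included* in its own background — the background
is defined over all cell groups with no exclusion — which biases MES toward
0 as the group's share of the compendium grows; with many groups of
moderate size the effect is small, but MES values of a group comprising
most of a compendium should be read with that in mind.

**MES edge cases.** When `p` underflows to exactly 0 in double precision,
or the background scores are constant, MES is reported as `NA` rather than
clamped: a clamped value would impose an arbitrary ceiling on a score whose
scale is otherwise meaningful. At `p = 1` the score is 0, which carries no
sign; the sign rule applies to every non-zero score. `NA` is written as
the literal string `NA` in output tables.

**Detection calibration reading.** The absent-fraction criterion is
evaluated *per score* — the threshold is the largest `t` such that every
score below `t` individually has an absent fraction at or above the
target — not cumulatively over all cells below `t`. The full fraction
vector is returned so the cumulative reading can be checked by the user.
Marginal calls count as not absent. A score with no cells yields `NA` and
breaks the qualifying run; a compendium where every score qualifies
reports `n_bins` with a saturation flag.

**Marker QC rule.** A sample passes when, for every marker of its group's
panel, at least one of the marker's probe sets reaches the detection
threshold. The every-marker/any-probe logic and the threshold are panel
configuration, not code, so alternative admission rules are a panel file
away.

**Unannotated probes.** Probes missing from the annotation stay in the
matrix — they occupy rank positions on the physical array and removing them
would shift every score — but are excluded from gene-symbol/alias/ID
queries. The loader takes the annotation's absence as the exclusion
signal rather than attempting to infer multi-gene mappings itself.

## The synthetic compendium

`generate_compendium()` emulates an annotated multi-experiment compendium:
five immune cell groups × 60 samples (each split over 6 series), 2,000
probe sets, 100 bins. Background signals are log-normal with
probe-specific baselines (`meanlog ~ N(5, 1.5)`, `sdlog = 0.6`), giving the
heavy-tailed positive intensities and probe-to-probe dynamic range typical
of array data. Planted patterns are *engineered in signal space but
specified in rank space*: for each planted probe and sample a target score
is drawn from the pattern's band and the signal is inserted between the
order statistics of that sample's background signals so the target is
realised exactly. Because placement is exact, a single post-generation
verification pass (re-rank, compare to targets) replaces iterative
re-planting; an infeasible plant — more probes targeting a score than its
block holds — fails loudly. Default plant bands (scores): markers 90–100
in-group / 10–40 elsewhere; silenced markers 1–10 / 45–80; plastic genes
bimodal 85–100 (40% of samples) and 5–20 / 40–60 elsewhere; disease shifts
85–100 vs 1–15. Twelve percent of samples are planted as QC violators
(their group's QC marker below score 25), and detection calls are absent
with probability 0.995 below score 25 and 0.02 at or above it — rates
chosen so the per-score absent fraction sits clearly on either side of the
0.99 calibration target at the generated cell counts (6,000 cells per
score).

What the generator does *not* emulate: probe-level (PM/MM) structure,
batch or series effects correlated across probes, realistic metadata text,
and any dependence between genes. Passing the recovery tests therefore
shows the pipeline is sound on data satisfying the rank-score model's
assumptions; it does not certify behaviour under batch confounding or
correlated biology.

## Problem sizes used in validation

The test-suite compendium is the default spec above (2,000 × 300). Exact
Wilcoxon enumeration is validated on 200 random instances with group and
background sizes up to 8; quantile/GPL/ARS against brute force on 500
random vectors (n = 3–200); electronic sorting against a brute-force
filter over 1,000 random queries; and the array-sized binning constants on
single 54,675- and 45,101-probe arrays. These sizes were chosen to
exercise every code path and boundary while keeping the default suite
comfortably interactive.

## Known limitations

* Rank scores saturate: genes above the ~99th percentile are
  indistinguishable, and compression at the extremes understates fold
  changes among very high expressors.
* MES is a raw signed score; no multiple-testing correction is applied
  across probes, and MES magnitudes grow with sample size, so they compare
  probes within a compendium, not across compendia of different sizes.
* GPL conflates biological plasticity with technical variability; a noisy
  probe is indistinguishable from a plastic gene without replicate
  structure, which the model does not use.
* The detection calibration assumes detection calls are available and
  trustworthy; it does not compute calls from probe-level data.
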