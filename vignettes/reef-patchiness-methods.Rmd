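---
title: "Scoring reef condition and true patchiness from video transects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring reef condition and true patchiness from video transects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefpatch)
```

## The problem

*Sabellaria spinulosa* reef is a biogenic habitat: a polychaete worm
consolidates sand into tubes that, in aggregate, rise above the seabed and
qualify as protected reef. Condition monitoring asks whether reef at a
site is consolidating or fragmenting over time. Percentage cover alone
cannot answer that: a tow across one solid block of reef and a tow across
many scattered fragments can both show 50% cover. What distinguishes them
is how presence is *arranged* along the transect — its patchiness.

`reefpatch` implements the along-transect workflow: fixed-duration
segment scoring, an ordinal condition class per segment, and a
randomization statistic for clustering.

## Segment model

A tow is split into contiguous half-open intervals $[kd, (k+1)d)$ of
$d = 5$ s (0-based index; a trailing sliver shorter than 1 s is dropped).
Five seconds is the finest practical annotation unit: shorter segments
measure patchiness more finely because gaps are less likely to hide
inside a segment, at proportionally higher analyst cost. Per segment the
analyst records:

* **quality** — `unusable` where the seabed is obscured; such segments are
  `Missing` throughout and never silently counted as reef absence;
* **cover** (`[0, 100]` %) — summed over the segment's cover estimates and
  divided by the number of new fields of view seen, so slow and fast tows
  are comparable (`normalize_cover()`); when annotations lack explicit
  field-of-view events we count one view per cover estimate;
* **elevation** (cm) — mean tube height against the laser scale; when
  cover is positive but no tube height is measurable we record 0 cm,
  which conservatively classifies as *Not a reef*.

`presence` is derived, never stored: 1 iff cover > 0, 0 iff cover = 0,
missing iff unusable. Re-deriving on every read (`as_segment_table()`)
makes inconsistent tables impossible.

Broad-scale habitat sections (`broadscale_segments()`) keep only label
runs persisting longer than a minute; shorter runs are merged into the
preceding section and reported as incidental patches. We attach
incidental runs to the *preceding* section because it is order-stable;
when a merged run leaves two same-label sections adjacent they are
coalesced. Habitat labels are attached per segment upstream, so a segment
straddling a change is assigned by majority time there.

## The reef structure matrix

Condition per segment is the cell of a 4×4 matrix of cover bands
(`<10`, `10–20`, `20–30`, `>30` %) by elevation bands
(`<2`, `2–5`, `5–10`, `>10` cm):

```{r}
reef_status_matrix()
```

Anything under 10% cover *or* 2 cm elevation is structurally *Not a
reef*; zero cover is the distinct class *No reef*. The printed band
labels do not say which band owns a shared edge; we use left-closed
intervals (`[10, 20)` and so on) because they are contiguous and
deterministic. The matrix is a config object validated on load
(`read_status_matrix()`): band contiguity and ordinal monotonicity along
both axes are enforced, so a site-specific variant (e.g. the original
Gubbay bands) can be swapped in without touching code but cannot be
mis-specified silently.

## True patchiness

Presence along a tow, cleaned of missing values, is a binary string. A
patch is a maximal run of 1s; a run ended by the end of the transect
counts (this keeps the patch sizes summing to the number of presence
segments). Missing values are deleted *before* patch extraction, so a
gap between two presence runs bridges them:

```{r}
patch_sizes(parse_presence("10011100110"))
patch_sizes(clean_presence(parse_presence("01*110")))
```

The statistic is $K = p_o / p_r$ with $p_o$ the observed mean patch size
and $p_r$ its expectation if the same presence observations were randomly
arranged. "Randomly arranged" is made precise as a uniform random
permutation of the cleaned string: conditioning on the counts of 1s and
0s isolates *arrangement* from *abundance*, which is exactly the
distinction cover-based metrics miss. $p_r$ averages the mean patch size
over 1,000 permutations (the default); the p-value is the proportion of
permutations whose mean patch size exceeds $p_o$. Missing values are
deleted before randomization too, so observed statistic and null operate
on the same string. A constant string (all presence or all absence) is a
hard error rather than $K = 1$: the statistic is uninformative there and
a silent default would corrupt a monitoring time series.

For short strings the null needs no sampling: `exact_null()` enumerates
all $\binom{n}{k}$ arrangements. It doubles as the oracle the randomized
path is tested against:

```{r}
exact_null(c(1, 1, 0))$p_r      # 5/3 over the arrangements 110, 101, 011
k_statistic(c(1, 1, 0), exact = TRUE)$k
k_statistic(c(1, 0, 1, 0), exact = TRUE)$k  # regular spacing: K < 1
```

### Ties and the p-value

The mean patch size under permutation is discrete, so randomized means
tie with $p_o$ with non-negligible probability. The default `p_value`
is the plain strictly-greater proportion. Because of the ties it is
*sub-uniform* under the null — slightly anti-conservative — by
construction. The result object therefore also carries:

* `n_ties`, so any convention can be recomputed;
* `p_value_mid` — ties counted half, the calibrated choice for a
  discrete statistic; this is what the package's own null-calibration
  test checks for uniformity;
* `tie_corrected = TRUE` — the $(g + t + 1)/(N + 1)$ variant, which is
  conservative.

For monitoring decisions at conventional thresholds the three rarely
disagree; for sequences of a few dozen segments, prefer `p_value_mid` or
the exact null.

### Determinism

One master seed reproduces an entire run. Per-tow sub-seeds are derived
deterministically from (seed, tow id), so a tow's result does not depend
on which other tows are in the table or the order they arrive in. The
randomized null permutes a canonical arrangement of the multiset, so two
sequences with the same counts share an identical null under the same
seed — permutation invariance holds exactly, not just in distribution.

## Per-tow summaries

`summarize_tows()` emits the reporting row per tow: percentages of usable
segments in each status class (these sum to 100; missing segments are
excluded from the denominator), patch count, mean/median patch length,
patch size range, K and p. Rows are ordered by descending largest patch,
the convention for condition reports, overridable via `order_by`. A
degenerate tow keeps its row with K and p absent and a warning, so a
pipeline over many tows never dies on one odd transect.

## The synthetic transect generator

There is no deposited segment-level dataset to test against, so the
generator is first-class: presence follows a two-state Markov chain —
the simplest process with tunable clustering — with stay-probabilities
$a = P(1\to1)$ and $b = P(0\to0)$, stationary prevalence
$(1-b)/((1-a)+(1-b))$, and geometric true run length with mean
$1/(1-a)$. Defaults are one fixed description of a strongly clustered
reef: $a = 0.9$, prevalence 0.3 (so $b = 67/70$), 120 segments (the
10-minute minimum tow at 5-s segments), 5% missing. Cover is uniform on
$(0, 100]$ and elevation uniform on $(0, 15)$ cm given presence — the
simplest defensible families in the absence of measured distributions;
both are pluggable functions. Missingness is i.i.d. by default, with a
burst mode (missing runs of configurable mean length) because obscured
seabed occurs in runs in real footage.

What the generator does *not* emulate: along-tow trends in prevalence,
analyst disagreement in cover and elevation scoring, spatial (2-D)
structure across tows, and any coupling between cover magnitude and run
length. Tests passing on synthetic transects therefore validate the
*statistical machinery* — patch accounting, null construction,
calibration, detection power — not the field protocol.

## Numerical and design choices

* **Problem sizes in the test suite** (the package's own choice of
  precision targets): oracle equivalence sweeps every (length ≤ 10,
  count) multiset at 10,000 randomizations; null calibration uses 500
  i.i.d. sequences of 200 segments at prevalence 0.3; detection power
  uses 200 replicates of 500-segment chains at $a = 0.9$. At those sizes
  the randomized $p_r$ sits within 0.05 of the exact value, mean K under
  the i.i.d. null lands in $1 \pm 0.05$, and clustered chains are flagged
  (K > 1, p < 0.05) in well over 95% of replicates.
* **Why mid-p for the calibration check**: the strictly-greater p-value
  is deterministically sub-uniform for a discrete statistic (its CDF
  exceeds uniform by up to the tie mass, ~0.1 at 200 segments), so
  testing *it* for uniformity would measure the convention, not the
  machinery. The mid-p variant is the estimator of calibration that is
  unbiased under ties; the default reported p-value remains the
  strictly-greater convention.
* **Degenerate inputs**: all-missing sequences, constant sequences, and
  empty tables are hard errors with explanatory messages; degenerate
  tows inside a multi-tow summary degrade to NA fields with a warning.
* **Enumeration cap**: `exact_null()` refuses beyond $10^6$ arrangements
  and points to the randomized path.

## Limitations

* The statistic is strictly one-dimensional (along-tow); it says nothing
  about patch shape or extent across tows.
* K depends on segment duration: shorter segments resolve finer gaps.
  Comparisons are only valid at a common segment length (5 s here).
* Tows of very different lengths are not directly comparable; trimming
  analysis to start at the first reef observation
  (`trim_to_first_presence()`, CLI `--start-at-first-presence`) mitigates
  unequal lead-ins but not unequal lengths.
* Cover and elevation arrive analyst-scored; no attempt is made to
  extract them from imagery.
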