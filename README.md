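# reefpatch

Condition assessment of *Sabellaria spinulosa* (Ross worm) biogenic reef
from drop-down video transects, for Marine Protected Area monitoring.

*S. spinulosa* builds consolidated sand-tube reefs that are protected as
Annex I habitat, and their condition must be assessed in a way that is
repeatable between surveys and between years. Two things make that hard:
(a) "percentage cover" alone conflates reef density with reef structure,
and (b) nearest-neighbour style dispersion indices cannot grade *degrees*
of along-transect clustering. `reefpatch` implements a segment-scoring and
randomization workflow that addresses both:

1. **Segment scoring.** Each video tow is split into 5-second segments.
   Each usable segment gets an analyst-estimated percentage cover
   (normalized by the number of new fields of view seen in the segment)
   and a tube elevation in cm, and is classified on a reef structure
   matrix — cover bands `<10`, `10–20`, `20–30`, `>30` % crossed with
   elevation bands `<2`, `2–5`, `5–10`, `>10` cm — into the ordinal
   classes *No reef < Not a reef < Low < Medium < High*.

2. **True patchiness.** Presence per segment is `1` if cover > 0, else
   `0`; unusable segments are deleted (a gap between two presence runs
   bridges them). A *patch* is a maximal run of 1s. The statistic is

   **K = p₀ / pᵣ**

   where p₀ is the observed mean patch size (in segments) and pᵣ the mean
   patch size if the same presence observations were arranged at random —
   estimated from 1,000 uniform permutations of the cleaned sequence
   (or exactly, by exhaustive enumeration, for short sequences).
   K > 1 indicates clustering ("patchiness"); the permutation p-value is
   the proportion of randomizations whose mean patch size exceeds p₀.

The package also ships a per-tow summary table (class percentages, patch
count, mean/median/range of patch lengths, K, p), a Markov-chain synthetic
transect generator for testing and power exploration, GeoJSON export, and
a command-line front-end (`inst/exec/reefpatch`) with subcommands
`score`, `patchiness`, `summarize`, `simulate` and `oracle`.

## Worked example

The presence sequence `1 0 0 1 1 1 0 0 1 1 0` contains patches of sizes
1, 3 and 2:

```r
library(reefpatch)

k <- k_statistic(parse_presence("10011100110"), n_randomizations = 1000, seed = 42)
k
#> True patchiness (randomization test)
#>   segments: 6 present, 5 absent, 0 missing (excluded)
#>   patches:  3 (sizes 1, 3, 2)
#>   p_o = 2   p_r = 2.002 (randomized, n = 1000)
#>   K = 0.9991   p = 0.176
```

Eleven segments are far too few to call clustering: K ≈ 1 (observed mean
patch size indistinguishable from random arrangement) and p = 0.18. On a
simulated survey of three 20-minute tows over strongly clustered reef
(stay-probability 0.9, prevalence 0.3), the summary table — ordered, as
condition reports are, by the largest patch observed — shows what real
patchiness looks like:

```r
tows <- simulate_transects(3, simulation_config(n_segments = 240), seed = 7)
summarize_tows(tows, n_randomizations = 1000, seed = 7)
#>   tow_id n_patches mean_patch_len median_patch_len patch_size_max    k p_value
#> 1     T3         6          13.33                8             46 8.65       0
#> 2     T2         7          11.43                8             27 7.37       0
#> 3     T1         7           7.57                3             25 5.83       0
```

Every tow's mean patch is 6–9 times longer than random arrangement of the
same presence counts would produce (K = 5.8–8.7), and no randomization
ever beat the observed mean (p < 0.001 at 1,000 randomizations). The
omitted columns hold the status-class percentages of each tow
(`pct_no_reef` … `pct_high`), which sum to 100 over usable segments.

Missing observations bridge patches, exactly as scored in the field:

```r
patch_sizes(clean_presence(parse_presence("01*110")))
#> [1] 3
```

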