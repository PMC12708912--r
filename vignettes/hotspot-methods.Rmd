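---
title: "Methods: diversity hotspots, conservation gaps and climate-driven threat reassessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity hotspots, conservation gaps and climate-driven threat reassessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotr)
```

## The analysis in outline

`hotspotr` implements a complete conservation-prioritization workflow on a
regular planar grid. Its stages are:

1. **Gridding.** Occurrence records `(species, x, y)` are assigned to
   square cells; presence (not abundance) per cell and species defines the
   presence matrix, from which range sizes (occupied-cell counts) follow.
2. **Diversity surfaces.** Three algorithms score every cell for each of
   three species subsets (all, endemic, threatened): species *richness*
   (count of species present), greedy *complementarity* (iterative
   set-cover selection of the cell adding the most not-yet-represented
   species), and *weighted endemism* (range-size rarity: the sum over
   present species of the reciprocal of their range size).
3. **Hotspot identification.** Per algorithm, the three subset surfaces
   are min-max standardized and summed into a composite; the top *k*% of
   the occupied cells is selected per algorithm (with boundary-tie
   inclusion); cells picked by three, two or one algorithm are Class I, II
   or III consensus hotspots, ordered by the sum of their per-algorithm
   ranks.
4. **Reserve overlay.** Two-tier reserve polygons (NNR national, PNR
   provincial) are intersected with hotspot cells; effectiveness and gap
   tables count protected/unprotected cells and the species they contain,
   and a record-level analysis computes each species' protected fraction
   of occurrence records.
5. **Climate impact.** Per-species habitat-suitability surfaces for a
   current and a future scenario are binarized at suitability > 0.6; loss
   of suitable area (LSA, the fraction of current-range cells falling
   below threshold) maps to threat bands EX (= 100%), CR [80, 100)%,
   EN [50, 80)%, VU [30, 50)%, CC (< 30%), applied as *upgrades* to
   currently unthreatened (NT/CC) species only.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cell_size` | 50 | km | standard national-scale macroecology resolution |
| hotspot fractions | 5, 10, 17, 30 | % of occupied cells | 17% and 30% are the Aichi and post-2020 area targets; 5/10% are stricter cores |
| suitability threshold `s_min` | 0.6 | – | values above 0.6 indicate high occurrence potential; strictly-greater rule |
| record minimum | 5 | records | distribution models are unreliable below five points; `>= 5` retained |
| AUC minimum | 0.7 | – | conventional discrimination floor; `>= 0.7` retained |
| collinearity cutoff `r_max` | 0.85 | – | pairs with `|r| > 0.85` are redundant; later-listed layer dropped |
| correlation bands | 0.1/0.4/0.7/0.9 | on `\|r\|` | left-closed conventional strength scale |

## The synthetic study system

The generator (`synthetic_config()` + `generate_*()`) produces every input
the pipeline consumes, so the whole analysis is testable offline. Its
defaults define the study conditions the package is built around: 458
species — 264 threatened split CR 66 / EN 102 / VU 96 (the threatened
total is fixed by the checklist composition; its split across the three
threatened categories is not, so the package fixes one plausible split
once), 56 NT, 138 CC — with endemism probability 232/458, on a 64 × 64
grid of 50-km cells (4096 cells, matching the scale of a ~4000-cell
national grid).

Category counts are apportioned by largest-remainder rounding so the
composition is exact and reproducible; endemic flags are independent
Bernoulli draws, so the *realized* endemic count varies by seed around
232. Occupied-cell counts per species follow a truncated discrete
lognormal (`meanlog = log 8`, `sdlog = 1.3`): many narrow-range species
and a long tail of wide-ranging ones, the rarity structure weighted
endemism is designed to exploit. The distribution family is a modeling
choice — occupancy data motivate a heavy right tail but do not pin down a
family. Narrow-range species (target ≤ 3 cells) are planted inside one of
`n_hotspot_clusters` disks, creating recoverable hotspot structure; all
other species scatter uniformly. Reserves are axis-aligned rectangles
whose areas sum to `reserve_coverage` of the extent; rectangles may
overlap, so *union* coverage can fall slightly short of the target, which
the overlay semantics do not depend on. Suitability is ~0.8 on range
cells and ~0.2 off-range, jittered but bounded away from 0.6 so the
binarization rule is unambiguous; the future scenario drops exactly
`round(loss_fraction × range)` range cells below threshold and raises
`round(gain_fraction × range)` new cells above it, making every planted
loss fraction recoverable to within half a cell. Default loss and gain
fractions are drawn per species from U(0, 0.7) and U(0, 0.8), giving a
mixed contraction/expansion regime comparable to published projections.

What the generator does **not** emulate: spatial autocorrelation of
sampling effort, coastline-clipped cells, realistic reserve shapes,
dispersal limits, or any climate-response mechanism. Passing tests
therefore demonstrate the *contracts* of the pipeline — not that any
real flora behaves like the synthetic one.

### Recovery-test geometry

The planted-cluster tests use a 20 × 20 grid (400 cells) with 200
species, ~half of them narrow and packed into one disk of radius 135 km
(~22 cells — deliberately just above the nominal top-5% count of a fully
occupied base, ~20 cells). With that geometry the top-5%
weighted-endemism set should sit almost entirely inside the cluster, so
the Jaccard similarity between cluster cells and the top-5% set is
expected near 20/22 ≈ 0.9, and the Class-I consensus core is expected to
be a pure subset of the cluster covering most of it. The tests assert
Jaccard ≥ 0.8 in at least 8 of 10 seeds, and (Class-I ⊆ cluster) ∧
(Class-I covers ≥ half the cluster) in at least 8 of 10.

## Numerical and procedural choices

* **Half-open cells, lower-left closed.** A point on a shared edge belongs
  to exactly one cell; records outside the grid are dropped (with a
  count), never clamped.
* **Percentile base = occupied cells**, not all grid cells: thresholds are
  fractions of the cells that carry information. Configurable via
  `base_cells`.
* **Nominal count then boundary ties.** The top-*k*% count is
  `round(k × n_base)` (halves up); every cell tying the boundary score is
  included, so a nominal 280 can return 281. If the composite is constant
  over the base the grid is degenerate and an empty set is returned with a
  warning rather than the whole grid.
* **Complementarity per-cell value** = species gain at selection, zero
  elsewhere. The greedy algorithm returns an ordered cell list, not a
  surface; gain-at-selection is the natural scalarization for
  standardizing and correlating it with the other two metrics, and it
  reproduces the characteristically scattered look of complementarity
  maps. One cell is selected per iteration; ties go to the lowest cell
  id. A consequence worth knowing: the surface is zero on unselected
  cells, so at high thresholds the boundary score can hit zero and
  tie-inclusion then returns the entire base for that algorithm —
  consensus classes remain well-defined, but unions saturate.
* **Standardization = min-max** to [0, 1] (z-score available): keeps the
  three subset contributions commensurable and non-negative; a constant
  surface standardizes to zeros and simply drops out of its composite.
* **Final hotspot set = union** of the three algorithms' top sets
  (intersection available via `combine`).
* **Protection = positive-area intersection.** A cell is protected by a
  tier iff some polygon of that tier overlaps it with positive area; edge
  contact does not protect. A gap is a hotspot cell protected by neither
  tier. Records on a polygon boundary count as inside (tolerance 1e-9 km).
* **Species denominators** in effectiveness tables are the full checklist
  group totals (458/232/264-style), not the species present in hotspots.
  Percentages are rounded half-up: 2 decimals in tables, 1 decimal for
  the record-protection share, matching reporting conventions.
* **Cell and area tie-breaks** are always "lowest cell id first", making
  every ordering deterministic.
* **Habitat shift denominator.** The shift fraction is
  (gained + lost) / current range; the |net change| / current range
  alternative can be derived from the returned counts. "No change" is
  strict equality of range sizes.
* **Reclassification scope.** LSA bands are computed for every assessed
  species, but only NT/CC species are counted as upgrades; threatened
  species are never downgraded.
* **Collinearity pruning** walks pairs in input order and drops the
  later-listed member, so callers encode their variable priority by
  ordering columns; constant layers cannot enter a correlation and are
  retained with a message. Pruning is idempotent.

## Problem sizes

Unit and property tests run on grids of 4–400 cells with 10–200 species;
the set-cover oracle compares greedy selections against exhaustive minimum
covers on 200 instances of up to 12 cells × 12 species; mass-conservation
identities run on 100 random instances; the recovery suite spans 10 seeds
of the cluster geometry above. The acceptance script runs the full
pipeline once at the 4096-cell, 458-species defaults. These sizes are the
package's chosen test conditions; all scale linearly in cells × species if
users need more.

## Known limitations

* Planar kilometre coordinates only: real-data users must pre-project;
  there is no geodesic math and no coastline clipping, so edge cells are
  treated as full cells.
* The complementarity tie-balloon at high thresholds described above.
* Pearson correlations between surfaces carry no spatial-autocorrelation
  correction; their p-values are anti-conservative on autocorrelated
  data.
* Suitability modelling itself (MaxEnt or otherwise) is out of scope: the
  climate module consumes suitability surfaces and AUC metadata produced
  elsewhere, or synthetic stand-ins.
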