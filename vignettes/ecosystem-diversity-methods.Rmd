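---
title: "Methods: millennium-scale ecosystem diversity from gridded land-use histories"
author: "ecodivgrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: millennium-scale ecosystem diversity from gridded land-use histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecodivgrid)
```

## The problem

Land use has been redistributing the world's ecosystem types for centuries.
If one treats land-cover classes — primary forest, rangeland, cropland, and so
on — as "ecosystem types", then each landscape (a grid cell of a few hundred
km²) holds a small community of such types, and the standard machinery of
community ecology applies: within-cell (α) diversity measured by richness,
evenness, heterogeneity and compositional entropy, and between-cell (β)
diversity measured by pairwise dissimilarity. `ecodivgrid` implements this
analysis end to end for gridded annual fractional land-use reconstructions in
the LUH2 "states" schema: twelve fraction layers per 0.25° cell per year
(`primf`, `primn`, `secdf`, `secdn`, `pastr`, `range`, `urban`, and five crop
layers), where per-cell fractions sum to the cell's land fraction.

Because the real reconstruction is a multi-gigabyte download, the package
ships a seeded synthetic generator that emulates the schema and its key
statistical structure, so the full pipeline is exercised and tested offline.

## Data model

`LandUseGrid` extends `SummarizedExperiment`: rows are cells (row-major from
the south-west corner), columns are years, and each assay is one type's
cells × years fraction matrix. The class invariant is *closure*: for every
cell and year the fractions sum to the cell's land fraction
(`landArea/cellArea`) within 1e-8. All spatial operations — equal-area
regridding, zone overlay, grain aggregation — treat cells as axis-aligned
rectangles in a cylindrical equal-area projection (x = Rλ, y = R·sin φ, with
the authalic Earth radius R = 6371.0072 km and standard parallel 0°), in
which any lon-lat rectangle maps to a rectangle of exactly its spherical
area. Rectangle intersections are therefore products of 1-D interval
overlaps, computed exactly; no polygon library is involved, and area
conservation under regridding and aggregation holds to floating-point
accuracy (the test suite asserts 1e-6 relative; observed errors are ~1e-15).

The target equal-area grid is built from a configurable cell area
(`GridSpec(targetCellArea = 769)` km², the 0.25°-equivalent at the equator).
The domain is tiled with the nearest integer number of columns and rows of
side `sqrt(targetCellArea)`, so realized cell areas can deviate slightly from
the request but are identical across cells — the property the analysis needs.

## Classification schemes

The twelve layers collapse to nine base ecosystem types: the four natural
layers map one-to-one, the annual crop layers (`c3ann`, `c4ann`, `c3nfx`)
group to *cropland*, and the perennial (woody) crop layers (`c3per`, `c4per`)
to *tree plantations*. The source data do not dictate this split; we group by
growth form because perennial crops are the schema's woody-plantation layers,
which is the structural distinction the nine-type classification encodes.
Two sensitivity classifications cross types with biomes: `natural_x_biome`
(4·B natural + 5 global anthropogenic types; 61 with B = 14 biomes) and
`all_x_biome` (9·B; 126 with 14). Type ids are stable strings
`<base>@<biome>` or `<base>@GLOBAL`, making the cross-products auditable.
Cells whose footprint overlaps two or more biomes are flagged by
`overlayZones()` and excluded from all metrics, because biome boundaries are
not temporally stable; the overlap test uses exact rectangle intersection
with a 1e-9 relative-area tolerance, so a divide lying exactly on a cell edge
flags nothing.

## α metrics

Per cell and year, with `p` the coverage composition (each present type's
share of the cell's land area; Σp = 1):

* richness `E` — number of present types (area > `presenceThreshold`,
  default 0: any strictly positive area counts);
* Shannon `H' = -Σ p log p` (natural log, so the Pielou convention
  `J = H'/log E` holds);
* Pielou `J`, defined only for `E ≥ 2`; undefined values are *dropped* from
  spatial averages, never zero-filled;
* Gini–Simpson `D = 1 - Σ p²` (this, not Simpson's concentration, is forced
  by the requirement that Rao's Q with unit distances equal it);
* Rao's quadratic entropy `Q = Σᵢ Σⱼ d_ij p_i p_j`, the expected
  compositional distance between two random points in the cell.

The dissimilarity matrix `d` is assembled by `buildDissimilarityMatrix()`
from a table of 1 − Sørensen dissimilarities among field-survey land-use
categories: both primary types share the "primary vegetation" values (hence
d = 0 between them), pasture and rangeland share "pasture", non-forested
secondary is the mean of the "intermediate" and "young" secondary rows,
forested secondary is "mature secondary", and everything is rescaled by the
off-diagonal maximum so max d = 1. The shipped default table
(`inst/extdata/source_dissimilarity_synthetic.csv`) is a *synthetic*,
plausible stand-in that exercises the mapping rules; an empirically derived
table is a drop-in CSV replacement. Rao's Q is computed only under the
nine-type scheme: how `d` should extend across biome-crossed types is
genuinely unspecified, so rather than invent a rule we leave Q undefined
there (a mapping error).

## β metrics

Pairwise dissimilarity between cells uses the Baselga partitions.
Incidence-based Jaccard, with `a` shared and `b`, `c` unique types:
`βjac = (b+c)/(a+b+c)`, turnover `βjtu = 2·min(b,c)/(a+2·min(b,c))`,
nestedness `βjne = βjac − βjtu`. Abundance-based Bray–Curtis on absolute type
areas (km², not renormalized shares, so part-land cells weigh as their land),
with `A = Σ min(x,y)`, `B = Σx − A`, `C = Σy − A`:
`βbc = (B+C)/(2A+B+C)`, balanced variation `βbc-bal = min(B,C)/(A+min(B,C))`,
gradient `βbc-gra = βbc − βbc-bal`. Both partitions are exact identities,
asserted to 1e-12 over 10⁴ random pairs; totals are cross-checked against
`vegan::vegdist` in the test suite.

`meanPairwiseDissimilarity()` implements the grain × extent estimator
`β̄ = Σ p_k,i / N`: per pair, the dissimilarity is first averaged over the
years of the time window, then averaged over all qualifying pairs — all pairs
within each extent block at sub-global extent, all pairs at global extent.
Where the pair universe is too large, the estimator subsamples: each draw
takes `sampleSize` cells uniformly without replacement (no regional
stratification — unlike the α bootstrap, which is deliberately stratified),
and the spread over draws is summarized by 1st/9th deciles.
`betaTimeseries()` fixes the cell draws *once* and reuses them across
windows, so each draw traces a coherent trajectory and net change (value
minus the first-window value) is well defined per draw.

## Temporal conventions

Reconstructed land-use values are not independent year to year: they are
piecewise constant within centuries before 1700 and within decades after.
All series are therefore window-averaged first: centurial windows over the
full span (900–999, …, midpoint start + 50, so 950 for the first) and decadal
windows from 1700 (1700–1709, midpoint start + 5 = 1705, mirroring the
centurial rule). Trailing partial windows are dropped with a message. Net
change is the difference to the first (baseline) window of each series —
a baseline that is *not* pristine, merely the series start.

Spatial averages weight cells by land area, globally and per region/biome
(the same weighting rule at every scope). Variability of the global mean is
estimated by a stratified bootstrap: draws of `n` cells without replacement,
allocated across regions proportionally to region size by largest-remainder
rounding (allocations sum exactly to `n` and are each within 1 of exact
proportionality), defaulting to 1% of retained cells per draw and 1000 draws.
The interdecile band (1st to 9th decile of draw means, computed with the
inclusive linear-interpolation quantile definition, R type 7) summarizes each
window; a change between two windows is judged *significant* when the two
bands do not overlap. Presence persistence of a type between two windows
counts a cell as occupied if the type is present in ≥ 1 year of the window —
the weakest, most conservative aggregation, chosen because no within-window
rule is dictated by the problem.

## The synthetic generator

`generateHistory()` emulates what the analysis assumes about the real data:

* the LUH2 schema (12 layers, closure to a static land fraction, 0.25° grid);
* the temporal dependence structure — values constant within centuries before
  the onset year and within decades after, which is exactly what makes
  window-averaging meaningful;
* monotone anthropogenic expansion in the noise-free setting: conversion
  removes primary vegetation in proportion to its remaining stock
  (`1 − exp(−r·Δt)` per block), drawing on secondary vegetation only where
  primary cover has fallen below 5% of the land, so natural types decay
  exponentially and never vanish — presence persists, as in the real record;
* gradual appearance of anthropogenic types: converted area is allocated
  across the eight anthropogenic layers with cell-specific random weights,
  each layer activating only once the cell's cumulative converted share
  passes a seeded threshold (pasture and annual crops are active from the
  start, reflecting year-900 agriculture);
* observation noise on the logit scale, applied per temporal block to
  positive fractions only and renormalized, so closure stays exact and noise
  never creates or destroys presences.

Defaults are fixed once as the study conditions: a 36 × 18-cell 0.25° grid
centred on the equator (the real analysis uses the full globe; a few hundred
cells keep every stage exercised at desk scale), years 900–2000 with onset
1700, post-onset conversion rate 0.003/yr (about 60% of primary stock
converted over three centuries, a realistic order of magnitude; pre-onset
conversion runs at one tenth of that), logit noise sd 0.1, 14 biomes as
longitudinal bands and 17 regions as latitudinal bands, and the 1%-of-cells
sampling rule for both the α bootstrap (1000 draws) and β subsampling
(100 draws).

What the generator does **not** emulate — hence what passing tests do *not*
show about real data: realistic geography (continents, latitudinal biome
structure, spatial autocorrelation of land use), abandonment and secondary
regrowth, crop-functional-type realism beyond the five-layer schema, or any
statistical match to real LUH2 trajectories. Tests on synthetic worlds
establish that the *machinery* is correct (conservation, identities,
estimator behaviour, qualitative signatures), not that real-world numbers
would be reproduced. One scale artefact is worth noting: on a 36-column grid,
14 biome bands put a band edge in roughly every third column, so when band
edges fall inside target cells the flagged fraction is far larger than the
~5% of a global grid; with the default cell-area configuration the target
grid happens to align with the source columns and no cells are flagged. The
boundary machinery is exercised by dedicated constructed layouts in the test
suite instead.

## Numerical and design choices

* Quantiles: R type 7 everywhere (stated for reproducibility; the choice is
  otherwise unconstrained).
* Presence threshold: 0 km² (strictly positive area is present),
  configurable; no minimum-area rule is imposed by the method.
* Grain aggregation: block sums of areas with factor `k`; trailing partial
  blocks are dropped (deterministic and conservative) with a message; zone
  assignments are dropped on aggregation and must be re-overlaid.
* Degenerate inputs: zero-land cells and biome-boundary cells are excluded
  from all metrics; empty compositions and empty-pair comparisons raise
  classed conditions rather than returning zeros; an undefined Pielou value
  propagates as `NA` and is excluded from means.
* Largest-remainder bootstrap allocation ties are broken by stratum order;
  with a valid sample size the allocation can never exceed a stratum, but
  the guard remains as a classed error.
* The orchestration config is a plain named R list (recorded in every output
  row via an MD5 hash plus the seed); a declarative text format would add a
  dependency without adding reproducibility.
* `runAlpha()` bootstraps the global mean by default; regional interdecile
  bands are omitted from the default outputs to keep the default run cheap,
  and can be obtained by calling `bootstrapMeans()` per region.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on grids between 2 and 200 cells with spans of
3–1101 years; the decomposition identities use 10⁴ random pairs and the
Rao–Simpson identity 10³ random compositions. The acceptance script runs the
full pipeline on the default 36 × 18 world (~645 retained land cells,
depending on the seed; 900–2000), with a 1000-draw stratified bootstrap and
100-draw β subsampling.
These sizes are the package's chosen desk-scale study conditions; every
stage scales to larger grids through the same code paths (sparse overlap
operators, vectorized pair computations, and per-distinct-state evaluation
that exploits the blockwise-constant temporal structure).

## Limitations

Rao's Q is restricted to the nine-type scheme. The real biome/region
geometries (and hence the published regional numbers) are out of scope; zone
maps are rasterized integer layers. No spline smoothing is provided — the
smoothed curves in typical presentations of such analyses are visualization
aids, not part of the computational contract. Multi-site (> 2 cells) β
measures and distance-decay analyses are out of scope.
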