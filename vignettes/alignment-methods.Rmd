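---
title: "Measuring the alignment of land acquisitions with conservation priority areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the alignment of land acquisitions with conservation priority areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prioralign)
```

## The question and the data model

Land trusts protect biodiversity by acquiring land outright (fee simple) or by
buying development rights (conservation easements). Systematic conservation
planning delineates *priority areas* — the polygons an ecoregional assessment
says must be protected to represent the region's biodiversity. A natural audit
question is whether the portfolio of acquisitions actually sits inside those
priority areas more often than blind acquisition would.

`prioralign` answers that question from three polygon layers:

* **lands** — one record per acquisition, with optional acquisition date and
  tenure class (`easement` / `fee` / `unknown`);
* **priorities** — the priority-area polygons;
* **states** — jurisdiction boundaries used for clipping and for per-state
  summaries.

All layers are tibbles with a `geometry` list-column of multipolygons in a
planar equal-area frame with kilometre units, because every statistic below is
an area ratio and only an equal-area frame makes those ratios meaningful.
Geographic input is projected with a spherical Albers equal-area conic
(authalic radius, standard parallels 29.5° and 45.5°); the sphere-vs-ellipsoid
approximation changes local areas by well under a percent, which is far below
the sampling noise of anything computed here.

## The overlay pipeline

The assessment follows the standard vector-GIS recipe:

1. **repair** every geometry on load (self-intersections resolved by even-odd
   decomposition), and again after each overlay step;
2. **clip** lands and priorities to the state boundaries, removing marine and
   out-of-region slivers;
3. **stratify** the land records: all records; three acquisition-date periods
   (`[date_min, 2000-01-01)`, `[2000-01-01, 2006-01-01)`, `[2006-01-01,
   extraction_date]`, half-open so boundary dates are unambiguous); easements;
   fee-simple. Undated records stay in the all-records stratum only; records
   with unknown tenure stay in the non-tenure strata;
4. **dissolve** each stratum so overlapping or duplicated records are not
   double-counted, then **intersect** with the dissolved priority layer;
5. summarise nationally per stratum, and per state for the all-records
   stratum.

Dissolving happens *after* subsetting, so a parcel recorded both as an
easement and inside a date window contributes its full area to each stratum it
belongs to. Per-state results are obtained by intersecting the dissolved
layers with each state polygon; for area accounting this is equivalent to a
union overlay with the state layer and is easier to verify: the per-state
overlap areas must add up to the national overlap area, which the test suite
asserts to 1e-6 relative.

## The science influence score

Let $P_{TNC} = A_O / A_{TNC}$ be the fraction of acquired area inside
priority areas, and $P_S = A_P / A_S$ the fraction of the region designated as
priority. If acquisitions ignored the priorities, the expected alignment is
$P_S$ by area-proportional chance. The score

$$ s = \frac{P_{TNC} - P_S}{1 - P_S} $$

rescales the excess alignment so that 0 means chance level and 1 means every
hectare acquired was inside a priority area. It has a generative reading: if a
fraction $s$ of the portfolio is placed always-inside-priorities and the rest
is placed blindly, the expected alignment is $s + (1-s)P_S$, and plugging that
into the formula returns $s$. The score can be negative (alignment worse than
chance), down to $-P_S/(1-P_S)$; negative values are reported as-is. With no
acquired area the score is undefined and reported as `NA`, and a region fully
covered by priorities ($P_S = 1$) is a typed error since alignment carries no
information there.

Scores are computed from unrounded proportions; rounding (half away from
zero, one decimal by default) happens only when reports are rendered. This
matters when checking against published tables whose inputs were themselves
rounded before printing: recomputing a score from printed one-decimal
percentages can drift by ±0.1–0.2 in the final digit.

## The centroid chi-square test

Area ratios do not come with a significance test, so the analysis is reframed
per *event*: each record's geometric centroid either falls inside a priority
area or it does not. Under the area-proportional null the probability of
"inside" is `p_null`, by default the priority fraction of the region's area
computed from the supplied geometry (a printed coverage figure is data, not
method). With observed counts $(n_{in}, n_{out})$ the two-cell Pearson
statistic

$$ \chi^2 = \frac{(n_{in} - p n)^2}{p n} + \frac{(n_{out} - (1-p) n)^2}{(1-p) n} $$

is compared to the upper tail of a chi-square distribution with one degree of
freedom, without continuity correction. Centroids are taken on the
*per-record* (pre-dissolve) geometries because records are the acquisition
events; all records are tested, dated or not. The centroid of a multipolygon
record is the area-weighted centroid of the whole geometry, even if it falls
outside every part; a boundary hit counts as inside (a measure-zero
convention, made deterministic). Expected cell counts below 5 set a
small-sample flag and a warning but the statistic is still returned.

## The synthetic landscape generator

The real land-holdings data behind this kind of audit is partly sensitive, so
the package ships a generator whose output exercises every pipeline stage and
whose parameters are recoverable — the package's primary form of validation.

* **States** are squares tiled in a near-square grid (default two states of
  700 km side, a regional scale at which coordinates stay moderate).
* **Priority patches** are rectangles of equal area and random aspect ratio
  (between 0.5 and 2) whose total area per state matches the configured
  coverage *analytically*, so coverage is exact to machine precision rather
  than approximate. Patches are assigned to distinct cells of a grid and
  jittered uniformly within their cell: placement stays seeded-random but is
  disjoint by construction and terminates at any feasible coverage, where
  free rejection sampling provably stalls once coverage approaches ~0.5.
  The default coverage 0.364 matches the published national priority
  fraction.
* **Parcels** follow the mixture process that defines the score's semantics:
  with probability `influence` (optionally tenure-specific) a parcel is placed
  wholly inside a priority patch chosen proportionally to patch area, with its
  centre uniform over the patch shrunk by half the parcel side; otherwise its
  centre is uniform over the state and the parcel is clipped at the state
  boundary. Square parcels are used because shape is irrelevant to every
  statistic computed and squares keep area bookkeeping exact.

Attributes mirror the published portfolio's audit trail: 57% of records carry
no acquisition date; dated records fall into the three periods with weights
0.48/0.28/0.24 (the published per-period area shares); tenure splits
0.78/0.22 easement/fee (the published area split). Each generator stage draws
from its own deterministic sub-stream of the seed, so adding parcels does not
perturb the state or priority geometry.

**Parcel sizes and the small-parcel regime.** Parcel side lengths are
lognormal, by default `meanlog = log(0.2)`, `sdlog = 0.6` (median 4 ha). The
published data constrain only state totals, not the size distribution, so the
choice is a modelling convenience — but not an arbitrary one. The identity
"expected score = influence" holds exactly only in the small-parcel limit:
priority-driven parcels concentrate in the priority fraction of the landscape,
so their union self-overlaps more than the chance group's, and with median
sides of ~0.5 km this differential shrink biases recovered scores by up to
−0.013 at low coverage (a Boolean-model calculation, confirmed by
simulation). At the default sizes the predicted bias is below 0.002, an order
of magnitude inside the ±0.01 recovery tolerance the validation suite uses.
A 99th-percentile parcel side larger than a quarter of the smallest patch
side is rejected at configuration time; the rare draws beyond the 99th
percentile are clamped to the smallest patch side so every priority-driven
parcel fits its patch.

**Validation scale.** The recovery studies run 20,000 parcels per replicate
and average 20 seeded replicates per condition, across influence
{0, 0.25, 0.5, 0.75, 1} and coverage {0.15, 0.364, 0.55}; at that scale the
replicate standard deviation of the recovered score is ~0.011, so the mean of
20 replicates pins the bias to ~±0.005 at 95% confidence. Passing these tests
shows the pipeline and the score arithmetic are mutually consistent with the
mixture semantics — it does *not* show that real acquisitions follow a
mixture process, that real parcels are square, or that real priority areas
are rectangles.

## Numerical choices

* All polygon boolean operations go through the Clipper integer-arithmetic
  engine on one fixed grid (origin 0, resolution 1e-10 km). A shared grid
  makes results of different calls mutually consistent: conservation
  identities such as `area(A∩B) + area(A∖B) = area(A)` hold to better than
  1e-9 relative, and repeated repair of a valid geometry changes its area by
  less than the grid resolution times its perimeter.
* The engine accepts only a few thousand rings per call (an R protection
  limit), so unions of large layers are computed by recursive bounding-box
  bisection: features straddling a split line are clipped into both halves
  and the resulting pieces have pairwise-disjoint interiors, so their areas
  add exactly. A dissolve therefore returns a minimal *set* of features
  rather than always a single feature; all downstream operations treat the
  two forms identically.
* Overlay artifacts below 1e-9 km² are dropped as slivers.
* Degenerate inputs are explicit: zero-area records are excluded from the
  centroid test with a warning; empty land layers yield a flagged report with
  `NA` alignment rather than zeros; an empty priority layer is an error.
* Report percentages round half away from zero at one decimal, so rendered
  tables are reproducible across platforms regardless of banker's-rounding
  behaviour.

## Interfaces and limitations

File exchange uses GeoJSON (with a `crs_tag` member recording the planar
frame); CSV/JSON for report tables; YAML for run configuration. ESRI
Shapefile and GeoPackage are not read in this build — no vector driver for
them is available to the package — and requests for those extensions fail
with an error naming the supported formats. The `prioralign` command-line
script (in `inst/scripts/`) wraps the two entry points: `simulate` writes a
seeded synthetic landscape plus a manifest echoing the resolved
configuration, and `assess` runs the full assessment on three layer files and
writes the report tables; exit codes are 0 (success), 2 (configuration or
usage error) and 3 (data error).

Known limitations: geodesic (ellipsoidal) areas are not computed; the
centroid null ignores parcel shape and spatial autocorrelation (a
parcel-shape-aware null would be strictly harder and is out of scope); the
score comes with no confidence interval; and the synthetic landscape's
rectangles cannot emulate coastline clipping effects, road- or
hydrology-constrained parcel shapes, or spatially correlated willingness to
sell. Whether a jurisdiction's total area should come from the clipped
geometry or an external constant is exposed as a choice to the caller —
summaries here always use the geometry-derived area.
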