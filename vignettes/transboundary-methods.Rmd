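---
title: "Classifying transboundary marine species and accounting their fisheries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transboundary marine species and accounting their fisheries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transbound)
```

## The problem

Fish do not respect maritime boundaries. When a commercially exploited
species' distribution straddles the Exclusive Economic Zones (EEZs) of two
bordering coastal states, both states draw catch from what is ecologically
one resource, and unilateral management tends to underperform. This package
implements a transparent, testable procedure for deciding, species by species
and EEZ by EEZ, whether a stock should be treated as *transboundary* —
shared with a neighbor — or *discrete*, and for quantifying the catch and
ex-vessel revenue attached to each class of stock.

The procedure needs only gridded inputs: binary presence layers on a
0.5° × 0.5° grid from several independent sources, EEZ polygons with
country/territory metadata, per-stock annual catch series, and
price/CPI tables. Because the real global inputs are large, proprietary in
part, and only partially redistributable, the package ships a synthetic world
generator with recorded ground truth; every claim the test suite makes is a
claim about behavior that can be verified offline.

## The classification model

**Criterion 1 — neighboring EEZs.** The unit of analysis is the EEZ *region*
(a country's EEZ may be split into several regions). Two regions are
neighbors when their polygons touch. Political structure then filters the
edge set: edges between sub-regions of the same country are unusable (a
species crossing a Gulf/Atlantic split of one country is not "shared");
edges between a nation and its own non-continental territory are unusable;
edges between a nation and *another* nation's territory remain usable; and
associated states inherit their parent country identity before evaluation,
so no usable edge can exist between them and the parent. Each unusable edge
carries exactly one reason code (`same-country-subregion` or
`same-nation-territory`), keeping the filter auditable.

**Criterion 2 — data agreement.** A species is taken to be present in a grid
cell only when every presence source agrees: occurrence data, an
environmental niche model, a trait-based distribution model, and the
spatialized catch record. The catch source is sharpened into a filter:
the cell must show strictly positive catch in at least one year of the
2005–2014 reference window. The rationale is that a commercial species
predicted inside a fishing country's EEZ would have been fished — and
reported — at some point in the last decade of data; cells that were never
fished are treated as model over-prediction. Unanimity makes the resulting
range, and everything downstream, deliberately conservative.

**Criterion 3 — spatial distribution.** Presence in a single boundary cell
should not make a species "shared". For each usable neighbor pair (a, b),
the *Area Index* of side a is

$$AI_a = \frac{A_a}{A_a + A_b}, \qquad AI_a + AI_b = 1,$$

where \(A_a\) is the area of the species' consensus cells assigned to region
a. The pair passes when \(\min(AI_a, AI_b) > 0.25\), strictly: both
neighbors must enclose *over* a quarter of the joint shared distribution.
A species is transboundary when at least one pair passes anywhere in its
range; each region holding consensus cells gets a stock label —
`transboundary` if an incident pair passes, `excluded_stock` if the species
passes only elsewhere, `discrete_stock` if it passes nowhere. The canonical
example is an anchoveta-like species spanning three coastal EEZs in a chain:
the two large-share neighbors pass, the small-share tail (around 10% of its
pair's joint distribution) fails, and that tail's catch is accounted as an
excluded stock even though the species is transboundary.

### Design choices that were genuinely open

* **Pairwise index.** The Area Index is evaluated per neighbor pair, not
  over the full multi-EEZ distribution: the three-EEZ example above is
  described in pair terms ("the spatial threshold *between* the two
  countries"), and a joint index over chains is not defined by the source
  procedure. A region is transboundary if *any* incident usable pair passes.
* **Cell assignment.** Cells belong to the region containing their center
  point. This makes assignment a function (each cell counts once), is
  deterministic and cheap, and gives the exact identity \(AI_a + AI_b = 1\).
  A majority-area approximation (a k × k sample lattice per cell) is
  available as an option.
* **Area weighting.** Shares are km²-weighted by default using the spherical
  approximation \(A_{eq}\cos(\mathrm{lat})\) with an authalic Earth radius
  of 6371.0088 km (error well under 0.5% for half-degree cells); raw cell
  counts are available via `weighting = "count"`. The source procedure does
  not state which it used; on the low-latitude synthetic worlds the two
  agree to within a cell.
* **Corner touches.** Whether two regions meeting only at a point are
  "neighbors" is not specified anywhere; both behaviors are exposed
  (`corner_touch`, default `TRUE` — any polygon intersection counts).
* **Strict threshold.** Values exactly at the threshold fail, matching the
  "over 25%" phrasing. At a threshold of 0.5 the classification vanishes
  identically, since both shares of a pair cannot exceed one half — a useful
  end-to-end invariant.
* **Region-level evaluation.** Area Indices are computed at region level;
  aggregation to countries (a species in several sub-regions of one country
  counts once per country) happens afterward, in the accounting layer.

## Catch-trend categories

Each species × EEZ series (annual tonnes, 1951–2014, gaps allowed) is
assessed only when ≥ 10 data years and ≥ 5 *consecutive* data years exist.
Per year, with `max` the historical maximum of the series:

* **B (constant)** — catch > 0.5·max. Unconditional.
* **A (increasing)** — any of: the maximum falls in the final data year;
  the year precedes the maximum and catch ≤ 0.5·max (the one non-strict
  comparison in the printed rule set, kept as printed); or the series
  collapsed after its peak (post-maximum minimum < 0.1·max), the year
  follows that minimum, and catch is between 0.1·max and 0.5·max — a
  rebuilding fishery.
* **C (decreasing)** — the year follows the maximum and catch is under
  0.5·max (either side of 0.1·max).

The A-rebuilding range and C's range overlap after a collapse; precedence
**B → A → C** resolves it (a rebuilding clause that lost to C would never
fire, and B's rule is unconditional). Boundary equalities — catch exactly at
0.1·max or 0.5·max in post-peak years — satisfy neither strict inequality
and fall through to `unassigned`. Ties in the year of the maximum and of the
post-maximum minimum break to the earliest year; this affects only boundary
cases, which the oracle tests confirm. Categories are invariant to positive
rescaling of the series.

The *predominant* category is the mode of the per-year categories over
window years with data (unassigned years do not vote; missing years are not
interpolated). Ties break to the category of the latest categorized window
year among the tied set. Ineligible series report `NoCategory`
(reason `ineligible`); eligible series whose window years are all
unassigned report `NoCategory` with the distinct reason
`no_categorized_window_years`.

## Revenue accounting

Revenue is catch × ex-vessel price per species, country and year, with
prices in 2010 real USD standardized to 2019 USD by the annual-mean US CPI
ratio (upstream, the annual index is the mean of monthly values). Price gaps
fill in three steps: nearest observed year within the species × country
(ties to the earlier year); else the species' cross-country mean for that
year; else the row is flagged unfillable and dropped with a warning count.
Window means divide by the number of window years (10), not
years-with-data, so missing years count as zero catch — matching an
"annual average over 2005–2014" reading.

Stock-class accounts partition every classified species × region into
transboundary / excluded / discrete exactly (conservation is asserted at
1e-6 relative). Rollups aggregate to countries and UN sub-regions;
per-km² figures divide by the summed area of the EEZ regions that actually
host at least one stock of the class, and sub-region rows report the
mean ± sd across member countries (sample sd, configurable in principle;
single-country groups report an sd of 0 and carry a `degenerate` flag).

## The synthetic world

The generator's defaults describe a fixed stated world, not a tuning
surface:

* **Mosaic** — `n_regions` Voronoi cells of uniformly drawn seed points,
  snapped to the 0.5° grid, over a 20° × 10° low-latitude box. Voronoi
  partitions guarantee the properties that matter downstream — full
  coverage, no overlap, a rich adjacency structure — while making no claim
  of coastline realism. Seeds are redrawn (deterministically) until every
  region is nonempty.
* **Ranges** — per-species target shares over regions, mostly two-region
  splits along a usable edge with the minor share drawn U(0.05, 0.5), so
  both passing and failing pairs occur; realized shares (count and km²) are
  recorded as ground truth. Cells are sampled within regions by
  largest-remainder apportionment, so realized count shares sit within one
  cell of the target.
* **Presence sources** — the three model/observation layers drop each range
  cell and add each outside cell independently with probability
  1 − agreement rate (the simplest noise that exercises a unanimity rule);
  the catch layer is the range itself, since the generator spatializes
  positive window catch onto exactly those cells.
* **Catch series** — constructed by inverting the category rules: B-series
  draw every year above 55% of the maximum; C-series peak mid-series and
  decline into the window at 12–45% of max with the post-peak minimum held
  above 10%; A-series are either late-peak (maximum in the final year) or
  collapse-and-rebuild shapes; NoCategory series emit 8 scattered years.
  Magnitudes are lognormal (median 50 kt) — no claim of realism for catch
  magnitudes is made beyond the category structure.
* **Prices/CPI** — lognormal species base prices (median 1,500 USD/t),
  country multipliers, a mild year drift; a smooth 2.1%/yr CPI with
  2010 = 100.

What a green test does establish: the classifier, trend assessor and
accountant reproduce known truth exactly on noise-free worlds, agree with
brute-force oracles, and satisfy the structural invariants. What it does not
establish: behavior on real coastline geometry (antimeridian crossings,
multipart EEZs with holes), realistic spatial autocorrelation of presence
noise, or realistic catch magnitude distributions.

## Numerical notes

* Geometry is planar lon/lat. Containment is an even-odd ray cast; adjacency
  classifies segment pairs as collinear-overlap (edge touch) versus
  point intersection (corner touch) with an epsilon of 1e-9 degrees. For
  the lattice-aligned polygons the generator emits, these predicates are
  exact; no external spatial library is required or used.
* Grid-cell centers are strictly interior to lattice-aligned regions, so
  boundary ambiguity in containment cannot arise in generated worlds;
  overlapping regions that both contain a cell center raise an error
  naming the pair.
* All-zero catch series are degenerate: every year is unassigned and the
  assessment reports `NoCategory` rather than dividing by a zero maximum.
* Accumulations use double-precision sums in fixed (sorted) order, so
  conservation checks hold to 1e-6 relative and reruns are bitwise
  identical.

## Known limitations

* Real-world EEZ shapefiles with curved geometry are readable (GeoJSON) but
  the adjacency predicate has only been validated on lattice-aligned
  polygons; with no `sf`/GEOS dependency available, antimeridian splitting
  and exotic geometry are out of scope.
* Straddling (EEZ + high seas) and highly-migratory designations, distance-
  based neighborhoods, and within-EEZ genetic stock structure are
  deliberately not modeled.
* The significance tests reported alongside the original analysis (ANOVA /
  MANOVA / post-hoc comparisons) are standard library calls on the rollup
  tables and are not re-implemented here.
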