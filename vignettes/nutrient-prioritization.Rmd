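---
title: "Prioritizing subwatersheds for nutrient-reduction conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing subwatersheds for nutrient-reduction conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Excess nitrogen (N) and phosphorus (P) from nonpoint agricultural sources
degrade surface and ground waters, and conservation resources are limited.
A national, synoptic prioritization asks two questions for every HUC8
subwatershed: *does this subwatershed need nutrient reduction at all*, and
if so, *which combination of conservation practice types is most likely to
deliver it* — in-field measures (reducing nutrient inputs, keeping
nutrients from leaving fields) and/or edge-of-field measures (buffers,
restored wetlands, treatment of tile-drainage effluent).

`nutprior` implements that framework as a reusable pipeline: nutrient
budgets from component fluxes, landscape metrics from land-cover grids, a
five-step threshold decision tree, and basin/national reporting products,
plus a seeded synthetic-data generator so the whole pipeline can be run
and tested without access to the original national datasets.

## Nutrient budgets

For each subwatershed and year the agricultural surplus is

$$ S = \frac{I - O}{A} \quad \left[\mathrm{kg\,ha^{-1}\,yr^{-1}}\right] $$

where the inputs $I$ are synthetic fertilizer, cultivated biological
fixation, atmospheric deposition onto farmland and livestock waste for N
(fertilizer and livestock waste only for P), the single output $O$ is crop
removal, and $A$ is the *total* watershed area in hectares — not
agricultural area — so that the flux reflects likely pressure on the
watershed's waters. Nutrient use efficiency is $E = O / I$, undefined
(missing) when $I = 0$. The two are linked by the identity
$S \cdot A = I\,(1 - E)$, which the test suite asserts on $10^4$ random
records at relative tolerance $10^{-9}$.

Negative surpluses are meaningful (soil mining: crop removal drawing down
soil reserves) and are never clipped. Surplus and efficiency are averaged
over the census years (2002, 2007, 2012 in the national application) to
smooth short-term swings; missing efficiencies are excluded from that mean
with the count of contributing years reported. Legacy P is the inclusive
sum of annual P surpluses over 1945–2001.

One definitional point was genuinely open: the narrative description of
efficiency mentions nutrients incorporated into "crop harvest and
livestock", while the tabulated definition counts outputs as crop removal
only. We follow the tabulated definition — outputs are crop removal —
because it is the one the budget identity and the published data
dictionary support; livestock products are not a separate output term.

## Landscape metrics

The tile-drainage metric starts from a fine (30 m) binary prediction grid.
`coarsen_binary()` aggregates it (factor 5, to 150 m) by **block mean**,
yielding fractional cover. The original analysis states only the target
resolution, not the aggregation statistic; we chose the block mean over
majority vote because it conserves total tile area exactly
($\sum \text{coarse} \times f^2 = \sum \text{fine}$), and conserved area
is what the zonal percentages consume. Grids not divisible by the factor
are padded with zeros (non-tile, non-agriculture); padded cells carry a
missing zone id and are excluded from zonal sums.

`zonal_percent()` assigns cells to watersheds by a zone-id grid (exact
raster intersection — at this scale polygon-overlay precision is not the
limiting error), sums tile and agricultural cover per zone, and reports
$100 \times \text{tile}/\text{ag}$. Zones with no agricultural area get a
missing percentage with a warning. Nonbuffered agriculture is expressed as
a percent of the *watershed* (not of agricultural land) via
`percent_of_watershed()`: the same unbuffered area matters more in an
agriculture-heavy watershed.

Grids are plain matrices (row-major, origin upper-left), read and written
as single-band TIFF via the `tiff` package; zone grids for small fixtures
can be CSV `(row, col, zone)` triples. No georeferencing arithmetic is
needed for the correctness of any metric.

## The decision tree

Classification is per nutrient, independently for N and P, with five
gates (defaults in parentheses):

1. surplus at or above the high-surplus cutoff (7 kg-N, 1 kg-P ha⁻¹ yr⁻¹
   — the national medians) — otherwise `NOT_PRIORITY`;
2. efficiency **below** 0.7 (≈ the 75th percentile nationally, and a
   widely promoted stewardship goal) puts the record on the in-field
   branch: input reduction leads the strategy. Field-loss prevention
   (cover crops, reduced tillage) applies to every priority record
   regardless of efficiency;
3. tile drainage ≥ 30% of agricultural land (≈ 95th percentile) flags
   drainage-effluent management;
4. nonbuffered agriculture ≥ 2% of the watershed (40th percentile) flags
   edge-of-field buffering;
5. where step 3 or 4 fired, potentially restorable wetlands ≥ 10% of
   agricultural land (≈ the national median) selects wetland restoration
   as the buffering mechanism.

Boundary semantics follow the published wording exactly: `>=` everywhere
except the efficiency gate, which is strict `<` — a subwatershed at
exactly 0.7 is already "operating efficiently" and goes to the
edge-of-field branch. The class labels combine branch (`INFIELD_`/`EDGE_`)
with the stacked actions (`WETLAND`, `BUFFER`, `_DRAINAGE`); an
edge-branch record needing neither drainage management nor buffers falls
back to `INFIELD_ONLY`, since field-loss prevention is all that remains
(this reproduces the published handling of a high-efficiency,
well-buffered Texas subwatershed). Wetland suitability is evaluated
whenever either drainage or buffering is needed, because constructed
wetlands are also the canonical treatment for tile effluent.

Priority records with a missing downstream metric become
`UNCLASSIFIED_MISSING` with the reason recorded, rather than silently
passing with partial flags. Records below the surplus gate may carry
missing downstream metrics freely — they short-circuit at step 1. The
coverage filter (`pct_land >= 1.5`, configurable) drops coastal
subwatersheds before classification, mirroring the national analysis.

`sensitivity_scan()` re-runs the classification over a grid of thresholds;
monotonicity (raising a "high" cutoff never increases its flag count;
raising the efficiency cutoff never decreases the input-reduction count)
is asserted in the tests.

## Summaries

`tally()` counts classes per HUC2 basin and nationally on a complete
grid (explicit zeros), so counts always partition the record set;
`tally_aggregates()` adds the derived step counts (priority, in-field
branch, stacked, edge branch). `percent_share()` reproduces the reporting
convention: one decimal, halves rounded away from zero.
`net_surplus_share()` uses *net* semantics — negative surpluses stay in
both numerator and denominator — so shares above 100% are possible and
meaningful. The Spearman matrix (average ranks, pairwise-complete
deletion) is intended for the area-based metrics (km²), while basin
median/IQR summaries use the percent metrics; quantiles use linear
interpolation between order statistics (R's default type 7 — the source
analysis does not state a convention).

## The synthetic generator

`simulate_metrics()` draws a latent multivariate normal, maps each column
through a marginal quantile function (Gaussian copula), and derives the
percent metrics from simulated areas. Its defaults are the national study
conditions: 2092 subwatersheds over 18 basins, with basin sizes drawn from
a Dirichlet weight vector to mimic uneven basin totals.

**Correlation targets.** The published pairwise Spearman correlations
(e.g. NUE–PUE 0.91, nonbuffered–agricultural area 0.91, N surplus–
agricultural area 0.68) are converted to latent Pearson correlations by
$\rho_P = 2\sin(\pi\rho_S/6)$. The resulting matrix is not positive
definite — published pairwise values need not be jointly consistent — so
it is completed by alternating projection between the positive-definite
cone (Higham's nearest correlation matrix, via `Matrix::nearPD`) and the
affine set holding the published entries fixed. Only unspecified entries
move; the completion sits on the PSD boundary and a $10^{-6}$ ridge keeps
the Cholesky factor stable. A plain nearest-PD repair was rejected because
it shifted published pairs by up to ~0.05.

Unspecified pairs default to zero, with one exception: pasture area versus
agricultural area defaults to 0.6. Pasture is a subset of agricultural
land, so independence is unphysical — with independent heavy-tailed
marginals the subset constraint forced clipping in roughly a quarter of
rows, which both induced a spurious pasture–agriculture correlation and
diluted the published pasture–P-surplus pair.

**Marginals and anchors.** Areas are lognormal, surpluses shifted
lognormal (so negative P surpluses — soil mining — occur, in about 10% of
records), efficiencies logit-normal on (0, 1). Parameters were calibrated
once, from closed-form lognormal moments plus a single large calibration
draw, against the published quantile anchors and national totals: median
surpluses 7 and 1 kg ha⁻¹ yr⁻¹; NUE median 0.46 (IQR 0.26–0.65) and PUE
median 0.41 (IQR 0.19–0.72); percent tile of agricultural land with 95th
percentile near 30%; percent nonbuffered near 2% at its 40th percentile
with a national total near 741,000 km²; percent restorable wetlands with
median near 10%; tile and wetland totals near 223,000 and 514,000 km²;
percent agriculture median 16%. At $n = 5000$ every published pair is
recovered within ±0.05 and every anchor within the tolerances asserted in
the test suite.

**Consistency between tables.** In a closed budget, $E < 1$ iff $S > 0$;
the copula treats efficiencies and surpluses as separate marginals, so a
small fraction of rows violate that accounting link. `simulate_metrics()`
returns the raw draw (that is what the correlation and anchor checks
measure); `simulate_fluxes()` refuses sign-inconsistent rows; and
`simulate_bundle()` first mirrors the efficiency across 1
($e \to 2 - e$, preserving distance from break-even) on the affected rows
so that component fluxes exist and budgets recomputed from them reproduce
the metrics to $10^{-9}$. Component splits (fertilizer/fixation/
deposition/livestock for N, fertilizer/livestock for P) are jittered
Dirichlet draws around typical proportions; totals per year are exact, so
multi-year means round-trip exactly.

**What the generator does not emulate.** Watershed ids are labels: there
is no spatial autocorrelation or contiguous geography, and the true
marginal shapes of the national inventory are unpublished — only the
anchors above are matched. Consequently class *counts* on synthetic data
approximate but do not reproduce the published national tallies, and
passing tests demonstrate correctness of the pipeline's logic, not
fidelity of any specific synthetic map to the real landscape.

## Problem sizes and numerical choices

Property tests use $10^4$ flux records for the budget identity, 5000
synthetic records for partition/tally and copula-recovery checks, 2000 for
threshold sweeps, and 50×50 grids for zonal oracles; the analysis scripts
run the full 2092-record national configuration. Key tolerances: budget
identity and bundle round-trip $10^{-9}$ (relative); Spearman agreement
with an independent rank-then-Pearson implementation $10^{-12}$;
correlation recovery ±0.05 at $n = 5000$; anchor recovery ±1 kg (N
median), ±0.3 kg (P median), ±6/±1/±2.5 percentage points for the
tile/nonbuffered/wetland anchors, reflecting sampling error plus the
approximation error of the derived-ratio marginals. Ties in ranks use
average ranks; duplicate watershed ids are errors everywhere; zero-input
watersheds carry missing efficiency and are excluded from the efficiency
gate (they cannot be high-surplus in practice, and the ratio is
undefined).

## Known limitations

- Nonbuffered-agriculture and restorable-wetland percentages are consumed
  as inputs; deriving them from elevation/land-cover flowpath tracing is
  out of scope, as is constructing the national nutrient inventory from
  raw census data.
- The decision tree is deliberately coarse: it recommends strategy
  *types*, not practices, and ignores economics and adoption likelihood.
- Efficiencies simulated by the generator stay below 1 before
  reconciliation, whereas real inventories occasionally exceed 1; only
  sign-reconciled rows do so here.
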