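---
title: "Ecosystem natural capital accounting for landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecosystem natural capital accounting for landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(encaland)
```

## The accounting model

Ecosystem natural capital accounting (ENCA) tracks, in purely biophysical
units, how much a bounded landscape can deliver and how that capacity changes
between an opening and a closing date. The package implements the full chain
for a landscape partitioned into **socio-ecological landscape units (SELUs)**
— one unit per sub-watershed, typed by its dominant land-cover group — with
four linked accounts:

1. **Land cover.** Two co-registered categorical rasters are
   cross-tabulated; every changed pixel is assigned to one of seven causal
   *land-cover flow* classes (lf1 artificialisation … lf7 other; lf0 = no
   change). The account records, per class and in hectares, the opening
   stock, formation and consumption by flow class, and the closing stock.
   The closure identity `closing = opening + formation − consumption` holds
   exactly by construction, and every changed hectare is counted once as a
   formation (of its destination class) and once as a consumption (of its
   origin class).

2. **Water** (thousand m³ per SELU). Stocks (W1_x), inflows (W2_x: rainfall,
   drainage net of percolation, upstream inflows, secondary returns) and
   outflows (W3_x: actual evapotranspiration, downstream outflow,
   abstraction). Derived rows follow fixed identities, notably the net
   accessible resource `W6 = W2a + W2b − W3_2 − W3_3` and total use
   `W9 = W3_1 + W3_4`. The sustainable-use index is the capped ratio
   `W13 = min(1, W6/W9)`; with the composite health index W14 (an input —
   no diagnostic formula is defined for it, so it must be supplied; the
   synthetic generator uses 0.95) it yields the water internal unit value
   W15.

3. **Carbon** (tonnes C per SELU). Stocks by pool (aboveground, litter,
   roots, soil organic carbon, livestock), inflows dominated by net primary
   production, withdrawals (crops, grazing, roundwood) and indirect losses
   (fuel combustion). The accessible surplus is `C10 = C10_1 × C10_2`, where
   C10_2 in [0, 1] encodes the limitation of use due to nature protection.
   Sustainable use is `SCU = min(1, C10/C5)` with `C5 = C3 + C4`, combined
   with the carbon health index CEH into CIUV.

4. **Infrastructure functional services.** Per-SELU landscape potential
   `LEP = GBLI × HNVI × FI` — greenness (0–100), high-nature-value
   multiplier (≥ 1), and a fragmentation index — and river potential
   `REP = RAWI × HNVI_riv × frag_riv` with
   `RAWI = Σ length × log10(discharge)`. Their area-integrated net values
   add to the total potential `TEIP = NLEP + NREP`; use intensity is
   `EISU = min(1, TEIP2_adj / TEIP1_adj)` on calibrated potentials, combined
   with a health index EHI into EIIUV.

The three internal unit values average into the per-SELU capability unit
value `ECU_P = (CIUV + W15 + EIIUV)/3`, which multiplies each accessible
resource: `TEC = C10·ECU_P + W6·ECU_P + TEIP_adj·ECU_P`, summed over SELUs.
The inter-date difference in total ecosystem capability is the **ecological
debt** (negative) or **credit** (positive).

## Design choices where the method leaves room

Several points of the published method are under-determined; the package
fixes them explicitly and keeps each one configurable.

* **Index combination.** The method text describes the internal unit value
  as a *multiplication* of the use and health indices, but every published
  internal unit value is reproduced by their *arithmetic mean* (e.g. use
  0.50 and health 0.95 print as 0.72, not 0.475). The mean is therefore the
  default; `combiner = "product"` switches to the multiplicative form
  everywhere.

* **Evapotranspiration orientation.** The printed estimation formula
  `ETr = (Pavg/ETravg) · P` yields ETr > P whenever long-run precipitation
  exceeds long-run evapotranspiration, which contradicts the meaning of
  *real* evapotranspiration. [estimate_etr()] therefore defaults to the
  inverted ratio `(ETravg/Pavg) · P` and says so with a message; the
  as-printed orientation remains available. The discrepancy is documented,
  not silently repaired.

* **Aggregate lines.** Published C2/C3 totals exceed the sums of their
  printed components — unprinted component lines exist. The assemblers
  never hard-code a component list: they sum whatever components are
  supplied, treat a supplied aggregate row as authoritative, and report the
  gap in a `reconciliation` attribute rather than forcing either number.

* **Fragmentation normalisation.** The fragmentation index averages three
  components; the method names them (effective mesh size, patch count,
  tree/basin ratio) without normalisations. We use `meff/A`, `1/N_patches`
  (1 for a single patch, 0 for no habitat) and the clamped tree-cover
  share, so that all three equal 1 in an intact landscape — consistent with
  published forest SELUs scoring ≈ 1. Habitat patches are connected
  components under rook (4-neighbour) adjacency.

* **Potential calibration.** The published adjusted infrastructure
  potentials are a constant multiple of the raw ones within each year
  (×1.1287 at the opening date, ×1.0854 at the closing date) but the
  derivation of the scalar is not given. It is a declared configuration
  input (`adjustment`), applied uniformly to all SELUs.

* **Aggregation order for net potentials.** Printed NLEP/NREP cannot be
  reconstructed from printed SELU-mean indices, so the spatial aggregation
  order is declared: per-pixel greenness × protection products are summed
  first, then scaled by the SELU fragmentation index and `pixel_area/100`;
  NREP mirrors this as `REP/100 × area`.

* **Flow classification.** The published account does not print a
  cell-level transition→flow mapping. The default rules are
  destination-driven with origin overrides (to village → lf1; crop→crop and
  within-family forest-density changes → lf3; other changes into crops →
  lf2; woody cover degrading to savannah/shrub → lf4; changes into woody
  cover → lf5; into barren/tan/water → lf6; else lf7) and are a plain
  character matrix, fully overridable.

* **Ties and degenerate inputs.** Dominant-land-cover ties break by a fixed
  natural-first priority (Forest > Mangrove > Wetland > Shrubland >
  Agricultural > Estuary > Human footprint). Zero use scores a
  sustainable-use index of 1; negative accessible water clamps to 0; a
  zero opening potential leaves EISU undefined and flagged. A pixel that is
  nodata at either date is excluded at both, keeping the two universes
  identical. All internal arithmetic is full precision; two-decimal indices
  and integer volumes are presentation only, and capability chains use
  unrounded indices throughout.

## The synthetic scene generator

No satellite, climate or survey inputs ship with the package; instead
[generate_scene()] builds a fully known synthetic study area: contiguous
land-cover patches from seeded region growing (contiguity matters because
fragmentation metrics are computed on the result), watersheds as Voronoi
cells of random seed points (an irregular partition without needing a DEM),
a river network as a spanning tree over watershed centroids with discharge
growing downstream and an outlet to the sea, and a protection hard core
covering the most forested watersheds up to a target area share
(default 25%, multiplier 1.14 as in the case-study zoning).

Its default conditions mirror the Mahavavy-Kinkony setting: the 16-class
dry-tropical nomenclature, 15 m pixels (0.0225 ha), 7 watersheds, long-run
precipitation 1554 mm/yr (the study area's annual rainfall) against 1300
mm/yr evapotranspiration, and a slightly drier closing period (1480 mm).
Per-class carbon densities and greenness weights are stylized
order-of-magnitude values for such a mosaic (dense dry forest 90 tC/ha
aboveground, mangroves 120 tC/ha with carbon-rich soils, savannah and crops
low; greenness 80–100 for woody classes, 40–60 for crops, ≤ 20 for water,
barren and villages). Line items are *deterministic* functions of the
rasters, climate and parameters — runoff accumulates down the river tree so
the water account is mass-consistent, carbon stocks scale linearly with
per-class densities — so an unchanged landscape provably yields a zero
ecological balance, which the tests exercise end-to-end.

What the generator does **not** emulate: classification error and mixed
pixels, seasonality within an accounting period, groundwater dynamics,
survey-based use estimates, or spatial autocorrelation of climate. Passing
tests on synthetic scenes therefore demonstrate the *accounting* is correct
given its inputs, not that any particular real landscape was measured
correctly.

## Worked example: the Mahavavy-Kinkony Complex accounts

The package ships the published 2013–2018 line items of the
Mahavavy-Kinkony Complex protected area (north-western Madagascar,
~350,762 ha) as plain CSVs; all derived rows are recomputed:

```{r mkc}
water13 <- assemble_water_account(mkc_water_items(2013))
round(water13[c("W6", "W9", "W13", "W15"), c(5, 8)], 2)

carbon13 <- assemble_carbon_account(mkc_carbon_items(2013))
round(carbon13[c("C5", "C10", "SCU", "CIUV"), c(4, 8)], 2)

fa <- mkc_landcover_account()
fa$net_change["Dense dry forest"]
```

Dense dry forest lost a net 3,528 ha over the five years; the mangrove SELU
used water at 78% sustainability and carbon at 53%; the forest SELU's carbon
use index is 0.83. Chaining the three accounts:

```{r cap}
tec18 <- sum(mkc_capability(2018)$TEC)
ecological_balance(5418668, tec18)
```

A −5% loss of total ecosystem capability: an ecological debt of 275,164 ECU.

## A complete synthetic run

```{r run}
run <- run_pipeline(
  scene_config(grid_shape = c(24, 24), seed = 7),
  scenario = data.frame(from = 61, to = 41, n_pixels = 15)
)
run
```

Converting dense dry forest to cropland lowers the closing-date carbon
inflow and greenness, producing a (small) synthetic ecological debt.

## Problem sizes, numerics, limitations

The test suite runs on grids up to 32 × 32 (against per-pixel brute-force
oracles) and scenes of 20–30 pixels a side with 4–7 watersheds; the
generator scales to a few hundred pixels a side in pure R, which is ample
for validation work. Published-table reproductions are exact for additive
rows, to two decimals for indices, and within the ±1–4 unit rounding drift
the printed tables themselves carry (their grand totals differ from their
own cell sums by up to 4 ha). One printed inconsistency is surfaced rather
than matched: the published W9 *Total* (502,033) is not the sum of its own
per-SELU row (775,875); the engine reports the consistent sum. Capability
rows chain unrounded indices, so recomputing them from the *printed*
two-decimal components reproduces the published capabilities only to within
about 2% — the accounts must be chained at full precision, which is what
`run_pipeline()` does.

Known limitations: no DEM-based watershed delineation or hydrological
simulation; no image classification (rasters are inputs); river segments
are attributed to their upstream watershed rather than split at boundaries;
monetary valuation of the debt is out of scope.
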