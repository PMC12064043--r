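# encaland

Biophysical **ecosystem natural capital accounting (ENCA)** for bounded
landscapes, in R. The package is aimed at protected-area managers and
ecosystem-accounting practitioners who have two dated land-cover maps, a
sub-watershed partition and per-unit resource line items, and want the full
chain of ENCA accounts:

* a diachronic **land-cover stock/flow account** (formation and consumption
  by causal flow class lf1–lf7, in hectares, with exact stock closure
  `closing = opening + F − C`);
* **socio-ecological landscape units** (SELUs): one unit per sub-watershed,
  typed by dominant land-cover group;
* the **water account** (per-SELU stocks/inflows/outflows in 1000 m³; net
  accessible resource `W6 = W2a + W2b − W3_2 − W3_3`, total use
  `W9 = W3_1 + W3_4`, use index `W13 = min(1, W6/W9)`, internal unit value
  `W15`);
* the **carbon account** (tC; accessible surplus `C10 = C10_1 × C10_2`, use
  `C5 = C3 + C4`, sustainability `SCU = min(1, C10/C5)`, internal unit
  value `CIUV`);
* the **infrastructure functional-services account**
  (`LEP = GBLI × HNVI × FI` with an effective-mesh-size-based fragmentation
  index, river potential from `RAWI = Σ length × log10(discharge)`,
  `TEIP = NLEP + NREP`, use intensity
  `EISU = min(1, TEIP2_adj/TEIP1_adj)`);
* the **capability account**: `ECU_P = (CIUV + W15 + EIIUV)/3`, total
  ecosystem capability `TEC = (C10 + W6 + TEIP_adj) × ECU_P` summed over
  SELUs, and the inter-date **ecological debt/credit**.

A seeded synthetic-landscape generator (`generate_scene()`,
`apply_change_scenario()`) provides fully known ground truth — contiguous
land-cover patches, Voronoi watersheds, a routed river network, protection
zoning and deterministic line items — so every account is testable without
external data. The published 2013–2018 accounts of the Mahavavy-Kinkony
Complex protected area (Madagascar) ship as plain-CSV worked-example data
(`mkc_*()` accessors).

## Worked example

Reassembling the published water and carbon accounts from their raw line
items and computing the ecological balance:

```r
library(encaland)

water13 <- assemble_water_account(mkc_water_items(2013))
round(water13[c("W6", "W9", "W13", "W15"), "Mangrove Landscape"], 2)
#>       W6       W9      W13      W15
#> 53983.00 68974.00     0.78     0.87

carbon13 <- assemble_carbon_account(mkc_carbon_items(2013))
round(carbon13[c("SCU", "CIUV"), "Forest landscape"], 2)
#>  SCU CIUV
#> 0.83 0.92

ecological_balance(5418668, sum(mkc_capability(2018)$TEC))
#>    delta percent label
#> 1 -275164      -5  debt
```

The mangrove SELU used 78% of its accessible water sustainably in 2013; the
forest SELU's carbon use scored 0.83; over 2013–2018 the whole protected
area lost 5% of its total ecosystem capability — an ecological debt of
275,164 ECU.

A fully synthetic end-to-end run:

```r
run <- run_pipeline(scene_config(grid_shape = c(24, 24), seed = 7),
                    scenario = data.frame(from = 61, to = 41, n_pixels = 15))
run$summary$label  # "debt": forest-to-cropland conversion lowers capability
```

See `vignettes/enca-accounting.Rmd` for the model, its assumptions, and all
design choices.

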