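---
title: "Identifying métiers from haul-level logbooks and sales notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying métiers from haul-level logbooks and sales notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metierid)
```

## The problem

Multi-gear coastal fleets — hundreds of vessels switching between traps,
gillnets, trammel nets, dredges and longlines, catching hundreds of species —
make gear-specific fishing effort hard to quantify. The EU Data Collection
Framework's *métier* concept stratifies fishing operations by gear, target
species (assemblage), area and season; "level 6" adds gear-selectivity detail
such as mesh or hook size. `metierid` implements a complete, auditable
pipeline that identifies métiers at haul level from two administrative data
streams that already exist for most EU fleets:

* **electronic logbooks** — one record per haul: gear, positions, set/haul
  timestamps, per-species catch weights;
* **sales notes** — one record per trip: species sold, weights and values,
  from which per-trip average prices follow.

The unit of effort throughout is the *haul*. The pipeline stages are quality
control, value-based target attribution, métier keying and rank-frequency
selection, environmental annotation, and statistical characterization. A
seeded synthetic-fleet generator makes every stage testable without
confidential data.

## Target species by value

The target species of a haul is the species contributing the largest *sale
value* (weight × the trip's average price), not the largest weight: métiers
targeting small catches of valuable species (lobsters, soles) would otherwise
disappear into bycatch. Ties are broken by greater catch weight, then
lexicographically, so attribution is deterministic. The potential métier is
keyed on gear × target species; the selectivity descriptor (modal mesh size
or hook number of the métier's hauls, with the observed min–max range) is
attached at reporting time, because a métier has one characteristic gear
configuration, not one per haul.

A consequence worth keeping in mind: a routinely caught bycatch species that
happens to fetch a high price can top a haul's value and found a spurious
métier. This is why selection is followed by *validation* — an external
table (literature, on-board observation, interviews) that the pipeline only
consumes, never computes.

## Quality control

Seven exclusion rules are evaluated exhaustively for every haul (a haul is
removed once but the report lists every rule it violates):
outside FAO subarea 27.9; midpoint depth beyond 2000 m (outside the fleet's
operating range; midpoints on missing bathymetry are *not* removed, since
the excess depth cannot be asserted); trips not departing from and returning
to a mainland port; miscellaneous gear; zero catches; a caught species with
no price in the trip's sales note; and abnormally high reported weights.
The last rule is operationalized at trip level — the summed logbook weight
of a species across the trip's hauls exceeding `weight_tolerance` (default
1.0) times its sold weight — because sales notes are trip-level; every haul
of the trip carrying that species is flagged. The report also restates the
removal accounting restricted to hauls already inside subarea 27.9, since
the ordering of that first selection step relative to the percentage is a
legitimate ambiguity.

## Rank-frequency selection

With hundreds of potential métiers per decade, most represented by a handful
of hauls, the important ones are chosen per gear from the rank-frequency
curve. Instead of a visual judgement of where the curvature stabilizes, the
package fixes a reproducible knee rule: truncate the ranked counts at
`max_rank` (default 20), min–max normalize both axes, and take the rank with
the greatest perpendicular distance to the chord joining the first and last
points. Ties go to the larger rank; a flat curve keeps everything; a single
métier is always kept, so even sparsely used gears retain at least one
métier. The rule is scale-invariant by construction. Raw counts are used
(not logs); both the cap and the normalization are exposed as arguments.

The exclusion accounting mirrors the published fleet summary shipped in
`fleet_gear_summary()` / `fleet_metier_summary()`: feeding those reference
tables through `selection_accounting()` reproduces the printed totals —
197,081 valid hauls, 307 potential métiers, 270 excluded carrying 6% of
hauls at 4.5 hauls per métier per year, 28 of 37 selected métiers validated.

## Environmental annotation

Each haul is annotated at the midpoint of its set and haul positions:

* **season** from the set timestamp (Winter Jan–Mar, Spring Apr–Jun, Summer
  Jul–Sep, Autumn Oct–Dec). The set time is used because it is when the
  fishing decision is made; landing dates can fall in the next quarter.
* **fishing area** from an ordered latitude/longitude rule encoding the
  canyon landmarks that structure the Portuguese shelf: NW/CW split at
  39.6°N (Nazaré Canyon), CW/SW at 38.4°N (Setúbal Canyon, just south of
  Sesimbra), SW/S at the −8.99°E cape corner where the west coast turns
  into the south coast. The published landmarks are geographic features,
  not coordinates, so the three numbers are configuration, recorded with
  every analysis output, rather than false precision.
* **depth stratum** from a bathymetry raster: Shallow < 200 m,
  Medium 200–500 m (closed interval — both boundaries are Medium),
  Deep > 500 m.
* **sediment class** from a substrate raster with the six-class vocabulary
  Mud, Sand, Coarse, Mixed, Rock, Unknown. Missing substrate becomes the
  explicit `Unknown` class and the haul is kept.

Rasters use a plain-text single-band format with a sub-0.01° pixel
contract, and point sampling is containing-cell lookup with no
interpolation — the right semantics for a categorical substrate raster.
Midpoints outside raster coverage are flagged and excluded from area-based
tests only.

## Statistical characterization

Effort distributions are compared with chi-square machinery guarded the way
small expected counts demand:

* `gof_uniform()` tests uniform effort across the levels of area, season
  and depth for each métier. The test is *not applied* when any observed
  level frequency is below 5 (usually a zero); the result instead carries an
  advisory flag — for samples of thousands of hauls, a season or area with
  zero hauls is an intentional decision not to fish, equivalent in substance
  to rejecting uniformity, but no p-value is fabricated for it. Sediment is
  not tested (too many levels plus Unknown).
* `independence_test()` crosses the two most descriptive variables, area ×
  season, after dropping all-zero margins, with the same observed-count
  guard and no continuity correction.
* Bonferroni families are formed per variable across métiers, counting only
  the applied tests; decisions use adjusted p-values at α = 0.01.
* `trend_test()` regresses yearly haul counts (missing years count zero) on
  calendar year by OLS; a métier with identical counts every year has zero
  variance, reported as slope 0 with p = 1 by convention.
* `effort_grid()` bins midpoints into cells (default 0.05°); the count grid
  is the analysis surface behind effort heat maps.

The per-métier summary reports, for each variable, the levels holding more
than 50% of hauls, or the top two levels otherwise.

## The synthetic fleet

`sim_config()` / `generate_env()` / `generate_records()` emulate the study
system: ~150 vessels, 2014–2023, six main gears, roughly 50,000 hauls per
decade, and record-error rates summing to ≈1.8% of hauls — the removal rate
observed in the real fleet. Design choices, and what they do and do not
emulate:

* **Geometry.** Bathymetry is a deterministic offshore gradient (linear to
  3000 m over ~1.2° west, ~1° south, with the west coastline bending
  offshore south of 38.4°N so the southwest area keeps shelf water) plus
  smooth sinusoidal noise; sediment is a seeded block patchwork with a
  configurable Unknown fraction. Real canyon bathymetry is far rougher;
  nothing here tests sensitivity to fine-scale topography.
* **Planted métiers.** Twelve métiers across the six gears, inspired by the
  fleet's leading fisheries (octopus traps dominating FPO, hake gillnets,
  soles trammel nets, deep-water black scabbardfish longlines, a surf-clam
  dredge fishery, a small swordfish drifting-longline fishery). Within-gear
  haul counts decay steeply (≈ 1 : 0.12 : 0.03), echoing the strongly
  skewed published rank-frequency curves. Every métier carries *decisive*
  preferences — one level near or above 70%, or two levels near 45% each —
  so the planted structure is unambiguous; the generator does not emulate
  genuinely diffuse fisheries, and recovery results say nothing about them.
* **Dominance.** Catches are target plus bycatch from a per-gear roster of
  commercial species disjoint from the planted targets. With probability
  `dominance` (default 0.9) the target tops haul value (over-valuable
  bycatch is scaled down); otherwise one bycatch species is boosted above
  it. The misassigned hauls found new, unplanted gear × species
  combinations — reproducing the real phenomenon of spurious,
  never-validated métiers created by valuable bycatch — and a configurable
  rare tail of 1–10-haul nuisance combinations reproduces the long tail
  that makes the 307-to-37 selection problem.
* **Trips and prices.** Hauls are drawn independently per métier-year
  (Poisson counts) and grouped into trips by vessel × calendar day, giving
  trips ≫ vessels and several hauls per trip without simulating vessel
  movement. Prices are one average per species per trip (lognormal around a
  species base price); haul-level price variation is out of scope. Catch
  weights are lognormal — a modelling choice, flagged here, not an
  empirical claim.
* **Injections.** Each haul draws at most one violation (mutually exclusive
  categorical draw); non-mainland trips are injected at trip level, and the
  price/weight violations use haul-unique marker species so the trip-level
  rules flag exactly the injected haul. This keeps the truth table exactly
  invertible: per-rule QC counts must equal injection counts, with no
  tolerance.

## Numerical and reporting conventions

* Chi-square guards apply to *observed* counts; statistics come from the
  standard Pearson formulation (verified in the tests against a brute-force
  implementation to 10⁻¹⁰).
* The knee rule resolves distance ties to the larger rank with a 10⁻¹²
  tolerance; degenerate flat curves keep all métiers.
* Recovery checks compare the summary's dominant levels with the planted
  preference by *consistency*, not set equality: the >50%/top-2 reporting
  rule is discontinuous at the majority boundary, so a métier planted with
  two 45% levels can legitimately report either both levels or whichever
  crossed 50% in sample. A reported set is consistent when it is non-empty
  and contained in the planted dominant set; reporting any low-weight level
  remains a failure.
* Problem sizes: the packaged analysis and acceptance runs use the full
  default fleet (~50,000 hauls, 10 years); unit and property tests use a
  reduced two-gear fleet (~5,000 hauls, 1 year) and 20-seed replication for
  the selection-recovery property.

## Limitations

Validation is external input by design; the pipeline cannot detect a
misassigned métier on its own. The label grammar is a documented local
dialect, not the full DCF level-6 code vocabulary. Clustering-based métier
discovery is deliberately out of scope. Real electronic-logbook exports
need an adapter to the package's documented CSV schemas; datum
transformations and antimeridian handling are not implemented. OLS trend
tests assume homoscedastic yearly counts; with ten annual observations no
heteroscedasticity correction is attempted.
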