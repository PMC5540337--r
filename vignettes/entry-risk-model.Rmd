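---
title: "The bed-net entry-risk model: assumptions, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bed-net entry-risk model: assumptions, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netentry)
```

## The problem

Bed nets fail physically before they fail chemically. Field programmes
grade net condition with the WHOPES proportionate hole index (pHI), which
multiplies hole counts in four size classes by area-derived weights and
compares the sum against the 64 (good/acceptable) and 642
(acceptable/too-torn) thresholds. Two things are lost in that score: hole
*location*, although host-seeking *Anopheles gambiae* concentrate
overwhelmingly on the roof and the lowest 30 cm of the sides, and hole
*shape*, although most real holes are elongated rather than round.
`netentry` scores a net by the expected number of mosquito entries per
hour instead, and reports the pHI alongside so the two can be compared on
the same inventory.

## Model structure

Entry is decomposed into three stages, each with its own empirical
submodel:

1. **Appearance.** A mosquito appears (flies within 1–1.5 cm of the net)
   in the 30 cm × 30 cm neighbourhood of a hole at a rate set by the
   hole's functional area. With one mosquito attacking constantly, the
   default rates are 72.3/h on the roof (FA1), 9.5/h at FA2-low, 1.5/h at
   FA2-high and 0.3/h at FA3. These derive from chamber measurements with
   200 mosquitoes (per-area activity ratios of roughly 250:33:5:1),
   divided by the group size; the roof constant is the conventionally
   printed 72.3.
2. **Encounter.** Per appearance, the probability of impinging on the
   hole is `9e-6 × (P + A)` with perimeter P in mm and area A in mm²,
   clamped to [0, 1]. The perimeter term captures "bouncing" flight along
   the surface, the area term "visiting" flight onto the net plane. A
   hypothetical hole the size of the sampling area itself (300 × 300 mm)
   yields 0.82, close to the value of 1 it should have, which is the
   model's own extrapolation sanity check.
3. **Passage.** Per encounter, the probability of getting through is
   log-linear in the hole's average passable width w (mm):
   `0.34 ln w − 0.55` on the roof, `0.30 ln w − 0.52` on the sides,
   clamped to [0, 1]. Widths of 5 mm or less are impassable — consistent
   with the fitted lines themselves, whose x-intercepts sit at
   `exp(0.55/0.34) ≈ 5.0` and `exp(0.52/0.30) ≈ 5.7` mm, which is also
   why widths enter in millimetres. Roof holes are ~20% more passable at
   equal width (gravity assist and the rising host-odour plume).

The per-hole rate is the product of the three stages; net risk is the sum
over holes. The clamp on passage matters in practice: the formulas exceed
1 above ~95 mm (roof) and ~175 mm (side), and wide holes are simply
treated as fully passable. Without the clamp the equal-risk FA3 solution
below would not reproduce.

## Conventions and usage rules

* **One-mosquito-constantly-present.** Each entrant is instantly replaced,
  so risk scales linearly: `scale_risk()` multiplies by mosquito count and
  hours.
* **300 mm cap.** All rates are calibrated on 30 cm sampling units, so no
  single entry may exceed 300 mm in length or width. `split_long_hole()`
  divides longer rectangles into equal pieces, each keeping its own full
  perimeter and area (the cut edges are intentionally double-counted,
  matching the original entry-per-line treatment; an equal split is used
  because any split is admissible and equal pieces are deterministic).
  Non-rectangular shapes over the cap are rejected with instructions to
  apportion manually.
* **Roof holes are always FA1** — sleepers move and share nets, so the
  cautious reading applies pressure-zone FA1 to the whole roof.
* **Holes spanning bands** are entered per band;
  `apportion_side_rectangle()` cuts at the 300/600 mm heights.
* **Exits are ignored.** The net is treated as a perfect sink; modelling
  exit would make the tool less conservative on the quantity it exists to
  bound.

## Geometry

`average_width()` implements the field procedure: tile the hole's longest
axis with 10 mm sections (final partial section kept, midpoints at 5, 15,
25, … mm from one end), take the transverse width at each midpoint, and
average the widths strictly greater than 5 mm; if none qualifies the hole
is impassable (width 0). The threshold comparison uses unrounded widths;
rounding to whole millimetres happens only in display. For a 120 × 8 mm
ellipse this yields 7 mm (two sections at each end excluded); for 210 mm
isosceles triangles with bases 25, 36 and 80 mm it yields 15, 21 and
42 mm.

Ellipses use `A = πab` and `Pe = 2π√((a² + b²)/2)` (semi-axes a, b). The
perimeter form is good to about 5% while the aspect ratio is at most 3 —
measured against arc-length quadrature the error rises monotonically and
peaks at 5.1% exactly at 3:1, marginally above the nominal figure, which
the tests record explicitly. For much narrower ellipses an optional
fallback (`narrow_fallback = TRUE`) estimates the perimeter as twice the
major axis; it is off by default so that the reported perimeter is a
continuous function of shape.

Irregular outlines are simple polygons: area by the shoelace formula, and
an *effective perimeter* equal to the smaller of the raw boundary length
and the convex-hull perimeter, so that deeply indented outlines do not
overstate encounter opportunity (both values are kept in the metrics).
The width-profile axis for a polygon is its maximal vertex-to-vertex
extent — the choice is not dictated by the measurement procedure, but it
is deterministic and matches how elongated holes are measured in
practice; widths are the total cross-section perpendicular to that axis.

## Worked quantities the package reproduces

```{r headline}
inv <- system.file("extdata", "mixed_damage.json", package = "netentry")
a <- assess_net(read_inventory(inv))
round(a$total_entries_per_hour, 1)   # 6.3 entries/h
round(100 * a$share_side)            # 81 % from the side holes

ref <- hole_entry_rate(hole("ref", "FA1",
                            hole_shape("circle", diameter = 25)))
round(equivalent_diameter(ref$entries_per_hour, "FA2_LOW") / 10, 1)  # 6.3 cm
round(equivalent_diameter(ref$entries_per_hour, "FA2_HIGH") / 10, 1) # 13.9 cm
```

The FA3 solution of the same equivalence sits on the passage clamp and
solves to ~30.6 cm; because it depends on the clamp convention it is
reported by `scenario("equal_risk")` rather than asserted to a printed
digit. `scenario("size_class_extremes")` tabulates roof risk at the pHI
class boundaries under both a round-hole and a square-hole reading — the
smallest passable "smaller than thumb" hole (6 mm; 5 mm is impassable)
scores 0.002 entries/h either way, while the class maximum (20 mm) is
~70× riskier, which is the core argument against unlocated, coarsely
binned hole counts.

## Calibration

`fit_passage_model()` refits the passage stage from
encounter/passage count tables (`width_mm, length_mm, location, shape,
encounters, passages`) by ordinary least squares on per-row proportions.
Unweighted OLS is the default; rows can differ more than tenfold in
encounters, so encounter-weighted fitting is available
(`weighted = TRUE`) and documented to differ. `compare_predictors()`
ranks ln(width), width, perimeter, area and length by R²; on data
actually generated from the log-width mechanism, ln(width) ranks first
once counts are moderate. The packaged `passage_trials.csv` is a
hand-transcribed trial summary whose digit stream required
interpretation in two side-hole rows; it ships for demonstration and
should be verified against the typeset source before quantitative reuse,
which is why the package's calibration tests rely on synthetic binomial
data instead. The printed historical R² values are not asserted: whether
the original fits pooled lengths or weighted rows is unstated, so exact
reproduction is not a meaningful check.

## Synthetic data and the stochastic validator

`generate_inventory()` draws hole widths log-uniformly on 1–300 mm —
covering impassable slits through cap-exceeding gashes — across all
functional areas and shape variants; it emulates the *inventory* of a
damaged net, not the physics of damage (no wear process, no spatial
clustering of holes along seams), so passing tests speak to the model
pipeline, not to field damage patterns. `generate_polygon_hole()` builds
star-shaped (hence simple) outlines with smoothed radial noise, rescaled
to an exact target area.

`simulate_entries()` realises the model stochastically: Poisson
appearances per hole thinned by Bernoulli encounter and passage. Under
this construction total entries are Poisson with mean equal to the
deterministic rate times exposure, so the simulator validates the rate
arithmetic (tests use 10⁴ replicate-hours and a 3-standard-error band)
without assuming anything new. Appearances are homogeneous in time; real
within-session activity fluctuates, but only hourly expectations enter
the model.

## Numerical choices

* Probabilities are clamped to [0, 1] at both stages; `ln w` is guarded
  by the impassability threshold, so the log is never taken below 5 mm.
* `equivalent_diameter()` brackets on [5 mm, 1000 mm] and bisects to
  0.01 mm; the rate is strictly increasing in diameter (the encounter
  term grows even where passage is clamped), so the root is unique.
* All metrics are kept at full double precision; reports round rates to
  two decimals and shares to whole percent only at display time, and the
  JSON report writes 17 significant digits so a written report parses
  back bit-identically.
* Fits, roots and quadrature use `stats::lm`, `stats::uniroot` and
  `stats::integrate`; the convex hull uses `grDevices::chull` (the test
  suite checks it against an independently written Jarvis march).

## Limitations

* Parameters are laboratory *An. gambiae* values on untreated netting;
  other vectors press on nets differently, and insecticide roughly
  halves-to-quarters activity — both are recalibration matters
  (`read_species_params()`, `fit_passage_model()`), not model changes.
* Still-air assumption: drafts that disturb the host-odour plume are not
  modelled.
* No confidence limits are produced: the variance inputs of the original
  fits are not available, so the report schema reserves the fields but
  the package does not invent them.
* The pHI weights (1, 23, 196, 578) are WHO-derived configuration
  values, not outputs of this model; only the size classes and the
  64/642 thresholds are inherent to the index.
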