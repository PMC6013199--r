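---
title: "The evacuation time-budget model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The evacuation time-budget model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evacmargin)
```

## The model

`evacmargin` asks, for each power-dependent homecare recipient in a tsunami
inundation area, whether an assisted evacuation finishes before a 30-cm
tsunami flow reaches the destination shelter. The evacuation is a fixed
three-leg sequence — a visiting nurse drives from the nearest nursing
station to the home, transfers the recipient from bed to wheelchair, and
pushes the wheelchair to a welfare evacuation shelter — so the model is a
deterministic time budget:

$$t_\mathrm{total} = \frac{d_\mathrm{station}}{v_\mathrm{nurse}} + t_\mathrm{transfer} + \frac{d_\mathrm{shelter}}{v_\mathrm{walk}},
\qquad m = t_\mathrm{arrival} - t_\mathrm{total}.$$

A non-positive margin $m$ is a *delayed escape*: the shelter floods before
the evacuation completes, which for a recipient dependent on powered medical
equipment is life-threatening even if the building itself survives.

The model's assumptions are deliberately simple and worth stating:

* the nurse is the rescuer (neighbours and care helpers cannot operate the
  medical equipment; the fire brigade is saturated during a mass-casualty
  event), and departs from the *network-nearest* station;
* travel is unimpeded — no congestion, road blockage, or one-way
  restrictions (edges are undirected);
* the recipient evacuates to the network-nearest shelter, unless that
  shelter stands in a level-3 inundation zone, in which case the nearest
  shelter at level 1, 2, or outside the inundation area is used — level-3
  shelters are excluded from candidacy entirely, not merely deprioritised;
* distances are road-network shortest-path distances; the offset between a
  site and its nearest road node is reported as a diagnostic but not added
  to the distance, keeping the distance semantics of the original GIS
  workflow.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `nurse_speed` | 360 | m/min | nurse's car speed, average urban travel speed in the study area |
| `transfer_time` | 4.9 | min | bed-to-wheelchair transfer, national visiting-nurse survey average |
| `walk_speed` | 33.3 | m/min | wheelchair push speed of a carer accompanying a disabled person |
| arrival time | per site | min | predicted 30-cm tsunami flow arrival at the shelter (government inundation model) |

One inconsistency in the source material had to be resolved: the study text
quotes the wheelchair speed as 1.88 km/h (31.3 m/min), but the result-table
header states 33.3 m/min, and only 33.3 reproduces the published walk times
(4,543 m → 136.4 min; at 31.3 m/min it would be 145.1 min). The package
therefore uses 33.3 m/min as the base value. Both are, of course, just
`model_parameters(walk_speed = ...)` away.

## Numerical conventions

All arithmetic is carried out at full double precision; rounding happens
only at display. Published tables round halves *away from zero*, which
differs from R's default round-half-to-even, so the package implements
`round_display()` explicitly and uses it everywhere a table is written.

Two classification rules coexist, both from the source tables:

* **base case** (0.1-min display): delayed iff the full-precision margin is
  strictly negative;
* **sensitivity tables** (whole-minute display): delayed iff the
  integer-rounded margin is $\le 0$ — the published tables state explicitly
  that zero cells count as delayed escapes.

Delayed-escape percentages use *all* recipients in the inundation area as
the denominator, including those outside the 30-cm arrival field whose
margins are undefined (17 delayed of 21 recipients = 81.0%); this is the
only denominator consistent with the published percentages.

Deterministic tie-breaks: among equal-length shortest paths the
lexicographically smallest node-id sequence is returned; among equidistant
nearest facilities the smallest site id wins; a point exactly on a hazard
polygon's boundary counts as *inside* (a shelter on the zone edge must not
silently escape classification). Containment is even-odd ray casting over
all rings, so polygon holes are honoured; the tests check it against an
independent winding-number oracle and `sp::point.in.polygon`.

## Reproduction of the published tables, and one divergence

On the packaged study inputs (`kochi_recipients()`, 21 recipients, four of
them outside the 30-cm arrival field) the pipeline reproduces:

* the nurse, walk, and total time columns of the per-recipient table to
  ±0.05 min for all 21 rows;
* every cell of the one-way sensitivity table and its delayed counts
  (7/7/7/7 for nurse speed and transfer time, 12/4 for wheelchair speed,
  14/4 for arrival time);
* the multi-way corner scenarios A and P row by row, and all 16 bottom-row
  delayed counts (17, 7, 12, 2, 16, 6, 10, 0, 17, 7, 12, 1, 16, 6, 7, 0).

Eight of the 21 published base-case margins, however, are not
arithmetically consistent with the published distance and time columns
under the stated formula $m = t_\mathrm{arrival} - t_\mathrm{total}$; the
deviations range from 1 to 22.5 min, and one (recipient 50: printed −8.2,
computed +14.3) flips sign. Consequently the published headline of *eight*
base-case delayed escapes is not recoverable from the formula, which yields
seven. The package follows the formula — the sensitivity tables, which are
fully formula-consistent, corroborate it — and asserts the base margins
only for the nine consistent rows. `reproduce_study()` reports what the
formula produces; it does not patch values toward the published table.

A second, minor divergence: recipient 27's multi-way cells under scenarios
C and D differ from the computation by 1 min, consistent with the same
transcription offset already visible in that recipient's base-case row.
Scenario columns A and P are unaffected.

## The synthetic scenario generator

`generate_scenario()` builds a stylised coastal city so the full geospatial
pipeline — file I/O, graph construction, snapping, routing, zoning,
assignment, sensitivity — runs end-to-end with no external data. Its
geometry mirrors the study area's structure: the coast is the line $y = 0$
and the tsunami propagates inland in $+y$; inundation levels 3/2/1 occupy
bands 0–800, 800–1,800 and 1,800–2,800 m from the coast; 30-cm arrival
times of 35/50/60 min occupy bands to 1,200/2,400/3,600 m, undefined
beyond. Roads form a grid (default 250-m spacing) with 10% of edges dropped
at random, re-drawn until the graph is connected. Default site counts (21
recipients, 9 stations, 33 shelters) match the study area, and recipients
are rejection-sampled until their network distances fall inside the
observed envelopes: 50–2,700 m to the nearest station, 300–4,600 m to the
nearest eligible shelter.

The generator is a pure function of its `scenario_config()` (a single seed
drives one R random stream), so identical configs give byte-identical
scenarios. It deliberately does **not** emulate real bathymetry, irregular
street networks, building footprints, or population clustering — passing
tests on synthetic scenarios therefore demonstrate the pipeline's
*correctness* (assignment rules, conservation of the time-budget identity,
dominance of sensitivity scenarios), not predictive validity for any real
city. Test problem sizes were chosen to exercise every code path at small
scale: suites run a 2.5-km grid city with 5 recipients over 25–100 seeds,
and the routing property tests compare Dijkstra against brute-force path
enumeration on 1,000 random graphs of at most 8 nodes.

## Sensitivity analysis

The four parameters — nurse speed, transfer time, wheelchair speed, arrival
time — are varied to 0.5× and 2.0× of base. One-way analysis
(`one_way_sensitivity()`) scales a single parameter; multi-way analysis
(`multi_way_sensitivity()`) enumerates all $2^4 = 16$ corner combinations,
labelled A–P with nurse speed outermost and arrival time innermost, so A is
uniformly adverse (slow nurse, long transfer, slow wheelchair, early
tsunami) and P uniformly favourable. Directionality is parameter-specific:
"adverse" halves a speed but doubles the transfer time and halves the
arrival time. Because the margin is monotone in every parameter, each
recipient's 16 margins are bracketed by scenarios A and P — a property the
tests assert both on the study fixture and on synthetic scenarios.

## Known limitations

* Congestion, road damage, and one-way restrictions are ignored; real
  post-earthquake travel speeds will be lower.
* The transfer time is a survey average over a less severely equipped
  population; for ventilator users it is likely an underestimate, which
  matters for recipients whose margin is within a few minutes of zero.
* Each nurse rescues one recipient; no scheduling of multiple rescues.
* Hazard zones are static polygons; no flow-depth dynamics between zones.
* GeoJSON support covers LineString/MultiLineString/Polygon/MultiPolygon
  with planar coordinates; geographic coordinates must be projected to
  metres before use.
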