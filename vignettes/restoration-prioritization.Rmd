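---
title: "Methods: SAR benefits and exact site selection in sarplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAR benefits and exact site selection in sarplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarplan)
```

## The planning problem

`sarplan` prioritizes pixels for habitat restoration on an equal-area
grid. Each candidate pixel is scored by the extinction-risk reduction
it would deliver to a set of indicator species, divided by its land
cost, and a constrained optimizer picks the portfolio. This vignette
records the model, the numerical conventions, and the design choices
that were genuinely open — the things a maintainer would want to know
before changing anything.

## Species–area benefits

For species $j$, extinction risk is modeled from the fraction of its
original habitat that remains:

$$ r_{0j} = 1 - \left( \frac{A_c}{A_O} \right)^{z}, $$

with $A_c$ the current and $A_O$ the original (historical) range area,
both measured as planar polygon areas in km² — *not* rasterized cell
counts, so they are independent of analysis resolution. Restoring one
pixel of area $A_{x_i}$ lowers the risk to
$r_{1j} = 1 - ((A_c + A_{x_i})/A_O)^z$, and the pixel's benefit is
$b_{ij} = c_{ij}\,(r_{0j} - r_{1j})$ with $c_{ij} \in [0,1]$ an
optional climate-suitability weight ($c \equiv 1$ when climate
scenarios are off). Total benefit is $B_{x_i} = \sum_j w_j b_{ij}$
(weights default to 1).

Assumptions worth stating plainly:

* any pixel inside the species' historical range, of its preferred
  habitat community, and currently in restorable land cover will
  *eventually* become habitat — the SAR here is a long-run risk model;
* the risk-reduction factor is evaluated at the species' current
  $A_c$, so within one optimization iteration it is spatially
  constant; spatial differentiation comes from eligibility, dispersal
  weighting, and suitability;
* because $z < 1$ the relationship is concave: each successive pixel
  is worth less, which is why the optimization is iterated (below).

Numerical conventions: SAR areas are km² everywhere inside the
species module; hectares appear only on the cost side, and the two
never mix (a 960 m pixel is 92.16 ha = 0.9216 km²). If independently
sourced maps give $A_c > A_O$, the risk is clamped to 0 with a
warning rather than going negative. Tunable parameters: $z$ (default
0.25, sensitivity sweep $\{0.1, 0.25, 0.4\}$), per-species dispersal
distance in km, and nonnegative aggregation weights $w_j$.

## Dispersal weighting

Three scenarios weight pixels by reachability from the current range:
*none* (weight 1 everywhere — the buffer is not even computed),
*intermediate* (1 inside the dispersal buffer, 0.5 outside), and
*natural* (1 inside, 0 outside). The buffer is built once from the
original current-range geometry and held fixed across iterations;
restored pixels do not act as stepping stones, which keeps scenarios
comparable and the benefit operator monotone.

Buffering is performed in **raster space**: the current range is
rasterized (cell-center rule), an exact Euclidean distance transform
gives each cell's distance to the nearest range cell, and the buffer
is the set of cells within the dispersal distance. A vector
(Minkowski) buffer would require a polygon-offsetting engine and adds
nothing at analysis resolution: the raster buffer is exactly monotone
in the distance, always contains the range, and its area converges to
the closed-form $A + P d + \pi d^2$ of the true buffer as cells
shrink (verified in the tests on a unit square). The same cell-center
rule is used for every rasterization, including the historical-range
eligibility mask.

## Costs

Land-value layers following the fair-market-value convention arrive
in ln USD/ha; `exp_transform_cost()` converts to USD/ha. When the
analysis is coarsened (e.g. 480 m → 960 m), continuous layers
aggregate by block means and categorical layers by modal code with
ties broken toward the lowest code. The literature does not pin down
whether cost aggregation should average dollars or log-dollars, so
the order is a config switch (`cost_transform_order`), defaulting to
*exp-then-coarsen* (arithmetic dollar means; the alternative is a
geometric-mean-like aggregation, always ≤ by Jensen's inequality).
Pixels with nodata in *any* layer leave the analyzable set entirely.

## Exact site selection

The selection problem is

$$ \max \sum_i \frac{B_{x_i}}{C_{x_i}} x_i
   \quad\text{s.t.}\quad \sum_i A_{x_i} x_i \le T_A,\qquad
   \sum_{i \in G_a} A_{x_i} x_i \ge H_A(a)\ \forall a,\qquad x_i \in \{0,1\}. $$

The objective is the *sum of per-pixel ratios* — exactly as written,
not total-benefit over total-cost; that is what keeps the problem
linear, and readers expecting the other form should note this
prominently.

Because every pixel on an equal-area grid has the same area, both
constraints are cardinality constraints over a partition of the
pixels, and the optimum has a closed combinatorial form. Any feasible
solution can be rearranged class by class, without lowering the
objective, so that it takes each class's highest-ratio members; the
remaining freedom is how many pixels $n_a \ge k_a$ to take per class
under $\sum_a n_a \le K$, a separable concave maximization whose
greedy solution (take the forced top $k_a$ per class, then repeatedly
the globally best remaining positive-ratio pixel) is optimal. This is
what `solve_site_selection()` implements; it returns the same optimum
an integer-programming solver would, which the test suite verifies by
exhaustive enumeration of all $2^N$ subsets on one hundred seeded
instances with binding and non-binding minima. Zero-benefit pixels
are selected only when a habitat minimum forces them, cheapest first,
so degenerate problems (benefit identically zero) return the minimal
feasible, cheapest selection. Ties are broken deterministically by
ratio, then cost, then pixel index. When the cost is moved to a
budget constraint instead (`budget_usd`), the problem is a genuine
0/1 knapsack and an exact branch-and-bound with a fractional bound is
used; it is intended for small instances (hundreds of pixels) and is
likewise enumeration-verified.

Rounding of the constraint counts: the per-iteration cap is
$\lfloor f_{iter} N \rfloor$ pixels and each habitat minimum
$\lceil (f_{min}/n_{iter})\, |G_a| \rceil$ — the ceiling guarantees
the *cumulative* minimum is met after all iterations, and the "0.067"
per-iteration habitat coefficient of the 20%/3-iteration design is
treated as exactly $0.20/3$. The minima are applied per iteration,
matching the constraint as written; $N$ and $|G_a|$ are fixed at
their initial values while the candidate set shrinks.

## The iteration loop

The default design restores 30% of the available pixels in three
iterations of 10%. After each iteration, every restored pixel that is
eligible for a species (historical range ∩ preferred habitat)
increments that species' $A_c$, and all $b_{ij}$ are recomputed —
diminishing returns propagate into the next selection. Restoration is
permanent: selected pixels leave the candidate set. Whether a
restored eligible pixel *outside* a species' dispersal buffer should
still increment $A_c$ in the natural scenario is genuinely ambiguous;
the default counts it (habitat exists regardless of colonization
speed, and the SAR is a long-run model), and
`a_c_update = "within_buffer"` excludes it for users who prefer the
stricter reading.

## Synthetic study conditions

The generator (`synthetic_spec()` / `generate_bundle()`) fixes the
conditions under which the pipeline is exercised and tested:

* 200 × 200 cells at 960 m (≈ 192 × 192 km, a Great-Plains-scale
  subregion at the resolution the method is typically run);
* three habitat classes in noisy longitudinal bands via nearest-seed
  tessellation, mirroring a shortgrass → mixed-grass → tallgrass
  gradient (a fully random mosaic mode exists);
* land cover with exactly 32% restorable cells (classes 81/82),
  spatially clumped;
* a cost field $\exp(\mu + \sigma Z)$ with $\mu = \ln 2500$,
  $\sigma = 0.5$ and $Z$ a standardized Gaussian field smoothed over
  8 cells, stored in ln USD/ha so the dollar conversion is exercised;
* five species spanning the gradient (a tallgrass grouse, a
  short/mixed-grass grouse, a mesocarnivore, a wide-ranging ungulate,
  a low-vagility butterfly) with field-typical dispersal distances
  (15/15/30/50/5 km) and blob ranges large enough that their current
  ranges overlap the landscape — the regime in which the natural-
  dispersal candidate pool exceeds the per-iteration cap, as in the
  study design the scenarios come from;
* nested current ⊂ historical ranges as concentric disjoint discs, so
  the current/historical area ratio (default 0.5) holds exactly;
* smooth suitability fields rescaled to $[0,1]$.

All randomness flows from one integer seed through fixed per-layer
sub-seeds; identical specs give bit-identical bundles. What the
generator does *not* emulate: real land-price spatial regimes beyond
lognormal autocorrelation, range-map irregularity (real ranges are not
disc unions, and holes are unsupported in the geometry model),
correlation between cost and habitat, and SDM-derived suitability
structure. Passing tests on synthetic bundles therefore demonstrate
the machinery — masking, weighting, exact optimization, accounting —
not the absolute magnitudes any real landscape would produce.

A hand-coded 6 × 6 example (`generate_worked_example()`) provides
exact-value tests: its optimal selections under a six-pixel cap, with
and without habitat minima, are frozen in the test suite against
exhaustive enumeration, and its totals can be summed by hand.

## Reporting conventions

Scenario totals are exact 64-bit sums; only the *display* average
cost per hectare is rounded, to the nearest \$10 using R's
round-half-to-even. `scenario_cost_per_ha()` reproduces the
case-study table convention (total ÷ 30% of the available area in
hectares, rounded to \$10). Risk improvements are reported as
percentage points, $100\,(r_{0,\text{before}} - r_{0,\text{after}})$,
across the z sweep.

## Problem sizes used in the tests

Unit and property tests run on 40–100-cell-wide bundles; the
scenario-structure checks run the full default 200 × 200 bundle
(12,800 available pixels), including a 30-iteration run, which
completes in seconds. Enumeration oracles are capped at 15-pixel
instances ($2^{15}$ subsets); greedy-equivalence checks go to 5,000
pixels. These sizes were chosen so the whole suite and the acceptance
script each finish in well under a minute while still covering every
constraint-binding regime.

## Known limitations

* Geometry is deliberately minimal: simple disjoint rings, no holes,
  no reprojection — inputs must already share one projected equal-area
  CRS, and geographic grids are rejected outright.
* The ratio objective is not total-benefit/total-cost (see above);
  with very heterogeneous costs the two can rank portfolios
  differently.
* Dispersal buffers are static across iterations; stepping-stone
  colonization is out of scope.
* The budget-constrained mode is exact but exponential in the worst
  case; it is a tool for small decision problems, not state-wide
  grids.
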