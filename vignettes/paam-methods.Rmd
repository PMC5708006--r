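---
title: "Methods: simulating small-area inpatient supply and demand with paam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating small-area inpatient supply and demand with paam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paam)
```

## The problem

Where and when will inpatient demand outgrow hospital beds? Administrative
planning districts are too coarse to answer this: patients routinely cross
district borders, and shortages emerge in pockets a few kilometres wide.
paam therefore works at the resolution of a 500-m population mesh and asks,
for every mesh and every future year, whether the patients arising there can
find a bed at a hospital they can actually reach.

The model has four stages. Each is a plain function that can be used on its
own; `run_scenario()` composes them.

## 1. Stochastic cohort-component projection

Each mesh carries an 18-band age-by-sex population (5-year bands, 85+
absorbing). One 5-year step applies, in this fixed order:

1. **Survival** — survivors per sex and band are drawn
   $\mathrm{Binomial}(n, s_{g,a})$ with per-step survival $s_{g,a}$.
2. **Net migration** — with signed per-step rate $m_{g,a}$: additions are
   $\mathrm{Poisson}(m\,n)$ when $m \ge 0$, removals
   $\mathrm{Binomial}(n, |m|)$ when $m < 0$. Poisson keeps inflows integral
   and unbounded; the binomial keeps outflows no larger than the cohort.
   Both have mean $m\,n$, so the expected-value mode is sign-uniform.
3. **Aging** — every cohort shifts up one band; 85+ absorbs.
4. **Births** — $\mathrm{Poisson}\!\left(\sum_a f_a W_a\right)$ from
   post-shift women 15–49, split male/female binomially with male share
   $\mathrm{SRB}/(1+\mathrm{SRB})$, then thinned by band-0 survival
   (`newborn_survival = TRUE` by default; the switch exists because
   applying within-step mortality to newborns is a modelling convention,
   not a law).

The event order (survive → migrate → age → give birth) is a choice; it is
fixed and documented here so that results are reproducible, and the
expected mode (`mode = "expected"`) runs the identical arithmetic on
expectations. That mode is deterministic and linear in the starting
population, and serves as the oracle for the sampler: the test suite checks
that per-band stochastic means match it to within three standard errors.

Small-area counts are exactly why sampling is per person: with a handful of
residents per band, expected values below one person are meaningless, and
the sampling noise between replications is part of the signal the model is
meant to convey.

### Seeding

Every (mesh, step, sampling) triple draws from its own substream, seeded by
mixing the scenario seed with the stage code, sampling index, step and the
mesh id's code points (`derive_seed()`, a Lehmer-style mix modulo
$2^{31}-1$). Projection of a mesh is therefore identical whether it is
projected alone or alongside others, in any order — a property the suite
asserts — and a single integer reproduces a full 100-sampling experiment.

## 2. From population to daily inpatient demand

The expected daily inpatient census of an area is

$$N \;=\; \sum_{g,a} P_{g,a}\; r_{g,a}\,(1-R_{ad})\,(1-D_{ad}),$$

where $r_{g,a}$ is the probability that a person of sex $g$ and age band
$a$ is a hospital inpatient on a given day, $R_{ad}$ a fractional reduction
of that rate (disease control, outpatient substitution), and $D_{ad}$ a
fractional reduction of the average length of stay: if stays shorten by
10%, the same admissions occupy 10% fewer beds on any given day, so the
daily census scales by $(1-D_{ad})$. The two factors are mathematically
interchangeable, which the suite asserts. The stochastic form draws each
person's status as a Bernoulli trial with the adjusted probability.

No admission/discharge queue is modelled: demand is a daily census, and
length-of-stay effects enter only through $(1-D_{ad})$. Inpatient rates are
all-cause per sex and band; a disease axis would be a schema extension.

## 3. Patient Access Areas

Travel minutes from every mesh centroid to every hospital are computed on a
road network (undirected edges weighted in minutes; Dijkstra via igraph).
Centroids and hospitals snap to their nearest network node by Euclidean
distance, ties to the lowest node id; walk-to-road time is ignored. A
`direct` mode bypasses the network with straight-line distance over a
configured speed.

A hospital belongs to a mesh's PAA when its time is **within the threshold,
inclusively** (the boundary case is a convention; we include it), 60
minutes by car by default. Disconnection is meaningful — an unreachable
mesh has an empty PAA and its patients are over-demand by construction.
One uniform threshold applies to all hospitals by default; per-run
thresholds are a scenario field, since access standards may reasonably
vary with the role of an institution.

## 4. Allocation under capacity

Supply is not licensed beds but *available* beds:
`floor(total_beds × utilization_rate)`, floored so capacity is never
overstated, and further multiplied by an external-bed fraction (default
20%) for hospitals outside the study region, reflecting that border
facilities admit outside patients only up to a share of their capacity.
The discount is applied to capacity once, rather than tracked as a running
quota — the simplest reading of "up to a fraction of available beds".

All patients from all meshes are shuffled into one global random order.
Each patient in turn takes a bed at the best-ranked hospital of their
mesh's PAA with remaining capacity:

* `size_first` (default): size class descending (large > medium > small),
  then travel minutes ascending, then hospital id. Surveyed health-seeking
  behaviour prefers large, well-equipped hospitals close to home; size
  dominating distance is our reading, and `time_first` is provided for the
  opposite ordering.
* `huff`: each patient instead draws one hospital with probability
  proportional to $\text{beds}^{\alpha}/\text{minutes}^{\beta}$
  (defaults $\alpha = 1$, $\beta = 2$, the classic gravity form; minutes
  are floored at 1 so a co-located hospital keeps a finite weight).

Size classes follow the registry convention small ≤ 100 beds,
medium 101–399, large ≥ 400; the boundaries overlap in common usage and we
assign 400 itself to large. Ties anywhere are broken by hospital id so a
run is fully determined by its seed.

A patient with no free bed in their PAA is **over-demand** for their mesh;
beds never filled are **over-supply** for their hospital. Two identities
hold on every run and are asserted in the tests: allocated + remaining =
available per hospital, and allocated + unallocated = patients overall.
The greedy allocator is deliberately myopic — it models individual choice,
not central optimisation — so its over-demand is bounded below by the
maximum-bipartite-flow optimum; the suite checks the bound on random small
instances, with equality when every mesh sees the same hospitals.

## Scenarios

A scenario bundles $R_{ad}$, $D_{ad}$, the bed utilization rate, the
external-bed cap, the PAA threshold and the sampling count (default 100).
The standard suite spans a current-projection baseline and two improvement
scenarios:

| | inpatient rate | length of stay | utilization |
|---|---|---|---|
| Ex.1 current projection | ±0% | ±0% | 80% |
| Ex.2 5% improvement | −5% | −5% | 85% |
| Ex.3 10% improvement | −10% | −10% | 90% |

Demand scales by $(1-R_{ad})(1-D_{ad})$ while capacity scales with
utilization, so mean over-demand must be non-increasing from Ex.1 to Ex.3
and the first year with positive mean over-demand weakly later — the
qualitative pattern the evaluation reproduces on synthetic regions.

Population is re-projected independently in every sampling (demand
uncertainty includes demographic uncertainty); `reuse_projection = TRUE`
shares one projection across samplings as a variance-reduction option.
Standard deviations across samplings are always reported alongside means;
they cost nothing and make statistical checks precise.

## The synthetic region generator

`generate_region()` replaces the census, hospital registry and road data a
real application would use:

* **Meshes** — an `nx × ny` grid of 500-m cells. Populations come from one
  multinomial draw over mesh × sex × band, so the grand total is exact;
  mesh weights follow a Gaussian urban-core kernel plus a uniform floor,
  giving the centre-heavy density under which hospital shortages actually
  arise.
* **Hospitals** — placed at mesh centroids sampled proportionally to
  population (or uniformly), with bed counts drawn from a
  small/medium/large mixture.
* **Rates** — `default_rate_tables()`: total fertility ≈ 1.4 births per
  woman, sex ratio at birth 1.05, survival high through midlife and
  falling steeply after 75, mild net out-migration with a young-adult
  urban inflow, and all-cause daily inpatient rates rising from ≈1/1000 in
  youth to 45/1000 above 85 (population mean ≈ 6/1000, comparable to a
  large metropolitan area). These are plain parameters emulating an aging
  society, not any country's vital statistics.
* **Network** — a 4-connected grid over mesh centroids, edge minutes =
  edge length / speed (default 40 km/h); `edge_removal_fraction` severs
  random edges to create access-poor pockets for testing.

`demo_region_spec()` fixes the demonstration conditions used by the
evaluation scripts: 20 × 20 meshes, 50,000 people, and 10 small hospitals
of 30–60 beds (expected total ≈ 450 beds ≈ 9 per 1,000 population, within
metropolitan per-capita supply). With that calibration, baseline daily
demand (≈ 330) sits just below available capacity (≈ 350 at 80%
utilization), and population aging pushes it past capacity within the
30-year horizon — capacity crosses later or not at all under the
improvement scenarios. The registry is deliberately all-small: with only
ten facilities, a rare 400-bed draw would double regional capacity and
swamp the comparison between scenarios.

**What passing tests do and do not show.** The generator produces ideal
inputs: complete age/sex tables, one travel mode, a homogeneous road grid,
hospitals undifferentiated by function. Tests passing on such regions
verify the *mechanics* — conservation, capacity limits, access containment,
scenario orderings, reproducibility — not that any real area will see the
simulated over-demand. Real applications also face data problems the
generator sidesteps: privacy-merged meshes, unknown-age records, railway
access, and hospital case-mix, the latter being the largest source of
real-world error since patients are matched to beds, not to the right
*kind* of bed.

## Numerical choices and degenerate inputs

* Capacities are floored per hospital, never rounded up.
* The PAA threshold comparison is inclusive (`<=`).
* Unreachable pairs carry `Inf`, never `NA`; empty PAAs are legal and mean
  total over-demand for that mesh.
* Zero-population meshes, zero-patient samplings, and zero-capacity
  hospitals are all ordinary inputs (binomial draws of size 0, empty
  shuffles, candidates skipped).
* All ties (snapping, ranking, class boundaries) break deterministically,
  by id or by the documented convention.
* Counts stay integral in every stochastic path; only expected mode and
  aggregated means are real-valued. Means over samplings are kept
  real-valued, not rounded.

## Problem sizes

The shipped test and evaluation runs use sizes chosen to exercise every
code path while keeping a full check of the package quick on a laptop:
property sweeps on 2–4-mesh regions (hundreds of replicates), shortest-path
oracles on ≤ 8-node graphs where exhaustive path enumeration is feasible,
and the full demonstration at 400 meshes × 10 hospitals × 3 scenarios ×
100 samplings × 7 year points (a few minutes). Larger regions scale
linearly in meshes, samplings and years.

## Known limitations

* Geographic accessibility only: availability of a bed within reach, not
  affordability, quality, or patient preference heterogeneity.
* No hospital case-mix or treatment phases; a bed is a bed.
* No multi-modal routing or congestion; one speed per edge.
* Rates are held constant across steps unless a per-step list is supplied;
  no feedback from shortage to demand or migration.
* The allocator is a one-shot daily snapshot; no re-admission dynamics or
  queueing.
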