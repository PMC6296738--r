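---
title: "herdsim: model, parameters and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{herdsim: model, parameters and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdsim)
```

## What the model is

`herdsim` simulates a population of cattle holdings over annual time
steps. Its purpose is twofold: to ask which of four contested social
mechanisms — lack of succession, leisure farming, tourism
diversification, industrialization — are needed to reproduce the observed
polarization of farm sizes (rising counts of small and large farms while
medium farms decline, the *disappearing middle*), and to explore how
permanent post-2019 trade-price shocks interact with those pre-existing
trends.

The unit of analysis is the *holding*: herd counts for eight cattle types
(beef and dairy finishers, calves, breeders/suckler cows, service bulls,
other), areas of barley, oats, grass and rough grazing, the owner's age,
status flags (no-successor, leisure, diversified, industrialized,
manager-run), planar coordinates in km and a region id. Size classes use
head-count cut-offs of 131 (small/medium) and 368 (medium/large), with
the boundary belonging to the larger class; the cut-offs are taken as
configuration and held fixed.

## Annual scheduling

Each simulated year executes, in order:

1. **Exogenous updates.** Owner ages advance one year.
2. **Mechanism updates** (only for toggled-on mechanisms), synchronously
   in the start-of-year statuses: tourism adoption, industrialization
   adoption, no-successor flagging. All three states are absorbing.
3. **Behavioural rule selection.** Precedence is succession first
   (an ageing owner without a successor cannot maintain the farm whatever
   its income source), then leisure/diversified status-quo, then
   profit-driven. With a mechanism off, its flag is never read — we
   verify this by perturbing the off-mechanism's inputs and asserting
   identical trajectories.
4. **Profit computation** from the *previous* year's prices: last
   period's sales guide this period's decision.
5. **Decisions**, in reverse supply-chain order: finishers first (sign of
   profit), then aggregate calf demand, breeder demand and service-bull
   demand, each upstream tier scaling proportionally toward the demand
   not covered by fixed-behaviour (non-profit-driven) holdings.
6. **Application and reclassification**, with herd counts rounded
   half-up and floored at zero. Holdings whose herd reaches zero stay in
   the population; there are no exits and no new entrants.

Because prices are exogenous there is no feedback from aggregate supply
to price.

## The profit sub-model

For finisher type $k$ (beef or dairy) on holding $i$:

$$\pi_{ki} = p_k\,\mathrm{yield}_k\,n_{ki}
  - p_{hay}\max(0,\mathrm{feed}_k - \mathrm{feedOwn}_{ki})\,n_{ki}
  - p_{straw}\max(0,\mathrm{straw}_k - \mathrm{strawOwn}_{ki})\,n_{ki}$$

Revenue is price times yield (saleable beef weight in kg, or annual milk
yield in litres) times herd size. Feed (hay) and bedding (straw)
purchases cover only the deficit between the per-head requirement and
on-farm production; the clamp at zero makes self-sufficient holdings buy
nothing. On-farm hay comes from grass and rough-grazing areas, straw from
barley and oats, each with its own conversion rate (t/ha); production is
allocated between the beef and dairy herds in proportion to their total
requirements, so the two allocation weights sum to one whenever the
weighted herd is non-empty. When a holding has no animals of type $k$ the
per-head allocation is defined as zero. The per-unit prices enter the
cost terms linearly (once), as dimensional analysis requires.

Units are fixed as £/kg × kg for beef and £/litre × litres for milk;
parameter defaults are chosen at plausible magnitudes for the sector
around 2000 and are all configuration:

| parameter | default | unit | rationale |
|---|---|---|---|
| beef price | 3.0 | £/kg | saleable-weight price level |
| saleable beef weight | 300 | kg/head/yr | carcass-weight order of magnitude |
| dairy price | 0.28 | £/litre | farm-gate milk price level |
| milk yield | 7000 | l/cow/yr | typical herd average |
| hay price | 130 | £/t | purchased-forage level |
| straw price | 60 | £/t | bedding-straw level |
| feed per head, beef / dairy | 5.5 / 6.5 | t/head/yr | dairy ≥ beef (longer on farm) |
| straw per head, beef / dairy | 1.5 / 2.0 | t/head/yr | idem |
| conversion, grass / rough | 3.0 / 0.8 | t hay/ha | grass grazes better than rough |
| conversion, barley / oats | 2.2 / 2.5 | t straw/ha | straw yields |

These levels give beef finishers a purchased-input cost around 50–70 % of
revenue on holdings with average on-farm forage. That margin structure
matters: every finisher is profitable at baseline prices, while a −45 %
beef-price shock (the UTL scenario) pushes a substantial fraction of
beef finishers — those with little own forage — below zero, which is what
lets the scenario experiments separate.

## Behavioural and supply-chain parameters

| parameter | default | rationale |
|---|---|---|
| no-successor shrink rate | 0.20/yr | "rapid" decline quantified |
| expand / shrink rate | 0.10/yr | see calibration below |
| industrialized expansion multiplier | 2.0 | industrialized farms expand faster |
| profit dead band | 0 £ | sign of profit decides |
| depreciation, finishers / breeders | 0.25 / 0.20 /yr | finisher turnover faster |
| calves per breeder | 0.9 /yr | calving rate |
| breeders per bull | 25 | service ratio |
| tourism adoption | p = min(1, 0.002 + 0.05·f) /yr | see calibration |
| industrialization adoption | p = min(1, 0.01 + 0.05·f) /yr, ≥50 head | idem |
| no-successor hazard over 65 | 0.05/yr | idem |

`f` is the fraction of neighbours (Euclidean distance on the km grid;
10 km for tourism, 15 km for industrialization) already in the state at
the start of the year. The linear capped form is the simplest function
consistent with adoption probability increasing in the neighbour
fraction; the true functional form is not identified by any data we
emulate, so all parameters are exposed in configuration.

The translation of finisher choices into upstream demand is likewise not
pinned down externally; we use explicit conversion ratios (calves per
breeder, breeders per bull) plus tier depreciation, and test that each
tier's post-decision aggregate matches its computed demand to within
per-holding rounding. When positive demand meets zero profit-driven
capacity it is left unmet with a logged warning — there are no new
entrants to absorb it. Profit-driven expansion is not bounded by land
area; we left it unbounded because the model asks about direction of
change, not carrying capacity.

## The synthetic census generator

The generator emulates the statistical structure the analysis assumes,
not any real geography:

* **Size classes by construction.** Exactly the target shares
  (59.3/33/7.7 % by default) of holdings are apportioned to the three
  classes, and each draws its total herd log-uniformly within its class
  band ([1, 131), [131, 368), [368, 2000]). Every holding keeps at least
  one head.
* **Supply-chain roles.** Each holding draws one of six role profiles
  (beef/dairy finisher, calf rearer, breeder, bull keeper, mixed) and
  splits its herd multinomially over the eight types. The role
  probabilities were solved by least squares so that tier aggregates
  start near the chain's steady state (calves ≈ finisher replacement +
  growth, breeders ≈ calves/0.9, bulls ≈ breeders/25) — a census of an
  operating sector would not show tiers far from balance.
* **Flags.** The no-successor flag is assigned only among owners over 65
  (ages are Normal(57, 12²), truncated 21–95), at exactly the overall
  10.4 % target. Leisure status (40.7 %) has a propensity decaying with
  herd size (scale 150 head) — the no-full-time-worker definition makes
  leisure farms small. Manager-run status (10 %) is size-weighted with an
  exponent solved so manager-run holdings are on average about 1.27×
  larger than family-run ones; holdings initialize as industrialized if
  manager-run with at least 50 cattle. Tourism (5 %) concentrates around
  a few spatial hotspots.
* **Space.** Locations follow a Thomas-type clustered point process
  (default 70 % of holdings scattered around 25 parent centres with a
  12 km Gaussian spread) in a 300 × 300 km rectangle; regions are the
  Voronoi cells of 73 random seed points, standing in for parliamentary
  constituencies.
* **Prices.** The 2000–2012 series are geometric random walks with small
  drift (0.5 %/yr, 3 % volatility) around the base levels; after 2012 the
  last observed record is held constant, since the simulation runs to
  2030 with no stated extrapolation rule. Scenario shocks multiply prices
  permanently from 2019 (wheat feed changes map to the hay price, barley
  to straw, because the profit model's purchased inputs are hay and
  straw).

One documented ambiguity: the emulated source quotes the no-successor and
leisure shares "at the start of the model" but in a later year than the
simulation start; we treat both as initialization-time targets at the
first simulated year (2000).

What the generator does **not** emulate: real spatial covariance between
region, land capability and herd composition; serial correlation between
a holding's flags; the empirical (heavier-than-log-uniform) upper tail of
herd sizes; land quality classes. Passing tests therefore show that the
pipeline behaves correctly under the stated statistical structure, not
that the calibrated defaults would match any particular real census.

## Pattern-oriented selection and calibration

The POM criterion is operationalized as slope signs: for each of the
small/medium/large annual counts, an OLS slope is fitted to the
ensemble-mean trajectory over the pre-shock window (2000–2018 by
default) and compared with the target direction (+, −, +). A slope within
±10⁻⁹ of zero is treated as signless to keep exactly-flat trajectories
from passing on floating-point noise. A stricter optional mode requires a
supplied empirical trajectory to lie inside the replicate min/max
envelope; we provide both because a visual envelope comparison does not
pin down one rule. The sweep runs under the no-shock scenario, since the
selection window predates the shock year.

The behavioural defaults were calibrated — deliberately, as part of the
model's definition — so that the mechanism selection behaves as the
disappearing-middle phenomenon demands on the default synthetic
population (2000 holdings, 10 replicates):

* with succession **and** leisure on, the (+, −, +) pattern holds:
  no-successor mediums shrink into the small class while profit-driven
  mediums grow into the large class, and leisure keeps the small class
  from emptying upward;
* with neither (profit-driven only), every holding expands and the small
  count falls — the pattern fails;
* combinations lacking either succession or leisure fail at least one
  statistic. The expansion rate (0.10/yr) is high enough that unshielded
  small farms grow out of the small class when leisure is off, and the
  tourism background adoption rate (0.002/yr) is low enough that
  diversification cannot substitute for leisure as a hold-in-place
  mechanism.

Under these defaults exactly the four combinations containing both
succession and leisure pass the sweep. This is a calibration outcome, not
an inference: it demonstrates that the mechanism-selection machinery can
discriminate, under the stated conditions.

## Numerical choices and degenerate inputs

* Herd counts are integers; all rate applications round half-up
  (`floor(x + 0.5)`), so counts like 2 under a 20 % shrink are sticky —
  herds decline to a small residual rather than exactly zero.
* A holding at exactly a size cut-off belongs to the larger class.
* Neighbourhoods exclude the focal holding; co-located other holdings are
  neighbours even at radius 0. Neighbour indices are built once per run
  (locations are static) in memory-bounded chunks.
* `n = 0` populations are valid generator output (empty table, full
  schema); zero-herd types get zero per-head allocations; regions with no
  cattle at the comparison start year yield an undefined percentage
  change rather than a division by zero.
* Replicate seeds derive deterministically from a base seed
  (`sample.int` under `set.seed(base_seed)`), so a `(configuration,
  base seed)` pair fixes an entire ensemble, and the price stream uses an
  offset seed so holdings and prices are independently reproducible.

## Problem sizes

The shipped study conditions use 2000 holdings, 10 replicates and the
2000–2018 selection window (2000–2030 for scenario runs); the full
16-combination sweep at these sizes runs in a few minutes on one CPU.
These sizes were chosen because the ensemble-mean slopes they produce are
stable to well under one farm per year across base seeds, so larger
designs change no qualitative conclusion. The generator scales to the
full 13,406-holding census size if heavier experiments are wanted.

## Known limitations

* Prices are exogenous; there is no supply-to-price feedback, land
  market, tenancy change or new entry.
* The profit model omits subsidies, labour, veterinary and capital costs.
* Leisure status is a static input by default (annual overrides can be
  supplied); the model does not explain *why* owners lack successors.
* The expansion/shrink response is a fixed rate on the profit sign, not a
  magnitude response; a dead band is available but defaults to zero.
* Scenario shocks are single permanent multiplicative shifts, not price
  paths.
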