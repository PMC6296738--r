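# herdsim

An agent-based simulation of structural change in a regional cattle-farming
sector, built for policy analysts and agricultural-systems modellers who
want to study why mid-sized family farms are vanishing — the
"disappearing middle" — and how post-2019 trade shocks interact with that
trend. The original analysis of this kind was built on confidential farm
census microdata; `herdsim` ships a synthetic census generator with the
same statistical structure, so the entire pipeline — population, annual
decisions, mechanism selection, scenario analysis — runs and is tested
end-to-end without any restricted data.

## The model

Each agent is an agricultural holding with herds of eight cattle types
linked in a supply chain (service bulls → breeders/suckler cows → calves →
beef/dairy finishers), land areas, an owner age, and status flags. Each
simulated year every holding follows one behavioural rule:

* **no-successor shrink** — owners over 65 without a successor run the
  herd down rapidly (default 20 %/yr);
* **status-quo hold** — leisure farms (no full-time worker, off-farm
  income) and farms diversified into tourism keep herd size constant
  (replacement = depreciation);
* **profit-driven** — finishers expand or shrink on the sign of last
  year's profit

  π<sub>ki</sub> = p<sub>k</sub>·yield<sub>k</sub>·n<sub>ki</sub>
  − p<sub>hay</sub>·max(0, feed<sub>k</sub> − feedOwn<sub>ki</sub>)·n<sub>ki</sub>
  − p<sub>straw</sub>·max(0, straw<sub>k</sub> − strawOwn<sub>ki</sub>)·n<sub>ki</sub>

  where on-farm feed and straw production (from grass/rough-grazing and
  barley/oats areas) is allocated between beef and dairy herds in
  proportion to their requirements, and purchases are clamped at zero for
  self-sufficient holdings.

Decisions travel the supply chain in reverse: finishers decide first from
prices; their next-year herds set aggregate calf demand (replacement plus
net expansion), which sets breeder demand, which sets service-bull demand,
with profit-driven upstream holdings scaling proportionally toward demand.

Four contested social mechanisms — succession, leisure farming, tourism
diversification (neighbour contagion within 10 km), industrialization
(neighbour contagion within 15 km, 50-head floor, faster expansion) — are
Boolean toggles. A pattern-oriented-modelling (POM) sweep runs all 2⁴ = 16
combinations and keeps those whose replicate ensembles reproduce the
disappearing-middle pattern: small farms ↑, medium farms ↓, large farms ↑.
Trade scenarios (FTA, WTO, UTL) enter as permanent commodity price shifts
from 2019 (e.g. WTO: beef +17 %, dairy +30 %; UTL: beef −45 %, dairy −10 %).

## Worked example

```r
library(herdsim)

cfg      <- synthetic_config(n_holdings = 2000, seed = 1)
holdings <- generate_population(cfg)
prices   <- generate_price_series(cfg, 2000:2018)

table(holdings$size_group)
#>  large medium  small
#>    154    660   1186

ens <- run_replications(holdings, prices,
                        mechanism_toggles(succession = TRUE, leisure = TRUE),
                        scenario_spec("no_brexit"),
                        years = 2000:2018, n_reps = 10, base_seed = 1)
m <- match_pattern(ens, pattern_target(), window = 2000:2018)
m$detail
#>      statistic      slope  direction pass
#> 1  small_farms   3.860877 increasing TRUE
#> 2 medium_farms -26.222281 decreasing TRUE
#> 3  large_farms  22.361404 increasing TRUE
m$overall
#> [1] TRUE
```

The generated population starts at the configured 59.3/33/7.7 % size-class
split (1186/660/154 of 2000). With succession and leisure active, the
ensemble-mean trajectories lose about 26 medium farms a year while small
and large counts rise — the disappearing middle. The replicate envelope is
available per statistic:

```r
tail(envelope(ens, "n_medium"), 3)
#>    year statistic  mean min max
#> 17 2016  n_medium 194.8 182 210
#> 18 2017  n_medium 191.2 180 206
#> 19 2018  n_medium 189.4 174 199
```

`sweep_combinations()` runs all sixteen mechanism combinations;
`run_simulation()` / `run_replications()` accept any
`scenario_spec("no_brexit" | "FTA" | "WTO" | "UTL")`; and
`regional_change()` reports 2019–2030 percentage changes in all/beef/dairy
cattle per synthetic region. A thin command-line surface
(`herdsim_cli()`, script in `inst/cli/herdsim.R`) exposes
`generate | run | sweep | report` with a YAML configuration file.

## Package layout

* `R/synthetic-population.R` — synthetic census and price-series generator
* `R/economics.R` — the profit sub-model (revenue, on-farm feed/straw, costs)
* `R/mechanisms.R` — succession, leisure, diversification, industrialization
* `R/decision-engine.R` — behavioural rules and reverse supply-chain decisions
* `R/simulation.R` — annual step, scenarios, replicate ensembles
* `R/pom.R` — envelopes, pattern matching, the 16-combination sweep
* `R/reporting.R`, `R/cli.R` — regional reports and the CLI
* `vignettes/model-and-calibration.Rmd` — model description, parameter
  defaults and their rationale, known limitations
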