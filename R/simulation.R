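#' Size-class cut-offs
#'
#' Herd-size boundaries between small/medium (default 131 head) and
#' medium/large (default 368 head) holdings; derived originally from a
#' cluster analysis of census herd variables and taken here as
#' configuration, constant throughout a simulation.
#'
#' @param small_medium,medium_large Head-count cut-offs,
#'   `0 < small_medium < medium_large`.
#' @return A list of class `"size_cutoffs"`.
#' @export
size_cutoffs <- function(small_medium = 131, medium_large = 368) {
  if (!(small_medium > 0 && small_medium < medium_large))
    stop_config("need 0 < small_medium < medium_large")
  structure(list(small_medium = small_medium, medium_large = medium_large),
            class = "size_cutoffs")
}

#' Classify herd sizes into small/medium/large
#'
#' Boundary convention: a holding at exactly the cut-off belongs to the
#' larger class (`n < 131` small, `131 <= n < 368` medium, `n >= 368`
#' large under the defaults).
#'
#' @param n_cattle_total Integer vector of total head counts, `>= 0`.
#' @param cutoffs A [size_cutoffs()].
#' @return Character vector of `"small"`, `"medium"`, `"large"`.
#' @export
#' @examples
#' classify_size(c(0, 130, 131, 367, 368))
classify_size <- function(n_cattle_total, cutoffs = size_cutoffs()) {
  stopifnot(all(n_cattle_total >= 0))
  ifelse(n_cattle_total >= cutoffs$medium_large, "large",
         ifelse(n_cattle_total >= cutoffs$small_medium, "medium", "small"))
}

#' Trade scenario specification
#'
#' Named permanent percentage price changes applied from `start_year`
#' (default 2019) onward. The built-in presets are `no_brexit` (no
#' change), `FTA` (bespoke free-trade agreement, marginal changes), `WTO`
#' (most-favoured-nation tariffs, the no-deal case) and `UTL` (unilateral
#' trade liberalisation). The wheat and barley feed-price changes are
#' mapped onto the model's purchased inputs: wheat onto hay, barley onto
#' straw.
#'
#' @param name One of `"no_brexit"`, `"FTA"`, `"WTO"`, `"UTL"` or
#'   `"custom"`.
#' @param pct_change_beef,pct_change_dairy,pct_change_feed_wheat,pct_change_feed_barley
#'   Percentage changes (e.g. `17` for +17 %); required (and only used)
#'   when `name = "custom"`, otherwise taken from the preset.
#' @param start_year First year the shock applies.
#' @return A list of class `"scenario_spec"`.
#' @export
#' @examples
#' scenario_spec("WTO")
scenario_spec <- function(name = c("no_brexit", "FTA", "WTO", "UTL", "custom"),
                          pct_change_beef = 0, pct_change_dairy = 0,
                          pct_change_feed_wheat = 0,
                          pct_change_feed_barley = 0,
                          start_year = 2019) {
  name <- match.arg(name)
  presets <- list(
    no_brexit = c(0, 0, 0, 0),
    FTA = c(3, 1, -1, -1),
    WTO = c(17, 30, -4, -5),
    UTL = c(-45, -10, -5, -7))
  ch <- if (name == "custom")
    c(pct_change_beef, pct_change_dairy, pct_change_feed_wheat,
      pct_change_feed_barley)
  else presets[[name]]
  structure(list(name = name,
                 pct_change_beef = ch[1], pct_change_dairy = ch[2],
                 pct_change_feed_wheat = ch[3],
                 pct_change_feed_barley = ch[4],
                 start_year = start_year),
            class = "scenario_spec")
}

#' Apply a trade scenario to a baseline price series
#'
#' From `start_year` onward, beef and dairy prices are multiplied by
#' `1 + pct/100`; the hay price carries the wheat feed change and the
#' straw price the barley feed change. Earlier years are untouched.
#'
#' @param prices Price series from [generate_price_series()].
#' @param scenario A [scenario_spec()], or `NULL` to leave prices as they
#'   are.
#' @return The adjusted price series.
#' @export
apply_scenario <- function(prices, scenario) {
  if (is.null(scenario)) return(prices)
  i <- prices$year >= scenario$start_year
  prices$p_beef[i] <- prices$p_beef[i] * (1 + scenario$pct_change_beef / 100)
  prices$p_dairy[i] <- prices$p_dairy[i] * (1 + scenario$pct_change_dairy / 100)
  prices$p_hay[i] <- prices$p_hay[i] * (1 + scenario$pct_change_feed_wheat / 100)
  prices$p_straw[i] <- prices$p_straw[i] * (1 + scenario$pct_change_feed_barley / 100)
  prices
}

#' Default simulation parameter bundle
#'
#' @param feed A [feed_parameters()].
#' @param behaviour A [behaviour_parameters()].
#' @param adoption An [adoption_parameters()].
#' @param cutoffs A [size_cutoffs()].
#' @return A list of class `"sim_parameters"`.
#' @export
sim_parameters <- function(feed = feed_parameters(),
                           behaviour = behaviour_parameters(),
                           adoption = adoption_parameters(),
                           cutoffs = size_cutoffs()) {
  structure(list(feed = feed, behaviour = behaviour, adoption = adoption,
                 cutoffs = cutoffs), class = "sim_parameters")
}

annual_aggregate <- function(holdings, year) {
  sg <- holdings$size_group
  data.frame(year = year,
             n_small = sum(sg == "small"),
             n_medium = sum(sg == "medium"),
             n_large = sum(sg == "large"),
             cattle_total = sum(holdings$n_cattle_total),
             cattle_beef = sum(as.matrix(holdings[beef_line_cols()])),
             cattle_dairy = sum(as.matrix(holdings[dairy_line_cols()])),
             n_tourism = sum(holdings$diversified),
             n_industrialized = sum(holdings$industrialized),
             n_no_successor = sum(holdings$no_successor),
             n_leisure = sum(holdings$leisure))
}

regional_aggregate <- function(holdings, year) {
  all_c <- tapply(holdings$n_cattle_total, holdings$region_id, sum)
  beef_c <- tapply(rowSums(as.matrix(holdings[beef_line_cols()])),
                   holdings$region_id, sum)
  dairy_c <- tapply(rowSums(as.matrix(holdings[dairy_line_cols()])),
                    holdings$region_id, sum)
  rid <- as.integer(names(all_c))
  data.frame(year = year,
             region_id = rep(rid, 3),
             cattle_type = rep(c("all", "beef", "dairy"), each = length(rid)),
             count = c(as.vector(all_c), as.vector(beef_c),
                       as.vector(dairy_c)))
}

#' One annual simulation step
#'
#' Executes, in order: (1) exogenous updates — owner ages increment by one
#' year; (2) mechanism updates per the toggles (diversification,
#' industrialization, succession), with neighbour fractions taken from the
#' start-of-year statuses; (3) behavioural rule selection; (4) profit
#' computation from the previous year's prices (last period's sales guide
#' this period's decision); (5) finisher decisions, then demand
#' propagation upstream (calves, breeders, service bulls); (6) decision
#' application with rounding; (7) reclassification. Stochasticity enters
#' only through the mechanism updates, so the step is deterministic given
#' the state and RNG position.
#'
#' @param holdings Holding table (state at the start of the year).
#' @param year The simulated year.
#' @param toggles A [mechanism_toggles()].
#' @param params A [sim_parameters()].
#' @param prices Scenario-adjusted price series covering `year - 1` (or
#'   `year` for the first simulated year).
#' @param nbr_tourism,nbr_industrial Precomputed neighbour indices (built
#'   internally when `NULL`).
#' @param collect_decisions If `TRUE`, attach the year's decision log as
#'   attribute `"decisions"`.
#' @return The end-of-year holding table.
#' @export
sim_step <- function(holdings, year, toggles, params, prices,
                     nbr_tourism = NULL, nbr_industrial = NULL,
                     collect_decisions = FALSE) {
  # (1) exogenous: ages advance
  holdings$owner_age <- holdings$owner_age + 1L

  # (2) mechanism updates (synchronous in the start-of-year statuses)
  if (toggles$diversification)
    holdings <- update_diversification(holdings, params$adoption, nbr_tourism)
  if (toggles$industrialization)
    holdings <- update_industrialization(holdings, params$adoption,
                                         nbr_industrial)
  if (toggles$succession)
    holdings <- update_succession(holdings, params$adoption)

  # (3) behavioural rules
  rule <- behavioural_rule(holdings, toggles)

  # (4) profit from last period's prices
  py <- max(prices$year[prices$year <= year - 1], prices$year[1])
  prow <- prices[prices$year == py, ]
  if (nrow(prow) != 1) stop_config("price series does not cover year %d", year - 1)
  pi_beef <- profit(holdings, "beef_cattle", prow, params$feed)$profit
  pi_dairy <- profit(holdings, "dairy_cattle", prow, params$feed)$profit

  # (5) finishers first, then demand perpetuates upstream
  ind_active <- toggles$industrialization & holdings$industrialized
  fin <- decide_finishers(holdings, pi_beef, pi_dairy, params$behaviour,
                          profit_driven = rule == "profit_driven",
                          industrialized_active = ind_active)
  upstream <- propagate_demand(holdings, fin, params$behaviour, rule)
  nonprofit <- decide_non_profit(holdings, rule, params$behaviour)
  decisions <- rbind(nonprofit, fin, upstream)

  # (6)-(7) apply and reclassify
  holdings <- apply_decisions(holdings, decisions, params$cutoffs)
  if (collect_decisions) attr(holdings, "decisions") <- decisions
  holdings
}

#' Run one replicate of the simulation
#'
#' Simulates the holding population over the year range: the first year is
#' the initial state (recorded, not simulated) and each later year is one
#' [sim_step()]. Results are aggregated into annual national statistics
#' and per-region cattle counts.
#'
#' @param holdings Initial holding table (e.g. from
#'   [generate_population()]).
#' @param prices Baseline price series covering the year range.
#' @param toggles A [mechanism_toggles()].
#' @param scenario A [scenario_spec()] or `NULL` for raw baseline prices.
#' @param params A [sim_parameters()].
#' @param years Simulation horizon, e.g. `2000:2030`.
#' @param seed Integer seed fixing the replicate's stochastic stream.
#' @return An object of class `"farm_run"`: list with `annual`
#'   (year-by-year national statistics), `regional` (year x region x
#'   cattle-type counts), `final` (final-year holding table), `seed`,
#'   `toggles`, `scenario`.
#' @export
run_simulation <- function(holdings, prices, toggles = mechanism_toggles(),
                           scenario = scenario_spec("no_brexit"),
                           params = sim_parameters(),
                           years = 2000:2030, seed = 1L) {
  stopifnot(nrow(holdings) > 0, length(years) >= 1)
  years <- sort(unique(as.integer(years)))
  if (!all(years %in% prices$year))
    stop_config("price series must cover every simulated year")
  set.seed(seed)
  adj_prices <- apply_scenario(prices, scenario)

  nbr_t <- if (toggles$diversification)
    build_neighbour_index(holdings, params$adoption$tourism_radius) else NULL
  nbr_i <- if (toggles$industrialization)
    build_neighbour_index(holdings, params$adoption$industrialization_radius)
  else NULL

  annual <- vector("list", length(years))
  regional <- vector("list", length(years))
  annual[[1]] <- annual_aggregate(holdings, years[1])
  regional[[1]] <- regional_aggregate(holdings, years[1])
  for (j in seq_along(years)[-1]) {
    holdings <- sim_step(holdings, years[j], toggles, params, adj_prices,
                         nbr_tourism = nbr_t, nbr_industrial = nbr_i)
    annual[[j]] <- annual_aggregate(holdings, years[j])
    regional[[j]] <- regional_aggregate(holdings, years[j])
  }
  annual <- do.call(rbind, annual)
  regional <- do.call(rbind, regional)
  rownames(annual) <- rownames(regional) <- NULL
  structure(list(annual = annual,
                 regional = regional,
                 final = holdings,
                 seed = seed, toggles = toggles,
                 scenario = if (is.null(scenario)) "none" else scenario$name),
            class = "farm_run")
}

#' Run a replicate ensemble
#'
#' Runs `n_reps` independent replicates whose seeds are derived
#' deterministically from `base_seed`, and summarizes the annual
#' statistics by per-year mean, minimum and maximum — the envelope used
#' for pattern matching and for averaging out mechanism stochasticity.
#'
#' @inheritParams run_simulation
#' @param n_reps Number of replicates (40 in the full design; smaller for
#'   quick analyses).
#' @param base_seed Integer seed fixing the whole ensemble.
#' @return An object of class `"farm_ensemble"`: list with `runs` (list of
#'   `farm_run`), `summary` (long `data.frame`: year, statistic, mean,
#'   min, max), `seeds`, `toggles`, `scenario`.
#' @export
run_replications <- function(holdings, prices, toggles = mechanism_toggles(),
                             scenario = scenario_spec("no_brexit"),
                             params = sim_parameters(), years = 2000:2030,
                             n_reps = 40, base_seed = 1L) {
  stopifnot(n_reps >= 1)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  runs <- lapply(seeds, function(s)
    run_simulation(holdings, prices, toggles, scenario, params, years,
                   seed = s))
  structure(list(runs = runs, summary = ensemble_summary(runs),
                 seeds = seeds, toggles = toggles,
                 scenario = if (is.null(scenario)) "none" else scenario$name),
            class = "farm_ensemble")
}

ensemble_summary <- function(runs) {
  stats_cols <- setdiff(names(runs[[1]]$annual), "year")
  years <- runs[[1]]$annual$year
  out <- list()
  for (s in stats_cols) {
    m <- vapply(runs, function(r) r$annual[[s]], numeric(length(years)))
    m <- matrix(m, nrow = length(years))
    out[[s]] <- data.frame(year = years, statistic = s,
                           mean = rowMeans(m),
                           min = apply(m, 1, min),
                           max = apply(m, 1, max))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
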