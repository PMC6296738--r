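#' Behavioural rates and supply-chain conversion parameters
#'
#' Rates at which holdings expand or shrink herds, the rapid-shrink rate of
#' no-successor farms, annual depreciation (turnover) by supply-chain tier,
#' and the conversion ratios that translate finisher demand upstream into
#' calf, breeder and service-bull demand.
#'
#' @param no_successor_shrink_rate Annual shrink rate of farms without a
#'   successor (rapid decline as the owner ages out).
#' @param expand_rate,shrink_rate Annual herd change rates of profit-driven
#'   finishers on positive / negative profit.
#' @param industrialized_expand_multiplier Expansion multiplier (>= 1) for
#'   industrialized farms, applied only when the industrialization
#'   mechanism is on.
#' @param profit_dead_band Half-width (GBP) of the profit band treated as
#'   zero (status quo); default 0, i.e. the profit sign alone decides.
#' @param depreciation_finisher,depreciation_breeder Annual replacement
#'   fractions: finishers are slaughtered and replaced faster than
#'   breeding stock.
#' @param calves_per_breeder Calves produced per breeder (suckler cow) per
#'   year; breeder demand = calf demand / this ratio.
#' @param breeders_per_bull Breeders served per service bull; bull demand
#'   = breeder herd / this ratio.
#' @return A list of class `"behaviour_parameters"`.
#' @export
behaviour_parameters <- function(no_successor_shrink_rate = 0.20,
                                 expand_rate = 0.10,
                                 shrink_rate = 0.10,
                                 industrialized_expand_multiplier = 2,
                                 profit_dead_band = 0,
                                 depreciation_finisher = 0.25,
                                 depreciation_breeder = 0.20,
                                 calves_per_breeder = 0.9,
                                 breeders_per_bull = 25) {
  p <- list(no_successor_shrink_rate = no_successor_shrink_rate,
            expand_rate = expand_rate, shrink_rate = shrink_rate,
            industrialized_expand_multiplier = industrialized_expand_multiplier,
            profit_dead_band = profit_dead_band,
            depreciation_finisher = depreciation_finisher,
            depreciation_breeder = depreciation_breeder,
            calves_per_breeder = calves_per_breeder,
            breeders_per_bull = breeders_per_bull)
  rates <- c(p$no_successor_shrink_rate, p$expand_rate, p$shrink_rate,
             p$depreciation_finisher, p$depreciation_breeder)
  if (any(rates < 0) || any(rates > 1))
    stop_config("rates must lie in [0, 1]")
  if (p$industrialized_expand_multiplier < 1)
    stop_config("industrialized_expand_multiplier must be >= 1")
  if (p$calves_per_breeder <= 0 || p$breeders_per_bull <= 0)
    stop_config("conversion ratios must be > 0")
  class(p) <- "behaviour_parameters"
  p
}

#' Select each holding's behavioural rule
#'
#' Precedence: a holding whose owner has no successor (succession
#' mechanism on) shrinks rapidly regardless of any other status — an
#' ageing owner without a successor cannot maintain the farm whatever the
#' income source. Otherwise leisure or diversified holdings (respective
#' mechanism on) hold herd size constant; profit from farming is not a
#' factor for them. Everyone else is profit-driven. With a mechanism off,
#' its flag is never read.
#'
#' @param holdings Holding table.
#' @param toggles A [mechanism_toggles()].
#' @return Character vector: `"no_successor_shrink"`, `"status_quo_hold"`
#'   or `"profit_driven"`, one per holding.
#' @export
behavioural_rule <- function(holdings, toggles) {
  n <- nrow(holdings)
  rule <- rep("profit_driven", n)
  hold <- (toggles$leisure & holdings$leisure) |
    (toggles$diversification & holdings$diversified)
  rule[hold] <- "status_quo_hold"
  if (toggles$succession) rule[holdings$no_successor] <- "no_successor_shrink"
  rule
}

new_decision <- function(code, object, action, rate, tier) {
  data.frame(decision_maker = code, decision_object = object,
             action_type = action, rate = rate, tier = tier,
             stringsAsFactors = FALSE)
}

#' Finisher herd-size decisions from last period's profit
#'
#' The most downstream tier decides first: for each finisher type held by
#' a profit-driven holding, positive profit leads to expansion at
#' `expand_rate` (doubled by the industrialized multiplier where the
#' industrialization mechanism is on and the holding is industrialized),
#' negative profit to shrinking at `shrink_rate`, and profit inside the
#' dead band to status quo.
#'
#' @param holdings Holding table.
#' @param profit_beef,profit_dairy Numeric vectors, one profit per holding
#'   (GBP, from last period's prices).
#' @param params A [behaviour_parameters()].
#' @param profit_driven Logical vector marking profit-driven holdings
#'   (from [behavioural_rule()]); others get no finisher decision here.
#' @param industrialized_active Logical vector: industrialized flag gated
#'   by the industrialization toggle.
#' @return A decision `data.frame`: `decision_maker`, `decision_object`,
#'   `action_type` (expand/shrink/status_quo), `rate`, `tier`.
#' @export
decide_finishers <- function(holdings, profit_beef, profit_dairy, params,
                             profit_driven = rep(TRUE, nrow(holdings)),
                             industrialized_active = rep(FALSE, nrow(holdings))) {
  out <- list()
  mult <- ifelse(industrialized_active,
                 params$industrialized_expand_multiplier, 1)
  for (type in c("beef_cattle", "dairy_cattle")) {
    pi_k <- if (type == "beef_cattle") profit_beef else profit_dairy
    held <- profit_driven & holdings[[paste0("n_", type)]] > 0
    if (!any(held)) next
    act <- ifelse(pi_k[held] > params$profit_dead_band, "expand",
                  ifelse(pi_k[held] < -params$profit_dead_band,
                         "shrink", "status_quo"))
    rate <- ifelse(act == "expand", params$expand_rate * mult[held],
                   ifelse(act == "shrink", params$shrink_rate, 0))
    out[[type]] <- new_decision(holdings$holding_code[held], type, act,
                                rate, tier = 1L)
  }
  if (length(out)) do.call(rbind, out) else
    new_decision(character(0), character(0), character(0), numeric(0),
                 integer(0))
}

# post-decision count for one vector of counts under a decision set
post_counts <- function(counts, action, rate) {
  ifelse(action == "expand", round_half_up(counts * (1 + rate)),
         ifelse(action == "shrink",
                pmax(0, round_half_up(counts * (1 - rate))), counts))
}

# decisions for every type held by non-profit-driven holdings: rapid
# shrink for no-successor farms, status quo for leisure/diversified holds
decide_non_profit <- function(holdings, rule, params) {
  out <- list()
  for (type in cattle_types()) {
    n_k <- holdings[[paste0("n_", type)]]
    shr <- rule == "no_successor_shrink" & n_k > 0
    sq <- rule == "status_quo_hold" & n_k > 0
    if (any(shr))
      out[[paste0(type, ".s")]] <- new_decision(
        holdings$holding_code[shr], type, "shrink",
        params$no_successor_shrink_rate, tier = 0L)
    if (any(sq))
      out[[paste0(type, ".q")]] <- new_decision(
        holdings$holding_code[sq], type, "status_quo", 0, tier = 0L)
  }
  if (length(out)) do.call(rbind, out) else
    new_decision(character(0), character(0), character(0), numeric(0),
                 integer(0))
}

# scale one upstream tier's adjustable (profit-driven) holdings toward the
# aggregate demand left after fixed (non-profit-driven) supply
scale_tier <- function(holdings, type, demand, adjustable, fixed_post, tier) {
  n_k <- holdings[[paste0("n_", type)]]
  target <- max(0, demand - fixed_post)
  supply <- sum(n_k[adjustable])
  held <- adjustable & n_k > 0
  if (supply == 0) {
    if (target > 0.5)
      warning(sprintf("no %s capacity among profit-driven holdings; demand of %.0f head unmet",
                      type, target), call. = FALSE)
    return(new_decision(character(0), character(0), character(0),
                        numeric(0), integer(0)))
  }
  s <- target / supply
  act <- if (s > 1) "expand" else if (s < 1) "shrink" else "status_quo"
  rate <- abs(s - 1)
  new_decision(holdings$holding_code[held], type, act, rate, tier)
}

#' Propagate finisher demand upstream through the supply chain
#'
#' Decisions perpetuate from downstream to upstream in reverse
#' supply-chain order: finisher decisions fix next year's finisher herds,
#' whose replacement (depreciation) plus net expansion gives aggregate
#' calf demand per product line; profit-driven calf rearers scale their
#' calf herds proportionally toward the demand not covered by
#' non-profit-driven (fixed-behaviour) holdings. Calf demand divided by
#' `calves_per_breeder` gives breeder demand, and the post-decision
#' breeder herd divided by `breeders_per_bull` gives service-bull demand.
#' There are no new entrants: demand exceeding total upstream capacity is
#' left unmet with a warning.
#'
#' @param holdings Holding table (current-year herds).
#' @param finisher_decisions Output of [decide_finishers()].
#' @param params A [behaviour_parameters()].
#' @param rule Behavioural rule per holding (see [behavioural_rule()]);
#'   only `"profit_driven"` holdings adjust to demand, the others follow
#'   their own rule.
#' @return A decision `data.frame` for calves (tier 2), breeders (tier 3)
#'   and service bulls (tier 4).
#' @export
propagate_demand <- function(holdings, finisher_decisions, params,
                             rule = rep("profit_driven", nrow(holdings))) {
  adjustable <- rule == "profit_driven"
  # with no profit-driven holding at all, no tier responds to demand
  if (!any(adjustable))
    return(new_decision(character(0), character(0), character(0),
                        numeric(0), integer(0)))
  fixed_factor <- ifelse(rule == "no_successor_shrink",
                         1 - params$no_successor_shrink_rate, 1)
  out <- list()
  breeder_post_total <- 0

  for (line in c("beef", "dairy")) {
    fin <- paste0(line, "_cattle")
    calf <- paste0(line, "_calf")
    breeder <- paste0(line, "_breeder")
    n_fin <- holdings[[paste0("n_", fin)]]

    # next-year finisher herd: profit-driven via decisions, others via rule
    post_fin <- round_half_up(n_fin * fixed_factor)
    d <- finisher_decisions[finisher_decisions$decision_object == fin, ]
    if (nrow(d)) {
      i <- match(d$decision_maker, holdings$holding_code)
      post_fin[i] <- post_counts(n_fin[i], d$action_type, d$rate)
    }
    H <- sum(n_fin)
    H_next <- sum(post_fin)
    calf_demand <- max(0, H_next * params$depreciation_finisher +
                         (H_next - H))

    n_calf <- holdings[[paste0("n_", calf)]]
    fixed_calf_post <- sum(round_half_up(
      n_calf[!adjustable] * fixed_factor[!adjustable]))
    out[[calf]] <- scale_tier(holdings, calf, calf_demand, adjustable,
                              fixed_calf_post, tier = 2L)

    breeder_demand <- calf_demand / params$calves_per_breeder
    n_br <- holdings[[paste0("n_", breeder)]]
    fixed_br_post <- sum(round_half_up(
      n_br[!adjustable] * fixed_factor[!adjustable]))
    dec_br <- scale_tier(holdings, breeder, breeder_demand, adjustable,
                         fixed_br_post, tier = 3L)
    out[[breeder]] <- dec_br

    post_br <- round_half_up(n_br * fixed_factor)
    if (nrow(dec_br)) {
      i <- match(dec_br$decision_maker, holdings$holding_code)
      post_br[i] <- post_counts(n_br[i], dec_br$action_type, dec_br$rate)
    }
    breeder_post_total <- breeder_post_total + sum(post_br)
  }

  bull_demand <- breeder_post_total / params$breeders_per_bull
  n_bull <- holdings$n_service_bull
  fixed_bull_post <- sum(round_half_up(
    n_bull[!adjustable] * fixed_factor[!adjustable]))
  out[["service_bull"]] <- scale_tier(holdings, "service_bull", bull_demand,
                                      adjustable, fixed_bull_post, tier = 4L)
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  # decisions perpetuate tier by tier: calves, then breeders, then bulls
  res[order(res$tier), , drop = FALSE]
}

#' Apply a set of decisions to the holding table
#'
#' Expand: `n <- round(n * (1 + rate))`; shrink:
#' `n <- max(0, round(n * (1 - rate)))`; status quo leaves the count
#' unchanged (replacement equals depreciation). Rounding is half-up; no
#' count drops below zero and holdings whose herd reaches zero stay in the
#' population (there are no exits or new entries). Totals and size groups
#' are recomputed. Decisions on a type the holding does not hold are
#' ignored with a warning.
#'
#' @param holdings Holding table.
#' @param decisions Decision `data.frame` (at most one decision per
#'   holding and type).
#' @param cutoffs A [size_cutoffs()] for reclassification.
#' @return The updated holding table.
#' @export
apply_decisions <- function(holdings, decisions, cutoffs = size_cutoffs()) {
  for (type in unique(decisions$decision_object)) {
    col <- paste0("n_", type)
    d <- decisions[decisions$decision_object == type, ]
    i <- match(d$decision_maker, holdings$holding_code)
    unheld <- holdings[[col]][i] == 0
    if (any(unheld)) {
      warning(sprintf("%d decision(s) on %s ignored: holding(s) do not hold that type",
                      sum(unheld), type), call. = FALSE)
      d <- d[!unheld, ]
      i <- i[!unheld]
    }
    holdings[[col]][i] <- as.integer(
      post_counts(holdings[[col]][i], d$action_type, d$rate))
  }
  holdings$n_cattle_total <- as.integer(
    rowSums(as.matrix(holdings[herd_cols()])))
  holdings$size_group <- classify_size(holdings$n_cattle_total, cutoffs)
  holdings
}
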