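#' Mechanism toggles
#'
#' The four contested social mechanisms are Boolean switches: when a
#' mechanism is off its state variables are never read or written by the
#' decision engine. The 16 on/off combinations form the
#' pattern-oriented-modelling sweep.
#'
#' @param succession,leisure,diversification,industrialization Logical
#'   flags.
#' @return A list of class `"mechanism_toggles"`.
#' @export
#' @examples
#' mechanism_toggles(succession = TRUE, leisure = TRUE)
mechanism_toggles <- function(succession = FALSE, leisure = FALSE,
                              diversification = FALSE,
                              industrialization = FALSE) {
  t <- list(succession = succession, leisure = leisure,
            diversification = diversification,
            industrialization = industrialization)
  if (!all(vapply(t, function(x) is.logical(x) && length(x) == 1 && !is.na(x),
                  logical(1))))
    stop_config("each toggle must be a single TRUE/FALSE")
  class(t) <- "mechanism_toggles"
  t
}

#' All sixteen mechanism combinations
#'
#' @return A 16-row `data.frame` with logical columns `succession`,
#'   `leisure`, `diversification`, `industrialization` and a `label`
#'   column; the all-off row is labelled `"profit_driven_only"`.
#' @export
toggle_combinations <- function() {
  g <- expand.grid(succession = c(FALSE, TRUE), leisure = c(FALSE, TRUE),
                   diversification = c(FALSE, TRUE),
                   industrialization = c(FALSE, TRUE),
                   KEEP.OUT.ATTRS = FALSE)
  on <- names(g)
  g$label <- apply(g, 1, function(r)
    if (!any(as.logical(r))) "profit_driven_only"
    else paste(on[as.logical(r)], collapse = "+"))
  g
}

#' Adoption and succession parameters
#'
#' Parameters of the three stochastic state transitions. Tourism
#' diversification spreads among neighbours within 10 km (about 5-10
#' minutes' drive); industrialization within 15 km (information travels
#' further than tourism custom) and only holdings with at least 50 cattle
#' can sustain a professional manager; owners over 65 acquire no-successor
#' status at a constant annual hazard. Adoption probabilities are linear
#' and capped: `p = min(1, base + slope * f)` with `f` the fraction of
#' neighbours already in the state.
#'
#' @param tourism_radius,industrialization_radius Neighbourhood radii (km).
#' @param industrialization_min_cattle Eligibility floor (head of cattle).
#' @param tourism_base_prob,tourism_slope Intercept and neighbour-fraction
#'   slope of the annual tourism adoption probability.
#' @param industrialization_base_prob,industrialization_slope As above for
#'   industrialization.
#' @param no_successor_prob_over_65 Annual probability that an unflagged
#'   owner over 65 is recognized as having no successor.
#' @return A list of class `"adoption_parameters"`.
#' @export
adoption_parameters <- function(tourism_radius = 10,
                                industrialization_radius = 15,
                                industrialization_min_cattle = 50,
                                tourism_base_prob = 0.002,
                                tourism_slope = 0.05,
                                industrialization_base_prob = 0.01,
                                industrialization_slope = 0.05,
                                no_successor_prob_over_65 = 0.05) {
  p <- list(tourism_radius = tourism_radius,
            industrialization_radius = industrialization_radius,
            industrialization_min_cattle = industrialization_min_cattle,
            tourism_base_prob = tourism_base_prob,
            tourism_slope = tourism_slope,
            industrialization_base_prob = industrialization_base_prob,
            industrialization_slope = industrialization_slope,
            no_successor_prob_over_65 = no_successor_prob_over_65)
  if (p$tourism_radius <= 0 || p$industrialization_radius <= 0)
    stop_config("radii must be > 0")
  probs <- c(p$tourism_base_prob, p$tourism_slope,
             p$industrialization_base_prob, p$industrialization_slope,
             p$no_successor_prob_over_65)
  if (any(probs < 0) || any(probs > 1))
    stop_config("probabilities must lie in [0, 1]")
  if (p$tourism_base_prob + p$tourism_slope > 1 ||
      p$industrialization_base_prob + p$industrialization_slope > 1)
    stop_config("base + slope must be <= 1")
  class(p) <- "adoption_parameters"
  p
}

#' Holdings within a radius of a focal holding
#'
#' Euclidean distance on the planar km grid; the focal holding itself is
#' excluded, co-located other holdings (distance 0) are included even at
#' radius 0. The relation is symmetric.
#'
#' @param holding A single-row holding (or its `holding_code`).
#' @param holdings The holding table.
#' @param radius Radius in km, `>= 0`.
#' @return Character vector of neighbouring holding codes.
#' @export
neighbours_within <- function(holding, holdings, radius) {
  if (radius < 0) stop_config("radius must be >= 0")
  if (is.character(holding)) {
    i <- match(holding, holdings$holding_code)
    if (is.na(i)) stop_config("holding '%s' not found", holding)
    holding <- holdings[i, ]
  }
  d2 <- (holdings$x - holding$x)^2 + (holdings$y - holding$y)^2
  sel <- d2 <= radius^2 & holdings$holding_code != holding$holding_code
  holdings$holding_code[sel]
}

# adjacency index for a fixed radius: list of integer vectors, one per
# holding, excluding self; locations are static so this is built once per
# run; chunked so memory stays O(chunk * n)
build_neighbour_index <- function(holdings, radius) {
  n <- nrow(holdings)
  out <- vector("list", n)
  if (n == 0) return(out)
  r2 <- radius^2
  chunk <- max(1L, floor(5e6 / max(n, 1)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(holdings$x[s:e], holdings$x, "-")^2 +
      outer(holdings$y[s:e], holdings$y, "-")^2
    for (i in s:e) {
      nb <- which(d2[i - s + 1L, ] <= r2)
      out[[i]] <- nb[nb != i]
    }
  }
  out
}

# fraction of neighbours with status TRUE, 0 when no neighbours;
# statuses are the previous year's (synchronous update)
neighbour_fraction <- function(status, nbr_index) {
  vapply(nbr_index, function(nb)
    if (length(nb)) mean(status[nb]) else 0, numeric(1))
}

#' Annual tourism-diversification update
#'
#' Each non-diversified holding adopts tourism with probability
#' `min(1, base + slope * f)`, where `f` is the fraction of its neighbours
#' within `tourism_radius` already diversified at the start of the year.
#' The diversified state is absorbing.
#'
#' @param holdings Holding table.
#' @param params An [adoption_parameters()].
#' @param nbr_index Optional precomputed neighbour index for
#'   `tourism_radius` (built internally if missing).
#' @return The updated holding table.
#' @export
update_diversification <- function(holdings, params = adoption_parameters(),
                                   nbr_index = NULL) {
  if (nrow(holdings) == 0) return(holdings)
  if (is.null(nbr_index))
    nbr_index <- build_neighbour_index(holdings, params$tourism_radius)
  f <- neighbour_fraction(holdings$diversified, nbr_index)
  p <- pmin(1, params$tourism_base_prob + params$tourism_slope * f)
  adopt <- !holdings$diversified & stats::runif(nrow(holdings)) < p
  holdings$diversified <- holdings$diversified | adopt
  holdings
}

#' Annual industrialization update
#'
#' Holdings with fewer than `industrialization_min_cattle` head never
#' industrialize. Eligible, not-yet-industrialized holdings adopt with
#' probability `min(1, base + slope * f)`, `f` being the fraction of
#' neighbours within `industrialization_radius` already industrialized at
#' the start of the year. Absorbing.
#'
#' @inheritParams update_diversification
#' @param nbr_index Optional precomputed neighbour index for
#'   `industrialization_radius`.
#' @return The updated holding table.
#' @export
update_industrialization <- function(holdings, params = adoption_parameters(),
                                     nbr_index = NULL) {
  if (nrow(holdings) == 0) return(holdings)
  if (is.null(nbr_index))
    nbr_index <- build_neighbour_index(holdings, params$industrialization_radius)
  f <- neighbour_fraction(holdings$industrialized, nbr_index)
  p <- pmin(1, params$industrialization_base_prob +
              params$industrialization_slope * f)
  eligible <- holdings$n_cattle_total >= params$industrialization_min_cattle
  adopt <- !holdings$industrialized & eligible &
    stats::runif(nrow(holdings)) < p
  holdings$industrialized <- holdings$industrialized | adopt
  holdings
}

#' Annual succession update
#'
#' Owners strictly over 65 (the male pension age at the study period) who
#' are not yet flagged acquire no-successor status with probability
#' `no_successor_prob_over_65`; owners 65 or younger are never flagged.
#' The flag is absorbing. Ages themselves are incremented by the
#' simulation step, not here.
#'
#' @inheritParams update_diversification
#' @return The updated holding table.
#' @export
update_succession <- function(holdings, params = adoption_parameters()) {
  if (nrow(holdings) == 0) return(holdings)
  flag <- !holdings$no_successor & holdings$owner_age > 65 &
    stats::runif(nrow(holdings)) < params$no_successor_prob_over_65
  holdings$no_successor <- holdings$no_successor | flag
  holdings
}
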