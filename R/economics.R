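#' Feed and straw requirement parameters
#'
#' Per-head annual requirements of purchased-equivalent feed (hay) and
#' bedding straw for beef and dairy finishers, and the conversion rates
#' from land area to on-farm production: grass and rough grazing convert to
#' hay, barley and oats to straw. Dairy cattle require at least as much
#' feed and straw per head as beef cattle (they are kept longer and turned
#' over more slowly).
#'
#' @param feed_per_head_beef,feed_per_head_dairy Hay requirement
#'   (tonnes/head/year).
#' @param straw_per_head_beef,straw_per_head_dairy Straw requirement
#'   (tonnes/head/year).
#' @param r_grass,r_rough Hay produced per hectare of grass / rough grazing
#'   (tonnes/ha).
#' @param r_barley,r_oats Straw produced per hectare of barley / oats
#'   (tonnes/ha).
#' @return A list of class `"feed_parameters"`.
#' @export
feed_parameters <- function(feed_per_head_beef = 5.5,
                            feed_per_head_dairy = 6.5,
                            straw_per_head_beef = 1.5,
                            straw_per_head_dairy = 2.0,
                            r_grass = 3.0, r_rough = 0.8,
                            r_barley = 2.2, r_oats = 2.5) {
  p <- list(feed_per_head_beef = feed_per_head_beef,
            feed_per_head_dairy = feed_per_head_dairy,
            straw_per_head_beef = straw_per_head_beef,
            straw_per_head_dairy = straw_per_head_dairy,
            r_grass = r_grass, r_rough = r_rough,
            r_barley = r_barley, r_oats = r_oats)
  if (any(unlist(p) < 0)) stop_config("feed parameters must be >= 0")
  if (feed_per_head_dairy < feed_per_head_beef ||
      straw_per_head_dairy < straw_per_head_beef)
    stop_config("dairy per-head requirements must be >= beef requirements")
  class(p) <- "feed_parameters"
  p
}

check_finisher_type <- function(cattle_type) {
  if (!cattle_type %in% c("beef_cattle", "dairy_cattle"))
    stop_config("profit is defined for finisher types 'beef_cattle' and 'dairy_cattle', not '%s'",
                cattle_type)
  cattle_type
}

# allocation weight w_k: share of on-farm production allotted to type k,
# proportional to that type's total requirement; w_beef + w_dairy = 1
# whenever the weighted herd is non-empty
allocation_weight <- function(holdings, cattle_type, params) {
  fb <- if (startsWith(cattle_type, "beef")) params$feed_per_head_beef else
    params$feed_per_head_dairy
  num <- fb * holdings[[paste0("n_", cattle_type)]]
  den <- params$feed_per_head_beef * holdings$n_beef_cattle +
    params$feed_per_head_dairy * holdings$n_dairy_cattle
  ifelse(den > 0, num / den, 0)
}

allocation_weight_straw <- function(holdings, cattle_type, params) {
  sb <- if (startsWith(cattle_type, "beef")) params$straw_per_head_beef else
    params$straw_per_head_dairy
  num <- sb * holdings[[paste0("n_", cattle_type)]]
  den <- params$straw_per_head_beef * holdings$n_beef_cattle +
    params$straw_per_head_dairy * holdings$n_dairy_cattle
  ifelse(den > 0, num / den, 0)
}

#' On-farm feed (hay) production per head
#'
#' Hay produced on the holding's grass and rough-grazing area, allotted to
#' the given finisher type in proportion to its share of the total feed
#' requirement, expressed per head of that type. Holdings with no animals
#' of the type get 0 (no per-head allocation without heads).
#'
#' @param holdings Holding table (vectorized over rows).
#' @param cattle_type `"beef_cattle"` or `"dairy_cattle"`.
#' @param params A [feed_parameters()].
#' @return Numeric vector, tonnes of hay per head per year.
#' @export
own_feed_per_head <- function(holdings, cattle_type, params = feed_parameters()) {
  check_finisher_type(cattle_type)
  if (any(holdings$area_grass < 0) || any(holdings$area_rough < 0))
    stop_config("land areas must be >= 0")
  n_k <- holdings[[paste0("n_", cattle_type)]]
  if (any(n_k < 0)) stop_config("herd counts must be >= 0")
  hay <- holdings$area_grass * params$r_grass +
    holdings$area_rough * params$r_rough
  w <- allocation_weight(holdings, cattle_type, params)
  ifelse(n_k > 0, hay * w / n_k, 0)
}

#' On-farm straw production per head
#'
#' Straw produced on the holding's barley and oats area, allotted to the
#' given finisher type in proportion to its share of the total straw
#' requirement, per head of that type.
#'
#' @inheritParams own_feed_per_head
#' @return Numeric vector, tonnes of straw per head per year.
#' @export
own_straw_per_head <- function(holdings, cattle_type, params = feed_parameters()) {
  check_finisher_type(cattle_type)
  if (any(holdings$area_barley < 0) || any(holdings$area_oats < 0))
    stop_config("land areas must be >= 0")
  n_k <- holdings[[paste0("n_", cattle_type)]]
  if (any(n_k < 0)) stop_config("herd counts must be >= 0")
  straw <- holdings$area_barley * params$r_barley +
    holdings$area_oats * params$r_oats
  w <- allocation_weight_straw(holdings, cattle_type, params)
  ifelse(n_k > 0, straw * w / n_k, 0)
}

#' Annual profit from a finisher cattle type
#'
#' Revenue from selling the final product (beef by saleable weight, milk by
#' annual yield) minus the cost of purchased hay and straw. Purchases cover
#' only the per-head deficit between the requirement and on-farm
#' production, clamped at zero: self-sufficient holdings buy nothing.
#'
#' \deqn{\pi_k = p_k\,\mathrm{yield}_k\,n_k
#'   - p_{hay}\max(0, \mathrm{feed}_k - \mathrm{feedOwn}_k)\,n_k
#'   - p_{straw}\max(0, \mathrm{straw}_k - \mathrm{strawOwn}_k)\,n_k}
#'
#' @inheritParams own_feed_per_head
#' @param prices A single-row price record (one year) with columns
#'   `p_beef`, `p_dairy`, `p_hay`, `p_straw`, `beef_weight_per_head`,
#'   `milk_yield_per_cow`.
#' @return A `data.frame` with one row per holding: `revenue`,
#'   `own_feed_per_head`, `own_straw_per_head`, `feed_cost`, `straw_cost`,
#'   `profit` (GBP/year); `profit = revenue - feed_cost - straw_cost`.
#' @export
profit <- function(holdings, cattle_type, prices, params = feed_parameters()) {
  check_finisher_type(cattle_type)
  stopifnot(nrow(prices) == 1)
  n_k <- holdings[[paste0("n_", cattle_type)]]
  if (cattle_type == "beef_cattle") {
    p_k <- prices$p_beef
    yield_k <- prices$beef_weight_per_head
    req_feed <- params$feed_per_head_beef
    req_straw <- params$straw_per_head_beef
  } else {
    p_k <- prices$p_dairy
    yield_k <- prices$milk_yield_per_cow
    req_feed <- params$feed_per_head_dairy
    req_straw <- params$straw_per_head_dairy
  }
  own_f <- own_feed_per_head(holdings, cattle_type, params)
  own_s <- own_straw_per_head(holdings, cattle_type, params)
  revenue <- p_k * yield_k * n_k
  feed_cost <- prices$p_hay * pmax(0, req_feed - own_f) * n_k
  straw_cost <- prices$p_straw * pmax(0, req_straw - own_s) * n_k
  data.frame(revenue = revenue,
             own_feed_per_head = own_f,
             own_straw_per_head = own_s,
             feed_cost = feed_cost,
             straw_cost = straw_cost,
             profit = revenue - feed_cost - straw_cost)
}
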