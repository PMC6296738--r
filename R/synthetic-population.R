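#' Configuration for the synthetic holding generator
#'
#' Bundles every parameter of the synthetic census: population size, target
#' marginal shares, herd-size mixture supports, supply-chain role mix, land
#' priors, spatial layout and price-series parameters. The defaults emulate
#' the structure of the Scottish cattle sector around 2000: 59.3/33/7.7 %
#' small/medium/large holdings under the 131/368-head cut-offs, 10.4 %
#' holdings without a successor, 40.7 % leisure holdings (no full-time
#' worker), and a beef-dominated supply-chain role mix.
#'
#' @param n_holdings Number of holdings to generate.
#' @param share_small,share_medium,share_large Target size-class shares;
#'   must sum to 1.
#' @param share_no_successor Target overall share of holdings whose owner
#'   (aged over 65) has no successor.
#' @param share_leisure Target share of leisure holdings (off-farm income,
#'   no full-time worker). Leisure propensity decays with herd size on the
#'   scale `leisure_size_scale` (heads), so leisure farms concentrate among
#'   small herds, as the no-full-time-worker definition implies.
#' @param share_tourism Target share of holdings already diversified into
#'   tourism at initialization; seeded near spatial hotspots.
#' @param share_manager Target share of manager-run (vs family-run) holdings.
#' @param manager_size_ratio Target ratio of mean herd size on manager-run
#'   holdings to family-run ones (default 1.27).
#' @param leisure_size_scale Herd-size decay scale (heads) of the leisure
#'   propensity.
#' @param cutoffs [size_cutoffs()]; the herd-size mixture components are
#'   supported on the size-class bands these define.
#' @param herd_large_max Upper support (heads) of the large-class component.
#' @param role_probs Named probabilities of the six supply-chain role
#'   profiles (beef_finisher, dairy_finisher, calf_rearer, breeder,
#'   bull_keeper, mixed); normalized internally.
#' @param grass_ha_per_head,rough_ha_per_head,barley_ha_per_head,oats_ha_per_head
#'   Mean land area (ha) per head of cattle for the four land uses.
#' @param land_sdlog Log-scale standard deviation of the per-holding
#'   lognormal noise on land areas.
#' @param extent_km Width and height (km) of the planar study rectangle.
#' @param n_parents Number of cluster centres of the Thomas-type point
#'   process that places holdings.
#' @param cluster_sd_km Gaussian scatter (km) of holdings around their
#'   cluster centre.
#' @param cluster_intensity Fraction of holdings placed around cluster
#'   centres (the rest are uniform); 0 gives complete spatial randomness.
#' @param tourism_hotspots Number of cluster centres acting as tourism
#'   hotspots.
#' @param tourism_hotspot_sd_km Kernel width (km) of the tourism propensity
#'   around hotspots.
#' @param n_regions Number of synthetic regions (default 73, the number of
#'   Scottish Parliament constituencies used for spatial aggregation).
#' @param owner_age_mean,owner_age_sd Normal parameters (years) of the
#'   owner-age distribution, truncated to 21–95.
#' @param price_base Named list of base price levels: `p_beef` (GBP/kg),
#'   `p_dairy` (GBP/litre), `p_hay` (GBP/tonne), `p_straw` (GBP/tonne).
#' @param beef_weight_per_head Saleable beef weight (kg) per finisher head
#'   per year.
#' @param milk_yield_per_cow Milk yield (litres) per dairy head per year.
#' @param price_drift,price_sd Annual drift and volatility of the geometric
#'   random walk used for the emulated 2000–2012 price series.
#' @param data_horizon Last year with emulated observations; later years
#'   hold the last observed record constant.
#' @param seed Integer RNG seed; identical `(config, seed)` give
#'   byte-identical outputs.
#'
#' @return A list of class `"synthetic_config"`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_holdings = 500, seed = 1)
#' holdings <- generate_population(cfg)
#' table(holdings$size_group)
synthetic_config <- function(n_holdings = 2000,
                             share_small = 0.593,
                             share_medium = 0.330,
                             share_large = 0.077,
                             share_no_successor = 0.104,
                             share_leisure = 0.407,
                             share_tourism = 0.05,
                             share_manager = 0.10,
                             manager_size_ratio = 1.27,
                             leisure_size_scale = 150,
                             cutoffs = size_cutoffs(),
                             herd_large_max = 2000,
                             role_probs = c(beef_finisher = 0.40,
                                            dairy_finisher = 0.18,
                                            calf_rearer = 0.12,
                                            breeder = 0.27,
                                            bull_keeper = 0.01,
                                            mixed = 0.02),
                             grass_ha_per_head = 0.25,
                             rough_ha_per_head = 0.40,
                             barley_ha_per_head = 0.05,
                             oats_ha_per_head = 0.02,
                             land_sdlog = 0.6,
                             extent_km = c(300, 300),
                             n_parents = 25,
                             cluster_sd_km = 12,
                             cluster_intensity = 0.7,
                             tourism_hotspots = 5,
                             tourism_hotspot_sd_km = 15,
                             n_regions = 73,
                             owner_age_mean = 57,
                             owner_age_sd = 12,
                             price_base = list(p_beef = 3.0, p_dairy = 0.28,
                                               p_hay = 130, p_straw = 60),
                             beef_weight_per_head = 300,
                             milk_yield_per_cow = 7000,
                             price_drift = 0.005,
                             price_sd = 0.03,
                             data_horizon = 2012,
                             seed = 1L) {
  cfg <- list(n_holdings = n_holdings,
              share_small = share_small, share_medium = share_medium,
              share_large = share_large,
              share_no_successor = share_no_successor,
              share_leisure = share_leisure,
              share_tourism = share_tourism,
              share_manager = share_manager,
              manager_size_ratio = manager_size_ratio,
              leisure_size_scale = leisure_size_scale,
              cutoffs = cutoffs, herd_large_max = herd_large_max,
              role_probs = role_probs,
              grass_ha_per_head = grass_ha_per_head,
              rough_ha_per_head = rough_ha_per_head,
              barley_ha_per_head = barley_ha_per_head,
              oats_ha_per_head = oats_ha_per_head,
              land_sdlog = land_sdlog,
              extent_km = extent_km, n_parents = n_parents,
              cluster_sd_km = cluster_sd_km,
              cluster_intensity = cluster_intensity,
              tourism_hotspots = tourism_hotspots,
              tourism_hotspot_sd_km = tourism_hotspot_sd_km,
              n_regions = n_regions,
              owner_age_mean = owner_age_mean, owner_age_sd = owner_age_sd,
              price_base = price_base,
              beef_weight_per_head = beef_weight_per_head,
              milk_yield_per_cow = milk_yield_per_cow,
              price_drift = price_drift, price_sd = price_sd,
              data_horizon = data_horizon,
              seed = seed)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  shares <- c(cfg$share_small, cfg$share_medium, cfg$share_large,
              cfg$share_no_successor, cfg$share_leisure,
              cfg$share_tourism, cfg$share_manager)
  if (any(!is.finite(shares)) || any(shares < 0) || any(shares > 1))
    stop_config("all target shares must lie in [0, 1]")
  if (abs(cfg$share_small + cfg$share_medium + cfg$share_large - 1) > 1e-9)
    stop_config("size-class shares must sum to 1 (got %.6f)",
                cfg$share_small + cfg$share_medium + cfg$share_large)
  if (cfg$n_holdings < 0) stop_config("n_holdings must be >= 0")
  if (cfg$n_regions < 1) stop_config("n_regions must be >= 1")
  if (any(unlist(cfg$price_base) <= 0) ||
      cfg$beef_weight_per_head <= 0 || cfg$milk_yield_per_cow <= 0)
    stop_config("price and yield base levels must be strictly positive")
  if (cfg$cluster_intensity < 0 || cfg$cluster_intensity > 1)
    stop_config("cluster_intensity must lie in [0, 1]")
  invisible(cfg)
}

# role profile -> expected herd composition weights over the eight types;
# together with the default role probabilities these put the tier
# aggregates near the supply chain's steady state (calves ~ finisher
# replacement + growth, breeders ~ calves / calving rate, bulls ~
# breeders / service ratio), as a census of an operating sector would be
role_composition <- function() {
  w <- rbind(
    beef_finisher  = c(0.85, 0.00, 0.10, 0.00, 0.00, 0.00, 0.00, 0.05),
    dairy_finisher = c(0.00, 0.80, 0.00, 0.12, 0.00, 0.03, 0.00, 0.05),
    calf_rearer    = c(0.20, 0.05, 0.45, 0.20, 0.00, 0.00, 0.00, 0.10),
    breeder        = c(0.15, 0.02, 0.10, 0.03, 0.50, 0.13, 0.02, 0.05),
    bull_keeper    = c(0.30, 0.00, 0.05, 0.00, 0.30, 0.05, 0.25, 0.05),
    mixed          = c(0.30, 0.12, 0.12, 0.05, 0.20, 0.08, 0.01, 0.12))
  colnames(w) <- cattle_types()
  w
}

# exact-count class assignment: largest-remainder apportionment of n slots
# to classes, shuffled; keeps realized shares on target up to rounding
apportion_classes <- function(n, shares, labels) {
  k <- floor(n * shares)
  rem <- n - sum(k)
  if (rem > 0) {
    frac <- n * shares - k
    k[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      k[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  sample(rep(labels, k))
}

# flag exactly round(n * share) holdings, drawn without replacement with
# the given propensity weights
flag_exact <- function(n, share, weights = rep(1, n), eligible = rep(TRUE, n)) {
  k <- min(round(n * share), sum(eligible))
  out <- rep(FALSE, n)
  if (k > 0)
    out[sample(which(eligible), k, prob = weights[eligible])] <- TRUE
  out
}

empty_holding_table <- function() {
  cols <- c(list(holding_code = character(0)),
            stats::setNames(rep(list(integer(0)), 8), herd_cols()),
            list(n_cattle_total = integer(0),
                 area_barley = numeric(0), area_oats = numeric(0),
                 area_grass = numeric(0), area_rough = numeric(0),
                 total_area = numeric(0),
                 size_group = character(0),
                 owner_age = integer(0),
                 no_successor = logical(0), leisure = logical(0),
                 diversified = logical(0), industrialized = logical(0),
                 manager_run = logical(0),
                 role = character(0),
                 x = numeric(0), y = numeric(0),
                 region_id = integer(0)))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Generate a synthetic holding-level population
#'
#' Draws a holding table with the marginal structure set in the
#' configuration. Herd sizes come from a three-component mixture (one
#' log-uniform component per size class, supported on the bands the
#' 131/368 cut-offs define, with component weights equal to the target
#' shares), so the size-class targets hold by construction. Every holding
#' keeps at least one head of cattle. The no-successor flag is assigned
#' only among owners over 65, at the probability that solves for the
#' overall target share; leisure propensity decays with herd size;
#' manager-run status is size-weighted so manager-run holdings are
#' stochastically larger; locations follow a clustered (Thomas-type) point
#' process and tourism status is seeded near a subset of cluster centres,
#' giving spatially aggregated tourism/industrialization seeds.
#'
#' @param config A [synthetic_config()].
#' @return A `data.frame` with one row per holding: `holding_code`, the
#'   eight herd-count columns `n_beef_cattle` ... `n_other_cattle`,
#'   `n_cattle_total`, land areas (ha), `total_area`, `size_group`,
#'   `owner_age`, flags `no_successor`, `leisure`, `diversified`,
#'   `industrialized`, `manager_run`, the supply-chain `role`, planar
#'   coordinates `x`, `y` (km) and `region_id`.
#' @export
generate_population <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_holdings
  if (n == 0) return(empty_holding_table())
  set.seed(config$seed)

  cut1 <- config$cutoffs$small_medium
  cut2 <- config$cutoffs$medium_large

  # --- herd size mixture: log-uniform within each size band ---------------
  cls <- apportion_classes(n, c(config$share_small, config$share_medium,
                                config$share_large),
                           c("small", "medium", "large"))
  lo <- c(small = 1, medium = cut1, large = cut2)[cls]
  hi <- c(small = cut1 - 1, medium = cut2 - 1,
          large = config$herd_large_max)[cls]
  herd <- round(exp(stats::runif(n, log(lo), log(hi + 1))))
  herd <- pmin(pmax(herd, lo), hi)

  # --- supply-chain roles and herd composition ----------------------------
  comp <- role_composition()
  role_p <- config$role_probs / sum(config$role_probs)
  role <- sample(rownames(comp), n, replace = TRUE, prob = role_p)
  counts <- matrix(0L, n, 8, dimnames = list(NULL, herd_cols()))
  for (r in rownames(comp)) {
    idx <- which(role == r)
    if (!length(idx)) next
    # rmultinom takes a scalar size; draw per holding
    draws <- vapply(herd[idx],
                    function(h) stats::rmultinom(1, h, comp[r, ])[, 1],
                    integer(8))
    counts[idx, ] <- t(draws)
  }
  total <- as.integer(rowSums(counts))
  stopifnot(all(total == herd), all(total >= 1))

  # --- land areas ---------------------------------------------------------
  ln <- function(mu_ha) herd * mu_ha *
    stats::rlnorm(n, -config$land_sdlog^2 / 2, config$land_sdlog)
  area_grass <- ln(config$grass_ha_per_head)
  area_rough <- ln(config$rough_ha_per_head)
  area_barley <- ln(config$barley_ha_per_head)
  area_oats <- ln(config$oats_ha_per_head)
  total_area <- area_grass + area_rough + area_barley + area_oats

  # --- owner age and no-successor flag ------------------------------------
  age <- as.integer(pmin(pmax(round(stats::rnorm(
    n, config$owner_age_mean, config$owner_age_sd)), 21), 95))
  over65 <- age > 65
  no_successor <- flag_exact(n, config$share_no_successor,
                             eligible = over65)

  # --- leisure: propensity decays with herd size --------------------------
  w_l <- exp(-herd / config$leisure_size_scale)
  leisure <- flag_exact(n, config$share_leisure, weights = w_l)

  # --- locations: Thomas-type clustered point process ---------------------
  ex <- config$extent_km
  parents <- cbind(stats::runif(config$n_parents, 0, ex[1]),
                   stats::runif(config$n_parents, 0, ex[2]))
  clustered <- stats::runif(n) < config$cluster_intensity
  pid <- sample.int(config$n_parents, n, replace = TRUE)
  x <- ifelse(clustered,
              parents[pid, 1] + stats::rnorm(n, 0, config$cluster_sd_km),
              stats::runif(n, 0, ex[1]))
  y <- ifelse(clustered,
              parents[pid, 2] + stats::rnorm(n, 0, config$cluster_sd_km),
              stats::runif(n, 0, ex[2]))
  x <- pmin(pmax(x, 0), ex[1])
  y <- pmin(pmax(y, 0), ex[2])

  # --- tourism seeding near hotspots --------------------------------------
  nh <- min(config$tourism_hotspots, config$n_parents)
  hs <- parents[sample.int(config$n_parents, nh), , drop = FALSE]
  d2 <- vapply(seq_len(nh),
               function(k) (x - hs[k, 1])^2 + (y - hs[k, 2])^2,
               numeric(n))
  dmin2 <- if (nh > 1) do.call(pmin, as.data.frame(d2)) else d2[, 1]
  w_t <- exp(-dmin2 / (2 * config$tourism_hotspot_sd_km^2)) + 0.02
  diversified <- flag_exact(n, config$share_tourism, weights = w_t)

  # --- manager-run status, size-weighted to hit the 1.27 mean ratio -------
  manager_run <- assign_manager_run(herd, w_t, config$share_manager,
                                    config$manager_size_ratio)
  industrialized <- manager_run & herd >= 50

  holdings <- data.frame(holding_code = sprintf("H%05d", seq_len(n)),
                         counts,
                         n_cattle_total = total,
                         area_barley = area_barley, area_oats = area_oats,
                         area_grass = area_grass, area_rough = area_rough,
                         total_area = total_area,
                         size_group = cls,
                         owner_age = age,
                         no_successor = no_successor, leisure = leisure,
                         diversified = diversified,
                         industrialized = industrialized,
                         manager_run = manager_run,
                         role = role,
                         x = x, y = y,
                         region_id = NA_integer_,
                         stringsAsFactors = FALSE)
  holdings$size_group <- classify_size(holdings$n_cattle_total, config$cutoffs)
  assign_regions(holdings, config$n_regions)
}

# probability of manager-run increases with herd size (and mildly with the
# hotspot kernel so industrialization seeds are spatially aggregated too);
# the size exponent is solved so the expected manager/family mean herd-size
# ratio matches the target
assign_manager_run <- function(herd, w_spatial, share, target_ratio) {
  n <- length(herd)
  if (share <= 0) return(rep(FALSE, n))
  w_s <- 0.5 + 0.5 * w_spatial / max(w_spatial)
  prob_for <- function(alpha) {
    w <- herd^alpha * w_s
    pmin(1, share * w / mean(w))
  }
  ratio_for <- function(alpha) {
    p <- prob_for(alpha)
    if (sum(p) == 0 || sum(1 - p) == 0) return(NA_real_)
    sum(p * herd) / sum(p) / (sum((1 - p) * herd) / sum(1 - p))
  }
  alpha <- tryCatch({
    f <- function(a) ratio_for(a) - target_ratio
    if (!is.finite(f(0)) || !is.finite(f(2)) || f(0) * f(2) > 0) 0.3
    else stats::uniroot(f, c(0, 2), tol = 1e-4)$root
  }, error = function(e) 0.3)
  flag_exact(n, share, weights = herd^alpha * w_s)
}

#' Assign each holding to the nearest of random region seed points
#'
#' Synthetic regions stand in for the 73 Scottish Parliament constituencies:
#' `n_regions` seed points are scattered over the bounding box of the
#' holdings and every holding joins the region of its nearest seed, giving a
#' Voronoi partition (holdings at identical coordinates share a region).
#'
#' @param holdings A holding table with `x`, `y` columns (km).
#' @param n_regions Number of regions, at least 1.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (as when called from [generate_population()]).
#' @return The holding table with `region_id` filled in (integers in
#'   `1..n_regions`).
#' @export
assign_regions <- function(holdings, n_regions, seed = NULL) {
  if (n_regions < 1) stop_config("n_regions must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(holdings)
  if (n == 0) return(holdings)
  if (n_regions == 1) {
    holdings$region_id <- 1L
    return(holdings)
  }
  sx <- stats::runif(n_regions, min(holdings$x), max(holdings$x))
  sy <- stats::runif(n_regions, min(holdings$y), max(holdings$y))
  d2 <- outer(holdings$x, sx, "-")^2 + outer(holdings$y, sy, "-")^2
  holdings$region_id <- max.col(-d2, ties.method = "first")
  holdings
}

#' Generate a synthetic annual price and yield series
#'
#' Emulates the exogenous annual series of beef price (GBP/kg), dairy price
#' (GBP/litre), hay and straw prices (GBP/tonne), saleable beef weight per
#' head (kg) and milk yield per cow (litres/year). Within the emulated data
#' horizon the prices follow geometric random walks with small drift around
#' the configured base levels; beyond the horizon the last observed record
#' is held constant (the baseline used when simulating out to 2030 with
#' observations ending in 2012).
#'
#' @param config A [synthetic_config()] (price parameters and seed).
#' @param years Integer vector of years, e.g. `2000:2030`; must be
#'   non-empty.
#' @return A `data.frame` with one row per year: `year`, `p_beef`,
#'   `p_dairy`, `p_hay`, `p_straw`, `beef_weight_per_head`,
#'   `milk_yield_per_cow`; all values strictly positive.
#' @export
generate_price_series <- function(config, years) {
  validate_synthetic_config(config)
  if (length(years) == 0) stop_config("year range must be non-empty")
  years <- sort(unique(as.integer(years)))
  set.seed(config$seed + 7919L)  # offset stream: prices independent of holdings
  obs_years <- years[years <= config$data_horizon]
  if (length(obs_years) == 0) obs_years <- years[1]
  n_obs <- length(obs_years)
  grw <- function(base, sd = config$price_sd) {
    steps <- stats::rnorm(n_obs, config$price_drift, sd)
    base * exp(cumsum(steps) - steps[1])
  }
  pb <- config$price_base
  obs <- data.frame(year = obs_years,
                    p_beef = grw(pb$p_beef),
                    p_dairy = grw(pb$p_dairy),
                    p_hay = grw(pb$p_hay),
                    p_straw = grw(pb$p_straw),
                    beef_weight_per_head = grw(config$beef_weight_per_head, 0.01),
                    milk_yield_per_cow = grw(config$milk_yield_per_cow, 0.01))
  out <- obs[match(pmin(years, max(obs_years)), obs$year), ]
  out$year <- years
  rownames(out) <- NULL
  stopifnot(all(as.matrix(out[-1]) > 0))
  out
}
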