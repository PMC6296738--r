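# shared fixtures, built in code at test time

# default study-condition population/prices, generated once per test run
.fixture_env <- new.env(parent = emptyenv())

default_population <- function() {
  if (is.null(.fixture_env$pop))
    .fixture_env$pop <- generate_population(synthetic_config(seed = 1))
  .fixture_env$pop
}

default_prices <- function() {
  if (is.null(.fixture_env$prices))
    .fixture_env$prices <- generate_price_series(synthetic_config(seed = 1),
                                                 2000:2030)
  .fixture_env$prices
}

# minimal full-schema holding table for hand-built cases; any column can be
# overridden by name, scalar values are recycled
make_holdings <- function(n = 1, ...) {
  h <- data.frame(holding_code = sprintf("F%03d", seq_len(n)),
                  n_beef_cattle = 0L, n_dairy_cattle = 0L,
                  n_beef_calf = 0L, n_dairy_calf = 0L,
                  n_beef_breeder = 0L, n_dairy_breeder = 0L,
                  n_service_bull = 0L, n_other_cattle = 0L,
                  n_cattle_total = 0L,
                  area_barley = 0, area_oats = 0,
                  area_grass = 0, area_rough = 0, total_area = 0,
                  size_group = "small", owner_age = 50L,
                  no_successor = FALSE, leisure = FALSE,
                  diversified = FALSE, industrialized = FALSE,
                  manager_run = FALSE, role = "mixed",
                  x = 0, y = 0, region_id = 1L,
                  stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) h[[nm]] <- over[[nm]]
  h$n_cattle_total <- as.integer(rowSums(h[paste0("n_", cattle_types())]))
  h$size_group <- classify_size(h$n_cattle_total)
  h
}

# random holdings with full schema for oracle-equivalence sweeps
random_holdings <- function(n, seed) {
  set.seed(seed)
  make_holdings(n,
                n_beef_cattle = rbinom(n, 200, 0.3) *
                  rbinom(n, 1, 0.8),
                n_dairy_cattle = rbinom(n, 150, 0.3) *
                  rbinom(n, 1, 0.5),
                n_beef_calf = rbinom(n, 60, 0.4),
                n_dairy_calf = rbinom(n, 40, 0.4),
                n_beef_breeder = rbinom(n, 70, 0.4),
                n_dairy_breeder = rbinom(n, 30, 0.3),
                n_service_bull = rbinom(n, 5, 0.4),
                n_other_cattle = rbinom(n, 20, 0.3),
                area_barley = runif(n, 0, 30) * rbinom(n, 1, 0.6),
                area_oats = runif(n, 0, 15) * rbinom(n, 1, 0.4),
                area_grass = runif(n, 0, 120) * rbinom(n, 1, 0.9),
                area_rough = runif(n, 0, 200) * rbinom(n, 1, 0.7),
                x = runif(n, 0, 100), y = runif(n, 0, 100))
}
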