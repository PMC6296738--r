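#' Target pattern for pattern-oriented model selection
#'
#' The "disappearing middle": over the evaluation window the numbers of
#' small and large farms increase while the number of medium-sized farms
#' decreases. Directions may be `"increasing"`, `"decreasing"` or
#' `"flat"`.
#'
#' @param small_farms,medium_farms,large_farms Expected trend direction of
#'   the respective annual farm counts.
#' @param flat_tol Absolute slope (farms/year) below which a trend counts
#'   as flat.
#' @return A list of class `"pattern_target"`.
#' @export
pattern_target <- function(small_farms = "increasing",
                           medium_farms = "decreasing",
                           large_farms = "increasing",
                           flat_tol = 1) {
  dirs <- c(small_farms = small_farms, medium_farms = medium_farms,
            large_farms = large_farms)
  if (!all(dirs %in% c("increasing", "decreasing", "flat")))
    stop_config("directions must be increasing/decreasing/flat")
  structure(list(small_farms = small_farms, medium_farms = medium_farms,
                 large_farms = large_farms, flat_tol = flat_tol),
            class = "pattern_target")
}

#' Per-year min/mean/max envelope of an ensemble
#'
#' The replicate envelope (minimum and maximum across runs, with the mean)
#' for each annual statistic — the band compared against the empirical
#' trajectory in pattern-oriented model selection.
#'
#' @param ensemble A `"farm_ensemble"` from [run_replications()].
#' @param statistics Optional character vector restricting the statistics.
#' @return Long `data.frame`: `year`, `statistic`, `mean`, `min`, `max`,
#'   with `min <= mean <= max` everywhere.
#' @export
envelope <- function(ensemble, statistics = NULL) {
  stopifnot(inherits(ensemble, "farm_ensemble"),
            length(ensemble$runs) >= 1)
  s <- ensemble$summary
  if (!is.null(statistics)) s <- s[s$statistic %in% statistics, ]
  rownames(s) <- NULL
  s
}

pattern_stat_cols <- function() {
  c(small_farms = "n_small", medium_farms = "n_medium",
    large_farms = "n_large")
}

#' Match an ensemble against the disappearing-middle pattern
#'
#' For each size-class count, an ordinary least-squares slope is fitted to
#' the ensemble-mean trajectory over the window; a statistic passes when
#' the slope sign matches the target direction (a "flat" target requires
#' `|slope| < flat_tol`). The combination passes overall only if all
#' three statistics pass — the patterns must be reproduced
#' simultaneously. An optional stricter mode additionally requires a
#' supplied empirical trajectory to lie inside the replicate min/max
#' envelope.
#'
#' @param ensemble A `"farm_ensemble"`.
#' @param target A [pattern_target()].
#' @param window Integer year range (length >= 3) within the simulated
#'   years.
#' @param empirical Optional `data.frame` (`year`, `n_small`, `n_medium`,
#'   `n_large`) for envelope containment.
#' @return List with `overall` (logical), `detail` (per-statistic
#'   `data.frame` with slope, direction and pass flag) and, when
#'   `empirical` is given, `containment`.
#' @export
match_pattern <- function(ensemble, target = pattern_target(),
                          window = 2000:2018, empirical = NULL) {
  if (length(window) < 3) stop_config("window must span at least 3 years")
  env <- envelope(ensemble)
  if (!all(window %in% env$year))
    stop_config("window must lie within the simulated years")
  detail <- lapply(names(pattern_stat_cols()), function(stat) {
    col <- pattern_stat_cols()[[stat]]
    s <- env[env$statistic == col & env$year %in% window, ]
    slope <- unname(stats::coef(stats::lm(mean ~ year, data = s))["year"])
    # guard the sign test against floating-point noise on flat trajectories
    eps <- 1e-9
    want <- target[[stat]]
    pass <- switch(want,
                   increasing = slope > eps,
                   decreasing = slope < -eps,
                   flat = abs(slope) < target$flat_tol)
    data.frame(statistic = stat, slope = slope, direction = want,
               pass = pass)
  })
  detail <- do.call(rbind, detail)
  out <- list(overall = all(detail$pass), detail = detail)
  if (!is.null(empirical)) {
    cont <- vapply(names(pattern_stat_cols()), function(stat) {
      col <- pattern_stat_cols()[[stat]]
      s <- env[env$statistic == col, ]
      i <- match(empirical$year, s$year)
      all(empirical[[col]] >= s$min[i] & empirical[[col]] <= s$max[i],
          na.rm = TRUE)
    }, logical(1))
    out$containment <- cont
    out$overall <- out$overall && all(cont)
  }
  out
}

#' Sweep all sixteen mechanism combinations
#'
#' Runs the replicate ensemble for every on/off combination of the four
#' mechanisms (including the all-off, profit-driven-only case) under the
#' no-shock baseline, and evaluates each against the disappearing-middle
#' pattern. Per-combination seeds derive deterministically from
#' `base_seed`, so the whole sweep is reproducible.
#'
#' @inheritParams run_replications
#' @param target A [pattern_target()].
#' @param window Evaluation window for [match_pattern()].
#' @return A list of class `"pom_sweep"`: `table` (16-row `data.frame`
#'   with the four toggle columns, `label`, per-statistic pass flags,
#'   `pass_overall`) and `ensembles` (named list of the 16 ensembles).
#' @export
sweep_combinations <- function(holdings, prices,
                               scenario = scenario_spec("no_brexit"),
                               params = sim_parameters(),
                               years = 2000:2018, n_reps = 40,
                               base_seed = 1L,
                               target = pattern_target(),
                               window = NULL) {
  combos <- toggle_combinations()
  if (is.null(window)) window <- years
  set.seed(base_seed)
  combo_seeds <- sample.int(.Machine$integer.max - 1L, nrow(combos))
  rows <- vector("list", nrow(combos))
  ensembles <- vector("list", nrow(combos))
  for (j in seq_len(nrow(combos))) {
    tg <- mechanism_toggles(succession = combos$succession[j],
                            leisure = combos$leisure[j],
                            diversification = combos$diversification[j],
                            industrialization = combos$industrialization[j])
    ens <- run_replications(holdings, prices, tg, scenario, params, years,
                            n_reps = n_reps, base_seed = combo_seeds[j])
    m <- match_pattern(ens, target, window)
    rows[[j]] <- data.frame(combos[j, ],
                            pass_small = m$detail$pass[1],
                            pass_medium = m$detail$pass[2],
                            pass_large = m$detail$pass[3],
                            pass_overall = m$overall,
                            row.names = NULL)
    ensembles[[j]] <- ens
  }
  names(ensembles) <- combos$label
  structure(list(table = do.call(rbind, rows), ensembles = ensembles,
                 base_seed = base_seed),
            class = "pom_sweep")
}
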