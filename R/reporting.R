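#' Regional percentage change in cattle numbers
#'
#' Percentage change in the number of all, beef and dairy cattle per
#' region between a start year (default 2019, the shock year) and an end
#' year (default 2030) of one run. Regions with no cattle of a type at
#' the start year get an undefined change.
#'
#' @param run A `"farm_run"` from [run_simulation()].
#' @param start_year,end_year Comparison years; both must be present in
#'   the run.
#' @return A `data.frame` with one row per (region, cattle type):
#'   `region_id`, `cattle_type`, `count_start`, `count_end`, `pct_change`
#'   (`100 * (end - start) / start`, `NA` when `count_start` is 0) and
#'   `direction` (`increase`/`decrease`/`flat`/`undefined`).
#' @export
regional_change <- function(run, start_year = 2019, end_year = 2030) {
  reg <- run$regional
  if (!all(c(start_year, end_year) %in% reg$year))
    stop_config("both comparison years must be present in the run")
  a <- reg[reg$year == start_year, c("region_id", "cattle_type", "count")]
  b <- reg[reg$year == end_year, c("region_id", "cattle_type", "count")]
  names(a)[3] <- "count_start"
  names(b)[3] <- "count_end"
  out <- merge(a, b, by = c("region_id", "cattle_type"), sort = TRUE)
  out$pct_change <- ifelse(out$count_start > 0,
                           100 * (out$count_end - out$count_start) /
                             out$count_start, NA_real_)
  out$direction <- ifelse(out$count_start == 0, "undefined",
                          ifelse(out$pct_change > 0, "increase",
                                 ifelse(out$pct_change < 0, "decrease",
                                        "flat")))
  out[order(out$region_id, out$cattle_type), ]
}

#' Share percentages from class counts
#'
#' Converts class counts into percentage shares of their total, e.g. the
#' initialization size-class shares from the counts of small, medium and
#' large holdings.
#'
#' @param counts Named (or unnamed) non-negative numeric vector.
#' @return Numeric vector of percentages summing to 100.
#' @export
#' @examples
#' share_percentages(c(small = 7952, medium = 4424, large = 1030))
share_percentages <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  100 * counts / sum(counts)
}

write_run_csv <- function(run, dir) {
  utils::write.csv(run$annual, file.path(dir, "trajectories.csv"),
                   row.names = FALSE)
  utils::write.csv(run$regional, file.path(dir, "regional.csv"),
                   row.names = FALSE)
}
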