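test_that("behavioural rule precedence is succession, then hold, then profit", {
  h <- make_holdings(5,
                     no_successor = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                     leisure = c(TRUE, FALSE, TRUE, FALSE, FALSE),
                     diversified = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  all_on <- mechanism_toggles(TRUE, TRUE, TRUE, TRUE)
  expect_identical(behavioural_rule(h, all_on),
                   c("no_successor_shrink", "no_successor_shrink",
                     "status_quo_hold", "status_quo_hold", "profit_driven"))
  # with a mechanism off its flag is never read
  off <- mechanism_toggles()
  expect_identical(behavioural_rule(h, off), rep("profit_driven", 5))
  succ_only <- mechanism_toggles(succession = TRUE)
  expect_identical(behavioural_rule(h, succ_only)[3], "profit_driven")
})

test_that("finisher decisions follow the profit sign and rates", {
  h <- make_holdings(3, n_beef_cattle = c(100L, 100L, 100L),
                     n_dairy_cattle = c(0L, 50L, 50L),
                     industrialized = c(TRUE, FALSE, FALSE))
  bp <- behaviour_parameters(expand_rate = 0.05, shrink_rate = 0.04,
                             industrialized_expand_multiplier = 2)
  d <- decide_finishers(h, profit_beef = c(10, 0, -5),
                        profit_dairy = c(0, 3, -1), bp,
                        industrialized_active = h$industrialized)
  beef <- d[d$decision_object == "beef_cattle", ]
  expect_identical(beef$action_type, c("expand", "status_quo", "shrink"))
  expect_equal(beef$rate, c(0.10, 0, 0.04))  # multiplier doubles expansion
  dairy <- d[d$decision_object == "dairy_cattle", ]
  expect_identical(dairy$action_type, c("expand", "shrink"))
  expect_equal(dairy$rate, c(0.05, 0.04))

  # non-profit-driven holdings receive no finisher decision
  d2 <- decide_finishers(h, c(10, 10, 10), c(1, 1, 1), bp,
                         profit_driven = c(FALSE, TRUE, FALSE))
  expect_true(all(d2$decision_maker == "F002"))
  expect_setequal(d2$decision_object, c("beef_cattle", "dairy_cattle"))
})

test_that("decision arithmetic rounds half-up and floors at zero", {
  h <- make_holdings(3, n_beef_cattle = c(100L, 1L, 30L))
  d <- rbind(
    data.frame(decision_maker = "F001", decision_object = "beef_cattle",
               action_type = "expand", rate = 0.05, tier = 1L),
    data.frame(decision_maker = "F002", decision_object = "beef_cattle",
               action_type = "shrink", rate = 0.9, tier = 1L),
    data.frame(decision_maker = "F003", decision_object = "beef_cattle",
               action_type = "status_quo", rate = 0, tier = 1L))
  out <- apply_decisions(h, d)
  expect_identical(out$n_beef_cattle, c(105L, 0L, 30L))
  expect_identical(out$n_cattle_total, c(105L, 0L, 30L))
  # shrunken-to-zero holding stays in the population
  expect_identical(nrow(out), 3L)
  expect_identical(out$size_group, c("small", "small", "small"))

  # a decision on a type the holding does not hold is ignored with warning
  bad <- data.frame(decision_maker = "F002",
                    decision_object = "dairy_cattle",
                    action_type = "expand", rate = 0.5, tier = 1L)
  expect_warning(out2 <- apply_decisions(h, bad), "ignored")
  expect_identical(out2$n_dairy_cattle, h$n_dairy_cattle)
})

test_that("demand propagation conserves the supply chain against a scalar oracle", {
  h <- random_holdings(200, seed = 41)
  bp <- behaviour_parameters()
  rule <- rep("profit_driven", nrow(h))
  fin <- decide_finishers(h, profit_beef = rep(10, 200),
                          profit_dairy = rep(-3, 200), bp)
  up <- propagate_demand(h, fin, bp, rule)
  out <- suppressWarnings(apply_decisions(h, rbind(fin, up)))

  # scalar oracle: per-farm loop computing aggregate demands
  for (line in c("beef", "dairy")) {
    fin_col <- paste0("n_", line, "_cattle")
    H <- 0; H_next <- 0
    for (i in seq_len(nrow(h))) {
      n <- h[[fin_col]][i]
      H <- H + n
      if (n > 0) {
        rate <- if (line == "beef") bp$expand_rate else -bp$shrink_rate
        H_next <- H_next + floor(n * (1 + rate) + 0.5)
      }
    }
    calf_demand <- max(0, H_next * bp$depreciation_finisher + (H_next - H))
    calf_post <- sum(out[[paste0("n_", line, "_calf")]])
    expect_lt(abs(calf_post - calf_demand), nrow(h))

    breeder_demand <- calf_demand / bp$calves_per_breeder
    breeder_post <- sum(out[[paste0("n_", line, "_breeder")]])
    expect_lt(abs(breeder_post - breeder_demand), nrow(h))
  }
  bull_demand <- (sum(out$n_beef_breeder) + sum(out$n_dairy_breeder)) /
    bp$breeders_per_bull
  expect_lt(abs(sum(out$n_service_bull) - bull_demand), nrow(h))
})

test_that("decisions proceed from finishers upstream to bulls", {
  h <- random_holdings(100, seed = 43)
  bp <- behaviour_parameters()
  fin <- decide_finishers(h, rep(5, 100), rep(5, 100), bp)
  up <- propagate_demand(h, fin, bp)
  log <- rbind(fin, up)
  tier_of <- c(beef_cattle = 1, dairy_cattle = 1, beef_calf = 2,
               dairy_calf = 2, beef_breeder = 3, dairy_breeder = 3,
               service_bull = 4)
  expect_identical(unname(tier_of[log$decision_object]),
                   as.numeric(log$tier))
  # tiers appear in non-decreasing order in the combined log
  expect_true(!is.unsorted(log$tier))
})

test_that("all-status-quo finishers leave upstream demand at pure replacement", {
  h <- make_holdings(4,
                     n_beef_cattle = c(400L, 0L, 0L, 0L),
                     n_beef_calf = c(0L, 60L, 60L, 0L),
                     n_beef_breeder = c(0L, 0L, 0L, 120L))
  bp <- behaviour_parameters(depreciation_finisher = 0.25,
                             calves_per_breeder = 0.9)
  fin <- decide_finishers(h, profit_beef = rep(0, 4),
                          profit_dairy = rep(0, 4), bp)
  expect_true(all(fin$action_type == "status_quo"))
  up <- suppressWarnings(propagate_demand(h, fin, bp))
  out <- suppressWarnings(apply_decisions(h, rbind(fin, up)))
  expect_identical(sum(out$n_beef_cattle), 400L)
  expect_identical(sum(out$n_beef_calf), 100L)  # 400 * 0.25
})

test_that("unmet upstream demand warns when no capacity exists", {
  h <- make_holdings(2, n_beef_cattle = c(200L, 200L))
  bp <- behaviour_parameters()
  fin <- decide_finishers(h, c(10, 10), c(0, 0), bp)
  expect_warning(propagate_demand(h, fin, bp), "unmet")
})

test_that("behaviour parameter contracts hold", {
  expect_error(behaviour_parameters(expand_rate = 1.5), "\\[0, 1\\]")
  expect_error(behaviour_parameters(industrialized_expand_multiplier = 0.5),
               ">= 1")
  expect_error(behaviour_parameters(calves_per_breeder = 0), "> 0")
})
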