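# independent scalar transcriptions of the profit sub-model, kept separate
# from the vectorized implementation they check

oracle_own_feed <- function(grass, rough, n_beef, n_dairy, type, fp) {
  hay <- grass * fp$r_grass + rough * fp$r_rough
  req <- c(beef_cattle = fp$feed_per_head_beef,
           dairy_cattle = fp$feed_per_head_dairy)
  n_k <- if (type == "beef_cattle") n_beef else n_dairy
  den <- fp$feed_per_head_beef * n_beef + fp$feed_per_head_dairy * n_dairy
  if (n_k == 0 || den == 0) return(0)
  hay * (req[[type]] * n_k / den) / n_k
}

oracle_own_straw <- function(barley, oats, n_beef, n_dairy, type, fp) {
  straw <- barley * fp$r_barley + oats * fp$r_oats
  req <- c(beef_cattle = fp$straw_per_head_beef,
           dairy_cattle = fp$straw_per_head_dairy)
  n_k <- if (type == "beef_cattle") n_beef else n_dairy
  den <- fp$straw_per_head_beef * n_beef + fp$straw_per_head_dairy * n_dairy
  if (n_k == 0 || den == 0) return(0)
  straw * (req[[type]] * n_k / den) / n_k
}

oracle_profit <- function(row, type, pr, fp) {
  n_k <- row[[paste0("n_", type)]]
  if (type == "beef_cattle") {
    p_k <- pr$p_beef; yield <- pr$beef_weight_per_head
    req_f <- fp$feed_per_head_beef; req_s <- fp$straw_per_head_beef
  } else {
    p_k <- pr$p_dairy; yield <- pr$milk_yield_per_cow
    req_f <- fp$feed_per_head_dairy; req_s <- fp$straw_per_head_dairy
  }
  own_f <- oracle_own_feed(row$area_grass, row$area_rough,
                           row$n_beef_cattle, row$n_dairy_cattle, type, fp)
  own_s <- oracle_own_straw(row$area_barley, row$area_oats,
                            row$n_beef_cattle, row$n_dairy_cattle, type, fp)
  p_k * yield * n_k -
    pr$p_hay * max(0, req_f - own_f) * n_k -
    pr$p_straw * max(0, req_s - own_s) * n_k
}

test_price_row <- function() {
  data.frame(year = 2000, p_beef = 3, p_dairy = 0.28, p_hay = 130,
             p_straw = 60, beef_weight_per_head = 300,
             milk_yield_per_cow = 7000)
}

test_that("on-farm feed and straw handle the boundary cases", {
  fp <- feed_parameters()
  bare <- make_holdings(1, n_beef_cattle = 40L)
  expect_identical(own_feed_per_head(bare, "beef_cattle", fp), 0)
  expect_identical(own_straw_per_head(bare, "beef_cattle", fp), 0)

  # single-type herd takes the whole allocation: total hay / n
  dairy_only <- make_holdings(1, n_dairy_cattle = 25L, area_grass = 30,
                              area_rough = 10)
  expect_equal(own_feed_per_head(dairy_only, "dairy_cattle", fp),
               (30 * fp$r_grass + 10 * fp$r_rough) / 25)
  expect_identical(own_feed_per_head(dairy_only, "beef_cattle", fp), 0)

  beef_only <- make_holdings(1, n_beef_cattle = 50L, area_barley = 12,
                             area_oats = 4)
  expect_equal(own_straw_per_head(beef_only, "beef_cattle", fp),
               (12 * fp$r_barley + 4 * fp$r_oats) / 50)

  expect_error(own_feed_per_head(bare, "beef_calf", fp), "finisher")
  neg <- make_holdings(1, area_grass = -1)
  expect_error(own_feed_per_head(neg, "beef_cattle", fp), ">= 0")
})

test_that("vectorized profit model equals the scalar transcription", {
  fp <- feed_parameters()
  pr <- test_price_row()
  h <- random_holdings(1000, seed = 21)
  for (type in c("beef_cattle", "dairy_cattle")) {
    own_f <- own_feed_per_head(h, type, fp)
    own_s <- own_straw_per_head(h, type, fp)
    pi_vec <- profit(h, type, pr, fp)$profit
    for (i in seq_len(nrow(h))) {
      expect_equal(own_f[i],
                   oracle_own_feed(h$area_grass[i], h$area_rough[i],
                                   h$n_beef_cattle[i], h$n_dairy_cattle[i],
                                   type, fp),
                   tolerance = 1e-12)
      expect_equal(own_s[i],
                   oracle_own_straw(h$area_barley[i], h$area_oats[i],
                                    h$n_beef_cattle[i], h$n_dairy_cattle[i],
                                    type, fp),
                   tolerance = 1e-12)
      expect_equal(pi_vec[i], oracle_profit(h[i, ], type, pr, fp),
                   tolerance = 1e-9)
    }
  }
})

test_that("profit breakdown is internally consistent", {
  fp <- feed_parameters()
  pr <- test_price_row()
  h <- random_holdings(200, seed = 33)
  b <- profit(h, "beef_cattle", pr, fp)
  expect_true(all(b$feed_cost >= 0))
  expect_true(all(b$straw_cost >= 0))
  expect_equal(b$profit, b$revenue - b$feed_cost - b$straw_cost)

  none <- make_holdings(1)
  b0 <- profit(none, "beef_cattle", pr, fp)
  expect_true(all(unlist(b0) == 0))

  # self-sufficient holding: clamp makes purchases zero, profit = revenue
  rich <- make_holdings(1, n_beef_cattle = 10L, area_grass = 1000,
                        area_barley = 1000)
  br <- profit(rich, "beef_cattle", pr, fp)
  expect_identical(br$feed_cost, 0)
  expect_identical(br$straw_cost, 0)
  expect_equal(br$profit, br$revenue)
})

test_that("revenue scales with output price while costs do not", {
  fp <- feed_parameters()
  pr <- test_price_row()
  pr2 <- pr; pr2$p_beef <- 2 * pr$p_beef
  h <- random_holdings(100, seed = 5)
  b1 <- profit(h, "beef_cattle", pr, fp)
  b2 <- profit(h, "beef_cattle", pr2, fp)
  expect_equal(b2$revenue, 2 * b1$revenue)
  expect_equal(b2$feed_cost, b1$feed_cost)
  expect_equal(b2$straw_cost, b1$straw_cost)
})

test_that("profit is non-decreasing in land area", {
  fp <- feed_parameters()
  pr <- test_price_row()
  base <- make_holdings(1, n_beef_cattle = 80L, n_dairy_cattle = 20L,
                        area_grass = 10, area_rough = 5, area_barley = 3,
                        area_oats = 1)
  p0 <- profit(base, "beef_cattle", pr, fp)$profit
  for (col in c("area_grass", "area_rough", "area_barley", "area_oats")) {
    for (extra in c(5, 50, 500)) {
      more <- base
      more[[col]] <- more[[col]] + extra
      expect_gte(profit(more, "beef_cattle", pr, fp)$profit, p0)
    }
  }
})

test_that("allocation weights sum to one over the two finisher types", {
  fp <- feed_parameters()
  h <- random_holdings(300, seed = 8)
  wb <- ifelse(h$n_beef_cattle > 0,
               own_feed_per_head(h, "beef_cattle", fp) * h$n_beef_cattle, 0)
  wd <- ifelse(h$n_dairy_cattle > 0,
               own_feed_per_head(h, "dairy_cattle", fp) * h$n_dairy_cattle, 0)
  hay <- h$area_grass * fp$r_grass + h$area_rough * fp$r_rough
  any_herd <- h$n_beef_cattle + h$n_dairy_cattle > 0
  expect_equal(wb[any_herd] + wd[any_herd], hay[any_herd])
})

test_that("feed parameter contracts hold", {
  expect_error(feed_parameters(feed_per_head_dairy = 1,
                               feed_per_head_beef = 2), "dairy")
  expect_error(feed_parameters(r_grass = -1), ">= 0")
})
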