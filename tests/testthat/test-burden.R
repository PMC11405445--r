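test_that("burden splits reproduce the published device/nondevice rows", {
  vap <- split_burden(157500, 0.391)
  expect_equal(vap$device, 61600)
  expect_equal(vap$nondevice, 95900)
  cauti <- split_burden(93300, 0.677)
  expect_equal(cauti$device, 63200)
  expect_equal(cauti$nondevice, 30100)
  cdi <- split_burden(123100, 0.709)
  expect_equal(cdi$device, 87300)
  expect_equal(cdi$nondevice, 35800)
  z <- split_burden(157500, 0)
  expect_equal(z$device, 0)
  expect_equal(z$nondevice, 157500)
  expect_error(split_burden(1000, 1.2), "proportion")
})

test_that("rounding to the nearest hundred is half-away-from-zero", {
  expect_equal(round_to_100(c(49, 50, 149, 150, 63164.1)),
               c(0, 100, 100, 200, 63200))
})

test_that("burden tables validate their ordering and granularity", {
  ok <- data.frame(infection = c("a", "b"), group = c("device", "nondevice"),
                   central = c(500, 300), low = c(100, 0), high = c(900, 800))
  expect_s3_class(burden_table(ok), "burden_table")
  bad <- ok; bad$low[1] <- 600
  expect_error(burden_table(bad), "low <= central")
  bad2 <- ok; bad2$central[1] <- 510
  expect_error(burden_table(bad2), "multiples of 100")
})

test_that("national totals multiply, sum, and guard currency years", {
  att <- data.frame(infection = c("a", "b"), mean_cost = c(10, 20),
                    cost_year = 2017)
  bur <- data.frame(infection = c("a", "b"), group = c("device", "nondevice"),
                    central = c(100, 200), low = c(0, 100), high = c(300, 400))
  nct <- national_totals(att, bur)
  expect_equal(nct$by_infection$total_central, c(1000, 4000))
  expect_equal(nct$grand[["central"]], 5000)
  expect_equal(nct$grand[["low"]], 2000)
  expect_equal(nct$subtotals["device", "central"], 1000)
  # zero burden keeps a zero row
  bur0 <- bur; bur0[, c("central", "low", "high")] <- 0
  expect_equal(national_totals(att, bur0)$grand[["central"]], 0)
  att_mixed <- att; att_mixed$cost_year <- c(2017, 2011)
  expect_error(national_totals(att_mixed, bur), "currency")
  expect_error(national_totals(att[1, ], bur), "\\bb\\b")
})

test_that("recomputation from published rounded inputs matches printed totals", {
  for (year in c(2011, 2016)) {
    ref <- reference_national_table(year)
    rows <- ref[ref$row_type == "infection", ]
    att <- data.frame(infection = rows$infection, mean_cost = rows$att_cost_2017,
                      cost_year = 2017)
    bur <- data.frame(infection = rows$infection, group = rows$group,
                      central = rows$burden_central, low = rows$burden_low,
                      high = rows$burden_high)
    nct <- national_totals(att, bur)
    printed_grand <- ref$total_central[ref$row_type == "grand"]
    expect_lt(abs(nct$grand[["central"]] - printed_grand) / printed_grand, 0.001)
    # low <= central <= high propagates to every row and total
    expect_true(all(nct$by_infection$total_low <= nct$by_infection$total_central))
    expect_true(all(nct$by_infection$total_central <= nct$by_infection$total_high))
    expect_lte(nct$grand[["low"]], nct$grand[["central"]])
    expect_lte(nct$grand[["central"]], nct$grand[["high"]])
  }
})

test_that("printed per-infection totals sum to printed subtotals within $2", {
  for (year in c(2011, 2016)) {
    ref <- reference_national_table(year)
    for (grp in c("device", "nondevice")) {
      rows <- ref[ref$row_type == "infection" & ref$group == grp, ]
      printed <- ref$total_central[ref$row_type == "subtotal" & ref$group == grp]
      expect_lte(abs(sum(rows$total_central) - printed), 2)
    }
    grand <- ref$total_central[ref$row_type == "grand"]
    subs <- ref$total_central[ref$row_type == "subtotal"]
    expect_equal(sum(subs), grand)
  }
})

test_that("scaling every attributable cost scales totals and fixes shares", {
  ref <- reference_national_table(2016)
  rows <- ref[ref$row_type == "infection", ]
  att <- data.frame(infection = rows$infection, mean_cost = rows$att_cost_2017,
                    cost_year = 2017)
  bur <- data.frame(infection = rows$infection, group = rows$group,
                    central = rows$burden_central, low = rows$burden_low,
                    high = rows$burden_high)
  n1 <- national_totals(att, bur)
  att2 <- att; att2$mean_cost <- 2 * att2$mean_cost
  n2 <- national_totals(att2, bur)
  expect_equal(n2$grand, 2 * n1$grand)
  expect_equal(cost_shares(n2)$nondevice_share_percent,
               cost_shares(n1)$nondevice_share_percent)
  expect_equal(cost_shares(n2)$within_group$share_percent,
               cost_shares(n1)$within_group$share_percent)
})

test_that("cost shares match the published nondevice pattern", {
  nct <- as_national_cost_table(reference_national_table(2016))
  sh <- cost_shares(nct)
  expect_equal(round(sh$nondevice_share_percent), 28)
  pneu <- sh$within_group$share_percent[sh$within_group$infection == "pneumonia"]
  expect_equal(round(pneu), 40)
  # a single-type group holds 100% of its subtotal
  one <- structure(list(by_infection = data.frame(
    infection = "x", group = "nondevice", mean_cost = 5,
    total_central = 500, total_low = 100, total_high = 900),
    subtotals = NULL, grand = c(central = 500, low = 100, high = 900),
    cost_year = 2017, burden_year = NA), class = "national_cost_table")
  expect_equal(cost_shares(one)$within_group$share_percent, 100)
  expect_equal(cost_shares(one)$nondevice_share_percent, 100)
})
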