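test_that("strategy tallies partition the records and add up across basins", {
  m <- simulate_metrics(simulation_config(n_watersheds = 500, seed = 3))
  asg <- classify_table(m)
  tl <- tally(asg)

  # independent filter-and-count per class, nationally
  conus <- tl[tl$basin_id == "CONUS", ]
  for (nu in c("N", "P")) {
    a <- asg[asg$nutrient == nu, ]
    for (cl in strategy_classes) {
      expect_equal(conus$n[conus$nutrient == nu & conus$strategy_class == cl],
                   sum(a$strategy_class == cl))
    }
    # partition: class counts sum to the record count
    expect_equal(sum(conus$n[conus$nutrient == nu]), nrow(a))
  }

  # CONUS tally equals the sum of basin tallies, class by class
  basins <- tl[tl$basin_id != "CONUS", ]
  by_class <- stats::aggregate(n ~ nutrient + strategy_class, basins, sum)
  for (i in seq_len(nrow(by_class))) {
    expect_equal(
      conus$n[conus$nutrient == by_class$nutrient[i] &
              conus$strategy_class == by_class$strategy_class[i]],
      by_class$n[i]
    )
  }

  # empty input and all-NOT_PRIORITY input
  expect_equal(nrow(tally(asg[0, ])), 0)
  m0 <- m
  m0$n_surplus <- 0.5
  m0$p_surplus <- 0.1
  agg0 <- tally_aggregates(classify_table(m0), group_by = "CONUS")
  expect_true(all(agg0$n[agg0$measure == "priority"] == 0))
})

test_that("derived step counts obey the stacked-class identity", {
  m <- simulate_metrics(simulation_config(n_watersheds = 600, seed = 17))
  asg <- classify_table(m)
  agg <- tally_aggregates(asg, group_by = "CONUS")
  tl <- tally(asg, group_by = "CONUS")
  for (nu in c("N", "P")) {
    g <- function(meas) agg$n[agg$nutrient == nu & agg$measure == meas]
    a <- asg[asg$nutrient == nu, ]
    # in-field branch = stacked + in-field-only members of that branch
    infield_only_in_branch <- sum(a$input_reduction &
                                  a$strategy_class == "INFIELD_ONLY")
    expect_equal(g("in_field_branch"), g("stacked") + infield_only_in_branch)
    expect_equal(g("priority"), g("in_field_branch") + g("edge_branch"))
    expect_equal(g("total"), nrow(a))
  }
})

test_that("percentage shares reproduce the reported rounding convention", {
  expect_equal(percent_share(928, 1082), 85.8)
  expect_equal(percent_share(919, 1046), 87.9)
  expect_equal(percent_share(0, 10), 0)
  # half rounds away from zero: 1/16 = 6.25% -> 6.3
  expect_equal(percent_share(1, 16), 6.3)
  expect_error(percent_share(1, 0), "> 0")
  expect_error(percent_share(5, 4), "between")
})

test_that("net surplus shares use net semantics including soil mining", {
  m2 <- dplyr::bind_rows(
    metrics_row(watershed_id = "01000001", n_surplus = 10, area_km2 = 50),
    metrics_row(watershed_id = "02000001", n_surplus = 0, area_km2 = 50)
  )
  asg2 <- classify_table(m2, nutrients = "N")
  expect_equal(net_surplus_share(m2, asg2, "N"), 100)

  # negative surplus shrinks the denominator: share exceeds 100%
  m3 <- dplyr::bind_rows(
    metrics_row(watershed_id = "01000001", n_surplus = 10, area_km2 = 50),
    metrics_row(watershed_id = "02000001", n_surplus = -2, area_km2 = 50)
  )
  asg3 <- classify_table(m3, nutrients = "N")
  expect_equal(net_surplus_share(m3, asg3, "N"), 125)

  # invariance to splitting a watershed at the same per-ha surplus
  m4 <- dplyr::bind_rows(
    metrics_row(watershed_id = "01000001", n_surplus = 10, area_km2 = 25),
    metrics_row(watershed_id = "01000002", n_surplus = 10, area_km2 = 25),
    metrics_row(watershed_id = "02000001", n_surplus = -2, area_km2 = 50)
  )
  asg4 <- classify_table(m4, nutrients = "N")
  expect_equal(net_surplus_share(m4, asg4, "N"),
               net_surplus_share(m3, asg3, "N"))

  m5 <- m3
  m5$n_surplus <- c(-10, -2)
  expect_error(net_surplus_share(m5, classify_table(m5, nutrients = "N"), "N"),
               "not positive")
})

test_that("spearman matrix matches rank-then-Pearson with ties and NAs", {
  inc <- data.frame(a = 1:10, b = (1:10)^2, c = -(1:10))
  sm <- spearman_matrix(inc, c("a", "b", "c"))
  expect_equal(sm$rho["a", "b"], 1)
  expect_equal(sm$rho["a", "c"], -1)
  expect_equal(diag(sm$rho), c(a = 1, b = 1, c = 1))
  expect_equal(sm$rho, t(sm$rho))

  # ties and pairwise-complete deletion against the manual oracle
  set.seed(8)
  tied <- data.frame(
    x = sample(1:4, 40, TRUE) + 0,
    y = sample(1:5, 40, TRUE) + 0,
    z = rnorm(40)
  )
  tied$y[c(3, 11)] <- NA
  sm2 <- spearman_matrix(tied, c("x", "y", "z"))
  expect_equal(sm2$rho["x", "y"], oracle_spearman(tied$x, tied$y),
               tolerance = 1e-12)
  expect_equal(sm2$rho["y", "z"], oracle_spearman(tied$y, tied$z),
               tolerance = 1e-12)
  expect_equal(sm2$n_pairs["x", "y"], 38)

  # random tables agree with the independent implementation to 1e-12
  for (rep_i in 1:5) {
    r <- data.frame(u = rnorm(30), v = rnorm(30), w = runif(30))
    smr <- spearman_matrix(r, c("u", "v", "w"))
    for (pair in list(c("u", "v"), c("u", "w"), c("v", "w"))) {
      expect_equal(smr$rho[pair[1], pair[2]],
                   oracle_spearman(r[[pair[1]]], r[[pair[2]]]),
                   tolerance = 1e-12)
    }
  }

  const <- data.frame(a = 1:5, b = rep(2, 5))
  expect_warning(smc <- spearman_matrix(const, c("a", "b")), "constant")
  expect_true(is.na(smc$rho["a", "b"]))
})

test_that("basin summaries report median and IQR by linear interpolation", {
  m <- dplyr::bind_rows(
    metrics_row(watershed_id = "01000001", nue = 0.2),
    metrics_row(watershed_id = "01000002", nue = 0.4),
    metrics_row(watershed_id = "01000003", nue = 0.9),
    metrics_row(watershed_id = "02000001", nue = 0.55)
  )
  bs <- basin_summary(m, "nue")
  b1 <- bs[bs$basin_id == "01", ]
  expect_equal(b1$median, 0.4)
  expect_equal(b1$q25, stats::quantile(c(0.2, 0.4, 0.9), 0.25, names = FALSE))
  b2 <- bs[bs$basin_id == "02", ]
  expect_equal(unlist(b2[, c("q25", "median", "q75")], use.names = FALSE),
               rep(0.55, 3))
  expect_true(all(bs$q25 <= bs$median & bs$median <= bs$q75))
})
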