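test_that("decision-tree flags follow the five gates with printed boundary semantics", {
  thr <- threshold_set()

  # below the surplus gate: nothing else is evaluated
  low <- metrics_row(n_surplus = 6.9)
  f <- evaluate_flags(low, thr, "N")
  expect_false(f$priority)
  expect_equal(assign_class(f), "NOT_PRIORITY")

  # low efficiency, no edge-of-field need: in-field flags only
  m1 <- metrics_row(n_surplus = 10, nue = 0.5, pct_tile_of_ag = 5,
                    pct_nonbuffered_ws = 1, pct_prw_of_ag = 20)
  f1 <- evaluate_flags(m1, thr, "N")
  expect_true(f1$input_reduction && f1$field_loss_prevention)
  expect_false(f1$drainage_mgmt || f1$buffer_needed || f1$wetland_suitable)

  # efficient but tiled, unbuffered, wetland-suitable: edge branch stack
  m2 <- metrics_row(p_surplus = 3, pue = 0.8, pct_tile_of_ag = 40,
                    pct_nonbuffered_ws = 5, pct_prw_of_ag = 15)
  f2 <- evaluate_flags(m2, thr, "P")
  expect_false(f2$input_reduction)
  expect_true(f2$field_loss_prevention && f2$drainage_mgmt &&
              f2$buffer_needed && f2$wetland_suitable)

  # boundaries exactly as printed: >= for surplus/tile/nonbuffered/prw,
  # strict < for efficiency
  mb <- metrics_row(n_surplus = 7, nue = 0.7, pct_tile_of_ag = 30,
                    pct_nonbuffered_ws = 2, pct_prw_of_ag = 10)
  fb <- evaluate_flags(mb, thr, "N")
  expect_true(fb$priority)
  expect_false(fb$input_reduction)   # 0.7 is not below 0.7
  expect_true(fb$drainage_mgmt && fb$buffer_needed && fb$wetland_suitable)
})

test_that("class labels encode the in-field/edge branch and stacked actions", {
  # the well-buffered high-efficiency case (e.g. the Texas subwatershed):
  # edge branch with no drainage or buffer need falls back to in-field only
  tx <- metrics_row(watershed_id = "12050006", p_surplus = 2, pue = 0.85,
                    pct_tile_of_ag = 3, pct_nonbuffered_ws = 1.2)
  ftx <- evaluate_flags(tx, threshold_set(), "P")
  expect_false(ftx$input_reduction)
  expect_equal(assign_class(ftx), "INFIELD_ONLY")

  # full stack on the in-field branch
  full <- evaluate_flags(
    metrics_row(n_surplus = 20, nue = 0.3, pct_tile_of_ag = 45,
                pct_nonbuffered_ws = 6, pct_prw_of_ag = 25),
    threshold_set(), "N"
  )
  expect_equal(assign_class(full), "INFIELD_WETLAND_DRAINAGE")

  # assign_class is total and deterministic over all flag combinations
  combos <- expand.grid(priority = c(TRUE, FALSE),
                        input_reduction = c(TRUE, FALSE),
                        drainage_mgmt = c(TRUE, FALSE),
                        buffer_needed = c(TRUE, FALSE),
                        wetland_suitable = c(TRUE, FALSE))
  combos$field_loss_prevention <- combos$priority
  combos$missing_reason <- NA_character_
  combos$watershed_id <- sprintf("%08d", seq_len(nrow(combos)))
  c1 <- assign_class(combos)
  c2 <- assign_class(combos)
  expect_identical(c1, c2)
  expect_true(all(c1 %in% strategy_classes))
  expect_true(all(c1[!combos$priority] == "NOT_PRIORITY"))
})

test_that("priority records with missing downstream metrics are unclassified", {
  m <- metrics_row(n_surplus = 12, nue = NA_real_)
  f <- evaluate_flags(m, threshold_set(), "N")
  expect_equal(assign_class(f), "UNCLASSIFIED_MISSING")
  expect_match(f$missing_reason, "efficiency")
  expect_false(f$field_loss_prevention)

  # wetland metric only needs to exist when an edge-of-field flag is set
  m2 <- metrics_row(n_surplus = 12, nue = 0.5, pct_tile_of_ag = 1,
                    pct_nonbuffered_ws = 1, pct_prw_of_ag = NA_real_)
  f2 <- evaluate_flags(m2, threshold_set(), "N")
  expect_equal(assign_class(f2), "INFIELD_ONLY")
  m3 <- metrics_row(n_surplus = 12, nue = 0.5, pct_tile_of_ag = 50,
                    pct_nonbuffered_ws = 1, pct_prw_of_ag = NA_real_)
  expect_equal(assign_class(evaluate_flags(m3, threshold_set(), "N")),
               "UNCLASSIFIED_MISSING")
})

test_that("classification matches the scalar hand-trace over a boundary-straddling grid", {
  thr <- threshold_set()
  grid <- expand.grid(
    n_surplus = c(3, 7 - 1e-9, 7, 15),
    nue = c(0.4, 0.7 - 1e-9, 0.7, 0.9),
    pct_tile_of_ag = c(10, 30 - 1e-6, 30, 60),
    pct_nonbuffered_ws = c(1, 2 - 1e-6, 2, 8),
    pct_prw_of_ag = c(4, 10 - 1e-6, 10, 30)
  )
  m <- metrics_row()[rep(1, nrow(grid)), ]
  m$watershed_id <- sprintf("%08d", seq_len(nrow(grid)))
  for (cl in names(grid)) m[[cl]] <- grid[[cl]]
  asg <- classify_table(m, thr, nutrients = "N")
  expected <- vapply(seq_len(nrow(m)),
                     function(i) oracle_classify_one(m[i, ], thr, "N"),
                     character(1))
  expect_identical(asg$strategy_class, expected)
})

test_that("classify_table emits one assignment per nutrient per record", {
  empty <- metrics_row()[0, ]
  expect_equal(nrow(classify_table(empty)), 0)
  one <- metrics_row()
  expect_equal(nrow(classify_table(one)), 2)
  expect_setequal(classify_table(one)$nutrient, c("N", "P"))

  dup <- dplyr::bind_rows(one, one)
  expect_error(classify_table(dup), "duplicate")

  # 200 synthetic records equal the per-record loop for both nutrients
  m <- simulate_metrics(simulation_config(n_watersheds = 200, seed = 9))
  asg <- classify_table(m)
  thr <- threshold_set()
  for (nu in c("N", "P")) {
    got <- asg$strategy_class[asg$nutrient == nu]
    want <- vapply(seq_len(nrow(m)),
                   function(i) oracle_classify_one(m[i, ], thr, nu),
                   character(1))
    expect_identical(got, want)
  }
})

test_that("threshold sweeps move flag counts monotonically", {
  m <- simulate_metrics(simulation_config(n_watersheds = 800, seed = 13))

  scan_default <- sensitivity_scan(m, list(surplus_n = 7))
  base <- classify_table(m)
  base_n <- base[base$nutrient == "N", ]
  row_n <- scan_default[scan_default$nutrient == "N", ]
  expect_equal(row_n$n_priority, sum(base_n$priority))
  expect_equal(row_n$n_INFIELD_ONLY,
               sum(base_n$strategy_class == "INFIELD_ONLY"))

  sn <- sensitivity_scan(m, list(surplus_n = c(5, 7, 9, 12)))
  sn_n <- sn[sn$nutrient == "N", ]
  expect_true(all(diff(sn_n$n_priority[order(sn_n$surplus_n)]) <= 0))

  se <- sensitivity_scan(m, list(efficiency = c(0.5, 0.7, 0.9)))
  se_n <- se[se$nutrient == "N", ]
  expect_true(all(diff(se_n$n_input_reduction[order(se_n$efficiency)]) >= 0))

  st <- sensitivity_scan(m, list(tile_pct = c(10, 30, 50)), nutrients = "N")
  expect_true(all(diff(st$n_drainage_mgmt[order(st$tile_pct)]) <= 0))

  expect_error(sensitivity_scan(m, list()), "empty")
  expect_error(sensitivity_scan(m, list(bogus = 1)), "unknown")
})
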