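test_that("blood:water partitioning follows the LogD calibration", {
  expect_equal(blood_water_partition(0.88 / 0.73), 1.0)
  expect_equal(blood_water_partition(1.31), 1.19, tolerance = 0.005)
  expect_equal(blood_water_partition(4.26), 169.75, tolerance = 0.001)
  # configurable coefficients
  expect_equal(blood_water_partition(2, slope = 0.5, intercept = 0), 10)
})

test_that("steady-state plasma prediction scales water concentration", {
  expect_equal(predict_fss_pc(0, 123), 0)
  expect_equal(predict_fss_pc(1, 1.19), 1.19)
  expect_equal(predict_fss_pc(2, 0.5), 1.0)
  expect_error(predict_fss_pc(-1, 1), ">= 0")
})

test_that("original and refined TWC reproduce printed examples", {
  # meloxicam: Cmax 0.4, LogD(7.4) -1.12
  expect_equal(twc_original(0.4, blood_water_partition(-1.12)),
               19.94, tolerance = 0.01)
  # cilostazol: Cmax 1.2, LogD(7.4) 2.97
  expect_equal(twc_original(1.2, blood_water_partition(2.97)),
               0.062, tolerance = 0.01)
  expect_equal(twc_original(5, 5), 1.0)
  # ibuprofen refined: Cmax 15, Rfu 55, LogD(7.9) 0.87
  expect_equal(twc_refined(15, 55, blood_water_partition(0.87)),
               0.48, tolerance = 0.01)
  # tolbutamide refined: Cmax 45, Rfu 35, LogD(7.9) 1.21
  expect_equal(twc_refined(45, 35, blood_water_partition(1.21)),
               1.28, tolerance = 0.01)
  # Rfu = 1 leaves the original model unchanged at the same partitioning
  expect_equal(twc_refined(10, 1, 2.5), twc_original(10, 2.5))
  # absences propagate as absences
  expect_true(is.na(twc_original(NA_real_, 2)))
  expect_true(is.na(twc_refined(10, NA_real_, 2)))
  expect_true(is.na(twc_refined(10, 0, 2)))  # below quantification
})

test_that("TWC identity and monotonicity hold in unrounded arithmetic", {
  set.seed(11)
  for (i in 1:50) {
    cmax <- runif(1, 1e-4, 50)
    r <- runif(1, 0.05, 100)
    ph <- runif(1, 0.01, 200)
    pf <- runif(1, 0.01, 200)
    expect_equal(twc_original(cmax, ph) / twc_refined(cmax, r, pf),
                 r * pf / ph, tolerance = 1e-12)
  }
  logd <- seq(-2, 5, by = 0.1)
  expect_true(all(diff(twc_original(1, blood_water_partition(logd))) < 0))
  rfu <- seq(0.1, 100, by = 0.5)
  expect_true(all(diff(twc_refined(1, rfu, 1)) < 0))
})

test_that("conservatism assessment compares TWC with chronic effect data", {
  twc <- data.frame(twc_original = 15.63, twc_refined = 0.57)
  out <- assess_conservatism(twc, noec = 0.1, loec = 0.3)
  expect_equal(out$ratio_orig_to_loec, 52.1, tolerance = 0.001)
  expect_equal(out$ratio_refined_to_loec, 1.9, tolerance = 0.001)
  # neither model variant is conservative here: both TWCs exceed the LOEC
  expect_false(out$conservative_original)
  expect_false(out$conservative_refined)
  # boundary is inclusive
  out2 <- assess_conservatism(
    data.frame(twc_original = 0.3, twc_refined = 0.1), loec = 0.3)
  expect_true(out2$conservative_original)
  # NOEC only: ratio against NOEC, conservatism flag absent
  out3 <- assess_conservatism(
    data.frame(twc_original = 12.58, twc_refined = 0.48),
    noec = 0.68, loec = NA)
  expect_equal(out3$ratio_orig_to_loec, 12.58 / 0.68)
  expect_true(is.na(out3$conservative_original))
})

test_that("screen reproduces the full printed table within printed precision", {
  fx <- load_fixture()
  twc <- fpm_screen(fx$apis, rfu = fx$rfu$rfu_trout_max_human_min)
  expect_equal(twc$api_name, fx$apis$name)   # deterministic input order
  raw <- fixture_printed()
  rfu_slack <- printed_input_rel(raw$rfu_trout_max_human_min)
  cases <- list(
    list("p_bw_original", "pbw_fish", 0),
    list("p_bw_refined", "pbw_trout", 0),
    list("twc_original", "twc_original_mg_per_L", 0),
    list("twc_refined", "twc_refined_mg_per_L", rfu_slack),
    list("twc_ratio", "twc_orig_over_refined", rfu_slack),
    list("ratio_orig_to_loec", "twc_orig_over_loec", 0),
    list("ratio_refined_to_loec", "twc_refined_over_loec", rfu_slack))
  n_cells <- n_1pct <- 0L
  for (cs in cases) {
    computed <- twc[[cs[[1]]]]
    printed <- as.numeric(raw[[cs[[2]]]])
    tol <- printed_tolerance(raw[[cs[[2]]]], rel = 0.05,
                             input_rel = cs[[3]])
    idx <- which(!is.na(printed) & !is.na(computed))
    expect_true(all(abs(computed[idx] - printed[idx]) <= tol[idx]),
                info = cs[[1]])
    nz <- idx[printed[idx] != 0]
    n_cells <- n_cells + length(nz)
    n_1pct <- n_1pct +
      sum(abs(computed[nz] - printed[nz]) <= 0.01 * abs(printed[nz]))
  }
  # the bulk of the printed cells agree to better than 1% relative;
  # the remainder is printed-resolution and Rf_u-rounding slack
  expect_gt(n_1pct / n_cells, 0.5)
  # APIs lacking C_max keep absent TWC fields
  expect_true(all(is.na(twc$twc_original[is.na(fx$apis$cmax_mg_per_L)])))
})

test_that("screen handles edge inputs and reports missing LogD columns", {
  fx <- load_fixture()
  empty <- fpm_screen(fx$apis[0, ], rfu = numeric(0))
  expect_equal(nrow(empty), 0L)
  expect_error(fpm_screen(fx$apis, species = "goldfish",
                          rfu = fx$rfu$rfu_trout_max_human_min),
               "rainbow_trout")
  no_logd <- fx$apis
  no_logd$`logd_ph7.9` <- NULL
  expect_error(fpm_screen(no_logd, rfu = fx$rfu$rfu_trout_max_human_min),
               "logd_ph7.9")
})

test_that("median-rule screening uses the median Rf_u column", {
  fx <- load_fixture()
  rfu_df <- data.frame(api_name = fx$apis$name,
                       rfu_median = rep(2, 44),
                       rfu_max = fx$rfu$rfu_trout_max_human_min)
  by_median <- fpm_screen(fx$apis, rfu = rfu_df, rfu_rule = "median")
  expect_true(all(by_median$rfu_used == 2))
  by_max <- fpm_screen(fx$apis, rfu = rfu_df, rfu_rule = "max")
  expect_equal(by_max$rfu_used, fx$rfu$rfu_trout_max_human_min)
})
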