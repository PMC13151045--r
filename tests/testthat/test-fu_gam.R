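test_that("the transformation ladder stops at the first normal rung", {
  set.seed(2)
  near_normal <- pmin(pmax(rnorm(30, 0.5, 0.1), 1e-3), 1)
  expect_equal(transform_ladder(near_normal)$transform_name, "none")

  # fourth powers of normal variates: only the fourth root restores
  # normality (construction checked by Shapiro-Wilk at this seed)
  set.seed(1)
  z <- rnorm(80, 0.6, 0.15)
  x <- z^4
  ladder <- transform_ladder(x)
  expect_equal(ladder$transform_name, "fourth_root")
  expect_equal(ladder$values, z, tolerance = 1e-12)
  expect_true(all(ladder$shapiro_p[c("none", "log10", "sqrt")] <= 0.05))

  expect_error(transform_ladder(c(0.1, 0.2)), "at least 3")
  expect_error(transform_ladder(c(0.1, 0.2, 1.5)), "\\(0, 1\\]")
})

# shared synthetic panel: strong LogD effect, MW and pKa inert
gam_panel <- function(seed = 7, n = 200) {
  cfg <- synthetic_config(seed = seed, n_apis = n)
  panel <- generate_api_panel(cfg)
  fus <- aggregate_fu(simulate_dialysis(panel, cfg))
  tr <- fus[fus$species == "rainbow_trout", ]
  data.frame(fu = pmin(tr$fu_median[match(panel$name, tr$api)], 1),
             mw = panel$mw, logd = panel$`logd_ph7.9`, pka = panel$pka,
             charge_class = panel$charge_class)
}

test_that("the additive model finds the built-in LogD effect and not MW", {
  d <- gam_panel(seed = 7, n = 200)
  fit <- fit_fu_gam(d, species = "rainbow_trout",
                    transform = "fourth_root")
  expect_lt(fit$predictor_significance[["logd"]], 0.01)
  expect_gt(fit$predictor_significance[["mw"]], 0.1)
  expect_equal(fit$family, "gamma, log link")
  expect_equal(fit$basis_dim_k, 4)
  expect_true(all(fit$smooth_edf <= fit$basis_dim_k - 1 + 1e-6))
  expect_true(fit$deviance_explained_pct >= 0 &&
                fit$deviance_explained_pct <= 100)

  # brute-force cross-check: dropping the LogD smooth costs far more
  # residual deviance than dropping the MW smooth
  full <- fit$fit
  no_logd <- mgcv::gam(fu_t ~ s(mw, k = 4) + s(pka, k = 4) + charge_class,
                       family = Gamma(link = "log"),
                       data = transform(d, fu_t = fu^0.25),
                       method = "GCV.Cp")
  no_mw <- mgcv::gam(fu_t ~ s(logd, k = 4) + s(pka, k = 4) + charge_class,
                     family = Gamma(link = "log"),
                     data = transform(d, fu_t = fu^0.25),
                     method = "GCV.Cp")
  drop_logd <- deviance(no_logd) - deviance(full)
  drop_mw <- deviance(no_mw) - deviance(full)
  expect_gt(drop_logd, 50 * max(drop_mw, 1e-8))
})

test_that("an effectively constant response explains almost no deviance", {
  set.seed(4)
  n <- 40
  d <- data.frame(fu = rep(0.5, n) * exp(rnorm(n, 0, 1e-4)),
                  mw = runif(n, 150, 700), logd = runif(n, -2, 5),
                  pka = runif(n, 1, 13),
                  charge_class = sample(c("anionic", "cationic",
                                          "neutral", "zwitterionic"),
                                        n, replace = TRUE))
  fit <- fit_fu_gam(d, transform = "fourth_root")
  expect_lt(fit$deviance_explained_pct, 25)
})

test_that("a charge-only effect is detected, confirmed by permutation", {
  set.seed(9)
  n <- 44
  charge <- sample(c("anionic", "cationic", "neutral", "zwitterionic"),
                   n, replace = TRUE, prob = c(0.4, 0.4, 0.15, 0.05))
  mu <- c(anionic = 0.5, cationic = 0.08, neutral = 0.15,
          zwitterionic = 0.2)[charge]
  d <- data.frame(fu = pmin(pmax(mu * exp(rnorm(n, 0, 0.25)), 1e-3), 1),
                  mw = runif(n, 150, 700), logd = runif(n, -2, 5),
                  pka = runif(n, 1, 13), charge_class = charge)
  fit <- fit_fu_gam(d, transform = "fourth_root")
  expect_lt(fit$predictor_significance[["charge"]], 0.05)
  p_perm <- gam_term_permutation_p(d, "charge_class", n_perm = 200,
                                   seed = 1, transform = "fourth_root")
  expect_lt(p_perm, 0.05)
})

test_that("deviance explained is invariant to column order and rescaling", {
  d <- gam_panel(seed = 5, n = 60)
  fit1 <- fit_fu_gam(d, transform = "fourth_root")
  fit2 <- fit_fu_gam(d[, c("pka", "charge_class", "fu", "logd", "mw")],
                     transform = "fourth_root")
  expect_equal(fit1$deviance_explained_pct, fit2$deviance_explained_pct,
               tolerance = 1e-6)
  rescaled <- transform(d, mw = (mw - 300) / 100, logd = 10 * logd,
                        pka = pka / 3 + 1)
  fit3 <- fit_fu_gam(rescaled, transform = "fourth_root")
  expect_equal(fit1$deviance_explained_pct, fit3$deviance_explained_pct,
               tolerance = 1e-6)
})

test_that("basis dimension checks flag smooths near saturation", {
  fake <- structure(list(smooth_edf = c(mw = 1.0, logd = 2.9),
                         basis_dim_k = 4), class = "fu_gam_fit")
  chk <- check_basis_dimension(fake)
  expect_true(chk$adequate[chk$term == "mw"])      # 1.0 < 2.7
  expect_false(chk$adequate[chk$term == "logd"])   # 2.9 >= 2.7

  # linear truth: all smooths should stay near one degree of freedom
  set.seed(3)
  n <- 120
  d <- data.frame(mw = runif(n, 150, 700), logd = runif(n, -2, 5),
                  pka = runif(n, 1, 13),
                  charge_class = sample(c("anionic", "cationic"),
                                        n, replace = TRUE))
  d$fu <- pmin(pmax(
    0.35 - 0.04 * d$logd + 0.0001 * (d$mw - 400) +
      rnorm(n, 0, 0.01), 1e-3), 1)
  fit <- fit_fu_gam(d, transform = "fourth_root")
  expect_true(all(check_basis_dimension(fit)$adequate))
})

test_that("degenerate predictors are dropped with a warning", {
  d <- gam_panel(seed = 6, n = 50)
  d$pka <- 7
  expect_warning(fit <- fit_fu_gam(d, transform = "fourth_root"),
                 "pka")
  expect_true("pka" %in% fit$dropped_terms)
  expect_false("pka" %in% names(fit$predictor_significance))
  expect_error(fit_fu_gam(d[1:10, ], transform = "fourth_root"),
               ">= 20")
})
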