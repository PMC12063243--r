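test_that("mediator model fit matches saturated logit algebra", {
  d <- exact_binary_mediator_data()  # P(M|A=0)=0.07, P(M|A=1)=0.10 exactly
  fit <- fit_mediator_model(d, "m", "apoe4")
  expect_identical(fit$link, "logit")
  expect_equal(fit$beta0, logit(0.07), tolerance = 1e-4)
  expect_equal(fit$beta1, logit(0.10) - logit(0.07), tolerance = 1e-4)
  expect_equal(round(fit$beta0, 4), -2.5867)
  expect_equal(round(fit$beta1, 4), 0.3895)
})

test_that("model fits are consistent and reject degenerate designs", {
  withr::with_seed(31, {
    n <- 2e4
    a <- rbinom(n, 1, 0.3)
    m <- 0.15 * a + rnorm(n)
    y <- 0.1 * a + 0.25 * m + rnorm(n)
    d <- data.frame(apoe4 = a, m = m, y = y, dup = a)
    mf <- fit_mediator_model(d, "m", "apoe4")
    expect_identical(mf$link, "identity")
    expect_lt(abs(mf$beta1 - 0.15), 3 * 1 / sqrt(n * 0.3 * 0.7))
    expect_gt(mf$sigma, 0)

    of <- fit_outcome_model(d, "y", "apoe4", "m")
    expect_lt(abs(of$theta2[["m"]] - 0.25), 0.03)
    expect_lt(abs(of$theta3[["m"]]), 0.05)  # true interaction is zero

    # mediator independent of exposure
    d$m0 <- rnorm(n)
    expect_lt(abs(fit_mediator_model(d, "m0", "apoe4")$beta1), 0.03)

    # exposure duplicated as confounder: rank deficient
    expect_error(fit_mediator_model(d, "m", "apoe4", "dup"), "rank-deficient")
    # separation: binary outcome equal to exposure
    d$sep <- d$apoe4
    expect_error(fit_outcome_model(d, "sep", "apoe4", "m"), "separation")
  })
})

test_that("closed-form natural effects agree with the truth oracle in all four model combinations", {
  combos <- list(
    c(med = "identity", out = "identity"),
    c(med = "logit", out = "identity"),
    c(med = "identity", out = "logit"),
    c(med = "logit", out = "logit"))
  seeds <- c(101, 202, 303, 404)
  for (i in seq_along(combos)) {
    cc <- combos[[i]]
    cfg <- random_small_dgp(seeds[i])
    cfg$mediators$m <- if (cc[["med"]] == "identity")
      list(link = "identity", b0 = 0.2, b_exposure = 0.4, sd = 0.9)
    else list(link = "logit", b0 = logit(0.15), b_exposure = 0.45)
    cfg$outcomes$y <- if (cc[["out"]] == "identity")
      list(link = "identity", t0 = 0.1, t_exposure = -0.2,
           t_mediator = c(m = 0.3), t_interaction = c(m = 0.15), sd = 1)
    else list(link = "logit", t0 = logit(0.01), t_exposure = 0.4,
              t_mediator = c(m = 0.3), t_interaction = c(m = 0.1))
    cfg$confounders <- list()

    tf <- true_fits(cfg)
    dec <- natural_effects(tf$mfit, tf$ofit, data.frame(x = 1))
    tr <- counterfactual_oracle(cfg, "y", "m", mc_reps = 2e5,
                                seed = seeds[i] + 1)
    expect_decomposition_identity(dec)
    if (dec$scale == "difference") {
      d <- tr$difference
      expect_lt(abs(dec$nde - d$nde), 3 * d$mc_se[["nde"]] + 1e-9)
      expect_lt(abs(dec$nie - d$nie), 3 * d$mc_se[["nie"]] + 1e-9)
    } else {
      # closed form is the rare-outcome approximation; the oracle is exact,
      # so allow the O(prevalence) approximation slack on the log scale
      o <- tr$odds_ratio
      expect_lt(abs(log(dec$nde) - log(o$nde)), 3 * o$mc_se[["nde"]] + 0.03)
      expect_lt(abs(log(dec$nie) - log(o$nie)), 3 * o$mc_se[["nie"]] + 0.03)
    }
  }
})

test_that("no mediated path means NIE = 0 and TE = NDE exactly", {
  cfg <- dgp_config(
    n = 10, seed = 1, p_exposure = 0.283,
    mediators = list(m = list(link = "logit", b0 = logit(0.07),
                              b_exposure = logit(0.10) - logit(0.07))),
    outcomes = list(y = list(link = "identity", t0 = 0, t_exposure = -0.015,
                             t_mediator = c(m = 0), t_interaction = c(m = 0),
                             sd = 1)))
  tf <- true_fits(cfg)
  dec <- natural_effects(tf$mfit, tf$ofit, data.frame(x = 1))
  expect_identical(dec$nie, 0)
  expect_identical(dec$te, dec$nde)
  expect_identical(as.numeric(dec$pm), 0)
})

test_that("general interaction formulas reduce to no-interaction closed forms when theta3 = 0", {
  cfg <- random_small_dgp(77)
  cfg$confounders <- list()
  cfg$mediators$m <- list(link = "identity", b0 = 0.3, b_exposure = 0.25,
                          sd = 1.1)
  cfg$outcomes$y <- list(link = "identity", t0 = 0, t_exposure = -0.1,
                         t_mediator = c(m = 0.35), t_interaction = c(m = 0),
                         sd = 1)
  tf <- true_fits(cfg)
  dec <- natural_effects(tf$mfit, tf$ofit, data.frame(x = 1))
  expect_equal(dec$nde, -0.1, tolerance = 1e-12)        # theta1
  expect_equal(dec$nie, 0.35 * 0.25, tolerance = 1e-12) # theta2 beta1
})

test_that("estimated decomposition recovers the cog1 world and its identity", {
  d <- generate_cohort(calibration_dgp("cog1", n = 4e5, seed = 13))
  mfit <- fit_mediator_model(d, "mb2", "apoe4")
  ofit <- fit_outcome_model(d, "gfactor", "apoe4", "mb2")
  dec <- natural_effects(mfit, ofit, d)
  expect_decomposition_identity(dec)
  expect_lt(abs(dec$nde - (-0.015)), 0.01)
  expect_lt(abs(dec$nie - (-0.005)), 0.004)
  # decomposition TE equals the saturated total-effect regression exactly
  te <- total_effect(d, "gfactor", "apoe4")
  expect_lt(abs(dec$te - te$estimate), 0.002)
})

test_that("rare-outcome guard rejects common binary outcomes", {
  withr::with_seed(55, {
    n <- 5000
    a <- rbinom(n, 1, 0.3)
    m <- rbinom(n, 1, 0.2)
    y <- rbinom(n, 1, expit(-0.5 + 0.3 * a + 0.2 * m))  # ~40% prevalence
    d <- data.frame(apoe4 = a, m = m, y = y)
    mfit <- fit_mediator_model(d, "m", "apoe4")
    ofit <- fit_outcome_model(d, "y", "apoe4", "m")
    expect_error(natural_effects(mfit, ofit, d), "rare-outcome")
    expect_warning(natural_effects(mfit, ofit, d, rare_ok = TRUE),
                   "rare-outcome")
  })
})

expit <- stats::plogis

test_that("proportion mediated follows the stated formulas and flags", {
  mk <- function(scale, te, nde, nie)
    structure(list(scale = scale, te = te, nde = nde, nie = nie),
              class = "effect_decomposition")
  expect_equal(as.numeric(proportion_mediated(
    mk("difference", -0.020, -0.015, -0.005))), 0.25)
  expect_equal(as.numeric(proportion_mediated(
    mk("difference", -0.015, -0.015, 0))), 0)
  expect_equal(as.numeric(proportion_mediated(
    mk("difference", -0.005, 0, -0.005))), 1)
  pm_or <- proportion_mediated(mk("odds-ratio", 2.28 * 1.03, 2.28, 1.03))
  expect_equal(as.numeric(pm_or), 2.28 * 0.03 / (2.28 * 1.03 - 1),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(pm_or), 4), 0.0507)

  expect_warning(pm <- proportion_mediated(
    mk("difference", 1e-12, 0.002, -0.002)), "unstable")
  expect_true(attr(pm, "unstable"))
  pm2 <- proportion_mediated(mk("difference", 0.01, 0.03, -0.02))
  expect_true(attr(pm2, "opposite_signs"))
})

test_that("total effect is null under a null DGP", {
  cfg <- dgp_config(
    n = 2e4, seed = 6, p_exposure = 0.3,
    mediators = list(m = list(link = "identity", b0 = 0, b_exposure = 0,
                              sd = 1)),
    outcomes = list(y = list(link = "identity", t0 = 0, t_exposure = 0,
                             t_mediator = c(m = 0), sd = 1),
                    yb = list(link = "logit", t0 = logit(0.05),
                              t_exposure = 0, t_mediator = c(m = 0))))
  d <- generate_cohort(cfg)
  expect_lt(abs(total_effect(d, "y", "apoe4")$estimate), 0.05)
  expect_lt(abs(total_effect(d, "yb", "apoe4")$estimate - 1), 0.15)
})

test_that("bootstrap machinery: CLT width, determinism, edge cases", {
  withr::with_seed(91, {
    d <- data.frame(x = rnorm(1e4))
    bs <- bootstrap(function(dd) mean(dd$x), d, B = 1000, seed = 5)
    width <- bs$ci_high - bs$ci_low
    expect_lt(abs(width - 2 * 1.96 / sqrt(1e4)) / (2 * 1.96 / sqrt(1e4)),
              0.15)
    expect_identical(bootstrap(function(dd) mean(dd$x), d, B = 1000,
                               seed = 5), bs)
    # constant analysis: degenerate interval
    bc <- bootstrap(function(dd) 3.5, d[1:50, , drop = FALSE], B = 50,
                    seed = 1)
    expect_identical(unname(c(bc$ci_low, bc$point, bc$ci_high)),
                     c(3.5, 3.5, 3.5))
    # analyses that fail on > 1% of resamples are rejected with a count
    # fails whenever subject 1 is resampled more than once (~26% of draws)
    flaky <- function(dd) { if (sum(dd$id == 1) > 1) stop("boom"); mean(dd$v) }
    dd <- data.frame(id = 1:100, v = rnorm(100))
    expect_error(bootstrap(flaky, dd, B = 100, seed = 2), "failed")
    expect_error(bootstrap(function(dd) 1, d, B = 1), "B must be")
  })
})

test_that("bootstrap point estimate sits inside its own CI (flakiness guard)", {
  withr::with_seed(17, {
    inside <- 0L
    for (s in 1:20) {
      d <- data.frame(x = rnorm(300, 0.2))
      bs <- bootstrap(function(dd) mean(dd$x), d, B = 200, seed = s)
      inside <- inside + (bs$ci_low <= bs$point && bs$point <= bs$ci_high)
    }
    expect_gte(inside, 19L)
  })
})

test_that("pooling across imputations follows the stated rules", {
  d <- data.frame(x = rnorm(500))
  b1 <- bootstrap(function(dd) mean(dd$x), d, B = 200, seed = 3)
  # m identical results pool to the same point and CI
  pooled <- pool_imputations(list(b1, b1, b1))
  expect_equal(pooled$point, b1$point)
  expect_equal(unname(pooled$ci_low), unname(b1$ci_low), tolerance = 1e-10)
  # arithmetic pooling of points
  b2 <- b1; b2$point <- 0.2; b3 <- b1; b3$point <- 0.3
  b1b <- b1; b1b$point <- 0.1
  expect_equal(unname(pool_imputations(list(b1b, b2, b3))$point), 0.2)
  # mixed estimands rejected
  b4 <- b1; b4$estimand <- "other"
  expect_error(pool_imputations(list(b1, b4)), "mixed")
})

test_that("imputation no-op: pooled analysis on complete data equals the single-table analysis", {
  d <- generate_cohort(calibration_dgp("cog1", n = 5000, seed = 19))
  attr(d, "covariables") <- character(0)
  imp <- impute_covariables(d, m = 5, seed = 4, covariables = character(0))
  per <- lapply(imp$completed_tables, function(tb)
    mediate(tb, "gfactor", "apoe4", "mb2", B = 200, seed = 7))
  pooled_dec <- pool_imputations(lapply(per, `[[`, "decomposition"))
  pooled_boot <- pool_imputations(lapply(per, `[[`, "boot"))
  single <- mediate(d, "gfactor", "apoe4", "mb2", B = 200, seed = 7)
  expect_equal(pooled_dec$te, single$decomposition$te, tolerance = 1e-12)
  expect_equal(pooled_dec$nie, single$decomposition$nie, tolerance = 1e-12)
  expect_equal(unname(pooled_boot$point), unname(single$boot$point),
               tolerance = 1e-12)
  expect_equal(unname(pooled_boot$ci_low), unname(single$boot$ci_low),
               tolerance = 1e-12)
})
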