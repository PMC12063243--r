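test_that("invalid configs are rejected with the offending field named", {
  expect_error(dgp_config(n = 0, p_exposure = 0.3), "'n'")
  expect_error(dgp_config(n = 10, p_exposure = 1.3), "p_exposure")
  expect_error(
    dgp_config(n = 10, p_exposure = 0.3,
               confounders = list(age = list(dist = "normal", mean = 0,
                                             sd = -1))),
    "age\\$sd")
  expect_error(
    dgp_config(n = 10, p_exposure = 0.3,
               mediators = list(m = list(link = "identity", b0 = 0,
                                         b_exposure = 0, sd = 1,
                                         b_conf = c(bmi = 1)))),
    "undeclared confounder")
  expect_error(
    dgp_config(n = 10, p_exposure = 0.3,
               mediators = list(m = list(link = "identity", b0 = 0,
                                         b_exposure = 0, sd = 1)),
               outcomes = list(y = list(link = "identity", t0 = 0,
                                        t_exposure = 0,
                                        t_mediator = c(zz = 1), sd = 1))),
    "undeclared mediator")
  expect_error(
    dgp_config(n = 10, p_exposure = 0.3, missingness = c(apoe4 = 0.1)),
    "non-covariable")
})

test_that("generation is seed-deterministic and substream-stable", {
  cfg <- calibration_dgp("cog1", n = 500, seed = 9)
  d1 <- generate_cohort(cfg)
  d2 <- generate_cohort(cfg)
  expect_identical(d1, d2)

  # adding a second outcome must not perturb previously generated columns
  cfg2 <- cfg
  cfg2$outcomes$extra <- list(link = "identity", t0 = 0, t_exposure = 1,
                              t_mediator = c(mb2 = 0), sd = 1)
  d3 <- generate_cohort(cfg2)
  expect_identical(d1$apoe4, d3$apoe4)
  expect_identical(d1$mb2, d3$mb2)
  expect_identical(d1$gfactor, d3$gfactor)
})

test_that("column marginals match the configured targets", {
  # carrier prevalence
  d <- generate_cohort(calibration_dgp("cog1", n = 2e4, seed = 3))
  expect_lt(abs(mean(d$apoe4) - 0.283),
            3 * sqrt(0.283 * 0.717 / 2e4))

  # microbleed-burden prevalence by exposure, tight binomial check
  cfg <- dgp_config(
    n = 1e6, seed = 4, p_exposure = 0.283,
    mediators = list(mb2 = list(link = "logit", b0 = logit(0.074),
                                b_exposure = logit(0.102) - logit(0.074))))
  d <- generate_cohort(cfg)
  expect_lt(abs(mean(d$mb2[d$apoe4 == 0]) - 0.074), 0.002)
  expect_lt(abs(mean(d$mb2[d$apoe4 == 1]) - 0.102), 0.002)
})

test_that("null DGP yields mediators and outcomes independent of exposure", {
  cfg <- dgp_config(
    n = 1e4, seed = 5, p_exposure = 0.283,
    mediators = list(m = list(link = "logit", b0 = logit(0.1),
                              b_exposure = 0)),
    outcomes = list(y = list(link = "identity", t0 = 0, t_exposure = 0,
                             t_mediator = c(m = 0), sd = 1)))
  d <- generate_cohort(cfg)
  expect_gt(stats::chisq.test(table(d$apoe4, d$m))$p.value, 0.001)
  expect_gt(stats::t.test(d$y ~ d$apoe4)$p.value, 0.001)
})

test_that("the default cohort satisfies its structural invariants", {
  d <- generate_cohort(default_dgp_config(n = 3000, seed = 7))
  expect_true(all(d$wmh > 0))
  expect_true(all(d$dementia_time > 0))
  expect_identical(d$dementia_subtype == "none", d$dementia == 0L)
  expect_true(all(d$mb_count >= 0))
  expect_true(all(d$mb_lobar_count <= d$mb_count))
  expect_identical(as.integer(d$mb_count >= 2), d$mb2)
  # Table-1-like marginals (loose sampling bands)
  expect_lt(abs(mean(d$age) - 65), 0.8)
  expect_lt(abs(mean(d$hv) - 7.8), 0.1)
  expect_lt(abs(stats::median(d$wmh) - 3.1), 0.4)
  expect_lt(abs(mean(d$mb2) - 0.082), 0.02)
  expect_lt(mean(d$dementia), 0.10)  # rare-outcome regime
})

test_that("counterfactual oracle recovers closed-form truths", {
  # no mediator->outcome path: nie and pm vanish
  cfg0 <- dgp_config(
    n = 10, seed = 1, p_exposure = 0.3,
    mediators = list(m = list(link = "identity", b0 = 0, b_exposure = 0.5,
                              sd = 1)),
    outcomes = list(y = list(link = "identity", t0 = 0, t_exposure = 0.2,
                             t_mediator = c(m = 0), t_interaction = c(m = 0),
                             sd = 1)))
  tr0 <- counterfactual_oracle(cfg0, "y", "m", mc_reps = 5e4, seed = 2)
  expect_lt(abs(tr0$difference$nie), 3 * tr0$difference$mc_se[["nie"]] + 1e-12)
  expect_lt(abs(tr0$difference$pm), 0.05)

  # binary-mediator linear-outcome world: NDE = theta1, NIE = theta2 (p1 - p0)
  tr1 <- counterfactual_oracle(calibration_dgp("cog1", n = 10, seed = 1),
                               "gfactor", "mb2", mc_reps = 2e5, seed = 3)
  se <- tr1$difference$mc_se
  expect_lt(abs(tr1$difference$nde - (-0.015)), 3 * se[["nde"]])
  expect_lt(abs(tr1$difference$nie - (-0.005)), 3 * se[["nie"]])
  expect_lt(abs(tr1$difference$te - (-0.020)), 3 * se[["te"]])
  expect_lt(abs(tr1$difference$pm - 0.25), 0.02)

  # rare-outcome odds-ratio world: PM = 2.28 x 0.030 / 1.3484 = 5.07%
  tr2 <- counterfactual_oracle(calibration_dgp("dem1", n = 10, seed = 1),
                               "dementia", "mb2", mc_reps = 4e5, seed = 4)
  expect_lt(abs(tr2$odds_ratio$pm - 0.0507), 0.01)
  expect_lt(abs(log(tr2$odds_ratio$te) - log(2.345)),
            3 * tr2$odds_ratio$mc_se[["te"]])
})

test_that("oracle properties hold over random small DGPs", {
  for (seed in 1:5) {
    cfg <- random_small_dgp(seed, n = 10)
    tr <- counterfactual_oracle(cfg, "y", "m", mc_reps = 2e4, seed = seed + 100)
    d <- tr$difference
    # additivity te = nde + nie within Monte-Carlo error
    expect_lt(abs(d$te - (d$nde + d$nie)),
              3 * (d$mc_se[["te"]] + d$mc_se[["nde"]] + d$mc_se[["nie"]]) +
                1e-12)
    if (!is.null(tr$odds_ratio)) {
      o <- tr$odds_ratio
      expect_lt(abs(log(o$te) - log(o$nde) - log(o$nie)),
                3 * sum(o$mc_se) + 1e-12)
    }
  }

  # null structural coefficients: all true effects vanish
  cfg <- dgp_config(
    n = 10, seed = 2, p_exposure = 0.3,
    mediators = list(m = list(link = "identity", b0 = 0.2, b_exposure = 0,
                              sd = 1)),
    outcomes = list(y = list(link = "identity", t0 = 0, t_exposure = 0,
                             t_mediator = c(m = 0), sd = 1)))
  tr <- counterfactual_oracle(cfg, "y", "m", mc_reps = 5e4, seed = 11)
  for (q in c("te", "nde", "nie"))
    expect_lt(abs(tr$difference[[q]]), 3 * tr$difference$mc_se[[q]] + 1e-12)

  # linear no-interaction DGP: oracle nie matches theta2 * beta1
  cfg <- dgp_config(
    n = 10, seed = 3, p_exposure = 0.3,
    mediators = list(m = list(link = "identity", b0 = 0.1, b_exposure = 0.4,
                              sd = 1)),
    outcomes = list(y = list(link = "identity", t0 = 0, t_exposure = 0.1,
                             t_mediator = c(m = 0.3), sd = 1)))
  tr <- counterfactual_oracle(cfg, "y", "m", mc_reps = 1e5, seed = 12)
  expect_lt(abs(tr$difference$nie - 0.3 * 0.4),
            3 * tr$difference$mc_se[["nie"]])
})

test_that("oracle records a warning for low mc_reps", {
  cfg <- calibration_dgp("cog1", n = 10, seed = 1)
  expect_warning(
    tr <- counterfactual_oracle(cfg, "gfactor", "mb2", mc_reps = 500,
                                seed = 1),
    "mc_reps")
  expect_true(length(tr$warnings) == 1L)
})

test_that("missingness injection is MCAR at the configured rates", {
  cfg <- default_dgp_config(n = 1e5, seed = 8)
  coh <- generate_cohort(cfg)
  masked <- inject_missingness(coh, cfg)
  expect_lt(abs(mean(is.na(masked$diabetes)) - 0.010), 0.002)
  expect_lt(abs(mean(is.na(masked$af)) - 0.010), 0.002)
  expect_lt(abs(mean(is.na(masked$bp_med)) - 0.006), 0.002)
  # exposure/mediator/outcome columns untouched
  expect_false(anyNA(masked$apoe4))
  expect_false(anyNA(masked$hv))
  expect_false(anyNA(masked$dementia))

  # zero rates: unchanged; unit rate: entirely missing; bad target: rejected
  cfg0 <- cfg
  cfg0$missingness <- c(diabetes = 0, af = 0, bp_med = 0)
  expect_identical(inject_missingness(coh, cfg0), coh)
  cfg1 <- cfg
  cfg1$missingness <- c(diabetes = 1.0)
  expect_true(all(is.na(inject_missingness(coh, cfg1)$diabetes)))
  cfgbad <- cfg
  cfgbad$missingness <- c(hv = 0.1)
  expect_error(inject_missingness(coh, cfgbad), "non-covariable")
})
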