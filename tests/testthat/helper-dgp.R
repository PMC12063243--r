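# Shared fixtures: small hand-built data frames and randomly drawn small
# DGPs for property-style tests. Everything is generated in code under fixed
# seeds; no stored fixtures.

# a minimal confounder-free cohort for fit sanity checks, with exact cell
# frequencies so saturated-model coefficients are known in closed form
exact_binary_mediator_data <- function(n0 = 1000L, n1 = 1000L,
                                       k0 = 70L, k1 = 100L) {
  data.frame(
    apoe4 = rep(c(0L, 1L), c(n0, n1)),
    m = c(rep(c(1L, 0L), c(k0, n0 - k0)), rep(c(1L, 0L), c(k1, n1 - k1))))
}

# random small DGP for oracle-agreement and identity properties; rare binary
# outcomes are kept around 1-3% prevalence so the odds-ratio closed form is
# in its regime of validity
random_small_dgp <- function(seed, n = 2e5) {
  withr::with_seed(seed, {
    med_link <- sample(c("identity", "logit"), 1L)
    out_link <- sample(c("identity", "logit"), 1L)
    n_conf <- sample(0:2, 1L)
    conf <- if (n_conf > 0) {
      stats::setNames(
        replicate(n_conf, list(dist = "normal", mean = 0, sd = 1),
                  simplify = FALSE),
        paste0("c", seq_len(n_conf)))
    } else list()
    rc <- function(lo, hi) stats::runif(1L, lo, hi)
    b_conf <- if (n_conf) stats::setNames(stats::runif(n_conf, -0.2, 0.2),
                                          names(conf)) else NULL
    t_conf <- if (n_conf) stats::setNames(stats::runif(n_conf, -0.2, 0.2),
                                          names(conf)) else NULL
    med <- if (med_link == "identity")
      list(link = "identity", b0 = rc(-0.5, 0.5), b_exposure = rc(-0.5, 0.5),
           b_conf = b_conf, sd = rc(0.5, 1.5))
    else
      list(link = "logit", b0 = logit(rc(0.05, 0.3)),
           b_exposure = rc(-0.5, 0.5), b_conf = b_conf)
    out <- if (out_link == "identity")
      list(link = "identity", t0 = rc(-0.5, 0.5), t_exposure = rc(-0.3, 0.3),
           t_mediator = c(m = rc(-0.4, 0.4)),
           t_interaction = c(m = rc(-0.2, 0.2)), t_conf = t_conf, sd = 1)
    else
      list(link = "logit", t0 = logit(0.01), t_exposure = rc(-0.3, 0.3),
           t_mediator = c(m = rc(-0.3, 0.3)),
           t_interaction = c(m = rc(-0.15, 0.15)), t_conf = t_conf)
    dgp_config(n = n, seed = seed, p_exposure = stats::runif(1L, 0.2, 0.5),
               confounders = conf, mediators = list(m = med),
               outcomes = list(y = out))
  })
}

# mediator/outcome fit objects built directly from a DGP's true coefficients
# (bypassing estimation), to test the natural-effect formulas in isolation
true_fits <- function(cfg, mean_y = 0.01) {
  ms <- cfg$mediators$m
  os <- cfg$outcomes$y
  cn <- names(cfg$confounders)
  mfit <- structure(
    list(link = ms$link, beta0 = ms$b0, beta1 = ms$b_exposure,
         beta2 = stats::setNames((ms$b_conf %||% numeric(0))[cn], cn),
         sigma = ms$sd %||% NULL, n = cfg$n, mediator = "m",
         exposure = "apoe4", confounders = cn),
    class = "mediator_fit")
  ofit <- structure(
    list(link = os$link, theta0 = os$t0, theta1 = os$t_exposure,
         theta2 = os$t_mediator, theta3 = os$t_interaction,
         theta4 = stats::setNames((os$t_conf %||% numeric(0))[cn], cn),
         resid_sd = os$sd %||% NULL, mean_y = mean_y, n = cfg$n,
         outcome = "y", exposure = "apoe4", mediators = "m",
         confounders = cn),
    class = "outcome_fit")
  list(mfit = mfit, ofit = ofit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
logit <- stats::qlogis

expect_decomposition_identity <- function(dec, tol = 1e-10) {
  if (dec$scale == "difference") {
    expect_lt(abs(dec$te - (dec$nde + dec$nie)), tol)
  } else {
    expect_lt(abs(log(dec$te) - (log(dec$nde) + log(dec$nie))), tol)
  }
}
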