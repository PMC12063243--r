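# Synthetic cohort generator: an explicit data-generating process (DGP) that
# emulates a population-based neuroimaging cohort (exposure = APOE e4
# carriership, mediators = MRI markers, outcomes = global cognition and
# incident dementia), plus an exact Monte-Carlo counterfactual oracle for the
# same DGP so every estimator in the package can be validated against known
# truths without access to any real cohort.

#' Specify a synthetic-cohort data-generating process
#'
#' A `dgp_config` fully parameterises the causal chain
#' confounders -> exposure, confounders -> mediators <- exposure,
#' (exposure, mediators, confounders) -> outcomes. Mediator models are linear
#' (`link = "identity"`, Gaussian residual) or logistic (`link = "logit"`);
#' outcome models likewise, with optional exposure-by-mediator interaction
#' coefficients.
#'
#' @param n number of subjects (>= 1).
#' @param seed base integer seed. Every generated column draws from its own
#'   named substream derived from this seed, so adding a column to the config
#'   never perturbs previously generated columns.
#' @param p_exposure carrier prevalence, in `[0, 1]`.
#' @param confounders named list; each element is a list with `dist` one of
#'   `"normal"` (`mean`, `sd`), `"binary"` (`p`), or `"categorical"` (`probs`,
#'   generating integer codes `1..k`).
#' @param mediators named list; each element has `link` (`"identity"` or
#'   `"logit"`), `b0` (intercept), `b_exposure`, optional named `b_conf`
#'   vector over declared confounders, and `sd` (identity link only).
#' @param outcomes named list; each element has `link`, `t0`, `t_exposure`,
#'   named `t_mediator` and optional `t_interaction` vectors over declared
#'   mediators, optional named `t_conf`, and `sd` (identity link only).
#' @param cognition `NULL`, or a list describing a battery of test scores
#'   generated from a named continuous outcome (the latent cognition score):
#'   `outcome`, `loadings` (named), `reverse_coded` (test names stored with
#'   flipped sign, i.e. higher = worse), `p_incomplete` (fraction of subjects
#'   with incomplete assessment, missing at random across tests).
#' @param followup `NULL`, or a list attaching follow-up to a named binary
#'   outcome: `outcome`, `median_years`, `spread` (SD of the censoring-time
#'   distribution), `max_years`, `p_ad` (probability an event is clinical
#'   Alzheimer's disease).
#' @param missingness named numeric vector of MCAR rates over confounder
#'   (covariable) columns, applied by [inject_missingness()].
#' @param imaging_extras if `TRUE`, also generate microbleed counts (with a
#'   lobar subset), a cortical-infarct indicator, and a raw
#'   white-matter-hyperintensity volume `wmh = exp(ln_wmh)`; requires
#'   mediators named `mb2` and (for `wmh`) `ln_wmh`.
#'
#' @return an object of class `dgp_config`.
#' @seealso [generate_cohort()], [counterfactual_oracle()],
#'   [default_dgp_config()]
#' @export
dgp_config <- function(n, seed = 1L, p_exposure,
                       confounders = list(),
                       mediators = list(),
                       outcomes = list(),
                       cognition = NULL,
                       followup = NULL,
                       missingness = numeric(0),
                       imaging_extras = FALSE) {
  cfg <- structure(
    list(n = as.integer(n), seed = as.integer(seed), p_exposure = p_exposure,
         confounders = confounders, mediators = mediators,
         outcomes = outcomes, cognition = cognition, followup = followup,
         missingness = missingness, imaging_extras = imaging_extras),
    class = "dgp_config")
  validate_dgp_config(cfg)
  cfg
}

validate_dgp_config <- function(cfg) {
  fail <- function(field, msg) stop("invalid dgp_config field '", field, "': ",
                                    msg, call. = FALSE)
  if (!is.finite(cfg$n) || cfg$n < 1L) fail("n", "must be >= 1")
  if (!is.numeric(cfg$p_exposure) || cfg$p_exposure < 0 || cfg$p_exposure > 1)
    fail("p_exposure", "must be a probability in [0,1]")
  cn <- names(cfg$confounders)
  if (length(cfg$confounders) && (is.null(cn) || any(cn == "")))
    fail("confounders", "must be a named list")
  for (nm in cn) {
    cs <- cfg$confounders[[nm]]
    d <- cs$dist %||% "normal"
    if (d == "normal") {
      if (!is.numeric(cs$sd) || cs$sd <= 0)
        fail(paste0("confounders$", nm, "$sd"), "must be > 0")
    } else if (d == "binary") {
      if (!is.numeric(cs$p) || cs$p < 0 || cs$p > 1)
        fail(paste0("confounders$", nm, "$p"), "must be in [0,1]")
    } else if (d == "categorical") {
      if (any(cs$probs < 0) || abs(sum(cs$probs) - 1) > 1e-8)
        fail(paste0("confounders$", nm, "$probs"), "must be a simplex")
    } else fail(paste0("confounders$", nm, "$dist"), "unknown distribution")
  }
  for (nm in names(cfg$mediators)) {
    ms <- cfg$mediators[[nm]]
    if (!(ms$link %in% c("identity", "logit")))
      fail(paste0("mediators$", nm, "$link"), "must be identity or logit")
    if (ms$link == "identity" && (!is.numeric(ms$sd) || ms$sd <= 0))
      fail(paste0("mediators$", nm, "$sd"), "must be > 0 for identity link")
    bad <- setdiff(names(ms$b_conf %||% numeric(0)), cn)
    if (length(bad))
      fail(paste0("mediators$", nm, "$b_conf"),
           paste0("references undeclared confounder(s): ",
                  paste(bad, collapse = ", ")))
  }
  mn <- names(cfg$mediators)
  for (nm in names(cfg$outcomes)) {
    os <- cfg$outcomes[[nm]]
    if (!(os$link %in% c("identity", "logit")))
      fail(paste0("outcomes$", nm, "$link"), "must be identity or logit")
    if (os$link == "identity" && (!is.numeric(os$sd) || os$sd <= 0))
      fail(paste0("outcomes$", nm, "$sd"), "must be > 0 for identity link")
    for (fld in c("t_mediator", "t_interaction")) {
      bad <- setdiff(names(os[[fld]] %||% numeric(0)), mn)
      if (length(bad))
        fail(paste0("outcomes$", nm, "$", fld),
             paste0("references undeclared mediator(s): ",
                    paste(bad, collapse = ", ")))
    }
    bad <- setdiff(names(os$t_conf %||% numeric(0)), cn)
    if (length(bad))
      fail(paste0("outcomes$", nm, "$t_conf"),
           paste0("references undeclared confounder(s): ",
                  paste(bad, collapse = ", ")))
  }
  if (length(cfg$missingness)) {
    if (any(cfg$missingness < 0 | cfg$missingness > 1))
      fail("missingness", "rates must be in [0,1]")
    bad <- setdiff(names(cfg$missingness), cn)
    if (length(bad))
      fail("missingness", paste0("non-covariable column(s): ",
                                 paste(bad, collapse = ", ")))
  }
  if (isTRUE(cfg$imaging_extras) && !("mb2" %in% mn))
    fail("imaging_extras", "requires a mediator named 'mb2'")
  invisible(cfg)
}

draw_confounders <- function(cfg, n, seed, prefix = "conf") {
  out <- list()
  for (nm in names(cfg$confounders)) {
    cs <- cfg$confounders[[nm]]
    d <- cs$dist %||% "normal"
    out[[nm]] <- with_substream(seed, paste0(prefix, ":", nm), switch(
      d,
      normal = stats::rnorm(n, cs$mean, cs$sd),
      binary = stats::rbinom(n, 1L, cs$p),
      categorical = sample.int(length(cs$probs), n, replace = TRUE,
                               prob = cs$probs)))
  }
  out
}

mediator_lp <- function(ms, a, conf) {
  lp <- ms$b0 + ms$b_exposure * a
  for (cn in names(ms$b_conf %||% numeric(0)))
    lp <- lp + ms$b_conf[[cn]] * conf[[cn]]
  lp
}

outcome_lp <- function(os, a, med, conf) {
  lp <- os$t0 + os$t_exposure * a
  for (mn in names(os$t_mediator %||% numeric(0)))
    lp <- lp + os$t_mediator[[mn]] * med[[mn]]
  for (mn in names(os$t_interaction %||% numeric(0)))
    lp <- lp + os$t_interaction[[mn]] * a * med[[mn]]
  for (cn in names(os$t_conf %||% numeric(0)))
    lp <- lp + os$t_conf[[cn]] * conf[[cn]]
  lp
}

#' Generate a synthetic cohort from a DGP configuration
#'
#' Columns are drawn in causal order: confounders, then exposure (`apoe4`),
#' then mediators given exposure and confounders, then outcomes given all of
#' the above, then any cognition battery and dementia follow-up decoration.
#' Generation is bit-reproducible given `config$seed`; each column uses a
#' named RNG substream.
#'
#' @param config a [dgp_config()].
#' @return a `data.frame` with one row per subject, carrying the config as
#'   attribute `dgp_config` and the confounder names as attribute
#'   `covariables`.
#' @export
generate_cohort <- function(config) {
  validate_dgp_config(config)
  n <- config$n
  seed <- config$seed
  cols <- list(subject_id = seq_len(n))
  conf <- draw_confounders(config, n, seed)
  cols <- c(cols, conf)

  cols$apoe4 <- with_substream(seed, "exposure",
                               stats::rbinom(n, 1L, config$p_exposure))
  a <- cols$apoe4

  med <- list()
  for (nm in names(config$mediators)) {
    ms <- config$mediators[[nm]]
    lp <- mediator_lp(ms, a, conf)
    med[[nm]] <- with_substream(seed, paste0("mediator:", nm),
      if (ms$link == "identity") lp + stats::rnorm(n, 0, ms$sd)
      else stats::rbinom(n, 1L, expit(lp)))
  }
  cols <- c(cols, med)

  outc <- list()
  for (nm in names(config$outcomes)) {
    os <- config$outcomes[[nm]]
    lp <- outcome_lp(os, a, med, conf)
    outc[[nm]] <- with_substream(seed, paste0("outcome:", nm),
      if (os$link == "identity") lp + stats::rnorm(n, 0, os$sd)
      else stats::rbinom(n, 1L, expit(lp)))
  }
  cols <- c(cols, outc)

  if (isTRUE(config$imaging_extras)) {
    # microbleed counts consistent with the >=2 indicator: subjects with
    # mb2 = 1 get 2 + Poisson extra bleeds, others 0 or 1 (zero-inflated
    # shape; only the >=2 prevalence is calibrated, as the analyses only use
    # the dichotomy)
    mb2 <- med$mb2
    cols$mb_count <- with_substream(seed, "mb_count",
      ifelse(mb2 == 1L, 2L + stats::rpois(n, 1), stats::rbinom(n, 1L, 0.12)))
    cols$mb_lobar_count <- with_substream(seed, "mb_lobar",
      stats::rbinom(n, cols$mb_count, 0.75))
    cols$cortical_infarct <- with_substream(seed, "cortical_infarct",
      stats::rbinom(n, 1L, 0.03))
    if (!is.null(med$ln_wmh)) {
      cols$wmh <- exp(med$ln_wmh)
      cols$ln_wmh <- NULL
    }
  }

  if (!is.null(config$cognition)) {
    cg <- config$cognition
    g <- outc[[cg$outcome]]
    tests <- list()
    for (tn in names(cg$loadings)) {
      lam <- cg$loadings[[tn]]
      sc <- with_substream(seed, paste0("test:", tn),
                           lam * g + stats::rnorm(n, 0, sqrt(max(1 - lam^2, 0.05))))
      if (tn %in% (cg$reverse_coded %||% character(0))) sc <- -sc
      tests[[tn]] <- sc
    }
    p_inc <- cg$p_incomplete %||% 0
    if (p_inc > 0) {
      inc <- with_substream(seed, "test:incomplete", {
        idx <- which(stats::runif(n) < p_inc)
        # each incomplete subject misses a random non-empty subset of tests
        k <- length(tests)
        miss <- matrix(FALSE, n, k)
        if (length(idx)) {
          sub <- matrix(stats::runif(length(idx) * k) < 0.5, ncol = k)
          for (j in which(rowSums(sub) == 0))  # ensure >= 1 missing test
            sub[j, sample.int(k, 1L)] <- TRUE
          miss[idx, ] <- sub
        }
        miss
      })
      for (j in seq_along(tests)) tests[[j]][inc[, j]] <- NA_real_
    }
    cols <- c(cols, tests)
  }

  if (!is.null(config$followup)) {
    fu <- config$followup
    ev <- outc[[fu$outcome]]
    cols$dementia_time <- with_substream(seed, "followup", {
      cens <- pmin(pmax(stats::rnorm(n, fu$median_years, fu$spread), 0.1),
                   fu$max_years)
      ifelse(ev == 1L, stats::runif(n, 0, fu$max_years), cens)
    })
    cols$dementia_subtype <- with_substream(seed, "subtype",
      ifelse(ev == 1L,
             ifelse(stats::runif(n) < fu$p_ad, "AD", "other"),
             "none"))
  }

  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  attr(out, "dgp_config") <- config
  attr(out, "covariables") <- names(config$confounders)
  out
}

#' Exact counterfactual truths for a DGP by Monte-Carlo simulation
#'
#' Simulates the potential outcomes Y(a, M(a)), Y(a, M(a*)) and Y(a*, M(a*))
#' directly from the known structural equations, averaging over fresh draws of
#' confounders and mediator noise, and returns the true total, natural direct
#' and natural indirect effects and proportion mediated. For a binary outcome
#' the odds-ratio-scale effects are additionally computed from the
#' counterfactual risks. Mediators of the DGP that are not in `mediators` are
#' held at their value under the outcome's own exposure level, i.e. treated as
#' part of the direct path.
#'
#' This is the package's independent truth oracle: it never uses the
#' regression-based estimator and serves as its validation standard.
#'
#' @param config a [dgp_config()].
#' @param outcome name of an outcome declared in `config`.
#' @param mediators character vector of mediator names whose joint path is the
#'   "indirect" channel.
#' @param a,a_star the exposure contrast (default carrier vs non-carrier).
#' @param mc_reps Monte-Carlo sample size. Below 1,000 a warning is recorded
#'   in the result (field `warnings`).
#' @param seed RNG seed for the oracle draws (independent of `config$seed`).
#' @param n_batches batches used for the Monte-Carlo standard errors.
#' @return object of class `mediation_truth` with elements `difference`
#'   (te/nde/nie/pm + `mc_se`), `odds_ratio` (binary outcomes only), `mc_reps`,
#'   `warnings`.
#' @export
counterfactual_oracle <- function(config, outcome, mediators,
                                  a = 1, a_star = 0,
                                  mc_reps = 1e5, seed = 1L, n_batches = 20L) {
  validate_dgp_config(config)
  if (!outcome %in% names(config$outcomes))
    stop("outcome '", outcome, "' not declared in config")
  if (!all(mediators %in% names(config$mediators)))
    stop("mediator(s) not declared in config: ",
         paste(setdiff(mediators, names(config$mediators)), collapse = ", "))
  warnings <- character(0)
  if (mc_reps < 1e3) {
    warnings <- c(warnings, sprintf("mc_reps = %d < 1000; truths are noisy",
                                    mc_reps))
    warning(warnings[[1]], call. = FALSE)
  }
  n <- as.integer(mc_reps)
  conf <- draw_confounders(config, n, seed, prefix = "oracle:conf")

  # mediator draws under each exposure level, common random numbers
  med_at <- list()  # med_at[[level]][[name]]
  for (nm in names(config$mediators)) {
    ms <- config$mediators[[nm]]
    noise <- with_substream(seed, paste0("oracle:med:", nm),
      if (ms$link == "identity") stats::rnorm(n, 0, ms$sd)
      else stats::runif(n))
    for (lv in c("a", "a_star")) {
      x <- if (lv == "a") a else a_star
      lp <- mediator_lp(ms, x, conf)
      med_at[[lv]][[nm]] <- if (ms$link == "identity") lp + noise
                            else as.numeric(noise < expit(lp))
    }
  }

  os <- config$outcomes[[outcome]]
  mu <- function(x_y, lv_set, lv_other) {
    med <- med_at[[lv_other]]
    med[mediators] <- med_at[[lv_set]][mediators]
    lp <- outcome_lp(os, x_y, med, conf)
    if (os$link == "identity") lp else expit(lp)
  }
  y11 <- mu(a, "a", "a")            # Y(a,  M(a))
  y10 <- mu(a, "a_star", "a")       # Y(a,  M(a*))
  y00 <- mu(a_star, "a_star", "a_star")

  batch <- rep_len(seq_len(n_batches), n)
  bmean <- function(v) tapply(v, batch, mean)
  b11 <- bmean(y11); b10 <- bmean(y10); b00 <- bmean(y00)
  se <- function(v) stats::sd(v) / sqrt(n_batches)

  te <- mean(y11) - mean(y00)
  nde <- mean(y10) - mean(y00)
  nie <- mean(y11) - mean(y10)
  diff <- list(
    te = te, nde = nde, nie = nie,
    pm = if (abs(te) > 0) nie / te else NA_real_,
    mc_se = c(te = se(b11 - b00), nde = se(b10 - b00), nie = se(b11 - b10),
              pm = stats::sd((b11 - b10) / pmax(abs(b11 - b00), 1e-12) *
                               sign(b11 - b00)) / sqrt(n_batches)))

  or <- NULL
  if (os$link == "logit") {
    odds <- function(p) p / (1 - p)
    or_te <- odds(mean(y11)) / odds(mean(y00))
    or_nde <- odds(mean(y10)) / odds(mean(y00))
    or_nie <- odds(mean(y11)) / odds(mean(y10))
    pm_or <- or_nde * (or_nie - 1) / (or_nde * or_nie - 1)
    blog <- function(p1, p0) log(odds(p1) / odds(p0))
    or <- list(
      te = or_te, nde = or_nde, nie = or_nie, pm = pm_or,
      mc_se = c(te = se(blog(b11, b00)), nde = se(blog(b10, b00)),
                nie = se(blog(b11, b10))))
  }

  structure(list(outcome = outcome, mediators = mediators, a = a,
                 a_star = a_star, difference = diff, odds_ratio = or,
                 mc_reps = n, warnings = warnings),
            class = "mediation_truth")
}

#' Apply missing-completely-at-random masks to covariable columns
#'
#' Only confounder (covariable) columns may be masked; exposure, mediators and
#' outcomes are never missing by construction, mirroring a cohort with
#' complete genotyping, imaging and follow-up but occasional missing
#' interview/laboratory covariables.
#'
#' @param cohort a cohort `data.frame` from [generate_cohort()].
#' @param config the [dgp_config()] whose `missingness` rates to apply; by
#'   default the config attached to the cohort.
#' @return the cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, config = attr(cohort, "dgp_config")) {
  rates <- config$missingness
  if (!length(rates)) return(cohort)
  covars <- attr(cohort, "covariables") %||% names(config$confounders)
  bad <- setdiff(names(rates), covars)
  if (length(bad))
    stop("cannot mask non-covariable column(s): ", paste(bad, collapse = ", "))
  n <- nrow(cohort)
  for (nm in names(rates)) {
    mask <- with_substream(config$seed, paste0("missing:", nm),
                           stats::runif(n) < rates[[nm]])
    cohort[[nm]][mask] <- NA
  }
  cohort
}

#' Default Rotterdam-like DGP
#'
#' A realistic single source of synthetic data for the full study pipeline:
#' confounder marginals match the published cohort description (mean age 65.0,
#' SD 10.9; 55% women; carrier prevalence 28.3%; etc.), mediators are the four
#' imaging markers (hippocampal volume `hv` in ml, Alzheimer-signature
#' cortical thickness `ct_ad` in mm, log white-matter-hyperintensity volume
#' `ln_wmh` calibrated to a 3.1 ml median, and the `mb2` indicator of >= 2
#' microbleeds at 7.4% vs 10.2% prevalence by carriership), and the effect
#' sizes are calibrated so the carrier total effect on the cognition Z-score
#' is about -0.02 with roughly 25% mediated by microbleeds and 12% by WMH, and
#' the carrier odds ratio on dementia about 2.3 at ~6% cumulative incidence.
#'
#' @param n cohort size.
#' @param seed base seed.
#' @return a [dgp_config()].
#' @export
default_dgp_config <- function(n = 5510L, seed = 1L) {
  dgp_config(
    n = n, seed = seed, p_exposure = 0.283,
    confounders = list(
      age       = list(dist = "normal", mean = 65.0, sd = 10.9),
      sex       = list(dist = "binary", p = 0.55),
      education = list(dist = "categorical",
                       probs = c(0.090, 0.383, 0.305, 0.222)),
      smoking   = list(dist = "categorical",
                       probs = c(0.300, 0.497, 0.203)),
      bmi       = list(dist = "normal", mean = 27.5, sd = 4.2),
      sbp       = list(dist = "normal", mean = 140.2, sd = 21.6),
      bp_med    = list(dist = "binary", p = 0.367),
      nonhdl    = list(dist = "normal", mean = 4.1, sd = 1.0),
      lipid_med = list(dist = "binary", p = 0.253),
      diabetes  = list(dist = "binary", p = 0.129),
      af        = list(dist = "binary", p = 0.048),
      stroke    = list(dist = "binary", p = 0.033),
      icv       = list(dist = "normal", mean = 1140.1, sd = 116.1)),
    mediators = list(
      hv = list(link = "identity", b0 = 7.47, b_exposure = -0.02,
                b_conf = c(age = -0.03, icv = 0.002), sd = 0.80),
      ct_ad = list(link = "identity", b0 = 2.695, b_exposure = -0.0005,
                   b_conf = c(age = -0.003), sd = 0.09),
      ln_wmh = list(link = "identity", b0 = -1.469, b_exposure = 0.05,
                    b_conf = c(age = 0.04), sd = 0.41),
      mb2 = list(link = "logit", b0 = -5.126, b_exposure = 0.352,
                 b_conf = c(age = 0.04))),
    outcomes = list(
      gfactor = list(
        link = "identity", t0 = -4.081, t_exposure = -0.0103,
        t_mediator = c(hv = 0.07, ct_ad = 1.5, ln_wmh = -0.048, mb2 = -0.18),
        t_interaction = c(hv = 0, ct_ad = 0, ln_wmh = 0, mb2 = 0),
        t_conf = c(age = -0.045, education = 0.08, icv = 0.0005), sd = 0.85),
      dementia = list(
        link = "logit", t0 = -6.0, t_exposure = log(2.28),
        t_mediator = c(hv = -0.15, ct_ad = -1.0, ln_wmh = 0.25,
                       mb2 = log(2.075)),
        t_interaction = c(hv = 0, ct_ad = 0, ln_wmh = 0, mb2 = 0),
        t_conf = c(age = 0.09), sd = NULL)),
    cognition = list(
      outcome = "gfactor",
      loadings = c(stroop = 0.75, wft = 0.70, ldst = 0.80, wlt15 = 0.65,
                   ppb = 0.50),
      reverse_coded = "stroop",
      p_incomplete = 0.172),
    followup = list(outcome = "dementia", median_years = 11, spread = 3,
                    max_years = 15, p_ad = 0.8),
    missingness = c(diabetes = 0.010, af = 0.010, bp_med = 0.006),
    imaging_extras = TRUE)
}

#' @export
print.mediation_truth <- function(x, ...) {
  cat("Counterfactual truth (", x$outcome, " | ",
      paste(x$mediators, collapse = " + "), "), mc_reps = ", x$mc_reps,
      "\n", sep = "")
  d <- x$difference
  cat(sprintf("  difference scale: TE=%.5f NDE=%.5f NIE=%.5f PM=%.3f\n",
              d$te, d$nde, d$nie, d$pm))
  if (!is.null(x$odds_ratio)) {
    o <- x$odds_ratio
    cat(sprintf("  odds-ratio scale: TE=%.4f NDE=%.4f NIE=%.4f PM=%.3f\n",
                o$te, o$nde, o$nie, o$pm))
  }
  invisible(x)
}
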