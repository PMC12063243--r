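# Regression-based counterfactual mediation: mediator and outcome model fits,
# closed-form natural direct/indirect effects with exposure-mediator
# interaction on the difference scale and the rare-outcome odds-ratio scale,
# proportion mediated, percentile-bootstrap inference, and pooling across
# multiple imputations.

build_design <- function(data, exposure, mediators = character(0),
                         confounders = character(0), interaction = FALSE) {
  n <- nrow(data)
  parts <- list(`(Intercept)` = rep.int(1, n))
  parts[[exposure]] <- as.numeric(data[[exposure]])
  for (m in mediators) parts[[m]] <- as.numeric(data[[m]])
  if (interaction)
    for (m in mediators)
      parts[[paste0(exposure, ":", m)]] <-
        parts[[exposure]] * as.numeric(data[[m]])
  for (cc in confounders) parts[[cc]] <- as.numeric(data[[cc]])
  X <- do.call(cbind, parts)
  colnames(X) <- names(parts)
  X
}

# least-squares / logistic fit on a prebuilt design matrix with rank and
# separation diagnostics; returns coefficients, residual SD (identity) and n
fit_link <- function(X, y, link) {
  if (anyNA(X) || anyNA(y)) stop("missing cells in model frame")
  if (link == "identity") {
    fit <- stats::lm.fit(X, y)
    if (fit$rank < ncol(X))
      stop("rank-deficient design (collinear columns): ",
           paste(colnames(X)[is.na(fit$coefficients)], collapse = ", "))
    sigma <- sqrt(sum(fit$residuals^2) / (length(y) - fit$rank))
    list(coef = fit$coefficients, sigma = sigma)
  } else {
    fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
    if (any(is.na(fit$coefficients)))
      stop("rank-deficient design (collinear columns): ",
           paste(colnames(X)[is.na(fit$coefficients)], collapse = ", "))
    if (!fit$converged || any(abs(fit$coefficients) > 100))
      stop("logistic fit failed (separation or non-convergence); ",
           "largest |coef| = ",
           format(max(abs(fit$coefficients)), digits = 3))
    list(coef = fit$coefficients, sigma = NULL)
  }
}

infer_link <- function(y, link) {
  if (!is.null(link)) return(match.arg(link, c("identity", "logit")))
  if (is_binary01(y)) "logit" else "identity"
}

#' Fit the mediator regression model
#'
#' Regresses the mediator on the exposure and confounders: a linear model for
#' a continuous mediator (identity link) or a logistic model for a binary
#' mediator. The fitted coefficient block (beta0, beta1, beta2, sigma) feeds
#' the closed-form natural-effect formulas.
#'
#' @param data complete-case data.frame.
#' @param mediator,exposure,confounders column names.
#' @param link `"identity"`, `"logit"`, or `NULL` to infer from the data
#'   (0/1-valued mediators are treated as binary).
#' @return object of class `mediator_fit`.
#' @export
fit_mediator_model <- function(data, mediator, exposure,
                               confounders = character(0), link = NULL) {
  y <- as.numeric(data[[mediator]])
  link <- infer_link(y, link)
  X <- build_design(data, exposure, confounders = confounders)
  f <- fit_link(X, y, link)
  beta2 <- f$coef[confounders]
  names(beta2) <- confounders
  structure(list(link = link, beta0 = unname(f$coef[["(Intercept)"]]),
                 beta1 = unname(f$coef[[exposure]]), beta2 = beta2,
                 sigma = f$sigma, n = nrow(data), mediator = mediator,
                 exposure = exposure, confounders = confounders),
            class = "mediator_fit")
}

#' Fit the outcome regression model with exposure-mediator interaction
#'
#' Regresses the outcome on exposure, mediator(s), exposure-by-mediator
#' interaction(s) and confounders. The interaction term is always present
#' (its estimate may be ~0), so mediation never assumes it away.
#'
#' @inheritParams fit_mediator_model
#' @param outcome column name; continuous (identity) or binary 0/1 (logit).
#' @param mediator one mediator name, or several for a joint outcome model.
#' @return object of class `outcome_fit` with coefficient blocks `theta0`,
#'   `theta1`, `theta2` (named per mediator), `theta3` (interactions),
#'   `theta4` (confounders), `resid_sd` (identity only) and the outcome's
#'   sample prevalence/mean (`mean_y`, used for the rare-outcome guard).
#' @export
fit_outcome_model <- function(data, outcome, exposure, mediator,
                              confounders = character(0), link = NULL) {
  y <- as.numeric(data[[outcome]])
  link <- infer_link(y, link)
  X <- build_design(data, exposure, mediators = mediator,
                    confounders = confounders, interaction = TRUE)
  f <- fit_link(X, y, link)
  theta2 <- f$coef[mediator]
  names(theta2) <- mediator
  theta3 <- f$coef[paste0(exposure, ":", mediator)]
  names(theta3) <- mediator
  theta4 <- f$coef[confounders]
  names(theta4) <- confounders
  structure(list(link = link, theta0 = unname(f$coef[["(Intercept)"]]),
                 theta1 = unname(f$coef[[exposure]]), theta2 = theta2,
                 theta3 = theta3, theta4 = theta4, resid_sd = f$sigma,
                 mean_y = mean(y), n = nrow(data), outcome = outcome,
                 exposure = exposure, mediators = mediator,
                 confounders = confounders),
            class = "outcome_fit")
}

new_decomposition <- function(scale, te, nde, nie, a, a_star,
                              confounder_reference, extra = list()) {
  d <- structure(c(list(scale = scale, te = te, nde = nde, nie = nie,
                        pm = NA_real_, a = a, a_star = a_star,
                        confounder_reference = confounder_reference),
                   extra),
                 class = "effect_decomposition")
  d$pm <- proportion_mediated(d)
  d
}

#' Closed-form natural-effect decomposition
#'
#' Combines a fitted mediator model and a fitted outcome model (with
#' interaction) into the natural direct effect (NDE), natural indirect effect
#' (NIE) and total effect (TE) for the exposure contrast `a` vs `a_star`,
#' averaged over the empirical confounder distribution of the analysis sample
#' (or evaluated at confounder means). Four model combinations are supported:
#'
#' * continuous outcome, continuous mediator: difference scale,
#'   `NDE = (theta1 + theta3 (beta0 + beta1 a* + beta2'c))(a - a*)`,
#'   `NIE = (theta2 beta1 + theta3 beta1 a)(a - a*)`;
#' * continuous outcome, binary mediator: the mediator mean is
#'   `expit(beta0 + beta1 x + beta2'c)`;
#' * rare binary outcome, continuous mediator: log-odds-ratio analogues with
#'   the Gaussian-mediator correction terms `theta2 sigma^2` and
#'   `0.5 theta3^2 sigma^2 (a^2 - a*^2)`;
#' * rare binary outcome, binary mediator: exact conditional odds-ratio
#'   expressions under the rare-outcome approximation.
#'
#' On the odds-ratio scale the per-subject log odds ratios are averaged over
#' confounders and `TE = NDE x NIE`; on the difference scale `TE = NDE + NIE`.
#' Both identities hold to machine precision by construction.
#'
#' @param mfit a [fit_mediator_model()] result.
#' @param ofit a [fit_outcome_model()] result (single mediator, matching
#'   `mfit`).
#' @param data the analysis sample providing the empirical confounder rows.
#' @param a,a_star exposure contrast (default 1 vs 0).
#' @param confounder_reference `"empirical"` (average over the sample) or
#'   `"means"` (evaluate at confounder means).
#' @param rare_ok for a binary outcome with prevalence above 10% the
#'   rare-outcome odds-ratio approximation is invalid and the call is
#'   rejected unless `rare_ok = TRUE` (then it proceeds with a warning).
#' @return object of class `effect_decomposition` with `scale`
#'   (`"difference"` or `"odds-ratio"`), `te`, `nde`, `nie`, `pm`.
#' @export
natural_effects <- function(mfit, ofit, data, a = 1, a_star = 0,
                            confounder_reference = c("empirical", "means"),
                            rare_ok = FALSE) {
  confounder_reference <- match.arg(confounder_reference)
  if (length(ofit$mediators) != 1L)
    stop("natural_effects() is the single-mediator engine; use ",
         "joint_natural_effects() for mediator sets")
  if (!identical(mfit$mediator, ofit$mediators))
    stop("mediator/outcome fits disagree on the mediator")
  if (ofit$link == "logit" && ofit$mean_y >= 0.10) {
    msg <- sprintf(paste0("outcome prevalence %.1f%% >= 10%%: rare-outcome ",
                          "odds-ratio approximation unreliable"),
                   100 * ofit$mean_y)
    if (!rare_ok) stop(msg, " (pass rare_ok = TRUE to override)")
    warning(msg)
  }
  cf <- mfit$confounders
  if (length(cf)) {
    Z <- as.matrix(data[cf])
    storage.mode(Z) <- "double"
    if (confounder_reference == "means")
      Z <- matrix(colMeans(Z), nrow = 1L, dimnames = list(NULL, cf))
    zb <- drop(Z %*% mfit$beta2)
  } else zb <- 0
  lp_astar <- mfit$beta0 + mfit$beta1 * a_star + zb
  lp_a <- mfit$beta0 + mfit$beta1 * a + zb
  th1 <- ofit$theta1; th2 <- unname(ofit$theta2[[1]])
  th3 <- unname(ofit$theta3[[1]]); b1 <- mfit$beta1
  d <- a - a_star

  if (ofit$link == "identity" && mfit$link == "identity") {
    nde <- mean((th1 + th3 * lp_astar) * d)
    nie <- (th2 * b1 + th3 * b1 * a) * d
    dec <- new_decomposition("difference", nde + nie, nde, nie, a, a_star,
                             confounder_reference)
  } else if (ofit$link == "identity" && mfit$link == "logit") {
    p_astar <- expit(lp_astar); p_a <- expit(lp_a)
    nde <- mean(d * (th1 + th3 * p_astar))
    nie <- mean((th2 + th3 * a) * (p_a - p_astar))
    dec <- new_decomposition("difference", nde + nie, nde, nie, a, a_star,
                             confounder_reference)
  } else if (ofit$link == "logit" && mfit$link == "identity") {
    s2 <- mfit$sigma^2
    log_nde <- mean((th1 + th3 * (lp_astar + th2 * s2)) * d +
                      0.5 * th3^2 * s2 * (a^2 - a_star^2))
    log_nie <- (th2 * b1 + th3 * b1 * a) * d
    dec <- new_decomposition("odds-ratio", exp(log_nde + log_nie),
                             exp(log_nde), exp(log_nie), a, a_star,
                             confounder_reference)
  } else {
    log_nde <- mean(th1 * d +
                      log1p(exp(th2 + th3 * a + lp_astar)) -
                      log1p(exp(th2 + th3 * a_star + lp_astar)))
    log_nie <- mean(log1p(exp(lp_astar)) + log1p(exp(th2 + th3 * a + lp_a)) -
                      log1p(exp(lp_a)) - log1p(exp(th2 + th3 * a + lp_astar)))
    dec <- new_decomposition("odds-ratio", exp(log_nde + log_nie),
                             exp(log_nde), exp(log_nie), a, a_star,
                             confounder_reference)
  }
  dec
}

#' Proportion mediated from an effect decomposition
#'
#' Difference scale: `NIE / TE`. Odds-ratio scale: the excess-odds-ratio form
#' `NDE (NIE - 1) / (NDE NIE - 1)`. When the total effect is numerically null
#' (|TE| or |log TE| below `tol`) the value is still returned but flagged
#' unstable via a warning and the `"unstable"` attribute; a PM from
#' opposite-signed NDE and NIE (which may fall outside [0, 1]) is flagged via
#' the `"opposite_signs"` attribute.
#'
#' @param d an `effect_decomposition`.
#' @param tol instability tolerance on TE (difference) or log TE (OR scale).
#' @return the proportion mediated (unitless; multiply by 100 for percent).
#' @export
proportion_mediated <- function(d, tol = 1e-8) {
  if (d$scale == "difference") {
    unstable <- abs(d$te) < tol
    pm <- d$nie / d$te
    opposite <- d$nde * d$nie < 0
  } else {
    unstable <- abs(log(d$te)) < tol
    pm <- d$nde * (d$nie - 1) / (d$nde * d$nie - 1)
    opposite <- (d$nde - 1) * (d$nie - 1) < 0
  }
  if (unstable)
    warning("total effect is numerically null; proportion mediated unstable")
  attr(pm, "unstable") <- unstable
  attr(pm, "opposite_signs") <- opposite
  pm
}

#' Confounder-adjusted total effect of the exposure on an outcome
#'
#' The exposure-on-outcome model without mediator terms: the linear-model
#' coefficient (continuous outcome) or the odds ratio (binary outcome).
#'
#' @inheritParams fit_mediator_model
#' @param outcome column name.
#' @return object of class `total_effect` with `estimate` (beta or OR),
#'   `scale`, `coef` (always on the coefficient scale) and `n`.
#' @export
total_effect <- function(data, outcome, exposure,
                         confounders = character(0), link = NULL) {
  y <- as.numeric(data[[outcome]])
  link <- infer_link(y, link)
  X <- build_design(data, exposure, confounders = confounders)
  f <- fit_link(X, y, link)
  b <- unname(f$coef[[exposure]])
  structure(list(estimate = if (link == "logit") exp(b) else b,
                 coef = b,
                 scale = if (link == "logit") "odds-ratio" else "difference",
                 link = link, n = nrow(data), outcome = outcome,
                 exposure = exposure, confounders = confounders),
            class = "total_effect")
}

#' Nonparametric bootstrap of an analysis function
#'
#' Resamples subjects with replacement, re-runs `analysis` on each resample,
#' and summarises each returned component by its percentile 95% CI and a
#' two-sided bootstrap p-value `2 min(#{<= null} + 1, #{>= null} + 1)/(B + 1)`
#' against a null of 0 (difference scale) or log-ratio 0 (odds-ratio scale).
#' Replicates on which `analysis` errors are dropped; more than 1% failures
#' rejects the run.
#'
#' @param analysis function `data.frame -> numeric` (scalar or named vector).
#' @param data subject-level data.frame.
#' @param B replications (default 1,000, >= 2).
#' @param seed RNG seed; same seed, same summary.
#' @param scale per-component `"difference"`, `"odds-ratio"`, or `"none"`
#'   (no p-value); length 1 or one per component.
#' @return object of class `bootstrap_summary`: `point`, `ci_low`, `ci_high`,
#'   `p_value`, `B` (effective), `n_failed`, `seed`, and the replicate
#'   `draws` matrix (kept so imputation pooling can pool draws).
#' @export
bootstrap <- function(analysis, data, B = 1000L, seed = 1L,
                      scale = "difference") {
  if (B < 2L) stop("B must be >= 2")
  point <- analysis(data)
  k <- length(point)
  scale <- rep_len(scale, k)
  n <- nrow(data)
  draws <- withr::with_seed(substream_seed(seed, "bootstrap"), {
    out <- matrix(NA_real_, B, k)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(analysis(data[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (!is.null(val)) out[b, ] <- as.numeric(val)
    }
    out
  })
  ok <- !is.na(draws[, 1L])
  n_failed <- sum(!ok)
  if (n_failed > 0.01 * B)
    stop("bootstrap: ", n_failed, " of ", B, " replicates failed (> 1%)")
  draws <- draws[ok, , drop = FALSE]
  colnames(draws) <- names(point)
  # inverse-ECDF (type 1) percentiles: pooling m identical replicate sets
  # across imputations then leaves the interval exactly unchanged
  ci <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE, type = 1)
  pv <- vapply(seq_len(k), function(j) {
    if (scale[j] == "none") return(NA_real_)
    dj <- if (scale[j] == "odds-ratio") log(draws[, j]) else draws[, j]
    nb <- length(dj)
    min(1, 2 * min(sum(dj <= 0) + 1, sum(dj >= 0) + 1) / (nb + 1))
  }, numeric(1))
  structure(list(point = point, ci_low = ci[1L, ], ci_high = ci[2L, ],
                 p_value = stats::setNames(pv, names(point)),
                 B = nrow(draws), B_requested = as.integer(B),
                 n_failed = n_failed, seed = as.integer(seed),
                 scale = scale, draws = draws,
                 estimand = names(point) %||% "value"),
            class = "bootstrap_summary")
}

#' Pool mediation results across multiple imputations
#'
#' Point estimates are averaged over the `m` imputations (log scale for
#' odds-ratio components, preserving `TE = NDE x NIE`); bootstrap replicate
#' draws are pooled across imputations before taking the percentile CI and
#' bootstrap p-value, so between-imputation variability widens the interval.
#'
#' @param results list of `bootstrap_summary` objects (or of
#'   `effect_decomposition` objects, pooled point-wise) for the same estimand.
#' @return a pooled object of the same class.
#' @export
pool_imputations <- function(results) {
  stopifnot(length(results) >= 1L)
  if (length(results) == 1L) return(results[[1L]])
  cls <- unique(vapply(results, function(r) class(r)[1L], character(1)))
  if (length(cls) != 1L) stop("mixed result types cannot be pooled")
  if (cls == "bootstrap_summary") {
    est <- unique(lapply(results, `[[`, "estimand"))
    if (length(est) != 1L ||
        length(unique(lapply(results, `[[`, "scale"))) != 1L)
      stop("mixed estimands cannot be pooled")
    r1 <- results[[1L]]
    pts <- do.call(rbind, lapply(results, `[[`, "point"))
    point <- vapply(seq_along(r1$point), function(j)
      if (r1$scale[j] == "odds-ratio") exp(mean(log(pts[, j])))
      else mean(pts[, j]), numeric(1))
    names(point) <- names(r1$point)
    draws <- do.call(rbind, lapply(results, `[[`, "draws"))
    ci <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE, type = 1)
    pv <- vapply(seq_along(point), function(j) {
      if (r1$scale[j] == "none") return(NA_real_)
      dj <- if (r1$scale[j] == "odds-ratio") log(draws[, j]) else draws[, j]
      nb <- length(dj)
      min(1, 2 * min(sum(dj <= 0) + 1, sum(dj >= 0) + 1) / (nb + 1))
    }, numeric(1))
    structure(list(point = point, ci_low = ci[1L, ], ci_high = ci[2L, ],
                   p_value = stats::setNames(pv, names(point)),
                   B = nrow(draws), B_requested = sum(vapply(results, `[[`,
                     integer(1), "B_requested")),
                   n_failed = sum(vapply(results, `[[`, integer(1),
                                         "n_failed")),
                   seed = r1$seed, scale = r1$scale, draws = draws,
                   estimand = r1$estimand, m = length(results)),
              class = "bootstrap_summary")
  } else if (cls == "effect_decomposition") {
    sc <- unique(vapply(results, `[[`, character(1), "scale"))
    if (length(sc) != 1L) stop("mixed estimands cannot be pooled")
    agg <- function(f) {
      v <- vapply(results, `[[`, numeric(1), f)
      if (sc == "odds-ratio") exp(mean(log(v))) else mean(v)
    }
    r1 <- results[[1L]]
    new_decomposition(sc, agg("te"), agg("nde"), agg("nie"), r1$a, r1$a_star,
                      r1$confounder_reference, extra = list(m = length(results)))
  } else stop("cannot pool objects of class ", cls)
}

#' One-call single-mediator mediation analysis with bootstrap inference
#'
#' Fits the mediator and outcome models on `data`, forms the closed-form
#' natural-effect decomposition, and bootstraps TE, NDE, NIE and PM by
#' refitting both models on each resample. The p-value attached to PM is the
#' bootstrap p-value of the natural indirect effect (the test of mediation).
#'
#' @inheritParams natural_effects
#' @inheritParams fit_outcome_model
#' @param mediator single mediator column name.
#' @param mediator_link,outcome_link optional link overrides.
#' @param B bootstrap replications; `B = 0` skips inference.
#' @param seed RNG seed for the bootstrap.
#' @return list with `decomposition` (point estimates) and `boot`
#'   (a `bootstrap_summary` over `c(te, nde, nie, pm)`, or `NULL`).
#' @export
mediate <- function(data, outcome, exposure, mediator,
                    confounders = character(0), outcome_link = NULL,
                    mediator_link = NULL, B = 1000L, seed = 1L,
                    a = 1, a_star = 0,
                    confounder_reference = "empirical", rare_ok = FALSE) {
  run <- function(d) {
    mfit <- fit_mediator_model(d, mediator, exposure, confounders,
                               link = mediator_link)
    ofit <- fit_outcome_model(d, outcome, exposure, mediator, confounders,
                              link = outcome_link)
    natural_effects(mfit, ofit, d, a = a, a_star = a_star,
                    confounder_reference = confounder_reference,
                    rare_ok = rare_ok)
  }
  dec <- run(data)
  boot <- NULL
  if (B > 0L) {
    analysis <- function(d) {
      x <- run(d)
      c(te = x$te, nde = x$nde, nie = x$nie, pm = as.numeric(x$pm))
    }
    boot <- bootstrap(analysis, data, B = B, seed = seed,
                      scale = c(rep(dec$scale, 3L), "none"))
    boot$p_value[["pm"]] <- boot$p_value[["nie"]]
  }
  list(decomposition = dec, boot = boot)
}

#' @export
print.effect_decomposition <- function(x, ...) {
  cat(sprintf("Natural-effect decomposition (%s scale, a=%g vs a*=%g)\n",
              x$scale, x$a, x$a_star))
  cat(sprintf("  TE=%.5g  NDE=%.5g  NIE=%.5g  PM=%.1f%%\n",
              x$te, x$nde, x$nie, 100 * as.numeric(x$pm)))
  invisible(x)
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("Bootstrap summary (B=%d, %d failed, seed=%d)\n",
              x$B, x$n_failed, x$seed))
  for (j in seq_along(x$point))
    cat(sprintf("  %-4s %.5g  [%.5g, %.5g]  p=%.3g\n",
                names(x$point)[j] %||% "", x$point[j], x$ci_low[j],
                x$ci_high[j], x$p_value[j]))
  invisible(x)
}
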