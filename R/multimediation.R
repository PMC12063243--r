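# Joint natural-effect decomposition for sets of mediators: one mediator
# model per marker (conditionally independent given exposure and
# confounders), one outcome model with all mediators and all
# exposure-by-mediator interactions, and Monte-Carlo g-computation of the
# three counterfactual means E[Y(a, M(a))], E[Y(a, M(a*))], E[Y(a*, M(a*))].

#' Fit the joint mediator-set and outcome models
#'
#' @inheritParams fit_outcome_model
#' @param mediators character vector of 1-4 mediator column names.
#' @param mediator_links optional named character vector of link overrides.
#' @param cond_tol condition-number guard: the correlation structure of the
#'   mediator columns must have `kappa < cond_tol` (collinear or duplicated
#'   mediators are rejected).
#' @return object of class `joint_mediator_fit` with `mediator_fits` (list of
#'   [fit_mediator_model()] results), `outcome_fit` (vector-coefficient
#'   [fit_outcome_model()] result) and `mediator_names`.
#' @export
fit_joint <- function(data, outcome, exposure, mediators,
                      confounders = character(0), mediator_links = NULL,
                      link = NULL, cond_tol = 1e6) {
  stopifnot(length(mediators) >= 1L)
  if (anyDuplicated(mediators))
    stop("duplicated mediator name(s): ",
         paste(unique(mediators[duplicated(mediators)]), collapse = ", "))
  if (length(mediators) > 1L) {
    M <- vapply(mediators, function(m) as.numeric(data[[m]]),
                numeric(nrow(data)))
    kap <- kappa(stats::cor(M), exact = TRUE)
    if (!is.finite(kap) || kap > cond_tol)
      stop("collinear mediators (condition number ", format(kap, digits = 3),
           " > ", cond_tol, ")")
  }
  mfits <- lapply(mediators, function(m)
    fit_mediator_model(data, m, exposure, confounders,
                       link = mediator_links[[m]] %||% NULL))
  names(mfits) <- mediators
  ofit <- fit_outcome_model(data, outcome, exposure, mediators, confounders,
                            link = link)
  structure(list(mediator_fits = mfits, outcome_fit = ofit,
                 mediator_names = mediators, exposure = exposure,
                 confounders = confounders),
            class = "joint_mediator_fit")
}

#' Joint natural effects for a mediator set by Monte-Carlo g-computation
#'
#' For every subject's confounder row, the mediator vector is drawn from its
#' fitted conditional law under exposure `a` and under `a_star` using common
#' random numbers (the same Gaussian/uniform innovations at both exposure
#' levels, which removes mediator noise from the effect contrasts wherever it
#' cancels), pushed through the fitted outcome model, and averaged over
#' `mc_draws` draws per subject. Mediators are conditionally independent
#' given exposure and confounders; no mediator-to-mediator paths are assumed.
#' For a binary outcome the three counterfactual risks are converted to odds
#' ratios directly — no rare-outcome shortcut is needed here.
#'
#' @param fit a [fit_joint()] result.
#' @param data the analysis sample (empirical confounder distribution).
#' @param a,a_star exposure contrast.
#' @param mc_draws mediator draws per subject per exposure level (default 5;
#'   the per-subject average over the full sample makes the Monte-Carlo error
#'   tiny).
#' @param seed RNG seed for the mediator draws.
#' @return an `effect_decomposition` (difference scale for a continuous
#'   outcome, odds-ratio scale for a binary outcome) with Monte-Carlo
#'   metadata fields `mc_draws` and `mc_se` (batch SE over draws of the NIE).
#' @export
joint_natural_effects <- function(fit, data, a = 1, a_star = 0,
                                  mc_draws = 5L, seed = 1L) {
  ofit <- fit$outcome_fit
  mfits <- fit$mediator_fits
  n <- nrow(data)
  cf <- fit$confounders
  conf <- if (length(cf)) lapply(data[cf], as.numeric) else list()

  lp_med <- lapply(mfits, function(mf) {
    list(a = mediator_lp(list(b0 = mf$beta0, b_exposure = mf$beta1,
                              b_conf = mf$beta2), a, conf),
         a_star = mediator_lp(list(b0 = mf$beta0, b_exposure = mf$beta1,
                                   b_conf = mf$beta2), a_star, conf))
  })

  base_lp <- function(x) {
    lp <- ofit$theta0 + ofit$theta1 * x
    for (cc in names(ofit$theta4 %||% numeric(0)))
      lp <- lp + ofit$theta4[[cc]] * conf[[cc]]
    lp
  }
  lp_y_a <- base_lp(a)
  lp_y_astar <- base_lp(a_star)

  mu_y <- function(x_lp, x, med) {
    lp <- x_lp
    for (mn in fit$mediator_names)
      lp <- lp + (ofit$theta2[[mn]] + ofit$theta3[[mn]] * x) * med[[mn]]
    if (ofit$link == "identity") lp else expit(lp)
  }

  sums <- withr::with_seed(substream_seed(seed, "gcomp"), {
    acc <- c(y11 = 0, y10 = 0, y00 = 0)
    per_draw_nie <- numeric(mc_draws)
    for (dr in seq_len(mc_draws)) {
      med_a <- list(); med_astar <- list()
      for (mn in fit$mediator_names) {
        mf <- mfits[[mn]]
        if (mf$link == "identity") {
          eps <- stats::rnorm(n, 0, mf$sigma)
          med_a[[mn]] <- lp_med[[mn]]$a + eps
          med_astar[[mn]] <- lp_med[[mn]]$a_star + eps
        } else {
          u <- stats::runif(n)
          med_a[[mn]] <- as.numeric(u < expit(lp_med[[mn]]$a))
          med_astar[[mn]] <- as.numeric(u < expit(lp_med[[mn]]$a_star))
        }
      }
      y11 <- mean(mu_y(lp_y_a, a, med_a))
      y10 <- mean(mu_y(lp_y_a, a, med_astar))
      y00 <- mean(mu_y(lp_y_astar, a_star, med_astar))
      acc <- acc + c(y11 = y11, y10 = y10, y00 = y00)
      per_draw_nie[dr] <- y11 - y10
    }
    list(means = acc / mc_draws, per_draw_nie = per_draw_nie)
  })
  mns <- sums$means
  mc_se <- if (mc_draws > 1L)
    stats::sd(sums$per_draw_nie) / sqrt(mc_draws) else NA_real_

  extra <- list(mc_draws = as.integer(mc_draws), mc_se = mc_se,
                mediators = fit$mediator_names, counterfactual_means = mns)
  if (ofit$link == "identity") {
    nde <- mns[["y10"]] - mns[["y00"]]
    nie <- mns[["y11"]] - mns[["y10"]]
    new_decomposition("difference", nde + nie, nde, nie, a, a_star,
                      "empirical", extra = extra)
  } else {
    odds <- function(p) p / (1 - p)
    nde <- odds(mns[["y10"]]) / odds(mns[["y00"]])
    nie <- odds(mns[["y11"]]) / odds(mns[["y10"]])
    new_decomposition("odds-ratio", nde * nie, nde, nie, a, a_star,
                      "empirical", extra = extra)
  }
}

#' One-call multi-mediator mediation analysis with bootstrap inference
#'
#' @inheritParams fit_joint
#' @inheritParams joint_natural_effects
#' @param B bootstrap replications over subjects (both model stages refitted
#'   per resample); `B = 0` skips inference.
#' @param seed seed for both the g-computation draws and the bootstrap.
#' @return list with `decomposition` and `boot` (as in [mediate()]).
#' @export
multimediate <- function(data, outcome, exposure, mediators,
                         confounders = character(0), mediator_links = NULL,
                         outcome_link = NULL, B = 1000L, seed = 1L,
                         a = 1, a_star = 0, mc_draws = 5L) {
  run <- function(d, s) {
    jf <- fit_joint(d, outcome, exposure, mediators, confounders,
                    mediator_links = mediator_links, link = outcome_link)
    joint_natural_effects(jf, d, a = a, a_star = a_star,
                          mc_draws = mc_draws, seed = s)
  }
  dec <- run(data, seed)
  boot <- NULL
  if (B > 0L) {
    analysis <- function(d) {
      x <- run(d, seed)
      c(te = x$te, nde = x$nde, nie = x$nie, pm = as.numeric(x$pm))
    }
    boot <- bootstrap(analysis, data, B = B, seed = seed,
                      scale = c(rep(dec$scale, 3L), "none"))
    boot$p_value[["pm"]] <- boot$p_value[["nie"]]
  }
  list(decomposition = dec, boot = boot)
}
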