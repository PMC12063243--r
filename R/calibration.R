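# Calibrated validation worlds: small explicit DGPs whose natural-effect
# truths are hand-computable and match the headline effect sizes the package
# is designed to estimate (carrier prevalence 28.3% throughout). They back
# the parameter-recovery acceptance suite and the acceptance report.

#' Calibrated validation DGPs with closed-form truths
#'
#' Four data-generating processes whose true mediation quantities are known
#' in closed form:
#'
#' * `"cog1"` — continuous cognition outcome, binary mediator (microbleed
#'   burden): P(M=1|A=0)=0.07, P(M=1|A=1)=0.10,
#'   `Y = -0.015 A - (1/6) M + N(0,1)`.
#'   Truths: NDE = -0.015, NIE = -(1/6)(0.10-0.07) = -0.005, TE = -0.020,
#'   PM = 25%.
#' * `"dem1"` — rare binary dementia outcome, same binary mediator:
#'   `logit P(Y=1) = logit(0.01) + log(2.28) A + log(2.075) M`.
#'   Truths: marginal total-effect OR = 2.345 (from the four cell risks),
#'   rare-outcome OR_NIE = (1 + 1.075 x 0.10)/(1 + 1.075 x 0.07) = 1.030,
#'   PM on the OR scale = 2.28 x 0.030 / (2.28 x 1.030 - 1) = 5.07%.
#' * `"cog2"` — two mediators (binary as above; continuous
#'   `M2 = 0.15 A + N(0,1)`), `Y = -0.0365 A - 0.3 M1 - 0.03 M2 + N(0,1)`.
#'   Truths: joint NIE = -(0.3 x 0.03 + 0.03 x 0.15) = -0.0135, TE = -0.05,
#'   joint PM = 27%.
#' * `"cog3"` — one continuous mediator `M = 0.15 A + N(0,1)`,
#'   `Y = -0.044 A - 0.04 M + N(0,1)`.
#'   Truths: NIE = -0.006, TE = -0.05, PM = 12%.
#'
#' @param name which world.
#' @param n cohort size (parameter recovery uses 4,000,000).
#' @param seed generator seed.
#' @return a [dgp_config()].
#' @export
calibration_dgp <- function(name = c("cog1", "dem1", "cog2", "cog3"),
                            n = 4e6, seed = 1L) {
  name <- match.arg(name)
  mb <- list(link = "logit", b0 = logit(0.07),
             b_exposure = logit(0.10) - logit(0.07))
  switch(name,
    cog1 = dgp_config(
      n = n, seed = seed, p_exposure = 0.283,
      mediators = list(mb2 = mb),
      outcomes = list(gfactor = list(
        link = "identity", t0 = 0, t_exposure = -0.015,
        t_mediator = c(mb2 = -1/6), t_interaction = c(mb2 = 0), sd = 1))),
    dem1 = dgp_config(
      n = n, seed = seed, p_exposure = 0.283,
      mediators = list(mb2 = mb),
      outcomes = list(dementia = list(
        link = "logit", t0 = logit(0.01), t_exposure = log(2.28),
        t_mediator = c(mb2 = log(2.075)), t_interaction = c(mb2 = 0)))),
    cog2 = dgp_config(
      n = n, seed = seed, p_exposure = 0.283,
      mediators = list(
        mb2 = mb,
        wmh_z = list(link = "identity", b0 = 0, b_exposure = 0.15, sd = 1)),
      outcomes = list(gfactor = list(
        link = "identity", t0 = 0, t_exposure = -0.0365,
        t_mediator = c(mb2 = -0.3, wmh_z = -0.03),
        t_interaction = c(mb2 = 0, wmh_z = 0), sd = 1))),
    cog3 = dgp_config(
      n = n, seed = seed, p_exposure = 0.283,
      mediators = list(
        wmh_z = list(link = "identity", b0 = 0, b_exposure = 0.15, sd = 1)),
      outcomes = list(gfactor = list(
        link = "identity", t0 = 0, t_exposure = -0.044,
        t_mediator = c(wmh_z = -0.04), t_interaction = c(wmh_z = 0),
        sd = 1))))
}
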