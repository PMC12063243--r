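# Pre-analysis transformations: ln-WMH, Z-standardisation, microbleed
# dichotomisation, global-cognition g-factor extraction, chained-equations
# multiple imputation of covariables, and the age-equivalent conversion of a
# cognition effect.

#' Natural-log transform of white-matter-hyperintensity volumes
#'
#' @param wmh numeric vector of volumes in ml; all values must be strictly
#'   positive (lognormal marker; a zero would indicate a segmentation
#'   failure, and no silent offset is applied).
#' @param subject_id optional ids used in the error message.
#' @return `log(wmh)`.
#' @export
ln_transform_wmh <- function(wmh, subject_id = seq_along(wmh)) {
  bad <- which(!is.na(wmh) & wmh <= 0)
  if (length(bad))
    stop("non-positive WMH volume for subject(s): ",
         paste(utils::head(subject_id[bad], 5L), collapse = ", "))
  log(wmh)
}

#' Z-standardise a numeric vector (mean 0, SD 1, denominator n - 1)
#'
#' @param values numeric vector with at least two distinct non-missing values.
#' @return standardised vector (NAs preserved).
#' @export
zscore <- function(values) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2L)
    stop("cannot standardise: fewer than 2 distinct values")
  (values - mean(v)) / stats::sd(v)
}

#' Dichotomise microbleed counts at a burden threshold
#'
#' @param mb_count non-negative integer counts.
#' @param threshold burden cut-point; default 2 (">= 2 bleeds").
#' @return integer 0/1 indicator, 1 iff `mb_count >= threshold`.
#' @export
dichotomize_microbleeds <- function(mb_count, threshold = 2) {
  if (any(mb_count < 0, na.rm = TRUE)) stop("negative microbleed count")
  as.integer(mb_count >= threshold)
}

#' Global-cognition g-factor from a cognitive test battery
#'
#' The g-factor is the first unrotated principal component of the
#' Z-standardised test scores. Tests listed in `reverse_coded` (higher score =
#' worse performance, e.g. Stroop completion time) are negated before
#' extraction so all loadings are interpretable on a "higher = better" scale.
#' The component sign is fixed so the loading on `orient_test` (a memory test
#' by default) is positive, making higher scores mean better cognition.
#'
#' @param test_scores data.frame or matrix, subjects x tests; complete rows
#'   only (subjects with incomplete assessment must be excluded by the
#'   caller, mirroring a complete-battery analysis subsample).
#' @param include_ppb keep the Purdue Pegboard column (motor function)? When
#'   `FALSE` a column named `ppb` is dropped before extraction.
#' @param reverse_coded names of tests to negate before extraction.
#' @param orient_test test whose loading anchors the component sign; defaults
#'   to `"wlt15"` when present, else the first test.
#' @return object of class `g_factor` with `scores` (mean 0), `loadings`,
#'   `variance_explained`, `included_tests`.
#' @export
compute_g_factor <- function(test_scores, include_ppb = TRUE,
                             reverse_coded = "stroop",
                             orient_test = NULL) {
  x <- as.data.frame(test_scores)
  if (!include_ppb) x$ppb <- NULL
  if (anyNA(x))
    stop("incomplete test scores: filter to complete assessments first")
  if (nrow(x) < ncol(x))
    stop("need at least as many subjects as tests")
  for (nm in intersect(reverse_coded, names(x))) x[[nm]] <- -x[[nm]]
  z <- vapply(x, zscore, numeric(nrow(x)))
  eg <- eigen(stats::cor(z), symmetric = TRUE)
  v1 <- eg$vectors[, 1L]
  names(v1) <- colnames(z)
  if (is.null(orient_test))
    orient_test <- if ("wlt15" %in% names(v1)) "wlt15" else names(v1)[1L]
  if (v1[[orient_test]] < 0) v1 <- -v1
  scores <- drop(z %*% v1)
  structure(list(scores = scores - mean(scores), loadings = v1,
                 variance_explained = eg$values[1L] / ncol(z),
                 included_tests = colnames(z)),
            class = "g_factor")
}

#' Fivefold multiple imputation of covariables by chained equations
#'
#' Missing covariable cells are filled by iterated conditional modelling:
#' each incomplete column is regressed on the other covariables (linear model
#' for continuous, logistic for binary targets) on its observed rows, and
#' missing entries are replaced by predictive draws from the fitted model.
#' Cycling over columns a fixed number of times yields one completed table;
#' this is repeated `m` times with independent draws.
#'
#' @param cohort data.frame; missingness must be confined to `covariables`.
#' @param m number of imputed tables (default 5).
#' @param seed RNG seed; identical inputs give a bit-identical result.
#' @param covariables columns eligible for imputation (and used as
#'   predictors); defaults to the cohort's `covariables` attribute.
#' @param ignore columns allowed to remain missing without being imputed
#'   (e.g. cognitive test scores of subjects with incomplete assessment,
#'   which the analysis excludes rather than imputes).
#' @param n_cycles chained-equation cycles per table (default 10).
#' @return object of class `imputation_set`: `m`, `completed_tables` (list of
#'   m data.frames), `imputed_columns`, `seed`. When the input is complete,
#'   the tables are `m` identical copies of the input.
#' @export
impute_covariables <- function(cohort, m = 5L, seed = 1L,
                               covariables = attr(cohort, "covariables"),
                               ignore = character(0), n_cycles = 10L) {
  if (is.null(covariables))
    stop("no covariable list: pass `covariables` or use a generated cohort")
  has_na <- names(cohort)[vapply(cohort, anyNA, logical(1))]
  bad <- setdiff(has_na, c(covariables, ignore))
  if (length(bad))
    stop("missingness outside covariables (exposure/mediator/outcome ",
         "columns must be complete): ", paste(bad, collapse = ", "))
  targets <- intersect(covariables, has_na)
  for (nm in targets)
    if (sum(!is.na(cohort[[nm]])) < 50L)
      stop("column '", nm, "' has fewer than 50 observed values")
  tables <- withr::with_seed(substream_seed(seed, "impute"), {
    lapply(seq_len(m), function(i) {
      tab <- cohort
      # initialise missing cells from the observed marginal
      for (nm in targets) {
        isna <- is.na(tab[[nm]])
        tab[[nm]][isna] <- sample(tab[[nm]][!isna], sum(isna), replace = TRUE)
      }
      if (!length(targets)) return(tab)
      preds <- setdiff(covariables, character(0))
      for (cycle in seq_len(n_cycles)) {
        for (nm in targets) {
          isna <- is.na(cohort[[nm]])
          rhs <- setdiff(preds, nm)
          X <- cbind(`(Intercept)` = 1,
                     as.matrix(tab[rhs]))
          y <- tab[[nm]]
          if (is_binary01(y)) {
            fit <- suppressWarnings(
              stats::glm.fit(X[!isna, , drop = FALSE], y[!isna],
                             family = stats::binomial()))
            cf <- fit$coefficients
            cf[is.na(cf)] <- 0  # aliased predictors (e.g. constant strata)
            p <- expit(drop(X[isna, , drop = FALSE] %*% cf))
            tab[[nm]][isna] <- stats::rbinom(sum(isna), 1L, p)
          } else {
            fit <- stats::lm.fit(X[!isna, , drop = FALSE], y[!isna])
            cf <- fit$coefficients
            cf[is.na(cf)] <- 0
            sigma <- sqrt(sum(fit$residuals^2) /
                            max(length(fit$residuals) - fit$rank, 1L))
            mu <- drop(X[isna, , drop = FALSE] %*% cf)
            tab[[nm]][isna] <- stats::rnorm(sum(isna), mu, sigma)
          }
        }
      }
      tab
    })
  })
  structure(list(m = as.integer(m), completed_tables = tables,
                 imputed_columns = targets, seed = as.integer(seed)),
            class = "imputation_set")
}

#' Convert a cognition effect to equivalent months of ageing
#'
#' Divides the exposure coefficient by the per-year age coefficient from the
#' same cognition scale and expresses the ratio in months.
#'
#' @param beta_exposure exposure effect on cognition (Z-score units).
#' @param beta_age age effect on cognition (Z-score units per year); must be
#'   non-zero.
#' @return equivalent ageing in months: `12 * beta_exposure / beta_age`.
#' @export
age_equivalent <- function(beta_exposure, beta_age) {
  if (!is.finite(beta_age) || beta_age == 0)
    stop("beta_age must be non-zero")
  12 * beta_exposure / beta_age
}
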