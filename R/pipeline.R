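# Study orchestration: preprocessing, the 4-mediators x 2-outcomes grid of
# single-mediator decompositions, the multiple-mediator sets, the sensitivity
# analyses, and plain-text report rendering.

#' Study configuration
#'
#' Defaults encode the primary analysis: four imaging mediators (standardised
#' hippocampal volume, standardised Alzheimer-signature cortical thickness,
#' standardised ln-WMH volume, and the binary >= 2-microbleeds indicator),
#' two outcomes (the cognition g-factor, continuous; incident dementia,
#' binary), the full covariable adjustment set, and intracranial-volume
#' adjustment for the volumetric/thickness mediators only.
#'
#' @param boot_B bootstrap replications per cell.
#' @param seed base seed for imputation, bootstrap and g-computation.
#' @param m_imputations imputed tables when covariables are missing.
#' @param mc_draws Monte-Carlo draws per subject in multi-mediator cells.
#' @param multi_sets list of mediator-name vectors analysed jointly.
#' @param min_subjects,min_events an analysis cell on a stratum smaller than
#'   this is marked `underpowered` and skipped.
#' @return object of class `study_config`.
#' @export
study_config <- function(boot_B = 1000L, seed = 1L, m_imputations = 5L,
                         mc_draws = 5L,
                         multi_sets = list(c("hv", "wmh"), c("hv", "mb2"),
                                           c("wmh", "mb2"),
                                           c("hv", "wmh", "mb2"),
                                           c("hv", "ct_ad", "wmh", "mb2")),
                         min_subjects = 100L, min_events = 10L) {
  mediators <- list(
    hv    = list(col = "hv_z",    type = "continuous", icv = TRUE),
    ct_ad = list(col = "ct_z",    type = "continuous", icv = TRUE),
    wmh   = list(col = "lnwmh_z", type = "continuous", icv = TRUE),
    mb2   = list(col = "mb2",     type = "binary",     icv = FALSE))
  for (s in multi_sets)
    if (!all(s %in% names(mediators)))
      stop("multi_sets references unknown mediator(s)")
  structure(list(
    mediators = mediators,
    outcomes = list(
      cognition = list(col = "g",        type = "continuous"),
      dementia  = list(col = "dementia", type = "binary")),
    confounders = c("age", "sex", "education", "smoking", "bmi", "sbp",
                    "bp_med", "nonhdl", "lipid_med", "diabetes", "af",
                    "stroke"),
    icv_col = "icv",
    multi_sets = multi_sets,
    boot_B = as.integer(boot_B), seed = as.integer(seed),
    m_imputations = as.integer(m_imputations),
    mc_draws = as.integer(mc_draws),
    min_subjects = as.integer(min_subjects),
    min_events = as.integer(min_events)),
    class = "study_config")
}

#' Derive analysis columns and the exclusion ledger from a raw cohort
#'
#' Adds `mb2` (and `mb2_lobar`) from the microbleed counts, `lnwmh_z`,
#' `hv_z`, `ct_z` (Z-standardised on the analysis sample), and the cognition
#' g-factors `g` (full battery) and `g_noppb` (motor test excluded), which
#' are `NA` for subjects with incomplete cognitive assessment.
#'
#' @param cohort raw cohort data.frame (columns as produced by
#'   [generate_cohort()] with `imaging_extras = TRUE`).
#' @return list with `data` (decorated cohort) and `exclusions` (named
#'   integer ledger; `n_input = n_analyzed + sum(exclusions)`).
#' @export
preprocess_cohort <- function(cohort) {
  n_input <- nrow(cohort)
  excl <- c(missing_exposure = sum(is.na(cohort$apoe4)))
  data <- cohort[!is.na(cohort$apoe4), , drop = FALSE]

  data$mb2 <- dichotomize_microbleeds(data$mb_count)
  if (!is.null(data$mb_lobar_count))
    data$mb2_lobar <- dichotomize_microbleeds(data$mb_lobar_count)
  data$hv_z <- zscore(data$hv)
  data$ct_z <- zscore(data$ct_ad)
  data$lnwmh_z <- zscore(ln_transform_wmh(data$wmh, data$subject_id))

  tests <- intersect(c("stroop", "wft", "ldst", "wlt15", "ppb"), names(data))
  complete <- stats::complete.cases(data[tests])
  data$g <- NA_real_
  data$g_noppb <- NA_real_
  gf <- compute_g_factor(data[complete, tests], include_ppb = TRUE)
  gf2 <- compute_g_factor(data[complete, tests], include_ppb = FALSE)
  data$g[complete] <- gf$scores
  data$g_noppb[complete] <- gf2$scores
  attr(data, "g_factor") <- gf

  list(data = data,
       exclusions = c(excl,
                      incomplete_cognition_battery = sum(!complete)),
       n_input = n_input,
       n_analyzed = nrow(data),
       n_cognition = sum(complete))
}

cell_confounders <- function(config, icv_needed) {
  if (icv_needed) c(config$confounders, config$icv_col) else config$confounders
}

result_row <- function(outcome, mediator_set, variant, dec, boot, n,
                       n_events, status = "ok", reason = "") {
  g <- function(comp, fld) {
    if (is.null(boot)) return(NA_real_)
    boot[[fld]][[comp]]
  }
  data.frame(
    outcome = outcome, mediator_set = paste(mediator_set, collapse = "+"),
    variant = variant,
    scale = if (is.null(dec)) NA_character_ else dec$scale,
    te = if (is.null(dec)) NA_real_ else dec$te,
    te_lo = g("te", "ci_low"), te_hi = g("te", "ci_high"),
    te_p = g("te", "p_value"),
    nde = if (is.null(dec)) NA_real_ else dec$nde,
    nde_lo = g("nde", "ci_low"), nde_hi = g("nde", "ci_high"),
    nde_p = g("nde", "p_value"),
    nie = if (is.null(dec)) NA_real_ else dec$nie,
    nie_lo = g("nie", "ci_low"), nie_hi = g("nie", "ci_high"),
    nie_p = g("nie", "p_value"),
    pm = if (is.null(dec)) NA_real_ else as.numeric(dec$pm),
    pm_lo = g("pm", "ci_low"), pm_hi = g("pm", "ci_high"),
    pm_p = g("pm", "p_value"),
    n = n, n_events = n_events, status = status, reason = reason,
    stringsAsFactors = FALSE)
}

run_cells <- function(tables, config, variant = "primary",
                      outcomes = NULL, mediators = NULL,
                      multi_sets = NULL, mediator_cols = NULL) {
  outcomes <- outcomes %||% names(config$outcomes)
  mediators <- mediators %||% names(config$mediators)
  multi_sets <- multi_sets %||% config$multi_sets
  rows <- list()
  for (on in outcomes) {
    os <- config$outcomes[[on]]
    sub <- lapply(tables, function(tb) {
      if (on == "cognition") tb[!is.na(tb[[os$col]]), , drop = FALSE] else tb
    })
    n <- nrow(sub[[1]])
    n_events <- if (os$type == "binary") sum(sub[[1]][[os$col]]) else NA_integer_
    power_ok <- n >= config$min_subjects &&
      (os$type != "binary" || n_events >= config$min_events)

    run_one <- function(set, is_multi) {
      if (!power_ok)
        return(result_row(on, set, variant, NULL, NULL, n, n_events,
                          status = "underpowered",
                          reason = sprintf("n=%d, events=%s", n,
                                           format(n_events))))
      cols <- vapply(set, function(m)
        (mediator_cols[[m]] %||% config$mediators[[m]]$col), character(1))
      icv <- any(vapply(set, function(m) config$mediators[[m]]$icv,
                        logical(1)))
      confs <- cell_confounders(config, icv)
      res <- tryCatch({
        per_imp <- lapply(seq_along(sub), function(i) {
          if (is_multi) {
            multimediate(sub[[i]], os$col, "apoe4", cols, confs,
                         outcome_link = if (os$type == "binary") "logit"
                                        else "identity",
                         B = config$boot_B,
                         seed = substream_seed(config$seed,
                                               paste(on,
                                                     paste(set, collapse = "+"),
                                                     i, sep = "|")),
                         mc_draws = config$mc_draws)
          } else {
            mediate(sub[[i]], os$col, "apoe4", cols, confs,
                    outcome_link = if (os$type == "binary") "logit"
                                   else "identity",
                    B = config$boot_B,
                    seed = substream_seed(config$seed,
                                          paste(on, set, i, sep = "|")))
          }
        })
        dec <- pool_imputations(lapply(per_imp, `[[`, "decomposition"))
        boot <- if (config$boot_B > 0L)
          pool_imputations(lapply(per_imp, `[[`, "boot")) else NULL
        if (!is.null(boot) && all(c("pm", "nie") %in% names(boot$p_value)))
          boot$p_value[["pm"]] <- boot$p_value[["nie"]]  # test of mediation
        result_row(on, set, variant, dec, boot, n, n_events,
                   status = if (config$boot_B < 100L) "low_precision" else "ok")
      }, error = function(e)
        result_row(on, set, variant, NULL, NULL, n, n_events,
                   status = "failed", reason = conditionMessage(e)))
      res
    }

    for (mn in mediators) rows[[length(rows) + 1L]] <- run_one(mn, FALSE)
    for (s in multi_sets) rows[[length(rows) + 1L]] <- run_one(s, TRUE)
  }
  do.call(rbind, rows)
}

#' Run the primary mediation analysis grid
#'
#' Preprocesses the cohort, imputes missing covariables (fivefold chained
#' equations), runs every single-mediator cell (4 mediators x 2 outcomes) and
#' every configured multi-mediator cell with percentile-bootstrap inference
#' pooled across imputations, and attaches the exclusion ledger.
#'
#' @param cohort raw cohort data.frame.
#' @param config a [study_config()].
#' @return a `results_table` data.frame, one row per (outcome, mediator-set)
#'   cell, with attributes `exclusions` and `config_hash`.
#' @export
run_primary <- function(cohort, config = study_config()) {
  prep <- preprocess_cohort(cohort)
  imp <- impute_covariables(prep$data, m = config$m_imputations,
                            seed = config$seed,
                            covariables = c(config$confounders,
                                            config$icv_col),
                            ignore = c("stroop", "wft", "ldst", "wlt15",
                                       "ppb", "g", "g_noppb"))
  tables <- if (length(imp$imputed_columns)) imp$completed_tables
            else list(prep$data)
  res <- run_cells(tables, config, variant = "primary")
  attr(res, "exclusions") <- prep[c("n_input", "n_analyzed", "n_cognition",
                                    "exclusions")]
  attr(res, "config_hash") <- object_hash(config)
  attr(res, "seed") <- config$seed
  class(res) <- c("results_table", class(res))
  res
}

#' Run one sensitivity analysis variant
#'
#' Variants (mirroring the study's sensitivity list): `age_gt75` (dementia
#' cells on the over-75 stratum), `ad_only` (clinical Alzheimer's-type events
#' only), `no_cortical_infarct` (WMH/microbleed cells excluding cortical
#' infarction), `followup_3/5/10/15` (dementia = 1 only when the event falls
#' inside the horizon), `sex_male`/`sex_female`, `g_noppb` (cognition
#' g-factor excluding the motor test), `lobar_mb` (>= 2 lobar microbleeds as
#' the microbleed mediator).
#'
#' @inheritParams run_primary
#' @param variant one of the variant names above.
#' @return a `results_table` for the variant's cells.
#' @export
run_sensitivity <- function(cohort, config = study_config(), variant) {
  horizons <- c(followup_3 = 3, followup_5 = 5, followup_10 = 10,
                followup_15 = 15)
  valid <- c("age_gt75", "ad_only", "no_cortical_infarct", names(horizons),
             "sex_male", "sex_female", "g_noppb", "lobar_mb")
  variant <- match.arg(variant, valid)

  prep <- preprocess_cohort(cohort)
  data <- prep$data
  outcomes <- NULL; mediators <- NULL; multi_sets <- config$multi_sets
  mediator_cols <- list()

  if (variant == "age_gt75") {
    data <- data[data$age > 75, , drop = FALSE]
    outcomes <- "dementia"
  } else if (variant == "ad_only") {
    data$dementia <- as.integer(data$dementia == 1L &
                                  data$dementia_subtype == "AD")
    outcomes <- "dementia"
  } else if (variant == "no_cortical_infarct") {
    data <- data[data$cortical_infarct == 0, , drop = FALSE]
    mediators <- c("wmh", "mb2")
    multi_sets <- list(c("wmh", "mb2"))
  } else if (variant %in% names(horizons)) {
    h <- horizons[[variant]]
    data$dementia <- as.integer(data$dementia == 1L & data$dementia_time <= h)
    outcomes <- "dementia"
  } else if (variant == "sex_male") {
    data <- data[data$sex == 0, , drop = FALSE]
  } else if (variant == "sex_female") {
    data <- data[data$sex == 1, , drop = FALSE]
  } else if (variant == "g_noppb") {
    data$g <- data$g_noppb
    outcomes <- "cognition"
  } else if (variant == "lobar_mb") {
    mediators <- "mb2"
    mediator_cols$mb2 <- "mb2_lobar"
    multi_sets <- list()
  }

  imp <- impute_covariables(data, m = config$m_imputations,
                            seed = config$seed,
                            covariables = c(config$confounders,
                                            config$icv_col),
                            ignore = c("stroop", "wft", "ldst", "wlt15",
                                       "ppb", "g", "g_noppb"))
  tables <- if (length(imp$imputed_columns)) imp$completed_tables
            else list(data)
  res <- run_cells(tables, config, variant = variant, outcomes = outcomes,
                   mediators = mediators, multi_sets = multi_sets,
                   mediator_cols = mediator_cols)
  attr(res, "config_hash") <- object_hash(config)
  class(res) <- c("results_table", class(res))
  res
}

#' Render a results table to plain-text report files
#'
#' Writes `results.csv` (with the proportion mediated additionally rendered
#' as a rounded percent, raw value retained), `results.json`,
#' `exclusions.json` and a `run.log` recording the seed and config hash.
#' Output is byte-identical for identical results (no timestamps).
#'
#' @param results a `results_table` (rows from [run_primary()] /
#'   [run_sensitivity()], possibly rbind-ed).
#' @param out_dir directory to write into (created if needed).
#' @return invisibly, the paths written.
#' @export
render_report <- function(results, out_dir) {
  if (!nrow(results)) stop("empty results table")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- results
  csv$pm_pct <- ifelse(is.na(csv$pm), NA, round(100 * csv$pm))
  paths <- c(results_csv = file.path(out_dir, "results.csv"),
             results_json = file.path(out_dir, "results.json"),
             exclusions_json = file.path(out_dir, "exclusions.json"),
             log = file.path(out_dir, "run.log"))
  utils::write.csv(csv, paths[["results_csv"]], row.names = FALSE)
  jsonlite::write_json(results, paths[["results_json"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  excl <- attr(results, "exclusions")
  if (is.null(excl)) {
    jsonlite::write_json(list(note = "no exclusion ledger attached"),
                         paths[["exclusions_json"]], auto_unbox = TRUE)
  } else {
    jsonlite::write_json(excl, paths[["exclusions_json"]], auto_unbox = TRUE,
                         digits = NA)
  }
  log_lines <- c(
    sprintf("apoemed %s", as.character(utils::packageVersion("apoemed"))),
    sprintf("seed: %s", format(attr(results, "seed") %||% NA)),
    sprintf("config_hash: %s", attr(results, "config_hash") %||% "NA"),
    sprintf("cells: %d (%d ok, %d underpowered, %d failed)",
            nrow(results), sum(results$status %in% c("ok", "low_precision")),
            sum(results$status == "underpowered"),
            sum(results$status == "failed")),
    "note: no multiple-testing adjustment across cells")
  writeLines(log_lines, paths[["log"]])
  invisible(paths)
}
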