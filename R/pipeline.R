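#' Energy under-reporting cut-offs
#'
#' Implausible mean daily energy intakes: below 800 kcal/d for men and 500
#' kcal/d for women, stored in kJ (1 kcal = 4.184 kJ).
#'
#' @return named numeric vector (kJ/d): male 3347.2, female 2092.0.
#' @export
energy_cutoffs_kj <- function() c(male = 800 * 4.184, female = 500 * 4.184)

#' Subset a survey design to selected rows
#' @param design a [survey_design()].
#' @param keep logical or integer row index.
#' @return the subset design.
#' @export
subset_design <- function(design, keep) {
  survey_design(design$participant_id[keep], design$weight[keep],
                design$rep_weights[keep, , drop = FALSE],
                design$variance_factor)
}

subset_cohort <- function(cohort, keep_ids) {
  keep_ids <- as.character(keep_ids)
  f <- function(df) df[as.character(df$participant_id) %in% keep_ids, ,
                       drop = FALSE]
  cohort$demographics <- f(cohort$demographics)
  cohort$recalls <- f(cohort$recalls)
  cohort$nutrients <- f(cohort$nutrients)
  cohort$biomarkers <- f(cohort$biomarkers)
  keep <- cohort$design$participant_id %in% keep_ids
  cohort$design <- subset_design(cohort$design, keep)
  if (!is.null(cohort$intakes))
    cohort$intakes <- lapply(cohort$intakes,
                             function(m) m[rownames(m) %in% keep_ids, ,
                                           drop = FALSE])
  if (!is.null(cohort$true_scores)) cohort$true_scores <- f(cohort$true_scores)
  cohort
}

#' Apply the study's exclusion rules
#'
#' Removes participants sequentially: (i) age under 18; (ii) only one 24-h
#' recall completed; (iii) suspected energy under-reporting (two-day mean
#' energy below the sex-specific cut-off); (iv) missing data for any
#' covariate or analysis variable. Each participant is counted once, at the
#' first rule that removes them.
#'
#' @param cohort a cohort (from [generate_cohort()] or [read_fixture()]).
#' @param cutoffs energy cut-offs in kJ/d ([energy_cutoffs_kj()]).
#' @return list with `cohort` (retained participants) and `report`, a
#'   data.frame of per-rule removal counts plus initial and final n.
#' @export
apply_exclusions <- function(cohort, cutoffs = energy_cutoffs_kj()) {
  dem <- cohort$demographics
  ids <- as.character(dem$participant_id)
  n0 <- length(ids)
  alive <- rep(TRUE, length(ids)); names(alive) <- ids

  # (i) age
  out_age <- is.na(dem$age) | dem$age < 18
  removed_age <- sum(alive & out_age)
  alive <- alive & !out_age

  # (ii) single recall
  days <- tapply(cohort$recalls$day,
                 as.character(cohort$recalls$participant_id),
                 function(d) length(unique(d)))
  ndays <- ifelse(ids %in% names(days), days[ids], 0L)
  out_recall <- ndays < 2L
  removed_recall <- sum(alive & out_recall)
  alive <- alive & !out_recall

  # (iii) energy under-reporting, two-day mean
  me <- tapply(cohort$nutrients$energy_kj,
               as.character(cohort$nutrients$participant_id), mean)
  mean_energy <- me[ids]
  cutoff <- cutoffs[ifelse(dem$sex == "male", "male", "female")]
  out_energy <- is.na(mean_energy) | mean_energy < cutoff
  removed_energy <- sum(alive & out_energy)
  alive <- alive & !out_energy

  # (iv) missing data for any covariate or variable of interest
  bio <- cohort$biomarkers[match(ids, cohort$biomarkers$participant_id), ]
  need_bio <- c("egfr", "acr", "hba1c", "height_cm", "weight_kg", "waist_cm",
                "sys1", "dia1", "sys2", "dia2")
  need_dem <- c("sex", "education", "smoking", "physical_activity")
  alc <- tapply(cohort$nutrients$alcohol_g,
                as.character(cohort$nutrients$participant_id), mean)[ids]
  out_missing <- rowSums(is.na(bio[, need_bio])) > 0 |
    rowSums(is.na(dem[, need_dem, drop = FALSE]) |
              dem[, need_dem, drop = FALSE] == "") > 0 |
    is.na(alc)
  removed_missing <- sum(alive & out_missing)
  alive <- alive & !out_missing

  report <- data.frame(
    rule = c("under_18", "single_recall", "energy_underreport", "missing_data"),
    removed = c(removed_age, removed_recall, removed_energy, removed_missing),
    stringsAsFactors = FALSE)
  attr(report, "initial_n") <- n0
  attr(report, "final_n") <- sum(alive)
  if (!any(alive))
    stop("pipeline abort: no participants remain after exclusions")
  list(cohort = subset_cohort(cohort, ids[alive]), report = report)
}

#' Covariate sets of the regression model ladder
#'
#' Models 1-5 are the linear-regression ladder (Model 1: age and sex; Model
#' 2: + education, physical activity, smoking; Model 3: Model 2 + BMI; Model
#' 4: Model 2 + energy and alcohol intakes; Model 5: Model 2 + BMI + energy
#' and alcohol). "fig2" is the fully adjusted CKD logistic model: age, sex,
#' energy intake, education, physical activity, smoking, diabetes,
#' hypertension, BMI and alcohol intake. Adiposity outcomes (BMI, waist
#' circumference) never adjust for BMI.
#'
#' @param model_id one of "M1".."M5", "fig2".
#' @param drop_bmi drop BMI from the covariate list (adiposity outcomes).
#' @return character vector of covariate names.
#' @export
model_covariates <- function(model_id, drop_bmi = FALSE) {
  base2 <- c("age", "sex", "education", "physical_activity", "smoking")
  cov <- switch(model_id,
                M1 = c("age", "sex"),
                M2 = base2,
                M3 = c(base2, "bmi"),
                M4 = c(base2, "energy_kj", "alcohol_g"),
                M5 = c(base2, "bmi", "energy_kj", "alcohol_g"),
                fig2 = c("age", "sex", "energy_kj", "education",
                         "physical_activity", "smoking", "diabetes",
                         "hypertension", "bmi", "alcohol_g"),
                stop("unknown model id: ", model_id))
  if (drop_bmi) cov <- setdiff(cov, "bmi")
  cov
}

#' Default linear-outcome table
#'
#' Outcome variables for the linear model ladder and whether each is
#' modelled on the natural log scale (right-skewed outcomes) and is an
#' adiposity measure (never adjusted for BMI).
#' @return data.frame with outcome, log_outcome, adiposity.
#' @export
linear_outcomes <- function() {
  data.frame(
    outcome = c("bmi", "waist_cm", "systolic", "diastolic", "total_chol",
                "hdl", "ldl", "tag", "glucose", "hba1c", "apob"),
    log_outcome = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE,
                    TRUE, TRUE, FALSE),
    adiposity = c(TRUE, TRUE, rep(FALSE, 9)),
    stringsAsFactors = FALSE)
}

#' Assemble the per-participant analysis table
#'
#' Runs decomposition, two-day averaging, weighted quintile scoring, derived
#' nutrients and outcome classification on a (post-exclusion) cohort.
#'
#' @param cohort cohort after [apply_exclusions()].
#' @return list with `data` (analysis data.frame), `scores`, `classified`,
#'   `cutpoints` and the aligned `design`.
#' @export
build_analysis_table <- function(cohort) {
  intakes <- cohort_intakes(cohort$recalls, cohort$composition)
  ids <- rownames(intakes$mean)
  design <- cohort$design
  ord <- match(ids, design$participant_id)
  design <- subset_design(design, ord)
  cuts <- compute_cutpoints(intakes$mean, design$weight)
  scores <- score_cohort(intakes$mean, cuts)

  nut <- cohort$nutrients
  d1 <- nut[nut$day == 1L, ][match(ids, nut$participant_id[nut$day == 1L]), ]
  d2 <- nut[nut$day == 2L, ][match(ids, nut$participant_id[nut$day == 2L]), ]
  nm <- mean_profile(d1, d2)
  bio <- cohort$biomarkers[match(ids, cohort$biomarkers$participant_id), ]
  dem <- cohort$demographics[match(ids, cohort$demographics$participant_id), ]
  cls <- classify_outcomes(bio)

  dat <- data.frame(
    participant_id = ids,
    age = dem$age,
    sex = factor(dem$sex, levels = c("female", "male")),
    education = factor(dem$education, levels = c("low", "medium", "high")),
    smoking = factor(dem$smoking, levels = c("never", "ex", "current")),
    physical_activity = factor(dem$physical_activity,
                               levels = c("sedentary", "low", "moderate",
                                          "high")),
    energy_kj = nm$energy_kj, alcohol_g = nm$alcohol_g,
    pral = pral(nm),
    protein_fibre = suppressWarnings(protein_fibre_ratio(nm)),
    pdi = scores$pdi, hpdi = scores$hpdi, updi = scores$updi,
    bmi = cls$bmi, waist_cm = bio$waist_cm,
    systolic = cls$systolic, diastolic = cls$diastolic,
    hypertension = cls$hypertension, diabetes = cls$diabetes,
    any_ckd = cls$any_ckd, moderate_severe = cls$moderate_severe,
    total_chol = bio$total_chol, hdl = bio$hdl, ldl = bio$ldl,
    tag = bio$tag, glucose = bio$glucose, hba1c = bio$hba1c, apob = bio$apob,
    stringsAsFactors = FALSE)
  list(data = dat, scores = scores, classified = cls, cutpoints = cuts,
       design = design)
}

fit_index_model <- function(dat, design, index, outcome, model_id,
                            family, log_outcome, adiposity = FALSE) {
  cov <- model_covariates(model_id, drop_bmi = adiposity)
  keep <- !is.na(dat[[outcome]])
  d <- dat[keep, , drop = FALSE]
  des <- if (all(keep)) design else subset_design(design, keep)
  fml <- stats::as.formula(paste(outcome, "~", paste(c(index, cov),
                                                     collapse = " + ")))
  fit <- fit_survey_glm(fml, d, des, family = family,
                        log_outcome = log_outcome)
  row <- fit_term(fit, index)
  out <- data.frame(model_id = model_id, family = family, outcome = outcome,
                    log_outcome = log_outcome, index = index,
                    estimate = row$estimate, se = row$se,
                    ci_low = row$ci_low, ci_high = row$ci_high, p = row$p,
                    n = fit$n, stringsAsFactors = FALSE)
  if (family == "logistic") {
    out$odds_ratio <- row$odds_ratio
    out$or_low <- row$or_low
    out$or_high <- row$or_high
  } else {
    out$odds_ratio <- NA_real_; out$or_low <- NA_real_; out$or_high <- NA_real_
  }
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates exclusions, decomposition, scoring, derived nutrients,
#' outcome classification and the regression model ladder: for each of the
#' three diet indices, survey-weighted linear models of the configured
#' continuous outcomes at each requested ladder model, and fully adjusted
#' ("fig2") logistic models of any CKD and moderate-severe CKD. Writes
#' result CSVs and a machine-readable manifest when `out_dir` is given;
#' outputs are deterministic given the cohort.
#'
#' @param cohort a cohort object.
#' @param models character vector from M1..M5 for the linear ladder.
#' @param logistic_model model id for the CKD logistic fits (default "fig2").
#' @param outcomes data.frame like [linear_outcomes()]; NULL skips linear
#'   fits.
#' @param out_dir optional output directory.
#' @return list with results (data.frame), exclusions report, scores,
#'   classified outcomes, cutpoints and manifest.
#' @export
run_analysis <- function(cohort, models = c("M1", "M5"),
                         logistic_model = "fig2",
                         outcomes = linear_outcomes(), out_dir = NULL) {
  excl <- apply_exclusions(cohort)
  tab <- build_analysis_table(excl$cohort)
  dat <- tab$data
  design <- tab$design

  res <- list()
  for (index in c("pdi", "hpdi", "updi")) {
    for (ckd_out in c("any_ckd", "moderate_severe")) {
      res[[length(res) + 1L]] <-
        fit_index_model(dat, design, index, ckd_out, logistic_model,
                        family = "logistic", log_outcome = FALSE)
    }
    if (!is.null(outcomes)) {
      for (m in models) for (j in seq_len(nrow(outcomes))) {
        res[[length(res) + 1L]] <-
          fit_index_model(dat, design, index, outcomes$outcome[j], m,
                          family = "linear",
                          log_outcome = outcomes$log_outcome[j],
                          adiposity = outcomes$adiposity[j])
      }
    }
  }
  results <- do.call(rbind, res)

  manifest <- list(
    package_version = as.character(utils::packageVersion("plantdex")),
    seed = if (!is.null(cohort$config)) cohort$config$seed else NA,
    models = models, logistic_model = logistic_model,
    n_initial = attr(excl$report, "initial_n"),
    n_final = attr(excl$report, "final_n"),
    exclusions = excl$report,
    config = if (!is.null(cohort$config)) {
      cfg <- cohort$config; cfg$intake_params <- NULL; cfg
    })

  out <- list(results = results, exclusions = excl$report,
              scores = tab$scores, classified = tab$classified,
              cutpoints = tab$cutpoints, data = dat, design = design,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    sc <- tab$scores
    sc$pdi_quintile <- score_quintile(sc$pdi, design$weight)
    sc$hpdi_quintile <- score_quintile(sc$hpdi, design$weight)
    sc$updi_quintile <- score_quintile(sc$updi, design$weight)
    utils::write.csv(sc, file.path(out_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(tab$classified, file.path(out_dir, "classified.csv"),
                     row.names = FALSE)
    er <- excl$report
    er$final_n <- attr(excl$report, "final_n")
    utils::write.csv(er, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}
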