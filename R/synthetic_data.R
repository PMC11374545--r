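#' Synthetic food-composition table
#'
#' A small stand-in for the restricted ingredient-level food-composition
#' database: 46 single-ingredient codes (one per scoring unit) plus eight
#' multi-ingredient products whose fractions decompose into several groups.
#' Codes are synthetic 8-digit identifiers; the table is also shipped as
#' \code{inst/extdata/food_composition_synthetic.csv}.
#'
#' @return data.frame with columns food_code, context, group_id, fraction.
#' @export
default_composition <- function() {
  u <- unit_layout()
  pure <- data.frame(
    food_code = sprintf("1%02d%1d0000", u$group_id,
                        match(u$context, contexts())),
    context = u$context, group_id = u$group_id, fraction = 1,
    stringsAsFactors = FALSE)
  mix <- function(code, context, ids, fr)
    data.frame(food_code = code, context = context, group_id = ids,
               fraction = fr, stringsAsFactors = FALSE)
  mixed <- rbind(
    mix("20000001", "discretionary", c(8L, 11L, 17L, 2L), c(.50, .25, .15, .10)),
    mix("20000002", "discretionary", c(8L, 3L, 15L, 19L), c(.45, .20, .25, .10)),
    mix("20000003", "core",          c(3L, 5L, 23L),      c(.70, .20, .10)),
    mix("20000004", "core",          c(1L, 4L, 2L),       c(.60, .15, .25)),
    mix("20000005", "core",          c(14L, 2L, 11L),     c(.80, .15, .05)),
    mix("20000006", "core",          c(18L, 3L, 6L, 8L),  c(.40, .40, .10, .10)),
    mix("20000007", "discretionary", c(11L, 10L, 15L),    c(.50, .30, .20)),
    mix("20000008", "discretionary", c(8L, 19L, 13L, 23L), c(.50, .30, .10, .10)))
  out <- rbind(pure, mixed)
  validate_composition(out)
  out
}

#' Default intake-distribution parameters
#'
#' Each scoring unit's grams/day is drawn from a zero-inflated log-normal:
#' with probability \code{pi0} a recall day records zero for the unit
#' (episodically consumed foods such as legumes and fish are strongly
#' zero-inflated); otherwise the day's intake is log-normal around a
#' participant-level latent mean \code{mu + delta * h + person noise}, where
#' h is the participant's latent diet-healthfulness trait. Positive
#' \code{delta} on healthy-plant core units and negative \code{delta} on
#' unhealthy/discretionary units give the generated cohort the expected
#' negative correlation between the unhealthy index and fibre, magnesium and
#' potassium intakes.
#'
#' @param groups food-group table.
#' @return data.frame with unit, group_id, context, pi0, mu (meanlog of the
#'   typical grams/day), delta (loading on the latent trait).
#' @export
default_intake_params <- function(groups = food_groups()) {
  base_core <- 0.8 * c(60, 150, 180, 15, 30, 12, 400,          # healthy plant
                       90, 120, 8, 20, 25,                     # unhealthy plant
                       8, 90, 100, 40, 30, 40, 60, 80, 15, 5, 20)  # animal
  pi0_core <- c(0.20, 0.10, 0.05, 0.55, 0.60, 0.35, 0.15,
                0.30, 0.50, 0.60, 0.40, 0.35,
                0.50, 0.45, 0.30, 0.35, 0.50, 0.55, 0.35, 0.30, 0.50, 0.85, 0.50)
  cat23 <- as.character(groups$category)
  disc_scale <- ifelse(cat23 == "unhealthy_plant", 1.0, 0.3)
  delta_core <- c(healthy_plant = 0.5, unhealthy_plant = -0.3, animal = -0.1)[cat23]
  delta_disc <- c(healthy_plant = -0.2, unhealthy_plant = -0.6, animal = -0.3)[cat23]
  u <- unit_layout()
  core <- u$context == "core"
  data.frame(
    unit = u$unit, group_id = u$group_id, context = u$context,
    pi0 = ifelse(core, pi0_core[u$group_id],
                 pmin(0.9, pi0_core[u$group_id] + 0.2)),
    mu = ifelse(core, log(base_core[u$group_id]),
                log(base_core[u$group_id] * disc_scale[u$group_id])),
    delta = ifelse(core, delta_core[u$group_id], delta_disc[u$group_id]),
    stringsAsFactors = FALSE)
}

# per-gram nutrient coefficients by food group (plausible whole-food values)
nutrient_coefs <- function() {
  m <- rbind(
    energy_kj    = c(15, 2.5, 1.5, 25, 5, 35, 0.7, 15, 1.8, 35, 16, 10,
                     35, 2.5, 3.5, 5.5, 6.5, 8, 11, 7.5, 8, 6, 5),
    protein_g    = c(0.10, 0.008, 0.02, 0.20, 0.08, 0, 0.002, 0.09, 0.005,
                     0, 0, 0.03, 0, 0.035, 0.033, 0.05, 0.125, 0.20, 0.15,
                     0.22, 0.10, 0.18, 0.03),
    fibre_g      = c(0.07, 0.022, 0.026, 0.08, 0.065, 0, 0.001, 0.025,
                     0.002, 0, 0, 0.02, rep(0, 11)),
    phosphorus_mg = c(2.5, 0.15, 0.4, 4.5, 1.2, 0, 0.05, 1.0, 0.1, 0, 0,
                      0.6, 0.1, 0.95, 0.9, 1.2, 1.9, 2.2, 1.8, 2.1, 1.0,
                      2.5, 0.4),
    potassium_mg = c(3.5, 1.8, 2.8, 6.0, 3.0, 0, 0.3, 1.2, 1.5, 0, 0.2,
                     1.5, 0.2, 1.5, 1.4, 1.0, 1.3, 3.3, 2.5, 3.3, 1.5,
                     2.8, 1.0),
    magnesium_mg = c(1.0, 0.1, 0.18, 2.5, 0.5, 0, 0.03, 0.25, 0.1, 0, 0,
                     0.4, 0, 0.11, 0.11, 0.08, 0.11, 0.3, 0.2, 0.25, 0.1,
                     0.2, 0.1),
    calcium_mg   = c(0.3, 0.1, 0.35, 0.8, 0.5, 0, 0.05, 0.5, 0.1, 0, 0.05,
                     0.3, 0.05, 1.2, 1.15, 4.0, 0.5, 0.7, 0.3, 0.15, 0.5,
                     0.1, 0.3),
    sodium_mg    = c(2.0, 0.01, 0.3, 1.5, 1.0, 0.05, 0.02, 4.5, 0.05, 1.0,
                     0.3, 4.0, 3.0, 0.5, 0.5, 5.0, 1.3, 2.5, 8.0, 0.6,
                     3.5, 1.0, 10),
    sat_fat_g    = c(0.003, 0.001, 0.001, 0.06, 0.003, 0.12, 0, 0.004, 0,
                     0.45, 0, 0.03, 0.45, 0.01, 0.02, 0.12, 0.03, 0.02,
                     0.08, 0.03, 0.05, 0.03, 0.02),
    poly_fat_g   = c(0.01, 0.001, 0.002, 0.18, 0.01, 0.45, 0, 0.005, 0,
                     0.05, 0, 0.02, 0.04, 0.002, 0.003, 0.01, 0.02, 0.03,
                     0.03, 0.02, 0.02, 0.02, 0.01))
  colnames(m) <- sprintf("g%02d", 1:23)
  m
}

#' Generator configuration
#'
#' Study conditions for the synthetic national-nutrition-survey cohort. The
#' defaults reproduce the analysed sample: 2060 adults, any-CKD prevalence
#' 250/2060, 103/250 (41.2\%) of CKD cases moderate-severe, and a per-unit
#' log-odds effect of the unhealthy plant-based diet index on moderate-severe
#' CKD of ln(1.037). Covariate effects on moderate-severe CKD are
#' order-of-magnitude plausible and configurable; they carry no claim to
#' match the survey.
#'
#' @param n cohort size.
#' @param seed integer RNG seed.
#' @param ckd_prevalence_target marginal probability of any CKD.
#' @param moderate_severe_fraction fraction of CKD that is stage 3-5.
#' @param updi_ckd_log_or per-unit log odds ratio of uPDI on stage 3-5 CKD.
#' @param covariate_effects named numeric vector of log-odds effects on
#'   stage 3-5 CKD (age per year centred at 50, sex_male, diabetes,
#'   hypertension, bmi per kg/m2 centred at 27, smoking_current).
#' @param intake_params per-unit intake distribution table
#'   ([default_intake_params()]).
#' @param person_sd,day_sd log-scale person-level and day-level intake
#'   dispersion.
#' @param nutrient_noise multiplicative log-sd noise on derived nutrients.
#' @param fasting_prob probability a participant fasted >= 8 h (1 keeps the
#'   default cohort complete).
#' @param rep_groups number of delete-a-group jackknife replicate groups R.
#' @param population_total sum the calibration weights are scaled to.
#' @return list of class "generator_config".
#' @export
generator_config <- function(n = 2060L, seed = 1L,
                             ckd_prevalence_target = 250 / 2060,
                             moderate_severe_fraction = 103 / 250,
                             updi_ckd_log_or = log(1.037),
                             covariate_effects = c(age = 0.03, sex_male = 0.3,
                                                   diabetes = 0.5,
                                                   hypertension = 0.4,
                                                   bmi = 0.02,
                                                   smoking_current = 0.3),
                             intake_params = default_intake_params(),
                             person_sd = 0.5, day_sd = 0.35,
                             nutrient_noise = 0.05, fasting_prob = 1,
                             rep_groups = 60L,
                             population_total = 8769986) {
  stopifnot(n >= 50L, rep_groups >= 2L,
            ckd_prevalence_target > 0, ckd_prevalence_target < 1,
            moderate_severe_fraction > 0, moderate_severe_fraction < 1,
            fasting_prob >= 0, fasting_prob <= 1)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 ckd_prevalence_target = ckd_prevalence_target,
                 moderate_severe_fraction = moderate_severe_fraction,
                 updi_ckd_log_or = updi_ckd_log_or,
                 covariate_effects = covariate_effects,
                 intake_params = intake_params,
                 person_sd = person_sd, day_sd = day_sd,
                 nutrient_noise = nutrient_noise,
                 fasting_prob = fasting_prob,
                 rep_groups = as.integer(rep_groups),
                 population_total = population_total),
            class = "generator_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

draw_intake_day <- function(latent_log, pi0) {
  n <- nrow(latent_log)
  on <- matrix(stats::runif(length(latent_log)) >= rep(pi0, each = n),
               nrow = n)
  latent_log * on
}

# convert a day's intake matrix to food records: single-ingredient codes per
# unit, with part of the cake-compatible discretionary intake emitted as the
# multi-ingredient cake product so decomposition is exercised end to end
intakes_to_records <- function(m, day) {
  ids <- rownames(m)
  cake_units <- c("g08.discretionary", "g11.discretionary",
                  "g17.discretionary", "g02.discretionary")
  cake_fr <- c(.50, .25, .15, .10)
  sub <- m[, cake_units, drop = FALSE]
  ok <- rowSums(sub > 0) == 4L
  cake_g <- numeric(nrow(m))
  cake_g[ok] <- 0.5 * apply(sub[ok, , drop = FALSE], 1L,
                            function(x) min(x / cake_fr))
  m[, cake_units] <- m[, cake_units] - outer(cake_g, cake_fr)
  u <- unit_layout()
  codes <- sprintf("1%02d%1d0000", u$group_id, match(u$context, contexts()))
  pos <- which(m > 1e-12, arr.ind = TRUE)
  rec <- data.frame(participant_id = ids[pos[, 1L]], day = day,
                    food_code = codes[pos[, 2L]], grams = m[pos],
                    stringsAsFactors = FALSE)
  if (any(cake_g > 0))
    rec <- rbind(rec, data.frame(participant_id = ids[cake_g > 0], day = day,
                                 food_code = "20000001",
                                 grams = cake_g[cake_g > 0],
                                 stringsAsFactors = FALSE))
  rec[order(rec$participant_id, rec$food_code), , drop = FALSE]
}

nutrients_from_intakes <- function(m, alcohol_g, noise_sd) {
  u <- unit_layout()
  # nutrients depend on the group, not the context
  bygroup <- t(rowsum(t(m), group = sprintf("g%02d", u$group_id)))
  coefs <- nutrient_coefs()
  nut <- bygroup %*% t(coefs[, colnames(bygroup)])
  baseline <- c(energy_kj = 1800, protein_g = 10, fibre_g = 2,
                phosphorus_mg = 150, potassium_mg = 300, magnesium_mg = 30,
                calcium_mg = 100, sodium_mg = 300, sat_fat_g = 3,
                poly_fat_g = 2)
  nut <- sweep(nut, 2L, baseline[colnames(nut)], "+")
  nut <- nut * exp(matrix(stats::rnorm(length(nut), 0, noise_sd), nrow(nut)))
  out <- as.data.frame(nut)
  out$alcohol_g <- alcohol_g
  out$energy_kj <- out$energy_kj + 29 * alcohol_g
  out[, nutrient_cols()]
}

solve_intercept <- function(lp, target) {
  f <- function(a) mean(stats::plogis(a + lp)) - target
  lo <- -40; hi <- 20
  if (f(lo) > 0 || f(hi) < 0)
    stop("calibration failure: prevalence target ", signif(target, 4),
         " infeasible for the configured effects")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic survey cohort
#'
#' Draws a complete cohort with the statistical structure the analysis
#' assumes: a latent diet-healthfulness trait drives zero-inflated log-normal
#' intakes for the 46 scoring units over two independent recall days;
#' nutrient profiles are derived from the intakes (plus noise); biomarkers,
#' anthropometrics and 2-3 blood-pressure readings are drawn with plausible
#' ranges; and the probability of moderate-severe CKD follows a logistic
#' model whose linear predictor contains the participant's true uPDI (scored
#' internally from the generated intakes with the cohort's own weighted
#' quintiles) times \code{updi_ckd_log_or} plus the configured covariate
#' effects, with the intercept solved numerically so the marginal CKD
#' prevalences hit their targets. Stage 1-2 CKD (albuminuria with preserved
#' eGFR) has constant probability chosen so that total CKD prevalence matches
#' its target. Calibration weights are log-normal and replicate weights are
#' built by delete-a-group perturbation with round-robin group assignment.
#'
#' @param cfg a [generator_config()].
#' @return object of class "synthetic_cohort": list with demographics,
#'   recalls, nutrients (per participant and day), biomarkers, design
#'   ([survey_design()]), composition table, the generator-side intake
#'   matrices and true scores, and the config.
#' @export
generate_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  ids <- sprintf("P%05d", seq_len(n))

  ## demographics
  age <- sample(18:85, n, replace = TRUE,
                prob = 0.995^(0:67))  # gently decreasing with age
  sex <- ifelse(stats::runif(n) < 928 / 2060, "male", "female")
  education <- sample(c("low", "medium", "high"), n, replace = TRUE,
                      prob = c(0.30, 0.45, 0.25))
  smoking <- sample(c("never", "ex", "current"), n, replace = TRUE,
                    prob = c(0.55, 0.28, 0.17))
  physical_activity <- sample(c("sedentary", "low", "moderate", "high"), n,
                              replace = TRUE, prob = c(0.20, 0.35, 0.30, 0.15))
  demographics <- data.frame(participant_id = ids, age = age, sex = sex,
                             education = education, smoking = smoking,
                             physical_activity = physical_activity,
                             stringsAsFactors = FALSE)

  ## intakes: latent trait -> per-unit person level -> two recall days
  h <- stats::rnorm(n)
  ip <- cfg$intake_params
  nu <- nrow(ip)
  person_log <- matrix(rep(ip$mu, each = n), n) +
    outer(h, ip$delta) +
    matrix(stats::rnorm(n * nu, 0, cfg$person_sd), n)
  day_mat <- function() {
    lv <- exp(person_log + matrix(stats::rnorm(n * nu, 0, cfg$day_sd), n))
    consumed <- matrix(stats::runif(n * nu) >= rep(ip$pi0, each = n), n)
    m <- lv * consumed
    dimnames(m) <- list(ids, ip$unit)
    class(m) <- c("intake_matrix", class(m))
    m
  }
  day1 <- day_mat(); day2 <- day_mat()
  intake_mean <- average_days(day1, day2)

  ## recalls and nutrients
  recalls <- rbind(intakes_to_records(day1, 1L), intakes_to_records(day2, 2L))
  rownames(recalls) <- NULL
  drinker <- stats::runif(n) >= 0.6
  alc <- function() drinker * stats::rlnorm(n, log(20), 0.6)
  nut1 <- cbind(data.frame(participant_id = ids, day = 1L),
                nutrients_from_intakes(day1, alc(), cfg$nutrient_noise))
  nut2 <- cbind(data.frame(participant_id = ids, day = 2L),
                nutrients_from_intakes(day2, alc(), cfg$nutrient_noise))
  nutrients <- rbind(nut1, nut2)

  ## anthropometry, blood pressure, biochemistry
  height <- ifelse(sex == "male", stats::rnorm(n, 175, 7),
                   stats::rnorm(n, 162, 6.5))
  bmi_true <- exp(stats::rnorm(n, log(27), 0.15) - 0.03 * h)
  weight <- bmi_true * (height / 100)^2
  waist <- 0.5 * height + 2.2 * (bmi_true - 22) + stats::rnorm(n, 0, 5)
  sys_lat <- 122 + 0.45 * (age - 50) - 1.5 * h + stats::rnorm(n, 0, 13)
  dia_lat <- 72 + 0.3 * (sys_lat - 120) + stats::rnorm(n, 0, 7)
  reading <- function(lat, sd = 5) lat + stats::rnorm(n, 0, sd)
  sys1 <- reading(sys_lat); sys2 <- reading(sys_lat)
  dia1 <- reading(dia_lat, 4); dia2 <- reading(dia_lat, 4)
  clamp_bp <- function(s, d) list(s = pmin(250, pmax(70, s)),
                                  d = pmin(150, pmax(40, d)))
  b1 <- clamp_bp(sys1, dia1); b2 <- clamp_bp(sys2, dia2)
  third <- abs(b1$s - b2$s) > 10 | abs(b1$d - b2$d) > 10
  b3 <- clamp_bp(reading(sys_lat), reading(dia_lat, 4))
  sys3 <- ifelse(third, b3$s, NA_real_)
  dia3 <- ifelse(third, b3$d, NA_real_)

  hba1c <- pmin(15, pmax(4, exp(stats::rnorm(n, log(5.4), 0.1)) +
                           0.03 * pmax(bmi_true - 27, 0)))
  fasted <- stats::runif(n) < cfg$fasting_prob
  total_chol <- pmax(2, stats::rnorm(n, 5.2, 1.0))
  hdl <- stats::rlnorm(n, log(1.4), 0.2)
  tag <- stats::rlnorm(n, log(1.3), 0.4)
  ldl <- pmax(0.5, total_chol - hdl - 0.45 * tag + stats::rnorm(n, 0, 0.2))
  glucose <- stats::rlnorm(n, log(5.2), 0.1) + 2 * (hba1c >= 6.5)
  apob <- pmax(0.3, 0.25 * total_chol + stats::rnorm(n, 0, 0.1))

  ## survey design
  w <- stats::rlnorm(n, log(cfg$population_total / n), 0.3)
  w <- w * cfg$population_total / sum(w)
  R <- cfg$rep_groups
  grp <- ((seq_len(n) - 1L) %% R) + 1L
  repw <- outer(seq_len(n), seq_len(R),
                function(i, r) ifelse(grp[i] == r, 0, w[i] * R / (R - 1)))
  design <- survey_design(ids, w, repw)

  ## true uPDI, scored on the generated cohort's own weighted quintiles
  cuts <- compute_cutpoints(intake_mean, w)
  scores <- score_cohort(intake_mean, cuts)

  ## CKD assignment: logistic stage 3-5 with calibrated intercept
  bp_sel <- select_bp(cbind(b1$s, b1$d, b2$s, b2$d, sys3, dia3))
  htn <- classify_hypertension(bp_sel$systolic, bp_sel$diastolic)
  diab <- classify_diabetes_risk(hba1c) == "diabetes"
  ce <- cfg$covariate_effects
  lp <- cfg$updi_ckd_log_or * scores$updi +
    ce["age"] * (age - 50) + ce["sex_male"] * (sex == "male") +
    ce["diabetes"] * diab + ce["hypertension"] * htn +
    ce["bmi"] * (bmi_true - 27) + ce["smoking_current"] * (smoking == "current")
  p_ms <- cfg$ckd_prevalence_target * cfg$moderate_severe_fraction
  a3 <- solve_intercept(lp, p_ms)
  p3 <- stats::plogis(a3 + lp)
  stage3 <- stats::runif(n) < p3
  p12 <- (cfg$ckd_prevalence_target - p_ms) / (1 - p_ms)
  stage12 <- !stage3 & stats::runif(n) < p12

  thr <- acr_thresholds()[sex]
  egfr <- ifelse(stage3, stats::runif(n, 20, 59.5),
                 pmax(60.01, stats::rnorm(n, 95, 15)))
  acr <- ifelse(stage12 | (stage3 & stats::runif(n) < 0.5),
                thr + stats::rexp(n, 1 / 5),
                thr * stats::runif(n, 0, 0.95))

  biomarkers <- data.frame(
    participant_id = ids, sex = sex, fasted_8h = fasted,
    egfr = egfr, acr = acr, total_chol = total_chol, hdl = hdl,
    ldl = ifelse(fasted, ldl, NA_real_), tag = ifelse(fasted, tag, NA_real_),
    glucose = ifelse(fasted, glucose, NA_real_), hba1c = hba1c, apob = apob,
    height_cm = height, weight_kg = weight, waist_cm = waist,
    sys1 = b1$s, dia1 = b1$d, sys2 = b2$s, dia2 = b2$d,
    sys3 = sys3, dia3 = dia3, stringsAsFactors = FALSE)

  structure(list(demographics = demographics, recalls = recalls,
                 nutrients = nutrients, biomarkers = biomarkers,
                 design = design, composition = default_composition(),
                 intakes = list(day1 = day1, day2 = day2, mean = intake_mean),
                 true_scores = scores, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic survey cohort:", nrow(x$demographics), "participants, seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Inject missingness completely at random
#'
#' Sets the named fields to NA independently at the given rate, for testing
#' the missing-data exclusion rule.
#'
#' @param cohort a synthetic cohort.
#' @param rate missingness probability in [0, 1).
#' @param seed RNG seed for the mask.
#' @param fields character vector of biomarker or demographic column names.
#' @return the cohort with missing values injected.
#' @export
inject_missingness <- function(cohort, rate, seed = 1L,
                               fields = c("egfr", "acr", "hba1c")) {
  if (rate < 0 || rate >= 1) stop("missingness rate must be in [0, 1)")
  if (rate == 0) return(cohort)
  set.seed(seed)
  n <- nrow(cohort$biomarkers)
  for (f in fields) {
    tab <- if (f %in% names(cohort$biomarkers)) "biomarkers" else "demographics"
    if (!f %in% names(cohort[[tab]])) stop("unknown field: ", f)
    mask <- stats::runif(n) < rate
    cohort[[tab]][[f]][mask] <- NA
  }
  cohort
}

#' Write / read a cohort fixture as a CSV file set
#'
#' Emits the file set consumed by the pipeline: demographics.csv,
#' recalls.csv, nutrients.csv, biomarkers.csv, design.csv,
#' food_composition.csv and manifest.json (config and seed).
#'
#' @param cohort a synthetic cohort.
#' @param dir output directory (created if needed).
#' @return `write_fixture` returns the directory invisibly; `read_fixture`
#'   returns a "synthetic_cohort" (without generator-side truth).
#' @export
write_fixture <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                         row.names = FALSE, quote = FALSE)
  wr(cohort$demographics, "demographics.csv")
  wr(cohort$recalls, "recalls.csv")
  wr(cohort$nutrients, "nutrients.csv")
  wr(cohort$biomarkers, "biomarkers.csv")
  d <- cohort$design
  des <- data.frame(participant_id = d$participant_id, weight = d$weight)
  repw <- as.data.frame(d$rep_weights)
  names(repw) <- sprintf("repwt_%d", seq_len(ncol(repw)))
  wr(cbind(des, repw), "design.csv")
  wr(cohort$composition, "food_composition.csv")
  cfg <- unclass(cohort$config)
  cfg$intake_params <- NULL  # reproducible from the packaged defaults
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                                    colClasses = NA)
  demographics <- rd("demographics.csv")
  recalls <- rd("recalls.csv")
  recalls$food_code <- as.character(recalls$food_code)
  nutrients <- rd("nutrients.csv")
  biomarkers <- rd("biomarkers.csv")
  des <- rd("design.csv")
  comp <- rd("food_composition.csv")
  comp$food_code <- as.character(comp$food_code)
  repcols <- grep("^repwt_", names(des))
  design <- survey_design(des$participant_id, des$weight,
                          as.matrix(des[, repcols]))
  structure(list(demographics = demographics, recalls = recalls,
                 nutrients = nutrients, biomarkers = biomarkers,
                 design = design, composition = comp,
                 intakes = NULL, true_scores = NULL, config = NULL),
            class = "synthetic_cohort")
}
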