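#' @title Synthetic dual-payer claims generator
#' @description Generates patient-year cohorts with the statistical
#'   structure the calibration analysis assumes: a veteran-like demographic
#'   mix (93.5% male, mean age 63), chronic-condition prevalences matching a
#'   large integrated health system (diabetes 22.1%, PTSD 10.4%, dementia
#'   0.8%, any psychiatric diagnosis ~36%), heavily right-skewed costs via
#'   mean-one multiplicative lognormal noise, an age-ramped Medicare cost
#'   share above 65, and a known true cost model so parameter recovery and
#'   calibration behaviour can be verified exactly. Psychiatric
#'   under-pricing is injected through configurable channels rather than
#'   baked in.
#' @name synthetic_data
NULL

#' Default 47-category psychiatric table for the synthetic fixture
#'
#' One row per category: id, display name, marginal prevalence, the
#' unpriced dollar increment used under `MH_UNPRICED`, the condition
#' category it maps to in the fixture risk model (`NA` = invisible to the
#' risk model, the mechanism under study), and its fabricated diagnosis
#' code. The four categories mapped to the model's MH/SA condition
#' categories carry their cost through the priced coefficients instead
#' (increment 0).
#'
#' @return data frame with 47 rows.
#' @export
psycms_category_defaults <- function() {
  x <- rbind(
    c("schizophrenia",        "Schizophrenia",                          0.014,    0, "CC57", "2950"),
    c("schizoaffective",      "Schizoaffective disorder",               0.005,    0, "CC57", "29570"),
    c("bipolar",              "Bipolar disorder",                       0.022,    0, "CC58", "29640"),
    c("major_depression",     "Major depressive disorder",              0.050,    0, "CC58", "29620"),
    c("paranoid",             "Paranoid disorder",                      0.004,    0, "CC58", "2971"),
    c("drug_psychosis",       "Drug-induced psychosis",                 0.004,    0, "CC54", "2920"),
    c("alcohol_psychosis",    "Alcohol-induced psychosis",              0.003,    0, "CC54", "2910"),
    c("drug_dependence",      "Drug dependence",                        0.024,    0, "CC55", "3040"),
    c("alcohol_dependence",   "Alcohol dependence",                     0.042,    0, "CC55", "3030"),
    c("depression_nos",       "Depression, not otherwise specified",    0.080, 1800, NA,     "311"),
    c("neurotic_depression",  "Neurotic depression",                    0.018, 1200, NA,     "3004"),
    c("ptsd",                 "Posttraumatic stress disorder",          0.104, 2500, NA,     "30981"),
    c("anxiety",              "Anxiety, not otherwise specified",       0.032, 1000, NA,     "30000"),
    c("general_anxiety",      "General anxiety disorder",               0.013, 1000, NA,     "30002"),
    c("panic",                "Panic disorder",                         0.010, 1200, NA,     "30001"),
    c("phobia",               "Phobic disorder",                        0.006,  800, NA,     "30020"),
    c("ocd",                  "Obsessive-compulsive disorder",          0.005, 1200, NA,     "3003"),
    c("nicotine_dependence",  "Nicotine dependence",                    0.100,  900, NA,     "3051"),
    c("alcohol_abuse",        "Alcohol abuse",                          0.036, 1500, NA,     "30500"),
    c("drug_abuse",           "Drug abuse",                             0.024, 1800, NA,     "30590"),
    c("adjustment_reaction",  "Adjustment reaction",                    0.020,  900, NA,     "3090"),
    c("organic_other",        "Organic mental disorder, other",         0.018, 2500, NA,     "29481"),
    c("sexual_dysfunction",   "Sexual dysfunction",                     0.014,  500, NA,     "30270"),
    c("dementia_alzheimers",  "Dementia, Alzheimer type",               0.005, 2000, NA,     "3310"),
    c("dementia_vascular",    "Dementia, vascular",                     0.002, 2000, NA,     "29040"),
    c("dementia_other",       "Dementia, other",                        0.0015, 2000, NA,    "29410"),
    c("somatoform",           "Somatoform disorder",                    0.004,  800, NA,     "30080"),
    c("personality",          "Personality disorder",                   0.010, 1500, NA,     "3019"),
    c("adhd",                 "Attention-deficit disorder",             0.006,  600, NA,     "3140"),
    c("insomnia",             "Sleep disorder, nonorganic",             0.008,  500, NA,     "30741"),
    c("eating",               "Eating disorder",                        0.002, 1000, NA,     "3071"),
    c("impulse_control",      "Impulse control disorder",               0.003,  800, NA,     "31230"),
    c("psychosis_nos",        "Psychosis, not otherwise specified",     0.006, 3000, NA,     "2989"),
    c("acute_stress",         "Acute stress reaction",                  0.005,  700, NA,     "3080"),
    c("grief",                "Bereavement reaction",                   0.004,  500, NA,     "30900"),
    c("conduct",              "Conduct disorder",                       0.001,  800, NA,     "31281"),
    c("dissociative",         "Dissociative disorder",                  0.001,  800, NA,     "30015"),
    c("autism",               "Autism spectrum disorder",               0.001, 1500, NA,     "29900"),
    c("intellectual",         "Intellectual disability",                0.003, 1500, NA,     "317"),
    c("tbi_behavior",         "Behavioral disorder after brain injury", 0.004, 2000, NA,     "31002"),
    c("delirium",             "Delirium",                               0.004, 2500, NA,     "2930"),
    c("opioid_use",           "Opioid use disorder",                    0.010, 3000, NA,     "30550"),
    c("cocaine_use",          "Cocaine use disorder",                   0.006, 2500, NA,     "30560"),
    c("cannabis_use",         "Cannabis use disorder",                  0.010, 1000, NA,     "30520"),
    c("gambling",             "Pathological gambling",                  0.001,  800, NA,     "31231"),
    c("psychogenic_pain",     "Psychogenic pain disorder",              0.003,  900, NA,     "30780"),
    c("other_mh",             "Other mental health disorder",           0.007,  700, NA,     "3009"))
  data.frame(category_id = x[, 1], category_name = x[, 2],
             prevalence = as.numeric(x[, 3]), mh_increment = as.numeric(x[, 4]),
             cc = x[, 5], code = x[, 6], stringsAsFactors = FALSE)
}

# general-medical conditions of the synthetic fixture
medical_condition_defaults <- function() {
  data.frame(
    condition = c("diabetes", "diabetes_complicated", "chf", "copd", "renal", "cancer"),
    prevalence = c(0.221, NA, 0.10, 0.12, 0.05, 0.04), # complicated drawn within diabetics
    cc = c("CC19", "CC18", "CC85", "CC108", "CC136", "CC12"),
    code = c("25000", "25040", "4280", "496", "5856", "1749"),
    stringsAsFactors = FALSE)
}

#' Fixture risk model specification
#'
#' A synthetic 10-category model in the published bundle layout: two-level
#' diabetes and psychosis/depression and drug/alcohol hierarchies, four
#' designated mental-health/substance-use categories, sex-by-age demographic
#' cells, and dollar-scale coefficients (so a score approximates an expected
#' annual cost). Institutional coefficients equal community ones: in this
#' fixture custodial long-term-care cost is, by design, not separately
#' priced — that is the miscalibration channel the generator can inject.
#'
#' @param psy_table,medical_table condition tables (defaults as in
#'   [generator_config()]); overriding lets a custom generator keep codes,
#'   model, and code list aligned.
#' @return a `risk_model_spec`.
#' @export
fixture_model_spec <- function(psy_table = psycms_category_defaults(),
                               medical_table = medical_condition_defaults()) {
  med <- medical_table
  psy <- psy_table
  psy <- psy[!is.na(psy$cc), c("code", "cc")]
  icd <- rbind(med[, c("code", "cc")], psy)
  coefs <- data.frame(
    cc = c("CC12", "CC18", "CC19", "CC54", "CC55", "CC57", "CC58",
           "CC85", "CC108", "CC136"),
    community = c(22000, 12000, 6000, 8000, 4000, 10000, 5000,
                  12000, 8000, 20000),
    stringsAsFactors = FALSE)
  coefs$institutional <- coefs$community
  cells <- expand.grid(sex = c("M", "F"),
                       band = 1:6, stringsAsFactors = FALSE)
  lo <- c(0, 45, 55, 65, 75, 85)[cells$band]
  hi <- c(45, 55, 65, 75, 85, 120)[cells$band]
  base <- c(2500, 3200, 4000, 5000, 6500, 8000)[cells$band]
  cells <- data.frame(sex = cells$sex, age_lo = lo, age_hi = hi,
                      community = base + ifelse(cells$sex == "F", 300, 0),
                      stringsAsFactors = FALSE)
  cells$institutional <- cells$community
  risk_model_spec(
    icd_to_cc = icd,
    hierarchies = data.frame(dominant = c("CC18", "CC57", "CC54"),
                             suppressed = c("CC19", "CC58", "CC55"),
                             stringsAsFactors = FALSE),
    demographic_cells = cells,
    cc_coefficients = coefs,
    mh_hccs = c("CC54", "CC55", "CC57", "CC58"),
    scale = "dollar")
}

#' Fixture 47-category psychiatric code list
#'
#' @param psy_table category table (defaults as in [generator_config()]).
#' @return a `psycms_codelist` built from the category table, with the
#'   standard flag definitions (any_mh_sa, ptsd, mood_disorder,
#'   serious_mental_illness, substance_abuse, dementia,
#'   nicotine_dependence).
#' @export
fixture_psycms_codelist <- function(psy_table = psycms_category_defaults()) {
  tab <- psy_table
  psycms_codelist(
    categories = tab[, c("category_id", "category_name")],
    codes = tab[, c("code", "category_id")],
    flag_definitions = list(
      any_mh_sa = tab$category_id,
      ptsd = "ptsd",
      mood_disorder = c("bipolar", "major_depression", "depression_nos",
                        "neurotic_depression"),
      serious_mental_illness = c("schizophrenia", "schizoaffective",
                                 "bipolar", "paranoid", "psychosis_nos"),
      substance_abuse = c("drug_psychosis", "alcohol_psychosis",
                          "drug_dependence", "alcohol_dependence",
                          "alcohol_abuse", "drug_abuse", "opioid_use",
                          "cocaine_use", "cannabis_use"),
      dementia = c("dementia_alzheimers", "dementia_vascular", "dementia_other"),
      nicotine_dependence = "nicotine_dependence"))
}

#' Generator configuration
#'
#' Defaults encode the emulated study conditions: 93.5% male, age
#' 63.0 (SD 16.1), diabetes 22.1%, the 47 psychiatric category prevalences
#' of [psycms_category_defaults()], lognormal noise sigma 1.1 (mean/median
#' cost ratio around 3), latent psychiatric correlation 0.3, a Medicare
#' cost share of zero below age 65 ramping with age above it, dementia-linked
#' long-term-care days, and a ~2% exclusion-flag rate.
#'
#' @param n number of patients (>= 10).
#' @param seed integer RNG seed; everything downstream is deterministic in
#'   (config, seed).
#' @param cost_year analysis year (diagnoses come from the prior year).
#' @param mispricing one of `"NONE"`, `"MH_UNPRICED"`,
#'   `"DEMENTIA_CUSTODIAL"`; see [inject_mispricing()].
#' @param sigma lognormal noise scale.
#' @param rho latent correlation shared by the psychiatric categories.
#' @param prop_male,age_mean,age_sd demographic mix.
#' @param dementia_gamma relative custodial increment under
#'   `DEMENTIA_CUSTODIAL` (0.6 = dementia raises true cost 60%).
#' @param medication_only_rate,no_va_use_rate exclusion-flag rates.
#' @param psy_table psychiatric category table (see
#'   [psycms_category_defaults()]); override to change prevalences or
#'   unpriced increments.
#' @param medical_table general-medical condition table (see the package
#'   source for the default layout).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n = 10000L, seed = 1L, cost_year = 2012L,
                             mispricing = "NONE", sigma = 1.1, rho = 0.3,
                             prop_male = 0.935, age_mean = 63.0, age_sd = 16.1,
                             dementia_gamma = 0.6,
                             medication_only_rate = 0.015,
                             no_va_use_rate = 0.005,
                             psy_table = psycms_category_defaults(),
                             medical_table = medical_condition_defaults()) {
  if (n < 10) stop_rc("n must be at least 10", class = "riskcalib_config_error")
  rates <- c(prop_male, rho, medication_only_rate, no_va_use_rate,
             psy_table$prevalence,
             medical_table$prevalence[!is.na(medical_table$prevalence)])
  if (any(rates < 0 | rates > 1)) {
    stop_rc("proportions must lie in [0, 1]", class = "riskcalib_config_error")
  }
  if (sigma < 0 || age_sd <= 0 || dementia_gamma < 0) {
    stop_rc("sigma, age_sd, dementia_gamma must be non-negative",
            class = "riskcalib_config_error")
  }
  if (!mispricing %in% c("NONE", "MH_UNPRICED", "DEMENTIA_CUSTODIAL")) {
    stop_rc("unknown mispricing mode '%s'", mispricing,
            class = "riskcalib_config_error")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 cost_year = as.integer(cost_year), mispricing = mispricing,
                 sigma = sigma, rho = rho, prop_male = prop_male,
                 age_mean = age_mean, age_sd = age_sd,
                 dementia_gamma = dementia_gamma,
                 medication_only_rate = medication_only_rate,
                 no_va_use_rate = no_va_use_rate,
                 psy_table = psy_table, medical_table = medical_table),
            class = "generator_config")
}

#' Select an under-pricing channel
#'
#' Returns a config identical to the input except for the mispricing mode:
#' `NONE` (costs exactly priced by the risk model), `MH_UNPRICED` (the 43
#' psychiatric categories invisible to the risk model carry real dollar
#' increments), or `DEMENTIA_CUSTODIAL` (dementia multiplies true cost by
#' `1 + dementia_gamma`, unmatched by the institutional coefficients).
#'
#' @param config a `generator_config`.
#' @param mode mispricing mode.
#' @return a `generator_config`.
#' @export
inject_mispricing <- function(config, mode) {
  if (!mode %in% c("NONE", "MH_UNPRICED", "DEMENTIA_CUSTODIAL")) {
    stop_rc("unknown mispricing mode '%s'", mode,
            class = "riskcalib_config_error")
  }
  config$mispricing <- mode
  config
}

#' Generate a synthetic dual-payer cohort with known truth
#'
#' Draws demographics, medical and psychiatric conditions (the psychiatric
#' categories share a latent Gaussian propensity with correlation `rho`),
#' emits diagnosis events in the diagnosis year using the fixture code
#' lists (so scoring and grouping do real mapping work), prices each
#' patient through the fixture risk model, applies the configured unpriced
#' increments, and draws cost as `true_expected * exp(eps)` with
#' `eps ~ N(-sigma^2/2, sigma^2)` (mean-one multiplicative noise). Total
#' cost is split VA/Medicare by an age ramp (share 0 below 65) and Medicare
#' is sub-split into Parts A/B/D.
#'
#' @param config a `generator_config`.
#' @return list with `claims` (the three raw tables, including excluded
#'   patients and out-of-window events), `cohort` (the assembled
#'   `claims_cohort`), `spec`, `codelist`, `truth` (per-patient data frame:
#'   priced component, unpriced component, true expected cost, condition
#'   flags), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  n <- config$n
  dx_year <- config$cost_year - 1L

  patient_id <- sprintf("P%07d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$prop_male, "M", "F")
  age <- pmin(100, pmax(22, round(stats::rnorm(n, config$age_mean, config$age_sd))))

  med <- config$medical_table
  diabetes <- stats::runif(n) < med$prevalence[med$condition == "diabetes"]
  diabetes_comp <- diabetes & stats::runif(n) < 0.3
  chf <- stats::runif(n) < med$prevalence[med$condition == "chf"]
  copd <- stats::runif(n) < med$prevalence[med$condition == "copd"]
  renal <- stats::runif(n) < med$prevalence[med$condition == "renal"]
  cancer <- stats::runif(n) < med$prevalence[med$condition == "cancer"]

  psy <- config$psy_table
  u <- stats::rnorm(n)
  psy_flags <- matrix(FALSE, n, nrow(psy), dimnames = list(NULL, psy$category_id))
  for (j in seq_len(nrow(psy))) {
    z <- sqrt(config$rho) * u + sqrt(1 - config$rho) * stats::rnorm(n)
    psy_flags[, j] <- z < stats::qnorm(psy$prevalence[j])
  }
  dementia <- psy_flags[, "dementia_alzheimers"] |
    psy_flags[, "dementia_vascular"] | psy_flags[, "dementia_other"]
  any_psych <- rowSums(psy_flags) > 0

  p_inst <- ifelse(dementia, 0.4, 0.004)
  inst <- stats::runif(n) < p_inst
  ltc_days <- ifelse(inst, pmin(366L, 91L + stats::rpois(n, 120)),
                     ifelse(stats::runif(n) < 0.03,
                            1L + as.integer(stats::runif(n) * 60), 0L))

  medication_only <- stats::runif(n) < config$medication_only_rate
  any_va_use <- stats::runif(n) >= config$no_va_use_rate

  # diagnosis events: one per condition, a 30% chance of a repeat code, a
  # 30% chance of an unmapped nuisance code, a 5% chance of an event dated
  # in the cost year (outside the diagnosis window)
  ev_id <- list(); ev_code <- list()
  add <- function(who, code) {
    if (length(who)) { ev_id[[length(ev_id) + 1L]] <<- who
                       ev_code[[length(ev_code) + 1L]] <<- rep(code, length(who)) }
  }
  mcode <- function(cond) med$code[med$condition == cond]
  add(patient_id[diabetes], mcode("diabetes"))
  add(patient_id[diabetes_comp], mcode("diabetes_complicated"))
  add(patient_id[chf], mcode("chf"))
  add(patient_id[copd], mcode("copd"))
  add(patient_id[renal], mcode("renal"))
  add(patient_id[cancer], mcode("cancer"))
  for (j in seq_len(nrow(psy))) add(patient_id[psy_flags[, j]], psy$code[j])
  ids <- unlist(ev_id); codes <- unlist(ev_code)
  dup <- stats::runif(length(ids)) < 0.3
  ids <- c(ids, ids[dup]); codes <- c(codes, codes[dup])
  noise <- stats::runif(n) < 0.3
  ids <- c(ids, patient_id[noise])
  codes <- c(codes, sample(c("V700", "7999", "78900"), sum(noise), replace = TRUE))
  dates <- as.Date(sprintf("%d-01-01", dx_year)) +
    as.integer(stats::runif(length(ids)) * 365)
  src_p <- ifelse(age[match(ids, patient_id)] >= 65, 0.25, 0.05)
  source <- ifelse(stats::runif(length(ids)) < src_p, "MEDICARE", "VA")
  oow <- stats::runif(n) < 0.05
  ids <- c(ids, patient_id[oow]); codes <- c(codes, rep("4280", sum(oow)))
  dates <- c(dates, as.Date(sprintf("%d-06-15", config$cost_year)) + integer(sum(oow)))
  source <- c(source, rep("VA", sum(oow)))
  diagnoses <- data.frame(patient_id = ids, code = codes,
                          service_date = dates, source = source,
                          stringsAsFactors = FALSE)
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$code,
                               diagnoses$service_date), , drop = FALSE]
  rownames(diagnoses) <- NULL

  demographics <- data.frame(patient_id = patient_id, age = age, sex = sex,
                             ltc_days = ltc_days,
                             medication_only = medication_only,
                             any_va_use = any_va_use, stringsAsFactors = FALSE)

  # price every patient (including ones later excluded) through the engine
  spec <- fixture_model_spec(psy, med)
  codelist <- fixture_psycms_codelist(psy)
  in_window <- as.integer(format(diagnoses$service_date, "%Y")) == dx_year
  full <- structure(list(patients = demographics,
                         diagnoses = diagnoses[in_window, , drop = FALSE],
                         cost_year = config$cost_year, diagnosis_year = dx_year),
                    class = "claims_cohort")
  priced <- score_cohort(full, spec)$profiles$score

  unpriced <- numeric(n)
  if (config$mispricing == "MH_UNPRICED") {
    unpriced <- unpriced + as.numeric(psy_flags %*% psy$mh_increment)
  }
  if (config$mispricing == "DEMENTIA_CUSTODIAL") {
    unpriced <- unpriced + config$dementia_gamma * priced * dementia
  }
  true_expected <- priced + unpriced
  eps <- if (config$sigma > 0)
    stats::rnorm(n, -config$sigma^2 / 2, config$sigma) else numeric(n)
  total_cents <- pmax(1L, as.integer(round(true_expected * exp(eps) * 100)))

  mc_share <- ifelse(age < 65, 0, pmin(0.65, 0.25 + 0.02 * (age - 65)))
  mc_cents <- as.integer(round(total_cents * mc_share))
  va_cents <- total_cents - mc_cents
  a_cents <- as.integer(round(0.6 * mc_cents))
  b_cents <- as.integer(round(0.3 * mc_cents))
  d_cents <- mc_cents - a_cents - b_cents
  costs <- rbind(
    data.frame(patient_id = patient_id, payer = "VA",
               amount = cents_to_dollars(va_cents), stringsAsFactors = FALSE),
    data.frame(patient_id = patient_id, payer = "MEDICARE_A",
               amount = cents_to_dollars(a_cents), stringsAsFactors = FALSE),
    data.frame(patient_id = patient_id, payer = "MEDICARE_B",
               amount = cents_to_dollars(b_cents), stringsAsFactors = FALSE),
    data.frame(patient_id = patient_id, payer = "MEDICARE_D",
               amount = cents_to_dollars(d_cents), stringsAsFactors = FALSE))
  costs <- costs[costs$amount > 0 | costs$payer == "VA", , drop = FALSE]
  costs$year <- config$cost_year
  costs <- costs[order(costs$patient_id, costs$payer), , drop = FALSE]
  rownames(costs) <- NULL

  claims <- list(diagnoses = diagnoses, costs = costs,
                 demographics = demographics)
  cohort <- assemble_cohort(claims, config$cost_year)

  truth <- data.frame(patient_id = patient_id, age = age, sex = sex,
                      priced = priced, unpriced = unpriced,
                      true_expected = true_expected,
                      total_cost = cents_to_dollars(total_cents),
                      diabetes = diabetes, dementia = dementia,
                      any_psych = any_psych, ltc_days = ltc_days,
                      stringsAsFactors = FALSE)

  list(claims = claims, cohort = cohort, spec = spec, codelist = codelist,
       truth = truth, config = config)
}

#' Write all synthetic artifacts as delimited text
#'
#' Emits the claim tables [write_claims()] reads, the risk-model bundle,
#' the psychiatric code list bundle, and the truth table under `dir`.
#'
#' @param gen result of [generate_cohort()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_synthetic <- function(gen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_claims(gen$claims, file.path(dir, "claims"))
  write_model_spec(gen$spec, file.path(dir, "model_spec"))
  write_psycms_codelist(gen$codelist, file.path(dir, "psycms"))
  utils::write.csv(gen$truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
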