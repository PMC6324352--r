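# Small in-code fixtures shared across test files.

# 6-category model with a two-level cascade (A suppresses B, B suppresses C)
# plus an unrelated pair (D suppresses E); F is free-standing.
tiny_spec <- function(hierarchies = NULL) {
  if (is.null(hierarchies)) {
    hierarchies <- data.frame(dominant = c("A", "B", "D"),
                              suppressed = c("B", "C", "E"),
                              stringsAsFactors = FALSE)
  }
  risk_model_spec(
    icd_to_cc = data.frame(
      code = c("1000", "2000", "3000", "4000", "5000", "6000", "6001"),
      cc = c("A", "B", "C", "D", "E", "F", "F"),
      stringsAsFactors = FALSE),
    hierarchies = hierarchies,
    demographic_cells = data.frame(
      sex = c("M", "M", "F", "F"),
      age_lo = c(0, 60, 0, 60), age_hi = c(60, 120, 60, 120),
      community = c(0.30, 0.40, 0.32, 0.45),
      institutional = c(1.00, 1.10, 1.02, 1.15),
      stringsAsFactors = FALSE),
    cc_coefficients = data.frame(
      cc = c("A", "B", "C", "D", "E", "F"),
      community = c(0.90, 0.30, 0.25, 0.50, 0.20, 0.15),
      institutional = c(0.80, 0.28, 0.22, 0.45, 0.18, 0.12),
      stringsAsFactors = FALSE),
    mh_hccs = c("D", "E"),
    scale = "relative")
}

# independent brute-force hierarchy applier, by the recursive definition:
# an input category survives iff no rule suppresses it whose dominant
# category itself survives (well-founded because the rule graph is acyclic)
brute_force_hierarchy <- function(ccs, rules) {
  survives <- function(x) {
    if (!x %in% ccs) return(FALSE)
    doms <- rules$dominant[rules$suppressed == x]
    !any(vapply(doms, survives, logical(1)))
  }
  sort(ccs[vapply(ccs, survives, logical(1))])
}

all_subsets <- function(x) {
  unlist(lapply(0:length(x), function(k) {
    if (k == 0) return(list(character(0)))
    asplit(utils::combn(x, k), 2)
  }), recursive = FALSE)
}

# minimal three-table claims fixture written to a temp dir; returns paths
write_tiny_claims <- function(dir,
                              dx_lines = c("patient_id,code,service_date,source",
                                           "P1,296.1,2011-03-02,VA"),
                              cost_lines = c("patient_id,payer,amount,year",
                                             "P1,VA,100,2012"),
                              demo_lines = c("patient_id,age,sex,ltc_days,medication_only,any_va_use",
                                             "P1,55,M,0,FALSE,TRUE")) {
  paths <- file.path(dir, c("dx.csv", "cost.csv", "demo.csv"))
  writeLines(dx_lines, paths[1])
  writeLines(cost_lines, paths[2])
  writeLines(demo_lines, paths[3])
  paths
}

# rebuild raw claim tables from an assembled cohort (used to check that
# re-assembly is the identity on an already-assembled cohort)
claims_from_cohort <- function(cohort) {
  p <- cohort_patients(cohort)
  costs <- rbind(
    data.frame(patient_id = p$patient_id, payer = "VA", amount = p$va_cost,
               year = cohort$cost_year, stringsAsFactors = FALSE),
    data.frame(patient_id = p$patient_id, payer = "MEDICARE_A",
               amount = p$medicare_cost, year = cohort$cost_year,
               stringsAsFactors = FALSE))
  list(diagnoses = cohort$diagnoses, costs = costs,
       demographics = p[, c("patient_id", "age", "sex", "ltc_days",
                            "medication_only", "any_va_use")])
}

# small cached synthetic run shared by several test files
shared_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(generator_config(n = 4000, seed = 42,
                                                 mispricing = "MH_UNPRICED"))
    }
    cache
  }
})
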