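test_that("model spec bundles round-trip through disk with validation", {
  spec <- tiny_spec()
  d <- withr::local_tempdir()
  write_model_spec(spec, d)
  spec2 <- load_model_spec(d)
  expect_equal(spec2$cc_coefficients, spec$cc_coefficients)
  expect_equal(spec2$mh_hccs, spec$mh_hccs)
  expect_equal(spec2$scale, "relative")
  expect_equal(nrow(spec2$icd_to_cc), nrow(spec$icd_to_cc))
})

test_that("spec validation names unknown categories and cycles", {
  expect_error(
    risk_model_spec(
      icd_to_cc = data.frame(code = "1000", cc = "A"),
      hierarchies = data.frame(dominant = "A", suppressed = "CC99"),
      demographic_cells = data.frame(sex = "M", age_lo = 0, age_hi = 120,
                                     community = 1, institutional = 1),
      cc_coefficients = data.frame(cc = "A", community = 1, institutional = 1),
      mh_hccs = character()),
    "CC99", class = "riskcalib_spec_error")
  expect_error(
    tiny_spec(hierarchies = data.frame(dominant = c("A", "B"),
                                       suppressed = c("B", "A"))),
    "cycle", class = "riskcalib_spec_error")
  expect_error(
    risk_model_spec(
      icd_to_cc = data.frame(code = "1000", cc = "A"),
      hierarchies = data.frame(dominant = character(), suppressed = character()),
      demographic_cells = data.frame(sex = c("M", "M"), age_lo = c(0, 50),
                                     age_hi = c(60, 120),
                                     community = c(1, 2), institutional = c(1, 2)),
      cc_coefficients = data.frame(cc = "A", community = 1, institutional = 1),
      mh_hccs = "A"),
    "overlap", class = "riskcalib_spec_error")
})

test_that("diagnosis mapping has set semantics and counts unmapped codes", {
  spec <- tiny_spec()
  expect_equal(map_diagnoses(character(), spec)$ccs, character())
  m <- map_diagnoses(c("6000", "6001"), spec)  # two codes, same category
  expect_equal(m$ccs, "F")
  m2 <- map_diagnoses(c("1000", "2000", "9999"), spec)
  expect_equal(m2$ccs, c("A", "B"))
  expect_equal(m2$n_unmapped, 1L)
})

test_that("a suppressed category no longer suppresses its own subordinates", {
  spec <- tiny_spec()  # rules A>B, B>C, D>E
  expect_equal(impose_hierarchies(character(), spec), character())
  expect_equal(impose_hierarchies(c("A", "B"), spec), "A")
  # cascade case: A removes B; the suppressed B leaves C alone
  expect_equal(impose_hierarchies(c("A", "B", "C"), spec), c("A", "C"))
  expect_equal(impose_hierarchies(c("B", "C"), spec), "B")
})

test_that("hierarchy imposition matches a brute-force applier on every subset", {
  spec <- tiny_spec()
  for (s in all_subsets(c("A", "B", "C", "D", "E", "F"))) {
    got <- impose_hierarchies(s, spec)
    expect_equal(got, brute_force_hierarchy(s, spec$hierarchies))
    expect_true(all(got %in% s))                      # subset of input
    expect_equal(impose_hierarchies(got, spec), got)  # fixed point
  }
})

test_that("demographic lookup uses half-open (lo, hi] bands and errors off-grid", {
  spec <- tiny_spec()
  expect_equal(demographic_coefficient(65, "M", "COMMUNITY", spec), 0.40)
  expect_equal(demographic_coefficient(60, "M", "COMMUNITY", spec), 0.30)  # upper edge -> lower band
  expect_equal(demographic_coefficient(60, "M", "INSTITUTIONAL", spec), 1.00)
  expect_error(demographic_coefficient(150, "M", "COMMUNITY", spec),
               class = "riskcalib_no_band_error")
  no_f <- tiny_spec()
  no_f$demographic_cells <- no_f$demographic_cells[no_f$demographic_cells$sex == "M", ]
  expect_error(demographic_coefficient(40, "F", "COMMUNITY", no_f),
               class = "riskcalib_no_band_error")
})

test_that("risk scores are additive in demographic and category coefficients", {
  spec <- tiny_spec()
  r <- compute_risk_score(list(patient_id = "P1", age = 65, sex = "M",
                               ltc_days = 0, codes = character()), spec)
  expect_equal(r$score, 0.40)  # empty-sum case: demographic alone
  r2 <- compute_risk_score(list(patient_id = "P2", age = 65, sex = "M",
                                ltc_days = 0, codes = c("2000", "3000")), spec)
  expect_equal(r2$hccs, "B")  # B suppresses C
  expect_equal(r2$score, 0.40 + 0.30)
  # removing an HCC reduces the score by exactly its coefficient
  r3 <- compute_risk_score(list(patient_id = "P3", age = 65, sex = "M",
                                ltc_days = 0, codes = c("2000", "6000")), spec)
  expect_equal(r3$score - r2$score, 0.15)  # F's coefficient
})

test_that("the 90-day rule is strict and switches coefficient tables", {
  spec <- tiny_spec()
  mk <- function(ltc) compute_risk_score(
    list(patient_id = "P", age = 65, sex = "M", ltc_days = ltc,
         codes = "1000"), spec)
  expect_equal(mk(90)$variant, "COMMUNITY")
  expect_equal(mk(91)$variant, "INSTITUTIONAL")
  expect_equal(mk(90)$score, 0.40 + 0.90)
  expect_equal(mk(91)$score, 1.10 + 0.80)
})

test_that("MH/SA detection intersects post-hierarchy categories", {
  spec <- tiny_spec()  # mh_hccs = {D, E}
  mk <- function(codes) compute_risk_score(
    list(patient_id = "P", age = 40, sex = "F", ltc_days = 0, codes = codes), spec)
  expect_true(has_mh_hcc(mk("4000"), spec))
  expect_false(has_mh_hcc(mk(character()), spec))
  expect_false(has_mh_hcc(mk("1000"), spec))
  # E is suppressed by D, but D itself is MH, so still TRUE
  expect_true(has_mh_hcc(mk(c("4000", "5000")), spec))
})

test_that("adding a diagnosis never shrinks the pre-hierarchy category set", {
  spec <- tiny_spec()
  codes <- c("1000", "2000", "3000", "4000", "5000", "6000", "9999")
  set.seed(7)
  for (i in 1:20) {
    base <- sample(codes, sample(0:5, 1))
    extra <- sample(codes, 1)
    a <- map_diagnoses(base, spec)$ccs
    b <- map_diagnoses(c(base, extra), spec)$ccs
    expect_true(all(a %in% b))
  }
})

test_that("vectorized cohort scoring agrees with per-record scoring", {
  gen <- shared_gen()
  co <- gen$cohort
  prof <- score_cohort(co, gen$spec)
  expect_equal(prof$profiles$patient_id, co$patients$patient_id)
  idx <- seq(1, nrow(co$patients), length.out = 25)
  for (i in as.integer(idx)) {
    p <- co$patients[i, ]
    codes <- co$diagnoses$code[co$diagnoses$patient_id == p$patient_id]
    r <- compute_risk_score(list(patient_id = p$patient_id, age = p$age,
                                 sex = p$sex, ltc_days = p$ltc_days,
                                 codes = codes), gen$spec)
    expect_equal(prof$profiles$score[i], r$score)
    expect_equal(prof$profiles$variant[i], r$variant)
    expect_equal(sort(prof$hccs$cc[prof$hccs$patient_id == p$patient_id]),
                 r$hccs)
    expect_equal(has_mh_hcc(r, gen$spec), prof$profiles$has_mh_hcc[i])
  }
})
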