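test_that("claims parsing normalizes codes and collects row-level errors", {
  d <- withr::local_tempdir()
  paths <- write_tiny_claims(
    d,
    dx_lines = c("patient_id,code,service_date,source",
                 "P1,2961,2011-03-02,VA",
                 "P1,296.1,2011-04-05,MEDICARE",
                 "P2,4280,not-a-date,VA"),
    cost_lines = c("patient_id,payer,amount,year",
                   "P1,VA,100.25,2012",
                   "P1,MEDICARE_A,-5,2012",
                   "P2,VA,abc,2012"),
    demo_lines = c("patient_id,age,sex,ltc_days,medication_only,any_va_use",
                   "P1,55,M,0,FALSE,TRUE",
                   "P2,70,F,0,FALSE,TRUE"))
  cl <- read_claims(paths[1], paths[2], paths[3])
  expect_equal(cl$diagnoses$code, c("2961", "2961"))
  expect_s3_class(cl$diagnoses$service_date, "Date")
  expect_equal(nrow(cl$costs), 1L)
  expect_equal(cl$costs$amount, 100.25)
  expect_equal(cl$report$n_rejected, 3L)
  expect_true(any(grepl("negative amount", cl$report$errors$message)))
  expect_true(any(grepl("unparseable date", cl$report$errors$message)))
})

test_that("a missing column is a schema error naming the column", {
  d <- withr::local_tempdir()
  paths <- write_tiny_claims(d)
  writeLines(c("patient_id,code,source", "P1,2961,VA"), paths[1])
  expect_error(read_claims(paths[1], paths[2], paths[3]),
               "service_date", class = "riskcalib_schema_error")
})

test_that("cohort assembly applies exclusions, the diagnosis window, and exact cost sums", {
  d <- withr::local_tempdir()
  paths <- write_tiny_claims(
    d,
    dx_lines = c("patient_id,code,service_date,source",
                 "P1,2961,2011-03-02,VA",
                 "P1,4280,2012-03-02,VA",   # cost-year dated: outside window
                 "P3,3051,2011-07-01,VA"),
    cost_lines = c("patient_id,payer,amount,year",
                   "P1,VA,8547,2012",
                   "P1,MEDICARE_A,2000,2012",
                   "P1,MEDICARE_B,1579,2012",
                   "P1,VA,999,2011",          # wrong year: ignored
                   "P2,VA,50,2012",
                   "P3,VA,70,2012"),
    demo_lines = c("patient_id,age,sex,ltc_days,medication_only,any_va_use",
                   "P1,55,M,0,FALSE,TRUE",
                   "P2,60,M,0,TRUE,TRUE",     # medication only -> excluded
                   "P3,64,F,0,FALSE,TRUE"))
  cl <- read_claims(paths[1], paths[2], paths[3])
  co <- assemble_cohort(cl, 2012)
  expect_s3_class(co, "claims_cohort")
  expect_setequal(co$patients$patient_id, c("P1", "P3"))
  expect_equal(unname(co$exclusions["medication_only"]), 1L)
  p1 <- cohort_patients(co)
  p1 <- p1[p1$patient_id == "P1", ]
  expect_identical(p1$va_cost, 8547)
  expect_identical(p1$medicare_cost, 3579)
  expect_identical(p1$total_cost, 12126)
  # only the prior-year diagnosis is attached
  expect_equal(co$diagnoses$code[co$diagnoses$patient_id == "P1"], "2961")
})

test_that("excluding everyone raises an empty-cohort error", {
  d <- withr::local_tempdir()
  paths <- write_tiny_claims(
    d, demo_lines = c("patient_id,age,sex,ltc_days,medication_only,any_va_use",
                      "P1,55,M,0,TRUE,TRUE"))
  cl <- read_claims(paths[1], paths[2], paths[3])
  expect_error(assemble_cohort(cl, 2012), class = "riskcalib_empty_cohort")
})

test_that("cost additivity is exact and re-assembly is the identity", {
  gen <- shared_gen()
  co <- gen$cohort
  expect_identical(co$patients$total_cents,
                   co$patients$va_cents + co$patients$medicare_cents)
  co2 <- assemble_cohort(claims_from_cohort(co), co$cost_year)
  expect_equal(cohort_patients(co2)[names(cohort_patients(co))],
               cohort_patients(co))
  expect_equal(nrow(co2$diagnoses), nrow(co$diagnoses))
})

test_that("descriptive summary percentages and strata are consistent", {
  gen <- shared_gen()
  co <- gen$cohort
  psy <- classify_cohort(co, gen$codelist)
  tab <- summarize_cohort(co, flags = list(any_mh = psy$flags$any_mh_sa))
  counts <- tab[tab$statistic == "count", ]
  expect_equal(counts$overall, counts$ge65 + counts$lt65)
  mh <- tab[tab$characteristic == "any_mh" & tab$statistic == "pct", ]
  mh_n <- tab[tab$characteristic == "any_mh" & tab$statistic == "count", ]
  n <- tab[tab$characteristic == "n", ]
  expect_equal(mh$overall, prevalence_pct(mh_n$overall, n$overall))
  expect_equal(mh$ge65, prevalence_pct(mh_n$ge65, n$ge65))
})

test_that("degenerate constant costs give mean = median and zero IQR width", {
  d <- withr::local_tempdir()
  paths <- write_tiny_claims(
    d,
    dx_lines = c("patient_id,code,service_date,source"),
    cost_lines = c("patient_id,payer,amount,year",
                   "P1,VA,500,2012", "P2,VA,500,2012", "P3,VA,500,2012"),
    demo_lines = c("patient_id,age,sex,ltc_days,medication_only,any_va_use",
                   "P1,55,M,0,FALSE,TRUE", "P2,60,M,0,FALSE,TRUE",
                   "P3,64,F,0,FALSE,TRUE"))
  cl <- read_claims(paths[1], paths[2], paths[3])
  tab <- summarize_cohort(assemble_cohort(cl, 2012))
  tc <- tab[tab$characteristic == "total_cost", ]
  expect_equal(tc$overall[tc$statistic == "mean"], 500)
  expect_equal(tc$overall[tc$statistic == "median"], 500)
  expect_equal(tc$overall[tc$statistic == "q3"] - tc$overall[tc$statistic == "q1"], 0)
})

test_that("prevalence percentages round half away from zero to one decimal", {
  expect_identical(prevalence_pct(694706, 5472629), 12.7)
  expect_identical(prevalence_pct(41275, 5472629), 0.8)
  expect_identical(round_half_away(0.25, 1), 0.3)
  expect_identical(round_half_away(-0.25, 1), -0.3)
  expect_identical(round_half_away(-104.5), -105)
})
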