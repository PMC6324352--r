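test_that("the code list enforces exactly 47 categories and known references", {
  cl <- fixture_psycms_codelist()
  expect_s3_class(cl, "psycms_codelist")
  expect_equal(nrow(cl$categories), 47L)
  short <- psycms_category_defaults()[1:46, ]
  expect_error(
    psycms_codelist(short[, c("category_id", "category_name")],
                    short[, c("code", "category_id")],
                    list(any = short$category_id)),
    "47", class = "riskcalib_spec_error")
  tab <- psycms_category_defaults()
  expect_error(
    psycms_codelist(tab[, c("category_id", "category_name")],
                    tab[, c("code", "category_id")],
                    list(bad = "no_such_category")),
    "no_such_category", class = "riskcalib_spec_error")
})

test_that("code list bundles round-trip through disk", {
  cl <- fixture_psycms_codelist()
  d <- withr::local_tempdir()
  write_psycms_codelist(cl, d)
  cl2 <- load_psycms_codelist(d)
  expect_equal(cl2$categories, cl$categories)
  expect_equal(cl2$flag_definitions, cl$flag_definitions)
  expect_equal(cl2$codes[order(cl2$codes$code), ],
               cl$codes[order(cl$codes$code), ], ignore_attr = TRUE)
})

test_that("classification unions categories and derives flags", {
  cl <- fixture_psycms_codelist()
  p0 <- classify(character(), cl)
  expect_equal(p0$categories, character())
  expect_false(any(p0$flags))
  p1 <- classify("30981", cl)  # PTSD
  expect_equal(p1$categories, "ptsd")
  expect_true(p1$flags[["ptsd"]])
  expect_true(p1$flags[["any_mh_sa"]])
  expect_false(p1$flags[["mood_disorder"]])
  p2 <- classify(c("29640", "3051", "296.40"), cl)  # bipolar (dotted + undotted) + nicotine
  expect_equal(p2$categories, c("bipolar", "nicotine_dependence"))
  expect_true(p2$flags[["mood_disorder"]])
  expect_true(p2$flags[["nicotine_dependence"]])
  expect_true(p2$flags[["serious_mental_illness"]])
})

test_that("classification is permutation-invariant in the diagnosis list", {
  cl <- fixture_psycms_codelist()
  codes <- c("30981", "311", "3051", "9999", "29620")
  set.seed(11)
  base <- classify(codes, cl)
  for (i in 1:5) {
    expect_equal(classify(sample(codes), cl), base)
  }
})

test_that("missed-diagnosis analysis defines the missed set and percentages correctly", {
  gen <- shared_gen()
  hcc <- score_cohort(gen$cohort, gen$spec)
  psy <- classify_cohort(gen$cohort, gen$codelist)
  tab <- missed_mh_analysis(hcc, psy, gen$codelist, top_n = 10)
  expect_equal(tab$denominator,
               sum(psy$flags$any_mh_sa & !hcc$profiles$has_mh_hcc))
  expect_lte(nrow(tab$rows), 10L)
  expect_true(all(diff(tab$rows$count) <= 0))
  expect_true(all(tab$rows$count <= tab$denominator))
  # percent column recomputable exactly under half-away-from-zero rounding
  expect_equal(tab$rows$pct,
               round_half_away(100 * tab$rows$count / tab$denominator, 1))
  # partition: {any PsyCMS} = {MH HCC & PsyCMS} + {missed}, disjointly
  n_any <- sum(psy$flags$any_mh_sa)
  n_both <- sum(psy$flags$any_mh_sa & hcc$profiles$has_mh_hcc)
  expect_equal(n_both + tab$denominator, n_any)
  # none of the four model-priced groups can appear among missed patients'
  # model-visible categories: every missed patient lacks MH HCCs
  missed_ids <- psy$flags$patient_id[psy$flags$any_mh_sa & !hcc$profiles$has_mh_hcc]
  mh_cc <- hcc$hccs[hcc$hccs$cc %in% gen$spec$mh_hccs, ]
  expect_length(intersect(missed_ids, mh_cc$patient_id), 0)
})

test_that("an empty missed set yields an empty table, not an error", {
  cl <- fixture_psycms_codelist()
  flags <- data.frame(patient_id = c("P1", "P2"), any_mh_sa = c(TRUE, FALSE))
  psy <- structure(list(flags = flags,
                        categories = data.frame(patient_id = "P1",
                                                category_id = "ptsd")),
                   class = "psycms_profiles")
  hcc <- structure(list(profiles = data.frame(patient_id = c("P1", "P2"),
                                              has_mh_hcc = c(TRUE, FALSE)),
                        hccs = data.frame(patient_id = "P1", cc = "CC57")),
                   class = "hcc_profiles")
  tab <- missed_mh_analysis(hcc, psy, cl)
  expect_equal(tab$denominator, 0L)
  expect_equal(nrow(tab$rows), 0L)
})

test_that("missed-table ties rank alphabetically by category name", {
  cl <- fixture_psycms_codelist()
  flags <- data.frame(patient_id = c("P1", "P2"),
                      any_mh_sa = c(TRUE, TRUE))
  cats <- data.frame(patient_id = c("P1", "P1", "P2", "P2"),
                     category_id = c("ptsd", "anxiety", "ptsd", "anxiety"))
  psy <- structure(list(flags = flags, categories = cats),
                   class = "psycms_profiles")
  hcc <- structure(list(profiles = data.frame(patient_id = c("P1", "P2"),
                                              has_mh_hcc = c(FALSE, FALSE)),
                        hccs = data.frame(patient_id = character(),
                                          cc = character())),
                   class = "hcc_profiles")
  tab <- missed_mh_analysis(hcc, psy, cl)
  # equal counts: "Anxiety, not otherwise specified" precedes "Posttraumatic..."
  expect_equal(tab$rows$category_id, c("anxiety", "ptsd"))
  expect_equal(tab$rows$pct, c(100, 100))
})
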