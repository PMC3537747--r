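test_that("cohort generation honours counts, uniqueness, and the date window", {
  cohort <- generate_cohort(100, 1)
  expect_equal(nrow(cohort$subjects), 100L)
  expect_gte(nrow(cohort$tests), 100L)
  expect_false(anyDuplicated(cohort$subjects$mrn) > 0)
  expect_true(all(grepl("^[0-9]{8}$", cohort$subjects$mrn)))

  params <- cohort$params
  expect_true(all(cohort$tests$exam_date >= params$date_start))
  expect_true(all(cohort$tests$exam_date <= params$date_end))
  expect_true(all(cohort$subjects$consent_date >= params$date_start))
  expect_true(all(cohort$subjects$consent_date <= params$date_end))

  # each subject has >= 1 test with distinct exam dates
  per <- split(cohort$tests$exam_date, cohort$tests$subject_id)
  expect_true(all(vapply(per, length, integer(1)) >= 1L))
  expect_true(all(vapply(per, anyDuplicated, integer(1)) == 0L))
})

test_that("generation is deterministic and the empty cohort degenerates cleanly", {
  a <- generate_cohort(25, 9)
  b <- generate_cohort(25, 9)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$tests, b$tests)

  z <- generate_cohort(0, 1)
  expect_equal(nrow(z$subjects), 0L)
  expect_equal(nrow(z$tests), 0L)
})

test_that("ground-truth values respect the configured physiologic ranges", {
  cohort <- generate_cohort(40, 3)
  tt <- cohort$tests
  in_range <- function(x, lo, hi) all(is.na(x) | (x >= lo & x <= hi))
  expect_true(in_range(tt$fvc_l, 1.0, 5.5))
  expect_true(in_range(tt$tlc_l, 2.5, 8.0))
  expect_true(in_range(tt$dlco, 4, 40))
  expect_true(in_range(tt$fvc_pct_pred, 25, 130))
  expect_true(in_range(tt$tlc_pct_pred, 25, 130))
  expect_true(in_range(tt$spo2_rest_pct, 88, 100))
  expect_true(all(tt$gender %in% c("F", "M")))

  # a range override is honoured
  narrow <- generate_cohort(10, 3, cohort_params(ranges = list(fvc_l = c(2, 2.5))))
  expect_true(in_range(narrow$tests$fvc_l, 2, 2.5))
})

test_that("invalid generator settings are rejected", {
  expect_error(cohort_params(p_lung_volume = 1.2), "\\[0, 1\\]")
  expect_error(cohort_params(tests_min = 0), "tests_min")
  expect_error(cohort_params(ranges = list(fvc_l = c(5, 1))), "fvc_l")
  expect_error(cohort_params(ranges = list(fvc_l = c(-1, 2))), "fvc_l")
})

test_that("rendered reports carry exactly the administered sections", {
  cohort <- generate_cohort(1, 5)
  truth <- cohort$tests[1, ]

  full <- render_report(truth, include_lung_volume = TRUE, include_diffusion = TRUE)
  for (s in c("SPIROMETRY", "LUNG VOLUMES", "DIFFUSION", "PULSE OXIMETRY", "NOTES")) {
    expect_match(full, paste0("\n", s, "\n"), fixed = TRUE)
  }
  expect_match(full, "^PULMONARY FUNCTION TEST REPORT\n")

  no_diff <- render_report(truth, include_diffusion = FALSE)
  expect_no_match(no_diff, "DIFFUSION")
  no_lv <- render_report(truth, include_lung_volume = FALSE, include_diffusion = FALSE)
  expect_no_match(no_lv, "LUNG VOLUMES")

  # byte-identical re-render
  expect_identical(render_report(truth), render_report(truth))
})

test_that("extraction of rendered reports recovers ground truth exactly (round trip)", {
  rs <- default_ruleset()
  ft <- regexmart:::pft_field_table()
  for (seed in 1:3) {
    cohort <- generate_cohort(8, seed)
    docs <- render_cohort(cohort)
    for (i in seq_len(nrow(docs))) {
      res <- apply_ruleset(rs, docs$text[i])
      bad <- roundtrip_mismatches(cohort$tests[i, ], res, ft)
      expect_identical(bad, character(0),
                       label = sprintf("seed %d, doc %s", seed, docs$doc_id[i]))
    }
  }
})

test_that("manual-entry simulation corrupts exactly the planned cells", {
  cohort <- generate_cohort(100, 106)
  truth <- validation_truth(cohort)

  # empty plan: identity
  expect_identical(simulate_manual_entry(truth, error_plan()), truth)

  # shipped plan: exactly six differing cells with the right kinds
  manual <- simulate_manual_entry(truth, paper_error_plan())
  diffs <- 0L
  for (f in validation_fields()) {
    diffs <- diffs + sum(
      xor(is.na(truth[[f]]), is.na(manual[[f]])) |
        (!is.na(truth[[f]]) & !is.na(manual[[f]]) &
           as.character(truth[[f]]) != as.character(manual[[f]])))
  }
  expect_equal(diffs, 6L)
  expect_identical(manual$subject_id, truth$subject_id)

  plan <- paper_error_plan()
  for (i in seq_len(nrow(plan))) {
    expect_false(identical(manual[[plan$field[i]]][plan$subject[i]],
                           truth[[plan$field[i]]][plan$subject[i]]))
  }
  # date shifts stay within +/- 30 days and are nonzero
  for (i in which(plan$kind == "date_shift")) {
    shift <- as.numeric(manual$exam_date[plan$subject[i]] - truth$exam_date[plan$subject[i]])
    expect_true(abs(shift) >= 1 && abs(shift) <= 30)
  }
  # gender swap flips the code
  gi <- plan$subject[plan$kind == "category_swap"]
  expect_setequal(c(truth$gender[gi], manual$gender[gi]), c("M", "F"))

  # Hamming distance equals plan size for an arbitrary plan
  p3 <- error_plan(subject = c(1L, 2L, 2L), field = c("weight", "fvc_l", "mrn"),
                   kind = c("value_typo", "value_typo", "digit_typo"), seed = 5L)
  m3 <- simulate_manual_entry(truth, p3)
  d3 <- 0L
  for (f in validation_fields()) {
    d3 <- d3 + sum(!is.na(truth[[f]]) &
                     as.character(truth[[f]]) != as.character(m3[[f]]))
  }
  expect_equal(d3, 3L)
})

test_that("error plans reject duplicate or unreachable cells", {
  expect_error(
    error_plan(subject = c(1L, 1L), field = c("mrn", "mrn"),
               kind = c("digit_typo", "digit_typo")),
    "distinct")
  cohort <- generate_cohort(2, 1)
  truth <- validation_truth(cohort)
  expect_error(
    simulate_manual_entry(truth, error_plan(99L, "mrn", "digit_typo")),
    "missing cell")
})
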