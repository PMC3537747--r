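test_that("rule configurations load with order, counts, and schema intact", {
  rs <- load_ruleset(text = tiny_ruleset_text())
  expect_s3_class(rs, "pft_ruleset")
  expect_length(rs$rules, 2L)
  expect_equal(nrow(rs$schema), 3L)
  expect_equal(vapply(rs$rules, `[[`, "", "rule_id"), c("fvc", "ident"))
  expect_false(rs$rules[[1]]$required)

  fs <- field_summary(rs)
  expect_equal(fs$total, 3L)
  expect_equal(fs$numeric, 2L)
  expect_equal(unname(fs$by_category[c("spirometry", "patient_meta")]), c(2L, 1L))
})

test_that("structural defects in a configuration are rejected with names", {
  dup <- paste(tiny_ruleset_text(),
    "[rule again]",
    "pattern = ^AGAIN\\s+(?<fvc_l>\\d+\\.\\d+)$",
    "bind fvc_l -> fvc_l : decimal",
    sep = "\n")
  expect_error(load_ruleset(text = dup), "fvc_l")

  undeclared <- paste(
    "[fields]", "fvc_l, spirometry, decimal, L",
    "[rule r1]",
    "pattern = ^X (?<ghost>\\d+)$",
    "bind ghost -> ghost_field : integer", sep = "\n")
  expect_error(load_ruleset(text = undeclared), "ghost_field")

  malformed <- paste(
    "[fields]", "fvc_l, spirometry, decimal, L",
    "[rule broken]",
    "pattern = ^X (?<fvc_l>[\\d+$",
    "bind fvc_l -> fvc_l : decimal", sep = "\n")
  expect_error(load_ruleset(text = malformed), "broken")

  mismatch <- paste(
    "[fields]", "fvc_l, spirometry, decimal, L",
    "[rule r1]",
    "pattern = ^X (?<a>\\d+) (?<b>\\d+)$",
    "bind a -> fvc_l : decimal", sep = "\n")
  expect_error(load_ruleset(text = mismatch), "\\bb\\b")

  # numeric value kinds only in physiologic categories
  offcat <- paste(
    "[fields]", "oddball, patient_meta, decimal, L", sep = "\n")
  expect_error(load_ruleset(text = offcat), "oddball")

  unbound <- paste(
    "[fields]", "fvc_l, spirometry, decimal, L", "tlc_l, lung_volume, decimal, L",
    "[rule r1]",
    "pattern = ^X (?<fvc_l>\\d+\\.\\d+)$",
    "bind fvc_l -> fvc_l : decimal", sep = "\n")
  expect_warning(load_ruleset(text = unbound), "tlc_l")
  issues <- suppressWarnings(lint_ruleset(text = unbound))
  expect_gt(nrow(issues), 0L)
  expect_match(issues$message, "tlc_l", all = FALSE)
})

test_that("rules extract typed values from matching lines", {
  rs <- load_ruleset(text = tiny_ruleset_text())
  res <- apply_ruleset(rs, "MRN: 12345678\nFVC        2.51      64\n")
  expect_identical(res$values$fvc_l, 2.51)
  expect_identical(res$values$fvc_pct_pred, 64)
  expect_identical(res$values$mrn, "12345678")
  expect_equal(unname(res$rule_status), c("matched", "matched"))
  # provenance points at the matched spans
  doc <- "MRN: 12345678\nFVC        2.51      64\n"
  p <- res$provenance$fvc_l
  expect_identical(substr(doc, p["start"], p["end"]), "2.51")
})

test_that("optional rules tolerate absent content; required rules do not", {
  rs <- load_ruleset(text = tiny_ruleset_text())
  res <- apply_ruleset(rs, "")
  expect_true(all(vapply(res$values, function(v) is.na(v)[1], logical(1))))
  expect_true(all(res$rule_status == "absent"))

  required <- sub("bind mrn -> mrn : text",
                  "bind mrn -> mrn : text\nrequired = true",
                  tiny_ruleset_text(), fixed = TRUE)
  rs2 <- load_ruleset(text = required)
  expect_error(apply_ruleset(rs2, "FVC  2.51  64"),
               class = "pft_extraction_error", regexp = "ident")
})

test_that("first match in document order wins", {
  rs <- load_ruleset(text = tiny_ruleset_text())
  res <- apply_ruleset(rs, "FVC  1.11  50\nFVC  2.22  60\n")
  expect_identical(res$values$fvc_l, 1.11)
})

test_that("conversion failures demote the rule's fields to MISSING with a warning", {
  txt <- paste(
    "[fields]", "fvc_l, spirometry, decimal, L", "fvc_pct_pred, spirometry, integer, %",
    "[rule fvc]",
    "pattern = ^FVC\\s+(?<fvc_l>\\S+)\\s+(?<fvc_pct_pred>\\S+)$",
    "bind fvc_l -> fvc_l : decimal",
    "bind fvc_pct_pred -> fvc_pct_pred : integer", sep = "\n")
  rs <- load_ruleset(text = txt)
  expect_warning(res <- apply_ruleset(rs, "FVC  n/a  64"), "conversion")
  expect_true(is.na(res$values$fvc_l))
  expect_true(is.na(res$values$fvc_pct_pred))
  expect_equal(unname(res$rule_status), "conversion_error")
})

test_that("extraction is deterministic and respects the MISSING partition", {
  cohort <- generate_cohort(3, 7)
  docs <- render_cohort(cohort)
  rs <- default_ruleset()
  for (i in seq_len(nrow(docs))) {
    r1 <- apply_ruleset(rs, docs$text[i])
    r2 <- apply_ruleset(rs, docs$text[i])
    expect_identical(r1, r2)
    n_missing <- sum(vapply(r1$values, function(v) is.na(v)[1], logical(1)))
    expect_equal(length(r1$values), 107L)
    expect_equal((107L - n_missing) + n_missing, 107L)
  }
})

test_that("a report without a section leaves exactly that section MISSING", {
  cohort <- generate_cohort(1, 11)
  truth <- cohort$tests[1, ]
  doc <- render_report(truth, include_lung_volume = TRUE, include_diffusion = FALSE)
  res <- apply_ruleset(default_ruleset(), doc)
  schema <- pft_schema()
  dlco_fields <- schema$name[schema$category == "dlco"]
  spiro_fields <- schema$name[schema$category == "spirometry"]
  expect_true(all(vapply(res$values[dlco_fields], is.na, logical(1))))
  expect_false(any(vapply(res$values[spiro_fields], is.na, logical(1))))
})

test_that("deleting a section's lines changes only that section's fields (locality)", {
  cohort <- generate_cohort(1, 13)
  truth <- cohort$tests[1, ]
  full <- render_report(truth, include_lung_volume = TRUE, include_diffusion = TRUE)
  lines <- strsplit(full, "\n")[[1]]
  i0 <- which(lines == "DIFFUSION")
  i1 <- which(lines == "PULSE OXIMETRY")
  cut <- paste(lines[-(i0:(i1 - 1))], collapse = "\n")

  rs <- default_ruleset()
  r_full <- apply_ruleset(rs, full)
  r_cut <- apply_ruleset(rs, cut)
  schema <- pft_schema()
  for (f in schema$name) {
    if (schema$category[schema$name == f] == "dlco") {
      expect_true(is.na(r_cut$values[[f]]))
    } else {
      expect_identical(r_cut$values[[f]], r_full$values[[f]])
    }
  }
})

test_that("extraction matches a brute-force per-line scan oracle", {
  rs <- default_ruleset()
  for (seed in 1:3) {
    cohort <- generate_cohort(2, seed)
    doc <- render_report(cohort$tests[1, ])
    res <- apply_ruleset(rs, doc)
    oracle <- scan_extract_oracle(rs, doc)
    for (f in names(oracle)) {
      expect_identical(res$values[[f]], oracle[[f]],
                       label = sprintf("field %s (seed %d)", f, seed))
    }
    # and the oracle found exactly the populated fields
    populated <- names(res$values)[!vapply(res$values, function(v) is.na(v)[1], logical(1))]
    expect_setequal(names(oracle), populated)
  }
})
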