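# Seeded synthetic cohort: ground-truth subjects, tests, and the simulated
# manual-abstraction table with an injectable transcription-error plan.

first_names <- function() {
  c("JAMES", "MARY", "ROBERT", "PATRICIA", "JOHN", "JENNIFER", "MICHAEL",
    "LINDA", "DAVID", "ELIZABETH", "SUSAN", "KAREN", "NANCY", "LISA",
    "BETTY", "HELEN", "SANDRA", "DONNA", "CAROL", "RUTH")
}

last_names <- function() {
  c("SMITH", "JOHNSON", "WILLIAMS", "BROWN", "JONES", "GARCIA", "MILLER",
    "DAVIS", "RODRIGUEZ", "MARTINEZ", "WILSON", "ANDERSON", "TAYLOR",
    "THOMAS", "MOORE", "JACKSON", "MARTIN", "LEE", "THOMPSON", "WHITE")
}

race_pool <- function() {
  list(values = c("White", "Black or African American", "Asian",
                  "American Indian or Alaska Native", "Other"),
       prob = c(0.70, 0.15, 0.08, 0.02, 0.05))
}

ethnicity_pool <- function() {
  list(values = c("Not Hispanic or Latino", "Hispanic or Latino"),
       prob = c(0.88, 0.12))
}

physician_pool <- function() {
  c("ADAMS, P", "BAKER, S", "COHEN, R", "DIAZ, M", "EVANS, T", "FOSTER, K")
}

technician_pool <- function() c("KLT", "MJR", "SAB", "TWD", "RNP")

notes_pool <- function() {
  c("Good patient effort.", "Acceptable and reproducible effort.",
    "Fair effort; interpret with caution.",
    "Patient coughing during maneuvers.", "Excellent cooperation.")
}

#' Generator settings for the synthetic cohort
#'
#' Defaults emulate the validation study's source population: a scleroderma
#' registry whose subjects undergo one to five PFTs between December 2004 and
#' September 2010, with consent dates inside the same window. Lung volumes
#' are administered in 90% of tests and diffusion in 85% (components are not
#' administered to every patient); spirometry, pulse oximetry and the header
#' are always present. Physiologic value ranges live in the field dictionary
#' (e.g. FVC 1.0-5.5 L, TLC 2.5-8.0 L, DLCO 4-40 mL/min/mmHg, percent
#' predicted 25-130) and can be overridden per field via `ranges`.
#'
#' @param p_lung_volume,p_diffusion Probability that a test includes the
#'   lung-volume / diffusion section.
#' @param tests_min,tests_max Bounds of the per-subject test count (uniform).
#' @param date_start,date_end Window for exam and consent dates.
#' @param p_female Probability a subject is female (scleroderma predominantly
#'   affects women).
#' @param ranges Named list of `c(lo, hi)` overrides for numeric fields.
#' @return A list of validated generator settings.
#' @export
cohort_params <- function(p_lung_volume = 0.90, p_diffusion = 0.85,
                          tests_min = 1L, tests_max = 5L,
                          date_start = as.Date("2004-12-01"),
                          date_end = as.Date("2010-09-30"),
                          p_female = 0.8, ranges = list()) {
  params <- list(p_lung_volume = p_lung_volume, p_diffusion = p_diffusion,
                 tests_min = as.integer(tests_min), tests_max = as.integer(tests_max),
                 date_start = as.Date(date_start), date_end = as.Date(date_end),
                 p_female = p_female, ranges = ranges)
  validate_cohort_params(params)
  params
}

validate_cohort_params <- function(params) {
  probs <- c(params$p_lung_volume, params$p_diffusion, params$p_female)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    rlang::abort("Section/sex probabilities must lie in [0, 1].")
  }
  if (params$tests_min < 1L || params$tests_max < params$tests_min) {
    rlang::abort("tests_min must be >= 1 and tests_max >= tests_min.")
  }
  if (params$date_end <= params$date_start) {
    rlang::abort("date_end must fall after date_start.")
  }
  for (f in names(params$ranges)) {
    r <- params$ranges[[f]]
    if (length(r) != 2L || any(!is.finite(r)) || any(r < 0) || r[2] < r[1]) {
      rlang::abort(sprintf("Invalid range for field '%s': need non-negative c(lo, hi) with lo <= hi.", f))
    }
  }
  invisible(params)
}

#' Generate a seeded ground-truth cohort
#'
#' Draws `n` subjects (unique 8-digit MRNs, demographics, a consent date) and
#' for each subject one to five PFTs with distinct exam dates. Every numeric
#' measure is drawn uniformly within its documented physiologic range and
#' rounded to the precision at which reports print it, so ground truth and
#' rendered text carry identical information. Post-bronchodilator spirometry
#' values are derived from the pre value and an integer percent change.
#' Tests omit the lung-volume and/or diffusion sections at the configured
#' rates; omitted sections have no ground-truth values (`NA`).
#'
#' Generation is fully deterministic for fixed `(n, seed, params)`.
#'
#' @param n Number of subjects (>= 0).
#' @param seed Integer RNG seed.
#' @param params Settings from [cohort_params()].
#' @return A `pft_cohort`: list with `subjects` (tibble: subject_id, mrn,
#'   name, gender, race, ethnicity, dob, consent_date, n_tests), `tests`
#'   (tibble: one row per test with doc_id, subject_id, consent_date, section
#'   flags and all 107 schema fields), `n_subjects`, `seed`, `params`.
#' @export
generate_cohort <- function(n, seed, params = cohort_params()) {
  stopifnot(length(n) == 1L, is.finite(n), n >= 0)
  n <- as.integer(n)
  validate_cohort_params(params)
  withr::with_seed(as.integer(seed), generate_cohort_impl(n, seed, params))
}

generate_cohort_impl <- function(n, seed, params) {
  ft <- pft_field_table()
  day0 <- as.integer(params$date_start)
  day1 <- as.integer(params$date_end)

  # --- subjects ---
  mrn <- as.character(sample.int(90000000L, n) + 9999999L)
  gender <- ifelse(stats::runif(n) < params$p_female, "F", "M")
  name <- paste0(sample(last_names(), n, replace = TRUE), ", ",
                 sample(first_names(), n, replace = TRUE))
  rp <- race_pool(); ep <- ethnicity_pool()
  race <- if (n) sample(rp$values, n, replace = TRUE, prob = rp$prob) else character()
  ethnicity <- if (n) sample(ep$values, n, replace = TRUE, prob = ep$prob) else character()
  consent_date <- as.Date(sample.int(day1 - day0 + 1L, n, replace = TRUE) + day0 - 1L,
                          origin = "1970-01-01")
  age_years <- stats::runif(n, 25, 80)
  dob <- consent_date - round(age_years * 365.25)
  n_tests <- if (params$tests_max > params$tests_min) {
    sample(seq(params$tests_min, params$tests_max), n, replace = TRUE)
  } else rep(params$tests_min, n)

  subjects <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    mrn = mrn, name = name, gender = gender, race = race,
    ethnicity = ethnicity, dob = dob, consent_date = consent_date,
    n_tests = as.integer(n_tests)
  )

  # --- per-subject exam dates (distinct within subject) ---
  exam_dates <- lapply(seq_len(n), function(i) {
    d <- sort(sample.int(day1 - day0 + 1L, n_tests[i]) + day0 - 1L)
    as.Date(d, origin = "1970-01-01")
  })

  total <- if (n) sum(n_tests) else 0L
  idx <- if (n) rep(seq_len(n), n_tests) else integer()

  tests <- tibble::tibble(
    subject_id = subjects$subject_id[idx],
    test_no = if (n) unlist(lapply(n_tests, seq_len)) else integer(),
    mrn = subjects$mrn[idx],
    name = subjects$name[idx],
    gender = subjects$gender[idx],
    race = subjects$race[idx],
    ethnicity = subjects$ethnicity[idx],
    dob = subjects$dob[idx],
    consent_date = subjects$consent_date[idx],
    exam_date = if (n) as.Date(unlist(exam_dates), origin = "1970-01-01") else as.Date(character())
  )
  tests$doc_id <- if (total) sprintf("%s_T%d", tests$subject_id, tests$test_no) else character()

  # --- per-test meta ---
  tests$patient_type <- if (total) sample(c("Outpatient", "Inpatient"), total,
                                          replace = TRUE, prob = c(0.9, 0.1)) else character()
  tests$ordering_physician <- if (total) sample(physician_pool(), total, replace = TRUE) else character()
  tests$technician <- if (total) sample(technician_pool(), total, replace = TRUE) else character()
  tests$test_quality <- if (total) sample(c("A", "B", "C", "D"), total,
                                          replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.05)) else character()
  tests$notes <- if (total) sample(notes_pool(), total, replace = TRUE) else character()

  # --- section presence ---
  tests$has_lung_volume <- stats::runif(total) < params$p_lung_volume
  tests$has_diffusion <- stats::runif(total) < params$p_diffusion

  # --- anthropometrics (gender-dependent heights) ---
  h_range <- params$ranges[["height"]] %||% c(NA, NA)
  if (all(is.finite(h_range))) {
    tests$height <- round_half_up(stats::runif(total, h_range[1], h_range[2]), 1)
  } else {
    lo <- ifelse(tests$gender == "F", 150, 163)
    hi <- ifelse(tests$gender == "F", 176, 193)
    tests$height <- round_half_up(stats::runif(total, lo, hi), 1)
  }
  w_range <- params$ranges[["weight"]] %||% c(42, 115)
  tests$weight <- round_half_up(stats::runif(total, w_range[1], w_range[2]), 1)

  field_range <- function(fname, default_lo, default_hi) {
    r <- params$ranges[[fname]]
    if (is.null(r)) c(default_lo, default_hi) else r
  }

  # --- spirometry: pre value + integer % change drive the post value ---
  for (i in seq_len(nrow(spiro_measures()))) {
    m <- spiro_measures()[i, ]
    vname <- paste0(m$base, "_", m$tag)
    r <- field_range(vname, m$lo, m$hi)
    pre <- round_half_up(stats::runif(total, r[1], r[2]), m$digits)
    chg <- sample(-10:15, total, replace = TRUE)
    tests[[vname]] <- pre
    tests[[paste0(m$base, "_pct_pred")]] <- as.numeric(sample(25:130, total, replace = TRUE))
    tests[[paste0(m$base, "_post_", m$tag)]] <- round_half_up(pre * (1 + chg / 100), m$digits)
    tests[[paste0(m$base, "_post_pct_pred")]] <- as.numeric(sample(25:130, total, replace = TRUE))
    tests[[paste0(m$base, "_pct_change")]] <- as.numeric(chg)
    tests[[paste0(m$base, "_lln")]] <- as.numeric(sample(0:1, total, replace = TRUE, prob = c(0.7, 0.3)))
  }

  two_col_draw <- function(tab, present) {
    for (i in seq_len(nrow(tab))) {
      m <- tab[i, ]
      r <- field_range(m$value_name, m$lo, m$hi)
      v <- round_half_up(stats::runif(total, r[1], r[2]), m$digits)
      p <- as.numeric(sample(25:130, total, replace = TRUE))
      v[!present] <- NA_real_
      p[!present] <- NA_real_
      tests[[m$value_name]] <<- v
      tests[[m$pct_name]] <<- p
    }
  }
  two_col_draw(lung_volume_measures(), tests$has_lung_volume)
  two_col_draw(diffusion_measures(), tests$has_diffusion)

  # --- pulse oximetry ---
  rest <- sample(88:100, total, replace = TRUE)
  tests$spo2_rest_pct <- as.numeric(rest)
  tests$spo2_exertion_pct <- as.numeric(pmax(rest - sample(0:8, total, replace = TRUE), 75L))

  structure(
    list(subjects = subjects, tests = tests, n_subjects = n,
         seed = as.integer(seed), params = params),
    class = "pft_cohort"
  )
}

#' @export
print.pft_cohort <- function(x, ...) {
  cat(sprintf("<pft_cohort: %d subjects, %d ground-truth tests (seed %d)>\n",
              x$n_subjects, nrow(x$tests), x$seed))
  invisible(x)
}

#' Ground-truth validation table: one index test per subject
#'
#' Selects, for every subject, the test performed closest to the consent
#' date (ties broken toward the earlier test) and returns the 11 validation
#' fields. This is what a perfectly accurate manual abstractor would enter.
#'
#' @param cohort A `pft_cohort`.
#' @return A tibble keyed by `subject_id` with the [validation_fields()]
#'   columns, one row per subject.
#' @export
validation_truth <- function(cohort) {
  stopifnot(inherits(cohort, "pft_cohort"))
  tests <- cohort$tests
  rows <- lapply(cohort$subjects$subject_id, function(sid) {
    sub <- tests[tests$subject_id == sid, ]
    select_index_test(sub, sub$consent_date[1])
  })
  out <- dplyr::bind_rows(rows)
  out[, c("subject_id", validation_fields())]
}

#' Build a transcription-error plan
#'
#' @param subject Integer row indices of the target subjects in the truth
#'   table.
#' @param field Validation field name per entry.
#' @param kind Error kind per entry: `digit_typo`, `date_shift`,
#'   `value_typo`, or `category_swap`.
#' @param seed Seed controlling which digit/shift each entry uses.
#' @return A `pft_error_plan` tibble.
#' @export
error_plan <- function(subject = integer(), field = character(),
                       kind = character(), seed = 1L) {
  kinds <- c("digit_typo", "date_shift", "value_typo", "category_swap")
  bad <- setdiff(kind, kinds)
  if (length(bad)) rlang::abort(sprintf("Unknown error kind(s): %s", paste(bad, collapse = ", ")))
  plan <- tibble::tibble(subject = as.integer(subject), field = field, kind = kind)
  if (anyDuplicated(plan[, c("subject", "field")])) {
    rlang::abort("Error-plan entries must target distinct (subject, field) cells.")
  }
  structure(plan, seed = as.integer(seed),
            class = c("pft_error_plan", class(plan)))
}

#' The shipped six-error plan behind the validation fixture
#'
#' Reproduces the validation study's observed manual-abstraction error
#' taxonomy as a deterministic fixture: two mistyped medical record numbers,
#' two shifted test dates, one mistyped height, and one gender miscoding —
#' six erroneous cells in a 100-subject, 11-field abstraction table.
#'
#' @return A `pft_error_plan` with six entries.
#' @export
paper_error_plan <- function() {
  error_plan(
    subject = c(7L, 52L, 19L, 64L, 33L, 81L),
    field = c("mrn", "mrn", "exam_date", "exam_date", "height", "gender"),
    kind = c("digit_typo", "digit_typo", "date_shift", "date_shift",
             "value_typo", "category_swap"),
    seed = 412L
  )
}

typo_digit_string <- function(s) {
  pos <- which(strsplit(s, "")[[1]] %in% as.character(0:9))
  if (!length(pos)) rlang::abort("Value has no digit to mistype.")
  p <- if (length(pos) == 1L) pos else sample(pos, 1L)
  ch <- strsplit(s, "")[[1]]
  ch[p] <- as.character((as.integer(ch[p]) + 1L) %% 10L)
  paste(ch, collapse = "")
}

#' Simulate manual data entry with injected transcription errors
#'
#' Copies the ground-truth abstraction table and corrupts exactly the cells
#' named by the plan: `digit_typo`/`value_typo` replace one digit of the
#' printed value with a different digit, `date_shift` moves a date by a
#' nonzero amount up to 30 days, and `category_swap` flips the sex code.
#' The result differs from the truth table at exactly `nrow(plan)` cells.
#'
#' @param truth A truth table from [validation_truth()] (or any table whose
#'   columns include the plan's fields).
#' @param plan A `pft_error_plan`.
#' @return The manual-abstraction tibble.
#' @export
simulate_manual_entry <- function(truth, plan = error_plan()) {
  stopifnot(inherits(plan, "pft_error_plan"))
  manual <- truth
  ft <- pft_field_table()
  if (nrow(plan) == 0L) return(manual)
  withr::with_seed(attr(plan, "seed"), {
    for (i in seq_len(nrow(plan))) {
      subj <- plan$subject[i]
      fld <- plan$field[i]
      if (subj < 1L || subj > nrow(manual) || !fld %in% names(manual)) {
        rlang::abort(sprintf("Error plan targets a missing cell: subject %d, field '%s'.", subj, fld))
      }
      cur <- manual[[fld]][subj]
      if (is.na(cur)) {
        rlang::abort(sprintf("Error plan targets a missing cell: subject %d, field '%s'.", subj, fld))
      }
      manual[[fld]][subj] <- switch(plan$kind[i],
        digit_typo = typo_digit_string(as.character(cur)),
        value_typo = {
          digits <- ft$digits[match(fld, ft$name)]
          as.numeric(typo_digit_string(fmt_decimal(cur, digits)))
        },
        date_shift = cur + sample(c(-30:-1, 1:30), 1L),
        category_swap = if (identical(cur, "M")) "F" else "M"
      )
    }
  })
  manual
}
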