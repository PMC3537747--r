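# Rendering ground-truth records as SensorMedics-style plain-text reports.

fmt_field <- function(value, kind, digits) {
  if (kind == "decimal") fmt_decimal(value, digits)
  else if (kind == "integer") fmt_integer(value)
  else as.character(value)
}

#' Render one ground-truth test record as a plain-text PFT report
#'
#' Produces a report following [canonical_layout()]: fixed header lines, then
#' aligned measure tables per section. Sections flagged as not administered
#' (`has_lung_volume`, `has_diffusion` on the record, overridable via
#' arguments) are absent from the output entirely. Rendering is deterministic
#' and, by construction, invertible by the default ruleset: extraction of a
#' rendered report recovers every included ground-truth value exactly.
#'
#' @param truth A one-row data frame (a row of `generate_cohort()$tests`)
#'   holding all schema fields, optionally `dob`, and the section flags.
#' @param include_lung_volume,include_diffusion Optional logical overrides of
#'   the record's own section flags.
#' @return The report as a single string.
#' @export
render_report <- function(truth, include_lung_volume = NULL,
                          include_diffusion = NULL) {
  truth <- as.list(truth)
  has_lv <- include_lung_volume %||% isTRUE(truth$has_lung_volume)
  has_diff <- include_diffusion %||% isTRUE(truth$has_diffusion)
  ft <- pft_field_table()

  need <- function(f) {
    v <- truth[[f]]
    if (is.null(v) || is.na(v)) {
      rlang::abort(sprintf("Cannot render report: field '%s' is missing from the record.", f))
    }
    v
  }
  num <- function(f) {
    i <- match(f, ft$name)
    fmt_field(need(f), ft$value_kind[i], ft$digits[i])
  }

  lines <- c(
    "PULMONARY FUNCTION TEST REPORT",
    strrep("-", 74),
    sprintf("Name: %s", need("name")),
    sprintf("MRN: %s          Exam Date: %s", need("mrn"),
            format(need("exam_date"), "%m/%d/%Y")),
    if (!is.null(truth$dob) && !is.na(truth$dob))
      sprintf("DOB: %s", format(truth$dob, "%m/%d/%Y")),
    sprintf("Gender: %s    Race: %s    Ethnicity: %s",
            need("gender"), need("race"), need("ethnicity")),
    sprintf("Patient Type: %s", need("patient_type")),
    sprintf("Height (cm): %s    Weight (kg): %s", num("height"), num("weight")),
    sprintf("Ordering Physician: %s", need("ordering_physician")),
    sprintf("Technician: %s", need("technician")),
    ""
  )

  sp <- spiro_measures()
  lines <- c(lines,
    "SPIROMETRY",
    sprintf("%-24s%9s%9s%9s%9s%8s%8s", "", "Pre", "%Pred", "Post", "%Pred", "%Chg", "LLN"),
    vapply(seq_len(nrow(sp)), function(i) {
      m <- sp[i, ]
      sprintf("%-24s%9s%9s%9s%9s%8s%8s",
              m$label,
              num(paste0(m$base, "_", m$tag)),
              num(paste0(m$base, "_pct_pred")),
              num(paste0(m$base, "_post_", m$tag)),
              num(paste0(m$base, "_post_pct_pred")),
              num(paste0(m$base, "_pct_change")),
              num(paste0(m$base, "_lln")))
    }, ""),
    "")

  two_col_block <- function(title, tab) {
    c(title,
      sprintf("%-24s%9s%9s", "", "Value", "%Pred"),
      vapply(seq_len(nrow(tab)), function(i) {
        m <- tab[i, ]
        sprintf("%-24s%9s%9s", m$label, num(m$value_name), num(m$pct_name))
      }, ""),
      "")
  }

  if (has_lv) lines <- c(lines, two_col_block("LUNG VOLUMES", lung_volume_measures()))
  if (has_diff) lines <- c(lines, two_col_block("DIFFUSION", diffusion_measures()))

  lines <- c(lines,
    "PULSE OXIMETRY",
    sprintf("SpO2 Rest (%%): %s", num("spo2_rest_pct")),
    sprintf("SpO2 Exertion (%%): %s", num("spo2_exertion_pct")),
    "",
    "NOTES",
    sprintf("Test Quality: %s", need("test_quality")),
    sprintf("Comments: %s", need("notes")))

  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Render every test of a cohort
#'
#' @param cohort A `pft_cohort` from [generate_cohort()].
#' @return A tibble with `doc_id` and `text`, one row per ground-truth test,
#'   in cohort test order.
#' @export
render_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "pft_cohort"))
  tests <- cohort$tests
  tibble::tibble(
    doc_id = tests$doc_id,
    text = vapply(seq_len(nrow(tests)), function(i) render_report(tests[i, ]), "")
  )
}
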