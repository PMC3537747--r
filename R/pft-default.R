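# The canonical PFT report grammar: 107-field dictionary, 39-rule default
# ruleset, and the report layout the synthetic generator renders.
#
# The field identities are a reconstruction: the mart design fixes category
# counts (54 spirometry / 26 lung volume / 12 diffusion / 2 pulse oximetry /
# 2 anthropometric numeric measures; 6 patient + 5 measurement non-numeric
# fields) but not individual field names, so the dictionary below names
# conventional PFT quantities that reconcile with every count. It is
# swappable via the rule file.

spiro_measures <- function() {
  if (!is.null(.pft_cache$spiro)) return(.pft_cache$spiro)
  .pft_cache$spiro <- tibble::tribble(
    ~base,       ~tag,   ~label,            ~units,  ~lo,  ~hi,  ~digits,
    "fvc",       "l",    "FVC (L)",         "L",     1.0,  5.5,  2,
    "fev1",      "l",    "FEV1 (L)",        "L",     0.8,  4.5,  2,
    "fev1_fvc",  "pct",  "FEV1/FVC (%)",    "%",     40,   95,   1,
    "fef25_75",  "ls",   "FEF25-75 (L/s)",  "L/s",   0.3,  5.0,  2,
    "pef",       "ls",   "PEF (L/s)",       "L/s",   2.0,  12.0, 2,
    "fef50",     "ls",   "FEF50 (L/s)",     "L/s",   0.5,  7.0,  2,
    "fivc",      "l",    "FIVC (L)",        "L",     1.0,  5.5,  2,
    "fiv1",      "l",    "FIV1 (L)",        "L",     0.8,  4.5,  2,
    "mvv",       "lmin", "MVV (L/min)",     "L/min", 30,   180,  1
  )
}

lung_volume_measures <- function() {
  if (!is.null(.pft_cache$lv)) return(.pft_cache$lv)
  .pft_cache$lv <- tibble::tribble(
    ~value_name,         ~pct_name,                ~label,                 ~units,        ~lo,   ~hi,  ~digits,
    "tlc_l",             "tlc_pct_pred",           "TLC (L)",              "L",           2.5,   8.0,  2,
    "vc_l",              "vc_pct_pred",            "VC (L)",               "L",           1.0,   5.5,  2,
    "frc_l",             "frc_pct_pred",           "FRC (L)",              "L",           1.5,   4.5,  2,
    "rv_l",              "rv_pct_pred",            "RV (L)",               "L",           1.0,   3.5,  2,
    "erv_l",             "erv_pct_pred",           "ERV (L)",              "L",           0.3,   1.5,  2,
    "ic_l",              "ic_pct_pred",            "IC (L)",               "L",           1.5,   4.0,  2,
    "rv_tlc_pct",        "rv_tlc_pct_pred",        "RV/TLC (%)",           "%",           20,    60,   1,
    "svc_l",             "svc_pct_pred",           "SVC (L)",              "L",           1.0,   5.5,  2,
    "tgv_l",             "tgv_pct_pred",           "TGV (L)",              "L",           1.5,   4.5,  2,
    "raw_cmh2o_l_s",     "raw_pct_pred",           "Raw (cmH2O/L/s)",      "cmH2O/L/s",   0.5,   3.5,  2,
    "sgaw_1_cmh2o_s",    "sgaw_pct_pred",          "sGaw (1/cmH2O/s)",     "1/cmH2O/s",   0.05,  0.5,  2,
    "vtg_l",             "vtg_pct_pred",           "VTG (L)",              "L",           1.5,   4.5,  2,
    "he_equil_time_min", "he_equil_time_pct_pred", "He Equil Time (min)",  "min",         1.0,   7.0,  1
  )
}

diffusion_measures <- function() {
  if (!is.null(.pft_cache$diff)) return(.pft_cache$diff)
  .pft_cache$diff <- tibble::tribble(
    ~value_name,  ~pct_name,             ~label,                   ~units,           ~lo,  ~hi,  ~digits,
    "dlco",       "dlco_pct_pred",       "DLCO (mL/min/mmHg)",     "mL/min/mmHg",    4,    40,   2,
    "dlco_corr",  "dlco_corr_pct_pred",  "DLCOcorr (mL/min/mmHg)", "mL/min/mmHg",    4,    40,   2,
    "dl_va",      "dl_va_pct_pred",      "DL/VA (mL/min/mmHg/L)",  "mL/min/mmHg/L",  2,    8,    2,
    "va_l",       "va_pct_pred",         "VA (L)",                 "L",              2,    7,    2,
    "ivc_l",      "ivc_pct_pred",        "IVC (L)",                "L",              1,    5,    2,
    "hb_g_dl",    "hb_pct_pred",         "Hb (g/dL)",              "g/dL",           9,    17,   1
  )
}

.pft_cache <- new.env(parent = emptyenv())

# Full internal field table: schema columns plus rendering/generation
# metadata (digits, physiologic range, report section, measure, role).
# Memoized: the dictionary is a constant and callers hit it in tight loops.
pft_field_table <- function() {
  if (!is.null(.pft_cache$field_table)) return(.pft_cache$field_table)
  .pft_cache$field_table <- build_pft_field_table()
  .pft_cache$field_table
}

build_pft_field_table <- function() {
  frow <- function(name, category, value_kind, units, digits = NA_real_,
                   lo = NA_real_, hi = NA_real_, section, measure = NA_character_,
                   role = NA_character_) {
    tibble::tibble(name = name, category = category, value_kind = value_kind,
                   units = units, digits = digits, lo = lo, hi = hi,
                   section = section, measure = measure, role = role)
  }

  header <- dplyr::bind_rows(
    frow("name", "patient_meta", "text", "", section = "HEADER"),
    frow("mrn", "patient_meta", "text", "", section = "HEADER"),
    frow("exam_date", "measurement_meta", "date", "", section = "HEADER"),
    frow("gender", "patient_meta", "sex_code", "", section = "HEADER"),
    frow("race", "patient_meta", "text", "", section = "HEADER"),
    frow("ethnicity", "patient_meta", "text", "", section = "HEADER"),
    frow("patient_type", "patient_meta", "text", "", section = "HEADER"),
    frow("height", "anthropometric", "decimal", "cm", digits = 1,
         lo = 145, hi = 193, section = "HEADER", role = "value"),
    frow("weight", "anthropometric", "decimal", "kg", digits = 1,
         lo = 40, hi = 120, section = "HEADER", role = "value"),
    frow("ordering_physician", "measurement_meta", "text", "", section = "HEADER"),
    frow("technician", "measurement_meta", "text", "", section = "HEADER")
  )

  sp <- spiro_measures()
  spiro <- dplyr::bind_rows(lapply(seq_len(nrow(sp)), function(i) {
    m <- sp[i, ]
    dplyr::bind_rows(
      frow(paste0(m$base, "_", m$tag), "spirometry", "decimal", m$units,
           digits = m$digits, lo = m$lo, hi = m$hi,
           section = "SPIROMETRY", measure = m$base, role = "value"),
      frow(paste0(m$base, "_pct_pred"), "spirometry", "integer", "%predicted",
           digits = 0, lo = 25, hi = 130,
           section = "SPIROMETRY", measure = m$base, role = "pct_pred"),
      frow(paste0(m$base, "_post_", m$tag), "spirometry", "decimal", m$units,
           digits = m$digits, lo = m$lo, hi = m$hi,
           section = "SPIROMETRY", measure = m$base, role = "post_value"),
      frow(paste0(m$base, "_post_pct_pred"), "spirometry", "integer", "%predicted",
           digits = 0, lo = 25, hi = 130,
           section = "SPIROMETRY", measure = m$base, role = "post_pct_pred"),
      frow(paste0(m$base, "_pct_change"), "spirometry", "integer", "%",
           digits = 0, lo = -10, hi = 15,
           section = "SPIROMETRY", measure = m$base, role = "pct_change"),
      frow(paste0(m$base, "_lln"), "spirometry", "integer", "flag",
           digits = 0, lo = 0, hi = 1,
           section = "SPIROMETRY", measure = m$base, role = "lln")
    )
  }))

  two_col <- function(tab, category, section) {
    dplyr::bind_rows(lapply(seq_len(nrow(tab)), function(i) {
      m <- tab[i, ]
      dplyr::bind_rows(
        frow(m$value_name, category, "decimal", m$units, digits = m$digits,
             lo = m$lo, hi = m$hi, section = section,
             measure = m$value_name, role = "value"),
        frow(m$pct_name, category, "integer", "%predicted", digits = 0,
             lo = 25, hi = 130, section = section,
             measure = m$value_name, role = "pct_pred")
      )
    }))
  }

  lv <- two_col(lung_volume_measures(), "lung_volume", "LUNG VOLUMES")
  diff <- two_col(diffusion_measures(), "dlco", "DIFFUSION")

  pulse <- dplyr::bind_rows(
    frow("spo2_rest_pct", "pulse_ox", "integer", "%", digits = 0,
         lo = 88, hi = 100, section = "PULSE OXIMETRY", role = "value"),
    frow("spo2_exertion_pct", "pulse_ox", "integer", "%", digits = 0,
         lo = 80, hi = 100, section = "PULSE OXIMETRY", role = "value")
  )

  notes <- dplyr::bind_rows(
    frow("test_quality", "measurement_meta", "text", "", section = "NOTES"),
    frow("notes", "measurement_meta", "text", "", section = "NOTES")
  )

  dplyr::bind_rows(header, spiro, lv, diff, pulse, notes)
}

#' The default PFT mart schema
#'
#' @return A tibble with columns `name`, `category`, `value_kind`, `units`:
#'   the 107-field dictionary behind [default_ruleset()].
#' @export
pft_schema <- function() {
  pft_field_table()[, c("name", "category", "value_kind", "units")]
}

#' The six warehouse key columns carried by every mart row
#'
#' Surrogate keys that would link a production mart row to patient,
#' encounter, order and document tables; here they are deterministic hashes
#' so rebuilds are reproducible.
#'
#' @return Character vector of the six key column names.
#' @export
mart_key_columns <- function() {
  c("patient_key", "encounter_key", "order_key", "document_key",
    "source_system", "mrn_key")
}

#' The 11-field validation set
#'
#' The fields compared between automated extraction and manual chart
#' abstraction: subject identity (MRN, exam date), demographics/anthropometrics
#' (gender, height, weight), and six physiologic measures (FVC and TLC and
#' DLCO, each with its percent predicted).
#'
#' @return Character vector of 11 schema field names.
#' @export
validation_fields <- function() {
  c("mrn", "exam_date", "gender", "height", "weight",
    "fvc_l", "fvc_pct_pred", "tlc_l", "tlc_pct_pred",
    "dlco", "dlco_pct_pred")
}

regex_escape <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

# Build the default rule configuration text. The shipped
# inst/extdata/pft_default.rules file is this function's output; a test pins
# the two together so the file cannot drift from the dictionary.
pft_rules_config_text <- function() {
  ft <- pft_field_table()
  out <- c("# Default PFT extraction ruleset: 39 rules over the 107-field dictionary.",
           "# Dialect: PCRE with named capture groups; the engine applies patterns in",
           "# multiline mode, so ^ and $ anchor to line boundaries.",
           "",
           "[fields]")
  out <- c(out, sprintf("%s, %s, %s, %s", ft$name, ft$category, ft$value_kind, ft$units))

  rule <- function(id, pattern, binds, required = FALSE) {
    c("",
      sprintf("[rule %s]", id),
      sprintf("pattern = %s", pattern),
      vapply(names(binds), function(g) {
        sprintf("bind %s -> %s : %s", g, binds[[g]][1], binds[[g]][2])
      }, "", USE.NAMES = FALSE),
      if (required) "required = true" else character())
  }

  dec <- "-?\\d+\\.\\d+"
  int <- "\\d+"
  sint <- "-?\\d+"

  out <- c(out,
    rule("identity",
         sprintf("^MRN:\\s+(?<mrn>%s)\\s+Exam Date:\\s+(?<exam_date>\\d{2}/\\d{2}/\\d{4})\\s*$", int),
         list(mrn = c("mrn", "text"), exam_date = c("exam_date", "date")),
         required = TRUE),
    rule("patient_name",
         "^Name:\\s+(?<name>.+)$",
         list(name = c("name", "text"))),
    rule("demographics",
         "^Gender:\\s+(?<gender>[A-Za-z]+)\\s{2,}Race:\\s+(?<race>.+?)\\s{2,}Ethnicity:\\s+(?<ethnicity>.+)$",
         list(gender = c("gender", "sex"), race = c("race", "text"),
              ethnicity = c("ethnicity", "text"))),
    rule("patient_type",
         "^Patient Type:\\s+(?<patient_type>Inpatient|Outpatient)\\s*$",
         list(patient_type = c("patient_type", "text"))),
    rule("anthropometrics",
         sprintf("^Height \\(cm\\):\\s+(?<height>%s)\\s+Weight \\(kg\\):\\s+(?<weight>%s)\\s*$",
                 "\\d+\\.\\d+", "\\d+\\.\\d+"),
         list(height = c("height", "decimal"), weight = c("weight", "decimal"))),
    rule("ordering_physician",
         "^Ordering Physician:\\s+(?<ordering_physician>.+)$",
         list(ordering_physician = c("ordering_physician", "text"))),
    rule("technician",
         "^Technician:\\s+(?<technician>.+)$",
         list(technician = c("technician", "text")))
  )

  sp <- spiro_measures()
  for (i in seq_len(nrow(sp))) {
    m <- sp[i, ]
    v <- paste0(m$base, "_", m$tag)
    g <- c(v, paste0(m$base, "_pct_pred"), paste0(m$base, "_post_", m$tag),
           paste0(m$base, "_post_pct_pred"), paste0(m$base, "_pct_change"),
           paste0(m$base, "_lln"))
    pattern <- sprintf(
      "^%s\\s+(?<%s>%s)\\s+(?<%s>%s)\\s+(?<%s>%s)\\s+(?<%s>%s)\\s+(?<%s>%s)\\s+(?<%s>[01])\\s*$",
      regex_escape(m$label), g[1], dec, g[2], int, g[3], dec, g[4], int, g[5], sint, g[6])
    binds <- list(c(g[1], "decimal"), c(g[2], "integer"), c(g[3], "decimal"),
                  c(g[4], "integer"), c(g[5], "integer"), c(g[6], "integer"))
    names(binds) <- g
    out <- c(out, rule(paste0("spiro_", m$base), pattern, binds))
  }

  row2 <- function(prefix, tab) {
    res <- character()
    for (i in seq_len(nrow(tab))) {
      m <- tab[i, ]
      pattern <- sprintf("^%s\\s+(?<%s>%s)\\s+(?<%s>%s)\\s*$",
                         regex_escape(m$label), m$value_name, dec, m$pct_name, int)
      binds <- list(c(m$value_name, "decimal"), c(m$pct_name, "integer"))
      names(binds) <- c(m$value_name, m$pct_name)
      res <- c(res, rule(paste0(prefix, m$value_name), pattern, binds))
    }
    res
  }
  out <- c(out, row2("lv_", lung_volume_measures()))
  out <- c(out, row2("dlco_", diffusion_measures()))

  out <- c(out,
    rule("spo2_rest",
         sprintf("^SpO2 Rest \\(%%\\):\\s+(?<spo2_rest_pct>%s)\\s*$", int),
         list(spo2_rest_pct = c("spo2_rest_pct", "integer"))),
    rule("spo2_exertion",
         sprintf("^SpO2 Exertion \\(%%\\):\\s+(?<spo2_exertion_pct>%s)\\s*$", int),
         list(spo2_exertion_pct = c("spo2_exertion_pct", "integer"))),
    rule("test_quality",
         "^Test Quality:\\s+(?<test_quality>.+)$",
         list(test_quality = c("test_quality", "text"))),
    rule("comments",
         "^Comments:\\s+(?<notes>.+)$",
         list(notes = c("notes", "text")))
  )

  paste0(paste(out, collapse = "\n"), "\n")
}

#' The shipped default PFT extraction ruleset
#'
#' Loads `pft_default.rules` from the package: 39 regular-expression rules
#' binding the 107-field dictionary, with the MRN/exam-date identity rule
#' required and every physiologic rule optional (not all PFT components are
#' administered to every patient).
#'
#' @return A `pft_ruleset`.
#' @export
default_ruleset <- function() {
  if (!is.null(.pft_cache$default_ruleset)) return(.pft_cache$default_ruleset)
  path <- system.file("extdata", "pft_default.rules", package = "regexmart",
                      mustWork = TRUE)
  .pft_cache$default_ruleset <- load_ruleset(path = path)
  .pft_cache$default_ruleset
}

#' Describe the canonical report layout
#'
#' The synthetic renderer and the default ruleset share one report template:
#' a header block (name, MRN, exam date, DOB, gender, race/ethnicity, patient
#' type, height, weight, ordering physician, technician) followed by
#' SPIROMETRY (one row per measure: pre-bronchodilator value, % predicted,
#' post-bronchodilator value, % predicted, % change, below-LLN flag), LUNG
#' VOLUMES and DIFFUSION (value, % predicted per row), PULSE OXIMETRY, and
#' NOTES. Lung-volume and diffusion sections may be absent entirely when not
#' administered.
#'
#' @return A tibble with one row per section: `section`, `optional`, and
#'   `fields` (list column of the schema fields the section carries).
#' @export
canonical_layout <- function() {
  ft <- pft_field_table()
  secs <- c("HEADER", "SPIROMETRY", "LUNG VOLUMES", "DIFFUSION",
            "PULSE OXIMETRY", "NOTES")
  tibble::tibble(
    section = secs,
    optional = secs %in% c("LUNG VOLUMES", "DIFFUSION"),
    fields = lapply(secs, function(s) ft$name[ft$section == s])
  )
}
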