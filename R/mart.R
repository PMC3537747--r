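# Batch pipeline: documents in, keyed wide table out, CSV export.

#' Read a directory of plain-text reports
#'
#' @param dir Directory containing one report per file.
#' @param pattern Filename filter (default `*.txt`).
#' @return A tibble with `doc_id` (file name without extension) and `text`.
#' @export
read_report_dir <- function(dir, pattern = "\\.txt$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  tibble::tibble(
    doc_id = sub("\\.[^.]*$", "", basename(files)),
    text = vapply(files, function(f) {
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    }, "", USE.NAMES = FALSE)
  )
}

mart_keys_for <- function(mrn, exam_date, doc_id) {
  date_str <- ifelse(is.na(exam_date), "", format(exam_date, "%Y-%m-%d"))
  tibble::tibble(
    patient_key = paste0("P", str_hash32(mrn)),
    encounter_key = paste0("E", str_hash32(paste0(mrn, "|", date_str))),
    order_key = paste0("O", str_hash32(paste0(mrn, "|", date_str, "|ORD"))),
    document_key = paste0("D", str_hash32(doc_id)),
    source_system = "PFT_LAB",
    mrn_key = mrn
  )
}

#' Build the data-mart table from a batch of report documents
#'
#' Applies the ruleset to every document and assembles one mart row per
#' successfully keyed document, in input order: the six surrogate key columns
#' first, then the schema fields in dictionary order. Surrogate keys are
#' deterministic hashes of the MRN, (MRN, exam date) and document id, so
#' rebuilding over the same inputs yields an identical table. Documents whose
#' required identity rule fails are quarantined into an attached error report
#' rather than dropped silently; rows + quarantined = input documents.
#'
#' @param documents A tibble/data frame with `doc_id` and `text` columns
#'   (doc_ids unique), or a named character vector of documents.
#' @param rs The ruleset (default: [default_ruleset()]).
#' @return A `mart_table` tibble; retrieve quarantined documents with
#'   [mart_quarantine()].
#' @export
build_mart <- function(documents, rs = default_ruleset()) {
  if (is.character(documents)) {
    documents <- tibble::tibble(
      doc_id = names(documents) %||% as.character(seq_along(documents)),
      text = unname(documents))
  }
  stopifnot(all(c("doc_id", "text") %in% names(documents)))
  if (anyDuplicated(documents$doc_id)) {
    rlang::abort("Document ids must be unique.")
  }

  schema <- rs$schema
  rows <- vector("list", nrow(documents))
  quarantined <- list()
  for (i in seq_len(nrow(documents))) {
    res <- tryCatch(
      apply_ruleset(rs, documents$text[i]),
      pft_extraction_error = function(e) e
    )
    if (inherits(res, "pft_extraction_error")) {
      quarantined[[length(quarantined) + 1]] <- tibble::tibble(
        doc_id = documents$doc_id[i],
        rule_id = res$rule_id %||% NA_character_,
        reason = conditionMessage(res))
      next
    }
    vals <- tibble::as_tibble(res$values)
    keys <- mart_keys_for(vals$mrn, vals$exam_date, documents$doc_id[i])
    rows[[i]] <- dplyr::bind_cols(keys, vals)
  }

  rows <- rows[!vapply(rows, is.null, logical(1))]
  mart <- if (length(rows)) {
    dplyr::bind_rows(rows)
  } else {
    empty_vals <- tibble::as_tibble(
      stats::setNames(lapply(schema$value_kind, function(k) missing_value(k)[0]),
                      schema$name))
    dplyr::bind_cols(mart_keys_for(character(), as.Date(character()), character()),
                     empty_vals)
  }
  quarantine <- if (length(quarantined)) dplyr::bind_rows(quarantined) else {
    tibble::tibble(doc_id = character(), rule_id = character(), reason = character())
  }
  structure(mart, quarantine = quarantine,
            class = c("mart_table", class(mart)))
}

#' Quarantined documents of a mart build
#'
#' @param mart A `mart_table`.
#' @return Tibble with `doc_id`, `rule_id`, `reason` for every input document
#'   that failed its required identity rule.
#' @export
mart_quarantine <- function(mart) {
  attr(mart, "quarantine") %||%
    tibble::tibble(doc_id = character(), rule_id = character(), reason = character())
}

#' Export a mart table to CSV
#'
#' RFC 4180 CSV, UTF-8, header row, stable column order (keys first, then
#' dictionary order). MISSING values are written as empty cells — not "NA" —
#' so the file loads cleanly into any statistics package. Dates are written
#' in ISO form.
#'
#' @param mart A `mart_table` (or any data frame).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
export_csv <- function(mart, path) {
  readr::write_csv(as.data.frame(mart), path, na = "")
  invisible(path)
}

#' Read a mart CSV back with schema-typed columns
#'
#' Inverse of [export_csv()] for marts built from a given ruleset: key
#' columns as character, numeric fields as double, dates as `Date`, empty
#' cells as `NA`. The round trip is lossless cell-for-cell.
#'
#' @param path CSV file written by [export_csv()].
#' @param rs Ruleset whose schema types the columns (default ruleset).
#' @return A tibble.
#' @export
read_mart_csv <- function(path, rs = default_ruleset()) {
  schema <- rs$schema
  kind_col <- function(kind) {
    switch(kind,
      decimal = readr::col_double(),
      integer = readr::col_double(),
      date = readr::col_date(format = "%Y-%m-%d"),
      readr::col_character())
  }
  cols <- c(
    stats::setNames(rep(list(readr::col_character()), length(mart_key_columns())),
                    mart_key_columns()),
    stats::setNames(lapply(schema$value_kind, kind_col), schema$name)
  )
  readr::read_csv(path, col_types = do.call(readr::cols, cols), na = "",
                  progress = FALSE)
}
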