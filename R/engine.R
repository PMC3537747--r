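# Rule application: one document in, one typed record out.

missing_value <- function(kind) {
  switch(kind,
    decimal = NA_real_,
    integer = NA_real_,
    date = as.Date(NA),
    text = NA_character_,
    sex_code = NA_character_
  )
}

convert_value <- function(raw, converter) {
  raw <- trimws(raw)
  switch(converter,
    decimal = {
      if (!grepl("^[+-]?[0-9]+(\\.[0-9]+)?$", raw)) return(NULL)
      as.numeric(raw)
    },
    integer = {
      if (!grepl("^[+-]?[0-9]+$", raw)) return(NULL)
      as.numeric(raw)
    },
    date = {
      d <- as.Date(raw, format = "%m/%d/%Y")
      if (is.na(d)) return(NULL)
      d
    },
    text = raw,
    sex = {
      s <- normalize_sex(raw)
      if (is.na(s)) return(NULL)
      s
    },
    NULL
  )
}

#' Apply an extraction ruleset to one report document
#'
#' Each rule is applied independently to the whole document in PCRE multiline
#' mode; the first match in document order wins. Rules that do not match
#' leave all their fields MISSING (`NA`) without failing the document, unless
#' the rule is marked `required`, in which case a document-level extraction
#' error (condition class `pft_extraction_error`) is signalled. A capture
#' whose text cannot be converted (for example non-numeric text in a numeric
#' capture) demotes the rule to `conversion_error` with a warning: all of
#' that rule's fields are MISSING.
#'
#' @param rs A `pft_ruleset` from [load_ruleset()] or [default_ruleset()].
#' @param doc The document as a single string (possibly empty).
#' @return A `pft_parse_result`: list with `values` (named list over exactly
#'   the schema fields; MISSING is a typed `NA`), `rule_status` (named
#'   character over rules: `"matched"`, `"absent"`, or `"conversion_error"`),
#'   and `provenance` (named list of `c(start, end)` character offsets for
#'   each populated field).
#' @export
apply_ruleset <- function(rs, doc) {
  stopifnot(inherits(rs, "pft_ruleset"), is.character(doc), length(doc) == 1L)
  schema <- rs$schema
  values <- stats::setNames(
    lapply(schema$value_kind, missing_value), schema$name)
  status <- stats::setNames(
    rep("absent", length(rs$rules)),
    vapply(rs$rules, `[[`, "", "rule_id"))
  provenance <- list()

  for (r in rs$rules) {
    m <- regexpr(paste0("(?m)", r$pattern), doc, perl = TRUE)
    if (m[1] == -1L) {
      if (isTRUE(r$required)) {
        rlang::abort(
          sprintf("Required rule '%s' did not match the document.", r$rule_id),
          class = "pft_extraction_error", rule_id = r$rule_id)
      }
      next
    }
    cs <- attr(m, "capture.start")[1L, ]
    cl <- attr(m, "capture.length")[1L, ]
    converted <- list()
    prov <- list()
    failed <- FALSE
    for (g in names(r$bindings)) {
      fld <- r$bindings[[g]]
      raw <- substr(doc, cs[[g]], cs[[g]] + cl[[g]] - 1L)
      val <- convert_value(raw, r$converters[[fld]])
      if (is.null(val)) {
        rlang::warn(sprintf(
          "Rule '%s': capture '%s' ('%s') failed %s conversion; fields demoted to MISSING.",
          r$rule_id, g, raw, r$converters[[fld]]))
        failed <- TRUE
        break
      }
      converted[[fld]] <- val
      prov[[fld]] <- c(start = unname(cs[[g]]), end = unname(cs[[g]] + cl[[g]] - 1L))
    }
    if (failed) {
      status[[r$rule_id]] <- "conversion_error"
      next
    }
    status[[r$rule_id]] <- "matched"
    for (fld in names(converted)) values[[fld]] <- converted[[fld]]
    provenance <- c(provenance, prov)
  }

  structure(
    list(values = values, rule_status = status, provenance = provenance),
    class = "pft_parse_result"
  )
}

#' @export
print.pft_parse_result <- function(x, ...) {
  n_missing <- sum(vapply(x$values, function(v) is.na(v)[1], logical(1)))
  cat(sprintf("<pft_parse_result: %d fields (%d populated, %d missing); rules: %d matched, %d absent, %d conversion errors>\n",
              length(x$values), length(x$values) - n_missing, n_missing,
              sum(x$rule_status == "matched"), sum(x$rule_status == "absent"),
              sum(x$rule_status == "conversion_error")))
  invisible(x)
}
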