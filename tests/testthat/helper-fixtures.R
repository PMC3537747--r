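# Shared fixtures and independent oracles. Oracles are deliberately written
# with plain loops and base-R comparisons, independent of the package's own
# normalization and matching code paths.

tiny_ruleset_text <- function() {
  paste(
    "[fields]",
    "fvc_l, spirometry, decimal, L",
    "fvc_pct_pred, spirometry, integer, %predicted",
    "mrn, patient_meta, text,",
    "",
    "[rule fvc]",
    "pattern = ^FVC\\s+(?<fvc_l>-?\\d+\\.\\d+)\\s+(?<fvc_pct_pred>\\d+)\\s*$",
    "bind fvc_l -> fvc_l : decimal",
    "bind fvc_pct_pred -> fvc_pct_pred : integer",
    "",
    "[rule ident]",
    "pattern = ^MRN:\\s+(?<mrn>\\d+)\\s*$",
    "bind mrn -> mrn : text",
    sep = "\n"
  )
}

# Brute-force per-line scan: for each rule, walk the lines in order and take
# the first line the (line-anchored) pattern matches; convert captures with
# ad-hoc base R code.
scan_extract_oracle <- function(rs, doc) {
  lines <- strsplit(doc, "\n", fixed = TRUE)[[1]]
  out <- list()
  for (r in rs$rules) {
    for (ln in lines) {
      m <- regexpr(r$pattern, ln, perl = TRUE)
      if (m[1] == -1) next
      cs <- attr(m, "capture.start")[1, ]
      cl <- attr(m, "capture.length")[1, ]
      for (g in names(r$bindings)) {
        raw <- trimws(substr(ln, cs[[g]], cs[[g]] + cl[[g]] - 1))
        fld <- r$bindings[[g]]
        out[[fld]] <- switch(r$converters[[fld]],
          decimal = as.numeric(raw),
          integer = as.numeric(raw),
          date = as.Date(raw, format = "%m/%d/%Y"),
          sex = toupper(substr(raw, 1, 1)),
          raw)
      }
      break
    }
  }
  out
}

# Naive double-loop cell-equality check over two keyed tables.
naive_compare_oracle <- function(auto, manual, fields, key = "subject_id") {
  keys <- union(auto[[key]], manual[[key]])
  comparisons <- 0L
  agreements <- 0L
  for (k in keys) {
    ia <- which(auto[[key]] == k)
    im <- which(manual[[key]] == k)
    for (f in fields) {
      comparisons <- comparisons + 1L
      if (length(ia) != 1L || length(im) != 1L) next  # missing row: disagreement
      a <- auto[[f]][ia]
      b <- manual[[f]][im]
      eq <- if (is.na(a) && is.na(b)) TRUE
        else if (is.na(a) || is.na(b)) FALSE
        else if (is.numeric(a)) isTRUE(all.equal(a, b, tolerance = 1e-12))
        else identical(as.character(a), as.character(b))
      if (eq) agreements <- agreements + 1L
    }
  }
  list(comparisons = comparisons, agreements = agreements)
}

# Count ground-truth/extraction mismatches for one rendered test record,
# using printed-precision string equality. Returns character() when clean.
roundtrip_mismatches <- function(truth_row, result, field_table) {
  bad <- character()
  for (i in seq_len(nrow(field_table))) {
    f <- field_table$name[i]
    truth_val <- truth_row[[f]]
    got <- result$values[[f]]
    section <- field_table$section[i]
    omitted <- (section == "LUNG VOLUMES" && !isTRUE(truth_row$has_lung_volume)) ||
      (section == "DIFFUSION" && !isTRUE(truth_row$has_diffusion))
    if (omitted) {
      if (!is.na(got)) bad <- c(bad, sprintf("%s: expected MISSING, got %s", f, got))
      next
    }
    a <- regexmart:::canon_cell(truth_val, field_table$value_kind[i], field_table$digits[i])
    b <- regexmart:::canon_cell(got, field_table$value_kind[i], field_table$digits[i])
    if (!identical(a, b)) bad <- c(bad, sprintf("%s: truth=%s extracted=%s", f, a, b))
  }
  bad
}
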