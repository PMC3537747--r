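#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

pft_categories <- function() {
  c("spirometry", "lung_volume", "dlco", "pulse_ox", "anthropometric",
    "patient_meta", "measurement_meta")
}

numeric_categories <- function() {
  c("spirometry", "lung_volume", "dlco", "pulse_ox", "anthropometric")
}

value_kinds <- function() c("decimal", "integer", "text", "date", "sex_code")

converter_names <- function() c("decimal", "integer", "date", "text", "sex")

numeric_kinds <- function() c("decimal", "integer")

#' Load a declarative extraction ruleset from its plain-text configuration
#'
#' The configuration is a UTF-8 stanza file. A `[fields]` stanza declares the
#' schema, one field per line as `name, category, value_kind, units` (units
#' may be empty). Each `[rule <id>]` stanza declares one extraction rule:
#' a `pattern = <regex>` line (PCRE source with named capture groups), one
#' `bind <group> -> <field> : <converter>` line per capture group, and an
#' optional `required = true`. Lines starting with `#` and blank lines are
#' ignored.
#'
#' Patterns use the PCRE dialect as compiled by base R (`perl = TRUE`); the
#' engine prepends `(?m)` so `^`/`$` anchor to line boundaries. Capture group
#' names and bindings must agree exactly, every bound field must be declared
#' in the schema, and no field may be produced by more than one rule.
#'
#' @param path Path to a rule configuration file.
#' @param text The configuration as a single string (alternative to `path`).
#' @return A `pft_ruleset`: list with `rules` (ordered list of rules, each
#'   with `rule_id`, `pattern`, `bindings` (capture group -> field),
#'   `converters` (field -> converter), `required`) and `schema` (tibble with
#'   columns `name`, `category`, `value_kind`, `units`).
#' @seealso [apply_ruleset()], [field_summary()], [lint_ruleset()]
#' @export
load_ruleset <- function(path = NULL, text = NULL) {
  if (is.null(text) && is.null(path)) {
    abort("Provide either `path` or `text`.")
  }
  lines <- if (!is.null(text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(path, encoding = "UTF-8", warn = FALSE)
  }
  parsed <- parse_rule_config(lines)
  build_ruleset(parsed$fields, parsed$rules)
}

parse_rule_config <- function(lines) {
  fields <- list()
  rules <- list()
  current <- NULL  # NULL, "fields", or rule id
  rule <- NULL

  flush_rule <- function() {
    if (!is.null(rule)) rules[[length(rules) + 1]] <<- rule
    rule <<- NULL
  }

  for (i in seq_along(lines)) {
    raw <- lines[[i]]
    ln <- trimws(raw)
    if (ln == "" || startsWith(ln, "#")) next

    if (grepl("^\\[fields\\]$", ln)) {
      flush_rule()
      current <- "fields"
      next
    }
    m <- regexpr("^\\[rule\\s+([A-Za-z0-9_.-]+)\\]$", ln, perl = TRUE)
    if (m[1] != -1) {
      flush_rule()
      current <- "rule"
      rule <- list(rule_id = sub("^\\[rule\\s+([A-Za-z0-9_.-]+)\\]$", "\\1", ln),
                   pattern = NULL, bindings = character(), converters = character(),
                   required = FALSE, line = i)
      next
    }

    if (identical(current, "fields")) {
      parts <- trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
      parts <- c(parts, rep("", max(0L, 4L - length(parts))))
      if (length(parts) > 4L) {
        abort(sprintf("Line %d: malformed [fields] entry (expected 'name, category, value_kind, units'): %s", i, ln))
      }
      fields[[length(fields) + 1]] <- parts
    } else if (identical(current, "rule")) {
      if (grepl("^pattern\\s*=", ln)) {
        rule$pattern <- sub("^pattern\\s*=\\s?", "", ln)
      } else if (grepl("^required\\s*=", ln)) {
        rule$required <- tolower(trimws(sub("^required\\s*=", "", ln))) %in% c("true", "yes", "1")
      } else if (grepl("^bind\\s+", ln)) {
        bm <- regexec("^bind\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*->\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*([a-z_]+)$",
                      ln, perl = TRUE)
        parts <- regmatches(ln, bm)[[1]]
        if (length(parts) != 4L) {
          abort(sprintf("Rule '%s', line %d: malformed bind line: %s", rule$rule_id, i, ln))
        }
        rule$bindings[[parts[2]]] <- parts[3]
        rule$converters[[parts[3]]] <- parts[4]
      } else {
        abort(sprintf("Rule '%s', line %d: unrecognized directive: %s", rule$rule_id, i, ln))
      }
    } else {
      abort(sprintf("Line %d: content outside any stanza: %s", i, ln))
    }
  }
  flush_rule()

  schema <- if (length(fields)) {
    tibble(
      name = vapply(fields, `[[`, "", 1L),
      category = vapply(fields, `[[`, "", 2L),
      value_kind = vapply(fields, `[[`, "", 3L),
      units = vapply(fields, `[[`, "", 4L)
    )
  } else {
    tibble(name = character(), category = character(),
           value_kind = character(), units = character())
  }
  list(fields = schema, rules = rules)
}

build_ruleset <- function(schema, rules) {
  # schema validation
  dup <- schema$name[duplicated(schema$name)]
  if (length(dup)) abort(sprintf("Duplicate field declaration: %s", paste(unique(dup), collapse = ", ")))
  bad_cat <- setdiff(unique(schema$category), pft_categories())
  if (length(bad_cat)) abort(sprintf("Unknown field category: %s", paste(bad_cat, collapse = ", ")))
  bad_kind <- setdiff(unique(schema$value_kind), value_kinds())
  if (length(bad_kind)) abort(sprintf("Unknown value_kind: %s", paste(bad_kind, collapse = ", ")))
  is_num <- schema$value_kind %in% numeric_kinds()
  should_num <- schema$category %in% numeric_categories()
  off <- schema$name[is_num != should_num]
  if (length(off)) {
    abort(sprintf(
      "Numeric value kinds are allowed exactly in the physiologic categories; offending field(s): %s",
      paste(off, collapse = ", ")))
  }

  # rule validation
  seen_fields <- character()
  for (r in rules) {
    if (is.null(r$pattern)) {
      abort(sprintf("Rule '%s': missing pattern", r$rule_id))
    }
    comp <- tryCatch(
      suppressWarnings(regexpr(paste0("(?m)", r$pattern), "", perl = TRUE)),
      error = function(e) e
    )
    if (inherits(comp, "error")) {
      abort(sprintf("Rule '%s': malformed regex: %s", r$rule_id, conditionMessage(comp)))
    }
    groups <- attr(comp, "capture.names")
    groups <- groups[groups != ""]
    bound_groups <- names(r$bindings)
    if (!setequal(groups, bound_groups)) {
      missing_bind <- setdiff(groups, bound_groups)
      extra_bind <- setdiff(bound_groups, groups)
      abort(sprintf(
        "Rule '%s': capture groups and bind lines disagree%s%s",
        r$rule_id,
        if (length(missing_bind)) paste0("; unbound group(s): ", paste(missing_bind, collapse = ", ")) else "",
        if (length(extra_bind)) paste0("; bind(s) without group: ", paste(extra_bind, collapse = ", ")) else ""))
    }
    bad_conv <- setdiff(unname(r$converters), converter_names())
    if (length(bad_conv)) {
      abort(sprintf("Rule '%s': unknown converter(s): %s", r$rule_id, paste(bad_conv, collapse = ", ")))
    }
    fields_bound <- unname(r$bindings)
    undeclared <- setdiff(fields_bound, schema$name)
    if (length(undeclared)) {
      abort(sprintf("Rule '%s': binding to undeclared field(s): %s",
                    r$rule_id, paste(undeclared, collapse = ", ")))
    }
    dup_local <- fields_bound[duplicated(fields_bound)]
    dup_cross <- intersect(fields_bound, seen_fields)
    dupes <- unique(c(dup_local, dup_cross))
    if (length(dupes)) {
      abort(sprintf("Field(s) bound more than once: %s (rule '%s')",
                    paste(dupes, collapse = ", "), r$rule_id))
    }
    seen_fields <- c(seen_fields, fields_bound)
  }

  unbound <- setdiff(schema$name, seen_fields)
  if (length(unbound)) {
    warn(sprintf("Schema field(s) not bound by any rule: %s", paste(unbound, collapse = ", ")))
  }

  structure(
    list(rules = rules, schema = schema),
    class = "pft_ruleset"
  )
}

#' Lint a ruleset configuration
#'
#' Runs the full set of structural checks over a rule configuration and
#' returns the problems found instead of aborting at the first one. Checks
#' cover: regex compilation, capture-group/bind agreement, undeclared fields,
#' fields bound more than once, and schema fields bound by no rule.
#'
#' @param path,text Passed to [load_ruleset()].
#' @return A tibble with columns `severity`, `where`, `message`; zero rows
#'   means the configuration is clean.
#' @export
lint_ruleset <- function(path = NULL, text = NULL) {
  issues <- list()
  rs <- withCallingHandlers(
    tryCatch(load_ruleset(path = path, text = text), error = function(e) e),
    warning = function(w) {
      issues[[length(issues) + 1]] <<- tibble(
        severity = "error", where = "ruleset", message = conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (inherits(rs, "error")) {
    issues[[length(issues) + 1]] <- tibble(
      severity = "error", where = "ruleset", message = conditionMessage(rs))
  }
  if (length(issues)) dplyr::bind_rows(issues) else {
    tibble(severity = character(), where = character(), message = character())
  }
}

#' Summarize a ruleset's field dictionary
#'
#' Counts schema fields per category and totals them by numeric versus
#' non-numeric value kind. For the default PFT ruleset this reproduces the
#' full mart dictionary: 54 spirometry, 26 lung-volume, 12 diffusion,
#' 2 pulse-oximetry and 2 anthropometric numeric measures plus 6 patient and
#' 5 measurement non-numeric fields — 96 numeric, 107 in all.
#'
#' @param rs A `pft_ruleset`.
#' @return A list with `by_category` (named integer vector over all seven
#'   categories), `numeric`, `non_numeric`, and `total`.
#' @export
field_summary <- function(rs) {
  stopifnot(inherits(rs, "pft_ruleset"))
  cats <- pft_categories()
  counts <- vapply(cats, function(cc) sum(rs$schema$category == cc), integer(1))
  n_num <- sum(rs$schema$value_kind %in% numeric_kinds())
  list(
    by_category = counts,
    numeric = n_num,
    non_numeric = nrow(rs$schema) - n_num,
    total = nrow(rs$schema)
  )
}

#' @export
print.pft_ruleset <- function(x, ...) {
  fs <- field_summary(x)
  cat(sprintf("<pft_ruleset: %d rules, %d fields (%d numeric, %d non-numeric)>\n",
              length(x$rules), fs$total, fs$numeric, fs$non_numeric))
  invisible(x)
}
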