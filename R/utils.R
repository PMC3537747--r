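# Internal helpers shared across modules.

# Deterministic 8-hex-character string hash (31-polynomial mod 2^31 - 1).
# Used only to derive reproducible surrogate keys; exact in double arithmetic
# because intermediate values stay far below 2^53.
str_hash32 <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    bytes <- utf8ToInt(enc2utf8(s))
    h <- 17
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", h)
  }, character(1), USE.NAMES = FALSE)
}

# Half-up rounding (base round() is half-even; agreement percentages are
# reported half-up so 1094/1100 -> 99.5).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

fmt_decimal <- function(x, digits) {
  formatC(x, format = "f", digits = digits)
}

fmt_integer <- function(x) {
  sprintf("%d", as.integer(round(x)))
}

normalize_sex <- function(x) {
  u <- toupper(trimws(x))
  out <- ifelse(u %in% c("M", "MALE"), "M",
         ifelse(u %in% c("F", "FEMALE"), "F", NA_character_))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
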