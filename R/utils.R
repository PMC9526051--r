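# Internal helpers shared across modules.

# Round half away from zero at `dp` decimal places. Table-style rounding:
# printed cM/rate columns use 5-up rounding (e.g. 0.25 -> 0.3), which base
# round() (round-half-even) does not reproduce.
round_half_up <- function(x, dp = 1) {
  p <- 10^dp
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Strip comma thousands separators and convert to numeric; NA stays NA.
strip_commas <- function(x) {
  suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tl <- function(...) stop(sprintf(...), call. = FALSE)
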