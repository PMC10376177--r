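#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# round half away from zero; base round() is banker's rounding, but reported
# integer masses follow the everyday convention (6515.5 -> 6516)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# |a - b| in parts-per-million of b
ppm_diff <- function(a, b) abs(a - b) / b * 1e6

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

stop_validation <- function(msg) abort(msg, class = "xlinkxic_validation_error")
stop_format <- function(msg) abort(msg, class = "xlinkxic_format_error")
stop_config <- function(msg) abort(msg, class = "xlinkxic_config_error")
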