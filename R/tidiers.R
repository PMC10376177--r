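#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.rate_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.rate_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r.squared = x$r2,
         window_start = x$window[1], window_end = x$window[2], n = x$n)
}

#' @exportS3Method generics::tidy
tidy.melt_fit <- function(x, ...) {
  tibble(term = c("tm", "onset"), estimate = c(x$tm, x$onset))
}

#' @exportS3Method generics::glance
glance.melt_fit <- function(x, ...) {
  tibble(tm = x$tm, onset = x$onset, amplitude = x$amplitude,
         direction = x$direction)
}

#' @exportS3Method generics::tidy
tidy.coelution_evidence <- function(x, ...) x$charges

#' @exportS3Method generics::glance
glance.coelution_evidence <- function(x, ...) {
  tibble(accepted = x$accepted, n_charges_found = x$n_charges_found,
         apex_rt = x$apex_rt, rt_spread = x$rt_spread,
         summed_intensity = x$summed_intensity)
}
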