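#' Assay context for specific-activity computation
#'
#' Bundles the Beer-Lambert parameters of a spectrophotometric assay: the
#' substrate's molar extinction coefficient (mM^-1 cm^-1, or M^-1 cm^-1
#' with `epsilon_unit = "M"`), the cuvette path length, the reaction volume,
#' and the enzyme amount. One enzyme unit U is 1 umol of substrate
#' converted per minute; `stoich_factor` (default 1, i.e. not applied)
#' rescales ΔA-derived rates when a reaction convention counts several
#' substrate molecules per chromophore change.
#'
#' @param substrate Substrate name (e.g. "ABTS", "H2O2").
#' @param epsilon Extinction coefficient at the monitored wavelength.
#' @param epsilon_unit `"mM"` for mM^-1 cm^-1 (default) or `"M"` for
#'   M^-1 cm^-1 (converted by x 1e-3).
#' @param wavelength Monitored wavelength, nm (metadata).
#' @param path_cm Optical path length, cm.
#' @param volume_ml Reaction volume, mL.
#' @param enzyme_mg Enzyme amount in the reaction, mg.
#' @param temperature,ph Assay conditions (metadata).
#' @param stoich_factor Substrate molecules per observed chromophore
#'   conversion.
#' @return An object of class `assay_context`.
#' @export
#' @examples
#' assay_context("ABTS", 31.1, wavelength = 414, volume_ml = 1, enzyme_mg = 0.01)
assay_context <- function(substrate, epsilon, epsilon_unit = c("mM", "M"),
                          wavelength = NA_real_, path_cm = 1, volume_ml,
                          enzyme_mg, temperature = NA_real_, ph = NA_real_,
                          stoich_factor = 1) {
  epsilon_unit <- match.arg(epsilon_unit)
  if (epsilon <= 0) stop_validation("epsilon must be > 0")
  if (path_cm <= 0) stop_validation("path length must be > 0")
  if (volume_ml <= 0) stop_validation("reaction volume must be > 0")
  if (enzyme_mg <= 0) stop_validation("enzyme amount must be > 0")
  structure(list(substrate = substrate, epsilon = epsilon,
                 epsilon_unit = epsilon_unit, wavelength = wavelength,
                 path_cm = path_cm, volume_ml = volume_ml,
                 enzyme_mg = enzyme_mg, temperature = temperature, ph = ph,
                 stoich_factor = stoich_factor),
            class = "assay_context")
}

#' @export
print.assay_context <- function(x, ...) {
  cat(sprintf("<assay_context> %s: eps = %g %s^-1 cm^-1 (%g nm), path %g cm, %g mL, %g mg enzyme\n",
              x$substrate, x$epsilon, x$epsilon_unit, x$wavelength,
              x$path_cm, x$volume_ml, x$enzyme_mg))
  invisible(x)
}

#' Read assay contexts from a YAML config keyed by substrate
#'
#' Each top-level key is a substrate name mapping to [assay_context()]
#' arguments. A bundled config with the usual peroxidase/catalase substrate
#' extinction coefficients ships as
#' `system.file("extdata", "assay_contexts.yaml", package = "xlinkxic")`.
#'
#' @param path YAML file.
#' @param ... Overrides applied to every context (e.g. `enzyme_mg`).
#' @return Named list of [assay_context()] objects.
#' @export
read_assay_contexts <- function(path, ...) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  overrides <- list(...)
  purrr::imap(raw, function(args, substrate) {
    args$substrate <- substrate
    args[names(overrides)] <- overrides
    do.call(assay_context, args)
  })
}

#' Fit the initial linear rate of an absorbance trace
#'
#' Ordinary least squares of absorbance on time. With an explicit window the
#' fit uses exactly those points; otherwise the maximal initial window with
#' R^2 >= `r2_threshold` is selected (the initial-rate convention), so
#' late-time curvature is excluded automatically. A perfectly flat trace has
#' zero residuals and is treated as R^2 = 1.
#'
#' @param trace Tibble with columns `time_min`, `absorbance` (from
#'   [simulate_kinetics_trace()] or read from CSV).
#' @param window Optional numeric length-2 time interval (minutes).
#' @param min_points Minimum points in the fit window (default 5).
#' @param r2_threshold R^2 criterion for automatic window growth.
#' @return An object of class `rate_fit`: `slope` (ΔA/min), `intercept`,
#'   `r2`, `window` (minutes), `n`.
#' @export
fit_linear_rate <- function(trace, window = NULL, min_points = 5L,
                            r2_threshold = 0.99) {
  stopifnot(all(c("time_min", "absorbance") %in% names(trace)))
  trace <- dplyr::arrange(as_tibble(trace), .data$time_min)
  if (!is.null(window)) {
    trace <- trace[trace$time_min >= window[1] & trace$time_min <= window[2], ]
    if (nrow(trace) < min_points) {
      stop_validation(sprintf("fewer than %d points in fit window", min_points))
    }
    n_use <- nrow(trace)
  } else {
    if (nrow(trace) < min_points) {
      stop_validation(sprintf("fewer than %d points in trace", min_points))
    }
    n_use <- min_points
    for (n in seq.int(min_points, nrow(trace))) {
      if (prefix_r2(trace, n) >= r2_threshold) n_use <- n else break
    }
    if (prefix_r2(trace, min_points) < r2_threshold) {
      warn(sprintf("no initial window reaches R^2 >= %g; using first %d points",
                   r2_threshold, min_points))
    }
    trace <- trace[seq_len(n_use), ]
  }
  fit <- stats::lm(absorbance ~ time_min, data = trace)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2_of(fit, trace$absorbance),
                 window = range(trace$time_min),
                 n = n_use),
            class = "rate_fit")
}

prefix_r2 <- function(trace, n) {
  d <- trace[seq_len(n), ]
  r2_of(stats::lm(absorbance ~ time_min, data = d), d$absorbance)
}

r2_of <- function(fit, y) {
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < .Machine$double.eps) {
    return(if (ss_res < .Machine$double.eps) 1 else 0)
  }
  1 - ss_res / ss_tot
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> slope %.5g dA/min over [%.3f, %.3f] min (n = %d, R^2 = %.4f)\n",
              x$slope, x$window[1], x$window[2], x$n, x$r2))
  invisible(x)
}

#' Specific enzymatic activity from an absorbance slope
#'
#' Beer-Lambert conversion of an absorbance rate to enzyme units:
#' `U/mg = |slope| / (epsilon_mM * path_cm) * volume_ml * stoich_factor /
#' enzyme_mg`, with the slope in ΔA/min. The quotient
#' `|slope| / (epsilon * path)` is the substrate conversion rate in mM/min,
#' i.e. umol per mL per minute; scaling by the reaction volume gives
#' umol/min (U) and dividing by the enzyme mass gives U/mg.
#'
#' @param slope Absorbance slope, ΔA/min (a [fit_linear_rate()] object is
#'   also accepted).
#' @param ctx An [assay_context()].
#' @return A one-row tibble: `substrate`, `slope`, `rate_mM_min`, `rate_u`
#'   (umol/min), `specific_activity` (U/mg).
#' @export
#' @examples
#' ctx <- assay_context("ABTS", 31.1, volume_ml = 1, enzyme_mg = 0.01)
#' specific_activity(0.311, ctx)   # 1 U/mg
specific_activity <- function(slope, ctx) {
  if (inherits(slope, "rate_fit")) slope <- slope$slope
  eps_mM <- if (ctx$epsilon_unit == "M") ctx$epsilon * 1e-3 else ctx$epsilon
  rate_mM <- abs(slope) / (eps_mM * ctx$path_cm)
  rate_u <- rate_mM * ctx$volume_ml * ctx$stoich_factor
  tibble(substrate = ctx$substrate, slope = slope, rate_mM_min = rate_mM,
         rate_u = rate_u, specific_activity = rate_u / ctx$enzyme_mg)
}

#' Melting point and onset from a fluorescence-ratio curve
#'
#' The melting temperature Tm is the inflection of the unfolding transition,
#' located as the maximum of the smoothed absolute first derivative of the
#' ratio versus temperature (a centered `smooth_window`-point moving average
#' applied to the curve before differencing and to the derivative after,
#' which leaves the symmetric inflection unbiased) with 3-point parabolic
#' refinement of the peak position. The
#' onset is the lowest temperature at which the curve departs from the
#' pre-transition baseline by more than `onset_frac` (default 2%) of the
#' total amplitude, in the direction of the transition. A flat curve raises
#' "no transition detected".
#'
#' @param curve Tibble with columns `temperature`, `ratio`.
#' @param smooth_window Centered moving-average window (points, odd).
#' @param onset_frac Baseline-departure fraction defining the onset.
#' @return An object of class `melt_fit`: `tm`, `onset` (degrees C),
#'   `amplitude`, `direction` (+1 increasing / -1 decreasing), `method`.
#' @export
melt_analysis <- function(curve, smooth_window = 5L, onset_frac = 0.02) {
  stopifnot(all(c("temperature", "ratio") %in% names(curve)))
  curve <- dplyr::arrange(as_tibble(curve), .data$temperature)
  if (nrow(curve) < 10L) stop_validation("need >= 10 points spanning the transition")
  t <- curve$temperature; y <- curve$ratio
  amplitude <- diff(range(y))
  if (amplitude < 1e-9 * max(1, stats::median(abs(y)))) {
    stop_validation("no transition detected: curve is flat")
  }
  movavg <- function(x) {
    as.numeric(stats::filter(x, rep(1 / smooth_window, smooth_window), sides = 2))
  }
  ys <- movavg(y)
  keep <- !is.na(ys)
  dmid <- diff(ys[keep]) / diff(t[keep])
  tmid <- (t[keep][-1] + t[keep][-sum(keep)]) / 2
  sm <- movavg(dmid)
  ok <- which(!is.na(sm))
  i <- ok[which.max(abs(sm[ok]))]
  tm <- refine_peak(tmid, abs(sm), i)
  direction <- sign(sm[i])

  # onset on the smoothed curve, and only where the departure persists for
  # three consecutive points, so noise at the threshold scale cannot fire it
  y_on <- ifelse(is.na(ys), y, ys)
  pre_n <- max(3L, min(10L, floor(nrow(curve) * 0.05)))
  baseline <- mean(y_on[seq_len(pre_n)])
  dep <- direction * (y_on - baseline) > onset_frac * amplitude
  persistent <- dep & dplyr::lead(dep, 1, default = TRUE) &
    dplyr::lead(dep, 2, default = TRUE)
  onset <- if (any(persistent)) t[which(persistent)[1]] else NA_real_
  structure(list(tm = tm, onset = onset, amplitude = amplitude,
                 direction = direction,
                 method = c(tm = "smoothed-derivative maximum",
                            onset = sprintf("%.0f%% amplitude departure", onset_frac * 100))),
            class = "melt_fit")
}

# 3-point parabolic interpolation of a discrete peak position
refine_peak <- function(x, y, i) {
  if (i <= 1L || i >= length(y) || is.na(y[i - 1]) || is.na(y[i + 1])) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (abs(denom) < .Machine$double.eps) return(x[i])
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  delta <- max(-0.5, min(0.5, delta))
  x[i] + delta * (x[i + 1] - x[i])
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> Tm = %.2f C, onset = %.2f C (%s transition)\n",
              x$tm, x$onset, if (x$direction > 0) "increasing" else "decreasing"))
  invisible(x)
}
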