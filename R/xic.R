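#' Extract an ion chromatogram
#'
#' For every scan, sums the intensities of centroid peaks within `tol_ppm`
#' of the target m/z. The apex is the scan with the maximum summed
#' intensity; an all-zero trace is allowed (apex RT is then `NA`).
#'
#' @param run An [ms_run()].
#' @param mz Target m/z in Th.
#' @param tol_ppm Matching half-window in ppm (default 10).
#' @return A tibble of class `xic` with columns `rt`, `intensity` (one row
#'   per scan) and attributes `mz`, `tol_ppm`, `apex_rt`, `apex_intensity`.
#' @export
extract_xic <- function(run, mz, tol_ppm = 10) {
  if (tol_ppm <= 0) stop_validation("tol_ppm must be > 0")
  halfwin <- mz * tol_ppm * 1e-6
  p <- run$peaks
  sel <- abs(p$mz - mz) <= halfwin
  trace <- rep(0, nrow(run$scans))
  if (any(sel)) {
    sums <- tapply(p$intensity[sel], factor(p$scan[sel], levels = run$scans$scan), sum)
    trace <- as.numeric(ifelse(is.na(sums), 0, sums))
  }
  out <- tibble(rt = run$scans$rt, intensity = trace)
  apex <- which.max(trace)
  attr(out, "mz") <- mz
  attr(out, "tol_ppm") <- tol_ppm
  attr(out, "apex_rt") <- if (trace[apex] > 0) out$rt[apex] else NA_real_
  attr(out, "apex_intensity") <- trace[apex]
  class(out) <- c("xic", class(out))
  out
}

#' @export
print.xic <- function(x, ...) {
  cat(sprintf("<xic> m/z %.4f +/- %g ppm, apex %.3f min (intensity %.4g)\n",
              attr(x, "mz"), attr(x, "tol_ppm"),
              attr(x, "apex_rt") %||% NA_real_, attr(x, "apex_intensity")))
  NextMethod()
}

# robust apex noise floor: a real chromatographic apex stands well above the
# bulk of its own trace, whereas a trace holding only stray noise hits does
# not (a single-point trace can never pass: apex equals its own median)
xic_noise_floor <- function(trace, k = 3) {
  nz <- trace[trace > 0]
  if (length(nz) == 0L) return(Inf)
  k * stats::median(nz)
}

#' Detect coelution of the charge states of a target species
#'
#' Extracts one XIC per theoretical charge state, keeps apexes whose
#' intensity exceeds a robust per-trace noise floor (3 x the median nonzero
#' trace intensity), and searches for the
#' largest set of apexes falling inside a retention-time window of width
#' `rt_tol`. Coelution of at least `min_charges` ion forms within that
#' window is the XIC-level evidence that the species is present.
#'
#' @param run An [ms_run()].
#' @param series Theoretical ion series ([ion_series()]).
#' @param tol_ppm XIC tolerance, ppm.
#' @param rt_tol Coelution retention-time window, minutes.
#' @param min_charges Minimum number of coeluting charge states.
#' @return An object of class `coelution_evidence`: list with `charges`
#'   (tibble: `z`, `mz`, `apex_rt`, `apex_intensity`, `above_floor`,
#'   `in_cluster`), `xics` (list of [extract_xic()] traces keyed by charge),
#'   `n_charges_found`, `rt_spread`, `apex_rt` (median of the cluster),
#'   `summed_intensity`, `accepted`, and the parameters used.
#' @export
detect_coelution <- function(run, series, tol_ppm = 10, rt_tol = 0.2,
                             min_charges = 2L) {
  if (nrow(series) == 0L) stop_validation("ion series is empty")
  xics <- purrr::map(series$mz, function(m) extract_xic(run, m, tol_ppm))
  names(xics) <- as.character(series$z)
  ch <- tibble(
    z = series$z, mz = series$mz,
    apex_rt = purrr::map_dbl(xics, function(x) attr(x, "apex_rt") %||% NA_real_),
    apex_intensity = purrr::map_dbl(xics, function(x) attr(x, "apex_intensity")),
    floor = purrr::map_dbl(xics, function(x) xic_noise_floor(x$intensity))
  )
  ch$above_floor <- !is.na(ch$apex_rt) & ch$apex_intensity > ch$floor
  ch$in_cluster <- FALSE

  found <- ch[ch$above_floor, ]
  cluster_idx <- integer()
  if (nrow(found) > 0L) {
    rts <- sort(found$apex_rt)
    # densest window of width rt_tol over the found apexes
    best <- 0L; best_lo <- NA_real_
    for (i in seq_along(rts)) {
      n_in <- sum(rts >= rts[i] & rts <= rts[i] + rt_tol)
      if (n_in > best) { best <- n_in; best_lo <- rts[i] }
    }
    cluster_idx <- which(ch$above_floor & ch$apex_rt >= best_lo &
                           ch$apex_rt <= best_lo + rt_tol)
    ch$in_cluster[cluster_idx] <- TRUE
  }
  n_found <- length(cluster_idx)
  spread <- if (n_found > 0L) diff(range(ch$apex_rt[cluster_idx])) else NA_real_
  structure(list(
    charges = ch[, c("z", "mz", "apex_rt", "apex_intensity", "above_floor", "in_cluster")],
    xics = xics,
    n_charges_found = n_found,
    rt_spread = spread,
    apex_rt = if (n_found > 0L) stats::median(ch$apex_rt[cluster_idx]) else NA_real_,
    summed_intensity = sum(ch$apex_intensity[cluster_idx]),
    accepted = n_found >= min_charges,
    tol_ppm = tol_ppm, rt_tol = rt_tol, min_charges = min_charges
  ), class = "coelution_evidence")
}

#' @export
print.coelution_evidence <- function(x, ...) {
  cat("<coelution_evidence> ",
      if (x$accepted) "ACCEPTED" else "not accepted",
      ": ", x$n_charges_found, " charge(s) coeluting",
      if (x$n_charges_found > 0)
        sprintf(" at %.3f min (spread %.4f min)", x$apex_rt, x$rt_spread),
      "\n", sep = "")
  print(x$charges)
  invisible(x)
}

#' Deconvolute coeluting charge states to a neutral monoisotopic mass
#'
#' In the scan nearest the coelution apex, takes for each supporting charge
#' the most intense peak within `tol_ppm` of the theoretical m/z and inverts
#' the ion-form relation, `M = z * m/z - z * proton`. Charges with no peak
#' in tolerance are dropped (degraded result); the mass estimate is the
#' median over charges and the dispersion the maximum absolute deviation
#' from it.
#'
#' @param run An [ms_run()].
#' @param series Theoretical ion series of the target.
#' @param evidence Accepted [detect_coelution()] evidence.
#' @param tol_ppm Peak-matching tolerance, ppm.
#' @return An object of class `deconvolution_result`: list with `mass`
#'   (median estimate, Da), `dispersion` (Da), `per_charge` (tibble `z`,
#'   `mz_observed`, `mass_estimate`), `rt` (scan RT used).
#' @export
deconvolute <- function(run, series, evidence, tol_ppm = 10) {
  if (!isTRUE(evidence$accepted)) {
    stop_validation("deconvolute() requires accepted coelution evidence")
  }
  scan_i <- which.min(abs(run$scans$rt - evidence$apex_rt))
  scan_id <- run$scans$scan[scan_i]
  p <- run$peaks[run$peaks$scan == scan_id, ]
  zs <- evidence$charges$z[evidence$charges$in_cluster]
  per <- purrr::map(zs, function(z) {
    mz_theo <- series$mz[series$z == z]
    sel <- which(abs(p$mz - mz_theo) <= mz_theo * tol_ppm * 1e-6)
    if (length(sel) == 0L) return(NULL)
    mz_obs <- p$mz[sel[which.max(p$intensity[sel])]]
    tibble(z = z, mz_observed = mz_obs,
           mass_estimate = z * mz_obs - z * mass_constants$proton)
  })
  per <- dplyr::bind_rows(per)
  if (nrow(per) == 0L) stop_validation("no supporting peaks within tolerance at the apex scan")
  est <- stats::median(per$mass_estimate)
  structure(list(mass = est,
                 dispersion = max(abs(per$mass_estimate - est)),
                 per_charge = per,
                 rt = run$scans$rt[scan_i]),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("<deconvolution_result> M = %.5f Da (dispersion %.2g Da, %d charge(s), RT %.3f min)\n",
              x$mass, x$dispersion, nrow(x$per_charge), x$rt))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.deconvolution_result <- function(x, ...) x$per_charge

#' @exportS3Method generics::glance
glance.deconvolution_result <- function(x, ...) {
  tibble(mass = x$mass, dispersion = x$dispersion,
         n_charges = nrow(x$per_charge), rt = x$rt)
}

#' Infer charge from isotopologue spacing
#'
#' Consecutive isotope peaks of a z-fold protonated species are separated by
#' 1.003355 / z Th. Given at least two centroid peaks of one envelope, the
#' charge is `round(1.003355 / median spacing)`. The spacing must be regular
#' (consecutive spacings within 20% of their median) and must land near an
#' integer charge (fractional part of `1.003355 / spacing` within 0.1, i.e.
#' 20% of the half-integer gap); otherwise the charge is ambiguous.
#'
#' @param mz Numeric vector of isotope-peak m/z values (>= 2).
#' @return Integer charge.
#' @export
#' @examples
#' infer_charge_from_isotopes(c(500, 500.250838, 500.501677))  # 4
infer_charge_from_isotopes <- function(mz) {
  if (length(mz) < 2L) stop_validation("need at least 2 isotope peaks")
  d <- diff(sort(mz))
  med <- stats::median(d)
  if (med <= 0) stop_validation("ambiguous charge: non-positive isotope spacing")
  if (any(abs(d - med) / med > 0.2)) {
    stop_validation("ambiguous charge: irregular isotope spacing (> 20% deviation)")
  }
  z_real <- mass_constants$isotope_spacing / med
  z <- round(z_real)
  if (z < 1 || abs(z_real - z) > 0.1) {
    stop_validation(sprintf(
      "ambiguous charge: spacing %.5f Th implies z = %.3f, not close to an integer",
      med, z_real))
  }
  as.integer(z)
}
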