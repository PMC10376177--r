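#' Averagine isotope envelope
#'
#' Approximates the isotopologue pattern of a peptide of monoisotopic mass M
#' using the averagine average-residue composition (C4.9384 H7.7583 N1.3577
#' O1.4773 S0.0417 per 111.1254 Da) and a Poisson model for the number of
#' heavy-isotope substitutions. Offsets are multiples of 1.003355 Da and
#' intensities are normalized to a maximum of 1.
#'
#' @param mass Neutral monoisotopic mass, Da (> 0).
#' @param n_peaks Number of isotope peaks to return (default: enough to
#'   cover the envelope, at least 5).
#' @return A tibble with columns `k` (isotope index from 0), `offset` (Da),
#'   `intensity` (max 1).
#' @export
#' @examples
#' isotope_envelope(1000)
isotope_envelope <- function(mass, n_peaks = NULL) {
  if (mass <= 0) stop_validation("mass must be > 0")
  lambda <- averagine_lambda(mass)
  if (is.null(n_peaks)) n_peaks <- max(5, ceiling(lambda + 4 * sqrt(lambda) + 1))
  k <- 0:(n_peaks - 1L)
  w <- stats::dpois(k, lambda)
  tibble(k = k, offset = k * mass_constants$isotope_spacing,
         intensity = w / max(w))
}

# expected number of +1 heavy-isotope substitutions per averagine unit,
# from the natural abundances of 13C, 2H, 15N, 17O, 33S
averagine_lambda <- function(mass) {
  per_unit <- 4.9384 * 0.0107 + 7.7583 * 0.000115 + 1.3577 * 0.00364 +
    1.4773 * 0.00038 + 0.0417 * 0.0075
  mass / 111.1254 * per_unit
}

#' Describe a planted species for run simulation
#'
#' @param mass Neutral monoisotopic mass, Da.
#' @param charges Integer vector of charge states carrying the species.
#' @param rt Elution center, minutes.
#' @param width Gaussian elution sigma, minutes.
#' @param abundance Apex intensity of the most intense isotope peak.
#' @param envelope Optional user-supplied envelope (tibble `offset`,
#'   `intensity`); default averagine.
#' @return One-row tibble with a list-column `envelope`.
#' @export
planted_species <- function(mass, charges, rt, width = 0.05,
                            abundance = 1e4, envelope = NULL) {
  if (mass <= 0) stop_validation("mass must be > 0")
  if (width <= 0) stop_validation("width must be > 0")
  if (any(charges < 1)) stop_validation("charges must be positive")
  env <- envelope %||% isotope_envelope(mass)
  tibble(mass = mass, charges = list(as.integer(charges)), rt = rt,
         width = width, abundance = abundance, envelope = list(env))
}

#' Noise model for simulated runs
#'
#' @param baseline Mean intensity of random noise peaks (exponential
#'   distribution); 0 disables noise peaks. The default, together with the
#'   default species abundance of 1e4, keeps the signal-to-noise ratio of
#'   the monoisotopic target channel of a 4-7 kDa species at or above 10
#'   (the envelope apex is ~100x the noise mean; the monoisotopic peak
#'   carries 10-30% of the apex intensity at these masses).
#' @param peaks_per_scan Number of random noise peaks per scan.
#' @param jitter_ppm Gaussian m/z jitter (standard deviation, ppm) applied
#'   to planted peaks; emulates instrument mass error.
#' @param mz_range m/z range for noise peaks, Th.
#' @param seed Integer seed; identical seeds give bit-identical runs.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(baseline = 100, peaks_per_scan = 20L,
                        jitter_ppm = 0.5, mz_range = c(300, 2000),
                        seed = 1L) {
  if (baseline < 0 || peaks_per_scan < 0 || jitter_ppm < 0) {
    stop_validation("noise model parameters must be >= 0")
  }
  structure(list(baseline = baseline, peaks_per_scan = as.integer(peaks_per_scan),
                 jitter_ppm = jitter_ppm, mz_range = mz_range,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a centroided LC-MS run with planted species
#'
#' Builds scans on a regular retention-time grid. Each species contributes,
#' for every charge state, its isotope envelope at
#' `(M + k * 1.003355 + z * proton) / z`, scaled by a Gaussian elution
#' profile (evaluated over +/- 6 sigma) and the species abundance. Noise
#' peaks and m/z jitter follow the noise model; everything is reproducible
#' from its seed. Species whose +/- 6 sigma elution window lies entirely
#' outside the run are flagged unobservable with a warning.
#'
#' @param species Tibble of [planted_species()] rows (bind with
#'   `dplyr::bind_rows()`).
#' @param scan_interval Scan spacing, minutes (default 0.01).
#' @param run_length Run length, minutes (default 60, a typical gradient).
#' @param noise A [noise_model()].
#' @return A list with `run` (an [ms_run()]) and `truth` (tibble:
#'   `species_id`, `mass`, `charges` ("/"-joined), `rt`, `width`,
#'   `abundance`, `observable`, `seed`).
#' @export
simulate_run <- function(species, scan_interval = 0.01, run_length = 60,
                         noise = noise_model()) {
  if (run_length <= 0) stop_validation("run_length must be > 0")
  rt_grid <- seq(0, run_length, by = scan_interval)
  n_scan <- length(rt_grid)

  observable <- species$rt - 6 * species$width < run_length &
    species$rt + 6 * species$width > 0
  if (any(!observable)) {
    warn(sprintf("%d species elute entirely outside the run and are unobservable",
                 sum(!observable)))
  }

  planted <- withr::with_seed(noise$seed, {
    parts <- purrr::map(which(observable), function(i) {
      sp <- species[i, ]
      scan_sel <- which(rt_grid >= sp$rt - 6 * sp$width &
                          rt_grid <= sp$rt + 6 * sp$width)
      profile <- exp(-(rt_grid[scan_sel] - sp$rt)^2 / (2 * sp$width^2))
      env <- sp$envelope[[1]]
      grid <- tidyr::expand_grid(z = sp$charges[[1]],
                                 iso = seq_len(nrow(env)))
      per_peak <- purrr::map(seq_len(nrow(grid)), function(g) {
        z <- grid$z[g]; iso <- grid$iso[g]
        mz0 <- (sp$mass + env$offset[iso] + z * mass_constants$proton) / z
        tibble(scan = scan_sel, mz = mz0,
               intensity = sp$abundance * env$intensity[iso] * profile)
      })
      dplyr::bind_rows(per_peak)
    })
    planted <- dplyr::bind_rows(parts)
    if (nrow(planted) == 0L) {
      planted <- tibble(scan = integer(), mz = double(), intensity = double())
    }
    if (nrow(planted) > 0 && noise$jitter_ppm > 0) {
      planted$mz <- planted$mz *
        (1 + stats::rnorm(nrow(planted), 0, noise$jitter_ppm * 1e-6))
    }
    noise_peaks <- NULL
    if (noise$peaks_per_scan > 0 && noise$baseline > 0) {
      n_noise <- noise$peaks_per_scan * n_scan
      noise_peaks <- tibble(
        scan = rep(seq_len(n_scan), each = noise$peaks_per_scan),
        mz = stats::runif(n_noise, noise$mz_range[1], noise$mz_range[2]),
        intensity = stats::rexp(n_noise, 1 / noise$baseline))
    }
    dplyr::bind_rows(planted, noise_peaks)
  })

  run <- ms_run(tibble(scan = seq_len(n_scan), rt = rt_grid), planted,
                metadata = list(source = "simulate_run", seed = noise$seed))
  truth <- tibble(
    species_id = sprintf("sp_%03d", seq_len(nrow(species))),
    mass = species$mass,
    charges = purrr::map_chr(species$charges, paste, collapse = "/"),
    rt = species$rt, width = species$width, abundance = species$abundance,
    observable = observable, seed = noise$seed)
  list(run = run, truth = truth)
}

#' Simulate a linear absorbance kinetics trace
#'
#' `A(t) = intercept + slope * t + N(0, noise_sd)`, sampled every
#' `interval` seconds for `duration` minutes; emulates an initial-rate
#' spectrophotometric recording.
#'
#' @param slope Slope in absorbance units per minute (negative for substrate
#'   depletion, e.g. the catalatic H2O2 decay at 240 nm).
#' @param intercept Absorbance at t = 0.
#' @param duration Trace length, minutes.
#' @param interval Sampling interval, seconds.
#' @param noise_sd Gaussian noise SD, absorbance units.
#' @param seed Integer seed.
#' @return A tibble with columns `time_min`, `absorbance`.
#' @export
simulate_kinetics_trace <- function(slope, intercept = 0.1, duration = 1,
                                    interval = 1, noise_sd = 0, seed = 1L) {
  if (duration <= 0) stop_validation("duration must be > 0")
  t <- seq(0, duration, by = interval / 60)
  withr::with_seed(seed, {
    tibble(time_min = t,
           absorbance = intercept + slope * t + stats::rnorm(length(t), 0, noise_sd))
  })
}

#' Simulate a sigmoidal thermal-unfolding curve
#'
#' Fluorescence 350/330 ratio versus temperature as a logistic transition:
#' `ratio(T) = lower + (upper - lower) / (1 + exp((tm - T) / steepness))`
#' plus Gaussian noise. The generator truth (`tm`) is the temperature of
#' 50% unfolding.
#'
#' @param tm Midpoint (melting temperature), degrees C; must lie within the
#'   grid (a midpoint at the grid edge is flagged with a warning).
#' @param steepness Transition width parameter, degrees C.
#' @param lower,upper Pre- and post-transition ratio asymptotes.
#' @param t_grid Temperature grid, degrees C (default 20-95 in 0.5 steps,
#'   the usual nanoDSF ramp).
#' @param noise_sd Gaussian noise SD on the ratio.
#' @param seed Integer seed.
#' @return A tibble with columns `temperature`, `ratio`.
#' @export
simulate_melt_curve <- function(tm, steepness = 2, lower = 0.85, upper = 1.05,
                                t_grid = seq(20, 95, by = 0.5), noise_sd = 0,
                                seed = 1L) {
  if (tm < min(t_grid) || tm > max(t_grid)) {
    stop_validation("tm must lie within the temperature grid")
  }
  if (tm <= min(t_grid) + 2 * steepness || tm >= max(t_grid) - 2 * steepness) {
    warn("tm close to the grid edge; the transition may be truncated")
  }
  withr::with_seed(seed, {
    tibble(temperature = t_grid,
           ratio = lower + (upper - lower) / (1 + exp((tm - t_grid) / steepness)) +
             stats::rnorm(length(t_grid), 0, noise_sd))
  })
}

#' Sample mass-resolved neutral masses for planting
#'
#' Rejection-samples uniform neutral masses so that no two species share an
#' m/z channel: every pair of isotopologue ions (isotope index 0 to
#' `n_iso - 1`, any charge in `charges`) of two accepted masses is at least
#' `min_mz_gap` apart in m/z. Species violating this are chimeric at XIC
#' level — the extracted chromatogram of one contains signal of the other —
#' and a targeted single-species search does not attempt to disentangle
#' such overlaps, so planted ground truth is defined on resolved species.
#'
#' @param n Number of masses.
#' @param range Length-2 mass range, Da.
#' @param charges Charge states the species will be planted with.
#' @param n_iso Isotope peaks per envelope considered.
#' @param min_mz_gap Minimum m/z separation between any two channels, Th.
#' @return Numeric vector of n masses (order of acceptance; uses the
#'   current RNG state).
#' @export
sample_resolved_masses <- function(n, range = c(4000, 7000), charges = 4:6,
                                   n_iso = 12L, min_mz_gap = 0.05) {
  channels <- function(m) {
    iso <- m + (0:(n_iso - 1L)) * mass_constants$isotope_spacing
    as.vector(outer(iso, charges,
                    function(M, z) (M + z * mass_constants$proton) / z))
  }
  out <- numeric(0)
  chan <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 1000L * n) stop_validation("cannot place resolved masses in range")
    x <- stats::runif(1, range[1], range[2])
    cx <- channels(x)
    if (length(chan) == 0L || min(abs(outer(cx, chan, "-"))) >= min_mz_gap) {
      out <- c(out, x)
      chan <- c(chan, cx)
    }
  }
  out
}

#' Synthetic catalase-peroxidase stand-in sequences
#'
#' Deterministically constructed SYNTHETIC protein records that mimic the
#' bookkeeping of the two study enzymes — natural chain lengths of 723
#' (thermophilic-like) and 750 (mesophilic-like) residues plus a C-terminal
#' 6xHis tag recorded as `tag_span` — and carry the Met-Tyr-Trp adduct
#' sites at the documented positions (M244/Y218/W90 and M264/Y238/W90,
#' numbering on the natural chain). Tryptic cleavage sites are placed so
#' every adduct site lies inside a peptide of ordinary length. These are
#' NOT the GenBank sequences; they exist so the whole search pipeline can
#' be exercised and tested without external downloads.
#'
#' @return A two-row protein tibble (ids `CthedisKatG_syn`, `MagKatG1_syn`).
#' @export
synthetic_katg <- function() {
  dplyr::bind_rows(
    synthetic_katg_one("CthedisKatG_syn", 723L, c(M = 244L, Y = 218L, W = 90L)),
    synthetic_katg_one("MagKatG1_syn", 750L, c(M = 264L, Y = 238L, W = 90L)))
}

synthetic_katg_one <- function(id, n, sites) {
  # background alphabet avoids K/R (cleavage), P (cleavage suppression),
  # M/Y/W/C (adduct and modification chemistry) so placements below are exact
  background <- c("A", "G", "S", "T", "V", "L", "E", "D", "N", "Q", "F", "H", "I")
  chars <- withr::with_seed(104729L, {
    sample(background, n, replace = TRUE)
  })
  cut_at <- seq(15L, n - 10L, by = 15L)          # tryptic K/R every 15 residues
  cut_at <- cut_at[!cut_at %in% sites & !(cut_at %in% (sites - 1L))]
  chars[cut_at] <- rep(c("K", "R"), length.out = length(cut_at))
  for (res in names(sites)) chars[sites[[res]]] <- res
  seq <- paste0(paste(chars, collapse = ""), "HHHHHH")
  protein_record(id, seq,
                 description = paste("synthetic stand-in,", n, "aa natural chain + 6xHis tag"),
                 tag_span = c(n + 1L, n + 6L))
}
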