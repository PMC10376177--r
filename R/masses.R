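#' Physical mass constants used throughout the package
#'
#' Monoisotopic masses in Da: the proton (charge carrier in positive-mode
#' electrospray), the hydrogen atom (lost twice per covalent crosslink bond),
#' water (added once per peptide on hydrolysis), and the averaged spacing
#' between adjacent isotopologue peaks of a peptide (dominated by
#' \eqn{^{13}C-^{12}C}).
#'
#' Values follow the standard tables used by proteomics search engines
#' (CODATA/AME-derived, as tabulated e.g. by Unimod and ExPASy).
#'
#' @format A named list with elements `proton`, `hydrogen`, `water`,
#'   `isotope_spacing` (all Da).
#' @export
#' @examples
#' mass_constants$proton
mass_constants <- list(
  proton          = 1.007276,
  hydrogen        = 1.007825,
  water           = 18.010565,
  water_average   = 18.01528,
  isotope_spacing = 1.003355
)

# Monoisotopic residue masses (Da), standard 20-letter alphabet.
# Source: ExPASy / Unimod standard amino-acid residue tables.
MONO_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Average (isotope-abundance-weighted) residue masses (Da), same source.
AVG_RESIDUE <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

#' Residue mass table
#'
#' The per-residue monoisotopic and average masses plus the mass constants,
#' optionally overridden from a plain-text configuration file with
#' `name = delta` lines (e.g. `G = 57.02146`). One-letter residue codes
#' override residue masses; the names `proton`, `hydrogen`, `water`,
#' `water_average` override the constants.
#'
#' @param config_file Optional path to a `name = value` override file. Lines
#'   starting with `#` and blank lines are ignored.
#' @return A list with elements `monoisotopic` (named numeric, 20 residues),
#'   `average` (named numeric), and the constants `proton`, `hydrogen`,
#'   `water`, `water_average`, `isotope_spacing`.
#' @export
#' @examples
#' tbl <- residue_mass_table()
#' tbl$monoisotopic[["G"]]
residue_mass_table <- function(config_file = NULL) {
  tbl <- c(list(monoisotopic = MONO_RESIDUE, average = AVG_RESIDUE),
           mass_constants)
  if (!is.null(config_file)) {
    ov <- read_mass_config(config_file)
    for (nm in names(ov)) {
      if (nchar(nm) == 1L && nm %in% names(MONO_RESIDUE)) {
        tbl$monoisotopic[[nm]] <- ov[[nm]]
      } else if (nm %in% c("proton", "hydrogen", "water", "water_average")) {
        tbl[[nm]] <- ov[[nm]]
      } else {
        stop_config(sprintf("unknown mass table entry '%s' in %s", nm, config_file))
      }
    }
  }
  if (any(tbl$monoisotopic <= 0) || any(tbl$average <= 0)) {
    stop_validation("all residue masses must be > 0")
  }
  tbl
}

read_mass_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop_format(sprintf("malformed config line: '%s'", ln))
    val <- suppressWarnings(as.numeric(trimws(parts[2])))
    if (is.na(val)) stop_format(sprintf("non-numeric value in config line: '%s'", ln))
    out[[trimws(parts[1])]] <- val
  }
  out
}

#' Fixed/variable modification scheme
#'
#' The search convention of the targeted adduct workflow: cysteine
#' carbamidomethylation as a fixed (always applied) modification and
#' methionine oxidation as a variable one, with a cap on the number of
#' variable modifications per peptide.
#'
#' @param fixed Named numeric vector of fixed modification deltas in Da,
#'   names are one-letter residue codes. Default: carbamidomethyl on C,
#'   +57.02146 Da.
#' @param variable Named numeric vector of variable modification deltas in
#'   Da. Default: oxidation on M, +15.99491 Da.
#' @param max_variable Maximum number of variable modifications applied per
#'   peptide (and, downstream, per crosslink candidate). Default 2.
#' @return An object of class `mod_scheme`.
#' @export
#' @examples
#' modification_scheme()
modification_scheme <- function(fixed = c(C = 57.02146),
                                variable = c(M = 15.99491),
                                max_variable = 2L) {
  check_mods <- function(x, what) {
    if (length(x) == 0L) return(invisible())
    if (is.null(names(x)) || any(!names(x) %in% names(MONO_RESIDUE))) {
      stop_validation(sprintf("%s modifications must be named by valid residue letters", what))
    }
    if (any(!is.finite(x))) stop_validation(sprintf("%s modification deltas must be finite", what))
  }
  check_mods(fixed, "fixed")
  check_mods(variable, "variable")
  if (!is_count(max_variable)) stop_validation("max_variable must be a non-negative count")
  structure(list(fixed = fixed, variable = variable,
                 max_variable = as.integer(max_variable)),
            class = "mod_scheme")
}

#' @export
print.mod_scheme <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(sprintf("%s%+0.5f", names(v), v), collapse = ", ") else "none"
  cat("<mod_scheme>\n")
  cat("  fixed:    ", fmt(x$fixed), "\n")
  cat("  variable: ", fmt(x$variable), " (max ", x$max_variable, " per peptide)\n", sep = "")
  invisible(x)
}
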