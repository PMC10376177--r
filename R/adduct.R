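#' Specify a covalent adduct target
#'
#' An adduct specification names, on one protein, the ordered chain of
#' residues joined by covalent bonds — for catalase–peroxidases the
#' Met–Tyr–Trp triad on the distal heme side (e.g. `"M244,Y218,W90"`). For a
#' linear chain of n sites the bond count is n − 1, and each bond forms with
#' the loss of two hydrogen atoms.
#'
#' @param protein_id Identifier of the protein carrying the adduct.
#' @param sites Either a string like `"M244,Y218,W90"` or a named integer
#'   vector `c(M = 244, Y = 218, W = 90)` of residue letters and 1-based
#'   positions, in chain order.
#' @param proteins Optional protein tibble; when given, the residue letters
#'   are checked against the sequence.
#' @return An object of class `adduct_spec` with fields `protein_id`,
#'   `residues`, `positions`, `bond_count`.
#' @export
#' @examples
#' adduct_spec("CthedisKatG_syn", "M244,Y218,W90")
adduct_spec <- function(protein_id, sites, proteins = NULL) {
  if (is.character(sites) && length(sites) == 1L) {
    parts <- trimws(strsplit(sites, ",")[[1]])
    if (!all(grepl("^[A-Z][0-9]+$", parts))) {
      stop_format(sprintf("cannot parse site list '%s' (expected e.g. 'M244,Y218,W90')", sites))
    }
    residues <- substr(parts, 1, 1)
    positions <- as.integer(sub("^[A-Z]", "", parts))
  } else {
    residues <- names(sites)
    positions <- as.integer(sites)
  }
  if (is.null(residues) || any(!residues %in% names(MONO_RESIDUE))) {
    stop_validation("site residue letters must be standard one-letter codes")
  }
  if (anyDuplicated(positions)) stop_validation("site positions must be distinct")
  if (!is.null(proteins)) {
    row <- proteins[proteins$id == protein_id, ]
    if (nrow(row) != 1L) stop_validation(sprintf("protein '%s' not found", protein_id))
    actual <- substring(row$sequence, positions, positions)
    bad <- which(actual != residues)
    if (length(bad)) {
      stop_validation(sprintf(
        "site %s%d: sequence of '%s' has '%s' at that position",
        residues[bad[1]], positions[bad[1]], protein_id, actual[bad[1]]))
    }
  }
  structure(list(protein_id = protein_id, residues = residues,
                 positions = positions,
                 bond_count = length(positions) - 1L),
            class = "adduct_spec")
}

#' @export
print.adduct_spec <- function(x, ...) {
  cat("<adduct_spec> ", x$protein_id, ": ",
      paste0(x$residues, x$positions, collapse = "-"),
      " (", x$bond_count, " bond", if (x$bond_count != 1) "s", ")\n", sep = "")
  invisible(x)
}

#' Bond-corrected crosslink mass
#'
#' Each covalent bond of the adduct forms with the loss of two hydrogen
#' atoms, so the crosslinked species is lighter than the arithmetic sum of
#' its component peptides by 2 × 1.007825 Da per bond.
#'
#' @param naive_sum Sum of component peptide monoisotopic masses, Da.
#' @param bond_count Number of covalent bonds (>= 0).
#' @return Corrected monoisotopic mass in Da.
#' @export
#' @examples
#' corrected_mass(6000, 2)   # 5995.9687
corrected_mass <- function(naive_sum, bond_count) {
  if (any(bond_count < 0)) stop_validation("bond_count must be >= 0")
  naive_sum - bond_count * 2 * mass_constants$hydrogen
}

#' Enumerate crosslink candidates covering the adduct sites
#'
#' For the full site chain and every contiguous sub-chain of length >= 2
#' (the experimentally observed species include both the full triple and
#' pairs), chooses one digested peptide per
#' site in every possible way, collapses duplicate peptides when one peptide
#' covers several sites, and computes the naive mass sum and the
#' bond-corrected mass (bonds = sites in the sub-chain − 1). Variable
#' modifications expand each candidate over total oxidation counts up to the
#' scheme cap. A one-site specification degenerates to plain targeted
#' peptide masses with zero bonds.
#'
#' @param peptides Digest tibble for the spec's protein ([digest()]).
#' @param spec An [adduct_spec()].
#' @param mods A [modification_scheme()]; its `max_variable` caps the total
#'   variable modifications per candidate.
#' @param include_noncontiguous Also emit non-contiguous site pairs
#'   (default `FALSE`; no evidence such species form).
#' @param table A [residue_mass_table()].
#' @return A tibble with one row per candidate: `candidate_id`, `protein_id`,
#'   `site_chain`, `n_sites`, `bond_count`, `peptides` (list-column of
#'   component peptide rows), `peptide_sequences` (collapsed `+`-joined
#'   label), `n_peptides`, `missed_cleavages`, `n_variable_mods`,
#'   `naive_sum_mass`, `corrected_mass`, in deterministic order.
#' @export
enumerate_candidates <- function(peptides, spec,
                                 mods = modification_scheme(),
                                 include_noncontiguous = FALSE,
                                 table = residue_mass_table()) {
  peptides <- peptides[peptides$protein_id == spec$protein_id, , drop = FALSE]
  n_sites <- length(spec$positions)
  covering <- lapply(spec$positions, function(pos) {
    idx <- which(peptides$start <= pos & peptides$end >= pos)
    if (length(idx) == 0L) {
      stop_validation(sprintf("uncovered site: no peptide covers position %d", pos))
    }
    idx
  })

  chains <- contiguous_chains(n_sites)
  if (include_noncontiguous && n_sites >= 3L) {
    extra <- utils::combn(n_sites, 2L, simplify = FALSE)
    extra <- extra[!purrr::map_lgl(extra, function(p) p[2] == p[1] + 1L)]
    chains <- c(chains, extra)
  }

  rows <- purrr::map(chains, function(chain) {
    grid <- expand.grid(rev(covering[chain]), KEEP.OUT.ATTRS = FALSE)
    grid <- grid[, rev(seq_along(chain)), drop = FALSE]   # site-major order
    purrr::map(seq_len(nrow(grid)), function(r) {
      sel <- unlist(grid[r, ], use.names = FALSE)
      comp <- peptides[unique(sel), , drop = FALSE]       # collapse duplicates
      comp <- dplyr::arrange(comp, .data$start, .data$end)
      list(chain = chain, comp = comp)
    })
  })
  rows <- purrr::flatten(rows)

  base <- purrr::map(rows, function(x) {
    chain_label <- paste0(spec$residues[x$chain], spec$positions[x$chain],
                          collapse = "-")
    bond_count <- length(x$chain) - 1L
    tibble(
      protein_id = spec$protein_id,
      site_chain = chain_label,
      n_sites = length(x$chain),
      bond_count = bond_count,
      peptides = list(x$comp),
      peptide_sequences = paste(x$comp$sequence, collapse = "+"),
      n_peptides = nrow(x$comp),
      missed_cleavages = sum(x$comp$missed_cleavages)
    )
  })
  out <- dplyr::bind_rows(base)

  # variable-mod expansion on the combined component peptides
  combined <- purrr::map_chr(out$peptides, function(p) paste(p$sequence, collapse = ""))
  n_avail <- purrr::map_int(combined, function(s) {
    sum(strsplit(s, "")[[1]] %in% names(mods$variable))
  })
  reps <- pmin(n_avail, mods$max_variable) + 1L
  out <- out[rep(seq_len(nrow(out)), reps), , drop = FALSE]
  out$n_variable_mods <- unlist(lapply(reps, function(r) 0:(r - 1L)))

  base_mass <- purrr::map_dbl(out$peptides, function(p) {
    sum(peptide_mass(p$sequence, mods, 0L, table))
  })
  var_delta <- if (length(mods$variable)) mods$variable[[1]] else 0
  out$naive_sum_mass <- base_mass + out$n_variable_mods * var_delta
  out$corrected_mass <- corrected_mass(out$naive_sum_mass, out$bond_count)

  out <- dplyr::arrange(out, dplyr::desc(.data$n_sites), .data$site_chain,
                        .data$peptide_sequences, .data$missed_cleavages,
                        .data$n_variable_mods)
  out$candidate_id <- sprintf("cand_%03d", seq_len(nrow(out)))
  dplyr::relocate(as_tibble(out), "candidate_id")
}

# contiguous sub-chains of 1..n: full chain and all runs of length >= 2;
# for a single-site spec, the single site itself
contiguous_chains <- function(n) {
  if (n == 1L) return(list(1L))
  chains <- list()
  for (len in n:2) {
    for (s in 1:(n - len + 1L)) {
      chains <- c(chains, list(seq.int(s, s + len - 1L)))
    }
  }
  chains
}

#' Theoretical multiply-charged ion series
#'
#' m/z of the protonated species for each charge in `[z_min, z_max]`:
#' `(M + z * proton) / z`, strictly decreasing in z.
#'
#' @param mass Neutral monoisotopic mass M in Da.
#' @param z_min,z_max Positive integer charge bounds.
#' @return A tibble with columns `z`, `mz` and attribute `mass`.
#' @export
#' @examples
#' ion_series(1000, 1, 3)
ion_series <- function(mass, z_min = 3L, z_max = 8L) {
  if (z_min < 1L || z_max < z_min) {
    stop_validation("charges must satisfy 1 <= z_min <= z_max")
  }
  z <- seq.int(z_min, z_max)
  out <- tibble(z = as.integer(z), mz = (mass + z * mass_constants$proton) / z)
  attr(out, "mass") <- mass
  out
}

#' Match an observed deconvoluted mass against a crosslink candidate
#'
#' Computes the offsets of the observed neutral monoisotopic mass from both
#' the naive (uncorrected) peptide-mass sum and the bond-corrected mass,
#' infers the apparent bond count from the naive offset (each bond shifts the
#' mass by 2 × 1.007825 = 2.01565 Da), and accepts the match when the
#' corrected offset is within tolerance. Integer masses are reported with
#' half-away-from-zero rounding, the convention of the printed values.
#'
#' @param observed Observed neutral monoisotopic mass, Da.
#' @param candidate One-row candidate tibble from [enumerate_candidates()].
#' @param tolerance Acceptance tolerance on `delta_to_corrected`, Da
#'   (default 0.05, Orbitrap-class deconvoluted-mass accuracy).
#' @return A one-row tibble: `candidate_id`, `observed_mass`,
#'   `rounded_observed`, `delta_to_naive` (naive − observed),
#'   `delta_to_corrected` (observed − corrected), `rounded_bond_shift`,
#'   `inferred_bond_count`, `accepted`.
#' @export
match_observed <- function(observed, candidate, tolerance = 0.05) {
  if (tolerance <= 0) stop_validation("tolerance must be > 0")
  delta_naive <- candidate$naive_sum_mass - observed
  delta_corr <- observed - candidate$corrected_mass
  tibble(
    candidate_id = candidate$candidate_id %||% NA_character_,
    observed_mass = observed,
    rounded_observed = round_half_away(observed),
    delta_to_naive = delta_naive,
    delta_to_corrected = delta_corr,
    rounded_bond_shift = round_half_away(delta_naive),
    inferred_bond_count = as.integer(round(delta_naive / (2 * mass_constants$hydrogen))),
    accepted = abs(delta_corr) <= tolerance
  )
}
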