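#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, with the scheme's
#' fixed modifications always applied and an optional count of variable
#' modifications (oxidation by default) added on top. Vectorised over
#' sequences.
#'
#' @param sequences Character vector of peptide sequences.
#' @param mods A [modification_scheme()] (`NULL` for none).
#' @param n_variable Integer vector (recycled) of variable-modification
#'   counts to apply per peptide; each must not exceed the number of
#'   modifiable residues nor the scheme cap.
#' @param table A [residue_mass_table()].
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' peptide_mass("G", mods = NULL)                      # 75.032025
#' peptide_mass("C")                                   # carbamidomethylated
peptide_mass <- function(sequences, mods = modification_scheme(),
                         n_variable = 0L, table = residue_mass_table()) {
  n_variable <- rep_len(as.integer(n_variable), length(sequences))
  purrr::map2_dbl(sequences, n_variable, function(seq, nv) {
    chars <- strsplit(seq, "")[[1]]
    bad <- which(!chars %in% names(table$monoisotopic))
    if (length(bad)) {
      stop_validation(sprintf("residue '%s' at position %d of '%s' absent from mass table",
                              chars[bad[1]], bad[1], seq))
    }
    m <- sum(table$monoisotopic[chars]) + table$water
    if (!is.null(mods)) {
      for (res in names(mods$fixed)) {
        m <- m + mods$fixed[[res]] * sum(chars == res)
      }
      if (nv > 0L) {
        if (length(mods$variable) == 0L) {
          stop_validation("variable modifications requested but none defined")
        }
        avail <- sum(chars %in% names(mods$variable))
        if (nv > min(avail, mods$max_variable)) {
          stop_validation(sprintf(
            "cannot place %d variable modification(s) on '%s' (available %d, cap %d)",
            nv, seq, avail, mods$max_variable))
        }
        # single variable-mod type per residue letter; sum of the deltas of
        # the chosen count (all variable mods share the delta when one type)
        m <- m + nv * mods$variable[[1]]
      }
    }
    unname(m)
  })
}

#' Expand peptides over variable-modification states
#'
#' For each peptide row, emits one row per admissible number of variable
#' modifications (0 up to the scheme cap and the number of modifiable
#' residues), with columns `n_variable_mods` and `mono_mass` added. Fixed
#' modifications are always included in `mono_mass`.
#'
#' @param peptides Peptide tibble from [digest()].
#' @param mods A [modification_scheme()].
#' @param table A [residue_mass_table()].
#' @return The expanded tibble, original order preserved within peptide.
#' @export
expand_modifications <- function(peptides, mods = modification_scheme(),
                                 table = residue_mass_table()) {
  var_res <- names(mods$variable)
  n_avail <- purrr::map_int(peptides$sequence, function(s) {
    sum(strsplit(s, "")[[1]] %in% var_res)
  })
  reps <- pmin(n_avail, mods$max_variable) + 1L
  out <- peptides[rep(seq_len(nrow(peptides)), reps), , drop = FALSE]
  out$n_variable_mods <- unlist(lapply(reps, function(r) 0:(r - 1L)))
  out$mono_mass <- peptide_mass(out$sequence, mods, out$n_variable_mods, table)
  as_tibble(out)
}

#' Average (isotope-abundance-weighted) protein mass
#'
#' Chain average mass in kDa, reported to 3 decimals as is conventional for
#' subunit molecular weights. When a tag interval is recorded on the record
#' it is excluded by default, so the value refers to the natural chain;
#' `include_tag = TRUE` computes the full stored sequence.
#'
#' @param proteins Protein tibble.
#' @param include_tag Include the recorded affinity-tag interval?
#' @param table A [residue_mass_table()].
#' @return Numeric vector of masses in kDa (3 decimals).
#' @export
#' @examples
#' protein_average_mass(protein_record("g", "G"))    # 0.075
protein_average_mass <- function(proteins, include_tag = FALSE,
                                 table = residue_mass_table()) {
  purrr::map_dbl(seq_len(nrow(proteins)), function(i) {
    row <- proteins[i, ]
    seq <- if (include_tag) row$sequence else untagged_sequence(row)
    chars <- strsplit(seq, "")[[1]]
    round((sum(table$average[chars]) + table$water_average) / 1000, 3)
  })
}

#' Protein chain length
#'
#' Residue count, excluding the recorded affinity-tag interval by default.
#'
#' @inheritParams protein_average_mass
#' @return Integer vector of lengths.
#' @export
protein_length <- function(proteins, include_tag = FALSE) {
  purrr::map_int(seq_len(nrow(proteins)), function(i) {
    row <- proteins[i, ]
    nchar(if (include_tag) row$sequence else untagged_sequence(row))
  })
}

#' Molar extinction coefficient at 280 nm
#'
#' Gill–von Hippel composition sum: 5500 per tryptophan, 1490 per tyrosine,
#' and 125 per cystine (disulfide-bonded cysteine pair). All cysteines are
#' assumed reduced by default (`n_cystine = 0`), matching a reduced/alkylated
#' sample; pass an explicit cystine count otherwise.
#'
#' @inheritParams protein_average_mass
#' @param n_cystine Number of disulfide bonds per chain (default 0).
#' @return Numeric vector of coefficients in M^-1 cm^-1.
#' @export
#' @examples
#' molar_extinction_280(protein_record("x", "WYG"))  # 6990
molar_extinction_280 <- function(proteins, n_cystine = 0, include_tag = FALSE) {
  purrr::map_dbl(seq_len(nrow(proteins)), function(i) {
    row <- proteins[i, ]
    seq <- if (include_tag) row$sequence else untagged_sequence(row)
    chars <- strsplit(seq, "")[[1]]
    sum(chars == "W") * 5500 + sum(chars == "Y") * 1490 + n_cystine * 125
  })
}
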