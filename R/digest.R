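#' In-silico enzymatic digestion
#'
#' Digests each protein in a protein tibble with the given enzyme rule and
#' returns all fully enzymatic peptides with up to `max_missed` missed
#' cleavages. The only rule currently implemented is `"trypsin"`: cleavage
#' C-terminal to K or R, suppressed when the next residue is P; the protein
#' termini are always peptide termini.
#'
#' @param proteins Protein tibble ([read_fasta()] / [protein_record()]).
#' @param enzyme Cleavage rule name; only `"trypsin"`.
#' @param max_missed Maximum number of internal uncleaved sites per peptide
#'   (default 2, the common search setting; guarantees coverage of
#'   adduct-site peptides with one stray missed cleavage).
#' @return A tibble with columns `protein_id`, `start`, `end` (1-based
#'   inclusive), `sequence`, `missed_cleavages`, ordered by protein, start,
#'   then length.
#' @export
#' @examples
#' digest(protein_record("p", "AKRPGCK"), max_missed = 1)
digest <- function(proteins, enzyme = "trypsin", max_missed = 2L) {
  if (!identical(enzyme, "trypsin")) {
    stop_config(sprintf("unknown enzyme '%s' (supported: 'trypsin')", enzyme))
  }
  if (!is_count(max_missed)) stop_validation("max_missed must be a non-negative count")
  out <- purrr::pmap(
    list(proteins$id, proteins$sequence),
    function(id, seq) digest_one(id, seq, as.integer(max_missed)))
  dplyr::bind_rows(out)
}

# positions i such that the bond after residue i is cleaved: seq[i] in {K,R}
# and seq[i+1] != P (the terminal residue is not a cleavage site)
tryptic_sites <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 2L) return(integer())
  which(chars[-n] %in% c("K", "R") & chars[-1] != "P")
}

digest_one <- function(id, seq, max_missed) {
  n <- nchar(seq)
  cuts <- c(0L, tryptic_sites(seq), n)          # fragment boundaries
  nfrag <- length(cuts) - 1L
  combos <- tidyr::expand_grid(i = seq_len(nfrag), m = 0:max_missed)
  combos <- combos[combos$i + combos$m <= nfrag, , drop = FALSE]
  start <- cuts[combos$i] + 1L
  end <- cuts[combos$i + combos$m + 1L]
  pep <- tibble(
    protein_id = id,
    start = start,
    end = end,
    sequence = substring(seq, start, end),
    missed_cleavages = as.integer(combos$m)
  )
  dplyr::arrange(pep, .data$start, .data$end - .data$start)
}
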