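#' Create a protein record
#'
#' A protein record is one row of a protein tibble: an identifier, a
#' description, an upper-case sequence over the 20 standard one-letter codes,
#' and an optional affinity-tag interval (`tag_start`/`tag_end`, 1-based
#' inclusive). Residue numbering is always on the stored chain; when the
#' natural (untagged) chain is of interest the tag interval can be excluded
#' by the property computations (see [protein_average_mass()]).
#'
#' @param id Accession or identifier string.
#' @param sequence Residue string (whitespace tolerated, case-insensitive).
#' @param description Free-text description.
#' @param tag_span Optional length-2 integer vector, 1-based inclusive
#'   interval of an affinity tag within the sequence.
#' @return A one-row tibble with columns `id`, `description`, `sequence`,
#'   `tag_start`, `tag_end`.
#' @export
#' @examples
#' protein_record("p1", "ACDEFGHIK")
protein_record <- function(id, sequence, description = "", tag_span = NULL) {
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  validate_sequence(sequence, id)
  tag_start <- NA_integer_; tag_end <- NA_integer_
  if (!is.null(tag_span)) {
    if (length(tag_span) != 2L || any(is.na(tag_span))) {
      stop_validation("tag_span must be a length-2 interval")
    }
    tag_span <- as.integer(tag_span)
    if (tag_span[1] < 1L || tag_span[2] > nchar(sequence) || tag_span[1] > tag_span[2]) {
      stop_validation(sprintf("tag_span [%d, %d] outside sequence [1, %d]",
                              tag_span[1], tag_span[2], nchar(sequence)))
    }
    tag_start <- tag_span[1]; tag_end <- tag_span[2]
  }
  tibble(id = as.character(id), description = as.character(description),
         sequence = sequence, tag_start = tag_start, tag_end = tag_end)
}

validate_sequence <- function(sequence, id = "?") {
  if (is.na(sequence) || !nzchar(sequence)) {
    stop_validation(sprintf("protein '%s': sequence is empty", id))
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(MONO_RESIDUE))
  if (length(bad)) {
    stop_validation(sprintf(
      "protein '%s': illegal residue letter '%s' at position %d",
      id, chars[bad[1]], bad[1]))
  }
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a standard multi-line FASTA file (via Biostrings) into a protein
#' tibble. Whitespace is stripped, residues upper-cased, and every character
#' checked against the 20 standard one-letter codes.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record (columns as in
#'   [protein_record()]), in file order. An empty file gives a zero-row
#'   tibble.
#' @export
#' @examples
#' fa <- system.file("extdata", "synthetic_katg.fasta", package = "xlinkxic")
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  empty_cols <- tibble(id = character(), description = character(),
                       sequence = character(), tag_start = integer(),
                       tag_end = integer())
  if (length(nonblank) == 0L) return(empty_cols)
  first <- lines[nonblank[1]]
  if (!startsWith(trimws(first), ">")) {
    stop_format(sprintf("not FASTA: line %d does not start with '>': '%s'",
                        nonblank[1], first))
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) return(empty_cols)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  recs <- purrr::pmap(
    list(ids, as.character(aa), descs),
    function(id, seq, desc) protein_record(id, seq, description = desc))
  dplyr::bind_rows(recs)
}

#' Write a protein tibble to FASTA
#'
#' @param proteins Protein tibble as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  lines <- purrr::pmap(
    list(proteins$id, proteins$description, proteins$sequence),
    function(id, desc, seq) {
      header <- if (nzchar(desc)) paste0(">", id, " ", desc) else paste0(">", id)
      body <- substring(seq, seq(1, nchar(seq), by = width),
                        pmin(seq(width, nchar(seq) + width - 1, by = width), nchar(seq)))
      c(header, body)
    })
  writeLines(unlist(lines), path)
  invisible(path)
}

# sequence with the tag interval removed (identity when no tag recorded)
untagged_sequence <- function(protein_row) {
  seq <- protein_row$sequence
  if (is.na(protein_row$tag_start)) return(seq)
  paste0(substr(seq, 1L, protein_row$tag_start - 1L),
         substr(seq, protein_row$tag_end + 1L, nchar(seq)))
}
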