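# shared helpers: independent oracles and tiny fixture builders

# brute-force tryptic digestion: every substring whose ends satisfy the
# cleavage rule and whose interior has <= max_missed uncleaved sites
brute_digest <- function(seq, max_missed) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  cut_after <- function(i) {
    i >= 1 && i < n && chars[i] %in% c("K", "R") && chars[i + 1] != "P"
  }
  out <- character()
  for (s in 1:n) for (e in s:n) {
    left_ok <- s == 1 || cut_after(s - 1)
    right_ok <- e == n || cut_after(e)
    if (!left_ok || !right_ok) next
    internal <- if (e > s) sum(vapply(s:(e - 1), cut_after, logical(1))) else 0L
    if (internal <= max_missed) out <- c(out, substr(seq, s, e))
  }
  out
}

# random valid protein sequence (no structure guarantees)
random_sequence <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# noiseless noise model for exact-recovery tests
quiet_noise <- function(seed = 1L) {
  noise_model(baseline = 0, peaks_per_scan = 0L, jitter_ppm = 0, seed = seed)
}

# one clean planted species in a short run
tiny_planted_run <- function(mass = 6516, charges = 4:6, rt = 5,
                             run_length = 10, seed = 1L) {
  simulate_run(planted_species(mass, charges, rt),
               run_length = run_length, noise = quiet_noise(seed))
}
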