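test_that("FASTA reading returns records in file order with clean sequences", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 first protein", "ACDEF", ">p2", "ghik", "lmn"), fa)
  recs <- read_fasta(fa)
  expect_equal(recs$id, c("p1", "p2"))
  expect_equal(recs$sequence, c("ACDEF", "GHIKLMN"))
  expect_equal(recs$description[1], "first protein")
})

test_that("empty FASTA gives an empty tibble; malformed input names the line", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), fa)
  expect_equal(nrow(read_fasta(fa)), 0L)

  writeLines(c("ACDEF", ">p1", "GG"), fa)
  expect_error(read_fasta(fa), "line 1", class = "xlinkxic_format_error")

  writeLines(c(">p1", "ACDExF"), fa)
  expect_error(read_fasta(fa), "position 5", class = "xlinkxic_validation_error")
})

test_that("FASTA round trip preserves records", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  p <- synthetic_katg()
  write_fasta(p, fa)
  back <- read_fasta(fa)
  expect_equal(back$id, p$id)
  expect_equal(back$sequence, p$sequence)
})

test_that("protein records validate sequence and tag span", {
  expect_error(protein_record("x", ""), "empty")
  expect_error(protein_record("x", "ACDB"), "position 4")
  expect_error(protein_record("x", "ACDEF", tag_span = c(3, 9)), "outside")
  rec <- protein_record("x", "acd ef")
  expect_equal(rec$sequence, "ACDEF")
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  p <- protein_record("p", "AKRPGCK")
  expect_equal(digest(p, max_missed = 0)$sequence, c("AK", "RPGCK"))
  expect_equal(digest(p, max_missed = 1)$sequence, c("AK", "AKRPGCK", "RPGCK"))
  expect_equal(digest(protein_record("q", "GGG"), max_missed = 0)$sequence, "GGG")
  expect_error(digest(p, enzyme = "chymotrypsin"), class = "xlinkxic_config_error")
})

test_that("zero-missed-cleavage peptides partition the protein", {
  set.seed(421)
  for (i in 1:20) {
    seq <- random_sequence(sample(5:60, 1))
    peps <- digest(protein_record("p", seq), max_missed = 0)
    expect_equal(paste(peps$sequence, collapse = ""), seq)
  }
})

test_that("digestion matches brute-force enumeration on random sequences", {
  set.seed(7)
  for (i in 1:40) {
    seq <- random_sequence(sample(3:30, 1))
    mm <- sample(0:3, 1)
    got <- digest(protein_record("p", seq), max_missed = mm)
    expect_setequal(got$sequence, brute_digest(seq, mm))
    expect_equal(got$sequence, substring(seq, got$start, got$end))
  }
})

test_that("monoisotopic peptide masses match independent reference values", {
  # frozen from standard residue tables; cross-checked against pyteomics
  expect_equal(peptide_mass("G", mods = NULL), 75.032025, tolerance = 1e-7)
  expect_equal(peptide_mass("AG", mods = NULL), 146.069135, tolerance = 1e-7)
  expect_equal(peptide_mass("ACDEFGHIKLMNPQRSTVWY", mods = NULL),
               2394.124907, tolerance = 1e-5)
  expect_equal(peptide_mass("PEPTIDER", mods = NULL), 955.461075, tolerance = 1e-5)
  # fixed carbamidomethylation is always applied
  expect_equal(peptide_mass("C"), 103.00919 + 57.02146 + 18.010565, tolerance = 1e-7)
  # variable oxidation adds its delta n times
  expect_equal(peptide_mass("MMK", n_variable = 2) - peptide_mass("MMK"),
               2 * 15.99491, tolerance = 1e-9)
  expect_error(peptide_mass("MK", n_variable = 2), "cannot place")
})

test_that("mass is additive over concatenation up to one water", {
  set.seed(99)
  for (i in 1:25) {
    a <- random_sequence(sample(1:15, 1))
    b <- random_sequence(sample(1:15, 1))
    expect_equal(peptide_mass(paste0(a, b), mods = NULL),
                 peptide_mass(a, mods = NULL) + peptide_mass(b, mods = NULL) -
                   mass_constants$water,
                 tolerance = 1e-9)
  }
})

test_that("adding any residue strictly increases mono and average mass", {
  base <- "ACDEF"
  p0 <- protein_record("x", base)
  for (res in strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
    p1 <- protein_record("x", paste0(base, res))
    expect_gt(peptide_mass(p1$sequence, mods = NULL),
              peptide_mass(base, mods = NULL))
    expect_gte(protein_average_mass(p1), protein_average_mass(p0))
  }
})

test_that("variable-mod expansion enumerates admissible oxidation states", {
  peps <- digest(protein_record("p", "MAMKGGK"), max_missed = 0)
  ex <- expand_modifications(peps)
  mamk <- ex[ex$sequence == "MAMK", ]
  expect_equal(mamk$n_variable_mods, 0:2)
  expect_equal(diff(mamk$mono_mass), rep(15.99491, 2), tolerance = 1e-9)
  ggk <- ex[ex$sequence == "GGK", ]
  expect_equal(ggk$n_variable_mods, 0L)
})

test_that("average protein mass is reported in kDa and respects the tag flag", {
  expect_equal(protein_average_mass(protein_record("g", "G")), 0.075)
  p <- protein_record("x", "ACDEFHHHHHH", tag_span = c(6, 11))
  expect_equal(protein_length(p), 5L)
  expect_equal(protein_length(p, include_tag = TRUE), 11L)
  expect_gt(protein_average_mass(p, include_tag = TRUE), protein_average_mass(p))
  # without a tag recorded the flag is a no-op
  q <- protein_record("y", "ACDEF")
  expect_equal(protein_average_mass(q, include_tag = TRUE), protein_average_mass(q))
})

test_that("extinction coefficient at 280 nm is the chromophore sum", {
  expect_equal(molar_extinction_280(protein_record("w", "W")), 5500)
  expect_equal(molar_extinction_280(protein_record("wyg", "WYG")), 6990)
  expect_equal(molar_extinction_280(protein_record("g", "GGG")), 0)
  expect_equal(molar_extinction_280(protein_record("c", "WCC"), n_cystine = 1), 5625)
})

test_that("mass table overrides load from name = value config files", {
  cfg <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# override glycine", "G = 57.5", "proton = 1.00728"), cfg)
  tbl <- residue_mass_table(cfg)
  expect_equal(tbl$monoisotopic[["G"]], 57.5)
  expect_equal(tbl$proton, 1.00728)
  writeLines("Z = 1.0", cfg)
  expect_error(residue_mass_table(cfg), class = "xlinkxic_config_error")
})

test_that("synthetic stand-in proteins honour their documented contract", {
  p <- synthetic_katg()
  expect_equal(protein_length(p), c(723L, 750L))
  expect_equal(protein_length(p, include_tag = TRUE), c(729L, 756L))
  expect_equal(substring(p$sequence[1], c(244, 218, 90), c(244, 218, 90)),
               c("M", "Y", "W"))
  expect_equal(substring(p$sequence[2], c(264, 238, 90), c(264, 238, 90)),
               c("M", "Y", "W"))
  # deterministic construction
  expect_identical(synthetic_katg(), p)
})
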