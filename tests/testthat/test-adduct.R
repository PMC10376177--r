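test_that("adduct specs parse site strings and check the sequence", {
  spec <- adduct_spec("p", "M244,Y218,W90")
  expect_equal(spec$residues, c("M", "Y", "W"))
  expect_equal(spec$positions, c(244L, 218L, 90L))
  expect_equal(spec$bond_count, 2L)
  p <- protein_record("p", "AWAMAYA")
  expect_silent(adduct_spec("p", "M4,Y6,W2", proteins = p))
  expect_error(adduct_spec("p", "M2,Y6,W4", proteins = p), "site M2")
  expect_error(adduct_spec("p", "M4,M4", ), "distinct")
  expect_error(adduct_spec("p", "bad-sites"), class = "xlinkxic_format_error")
})

test_that("bond correction removes two hydrogens per bond", {
  expect_equal(corrected_mass(6000, 2), 5995.9687, tolerance = 1e-9)
  expect_equal(corrected_mass(6000, 0), 6000)
  expect_error(corrected_mass(6000, -1), class = "xlinkxic_validation_error")
  # strictly decreasing with constant step 2.01565
  steps <- diff(corrected_mass(6000, 0:5))
  expect_equal(steps, rep(-2.01565, 5), tolerance = 1e-9)
  # the printed integer convention: 4 Da for two bonds, 2 Da for one
  expect_equal(round(6000 - corrected_mass(6000, 2)), 4)
  expect_equal(round(6000 - corrected_mass(6000, 1)), 2)
})

test_that("ion series follows (M + z proton)/z and inverts exactly", {
  s <- ion_series(1000, 1, 1)
  expect_equal(s$mz, 1001.007276, tolerance = 1e-9)
  expect_equal(ion_series(5995.9687, 4, 4)$mz, 1499.999451, tolerance = 1e-6)
  s3 <- ion_series(1000, 1, 3)
  expect_true(all(diff(s3$mz) < 0))
  expect_error(ion_series(1000, 0, 2), class = "xlinkxic_validation_error")
  # round trip over random masses and charges
  set.seed(5)
  for (i in 1:20) {
    m <- runif(1, 500, 9000); z <- sample(1:10, 1)
    mz <- ion_series(m, z, z)$mz
    expect_equal(z * mz - z * mass_constants$proton, m, tolerance = 1e-9)
  }
})

test_that("candidate enumeration emits the full chain plus contiguous sub-chains", {
  # distinct single-coverage peptides: 1 triple + 2 pairs
  p <- protein_record("p", "AWAKAYAKAMAK")
  spec <- adduct_spec("p", "M10,Y6,W2", proteins = p)
  peps <- digest(p, max_missed = 0)
  cands <- enumerate_candidates(peps, spec,
                                mods = modification_scheme(max_variable = 0))
  expect_equal(sum(cands$n_sites == 3), 1L)
  expect_equal(sum(cands$n_sites == 2), 2L)
  expect_equal(unique(cands$bond_count[cands$n_sites == 2]), 1L)
  tri <- cands[cands$n_sites == 3, ]
  expect_equal(tri$n_peptides, 3L)
  expect_equal(tri$corrected_mass, tri$naive_sum_mass - 2 * 2.01565,
               tolerance = 1e-9)
})

test_that("candidate count follows the product rule over covering peptides", {
  set.seed(31)
  for (i in 1:10) {
    # random protein with three marked sites in separate tryptic regions
    seq <- paste0(random_sequence(8, strsplit("AGSTVL", "")[[1]]), "W",
                  random_sequence(6, strsplit("AGSTVL", "")[[1]]), "K",
                  random_sequence(5, strsplit("AGSTVL", "")[[1]]), "Y",
                  random_sequence(6, strsplit("AGSTVL", "")[[1]]), "R",
                  random_sequence(4, strsplit("AGSTVL", "")[[1]]), "M",
                  random_sequence(5, strsplit("AGSTVL", "")[[1]]))
    p <- protein_record("p", seq)
    w <- regexpr("W", seq); y <- regexpr("Y", seq); m <- regexpr("M", seq)
    spec <- adduct_spec("p", c(M = m[1], Y = y[1], W = w[1]), proteins = p)
    mm <- sample(0:2, 1)
    peps <- digest(p, max_missed = mm)
    cands <- enumerate_candidates(peps, spec,
                                  mods = modification_scheme(max_variable = 0))
    cover <- vapply(spec$positions, function(pos) {
      sum(peps$start <= pos & peps$end >= pos)
    }, integer(1))
    chains <- list(1:3, 1:2, 2:3)
    expected <- sum(vapply(chains, function(ch) prod(cover[ch]), numeric(1)))
    expect_equal(nrow(cands), expected)
  }
})

test_that("a peptide covering several sites collapses into one component", {
  # no internal cleavage: one peptide covers all three sites
  p <- protein_record("p", "AWAYAMAG")
  spec <- adduct_spec("p", "M6,Y4,W2", proteins = p)
  peps <- digest(p, max_missed = 0)
  cands <- enumerate_candidates(peps, spec,
                                mods = modification_scheme(max_variable = 0))
  tri <- cands[cands$n_sites == 3, ]
  expect_equal(tri$n_peptides, 1L)
  expect_equal(tri$naive_sum_mass, peptide_mass("AWAYAMAG"), tolerance = 1e-9)
  # bonds are still counted: intra-peptide crosslink loses 4 H
  expect_equal(tri$corrected_mass, tri$naive_sum_mass - 2 * 2.01565,
               tolerance = 1e-9)
})

test_that("a one-site spec reduces to plain targeted peptide masses", {
  p <- protein_record("p", "AWAKAGAK")
  spec <- adduct_spec("p", "W2", proteins = p)
  cands <- enumerate_candidates(digest(p, max_missed = 0), spec,
                                mods = modification_scheme(max_variable = 0))
  expect_equal(cands$bond_count, 0L)
  expect_equal(cands$corrected_mass, cands$naive_sum_mass)
})

test_that("uncovered adduct sites raise a named error", {
  p <- protein_record("p", "AWAKAYAK")
  spec <- adduct_spec("p", "Y6,W2", proteins = p)
  peps <- digest(p, max_missed = 0)
  expect_error(enumerate_candidates(peps[peps$start > 4, ], spec),
               "position 2")
})

test_that("variable modifications expand candidates over oxidation counts", {
  p <- protein_record("p", "AWAKAYAKAMAK")
  spec <- adduct_spec("p", "M10,Y6,W2", proteins = p)
  cands <- enumerate_candidates(digest(p, max_missed = 0), spec)
  tri <- cands[cands$n_sites == 3, ]
  expect_equal(sort(tri$n_variable_mods), 0:1)   # one Met available
  expect_equal(diff(sort(tri$naive_sum_mass)), 15.99491, tolerance = 1e-9)
})

test_that("mass matching infers bond count and applies the tolerance", {
  cand <- tibble::tibble(candidate_id = "c1", naive_sum_mass = 6798.137,
                         corrected_mass = corrected_mass(6798.137, 2))
  hit <- match_observed(cand$corrected_mass, cand, tolerance = 0.05)
  expect_true(hit$accepted)
  expect_equal(hit$inferred_bond_count, 2L)
  expect_equal(hit$rounded_bond_shift, 4)
  miss <- match_observed(cand$naive_sum_mass, cand, tolerance = 0.05)
  expect_false(miss$accepted)
  expect_equal(miss$inferred_bond_count, 0L)
  expect_error(match_observed(6798, cand, tolerance = 0),
               class = "xlinkxic_validation_error")
})

test_that("integer mass reporting rounds half away from zero", {
  cand <- tibble::tibble(candidate_id = "c", naive_sum_mass = 6516.5,
                         corrected_mass = 6516.5)
  expect_equal(match_observed(6516.5, cand)$rounded_observed, 6517)
})
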