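# xlinkxic

Targeted detection of covalently crosslinked tryptic peptides in
centroided LC-MS data, built for the Met-Tyr-Trp (MYW) adduct of
catalase–peroxidases (KatGs).

KatGs are bifunctional heme oxidoreductases whose catalase activity
requires a post-translational covalent adduct between conserved Met, Tyr,
and Trp side chains on the distal heme side. After tryptic digestion the
adduct survives as a covalently linked peptide pair or triple. Such
species are invisible to ordinary database search engines; this package
implements the targeted arithmetic that finds them:

- **in-silico tryptic digestion** (cleave after K/R, not before P, with
  missed cleavages) and monoisotopic/average mass computation with fixed
  carbamidomethylation and variable oxidation;
- **crosslink candidate enumeration**: every combination of digested
  peptides covering the adduct sites, for the full site chain and its
  contiguous sub-chains, with the *naive* mass sum and the
  *bond-corrected* mass `M = Σ m_peptide − n_bonds × 2 × 1.007825 Da`
  (each covalent bond forms with loss of two hydrogen atoms — a rounded
  4 Da shift for the two-bond triple, 2 Da for a one-bond pair);
- **ion forms and detection**: `m/z = (M + z·1.007276)/z` over a charge
  range, per-charge extracted ion chromatograms (XIC), coelution of
  several charge states within a retention-time tolerance, and charge
  **deconvolution** back to the neutral monoisotopic mass (median over
  charges);
- a seeded **synthetic-run generator** (averagine isotope envelopes,
  Gaussian elution, exponential noise, ppm jitter) that provides ground
  truth for every stage, plus simulated absorbance kinetics traces and
  melting curves;
- **enzyme kinetics arithmetic**: specific activity
  `U/mg = |ΔA/min| / (ε·d) × V / m` via extinction coefficients
  (1 U = 1 µmol/min), and **thermal unfolding** analysis extracting the
  melting temperature Tm (smoothed-derivative inflection) and the onset
  of unfolding from fluorescence 350/330 ratio curves.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`, `glance()`, and `autoplot()` methods. mzML is read and written
through mzR (MS1 centroid subset), FASTA through Biostrings.

The two bundled protein records (`synthetic_katg()`,
`inst/extdata/synthetic_katg.fasta`) are **synthetic stand-ins** with the
study enzymes' bookkeeping — 723/750-residue natural chains, C-terminal
6×His tags, adduct sites at M244/Y218/W90 and M264/Y238/W90 — not the
GenBank sequences. Users with the real accessions supply them as FASTA
and the identical pipeline applies.

## Worked example

```r
library(xlinkxic)
library(dplyr)

proteins <- synthetic_katg()
spec  <- adduct_spec("CthedisKatG_syn", "M244,Y218,W90", proteins = proteins)
cands <- digest(proteins, max_missed = 1) |> enumerate_candidates(spec)

cands |>
  filter(missed_cleavages == 0, n_variable_mods == 0) |>
  select(candidate_id, site_chain, n_peptides, bond_count,
         naive_sum_mass, corrected_mass)
#> # A tibble: 3 × 6
#>   candidate_id site_chain    n_peptides bond_count naive_sum_mass corrected_mass
#>   <chr>        <chr>              <int>      <int>          <dbl>          <dbl>
#> 1 cand_001     M244-Y218-W90          3          2          6798.          6794.
#> 2 cand_055     M244-Y218              2          1          3485.          3483.
#> 3 cand_073     Y218-W90               2          1          5101.          5099.
```

The two-bond triple is 4.031 Da lighter than the naive sum, the one-bond
pairs 2.016 Da. Plant the triple in a synthetic run and search for it
end-to-end:

```r
tri <- cands |> filter(n_sites == 3, missed_cleavages == 0, n_variable_mods == 0)
sim <- simulate_run(planted_species(tri$corrected_mass, 4:6, rt = 10),
                    run_length = 20, noise = noise_model(seed = 42))
cfg <- pipeline_config(proteins, sim$run, "CthedisKatG_syn", "M244,Y218,W90",
                       max_missed = 1, z_min = 4, z_max = 6)
search_adduct(cfg)
#> <run_report> CthedisKatG_syn (M244-Y218-W90): 81 candidates, 1 coeluting, 1 accepted match(es)
#> accepted:
#> # A tibble: 1 × 7
#>   candidate_id site_chain    peptide_sequences    observed_mass rounded_observed
#>   <chr>        <chr>         <chr>                        <dbl>            <dbl>
#> 1 cand_001     M244-Y218-W90 DTLVAITEEITNNNWVGFV…         6794.             6794
#> # ℹ 2 more variables: delta_to_naive <dbl>, inferred_bond_count <int>
```

Of 81 enumerated candidates exactly the planted triple coelutes (charges
4–6 at 10 min), deconvolutes to 6794 Da, and is accepted with
`inferred_bond_count = 2` — the observed mass sits 4 Da below the naive
peptide sum, the signature of two covalent bonds.

The spectrophotometric companions:

```r
ctx <- assay_context("ABTS", 31.1, wavelength = 414, volume_ml = 1, enzyme_mg = 0.01)
tr  <- simulate_kinetics_trace(slope = 0.311, duration = 1, interval = 5)
specific_activity(fit_linear_rate(tr), ctx)
#> # A tibble: 1 × 5
#>   substrate slope rate_mM_min rate_u specific_activity
#>   <chr>     <dbl>       <dbl>  <dbl>             <dbl>
#> 1 ABTS      0.311        0.01   0.01                 1

melt_analysis(simulate_melt_curve(62.9, noise_sd = 0.004, seed = 1))
#> <melt_fit> Tm = 62.44 C, onset = 54.50 C (increasing transition)
```

A ΔA of 0.311/min with ε = 31.1 mM⁻¹cm⁻¹ in 1 mL over 0.01 mg enzyme is
1.0 U/mg; a logistic melting curve generated with Tm = 62.9 °C and 2%
noise is recovered within half a grid step.

A thin command-line interface wraps the same functions
(`inst/exec/xlinkxic`, subcommands `digest`, `candidates`, `simulate`,
`search`, `kinetics`, `melt`).

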