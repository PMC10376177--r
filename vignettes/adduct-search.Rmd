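---
title: "Targeted detection of the Met-Tyr-Trp adduct in LC-MS data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted detection of the Met-Tyr-Trp adduct in LC-MS data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlinkxic)
library(dplyr)
```

## The problem

Catalase–peroxidases (KatGs, EC 1.11.1.21) are bifunctional heme enzymes:
one active center supports both catalatic H~2~O~2~ dismutation and
peroxidatic one-electron substrate oxidation. The catalase mode depends on a
post-translational modification on the distal heme side: a covalent adduct
joining the side chains of a conserved methionine, tyrosine, and tryptophan
(in the fungal enzymes modeled by this package, Met244–Tyr218–Trp90 in the
thermophilic-like protein and Met264–Tyr238–Trp90 in the mesophilic-like
one, numbering on the natural chain).

A bottom-up proteomics experiment digests the protein with trypsin. If the
adduct is present, the three residues stay covalently joined, so the digest
contains a *crosslinked species*: two or three tryptic peptides sharing one
mass. Standard database search engines do not identify such species, and
the targeted workflow implemented here is the remedy:

1. digest the sequence in silico and enumerate every combination of
   peptides covering the adduct sites;
2. compute each combination's monoisotopic mass — the **naive sum** of the
   peptide masses, and the **bond-corrected** mass, which subtracts
   2 × 1.007825 Da per covalent bond (each bond forms with loss of two
   hydrogen atoms): for the triple (two bonds) the rounded shift is 4 Da,
   for a pair (one bond) 2 Da;
3. compute the multiply-protonated ion forms
   \(m/z = (M + z\,m_\mathrm{p})/z\) over a charge range;
4. extract an ion chromatogram (XIC) per ion form and require *coelution*:
   several charge states reaching their chromatographic apex at the same
   retention time;
5. deconvolute the coeluting charges back to a neutral monoisotopic mass,
   \(M = z \cdot m/z - z\,m_\mathrm{p}\), aggregated by the median;
6. match the observed mass against the bond-corrected candidate mass and
   infer the apparent bond count from the offset to the naive sum.

The package also implements the two spectrophotometric companions of such a
study: specific enzymatic activity from absorbance slopes via
Beer–Lambert (one unit U = 1 µmol substrate converted per minute), and
melting temperature / onset extraction from nanoDSF-style fluorescence
350/330 ratio curves.

## Mass arithmetic

Residue masses are the standard monoisotopic and average tables (ExPASy /
Unimod); the proton is 1.007276 Da, the hydrogen atom 1.007825 Da, water
18.010565 Da, and the isotopologue spacing 1.003355 Da. A peptide's
monoisotopic mass is the residue sum plus one water. The search convention
is carbamidomethylation of cysteine as a fixed modification (+57.02146 Da)
and methionine oxidation (+15.99491 Da) as a variable one, capped at two
per peptide or candidate; both are `modification_scheme()` parameters and
the mass table itself can be overridden from a `name = value` text file.

Tryptic digestion cleaves C-terminal to K or R except before P, with the
protein termini as peptide termini. The default of up to two missed
cleavages is the common search setting and guarantees that adduct-site
peptides are present even when a site neighbours a cleavage site. The
digestion routine is verified in the test suite against a brute-force
enumeration of all substrings satisfying the cleavage rule.

Candidate enumeration emits, for the ordered site chain, the full chain and
every contiguous sub-chain of length two or more — the experimentally
observed species include both the full triple and a pair — with one
candidate per way of choosing a covering peptide per site (peptides
covering several sites collapse to a single component, but the bond count
stays `sites − 1`). Non-contiguous pairs are off by default and
flag-enabled, as no such species is expected. Integer masses are reported
with half-away-from-zero rounding, the convention of printed values;
full-precision masses are always retained alongside.

## Signal model and detection

An `ms_run` is a centroided MS1 run: strictly increasing retention times
and per-scan peak lists sorted by m/z. mzML (read/write through mzR, MS1
centroid subset; profile data are rejected with guidance) and two
plain-text fixture formats (JSON, flat CSV) are supported.

XIC extraction sums, per scan, all centroid intensities within a ppm
half-window of the target (default 10 ppm, Orbitrap-class). Coelution
detection extracts one XIC per charge, keeps apexes exceeding a robust
noise floor — three times the median nonzero trace intensity, so a trace
holding only stray noise hits can never pass — and accepts when at least
`min_charges` (default 2; "several ion forms") apexes fall inside a
retention-time window of `rt_tol` (default 0.2 min). Deconvolution then
takes, in the scan nearest the coelution apex, the most intense peak
within tolerance of each theoretical m/z, inverts the ion-form relation
per charge, and reports the median with the maximum absolute deviation as
dispersion; charges without a supporting peak are dropped.

The deconvolution window is deliberately a single scan at the coelution
apex: the analysed "time window" of such experiments is not standardised,
and one scan keeps the estimate independent of elution-profile shape.

The end-to-end search probes coelution at the ion forms of the
bond-corrected mass first and, failing that, at the naive sum. This
mirrors how the original workflow operates — candidate masses are
calculated *disregarding* bond losses, the species is found anyway, and
the −4/−2 Da shift only becomes apparent at deconvolution. A species
sitting at the naive sum is therefore still observed, its mass shift
reported, and the match rejected by the corrected-mass tolerance (default
0.05 Da on the deconvoluted mass).

## The synthetic-data generator

`simulate_run()` builds a centroided run on a regular scan grid (defaults:
0.01 min interval, 60 min length, echoing a typical 60-min gradient). Each
planted species contributes, per charge, an averagine isotope envelope —
composition C~4.9384~H~7.7583~N~1.3577~O~1.4773~S~0.0417~ per 111.1254 Da,
with the heavy-isotope count Poisson-approximated from the natural
abundances — at \((M + k \cdot 1.003355 + z\,m_\mathrm{p})/z\), scaled by
a Gaussian elution profile evaluated over ±6σ (default σ = 0.05 min) and
the species abundance (default 10^4^). The noise model adds exponential
random noise peaks (default 20 per scan, mean 100) and Gaussian m/z jitter
(default 0.5 ppm); one integer seed makes the whole run bit-identical.
These defaults keep the signal-to-noise ratio of the *monoisotopic* target
channel of a 4–7 kDa species at or above 10 (the envelope apex sits near
100× the noise mean, and the monoisotopic isotope carries roughly 10–30%
of the apex intensity at these masses).

Ground truth is defined on *resolved* species: `sample_resolved_masses()`
rejection-samples masses so that no two planted species share an m/z
channel (any isotopologue of any planted charge) within 0.05 Th. Without
this constraint, randomly drawn masses regularly differ by near-integer
multiples of the isotope spacing, which aligns their isotope ladders at
every charge state inside a 10 ppm window and makes the XICs chimeric;
a targeted single-species search does not attempt to disentangle such
chimeras, so they are excluded from the truth definition (and the same
reasoning is why decoy targets are kept at least 20 Da from every planted
mass). This is also the main caveat when transferring the recovery rates
measured here to real data: a real digest background is far denser than
the generator's noise model, and co-isolating species, tailing peaks, and
saturation are not simulated. Passing the planted-recovery tests shows the
detection arithmetic is correct at realistic tolerances, not that the
workflow's false-negative rate on a real run is zero.

The generator also produces linear absorbance traces
(`simulate_kinetics_trace()`) and logistic melting curves
(`simulate_melt_curve()`,
\(r(T) = \ell + (u-\ell)/(1+e^{(T_m - T)/s})\), default grid 20–95 °C in
0.5 °C steps, the usual nanoDSF ramp) with known ground truth.

Two deterministic stand-in proteins, `synthetic_katg()`, carry the
bookkeeping of the study enzymes — natural chain lengths 723 and 750
residues plus a C-terminal 6×His tag recorded as `tag_span`, and the
adduct sites at the documented positions inside ordinary tryptic peptides.
They are explicitly synthetic: the real GenBank sequences are not bundled,
so sequence-derived values of the real enzymes (their printed crosslink
masses and subunit molecular weights) are not reproduced by this package;
users with the accessions supply them as FASTA and the same pipeline
applies. Residue numbering follows the natural (untagged) chain, which is
the convention under which "Trp90" is the same position in both enzymes;
`include_tag` flips any property computation to the full stored chain.

## Kinetics and unfolding arithmetic

`specific_activity()` implements
\[
U/\mathrm{mg} \;=\; \frac{|\Delta A/\mathrm{min}|}{\varepsilon\,
[\mathrm{mM^{-1}cm^{-1}}] \cdot d\,[\mathrm{cm}]} \times
V\,[\mathrm{mL}] \times \frac{f}{m_\mathrm{enzyme}\,[\mathrm{mg}]},
\]
where the quotient is the substrate conversion rate in mM/min (= µmol per
mL per min), ε in M^−1^cm^−1^ converts by 10^−3^, and the stoichiometry
factor *f* defaults to 1 — no per-reaction stoichiometry (such as two
H~2~O~2~ per catalatic turnover) is applied unless the assay context says
so, since conventions differ between laboratories. The bundled
`assay_contexts.yaml` carries the usual substrate coefficients (ABTS
31.1 mM^−1^cm^−1^ at 414 nm, guaiacol 26.6 at 470 nm, L-DOPA 3.6 at
470 nm, Mn^2+^ 6.5 at 238 nm, H~2~O~2~ 43.6 M^−1^cm^−1^ at 240 nm).
Note that published ε~280~ values for the two study enzymes appear with
swapped assignments in different places of the source literature;
`molar_extinction_280()` simply computes the Gill–von Hippel sum
(5500 nW + 1490 nY + 125 n~cystine~, all cysteines reduced by default)
from whatever sequence it is given and leaves arbitration to the user.

`fit_linear_rate()` is ordinary least squares with the initial-rate
convention: when no window is given it grows the window from the first
five points while R² stays at or above 0.99, so late-time curvature is
excluded automatically. A perfectly flat trace is defined as R² = 1 (zero
residuals). The window rule admits a short stretch past a kink — R² is a
global statistic — which is why an explicit window always overrides it.

`melt_analysis()` reads the melting temperature as the maximum of the
smoothed absolute first derivative of ratio versus temperature. A centered
five-point moving average is applied twice — to the curve before
differencing and to the derivative after — and the discrete peak is
refined by three-point parabolic interpolation; both operations are
symmetric, so the logistic inflection is unbiased. On the 0.5 °C grid
with noise at 2% of amplitude this recovers midpoints with a median error
near 0.3 °C; noiseless curves are recovered to well under one grid step.
The onset is the lowest temperature at which the curve departs from the
pre-transition baseline (mean of the first few points) by more than 2% of
the total amplitude in the transition direction — the published notion of
"where the molecules start to denaturate" has no operational definition,
and 2% is this package's choice, exposed as `onset_frac`. A flat curve
raises "no transition detected" rather than returning a number.

## Problem sizes and numerical choices

The shipped checks run at desk scale, chosen to exercise every code path
while staying quick: the planted-recovery study uses 100 resolved species
(charges 4–6) in a 50-min run at 0.01-min scans with 100 decoys, and the
melt-recovery study uses 100 noisy curves; both complete in well under a
minute each. End-to-end searches in the tests digest with one missed
cleavage, which keeps the candidate table at ~80 rows; the default of two
is appropriate for real searches.

Tie-breaks and degenerate inputs are resolved as follows: `which.max`
conventions make the earliest scan win ties for apexes; an all-zero XIC
has no apex (`NA`); coelution clustering picks the densest retention-time
window of width `rt_tol` over the found apexes, so the accepted spread
never exceeds the tolerance; charge inference from isotope spacing
declares ambiguity when consecutive spacings vary by more than 20% of
their median or the implied charge is farther than 0.1 from an integer;
`corrected_mass()` refuses negative bond counts; empty runs and
uncovered adduct sites are errors that name the offending input.

## Known limitations

No MS2-level localisation of the crosslink, no FDR estimation over decoy
crosslinks, no retention-time alignment across runs, no profile-mode peak
picking, and no chimera deconvolution — all deliberate non-goals. The
activity module fits initial rates only (no Michaelis–Menten), and the
melt module extracts Tm and onset only (no two-state thermodynamic fit).
Absolute specific activities of the study enzymes are not reproducible
from published material (enzyme amounts per cuvette are not stated), so
the kinetics checks here are arithmetic identities on synthetic traces.
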