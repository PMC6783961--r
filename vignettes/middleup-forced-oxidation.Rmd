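---
title: "Middle-up forced-oxidation analysis of IgG1 antibodies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Middle-up forced-oxidation analysis of IgG1 antibodies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forceox)
```

## Why middle-up, and what this package does

Methionine oxidation can change the stability, receptor binding and
half-life of a therapeutic IgG1 antibody, which makes a product's
susceptibility to oxidation a candidate critical quality attribute and a
sensitive probe when comparing a biosimilar (BS) against its reference
product (RP). The *middle-up* strategy digests the antibody with the IdeS
protease below the hinge and reduces disulfides, yielding three ~23–27 kDa
subunits per antibody — the light chain (LC), the heavy-chain N-terminal
fragment (Fd'), and half of the constant fragment (Fc/2) — small enough for
clean LC-ESI-QTOF mass measurement yet large enough to localize
modifications to a region in a single fast experiment.

`forceox` implements that workflow end to end as testable code:

1. in-silico IdeS digestion and methionine mapping (`ides_digest()`,
   `map_methionines()`, `compare_methionine_maps()`);
2. proteoform mass libraries and ppm matching (`enumerate_proteoforms()`,
   `match_mass()`, `annotate_mass_error()`);
3. a seeded synthetic LC-MS run generator driven by per-site oxidation
   kinetics (`default_scenario()`, `simulate_run()`, `write_mzml()`);
4. chromatographic peak detection, charge-series deconvolution and
   extracted-ion-chromatogram (EIC) quantification
   (`detect_chromatographic_peaks()`, `deconvolute()`, `extract_eic()`);
5. orchestration: species assignment, the relative-abundance statistic,
   RP/BS time-course comparison, site attribution and a biosimilarity
   report (`assign_run()`, `ox_relative_abundance()`, `time_course()`,
   `attribute_sites()`, `biosimilarity_report()`).

No public raw data exist for this kind of study, so the synthetic generator
is a first-class component: it defines the ground truth against which the
analysis layer is validated.

## Digestion model

IdeS cleaves IgG1 between the paired glycines of the lower-hinge motif
(...CPAPELLG | GPSV...). The package implements this as "cut between the
two G of the unique `LLGG` occurrence" and rejects heavy chains with zero
or multiple motifs rather than guessing. Reduction is modelled implicitly:
subunits are emitted as free chains with two copies per antibody, and no
disulfide bookkeeping is attempted because the analysis operates on fully
reduced chains. Site labels in the community numbering (EU numbering for
Fc/2) are produced by a per-subunit additive offset supplied in the mAb
configuration; this avoids embedding a full-antibody alignment engine for
what is purely a labelling concern.

The package ships a pair of *synthetic* IgG1-like sequences
(`synthetic_mab()`). They are constructed, not the marketed products', but
reproduce the methionine layout that makes the bevacizumab/infliximab
comparison informative: LC M4 vs LC M55; Fd' M34/M83 vs Fd' M18/M34/M85
(M83 and M85 homologous); Fc/2 M252/M358/M428 vs M255/M431. Users with real
sequences load them with `load_mab_fasta()` plus their own label offsets.

## Mass model

Masses are computed from frozen element tables (IUPAC 2021 standard atomic
weights; monoisotopic masses alongside) and residue compositions, so every
theoretical mass is bit-reproducible. The *average* mass is the matching
currency: at subunit size the deconvolved quantity is the isotope-averaged
mass, and the library is matched at ±70 ppm. Monoisotopic masses are kept
for verification only. Modification deltas are computed from composition,
never hard-coded: oxidation is +O; pyroglutamate is −NH₃ from Gln or −H₂O
from Glu; a retained C-terminal lysine adds one lysine residue; the
glycoforms are summed from monosaccharide residues (G0F = HexNAc₄Hex₃Fuc₁,
G1F = G0F + Hex). The proteoform library is the full cross-product of
glycan (Fc/2 only), pyroglutamate (Q/E N-terminus only), C-terminal lysine
(Fc/2 only) and 0..(n_met + 4) oxidations; the cap of 4 beyond the
methionine count accommodates the unspecific oxidation of other residues
that harsh peroxide stress produces. Mass-error annotations follow the
star convention used on middle-up chromatogram figures (≤0.5 Da `*`,
≤1.5 Da `**`, ≤4.0 Da `***`, above that rejection).

## Oxidation kinetics and the synthetic generator

Forced oxidation is modelled as independent pseudo-first-order reactions:
site *i* with rate constant $k_i$ (1/h) is oxidized by time $t$ with
probability $p_i = 1 - e^{-k_i t}$. The number of site oxidations on a
subunit is Poisson-binomial over its sites; an independent unspecific
count with mean $k_u t$ (truncated at the cap, renormalized) is convolved
on top. Control treatment zeroes every effective rate.

The default scenario (`default_scenario()`) encodes the qualitative
endpoint behaviour the workflow is designed to detect, with two rate
classes:

* **fast**, $k = 0.15$/h (≥97% conversion at 24 h): all Fc/2 methionines
  (surface-exposed, conserved) plus the infliximab-like LC M55 and Fd'
  M18;
* **slow**, $k = 0.002$/h for the RP: everything else (buried sites). The
  BS uses a ×2 multiplier on the slow class, emulating a biosimilar that
  converts faster under stress;
* **unspecific**, $k_u = 0.01$/h per chain.

Two of these numbers deserve justification. The slow rate is bounded
above by the requirement that a two-methionine subunit (the
bevacizumab-like Fd') keeps its unoxidized form most abundant through
48 h in both roles once the unspecific channel is included; 0.002/h
satisfies this with margin while still producing a clearly rising
time course. The unspecific rate 0.01/h is chosen so that the 3-fold
oxidized satellites of a one- or two-methionine subunit — the species the
time-course statistic is defined on — sit at observable minor abundance
(~0.3–6% over 24–72 h) rather than below the simulator's 10⁻⁴ species
floor; a much smaller $k_u$ would make those satellites unobservable and
the statistic degenerate.

Each proteoform above the floor becomes a Gaussian chromatographic peak
(σ = 0.08 min) at its subunit's base retention time, shifted −0.15 min per
oxidation: oxidized species are more hydrophilic, elute earlier on
reversed phase, and are only partially separated, as in real subunit
chromatograms. Intensity is spread over a Gaussian charge-state envelope
(mean $z^* = \mathrm{round}(M/1200)$, σ = 2.5 charges) with each charge
state an isotopically unresolved Gaussian in m/z (FWHM = 6/z Th), sampled
on an absolute 0.01 Th lattice inside m/z 600–3200 at 2 spectra/s. A flat
baseline plus Gaussian noise with an intensity-proportional term is added;
everything is driven by one integer seed and is bit-reproducible. The
retention-time axis defaults to 0–16 min with the three subunit clusters
at 5/8/12 min: the generator places no signal elsewhere, so simulating a
longer gradient would only add empty scans. Runs can be exported to and
re-read from mzML through `mzR`.

What the generator deliberately does **not** emulate: isotope fine
structure, adducts, in-source fragmentation, detector saturation,
retention drift between runs, and undigested heavy chain (available only
as a contaminant the annotation layer never assigns). Passing tests
therefore demonstrate correctness of the analysis logic under a plausible
forward model, not robustness to every artefact of real instrument data.

## Deconvolution and quantification

Vendor maximum-entropy deconvolution is not reimplemented. The package
uses a deterministic charge-series algorithm with an explicit contract:
every centroid expands into candidate masses $M = z(m/z - 1.00728)$ over
z = 8..40; candidates cluster on the mass axis (single-linkage, 0.2 Da
gap); clusters are consumed in order of total supporting intensity — which
suppresses the M/2 and 2M harmonics built from the same centroids — and
survive only with ≥3 distinct supporting charge states. On noiseless
envelopes the recovered mass is well inside 20 ppm, comfortably within
the 70 ppm matching window used downstream.

Semiquantification follows the EIC convention: for each species the most
intense charge state ($z^*$, recorded in the output) is monitored with an
m/z tolerance of ±0.01 Th, and the peak height is the maximum of the trace
inside the *species'* retention window. That window is anchored on the EIC
apex of the subunit's top species and shifted per oxidation. The
species-level window matters: the pyroglutamate +1ox proteoform is a −1 Da
isobar of the plain unoxidized chain (−17 + 16 Da), unresolvable in m/z at
this peak width, but it elutes one oxidation shift away and is excluded in
time. The relative abundance of the n-fold oxidized species is

$$a_r = \frac{I_{n\mathrm{ox}}}{I_{0\mathrm{ox}} + I_{n\mathrm{ox}}},$$

generalizing the 3ox-specific definition used for bevacizumab time
courses to any oxidation level; the bevacizumab-like default report uses
LC 3ox and Fd' 3ox, the infliximab-like default the 1ox species (its most
abundant oxidized form). Replicates are reported as individual points with
a mean ± sd summary, and a monotonicity diagnostic accompanies each
series.

## Site attribution

Cross-antibody attribution is a conservative set-difference, never
probabilistic. Per subunit: a most-abundant oxidation count equal to the
methionine count makes all sites susceptible; zero makes all resistant;
a partial count first imports verdicts for shared sites (identical labels,
or pairs declared homologous such as M83≡M85) from the other antibody and
attributes the remainder only if the counts force a unique solution.
Anything else — including evidence that oxidizes more shared sites than
the observed count — is `indeterminate` with a recorded conflict note.
Every methionine of both products receives exactly one verdict with an
evidence string.

## Numerical choices and edge cases

* Proton mass 1.00728 Da; charge range 8–40 covers 22–60 kDa inside
  m/z 600–3200.
* The m/z lattice is absolute (multiples of 0.01 Th), so a ±0.01 Th EIC
  window always contains two lattice points and the summed height varies
  by <0.2% with the alignment of the species' centroid — species ratios
  are therefore unbiased.
* Peak detection smooths the TIC (13 scans ≈ 0.1 min), thresholds at
  median + 8·MAD, merges maxima closer than 1 min (one subunit's
  oxidation ladder is one window) and cuts windows at 5% of peak height.
  Flat or empty chromatograms yield an empty window list.
* Exact abundance ties in `most_abundant_species()` break toward the
  lower oxidation state, then lexically.
* `relative_abundance()` refuses an all-zero denominator instead of
  returning NaN.
* Oxidation-state distributions are convolved directly (no FFT), so
  probabilities are exact to rounding and always renormalized; the
  truncated unspecific distribution is renormalized before convolution.
* Degenerate inputs: sequences with non-canonical residues fail with the
  position named; heavy chains without a unique hinge motif are rejected;
  species whose entire charge envelope falls outside the acquisition
  window are dropped with a warning.

## Problem sizes used in the shipped tests

The test suite exercises the complete study design — 2 products × RP/BS ×
(control 0/24/48/72 h + oxidation 24/48/72 h) × 3 replicates = 84 runs —
with the acquisition span trimmed to the 3.5–13 min elution window of the
three subunit clusters; a full-span run is what the acceptance script and
the worked examples use. The deconvolution contract is checked on 50
random noiseless species in 22–27 kDa, and mass arithmetic against an
independent elemental-composition oracle.

## Known limitations

* The kinetic scenario is generator truth, not an estimate: real rate
  constants for these products are unknown, and the package makes no
  claim to recover them — only species calls and the relative-abundance
  statistic are compared.
* The charge-series deconvolution assigns each centroid greedily to one
  mass; heavily overlapping envelopes of coeluting species of similar
  abundance can shadow one another. The matching window (70 ppm)
  downstream tolerates this for the species inventory used here.
* Attribution reasons over most-abundant counts only; partial oxidation
  levels between 0 and saturation contribute no evidence unless the other
  product resolves the shared sites.
* No statistical hypothesis testing of RP/BS differences is performed;
  differences are reported descriptively, as in the study design this
  package mirrors.
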