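# forceox

Middle-up LC-MS analysis of forced methionine oxidation in IgG1 monoclonal
antibodies, for biosimilarity assessment.

## The problem

Methionine oxidation can alter an antibody's stability, Fc-receptor binding
and target binding, so a product's susceptibility to oxidation is a
candidate critical quality attribute — and a sensitive way to compare a
biosimilar (BS) with its reference product (RP): stressing both with
hydrogen peroxide over a time course amplifies small differences that
unstressed comparisons miss. The *middle-up* level is the practical sweet
spot for this: IdeS digestion below the IgG1 hinge plus disulfide reduction
yields three ~23–27 kDa subunits — light chain (LC), the heavy-chain
N-terminal fragment (Fd'), and half the constant fragment (Fc/2) — whose
deconvoluted masses localize modifications to a region with minimal sample
preparation.

`forceox` implements this workflow as a tested pipeline for analysts and
method developers:

* **in-silico digestion** — cut at the unique lower-hinge `LLGG` motif,
  map methionines into community numbering (EU numbering for Fc/2) via
  label offsets;
* **proteoform libraries** — average masses from frozen IUPAC atomic
  weights for every combination of glycoform (G0F/G1F/none), N-terminal
  pyroglutamate, C-terminal lysine and 0..(n_met+4) oxidations, matched at
  ±70 ppm with star-notation mass-error annotation;
* **synthetic LC-ESI-QTOF runs** — a seeded generator built on per-site
  pseudo-first-order kinetics, p_i = 1 − exp(−k_i·t), with a
  Poisson-binomial site count plus a truncated-Poisson unspecific channel;
  charge-state envelopes in m/z 600–3200, partially separated oxidation
  ladders in retention time, mzML export via `mzR`;
* **deconvolution & quantification** — deterministic charge-series
  deconvolution (M = z·(m/z − 1.00728), ≥3 supporting charges, greedy
  harmonic suppression) and extracted-ion-chromatogram peak heights at the
  apex charge state (±0.01 Th);
* **comparison** — the relative-abundance statistic
  `ar = I_nox / (I_0ox + I_nox)` per (product, subunit, duration,
  replicate), RP-vs-BS time courses, cross-antibody methionine-site
  attribution, and a difference report.

## Worked example

Simulate one 48 h forced-oxidation run of the built-in synthetic
bevacizumab-like biosimilar and analyse it end to end:

```r
library(forceox)
mab <- synthetic_mab("bevacizumab_synthetic", role = "BS")
kin <- default_scenario(mab)
run <- simulate_run(mab, kin, treatment = "oxi", duration = 48, seed = 1)
ann <- assign_run(run, mab_library(mab))
ann
#> <run_annotation> 3 windows
#>   4.08-4.77 min [Fc/2]: Fc/2 G0F 3ox; Fc/2 G1F 3ox; Fc/2 G0F 4ox
#>   7.50-8.21 min [LC]: LC; LC 1ox; LC 2ox
#>   11.43-12.21 min [Fd']: Fd'; Fd' 1ox; Fd' 2ox
```

Three chromatographic windows are detected and annotated, coeluting
species listed in order of spectrum intensity: the Fc/2 window is
dominated by the triply oxidized glycoforms (all three Fc/2 methionines
oxidized), while LC and Fd' remain mostly unoxidized — the expected
forced-oxidation signature of this product.

```r
most_abundant_species(ann, "Fc/2")[, c("display_name", "observed_mass",
                                       "delta_ppm", "stars")]
#>   display_name observed_mass delta_ppm stars
#> 1 Fc/2 G0F 3ox      24401.16 0.2605771     *

rec <- ox_relative_abundance(run, ann, mab_library(mab),
                             c("LC" = 3L, "Fd'" = 3L))
rec[, c("subunit", "ox_level", "z", "i_0ox", "i_nox", "ar", "ar_truth")]
#>   subunit ox_level  z    i_0ox     i_nox         ar   ar_truth
#> 1      LC        3 20 16558.85  708.4735 0.04102972 0.04105847
#> 2     Fd'        3 21 12917.22 1164.1793 0.08267496 0.08147922
```

The deconvoluted Fc/2 mass sits 0.26 ppm from theory (`*` = within
0.5 Da). The EIC-based relative abundance of the 3ox species (`ar`,
measured at charge state 20/21 with ±0.01 Th tolerance) recovers the
generator's ground truth (`ar_truth`) to ~0.001: about 4% of the light
chain and 8% of Fd' have picked up three oxidations after 48 h in this
biosimilar. Repeating this over the full design
(`table1_design()`) and feeding the records to `time_course()` and
`biosimilarity_report()` yields the RP/BS comparison; `attribute_sites()`
turns the most-abundant oxidation counts of the two products into
per-methionine susceptible/resistant verdicts.

The methods vignette (`vignettes/middleup-forced-oxidation.Rmd`) documents
the kinetic model, the generator's parameters and the numerical choices.

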