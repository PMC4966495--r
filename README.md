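# adcdar

Characterization of cysteine-conjugated antibody-drug conjugates (ADCs) by
simulated heart-cutting two-dimensional liquid chromatography with mass
spectrometric detection — drug-load isomer enumeration, HIC-based
drug-to-antibody ratio (DAR) quantitation, ESI charge-state deconvolution,
and sub-unit-mass isoform assignment, with a synthetic-data generator that
makes the whole pipeline testable end to end.

## The science

Cysteine conjugation partially reduces the four inter-chain disulfides of
an IgG1 (two light–heavy, two heavy–heavy hinge bonds) and caps each freed
thiol with a maleimide drug-linker, so drug loads come in steps of
0, 2, 4, 6, 8 — with positional isomers at intermediate loads. `adcdar`
collapses the 2⁴ = 16 reduction states under the molecular symmetry group
into the canonical 9 isoform classes (multiplicities 1/2/3/2/1 by load)
and predicts, for each class, the covalent sub-units it dissociates into
under denaturing reversed-phase conditions (connected components over the
intact bonds), with masses

```
m(sub-unit) = Σ chain masses + glycoform Δ + n_drugs × m_drug
              − n internal intact bonds × 2.016 Da
```

The drug-load distribution is quantified from hydrophobic interaction
chromatography (HIC) peak areas: each load species contributes
`area% × load / 100` to the total DAR. Heart-cut fractions of individual
HIC peaks are identified by deconvolving their continuum electrospray
spectra to neutral average masses (a transparent greedy charge-comb
algorithm: score `Σ_z I((M + 1.00728 z)/z)`, extract, subtract, repeat)
and matching the observed mass multiset two-sidedly against the isoform
signature library.

## Worked example

```r
library(adcdar)

# the conjugate model: 9 positional isoforms of the reference IgG1
asm <- fixture_igg1()
enumerate_isoforms(asm)[, c("label", "dar", "n_members")]
#>   label   dar n_members
#>   0         0         1
#>   2a        2         2
#>   2b        2         2
#>   4a        4         1
#>   4b        4         4
#>   4c        4         1
#>   6a        6         2
#>   6b        6         2
#>   8         8         1

# what the fully loaded (DAR 8) species dissociates into
attr(dissociate("8", asm), "unique_masses")
#> [1] 23580.0 51630.6        # light + 1 drug, heavy(G0F) + 3 drugs

# DAR from per-load relative HIC areas (low-loaded batch)
dar_from_areas(c(`0` = 16.73, `2` = 40.71, `4` = 28.56,
                 `6` = 12.54, `8` = 1.50))
#> <dar_report> total DAR = 2.83

# full pipeline on a simulated high-loaded batch
report <- run_pipeline(run_config(batch = "high", seed = 3,
                                  out_dir = tempfile(), quiet = TRUE))
print(report)
#> <adc_report> batch: high | total DAR = 5.97
#> | Drug load | Area (%) | RSD (%) | DAR contribution |
#> | 0  | 0.37  | 0.36 | 0.00 |
#> | 2  | 3.40  | 0.14 | 0.07 |
#> | 4  | 30.67 | 0.12 | 1.23 |
#> | 6  | 28.63 | 0.18 | 1.72 |
#> | 8  | 36.92 | 0.07 | 2.95 |
#> | **Total DAR** | | 0.01 | **5.97** |
#> ... per-peak assignments: A→0, B→2a, C→4a, D→4b, E→6a, F→6b, G→6a, H→8
```

The total DAR is the area-weighted mean drug load; the per-peak table
shows which positional isoform uniquely explains each heart-cut fraction's
deconvolved sub-unit masses (peak H's pair 23,580.0 / 51,630.6 Da can only
arise from the fully conjugated DAR 8 species).

A thin CLI over the same functions is installed at
`system.file("scripts", "adcdar.R", package = "adcdar")` with subcommands
`enumerate`, `simulate`, `quantify`, `deconvolve`, `assign` and `run`.

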