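---
title: "Characterizing cysteine-conjugated ADCs by simulated 2D-LC/MS"
author: "adcdar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing cysteine-conjugated ADCs by simulated 2D-LC/MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcdar)
```

## The problem

Cysteine-conjugated antibody-drug conjugates (ADCs) are made by partially
reducing the four inter-chain disulfide bonds of an IgG1 and capping the
freed cysteines with a maleimide drug-linker. Each reduced bond frees two
thiols, so drug loads come in steps of 0, 2, 4, 6 and 8 — but the *same*
drug load can sit on different bonds, producing positional isomers.
Hydrophobic interaction chromatography (HIC) resolves the load species (and
often the isomers) as a peak profile whose relative areas give the
drug-to-antibody ratio (DAR), a critical quality attribute. HIC buffers are
incompatible with electrospray MS, so peak identities are obtained by
heart-cutting a narrow time slice of the HIC effluent onto a denaturing
reversed-phase column: the conjugate falls apart into its covalent
sub-units, and the sub-unit mass multiset identifies the isomer.

`adcdar` implements this entire workflow in silico: the combinatorial
isomer model, HIC peak integration and DAR computation, charge-state
deconvolution of continuum ESI spectra, signature matching, and a
synthetic-data generator that produces every input with known ground truth.

## The conjugate model

The conjugate is four chain instances (L1, L2, H1, H2) joined by four
inter-chain bonds: two light-heavy bonds and two heavy-heavy hinge bonds.
Chain base masses are *reduced* average masses (all inter-chain cysteines
as free thiols); every intact bond subtracts 2.016 Da (two hydrogens).
Defining masses in the reduced state makes all arithmetic additive and
mass conservation exact: thiol-maleimide Michael addition adds the full
drug mass (376.46 Da for the drug mimic, formula C23H24N2O3) with no
leaving group, so

```
sub-unit mass = sum(chain masses) + glycoform deltas
              + drugs x 376.46 - internal intact bonds x 2.016
```

A reduction state is a subset of the four bonds. Two states are the same
positional isoform when a molecular symmetry maps one onto the other. We
model the symmetry as the group generated by two involutions: the 2-fold
arm swap ((L1,H1) with (L2,H2), hinge-1 with hinge-2) and the exchange of
the two hinge bonds alone. The hinge exchange is a deliberate modeling
collapse: the two hinge disulfides join the same chain pair at adjacent
cysteines, and species differing only in *which* hinge bond is reduced
have identical composition and dissociation signature; the source data
cannot distinguish them either (the singly-hinge-reduced DAR 6 peak "may
represent either one of the isomers or both"). With only the arm swap the
16 reduction states fall into 10 orbits; with the full group they fall
into the canonical 9 classes with load multiplicities 1/2/3/2/1.

Labels follow the field's convention: within a drug load, suffixes a, b, c
are assigned by decreasing number of reduced light-heavy bonds. This
reproduces the three labels the study confirms (4a = both LC-HC reduced,
6a = both LC-HC + one hinge, 6b = one LC-HC + both hinge); the remaining
labels (2a, 2b, 4b, 4c) are forced by the scheme, not reported facts.

Dissociation under denaturing conditions is graph-theoretic: sub-units are
the connected components over the *intact* bonds, and each reduced bond
deposits one drug at each endpoint cysteine. Masses within 0.5 Da are
merged into one "unique" mass — well below what chromatography or
deconvolution can distinguish at 20-150 kDa.

### Reference chain masses

The mAb sequence behind the study is not public; the bundled fixture
back-derives the chain masses from the two reported conjugated sub-unit
masses: light 23,203.54 Da (so light + 1 drug = 23,580.0) and heavy(G0F)
50,501.22 Da (so heavy + 3 drugs = 51,630.6), with G1F at +162.14 Da.
These are synthetic reference values, marked as such in the documentation;
with them the 9 isoform classes yield 9 pairwise-distinct signatures.

## HIC quantitation

`detect_peaks()` uses local maxima with a topographic-prominence filter,
valley-to-valley boundaries between adjacent apices (perpendicular drop at
the local minimum — the usual treatment for partially resolved shoulders),
outer boundaries at baseline return, and trapezoidal integration over a
constant baseline estimated from the first and last 5% of the run. No
peak-shape model is fitted; the integration rule is deliberately the
simplest defensible one.

`dar_from_areas()` computes per-load contributions `area% x load / 100`
and their sum, the total DAR. This treats 220 nm relative areas as
relative molar abundances, which holds when the drug does not change the
UV response of the conjugate (the study's drug mimic was chosen for
exactly that property). `replicate_stats()` uses the sample (n-1) standard
deviation for RSDs, appropriate for triplicates.

The heart-cut bookkeeping is exact: a 0.20 min window at 0.500 mL/min
transfers 0.100 mL; a 0.05 min purge delay at each end trims the window
whose composition is transferred.

## Charge-comb deconvolution

Vendor maximum-entropy deconvolution is replaced by a transparent
charge-comb algorithm. For a candidate neutral mass M, the score is the
sum over charges z of the interpolated continuum intensity at
(M + 1.00728 z)/z inside the 500-4,000 Th window. Species are extracted
greedily:

1. score all masses on a grid (default step 0.1 Da);
2. walk the ranked local maxima and take the strongest candidate whose
   supporting charges form a *contiguous* run of at least `min_support`
   (default 2; a single peak cannot determine a charge, and a genuine
   electrospray envelope is contiguous in z);
3. refine the apex by a least-squares quadratic through the top 10% of the
   local score curve (a plain 3-point parabola is biased by interpolation
   ripple; the fitted apex is accurate to well under 0.1 Da);
4. subtract the supporting comb teeth from the residual spectrum, valley
   to valley, and repeat.

The contiguity requirement and the greedy subtraction together suppress
the classic artifacts of comb scoring: the comb of 2M coincides with M at
every second charge (equal score, gappy support), M/2 coincides at half
the charges (half score, removed with M's teeth), and chance two-tooth
coincidences lose their intensity once the true species are subtracted.
Candidates within 5 Da of an already-extracted mass are treated as residue
(noise fragments of a subtracted tooth) and removed without being
reported. A final harmonic filter (x2, x3 within 2 Da per order) remains
as a backstop. For wide survey windows spanning the whole signature
library (22-150 kDa) the pipeline raises `min_support` to 5, since every
plausible sub-unit species there spans far more than 5 charges inside the
acquisition window.

Average masses are used throughout — continuum spectra of 20-150 kDa
proteins do not resolve isotopes — and the charge carrier is the average
proton mass (1.00728 Da, positive mode).

## Assignment logic

Identification is two-sided: a fraction is uniquely assigned to an isoform
only when every observed mass is explained (directly, as a configured
glycoform variant, or as a single known modification satellite) *and*
every expected unique mass of that isoform is observed. The full
complement is what makes a signature diagnostic — the conjugated light
chain alone is shared by six of the nine isoforms. Match tolerance is
10 ppm with a 1.0 Da absolute floor (10 ppm of 23.6 kDa is only 0.24 Da,
below the deconvolution grid).

The modification table ships with dehydration (-18.02 +- 1.5 Da, covering
the ~17 Da water-loss satellite seen on the DAR 4 fraction) and one hexose
(+162.14 +- 0.8 Da, the G0F/G1F spacing). `uniqueness_analysis()` verifies
that no two signatures are identical and flags subset relations — notably
that the DAR 8 pair is contained in 6b's triple, so a fraction showing
only the pair cannot exclude co-eluting 6b on mass alone.

## What the synthetic data emulates — and what it does not

`make_hic_chromatogram()` builds each batch profile as a sum of Gaussians
with the reported per-load relative areas (low/medium/high batches),
split within a load by configured fractions: DAR 6 splits 43.7/14.1/42.2
across peaks E/F/G as reported; DAR 4 splits 80:20 across C:D — the major
DAR 4 species is C, but the actual split is not reported, so this is a
configurable convention. Apex times (A 2.0 ... H 7.5 min over a 10 min
run at 20 Hz) are conventions too; only the elution order (increasing
load/hydrophobicity) is meaningful. A peak sd of 0.07 min keeps adjacent
peaks near-baseline-resolved (cross-talk < 0.03% of area), consistent
with the resolved profiles the assignment rests on. Replicate jitter is
lognormal per peak at 0.3% CV — chosen so recovered RSDs land in the
reported order of magnitude (0.1-1.7%), not as a claim of equality; the
reported RSDs conflate instrument and integration variability that a
single CV knob cannot separate.

`make_envelope_spectrum()` emits one Gaussian peak per charge state with a
bell-shaped charge distribution, peak widths parameterized as a
mass-domain sd of 6 Da (sd in m/z = 6/z — the unresolved isotope envelope
of a large protein), a 0.025 Th continuum grid, and additive Gaussian
noise at 0.5% of the envelope maximum ("fixture noise"). Charge ranges
(15-25 below 30 kDa, 30-45 below 60 kDa, 45-60 above) keep all envelopes
inside 500-4,000 Th. Heart-cut spectra expand heavy-bearing sub-units
over a 60:40 G0F:G1F mix (uniform assignment across the heavy chains of a
sub-unit; the mixed G0F/G1F form of a two-heavy sub-unit is not emitted
but would be caught by the hexose satellite rule), and isoform 4a's
heavy-heavy sub-unit carries a -18.02 Da satellite at 0.25 relative
intensity, mirroring the observed water loss.

The generator's peak-to-isoform map assigns the MS-confirmed identities
(C = 4a, E = 6a, F = 6b, H = 8) and fills the unreported ones with the
kinetically preferred LC-HC-first products (B = 2a, D = 4b) and reuses 6a
for G. B, D and G are conventions: the study never identifies them, and
peak G may equally be a distinct or modified DAR 6 form.

None of this models retention physics, gradient shape, detector response,
ionization efficiency, peak tailing, adducts or in-source fragmentation
beyond the water-loss satellite. Passing tests therefore demonstrate the
*computational* pipeline — integration, combinatorics, deconvolution,
assignment — under the reported statistical structure, not instrument
fidelity.

## Numerical choices

* Unique-mass merge: 0.5 Da. Match tolerance: 10 ppm with 1.0 Da floor.
* Deconvolution grid 0.1 Da (surveys 1.0 Da), fine refinement on a 0.05 Da
  local grid with least-squares quadratic apex.
* Baseline: constant, from the outer 5% of the run; boundary floor 0.1% of
  apex height.
* DAR reported to 2 decimals; comparisons against the reported per-batch
  tables use +-0.01 because the printed areas are themselves rounded
  (recomputing the high batch from its rounded areas gives 5.96 vs the
  printed 5.97; the printed per-load percents sum to 99.96-100.04, and the
  generator normalizes them internally, which lands the simulated high
  batch at 5.97).
* Degenerate inputs are errors, not guesses: non-monotone time grids,
  empty spectra, windows outside the run, unassigned peaks, single
  replicates (RSD flagged `NA` with a warning).

## Problem sizes

The test suite and the acceptance script run at desk scale: 12,001-point
chromatograms (10 min at 20 Hz), 140,001-point continuum spectra (500 to
4,000 Th at 0.025 Th), full-library survey deconvolutions on a 1 Da grid,
narrow-window species deconvolutions on a 0.1 Da grid, and 20-replicate
noise studies. A full three-replicate batch pipeline (simulate ->
integrate -> deconvolve 8 fractions -> assign -> report) completes in
about a minute.

## Known limitations

* Odd drug loads (partial alkylation) and lysine conjugates are out of
  scope; the enumeration assumes even loads from inter-chain reduction.
* The two 6a hinge-regiochemistry variants are intentionally collapsed.
* Signature distinctness (and hence unique assignment) is a property of
  the fixture masses; a conjugate whose sub-unit masses collide within
  tolerance would need `uniqueness_analysis()` before trusting
  assignments.
* The deconvolution reports average masses only — no isotope-resolved
  fitting, charge-reduced species or adduct modeling.
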