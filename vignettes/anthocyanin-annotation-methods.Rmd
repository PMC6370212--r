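---
title: "Methods: anthocyanin annotation, quantification and network integration"
author: "anthoNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anthocyanin annotation, quantification and network integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthoNet)
```

anthoNet models decorated anthocyanins — flavylium-cation pigments carrying
sugar and acyl residues — and the measurements that identify and quantify
them: positive-mode MS/MS peak lists, UV-visible ratios, internal-standard
peak areas, and qRT-PCR threshold cycles. This vignette documents the
mathematical model behind each module, every tolerance and default, and the
known limits of the approach.

## 1. Exact-mass model

All masses are monoisotopic, computed from hard-coded IUPAC atomic masses
(C = 12 exactly, H = 1.00782503207, O = 15.9949146196, N, S). An intact
anthocyanin is detected as its flavylium cation [M]^+^, so the theoretical
m/z of a neutral-formula sum is the formula mass minus one electron mass
(0.00054858 Da):

```{r}
cationMass("C15H11O5")  # pelargonidin flavylium cation
```

A **composition** is an aglycone (pelargonidin C15H11O5^+^, cyanidin
C15H11O6^+^ or delphinidin C15H11O7^+^) plus a *multiset* of decoration
residues. Residue masses are condensation masses (free molecule minus
water):

| residue | formula | mass (Da) |
|---|---|---|
| hexose | C6H10O5 | 162.052824 |
| deoxyhexose | C6H10O4 | 146.057909 |
| malonyl | C3H2O3 | 86.000394 |
| coumaroyl | C9H6O2 | 146.036779 |
| caffeoyl | C9H6O3 | 162.031694 |
| feruloyl | C10H8O3 | 176.047344 |

Compositions are multisets, never structures: glucose vs galactose,
3- vs 5-position, E/Z acyl isomers, and rutinoside-vs-independent
attachment are all mass-identical and deliberately collapsed.

## 2. Precursor decomposition and fragment explanation

`decomposePrecursor()` enumerates every composition with at most
`maxGlycosyl = 4` glycosyl and `maxAcyl = 3` acyl residues (a lattice of
15 × 35 = 525 decoration count vectors per aglycone) and keeps those whose
theoretical cation m/z lies within `precursorTolPpm = 5` ppm of the
observed precursor. The 5 ppm working tolerance matches the observed
accuracy of modern orbitrap-class instruments; the bounds cover every
anthocyanin reported in gentian petals with headroom.

`explainFragments()` matches each fragment (tolerance
`fragmentTolPpm = 10` ppm, looser because fragment ions are lower
intensity) against the precursor minus *every* sub-multiset of the
decorations — linkage topology is unknown, so any combination of residues
may depart — plus the free-residue ion of each glycosyl (e.g. rhamnose at
146.0579).

Candidates are ranked by:

1. descending fraction of fragments explained;
2. descending **decoration coverage** — the fraction of the candidate's
   distinct residues evidenced by an explained proper-subset loss or
   free-residue ion. The bare aglycone ion is excluded from coverage
   because every candidate predicts it at the same m/z;
3. ascending |precursor ppm error|;
4. ascending total block count;
5. lexicographic block ids (determinism).

The coverage term exists because of an exact elemental degeneracy:
caffeoyl + deoxyhexose and coumaroyl + hexose are both C15H16O7, so
swapping those pairs gives a second composition at *identical* exact mass.
Coverage separates the twins whenever the fragment series carries
residue-level evidence; compositions whose full predicted fragment sets
coincide (possible when a structure contains all four of caffeoyl,
coumaroyl, deoxyhexose and hexose) are information-theoretically
indistinguishable by mass, and no ranking can resolve them. The test suite
asserts recovery *up to* this degeneracy on noiseless spectra, and top-1
accuracy ≥ 0.95 on 200 noisy (2 ppm) spectra, which holds because the
unresolvable cases are rare under uniform sampling of the lattice.

The aglycone diagnostic is independent of decomposition: a fragment within
`aglyconeWindowDa = 0.01` Da (an absolute window, since low-mass fragments
make ppm windows too tight) of a library aglycone m/z classifies the
spectrum as that aglycone type even when no full composition is found.

UV-visible evidence uses the E440/Emax rule: a ratio ≥ 40% indicates a
3-glycoside, ≤ 30% a 3,5-glycoside (the two exemplar classes sit near 52%
and 25%), anything between is reported ambiguous, and missing UV data
yields "absent".

## 3. Relative quantification

Each compound's abundance in a sample is the sum of its two quantifier
fragment areas divided by the summed area of the internal standard
(formononetin), giving unitless fold-over-IS values that cancel
run-to-run intensity drift (the normalization is exactly invariant to
global scaling — a tested property). Stage summaries report mean ± sd per
developmental stage and percent composition (each stage column sums to
100). Hierarchical clustering of compound profiles uses correlation
distance (1 − Pearson ρ between rows) with average linkage, the common
choice for abundance heatmaps; merge heights are verified against a naive
Lance–Williams oracle.

## 4. qRT-PCR expression

A standard curve is the least-squares line of Ct on log10(template ng);
efficiency = 10^(−1/slope)^ − 1 (slope −3.3219 ⇔ 100% efficiency). Fitting
requires ≥ 3 points spanning ≥ 2 decades; non-negative slopes and
r² < 0.9 warn. Quantities are interpolated as 10^((Ct − intercept)/slope)^,
technical replicates are averaged **on the quantity scale** (averaging Ct
would bias quantities), and levels are normalized to the housekeeping gene
(UBQ). Quantities below 10^−6^ of the per-gene maximum are floored to 0 as
a detection limit.

## 5. Correlation networks

Pearson correlations over n stage-replicate samples are tested with
t = ρ√((n−2)/(1−ρ²)), p = 2·pt(−|t|, n−2); pairs with p ≤ 0.05 are
significant (no multiple-testing correction by default, mirroring common
practice; Benjamini–Hochberg is available via `adjust = "BH"`). Node
strength ns is the mean |ρ| of a node over its *significant* pairs (0 if
none); network strength NS is the mean of ns over all nodes. The display
threshold |ρ| ≥ 0.65 only filters the exported edge list/GraphML — ns and
NS always use all significant pairs.

The pipeline correlates **log-transformed** fold-over-IS abundances and
relative expression: both are multiplicative (approximately log-normal)
quantities, so the log scale is where linear correlation is
well-specified.

## 6. Synthetic data generator

`synthDesign()` fixes the study geometry: 3 stages × 3 replicates (n = 9),
11 metabolites, 5 transcripts, internal standard area 10^6^, qPCR curve
slope −3.3219 / intercept 21 with a 100–0.16 ng dilution series and 3
technical replicates.

Correlated trajectories come from a single latent factor: per sample,
f = standardized(stage trend −1/0/1 + N(0, `trendNoiseSd` = 0.5)); each
feature's log level is `latentSd` (1.2) × (√λ·f + √(1−λ)·e) with
λ = `targetRho` = 0.76, so every feature pair has latent correlation
exactly 0.76 on the log scale. Measurement noise is lognormal
(σ = 0.25) on areas and Gaussian (σ = 0.2 cycles) on Ct.

Measured NS is *not* expected to equal 0.76 exactly: the significance
filter keeps only pairs whose sample |ρ| cleared the p ≤ 0.05 boundary at
n = 9 (truncation bias, upward), while measurement noise attenuates
correlations (downward). The net effect, established by simulation before
the tests were frozen, is a mean NS near 0.79–0.81; the acceptance band is
0.76 ± 0.05.

Ground-truth spectra carry one ion per single-residue loss plus the
full-decoration (aglycone) ion, optional free glycosyl ions, and k random
decoy peaks — deliberately *fewer* ion types than the annotator's
all-sub-multisets model admits, so validation never tests the code against
itself. m/z noise is Gaussian with σ = 2 ppm by default, matching the
observed deviations of the published peak list.

## 7. Problem sizes and numerics

Decomposition enumerates 1575 candidate compositions per spectrum
(3 aglycones × 525 count vectors) — brute-force-verifiable, which the test
suite exploits with an independent `expand.grid` oracle on 1000 random
masses. Fragment explanation enumerates sub-multisets of ≤ 7 decorations
(≤ 2^7 = 128, in practice far fewer after multiset deduplication). All
mass comparisons are done in double precision; 1 ppm at m/z 1000 is
10^−3^ Da, ten orders of magnitude above double-precision granularity, so
no special numerics are needed. Serialized m/z values keep ≥ 6 decimals to
preserve ppm-level semantics.

## 8. Worked example

```{r}
lib <- defaultBlockLibrary()
sp <- spectrum("pel-3,5-diglucoside", 595.16516,
               fragmentMz = c(433.11273, 271.05972),
               fragmentIntensity = c(500, 900))
ann <- annotateSpectrum(sp, lib)
ann
```

The precursor decomposes to pelargonidin + 2 hexose (0.99 ppm); the
433.1127 fragment is the single-hexose loss and 271.0597 the bare
aglycone, so both fragments are explained and the spectrum is classified
pelargonidin-type.
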