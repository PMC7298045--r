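---
title: "Models and methods: germline reversion and biophysical stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: germline reversion and biophysical stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abstab)
```

## The problem

Antibodies raised in transgenic animals acquire somatic hypermutations (SHM)
during affinity maturation. Some of these are *rare* SHM (rSHM): the mutated
residue occurs at that position in under 1% of human antibody repertoires.
rSHM in framework regions can destabilise the molecule and create T-cell
epitopes, compromising developability. The engineering strategy analysed
here reverts rSHM positions to the germline residue, builds a combinatorial
variant panel, and selects a lead by a multi-attribute funnel over binding,
immunogenicity scores and thermal/colloidal stability. The package
implements every computational step of that workflow — sequence analysis,
variant design, and the fitting of the biophysical assays used to rank
variants — together with a synthetic-data layer so the whole pipeline is
exercised end to end from published parameter values alone (no raw
instrument data are publicly deposited for this system).

## Sequence analysis

**Germline mapping.** Variable domains are aligned to their germline
precursor by global Needleman–Wunsch alignment (BLOSUM62, affine gaps, open
11 / extend 1, via `Biostrings::pairwiseAlignment`). V-domains are nearly
gap-free against their own germline, so the scoring scheme has little
leverage; it is configurable. Positions are sequential 1-based indices of
the query; Kabat/IMGT renumbering is out of scope, but the per-column
position map in the alignment object is the seam where it would plug in.
Mismatches involving `X` are skipped. The packaged germline scaffolds are
*synthetic stand-ins* (the source prints only the substitutions, not full
sequences), constructed so the documented SHM positions (heavy 14/20/81,
light 1) carry the documented residues; they are labelled synthetic in the
FASTA file name.

**rSHM flagging.** A positional frequency profile maps (position, residue)
to a repertoire frequency. An SHM is *rare* when its observed residue's
frequency is strictly below the threshold (default 0.01, per the < 1%
definition of an unusual residue). Two profiles are supported: the packaged
partial profile carrying exactly the six published frequencies for
heavy-chain positions 14/20/81 (0.15/95.03, 0.09/73.02, 1.60/57.58 %), and
profiles built from repertoires with `build_profile()`. Frequencies are
plain counts — no pseudocounts by default, because they are descriptive
rarity evidence, not probabilistic scores; a Laplace option exists.
Positions with fewer than 10 observations (configurable) are treated as
unknown rather than given an unstable estimate, and SHM at positions absent
from a profile are reported with status `"unknown"`, never dropped.
Note the published prose calls the 1.60% histidine at position 81 "unusual"
even though it exceeds the strict 1% cut; the flags carry both the boolean
and the frequency so either convention can be applied downstream.

**Variant design and the funnel.** `enumerate_reversions()` generates all
2^k reversion subsets in a deterministic order (subset size, then
lexicographic tokens). The published panel is 10 of the 16 combinations plus
the parent; no pruning rule is stated, so the panel is carried as a fixture,
not inferred. The selection funnel is stated qualitatively in the source
(binding, immunogenicity scores, thermal stability "at the top of the
screening funnel"); the package formalises it as a lexicographic rule:

1. discard variants with KD more than 2-fold above the parent (binding
   retention; the fold limit is configurable),
2. minimise the combined EpiMatrix score (heavy + light, unweighted sum —
   no weighting is published),
3. break ties by maximal aggregation onset (Tagg), then maximal Fab Tm,
   then name.

This rule reproduces the published selection exactly and each criterion is
individually documented in the source; the rule order is a configuration
knob. EpiMatrix scores are proprietary inputs and are never computed.

## Biophysical models

All energies are kJ/mol, R = 8.314 J/(mol·K), temperatures in kelvin
internally (°C at interfaces), ICD at 298.15 K.

**Chemical denaturation (LEM).** Two-state: ΔG(c) = ΔGu − m·c,
K = exp(−ΔG/RT), fU = K/(1+K); the observed F350/F330 ratio is
(1−fU)·(aN + bN·c) + fU·(aU + bU·c) with linear baselines. Three-state
(N⇌I⇌U): K1, K2 as above with (ΔG1, m1), (ΔG2, m2); populations
pN = 1/(1+K1+K1K2), pI = K1·pN, pU = K1K2·pN; the intermediate contributes a
concentration-independent signal (sloped intermediate baselines are rarely
identifiable — a documented limitation). c50 = ΔG/m is reported with the
identity enforced to numerical precision. Exponential arguments are clipped
to ±500.

Fitting is least squares (`minpack.lm::nls.lm`) with deterministic
multistart: midpoints seeded at smoothed-derivative peaks, m-values at
{5, 10, 20, 40} kJ/mol/M, baselines from the curve extremes. Flat curves
fail explicitly (fitted transition amplitude must exceed 5× the residual
scatter). Three-state fits are flagged non-identifiable when c50 ordering is
violated or when the free-energy standard errors exceed 50% — which is
exactly what happens when the three-state model is forced onto two-state
data. Model choice is by corrected AIC with a ΔAICc > 2 margin for the more
complex model (no selection criterion is published).

Because m-values are never printed, simulation truths derive them as
m = ΔG/c50 — flagged `derived` in the registry. The published precision
(ΔGu ± 2 kJ/mol, c50 ± 0.2 M) is explicitly the precision of n = 3
replicate averages; accordingly the assay protocol here
(`fit_icd_replicates()`) fits three replicate curves and averages the
parameters. A single sharp first transition (m1 ≈ 33 kJ/mol/M) sampled at
40 points over 0–6 M carries a single-curve ΔG1 uncertainty of ~4 kJ/mol at
noise σ = 0.002 — the replicate averaging is what brings the estimate into
the published envelope, matching how the assay was actually run.

**DSC.** Each transition contributes excess heat capacity
ΔHcal·ΔHvH/(R·T²)·K/(1+K)², K(T) = exp[−(ΔHvH/R)(1/T − 1/Tm)] — the
standard non-two-state form in which calorimetric (area) and van't Hoff
(shape) enthalpies are independent. Thermograms are in kcal/mol/°C at the
I/O boundary (×4.184 internally). Fitting deconvolves 1–3 transitions plus
a linear baseline; transition temperatures are seeded from smoothed peaks
with a deterministic split multistart for merged peaks. Conservation holds
by construction: the integrated excess of each fitted transition equals its
ΔHcal (checked to 1% in the tests). The generator samples at 0.1 °C — a
1 °C/min capillary scan logs several readings per degree — and the default
noise is 1/50 of the excess peak height. In the two-mAb comparison the
transition nearest 65 °C is labelled CH2/CH3 (these IgG4 scans show the CH2
and CH3 domains melting together there) and the other transition is the
Fab; the reference temperature is a configurable labelling convenience.

**DSF.** Melting temperatures are the maxima of the Savitzky–Golay-smoothed
first derivative of the F350/F330 ratio (window 11 points, configurable),
refined sub-grid by a local quadratic regression over ±4 °C around the
discrete argmax. Peaks must clear 5× the derivative's baseline spread and
20% of the tallest peak, which makes the detector invariant to affine
rescaling of the ratio. The unfolding onset is the first temperature at
which the ratio exceeds the pre-transition linear baseline by 5× the
baseline residual SD, sustained over three points. The aggregation onset
(Tagg) is the intersection of the pre-aggregation baseline with a tangent
regressed over the mid-rise (25–75%) of the scattering signal, after a
two-pass baseline fit that extends the baseline window up to just below the
first sustained exceedance. The onset detectors are this package's
definitions — the instrument vendor's are unpublished; both quantities'
names and values follow the source.

**1:1 Langmuir kinetics.** Within an association phase at concentration C,
R(t) = Req + (R0 − Req)·exp(−(ka·C + kd)·t) with Req = Rmax·C/(C + kd/ka);
dissociation decays as exp(−kd·t); R0 chains across phases, which yields
single-cycle traces for sequential low-to-high injections (default design:
five 3-fold steps from 30 nM, 30-min final dissociation). The closed form
is verified against a Runge–Kutta integration of dR/dt = ka·C·(Rmax−R) −
kd·R to 10⁻⁶ RU in the tests. Global fits share ka, kd, Rmax across all
traces and phases on log10 scales, with a deterministic start grid.
Identifiability guard: association-only data with fewer than three distinct
concentrations fail with a diagnostic (kd is then unconstrained).
Mass-transport limitation is not modelled — the published analysis is the
simple 1:1 model — and instrument file formats are out of scope; fits accept
reference-subtracted traces. The serum-interference readout is
ka(serum)/ka(buffer), classified "no interference" inside 0.8–1.25 (a
conventional bioanalytical equivalence band; the published comparison is
qualitative).

**Storage stability.** Aggregate time courses (days 0/14/28) reduce to the
change from time zero and an OLS slope. The accelerated-stress criterion is
a *strict* < 1% increase over 28 days at 40 °C — the change, not the
absolute level, matching how the month-over-baseline difference is plotted;
the same sentence in the source mixes "aggregates" and "aggregation
increase", and the delta reading is the one adopted here.

## The synthetic-data layer

`fixture_registry()` centralises every published value used as a generating
truth, each with a provenance note; derived quantities (m-values, sequence
scaffolds) are flagged. `generate_assay_suite()` produces the full input
bundle per molecule with one base seed; all randomness is drawn through
local RNG streams, so library calls never disturb the caller's RNG, equal
seeds give byte-identical bundles, and zero-noise bundles are identical
across seeds. Default noise levels — ICD/DSF ratio σ 0.002, DSC peak/50,
sensorgram 0.5 RU, BLI 0.02 nm, aggregate 0.05% — were chosen once so that
the published precisions are the achievable recovery envelope.

What the generator emulates: equilibrium curves with the published
parameters, linear instrument baselines, additive i.i.d. Gaussian noise,
and repertoires with exact per-position categorical frequencies. What it
deliberately does not emulate: instrument drift and spikes,
refractive-index jumps, scan-rate kinetics and irreversibility
(Lumry–Eyring) in DSC, mass transport in SPR, correlated noise, and
nucleotide-level repertoire structure. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated noise model,
not robustness to every instrument artifact of real data.

## Problem sizes and numerical choices

Analyses run at desk scale: 30–40-point denaturation curves, 751-point
thermograms, 151-point melts, ~2,500-point sensorgrams, 20,000-sequence
repertoires, triplicate ICD assays, and 3–5-scan DSC averages where the
overlapping parent transitions (61.8 vs 65 °C) make single-scan Tm
estimates statistically wide. Ties in equal-scoring alignments resolve by
Biostrings' deterministic traceback; all multistarts are deterministic
functions of the data; AICc margins, coverage minima and thresholds are
documented defaults, not tuned values.

## Known limitations

Sequential numbering only (no Kabat/IMGT); no CDR-aware frequency
stratification; no database connectivity — profiles are supplied or built
from user repertoires; EpiMatrix scores are inputs only, so no
immunogenicity predictor; no Gibbs–Helmholtz temperature extrapolation of
ΔGu; the three-state intermediate signal is a constant; DSC ΔCp extraction
and irreversibility are not modelled; chromatogram and AUC raw-data
processing are out of scope (only their derived summaries enter the
analysis).
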