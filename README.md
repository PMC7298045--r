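# abstab — antibody germline reversion and biophysical stability analysis

`abstab` implements the computational workflow behind a classic antibody
stability-engineering campaign: a transgenic-animal-derived mAb (the parent,
"PCa75") carries rare somatic hypermutations (rSHM — framework residues whose
positional frequency in human repertoires is below 1%) that compromise its
conformational and colloidal stability; reverting them to germline yields a
variant panel from which a lead ("PCa62") is selected on binding,
immunogenicity scores and stability. The package is aimed at antibody
engineers and biophysics analysts who want the full chain — sequence analysis,
variant design, assay model fitting, lead selection — as tested, scriptable R.

## What it computes

- **Germline mapping** — global Needleman–Wunsch alignment (BLOSUM62, affine
  gaps) of VH/VL against germline references; SHM enumeration with sequential
  1-based numbering.
- **rSHM flagging** — per-position amino-acid frequency profiles; an SHM is
  rare when its residue frequency f < 0.01 (strict). Profiles can be built
  from repertoires or supplied (the published frequencies ship as a fixture).
- **Variant design & funnel** — all 2^k germline-reversion combinations; lead
  selection by (1) KD retention within 2-fold of the parent, (2) minimal
  combined EpiMatrix score, ties by (3) Tagg then (4) Fab Tm.
- **Chemical denaturation (ICD)** — two-state and three-state linear
  extrapolation models, ΔG(c) = ΔGu − m·c, fU = K/(1+K) with
  K = exp(−ΔG/RT); least-squares fits with multistart, AICc model selection,
  c50 = ΔGu/m.
- **DSC** — non-two-state transitions, excess Cp =
  ΔHcal·ΔHvH/(RT²)·K/(1+K)²; 1–3-transition deconvolution with Fab vs
  CH2/CH3 assignment.
- **DSF** — Tm from smoothed-derivative maxima of the F350/F330 ratio,
  unfolding onset, and aggregation onset (Tagg) by tangent construction on
  scattering traces.
- **1:1 Langmuir kinetics** — closed-form single- and multi-cycle
  sensorgrams, global (ka, kd, Rmax) fits, KD = kd/ka, and the
  serum-interference ratio ka(serum)/ka(buffer).
- **Storage stability** — %-aggregate time courses, delta and OLS rate, and
  the strict <1%/28 d at 40 °C stress criterion.
- **Synthetic data** — every assay input is generated from a registry of the
  published fitted parameters, so the whole pipeline runs without any
  instrument download.

## Worked example

```r
library(abstab)

# 1. somatic hypermutations of the parent vs germline
parent <- parent_sequences(); germ <- germline_references()
shm <- identify_shm(align_to_germline(parent$VH, germ$VH))
shm
#>   position germline_residue observed_residue region
#> 1       14                P                R   <NA>
#> 2       20                L                P   <NA>
#> 3       81                Q                H   <NA>

# 2. which of them are rare (< 1% positional frequency)?
flag_rare(shm, printed_frequency_profile())[, c("position", "observed_frequency", "is_rare")]
#>   position observed_frequency is_rare
#> 1       14             0.0015    TRUE
#> 2       20             0.0009    TRUE
#> 3       81             0.0160   FALSE

# 3. run the published attribute panel through the selection funnel
sel <- select_lead(variant_panel_table(), parent_kd = 247.0)
sel$lead
#> [1] "PCa62"

# 4. intrinsic stability: fit a synthetic GdnCl curve generated from the
#    parent's published parameters (dGu 24.3 kJ/mol, c50 1.8 M)
cv <- simulate_denaturation_curve("two_state", list(dG1 = 24.3, m1 = 24.3 / 1.8),
                                  noise_sd = 0.002, seed = 42)
fit_two_state(cv)
#> <two_state_fit> dGu = 24.81 kJ/mol, m = 13.84 kJ/mol/M, c50 = 1.79 M (rss 0.000153)

# 5. affinity: global 1:1 fit of a noise-free single-cycle sensorgram
fit_1to1_global(simulate_sensorgram(6.70e5, 1.66e-4, 150, single_cycle_phases()))
#> <kinetic_fit> ka = 6.7e+05 1/(M s), kd = 0.000166 1/s, KD = 247.8 pM, Rmax = 150.0
```

The positions 14/20 flags (0.15% arginine vs 95.03% modal proline; 0.09%
proline vs 73.02% leucine) reproduce the published rarity analysis; the
funnel reproduces the published lead; the recovered ΔGu and KD land on the
published values within the assay precisions (±2 kJ/mol; rounding of the
printed rate constants).

## The analysis workflow

The numbered scripts under `analysis/` run the campaign end to end and write
their tables under `results/`:

```sh
Rscript analysis/01_germline_shm.R        # SHM mapping
Rscript analysis/02_rshm_flags.R          # rarity flags, printed vs synthetic repertoire
Rscript analysis/03_variant_funnel.R      # 16-variant enumeration + lead selection
Rscript analysis/04_chemical_denaturation.R
Rscript analysis/05_thermal_stability.R   # DSC / DSF / Tagg
Rscript analysis/06_binding_kinetics.R    # SPR + serum interference
Rscript analysis/07_storage_stability.R
Rscript analysis/08_full_pipeline.R       # one-call pipeline -> lead_report.json
```

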