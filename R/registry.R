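#' Fixture registry of published parameter truths
#'
#' Central store of the printed parameter values used as generating truths for
#' all simulation-plus-recovery analyses: ICD free energies and midpoints
#' (intact mAbs and Fabs), DSC/DSF transition temperatures, SPR/BLI rate
#' constants, serum-interference association rates, storage-aggregation deltas
#' and the positional amino-acid frequencies of the heavy-chain SHM positions.
#' Each entry carries a `provenance` note naming the table or results paragraph
#' it was read from; values that are derived rather than printed (m-values as
#' dG/c50, sequence scaffolds) are flagged `derived`.
#'
#' @return Nested list keyed by molecule (`PCa75`, `PCa62`, `PCa75_Fab`,
#'   `PCa62_Fab`) plus `frequencies`, `sequences` and `defaults` blocks.
#' @export
#' @examples
#' reg <- fixture_registry()
#' reg$PCa75$icd$dG1        # 24.3 kJ/mol
#' reg$PCa62$kinetics$ka    # 5.41e5 1/(M s)
fixture_registry <- function() {
  icd_entry <- function(model, dG1, c50_1, dG2 = NA_real_, c50_2 = NA_real_,
                        provenance) {
    list(model = model,
         dG1 = dG1, c50_1 = c50_1, m1 = dG1 / c50_1,
         dG2 = dG2, c50_2 = c50_2,
         m2 = if (is.na(dG2)) NA_real_ else dG2 / c50_2,
         provenance = provenance,
         derived = "m-values derived as dG/c50 (not printed)")
  }
  list(
    PCa75 = list(
      icd = icd_entry("two_state", 24.3, 1.8,
                      provenance = "intact-mAb ICD table (text variant c50 1.9 M noted)"),
      dsc = list(fab_tm = 61.8, ch2ch3_tm = 65.0,
                 dH_cal = 400, dH_vH = 500,
                 provenance = "DSC results paragraph; enthalpies are simulation conventions"),
      dsf = list(onset = 52.9, fab_tm = 59.0, tagg = 61.5,
                 provenance = "DSF screen of the parent"),
      kinetics = list(ka = 6.70e5, kd = 1.66e-4, kD_pM = 247.0,
                      provenance = "SPR affinity table"),
      aggregation = list(delta_4C = 0.5, delta_40C = 3.0,
                         provenance = "28-day SEC time-course text"),
      epimatrix = list(hc = 1.99, lc = -19.3, provenance = "variant attribute table")
    ),
    PCa62 = list(
      icd = icd_entry("three_state", 63.5, 1.9, 37.2, 2.9,
                      provenance = "intact-mAb ICD table (text prints dG2 37.3)"),
      dsc = list(fab_tm = 75.7, ch2ch3_tm = 65.0,
                 dH_cal = 400, dH_vH = 500,
                 provenance = "DSC results paragraph"),
      dsf = list(onset = 59.3, fab_tm = 69.4, tagg = 75.7,
                 provenance = "variant attribute table / DSF"),
      kinetics = list(ka = 5.41e5, kd = 1.74e-4, kD_pM = 323.3,
                      provenance = "SPR affinity table"),
      serum = list(ka_buffer = 2.04e5, ka_serum = 2.05e5,
                   provenance = "serum-interference results paragraph"),
      aggregation = list(delta_4C = 0.2, delta_40C = 0.8,
                         provenance = "derived: text states <0.3% and <1% bounds",
                         derived = TRUE),
      epimatrix = list(hc = -44.3, lc = -33.6, provenance = "variant attribute table")
    ),
    PCa75_Fab = list(
      icd = icd_entry("two_state", 34.8, 1.7, provenance = "Fab ICD results text"),
      dsf = list(fab_tm = 61.8, provenance = "Fab DSF results text")
    ),
    PCa62_Fab = list(
      icd = icd_entry("two_state", 42.5, 3.6, provenance = "Fab ICD results text"),
      dsf = list(fab_tm = 81.5, provenance = "Fab DSF results text")
    ),
    # printed positional frequencies for the three heavy-chain SHM positions
    frequencies = list(
      heavy = data.frame(
        position = c(14L, 14L, 20L, 20L, 81L, 81L),
        residue = c("R", "P", "P", "L", "H", "Q"),
        frequency = c(0.0015, 0.9503, 0.0009, 0.7302, 0.0160, 0.5758),
        stringsAsFactors = FALSE
      ),
      provenance = "positional-frequency results paragraph"
    ),
    sequences = list(
      heavy_germline = paste0(
        "EVQLLESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVSA",
        "ISGSGGTYYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYCAK"),
      light_germline = paste0(
        "DIQMTQSPSSLSASVGDRVTITCRASQGISNYLAWYQQKPGKAPKLLIYA",
        "ASTLQSGVPSRFSGSGSGTDFTLTISSLQPEDVATYYCLQHNSYPLTFGGGTKVEIK"),
      heavy_shm = data.frame(position = c(14L, 20L, 81L),
                             germline = c("P", "L", "Q"),
                             observed = c("R", "P", "H"),
                             stringsAsFactors = FALSE),
      light_shm = data.frame(position = 1L, germline = "D", observed = "A",
                             stringsAsFactors = FALSE),
      derived = paste("synthetic germline-like scaffolds; the source prints",
                      "only the substitutions, so full-length sequences are",
                      "constructed stand-ins with the SHM positions placed",
                      "at sequential positions 14/20/81 (heavy) and 1 (light)")
    ),
    defaults = list(
      temperature_K = 298.15,
      icd = list(native_baseline = c(0.86, 0.004),
                 unfolded_baseline = c(1.10, -0.004),
                 intermediate_signal = 0.99,
                 noise_sd = 0.002),
      dsc = list(baseline = c(2.0, 0.005), noise = "peak/50"),
      dsf = list(dH_vH = 500, native_baseline = c(0.85, 0.0015),
                 unfolded_baseline = c(1.05, 0.0005), noise_sd = 0.002),
      scattering = list(baseline = c(5, 0.02), rise_slope = 8,
                        knee_width = 0.5, noise_sd = 0.5),
      sensorgram = list(Rmax = 150, noise_sd = 0.5),
      aggregate = list(noise_sd = 0.05)
    )
  )
}

#' Parent antibody variable-domain sequences
#'
#' Builds the parent (PCa75) VH/VL sequences by applying the observed somatic
#' hypermutations to the synthetic germline scaffolds in [fixture_registry()].
#'
#' @return list with `VH` and `VL` [antibody_sequence] objects.
#' @export
parent_sequences <- function() {
  reg <- fixture_registry()$sequences
  apply_subs <- function(seq, tab) {
    ch <- seq_chars(seq)
    stopifnot(all(ch[tab$position] == tab$germline))
    ch[tab$position] <- tab$observed
    paste(ch, collapse = "")
  }
  list(
    VH = antibody_sequence("PCa75_VH", "heavy",
                           apply_subs(reg$heavy_germline, reg$heavy_shm)),
    VL = antibody_sequence("PCa75_VL", "kappa",
                           apply_subs(reg$light_germline, reg$light_shm))
  )
}

#' Germline reference sequences
#'
#' @return list with `VH` and `VL` [germline_reference] objects for the
#'   synthetic IGHV3-23-like and IGKV1-17-like scaffolds.
#' @export
germline_references <- function() {
  reg <- fixture_registry()$sequences
  list(
    VH = germline_reference("IGHV3-23*01-like", "heavy", reg$heavy_germline),
    VL = germline_reference("IGKV1-17*01-like", "kappa", reg$light_germline)
  )
}

#' Published variant attribute panel
#'
#' Reads the packaged variant attribute table (the 11-row panel of the parent
#' and its ten germline-reversion variants with EpiMatrix scores, Fab Tm, Tagg
#' and KD) shipped as plain CSV under `inst/extdata`.
#'
#' @return data.frame with one row per variant.
#' @export
variant_panel_table <- function() {
  path <- system.file("extdata", "variant_panel_attributes.csv",
                      package = "abstab", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Packaged heavy-chain positional frequency fixture
#'
#' The partial positional frequency profile carrying exactly the six printed
#' frequencies for heavy-chain positions 14, 20 and 81; all other positions
#' are absent (unknown). `n_sequences` is 0 to mark a fixture profile.
#'
#' @return A `positional_frequency_profile` object (partial).
#' @export
printed_frequency_profile <- function() {
  tab <- fixture_registry()$frequencies$heavy
  tab$n_obs <- 0L
  new_profile("heavy", tab, n_sequences = 0L, partial = TRUE)
}
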