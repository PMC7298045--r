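#' Repertoire specification with planted positional frequencies
#'
#' Builds per-position categorical residue distributions from a scaffold
#' sequence: unspecified positions concentrate most probability on the
#' scaffold residue with a small uniform background; `planted` positions use
#' the supplied named probability vectors, with any unassigned remainder
#' spread evenly over the other canonical residues.
#'
#' @param scaffold scaffold sequence (string or residue vector).
#' @param chain chain class.
#' @param planted named list: position (as character) -> named numeric vector
#'   of residue probabilities (may sum to < 1; remainder is spread).
#' @param scaffold_weight probability mass on the scaffold residue at
#'   unplanted positions, default 0.9.
#' @return list of class `repertoire_spec`: `chain`, `length`,
#'   `distributions` (list of named 20-vectors, one per position).
#' @export
repertoire_spec <- function(scaffold, chain = c("heavy", "kappa", "lambda"),
                            planted = list(), scaffold_weight = 0.9) {
  chain <- match.arg(chain)
  if (length(scaffold) == 1L) scaffold <- seq_chars(scaffold)
  check_residues(scaffold, "scaffold")
  dists <- lapply(seq_along(scaffold), function(p) {
    key <- as.character(p)
    probs <- setNames(rep(0, 20L), .AA20)
    if (key %in% names(planted)) {
      given <- planted[[key]]
      stopifnot(all(names(given) %in% .AA20), all(given >= 0), sum(given) <= 1 + 1e-9)
      probs[names(given)] <- given
      rest <- setdiff(.AA20, names(given))
      if (length(rest) > 0) probs[rest] <- (1 - sum(given)) / length(rest)
    } else {
      probs[] <- (1 - scaffold_weight) / 19
      probs[scaffold[p]] <- scaffold_weight
    }
    probs / sum(probs)
  })
  structure(list(chain = chain, length = length(scaffold),
                 distributions = dists),
            class = "repertoire_spec")
}

#' Generate a synthetic antibody repertoire
#'
#' Draws `n_sequences` i.i.d. sequences from the per-position categorical
#' distributions of a [repertoire_spec]. Randomness is local to the call
#' (the caller's RNG stream is untouched) and fully determined by `seed`.
#'
#' @param spec a [repertoire_spec].
#' @param n_sequences number of sequences to draw.
#' @param seed mandatory RNG seed.
#' @return character matrix (rows = sequences, columns = positions) with
#'   attributes `chain`; convert small repertoires with
#'   [as_antibody_sequences()].
#' @export
generate_repertoire <- function(spec, n_sequences, seed) {
  stopifnot(inherits(spec, "repertoire_spec"), n_sequences >= 1)
  if (missing(seed) || is.null(seed)) stop_input("seed is mandatory")
  bad <- vapply(spec$distributions, function(p)
    any(p < 0) || abs(sum(p) - 1) > 1e-6, logical(1))
  if (any(bad)) stop_input("invalid distribution at position(s) %s",
                           paste(which(bad), collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cols <- lapply(spec$distributions, function(p)
    sample(.AA20, n_sequences, replace = TRUE, prob = p))
  mat <- do.call(cbind, cols)
  attr(mat, "chain") <- spec$chain
  mat
}

#' @rdname generate_repertoire
#' @param mat repertoire matrix from [generate_repertoire()].
#' @param prefix id prefix for the resulting sequences.
#' @export
as_antibody_sequences <- function(mat, prefix = "rep") {
  chain <- attr(mat, "chain")
  lapply(seq_len(nrow(mat)), function(i)
    antibody_sequence(sprintf("%s_%04d", prefix, i), chain, mat[i, ]))
}

#' Generate the full synthetic assay bundle for one molecule
#'
#' Produces every assay input the pipeline consumes for a registry molecule,
#' each generated by the corresponding simulator with the registry truths:
#' an ICD denaturation curve, a DSC thermogram (intact mAbs), a DSF Fab melt,
#' a scattering trace (intact mAbs), a single-cycle sensorgram (intact mAbs),
#' buffer/serum association traces (PCa62), and 4/40 degC aggregate series
#' (intact mAbs). Generating truths are echoed in each object's `truth`
#' field for recovery testing.
#'
#' @param molecule_key one of `"PCa75"`, `"PCa62"`, `"PCa75_Fab"`,
#'   `"PCa62_Fab"`.
#' @param noise_level `"default"` (registry noise SDs), `"none"`, or a
#'   numeric multiplier applied to the default SDs.
#' @param seed base RNG seed; per-assay seeds are derived deterministically.
#' @return named list of assay objects (missing assays are `NULL`).
#' @export
generate_assay_suite <- function(molecule_key,
                                 noise_level = "default", seed = 1L) {
  reg <- fixture_registry()
  if (!molecule_key %in% c("PCa75", "PCa62", "PCa75_Fab", "PCa62_Fab"))
    stop_input("unknown molecule key '%s'", molecule_key)
  mol <- reg[[molecule_key]]
  def <- reg$defaults
  scale <- if (identical(noise_level, "default")) 1
           else if (identical(noise_level, "none")) 0
           else as.numeric(noise_level)
  sub_seed <- function(k) as.integer((as.numeric(seed) * 131 + k) %% 2000000000)

  icd <- simulate_denaturation_curve(
    model = mol$icd$model,
    pars = mol$icd[c("dG1", "m1", "dG2", "m2")],
    concentrations = seq(0, 6, length.out = if (mol$icd$model == "three_state") 40 else 30),
    native_baseline = def$icd$native_baseline,
    unfolded_baseline = def$icd$unfolded_baseline,
    intermediate_signal = def$icd$intermediate_signal,
    noise_sd = def$icd$noise_sd * scale, seed = sub_seed(1L))

  dsc <- NULL
  if (!is.null(mol$dsc)) {
    trans <- list(list(tm = mol$dsc$fab_tm, dH_cal = mol$dsc$dH_cal,
                       dH_vH = mol$dsc$dH_vH),
                  list(tm = mol$dsc$ch2ch3_tm, dH_cal = mol$dsc$dH_cal,
                       dH_vH = mol$dsc$dH_vH))
    noise <- if (scale == 0) 0 else "peak/50"
    dsc <- simulate_dsc(trans, baseline = def$dsc$baseline,
                        noise_sd = noise, seed = sub_seed(2L))
    if (scale != 0 && scale != 1)
      dsc$cp <- simulate_dsc(trans, baseline = def$dsc$baseline, noise_sd = 0)$cp +
        withr_rnorm(sub_seed(2L), length(dsc$cp), dsc$truth$noise_sd * scale)
  }

  dsf <- simulate_dsf_melt(mol$dsf$fab_tm, dH_vH = def$dsf$dH_vH,
                           baseline = def$dsf$native_baseline,
                           noise_sd = def$dsf$noise_sd * scale,
                           seed = sub_seed(3L))

  scattering <- NULL
  if (!is.null(mol$dsf$tagg))
    scattering <- simulate_scattering(mol$dsf$tagg,
                                      rise_slope = def$scattering$rise_slope,
                                      baseline = def$scattering$baseline,
                                      knee_width = def$scattering$knee_width,
                                      noise_sd = def$scattering$noise_sd * scale,
                                      seed = sub_seed(4L))

  sensorgram <- NULL
  if (!is.null(mol$kinetics))
    sensorgram <- simulate_sensorgram(mol$kinetics$ka, mol$kinetics$kd,
                                      Rmax = def$sensorgram$Rmax,
                                      phases = single_cycle_phases(),
                                      noise_sd = def$sensorgram$noise_sd * scale,
                                      seed = sub_seed(5L))

  serum <- NULL
  if (!is.null(mol$serum)) {
    concs <- 300e-9 / 3^(0:6)  # 300 nM down to 0.41 nM
    mk <- function(ka, s) lapply(seq_along(concs), function(i)
      simulate_sensorgram(ka, mol$kinetics$kd, Rmax = 1.2,
                          phases = data.frame(phase_id = 1, t_start = 0,
                                              t_end = 300, conc_M = concs[i],
                                              kind = "association"),
                          noise_sd = 0.02 * scale, seed = s + i, dt = 1))
    serum <- list(buffer = mk(mol$serum$ka_buffer, sub_seed(6L)),
                  serum = mk(mol$serum$ka_serum, sub_seed(7L)))
  }

  aggregates <- NULL
  if (!is.null(mol$aggregation)) {
    mk_agg <- function(cond, delta, s)
      simulate_aggregate_series(cond, start_percent = 0.3,
                                slope = delta / 28,
                                noise_sd = def$aggregate$noise_sd * scale,
                                seed = s)
    aggregates <- list(`4C` = mk_agg(4, mol$aggregation$delta_4C, sub_seed(8L)),
                       `40C` = mk_agg(40, mol$aggregation$delta_40C, sub_seed(9L)))
  }

  list(molecule = molecule_key, icd = icd, dsc = dsc, dsf = dsf,
       scattering = scattering, sensorgram = sensorgram, serum = serum,
       aggregates = aggregates)
}
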