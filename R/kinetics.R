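#' Phase table for a single-cycle kinetics design
#'
#' Sequential association steps of increasing analyte concentration with
#' short inter-step dissociations and a long final dissociation, mirroring a
#' capture-format single-cycle run (3-fold series injected low to high).
#'
#' @param top_conc highest analyte concentration, M (default 30 nM).
#' @param n_steps number of association steps, default 5.
#' @param fold dilution factor between steps, default 3.
#' @param t_assoc association time per step, s.
#' @param t_dissoc_step inter-step dissociation time, s.
#' @param t_dissoc_final final dissociation time, s (default 30 min).
#' @return data.frame with `phase_id`, `t_start`, `t_end`, `conc_M`, `kind`.
#' @export
single_cycle_phases <- function(top_conc = 30e-9, n_steps = 5, fold = 3,
                                t_assoc = 120, t_dissoc_step = 30,
                                t_dissoc_final = 1800) {
  concs <- top_conc / fold^((n_steps - 1):0)  # low to high
  rows <- list(); t0 <- 0; id <- 0
  for (i in seq_len(n_steps)) {
    id <- id + 1
    rows[[id]] <- data.frame(phase_id = id, t_start = t0, t_end = t0 + t_assoc,
                             conc_M = concs[i], kind = "association")
    t0 <- t0 + t_assoc
    t_d <- if (i < n_steps) t_dissoc_step else t_dissoc_final
    id <- id + 1
    rows[[id]] <- data.frame(phase_id = id, t_start = t0, t_end = t0 + t_d,
                             conc_M = 0, kind = "dissociation")
    t0 <- t0 + t_d
  }
  do.call(rbind, rows)
}

#' Multi-cycle phase tables (one association + dissociation per cycle)
#'
#' @param concs analyte concentrations, M (one sensorgram each).
#' @inheritParams single_cycle_phases
#' @return list of phase tables, one per concentration.
#' @export
multi_cycle_phases <- function(concs, t_assoc = 120, t_dissoc_final = 1800) {
  lapply(concs, function(cc)
    data.frame(phase_id = 1:2, t_start = c(0, t_assoc),
               t_end = c(t_assoc, t_assoc + t_dissoc_final),
               conc_M = c(cc, 0),
               kind = c("association", "dissociation")))
}

check_phases <- function(phases) {
  stopifnot(all(c("phase_id", "t_start", "t_end", "conc_M", "kind") %in%
                  names(phases)))
  phases <- phases[order(phases$t_start), , drop = FALSE]
  if (any(phases$t_end <= phases$t_start)) stop_input("empty phase")
  if (nrow(phases) > 1L &&
      any(abs(phases$t_start[-1] - phases$t_end[-nrow(phases)]) > 1e-9))
    stop_input("phases must tile the time axis without gaps or overlap")
  if (any(phases$conc_M < 0)) stop_input("negative concentration")
  if (any(phases$kind == "dissociation" & phases$conc_M != 0))
    stop_input("dissociation phases must have zero concentration")
  phases
}

# closed-form 1:1 Langmuir response at arbitrary times given a phase table;
# R0 chains across phases (single-cycle chaining)
langmuir_response <- function(times, phases, ka, kd, Rmax) {
  phases <- check_phases(phases)
  out <- numeric(length(times))
  R0 <- 0
  for (i in seq_len(nrow(phases))) {
    ph <- phases[i, ]
    sel <- times >= ph$t_start - 1e-9 & times <= ph$t_end + 1e-9
    tt <- times[sel] - ph$t_start
    if (ph$conc_M > 0) {
      kobs <- ka * ph$conc_M + kd
      Req <- Rmax * ph$conc_M / (ph$conc_M + kd / ka)
      out[sel] <- Req + (R0 - Req) * guarded_exp(-kobs * tt)
      R0 <- Req + (R0 - Req) * guarded_exp(-kobs * (ph$t_end - ph$t_start))
    } else {
      out[sel] <- R0 * guarded_exp(-kd * tt)
      R0 <- R0 * guarded_exp(-kd * (ph$t_end - ph$t_start))
    }
  }
  out
}

#' Simulate a 1:1 Langmuir sensorgram
#'
#' Closed-form integration of `dR/dt = ka C (Rmax - R) - kd R` per phase:
#' within an association phase at concentration `C` starting from `R0`,
#' `R(t) = Req + (R0 - Req) exp(-(ka C + kd) t)` with
#' `Req = Rmax C / (C + kd/ka)`; within dissociation `R(t) = R0 exp(-kd t)`.
#' `R0` chains across phases, giving single-cycle traces for sequential
#' injections.
#'
#' @param ka association rate constant, 1/(M s).
#' @param kd dissociation rate constant, 1/s.
#' @param Rmax saturating response, RU (or nm for BLI).
#' @param phases phase table as from [single_cycle_phases()].
#' @param noise_sd Gaussian noise SD in response units.
#' @param seed RNG seed for noisy traces.
#' @param dt sampling interval, s.
#' @return object of class `sensorgram`: `times`, `response`, `phases`,
#'   generating `truth`.
#' @export
simulate_sensorgram <- function(ka, kd, Rmax, phases, noise_sd = 0,
                                seed = NULL, dt = 1) {
  phases <- check_phases(phases)
  times <- sort(unique(unlist(lapply(seq_len(nrow(phases)), function(i)
    seq(phases$t_start[i], phases$t_end[i], by = dt)))))
  y <- langmuir_response(times, phases, ka, kd, Rmax)
  if (noise_sd > 0) {
    if (is.null(seed)) stop_input("seed required for noisy simulation")
    y <- y + withr_rnorm(seed, length(y), noise_sd)
  }
  structure(list(times = times, response = y, phases = phases,
                 truth = list(ka = ka, kd = kd, Rmax = Rmax,
                              noise_sd = noise_sd)),
            class = "sensorgram")
}

#' Global 1:1 Langmuir fit of one or more sensorgrams
#'
#' Least squares with `ka`, `kd` and `Rmax` shared across all traces and
#' phases (fitted on log10 scales for the rate constants). Initialisation is
#' a deterministic grid plus a kobs-based seed from the association phases.
#' Identifiability guard: fails when no dissociation data are present and
#' fewer than three distinct analyte concentrations constrain `kobs` vs `C`.
#'
#' @param sensorgrams a `sensorgram` or list of them.
#' @return object of class `kinetic_fit`: `ka`, `kd`, `KD` (`= kd/ka`, M),
#'   `Rmax`, `rss`, `covariance` (log10-scale), `status`; or
#'   `kinetic_fit_failure` with diagnostics.
#' @export
fit_1to1_global <- function(sensorgrams) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  concs <- unique(unlist(lapply(sensorgrams, function(s)
    s$phases$conc_M[s$phases$kind == "association"])))
  concs <- concs[concs > 0]
  has_dissoc <- any(unlist(lapply(sensorgrams, function(s)
    s$phases$kind == "dissociation")))
  n_assoc_steps <- sum(unlist(lapply(sensorgrams, function(s)
    s$phases$kind == "association")))
  if (length(concs) < 2L && n_assoc_steps < 3L)
    return(structure(list(status = "failed",
                          message = "need >= 2 concentrations or a single-cycle trace with >= 3 steps"),
                     class = "kinetic_fit_failure"))
  if (!has_dissoc && length(concs) < 3L)
    return(structure(list(status = "failed",
                          message = "kd unidentifiable: no dissociation data and too few concentrations"),
                     class = "kinetic_fit_failure"))

  y_all <- unlist(lapply(sensorgrams, `[[`, "response"))
  residual_fn <- function(par) {
    ka <- 10^par[1]; kd <- 10^par[2]; Rmax <- 10^par[3]
    unlist(lapply(sensorgrams, function(s)
      langmuir_response(s$times, s$phases, ka, kd, Rmax))) - y_all
  }
  Rmax0 <- max(y_all)
  # kobs seed: initial slope / plateau heuristic at the top concentration
  top <- max(concs)
  starts <- list()
  for (lka in c(4, 5, 6)) for (lkd in c(-3, -4)) {
    starts[[length(starts) + 1L]] <- c(lka, lkd, log10(max(Rmax0, 1)))
  }
  lower <- c(1, -7, log10(max(Rmax0 / 100, 1e-3)))
  upper <- c(9, 0, log10(max(Rmax0 * 100, 1)))
  best <- run_multistart(residual_fn, starts, lower, upper)
  if (is.null(best))
    return(structure(list(status = "failed", message = "no start converged"),
                     class = "kinetic_fit_failure"))
  p <- unname(best$par)
  ka <- 10^p[1]; kd <- 10^p[2]
  structure(list(ka = ka, kd = kd, KD = kd / ka, Rmax = 10^p[3],
                 rss = best$rss,
                 covariance = lm_covariance(best$fit, length(y_all)),
                 n = length(y_all), status = "ok"),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> ka = %.3g 1/(M s), kd = %.3g 1/s, KD = %.1f pM, Rmax = %.1f\n",
              x$ka, x$kd, x$KD * 1e12, x$Rmax))
  invisible(x)
}

#' @export
print.kinetic_fit_failure <- function(x, ...) {
  cat("<kinetic fit failure>", x$message, "\n"); invisible(x)
}

#' Serum interference ratio of association rates
#'
#' `ratio = ka_serum / ka_buffer`; binding is classified "no interference"
#' when the ratio lies within `band` (default 0.8-1.25, a conventional
#' bioanalytical equivalence band; the comparison itself is the published
#' readout).
#'
#' @param fit_buffer,fit_serum `kinetic_fit`s from buffer and serum runs.
#' @param band acceptance interval for the ratio.
#' @return list of class `serum_ratio`: `ratio`, `interference` (logical),
#'   `classification`.
#' @export
serum_interference_ratio <- function(fit_buffer, fit_serum,
                                     band = c(0.8, 1.25)) {
  for (f in list(fit_buffer, fit_serum))
    if (!inherits(f, "kinetic_fit") || f$status != "ok")
      stop_input("both fits must be valid kinetic fits")
  ratio <- fit_serum$ka / fit_buffer$ka
  ok <- ratio >= band[1] && ratio <= band[2]
  structure(list(ratio = ratio, interference = !ok,
                 classification = if (ok) "no interference" else "interference",
                 band = band),
            class = "serum_ratio")
}

#' @export
print.serum_ratio <- function(x, ...) {
  cat(sprintf("<serum_ratio> ka_serum/ka_buffer = %.4f (%s)\n",
              x$ratio, x$classification))
  invisible(x)
}

#' Sensorgram CSV I/O (response trace + side-car phase table)
#'
#' @param sensorgram a `sensorgram`.
#' @param path trace CSV (`time_s`, `response`, `phase_id`); the phase table
#'   is written next to it as `<path>.phases.csv`.
#' @export
write_sensorgram_csv <- function(sensorgram, path) {
  ph <- sensorgram$phases
  phase_of <- vapply(sensorgram$times, function(t)
    ph$phase_id[which(t >= ph$t_start - 1e-9 & t <= ph$t_end + 1e-9)][1],
    numeric(1))
  write.csv(data.frame(time_s = sensorgram$times,
                       response = sensorgram$response,
                       phase_id = phase_of),
            path, row.names = FALSE)
  write.csv(ph, paste0(path, ".phases.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensorgram_csv
#' @export
read_sensorgram_csv <- function(path) {
  tr <- read.csv(path)
  ph <- read.csv(paste0(path, ".phases.csv"))
  structure(list(times = tr$time_s, response = tr$response,
                 phases = check_phases(ph)),
            class = "sensorgram")
}
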