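# excess heat capacity of one non-two-state transition, kJ/mol/K
# K(T) = exp[-(dH_vH/R) (1/T - 1/Tm)], cp_ex = dH_cal dH_vH / (R T^2) K/(1+K)^2
dsc_excess_cp <- function(temp_C, tm, dH_cal, dH_vH) {
  TK <- temp_C + 273.15; TmK <- tm + 273.15
  K <- guarded_exp(-(dH_vH / .R_KJ) * (1 / TK - 1 / TmK))
  dH_cal * dH_vH / (.R_KJ * TK^2) * K / (1 + K)^2
}

KJ_PER_KCAL <- 4.184

#' Simulate a DSC thermogram
#'
#' Sum of independent non-two-state transitions over a linear instrument
#' baseline. Each transition contributes
#' `dH_cal * dH_vH / (R T^2) * K / (1 + K)^2` with van't Hoff equilibrium
#' constant `K(T) = exp[-(dH_vH / R)(1/T - 1/Tm)]` (temperatures in kelvin;
#' enthalpies kJ/mol). Heat capacity is reported in kcal/mol/degC as plotted
#' by instrument software.
#'
#' @param transitions list of lists with `tm` (degC), `dH_cal`, `dH_vH`
#'   (kJ/mol); may be empty for a baseline-only scan.
#' @param baseline `c(intercept, slope)` in kcal/mol/degC (per degC slope).
#' @param noise_sd Gaussian noise SD in kcal/mol/degC; `"peak/50"` scales to
#'   1/50 of the maximum excess peak height.
#' @param seed RNG seed (required for noisy scans).
#' @param temperatures degC, strictly increasing; default 25-100 at 0.1
#'   (a 1 degC/min capillary scan logs several readings per degC).
#' @param scan_rate degC/min, metadata only.
#' @return object of class `thermogram`: `temperatures`, `cp`
#'   (kcal/mol/degC), `scan_rate`, `buffer_subtracted`, generating `truth`.
#' @export
simulate_dsc <- function(transitions, baseline = c(2.0, 0.005),
                         noise_sd = "peak/50", seed = NULL,
                         temperatures = seq(25, 100, by = 0.1),
                         scan_rate = 1) {
  stopifnot(!is.unsorted(temperatures, strictly = TRUE))
  excess_kJ <- rep(0, length(temperatures))
  for (tr in transitions)
    excess_kJ <- excess_kJ + dsc_excess_cp(temperatures, tr$tm, tr$dH_cal, tr$dH_vH)
  cp <- baseline[1] + baseline[2] * temperatures + excess_kJ / KJ_PER_KCAL
  if (identical(noise_sd, "peak/50"))
    noise_sd <- if (length(transitions) > 0) max(excess_kJ / KJ_PER_KCAL) / 50 else 0
  if (noise_sd > 0) {
    if (is.null(seed)) stop_input("seed required for noisy simulation")
    cp <- cp + withr_rnorm(seed, length(cp), noise_sd)
  }
  structure(list(temperatures = temperatures, cp = cp, scan_rate = scan_rate,
                 buffer_subtracted = TRUE,
                 truth = list(transitions = transitions, baseline = baseline,
                              noise_sd = noise_sd)),
            class = "thermogram")
}

#' Fit non-two-state transitions to a DSC thermogram
#'
#' Least-squares deconvolution of `n_transitions` independent non-two-state
#' transitions plus a linear baseline (initialised from the pre- and
#' post-transition scan edges, refined in the fit). Transition temperatures
#' are seeded from smoothed-curve peaks with a deterministic split multistart
#' for overlapping transitions. Transitions are returned sorted by Tm.
#'
#' @param thermogram a `thermogram`.
#' @param n_transitions 1, 2 or 3.
#' @return list of class `dsc_fit`: `transitions` (data.frame `tm`, `dH_cal`,
#'   `dH_vH`, kJ/mol), `baseline`, `rss`, `status`; or `dsc_fit_failure` when
#'   the scan shows no transition above noise.
#' @export
fit_dsc <- function(thermogram, n_transitions = 2) {
  stopifnot(n_transitions %in% 1:3)
  temp <- thermogram$temperatures; cp <- thermogram$cp
  n <- length(temp)
  if (n < 50L) stop_input("need >= 50 points for DSC fitting")

  edge <- seq_len(max(10L, round(0.1 * n)))
  edges <- c(edge, n + 1L - edge)
  bl0 <- unname(coef(lm(cp[edges] ~ temp[edges])))
  resid_edge_sd <- sd(stats::residuals(lm(cp[edges] ~ temp[edges])))
  excess0 <- cp - (bl0[1] + bl0[2] * temp)
  sm <- signal::sgolayfilt(excess0, p = 2, n = 11)
  if (max(sm) < 6 * max(resid_edge_sd, 1e-6))
    return(structure(list(status = "failed",
                          message = "no transition above noise"),
                     class = "dsc_fit_failure"))

  pk <- pracma::findpeaks(sm, npeaks = n_transitions, sortstr = TRUE,
                          minpeakheight = 4 * max(resid_edge_sd, 1e-6))
  tm0 <- if (is.null(pk)) stats::quantile(temp, 0.5, names = FALSE) else sort(temp[pk[, 2]])
  area_kJ <- pracma::trapz(temp, pmax(excess0, 0)) * KJ_PER_KCAL

  make_tm_sets <- function() {
    if (length(tm0) >= n_transitions) return(list(tm0[seq_len(n_transitions)]))
    # fewer peaks than requested transitions: split the main peak
    main <- tm0[1]
    if (n_transitions == 2)
      lapply(c(1, 1.5, 2.5, 4), function(d) c(main - d, main + d))
    else
      lapply(c(1.5, 3), function(d) c(main - d, main, main + d))
  }
  residual_fn <- function(par) {
    k <- n_transitions
    model <- par[3 * k + 1] + par[3 * k + 2] * temp
    for (i in seq_len(k)) {
      model <- model + dsc_excess_cp(temp, par[3 * i - 2],
                                     exp(par[3 * i - 1]), exp(par[3 * i])) /
        KJ_PER_KCAL
    }
    model - cp
  }
  starts <- lapply(make_tm_sets(), function(tms) {
    st <- numeric(0)
    for (tm in tms)
      st <- c(st, tm, log(max(area_kJ / n_transitions, 50)), log(500))
    c(st, bl0)
  })
  lower <- c(rep(c(min(temp), log(5), log(5)), n_transitions), -Inf, -Inf)
  upper <- c(rep(c(max(temp), log(2e4), log(2e4)), n_transitions), Inf, Inf)
  best <- run_multistart(residual_fn, starts, lower, upper)
  if (is.null(best))
    return(structure(list(status = "failed", message = "no start converged"),
                     class = "dsc_fit_failure"))
  p <- unname(best$par); k <- n_transitions
  tab <- data.frame(tm = p[3 * seq_len(k) - 2],
                    dH_cal = exp(p[3 * seq_len(k) - 1]),
                    dH_vH = exp(p[3 * seq_len(k)]))
  tab <- tab[order(tab$tm), , drop = FALSE]; rownames(tab) <- NULL
  structure(list(transitions = tab, baseline = p[3 * k + 1:2],
                 rss = best$rss, n = n, status = "ok"),
            class = "dsc_fit")
}

#' @export
print.dsc_fit <- function(x, ...) {
  cat("<dsc_fit>\n"); print(round(x$transitions, 2)); invisible(x)
}

#' @export
print.dsc_fit_failure <- function(x, ...) {
  cat("<dsc fit failure>", x$message, "\n"); invisible(x)
}

#' Label DSC transitions as Fab vs CH2/CH3
#'
#' The transition closest to `ch2ch3_ref` (default 65 degC, the temperature
#' at which CH2 and CH3 melt together in these IgG4 scans) is labelled
#' `CH2CH3`; the remaining transition is the Fab. A labelling convenience
#' only, exposed for configurability.
#'
#' @param fit a `dsc_fit` with two transitions.
#' @param ch2ch3_ref reference temperature, degC.
#' @return the fit's transition table with an `assignment` column.
#' @export
assign_dsc_transitions <- function(fit, ch2ch3_ref = 65) {
  tab <- fit$transitions
  stopifnot(nrow(tab) == 2L)
  i_ch <- which.min(abs(tab$tm - ch2ch3_ref))
  tab$assignment <- ifelse(seq_len(2L) == i_ch, "CH2CH3", "Fab")
  tab
}

#' Simulate a DSF melting curve (F350/F330 ratio vs temperature)
#'
#' Each transition is a van't Hoff two-state sigmoid of amplitude
#' `amplitudes[i]`; the ratio rides on a linear pre-transition baseline.
#'
#' @param tm_values transition midpoints, degC.
#' @param dH_vH van't Hoff enthalpy controlling sigmoid steepness, kJ/mol
#'   (recycled across transitions).
#' @param amplitudes ratio-unit amplitude per transition (recycled).
#' @param baseline `c(intercept, slope per degC)`.
#' @param noise_sd ratio units, default 0.002.
#' @param seed RNG seed for noisy curves.
#' @param temperatures degC grid, default 20-95 at 0.5.
#' @return object of class `dsf_curve`: `temperatures`, `ratio`, `truth`.
#' @export
simulate_dsf_melt <- function(tm_values, dH_vH = 500, amplitudes = 0.2,
                              baseline = c(0.85, 0.0015),
                              noise_sd = 0.002, seed = NULL,
                              temperatures = seq(20, 95, by = 0.5)) {
  dH_vH <- rep_len(dH_vH, length(tm_values))
  amplitudes <- rep_len(amplitudes, length(tm_values))
  y <- baseline[1] + baseline[2] * temperatures
  for (i in seq_along(tm_values)) {
    TK <- temperatures + 273.15; TmK <- tm_values[i] + 273.15
    K <- guarded_exp(-(dH_vH[i] / .R_KJ) * (1 / TK - 1 / TmK))
    y <- y + amplitudes[i] * K / (1 + K)
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop_input("seed required for noisy simulation")
    y <- y + withr_rnorm(seed, length(y), noise_sd)
  }
  structure(list(temperatures = temperatures, ratio = y,
                 truth = list(tm_values = tm_values, dH_vH = dH_vH,
                              amplitudes = amplitudes, baseline = baseline,
                              noise_sd = noise_sd)),
            class = "dsf_curve")
}

# sub-grid refinement of a discrete peak: vertex of a quadratic regressed
# over a window around the argmax (more noise-tolerant than a 3-point fit)
refine_peak <- function(x, y, i, half_window = 8L) {
  lo <- max(1L, i - half_window); hi <- min(length(x), i + half_window)
  if (hi - lo < 4L) return(x[i])
  xx <- x[lo:hi] - x[i]; yy <- y[lo:hi]
  cf <- coef(lm(yy ~ xx + I(xx^2)))
  if (!is.finite(cf[3]) || cf[3] >= 0) return(x[i])
  vertex <- -cf[2] / (2 * cf[3])
  if (abs(vertex) > (x[hi] - x[lo]) / 2) return(x[i])
  x[i] + vertex
}

#' Melting temperatures and unfolding onset from a DSF ratio curve
#'
#' Tm values are the sub-grid-refined maxima of the Savitzky-Golay-smoothed
#' first derivative `d(ratio)/dT`; peaks must exceed a noise floor (5x the
#' derivative's baseline spread) and a relative prominence cut, making the
#' detector invariant to affine rescaling of the ratio. Tonset is the first
#' temperature at which the ratio deviates from the pre-transition linear
#' baseline by more than 5x the baseline residual SD (sustained over three
#' points).
#'
#' @param ratio_curve a `dsf_curve` (or list with `temperatures`, `ratio`).
#' @param window Savitzky-Golay window length (odd), default 11.
#' @param min_rel_height peaks below this fraction of the tallest derivative
#'   peak are ignored, default 0.2.
#' @return list of class `dsf_result`: `tm_values` (possibly empty),
#'   `tonset`, `status` (`"ok"` or `"no_transition"`).
#' @export
dsf_tm <- function(ratio_curve, window = 11, min_rel_height = 0.2) {
  temp <- ratio_curve$temperatures; y <- ratio_curve$ratio
  if (length(temp) < 30L) stop_input("need >= 30 points for DSF analysis")
  dT <- stats::median(diff(temp))
  smooth <- signal::sgolayfilt(y, p = 2, n = window)
  deriv <- signal::sgolayfilt(y, p = 2, n = window, m = 1, ts = dT)

  nb <- max(10L, round(0.1 * length(temp)))
  base_idx <- seq_len(nb)
  noise_floor <- 5 * max(mad(deriv[base_idx]), 1e-12)
  pk <- pracma::findpeaks(deriv, minpeakheight = max(noise_floor,
                                                     min_rel_height * max(deriv)),
                          minpeakdistance = max(3L, round(2 / dT)))
  if (is.null(pk) || max(deriv) <= noise_floor)
    return(structure(list(tm_values = numeric(0), tonset = NA_real_,
                          status = "no_transition"), class = "dsf_result"))
  idx <- sort(pk[, 2])
  tms <- vapply(idx, function(i) refine_peak(temp, deriv, i), numeric(1))

  blfit <- lm(y[base_idx] ~ temp[base_idx])
  bl_pred <- coef(blfit)[1] + coef(blfit)[2] * temp
  s <- max(sd(stats::residuals(blfit)), 1e-12)
  above <- (y - bl_pred) > 5 * s
  sustained <- which(above & c(above[-1], FALSE) & c(above[-(1:2)], FALSE, FALSE))
  tonset <- if (length(sustained) > 0) temp[sustained[1]] else NA_real_

  structure(list(tm_values = tms, tonset = tonset, status = "ok"),
            class = "dsf_result")
}

#' @export
print.dsf_result <- function(x, ...) {
  cat(sprintf("<dsf_result> Tm: %s; Tonset: %s\n",
              paste(round(x$tm_values, 2), collapse = ", "),
              ifelse(is.na(x$tonset), "NA", round(x$tonset, 2))))
  invisible(x)
}

#' Simulate a static-scattering (aggregation) trace
#'
#' Flat linear baseline up to the aggregation onset, then a linear rise; a
#' short quadratic knee of width `knee_width` joins the two segments smoothly.
#'
#' @param tagg onset temperature, degC.
#' @param rise_slope scattering slope above onset, mAU/degC.
#' @param baseline `c(intercept, slope)` in mAU.
#' @param knee_width degC over which the slope turns on, default 0.5.
#' @param noise_sd mAU.
#' @param seed RNG seed for noisy traces.
#' @param temperatures degC grid.
#' @return object of class `scattering_curve`.
#' @export
simulate_scattering <- function(tagg, rise_slope = 8,
                                baseline = c(5, 0.02), knee_width = 0.5,
                                noise_sd = 0.5, seed = NULL,
                                temperatures = seq(20, 95, by = 0.5)) {
  y <- baseline[1] + baseline[2] * temperatures
  d <- temperatures - tagg
  if (knee_width > 0) {
    knee <- d > 0 & d < knee_width
    y[knee] <- y[knee] + rise_slope * d[knee]^2 / (2 * knee_width)
    y[d >= knee_width] <- y[d >= knee_width] +
      rise_slope * (d[d >= knee_width] - knee_width / 2)
  } else {
    y[d > 0] <- y[d > 0] + rise_slope * d[d > 0]
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop_input("seed required for noisy simulation")
    y <- y + withr_rnorm(seed, length(y), noise_sd)
  }
  structure(list(temperatures = temperatures, scattering = y,
                 truth = list(tagg = tagg, rise_slope = rise_slope,
                              baseline = baseline, knee_width = knee_width,
                              noise_sd = noise_sd)),
            class = "scattering_curve")
}

#' Aggregation onset from a scattering trace
#'
#' Tagg is the intersection of the pre-aggregation linear baseline with the
#' tangent at the point of maximum slope of the smoothed scattering signal
#' (the standard tangent-construction onset).
#'
#' @param scattering_curve a `scattering_curve` (or list with `temperatures`,
#'   `scattering`).
#' @param baseline_points number of leading points used for the baseline fit
#'   (>= 10).
#' @param window Savitzky-Golay window, default 11.
#' @return list of class `tagg_result`: `tagg` (degC, `NA` when flat),
#'   `status` (`"ok"` / `"no_aggregation"`).
#' @export
detect_aggregation_onset <- function(scattering_curve, baseline_points = 15,
                                     window = 11) {
  temp <- scattering_curve$temperatures; y <- scattering_curve$scattering
  stopifnot(baseline_points >= 10L, length(temp) > baseline_points + window)
  dT <- stats::median(diff(temp))
  # two-pass baseline: seed from the leading points, locate the first
  # sustained exceedance, then refit over the whole pre-onset region so the
  # extrapolated baseline is not dominated by slope noise
  base_idx <- seq_len(baseline_points)
  for (pass in 1:2) {
    blfit <- lm(y[base_idx] ~ temp[base_idx])
    a <- unname(coef(blfit)[1]); b <- unname(coef(blfit)[2])
    s_base <- max(sd(stats::residuals(blfit)), 1e-12)
    if (pass == 2L) break
    exceed <- (y - (a + b * temp)) > 5 * s_base
    sust <- which(exceed & c(exceed[-1], FALSE) & c(exceed[-(1:2)], FALSE, FALSE))
    if (length(sust) == 0L) break
    cut <- max(baseline_points, sust[1] - round(2 / dT))
    base_idx <- seq_len(cut)
  }

  smooth <- signal::sgolayfilt(y, p = 2, n = window)
  deriv <- signal::sgolayfilt(y, p = 2, n = window, m = 1, ts = dT)
  i_max <- which.max(deriv)
  rise <- max(smooth) - (a + b * temp[which.max(smooth)])
  if (deriv[i_max] <= b + 1e-12 || rise < 10 * s_base)
    return(structure(list(tagg = NA_real_, status = "no_aggregation"),
                     class = "tagg_result"))
  # tangent from a regression over the mid-rise region (25-75% of the total
  # rise; more stable than a single-point tangent under noise)
  excess <- smooth - (a + b * temp)
  hs <- which(excess >= 0.25 * rise & excess <= 0.75 * rise &
                seq_along(temp) >= i_max - round(20 / dT))
  if (length(hs) < 3L) hs <- which(deriv >= 0.8 * deriv[i_max])
  tan_fit <- lm(y[hs] ~ temp[hs])
  slope <- unname(coef(tan_fit)[2]); icpt <- unname(coef(tan_fit)[1])
  if (slope <= b)
    return(structure(list(tagg = NA_real_, status = "no_aggregation"),
                     class = "tagg_result"))
  tagg <- (a - icpt) / (slope - b)
  structure(list(tagg = tagg, status = "ok",
                 max_slope = slope, max_slope_at = temp[i_max]),
            class = "tagg_result")
}

#' @export
print.tagg_result <- function(x, ...) {
  cat(sprintf("<tagg_result> %s\n",
              if (x$status == "ok") sprintf("Tagg = %.2f degC", x$tagg)
              else "no aggregation detected"))
  invisible(x)
}

#' Thermogram / DSF CSV I/O
#' @param x a `thermogram`, `dsf_curve` or `scattering_curve`.
#' @param path CSV path.
#' @export
write_thermal_csv <- function(x, path) {
  col <- intersect(c("cp", "ratio", "scattering"), names(x))[1]
  df <- data.frame(temperature_C = x$temperatures, value = x[[col]])
  names(df)[2] <- col
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thermal_csv
#' @export
read_thermal_csv <- function(path) {
  tab <- read.csv(path)
  col <- setdiff(names(tab), "temperature_C")[1]
  out <- list(temperatures = tab$temperature_C)
  out[[col]] <- tab[[col]]
  cls <- switch(col, cp = "thermogram", ratio = "dsf_curve",
                scattering = "scattering_curve")
  structure(out, class = cls)
}
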