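#' Two-state fraction unfolded under the linear extrapolation model
#'
#' LEM: the unfolding free energy depends linearly on denaturant,
#' `dG(c) = dG_u - m * c`; the equilibrium constant is
#' `K = exp(-dG(c)/RT)` and the unfolded fraction `fU = K / (1 + K)`.
#'
#' @param c denaturant concentration(s), M.
#' @param dG_u free energy of unfolding at zero denaturant, kJ/mol.
#' @param m_value m-value, kJ/mol/M (> 0 for a cooperative unfolder).
#' @param temperature K, default 298.15.
#' @return fraction unfolded in `[0, 1]`, strictly increasing in `c` when
#'   `m_value > 0`.
#' @export
two_state_fraction_unfolded <- function(c, dG_u, m_value,
                                        temperature = 298.15) {
  stopifnot(temperature > 0)
  RT <- .R_KJ * temperature
  K <- guarded_exp(-(dG_u - m_value * c) / RT)
  K / (1 + K)
}

two_state_signal <- function(c, dG_u, m_value, native_baseline,
                             unfolded_baseline, temperature = 298.15) {
  fU <- two_state_fraction_unfolded(c, dG_u, m_value, temperature)
  yn <- native_baseline[1] + native_baseline[2] * c
  yu <- unfolded_baseline[1] + unfolded_baseline[2] * c
  (1 - fU) * yn + fU * yu
}

#' Three-state (N = I = U) populations and signal
#'
#' Sequential three-state LEM: `K1 = exp(-(dG1 - m1 c)/RT)`,
#' `K2 = exp(-(dG2 - m2 c)/RT)`; populations
#' `pN = 1/(1 + K1 + K1 K2)`, `pI = K1 pN`, `pU = K1 K2 pN` (sum to 1).
#' The observed signal mixes two linear baselines and a constant
#' intermediate-state signal.
#'
#' @param c denaturant concentration(s), M.
#' @param dG1,m1 first-transition free energy (kJ/mol) and m-value (kJ/mol/M).
#' @param dG2,m2 second-transition parameters.
#' @param temperature K.
#' @return `three_state_populations`: data.frame with `pN`, `pI`, `pU`.
#' @export
three_state_populations <- function(c, dG1, m1, dG2, m2,
                                    temperature = 298.15) {
  stopifnot(temperature > 0)
  RT <- .R_KJ * temperature
  K1 <- guarded_exp(-(dG1 - m1 * c) / RT)
  K2 <- guarded_exp(-(dG2 - m2 * c) / RT)
  pN <- 1 / (1 + K1 + K1 * K2)
  data.frame(pN = pN, pI = K1 * pN, pU = K1 * K2 * pN)
}

#' @rdname three_state_populations
#' @param native_baseline,unfolded_baseline numeric `c(intercept, slope)`.
#' @param intermediate_signal concentration-independent intermediate signal.
#' @return `three_state_signal`: numeric signal vector.
#' @export
three_state_signal <- function(c, dG1, m1, dG2, m2, native_baseline,
                               unfolded_baseline, intermediate_signal,
                               temperature = 298.15) {
  p <- three_state_populations(c, dG1, m1, dG2, m2, temperature)
  yn <- native_baseline[1] + native_baseline[2] * c
  yu <- unfolded_baseline[1] + unfolded_baseline[2] * c
  p$pN * yn + p$pI * intermediate_signal + p$pU * yu
}

#' Simulate an isothermal chemical denaturation curve
#'
#' Generates an F350/F330-style ratio curve from the two- or three-state LEM
#' with linear baselines and additive Gaussian noise.
#'
#' @param model `"two_state"` or `"three_state"`.
#' @param pars list of model parameters: `dG1`, `m1` (and `dG2`, `m2` for
#'   three-state).
#' @param concentrations M, strictly increasing.
#' @param native_baseline,unfolded_baseline `c(intercept, slope)`.
#' @param intermediate_signal constant (three-state only).
#' @param noise_sd Gaussian noise SD in ratio units, default 0.002.
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @param temperature K.
#' @param denaturant label, default `"GdnCl"`.
#' @return object of class `denaturation_curve`: `concentrations`, `signal`,
#'   `temperature`, `denaturant`, and the generating `truth`.
#' @export
simulate_denaturation_curve <- function(model = c("two_state", "three_state"),
                                        pars,
                                        concentrations = seq(0, 6, length.out = 30),
                                        native_baseline = c(0.86, 0.004),
                                        unfolded_baseline = c(1.10, -0.004),
                                        intermediate_signal = 0.99,
                                        noise_sd = 0.002, seed = NULL,
                                        temperature = 298.15,
                                        denaturant = "GdnCl") {
  model <- match.arg(model)
  stopifnot(!is.unsorted(concentrations, strictly = TRUE))
  y <- if (model == "two_state")
    two_state_signal(concentrations, pars$dG1, pars$m1,
                     native_baseline, unfolded_baseline, temperature)
  else
    three_state_signal(concentrations, pars$dG1, pars$m1, pars$dG2, pars$m2,
                       native_baseline, unfolded_baseline,
                       intermediate_signal, temperature)
  if (noise_sd > 0) {
    if (is.null(seed)) stop_input("seed required for noisy simulation")
    y <- y + withr_rnorm(seed, length(y), noise_sd)
  }
  structure(list(denaturant = denaturant, concentrations = concentrations,
                 signal = y, temperature = temperature,
                 truth = c(list(model = model), pars,
                           list(native_baseline = native_baseline,
                                unfolded_baseline = unfolded_baseline,
                                intermediate_signal = intermediate_signal,
                                noise_sd = noise_sd))),
            class = "denaturation_curve")
}

# local-RNG normal draws: never disturbs the caller's RNG stream
withr_rnorm <- function(seed, n, sd) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rnorm(n, 0, sd)
}

# baseline seeds from the curve extremes
baseline_seeds <- function(conc, y, n_edge = 3L) {
  lo <- seq_len(n_edge); hi <- seq(length(conc) - n_edge + 1L, length(conc))
  fit_lin <- function(idx) {
    if (length(unique(conc[idx])) < 2L) return(c(mean(y[idx]), 0))
    unname(coef(lm(y[idx] ~ conc[idx])))
  }
  list(native = fit_lin(lo), unfolded = fit_lin(hi))
}

# transition-midpoint seeds from smoothed first-derivative peaks
c50_seeds <- function(conc, y, n_peaks = 2L) {
  dy <- diff(y) / diff(conc)
  mid <- (conc[-1] + conc[-length(conc)]) / 2
  if (length(dy) >= 7L) dy <- stats::filter(dy, rep(1 / 3, 3), sides = 2)
  dy[is.na(dy)] <- 0
  pk <- pracma::findpeaks(abs(as.numeric(dy)), npeaks = n_peaks, sortstr = TRUE)
  if (is.null(pk)) return(stats::quantile(conc, c(1, 2) / 3, names = FALSE)[seq_len(n_peaks)])
  s <- sort(mid[pk[, 2]])
  if (length(s) < n_peaks)
    s <- sort(c(s, stats::quantile(conc, 2 / 3, names = FALSE)))
  s[seq_len(n_peaks)]
}

icd_fail <- function(message, best = NULL) {
  structure(list(status = "failed", message = message, best_attempt = best),
            class = c("icd_fit_failure", "list"))
}

#' @export
print.icd_fit_failure <- function(x, ...) {
  cat("<icd fit failure>", x$message, "\n"); invisible(x)
}

# shared nls.lm driver over a list of start vectors; returns best converged
run_multistart <- function(residual_fn, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = residual_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(fit = fit, rss = rss, par = fit$par)
    }
  }
  best
}

lm_covariance <- function(fit, n) {
  p <- length(fit$par)
  s2 <- sum(fit$fvec^2) / max(n - p, 1)
  jtj <- fit$hessian
  cov <- tryCatch(s2 * solve(jtj), error = function(e) matrix(NA_real_, p, p))
  cov
}

#' Fit the two-state LEM to a denaturation curve
#'
#' Least squares of observed signal against
#' `(1 - fU) * native_baseline(c) + fU * unfolded_baseline(c)` with
#' deterministic multistart initialisation: the midpoint is seeded at the
#' smoothed-derivative peak and m-values at 5, 10, 20 and 40 kJ/mol/M;
#' baselines are seeded from the curve extremes.
#'
#' @param curve a `denaturation_curve` (or any list with `concentrations`,
#'   `signal`, `temperature`).
#' @param m_seeds m-value starting grid, kJ/mol/M.
#' @return object of class `two_state_fit`: `dG_u`, `m_value`,
#'   `c50 = dG_u / m_value`, baselines, `rss`, `covariance`, `status`;
#'   or an `icd_fit_failure` for degenerate input (e.g. a flat curve).
#' @export
fit_two_state <- function(curve, m_seeds = c(5, 10, 20, 40)) {
  conc <- curve$concentrations; y <- curve$signal
  temp <- if (is.null(curve$temperature)) 298.15 else curve$temperature
  if (length(conc) < 8L) stop_input("need >= 8 points for fitting")
  bl <- baseline_seeds(conc, y)
  resid_sd0 <- sd(c(stats::residuals(lm(y[1:3] ~ conc[1:3])),
                    stats::residuals(lm(y[(length(y) - 2):length(y)] ~
                                          conc[(length(y) - 2):length(y)]))))
  amp0 <- abs((bl$unfolded[1] + bl$unfolded[2] * mean(conc)) -
                (bl$native[1] + bl$native[2] * mean(conc)))
  if (amp0 < max(6 * resid_sd0, 1e-3) && diff(range(y)) < 20 * max(resid_sd0, 1e-4))
    return(icd_fail("no detectable transition (flat curve)"))

  c50_0 <- c50_seeds(conc, y, 1L)[1L]
  residual_fn <- function(par) {
    two_state_signal(conc, par[1], par[2], par[3:4], par[5:6], temp) - y
  }
  starts <- lapply(m_seeds, function(m)
    c(dG = m * c50_0, m = m, bl$native, bl$unfolded))
  lower <- c(0.01, 0.05, rep(-Inf, 4)); upper <- c(500, 200, rep(Inf, 4))
  best <- run_multistart(residual_fn, starts, lower, upper)
  if (is.null(best)) return(icd_fail("no start converged"))
  p <- unname(best$par)
  dG <- p[1]; m <- p[2]; c50 <- dG / m
  sigma <- sqrt(best$rss / length(y))
  amp_fit <- abs((p[5] + p[6] * c50) - (p[3] + p[4] * c50))
  if (m <= 0.1 || c50 < min(conc) - 1 || c50 > max(conc) + 1 ||
      amp_fit < 5 * sigma)
    return(icd_fail("fitted transition not credible", best))
  structure(list(dG_u = dG, m_value = m, c50 = c50,
                 native_baseline = p[3:4], unfolded_baseline = p[5:6],
                 rss = best$rss, covariance = lm_covariance(best$fit, length(y)),
                 n = length(y), n_par = 6L, temperature = temp,
                 status = "ok"),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("<two_state_fit> dGu = %.2f kJ/mol, m = %.2f kJ/mol/M, c50 = %.2f M (rss %.3g)\n",
              x$dG_u, x$m_value, x$c50, x$rss))
  invisible(x)
}

#' Fit the three-state LEM to a denaturation curve
#'
#' Least squares of [three_state_signal()] with multistart initialisation:
#' midpoints seeded at the two largest smoothed-derivative peaks, m-values on
#' a deterministic grid, intermediate signal at the mid-plateau level. Fits
#' with `c50_1 >= c50_2` or a second transition pushed outside the sampled
#' range are flagged non-identifiable.
#'
#' @inheritParams fit_two_state
#' @return object of class `three_state_fit` with `dG1`, `m1`, `dG2`, `m2`,
#'   `c50_1`, `c50_2`, `intermediate_signal`, baselines, `rss`, `covariance`,
#'   `status` (`"ok"` or `"non_identifiable"`), or an `icd_fit_failure`.
#' @export
fit_three_state <- function(curve, m_seeds = c(5, 10, 20, 40)) {
  conc <- curve$concentrations; y <- curve$signal
  temp <- if (is.null(curve$temperature)) 298.15 else curve$temperature
  if (length(conc) < 12L) stop_input("need >= 12 points for three-state fitting")
  bl <- baseline_seeds(conc, y)
  if (diff(range(y)) < 1e-3)
    return(icd_fail("no detectable transition (flat curve)"))
  c50s <- c50_seeds(conc, y, 2L)
  mid_level <- stats::approx(conc, y, xout = mean(c50s))$y

  residual_fn <- function(par) {
    three_state_signal(conc, par[1], par[2], par[3], par[4],
                       par[5:6], par[7:8], par[9], temp) - y
  }
  starts <- list()
  for (m1 in m_seeds) for (m2 in c(5, 15)) {
    starts[[length(starts) + 1L]] <-
      c(dG1 = m1 * c50s[1], m1 = m1, dG2 = m2 * c50s[2], m2 = m2,
        bl$native, bl$unfolded, yI = mid_level)
  }
  lower <- c(0.01, 0.05, 0.01, 0.05, rep(-Inf, 4), -Inf)
  upper <- c(500, 200, 500, 200, rep(Inf, 4), Inf)
  best <- run_multistart(residual_fn, starts, lower, upper)
  if (is.null(best)) return(icd_fail("no start converged"))
  p <- unname(best$par)
  c50_1 <- p[1] / p[2]; c50_2 <- p[3] / p[4]
  status <- "ok"
  covm <- lm_covariance(best$fit, length(y))
  se <- suppressWarnings(sqrt(diag(covm)))
  if (!(c50_1 < c50_2) || c50_2 > max(conc) + 1 || c50_1 < min(conc) - 1 ||
      p[3] > 480 || p[2] <= 0.1 || p[4] <= 0.1 ||
      any(!is.finite(se[c(1, 3)])) || se[1] > 0.5 * p[1] || se[3] > 0.5 * p[3])
    status <- "non_identifiable"
  structure(list(dG1 = p[1], m1 = p[2], dG2 = p[3], m2 = p[4],
                 c50_1 = c50_1, c50_2 = c50_2,
                 native_baseline = p[5:6], unfolded_baseline = p[7:8],
                 intermediate_signal = p[9],
                 rss = best$rss, covariance = covm,
                 n = length(y), n_par = 9L, temperature = temp,
                 status = status),
            class = "three_state_fit")
}

#' @export
print.three_state_fit <- function(x, ...) {
  cat(sprintf("<three_state_fit> dG1 = %.2f (c50 %.2f M), dG2 = %.2f (c50 %.2f M), status %s\n",
              x$dG1, x$c50_1, x$dG2, x$c50_2, x$status))
  invisible(x)
}

#' Choose between two- and three-state unfolding models
#'
#' Fits both models and selects by corrected AIC: three-state is preferred
#' only when its AICc improves on the two-state AICc by more than
#' `delta_aicc` (default 2) and the three-state fit is identifiable.
#'
#' @inheritParams fit_two_state
#' @param delta_aicc AICc margin required to accept the more complex model.
#' @return list of class `model_selection`: `model` (`"two_state"`,
#'   `"three_state"` or `"failed"`), `two_state`, `three_state` (both fit
#'   objects), `aicc` (named vector).
#' @export
select_unfolding_model <- function(curve, delta_aicc = 2) {
  f2 <- tryCatch(fit_two_state(curve), error = function(e) icd_fail(conditionMessage(e)))
  f3 <- tryCatch(fit_three_state(curve), error = function(e) icd_fail(conditionMessage(e)))
  ok2 <- inherits(f2, "two_state_fit")
  ok3 <- inherits(f3, "three_state_fit") && f3$status == "ok"
  a2 <- if (ok2) aicc_from_rss(f2$rss, f2$n, f2$n_par) else Inf
  a3 <- if (ok3) aicc_from_rss(f3$rss, f3$n, f3$n_par) else Inf
  model <- if (!ok2 && !ok3) "failed"
           else if (ok3 && a2 - a3 > delta_aicc) "three_state"
           else if (ok2) "two_state"
           else "three_state"
  structure(list(model = model, two_state = f2, three_state = f3,
                 aicc = c(two_state = a2, three_state = a3)),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> %s (AICc 2-state %.1f, 3-state %.1f)\n",
              x$model, x$aicc[1], x$aicc[2]))
  invisible(x)
}

#' Replicate ICD assay: fit each replicate curve and average the parameters
#'
#' The published intrinsic-stability values are averages of n = 3 replicate
#' denaturation runs; this helper reproduces that protocol. Each replicate is
#' simulated with its own seed, fitted with the requested model, and the
#' fitted thermodynamic parameters are averaged across the replicates that
#' converged.
#'
#' @param model `"two_state"` or `"three_state"`.
#' @param pars generating truth (`dG1`, `m1`, and for three-state `dG2`,
#'   `m2`), kJ/mol and kJ/mol/M.
#' @param n_replicates number of replicate curves, default 3.
#' @param seed base seed; replicate seeds are `seed + 1:n`.
#' @param ... further arguments to [simulate_denaturation_curve()].
#' @return list: `mean` (named averaged parameters), `fits` (per-replicate
#'   fit objects), `n_ok`.
#' @export
fit_icd_replicates <- function(model = c("two_state", "three_state"), pars,
                               n_replicates = 3, seed = 1L, ...) {
  model <- match.arg(model)
  fits <- lapply(seq_len(n_replicates), function(i) {
    cv <- simulate_denaturation_curve(model, pars, seed = seed + i, ...)
    if (model == "two_state") fit_two_state(cv) else fit_three_state(cv)
  })
  ok <- vapply(fits, function(f)
    inherits(f, c("two_state_fit", "three_state_fit")), logical(1))
  if (!any(ok)) return(list(mean = NULL, fits = fits, n_ok = 0L))
  grab <- if (model == "two_state") c("dG_u", "m_value", "c50")
          else c("dG1", "m1", "c50_1", "dG2", "m2", "c50_2")
  vals <- sapply(fits[ok], function(f) unlist(f[grab]))
  list(mean = rowMeans(vals), fits = fits, n_ok = sum(ok))
}

#' Denaturation-curve CSV I/O
#'
#' Columns `concentration_M`, `ratio_350_330`.
#' @param curve a `denaturation_curve`.
#' @param path CSV path.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(data.frame(concentration_M = curve$concentrations,
                       ratio_350_330 = curve$signal),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param temperature assay temperature, K.
#' @export
read_curve_csv <- function(path, temperature = 298.15) {
  tab <- read.csv(path)
  structure(list(denaturant = "GdnCl",
                 concentrations = tab$concentration_M,
                 signal = tab$ratio_350_330, temperature = temperature),
            class = "denaturation_curve")
}
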