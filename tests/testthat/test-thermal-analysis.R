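test_that("simulated DSC peak height and area follow the closed forms", {
  tm <- 70; dH_cal <- 400; dH_vH <- 500
  tg <- simulate_dsc(list(list(tm = tm, dH_cal = dH_cal, dH_vH = dH_vH)),
                     baseline = c(0, 0), noise_sd = 0,
                     temperatures = seq(30, 110, by = 0.05))
  # peak at Tm: dHcal * dHvH / (4 R Tm_K^2), in kcal units
  TmK <- tm + 273.15
  peak_kcal <- dH_cal * dH_vH / (4 * 8.314e-3 * TmK^2) / 4.184
  expect_equal(tg$cp[tg$temperatures == tm], peak_kcal, tolerance = 1e-9)
  expect_equal(tg$temperatures[which.max(tg$cp)], tm, tolerance = 0.3)
  # integrated excess area equals the calorimetric enthalpy within 0.1%
  area_kJ <- pracma::trapz(tg$temperatures, tg$cp) * 4.184
  expect_lt(abs(area_kJ / dH_cal - 1), 0.001)
  # no transitions: baseline only
  bl <- simulate_dsc(list(), baseline = c(2, 0.01), noise_sd = 0)
  expect_equal(bl$cp, 2 + 0.01 * bl$temperatures)
})

test_that("noise-free DSC fits are the inverse of the simulator", {
  tg <- simulate_dsc(list(list(tm = 70, dH_cal = 400, dH_vH = 500)),
                     noise_sd = 0)
  f <- fit_dsc(tg, 1)
  expect_equal(f$status, "ok")
  expect_lt(abs(f$transitions$tm - 70), 0.01)
  expect_lt(abs(f$transitions$dH_cal / 400 - 1), 0.005)
  expect_lt(abs(f$transitions$dH_vH / 500 - 1), 0.005)
  # conservation: integrated excess Cp of the fitted transition vs dH_cal
  ex <- abstab:::dsc_excess_cp(tg$temperatures, f$transitions$tm,
                               f$transitions$dH_cal, f$transitions$dH_vH)
  expect_lt(abs(pracma::trapz(tg$temperatures, ex) / f$transitions$dH_cal - 1),
            0.01)
})

test_that("two-transition thermograms resolve Fab and CH2/CH3 melting", {
  reg <- fixture_registry()
  fit_tms <- function(mol, seed) {
    d <- reg[[mol]]$dsc
    tg <- simulate_dsc(list(list(tm = d$fab_tm, dH_cal = 400, dH_vH = 500),
                            list(tm = d$ch2ch3_tm, dH_cal = 400, dH_vH = 500)),
                       noise_sd = "peak/50", seed = seed)
    f <- fit_dsc(tg, 2)
    expect_equal(f$status, "ok")
    a <- assign_dsc_transitions(f)
    c(fab = a$tm[a$assignment == "Fab"], ch = a$tm[a$assignment == "CH2CH3"])
  }
  # average over a few noisy scans (overlapping transitions carry the
  # largest statistical spread)
  res75 <- rowMeans(sapply(1:3, function(s) fit_tms("PCa75", s)))
  res62 <- rowMeans(sapply(1:3, function(s) fit_tms("PCa62", 100 + s)))
  expect_lt(abs(res75[["fab"]] - 61.8), 0.3)
  expect_lt(abs(res62[["fab"]] - 75.7), 0.3)
  expect_lt(abs((res62[["fab"]] - res75[["fab"]]) - 13.9), 0.5)
})

test_that("baseline-only thermograms produce a failure status", {
  tg <- simulate_dsc(list(), baseline = c(2, 0.01), noise_sd = 0)
  tg$cp <- tg$cp + abstab:::withr_rnorm(4, length(tg$cp), 0.05)
  expect_s3_class(fit_dsc(tg, 1), "dsc_fit_failure")
})

test_that("DSF derivative analysis finds midpoints of synthetic melts", {
  # symmetric Boltzmann sigmoid: derivative max coincides with the midpoint
  temp <- seq(20, 95, by = 0.5)
  boltz <- list(temperatures = temp, ratio = 1 / (1 + exp((70 - temp) / 2)))
  r <- dsf_tm(boltz)
  expect_equal(r$tm_values[1], 70, tolerance = 0.01)
  # noise-free van't Hoff melt at the printed variant-Fab midpoint
  r62 <- dsf_tm(simulate_dsf_melt(81.5, noise_sd = 0))
  expect_lt(abs(r62$tm_values[1] - 81.5), 0.1)
  # two well-separated transitions are both recovered
  r2 <- dsf_tm(simulate_dsf_melt(c(55, 80), amplitudes = c(0.12, 0.12),
                                 noise_sd = 0))
  expect_length(r2$tm_values, 2L)
  expect_lt(abs(r2$tm_values[1] - 55), 0.3)
  expect_lt(abs(r2$tm_values[2] - 80), 0.3)
})

test_that("DSF results are invariant to affine rescaling of the ratio", {
  m <- simulate_dsf_melt(72, noise_sd = 0.002, seed = 6)
  r1 <- dsf_tm(m)
  m$ratio <- 3.7 * m$ratio + 11
  r2 <- dsf_tm(m)
  expect_equal(r1$tm_values, r2$tm_values, tolerance = 1e-9)
  expect_equal(r1$tonset, r2$tonset)
})

test_that("onset precedes the midpoint and flat melts report no transition", {
  r <- dsf_tm(simulate_dsf_melt(72, noise_sd = 0.002, seed = 2))
  expect_false(is.na(r$tonset))
  expect_lt(r$tonset, min(r$tm_values))
  flat <- list(temperatures = seq(20, 95, 0.5),
               ratio = 0.9 + abstab:::withr_rnorm(8, 151, 0.002))
  expect_equal(dsf_tm(flat)$status, "no_transition")
})

test_that("aggregation onset is recovered by the tangent construction", {
  # sharp break at a known temperature
  sc <- simulate_scattering(55, knee_width = 0, noise_sd = 0.5, seed = 3)
  r <- detect_aggregation_onset(sc)
  expect_equal(r$status, "ok")
  expect_lt(abs(r$tagg - 55), 0.3)
  # onset generated at the printed lead-variant value
  sc62 <- simulate_scattering(75.7, noise_sd = 0.5, seed = 4)
  expect_lt(abs(detect_aggregation_onset(sc62)$tagg - 75.7), 0.5)
  # flat trace: no aggregation
  flat <- simulate_scattering(200, noise_sd = 0.5, seed = 5)
  expect_equal(detect_aggregation_onset(flat)$status, "no_aggregation")
})

test_that("thermal CSV I/O round-trips each curve type", {
  tg <- simulate_dsc(list(list(tm = 70, dH_cal = 400, dH_vH = 500)),
                     noise_sd = 0, temperatures = seq(25, 100, by = 1))
  tmp <- tempfile(fileext = ".csv")
  write_thermal_csv(tg, tmp)
  back <- read_thermal_csv(tmp)
  expect_s3_class(back, "thermogram")
  expect_equal(back$cp, tg$cp)
})
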