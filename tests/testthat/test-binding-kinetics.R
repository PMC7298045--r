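pca75_k <- function() fixture_registry()$PCa75$kinetics

test_that("simulated responses follow the Langmuir closed forms", {
  k <- pca75_k()
  KD <- k$kd / k$ka
  # half saturation at C = KD
  long <- data.frame(phase_id = 1, t_start = 0, t_end = 2e5, conc_M = KD,
                     kind = "association")
  sg <- simulate_sensorgram(k$ka, k$kd, 100, long, dt = 1000)
  expect_equal(sg$response[length(sg$response)], 50, tolerance = 1e-3)
  # pure dissociation decays exponentially from R0 = 0 here: identically zero
  sg0 <- simulate_sensorgram(k$ka, k$kd, 100,
                             data.frame(phase_id = 1, t_start = 0, t_end = 600,
                                        conc_M = 0, kind = "dissociation"))
  expect_true(all(sg0$response == 0))
  # bounds: response stays within [0, Rmax]
  sc <- simulate_sensorgram(k$ka, k$kd, 150, single_cycle_phases())
  expect_true(all(sc$response >= 0 & sc$response <= 150))
})

test_that("closed-form single-cycle trace matches a Runge-Kutta ODE oracle", {
  k <- pca75_k()
  phases <- single_cycle_phases()
  sg <- simulate_sensorgram(k$ka, k$kd, 150, phases, dt = 1)
  # integrate dR/dt = ka C (Rmax - R) - kd R phase by phase
  R0 <- 0; oracle <- numeric(0)
  for (i in seq_len(nrow(phases))) {
    tt <- seq(phases$t_start[i], phases$t_end[i], by = 1)
    sol <- deSolve::ode(c(R = R0), tt - tt[1],
                        function(t, y, parms)
                          list(k$ka * phases$conc_M[i] * (150 - y) - k$kd * y),
                        parms = NULL, method = "ode45",
                        atol = 1e-10, rtol = 1e-10)
    vals <- sol[, "R"]
    oracle <- c(oracle, if (i == 1) vals else vals[-1])
    R0 <- vals[length(vals)]
  }
  expect_lt(max(abs(oracle - sg$response)), 1e-6)
})

test_that("noise-free global fits invert the simulator to 0.1%", {
  k <- pca75_k()
  sg <- simulate_sensorgram(k$ka, k$kd, 150, single_cycle_phases())
  f <- fit_1to1_global(sg)
  expect_equal(f$status, "ok")
  expect_lt(abs(f$ka / k$ka - 1), 0.001)
  expect_lt(abs(f$kd / k$kd - 1), 0.001)
  expect_lt(abs(f$Rmax / 150 - 1), 0.001)
  # KD identity and the published affinity
  expect_lt(abs(f$KD * f$ka - f$kd) / f$kd, 1e-12)
  expect_equal(f$KD * 1e12, 247.76, tolerance = 0.01)
})

test_that("single-cycle and multi-cycle designs agree on noise-free data", {
  k <- pca75_k()
  f_sc <- fit_1to1_global(simulate_sensorgram(k$ka, k$kd, 150,
                                              single_cycle_phases()))
  concs <- 30e-9 / 3^(4:0)
  f_mc <- fit_1to1_global(lapply(multi_cycle_phases(concs),
                                 function(ph) simulate_sensorgram(k$ka, k$kd, 150, ph)))
  expect_lt(abs(f_sc$ka / f_mc$ka - 1), 0.005)
  expect_lt(abs(f_sc$kd / f_mc$kd - 1), 0.005)
})

test_that("noisy single-cycle data recover the affinity within 5%", {
  k <- pca75_k()
  sg <- simulate_sensorgram(k$ka, k$kd, 150, single_cycle_phases(),
                            noise_sd = 0.5, seed = 13)
  f <- fit_1to1_global(sg)
  expect_lt(abs(f$KD / (k$kd / k$ka) - 1), 0.05)
})

test_that("association-only single traces fail with a diagnostic", {
  sg <- simulate_sensorgram(6.7e5, 1.66e-4, 150,
                            data.frame(phase_id = 1, t_start = 0, t_end = 120,
                                       conc_M = 30e-9, kind = "association"))
  f <- fit_1to1_global(sg)
  expect_s3_class(f, "kinetic_fit_failure")
  expect_match(f$message, "unidentifiable|concentrations")
})

test_that("serum interference ratio classifies printed association rates as clean", {
  reg <- fixture_registry()$PCa62
  concs <- 300e-9 / 3^(0:6)
  mk <- function(ka, seed0) lapply(seq_along(concs), function(i)
    simulate_sensorgram(ka, reg$kinetics$kd, 1.2,
                        data.frame(phase_id = 1, t_start = 0, t_end = 300,
                                   conc_M = concs[i], kind = "association"),
                        noise_sd = 0.02, seed = seed0 + i))
  fb <- fit_1to1_global(mk(reg$serum$ka_buffer, 50))
  fs <- fit_1to1_global(mk(reg$serum$ka_serum, 80))
  r <- serum_interference_ratio(fb, fs)
  expect_equal(r$classification, "no interference")
  expect_gt(r$ratio, 0.99); expect_lt(r$ratio, 1.02)
  # identical fits give exactly 1; a halved serum rate is flagged
  expect_equal(serum_interference_ratio(fb, fb)$ratio, 1.0)
  fs_half <- fb; fs_half$ka <- fb$ka / 2
  r2 <- serum_interference_ratio(fb, fs_half)
  expect_equal(r2$ratio, 0.5)
  expect_equal(r2$classification, "interference")
})

test_that("phase validation rejects overlapping or mislabelled phases", {
  bad <- data.frame(phase_id = 1:2, t_start = c(0, 50), t_end = c(100, 150),
                    conc_M = c(1e-9, 0), kind = c("association", "dissociation"))
  expect_error(simulate_sensorgram(1e5, 1e-4, 100, bad), "tile")
  bad2 <- data.frame(phase_id = 1, t_start = 0, t_end = 100,
                     conc_M = 1e-9, kind = "dissociation")
  expect_error(simulate_sensorgram(1e5, 1e-4, 100, bad2), "zero concentration")
})

test_that("sensorgram CSV I/O round-trips trace and phase metadata", {
  sg <- simulate_sensorgram(6.7e5, 1.66e-4, 150,
                            single_cycle_phases(t_dissoc_final = 120), dt = 5)
  tmp <- tempfile(fileext = ".csv")
  write_sensorgram_csv(sg, tmp)
  back <- read_sensorgram_csv(tmp)
  expect_equal(back$response, sg$response)
  expect_equal(back$phases$conc_M, sg$phases$conc_M)
})
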