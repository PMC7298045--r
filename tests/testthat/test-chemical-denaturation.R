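pca75_pars <- function() list(dG1 = 24.3, m1 = 24.3 / 1.8)
pca62_pars <- function() list(dG1 = 63.5, m1 = 63.5 / 1.9,
                              dG2 = 37.2, m2 = 37.2 / 2.9)

test_that("two-state fraction unfolded follows the LEM closed form", {
  # half unfolded exactly at c50
  expect_equal(two_state_fraction_unfolded(1.8, 24.3, 24.3 / 1.8), 0.5)
  # closed-form value at zero denaturant
  RT <- 8.314e-3 * 298.15
  K0 <- exp(-24.3 / RT)
  expect_equal(two_state_fraction_unfolded(0, 24.3, 13.5), K0 / (1 + K0))
  expect_lt(two_state_fraction_unfolded(0, 24.3, 13.5), 1e-4)
  # monotone in c and in -dGu
  cgrid <- seq(0, 6, 0.1)
  expect_true(all(diff(two_state_fraction_unfolded(cgrid, 24.3, 13.5)) > 0))
  expect_true(all(diff(vapply(c(20, 24, 28, 32), function(dg)
    two_state_fraction_unfolded(1.5, dg, 13.5), numeric(1))) < 0))
  # large m with fixed c50 approaches a step at c50
  big <- two_state_fraction_unfolded(c(1.79, 1.81), 1.8 * 5000, 5000)
  expect_lt(big[1], 1e-3); expect_gt(big[2], 1 - 1e-3)
})

test_that("noise-free two-state fits recover the generating truth to 0.1%", {
  for (pars in list(pca75_pars(), list(dG1 = 34.8, m1 = 34.8 / 1.7),
                    list(dG1 = 42.5, m1 = 42.5 / 3.6))) {
    cv <- simulate_denaturation_curve("two_state", pars, noise_sd = 0)
    f <- fit_two_state(cv)
    expect_s3_class(f, "two_state_fit")
    expect_lt(abs(f$dG_u / pars$dG1 - 1), 0.001)
    expect_lt(abs(f$m_value / pars$m1 - 1), 0.001)
  }
})

test_that("two-state fit agrees with a brute-force SSE grid oracle", {
  conc <- seq(0, 6, length.out = 30)
  bn <- c(0.86, 0); bu <- c(1.10, 0)
  cv <- simulate_denaturation_curve("two_state", list(dG1 = 30, m1 = 15),
                                    concentrations = conc,
                                    native_baseline = bn,
                                    unfolded_baseline = bu, noise_sd = 0)
  dg_grid <- seq(20, 40, length.out = 200)
  m_grid <- seq(10, 20, length.out = 200)
  sse <- outer(dg_grid, m_grid, Vectorize(function(dg, m) {
    fu <- two_state_fraction_unfolded(conc, dg, m)
    sum(((1 - fu) * bn[1] + fu * bu[1] - cv$signal)^2)
  }))
  ij <- which(sse == min(sse), arr.ind = TRUE)[1, ]
  f <- fit_two_state(cv)
  # the fitted optimum lies within one lattice cell of the grid minimum
  expect_lt(abs(f$dG_u - dg_grid[ij[1]]), diff(dg_grid[1:2]) * 1.5)
  expect_lt(abs(f$m_value - m_grid[ij[2]]), diff(m_grid[1:2]) * 1.5)
})

test_that("flat curves yield an explicit failure, not a spurious fit", {
  flat <- list(concentrations = seq(0, 6, length.out = 30),
               signal = 0.9 + abstab:::withr_rnorm(3, 30, 0.002),
               temperature = 298.15)
  expect_s3_class(fit_two_state(flat), "icd_fit_failure")
  expect_equal(select_unfolding_model(flat)$model, "failed")
})

test_that("three-state populations are normalised and symmetric at K1 = 1", {
  p <- three_state_populations(seq(0, 6, 0.25), 63.5, 63.5 / 1.9, 37.2, 37.2 / 2.9)
  expect_true(all(abs(p$pN + p$pI + p$pU - 1) < 1e-12))
  # at the first midpoint with a negligible second step, pN = pI = 0.5
  p2 <- three_state_populations(2, 20, 10, 300, 1)
  expect_equal(p2$pN, 0.5, tolerance = 1e-9)
  expect_equal(p2$pI, 0.5, tolerance = 1e-9)
})

test_that("three-state signal matches an independent closed-form implementation", {
  pars <- pca62_pars()
  bn <- c(0.86, 0.004); bu <- c(1.10, -0.004)
  got <- three_state_signal(2.4, pars$dG1, pars$m1, pars$dG2, pars$m2,
                            bn, bu, 0.99)
  want <- three_state_signal_oracle(2.4, pars$dG1, pars$m1, pars$dG2, pars$m2,
                                    bn, bu, 0.99)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("noise-free three-state fits recover both transitions to 0.5%", {
  cv <- simulate_denaturation_curve("three_state", pca62_pars(),
                                    concentrations = seq(0, 6, length.out = 40),
                                    noise_sd = 0)
  f <- fit_three_state(cv)
  expect_equal(f$status, "ok")
  expect_lt(abs(f$dG1 / 63.5 - 1), 0.005)
  expect_lt(abs(f$dG2 / 37.2 - 1), 0.005)
  expect_lt(abs(f$c50_1 - 1.9), 0.01)
  expect_lt(abs(f$c50_2 - 2.9), 0.01)
})

test_that("fitting three states to two-state data is flagged non-identifiable", {
  cv <- simulate_denaturation_curve("two_state", pca75_pars(),
                                    noise_sd = 0.002, seed = 1)
  f <- fit_three_state(cv)
  expect_s3_class(f, "three_state_fit")
  expect_equal(f$status, "non_identifiable")
})

test_that("c50 * m = dG identity holds for every returned fit", {
  f2 <- fit_two_state(simulate_denaturation_curve("two_state", pca75_pars(),
                                                  noise_sd = 0.002, seed = 5))
  expect_lt(abs(f2$c50 * f2$m_value - f2$dG_u) / f2$dG_u, 1e-9)
  f3 <- fit_three_state(simulate_denaturation_curve("three_state", pca62_pars(),
                                                    concentrations = seq(0, 6, length.out = 40),
                                                    noise_sd = 0.002, seed = 5))
  expect_lt(abs(f3$c50_1 * f3$m1 - f3$dG1) / f3$dG1, 1e-9)
  expect_lt(abs(f3$c50_2 * f3$m2 - f3$dG2) / f3$dG2, 1e-9)
})

test_that("AICc model selection distinguishes one- from two-transition unfolders", {
  cv75 <- simulate_denaturation_curve("two_state", pca75_pars(),
                                      noise_sd = 0.002, seed = 8)
  cv62 <- simulate_denaturation_curve("three_state", pca62_pars(),
                                      concentrations = seq(0, 6, length.out = 40),
                                      noise_sd = 0.002, seed = 8)
  expect_equal(select_unfolding_model(cv75)$model, "two_state")
  expect_equal(select_unfolding_model(cv62)$model, "three_state")
})

test_that("noisy recovery sits inside the replicate-mean precision envelope", {
  # two-state: single noisy curve is already within +/-2 kJ/mol
  f <- fit_two_state(simulate_denaturation_curve("two_state", pca75_pars(),
                                                 noise_sd = 0.002, seed = 42))
  expect_lt(abs(f$dG_u - 24.3), 2)
  expect_lt(abs(f$c50 - 1.8), 0.2)
  # three-state: the triplicate-averaged assay protocol
  rep3 <- fit_icd_replicates("three_state", pca62_pars(), seed = 42,
                             concentrations = seq(0, 6, length.out = 40),
                             noise_sd = 0.002)
  expect_equal(rep3$n_ok, 3L)
  expect_lt(abs(rep3$mean[["c50_1"]] - 1.9), 0.2)
  expect_lt(abs(rep3$mean[["c50_2"]] - 2.9), 0.2)
})

test_that("curve CSV round trip preserves the measurements", {
  cv <- simulate_denaturation_curve("two_state", pca75_pars(), noise_sd = 0)
  tmp <- tempfile(fileext = ".csv")
  write_curve_csv(cv, tmp)
  back <- read_curve_csv(tmp)
  expect_equal(back$concentrations, cv$concentrations)
  expect_equal(back$signal, cv$signal)
})
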