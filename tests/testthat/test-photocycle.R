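test_that("photon flux converts power density correctly and linearly", {
  expect_equal(photon_flux(illumination(488, 0)), 0)
  # 488 nm photon energy hc/lambda = 4.07e-19 J
  expect_equal(photon_flux(illumination(488, 200)), 4.912e20,
               tolerance = 1e-3)
  f1 <- photon_flux(illumination(592, 123.4))
  f2 <- photon_flux(illumination(592, 246.8))
  expect_equal(f2, 2 * f1)
  expect_error(illumination(550, 100), "unsupported wavelength")
})

test_that("generator matrix has thermal entries in the dark and conserves", {
  p <- rsegfp2_params()
  K <- build_rate_matrix(p, list())
  # protonation of the trans anion: characteristic 50 us
  expect_equal(K["TH", "T_ANION"], 2e4)
  # no light-driven entries in the dark
  expect_equal(K["CH", "TH"], 0)
  expect_equal(K["T_ANION", "C_MINUS"], 0)
  # columns close to zero for arbitrary valid models/illuminations
  set.seed(42)
  for (i in 1:25) {
    Ki <- build_rate_matrix(random_params(), random_illums())
    expect_lt(max(abs(colSums(Ki))), 1e-9 * max(abs(Ki)))
    expect_true(all(Ki[row(Ki) != col(Ki)] >= 0))
    expect_true(all(Ki[, "BLEACHED"] == 0))
  }
})

test_that("C_MINUS outflow under 488 nm equals cross-section x flux x total yield", {
  p <- rsegfp2_params()
  il <- illumination(488, 300)
  K <- build_rate_matrix(p, list(il))
  expected <- sigma_488 <- p$sigma$C_MINUS[["488"]] * photon_flux(il) *
    (p$phi_off + p$phi_isc + p$phi_bleach_on)
  expect_equal(-K["C_MINUS", "C_MINUS"], expected, tolerance = 1e-12)
})

test_that("propagation is exact: identity at t=0, closed form for a pure decay", {
  p <- toy_off_params(phi_off = 0.01)
  il <- illumination(488, 200)
  K <- build_rate_matrix(p, list(il))
  p0 <- population()
  expect_identical(propagate(p0, K, 0), p0)
  k <- p$sigma$C_MINUS[["488"]] * photon_flux(il) * p$phi_off
  for (kt in c(0.1, 1, 5)) {
    t <- kt / k
    expect_equal(propagate(p0, K, t)[["C_MINUS"]], exp(-kt),
                 tolerance = 1e-9)
  }
})

test_that("propagator matches an adaptive ODE integrator on randomized models", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  for (i in 1:100) {
    prm <- random_params()
    K <- build_rate_matrix(prm, random_illums())
    p0 <- random_population()
    t <- exp(stats::runif(1, log(1e-6), log(0.05)))
    got <- propagate(p0, K, t)
    want <- ode_oracle(p0, K, t)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("propagation satisfies the semigroup property and conservation", {
  set.seed(99)
  for (i in 1:20) {
    prm <- random_params()
    K <- build_rate_matrix(prm, random_illums())
    p0 <- random_population()
    a <- stats::runif(1, 1e-5, 5e-3)
    b <- stats::runif(1, 1e-5, 5e-3)
    one <- propagate(p0, K, a + b)
    two <- propagate(propagate(p0, K, a), K, b)
    expect_lt(max(abs(one - two)), 1e-9)
    expect_equal(sum(one), 1, tolerance = 1e-9)
    expect_true(all(one >= -1e-12))
  }
})

test_that("expm fallback integral operator agrees with the spectral route", {
  p <- rsegfp2_params()
  K <- build_rate_matrix(p, list(illumination(488, 300)))
  ops <- rsfatigue:::make_ops(K)
  Jeig <- rsfatigue:::ops_integral(ops, 8e-4)
  Jexp <- rsfatigue:::ops_integral(list(type = "expm", K = K), 8e-4)
  expect_lt(max(abs(Jeig - Jexp)), 1e-9)
})

test_that("a dark window evolves populations by thermal rates only", {
  p <- rsegfp2_params()
  sch <- pulse_scheme(list(time_window(1e-3)))
  tr <- simulate_scheme(p, sch, p0 = population(c(T_ANION = 1)))
  fin <- final_population(tr)
  # protonation: 1 ms >> 50 us, essentially all in TH
  expect_equal(fin[["TH"]], 1, tolerance = 1e-8)
  expect_equal(max(tr$fluorescence_au), 0)
})

test_that("reduced model off-switches mono-exponentially at sigma*flux*phi_off", {
  p <- toy_off_params(phi_off = 0.008)
  il <- illumination(488, 500)
  k <- p$sigma$C_MINUS[["488"]] * photon_flux(il) * p$phi_off
  sch <- pulse_scheme(list(time_window(2 / k, il)))
  tr <- simulate_scheme(p, sch, n_per_window = 33)
  fl <- tr$fluorescence_au / tr$fluorescence_au[1]
  expect_equal(fl, exp(-k * tr$time_s), tolerance = 1e-8)
})

test_that("scheme end-state does not depend on within-window sampling", {
  p <- rsegfp2_params()
  sch <- fatigue_cycle()
  f1 <- final_population(simulate_scheme(p, sch, n_per_window = 2))
  f2 <- final_population(simulate_scheme(p, sch, n_per_window = 64))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("integrated fluorescence matches closed forms", {
  # static emitter: rectangle integral beta*sigma*flux*T
  p <- rate_params(sigma = list(C_MINUS = c("488" = 2e-16)),
                   phi_off = 0, phi_isc = 0, phi_on = 0, beta = 2)
  il <- illumination(488, 100)
  sch <- pulse_scheme(list(time_window(3e-3, il)))
  tr <- simulate_scheme(p, sch)
  expect_equal(integrated_fluorescence(tr),
               2 * 2e-16 * photon_flux(il) * 3e-3, tolerance = 1e-12)
  # all-dark trajectory integrates to zero
  dark <- simulate_scheme(p, pulse_scheme(list(time_window(1e-3))))
  expect_equal(integrated_fluorescence(dark), 0)
  # mono-exponential decay: beta*sigma*flux*(1 - exp(-kT))/k
  pd <- toy_off_params(phi_off = 0.01)
  ild <- illumination(488, 300)
  k <- pd$sigma$C_MINUS[["488"]] * photon_flux(ild) * pd$phi_off
  T <- 1.7 / k
  trd <- simulate_scheme(pd, pulse_scheme(list(time_window(T, ild))))
  expect_equal(integrated_fluorescence(trd),
               pd$sigma$C_MINUS[["488"]] * photon_flux(ild) *
                 (1 - exp(-k * T)) / k,
               tolerance = 1e-6)
  expect_error(integrated_fluorescence(trd, from = 0, to = 0), "empty")
})

test_that("fatigue-free limit cycles without loss", {
  p <- fatigue_free_params()
  curve <- run_fatigue(p, fatigue_cycle(), 50)
  s <- curve$signal / curve$signal[50]
  # near-steady from cycle 2, exactly periodic once the carry-over
  # populations have equilibrated
  expect_lt(max(abs(s[2:50] - 1)), 0.015)
  expect_lt(max(abs(s[8:50] - 1)), 1e-6)
})

test_that("off-switching shields the triplet state", {
  p <- rsegfp2_params()
  p0 <- population()
  il <- illumination(488, 300)
  long <- pulse_scheme(list(time_window(50e-3, il)))
  t1_with <- final_population(simulate_scheme(p, long, p0))[["T1"]]
  p_no <- p; p_no$phi_off <- 0
  t1_without <- final_population(simulate_scheme(p_no, long, p0))[["T1"]]
  expect_lt(t1_with, t1_without)
})

test_that("ensemble propagation agrees with a single-molecule Gillespie oracle", {
  p <- rsegfp2_params()
  sch <- pulse_scheme(list(
    time_window(1e-3, illumination(405, 160)),
    time_window(0.9e-3, illumination(488, 300)),
    time_window(10e-3)), repeats = 2)
  n_mol <- 10000
  emp <- gillespie_scheme(p, sch, n_mol = n_mol, seed = 314)
  det <- final_population(simulate_scheme(p, sch, n_per_window = 2))
  se <- sqrt(pmax(det * (1 - det), 1e-12) / n_mol)
  expect_true(all(abs(emp - det) <= 3 * se + 1e-9))
})

test_that("trajectories round-trip through CSV", {
  p <- rsegfp2_params()
  tr <- simulate_scheme(p, fatigue_cycle(), n_per_window = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(back$time_s, tr$time_s)
  expect_equal(back$fluorescence_au, tr$fluorescence_au)
  expect_equal(back$C_MINUS, tr$C_MINUS)
})
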