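test_that("ZZ curves obey the zero-mixing and no-exchange limits", {
  kin <- g399_kinetics()
  c0 <- zz_curves(kin, 1.5, delays = 0)
  expect_equal(c0$i_ab, 0)
  expect_equal(c0$i_ba, 0)
  # vanishing exchange: pure R1 decay, no cross peaks
  slow <- two_site_kinetics(1e-12, 1e-12)
  cs <- zz_curves(slow, 1.5, delays = c(0, 0.5, 1, 2), amplitudes = c(1, 1))
  expect_equal(cs$i_aa, exp(-1.5 * cs$delay), tolerance = 1e-9)
  expect_equal(cs$i_bb, exp(-1.5 * cs$delay), tolerance = 1e-9)
  expect_lt(max(abs(c(cs$i_ab, cs$i_ba))), 1e-9)
})

test_that("matrix-exponential propagation equals the equal-R1 closed form", {
  set.seed(3)
  for (i in 1:1000) {
    kin <- two_site_kinetics(10^runif(1, -2, 2), 10^runif(1, -2, 2))
    r1 <- 10^runif(1, -1, 1)
    delays <- sort(runif(4, 0, 2))
    amp <- runif(2, 0.5, 2)
    a <- zz_curves(kin, r1, delays = delays, amplitudes = amp)
    b <- zz_curves(kin, r1, delays = delays, amplitudes = amp, method = "closed")
    expect_equal(as.matrix(a[-1]), as.matrix(b[-1]), tolerance = 1e-10)
  }
})

test_that("total longitudinal magnetization decays with the R1 envelope", {
  kin <- g399_kinetics()
  delays <- seq(0, 2, by = 0.25)
  cur <- zz_curves(kin, 1.2, delays = delays, amplitudes = c(kin$p_a, kin$p_b))
  total <- cur$i_aa + cur$i_bb + cur$i_ab + cur$i_ba
  expect_equal(total, exp(-1.2 * delays), tolerance = 1e-10)
})

test_that("cross-peak build-up peaks at the closed-form optimal delay", {
  kin <- g399_kinetics()
  r1 <- 1.5
  t_star <- log((kin$k_ex + r1) / r1) / kin$k_ex
  delays <- seq(0.01, 2, by = 1e-4)
  cur <- zz_curves(kin, r1, delays = delays)
  expect_equal(delays[which.max(cur$i_ab)], t_star, tolerance = 1e-3)
})

test_that("noiseless ZZ fits are exact round trips", {
  kin <- g399_kinetics()
  z <- gen_zz(kin, r1 = 1.5)
  fit <- fit_zz(z$data)
  expect_equal(fit$kinetics$k_ex, 2.1, tolerance = 5e-3)
  expect_equal(fit$kinetics$p_a, 0.37, tolerance = 5e-3)
  expect_equal(unname(fit$r1), 1.5, tolerance = 5e-3)
  # symmetric truth recovers symmetric rates
  sym <- gen_zz(two_site_kinetics(1, 1), r1 = 1.0)
  fs <- fit_zz(sym$data)
  expect_equal(fs$kinetics$k_ab, fs$kinetics$k_ba, tolerance = 1e-6)
  # round trip holds for per-state R1 too
  ps <- zz_curves(kin, 1.2, 1.8, zz_fixture_delays())
  fps <- fit_zz(dplyr::mutate(ps, residue = "x"), share_r1 = FALSE)
  expect_equal(unname(fps$r1), c(1.2, 1.8), tolerance = 1e-3)
})

test_that("noisy replicates are well calibrated", {
  kin <- g399_kinetics()
  delays <- zz_fixture_delays()
  kex_hat <- numeric(300)
  se_kex <- numeric(300)
  for (i in seq_len(300)) {
    z <- gen_zz(kin, r1 = 1.5, delays = delays, noise_sd = 0.02, seed = 1000 + i)
    f <- suppressWarnings(fit_zz(z$data))
    kex_hat[i] <- f$kinetics$k_ex
    # delta method on log rates: var(kex) ~ grad' C grad with grad = (k_ab, k_ba)
    g <- c(f$kinetics$k_ab, f$kinetics$k_ba)
    se_kex[i] <- sqrt(drop(t(g) %*% f$covariance[1:2, 1:2] %*% g))
  }
  expect_lt(abs(median(kex_hat) - 2.1) / 2.1, 0.05)
  emp_sd <- sd(kex_hat)
  expect_gt(median(se_kex) / emp_sd, 0.5)
  expect_lt(median(se_kex) / emp_sd, 2)
})

test_that("detectability separates measurable from too-slow exchange", {
  obs <- zz_detectability(g399_kinetics(), r1 = 1.5)
  expect_true(obs$observable)
  slow <- zz_detectability(two_site_from_populations(0.37, 0.05), r1 = 1.5)
  expect_false(slow$observable)
  expect_lt(slow$max_crosspeak_fraction, 0.05)
  none <- zz_detectability(two_site_kinetics(1e-9, 1e-9), r1 = 1.5)
  expect_lt(none$max_crosspeak_fraction, 1e-8)
})

test_that("undetectable cross peaks abort the fit with a clear message", {
  slow <- two_site_from_populations(0.37, 0.01)
  z <- gen_zz(slow, r1 = 1.5, noise_sd = 0.02, seed = 5)
  expect_error(fit_zz(z$data), "too slow to quantify")
})
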