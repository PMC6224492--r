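hz_context <- function(sweep_ppm, points, bf = 70.95695) {
  spectrometer_context("15N", sweep = sweep_ppm, points = points,
                       base_frequency = bf)
}

two_site_hz <- function(delta_hz, k_ex, p_a, r2 = 10, bf = 70.95695,
                        center_ppm = 109) {
  kin <- two_site_from_populations(p_a = p_a, k_ex = k_ex)
  scheme_two_site(kin, shift_a = center_ppm, shift_b = center_ppm + delta_hz / bf,
                  r2 = r2)
}

test_that("a single state gives a Lorentzian of width R2/pi Hz", {
  bf <- 70.95695
  ctx <- hz_context(c(108, 110), 16384, bf)
  states <- exchange_state("A", "free-A", 109, r2 = 31.4)
  sch <- kinetic_scheme(states,
                        tibble::tibble(from = character(), to = character(),
                                       type = character(), rate = numeric()),
                        "TWO_SITE_ISO")
  sp <- simulate_lineshape(sch, ctx, populations = 1)
  peak <- which.max(sp$intensity)
  expect_equal(sp$ppm[peak], 109, tolerance = 1e-4)
  half <- max(sp$intensity) / 2
  above <- range(which(sp$intensity >= half))
  fwhm_hz <- (sp$ppm[above[2]] - sp$ppm[above[1]]) * bf
  expect_equal(fwhm_hz, 31.4 / pi, tolerance = 0.01)
})

test_that("fast exchange collapses to the population-weighted shift", {
  bf <- 70.95695
  sch <- two_site_hz(delta_hz = 100, k_ex = 1e5, p_a = 0.3)
  ctx <- hz_context(c(108, 111.5), 2^17, bf)
  sp <- simulate_lineshape(sch, ctx)
  peak_hz <- sp$ppm[which.max(sp$intensity)] * bf
  want_hz <- (0.3 * 109 + 0.7 * sch$states$shift[2]) * bf
  expect_lt(abs(peak_hz - want_hz), 0.1)
})

test_that("slow exchange gives resolved peaks with areas equal to populations", {
  # narrow lines, wide separation: negligible tail overlap across the midpoint
  sch <- two_site_hz(delta_hz = 200, k_ex = 0.1, p_a = 0.3, r2 = 5)
  ctx <- hz_context(c(99, 122), 2^15)
  sp <- simulate_lineshape(sch, ctx)
  mid <- mean(sch$states$shift)
  a_left <- trapz_spectrum(sp, -Inf, mid)
  a_right <- trapz_spectrum(sp, mid, Inf)
  expect_equal(a_left / (a_left + a_right), 0.3, tolerance = 0.01)
})

test_that("total integrated intensity is independent of the exchange rate", {
  areas <- vapply(c(1e-2, 1, 1e2, 1e4, 1e6), function(kex) {
    sch <- two_site_hz(delta_hz = 71, k_ex = kex, p_a = 0.37, r2 = 20)
    # wide sweep so the Lorentzian tails are captured
    ctx <- hz_context(c(60, 160), 2^14)
    trapz_spectrum(simulate_lineshape(sch, ctx))
  }, numeric(1))
  expect_lt(max(abs(areas / areas[1] - 1)), 0.005)
})

test_that("frequency-domain simulation matches time-domain FID propagation", {
  bf <- 70.95695
  # moderate-exchange two-site case
  kin <- two_site_from_populations(p_a = 0.37, k_ex = 40)
  sch <- scheme_two_site(kin, shift_a = 0.2, shift_b = 1.2, r2 = 15)
  ctx <- hz_context(c(-1.5, 3), 256, bf)
  fd <- simulate_lineshape(sch, ctx)
  td <- oracle_fid_spectrum(sch, ctx, c(kin$p_a, kin$p_b), t_max = 3, n_t = 6000)
  expect_lt(max(abs(fd$intensity - td$intensity)) / max(fd$intensity), 0.005)
})

test_that("symmetric two-site exchange coalesces at k_ex = pi * dnu / sqrt(2)", {
  count_maxima <- function(kex) {
    sch <- two_site_hz(delta_hz = 50, k_ex = kex, p_a = 0.5, r2 = 1)
    ctx <- hz_context(c(107.5, 111.2), 2^13)
    y <- simulate_lineshape(sch, ctx)$intensity
    n <- length(y)
    idx <- 1 + which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n])
    # merge peaks whose separating valley is shallower than 0.1% of the max
    # (a flat top produces floating-point micro-wiggles)
    while (length(idx) > 1) {
      valleys <- vapply(seq_len(length(idx) - 1), function(i) {
        min(y[idx[i]:idx[i + 1]])
      }, numeric(1))
      prom <- pmin(y[idx[-length(idx)]], y[idx[-1]]) - valleys
      i <- which.min(prom)
      if (prom[i] >= 1e-3 * max(y)) break
      drop <- if (y[idx[i]] < y[idx[i + 1]]) i else i + 1
      idx <- idx[-drop]
    }
    length(idx)
  }
  # the classic coalescence rate pi * dnu / sqrt(2) is the per-site jump
  # rate k_ab = k_ba; with k_ex = k_ab + k_ba the transition sits at 2 k_c
  k_c <- pi * 50 / sqrt(2)
  expect_equal(count_maxima(2 * 0.95 * k_c), 2)
  expect_equal(count_maxima(2 * 1.05 * k_c), 1)
})

test_that("the shipped slow-exchange fixture satisfies the regime criterion", {
  sch <- g399_scheme()
  kin <- g399_kinetics()
  delta_nu <- abs(diff(sch$states$shift)) * context_15n()$base_frequency
  expect_gte(delta_nu, 10 * kin$k_ex)
})

test_that("titration series limits behave physically", {
  ctx <- context_15n(512)
  u <- gw9662_trap220_scheme()
  ts <- simulate_titration(u, c(0, 0.5, 1, 2, 20), 200e-6, ctx)
  # ratio-0 point is exactly the ligand-free lineshape
  free_sp <- simulate_lineshape(u, ctx, free_ligand = 0, populations = c(1, 0))
  expect_equal(ts$spectrum[[1]]$intensity, free_sp$intensity)
  # at saturation the free-state peak is gone
  sat <- ts$spectrum[[5]]
  at_r <- which.min(abs(sat$ppm - 109))
  at_rp <- which.min(abs(sat$ppm - 109.8))
  expect_gt(sat$intensity[at_rp], 20 * sat$intensity[at_r])
  # 4-state scheme at saturation collapses onto bound-state peaks
  s4 <- t007_ncor1_scheme()
  ts4 <- simulate_titration(s4, c(0, 50), 200e-6, ctx)
  comp <- solve_binding_equilibrium(s4, 200e-6, 50 * 200e-6)
  expect_lt(sum(comp$populations[c("R", "R*")]), 0.01)
})

test_that("slow-dissociation peak areas track the bound fraction", {
  # k_off slow on the shift-difference scale: resolved free/bound peaks
  u <- scheme_u(shift_r = 108.5, shift_rp = 110.5, kd = 5e-6, k_off = 1,
                r2 = 15)
  ctx <- spectrometer_context("15N", sweep = c(100, 119), points = 2^14)
  for (ratio in c(0.4, 0.8)) {
    ts <- simulate_titration(u, c(0, ratio), 200e-6, ctx)
    sp <- ts$spectrum[[2]]
    bound_frac_area <- trapz_spectrum(sp, 109.5, Inf) / trapz_spectrum(sp)
    comp <- solve_binding_equilibrium(u, 200e-6, ratio * 200e-6)
    expect_equal(bound_frac_area, unname(comp$populations["RP"]),
                 tolerance = 0.02)
  }
})

test_that("assignment transfer recovers identity, tie-breaks and random maps", {
  ref <- tibble::tibble(label = c("G399", "V248", "I279"),
                        shift_h = c(8.1, 9.0, 7.4),
                        shift_n = c(109.5, 121.2, 115.8))
  obs <- ref[, c("shift_h", "shift_n")]
  out <- transfer_assignments(ref, obs)
  expect_equal(out$label, ref$label)
  expect_equal(out$distance, rep(0, 3))

  # equidistant in the combined metric, closer in 1H to the first
  ref2 <- tibble::tibble(label = c("a", "b"),
                         shift_h = c(8.00, 8.10),
                         shift_n = c(110.0, 110.5))
  # observed: dh to a = 0.05, dn = 0; to b: dh = 0.05, dn = 0.5 -> farther combined
  # make combined equal: to a dh=0.1 dn=0; to b dh=0.0 dn=0.5 (w=0.2 -> 0.1)
  obs2 <- tibble::tibble(shift_h = 8.10, shift_n = 110.0)
  out2 <- transfer_assignments(ref2, obs2, weight_n = 0.2)
  d_a <- 0.1; d_b <- sqrt(0 + (0.2 * 0.5)^2)
  expect_equal(d_a, d_b)
  expect_equal(out2$label, "b") # 1H distance 0 to b beats 0.1 to a

  # random 20-peak recovery under small perturbations, vs all-pairs oracle
  set.seed(21)
  for (rep in 1:5) {
    n <- 20
    ref3 <- tibble::tibble(label = sprintf("p%02d", 1:n),
                           shift_h = runif(n, 6, 10),
                           shift_n = runif(n, 105, 130))
    d_comb <- function(i, j) sqrt((ref3$shift_h[i] - ref3$shift_h[j])^2 +
                                  (0.2 * (ref3$shift_n[i] - ref3$shift_n[j]))^2)
    min_sep <- min(sapply(1:n, function(i) min(sapply(setdiff(1:n, i), d_comb, i = i))))
    pert <- 0.4 * min_sep / 2
    obs3 <- tibble::tibble(
      shift_h = ref3$shift_h + runif(n, -pert, pert) / sqrt(2),
      shift_n = ref3$shift_n + runif(n, -pert, pert) / (0.2 * sqrt(2)))
    out3 <- transfer_assignments(ref3, obs3)
    expect_equal(out3$label, ref3$label)
  }
})

test_that("assignments beyond the cutoff stay unassigned", {
  ref <- tibble::tibble(label = "x", shift_h = 8, shift_n = 110)
  obs <- tibble::tibble(shift_h = c(8.01, 9.5), shift_n = c(110, 125))
  out <- transfer_assignments(ref, obs, cutoff = 0.5)
  expect_equal(out$label, c("x", NA))
})
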