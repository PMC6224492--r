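test_that("two-site kinetics derives k_ex and populations by detailed balance", {
  kin <- two_site_kinetics(k_ab = 1.323, k_ba = 0.777)
  expect_equal(kin$k_ex, 2.1)
  expect_equal(kin$p_a, 0.37)
  expect_equal(kin$p_a + kin$p_b, 1)
  rt <- two_site_from_populations(p_a = 0.37, k_ex = 2.1)
  expect_equal(rt$k_ab, kin$k_ab)
  expect_error(two_site_kinetics(0, 1), "positive")
})

test_that("rate matrices conserve population and scale binding by free ligand", {
  sym <- scheme_two_site(two_site_kinetics(1, 1), 109, 110)
  expect_equal(unname(build_rate_matrix(sym)),
               matrix(c(-1, 1, 1, -1), 2, 2))

  u <- scheme_u(shift_r = 109, shift_rp = 110, kd = 1e-6, k_off = 1)
  k <- build_rate_matrix(u, free_ligand = 1e-6)
  expect_equal(k["RP", "R"], 1) # k_on * L = (1/1e-6) * 1e-6
  expect_equal(k["R", "RP"], 1)

  set.seed(42)
  for (topo in c("U", "U_RL", "U_R_RL")) {
    for (i in 1:5) {
      k <- build_rate_matrix(random_scheme(topo), free_ligand = 10^runif(1, -7, -4))
      expect_lt(max(abs(colSums(k))), 1e-12 * max(1, max(abs(k))))
      off <- k
      diag(off) <- 0
      expect_true(all(off >= 0))
    }
  }
})

test_that("invalid schemes are rejected with informative errors", {
  states <- dplyr::bind_rows(exchange_state("A", "free-A", 109),
                             exchange_state("B", "free-B", 110))
  edges <- tibble::tibble(from = c("A", "B"), to = c("B", "A"),
                          type = "first_order", rate = c(-1, 1))
  expect_error(kinetic_scheme(states, edges, "TWO_SITE_ISO"), "A -> B")
  expect_error(exchange_state("A", "free-A", 109, r1 = 0), "r1")
  # binding edge without reverse
  st_u <- dplyr::bind_rows(exchange_state("R", "free-A", 109),
                           exchange_state("RP", "bound-A", 110))
  e_u <- tibble::tibble(from = "R", to = "RP", type = "binding", rate = 1e6)
  expect_error(kinetic_scheme(st_u, e_u, "U"), "reverse")
})

test_that("equilibrium populations solve the null space", {
  expect_equal(unname(equilibrium_populations(matrix(c(-1, 1, 1, -1), 2))),
               c(0.5, 0.5))
  k <- build_rate_matrix(scheme_two_site(two_site_kinetics(1.323, 0.777), 109, 110))
  expect_equal(unname(equilibrium_populations(k)), c(0.37, 0.63))
  # three-state chain, all rates 1
  chain <- matrix(c(-1, 1, 0, 1, -2, 1, 0, 1, -1), 3, 3)
  expect_equal(unname(equilibrium_populations(chain)), rep(1 / 3, 3))
  # disconnected scheme rejected
  expect_error(equilibrium_populations(matrix(0, 2, 2)), "reducible")
})

test_that("equilibrium populations are fixed points of the propagator", {
  set.seed(7)
  for (i in 1:5) {
    sch <- random_scheme("U_R_RL")
    lig <- 10^runif(1, -7, -4)
    k <- build_rate_matrix(sch, lig)
    p <- equilibrium_populations(k)
    for (t in c(0.01, 1, 100)) {
      prop <- as.matrix(Matrix::expm(k * t))
      expect_equal(unname(prop %*% p), matrix(p, ncol = 1), tolerance = 1e-9)
    }
  }
})

test_that("a four-state cycle violating closure is rejected", {
  good <- t007_ncor1_scheme()
  bad_edges <- good$edges
  i <- which(bad_edges$from == "R*P" & bad_edges$to == "RP")
  bad_edges$rate[i] <- bad_edges$rate[i] * 1.01
  expect_error(kinetic_scheme(good$states, bad_edges, "U_R_RL"), "cycle closure")
  # the constructor closes the cycle by computing that rate itself
  expect_silent(kinetic_scheme(good$states, good$edges, "U_R_RL"))
})

test_that("binding equilibrium matches closed forms in the limits", {
  u <- scheme_u(shift_r = 109, shift_rp = 110, kd = 1e-6, k_off = 10)
  # no peptide: all receptor free
  c0 <- solve_binding_equilibrium(u, 200e-6, 0)
  expect_equal(unname(c0$populations), c(1, 0))
  # equal totals at Kd: quadratic closed form for the bound fraction
  tot <- 1e-6
  cb <- solve_binding_equilibrium(u, tot, tot)
  ktil <- 1e-6 / tot
  expect_equal(unname(cb$populations["RP"]),
               (2 + ktil - sqrt(ktil^2 + 4 * ktil)) / 2, tolerance = 1e-8)
  # saturation: free states vanish
  cs <- solve_binding_equilibrium(u, 200e-6, 1)
  expect_lt(cs$populations["R"], 1e-3)
  # free-state partition at zero ligand follows the isomerization equilibrium
  s4 <- t007_ncor1_scheme()
  f0 <- solve_binding_equilibrium(s4, 200e-6, 0)
  expect_equal(unname(f0$populations[c("R", "R*")]), c(0.37, 0.63))
})

test_that("binding equilibrium agrees with the fixed-point oracle on random draws", {
  set.seed(11)
  for (i in 1:100) {
    topo <- sample(c("U", "U_RL", "U_R_RL"), 1)
    sch <- random_scheme(topo)
    rt <- 10^runif(1, -5, -3)
    pt <- rt * runif(1, 0, 3)
    got <- solve_binding_equilibrium(sch, rt, pt)
    want <- oracle_binding_equilibrium(sch, rt, pt)
    expect_equal(got$free_ligand, want$free_ligand,
                 tolerance = 1e-6, label = sprintf("free ligand draw %d (%s)", i, topo))
    expect_equal(unname(got$populations), unname(want$populations),
                 tolerance = 1e-6)
    # both mass balances
    bound <- sch$states$role %in% c("bound-A", "bound-B")
    expect_lt(abs(sum(got$species) - rt), 1e-9 * rt)
    expect_lt(abs(got$free_ligand + sum(got$species[bound]) - pt),
              1e-9 * max(pt, rt))
  }
})
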