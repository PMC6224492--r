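#' Two-site exchange kinetics
#'
#' Microscopic rates for reversible two-site interconversion A <-> B in the
#' slow-exchange regime, together with the derived quantities used throughout
#' the package: the exchange rate `k_ex = k_ab + k_ba` and the equilibrium
#' fractions `p_a = k_ba / k_ex`, `p_b = k_ab / k_ex` (detailed balance).
#'
#' @param k_ab Forward rate A -> B, 1/s. Must be > 0.
#' @param k_ba Reverse rate B -> A, 1/s. Must be > 0.
#' @return An object of class `two_site_kinetics`: a list with elements
#'   `k_ab`, `k_ba`, `k_ex`, `p_a`, `p_b`.
#' @examples
#' two_site_kinetics(k_ab = 1.323, k_ba = 0.777) # p_a = 0.37, k_ex = 2.1
#' @export
two_site_kinetics <- function(k_ab, k_ba) {
  stopifnot(is.numeric(k_ab), is.numeric(k_ba), length(k_ab) == 1, length(k_ba) == 1)
  if (!is.finite(k_ab) || !is.finite(k_ba) || k_ab <= 0 || k_ba <= 0) {
    rlang::abort("`k_ab` and `k_ba` must be finite and > 0 (k_ex must be positive).")
  }
  k_ex <- k_ab + k_ba
  structure(
    list(k_ab = k_ab, k_ba = k_ba, k_ex = k_ex,
         p_a = k_ba / k_ex, p_b = k_ab / k_ex),
    class = "two_site_kinetics"
  )
}

#' @rdname two_site_kinetics
#' @param p_a Equilibrium fraction of state A (0 < p_a < 1).
#' @param k_ex Exchange rate `k_ab + k_ba`, 1/s.
#' @export
two_site_from_populations <- function(p_a, k_ex) {
  stopifnot(p_a > 0, p_a < 1, k_ex > 0)
  two_site_kinetics(k_ab = (1 - p_a) * k_ex, k_ba = p_a * k_ex)
}

#' @export
print.two_site_kinetics <- function(x, ...) {
  cat(sprintf(
    "Two-site exchange: k_ex = %.4g /s  (k_ab = %.4g, k_ba = %.4g)\n  populations: p_a = %.4f, p_b = %.4f\n",
    x$k_ex, x$k_ab, x$k_ba, x$p_a, x$p_b))
  invisible(x)
}

state_roles <- c("free-A", "free-B", "bound-A", "bound-B")

#' Define an exchange state
#'
#' One conformational/ligation state of the receptor: a label, its role in
#' the binding-isomerization topology, its chemical shift and relaxation
#' rates. Roles map the receptor species R, R*, RP, R*P onto
#' free/bound x A/B.
#'
#' @param label Short unique identifier (e.g. "R", "R*P").
#' @param role One of `"free-A"`, `"free-B"`, `"bound-A"`, `"bound-B"`.
#' @param shift Chemical shift, ppm.
#' @param r1 Longitudinal relaxation rate, 1/s (> 0).
#' @param r2 Transverse relaxation rate, 1/s (> 0).
#' @return A one-row tibble usable as a row of a scheme's state table.
#' @export
exchange_state <- function(label, role, shift, r1 = 1.5, r2 = 30) {
  role <- match.arg(role, state_roles)
  if (!is.finite(r1) || r1 <= 0) rlang::abort(sprintf("state '%s': r1 must be > 0", label))
  if (!is.finite(r2) || r2 <= 0) rlang::abort(sprintf("state '%s': r2 must be > 0", label))
  tibble::tibble(label = as.character(label), role = role,
                 shift = as.numeric(shift), r1 = as.numeric(r1), r2 = as.numeric(r2))
}

scheme_topologies <- c("TWO_SITE_ISO", "U", "U_RL", "U_R_RL")

#' Assemble a kinetic scheme
#'
#' A kinetic scheme is the exchange topology used by the lineshape and
#' equilibrium machinery: an ordered set of states plus directed rate-law
#' edges. Edges are either first-order (isomerization or dissociation,
#' rate in 1/s) or binding (association, rate constant in 1/M/s, which is
#' scaled by the free-ligand concentration when the rate matrix is built).
#'
#' Invariants enforced: nonnegative rates, unique state labels, every
#' binding edge paired with a reverse first-order edge, and for the
#' four-state `U_R_RL` topology thermodynamic cycle closure (the product of
#' equilibrium constants around the cycle must equal 1 within 1e-6).
#'
#' @param states Tibble of states, rows from [exchange_state()].
#' @param edges Tibble with columns `from`, `to` (state labels),
#'   `type` (`"first_order"` or `"binding"`), `rate`.
#' @param topology One of `"TWO_SITE_ISO"`, `"U"`, `"U_RL"`, `"U_R_RL"`.
#' @return An object of class `kinetic_scheme`.
#' @seealso [scheme_two_site()], [scheme_u()], [scheme_u_rl()],
#'   [scheme_u_r_rl()] for convenience constructors.
#' @export
kinetic_scheme <- function(states, edges, topology) {
  topology <- match.arg(topology, scheme_topologies)
  states <- tibble::as_tibble(states)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("label", "role", "shift", "r1", "r2") %in% names(states)),
            all(c("from", "to", "type", "rate") %in% names(edges)))
  if (anyDuplicated(states$label)) {
    rlang::abort("state labels must be unique within a scheme")
  }
  if (any(states$r1 <= 0) || any(states$r2 <= 0)) {
    rlang::abort("all states must have r1 > 0 and r2 > 0")
  }
  bad <- which(!is.finite(edges$rate) | edges$rate < 0)
  if (length(bad)) {
    rlang::abort(sprintf("negative or non-finite rate constant on edge %s -> %s",
                         edges$from[bad[1]], edges$to[bad[1]]))
  }
  unknown <- setdiff(c(edges$from, edges$to), states$label)
  if (length(unknown)) {
    rlang::abort(sprintf("edge references unknown state '%s'", unknown[1]))
  }
  if (!all(edges$type %in% c("first_order", "binding"))) {
    rlang::abort("edge type must be 'first_order' or 'binding'")
  }
  # every binding edge needs a reverse (dissociation) edge
  for (i in which(edges$type == "binding")) {
    rev <- edges$from == edges$to[i] & edges$to == edges$from[i] & edges$type == "first_order"
    if (!any(rev)) {
      rlang::abort(sprintf("binding edge %s -> %s has no reverse dissociation edge",
                           edges$from[i], edges$to[i]))
    }
  }
  scheme <- structure(list(states = states, edges = edges, topology = topology),
                      class = "kinetic_scheme")
  if (topology == "U_R_RL") .check_cycle_closure(scheme)
  scheme
}

# product of equilibrium constants around the 4-state cycle must be 1
.check_cycle_closure <- function(scheme, tol = 1e-6) {
  k <- function(from, to) {
    e <- scheme$edges
    i <- which(e$from == from & e$to == to)
    if (!length(i)) rlang::abort(sprintf("U_R_RL scheme is missing edge %s -> %s", from, to))
    e$rate[i[1]]
  }
  lab <- function(role) scheme$states$label[scheme$states$role == role][1]
  r <- lab("free-A"); rs <- lab("free-B"); rp <- lab("bound-A"); rsp <- lab("bound-B")
  prod_k <- (k(r, rs) / k(rs, r)) * (k(rs, rsp) / k(rsp, rs)) *
    (k(rsp, rp) / k(rp, rsp)) * (k(rp, r) / k(r, rp))
  if (abs(prod_k - 1) > tol) {
    rlang::abort(sprintf(
      "thermodynamic cycle closure violated: equilibrium-constant product around the R/R*/RP/R*P cycle is %.6g (must be 1 within %g)",
      prod_k, tol))
  }
  invisible(TRUE)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("Kinetic scheme [%s], %d states, %d edges\n",
              x$topology, nrow(x$states), nrow(x$edges)))
  print(x$states)
  invisible(x)
}

#' Two-site isomerization scheme
#'
#' The minimal scheme for slow interconversion between two free-receptor
#' conformations (no ligand), e.g. the doubled G399 amide peaks.
#'
#' @param kinetics A [two_site_kinetics()] object.
#' @param shift_a,shift_b Chemical shifts of states A and B, ppm.
#' @param r1,r2 Relaxation rates shared by both states, 1/s.
#' @export
scheme_two_site <- function(kinetics, shift_a, shift_b, r1 = 1.5, r2 = 30) {
  states <- dplyr::bind_rows(
    exchange_state("A", "free-A", shift_a, r1, r2),
    exchange_state("B", "free-B", shift_b, r1, r2))
  edges <- tibble::tibble(
    from = c("A", "B"), to = c("B", "A"),
    type = "first_order", rate = c(kinetics$k_ab, kinetics$k_ba))
  kinetic_scheme(states, edges, "TWO_SITE_ISO")
}

#' Two-state binding scheme (U)
#'
#' Simple binding R + P <-> RP with no receptor isomerization.
#'
#' @param shift_r,shift_rp Shifts of the free and bound states, ppm.
#' @param kd Dissociation constant, M.
#' @param k_off Dissociation rate, 1/s (association rate is `k_off / kd`).
#' @param r1,r2 Relaxation rates, 1/s.
#' @param r2_rp Optional distinct bound-state R2 (defaults to `r2`).
#' @export
scheme_u <- function(shift_r, shift_rp, kd, k_off, r1 = 1.5, r2 = 30, r2_rp = r2) {
  states <- dplyr::bind_rows(
    exchange_state("R", "free-A", shift_r, r1, r2),
    exchange_state("RP", "bound-A", shift_rp, r1, r2_rp))
  edges <- tibble::tibble(
    from = c("R", "RP"), to = c("RP", "R"),
    type = c("binding", "first_order"), rate = c(k_off / kd, k_off))
  kinetic_scheme(states, edges, "U")
}

#' Three-state binding scheme (U_RL)
#'
#' Binding followed by isomerization of the bound receptor:
#' R + P <-> RP <-> R*P.
#'
#' @param shift_r,shift_rp,shift_rsp Shifts of R, RP, R*P, ppm.
#' @param kd Dissociation constant for R + P <-> RP, M.
#' @param k_off Dissociation rate, 1/s.
#' @param k_iso_f,k_iso_b Bound-state isomerization rates RP -> R*P and
#'   back, 1/s.
#' @param r1,r2 Relaxation rates, 1/s.
#' @export
scheme_u_rl <- function(shift_r, shift_rp, shift_rsp, kd, k_off,
                        k_iso_f, k_iso_b, r1 = 1.5, r2 = 30) {
  states <- dplyr::bind_rows(
    exchange_state("R", "free-A", shift_r, r1, r2),
    exchange_state("RP", "bound-A", shift_rp, r1, r2),
    exchange_state("R*P", "bound-B", shift_rsp, r1, r2))
  edges <- tibble::tibble(
    from = c("R", "RP", "RP", "R*P"),
    to = c("RP", "R", "R*P", "RP"),
    type = c("binding", "first_order", "first_order", "first_order"),
    rate = c(k_off / kd, k_off, k_iso_f, k_iso_b))
  kinetic_scheme(states, edges, "U_RL")
}

#' Four-state binding-isomerization scheme (U_R_RL)
#'
#' Both free-receptor conformations bind ligand and the receptor
#' isomerizes in the free and bound ligation states:
#' R <-> R*, R + P <-> RP, R* + P <-> R*P, RP <-> R*P.
#' The reverse bound-isomerization rate (R*P -> RP) is computed from the
#' other seven rate constants so that the thermodynamic cycle closes
#' exactly; it is not an independent parameter.
#'
#' @param shift_r,shift_rs,shift_rp,shift_rsp Shifts of R, R*, RP, R*P, ppm.
#' @param k_ab,k_ba Free-receptor isomerization rates R -> R* and back,
#'   1/s (typically fixed from a ZZ-exchange fit).
#' @param kd_r,k_off_r Binding constants of the A conformation (R <-> RP).
#' @param kd_rs,k_off_rs Binding constants of the B conformation (R* <-> R*P).
#' @param k_bound_f Bound isomerization forward rate RP -> R*P, 1/s.
#' @param r1,r2 Relaxation rates, 1/s.
#' @export
scheme_u_r_rl <- function(shift_r, shift_rs, shift_rp, shift_rsp,
                          k_ab, k_ba, kd_r, k_off_r, kd_rs, k_off_rs,
                          k_bound_f, r1 = 1.5, r2 = 30) {
  k_on_r <- k_off_r / kd_r
  k_on_rs <- k_off_rs / kd_rs
  # cycle closure: (k_ab/k_ba)(k_on_rs/k_off_rs)(k_bound_b/k_bound_f)(k_off_r/k_on_r) = 1
  k_bound_b <- k_bound_f * (k_ba / k_ab) * (k_off_rs / k_on_rs) * (k_on_r / k_off_r)
  states <- dplyr::bind_rows(
    exchange_state("R", "free-A", shift_r, r1, r2),
    exchange_state("R*", "free-B", shift_rs, r1, r2),
    exchange_state("RP", "bound-A", shift_rp, r1, r2),
    exchange_state("R*P", "bound-B", shift_rsp, r1, r2))
  edges <- tibble::tibble(
    from = c("R", "R*", "R", "RP", "R*", "R*P", "RP", "R*P"),
    to = c("R*", "R", "RP", "R", "R*P", "R*", "R*P", "RP"),
    type = c("first_order", "first_order", "binding", "first_order",
             "binding", "first_order", "first_order", "first_order"),
    rate = c(k_ab, k_ba, k_on_r, k_off_r, k_on_rs, k_off_rs,
             k_bound_f, k_bound_b))
  kinetic_scheme(states, edges, "U_R_RL")
}

#' Build the first-order rate matrix of a scheme
#'
#' Returns the generator matrix K (1/s) of the scheme at a given
#' free-ligand concentration, with the convention dp/dt = K p:
#' `K[j, i]` is the rate i -> j, diagonal entries make every column sum to
#' zero (population conservation). Binding edges contribute the
#' pseudo-first-order rate `k_on * free_ligand`.
#'
#' @param scheme A [kinetic_scheme()].
#' @param free_ligand Free-ligand concentration, M (>= 0).
#' @return A square numeric matrix with state labels as dimnames.
#' @export
build_rate_matrix <- function(scheme, free_ligand = 0) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.finite(free_ligand) || free_ligand < 0) {
    rlang::abort("`free_ligand` must be a nonnegative concentration in M")
  }
  cc <- .scheme_cache(scheme)
  k <- .rate_matrix_fast(cc, free_ligand)
  dimnames(k) <- list(cc$labs, cc$labs)
  k
}

# plain-vector view of a scheme for hot loops (the tibble row access in
# the obvious implementation dominates fit runtime otherwise)
.scheme_cache <- function(scheme) {
  labs <- scheme$states$label
  e <- scheme$edges
  list(labs = labs, n = length(labs),
       from = match(e$from, labs), to = match(e$to, labs),
       rate = e$rate, is_bind = e$type == "binding",
       bound = scheme$states$role %in% c("bound-A", "bound-B"),
       shift = scheme$states$shift, r2 = scheme$states$r2)
}

.rate_matrix_fast <- function(cc, free_ligand) {
  r <- cc$rate
  r[cc$is_bind] <- r[cc$is_bind] * free_ligand
  k <- matrix(0, cc$n, cc$n)
  for (i in seq_along(r)) k[cc$to[i], cc$from[i]] <- k[cc$to[i], cc$from[i]] + r[i]
  diag(k) <- -colSums(k)
  k
}

# null-space solve without the validity checks of the public function
.eq_pops_fast <- function(k) {
  n <- nrow(k)
  a <- k
  a[n, ] <- 1
  p <- solve(a, c(rep(0, n - 1), 1))
  p <- pmax(p, 0)
  p / sum(p)
}

.pops_at_ligand_fast <- function(cc, free_l) {
  if (free_l <= 0 && any(cc$is_bind) && any(cc$bound)) {
    p <- numeric(cc$n)
    free_idx <- which(!cc$bound)
    if (length(free_idx) == 1L) {
      p[free_idx] <- 1
    } else {
      kf <- .rate_matrix_fast(cc, 0)[free_idx, free_idx, drop = FALSE]
      diag(kf) <- 0
      diag(kf) <- -colSums(kf)
      p[free_idx] <- .eq_pops_fast(kf)
    }
    return(p)
  }
  .eq_pops_fast(.rate_matrix_fast(cc, free_l))
}

# core of solve_binding_equilibrium on a scheme cache; returns free
# ligand and populations
.solve_equilibrium_cached <- function(cc, receptor_total, peptide_total) {
  if (!any(cc$is_bind) || peptide_total == 0 || receptor_total == 0) {
    free_l <- if (!any(cc$is_bind) || receptor_total == 0) peptide_total else 0
    return(list(free_ligand = free_l, populations = .pops_at_ligand_fast(cc, free_l)))
  }
  f <- function(free_l) {
    free_l + receptor_total * sum(.pops_at_ligand_fast(cc, free_l)[cc$bound]) -
      peptide_total
  }
  root <- stats::uniroot(f, lower = 0, upper = peptide_total,
                         tol = 1e-10 * peptide_total, maxiter = 200)
  free_l <- root$root
  # Newton polish for the tight mass-balance contract
  for (it in 1:40) {
    res <- f(free_l)
    if (abs(res) <= 1e-13 * max(peptide_total, receptor_total)) break
    h <- max(free_l, peptide_total) * 1e-7
    lo <- min(h, free_l)
    d <- (f(free_l + h) - f(free_l - lo)) / (h + lo)
    free_l <- min(max(free_l - res / d, 0), peptide_total)
  }
  if (abs(f(free_l)) > 1e-9 * max(peptide_total, receptor_total)) {
    rlang::abort(sprintf(
      "binding equilibrium did not converge: peptide mass-balance residual %.3g M",
      f(free_l)))
  }
  list(free_ligand = free_l, populations = .pops_at_ligand_fast(cc, free_l))
}

#' Equilibrium populations of a rate matrix
#'
#' Solves K p = 0 with sum(p) = 1 for the generator matrix of an
#' irreducible scheme.
#'
#' @param rate_matrix Square generator matrix with zero column sums
#'   (from [build_rate_matrix()]).
#' @return Named numeric vector of populations (nonnegative, sums to 1).
#' @export
equilibrium_populations <- function(rate_matrix) {
  k <- as.matrix(rate_matrix)
  n <- nrow(k)
  stopifnot(n == ncol(k))
  if (max(abs(colSums(k))) > 1e-8 * max(1, max(abs(k)))) {
    rlang::abort("rate matrix columns must sum to zero")
  }
  if (!.is_connected(k)) {
    rlang::abort("scheme is reducible (disconnected states); equilibrium populations are not unique")
  }
  a <- k
  a[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  p <- solve(a, b)
  p[p < 0 & p > -1e-12] <- 0
  if (any(p < 0)) rlang::abort("negative equilibrium population; scheme is ill-conditioned")
  p / sum(p)
}

# undirected connectivity over positive off-diagonal rates
.is_connected <- function(k) {
  n <- nrow(k)
  adj <- (k > 0) | t(k > 0)
  diag(adj) <- FALSE
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# equilibrium populations at a fixed free-ligand concentration; at zero
# ligand the bound states are unreachable, so the free sub-scheme is solved
.populations_at_ligand <- function(scheme, free_l) {
  cc <- .scheme_cache(scheme)
  stats::setNames(.pops_at_ligand_fast(cc, free_l), cc$labs)
}

#' Solve the coupled binding-isomerization equilibrium
#'
#' Given total receptor and peptide concentrations, finds the free-ligand
#' concentration and per-state species concentrations that satisfy all
#' mass-action equilibria of the scheme simultaneously (receptor and
#' peptide mass balances hold to better than 1e-9 relative). Used as the
#' composition engine for titration forward models.
#'
#' @param scheme A [kinetic_scheme()] whose topology involves binding
#'   (`U`, `U_RL`, `U_R_RL`), or a ligand-free scheme (then all receptor is
#'   distributed among free states).
#' @param receptor_total,peptide_total Total concentrations, M (>= 0).
#' @return An object of class `mixture_composition`: list with `totals`,
#'   `free_ligand` (M), `species` (named vector, M), `populations`
#'   (species / receptor_total).
#' @export
solve_binding_equilibrium <- function(scheme, receptor_total, peptide_total) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (receptor_total < 0 || peptide_total < 0) {
    rlang::abort("totals must be nonnegative concentrations in M")
  }
  cc <- .scheme_cache(scheme)
  sol <- .solve_equilibrium_cached(cc, receptor_total, peptide_total)
  p <- stats::setNames(sol$populations, cc$labs)
  comp <- list(
    totals = c(receptor = receptor_total, peptide = peptide_total),
    free_ligand = sol$free_ligand, species = p * receptor_total,
    populations = p)
  class(comp) <- "mixture_composition"
  comp
}

#' @export
print.mixture_composition <- function(x, ...) {
  cat(sprintf("Mixture: receptor %.3g M, peptide %.3g M, free ligand %.4g M\n",
              x$totals["receptor"], x$totals["peptide"], x$free_ligand))
  print(round(x$populations, 6))
  invisible(x)
}
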