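# Independent oracles used across the suite. These deliberately take the
# dumb, direct route (fixed-point iteration, step-wise propagation + DFT,
# all-triplet loops) so they share no code path with the implementation.

# brute-force mass-action oracle: species concentrations from products
# of equilibrium constants along edge paths (no rate-matrix null space),
# free ligand by bisection on the peptide mass balance
oracle_binding_equilibrium <- function(scheme, receptor_total, peptide_total) {
  labs <- scheme$states$label
  bound <- scheme$states$role %in% c("bound-A", "bound-B")
  e <- scheme$edges
  rel_at <- function(free_l) {
    rel <- stats::setNames(rep(NA_real_, length(labs)), labs)
    rel[1] <- 1
    repeat {
      progressed <- FALSE
      for (i in seq_len(nrow(e))) {
        from <- e$from[i]; to <- e$to[i]
        if (is.na(rel[from]) || !is.na(rel[to])) next
        kf <- if (e$type[i] == "binding") e$rate[i] * free_l else e$rate[i]
        j <- which(e$from == to & e$to == from)
        kr <- if (e$type[j[1]] == "binding") e$rate[j[1]] * free_l else e$rate[j[1]]
        if (kr > 0) {
          rel[to] <- rel[from] * kf / kr
          progressed <- TRUE
        }
      }
      if (!progressed || !anyNA(rel)) break
    }
    rel[is.na(rel)] <- 0
    rel
  }
  bal <- function(free_l) {
    rel <- rel_at(free_l)
    free_l + receptor_total * sum(rel[bound]) / sum(rel) - peptide_total
  }
  lo <- 0
  hi <- peptide_total
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (bal(mid) > 0) hi <- mid else lo <- mid
  }
  free_l <- (lo + hi) / 2
  rel <- rel_at(free_l)
  pops <- rel / sum(rel)
  list(free_ligand = free_l, populations = pops,
       species = pops * receptor_total)
}

# time-domain route to the spectrum: propagate the FID step by step with
# Matrix::expm and Fourier-transform by direct summation (half-weighted
# first point)
oracle_fid_spectrum <- function(scheme, context, populations,
                                free_ligand = 0, t_max = 4, n_t = 8192) {
  k <- build_rate_matrix(scheme, free_ligand)
  nu <- scheme$states$shift * context$base_frequency
  lambda <- diag(2i * pi * nu - scheme$states$r2, nrow = length(nu)) + k
  dt <- t_max / (n_t - 1)
  # complex propagator via the real 2n x 2n augmented representation
  n_s <- nrow(lambda)
  aug <- rbind(cbind(Re(lambda), -Im(lambda)), cbind(Im(lambda), Re(lambda)))
  g_aug <- as.matrix(Matrix::expm(aug * dt))
  m <- c(populations, rep(0, n_s))
  fid <- complex(n_t)
  fid[1] <- sum(populations)
  for (n in 2:n_t) {
    m <- g_aug %*% m
    fid[n] <- complex(real = sum(m[1:n_s]), imaginary = sum(m[(n_s + 1):(2 * n_s)]))
  }
  ppm <- seq(context$sweep[1], context$sweep[2], length.out = context$points)
  freq <- ppm * context$base_frequency
  tt <- (seq_len(n_t) - 1) * dt
  intensity <- vapply(freq, function(f) {
    w <- exp(-2i * pi * f * tt)
    Re(dt * (sum(w * fid) - 0.5 * fid[1]))
  }, numeric(1))
  tibble::tibble(ppm = ppm, intensity = intensity)
}

# trapezoid integral of a spectrum (optionally over a ppm window)
trapz_spectrum <- function(spectrum, lo = -Inf, hi = Inf) {
  keep <- spectrum$ppm >= lo & spectrum$ppm <= hi
  x <- spectrum$ppm[keep]
  y <- spectrum$intensity[keep]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# brute-force hydrogen-bond detection: loop over every (heavy, H, heavy)
# triple with its own donor bookkeeping
oracle_hbonds <- function(frame, max_dist = 3.5, min_angle = 100) {
  out <- list()
  no <- which(frame$element %in% c("N", "O"))
  hs <- which(frame$element == "H")
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  for (d in no) {
    for (h in hs) {
      if (sqrt(sum((xyz[d, ] - xyz[h, ])^2)) >= 1.2) next
      for (a in no) {
        if (a == d) next
        dda <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
        if (dda > max_dist) next
        v1 <- xyz[d, ] - xyz[h, ]
        v2 <- xyz[a, ] - xyz[h, ]
        ang <- acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
        if (ang >= min_angle) {
          out[[length(out) + 1]] <- c(d = d, h = h, a = a)
        }
      }
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 3))
  unique(do.call(rbind, out))
}

# random valid scheme generator for property tests
random_scheme <- function(topology = c("U", "U_RL", "U_R_RL")) {
  topology <- match.arg(topology)
  r2 <- stats::runif(1, 10, 40)
  switch(topology,
    U = scheme_u(shift_r = stats::runif(1, 105, 112),
                 shift_rp = stats::runif(1, 105, 112),
                 kd = 10^stats::runif(1, -7, -4), k_off = 10^stats::runif(1, 0, 2),
                 r2 = r2),
    U_RL = scheme_u_rl(stats::runif(1, 105, 112), stats::runif(1, 105, 112),
                       stats::runif(1, 105, 112),
                       kd = 10^stats::runif(1, -7, -4),
                       k_off = 10^stats::runif(1, 0, 2),
                       k_iso_f = 10^stats::runif(1, -1, 1),
                       k_iso_b = 10^stats::runif(1, -1, 1), r2 = r2),
    U_R_RL = scheme_u_r_rl(stats::runif(1, 105, 112), stats::runif(1, 105, 112),
                           stats::runif(1, 105, 112), stats::runif(1, 105, 112),
                           k_ab = 10^stats::runif(1, -1, 1),
                           k_ba = 10^stats::runif(1, -1, 1),
                           kd_r = 10^stats::runif(1, -7, -4),
                           k_off_r = 10^stats::runif(1, 0, 2),
                           kd_rs = 10^stats::runif(1, -7, -4),
                           k_off_rs = 10^stats::runif(1, 0, 2),
                           k_bound_f = 10^stats::runif(1, -1, 1), r2 = r2))
}
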