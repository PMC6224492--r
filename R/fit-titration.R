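# canonical parameter sets per binding topology; r1 does not affect the
# steady-state lineshape and is held at 1.5/s
.topology_params <- list(
  U = c("shift_r", "shift_rp", "r2", "kd", "k_off"),
  U_RL = c("shift_r", "shift_rp", "shift_rsp", "r2", "kd", "k_off",
           "k_iso_f", "k_iso_b"),
  U_R_RL = c("shift_r", "shift_rs", "shift_rp", "shift_rsp", "r2",
             "k_ab", "k_ba", "kd_r", "k_off_r", "kd_rs", "k_off_rs",
             "k_bound_f"))

.log_params <- c("r2", "kd", "k_off", "k_iso_f", "k_iso_b", "k_ab", "k_ba",
                 "kd_r", "k_off_r", "kd_rs", "k_off_rs", "k_bound_f")

scheme_from_params <- function(topology, p) {
  switch(topology,
    U = scheme_u(p$shift_r, p$shift_rp, p$kd, p$k_off, r1 = 1.5, r2 = p$r2),
    U_RL = scheme_u_rl(p$shift_r, p$shift_rp, p$shift_rsp, p$kd, p$k_off,
                       p$k_iso_f, p$k_iso_b, r1 = 1.5, r2 = p$r2),
    U_R_RL = scheme_u_r_rl(p$shift_r, p$shift_rs, p$shift_rp, p$shift_rsp,
                           p$k_ab, p$k_ba, p$kd_r, p$k_off_r, p$kd_rs,
                           p$k_off_rs, p$k_bound_f, r1 = 1.5, r2 = p$r2),
    rlang::abort(sprintf("unknown binding topology '%s'", topology)))
}

#' Parameters of a titration lineshape model
#'
#' Returns the canonical parameter names of a binding topology, used as
#' keys of the `fixed` and `init` maps of [fit_titration()]: chemical
#' shifts (`shift_*`, ppm), a shared transverse rate (`r2`, 1/s),
#' dissociation constants (`kd*`, M), dissociation rates (`k_off*`, 1/s)
#' and isomerization rates (`k_*`, 1/s).
#'
#' @param topology `"U"`, `"U_RL"` or `"U_R_RL"`.
#' @return Character vector of parameter names.
#' @export
titration_params <- function(topology) {
  if (!topology %in% names(.topology_params)) {
    rlang::abort(sprintf("unknown binding topology '%s'", topology))
  }
  .topology_params[[topology]]
}

#' Data-driven starting values for a titration fit
#'
#' Heuristic defaults: the free-state shift from the peak of the ratio-0
#' spectrum, bound-state shifts from the end-point spectrum, Kd of the
#' order of the receptor concentration, and moderate off/isomerization
#' rates. Any subset can be overridden through `init` in
#' [fit_titration()].
#'
#' @param series A `titration_series`.
#' @param topology Binding topology tag.
#' @return Named list of starting values for every model parameter.
#' @export
default_titration_init <- function(series, topology) {
  params <- titration_params(topology)
  # tallest local maxima (by height) of a spectrum
  peaks <- function(s, n) {
    y <- s$intensity
    m <- length(y)
    is_max <- c(FALSE, y[2:(m - 1)] >= y[1:(m - 2)] & y[2:(m - 1)] >= y[3:m], FALSE)
    idx <- which(is_max)
    if (!length(idx)) idx <- which.max(y)
    idx <- idx[order(-y[idx])]
    s$ppm[utils::head(idx, n)]
  }
  p0 <- peaks(series$spectrum[[1]], 2)
  p1 <- peaks(series$spectrum[[nrow(series)]], 2)
  shift_r <- p0[1]
  shift_rs <- if (length(p0) > 1) p0[2] else p0[1] + 0.5
  if (length(p1) > 1 && topology != "U") {
    # the bound state reached directly from R tends to sit nearer to R
    shift_rp <- p1[which.min(abs(p1 - shift_r))]
    shift_rsp <- p1[which.max(abs(p1 - shift_r))]
  } else {
    shift_rp <- p1[1]
    shift_rsp <- p1[1] + 0.5
  }
  rt <- series$receptor_total[1]
  defaults <- list(
    shift_r = shift_r, shift_rs = shift_rs,
    shift_rp = shift_rp, shift_rsp = shift_rsp,
    r2 = 20, kd = rt / 2, k_off = 20, k_iso_f = 2, k_iso_b = 2,
    k_ab = 1, k_ba = 1, kd_r = rt / 2, k_off_r = 20,
    kd_rs = rt / 2, k_off_rs = 20, k_bound_f = 2)
  defaults[params]
}

.series_context <- function(series) {
  ctx <- attr(series, "context")
  if (is.null(ctx)) ctx <- attr(series$spectrum[[1]], "context")
  if (is.null(ctx)) {
    rlang::abort("titration series carries no spectrometer context")
  }
  ctx
}

# model intensities for every titration point, evaluated on each data
# spectrum's own ppm axis
.titration_model <- function(p, topology, series, base_frequency) {
  scheme <- scheme_from_params(topology, p)
  cc <- .scheme_cache(scheme)
  purrr::map(seq_len(nrow(series)), function(i) {
    sol <- .solve_equilibrium_cached(cc, series$receptor_total[i],
                                     series$ratio[i] * series$receptor_total[i])
    .bloch_mcconnell_spectrum(
      nu = cc$shift * base_frequency,
      r2 = cc$r2, k = .rate_matrix_fast(cc, sol$free_ligand),
      m0 = sol$populations,
      nu_axis = series$spectrum[[i]]$ppm * base_frequency)
  })
}

#' Fit an exchange-lineshape model to a titration series
#'
#' Nonlinear least squares over all spectra of the series
#' simultaneously. Each titration point gets one free global scale
#' (receiver gain varies between experiments), profiled analytically at
#' every evaluation; kinetic and shift parameters are shared across the
#' series. Rates, dissociation constants and R2 are fitted on a log
#' scale. Any parameter can be pinned via `fixed` — the standard use is
#' pinning the free-receptor isomerization rates of the 4-state model to
#' ZZ-exchange values.
#'
#' @param series A `titration_series` (spectra carrying a context).
#' @param topology `"U"`, `"U_RL"` or `"U_R_RL"`.
#' @param fixed Named list of parameters to hold fixed.
#' @param init Named list of starting values for free parameters;
#'   defaults from [default_titration_init()].
#' @param n_starts Number of multi-starts (log-scale jitter on rate-like
#'   parameters; the first start is unjittered).
#' @param seed Seed controlling the jitter draws.
#' @return An object of class `titration_fit`: list with `topology`,
#'   `params` (full parameter list), `free` (names), `rss`, `n_obs`,
#'   `n_par`, `aicc`, `scales`, `converged`, `series`, `fitted`.
#' @export
fit_titration <- function(series, topology, fixed = list(), init = list(),
                          n_starts = 3, seed = 1) {
  stopifnot(inherits(series, "titration_series") || is.data.frame(series))
  params <- titration_params(topology)
  bad <- setdiff(c(names(fixed), names(init)), params)
  if (length(bad)) {
    rlang::abort(sprintf("unknown parameter(s) for %s: %s", topology,
                         paste(bad, collapse = ", ")))
  }
  ctx <- .series_context(series)
  full_init <- utils::modifyList(default_titration_init(series, topology), init)
  free <- setdiff(params, names(fixed))
  if (!length(free)) {
    # everything pinned: just evaluate
    p <- utils::modifyList(full_init, fixed)[params]
    return(.titration_eval(p, character(0), topology, series, ctx))
  }

  to_opt <- function(p) {
    v <- unlist(p[free])
    ln <- free %in% .log_params
    v[ln] <- log(v[ln])
    stats::setNames(v, free)
  }
  from_opt <- function(v) {
    p <- as.list(v)
    for (nm in free) if (nm %in% .log_params) p[[nm]] <- exp(p[[nm]])
    utils::modifyList(utils::modifyList(full_init, fixed), p)[params]
  }
  resid_fun <- function(v) {
    p <- from_opt(v)
    model <- tryCatch(.titration_model(p, topology, series, ctx$base_frequency),
                      error = function(e) NULL)
    if (is.null(model)) return(rep(1e6, sum(vapply(series$spectrum, nrow, 1L))))
    unlist(purrr::map(seq_len(nrow(series)), function(i) {
      y <- series$spectrum[[i]]$intensity
      s <- model[[i]]
      sc <- sum(y * s) / max(sum(s * s), 1e-300)
      y - sc * s
    }))
  }

  v0 <- to_opt(utils::modifyList(full_init, fixed))
  starts <- list(v0)
  if (n_starts > 1) {
    jit <- with_seed(seed, lapply(seq_len(n_starts - 1), function(i) {
      v <- v0
      ln <- free %in% .log_params
      v[ln] <- v[ln] + stats::runif(sum(ln), -log(4), log(4))
      v
    }))
    starts <- c(starts, jit)
  }
  fits <- purrr::map(starts, function(v) {
    tryCatch(minpack.lm::nls.lm(par = v, fn = resid_fun,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 300, ftol = 1e-13, ptol = 1e-13)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) {
    rlang::abort(sprintf("titration fit (%s) failed from every start", topology))
  }
  rss <- vapply(fits, function(f) sum(f$fvec^2), 1)
  best <- fits[[which.min(rss)]]
  out <- .titration_eval(from_opt(best$par), free, topology, series, ctx)
  out$converged <- best$info %in% 1:4
  if (!out$converged) {
    rlang::warn(sprintf("titration fit (%s) did not formally converge; best-so-far parameters returned", topology))
  }
  out
}

.titration_eval <- function(p, free, topology, series, ctx) {
  model <- .titration_model(p, topology, series, ctx$base_frequency)
  scales <- numeric(nrow(series))
  fitted <- vector("list", nrow(series))
  rss <- 0
  n_obs <- 0
  for (i in seq_len(nrow(series))) {
    y <- series$spectrum[[i]]$intensity
    s <- model[[i]]
    sc <- sum(y * s) / max(sum(s * s), 1e-300)
    scales[i] <- sc
    fitted[[i]] <- new_spectrum(series$spectrum[[i]]$ppm, sc * s, ctx)
    rss <- rss + sum((y - sc * s)^2)
    n_obs <- n_obs + length(y)
  }
  k_eff <- length(free) + nrow(series) + 1 # + per-point scales + variance
  structure(list(
    topology = topology, params = p, free = free,
    rss = rss, n_obs = n_obs, n_par = length(free),
    aicc = aicc_from_rss(rss, n_obs, k_eff),
    scales = scales, converged = TRUE,
    series = series, fitted = fitted), class = "titration_fit")
}

#' Small-sample corrected Akaike information criterion from an RSS
#'
#' `AICc = n log(RSS/n) + 2k + 2k(k+1)/(n-k-1)` for Gaussian residuals,
#' with `k` counting all estimated quantities (model parameters, nuisance
#' scales, and the residual variance). Returns `Inf` when the correction
#' denominator is not positive.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param k Number of estimated parameters (including the variance).
#' @export
aicc_from_rss <- function(rss, n, k) {
  if (n - k - 1 <= 0) return(Inf)
  n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("Titration lineshape fit [%s]: %d free parameter(s), RSS = %.4g, AICc = %.2f\n",
              x$topology, x$n_par, x$rss, x$aicc))
  p <- unlist(x$params)
  tag <- ifelse(names(p) %in% x$free, "", " (fixed)")
  cat(paste0(sprintf("  %-10s = %.6g", names(p), p), tag, collapse = "\n"), "\n")
  invisible(x)
}

#' Rank exchange topologies against a titration series
#'
#' Fits every candidate topology with [fit_titration()] and ranks the
#' results by the corrected Akaike information criterion, which balances
#' residual misfit against the number of free parameters for the short
#' series typical of titrations (both nested and non-nested comparisons).
#'
#' @param series A `titration_series`.
#' @param candidates Character vector of topology tags (>= 2).
#' @param fixed Either a single named list applied to every candidate
#'   (entries not belonging to a topology are dropped), or a list keyed
#'   by topology tag.
#' @param init As `fixed`, but for starting values.
#' @param n_starts,seed Passed to [fit_titration()].
#' @return A tibble of class `model_selection`, ranked: `topology`,
#'   `n_par`, `rss`, `aicc`, `delta_aicc`, `rank` and a `fit` list-column.
#' @export
select_model <- function(series, candidates = c("U", "U_RL", "U_R_RL"),
                         fixed = list(), init = list(), n_starts = 3, seed = 1) {
  stopifnot(length(candidates) >= 2)
  per_topo <- function(x, topo) {
    if (length(x) && all(names(x) %in% names(.topology_params))) {
      x[[topo]] %||% list()
    } else {
      x[intersect(names(x), titration_params(topo))]
    }
  }
  fits <- purrr::map(candidates, function(topo) {
    fit_titration(series, topo,
                  fixed = per_topo(fixed, topo), init = per_topo(init, topo),
                  n_starts = n_starts, seed = seed)
  })
  out <- tibble::tibble(
    topology = candidates,
    n_par = vapply(fits, function(f) f$n_par, 1L),
    rss = vapply(fits, function(f) f$rss, 1),
    aicc = vapply(fits, function(f) f$aicc, 1),
    fit = fits)
  # rank by AICc; exact ties go to the smaller model
  out <- dplyr::arrange(out, .data$aicc, .data$n_par)
  out$delta_aicc <- out$aicc - out$aicc[1]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("topology", "n_par", "rss", "aicc", "delta_aicc", "rank", "fit")]
  class(out) <- c("model_selection", class(out))
  out
}
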