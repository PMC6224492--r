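#' Pseudo-Voigt profile
#'
#' Unit-area linear mix of Lorentzian and Gaussian profiles sharing a
#' center and full width at half maximum: `eta * L + (1 - eta) * G`.
#'
#' @param x Evaluation points (same units as `center`/`fwhm`).
#' @param center Peak center.
#' @param fwhm Full width at half maximum (> 0).
#' @param eta Lorentzian fraction in \[0, 1\] (1 = pure Lorentzian).
#' @return Profile values; integrates to 1 over the real line.
#' @export
pseudo_voigt <- function(x, center, fwhm, eta = 1) {
  stopifnot(fwhm > 0, eta >= 0, eta <= 1)
  u <- (x - center) / fwhm
  lor <- (2 / (pi * fwhm)) / (1 + 4 * u^2)
  gau <- (2 / fwhm) * sqrt(log(2) / pi) * exp(-4 * log(2) * u^2)
  eta * lor + (1 - eta) * gau
}

# find initial centers: n largest local maxima after 3-point smoothing,
# ties broken toward downfield (larger ppm)
.init_centers <- function(ppm, intensity, n) {
  sm <- stats::filter(intensity, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- intensity[is.na(sm)]
  sm <- as.numeric(sm)
  m <- length(sm)
  is_max <- c(FALSE, sm[2:(m - 1)] >= sm[1:(m - 2)] & sm[2:(m - 1)] >= sm[3:m], FALSE)
  idx <- which(is_max)
  if (!length(idx)) idx <- which.max(sm)
  ord <- idx[order(-sm[idx], -ppm[idx])]
  # greedy pick with an exclusion zone so noise wiggles on one peak's top
  # cannot supply two starting centers
  excl <- diff(range(ppm)) / 20
  centers <- numeric(0)
  for (i in ord) {
    if (!length(centers) || min(abs(ppm[i] - centers)) > excl) {
      centers <- c(centers, ppm[i])
    }
    if (length(centers) == n) break
  }
  if (length(centers) < n) {
    centers <- c(centers, seq(min(ppm), max(ppm), length.out = n + 2)[2:(n + 1)])
  }
  sort(centers[seq_len(n)])
}

#' Deconvolve a 1D spectrum into pseudo-Voigt components
#'
#' Least-squares decomposition of a processed 1D spectrum (e.g. a 19F
#' helix-12 probe spectrum) into `n_components` pseudo-Voigt peaks plus a
#' polynomial baseline. Conformational state populations are reported as
#' component area fractions (not height fractions, since linewidths may
#' differ between states).
#'
#' @param spectrum An `nmr_spectrum` tibble (or any data frame with `ppm`
#'   and `intensity` columns).
#' @param n_components Number of components (>= 1).
#' @param init Optional numeric vector of initial centers, ppm; defaults
#'   to the `n_components` largest local maxima after 3-point smoothing
#'   (ties broken toward downfield).
#' @param baseline_degree Polynomial baseline degree: 0 (constant,
#'   default), 1 or 2.
#' @param eta_init Initial Lorentzian fraction per component (default 1).
#' @param fix_eta If not `NULL`, fixes all Lorentzian fractions to this
#'   value instead of fitting them.
#' @return An object of class `deconv_fit`: list with `components`
#'   (tibble: `center`, `fwhm`, `eta`, `area`, `height`, `population`),
#'   `populations`, `baseline` (coefficients, constant term first),
#'   `rss`, `fitted`, `spectrum`.
#' @export
deconvolve <- function(spectrum, n_components, init = NULL,
                       baseline_degree = 0, eta_init = 1, fix_eta = NULL) {
  d <- tibble::as_tibble(spectrum)
  stopifnot(all(c("ppm", "intensity") %in% names(d)), n_components >= 1,
            baseline_degree %in% 0:2)
  ppm <- d$ppm
  y <- d$intensity
  span <- diff(range(ppm))
  if (is.null(init)) {
    init <- .init_centers(ppm, y, n_components)
  } else {
    if (length(init) != n_components) {
      rlang::abort("`init` must supply one center per component")
    }
    if (any(init < min(ppm) | init > max(ppm))) {
      rlang::abort("initial centers must lie inside the spectrum axis")
    }
    init <- sort(init)
  }
  fit_eta <- is.null(fix_eta)
  eta_fixed <- if (fit_eta) NA_real_ else fix_eta

  # rough width/area guesses from the data around each initial center
  fwhm0 <- rep(span / 25, n_components)
  height0 <- vapply(init, function(c0) max(y[which.min(abs(ppm - c0))], max(y) / 50), 1)
  area0 <- height0 * fwhm0 * pi / 2

  nb <- baseline_degree + 1
  par0 <- c(rbind(init, log(fwhm0), log(area0),
                  if (fit_eta) rep(stats::qlogis(min(max(eta_init, 0.02), 0.98)), n_components)),
            rep(0, nb))
  per <- if (fit_eta) 4L else 3L

  unpack <- function(par) {
    comp <- matrix(par[seq_len(per * n_components)], nrow = per)
    list(center = comp[1, ], fwhm = exp(comp[2, ]), area = exp(comp[3, ]),
         eta = if (fit_eta) stats::plogis(comp[4, ]) else rep(eta_fixed, n_components),
         base = par[(per * n_components + 1):length(par)])
  }
  model_y <- function(p) {
    yy <- rep(0, length(ppm))
    for (j in seq_len(n_components)) {
      yy <- yy + p$area[j] * pseudo_voigt(ppm, p$center[j], p$fwhm[j], p$eta[j])
    }
    x0 <- ppm - mean(ppm)
    for (b in seq_len(nb)) yy <- yy + p$base[b] * x0^(b - 1)
    yy
  }
  # box bounds: centers stay on-axis, widths between 2 grid steps and the span
  dx <- span / (length(ppm) - 1)
  lo_c <- rbind(min(ppm), log(2 * dx), -Inf, if (fit_eta) -Inf)
  hi_c <- rbind(max(ppm), log(span), Inf, if (fit_eta) Inf)
  lower <- c(rep(lo_c, n_components), rep(-Inf, nb))
  upper <- c(rep(hi_c, n_components), rep(Inf, nb))
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(par) y - model_y(unpack(par)),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15, ptol = 1e-15))
  p <- unpack(fit$par)

  ord <- order(p$center)
  p$center <- p$center[ord]; p$fwhm <- p$fwhm[ord]
  p$area <- p$area[ord]; p$eta <- p$eta[ord]
  if (n_components > 1) {
    sep <- diff(p$center)
    mean_w <- (p$fwhm[-1] + p$fwhm[-n_components]) / 2
    if (any(sep < 0.05 * mean_w)) {
      rlang::abort(paste("fitted components collapsed onto each other",
                         "(center separation < 0.05 FWHM); try fewer components"))
    }
  }
  populations <- p$area / sum(p$area)
  components <- tibble::tibble(
    center = p$center, fwhm = p$fwhm, eta = p$eta, area = p$area,
    height = p$area * pseudo_voigt(p$center, p$center, p$fwhm, p$eta),
    population = populations)
  fitted_y <- model_y(p)
  structure(list(
    components = components,
    populations = populations,
    baseline = p$base,
    rss = sum((y - fitted_y)^2),
    fitted = tibble::tibble(ppm = ppm, intensity = fitted_y),
    spectrum = d,
    converged = fit$info %in% 1:4
  ), class = "deconv_fit")
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat(sprintf("Pseudo-Voigt deconvolution: %d component(s), RSS = %.3g\n",
              nrow(x$components), x$rss))
  print(dplyr::mutate(x$components, population = round(100 * .data$population, 2)))
  invisible(x)
}

#' Calibrate a chemical-shift axis against a reference signal
#'
#' Uniformly shifts the ppm axis so that an observed reference position
#' lands on its true value (e.g. an internal potassium fluoride 19F
#' reference defined to resonate at -119.522 ppm). Intensities are
#' untouched; applying the inverse calibration restores the original
#' axis exactly.
#'
#' @param spectrum An `nmr_spectrum` (or `ppm`/`intensity` data frame).
#' @param reference_observed Observed position of the reference, ppm;
#'   must lie within the axis range.
#' @param reference_true True position of the reference, ppm.
#' @return The spectrum with shifted axis.
#' @export
calibrate_axis <- function(spectrum, reference_observed, reference_true) {
  d <- tibble::as_tibble(spectrum)
  stopifnot(all(c("ppm", "intensity") %in% names(d)))
  if (reference_observed < min(d$ppm) || reference_observed > max(d$ppm)) {
    rlang::abort("`reference_observed` lies outside the spectrum axis")
  }
  out <- dplyr::mutate(d, ppm = .data$ppm + (reference_true - reference_observed))
  class(out) <- class(spectrum)
  attr(out, "context") <- attr(spectrum, "context")
  out
}
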