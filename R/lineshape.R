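# gyromagnetic-ratio fractions relative to 1H, used for ppm <-> Hz
.nucleus_fraction <- c("1H" = 1, "19F" = 0.94094011, "15N" = 0.10136767)

#' Spectrometer context for a 1D axis
#'
#' Holds what is needed to convert chemical shifts (ppm) to frequencies
#' (Hz) and to lay out a spectral axis: the nucleus, its base frequency at
#' the given field, and the ppm window. Contexts are always explicit
#' inputs; nothing in the package infers them from data.
#'
#' @param nucleus `"15N"`, `"19F"` or `"1H"`.
#' @param sweep Length-2 numeric, ppm window `c(low, high)`.
#' @param points Number of axis points (>= 2).
#' @param field_mhz Proton base frequency of the spectrometer, MHz
#'   (default 700). The nucleus base frequency is derived from the
#'   gyromagnetic-ratio fraction (at 700 MHz: 15N ~ 70.96 MHz,
#'   19F ~ 658.7 MHz).
#' @param base_frequency Optional explicit nucleus frequency, MHz;
#'   overrides `field_mhz`.
#' @return An object of class `spectrometer_context`.
#' @export
spectrometer_context <- function(nucleus = c("15N", "19F", "1H"),
                                 sweep, points = 512,
                                 field_mhz = 700, base_frequency = NULL) {
  nucleus <- match.arg(nucleus)
  if (is.null(base_frequency)) {
    base_frequency <- field_mhz * .nucleus_fraction[[nucleus]]
  }
  stopifnot(base_frequency > 0, points >= 2, length(sweep) == 2)
  if (sweep[1] >= sweep[2]) rlang::abort("`sweep` must be c(low, high) with low < high")
  structure(
    list(nucleus = nucleus, base_frequency = base_frequency,
         sweep = as.numeric(sweep), points = as.integer(points)),
    class = "spectrometer_context")
}

#' @export
print.spectrometer_context <- function(x, ...) {
  cat(sprintf("%s context: %.2f MHz, sweep [%g, %g] ppm, %d points\n",
              x$nucleus, x$base_frequency, x$sweep[1], x$sweep[2], x$points))
  invisible(x)
}

ppm_axis <- function(context) {
  seq(context$sweep[1], context$sweep[2], length.out = context$points)
}

#' Construct a 1D spectrum
#'
#' A spectrum is a tibble with columns `ppm` (strictly monotone) and
#' `intensity`, carrying its [spectrometer_context()] as an attribute.
#'
#' @param ppm Numeric axis, ppm, strictly monotone.
#' @param intensity Numeric intensities, same length.
#' @param context A [spectrometer_context()] (optional but needed for any
#'   ppm/Hz conversion downstream).
#' @return A tibble of class `nmr_spectrum`.
#' @export
new_spectrum <- function(ppm, intensity, context = NULL) {
  stopifnot(length(ppm) == length(intensity))
  d <- diff(ppm)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    rlang::abort("`ppm` axis must be strictly monotone")
  }
  out <- tibble::tibble(ppm = as.numeric(ppm), intensity = as.numeric(intensity))
  class(out) <- c("nmr_spectrum", class(out))
  attr(out, "context") <- context
  out
}

spectrum_context <- function(spectrum) attr(spectrum, "context")

#' Simulate an exchange-broadened 1D lineshape
#'
#' Solves the Bloch-McConnell steady-state spectrum for a kinetic scheme:
#' with state frequencies nu_j (Hz, from ppm via the context), transverse
#' rates R2_j and exchange generator K (1/s),
#' \deqn{S(\omega) = \mathrm{Re}\,[\, \mathbf{1}^T (i\omega I - \Lambda)^{-1} M_0\,],\qquad
#'       \Lambda = 2\pi i\,\mathrm{diag}(\nu_j) - \mathrm{diag}(R_{2,j}) + K,}
#' with the initial magnetization proportional to the state populations.
#' In the limits this reproduces the textbook behavior: a single state
#' gives a Lorentzian of full width at half maximum `R2/pi` Hz; slow
#' exchange gives one peak per state with areas proportional to
#' populations; fast exchange gives one peak at the population-weighted
#' shift.
#'
#' @param scheme A [kinetic_scheme()].
#' @param context A [spectrometer_context()] defining the axis.
#' @param free_ligand Free-ligand concentration, M, used to scale binding
#'   edges (default 0).
#' @param populations Optional state populations (nonnegative, sum 1);
#'   defaults to the equilibrium populations at `free_ligand`.
#' @return An `nmr_spectrum` tibble on the context axis.
#' @export
simulate_lineshape <- function(scheme, context, free_ligand = 0, populations = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(context, "spectrometer_context"))
  if (any(scheme$states$r2 <= 0)) {
    rlang::abort("all R2 must be > 0: the lineshape is singular at resonance otherwise")
  }
  k <- build_rate_matrix(scheme, free_ligand)
  if (is.null(populations)) {
    populations <- .populations_at_ligand(scheme, free_ligand)
  }
  if (any(populations < -1e-12) || abs(sum(populations) - 1) > 1e-8) {
    rlang::abort("`populations` must be nonnegative and sum to 1")
  }
  ppm <- ppm_axis(context)
  intensity <- .bloch_mcconnell_spectrum(
    nu = scheme$states$shift * context$base_frequency,
    r2 = scheme$states$r2, k = k, m0 = populations,
    nu_axis = ppm * context$base_frequency)
  new_spectrum(ppm, intensity, context)
}

# evaluate Re[1' (iwI - Lambda)^-1 m0] over the frequency axis via
# eigendecomposition of the (complex, non-Hermitian) evolution matrix
.bloch_mcconnell_spectrum <- function(nu, r2, k, m0, nu_axis) {
  lambda <- diag(2i * pi * nu - r2, nrow = length(nu)) + k
  eig <- eigen(lambda)
  v <- eig$vectors
  a <- colSums(v)                 # 1' V
  b <- solve(v, as.complex(m0))   # V^-1 m0
  w <- 2 * pi * nu_axis
  # S(w) = sum_j a_j b_j / (i w - lambda_j)
  s <- rowSums(sapply(seq_along(a), function(j) {
    Re(a[j] * b[j] / (1i * w - eig$values[j]))
  }))
  if (!all(is.finite(s))) rlang::abort("lineshape evaluation produced non-finite values")
  s
}

#' Simulate a peptide-titration series of 1D spectra
#'
#' For each molar ratio, solves the binding-isomerization equilibrium for
#' the species composition and free-ligand concentration, then simulates
#' the exchange lineshape with binding edges at their pseudo-first-order
#' rates. The ratio-0 point is the ligand-free spectrum.
#'
#' @param scheme A binding scheme (`U`, `U_RL` or `U_R_RL`).
#' @param ratios Nonnegative, nondecreasing molar ratios peptide:receptor.
#' @param receptor_total Total receptor concentration, M (default 200e-6,
#'   a typical protein NMR concentration).
#' @param context A [spectrometer_context()].
#' @return A `titration_series` tibble: one row per ratio with columns
#'   `ratio`, `receptor_total`, `free_ligand`, and a `spectrum` list-column
#'   of `nmr_spectrum` tibbles.
#' @export
simulate_titration <- function(scheme, ratios, receptor_total = 200e-6, context) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!scheme$topology %in% c("U", "U_RL", "U_R_RL")) {
    rlang::abort("titration simulation needs a binding topology (U, U_RL or U_R_RL)")
  }
  if (any(ratios < 0) || is.unsorted(ratios)) {
    rlang::abort("`ratios` must be nonnegative and nondecreasing")
  }
  rows <- purrr::map(ratios, function(r) {
    comp <- solve_binding_equilibrium(scheme, receptor_total, r * receptor_total)
    spec <- simulate_lineshape(scheme, context,
                               free_ligand = comp$free_ligand,
                               populations = comp$populations)
    tibble::tibble(ratio = r, receptor_total = receptor_total,
                   free_ligand = comp$free_ligand, spectrum = list(spec))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("titration_series", class(out))
  attr(out, "context") <- context
  out
}

#' Transfer peak assignments by minimum chemical-shift perturbation
#'
#' Maps observed 2D (1H, 15N) peaks onto reference assignments by the
#' combined distance `sqrt(d_h^2 + (w * d_n)^2)` (default weight
#' `w = 0.2`), assigning one-to-one greedily from the globally smallest
#' distance upward; ties are broken by the smaller 1H distance. Observed
#' peaks whose best distance exceeds `cutoff` are labelled `NA`
#' (unassigned), as are peaks left over once references are exhausted.
#'
#' @param reference_peaks Tibble/data frame with columns `label`,
#'   `shift_h`, `shift_n` (ppm).
#' @param observed_peaks Tibble/data frame with columns `shift_h`,
#'   `shift_n` (ppm).
#' @param weight_n Weight on the 15N shift difference (default 0.2).
#' @param cutoff Maximum combined distance for an assignment (default Inf).
#' @return A tibble with one row per observed peak: `shift_h`, `shift_n`,
#'   `label` (NA if unassigned), `distance`.
#' @export
transfer_assignments <- function(reference_peaks, observed_peaks,
                                 weight_n = 0.2, cutoff = Inf) {
  ref <- tibble::as_tibble(reference_peaks)
  obs <- tibble::as_tibble(observed_peaks)
  stopifnot(nrow(ref) > 0, nrow(obs) > 0,
            all(c("label", "shift_h", "shift_n") %in% names(ref)),
            all(c("shift_h", "shift_n") %in% names(obs)))
  dh <- outer(obs$shift_h, ref$shift_h, function(a, b) abs(a - b))
  dn <- outer(obs$shift_n, ref$shift_n, function(a, b) abs(a - b))
  dist <- sqrt(dh^2 + (weight_n * dn)^2)
  label <- rep(NA_character_, nrow(obs))
  best <- rep(NA_real_, nrow(obs))
  open_obs <- rep(TRUE, nrow(obs))
  open_ref <- rep(TRUE, nrow(ref))
  repeat {
    d <- dist
    d[!open_obs, ] <- Inf
    d[, !open_ref] <- Inf
    m <- min(d)
    if (!is.finite(m) || m > cutoff) break
    cand <- which(d <= m * (1 + 1e-9) + 1e-12, arr.ind = TRUE)
    if (nrow(cand) > 1) { # tie: smaller 1H distance wins
      hd <- dh[cand]
      cand <- cand[order(hd), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    label[i] <- ref$label[j]
    best[i] <- dist[i, j]
    open_obs[i] <- FALSE
    open_ref[j] <- FALSE
    if (!any(open_obs) || !any(open_ref)) break
  }
  tibble::tibble(shift_h = obs$shift_h, shift_n = obs$shift_n,
                 label = label, distance = best)
}
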