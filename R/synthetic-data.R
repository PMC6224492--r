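# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Ground truth attached to generated data
#'
#' Every generator returns, alongside its artifact, the exact parameter
#' set and seed that produced it, so recovery tests can compare against
#' known truth. Ground truths serialize losslessly through JSON.
#'
#' @param params Named list of generating parameters.
#' @param seed Integer seed used (or `NULL` for noiseless/deterministic).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(params, seed = NULL) {
  structure(list(params = params, seed = seed), class = "ground_truth")
}

#' @rdname ground_truth
#' @param truth A `ground_truth` object.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(obj$params, obj$seed)
}

#' Generate a synthetic ZZ-exchange dataset
#'
#' Build-up curves from [zz_curves()] plus additive Gaussian noise
#' (thermal-noise model for processed intensities). With `noise_sd = 0`
#' the output is exactly the forward model and [fit_zz()] round-trips it.
#'
#' @param kinetics A [two_site_kinetics()] (detailed balance holds by
#'   construction).
#' @param r1 Longitudinal relaxation rate, 1/s (shared by both states).
#' @param delays Mixing delays, s.
#' @param noise_sd Absolute intensity noise SD (same units as the unit
#'   total starting magnetization).
#' @param seed Integer seed for the noise draw.
#' @param residue Residue label recorded in the table.
#' @return List with `data` (tibble: `residue`, `delay`, `i_aa`, `i_bb`,
#'   `i_ab`, `i_ba`, `sd`) and `truth` ([ground_truth()]).
#' @export
gen_zz <- function(kinetics, r1, delays = zz_fixture_delays(),
                   noise_sd = 0, seed = NULL, residue = "G399") {
  curves <- zz_curves(kinetics, r1, r1, delays)
  d <- with_seed(seed, {
    noisy <- curves
    if (noise_sd > 0) {
      for (col in c("i_aa", "i_bb", "i_ab", "i_ba")) {
        noisy[[col]] <- noisy[[col]] + stats::rnorm(nrow(noisy), sd = noise_sd)
      }
    }
    noisy
  })
  d <- dplyr::mutate(d, residue = residue, sd = noise_sd, .before = 1)
  truth <- ground_truth(list(
    k_ab = kinetics$k_ab, k_ba = kinetics$k_ba, k_ex = kinetics$k_ex,
    p_a = kinetics$p_a, p_b = kinetics$p_b, r1 = r1,
    delays = delays, noise_sd = noise_sd), seed)
  list(data = d, truth = truth)
}

#' Generate a synthetic titration series
#'
#' Forward-simulates a peptide titration with [simulate_titration()] and
#' adds Gaussian noise scaled to the maximum intensity of the noiseless
#' series (`noise_sd` is fractional: 0.02 means 2% of the tallest peak).
#'
#' @param scheme Binding [kinetic_scheme()].
#' @param ratios Molar ratios peptide:receptor.
#' @param receptor_total Total receptor, M.
#' @param context A [spectrometer_context()].
#' @param noise_sd Fractional noise level relative to the series maximum.
#' @param seed Integer seed.
#' @return List with `series` (a `titration_series`) and `truth`.
#' @export
gen_titration <- function(scheme, ratios = c(0, 0.25, 0.5, 1, 2),
                          receptor_total = 200e-6, context,
                          noise_sd = 0, seed = NULL) {
  series <- simulate_titration(scheme, ratios, receptor_total, context)
  if (noise_sd > 0) {
    peak <- max(vapply(series$spectrum, function(s) max(abs(s$intensity)), 1))
    series$spectrum <- with_seed(seed, purrr::map(series$spectrum, function(s) {
      s$intensity <- s$intensity + stats::rnorm(nrow(s), sd = noise_sd * peak)
      s
    }))
  }
  truth <- ground_truth(list(
    topology = scheme$topology, states = scheme$states, edges = scheme$edges,
    ratios = ratios, receptor_total = receptor_total, noise_sd = noise_sd), seed)
  list(series = series, truth = truth)
}

#' Generate a synthetic 1D spectrum from pseudo-Voigt components
#'
#' @param components Tibble with columns `center`, `fwhm`, `area` and
#'   optionally `eta` (default 1, Lorentzian).
#' @param context A [spectrometer_context()] defining the axis.
#' @param noise_sd Fractional noise relative to the maximum intensity.
#' @param seed Integer seed.
#' @return List with `spectrum` (an `nmr_spectrum`) and `truth`.
#' @export
gen_spectrum <- function(components, context, noise_sd = 0, seed = NULL) {
  comp <- tibble::as_tibble(components)
  if (!"eta" %in% names(comp)) comp$eta <- 1
  ppm <- ppm_axis(context)
  y <- rep(0, length(ppm))
  for (j in seq_len(nrow(comp))) {
    y <- y + comp$area[j] * pseudo_voigt(ppm, comp$center[j], comp$fwhm[j], comp$eta[j])
  }
  if (noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(y), sd = noise_sd * max(abs(y))))
  }
  truth <- ground_truth(list(components = comp, noise_sd = noise_sd,
                             populations = comp$area / sum(comp$area)), seed)
  list(spectrum = new_spectrum(ppm, y, context), truth = truth)
}

# acceptor position at a prescribed donor-acceptor distance and
# donor-hydrogen-acceptor angle, for donor at `d` and hydrogen at `h`
.place_acceptor <- function(d, h, distance, angle_deg) {
  a <- angle_deg * pi / 180
  hd <- d - h
  hd <- hd / sqrt(sum(hd^2))                  # unit vector H -> D
  ref <- if (abs(hd[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  ey <- c(hd[2] * ref[3] - hd[3] * ref[2], hd[3] * ref[1] - hd[1] * ref[3],
          hd[1] * ref[2] - hd[2] * ref[1])
  ey <- ey / sqrt(sum(ey^2))
  dir <- cos(a) * hd + sin(a) * ey            # H->A at the requested DHA angle
  # solve |(h + r dir) - d| = distance for r > 0
  hd_vec <- d - h
  b <- -2 * sum(hd_vec * dir)
  cc <- sum(hd_vec^2) - distance^2
  r <- (-b + sqrt(b^2 - 4 * cc)) / 2
  h + r * dir
}

#' Generate toy multi-frame coordinates with planted hydrogen bonds
#'
#' Builds a small synthetic scene per frame — an arginine-like donor
#' (NH1/HH11), a ligand acceptor (N1), a second acceptor pair (ligand O1
#' and aspartate OD1) bridged by a water, plus inert carbons — and writes
#' it as a multi-MODEL PDB. The direct hydrogen bond and the water bridge
#' are each present exactly in the scheduled frames; absent frames move
#' the partner 5 Angstrom away. The direct-pair geometry (distance,
#' angle) is adjustable to probe the criteria boundaries.
#'
#' @param n_frames Number of frames.
#' @param direct_present Logical vector (length `n_frames`): frames in
#'   which the direct A:288:NH1 -- L:1:N1 hydrogen bond exists.
#' @param bridge_present Logical vector: frames with the water bridge
#'   between L:1:O1 and A:310:OD1.
#' @param direct_distance,direct_angle Planted donor-acceptor distance
#'   (Angstrom) and donor-H-acceptor angle (degrees) for present frames.
#' @param seed Integer seed for the inert-atom jitter.
#' @param path Optional path; when given, a multi-MODEL PDB is written.
#' @return List with `frames` (atom tibble with `frame` column), `truth`,
#'   and `path` (NULL if not written).
#' @export
gen_frames <- function(n_frames, direct_present = rep(TRUE, n_frames),
                       bridge_present = rep(FALSE, n_frames),
                       direct_distance = 2.9, direct_angle = 160,
                       seed = NULL, path = NULL) {
  stopifnot(length(direct_present) == n_frames, length(bridge_present) == n_frames)
  donor <- c(0, 0, 0)
  hyd <- c(1.01, 0, 0)
  acc_in <- .place_acceptor(donor, hyd, direct_distance, direct_angle)
  acc_out <- c(5, 3, 3)
  # bridge scene around x ~ 10: two acceptors + donating water
  o1 <- c(10, 0, 0)
  od1 <- c(10, 4.4, 0)
  wat_o_in <- c(10, 2.2, 1.8)
  wat_o_out <- c(10, 2.2, 8)
  frames <- with_seed(seed, purrr::map(seq_len(n_frames), function(f) {
    acc <- if (direct_present[f]) acc_in else acc_out
    wo <- if (bridge_present[f]) wat_o_in else wat_o_out
    wh1 <- wo + 0.97 * (o1 - wo) / sqrt(sum((o1 - wo)^2))
    wh2 <- wo + 0.97 * (od1 - wo) / sqrt(sum((od1 - wo)^2))
    inert <- matrix(c(-6, -6, 0, -6, -8, 2), ncol = 3, byrow = TRUE) +
      matrix(stats::rnorm(6, sd = 0.2), ncol = 3)
    tibble::tibble(
      frame = f,
      eleno = 1:10,
      name = c("NH1", "HH11", "N1", "O1", "OD1", "O", "H1", "H2", "CA", "CB"),
      element = c("N", "H", "N", "O", "O", "O", "H", "H", "C", "C"),
      resno = c(288L, 288L, 1L, 1L, 310L, 500L, 500L, 500L, 50L, 50L),
      resname = c("ARG", "ARG", "LIG", "LIG", "ASP", "WAT", "WAT", "WAT", "ALA", "ALA"),
      chain = c("A", "A", "L", "L", "A", "W", "W", "W", "A", "A"),
      x = c(donor[1], hyd[1], acc[1], o1[1], od1[1], wo[1], wh1[1], wh2[1], inert[, 1]),
      y = c(donor[2], hyd[2], acc[2], o1[2], od1[2], wo[2], wh1[2], wh2[2], inert[, 2]),
      z = c(donor[3], hyd[3], acc[3], o1[3], od1[3], wo[3], wh1[3], wh2[3], inert[, 3]))
  }))
  frames_tbl <- dplyr::bind_rows(frames)
  if (!is.null(path)) write_frames_pdb(frames_tbl, path)
  truth <- ground_truth(list(
    n_frames = n_frames, direct_present = direct_present,
    bridge_present = bridge_present,
    direct_occupancy = mean(direct_present),
    bridge_occupancy = mean(bridge_present),
    direct_distance = direct_distance, direct_angle = direct_angle), seed)
  list(frames = frames_tbl, truth = truth, path = path)
}

#' Write an atom table as a multi-MODEL PDB
#'
#' @param frames Atom tibble with a `frame` column (as from
#'   [gen_frames()]).
#' @param path Output path.
#' @export
write_frames_pdb <- function(frames, path) {
  frames <- tibble::as_tibble(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in sort(unique(frames$frame))) {
    fr <- frames[frames$frame == f, ]
    writeLines(sprintf("MODEL     %4d", f), con)
    for (i in seq_len(nrow(fr))) {
      nm <- fr$name[i]
      nm4 <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      writeLines(sprintf(
        "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        fr$eleno[i], nm4, fr$resname[i], fr$chain[i], fr$resno[i],
        fr$x[i], fr$y[i], fr$z[i], 1.00, 0.00, fr$element[i]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- shipped fixture constants -------------------------------------------
# Values the study conditions fix: ZZ-derived kinetics (p_A = 0.37,
# k_ex = 2.1 /s at 310 K), delays spanning 0-2 s, and shift conventions
# for the unprinted positions (15N states at 109/110 ppm; 19F components
# at -116.5/-115.5 ppm, FWHM 0.1 ppm).

#' Shipped fixture: G399-like two-site kinetics (p_A = 0.37, k_ex = 2.1/s)
#' @export
g399_kinetics <- function() two_site_from_populations(p_a = 0.37, k_ex = 2.1)

#' Shipped fixture: ZZ mixing delays spanning 0-2 s
#' @export
zz_fixture_delays <- function() c(0, 0.05, 0.1, 0.2, 0.4, 0.8, 1.2, 1.6, 2.0)

#' Shipped fixture: G399-like two-site isomerization scheme
#'
#' 15N states at 109.0 and 110.0 ppm (1.0 ppm apart, ~71 Hz at 70.96 MHz
#' — safely slow exchange against k_ex = 2.1/s), R1 = 1.5/s, R2 = 25/s.
#' @export
g399_scheme <- function() {
  scheme_two_site(g399_kinetics(), shift_a = 109.0, shift_b = 110.0,
                  r1 = 1.5, r2 = 25)
}

#' Shipped fixture: 15N spectrometer context (700 MHz, G399 window)
#' @param points Axis length.
#' @export
context_15n <- function(points = 256) {
  spectrometer_context("15N", sweep = c(106, 113), points = points)
}

#' Shipped fixture: 19F spectrometer context (700 MHz, BTFA window)
#' @param points Axis length.
#' @export
context_19f <- function(points = 2048) {
  spectrometer_context("19F", sweep = c(-118.5, -113.5), points = points)
}

#' Shipped fixture: two-component 19F peak set
#'
#' Lorentzian components at -116.5 ppm (major/right peak position) and
#' -115.5 ppm (minor/left), FWHM 0.1 ppm (10 linewidths apart), with the
#' requested area fractions.
#' @param fractions Length-2 area fractions `c(right, left)`; defaults to
#'   the inverse-agonist-free 78/22 pair.
#' @export
f19_components <- function(fractions = c(0.78, 0.22)) {
  stopifnot(length(fractions) == 2, all(fractions > 0))
  fractions <- fractions / sum(fractions)
  tibble::tibble(center = c(-116.5, -115.5), fwhm = 0.1, eta = 1,
                 area = fractions)
}

#' Shipped fixture: corepressor-like 4-state titration scheme
#'
#' U_R_RL topology with free-receptor isomerization fixed to the
#' ZZ-derived G399 kinetics and a 10x higher peptide affinity for the B
#' (corepressor-selective) conformation.
#' @export
t007_ncor1_scheme <- function() {
  kin <- g399_kinetics()
  scheme_u_r_rl(
    shift_r = 109.0, shift_rs = 110.0, shift_rp = 109.4, shift_rsp = 110.6,
    k_ab = kin$k_ab, k_ba = kin$k_ba,
    kd_r = 10e-6, k_off_r = 20, kd_rs = 1e-6, k_off_rs = 20,
    k_bound_f = 5, r1 = 1.5, r2 = 25)
}

#' Shipped fixture: coactivator-like 2-state titration scheme
#'
#' Simple U topology (R + P <-> RP) with a weaker, micromolar affinity.
#' @export
gw9662_trap220_scheme <- function() {
  scheme_u(shift_r = 109.0, shift_rp = 109.8, kd = 20e-6, k_off = 30,
           r1 = 1.5, r2 = 25)
}

#' Shipped fixture: 3-state titration scheme (binding then isomerization)
#' @export
u_rl_fixture_scheme <- function() {
  scheme_u_rl(shift_r = 109.0, shift_rp = 109.6, shift_rsp = 110.4,
              kd = 5e-6, k_off = 25, k_iso_f = 4, k_iso_b = 2,
              r1 = 1.5, r2 = 25)
}
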