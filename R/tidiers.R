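#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.zz_fit <- function(x, ...) {
  kin <- x$kinetics
  est <- c(k_ab = kin$k_ab, k_ba = kin$k_ba, k_ex = kin$k_ex,
           p_a = kin$p_a, p_b = kin$p_b,
           stats::setNames(as.numeric(x$r1), paste0("r1_", names(x$r1))),
           amp_a = unname(x$amplitudes[1]), amp_b = unname(x$amplitudes[2]))
  tibble::tibble(term = names(est), estimate = unname(est))
}

#' @export
glance.zz_fit <- function(x, ...) {
  tibble::tibble(k_ex = x$kinetics$k_ex, p_a = x$kinetics$p_a,
                 p_b = x$kinetics$p_b, r1 = unname(x$r1[1]),
                 rss = x$rss, n = nrow(x$data), converged = x$converged)
}

#' @export
tidy.titration_fit <- function(x, ...) {
  p <- unlist(x$params)
  tibble::tibble(term = names(p), estimate = unname(p),
                 fixed = !names(p) %in% x$free)
}

#' @export
glance.titration_fit <- function(x, ...) {
  tibble::tibble(topology = x$topology, n_par = x$n_par, n_obs = x$n_obs,
                 rss = x$rss, aicc = x$aicc, converged = x$converged)
}

#' @export
tidy.deconv_fit <- function(x, ...) x$components

#' @export
glance.deconv_fit <- function(x, ...) {
  tibble::tibble(n_components = nrow(x$components), rss = x$rss,
                 converged = x$converged)
}

#' Plot a 1D spectrum
#' @param object An `nmr_spectrum`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.nmr_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot ZZ-exchange build-up curves with their fit
#' @param object A `zz_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.zz_fit <- function(object, ...) {
  long <- function(d, what) {
    tidyr::pivot_longer(d, c("i_aa", "i_bb", "i_ab", "i_ba"),
                        names_to = "peak", values_to = "intensity") |>
      dplyr::mutate(peak = toupper(sub("^i_", "", .data$peak)), kind = what)
  }
  delays <- seq(0, max(object$data$delay), length.out = 100)
  smooth <- zz_curves(object$kinetics, object$r1[1],
                      if (length(object$r1) > 1) object$r1[2] else object$r1[1],
                      delays, amplitudes = unname(object$amplitudes))
  ggplot2::ggplot(long(object$data, "data"),
                  ggplot2::aes(x = .data$delay, y = .data$intensity,
                               colour = .data$peak)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = long(smooth, "fit")) +
    ggplot2::labs(x = "mixing delay (s)", y = "peak intensity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a deconvolution: data, components and their sum
#' @param object A `deconv_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.deconv_fit <- function(object, ...) {
  d <- object$spectrum
  comp_curves <- purrr::imap(split(object$components,
                                   seq_len(nrow(object$components))),
    function(cmp, j) {
      tibble::tibble(ppm = d$ppm,
                     intensity = cmp$area * pseudo_voigt(d$ppm, cmp$center,
                                                         cmp$fwhm, cmp$eta),
                     component = paste0("component ", j))
    }) |> dplyr::bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_line(data = comp_curves,
                       ggplot2::aes(colour = .data$component)) +
    ggplot2::geom_line(data = object$fitted, linetype = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a titration series as stacked 1D spectra
#' @param object A `titration_series`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.titration_series <- function(object, ...) {
  d <- tidyr::unnest(
    dplyr::mutate(tibble::as_tibble(object),
                  spectrum = purrr::map(.data$spectrum, tibble::as_tibble)),
    "spectrum")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ppm, y = .data$intensity,
                                  colour = factor(.data$ratio))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity",
                  colour = "peptide : receptor") +
    ggplot2::theme_minimal()
}
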