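#' Read a 1D spectrum from two-column text or CSV
#'
#' Accepts whitespace-separated or comma-separated `ppm intensity` rows;
#' blank lines, `#` comment lines and CRLF line endings are tolerated. A
#' non-monotone axis is sorted with a warning; non-numeric rows raise an
#' error naming the offending line.
#'
#' @param path File path.
#' @param context Optional [spectrometer_context()] to attach.
#' @return An `nmr_spectrum` tibble.
#' @export
read_spectrum <- function(path, context = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) rlang::abort(sprintf("%s: no data rows", path))
  sep_comma <- grepl(",", lines[keep[1]], fixed = TRUE)
  vals <- lapply(keep, function(i) {
    fields <- strsplit(trimws(lines[i]), if (sep_comma) "\\s*,\\s*" else "\\s+")[[1]]
    # tolerate a header row on the first data line
    v <- suppressWarnings(as.numeric(fields))
    if (length(v) < 2 || anyNA(v[1:2])) {
      if (i == keep[1] && anyNA(v)) return(NULL) # header
      rlang::abort(sprintf("%s line %d: expected two numeric columns, got '%s'",
                           path, i, lines[i]))
    }
    v[1:2]
  })
  vals <- Filter(Negate(is.null), vals)
  if (!length(vals)) rlang::abort(sprintf("%s: no numeric data rows", path))
  m <- do.call(rbind, vals)
  ppm <- m[, 1]
  intensity <- m[, 2]
  if (is.unsorted(ppm) && is.unsorted(rev(ppm))) {
    rlang::warn(sprintf("%s: ppm axis not monotone; sorting ascending", path))
    o <- order(ppm)
    ppm <- ppm[o]
    intensity <- intensity[o]
  }
  new_spectrum(ppm, intensity, context)
}

#' Write a 1D spectrum
#'
#' ppm values are written with 4 decimals and intensities with 6
#' significant figures, which exceeds the digital resolution of the data
#' and keeps write/read round trips stable.
#'
#' @param spectrum An `nmr_spectrum` (or `ppm`/`intensity` data frame).
#' @param path Output path.
#' @param format `"txt"` (whitespace two-column) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, format = c("txt", "csv")) {
  format <- match.arg(format)
  d <- tibble::as_tibble(spectrum)
  sep <- if (format == "csv") "," else " "
  lines <- paste(sprintf("%.4f", d$ppm), signif(d$intensity, 6), sep = sep)
  header <- if (format == "csv") "ppm,intensity" else "# ppm intensity"
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read / write ZZ-exchange intensity tables
#'
#' CSV with columns `residue`, `delay_s`, `I_AA`, `I_BB`, `I_AB`, `I_BA`
#' and optional `sd`.
#'
#' @param path File path.
#' @return [read_zz_table()]: a tibble with columns `residue`, `delay`,
#'   `i_aa`, `i_bb`, `i_ab`, `i_ba` (and `sd` when present) suitable for
#'   [fit_zz()].
#' @export
read_zz_table <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("residue", "delay_s", "I_AA", "I_BB", "I_AB", "I_BA")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    rlang::abort(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  }
  out <- tibble::tibble(residue = d$residue, delay = d$delay_s,
                        i_aa = d$I_AA, i_bb = d$I_BB, i_ab = d$I_AB, i_ba = d$I_BA)
  if ("sd" %in% names(d)) out$sd <- d$sd
  out
}

#' @rdname read_zz_table
#' @param dataset Tibble with columns `residue` (optional), `delay`,
#'   `i_aa`, `i_bb`, `i_ab`, `i_ba`, optional `sd`.
#' @export
write_zz_table <- function(dataset, path) {
  d <- tibble::as_tibble(dataset)
  out <- data.frame(residue = if ("residue" %in% names(d)) d$residue else "res",
                    delay_s = d$delay, I_AA = signif(d$i_aa, 6),
                    I_BB = signif(d$i_bb, 6), I_AB = signif(d$i_ab, 6),
                    I_BA = signif(d$i_ba, 6))
  if ("sd" %in% names(d)) out$sd <- signif(d$sd, 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Sparky-style peak list
#'
#' Lines of `label w1 w2` with an optional `Assignment w1 w2` header; for
#' (1H, 15N) amide lists w1 is conventionally the 15N shift and w2 the 1H
#' shift.
#'
#' @param path File path.
#' @return Tibble with columns `label`, `w1`, `w2`.
#' @export
read_peak_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- lines[!grepl("^\\s*(#|$)", lines) & !grepl("^\\s*Assignment", lines)]
  rows <- lapply(keep, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 3) rlang::abort(sprintf("%s: bad peak-list row '%s'", path, l))
    tibble::tibble(label = f[1],
                   w1 = as.numeric(f[2]), w2 = as.numeric(f[3]))
  })
  dplyr::bind_rows(rows)
}

#' Read a (multi-MODEL) PDB file into an atom table
#'
#' Each MODEL/ENDMDL block becomes one frame; a file without MODEL
#' records yields a single frame. Elements missing from the element
#' column are inferred from the atom name.
#'
#' @param path PDB file path.
#' @return Tibble with columns `frame`, `eleno`, `name`, `element`,
#'   `resno`, `resname`, `chain`, `x`, `y`, `z`.
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  n_atoms <- nrow(atoms)
  if (!n_atoms) rlang::abort(sprintf("%s: no ATOM records", path))
  n_frames <- nrow(pdb$xyz)
  elem <- atoms$elesy
  fallback <- !nzchar(trimws(ifelse(is.na(elem), "", elem)))
  elem[fallback] <- substr(gsub("[0-9 ]", "", atoms$elety[fallback]), 1, 1)
  elem <- toupper(trimws(elem))
  frames <- purrr::map(seq_len(n_frames), function(f) {
    xyz <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    tibble::tibble(
      frame = f, eleno = atoms$eleno, name = atoms$elety, element = elem,
      resno = atoms$resno, resname = atoms$resid,
      chain = ifelse(is.na(atoms$chain), "A", atoms$chain),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  dplyr::bind_rows(frames)
}

#' Compare conformational populations from ZZ exchange and deconvolution
#'
#' Order-normalizes the two two-state population pairs (minor state
#' against minor state) and reports the per-state difference in
#' percentage points — the cross-validation between the amide
#' ZZ-exchange populations and the 19F area fractions.
#'
#' @param zz A [fit_zz()] result, or a numeric length-2 population pair.
#' @param deconv A [deconvolve()] result (two components), or a numeric
#'   length-2 population pair.
#' @return Tibble with one row per state (`minor`, `major`):
#'   `zz_percent`, `deconv_percent`, `difference_points`.
#' @export
compare_populations <- function(zz, deconv) {
  get_pops <- function(x, what) {
    if (inherits(x, "zz_fit")) p <- c(x$kinetics$p_a, x$kinetics$p_b)
    else if (inherits(x, "deconv_fit")) p <- x$populations
    else if (is.numeric(x) && length(x) == 2) p <- x / sum(x)
    else rlang::abort(sprintf("`%s` must be a two-state fit or a length-2 numeric", what))
    if (length(p) != 2) rlang::abort(sprintf("`%s` is not two-state", what))
    sort(p) # minor first
  }
  pz <- get_pops(zz, "zz")
  pd <- get_pops(deconv, "deconv")
  tibble::tibble(
    state = c("minor", "major"),
    zz_percent = 100 * pz,
    deconv_percent = 100 * pd,
    difference_points = abs(100 * pz - 100 * pd))
}

run_config_keys <- c("stage", "seed", "input", "output", "params", "log_level")

#' Read / write a JSON run configuration
#'
#' A flat JSON object with keys among `stage`, `seed`, `input`, `output`,
#' `params`, `log_level`; unknown keys are rejected so that typos fail
#' loudly rather than being silently ignored.
#'
#' @param path JSON file path.
#' @return [read_run_config()]: a named list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    rlang::abort(sprintf("unknown run-config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg
}

#' @rdname read_run_config
#' @param config Named list with keys among the supported set.
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), run_config_keys)
  if (length(unknown)) {
    rlang::abort(sprintf("unknown run-config key(s): %s", paste(unknown, collapse = ", ")))
  }
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Serialize / deserialize a kinetic scheme as JSON
#'
#' @param scheme A [kinetic_scheme()].
#' @param path JSON file path.
#' @return [read_scheme_json()]: the reconstructed [kinetic_scheme()].
#' @export
write_scheme_json <- function(scheme, path) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  jsonlite::write_json(
    list(states = scheme$states, edges = scheme$edges, topology = scheme$topology),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kinetic_scheme(tibble::as_tibble(obj$states), tibble::as_tibble(obj$edges),
                 obj$topology)
}
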