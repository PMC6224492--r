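water_resnames <- c("HOH", "WAT", "TIP3", "SOL")

#' Geometric hydrogen-bond criteria
#'
#' The two thresholds of the standard distance/angle definition used by
#' trajectory analysis tools: heavy-donor to acceptor distance cutoff
#' (default 3.5 Angstrom) and minimum donor-hydrogen-acceptor angle
#' (default 100 degrees). The distance cutoff applies between the heavy
#' donor atom and the acceptor (not hydrogen-acceptor).
#'
#' @param max_da_distance Maximum donor(heavy)-acceptor distance, Angstrom.
#' @param min_dha_angle Minimum donor-hydrogen-acceptor angle, degrees.
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, min_dha_angle = 100) {
  stopifnot(max_da_distance > 0, min_dha_angle >= 0, min_dha_angle <= 180)
  structure(list(max_da_distance = max_da_distance, min_dha_angle = min_dha_angle),
            class = "hbond_criteria")
}

# donors: N/O heavy atoms with a covalently attached H (d(H) < 1.2 A);
# acceptors: any N/O. Ligand and nonstandard residues are classified by
# the same element + hydrogen-connectivity rule.
.classify_atoms <- function(frame) {
  elem <- frame$element
  heavy <- which(elem %in% c("N", "O"))
  hydro <- which(elem == "H")
  donors <- list()
  if (length(heavy) && length(hydro)) {
    hx <- as.matrix(frame[hydro, c("x", "y", "z")])
    dx <- as.matrix(frame[heavy, c("x", "y", "z")])
    for (i in seq_along(heavy)) {
      dist2 <- colSums((t(hx) - dx[i, ])^2)
      att <- hydro[dist2 < 1.2^2]
      if (length(att)) donors[[length(donors) + 1]] <- list(heavy = heavy[i], h = att)
    }
  }
  list(donors = donors, acceptors = heavy)
}

.angle_deg <- function(a, b, c) {
  # angle at vertex b, degrees
  v1 <- a - b
  v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(min(max(cosang, -1), 1)) * 180 / pi
}

#' Find hydrogen bonds in a single frame
#'
#' Enumerates donor-H-acceptor triplets satisfying both geometric
#' criteria: heavy-donor to acceptor distance <= `max_da_distance` and
#' donor-H-acceptor angle >= `min_dha_angle`. Donors are N/O atoms with
#' an attached hydrogen (within 1.2 Angstrom); acceptors are any N/O.
#' N/O atoms without hydrogens simply act as acceptors only.
#'
#' @param frame Atom tibble for one frame, with columns `name`, `element`,
#'   `resno`, `resname`, `chain`, `x`, `y`, `z` (from [read_frames()] or
#'   [gen_frames()]).
#' @param criteria An [hbond_criteria()].
#' @return Tibble of accepted triplets: donor/hydrogen/acceptor
#'   identifiers plus `distance` (Angstrom) and `angle` (degrees).
#' @export
find_hbonds <- function(frame, criteria = hbond_criteria()) {
  frame <- tibble::as_tibble(frame)
  cls <- .classify_atoms(frame)
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  out <- list()
  for (don in cls$donors) {
    d <- don$heavy
    for (acc in cls$acceptors) {
      if (acc == d) next
      dist <- sqrt(sum((xyz[d, ] - xyz[acc, ])^2))
      if (dist > criteria$max_da_distance) next
      for (h in don$h) {
        ang <- .angle_deg(xyz[d, ], xyz[h, ], xyz[acc, ])
        if (ang >= criteria$min_dha_angle) {
          out[[length(out) + 1]] <- tibble::tibble(
            donor_chain = frame$chain[d], donor_resno = frame$resno[d],
            donor_resname = frame$resname[d], donor_atom = frame$name[d],
            hydrogen = frame$name[h],
            acceptor_chain = frame$chain[acc], acceptor_resno = frame$resno[acc],
            acceptor_resname = frame$resname[acc], acceptor_atom = frame$name[acc],
            distance = dist, angle = ang)
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      donor_chain = character(), donor_resno = integer(),
      donor_resname = character(), donor_atom = character(),
      hydrogen = character(),
      acceptor_chain = character(), acceptor_resno = integer(),
      acceptor_resname = character(), acceptor_atom = character(),
      distance = numeric(), angle = numeric()))
  }
  dplyr::bind_rows(out)
}

# parse "chain:resno:atom" selectors with "*" wildcards; "WAT:*" selects
# any water atom
parse_selector <- function(sel) {
  if (sel %in% c("WAT:*", "HOH:*")) {
    return(list(water = TRUE))
  }
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) {
    rlang::abort(sprintf("selector '%s' must be 'chain:resno:atom' (wildcard '*') or 'WAT:*'", sel))
  }
  list(water = FALSE, chain = parts[1], resno = parts[2], atom = parts[3])
}

match_selector <- function(frame, sel) {
  s <- parse_selector(sel)
  if (isTRUE(s$water)) return(frame$resname %in% water_resnames)
  ok <- rep(TRUE, nrow(frame))
  if (s$chain != "*") ok <- ok & frame$chain == s$chain
  if (s$resno != "*") ok <- ok & frame$resno == as.integer(s$resno)
  if (s$atom != "*") ok <- ok & frame$name == s$atom
  ok
}

.hbond_between <- function(hb, frame, mask_a, mask_b) {
  # any listed triplet whose donor matches one mask and acceptor the other
  if (!nrow(hb)) return(FALSE)
  key <- function(i) paste(frame$chain[i], frame$resno[i], frame$name[i])
  ka <- key(which(mask_a)); kb <- key(which(mask_b))
  don <- paste(hb$donor_chain, hb$donor_resno, hb$donor_atom)
  acc <- paste(hb$acceptor_chain, hb$acceptor_resno, hb$acceptor_atom)
  any((don %in% ka & acc %in% kb) | (don %in% kb & acc %in% ka))
}

#' Find water bridges between two solute partners in a frame
#'
#' A bridge exists when a single water molecule simultaneously satisfies
#' the hydrogen-bond criteria with both partners; either side may act as
#' donor or acceptor. Several waters may bridge the same pair in one
#' frame, giving one record each (occupancy still counts the frame once).
#'
#' @param frame Atom tibble for one frame.
#' @param partner_a,partner_b Selectors `"chain:resno:atom"` (wildcard
#'   `"*"` allowed per field).
#' @param criteria An [hbond_criteria()].
#' @return Tibble with one row per bridging water (`water_resno`,
#'   `water_resname`).
#' @export
water_bridges <- function(frame, partner_a, partner_b, criteria = hbond_criteria()) {
  frame <- tibble::as_tibble(frame)
  hb <- find_hbonds(frame, criteria)
  mask_a <- match_selector(frame, partner_a)
  mask_b <- match_selector(frame, partner_b)
  waters <- unique(frame$resno[frame$resname %in% water_resnames])
  out <- list()
  for (wr in waters) {
    mask_w <- frame$resname %in% water_resnames & frame$resno == wr
    if (.hbond_between(hb, frame, mask_w, mask_a) &&
        .hbond_between(hb, frame, mask_w, mask_b)) {
      out[[length(out) + 1]] <- tibble::tibble(
        water_resno = wr,
        water_resname = frame$resname[which(mask_w)[1]])
    }
  }
  if (!length(out)) {
    return(tibble::tibble(water_resno = integer(), water_resname = character()))
  }
  dplyr::bind_rows(out)
}

#' Occupancy of a direct or water-bridged interaction across frames
#'
#' Fraction of frames in which the interaction between the two partners
#' exists: a direct hydrogen bond (either partner donating), or — with
#' `bridged = TRUE` — at least one water bridging both partners.
#'
#' @param frames Tibble of atoms for all frames with a `frame` column
#'   (from [read_frames()] / [gen_frames()]), or a list of single-frame
#'   tibbles.
#' @param partner_a,partner_b Selectors (see [water_bridges()]).
#' @param criteria An [hbond_criteria()].
#' @param bridged Count water-bridged rather than direct interactions.
#' @return One-row tibble: `partner_a`, `partner_b`, `bridged`,
#'   `frames_present`, `frames_total`, `fraction`.
#' @export
occupancy <- function(frames, partner_a, partner_b,
                      criteria = hbond_criteria(), bridged = FALSE) {
  if (is.data.frame(frames)) {
    stopifnot("frame" %in% names(frames))
    frames <- split(tibble::as_tibble(frames), frames$frame)
  }
  stopifnot(length(frames) >= 1)
  all_atoms <- dplyr::bind_rows(frames)
  for (sel in c(partner_a, partner_b)) {
    if (!any(match_selector(all_atoms, sel))) {
      rlang::abort(sprintf("selector '%s' matches no atoms in any frame", sel))
    }
  }
  present <- vapply(frames, function(fr) {
    if (bridged) {
      nrow(water_bridges(fr, partner_a, partner_b, criteria)) > 0
    } else {
      hb <- find_hbonds(fr, criteria)
      .hbond_between(hb, fr, match_selector(fr, partner_a), match_selector(fr, partner_b))
    }
  }, logical(1))
  tibble::tibble(partner_a = partner_a, partner_b = partner_b, bridged = bridged,
                 frames_present = sum(present), frames_total = length(frames),
                 fraction = sum(present) / length(frames))
}
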