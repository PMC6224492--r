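# a minimal frame: donor N with H along +x, acceptor placed explicitly
frame_with_pair <- function(dist, angle) {
  g <- gen_frames(1, direct_present = TRUE, bridge_present = FALSE,
                  direct_distance = dist, direct_angle = angle)
  g$frames
}

test_that("the distance and angle cutoffs act exactly at their thresholds", {
  crit <- hbond_criteria()
  inside <- find_hbonds(frame_with_pair(3.40, 160), crit)
  expect_true(any(inside$donor_atom == "NH1" & inside$acceptor_atom == "N1"))
  too_far <- find_hbonds(frame_with_pair(3.60, 160), crit)
  expect_false(any(too_far$donor_atom == "NH1" & too_far$acceptor_atom == "N1"))
  bent <- find_hbonds(frame_with_pair(3.00, 95), crit)
  expect_false(any(bent$donor_atom == "NH1" & bent$acceptor_atom == "N1"))
  # 0.05 units inside/outside each threshold
  expect_true(any(find_hbonds(frame_with_pair(3.45, 160), crit)$acceptor_atom == "N1"))
  expect_false(any(find_hbonds(frame_with_pair(3.55, 160), crit)$acceptor_atom == "N1"))
  expect_true(any(find_hbonds(frame_with_pair(3.0, 100.05), crit)$acceptor_atom == "N1"))
  expect_false(any(find_hbonds(frame_with_pair(3.0, 99.95), crit)$acceptor_atom == "N1"))
})

test_that("planted geometry reproduces the requested distance and angle", {
  fr <- frame_with_pair(3.2, 123)
  hb <- find_hbonds(fr, hbond_criteria(max_da_distance = 10, min_dha_angle = 0))
  row <- hb[hb$donor_atom == "NH1" & hb$acceptor_atom == "N1", ]
  expect_equal(row$distance, 3.2, tolerance = 1e-9)
  expect_equal(row$angle, 123, tolerance = 1e-9)
})

test_that("water bridges require both partners simultaneously", {
  g <- gen_frames(1, direct_present = FALSE, bridge_present = TRUE)
  br <- water_bridges(g$frames, "L:1:O1", "A:310:OD1")
  expect_equal(nrow(br), 1)
  expect_equal(br$water_resno, 500)
  # water far away: no bridge
  g0 <- gen_frames(1, direct_present = FALSE, bridge_present = FALSE)
  expect_equal(nrow(water_bridges(g0$frames, "L:1:O1", "A:310:OD1")), 0)
})

test_that("two bridging waters give two records but one present frame", {
  g <- gen_frames(1, direct_present = FALSE, bridge_present = TRUE)
  fr <- g$frames
  # duplicate the bridging water as residue 501
  wat <- fr[fr$resname == "WAT", ]
  wat$resno <- 501L
  wat$eleno <- wat$eleno + 100L
  wat$z <- wat$z + 0.05
  fr2 <- dplyr::bind_rows(fr, wat)
  br <- water_bridges(fr2, "L:1:O1", "A:310:OD1")
  expect_equal(nrow(br), 2)
  occ <- occupancy(fr2, "L:1:O1", "A:310:OD1", bridged = TRUE)
  expect_equal(occ$frames_present, 1)
  expect_equal(occ$fraction, 1)
})

test_that("occupancy follows the planted schedule", {
  sched <- rep(c(TRUE, FALSE), c(13, 7))
  g <- gen_frames(20, direct_present = sched,
                  bridge_present = rep(c(TRUE, FALSE), 10), seed = 2)
  expect_equal(occupancy(g$frames, "A:288:NH1", "L:1:N1")$fraction, 0.65)
  expect_equal(occupancy(g$frames, "L:1:O1", "A:310:OD1", bridged = TRUE)$fraction, 0.5)
  all_in <- gen_frames(3)
  expect_equal(occupancy(all_in$frames, "A:288:NH1", "L:1:N1")$fraction, 1)
  none <- gen_frames(3, direct_present = rep(FALSE, 3))
  expect_equal(occupancy(none$frames, "A:288:NH1", "L:1:N1")$fraction, 0)
  expect_error(occupancy(g$frames, "A:999:XX1", "L:1:N1"), "matches no atoms")
})

test_that("detection matches the brute-force all-triplet oracle on random frames", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 60
    fr <- tibble::tibble(
      frame = 1, eleno = 1:n,
      name = sprintf("X%d", 1:n),
      element = sample(c("N", "O", "H", "C"), n, replace = TRUE),
      resno = sample(1:10, n, replace = TRUE),
      resname = "UNK", chain = "A",
      x = runif(n, 0, 12), y = runif(n, 0, 12), z = runif(n, 0, 12))
    got <- find_hbonds(fr, hbond_criteria())
    want <- oracle_hbonds(fr)
    key <- function(d, h, a) paste(d, h, a)
    got_keys <- sort(key(got$donor_atom, got$hydrogen, got$acceptor_atom))
    want_keys <- sort(key(fr$name[want[, 1]], fr$name[want[, 2]], fr$name[want[, 3]]))
    expect_equal(got_keys, want_keys)
  }
})

test_that("occupancy is invariant to frame order and rigid-body motion", {
  sched <- rep(c(TRUE, FALSE), c(7, 3))
  g <- gen_frames(10, direct_present = sched, seed = 4)
  base <- occupancy(g$frames, "A:288:NH1", "L:1:N1")$fraction
  # permute frame order
  perm <- g$frames
  perm$frame <- match(perm$frame, sample(1:10))
  expect_equal(occupancy(perm, "A:288:NH1", "L:1:N1")$fraction, base)
  # rotate + translate one frame rigidly
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- g$frames
  i <- moved$frame == 3
  xyz <- as.matrix(moved[i, c("x", "y", "z")]) %*% rot
  moved[i, c("x", "y", "z")] <- as.data.frame(sweep(xyz, 2, c(5, -2, 1), "+"))
  expect_equal(occupancy(moved, "A:288:NH1", "L:1:N1")$fraction, base)
})

test_that("direct occupancy is monotone in the criteria", {
  g <- gen_frames(8, direct_present = rep(TRUE, 8),
                  direct_distance = 3.3, direct_angle = 120, seed = 6)
  f_at <- function(d, a) {
    occupancy(g$frames, "A:288:NH1", "L:1:N1",
              criteria = hbond_criteria(d, a))$fraction
  }
  expect_true(f_at(3.0, 100) <= f_at(3.4, 100))
  expect_true(f_at(3.4, 100) <= f_at(4.0, 100))
  expect_true(f_at(3.5, 130) >= f_at(3.5, 150))
  expect_true(f_at(3.5, 100) >= f_at(3.5, 130))
})
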