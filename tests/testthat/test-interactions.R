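test_that("lock distance is the exact charge-center separation", {
  # noise-free generator: distance is exactly d_closed
  lk <- make_two_state_lock_trajectory(0, d_closed = 10, noise_sd = 0,
                                       n_frames = 3, seed = 1)
  s <- ionic_lock_series(lk, generic_map(lk$topology))
  expect_equal(s$series$distance, rep(10, 3), tolerance = 1e-9)
  expect_equal(s$broken_fraction, 1)   # 10 A > 5 A threshold
})

test_that("a stably formed lock reports ~4.5 A and zero broken fraction", {
  lk <- make_two_state_lock_trajectory(0, noise_sd = 0.1, n_frames = 2000,
                                       seed = 2)
  s <- ionic_lock_series(lk, generic_map(lk$topology))
  expect_equal(mean(s$series$distance), 4.5, tolerance = 0.02)
  expect_equal(s$broken_fraction, 0)
  all_open <- make_two_state_lock_trajectory(1, noise_sd = 0.1,
                                             n_frames = 2000, seed = 2)
  expect_equal(ionic_lock_series(all_open,
                                 generic_map(all_open$topology))$broken_fraction,
               1)
})

test_that("the broken fraction tracks the hidden Markov states", {
  lk <- make_two_state_lock_trajectory(0.56, n_frames = 8000, dwell = 50,
                                       seed = 4)
  s <- ionic_lock_series(lk, generic_map(lk$topology))
  truth <- mean(lk$ground_truth$states)
  # noise can only flip frames near the threshold; with d_closed 4.5 and
  # threshold 5.0 the excess is P(N(0, 0.3) > 0.5) of closed frames
  excess <- pnorm(0.5, sd = 0.3, lower.tail = FALSE) * (1 - truth)
  expect_equal(s$broken_fraction, truth + excess, tolerance = 0.02)
  # autocorrelation-adjusted 3 SE band around the stationary probability
  rho <- 1 - 1 / (2 * 50 * 0.56) - 1 / (2 * 50 * 0.44)
  se <- sqrt(0.56 * 0.44 / 8000 * (1 + rho) / (1 - rho))
  expect_lt(abs(s$broken_fraction - 0.56), 3 * se + excess)
})

test_that("missing charge-group atoms are reported by name", {
  h <- make_ideal_helix(helix_spec(4))
  top <- h$topology
  top$residues$name[1] <- "ARG"
  top$residues$generic_number <- c("3.50", "6.30", NA, NA)
  top$residues$name[2] <- "GLU"
  fs <- frame_series(top, h$xyz, h$times)
  expect_error(ionic_lock_series(fs, generic_map(top)),
               class = "gact_missing_atom_error")
})

test_that("salt-bridge detection matches hand-placed N-O distances", {
  fs <- pattern_contact_trajectory(c(TRUE, FALSE, TRUE, TRUE))
  sb <- salt_bridge_contacts(fs, cutoff = 4.0)
  expect_equal(nrow(sb$pairs), 1)
  expect_equal(sb$series[[1]], c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(sb$pairs$fraction, 0.75)
  none <- pattern_contact_trajectory(c(FALSE, FALSE))
  expect_equal(nrow(salt_bridge_contacts(none, cutoff = 4.0)$pairs), 0)
})

test_that("designed salt-bridge occupancy is recovered within 2 SE", {
  oc <- make_occupancy_trajectory(c(0.73, 0.31), kind = "salt_bridge",
                                  n_frames = 4000, seed = 6)
  fr <- contact_fractions(salt_bridge_contacts(oc))
  expect_equal(nrow(fr), 2)
  got <- sort(fr$fraction)
  truth <- sort(colMeans(oc$ground_truth$truth))
  expect_equal(got, truth, tolerance = 1e-12)   # detector = truth, bit-exact
  expect_lt(max(abs(got - sort(c(0.31, 0.73)))),
            2 * sqrt(0.73 * 0.27 / 4000) + 2 * sqrt(0.31 * 0.69 / 4000))
})

hbond_geometry_fixture <- function(acceptor_xyz) {
  atoms <- data.frame(
    serial = 1:5,
    name = c("CB", "OG", "HG", "CB", "OG"),
    element = c("C", "O", "H", "C", "O"),
    resindex = c(1L, 1L, 1L, 2L, 2L),
    is_sidechain = TRUE, is_hydrogen = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  residues <- data.frame(author_number = c(1L, 20L), insertion_code = "",
                         name = "SER", chain = "A", segment = "OTHER",
                         generic_number = NA_character_)
  top <- topology(atoms, residues)
  xyz <- t(vapply(seq_len(nrow(acceptor_xyz)), function(i)
    as.vector(t(rbind(c(-1.4, 0, 0), c(0, 0, 0), c(0.97, 0, 0),
                      acceptor_xyz[i, ] + c(2, 0, 0), acceptor_xyz[i, ]))),
    numeric(15)))
  frame_series(top, xyz, times = seq_len(nrow(acceptor_xyz)))
}

test_that("hydrogen bonds need both the distance and the angle criterion", {
  # linear O-H...O at 2.9 A -> bond; perpendicular H -> no bond
  fs <- hbond_geometry_fixture(rbind(c(2.9, 0, 0), c(0, 2.9, 0)))
  hb <- hydrogen_bond_contacts(fs)
  expect_true(hb$settings$hydrogens_used)
  expect_equal(nrow(hb$pairs), 1)
  expect_equal(hb$series[[1]], c(TRUE, FALSE))
})

test_that("hydrogen-bond decisions match a brute-force oracle on random geometries", {
  set.seed(41)
  n <- 1000
  acc <- matrix(rnorm(3 * n), n, 3)
  acc <- acc / sqrt(rowSums(acc^2)) * runif(n, 1.5, 5)
  fs <- hbond_geometry_fixture(acc)
  hb <- hydrogen_bond_contacts(fs, d_cut = 3.5, angle_cut = 120)
  got <- if (nrow(hb$pairs)) hb$series[[1]] else rep(FALSE, n)
  D <- c(0, 0, 0); H <- c(0.97, 0, 0)
  want <- vapply(seq_len(n), function(i) {
    A <- acc[i, ]
    dist_ok <- sqrt(sum((A - D)^2)) <= 3.5
    v1 <- D - H; v2 <- A - H
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    dist_ok && ang >= 120
  }, logical(1))
  expect_identical(got, want)
})

test_that("without hydrogens the detector falls back to distance only", {
  fs <- pattern_contact_trajectory(c(TRUE, FALSE))  # no H atoms at all
  hb <- hydrogen_bond_contacts(fs, d_cut = 3.5)
  expect_false(hb$settings$hydrogens_used)
  expect_equal(hb$series[[1]], c(TRUE, FALSE))
})

test_that("hydrophobic contacts follow carbon proximity and exclude neighbors", {
  oc <- make_occupancy_trajectory(c(0.98), kind = "hydrophobic",
                                  contact_distance = 4.0,
                                  n_frames = 3000, seed = 8)
  hp <- hydrophobic_contacts(oc, cutoff = 4.5)
  expect_equal(nrow(hp$pairs), 1)
  expect_equal(hp$pairs$fraction, mean(oc$ground_truth$truth))
  expect_lt(abs(hp$pairs$fraction - 0.98), 0.01)
  far <- make_occupancy_trajectory(c(1), kind = "hydrophobic",
                                   contact_distance = 6.0,
                                   apart_distance = 9, n_frames = 10,
                                   seed = 8)
  expect_equal(nrow(hydrophobic_contacts(far, cutoff = 4.5)$pairs), 0)
  # mixed polar-apolar pairs count (carbon-mediated criterion)
  mx <- make_occupancy_trajectory(c(1), kind = "hbond", contact_distance = 4.0,
                                  n_frames = 5, seed = 8)
  mx$topology$residues$name[2] <- "ILE"   # SER-ILE
  expect_equal(nrow(hydrophobic_contacts(mx, cutoff = 6)$pairs), 1)
})

test_that("sequence neighbors in the same segment are excluded", {
  oc <- make_occupancy_trajectory(c(1), kind = "hydrophobic",
                                  contact_distance = 4.0, n_frames = 5,
                                  seed = 1)
  near <- oc
  near$topology$residues$author_number <- c(100L, 102L)  # |i-j| < 3
  expect_equal(nrow(hydrophobic_contacts(near, cutoff = 4.5)$pairs), 0)
  near$topology$residues$segment <- c("TM5", "TM6")      # different segments
  expect_equal(nrow(hydrophobic_contacts(near, cutoff = 4.5)$pairs), 1)
})

test_that("enlarging a cutoff never decreases any contact fraction", {
  oc <- make_occupancy_trajectory(c(0.4, 0.7), kind = "salt_bridge",
                                  contact_distance = 3.9,
                                  n_frames = 500, seed = 10)
  f1 <- contact_fractions(salt_bridge_contacts(oc, cutoff = 4.0))
  f2 <- contact_fractions(salt_bridge_contacts(oc, cutoff = 9.0))
  key <- function(d) paste(d$author_i, d$author_j)
  common <- match(key(f1), key(f2))
  expect_true(all(f2$fraction[common] >= f1$fraction))
})

test_that("ligand contact percentages are exact by construction", {
  pr <- make_pseudo_receptor(50, activation = TRUE, seed = 12)
  prof <- ligand_contact_profile(pr$frames, cutoff = 4.0)
  expect_true(all(prof$percentage >= 0 & prof$percentage <= 100))
  expect_false(is.unsorted(rev(prof$percentage)))
  expect_gte(max(prof$percentage), 99)
  seg <- pr$frames$topology$residues$segment[prof$resindex]
  expect_true(all(prof$percentage[seg == "TM1"] == 0))
  # ligand in contact in exactly half the frames
  fs <- pattern_contact_trajectory(rep(c(TRUE, FALSE), 20))
  top <- fs$topology
  top$residues$segment[2] <- "LIGAND"
  top$ligand_atom_indices <- which(top$atoms$resindex == 2)
  fs2 <- frame_series(top, fs$xyz, fs$times)
  prof2 <- ligand_contact_profile(fs2, cutoff = 4.0)
  expect_equal(prof2$percentage[1], 50)
  expect_error(ligand_contact_profile(fs, cutoff = 4.0),
               class = "gact_no_ligand_error")
})

test_that("all interaction detectors are invariant under rigid transforms", {
  lk <- make_two_state_lock_trajectory(0.5, n_frames = 200, seed = 14)
  rt <- random_rigid_transform(15)
  moved <- transform_frames(lk, rt)
  m <- generic_map(lk$topology)
  expect_equal(ionic_lock_series(moved, m)$series$distance,
               ionic_lock_series(lk, m)$series$distance, tolerance = 1e-6)
  oc <- make_occupancy_trajectory(c(0.6), n_frames = 300, seed = 16)
  oc_m <- transform_frames(oc, random_rigid_transform(17))
  expect_equal(salt_bridge_contacts(oc_m)$pairs$fraction,
               salt_bridge_contacts(oc)$pairs$fraction, tolerance = 1e-12)
})
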