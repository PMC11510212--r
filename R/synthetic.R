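# Synthetic topologies and trajectories with known ground truth: ideal and
# proline-kinked helices, a two-state ionic-lock Markov chain, designed
# contact occupancies, designed motion correlations, and a seven-helix
# pseudo-receptor with an activation-like TM6 swing.
#
# Every generator is a pure function of its spec + seed; the hidden truth
# (states, truth tables, construction angles) rides along in
# frames$ground_truth for oracle tests.

#' Ideal alpha-helix parameters
#'
#' @param n_residues number of residues (>= 4).
#' @param rise rise per residue along the axis, Angstrom (1.5 for an ideal
#'   alpha helix).
#' @param twist rotation per residue about the axis, degrees (100).
#' @param radius C-alpha helix radius, Angstrom (2.3).
#' @return a `helix_spec` list.
#' @export
helix_spec <- function(n_residues, rise = 1.5, twist = 100, radius = 2.3) {
  if (n_residues < 4) stop_gact("helix needs >= 4 residues", class = "gact_spec_error")
  if (rise <= 0) stop_gact("rise must be positive", class = "gact_spec_error")
  structure(list(n_residues = as.integer(n_residues), rise = rise,
                 twist = twist, radius = radius), class = "gact_helix_spec")
}

ca_only_topology <- function(n, resnames = "ALA", authors = seq_len(n),
                             segment = "OTHER", generic = NA_character_,
                             chain = "A") {
  resnames <- rep_len(resnames, n)
  atoms <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                      resindex = seq_len(n), is_sidechain = FALSE,
                      is_hydrogen = FALSE, stringsAsFactors = FALSE)
  residues <- data.frame(author_number = as.integer(authors),
                         insertion_code = "", name = resnames, chain = chain,
                         segment = rep_len(segment, n),
                         generic_number = rep_len(generic, n),
                         stringsAsFactors = FALSE)
  topology(atoms, residues)
}

ideal_helix_coords <- function(spec, k = seq_len(spec$n_residues) - 1L) {
  th <- deg2rad(spec$twist)
  cbind(spec$radius * cos(k * th), spec$radius * sin(k * th), k * spec$rise)
}

#' Generate a single-frame ideal alpha helix (C-alpha only)
#'
#' Residue `k` (0-based) sits at
#' `(radius cos(k twist), radius sin(k twist), k rise)`; the helix axis is
#' `+z`.
#'
#' @param spec a [helix_spec].
#' @return a single-frame [frame_series] of C-alpha pseudo-residues.
#' @export
make_ideal_helix <- function(spec) {
  stopifnot(inherits(spec, "gact_helix_spec"))
  co <- ideal_helix_coords(spec)
  frame_series(ca_only_topology(spec$n_residues), coords_to_row(co),
               times = 0, label = "ideal_helix")
}

#' Proline-kink construction parameters
#'
#' @param bend bend angle between pre- and post-kink axes, degrees in
#'   `[0, 180)`.
#' @param wobble direction of the bend about the pre-axis, degrees in
#'   `(-180, 180]`, measured from the kink-residue C-alpha radial direction,
#'   right-handed about the pre-axis.
#' @param face_shift change in helical phase across the kink, degrees in
#'   `(-180, 180]`.
#' @param kink_residue 1-based index of the kink ("proline") residue.
#' @return a `kink_spec` list.
#' @export
kink_spec <- function(bend, wobble, face_shift, kink_residue) {
  if (bend < 0 || bend >= 180)
    stop_gact("bend must be in [0, 180)", class = "gact_spec_error")
  structure(list(bend = bend, wobble = wrap_angle(wobble),
                 face_shift = wrap_angle(face_shift),
                 kink_residue = as.integer(kink_residue)),
            class = "gact_kink_spec")
}

#' Generate a proline-kinked helix with known bend/wobble/face-shift
#'
#' The pre-segment is an ideal helix; residues after the kink residue are the
#' ideal continuation rotated by `bend` about an in-plane axis whose
#' direction is set by `wobble` (measured from the kink-residue C-alpha
#' radial direction), then rotated about the new post-axis by `face_shift`.
#' The kink residue is shared and unmoved.  [prokink_angles] recovers the
#' construction parameters; that round trip is the package's kink-geometry
#' oracle.
#'
#' @param pre,post [helix_spec]s for the two segments; they must share
#'   rise/twist/radius.  Total length is `pre$n_residues + post$n_residues`.
#' @param kink a [kink_spec]; its `kink_residue` must be the last pre-segment
#'   residue (default).
#' @return a single-frame [frame_series]; `ground_truth` holds the
#'   construction angles.
#' @export
make_kinked_helix <- function(pre, post, kink) {
  stopifnot(inherits(pre, "gact_helix_spec"), inherits(post, "gact_helix_spec"),
            inherits(kink, "gact_kink_spec"))
  if (pre$rise != post$rise || pre$twist != post$twist ||
      pre$radius != post$radius)
    stop_gact("pre and post helix specs must share rise/twist/radius",
              class = "gact_spec_error")
  K <- kink$kink_residue
  if (K < 1 || K > pre$n_residues)
    stop_gact("kink residue %d outside pre-segment (1..%d)", K,
              pre$n_residues, class = "gact_spec_error")
  n <- pre$n_residues + post$n_residues
  co <- ideal_helix_coords(pre, k = seq_len(n) - 1L)
  kidx <- K            # 1-based row of the kink residue
  post_rows <- seq(kidx + 1L, n)
  # bend direction in the xy plane, wobble degrees from the kink CA radial
  th <- deg2rad(pre$twist)
  v_ref <- c(cos((kidx - 1L) * th), sin((kidx - 1L) * th), 0)
  d <- rotation_about(c(0, 0, 1), kink$wobble) %*% v_ref
  pivot <- c(0, 0, (kidx - 1L) * pre$rise)     # pre-axis point at kink height
  if (kink$bend > 0) {
    R_bend <- rotation_about(vcross(c(0, 0, 1), d), kink$bend)
  } else R_bend <- diag(3)
  u_post <- as.vector(R_bend %*% c(0, 0, 1))
  R_fs <- rotation_about(u_post, kink$face_shift)
  M <- R_fs %*% R_bend
  co[post_rows, ] <- t(M %*% (t(co[post_rows, , drop = FALSE]) - pivot) + pivot)
  frame_series(ca_only_topology(n), coords_to_row(co), times = 0,
               label = "kinked_helix",
               ground_truth = list(bend = kink$bend, wobble = kink$wobble,
                                   face_shift = kink$face_shift,
                                   kink_residue = kidx))
}

#' Generate a two-state ionic-lock trajectory (hidden Markov chain)
#'
#' Emulates the R3.50-E6.30 charge-center distance switching between a
#' formed state (`d_closed`, ~4.5 Angstrom) and a broken state (`d_open`,
#' ~12.5 Angstrom).  The hidden chain has stationary open probability
#' `p_open` and state dwell times `2 dwell p_open` (open) and
#' `2 dwell (1 - p_open)` (closed), so occupancy estimators face realistic
#' dwell autocorrelation rather than i.i.d. frames.
#'
#' @param p_open stationary probability of the broken state, in `[0, 1]`.
#' @param d_closed,d_open formed/broken charge-center distances, Angstrom.
#' @param noise_sd Gaussian distance noise per frame, Angstrom.
#' @param dwell mean frames per state episode (average over the two states).
#' @param n_frames number of frames.
#' @param seed RNG seed; same seed gives bit-identical coordinates.
#' @param time_step_ns frame spacing in ns.
#' @return a [frame_series] of two pseudo-residues (ARG with CZ/NH1/NH2, GLU
#'   with CD/OE1/OE2); `ground_truth$states` is the hidden open/closed
#'   series.
#' @export
make_two_state_lock_trajectory <- function(p_open, d_closed = 4.5,
                                           d_open = 12.5, noise_sd = 0.3,
                                           dwell = 50, n_frames = 8000,
                                           seed = 1, time_step_ns = 0.1) {
  if (p_open < 0 || p_open > 1)
    stop_gact("p_open must be in [0, 1]", class = "gact_spec_error")
  if (d_open <= d_closed)
    stop_gact("d_open must exceed d_closed", class = "gact_spec_error")
  states <- with_seed(seed, {
    if (p_open == 0) rep(FALSE, n_frames)
    else if (p_open == 1) rep(TRUE, n_frames)
    else {
      q_open <- min(1, 1 / (2 * dwell * p_open))        # leave open
      q_closed <- min(1, 1 / (2 * dwell * (1 - p_open)))  # leave closed
      s <- logical(n_frames)
      s[1] <- stats::runif(1) < p_open
      u <- stats::runif(n_frames)
      for (t in seq_len(n_frames - 1L))
        s[t + 1L] <- if (s[t]) u[t] >= q_open else u[t] < q_closed
      s
    }
  })
  noise <- with_seed(seed + 7919L, stats::rnorm(n_frames, 0, noise_sd))
  d <- ifelse(states, d_open, d_closed) + noise
  # zero-mean charge-group atom offsets: group mean is exactly the site
  off <- rbind(c(0, 0, 0.8), c(0.6, 0, -0.4), c(-0.6, 0, -0.4))
  atoms <- data.frame(
    serial = 1:8,
    name = c("CA", "CZ", "NH1", "NH2", "CA", "CD", "OE1", "OE2"),
    element = c("C", "C", "N", "N", "C", "C", "O", "O"),
    resindex = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
    is_sidechain = c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    is_hydrogen = FALSE, stringsAsFactors = FALSE)
  residues <- data.frame(
    author_number = c(173L, 318L), insertion_code = "",
    name = c("ARG", "GLU"), chain = "A", segment = c("TM3", "TM6"),
    generic_number = c("3.50", "6.30"), stringsAsFactors = FALSE)
  top <- topology(atoms, residues)
  base <- rbind(c(-2, 0, 0), off, c(0, 0, 0), off)  # GLU block shifted per frame
  xyz <- matrix(NA_real_, n_frames, 24)
  for (t in seq_len(n_frames)) {
    co <- base
    co[5, 1] <- d[t] + 2
    co[6:8, 1] <- co[6:8, 1] + d[t]
    xyz[t, ] <- coords_to_row(co)
  }
  frame_series(top, xyz, times = (seq_len(n_frames) - 1) * time_step_ns,
               label = sprintf("lock_p%.2f", p_open),
               ground_truth = list(states = states, p_open = p_open,
                                   dwell = dwell, d_closed = d_closed,
                                   d_open = d_open, noise_sd = noise_sd))
}

occupancy_templates <- function(kind) {
  # A-side offsets are absolute (proximal atom at the origin); B-side offsets
  # are relative to B's proximal atom, which sits at (g, 0, 0) per frame.
  switch(kind,
    salt_bridge = list(
      resA = "ARG",
      atomsA = data.frame(name = c("CA", "CB", "NE", "CZ", "NH1", "NH2"),
                          element = c("C", "C", "N", "C", "N", "N"),
                          x = c(-3, -2, -1.2, -0.8, 0, -1.0),
                          y = c(0, 0, 0.6, 0, 0, -1.0), z = 0),
      resB = "GLU",
      atomsB = data.frame(name = c("CA", "CB", "CD", "OE1", "OE2"),
                          element = c("C", "C", "C", "O", "O"),
                          x = c(3, 2, 0.8, 0, 1.0),
                          y = c(0, 0, 0, 0, 1.0), z = 0)),
    hydrophobic = list(
      resA = "LEU",
      atomsA = data.frame(name = c("CA", "CB", "CG", "CD1", "CD2"),
                          element = "C",
                          x = c(-3, -2, -1, 0, -1),
                          y = c(0, 0, 0, 0, 1), z = 0),
      resB = "ILE",
      atomsB = data.frame(name = c("CA", "CB", "CG1", "CD1", "CG2"),
                          element = "C",
                          x = c(3, 2, 1, 0, 1),
                          y = c(0, 0, 0, 0, 1), z = 0)),
    hbond = list(
      resA = "SER",
      atomsA = data.frame(name = c("CA", "CB", "OG", "HG"),
                          element = c("C", "C", "O", "H"),
                          x = c(-2.5, -1.4, 0, 0.97),
                          y = 0, z = 0),
      resB = "GLU",
      atomsB = data.frame(name = c("CA", "CB", "CD", "OE1", "OE2"),
                          element = c("C", "C", "C", "O", "O"),
                          x = c(2.5, 1.6, 1.2, 0, 1.2),
                          y = c(0, 0, 0, 0, 1.1), z = 0)),
    stop_gact("unknown occupancy kind '%s'", kind, class = "gact_spec_error"))
}

#' Generate a trajectory with designed contact occupancies
#'
#' Each requested pair is an isolated two-residue unit (pairs are 60 Angstrom
#' apart, hence independent).  Per frame, an independent Bernoulli draw at
#' the target fraction places the interacting groups at `contact_distance`
#' (in contact) or `apart_distance` (apart); the draw matrix is retained as
#' ground truth.
#'
#' @param fractions numeric vector of target contact fractions in `[0, 1]`,
#'   one per pair.
#' @param kind `"salt_bridge"` (ARG-GLU), `"hydrophobic"` (LEU-ILE) or
#'   `"hbond"` (SER-GLU) pair template.
#' @param contact_distance,apart_distance proximal-atom separations for the
#'   in-contact / apart states, Angstrom (`contact_distance <
#'   apart_distance`).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param time_step_ns frame spacing in ns.
#' @return a [frame_series]; `ground_truth$truth` is the frames-by-pairs
#'   contact truth table.
#' @export
make_occupancy_trajectory <- function(fractions, kind = "salt_bridge",
                                      contact_distance = 3.2,
                                      apart_distance = 8.0,
                                      n_frames = 5000, seed = 1,
                                      time_step_ns = 0.1) {
  if (any(fractions < 0 | fractions > 1))
    stop_gact("target fractions must lie in [0, 1]", class = "gact_spec_error")
  if (contact_distance >= apart_distance)
    stop_gact("contact_distance must be < apart_distance",
              class = "gact_spec_error")
  tpl <- occupancy_templates(kind)
  npair <- length(fractions)
  truth <- with_seed(seed, {
    m <- matrix(stats::runif(n_frames * npair), n_frames, npair)
    sweep(m, 2, fractions, `<`)
  })
  nA <- nrow(tpl$atomsA); nB <- nrow(tpl$atomsB)
  atoms <- list(); residues <- list(); base <- list()
  for (p in seq_len(npair)) {
    yoff <- 60 * (p - 1)
    riA <- 2L * p - 1L; riB <- 2L * p
    atoms[[p]] <- data.frame(
      name = c(tpl$atomsA$name, tpl$atomsB$name),
      element = c(tpl$atomsA$element, tpl$atomsB$element),
      resindex = c(rep(riA, nA), rep(riB, nB)), stringsAsFactors = FALSE)
    residues[[p]] <- data.frame(
      author_number = c(20L * riA, 20L * riB), insertion_code = "",
      name = c(tpl$resA, tpl$resB), chain = "A", segment = "OTHER",
      generic_number = NA_character_, stringsAsFactors = FALSE)
    base[[p]] <- rbind(
      cbind(tpl$atomsA$x, tpl$atomsA$y + yoff, tpl$atomsA$z),
      cbind(tpl$atomsB$x, tpl$atomsB$y + yoff, tpl$atomsB$z))
  }
  atab <- do.call(rbind, atoms)
  atab$serial <- seq_len(nrow(atab))
  atab$is_sidechain <- !(atab$name %in% BACKBONE_ATOMS)
  atab$is_hydrogen <- atab$element == "H"
  top <- topology(atab, do.call(rbind, residues))
  base_all <- do.call(rbind, base)
  b_rows <- unlist(lapply(seq_len(npair),
                          function(p) (p - 1L) * (nA + nB) + nA + seq_len(nB)))
  xyz <- matrix(NA_real_, n_frames, 3L * nrow(atab))
  for (t in seq_len(n_frames)) {
    co <- base_all
    g <- ifelse(truth[t, ], contact_distance, apart_distance)
    co[b_rows, 1] <- co[b_rows, 1] + rep(g, each = nB)
    xyz[t, ] <- coords_to_row(co)
  }
  frame_series(top, xyz, times = (seq_len(n_frames) - 1) * time_step_ns,
               label = sprintf("occupancy_%s", kind),
               ground_truth = list(truth = truth, fractions = fractions,
                                   kind = kind))
}

#' Generate a trajectory with designed residue-pair motion correlations
#'
#' Each pair is two C-alpha pseudo-residues; per-frame displacements are
#' drawn per axis from a bivariate normal with the target correlation, so
#' the displacement-vector correlation (DCCM entry) equals the target in
#' expectation (exactly for +/-1).
#'
#' @param correlations numeric vector of target Pearson correlations in
#'   `[-1, 1]`, one per pair.
#' @param displacement_sd per-axis displacement standard deviation, Angstrom.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param time_step_ns frame spacing in ns.
#' @return a [frame_series]; `ground_truth$correlations` holds the targets.
#' @export
make_correlated_trajectory <- function(correlations, displacement_sd = 1.0,
                                       n_frames = 10000, seed = 1,
                                       time_step_ns = 0.1) {
  if (any(abs(correlations) > 1))
    stop_gact("correlations must lie in [-1, 1]", class = "gact_spec_error")
  npair <- length(correlations)
  n <- 2L * npair
  top <- ca_only_topology(n, resnames = "GLY",
                          authors = 10L * seq_len(n))
  base <- matrix(0, n, 3)
  base[, 1] <- rep(c(0, 10), npair)
  base[, 2] <- rep(60 * (seq_len(npair) - 1), each = 2)
  xyz <- matrix(rep(coords_to_row(base), n_frames), nrow = n_frames,
                byrow = TRUE)
  disp <- with_seed(seed, {
    lapply(seq_len(npair), function(p) {
      z1 <- matrix(stats::rnorm(n_frames * 3, 0, displacement_sd), n_frames, 3)
      z2 <- matrix(stats::rnorm(n_frames * 3, 0, displacement_sd), n_frames, 3)
      c_ <- correlations[p]
      list(a = z1, b = c_ * z1 + sqrt(max(0, 1 - c_^2)) * z2)
    })
  })
  for (p in seq_len(npair)) {
    ia <- 2L * p - 1L; ib <- 2L * p
    xyz[, xyz_cols(ia)] <- xyz[, xyz_cols(ia)] + disp[[p]]$a
    xyz[, xyz_cols(ib)] <- xyz[, xyz_cols(ib)] + disp[[p]]$b
  }
  frame_series(top, xyz, times = (seq_len(n_frames) - 1) * time_step_ns,
               label = "correlated",
               ground_truth = list(correlations = correlations))
}

#' Generate a seven-helix pseudo-receptor ensemble
#'
#' Seven 31-residue C-alpha helices on a 12 Angstrom circle with alternating
#' up/down orientation (odd TMs run extracellular-to-intracellular, as in a
#' real 7TM bundle), Ballesteros-Weinstein generics x.30..x.60 anchored at
#' x.50 mid-membrane, an ARG at 3.50 and a GLU at 6.30 forming a 4.5
#' Angstrom charge-center ionic lock at the intracellular face.  With
#' `activation = TRUE` the intracellular third of TM6 swings outward
#' progressively over the second half of the frames (lock distance drifting
#' 4.5 -> 12.5 Angstrom) and a three-atom pseudo-ligand sits against the
#' extracellular ends of TM5/TM6.  Everything else only jitters.
#'
#' @param n_frames number of frames.
#' @param activation logical; generate the active-like ensemble?
#' @param seed RNG seed.
#' @param jitter_sd isotropic per-coordinate Gaussian jitter, Angstrom.
#' @param time_step_ns frame spacing in ns.
#' @return list with `frames` (a [frame_series]) and `map` (a `gact_bwmap`).
#' @export
make_pseudo_receptor <- function(n_frames = 200, activation = FALSE,
                                 seed = 1, jitter_sd = 0.15,
                                 time_step_ns = 0.1) {
  nres <- 31L; mid <- 16L; rise <- 1.5; twist <- deg2rad(100); rad <- 2.3
  bundle_r <- 12
  atoms <- list(); residues <- list(); coords <- list()
  centers <- list()
  for (h in 1:7) {
    ah <- 2 * pi * (h - 1) / 7
    ch <- c(bundle_r * cos(ah), bundle_r * sin(ah), 0)
    centers[[h]] <- ch
    up <- h %% 2 == 0
    k <- seq_len(nres)
    z <- (if (up) 1 else -1) * (k - mid) * rise
    ph <- k * twist
    co <- cbind(ch[1] + rad * cos(ph), ch[2] + rad * sin(ph), z)
    rname <- rep("ALA", nres)
    if (h == 3) rname[21] <- "ARG"
    if (h == 6) rname[1] <- "GLU"
    residues[[h]] <- data.frame(
      author_number = 100L * h + k, insertion_code = "", name = rname,
      chain = "A", segment = sprintf("TM%d", h),
      generic_number = sprintf("%d.%d", h, 29L + k), stringsAsFactors = FALSE)
    atoms[[h]] <- data.frame(name = "CA", element = "C",
                             resindex = k, stringsAsFactors = FALSE)
    coords[[h]] <- co
  }
  rtab <- do.call(rbind, residues)
  res_offset <- cumsum(c(0, rep(nres, 6)))
  for (h in 1:7) atoms[[h]]$resindex <- atoms[[h]]$resindex + res_offset[h]
  atab <- do.call(rbind, atoms)
  base <- do.call(rbind, coords)

  # ionic-lock charge groups between the intracellular ends of TM3 and TM6
  c3 <- centers[[3]]; c6 <- centers[[6]]
  u_lock <- vhat(c6 - c3)
  lock_mid <- (c3 + c6) / 2 + c(0, 0, -15)
  off <- rbind(c(0, 0, 0.8), c(0.6, 0, -0.4), c(-0.6, 0, -0.4))
  arg_res <- which(rtab$generic_number == "3.50")
  glu_res <- which(rtab$generic_number == "6.30")
  arg_xyz <- sweep(off, 2, lock_mid - 2.25 * u_lock, `+`)
  glu_xyz <- sweep(off, 2, lock_mid + 2.25 * u_lock, `+`)
  extra <- data.frame(name = c("CZ", "NH1", "NH2", "CD", "OE1", "OE2"),
                      element = c("C", "N", "N", "C", "O", "O"),
                      resindex = c(rep(arg_res, 3), rep(glu_res, 3)),
                      stringsAsFactors = FALSE)
  atab <- rbind(atab, extra)
  base <- rbind(base, arg_xyz, glu_xyz)
  glu_atom_rows <- nrow(atab) - 2:0

  lig_atom_rows <- integer()
  if (activation) {
    # pseudo-ligand pressed against the extracellular ends of TM5 and TM6
    p5 <- base[res_offset[5] + 6L, ]            # TM5 k=6, extracellular
    p6 <- base[res_offset[6] + 26L, ]           # TM6 k=26, extracellular
    in5 <- vhat(-c(centers[[5]][1:2], 0))
    in6 <- vhat(-c(centers[[6]][1:2], 0))
    lig <- rbind(p5 + 3.0 * in5, p6 + 3.0 * in6,
                 (p5 + 3.0 * in5 + p6 + 3.0 * in6) / 2)
    rtab <- rbind(rtab, data.frame(
      author_number = 900L, insertion_code = "", name = "LIG", chain = "A",
      segment = "LIGAND", generic_number = NA_character_,
      stringsAsFactors = FALSE))
    atab <- rbind(atab, data.frame(name = c("C1", "C2", "C3"), element = "C",
                                   resindex = nrow(rtab),
                                   stringsAsFactors = FALSE))
    lig_atom_rows <- nrow(atab) - 2:0
    base <- rbind(base, lig)
  }
  atab$serial <- seq_len(nrow(atab))
  atab$is_sidechain <- atab$name != "CA"
  atab$is_hydrogen <- FALSE
  atab <- atab[, c("serial", "name", "element", "resindex",
                   "is_sidechain", "is_hydrogen")]
  top <- topology(atab, rtab, ligand_atom_indices = lig_atom_rows)

  # activation motion: intracellular third of TM6 swings radially outward
  ramp <- rep(0, n_frames)
  if (activation && n_frames > 1) {
    half <- floor(n_frames / 2)
    ramp[(half + 1):n_frames] <- seq(0, 1, length.out = n_frames - half)
  }
  out6 <- vhat(c(centers[[6]][1:2], 0))
  w6 <- pmax(0, (11 - seq_len(nres)) / 10)      # 1 at k=1 -> 0 at k>=11
  tm6_rows <- res_offset[6] + seq_len(nres)
  na <- nrow(atab)
  jitter <- with_seed(seed, stats::rnorm(n_frames * 3L * na, 0, jitter_sd))
  xyz <- matrix(rep(coords_to_row(base), n_frames), nrow = n_frames,
                byrow = TRUE) +
    matrix(jitter, n_frames, 3L * na)
  if (activation) {
    amp <- 8 * ramp
    for (k in seq_len(nres)) {
      if (w6[k] == 0) next
      colsk <- xyz_cols(tm6_rows[k])
      xyz[, colsk[1]] <- xyz[, colsk[1]] + amp * w6[k] * out6[1]
      xyz[, colsk[2]] <- xyz[, colsk[2]] + amp * w6[k] * out6[2]
    }
    # GLU charge group rides outward along the lock axis: distance 4.5 + amp
    for (r in glu_atom_rows) {
      colsr <- xyz_cols(r)
      xyz[, colsr[1]] <- xyz[, colsr[1]] + amp * u_lock[1]
      xyz[, colsr[2]] <- xyz[, colsr[2]] + amp * u_lock[2]
      xyz[, colsr[3]] <- xyz[, colsr[3]] + amp * u_lock[3]
    }
  }
  fs <- frame_series(top, xyz, times = (seq_len(n_frames) - 1) * time_step_ns,
                     label = if (activation) "ACTIVE" else "INACTIVE",
                     ground_truth = list(activation = activation, ramp = ramp,
                                         lock_design = 4.5 + 8 * ramp))
  list(frames = fs, map = generic_map(top))
}
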