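# Superposition, fluctuation and dihedral geometry.

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation + translation minimising the RMSD of the
#' selected atoms of `mobile` onto `reference`.
#'
#' @param mobile,reference n_atoms-by-3 coordinate matrices.
#' @param sel optional [selection]; defaults to all atoms.  At least 3
#'   non-collinear atoms are required.
#' @return list with `rotation` (3x3, det +1), `translation` (length-3) and
#'   `rmsd` over the selection; apply as `coords %*% t(rotation) +
#'   translation`.
#' @export
kabsch_superpose <- function(mobile, reference, sel = NULL) {
  idx <- if (is.null(sel)) seq_len(nrow(mobile)) else sel$atom_indices
  if (length(idx) < 3)
    stop_gact("superposition needs >= 3 atoms", class = "gact_degenerate_error")
  A <- mobile[idx, , drop = FALSE]
  B <- reference[idx, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (qr(A0)$rank < 2)
    stop_gact("superposition atoms are collinear", class = "gact_degenerate_error")
  s <- svd(crossprod(A0, B0))       # 3x3
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B0)^2)))
  list(rotation = R, translation = as.vector(cb - R %*% ca), rmsd = rmsd)
}

apply_superposition <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, fit$translation, `+`)
}

# Superpose every frame of a FrameSeries onto reference coordinates, fitting
# on fit_sel atoms; returns a new xyz matrix (all atoms transformed).  With
# fewer than 3 fit atoms a least-squares fit is underdetermined and frames
# are used as-is (displacement statistics are rigid-motion invariant anyway).
superpose_frames <- function(frames, reference, fit_sel = NULL) {
  xyz <- frames$xyz
  idx <- if (is.null(fit_sel)) seq_len(n_atoms(frames)) else fit_sel$atom_indices
  if (length(idx) < 3) return(xyz)
  out <- xyz
  for (i in seq_len(nrow(xyz))) {
    co <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    f <- kabsch_superpose(co, reference, fit_sel)
    out[i, ] <- coords_to_row(apply_superposition(co, f))
  }
  out
}

#' Per-frame RMSD to a reference structure
#'
#' Each frame is independently superposed onto the reference (over the
#' selection) before the RMSD is computed, as in standard trajectory RMSD
#' traces.
#'
#' @param frames a [frame_series].
#' @param reference n_atoms-by-3 reference coordinates (e.g.
#'   `frame_coords(frames, 1)`).
#' @param sel [selection] of atoms to fit and measure (e.g. all C-alpha).
#' @return data.frame with `time_ns` and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(frames, reference, sel = NULL) {
  vals <- vapply(seq_len(n_frames(frames)), function(i)
    kabsch_superpose(frame_coords(frames, i), reference, sel)$rmsd,
    numeric(1))
  data.frame(time_ns = frames$times, rmsd = vals)
}

#' Root-mean-square fluctuation per residue
#'
#' Frames are superposed on `fit_sel` to their mean structure (mean, refit,
#' mean: two passes), then `RMSF_i = sqrt(<|r_i - <r_i>|^2>)` is reported for
#' every atom of `sel`, labelled by residue.
#'
#' @param frames a [frame_series] with >= 2 frames.
#' @param sel [selection] of atoms to report (typically C-alpha).
#' @param fit_sel [selection] to superpose on; defaults to `sel`.
#' @return data.frame with `resindex`, `author_number`, `label` and `rmsf`
#'   (Angstrom).
#' @export
rmsf <- function(frames, sel, fit_sel = sel) {
  if (n_frames(frames) < 2)
    stop_gact("RMSF needs >= 2 frames", class = "gact_insufficient_error")
  ref <- frame_coords(frames, 1)
  xyz <- superpose_frames(frames, ref, fit_sel)
  for (pass in 1:2) {
    mean_co <- matrix(colMeans(xyz), ncol = 3, byrow = TRUE)
    tmp <- frame_series(frames$topology, xyz, frames$times)
    xyz <- superpose_frames(tmp, mean_co, fit_sel)
  }
  mean_co <- matrix(colMeans(xyz), ncol = 3, byrow = TRUE)
  idx <- sel$atom_indices
  dev2 <- matrix(0, nrow(xyz), length(idx))
  for (j in seq_along(idx)) {
    cj <- xyz_cols(idx[j])
    dev2[, j] <- (xyz[, cj[1]] - mean_co[idx[j], 1])^2 +
      (xyz[, cj[2]] - mean_co[idx[j], 2])^2 +
      (xyz[, cj[3]] - mean_co[idx[j], 3])^2
  }
  ri <- frames$topology$atoms$resindex[idx]
  data.frame(resindex = ri,
             author_number = frames$topology$residues$author_number[ri],
             label = residue_label(frames$topology, ri),
             rmsf = sqrt(colMeans(dev2)))
}

#' Torsion angle of four points
#'
#' IUPAC sign convention: cis = 0, trans = 180; result in `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop_gact("dihedral undefined: collinear or coincident points",
              class = "gact_degenerate_error")
  m <- vcross(n1, vhat(b2))
  wrap_angle(rad2deg(atan2(sum(m * n2), sum(n1 * n2))))
}

# Vectorised dihedral over frames: a1..a4 atom indices into the topology.
dihedral_series_raw <- function(xyz, a1, a2, a3, a4) {
  P <- function(a) xyz[, xyz_cols(a), drop = FALSE]
  p1 <- P(a1); p2 <- P(a2); p3 <- P(a3); p4 <- P(a4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  b2h <- b2 / sqrt(rowSums(b2^2))
  m <- cr(n1, b2h)
  wrap_angle(rad2deg(atan2(rowSums(m * n2), rowSums(n1 * n2))))
}

#' Circular mean of angles
#'
#' `atan2(mean sin, mean cos)`, wrapped to `(-180, 180]`.  Plain arithmetic
#' averages are wrong near +/-180 (cf. backbone phi values around -157).
#'
#' @param angles numeric vector of angles in degrees.
#' @return the circular mean in degrees, with attribute `resultant` (mean
#'   resultant length in `[0, 1]`).
#' @export
circular_mean <- function(angles) {
  if (!length(angles))
    stop_gact("circular mean of an empty set", class = "gact_empty_error")
  s <- mean(sin(deg2rad(angles))); c <- mean(cos(deg2rad(angles)))
  r <- sqrt(s^2 + c^2)
  if (r < 1e-12)
    stop_gact("circular mean undefined: zero resultant", class = "gact_degenerate_error")
  structure(wrap_angle(rad2deg(atan2(s, c))), resultant = r)
}

#' Circular standard deviation of angles (degrees)
#'
#' `sqrt(-2 log R)` with `R` the mean resultant length (Mardia).
#'
#' @param angles numeric vector of angles in degrees.
#' @export
circular_sd <- function(angles) {
  s <- mean(sin(deg2rad(angles))); c <- mean(cos(deg2rad(angles)))
  r <- min(1, sqrt(s^2 + c^2))
  if (r < 1e-12) return(Inf)
  rad2deg(sqrt(-2 * log(r)))
}

summarise_dihedral_series <- function(values, kind, resindex,
                                      transition_threshold = 30) {
  nf <- length(values)
  half <- floor(nf / 2)
  m1 <- if (half >= 1) as.numeric(circular_mean(values[seq_len(half)])) else NA
  m2 <- if (nf - half >= 1)
    as.numeric(circular_mean(values[(half + 1):nf])) else NA
  flag <- !is.na(m1) && !is.na(m2) &&
    abs(wrap_angle(m1 - m2)) > transition_threshold
  structure(list(resindex = resindex, kind = kind, values = values,
                 circular_mean = as.numeric(circular_mean(values)),
                 circular_sd = circular_sd(values),
                 half_split = list(mean_first_half = m1,
                                   mean_second_half = m2,
                                   transition_flag = flag)),
            class = "gact_dihedral_series")
}

#' @export
print.gact_dihedral_series <- function(x, ...) {
  cat(sprintf("<%s series> residue %d: mean %.2f, sd %.2f, halves %.2f/%.2f%s\n",
              x$kind, x$resindex, x$circular_mean, x$circular_sd,
              x$half_split$mean_first_half, x$half_split$mean_second_half,
              if (x$half_split$transition_flag) " [transition]" else ""))
  invisible(x)
}

find_atom <- function(topology, resindex, name) {
  i <- residue_atoms(topology, resindex, names = name)
  if (length(i) != 1)
    stop_gact("residue %d (%s) lacks atom %s", resindex,
              topology$residues$name[resindex], name,
              class = "gact_missing_atom_error")
  i
}

#' Backbone phi/psi series for one residue
#'
#' phi = C(i-1)-N(i)-CA(i)-C(i); psi = N(i)-CA(i)-C(i)-N(i+1).  The summary
#' includes the circular mean/sd and the first-half vs second-half circular
#' means with a transition flag (difference beyond `transition_threshold`
#' degrees), mirroring half-trajectory dial-plot comparisons.
#'
#' @param frames a [frame_series].
#' @param resindex 1-based residue index.
#' @param kind `"phi"` or `"psi"`.
#' @param transition_threshold half-split transition threshold in degrees.
#' @return a `gact_dihedral_series`.
#' @export
backbone_dihedral_series <- function(frames, resindex, kind = c("phi", "psi"),
                                     transition_threshold = 30) {
  kind <- match.arg(kind)
  top <- frames$topology
  nres <- nrow(top$residues)
  if (kind == "phi") {
    if (resindex <= 1)
      stop_gact("phi undefined at the N-terminus", class = "gact_missing_atom_error")
    a <- c(find_atom(top, resindex - 1L, "C"), find_atom(top, resindex, "N"),
           find_atom(top, resindex, "CA"), find_atom(top, resindex, "C"))
  } else {
    if (resindex >= nres)
      stop_gact("psi undefined at the C-terminus", class = "gact_missing_atom_error")
    a <- c(find_atom(top, resindex, "N"), find_atom(top, resindex, "CA"),
           find_atom(top, resindex, "C"), find_atom(top, resindex + 1L, "N"))
  }
  vals <- dihedral_series_raw(frames$xyz, a[1], a[2], a[3], a[4])
  summarise_dihedral_series(vals, kind, resindex, transition_threshold)
}

#' Side-chain chi1/chi2 series for one residue
#'
#' chi1 = N-CA-CB-(gamma atom); chi2 = CA-CB-(gamma)-(delta atom), using the
#' standard per-residue atom tables.
#'
#' @inheritParams backbone_dihedral_series
#' @param kind `"chi1"` or `"chi2"`.
#' @return a `gact_dihedral_series`.
#' @export
sidechain_chi_series <- function(frames, resindex, kind = c("chi1", "chi2"),
                                 transition_threshold = 30) {
  kind <- match.arg(kind)
  top <- frames$topology
  res <- top$residues$name[resindex]
  g <- CHI1_GAMMA[res]
  if (is.na(g))
    stop_gact("%s has no %s (no gamma atom)", res, kind,
              class = "gact_missing_atom_error")
  if (kind == "chi1") {
    a <- c(find_atom(top, resindex, "N"), find_atom(top, resindex, "CA"),
           find_atom(top, resindex, "CB"), find_atom(top, resindex, g))
  } else {
    d <- CHI2_DELTA[res]
    if (is.na(d))
      stop_gact("%s has no chi2 (no delta atom)", res,
                class = "gact_missing_atom_error")
    a <- c(find_atom(top, resindex, "CA"), find_atom(top, resindex, "CB"),
           find_atom(top, resindex, g), find_atom(top, resindex, d))
  }
  vals <- dihedral_series_raw(frames$xyz, a[1], a[2], a[3], a[4])
  summarise_dihedral_series(vals, kind, resindex, transition_threshold)
}
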