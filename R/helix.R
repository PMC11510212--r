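# Helix-axis fitting and Prokink-style kink geometry (bend, wobble,
# face shift) for proline-kinked transmembrane helices.
#
# Axis fit: second differences of consecutive C-alpha positions point
# exactly toward the axis for an ideal helix (the rise cancels), so cross
# products of successive second differences lie exactly along the axis
# (Kahn construction).  The axis direction is their normalised sum; the
# axis position, radius, per-residue phase and twist then come from an
# algebraic (Kasa) circle fit in the axis-normal plane.  A raw principal
# direction of the C-alpha cloud is biased by several degrees on segments
# shorter than ~4 turns (partial-turn phase imbalance), which this
# construction avoids; see the methods vignette.

#' Fit a helix axis through C-alpha positions
#'
#' @param ca numeric m-by-3 matrix of consecutive C-alpha coordinates
#'   (N- to C-terminal order), m >= 4.
#' @return a `gact_helix_axis`: list with `point` (a point on the axis),
#'   `direction` (unit vector, N->C), `radius`, `twist` (signed degrees per
#'   residue about `direction`), `rise` (Angstrom per residue), `phases`
#'   (per-residue helical phase, degrees, in the axis frame `e1`/`e2`) and
#'   `e1`, `e2` (the in-plane reference frame).
#' @export
fit_helix_axis <- function(ca) {
  ca <- as.matrix(ca)
  m <- nrow(ca)
  if (m < 4)
    stop_gact("helix axis fit needs >= 4 points", class = "gact_insufficient_error")
  w <- ca[c(-1, -m), , drop = FALSE] * -2 +
    ca[-c(1, 2), , drop = FALSE] + ca[-c(m - 1, m), , drop = FALSE]
  nw <- nrow(w)
  acc <- c(0, 0, 0)
  for (k in seq_len(nw - 1L)) acc <- acc + vcross(w[k, ], w[k + 1L, ])
  if (vnorm(acc) < 1e-9)
    stop_gact("helix axis undefined: points are (nearly) collinear",
              class = "gact_degenerate_error")
  u <- vhat(acc)
  if (sum((ca[m, ] - ca[1, ]) * u) < 0) u <- -u
  ctr <- colMeans(ca)
  # refine: circle-fit in the axis-normal plane, strip the radial part and
  # re-estimate the direction from the near-axis residue points (exact on an
  # ideal helix; suppresses the noise amplification of second differences)
  circle_fit <- function(u) {
    e1 <- perp_vector(u); e2 <- vcross(u, e1)
    rel <- sweep(ca, 2, ctr)
    a <- rel %*% e1; b <- rel %*% e2
    # Kasa algebraic circle fit: 2 a0 a + 2 b0 b + c = a^2 + b^2
    X <- cbind(2 * a, 2 * b, 1)
    beta <- tryCatch(solve(crossprod(X), crossprod(X, a^2 + b^2)),
                     error = function(e) stop_gact(
                       "helix circle fit degenerate",
                       class = "gact_degenerate_error"))
    a0 <- beta[1]; b0 <- beta[2]
    list(e1 = e1, e2 = e2, a = a, b = b, a0 = a0, b0 = b0,
         radius = sqrt(max(0, beta[3] + a0^2 + b0^2)),
         ph = atan2(b - b0, a - a0))
  }
  for (iter in 1:3) {
    cf <- circle_fit(u)
    onaxis <- ca - (cf$radius * cos(cf$ph)) %*% t(cf$e1) -
      (cf$radius * sin(cf$ph)) %*% t(cf$e2)
    pc1 <- stats::prcomp(onaxis)$rotation[, 1]
    if (sum(pc1 * u) < 0) pc1 <- -pc1
    u <- as.vector(pc1)
  }
  cf <- circle_fit(u)
  e1 <- cf$e1; e2 <- cf$e2; a0 <- cf$a0; b0 <- cf$b0
  radius <- cf$radius
  zax <- sweep(ca, 2, ctr) %*% u
  phases <- rad2deg(cf$ph)
  steps <- wrap_angle(diff(phases))
  twist <- as.numeric(circular_mean(steps))
  structure(list(point = ctr + a0 * e1 + b0 * e2, direction = u,
                 radius = radius, twist = twist,
                 rise = mean(diff(as.vector(zax))),
                 phases = as.vector(phases), e1 = e1, e2 = e2),
            class = "gact_helix_axis")
}

axis_foot <- function(axis, p) {
  axis$point + sum((p - axis$point) * axis$direction) * axis$direction
}

phase_about <- function(axis_point, u, e1, e2, p) {
  v <- p - (axis_point + sum((p - axis_point) * u) * u)
  rad2deg(atan2(sum(v * e2), sum(v * e1)))
}

#' Per-frame proline-kink angles (bend, wobble, face shift)
#'
#' For each frame, axes are fitted independently to the pre- and post-kink
#' C-alpha ranges.  `bend` is the angle between the two axes.  `wobble` is
#' the signed angle (right-handed about the pre-axis, in its normal plane)
#' from the kink-residue C-alpha radial direction to the projection of the
#' post-axis: the direction in which the helix bends.  `face_shift` is the
#' circular mean over the post residues of (observed helical phase about the
#' post axis, in the pre-axis frame transported by the minimal rotation
#' carrying the pre-axis onto the post-axis) minus (the phase predicted by
#' extrapolating the pre-segment twist through the kink): the rotation of
#' the post-helix face relative to an unkinked continuation.  Wobble is
#' flagged unreliable whenever `bend < bend_floor` - the bend direction of a
#' nearly straight helix is meaningless.
#'
#' @param frames a [frame_series] containing the helix.
#' @param kink_residue 1-based residue index of the kink (proline) residue.
#' @param pre_range,post_range integer vectors of residue indices (each
#'   >= 4, disjoint, flanking the kink).
#' @param bend_floor reliability floor for the wobble angle, degrees.
#' @return a `gact_kink_series`: per-frame data.frame `series` (bend,
#'   wobble, face_shift, wobble_reliable) plus `average` (mean bend,
#'   circular-mean wobble/face_shift over reliable frames).
#' @export
prokink_angles <- function(frames, kink_residue, pre_range, post_range,
                           bend_floor = 5) {
  top <- frames$topology
  if (length(pre_range) < 4 || length(post_range) < 4)
    stop_gact("pre and post ranges need >= 4 residues each",
              class = "gact_insufficient_error")
  if (length(intersect(pre_range, post_range)))
    stop_gact("pre and post ranges overlap", class = "gact_spec_error")
  ca_of <- function(r) vapply(r, function(i) find_atom(top, i, "CA"), integer(1))
  pre_atoms <- ca_of(pre_range); post_atoms <- ca_of(post_range)
  kink_atom <- find_atom(top, kink_residue, "CA")
  nf <- n_frames(frames)
  bend <- wobble <- fshift <- numeric(nf)
  reliable <- logical(nf)
  for (f in seq_len(nf)) {
    co <- frame_coords(frames, f)
    axp <- fit_helix_axis(co[pre_atoms, , drop = FALSE])
    axq <- fit_helix_axis(co[post_atoms, , drop = FALSE])
    u1 <- axp$direction; u2 <- axq$direction
    bend[f] <- rad2deg(acos(max(-1, min(1, sum(u1 * u2)))))
    reliable[f] <- bend[f] >= bend_floor
    kca <- co[kink_atom, ]
    v <- kca - axis_foot(axp, kca)
    wobble[f] <- if (vnorm(u2 - sum(u2 * u1) * u1) < 1e-9) NA_real_
      else signed_angle_about(v, u2, u1)
    # transported pre-axis frame for phase comparison across the kink
    R <- rotation_between(u1, u2)
    e1t <- as.vector(R %*% axp$e1); e2t <- as.vector(R %*% axp$e2)
    phiK <- phase_about(axp$point, u1, axp$e1, axp$e2, kca)
    dphi <- vapply(seq_along(post_range), function(j) {
      obs <- phase_about(axq$point, u2, e1t, e2t, co[post_atoms[j], ])
      pred <- phiK + (post_range[j] - kink_residue) * axp$twist
      wrap_angle(obs - pred)
    }, numeric(1))
    fshift[f] <- as.numeric(circular_mean(dphi))
  }
  ok <- reliable & !is.na(wobble)
  avg <- list(
    bend = mean(bend),
    wobble = if (any(ok)) as.numeric(circular_mean(wobble[ok])) else NA_real_,
    face_shift = as.numeric(circular_mean(fshift)),
    wobble_reliable = all(reliable))
  structure(list(series = data.frame(time_ns = frames$times, bend = bend,
                                     wobble = wobble, face_shift = fshift,
                                     wobble_reliable = reliable),
                 average = avg, bend_floor = bend_floor),
            class = "gact_kink_series")
}

#' @export
print.gact_kink_series <- function(x, ...) {
  a <- x$average
  cat(sprintf("<gact_kink_series> %d frames: bend %.2f, wobble %.2f%s, face shift %.2f\n",
              nrow(x$series), a$bend, a$wobble,
              if (!a$wobble_reliable) " (unreliable)" else "", a$face_shift))
  invisible(x)
}
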