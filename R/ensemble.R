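# Ensemble-level statistics: differential contact networks, combined PCA,
# dynamic cross-correlation, windowed correlation fractions and helix-end
# membrane-plane projections.

#' Differential contact occupancy between two ensembles
#'
#' For every residue pair in either detector result, `delta = f_test -
#' f_ref` (a pair missing from one side contributes fraction 0 there).
#' Positive values mean the interaction forms in the test ensemble; negative
#' values mean it breaks (e.g. the ionic lock at -0.47 between agonist-bound
#' and apo).  Both inputs must come from the same detector with identical
#' settings.
#'
#' @param test,ref `gact_contact_set`s from the same detector.
#' @return a `gact_delta`: data.frame `pairs` with `f_test`, `f_ref`,
#'   `delta`, plus kind/labels metadata.
#' @export
delta_fractions <- function(test, ref) {
  stopifnot(inherits(test, "gact_contact_set"),
            inherits(ref, "gact_contact_set"))
  if (!identical(test$kind, ref$kind) ||
      !identical(test$settings, ref$settings))
    stop_gact("contact sets computed with different detectors/settings",
              class = "gact_settings_error")
  key <- function(p) paste(pmin(p$author_i, p$author_j),
                           pmax(p$author_i, p$author_j))
  tp <- test$pairs; rp <- ref$pairs
  keys <- union(if (nrow(tp)) key(tp) else character(),
                if (nrow(rp)) key(rp) else character())
  if (!length(keys)) {
    empty <- data.frame(label_i = character(), label_j = character(),
                        author_i = integer(), author_j = integer(),
                        f_test = numeric(), f_ref = numeric(),
                        delta = numeric(), stringsAsFactors = FALSE)
    return(structure(list(pairs = empty, kind = test$kind,
                          labels = c(test = test$label, ref = ref$label),
                          settings = test$settings), class = "gact_delta"))
  }
  take <- function(p, what) {
    m <- match(keys, if (nrow(p)) key(p) else character())
    out <- p[[what]][m]
    if (what == "fraction") out[is.na(m)] <- 0
    out
  }
  lab_i <- take(tp, "label_i"); lab_j <- take(tp, "label_j")
  ai <- take(tp, "author_i"); aj <- take(tp, "author_j")
  miss <- is.na(ai)
  lab_i[miss] <- take(rp, "label_i")[miss]
  lab_j[miss] <- take(rp, "label_j")[miss]
  ai[miss] <- take(rp, "author_i")[miss]
  aj[miss] <- take(rp, "author_j")[miss]
  f_test <- take(tp, "fraction"); f_ref <- take(rp, "fraction")
  pairs <- data.frame(label_i = lab_i, label_j = lab_j,
                      author_i = ai, author_j = aj,
                      f_test = f_test, f_ref = f_ref,
                      delta = f_test - f_ref, stringsAsFactors = FALSE)
  structure(list(pairs = pairs, kind = test$kind,
                 labels = c(test = test$label, ref = ref$label),
                 settings = test$settings),
            class = "gact_delta")
}

#' @export
print.gact_delta <- function(x, ...) {
  cat(sprintf("<gact_delta> %s: %s - %s, %d pairs\n", x$kind,
              x$labels["test"], x$labels["ref"], nrow(x$pairs)))
  invisible(x)
}

#' Rank the most changed contact pairs
#'
#' Pairs with `|delta| >= min_abs_delta`, in descending `|delta|`; ties
#' break deterministically by author residue numbers.
#'
#' @param delta a `gact_delta` from [delta_fractions].
#' @param min_abs_delta report threshold on `|delta|`.
#' @return the filtered, ordered pair data.frame.
#' @export
top_differential_pairs <- function(delta, min_abs_delta = 0.2) {
  stopifnot(inherits(delta, "gact_delta"))
  p <- delta$pairs[abs(delta$pairs$delta) >= min_abs_delta, , drop = FALSE]
  if (!nrow(p)) return(p)
  p[order(-abs(p$delta), p$author_i, p$author_j), , drop = FALSE]
}

#' Combined principal component analysis of concatenated ensembles
#'
#' Frames of all ensembles are concatenated, superposed to the concatenated
#' mean structure over the selection (mean and fit iterated twice, so
#' neither ensemble's mean biases the difference mode), and the 3N x 3N
#' coordinate covariance is eigendecomposed.  Per-frame projections keep
#' their ensemble tag for 2D score scatter plots; component contributions
#' are eigenvalue shares of the total variance.
#'
#' @param ensembles list of [frame_series] sharing a topology layout over
#'   the selection.
#' @param sel [selection] of atoms to analyse (typically all C-alpha).
#' @param fit superpose frames to the concatenated mean first (default).
#'   `FALSE` analyses raw coordinates - only meaningful when the frames are
#'   already aligned (e.g. designed toy modes).
#' @return a `gact_pca`: `eigenvalues` (Angstrom^2, descending),
#'   `contribution` (percent), `eigenvectors` (3N x k), `mean_structure`
#'   (N x 3), `projections` data.frame (ensemble, frame, PC1..), plus the
#'   selection and topology for trace export.
#' @export
combined_pca <- function(ensembles, sel, fit = TRUE) {
  if (inherits(ensembles, "gact_frames")) ensembles <- list(ensembles)
  idx <- sel$atom_indices
  cols <- xyz_cols(idx)
  ref_names <- ensembles[[1]]$topology$atoms$name[idx]
  for (e in ensembles) {
    if (n_atoms(e) < max(idx) ||
        !identical(e$topology$atoms$name[idx], ref_names))
      stop_gact("selection does not resolve identically in every ensemble",
                class = "gact_settings_error")
  }
  X <- do.call(rbind, lapply(ensembles, function(e) e$xyz[, cols, drop = FALSE]))
  tags <- rep(vapply(ensembles, function(e) e$label, character(1)),
              vapply(ensembles, n_frames, numeric(1)))
  if (nrow(X) < 2)
    stop_gact("combined PCA needs >= 2 frames", class = "gact_insufficient_error")
  n <- length(idx)
  ref <- matrix(colMeans(X), ncol = 3, byrow = TRUE)
  if (fit) {
    for (pass in 1:2) {
      for (i in seq_len(nrow(X))) {
        co <- matrix(X[i, ], ncol = 3, byrow = TRUE)
        f <- kabsch_superpose(co, ref)
        X[i, ] <- coords_to_row(apply_superposition(co, f))
      }
      ref <- matrix(colMeans(X), ncol = 3, byrow = TRUE)
    }
  }
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  centered <- sweep(X, 2, colMeans(X))
  scores <- centered %*% e$vectors
  proj <- data.frame(ensemble = tags, frame = seq_len(nrow(X)))
  k_show <- min(10, ncol(scores))
  for (k in seq_len(k_show)) proj[[sprintf("PC%d", k)]] <- scores[, k]
  structure(list(eigenvalues = ev, contribution = 100 * ev / sum(ev),
                 eigenvectors = e$vectors, mean_structure = ref,
                 projections = proj, selection = sel,
                 topology = ensembles[[1]]$topology),
            class = "gact_pca")
}

#' @export
print.gact_pca <- function(x, ...) {
  cat(sprintf("<gact_pca> %d modes; EV1 %.2f%%, EV2 %.2f%% of total variance\n",
              length(x$eigenvalues), x$contribution[1],
              x$contribution[2] %||% NA))
  invisible(x)
}

#' Per-residue displacement loading of one PCA mode
#'
#' @param pca a `gact_pca`.
#' @param component mode index.
#' @return numeric vector: per selected atom, the Euclidean norm of the
#'   mode's (x, y, z) loading.
#' @export
pca_mode_loadings <- function(pca, component = 1) {
  v <- pca$eigenvectors[, component]
  sqrt(colSums(matrix(v, nrow = 3)^2))
}

#' Export a mode as interpolated trace frames
#'
#' The mean structure displaced along an eigenvector at `n_frames` evenly
#' spaced amplitudes spanning `+/- amplitude * sqrt(eigenvalue)`, the
#' standard animated-trace representation of an essential mode.
#'
#' @param pca a `gact_pca`.
#' @param component mode index.
#' @param n_frames number of trace frames.
#' @param amplitude half-range in standard deviations of the mode.
#' @return a [frame_series] over the analysed atoms (writable with
#'   [write_frames]).
#' @export
ev_trace_frames <- function(pca, component = 1, n_frames = 6, amplitude = 2) {
  if (component < 1 || component > length(pca$eigenvalues))
    stop_gact("component %d out of range (1..%d)", component,
              length(pca$eigenvalues), class = "gact_index_error")
  sd_k <- sqrt(pca$eigenvalues[component])
  amps <- if (n_frames == 1) 0 else
    seq(-amplitude * sd_k, amplitude * sd_k, length.out = n_frames)
  v <- pca$eigenvectors[, component]
  mean_row <- coords_to_row(pca$mean_structure)
  xyz <- t(vapply(amps, function(a) mean_row + a * v, numeric(length(v))))
  idx <- pca$selection$atom_indices
  top <- pca$topology
  ri <- top$atoms$resindex[idx]
  sub_res <- top$residues[sort(unique(ri)), , drop = FALSE]
  atoms <- data.frame(serial = seq_along(idx),
                      name = top$atoms$name[idx],
                      element = top$atoms$element[idx],
                      resindex = match(ri, sort(unique(ri))),
                      is_sidechain = top$atoms$is_sidechain[idx],
                      is_hydrogen = top$atoms$is_hydrogen[idx],
                      stringsAsFactors = FALSE)
  frame_series(topology(atoms, sub_res), xyz,
               times = seq_along(amps) - 1,
               label = sprintf("EV%d_trace", component))
}

#' Dynamic cross-correlation matrix (DCCM)
#'
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)` with `dr` the
#' displacement of each selected atom (one per residue, typically C-alpha)
#' from its mean position after superposition on `fit_sel`.
#' Zero-variance atoms yield NA entries (undefined, never coerced to 0).
#'
#' @param frames a [frame_series] with >= 10 frames.
#' @param sel [selection] with one atom per residue.
#' @param fit_sel superposition selection; defaults to `sel`.  Use `NULL`
#'   to skip fitting (frames already superposed).
#' @return a `gact_dccm`: matrix `dccm` with residue labels, plus the
#'   selection.
#' @export
dccm <- function(frames, sel, fit_sel = sel) {
  if (n_frames(frames) < 10)
    stop_gact("DCCM needs >= 10 frames", class = "gact_insufficient_error")
  xyz <- frames$xyz
  if (!is.null(fit_sel)) {
    ref <- frame_coords(frames, 1)
    xyz <- superpose_frames(frames, ref, fit_sel)
    mean_co <- matrix(colMeans(xyz), ncol = 3, byrow = TRUE)
    xyz <- superpose_frames(frame_series(frames$topology, xyz, frames$times),
                            mean_co, fit_sel)
  }
  idx <- sel$atom_indices
  n <- length(idx)
  cols <- xyz_cols(idx)
  D <- sweep(xyz[, cols, drop = FALSE], 2, colMeans(xyz[, cols, drop = FALSE]))
  # inner products of displacement vectors: sum over x,y,z of per-axis covs
  G <- matrix(0, n, n)
  for (ax in 1:3) {
    block <- D[, seq(ax, 3 * n, by = 3), drop = FALSE]
    G <- G + crossprod(block) / nrow(D)
  }
  v <- diag(G)
  # variances indistinguishable from zero (relative to the selection) are
  # undefined, not zero-correlated
  zero <- v <= max(v, 0) * 1e-12
  denom <- sqrt(outer(v, v))
  M <- G / denom
  M[zero, ] <- NA_real_
  M[, zero] <- NA_real_
  diag(M)[!zero] <- 1
  ri <- frames$topology$atoms$resindex[idx]
  labs <- residue_label(frames$topology, ri)
  dimnames(M) <- list(labs, labs)
  structure(list(dccm = M, resindex = ri, selection = sel,
                 label = frames$label),
            class = "gact_dccm")
}

#' @export
print.gact_dccm <- function(x, ...) {
  cat(sprintf("<gact_dccm> %d x %d [%s]\n", nrow(x$dccm), ncol(x$dccm),
              x$label))
  invisible(x)
}

#' Windowed correlation fractions per residue pair
#'
#' The trajectory is cut into non-overlapping windows of `window` frames
#' (windows kept independent for the fraction statistic); a DCCM is computed
#' per window, and for every residue pair the fraction of windows with
#' `C > +threshold` (correlated) and `C < -threshold` (anti-correlated) is
#' reported.  Differencing these fractions across ensembles (via
#' [delta_correlation_fractions]) gives the correlation-network change map.
#'
#' @param frames a [frame_series]; needs at least two full windows.
#' @param sel [selection], one atom per residue.
#' @param window window length in frames.
#' @param threshold correlation threshold `t`.
#' @return a `gact_corr_fractions`: matrices `correlated` and
#'   `anticorrelated` of window fractions, `n_windows`, parameters.
#' @export
windowed_correlation_fractions <- function(frames, sel, window = 100,
                                           threshold = 0.5) {
  nf <- n_frames(frames)
  nw <- nf %/% window
  if (window < 10)
    stop_gact("window of %d frames is below the 10-frame DCCM minimum",
              window, class = "gact_window_error")
  if (nw < 2)
    stop_gact("trajectory too short: %d frames give %d window(s) of %d",
              nf, nw, window, class = "gact_window_error")
  # superpose once on the whole trajectory, then window without refit
  ref <- frame_coords(frames, 1)
  xyz <- superpose_frames(frames, ref, sel)
  mean_co <- matrix(colMeans(xyz), ncol = 3, byrow = TRUE)
  xyz <- superpose_frames(frame_series(frames$topology, xyz, frames$times),
                          mean_co, sel)
  fitted <- frame_series(frames$topology, xyz, frames$times, frames$label)
  n <- length(sel$atom_indices)
  pos <- matrix(0, n, n); neg <- matrix(0, n, n)
  for (w in seq_len(nw)) {
    rows <- ((w - 1) * window + 1):(w * window)
    sub <- frame_series(frames$topology, xyz[rows, , drop = FALSE],
                        frames$times[rows], frames$label)
    M <- dccm(sub, sel, fit_sel = NULL)$dccm
    pos <- pos + (!is.na(M) & M > threshold)
    neg <- neg + (!is.na(M) & M < -threshold)
  }
  labs <- dimnames(dccm(fitted, sel, fit_sel = NULL)$dccm)
  pos <- pos / nw; neg <- neg / nw
  dimnames(pos) <- dimnames(neg) <- labs
  structure(list(correlated = pos, anticorrelated = neg, n_windows = nw,
                 window = window, threshold = threshold,
                 label = frames$label),
            class = "gact_corr_fractions")
}

#' Differential windowed-correlation fractions between two ensembles
#'
#' `delta = fraction(test) - fraction(ref)` for both the correlated and the
#' anti-correlated window fractions; settings must match.
#'
#' @param test,ref `gact_corr_fractions` with identical window/threshold.
#' @return list of matrices `correlated` and `anticorrelated`.
#' @export
delta_correlation_fractions <- function(test, ref) {
  if (test$window != ref$window || test$threshold != ref$threshold)
    stop_gact("windowed-correlation settings differ between ensembles",
              class = "gact_settings_error")
  list(correlated = test$correlated - ref$correlated,
       anticorrelated = test$anticorrelated - ref$anticorrelated)
}

#' Membrane-plane (x/y) projection of a helix end
#'
#' Frames are globally superposed on all C-alpha atoms; the per-frame (x, y)
#' centroid of the `n_end_residues` C-alpha at the chosen end of the helix
#' is traced, and the extents `(max - min)` along x and y are reported -
#' the "range_x/range_y Angstrom" summary of helix-end mobility in the
#' membrane plane (membrane normal = +z).
#'
#' @param frames a [frame_series].
#' @param helix segment name, e.g. `"TM6"`.
#' @param end `"intracellular"` (lower mean z) or `"extracellular"`.
#' @param n_end_residues number of terminal residues to average.
#' @return a `gact_projection`: per-frame `trace` (time_ns, x, y) and
#'   `extents` (range_x, range_y).
#' @export
helix_end_projection <- function(frames, helix,
                                 end = c("intracellular", "extracellular"),
                                 n_end_residues = 4) {
  end <- match.arg(end)
  top <- frames$topology
  res <- which(top$residues$segment == helix)
  if (!length(res))
    stop_gact("no residues in segment %s", helix, class = "gact_segment_error")
  ca <- vapply(res, function(i) find_atom(top, i, "CA"), integer(1))
  all_ca <- which(top$atoms$name == "CA")
  fitsel <- selection(all_ca, "all CA")
  ref <- frame_coords(frames, 1)
  xyz <- superpose_frames(frames, ref, fitsel)
  mean_co <- matrix(colMeans(xyz), ncol = 3, byrow = TRUE)
  zmean <- mean_co[ca, 3]
  o <- order(zmean)
  pick <- if (end == "intracellular") o[seq_len(min(n_end_residues, length(o)))]
    else rev(o)[seq_len(min(n_end_residues, length(o)))]
  sel_atoms <- ca[pick]
  ctr <- group_center_series(xyz, sel_atoms)
  structure(list(trace = data.frame(time_ns = frames$times,
                                    x = ctr[, 1], y = ctr[, 2]),
                 extents = c(range_x = diff(range(ctr[, 1])),
                             range_y = diff(range(ctr[, 2]))),
                 helix = helix, end = end,
                 residues = top$residues$author_number[res][pick],
                 label = frames$label),
            class = "gact_projection")
}

#' @export
print.gact_projection <- function(x, ...) {
  cat(sprintf("<gact_projection> %s %s end [%s]: %.1f/%.1f A\n", x$helix,
              x$end, x$label, x$extents["range_x"], x$extents["range_y"]))
  invisible(x)
}
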