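rep_frac <- function(f, n) rep(c(TRUE, FALSE), c(round(f * n), n - round(f * n)))

test_that("delta fractions reproduce a designed ionic-lock-scale change", {
  n <- 100
  ref <- salt_bridge_contacts(pattern_contact_trajectory(rep_frac(0.97, n),
                                                         label = "APO"))
  tst <- salt_bridge_contacts(pattern_contact_trajectory(rep_frac(0.50, n),
                                                         label = "DOI"))
  d <- delta_fractions(tst, ref)
  expect_equal(d$pairs$delta, -0.47, tolerance = 1e-12)
  expect_equal(d$labels[["test"]], "DOI")
  # antisymmetry
  d2 <- delta_fractions(ref, tst)
  expect_equal(d2$pairs$delta, -d$pairs$delta)
})

test_that("pairs missing from one ensemble contribute fraction zero", {
  n <- 50
  tst <- salt_bridge_contacts(pattern_contact_trajectory(
    list(rep_frac(0.6, n), rep(FALSE, n))))
  ref <- salt_bridge_contacts(pattern_contact_trajectory(
    list(rep(FALSE, n), rep_frac(0.8, n))))
  d <- delta_fractions(tst, ref)
  expect_equal(nrow(d$pairs), 2)
  expect_setequal(round(d$pairs$delta, 10), c(0.6, -0.8))
  # identical detector settings are required
  other <- salt_bridge_contacts(pattern_contact_trajectory(rep_frac(0.5, n)),
                                cutoff = 5.0)
  expect_error(delta_fractions(tst, other), class = "gact_settings_error")
})

test_that("top pairs rank by |delta| with a deterministic tie-break", {
  n <- 100
  pats <- list(rep_frac(0.05, n), rep_frac(0.85, n),
               rep_frac(0.36, n), rep_frac(0.10, n))
  refs <- list(rep_frac(0.93, n), rep_frac(0.12, n),
               rep_frac(0.05, n), rep_frac(0.05, n))
  tst <- salt_bridge_contacts(pattern_contact_trajectory(pats))
  ref <- salt_bridge_contacts(pattern_contact_trajectory(refs))
  d <- delta_fractions(tst, ref)
  top <- top_differential_pairs(d, min_abs_delta = 0.2)
  expect_equal(round(top$delta, 2), c(-0.88, 0.73, 0.31))
  expect_equal(nrow(top_differential_pairs(d, min_abs_delta = 1.1)), 0)
  # exact tie: order falls back to author numbers
  t2 <- salt_bridge_contacts(pattern_contact_trajectory(
    list(rep_frac(0.5, n), rep_frac(0.5, n))))
  r2 <- salt_bridge_contacts(pattern_contact_trajectory(
    list(rep(FALSE, n), rep(FALSE, n))))
  tied <- top_differential_pairs(delta_fractions(t2, r2), 0.2)
  expect_equal(tied$author_i, sort(tied$author_i))
})

toy_mode_frames <- function() {
  # 3 atoms, two exactly orthogonal unit-variance mode scores with
  # injected variances 4 and 1 -> covariance eigenvalues in ratio 80:20
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  v1 <- c(1, 0, 0, 0, 0, 0, 0, 0, 0)
  v2 <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  s <- c(1, 1, -1, -1); u <- c(1, -1, 1, -1)      # orthogonal, mean zero
  xyz <- t(vapply(1:4, function(t)
    as.vector(t(base)) + 2 * s[t] * v1 + 1 * u[t] * v2, numeric(9)))
  frame_series(ca_only_fixture(3), xyz, times = 1:4)
}

ca_only_fixture <- function(n) {
  topology(
    data.frame(serial = seq_len(n), name = "CA", element = "C",
               resindex = seq_len(n), is_sidechain = FALSE,
               is_hydrogen = FALSE),
    data.frame(author_number = seq_len(n), insertion_code = "", name = "GLY",
               chain = "A", segment = "OTHER",
               generic_number = NA_character_))
}

test_that("PCA matches a brute-force eigen-solve and closed-form contributions", {
  fs <- toy_mode_frames()
  sel <- select_atoms(fs$topology, "name CA")
  p <- combined_pca(fs, sel, fit = FALSE)
  expect_equal(p$contribution[1:2], c(80, 20), tolerance = 1e-9)
  expect_equal(sum(p$contribution), 100, tolerance = 1e-6)
  # brute-force covariance eigendecomposition oracle
  X <- fs$xyz
  Xc <- sweep(X, 2, colMeans(X))
  oracle <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)$values
  expect_equal(p$eigenvalues, pmax(oracle, 0), tolerance = 1e-8)
  # total variance preserved and eigenvectors orthonormal
  expect_equal(sum(p$eigenvalues), sum(diag(crossprod(Xc) / (nrow(X) - 1))),
               tolerance = 1e-8)
  G <- crossprod(p$eigenvectors)
  expect_equal(G, diag(nrow(G)), tolerance = 1e-6)
})

test_that("PCA agrees with an independent library implementation", {
  skip_if_not_installed("bio3d")
  set.seed(19)
  n <- 4
  xyz <- matrix(rnorm(40 * 3 * n, sd = 1), 40, 3 * n) +
    matrix(rep(rnorm(3 * n, sd = 10), each = 40), 40)
  fs <- frame_series(ca_only_fixture(n), xyz, times = seq_len(40))
  p <- combined_pca(fs, select_atoms(fs$topology, "name CA"), fit = FALSE)
  ref <- bio3d::pca.xyz(xyz)
  expect_equal(p$eigenvalues, ref$L, tolerance = 1e-8)
})

test_that("a single designed motion mode dominates EV1", {
  set.seed(23)
  pr <- make_pseudo_receptor(2, activation = FALSE, seed = 2)
  base <- pr$frames$xyz[1, ]
  nf <- 80
  mode <- numeric(length(base))
  tm6 <- which(pr$frames$topology$residues$segment == "TM6")[1:6]
  tm6_atoms <- which(pr$frames$topology$atoms$resindex %in% tm6 &
                       pr$frames$topology$atoms$name == "CA")
  for (a in tm6_atoms) mode[(3 * a - 2)] <- 1
  # a pure internal mode: rigid-body components would be absorbed by the fit
  mode <- project_out_rigid(mode, matrix(base, ncol = 3, byrow = TRUE))
  scores <- rnorm(nf, 0, 3)
  xyz <- t(vapply(seq_len(nf), function(t)
    base + scores[t] * mode + rnorm(length(base), 0, 0.01),
    numeric(length(base))))
  fs <- frame_series(pr$frames$topology, xyz, seq_len(nf))
  sel <- select_atoms(fs$topology, "name CA and protein")
  p <- combined_pca(fs, sel)
  expect_gt(p$contribution[1], 99)
  sel_cols <- unlist(lapply(sel$atom_indices,
                            function(a) (3 * a - 2):(3 * a)))
  cosang <- abs(sum(p$eigenvectors[, 1] * mode[sel_cols]))
  expect_gt(cosang, 0.99)
})

test_that("identical ensembles project indistinguishably", {
  lk <- make_two_state_lock_trajectory(0.5, n_frames = 100, seed = 25)
  sel <- select_atoms(lk$topology, "heavy")
  p <- combined_pca(list(lk, frame_series(lk$topology, lk$xyz, lk$times,
                                          label = "copy")), sel)
  s1 <- p$projections$PC1[p$projections$ensemble == lk$label]
  s2 <- p$projections$PC1[p$projections$ensemble == "copy"]
  expect_equal(mean(s1), mean(s2), tolerance = 1e-6)
  expect_equal(stats::sd(s1), stats::sd(s2), tolerance = 1e-6)
})

coords_to_row_test <- function(m) as.vector(t(m))

test_that("EV trace frames span the mode symmetrically about the mean", {
  fs <- toy_mode_frames()
  p <- combined_pca(fs, select_atoms(fs$topology, "name CA"), fit = FALSE)
  tr <- ev_trace_frames(p, 1, n_frames = 6, amplitude = 2)
  expect_equal(n_frames(tr), 6)
  mid <- ev_trace_frames(p, 1, n_frames = 1)
  expect_equal(frame_coords(mid, 1), p$mean_structure, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(tr$xyz[1, ] + tr$xyz[6, ], 2 * coords_to_row_test(p$mean_structure),
               tolerance = 1e-9)
  expect_error(ev_trace_frames(p, 99), class = "gact_index_error")
  f <- tempfile(fileext = ".pdb")
  write_frames(tr, f)
  expect_equal(n_frames(load_frames(f, load_topology(f), 0.1)), 6)
})

test_that("DCCM recovers designed correlations and reports NA on zero variance", {
  ct <- make_correlated_trajectory(c(1, -1, 0.5, 0), n_frames = 10000,
                                   seed = 27)
  sel <- select_atoms(ct$topology, "name CA")
  M <- dccm(ct, sel, fit_sel = NULL)$dccm
  expect_equal(M[1, 2], 1, tolerance = 1e-12)
  expect_equal(M[3, 4], -1, tolerance = 1e-12)
  expect_equal(M[5, 6], 0.5, tolerance = 0.03)
  expect_equal(M[7, 8], 0, tolerance = 0.03)
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 8))
  # zero-variance residue -> NA, never 0
  xyz <- ct$xyz
  xyz[, 1:3] <- matrix(rep(xyz[1, 1:3], nrow(xyz)), ncol = 3, byrow = TRUE)
  frozen <- frame_series(ct$topology, xyz, ct$times)
  M2 <- dccm(frozen, sel, fit_sel = NULL)$dccm
  expect_true(all(is.na(M2[1, -1])))
  expect_error(dccm(slice_window(ct, 0, 0.5), sel),
               class = "gact_insufficient_error")
})

test_that("DCCM matches an independent library implementation", {
  skip_if_not_installed("bio3d")
  ct <- make_correlated_trajectory(c(0.7, -0.3), n_frames = 500, seed = 29)
  sel <- select_atoms(ct$topology, "name CA")
  M <- dccm(ct, sel, fit_sel = NULL)$dccm
  ref <- suppressWarnings(bio3d::dccm.xyz(ct$xyz, ncore = 1))
  expect_equal(unname(M), unname(ref[]), tolerance = 1e-8)
})

test_that("DCCM is invariant under a global rotation applied to every frame", {
  ct <- make_correlated_trajectory(c(0.6), n_frames = 300, seed = 31)
  sel <- select_atoms(ct$topology, "name CA")
  M <- dccm(ct, sel)$dccm
  moved <- transform_frames(ct, random_rigid_transform(33))
  M2 <- dccm(moved, sel)$dccm
  expect_equal(M, M2, tolerance = 1e-6)
})

test_that("windowed correlation fractions follow the designed block structure", {
  sel_of <- function(fs) select_atoms(fs$topology, "name CA")
  always <- make_correlated_trajectory(c(0.9), n_frames = 600, seed = 35)
  wf <- windowed_correlation_fractions(always, sel_of(always), window = 100,
                                       threshold = 0.5)
  expect_equal(wf$correlated[1, 2], 1)
  expect_equal(wf$anticorrelated[1, 2], 0)
  # alternating +0.9 / -0.9 blocks of one window each
  pos <- make_correlated_trajectory(c(0.9), n_frames = 300, seed = 37)
  neg <- make_correlated_trajectory(c(-0.9), n_frames = 300, seed = 38)
  xyz <- rbind(pos$xyz[1:100, ], neg$xyz[1:100, ], pos$xyz[101:200, ],
               neg$xyz[101:200, ], pos$xyz[201:300, ], neg$xyz[201:300, ])
  alt <- frame_series(pos$topology, xyz, times = seq_len(600))
  wa <- windowed_correlation_fractions(alt, sel_of(alt), window = 100,
                                       threshold = 0.5)
  expect_equal(wa$correlated[1, 2], 0.5)
  expect_equal(wa$anticorrelated[1, 2], 0.5)
  # pure-noise pair stays near the permutation null rate
  noise <- make_correlated_trajectory(c(0), n_frames = 600, seed = 39)
  wn <- windowed_correlation_fractions(noise, sel_of(noise), window = 100,
                                       threshold = 0.5)
  set.seed(40)
  perm <- noise$xyz[sample(600), ]
  wp <- windowed_correlation_fractions(
    frame_series(noise$topology, perm, noise$times), sel_of(noise),
    window = 100, threshold = 0.5)
  null_rate <- wp$correlated[1, 2] + wp$anticorrelated[1, 2]
  expect_lte(wn$correlated[1, 2] + wn$anticorrelated[1, 2],
             null_rate + 2 / wn$n_windows)
  # fractions bounded and jointly <= 1
  expect_true(all(wa$correlated + wa$anticorrelated <= 1 + 1e-12))
  expect_error(windowed_correlation_fractions(pos, sel_of(pos), window = 200),
               class = "gact_window_error")
  expect_error(delta_correlation_fractions(wf, wa), NA)
  expect_error(delta_correlation_fractions(
    wf, windowed_correlation_fractions(alt, sel_of(alt), window = 100,
                                       threshold = 0.6)),
    class = "gact_settings_error")
})

test_that("helix-end projections trace designed in-plane motion", {
  pr <- make_pseudo_receptor(2, activation = FALSE, seed = 41,
                             jitter_sd = 0)
  base <- pr$frames$xyz[1, ]
  static <- frame_series(pr$frames$topology,
                         matrix(rep(base, 10), 10, byrow = TRUE),
                         times = 1:10)
  pj <- helix_end_projection(static, "TM6", "intracellular")
  expect_equal(unname(pj$extents), c(0, 0), tolerance = 1e-9)
  # translate the 4 intracellular-end TM6 CA by up to +4.5 A along x
  top <- pr$frames$topology
  tm6 <- which(top$residues$segment == "TM6")[1:4]
  atoms <- which(top$atoms$resindex %in% tm6 & top$atoms$name == "CA")
  nf <- 20
  xyz <- matrix(rep(base, nf), nf, byrow = TRUE)
  shift <- seq(0, 4.5, length.out = nf)
  for (a in atoms) xyz[, 3 * a - 2] <- xyz[, 3 * a - 2] + shift
  moving <- frame_series(top, xyz, seq_len(nf))
  pj2 <- helix_end_projection(moving, "TM6", "intracellular")
  expect_equal(unname(pj2$extents["range_x"]), 4.5, tolerance = 0.25)
  expect_lt(pj2$extents["range_y"], 0.2)
  expect_error(helix_end_projection(static, "TM9"),
               class = "gact_segment_error")
})
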