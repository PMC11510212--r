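test_that("Kabsch superposition is exact on identical and rotated copies", {
  set.seed(1)
  P <- matrix(rnorm(30, sd = 5), 10, 3)
  f <- kabsch_superpose(P, P)
  expect_equal(f$rmsd, 0, tolerance = 1e-10)
  expect_equal(f$rotation, diag(3), tolerance = 1e-8)
  rt <- random_rigid_transform(2)
  Q <- sweep(P %*% t(rt$R), 2, rt$t, `+`)
  f2 <- kabsch_superpose(Q, P)
  expect_lt(f2$rmsd, 1e-9)
  expect_equal(det(f2$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]),
               class = "gact_degenerate_error")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), class = "gact_degenerate_error")
})

test_that("Kabsch matches a brute-force rotation-grid search on noisy points", {
  set.seed(7)
  P <- matrix(rnorm(15, sd = 4), 5, 3)
  Q <- P + matrix(rnorm(15, sd = 0.4), 5, 3)
  best <- kabsch_superpose(Q, P)$rmsd
  # grid search over z-y-z Euler rotations: coarse pass, then a fine pass
  # around the coarse optimum
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  rot <- function(th, ax) {
    c_ <- cos(th); s <- sin(th)
    if (ax == "z") matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
    else matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
  }
  scan <- function(as, bs, gs) {
    gmin <- Inf; arg <- c(0, 0, 0)
    for (a in as) for (b in bs) for (g in gs) {
      R <- rot(a, "z") %*% rot(b, "y") %*% rot(g, "z")
      v <- sqrt(mean(rowSums((Q0 %*% t(R) - P0)^2)))
      if (v < gmin) { gmin <- v; arg <- c(a, b, g) }
    }
    list(v = gmin, arg = arg)
  }
  step <- 6 * pi / 180
  coarse <- scan(seq(-pi, pi, by = step), seq(0, pi, by = step),
                 seq(-pi, pi, by = step))
  # polish the coarse grid optimum numerically (still Kabsch-free)
  obj <- function(x) {
    R <- rot(x[1], "z") %*% rot(x[2], "y") %*% rot(x[3], "z")
    sqrt(mean(rowSums((Q0 %*% t(R) - P0)^2)))
  }
  refined <- stats::optim(coarse$arg, obj,
                          control = list(reltol = 1e-14, maxit = 5000))$value
  expect_lt(best, refined + 1e-9)   # closed form is never worse
  expect_lt(abs(best - refined), 1e-3)
})

test_that("rmsd_series is zero for the reference and translated copies", {
  h <- make_ideal_helix(helix_spec(10))
  xyz <- rbind(h$xyz, h$xyz + 5, h$xyz - 3)   # rigid translations
  fs <- frame_series(h$topology, xyz, times = 0:2)
  r <- rmsd_series(fs, frame_coords(fs, 1),
                   select_atoms(fs$topology, "name CA"))
  expect_equal(r$rmsd, rep(0, 3), tolerance = 1e-9)
})

test_that("rmsd of noisy frames matches a direct brute-force average", {
  set.seed(11)
  h <- make_ideal_helix(helix_spec(12))
  base <- frame_coords(h, 1)
  sigma <- 0.4
  noisy <- t(vapply(1:40, function(i)
    as.vector(t(base + matrix(rnorm(36, 0, sigma), 12, 3))), numeric(36)))
  fs <- frame_series(h$topology, noisy, times = seq_len(40))
  got <- mean(rmsd_series(fs, base, select_atoms(fs$topology, "name CA"))$rmsd)
  # brute-force oracle: same noise level, direct fit-free RMSD is an upper
  # bound and sqrt(3) sigma its scale; fitted RMSD must sit just below it
  direct <- mean(vapply(1:40, function(i)
    sqrt(mean(rowSums((matrix(noisy[i, ], 12, 3, byrow = TRUE) - base)^2))),
    numeric(1)))
  expect_lt(got, direct)
  expect_gt(got, direct * 0.7)
})

test_that("RMSF is zero for static frames and sigma*sqrt(3) under jitter", {
  h <- make_ideal_helix(helix_spec(15))
  static <- frame_series(h$topology,
                         matrix(rep(h$xyz, 20), 20, byrow = TRUE),
                         times = seq_len(20))
  ca <- select_atoms(h$topology, "name CA")
  expect_equal(rmsf(static, ca)$rmsf, rep(0, 15), tolerance = 1e-9)
  expect_error(rmsf(make_ideal_helix(helix_spec(15)), ca),
               class = "gact_insufficient_error")
  set.seed(5)
  sigma <- 0.5
  n <- 400
  jit <- t(vapply(seq_len(n), function(i)
    h$xyz + rnorm(length(h$xyz), 0, sigma), numeric(length(h$xyz))))
  fs <- frame_series(h$topology, jit, times = seq_len(n))
  prof <- rmsf(fs, ca)
  # the least-squares fit absorbs 6 rigid degrees of freedom out of 3N
  expected <- sigma * sqrt(3) * sqrt(1 - 6 / (3 * 15))
  expect_equal(mean(prof$rmsf), expected, tolerance = 0.02)
})

test_that("dihedral obeys the IUPAC convention and the brute-force formula", {
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), -90)
  set.seed(3)
  for (i in 1:250) {
    p <- lapply(1:4, function(j) rnorm(3, sd = 2))
    got <- tryCatch(dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                    gact_degenerate_error = function(e) NA)
    if (is.na(got)) next
    ref <- brute_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_equal(got, ref, tolerance = 1e-8)
    # mirror reflection flips the sign
    m <- lapply(p, function(v) v * c(1, 1, -1))
    expect_equal(dihedral(m[[1]], m[[2]], m[[3]], m[[4]]),
                 -got, tolerance = 1e-8)
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               class = "gact_degenerate_error")
})

test_that("circular statistics wrap correctly and refuse zero resultants", {
  expect_equal(as.numeric(circular_mean(c(170, -170))), 180)
  expect_equal(as.numeric(circular_mean(c(10, 20, 30))), 20)
  expect_error(circular_mean(c(0, 90, 180, 270)),
               class = "gact_degenerate_error")
  expect_error(circular_mean(numeric()), class = "gact_empty_error")
  expect_lt(circular_sd(rep(42, 10)), 1e-6)
  # arithmetic averaging would fail at the wrap; circular does not
  expect_equal(abs(as.numeric(circular_mean(c(179, -179)))), 180)
})

test_that("helix-axis fit is equivariant and noise-tolerant", {
  h <- frame_coords(make_ideal_helix(helix_spec(11)), 1)
  ax <- fit_helix_axis(h)
  expect_equal(vnorm <- sqrt(sum(ax$direction^2)), 1, tolerance = 1e-9)
  expect_equal(as.vector(ax$direction), c(0, 0, 1), tolerance = 1e-6)
  expect_equal(ax$twist, 100, tolerance = 1e-6)
  expect_equal(ax$radius, 2.3, tolerance = 1e-6)
  rt <- random_rigid_transform(13)
  ax2 <- fit_helix_axis(sweep(h %*% t(rt$R), 2, rt$t, `+`))
  expect_equal(as.vector(ax2$direction), as.vector(rt$R %*% c(0, 0, 1)),
               tolerance = 1e-6)
  set.seed(17)
  hz <- frame_coords(make_ideal_helix(helix_spec(18)), 1)  # TM-helix length
  worst <- max(vapply(1:20, function(i) {
    noisy <- hz + matrix(rnorm(54, 0, 0.3), 18, 3)
    a <- fit_helix_axis(noisy)
    acos(min(1, abs(sum(a$direction * c(0, 0, 1))))) * 180 / pi
  }, numeric(1)))
  expect_lt(worst, 3)
  expect_error(fit_helix_axis(h[1:3, ]), class = "gact_insufficient_error")
  expect_error(fit_helix_axis(cbind(1:6, 0, 0)),
               class = "gact_degenerate_error")
})
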