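# Shared fixtures and independent oracles used across the suite.

# Random proper rotation + translation applied identically to every frame.
random_rigid_transform <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = rnorm(3, 0, 20))
}

transform_frames <- function(fs, rt) {
  xyz <- t(apply(fs$xyz, 1, function(row) {
    co <- matrix(row, ncol = 3, byrow = TRUE)
    as.vector(t(sweep(co %*% t(rt$R), 2, rt$t, `+`)))
  }))
  frame_series(fs$topology, xyz, fs$times, fs$label,
               ground_truth = fs$ground_truth)
}

# Independent brute-force dihedral: angle between the two bond planes via
# explicit normals, signed by the determinant test.
brute_dihedral <- function(p1, p2, p3, p4) {
  n1 <- pracma_cross(p2 - p1, p3 - p2)
  n2 <- pracma_cross(p3 - p2, p4 - p3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  # IUPAC sign: negative when (n1 x n2) points along the central bond
  s <- -sign(det(rbind(p3 - p2, n1, n2)))
  out <- if (s < 0) -ang else ang
  if (out <= -180) out + 360 else out
}
pracma_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                 a[3] * b[1] - a[1] * b[3],
                                 a[1] * b[2] - a[2] * b[1])

# Remove the rigid-body (3 translation + 3 rotation) components from a
# designed 3N displacement mode, so least-squares superposition leaves the
# mode untouched and PCA can recover it exactly.
project_out_rigid <- function(mode, base) {
  n <- nrow(base)
  rel <- sweep(base, 2, colMeans(base))
  basis <- matrix(0, 3 * n, 6)
  for (k in 1:3) basis[seq(k, 3 * n, by = 3), k] <- 1
  for (k in 1:3) {
    e <- c(0, 0, 0); e[k] <- 1
    g <- t(apply(rel, 1, function(r) pracma_cross(e, r)))
    basis[, 3 + k] <- as.vector(t(g))
  }
  Q <- qr.Q(qr(basis))
  m <- mode - Q %*% crossprod(Q, mode)
  as.vector(m / sqrt(sum(m^2)))
}

# ARG-GLU pair trajectory/trajectories whose contact states follow the given
# logical pattern(s) exactly (deterministic occupancy; contact at 3.0 A,
# apart at 8.0 A).  `patterns` is one logical vector or a list of them, one
# per independent pair (pairs spaced 60 A apart).
pattern_contact_trajectory <- function(patterns, label = "pattern") {
  if (!is.list(patterns)) patterns <- list(patterns)
  np <- length(patterns)
  nf <- length(patterns[[1]])
  atoms <- residues <- list()
  for (p in seq_len(np)) {
    riA <- 2L * p - 1L; riB <- 2L * p
    atoms[[p]] <- data.frame(
      name = c("CA", "CZ", "NH1", "CA", "CD", "OE1"),
      element = c("C", "C", "N", "C", "C", "O"),
      resindex = c(riA, riA, riA, riB, riB, riB),
      is_sidechain = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
      is_hydrogen = FALSE, stringsAsFactors = FALSE)
    residues[[p]] <- data.frame(
      author_number = c(30L * riA, 30L * riB), insertion_code = "",
      name = c("ARG", "GLU"), chain = "A", segment = "OTHER",
      generic_number = NA_character_, stringsAsFactors = FALSE)
  }
  atab <- do.call(rbind, atoms)
  atab$serial <- seq_len(nrow(atab))
  top <- topology(atab, do.call(rbind, residues))
  xyz <- t(vapply(seq_len(nf), function(t) {
    unlist(lapply(seq_len(np), function(p) {
      g <- if (patterns[[p]][t]) 3.0 else 8.0
      y <- 60 * (p - 1)
      as.vector(t(rbind(c(-3, y, 0), c(-1, y, 0), c(0, y, 0),
                        c(g + 3, y, 0), c(g + 1, y, 0), c(g, y, 0))))
    }))
  }, numeric(18 * np)))
  frame_series(top, xyz, times = (seq_len(nf) - 1) * 0.1, label)
}

# Toy multi-model PDB text for the reader tests.
toy_pdb_lines <- function() {
  c("MODEL     1",
    "ATOM      1  N   ALA A  10       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A  10       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A  10       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A  11       3.500   1.500   0.500  1.00  0.00           C",
    "ATOM      5  CA  SER A  12       5.100   2.600   1.200  1.00  0.00           C",
    "HETATM    6  C1  DOI A 900       8.000   8.000   8.000  1.00  0.00           C",
    "HETATM    7  O   HOH A 901      20.000  20.000  20.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL     2",
    "ATOM      1  N   ALA A  10       0.100   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A  10       1.558   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A  10       2.109   1.420   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A  11       3.600   1.500   0.500  1.00  0.00           C",
    "ATOM      5  CA  SER A  12       5.200   2.600   1.200  1.00  0.00           C",
    "HETATM    6  C1  DOI A 900       8.100   8.000   8.000  1.00  0.00           C",
    "HETATM    7  O   HOH A 901      20.000  20.000  20.000  1.00  0.00           O",
    "ENDMDL",
    "END")
}

write_toy_pdb <- function(lines = toy_pdb_lines()) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}
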