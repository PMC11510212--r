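# Internal-coordinate (NeRF) construction of polypeptide fixtures with
# prescribed phi/psi/chi torsions, plus the standard chi1/chi2 atom tables.

# chi1 = N-CA-CB-<gamma atom>; chi2 = CA-CB-<gamma>-<delta atom>.
CHI1_GAMMA <- c(ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG",
                GLU = "CG", HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG",
                MET = "CG", PHE = "CG", PRO = "CG", SER = "OG", THR = "OG1",
                TRP = "CG", TYR = "CG", VAL = "CG1")
CHI2_DELTA <- c(ARG = "CD", ASN = "OD1", ASP = "OD1", GLN = "CD", GLU = "CD",
                HIS = "ND1", ILE = "CD1", LEU = "CD1", LYS = "CD", MET = "SD",
                PHE = "CD1", PRO = "CD", TRP = "CD1", TYR = "CD1")

# Place atom D bonded to C with |CD| = bond, angle B-C-D = angle_deg and
# torsion A-B-C-D = torsion_deg (natural extension reference frame).
nerf_place <- function(A, B, C, bond, angle_deg, torsion_deg) {
  bc <- vhat(C - B)
  n <- vhat(vcross(B - A, bc))
  m <- vcross(n, bc)
  th <- deg2rad(180 - angle_deg)   # angle from the BC extension direction
  ph <- -deg2rad(torsion_deg)      # this frame is left-handed in the
                                   # measured A-B-C-D torsion; negate

  d <- bond * (cos(th) * bc + sin(th) * (cos(ph) * m + sin(ph) * n))
  C + d
}

#' Build a single-conformation peptide with prescribed torsions
#'
#' Constructs N/CA/C backbones residue by residue from standard bond lengths
#' and angles, with the given phi/psi torsions (omega fixed at 180).  When
#' `chi1`/`chi2` are supplied, CB and the chi-defining gamma/delta atoms are
#' added with the requested side-chain torsions.  An ideal alpha helix is
#' `phi = -57`, `psi = -47`.
#'
#' @param sequence character vector of 3-letter residue codes.
#' @param phi,psi numeric vectors of backbone torsions in degrees (phi of the
#'   first and psi of the last residue are not realisable and are ignored).
#' @param chi1,chi2 optional numeric vectors of side-chain torsions (NA to
#'   omit a residue's side chain beyond CB).
#' @param label ensemble label.
#' @return a single-frame [frame_series].
#' @export
build_peptide <- function(sequence, phi, psi, chi1 = NULL, chi2 = NULL,
                          label = "peptide") {
  n <- length(sequence)
  stopifnot(length(phi) == n, length(psi) == n)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329
  a_NCAC <- 111.2; a_CACN <- 116.6; a_CNCA <- 121.7
  atoms <- list(); coords <- list(); resindex <- integer()
  add <- function(name, el, ri, xyz) {
    atoms[[length(atoms) + 1L]] <<- list(name = name, el = el)
    coords[[length(coords) + 1L]] <<- xyz
    resindex[length(resindex) + 1L] <<- ri
  }
  # first residue backbone in the xy plane
  N <- c(0, 0, 0)
  CA <- c(b_NCA, 0, 0)
  C <- CA + b_CAC * c(cos(deg2rad(180 - a_NCAC)), sin(deg2rad(180 - a_NCAC)), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N <- nerf_place(prevN, prevCA, prevC, b_CN, a_CACN, psi[i - 1])
      CA <- nerf_place(prevCA, prevC, N, b_NCA, a_CNCA, 180)
      C <- nerf_place(prevC, N, CA, b_CAC, a_NCAC, phi[i])
    }
    add("N", "N", i, N); add("CA", "C", i, CA); add("C", "C", i, C)
    res <- sequence[i]
    want_chi1 <- !is.null(chi1) && !is.na(chi1[i])
    want_chi2 <- !is.null(chi2) && !is.na(chi2[i])
    if ((want_chi1 || want_chi2) && res == "GLY")
      stop_gact("GLY has no side chain: chi torsions impossible (residue %d)",
                i, class = "gact_missing_atom_error")
    if (res != "GLY" && (want_chi1 || want_chi2)) {
      CB <- nerf_place(C, N, CA, 1.53, 110.5, -122)
      add("CB", "C", i, CB)
      if (want_chi1 || want_chi2) {
        gname <- CHI1_GAMMA[res]
        if (is.na(gname))
          stop_gact("no chi1 atom defined for %s", res,
                    class = "gact_missing_atom_error")
        G <- nerf_place(N, CA, CB, 1.52, 114, if (want_chi1) chi1[i] else -60)
        add(gname, substr(gname, 1, 1), i, G)
        if (want_chi2) {
          dname <- CHI2_DELTA[res]
          if (is.na(dname))
            stop_gact("no chi2 atom defined for %s", res,
                      class = "gact_missing_atom_error")
          D <- nerf_place(CA, CB, G, 1.52, 114, chi2[i])
          add(dname, substr(dname, 1, 1), i, D)
        }
      }
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  atab <- data.frame(
    serial = seq_along(atoms),
    name = vapply(atoms, `[[`, "", "name"),
    element = vapply(atoms, `[[`, "", "el"),
    resindex = resindex, stringsAsFactors = FALSE)
  atab$is_sidechain <- !(atab$name %in% BACKBONE_ATOMS)
  atab$is_hydrogen <- atab$element == "H"
  rtab <- data.frame(
    author_number = seq_len(n), insertion_code = "",
    name = sequence, chain = "A", segment = "OTHER",
    generic_number = NA_character_, stringsAsFactors = FALSE)
  frame_series(topology(atab, rtab),
               coords_to_row(do.call(rbind, coords)),
               times = 0, label = label)
}

#' Build a torsion-swept peptide trajectory
#'
#' Rebuilds the peptide once per frame from per-frame torsion matrices;
#' used to generate trajectories whose dihedral statistics are known by
#' construction (e.g. a psi shift between the first and second halves).
#'
#' @param sequence 3-letter residue codes.
#' @param phi,psi frames-by-residues matrices of torsions in degrees.
#' @param chi1,chi2 optional frames-by-residues torsion matrices.
#' @param time_step_ns time between frames in ns.
#' @param label ensemble label.
#' @return a [frame_series] with one frame per torsion row.
#' @export
build_peptide_trajectory <- function(sequence, phi, psi, chi1 = NULL,
                                     chi2 = NULL, time_step_ns = 0.1,
                                     label = "peptide") {
  phi <- as.matrix(phi); psi <- as.matrix(psi)
  nf <- nrow(phi)
  one <- function(k) build_peptide(
    sequence, phi[k, ], psi[k, ],
    chi1 = if (!is.null(chi1)) as.matrix(chi1)[k, ],
    chi2 = if (!is.null(chi2)) as.matrix(chi2)[k, ], label = label)
  first <- one(1)
  xyz <- matrix(NA_real_, nf, ncol(first$xyz))
  xyz[1, ] <- first$xyz
  if (nf > 1) for (k in 2:nf) xyz[k, ] <- one(k)$xyz
  frame_series(first$topology, xyz, times = (seq_len(nf) - 1) * time_step_ns,
               label = label)
}
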