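# Canonical data model: Topology, FrameSeries, Selection.
#
# Conventions (documented in the methods vignette):
#   * coordinates in Angstrom, times in ns, membrane normal along +z;
#   * internal atom and residue indices are 1-based;
#   * user-facing labels use author residue numbers and Ballesteros-Weinstein
#     generic numbers.

WATER_ION_NAMES <- c("HOH", "WAT", "TIP3", "NA", "CL", "K")

SEGMENT_LEVELS <- c(paste0("TM", 1:7), "H8",
                    paste0("ICL", 1:3), paste0("ECL", 1:3),
                    "NTERM", "CTERM", "LIGAND", "OTHER")

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT",
                    "H", "H1", "H2", "H3", "HN", "HA", "HA2", "HA3")

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

#' Build a Topology object
#'
#' A Topology holds the atom table, the residue table and the indices of
#' ligand atoms; it is the static half of every [FrameSeries][frame_series].
#' Atom order must match the coordinate order of every frame.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resindex` (1-based residue index), `is_sidechain`, `is_hydrogen`.
#' @param residues data.frame with columns `author_number`, `insertion_code`,
#'   `name` (3-letter code), `chain`, `segment` (one of TM1..TM7, H8,
#'   ICL1..ICL3, ECL1..ECL3, NTERM, CTERM, LIGAND, OTHER) and
#'   `generic_number` (Ballesteros-Weinstein "helix.position" string or NA).
#' @param ligand_atom_indices integer vector of atom indices belonging to
#'   ligand residues.
#' @return object of class `gact_topology`.
#' @export
topology <- function(atoms, residues, ligand_atom_indices = integer()) {
  stopifnot(is.data.frame(atoms), is.data.frame(residues))
  atoms$name <- as.character(atoms$name)
  atoms$element <- as.character(atoms$element)
  if (anyDuplicated(atoms$serial))
    stop_gact("duplicate atom serial numbers in topology", class = "gact_format_error")
  if (any(!nzchar(atoms$element)))
    stop_gact("empty element symbol in atom table", class = "gact_format_error")
  if (any(atoms$resindex < 1L | atoms$resindex > nrow(residues)))
    stop_gact("atom refers to a residue outside the residue table",
              class = "gact_format_error")
  residues$segment <- as.character(residues$segment)
  bad <- setdiff(unique(residues$segment), SEGMENT_LEVELS)
  if (length(bad))
    stop_gact("unknown segment label(s): %s", paste(bad, collapse = ", "),
              class = "gact_format_error")
  gn <- residues$generic_number
  gn <- gn[!is.na(gn) & nzchar(gn)]
  if (anyDuplicated(gn))
    stop_gact("generic numbers must be unique within a topology",
              class = "gact_format_error")
  structure(list(atoms = atoms, residues = residues,
                 ligand_atom_indices = as.integer(ligand_atom_indices)),
            class = "gact_topology")
}

#' @export
print.gact_topology <- function(x, ...) {
  cat(sprintf("<gact_topology> %d atoms, %d residues, %d ligand atoms\n",
              nrow(x$atoms), nrow(x$residues), length(x$ligand_atom_indices)))
  invisible(x)
}

n_atoms <- function(x) UseMethod("n_atoms")
n_atoms.gact_topology <- function(x) nrow(x$atoms)
n_atoms.gact_frames <- function(x) nrow(x$topology$atoms)

#' Build a FrameSeries (coordinate ensemble)
#'
#' The universal trajectory object: a topology plus an ordered set of
#' coordinate frames with timestamps.
#'
#' @param topology a [topology] object.
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns in
#'   x1,y1,z1,x2,... order (Angstrom).
#' @param times numeric vector of frame times in ns, strictly increasing.
#' @param label ensemble name (e.g. `"APO"`, `"DOI"`).
#' @param ground_truth optional list of generator ground truth (hidden states,
#'   truth tables, kink parameters) carried along for oracle tests.
#' @return object of class `gact_frames`.
#' @export
frame_series <- function(topology, xyz, times, label = "ensemble",
                         ground_truth = NULL) {
  stopifnot(inherits(topology, "gact_topology"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop_gact("frame width %d does not match 3 x %d atoms",
              ncol(xyz), n_atoms(topology), class = "gact_alignment_error")
  if (length(times) != nrow(xyz))
    stop_gact("times length %d != number of frames %d", length(times),
              nrow(xyz), class = "gact_alignment_error")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop_gact("frame times must be strictly increasing", class = "gact_format_error")
  structure(list(topology = topology, xyz = unname(as.matrix(xyz)),
                 times = as.numeric(times), label = label,
                 ground_truth = ground_truth),
            class = "gact_frames")
}

#' @export
print.gact_frames <- function(x, ...) {
  cat(sprintf("<gact_frames> '%s': %d frames x %d atoms, t = %.4g..%.4g ns\n",
              x$label, n_frames(x), n_atoms(x),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a FrameSeries
#' @param x a `gact_frames` object.
#' @export
n_frames <- function(x) nrow(x$xyz)

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param x a `gact_frames` object.
#' @param i frame index (1-based).
#' @export
frame_coords <- function(x, i) {
  matrix(x$xyz[i, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

# xyz column indices for a set of atom indices.
xyz_cols <- function(atom_idx) {
  as.vector(rbind(3L * atom_idx - 2L, 3L * atom_idx - 1L, 3L * atom_idx))
}

coords_to_row <- function(m) as.vector(t(m))

#' Construct a Selection by explicit atom indices
#'
#' @param atom_indices integer atom indices (1-based), deduplicated and sorted.
#' @param description free-text description of the selection.
#' @param topology optional topology used to validate indices.
#' @return object of class `gact_selection`.
#' @export
selection <- function(atom_indices, description = "", topology = NULL) {
  idx <- sort(unique(as.integer(atom_indices)))
  if (!is.null(topology) && length(idx) &&
      (min(idx) < 1L || max(idx) > n_atoms(topology)))
    stop_gact("selection index outside topology (1..%d)", n_atoms(topology),
              class = "gact_selection_error")
  structure(list(atom_indices = idx, description = description),
            class = "gact_selection")
}

#' @export
print.gact_selection <- function(x, ...) {
  cat(sprintf("<gact_selection> %d atoms: %s\n",
              length(x$atom_indices), x$description))
  invisible(x)
}

#' Restrict a trajectory to a time window
#'
#' Keeps frames with `t_start <= time <= t_end` (the usual equilibrated
#' analysis window, e.g. 200-1000 ns of a 1 us run), order preserved.
#'
#' @param frames a `gact_frames` object.
#' @param t_start_ns,t_end_ns window bounds in ns, `t_start_ns < t_end_ns`.
#' @return a `gact_frames` object containing only the windowed frames.
#' @export
slice_window <- function(frames, t_start_ns, t_end_ns) {
  stopifnot(inherits(frames, "gact_frames"))
  if (!(t_start_ns < t_end_ns))
    stop_gact("t_start must be < t_end", class = "gact_window_error")
  eps <- 1e-9
  keep <- frames$times >= t_start_ns - eps & frames$times <= t_end_ns + eps
  if (!any(keep))
    stop_gact("window [%g, %g] ns selects no frames (trajectory spans %g..%g ns)",
              t_start_ns, t_end_ns, frames$times[1],
              frames$times[length(frames$times)], class = "gact_window_error")
  gt <- frames$ground_truth
  if (!is.null(gt)) {
    # keep per-frame ground-truth vectors aligned with the slice
    gt <- lapply(gt, function(v) {
      if ((is.vector(v) || is.factor(v)) && length(v) == length(keep)) v[keep]
      else if (is.matrix(v) && nrow(v) == length(keep)) v[keep, , drop = FALSE]
      else v
    })
  }
  frame_series(frames$topology, frames$xyz[keep, , drop = FALSE],
               frames$times[keep], frames$label, ground_truth = gt)
}

# Residue label like "R173(3.50)" used in tables and reports.
residue_label <- function(topology, resindex) {
  r <- topology$residues[resindex, ]
  gn <- ifelse(is.na(r$generic_number) | !nzchar(r$generic_number),
               as.character(r$segment), r$generic_number)
  code1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
             GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
             MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
             TYR = "Y", VAL = "V")[r$name]
  code1[is.na(code1)] <- "X"
  sprintf("%s%d(%s)", code1, r$author_number, gn)
}

# Atom indices of a residue, optionally filtered.
residue_atoms <- function(topology, resindex, names = NULL, heavy = FALSE,
                          sidechain = FALSE) {
  a <- topology$atoms
  sel <- a$resindex == resindex
  if (!is.null(names)) sel <- sel & a$name %in% names
  if (heavy) sel <- sel & !a$is_hydrogen
  if (sidechain) sel <- sel & a$is_sidechain
  which(sel)
}
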