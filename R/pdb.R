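# Multi-model PDB input/output: the canonical desk-scale trajectory format.
# Fixed-column parsing per the PDB 3.3 coordinate-record definition; an
# adapter seam for binary trajectory formats is provided by as_frame_series().

parse_pdb_atom_lines <- function(lines, line_numbers) {
  n <- length(lines)
  get <- function(from, to) substr(lines, from, to)
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad))
      stop_gact("unreadable %s field at line %d: '%s'", what,
                line_numbers[bad[1]], lines[bad[1]], class = "gact_format_error")
    v
  }
  data.frame(
    record  = trimws(get(1, 6)),
    serial  = as.integer(num(get(7, 11), "atom serial")),
    name    = trimws(get(13, 16)),
    altloc  = trimws(get(17, 17)),
    resname = trimws(get(18, 20)),
    chain   = trimws(get(22, 22)),
    resseq  = as.integer(num(get(23, 26), "residue number")),
    icode   = trimws(get(27, 27)),
    x = num(get(31, 38), "x"), y = num(get(39, 46), "y"),
    z = num(get(47, 54), "z"),
    element = trimws(get(77, 78)),
    stringsAsFactors = FALSE)
}

infer_element <- function(name) {
  # PDB atom names start with the element once digits are stripped; two-letter
  # elements are rare in proteins and ligands handled here.
  stripped <- sub("^[0-9]+", "", name)
  el <- substr(stripped, 1, 1)
  el[el == ""] <- "X"
  toupper(el)
}

#' Read the topology from a (multi-model) PDB file
#'
#' Atoms come from MODEL 1 (or the sole model) in file order.  HETATM
#' records whose residue name is not a recognised water/ion
#' (HOH, WAT, TIP3, NA, CL, K) become LIGAND residues; waters and ions are
#' excluded entirely.  Hydrogens are flagged from the element column (or
#' inferred from the atom name when the element column is blank).
#'
#' @param path path to a PDB file.
#' @return a [topology] object.
#' @export
load_topology <- function(path) {
  if (!file.exists(path))
    stop_gact("file not found: %s", path, class = "gact_io_error")
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  model_ends <- which(trimws(rec) == "ENDMDL")
  if (length(model_starts)) {
    keep <- seq(model_starts[1] + 1L,
                if (length(model_ends)) model_ends[1] - 1L else length(lines))
  } else keep <- seq_along(lines)
  is_atom <- trimws(rec[keep]) %in% c("ATOM", "HETATM")
  atom_lines <- keep[is_atom]
  if (!length(atom_lines))
    stop_gact("no ATOM/HETATM records in first model of %s", path,
              class = "gact_empty_error")
  tab <- parse_pdb_atom_lines(lines[atom_lines], atom_lines)
  tab <- tab[tab$altloc %in% c("", "A"), , drop = FALSE]
  # drop waters and ions entirely
  tab <- tab[!(tab$record == "HETATM" & tab$resname %in% WATER_ION_NAMES), ,
             drop = FALSE]
  tab <- tab[!(tab$resname %in% WATER_ION_NAMES), , drop = FALSE]
  if (!nrow(tab))
    return(topology(
      atoms = data.frame(serial = integer(), name = character(),
                         element = character(), resindex = integer(),
                         is_sidechain = logical(), is_hydrogen = logical()),
      residues = data.frame(author_number = integer(),
                            insertion_code = character(), name = character(),
                            chain = character(), segment = character(),
                            generic_number = character())))
  el <- tab$element
  el[!nzchar(el)] <- infer_element(tab$name[!nzchar(el)])
  res_key <- paste(tab$chain, tab$resseq, tab$icode, tab$resname)
  resindex <- cumsum(!duplicated(res_key))[match(res_key, res_key)]
  # first occurrence per residue, preserving file order
  first <- !duplicated(res_key)
  residues <- data.frame(
    author_number = tab$resseq[first],
    insertion_code = tab$icode[first],
    name = tab$resname[first],
    chain = tab$chain[first],
    segment = ifelse(tab$record[first] == "HETATM" &
                       !(tab$resname[first] %in% AMINO3), "LIGAND", "OTHER"),
    generic_number = NA_character_,
    stringsAsFactors = FALSE)
  is_h <- toupper(el) == "H"
  atoms <- data.frame(
    serial = tab$serial, name = tab$name, element = toupper(el),
    resindex = as.integer(resindex),
    is_sidechain = !(tab$name %in% BACKBONE_ATOMS),
    is_hydrogen = is_h,
    stringsAsFactors = FALSE)
  lig_res <- which(residues$segment == "LIGAND")
  topology(atoms, residues,
           ligand_atom_indices = which(atoms$resindex %in% lig_res))
}

#' Read all coordinate models of a multi-model PDB as a FrameSeries
#'
#' Every MODEL must contain the same atoms in the same order as `topology`.
#' Frame `k` (1-based) is stamped `(k - 1) * time_step_ns`.
#'
#' @param path path to a multi-model PDB file.
#' @param topology the [topology] the frames belong to (from [load_topology]).
#' @param time_step_ns time between saved frames in ns (the reference MD
#'   convention is 0.1 ns, i.e. one frame per 100 ps).
#' @param label ensemble label.
#' @return a [frame_series] object.
#' @export
load_frames <- function(path, topology, time_step_ns = 0.1,
                        label = basename(path)) {
  if (!file.exists(path))
    stop_gact("file not found: %s", path, class = "gact_io_error")
  lines <- readLines(path, warn = FALSE)
  rec <- trimws(substr(lines, 1, 6))
  starts <- which(rec == "MODEL")
  if (!length(starts)) { starts <- 1L; ends <- length(lines) }
  else {
    ends <- which(rec == "ENDMDL")
    if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  }
  na <- n_atoms(topology)
  want_key <- paste(topology$atoms$name, topology$atoms$resindex)
  frames <- matrix(NA_real_, nrow = length(starts), ncol = 3L * na)
  for (m in seq_along(starts)) {
    span <- starts[m]:ends[m]
    sel <- span[rec[span] %in% c("ATOM", "HETATM")]
    sub <- parse_pdb_atom_lines(lines[sel], sel)
    sub <- sub[!(sub$resname %in% WATER_ION_NAMES), , drop = FALSE]
    if (nrow(sub) != na)
      stop_gact("MODEL %d has %d atoms, topology has %d", m, nrow(sub), na,
                class = "gact_alignment_error")
    if (any(sub$name != topology$atoms$name))
      stop_gact("MODEL %d atom order differs from topology", m,
                class = "gact_alignment_error")
    frames[m, ] <- coords_to_row(cbind(sub$x, sub$y, sub$z))
  }
  frame_series(topology, frames,
               times = (seq_along(starts) - 1) * time_step_ns, label = label)
}

fmt_pdb_name <- function(name, element) {
  # 4-char atom-name field: single-letter elements start in column 14
  ifelse(nchar(name) >= 4L | nchar(element) == 2L,
         formatC(name, width = -4L),
         paste0(" ", formatC(name, width = -3L)))
}

#' Write a FrameSeries as a multi-model PDB file
#'
#' Coordinates are written at the standard 0.001 Angstrom PDB precision so a
#' write/reload round trip preserves them to that precision.
#'
#' @param frames a `gact_frames` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  stopifnot(inherits(frames, "gact_frames"))
  top <- frames$topology
  a <- top$atoms
  r <- top$residues[a$resindex, ]
  is_lig <- seq_len(nrow(a)) %in% top$ligand_atom_indices
  recname <- ifelse(is_lig, "HETATM", "ATOM  ")
  namef <- fmt_pdb_name(a$name, a$element)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_frames(frames))) {
    co <- frame_coords(frames, m)
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf("%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       recname, a$serial %% 100000L, namef, r$name,
                       substr(r$chain, 1, 1), r$author_number %% 10000L,
                       substr(paste0(r$insertion_code, " "), 1, 1),
                       co[, 1], co[, 2], co[, 3], 1, 0, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Adapter seam for externally parsed trajectories
#'
#' Binary formats (DCD/XTC, ...) are out of the package's own I/O scope; any
#' reader that yields a coordinate matrix can enter the analysis pipeline
#' through this constructor.
#'
#' @param topology a [topology].
#' @param xyz frames-by-3N coordinate matrix in Angstrom.
#' @param times frame times in ns.
#' @param label ensemble label.
#' @return a [frame_series] object.
#' @export
as_frame_series <- function(topology, xyz, times, label = "ensemble") {
  frame_series(topology, xyz, times, label)
}
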