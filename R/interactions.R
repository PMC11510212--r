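# Per-frame interaction detectors: ionic-lock distance, salt bridges,
# hydrogen bonds, hydrophobic contacts and ligand contacts.  All detectors
# aggregate at residue level (a pair is in contact in a frame if ANY
# qualifying atom pair is), matching residue-pair occupancy reporting.

APOLAR_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP",
                     "CYS")

# Per-frame x/y/z of one atom across the trajectory.
atom_track <- function(xyz, a) xyz[, xyz_cols(a), drop = FALSE]

dist_series <- function(xyz, a, b) {
  d <- atom_track(xyz, a) - atom_track(xyz, b)
  sqrt(rowSums(d^2))
}

min_dist_series <- function(xyz, A, B) {
  out <- NULL
  for (a in A) for (b in B) {
    d <- dist_series(xyz, a, b)
    out <- if (is.null(out)) d else pmin(out, d)
  }
  out
}

# Mean position of a set of atoms, per frame (n_frames x 3).
group_center_series <- function(xyz, atoms) {
  acc <- matrix(0, nrow(xyz), 3)
  for (a in atoms) acc <- acc + atom_track(xyz, a)
  acc / length(atoms)
}

charge_group_atoms <- function(topology, resindex) {
  rname <- topology$residues$name[resindex]
  want <- switch(rname,
                 ARG = c("CZ", "NH1", "NH2"),
                 LYS = "NZ",
                 GLU = c("CD", "OE1", "OE2"),
                 ASP = c("CG", "OD1", "OD2"),
                 stop_gact("residue %s has no defined charge group", rname,
                           class = "gact_missing_atom_error"))
  idx <- residue_atoms(topology, resindex, names = want)
  if (length(idx) != length(want))
    stop_gact("residue %s %d is missing charge-group atom(s) %s", rname,
              topology$residues$author_number[resindex],
              paste(setdiff(want, topology$atoms$name[idx]), collapse = ","),
              class = "gact_missing_atom_error")
  idx
}

#' Ionic-lock charge-center distance series
#'
#' Distance per frame between the basic charge center (mean of the Arg
#' guanidinium CZ/NH1/NH2, or Lys NZ) and the acidic carboxylate center
#' (mean of Glu CD/OE1/OE2 or Asp CG/OD1/OD2) of the lock pair, by default
#' R3.50-E6.30.  The broken fraction is the fraction of frames with distance
#' above `formed_threshold` (the formed lock sits around 4.5 Angstrom; a
#' broken lock ranges up to ~12.5 Angstrom).
#'
#' @param frames a [frame_series].
#' @param map a `gact_bwmap` resolving generic numbers.
#' @param pair character(2) of generic numbers, default `c("3.50", "6.30")`.
#' @param formed_threshold formed/broken distance threshold in Angstrom.
#' @return a `gact_lock_series`: `series` data.frame (time_ns, distance),
#'   `broken_fraction`, `formed_threshold`, `pair`.
#' @export
ionic_lock_series <- function(frames, map, pair = c("3.50", "6.30"),
                              formed_threshold = 5.0) {
  ri <- resolve_generic(map, pair)
  top <- frames$topology
  basic <- charge_group_atoms(top, ri[1])
  acidic <- charge_group_atoms(top, ri[2])
  d <- sqrt(rowSums((group_center_series(frames$xyz, basic) -
                       group_center_series(frames$xyz, acidic))^2))
  structure(list(series = data.frame(time_ns = frames$times, distance = d),
                 broken_fraction = mean(d > formed_threshold),
                 formed_threshold = formed_threshold,
                 pair = stats::setNames(residue_label(top, ri), pair),
                 label = frames$label),
            class = "gact_lock_series")
}

#' @export
print.gact_lock_series <- function(x, ...) {
  cat(sprintf("<gact_lock_series> %s-%s [%s]: mean %.2f A, broken %.1f%% (> %.1f A)\n",
              x$pair[1], x$pair[2], x$label, mean(x$series$distance),
              100 * x$broken_fraction, x$formed_threshold))
  invisible(x)
}

new_contact_set <- function(pairs, series, kind, settings, frames) {
  top <- frames$topology
  if (length(series)) {
    pairs$fraction <- vapply(series, mean, numeric(1))
    pairs$label_i <- residue_label(top, pairs$i)
    pairs$label_j <- residue_label(top, pairs$j)
    pairs$author_i <- top$residues$author_number[pairs$i]
    pairs$author_j <- top$residues$author_number[pairs$j]
  }
  structure(list(pairs = pairs, series = series, kind = kind,
                 settings = settings, n_frames = n_frames(frames),
                 label = frames$label),
            class = "gact_contact_set")
}

#' @export
print.gact_contact_set <- function(x, ...) {
  cat(sprintf("<gact_contact_set> %s [%s]: %d pairs over %d frames\n",
              x$kind, x$label, nrow(x$pairs), x$n_frames))
  invisible(x)
}

#' Contact-fraction table of a detector result
#'
#' @param x a `gact_contact_set`.
#' @return data.frame of residue pairs with occupancy fractions, descending.
#' @export
contact_fractions <- function(x) {
  stopifnot(inherits(x, "gact_contact_set"))
  p <- x$pairs
  if (!nrow(p)) return(p)
  p[order(-p$fraction, p$author_i, p$author_j), ]
}

#' Salt-bridge occupancy per basic-acidic residue pair
#'
#' A pair is in contact in a frame iff the minimum distance between any
#' basic side-chain nitrogen (Arg NE/NH1/NH2, Lys NZ, optionally His
#' ND1/NE2) and any acidic side-chain oxygen (Asp OD1/OD2, Glu OE1/OE2) is
#' at most `cutoff`.  One series per pair ever in contact.
#'
#' @param frames a [frame_series].
#' @param cutoff N-O distance cutoff, Angstrom.
#' @param his_basic count His as basic (protonation unknown; default FALSE).
#' @return a `gact_contact_set`.
#' @export
salt_bridge_contacts <- function(frames, cutoff = 4.0, his_basic = FALSE) {
  top <- frames$topology
  res <- top$residues
  basic_names <- c("ARG", "LYS", if (his_basic) "HIS")
  basic <- which(res$name %in% basic_names)
  acidic <- which(res$name %in% c("ASP", "GLU"))
  side_atoms <- function(ri, el) {
    a <- residue_atoms(top, ri, sidechain = TRUE, heavy = TRUE)
    a[top$atoms$element[a] == el]
  }
  pairs <- list(); series <- list()
  for (bi in basic) {
    Na <- side_atoms(bi, "N")
    if (!length(Na)) next
    for (ai in acidic) {
      Oa <- side_atoms(ai, "O")
      if (!length(Oa)) next
      s <- min_dist_series(frames$xyz, Na, Oa) <= cutoff
      if (any(s)) {
        pairs[[length(pairs) + 1L]] <- data.frame(i = bi, j = ai)
        series[[length(series) + 1L]] <- s
      }
    }
  }
  new_contact_set(if (length(pairs)) do.call(rbind, pairs)
                  else data.frame(i = integer(), j = integer()),
                  series, "salt_bridge",
                  list(cutoff = cutoff, his_basic = his_basic), frames)
}

#' Hydrogen-bond occupancy per residue pair
#'
#' Donors are N/O heavy atoms with an attached hydrogen (within 1.25
#' Angstrom in the first frame); acceptors are N/O heavy atoms.  A bond
#' exists in a frame iff the donor-acceptor heavy distance is at most
#' `d_cut` and the D-H...A angle (at the hydrogen) is at least `angle_cut`.
#' If the topology carries no hydrogens at all, the angle criterion is
#' skipped and only the distance criterion applies (`settings$hydrogens_used
#' = FALSE`).  A residue pair is in contact if ANY qualifying donor-acceptor
#' combination bonds that frame.
#'
#' @param frames a [frame_series].
#' @param d_cut donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param angle_cut minimum D-H...A angle, degrees.
#' @return a `gact_contact_set`.
#' @export
hydrogen_bond_contacts <- function(frames, d_cut = 3.5, angle_cut = 120) {
  top <- frames$topology
  a <- top$atoms
  heavy_no <- which(!a$is_hydrogen & a$element %in% c("N", "O"))
  hyd <- which(a$is_hydrogen)
  use_h <- length(hyd) > 0
  co1 <- frame_coords(frames, 1)
  donor_h <- list()
  if (use_h) {
    for (d in heavy_no) {
      hs <- hyd[a$resindex[hyd] == a$resindex[d]]
      if (!length(hs)) next
      dd <- sqrt(rowSums((co1[hs, , drop = FALSE] -
                            matrix(co1[d, ], length(hs), 3, byrow = TRUE))^2))
      att <- hs[dd <= 1.25]
      if (length(att)) donor_h[[as.character(d)]] <- att
    }
    donors <- as.integer(names(donor_h))
  } else donors <- heavy_no
  pair_key <- character(); pairs <- list(); series <- list()
  for (d in donors) {
    rd <- a$resindex[d]
    for (acc in heavy_no) {
      ra <- a$resindex[acc]
      if (ra == rd) next
      ds <- dist_series(frames$xyz, d, acc)
      ok <- ds <= d_cut
      if (!any(ok)) next
      if (use_h) {
        ang_ok <- rep(FALSE, length(ok))
        for (h in donor_h[[as.character(d)]]) {
          vD <- atom_track(frames$xyz, d) - atom_track(frames$xyz, h)
          vA <- atom_track(frames$xyz, acc) - atom_track(frames$xyz, h)
          ca <- rowSums(vD * vA) /
            (sqrt(rowSums(vD^2)) * sqrt(rowSums(vA^2)))
          ang_ok <- ang_ok | rad2deg(acos(pmax(-1, pmin(1, ca)))) >= angle_cut
        }
        ok <- ok & ang_ok
      }
      if (!any(ok)) next
      key <- paste(min(rd, ra), max(rd, ra))
      at <- match(key, pair_key)
      if (is.na(at)) {
        pair_key <- c(pair_key, key)
        pairs[[length(pairs) + 1L]] <- data.frame(i = min(rd, ra),
                                                  j = max(rd, ra))
        series[[length(series) + 1L]] <- ok
      } else series[[at]] <- series[[at]] | ok
    }
  }
  new_contact_set(if (length(pairs)) do.call(rbind, pairs)
                  else data.frame(i = integer(), j = integer()),
                  series, "hbond",
                  list(d_cut = d_cut, angle_cut = angle_cut,
                       hydrogens_used = use_h), frames)
}

#' Hydrophobic (carbon-mediated) contact occupancy per residue pair
#'
#' Eligible residues have at least one side-chain carbon; a pair is
#' considered when at least one partner is apolar (Ala, Val, Leu, Ile, Pro,
#' Phe, Met, Trp, Cys) - mixed pairs such as Ser-Ile count, the criterion
#' being carbon-mediated proximity.  Contact in a frame iff any side-chain
#' heavy-atom pair with at least one carbon is within `cutoff`.  Trivial
#' neighbours (sequence separation < 3 within the same segment) are
#' excluded.
#'
#' @param frames a [frame_series].
#' @param cutoff heavy-atom distance cutoff, Angstrom.
#' @return a `gact_contact_set`.
#' @export
hydrophobic_contacts <- function(frames, cutoff = 4.5) {
  top <- frames$topology
  res <- top$residues
  a <- top$atoms
  side_heavy <- function(ri) residue_atoms(top, ri, sidechain = TRUE,
                                           heavy = TRUE)
  has_c <- vapply(seq_len(nrow(res)), function(ri) {
    s <- side_heavy(ri); any(a$element[s] == "C")
  }, logical(1))
  eligible <- which(has_c & res$segment != "LIGAND")
  pairs <- list(); series <- list()
  if (length(eligible) >= 2) {
    for (ii in seq_len(length(eligible) - 1L)) for (jj in (ii + 1L):length(eligible)) {
      ri <- eligible[ii]; rj <- eligible[jj]
      if (!(res$name[ri] %in% APOLAR_RESIDUES ||
              res$name[rj] %in% APOLAR_RESIDUES)) next
      near <- abs(res$author_number[ri] - res$author_number[rj]) < 3 &&
        res$segment[ri] == res$segment[rj] && res$chain[ri] == res$chain[rj]
      if (near) next
      Ai <- side_heavy(ri); Aj <- side_heavy(rj)
      s <- NULL
      for (x in Ai) for (y in Aj) {
        if (a$element[x] != "C" && a$element[y] != "C") next
        d <- dist_series(frames$xyz, x, y)
        s <- if (is.null(s)) d <= cutoff else s | (d <= cutoff)
      }
      if (!is.null(s) && any(s)) {
        pairs[[length(pairs) + 1L]] <- data.frame(i = ri, j = rj)
        series[[length(series) + 1L]] <- s
      }
    }
  }
  new_contact_set(if (length(pairs)) do.call(rbind, pairs)
                  else data.frame(i = integer(), j = integer()),
                  series, "hydrophobic", list(cutoff = cutoff), frames)
}

#' Ligand-contact percentage per binding-site residue
#'
#' A residue is in contact in a frame iff any of its heavy atoms is within
#' `cutoff` of any ligand heavy atom; reported as the percentage of frames,
#' sorted descending.
#'
#' @param frames a [frame_series] whose topology has ligand atoms.
#' @param cutoff heavy-atom distance cutoff, Angstrom.
#' @return data.frame with `resindex`, `label`, `percentage`.
#' @export
ligand_contact_profile <- function(frames, cutoff = 4.0) {
  top <- frames$topology
  lig <- top$ligand_atom_indices
  lig <- lig[!top$atoms$is_hydrogen[lig]]
  if (!length(lig))
    stop_gact("topology has no ligand atoms", class = "gact_no_ligand_error")
  prot_res <- which(top$residues$segment != "LIGAND")
  out <- lapply(prot_res, function(ri) {
    atoms <- residue_atoms(top, ri, heavy = TRUE)
    if (!length(atoms)) return(NULL)
    s <- min_dist_series(frames$xyz, atoms, lig) <= cutoff
    data.frame(resindex = ri, label = residue_label(top, ri),
               percentage = 100 * mean(s))
  })
  out <- do.call(rbind, out)
  out[order(-out$percentage, out$resindex), ]
}
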