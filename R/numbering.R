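# Ballesteros-Weinstein generic numbering: segment table parsing, anchored
# number assignment and the forward/reverse residue map.
#
# A segment table maps receptor segments to author-number ranges with an
# optional anchor "H.pos@author" pinning a generic position to an author
# number, e.g. TM3 anchored at 3.50@173 gives 172 -> 3.49, 174 -> 3.51.
# Loop segments receive generic numbers only when the table anchors them
# explicitly (GPCRdb-style loop labels such as 45.52).

#' Read a segment-definition table
#'
#' YAML file of the form
#' ```
#' segments:
#'   TM3:  {start: 155, end: 180, anchor: "3.50@173"}
#'   TM6:  {start: 310, end: 340, anchor: "6.30@318"}
#'   ECL2: {start: 219, end: 230}
#' ```
#' with one entry per segment; `chain` defaults to all chains.
#'
#' @param path YAML file path.
#' @return a data.frame with columns segment, start, end, anchor.
#' @export
read_segment_table <- function(path) {
  if (!file.exists(path))
    stop_gact("segment table not found: %s", path, class = "gact_io_error")
  y <- yaml::read_yaml(path)
  segs <- y$segments %||% y
  if (!length(segs))
    stop_gact("segment table %s defines no segments", path,
              class = "gact_table_error")
  data.frame(
    segment = names(segs),
    start = vapply(segs, function(s) as.integer(s$start), integer(1)),
    end = vapply(segs, function(s) as.integer(s$end), integer(1)),
    anchor = vapply(segs, function(s) as.character(s$anchor %||% NA_character_),
                    character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

parse_anchor <- function(anchor) {
  m <- regmatches(anchor, regexec("^([0-9]+)\\.([0-9]+)@([0-9]+)$", anchor))[[1]]
  if (length(m) != 4)
    stop_gact("malformed anchor '%s' (expected 'H.pos@author')", anchor,
              class = "gact_table_error")
  list(helix = m[2], pos = as.integer(m[3]), author = as.integer(m[4]))
}

validate_segment_table <- function(tab) {
  stopifnot(is.data.frame(tab), all(c("segment", "start", "end") %in% names(tab)))
  if (!"anchor" %in% names(tab)) tab$anchor <- NA_character_
  bad <- setdiff(tab$segment, SEGMENT_LEVELS)
  if (length(bad))
    stop_gact("unknown segment(s) in table: %s", paste(bad, collapse = ", "),
              class = "gact_table_error")
  if (any(tab$end < tab$start))
    stop_gact("segment with end < start in table", class = "gact_table_error")
  o <- order(tab$start)
  s <- tab[o, ]
  if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
    stop_gact("overlapping segment ranges in table", class = "gact_table_error")
  for (k in which(!is.na(tab$anchor))) {
    a <- parse_anchor(tab$anchor[k])
    if (a$author < tab$start[k] || a$author > tab$end[k])
      stop_gact("anchor %s outside segment %s range %d-%d", tab$anchor[k],
                tab$segment[k], tab$start[k], tab$end[k],
                class = "gact_table_error")
  }
  tab
}

#' Assign Ballesteros-Weinstein generic numbers from a segment table
#'
#' Within an anchored segment the generic position increments by one per
#' residue from the anchor; residues of unanchored segments get the segment
#' label but no generic number.
#'
#' @param topology a [topology].
#' @param segment_table data.frame from [read_segment_table] (columns
#'   segment, start, end, anchor) or a path to a YAML table.
#' @return a `gact_bwmap`: list with `forward` (named integer vector,
#'   generic number -> residue index), `reverse` (residue index -> generic
#'   number) and `segment_bounds`.
#' @export
assign_generic_numbers <- function(topology, segment_table) {
  if (is.character(segment_table))
    segment_table <- read_segment_table(segment_table)
  tab <- validate_segment_table(segment_table)
  res <- topology$residues
  forward <- integer(0)
  reverse <- rep(NA_character_, nrow(res))
  segment <- res$segment
  for (k in seq_len(nrow(tab))) {
    in_seg <- which(res$author_number >= tab$start[k] &
                      res$author_number <= tab$end[k] &
                      res$segment != "LIGAND")
    segment[in_seg] <- tab$segment[k]
    if (is.na(tab$anchor[k])) next
    a <- parse_anchor(tab$anchor[k])
    pos <- a$pos + (res$author_number[in_seg] - a$author)
    ok <- pos > 0
    gn <- sprintf("%s.%d", a$helix, pos[ok])
    forward[gn] <- in_seg[ok]
    reverse[in_seg[ok]] <- gn
  }
  if (anyDuplicated(names(forward)))
    stop_gact("segment table produces duplicate generic numbers",
              class = "gact_table_error")
  structure(list(forward = forward, reverse = reverse,
                 segment = segment,
                 segment_bounds = tab[, c("segment", "start", "end")]),
            class = "gact_bwmap")
}

#' @export
print.gact_bwmap <- function(x, ...) {
  cat(sprintf("<gact_bwmap> %d generic numbers over %d segments\n",
              length(x$forward), nrow(x$segment_bounds)))
  invisible(x)
}

#' Annotate a topology with segments and generic numbers from a map
#'
#' @param topology a [topology].
#' @param map a `gact_bwmap` from [assign_generic_numbers].
#' @return the topology with `residues$segment` and `residues$generic_number`
#'   filled in.
#' @export
annotate_topology <- function(topology, map) {
  stopifnot(inherits(map, "gact_bwmap"))
  topology$residues$segment <- map$segment
  topology$residues$generic_number <- map$reverse
  topology
}

#' Build a generic-number map from an already annotated topology
#'
#' Used with synthetic topologies whose residues carry generic numbers.
#'
#' @param topology a [topology] with `residues$generic_number` filled.
#' @return a `gact_bwmap`.
#' @export
generic_map <- function(topology) {
  gn <- topology$residues$generic_number
  has <- which(!is.na(gn) & nzchar(gn))
  forward <- stats::setNames(as.integer(has), gn[has])
  segs <- topology$residues$segment
  bounds <- do.call(rbind, lapply(split(seq_along(segs), segs), function(i)
    data.frame(segment = segs[i[1]],
               start = min(topology$residues$author_number[i]),
               end = max(topology$residues$author_number[i]))))
  structure(list(forward = forward, reverse = gn, segment = segs,
                 segment_bounds = bounds[bounds$segment != "LIGAND", ]),
            class = "gact_bwmap")
}

#' Look up the residue index of a generic number
#'
#' @param map a `gact_bwmap`.
#' @param generic generic number string, e.g. `"3.50"`.
#' @return 1-based residue index.
#' @export
resolve_generic <- function(map, generic) {
  idx <- map$forward[generic]
  if (any(is.na(idx)))
    stop_gact("generic number(s) not in map: %s",
              paste(generic[is.na(idx)], collapse = ", "),
              class = "gact_table_error")
  unname(idx)
}
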