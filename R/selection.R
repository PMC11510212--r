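# A small atom-selection language, in the MDAnalysis/VMD tradition:
#   "name CA and segment TM6", "heavy and sidechain and resnum 100-110",
#   "generic 3.50", "protein or ligand", "not hydrogen", parentheses allowed.

SELECTION_KEYWORDS <- c("name", "segment", "resnum", "generic",
                        "sidechain", "backbone", "heavy", "hydrogen",
                        "protein", "ligand", "all",
                        "and", "or", "not", "(", ")")

tokenize_selection <- function(query) {
  q <- gsub("([()])", " \\1 ", query)
  toks <- strsplit(trimws(q), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Select atoms by a query expression
#'
#' Grammar: primitives `name <A[,B,...]>`, `segment <S[,S,...]>`,
#' `resnum <a>[-b][,c...]` (author numbers), `generic <h.p>[-h.q]`,
#' `sidechain`, `backbone`, `heavy`, `hydrogen`, `protein`, `ligand`, `all`;
#' combined with `and`, `or`, `not` and parentheses.  Generic-number
#' primitives require the topology to be annotated
#' (see [annotate_topology]).
#'
#' @param topology a [topology].
#' @param query selection expression string.
#' @return a [selection] with sorted, deduplicated atom indices.
#' @export
select_atoms <- function(topology, query) {
  toks <- tokenize_selection(query)
  if (!length(toks))
    stop_gact("empty selection query", class = "gact_selection_error")
  a <- topology$atoms
  r <- topology$residues
  na <- nrow(a)
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  fail <- function(tok, at = pos) stop_gact(
    "selection parse error at token %d ('%s') in: %s", at, tok, query,
    class = "gact_selection_error")

  prim_value <- function(keyword) {
    v <- peek()
    if (is.na(v) || v %in% SELECTION_KEYWORDS)
      stop_gact("selection keyword '%s' needs an argument (token %d) in: %s",
                keyword, pos, query, class = "gact_selection_error")
    advance()
  }

  resnum_mask <- function(valstr) {
    mask <- rep(FALSE, na)
    for (part in strsplit(valstr, ",")[[1]]) {
      m <- regmatches(part, regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", part))[[1]]
      if (!length(m)) fail(part)
      lo <- as.integer(m[2])
      hi <- if (nzchar(m[3])) as.integer(m[3]) else lo
      ok_res <- which(r$author_number >= lo & r$author_number <= hi)
      mask <- mask | a$resindex %in% ok_res
    }
    mask
  }

  generic_mask <- function(valstr) {
    gn <- r$generic_number
    mask <- rep(FALSE, na)
    for (part in strsplit(valstr, ",")[[1]]) {
      m <- regmatches(part,
                      regexec("^([0-9]+\\.[0-9]+)(?:-([0-9]+\\.[0-9]+))?$",
                              part))[[1]]
      if (!length(m)) fail(part)
      if (!nzchar(m[3])) {
        ok_res <- which(!is.na(gn) & gn == m[2])
      } else {
        h1 <- strsplit(m[2], ".", fixed = TRUE)[[1]]
        h2 <- strsplit(m[3], ".", fixed = TRUE)[[1]]
        if (h1[1] != h2[1])
          stop_gact("generic range spans helices: %s", part,
                    class = "gact_selection_error")
        p <- suppressWarnings(as.integer(sub("^[0-9]+\\.", "", gn)))
        h <- sub("\\..*$", "", gn)
        ok_res <- which(!is.na(gn) & h == h1[1] &
                          p >= as.integer(h1[2]) & p <= as.integer(h2[2]))
      }
      mask <- mask | a$resindex %in% ok_res
    }
    mask
  }

  parse_primitive <- function() {
    tok <- peek()
    if (is.na(tok)) fail("<end>")
    if (tok == "(") {
      advance()
      m <- parse_or()
      if (!identical(peek(), ")")) fail(peek() %||% "<end>")
      advance()
      return(m)
    }
    at <- pos
    advance()
    switch(tok,
      name = { v <- prim_value("name"); a$name %in% strsplit(v, ",")[[1]] },
      segment = {
        v <- prim_value("segment")
        a$resindex %in% which(r$segment %in% strsplit(v, ",")[[1]])
      },
      resnum = resnum_mask(prim_value("resnum")),
      generic = generic_mask(prim_value("generic")),
      sidechain = a$is_sidechain,
      backbone = !a$is_sidechain,
      heavy = !a$is_hydrogen,
      hydrogen = a$is_hydrogen,
      protein = !(a$resindex %in% which(r$segment == "LIGAND")),
      ligand = a$resindex %in% which(r$segment == "LIGAND"),
      all = rep(TRUE, na),
      fail(tok, at))
  }

  parse_not <- function() {
    if (identical(peek(), "not")) { advance(); return(!parse_not()) }
    parse_primitive()
  }
  parse_and <- function() {
    m <- parse_not()
    while (identical(peek(), "and")) { advance(); m <- m & parse_not() }
    m
  }
  parse_or <- function() {
    m <- parse_and()
    while (identical(peek(), "or")) { advance(); m <- m | parse_and() }
    m
  }

  mask <- parse_or()
  if (!is.na(peek())) fail(peek())
  selection(which(mask), description = query, topology = topology)
}
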