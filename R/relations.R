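#' The eight Pathway Commons binary relation types
#'
#' Pathway exports reduced to the simple interaction format (SIF) carry one of
#' eight binary relation types between a pair of proteins.  Five of them are
#' directed (`p1 controls-phosphorylation-of p2` is not the same statement as
#' its reverse); three are undirected.  Each type owns a fixed display color
#' (the primary visual channel in matrix cells and the Venn summary) and a
#' fixed 45-degree angular slot (the secondary, orientation channel), constant
#' across every cell so that a type is recognisable by angle alone.
#'
#' @return A data.frame with one row per type and columns `name`, `directed`
#'   (logical), `color` (RGB hex) and `slot` (integer 0..7).
#' @examples
#' relation_types()
#' @export
relation_types <- function() {
  data.frame(
    name = c(
      "controls-state-change-of",
      "controls-phosphorylation-of",
      "controls-transport-of",
      "controls-expression-of",
      "catalysis-precedes",
      "in-complex-with",
      "interacts-with",
      "neighbor-of"
    ),
    directed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    color = c(
      "#E41A1C", # red
      "#FF7F00", # orange
      "#FFD92F", # yellow
      "#4DAF4A", # green
      "#984EA3", # purple
      "#00CED1", # cyan
      "#F781BF", # pink
      "#377EB8"  # blue
    ),
    slot = 0:7,
    stringsAsFactors = FALSE
  )
}

# Fast lookups used throughout; recomputed cheaply (data is tiny).
rel_type_names <- function() relation_types()$name

rel_type_directed <- function() {
  tt <- relation_types()
  stats::setNames(tt$directed, tt$name)
}

rel_type_color <- function() {
  tt <- relation_types()
  stats::setNames(tt$color, tt$name)
}

rel_type_slot <- function() {
  tt <- relation_types()
  stats::setNames(tt$slot, tt$name)
}

# ---- relation elements ------------------------------------------------------
#
# A relation element is a (type, orientation) pair encoded as the string
# "type|orientation" with orientation one of "out", "in", "none".  Orientation
# is stored relative to the first protein of the pair under which the element
# is filed, so that R_ik and R_jk are directly comparable as "how i (resp. j)
# relates to k".  Undirected types always carry orientation "none".

rel_element <- function(type, orientation) paste(type, orientation, sep = "|")

rel_element_type <- function(el) sub("\\|[a-z]+$", "", el)

rel_element_orientation <- function(el) sub("^.*\\|", "", el)

# Flip orientation for filing under the reversed pair.
rel_element_flip <- function(el) {
  ors <- rel_element_orientation(el)
  flipped <- ifelse(ors == "out", "in", ifelse(ors == "in", "out", "none"))
  rel_element(rel_element_type(el), flipped)
}

canon_set <- function(x) sort(unique(x), method = "radix")

pair_key <- function(p, q) paste(p, q, sep = "\t")

#' Construct a pathway network from a relation table
#'
#' The core container: an ordered protein list plus a map from ordered protein
#' pair (p, q), p != q, to the set of relation elements R_pq expressed relative
#' to p.  Reciprocity is maintained internally: an element `(t, out)` filed
#' under (p, q) always has its mirror `(t, in)` filed under (q, p), and
#' undirected elements appear as `(t, none)` under both orderings.
#'
#' @param edges data.frame with character columns `source`, `type`, `target`;
#'   may have zero rows.
#' @return An object of class `pathway_network` with fields `proteins`
#'   (lexicographically sorted character vector) and `relations` (named list,
#'   keys `"p\tq"`, values canonical element sets).
#' @export
pathway_network <- function(edges = data.frame(source = character(),
                                               type = character(),
                                               target = character())) {
  stopifnot(all(c("source", "type", "target") %in% names(edges)))
  directed <- rel_type_directed()
  bad <- setdiff(unique(edges$type), names(directed))
  if (length(bad) > 0) {
    stop("unknown relation type(s): ", paste(bad, collapse = ", "))
  }
  if (any(edges$source == edges$target)) {
    stop("self relations (p, p) are not allowed")
  }
  rel <- list()
  add <- function(p, q, el) {
    k <- pair_key(p, q)
    rel[[k]] <<- c(rel[[k]], el)
  }
  for (i in seq_len(nrow(edges))) {
    s <- edges$source[i]; t <- edges$type[i]; g <- edges$target[i]
    if (directed[[t]]) {
      add(s, g, rel_element(t, "out"))
      add(g, s, rel_element(t, "in"))
    } else {
      add(s, g, rel_element(t, "none"))
      add(g, s, rel_element(t, "none"))
    }
  }
  rel <- lapply(rel, canon_set)
  proteins <- canon_set(c(edges$source, edges$target))
  structure(list(proteins = proteins, relations = rel),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("<pathway_network: %d proteins, %d relation elements>\n",
              length(x$proteins),
              sum(lengths(x$relations)) / 2))
  invisible(x)
}

#' Relation set between two proteins
#'
#' Returns R_pq, the set of relation elements between `p` and `q` expressed
#' relative to `p`.  The empty set (a zero-length character vector) is
#' returned when no relation exists, including when `p == q`.
#'
#' @param network a `pathway_network`
#' @param p,q protein names
#' @return character vector of `"type|orientation"` elements
#' @export
rel_set <- function(network, p, q) {
  if (p == q) return(character(0))
  v <- network$relations[[pair_key(p, q)]]
  if (is.null(v)) character(0) else v
}

#' Validate the internal invariants of a pathway network
#'
#' Checks reciprocity, absence of self pairs, protein-list coverage and
#' set-ness of every relation value.  Intended for test suites and for
#' guarding hand-built networks.
#'
#' @param network a `pathway_network`
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_network <- function(network) {
  keys <- names(network$relations)
  for (k in keys) {
    pq <- strsplit(k, "\t", fixed = TRUE)[[1]]
    if (pq[1] == pq[2]) stop("self pair present: ", pq[1])
    if (!all(pq %in% network$proteins)) {
      stop("relation key names unlisted protein: ", k)
    }
    v <- network$relations[[k]]
    if (anyDuplicated(v)) stop("duplicate elements in ", k)
    mirror <- rel_set(network, pq[2], pq[1])
    if (!identical(canon_set(rel_element_flip(v)), canon_set(mirror))) {
      stop("reciprocity violated for pair ", k)
    }
  }
  invisible(TRUE)
}

# ---- SIF I/O ----------------------------------------------------------------

#' Read an extended SIF file
#'
#' One relation per line, `SOURCE<TAB>relation-type<TAB>TARGET`, UTF-8, LF or
#' CRLF line endings.  Lines beginning with `#` are comments; blank lines are
#' skipped; surrounding whitespace in fields is stripped.  Duplicate lines
#' collapse to a single relation element, and for undirected types the order
#' of the two endpoints on the line is irrelevant.  Protein identity is the
#' exact (case-sensitive) name string.
#'
#' @param path file path
#' @return a [pathway_network()]
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*$", lines) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) return(pathway_network())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3)) {
    i <- which(nf != 3)[1]
    stop(sprintf("parse error at line %d: expected 3 tab-separated fields, got %d",
                 lineno[i], nf[i]))
  }
  m <- matrix(trimws(unlist(parts)), ncol = 3, byrow = TRUE)
  known <- rel_type_names()
  bad <- !(m[, 2] %in% known)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("parse error at line %d: unknown relation type '%s'",
                 lineno[i], m[i, 2]))
  }
  if (any(m[, 1] == "" | m[, 3] == "")) {
    i <- which(m[, 1] == "" | m[, 3] == "")[1]
    stop(sprintf("parse error at line %d: empty protein name", lineno[i]))
  }
  pathway_network(data.frame(source = m[, 1], type = m[, 2], target = m[, 3],
                             stringsAsFactors = FALSE))
}

#' Write a network to extended SIF
#'
#' Each directed relation is emitted once with the source first; each
#' undirected relation is emitted once with the lexicographically smaller
#' endpoint first.  Lines are sorted, written with LF endings.  Reading the
#' file back reproduces the network exactly.
#'
#' @param network a `pathway_network`
#' @param path output file path
#' @export
write_sif <- function(network, path) {
  lines <- character(0)
  for (k in names(network$relations)) {
    pq <- strsplit(k, "\t", fixed = TRUE)[[1]]
    p <- pq[1]; q <- pq[2]
    for (el in network$relations[[k]]) {
      o <- rel_element_orientation(el)
      t <- rel_element_type(el)
      if (o == "out" || (o == "none" && p < q)) {
        lines <- c(lines, paste(p, t, q, sep = "\t"))
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- sort(lines, method = "radix")
  if (length(lines) > 0) {
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(NULL)
}

# ---- complexes TSV ----------------------------------------------------------

#' Read a complex-membership TSV
#'
#' Two-column dialect `complex_id<TAB>member_ref`, one membership per line.
#' A member reference equal to another complex id creates nesting; any other
#' reference is a protein name.  Membership must form a DAG: a cycle is a
#' validation error and the offending cycle is reported.
#'
#' @param path file path
#' @return list of complex records, each `list(complex_id =, members =)`,
#'   named by complex id.
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*$", lines) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  recs <- list()
  if (length(lines) > 0) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 2)) {
      i <- which(nf != 2)[1]
      stop(sprintf("parse error at line %d: expected 2 tab-separated fields",
                   lineno[i]))
    }
    m <- matrix(trimws(unlist(parts)), ncol = 2, byrow = TRUE)
    for (cid in unique(m[, 1])) {
      recs[[cid]] <- list(complex_id = cid,
                          members = canon_set(m[m[, 1] == cid, 2]))
    }
  }
  validate_complexes(recs)
  recs
}

#' Validate complex records
#'
#' Checks that every record has members and that complex-in-complex
#' membership is acyclic; a cycle aborts with the cycle spelled out.
#'
#' @param records list of complex records as returned by [read_complexes()]
#' @return `TRUE` invisibly
#' @export
validate_complexes <- function(records) {
  ids <- names(records)
  for (cid in ids) {
    if (length(records[[cid]]$members) == 0) {
      stop("complex has no members: ", cid)
    }
  }
  # DFS cycle detection over complex->complex edges
  state <- stats::setNames(rep(0L, length(ids)), ids) # 0 new, 1 open, 2 done
  visit <- function(cid, stack) {
    if (state[[cid]] == 1L) {
      cyc <- c(stack[which(stack == cid):length(stack)], cid)
      stop("membership cycle: ", paste(cyc, collapse = " -> "))
    }
    if (state[[cid]] == 2L) return(invisible(NULL))
    state[[cid]] <<- 1L
    for (m in records[[cid]]$members) {
      if (m %in% ids) visit(m, c(stack, cid))
    }
    state[[cid]] <<- 2L
  }
  for (cid in ids) visit(cid, character(0))
  invisible(TRUE)
}

#' Write complex records as TSV
#'
#' @param records list of complex records
#' @param path output path
#' @export
write_complexes <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    paste(r$complex_id, r$members, sep = "\t")
  }), use.names = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(NULL)
}
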