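#' Build a complex hierarchy from membership records
#'
#' Resolves, for every complex, its transitive protein closure (the distinct
#' proteins it ultimately contains through any depth of nesting) and the
#' minimum nesting distance between every ancestor/descendant complex pair
#' (1 = direct member).  Complexes may share members and parents, so the
#' structure is a DAG rather than a tree.
#'
#' @param records list of complex records from [read_complexes()]
#' @return a `complex_hierarchy`: list with `records`, `protein_closure`
#'   (named list complex_id -> protein set) and `levels` (data.frame
#'   `ancestor`, `descendant`, `level`)
#' @export
complex_hierarchy <- function(records) {
  validate_complexes(records)
  ids <- names(records)
  closure <- list()
  resolve <- function(cid) {
    if (!is.null(closure[[cid]])) return(closure[[cid]])
    mem <- records[[cid]]$members
    sub <- mem[mem %in% ids]
    prot <- mem[!(mem %in% ids)]
    for (s in sub) prot <- c(prot, resolve(s))
    closure[[cid]] <<- canon_set(prot)
    closure[[cid]]
  }
  for (cid in ids) resolve(cid)
  # BFS from each complex over complex->complex membership edges
  anc <- character(0); dsc <- character(0); lvl <- integer(0)
  children <- lapply(records, function(r) r$members[r$members %in% ids])
  for (a in ids) {
    dist <- stats::setNames(rep(NA_integer_, length(ids)), ids)
    queue <- children[[a]]
    d <- 1L
    while (length(queue) > 0) {
      fresh <- unique(queue[is.na(dist[queue])])
      dist[fresh] <- d
      queue <- unique(unlist(children[fresh], use.names = FALSE))
      queue <- queue[is.na(dist[queue])]
      d <- d + 1L
    }
    hit <- names(dist)[!is.na(dist)]
    anc <- c(anc, rep(a, length(hit)))
    dsc <- c(dsc, hit)
    lvl <- c(lvl, unname(dist[hit]))
  }
  structure(list(records = records,
                 protein_closure = closure,
                 levels = data.frame(ancestor = anc, descendant = dsc,
                                     level = lvl,
                                     stringsAsFactors = FALSE)),
            class = "complex_hierarchy")
}

#' Complex sizes (distinct transitive protein counts)
#'
#' Size of a complex is the number of distinct proteins in its transitive
#' closure, not its direct member count: shared proteins are deduplicated.
#'
#' @param h a `complex_hierarchy`
#' @return named integer vector, complex_id -> size
#' @export
complex_sizes <- function(h) {
  vapply(h$protein_closure, length, integer(1))
}

#' Size-ordered listing with the parent-before-child constraint
#'
#' Complexes are sorted by size descending (name as tiebreak); a stable
#' repair pass then moves any complex that would precede one of its
#' ancestors to just after its last ancestor, so a nested complex always
#' appears below every parent.
#'
#' @param h a `complex_hierarchy`
#' @return character vector of complex ids
#' @export
ordered_listing <- function(h) {
  sizes <- complex_sizes(h)
  ids <- names(sizes)
  if (length(ids) == 0) return(character(0))
  listing <- ids[order(-sizes, ids, method = "radix")]
  lv <- h$levels
  budget <- 10L * length(ids)^2 + 10L
  repeat {
    moved <- FALSE
    for (i in seq_along(listing)) {
      d <- listing[i]
      anc <- lv$ancestor[lv$descendant == d]
      pos <- match(anc, listing)
      if (length(pos) > 0 && max(pos) > i) {
        target <- max(pos)
        listing <- append(listing[-i], d, after = target - 1L)
        moved <- TRUE
        break
      }
    }
    budget <- budget - 1L
    if (!moved || budget <= 0L) break
  }
  if (budget <= 0L) {
    # guard: priority topological order (largest eligible first)
    placed <- character(0)
    avail <- function() {
      cand <- setdiff(ids, placed)
      ok <- vapply(cand, function(d) {
        anc <- lv$ancestor[lv$descendant == d]
        all(anc %in% placed)
      }, logical(1))
      cand[ok]
    }
    while (length(placed) < length(ids)) {
      cand <- avail()
      cand <- cand[order(-sizes[cand], cand, method = "radix")]
      placed <- c(placed, cand[1])
    }
    listing <- placed
  }
  listing
}

#' Arc data for the descendants of a selected complex
#'
#' One arc per direct complex-membership edge reachable from `selected`,
#' connecting listing positions.  Arc thickness is the transitive protein
#' count of the arc's target sub-complex; saturation decays geometrically
#' with the nesting level away from the selection
#' (`s0 * decay^(level - 1)`).
#'
#' @param h a `complex_hierarchy`
#' @param selected complex id
#' @param listing optional precomputed [ordered_listing()]
#' @param s0 saturation of level-1 arcs
#' @param decay per-level saturation decay in (0, 1]
#' @return data.frame `from`, `to` (ids), `from_index`, `to_index`
#'   (positions in the listing), `thickness`, `saturation`, `level`
#' @export
descendant_arcs <- function(h, selected, listing = ordered_listing(h),
                            s0 = 1.0, decay = 0.6) {
  ids <- names(h$records)
  if (!(selected %in% ids)) stop("unknown complex id: ", selected)
  sizes <- complex_sizes(h)
  lv <- h$levels
  # level of each reachable complex measured from `selected`
  lev_from_sel <- stats::setNames(
    lv$level[lv$ancestor == selected],
    lv$descendant[lv$ancestor == selected])
  reachable <- c(selected, names(lev_from_sel))
  out <- list()
  for (a in reachable) {
    la <- if (a == selected) 0L else lev_from_sel[[a]]
    kids <- h$records[[a]]$members
    kids <- kids[kids %in% ids]
    for (child in kids) {
      level <- la + 1L
      out[[length(out) + 1L]] <- data.frame(
        from = a, to = child,
        from_index = match(a, listing), to_index = match(child, listing),
        thickness = unname(sizes[child]),
        saturation = s0 * decay^(level - 1),
        level = level,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      from_index = integer(0), to_index = integer(0),
                      thickness = numeric(0), saturation = numeric(0),
                      level = integer(0)))
  }
  do.call(rbind, out)
}

#' Complex-membership overlay grid for the matrix view
#'
#' Cell (i, j) counts the selected complexes whose transitive protein
#' closure contains both protein i and protein j; rendered darkness grows
#' with the count, so intersections of several complexes stand out.
#'
#' @param h a `complex_hierarchy`
#' @param proteins_in_order protein names in matrix order
#' @param selected character vector of complex ids, or `"all"`
#' @return symmetric integer matrix with `proteins_in_order` dimnames
#' @export
membership_overlay <- function(h, proteins_in_order, selected = "all") {
  n <- length(proteins_in_order)
  g <- matrix(0L, n, n, dimnames = list(proteins_in_order,
                                        proteins_in_order))
  ids <- if (identical(selected, "all")) names(h$records) else selected
  unknown <- setdiff(ids, names(h$records))
  if (length(unknown) > 0) stop("unknown complex id(s): ",
                                paste(unknown, collapse = ", "))
  for (cid in ids) {
    inside <- proteins_in_order %in% h$protein_closure[[cid]]
    g[inside, inside] <- g[inside, inside] + 1L
  }
  g
}

#' Export arc data as JSON
#'
#' @param arcs data.frame from [descendant_arcs()]
#' @param path output path
#' @export
write_arcs_json <- function(arcs, path) {
  jsonlite::write_json(arcs, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}
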