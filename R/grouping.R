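#' Relation profile of a protein
#'
#' The map k -> R_pk over all proteins k outside `exclude` and distinct from
#' `p`, with empty sets omitted and keys and element sets canonically sorted,
#' so two profiles compare by value with `identical()`.
#'
#' @param network a `pathway_network`
#' @param p protein name
#' @param exclude character vector of proteins to leave out of the profile
#' @return named list of canonical relation-element sets
#' @export
relation_profile <- function(network, p, exclude = character(0)) {
  if (!(p %in% network$proteins)) stop("unknown protein: ", p)
  out <- list()
  for (k in network$proteins) {
    if (k == p || k %in% exclude) next
    r <- rel_set(network, p, k)
    if (length(r) > 0) out[[k]] <- r
  }
  if (length(out) == 0) return(list())
  out[order(names(out), method = "radix")]
}

# Do p and q have identical relations to every third protein?
# The mutual pair entry is excluded on both sides: p matches q iff
# R_pk == R_qk for all k outside {p, q}.
profiles_match <- function(network, p, q) {
  identical(relation_profile(network, p, exclude = q),
            relation_profile(network, q, exclude = p))
}

# All profiles in one sweep over the relations map (equivalent to calling
# relation_profile per protein, but O(#pairs) instead of O(n^2) lookups).
all_profiles <- function(network) {
  profs <- stats::setNames(vector("list", length(network$proteins)),
                           network$proteins)
  for (i in seq_along(profs)) profs[[i]] <- list()
  for (k in names(network$relations)) {
    pq <- strsplit(k, "\t", fixed = TRUE)[[1]]
    profs[[pq[1]]][[pq[2]]] <- network$relations[[k]]
  }
  lapply(profs, function(pr) {
    if (length(pr) == 0) list() else pr[order(names(pr), method = "radix")]
  })
}

#' Group structurally equivalent proteins (leader algorithm)
#'
#' Single pass over the proteins in lexicographic order.  Each protein is
#' compared against the current leader list: it joins the follower list of
#' the first leader with an identical relation profile (relations to every
#' third protein, the mutual pair entry excluded), or founds a new group and
#' becomes its leader.  One pass suffices because profile identity is an
#' equivalence relation.
#'
#' @param network a `pathway_network`
#' @return a `grouped_network`: list with `groups` (each
#'   `list(leader, followers, size)`), `collapsed` (a `pathway_network` over
#'   group labels), `label_map` (label -> member names) and `self_cells`
#'   (label -> union of within-group relation sets).
#' @export
group_by_similarity <- function(network) {
  profs <- all_profiles(network)
  drop_key <- function(pr, k) {
    pr[[k]] <- NULL
    if (length(pr) == 0) list() else pr
  }
  match_pair <- function(p, q) {
    identical(drop_key(profs[[p]], q), drop_key(profs[[q]], p))
  }
  leaders <- character(0)
  followers <- list()
  for (p in network$proteins) {
    hit <- NA_character_
    for (q in leaders) {
      if (match_pair(p, q)) { hit <- q; break }
    }
    if (is.na(hit)) {
      leaders <- c(leaders, p)
      followers[[p]] <- character(0)
    } else {
      followers[[hit]] <- c(followers[[hit]], p)
    }
  }
  groups <- lapply(leaders, function(l) {
    list(leader = l, followers = followers[[l]],
         size = 1L + length(followers[[l]]))
  })
  names(groups) <- leaders
  collapse_groups(network, groups)
}

group_label <- function(g) {
  if (g$size == 1L) g$leader else sprintf("%s (+%d)", g$leader, g$size - 1L)
}

# Build the collapsed network and assemble the grouped_network object.
collapse_groups <- function(network, groups) {
  labels <- vapply(groups, group_label, character(1))
  label_map <- lapply(groups, function(g) c(g$leader, g$followers))
  names(label_map) <- labels
  leaders <- vapply(groups, `[[`, character(1), "leader")
  # relations between group nodes = relations between their leaders
  edges <- list()
  for (a in seq_along(groups)) {
    for (b in seq_along(groups)) {
      if (a == b) next
      r <- rel_set(network, leaders[a], leaders[b])
      for (el in r) {
        o <- rel_element_orientation(el)
        t <- rel_element_type(el)
        if (o == "out" || (o == "none" && a < b)) {
          edges[[length(edges) + 1L]] <-
            c(labels[a], t, labels[b])
        }
      }
    }
  }
  collapsed <- if (length(edges) > 0) {
    m <- do.call(rbind, edges)
    net <- pathway_network(data.frame(source = m[, 1], type = m[, 2],
                                      target = m[, 3],
                                      stringsAsFactors = FALSE))
    # isolated groups must still appear as nodes
    net$proteins <- canon_set(c(net$proteins, labels))
    net
  } else {
    net <- pathway_network()
    net$proteins <- canon_set(labels)
    net
  }
  # self cell of a group: union of relation sets over within-group pairs,
  # kept as metadata (never a network key, preserving the no-self-pair rule)
  self_cells <- lapply(groups, function(g) {
    mem <- c(g$leader, g$followers)
    acc <- character(0)
    for (m1 in mem) for (m2 in mem) {
      if (m1 != m2) acc <- c(acc, rel_set(network, m1, m2))
    }
    canon_set(acc)
  })
  names(self_cells) <- labels
  structure(list(groups = groups, collapsed = collapsed,
                 label_map = label_map, self_cells = self_cells),
            class = "grouped_network")
}

#' @export
print.grouped_network <- function(x, ...) {
  sizes <- vapply(x$groups, `[[`, integer(1), "size")
  cat(sprintf("<grouped_network: %d groups over %d proteins>\n",
              length(x$groups), sum(sizes)))
  invisible(x)
}

#' Export the group table as TSV
#'
#' Columns: group label, size, comma-separated member names.
#'
#' @param grouped a `grouped_network`
#' @param path output path
#' @export
write_groups_tsv <- function(grouped, path) {
  lines <- vapply(seq_along(grouped$groups), function(i) {
    g <- grouped$groups[[i]]
    paste(group_label(g), g$size,
          paste(c(g$leader, g$followers), collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(NULL)
}
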