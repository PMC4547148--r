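#' Specification for a synthetic pathway fixture
#'
#' The generator emulates pathway-database exports reduced to binary
#' relations: sparse typed relations over a protein set, planted groups of
#' structurally identical proteins (which the leader grouping must recover),
#' optional relation-disjoint communities, and a nested complex hierarchy.
#' Defaults mirror a mid-sized curated pathway: 150 proteins with roughly
#' 0.8 expected relations per pair gives several thousand typed relations.
#'
#' @param n_proteins number of proteins
#' @param relation_density expected number of relations per unordered pair
#' @param type_weights named numeric vector over the 8 relation types,
#'   summing to 1 (default uniform)
#' @param group_sizes integer vector of planted identical-profile group
#'   sizes (may be empty)
#' @param n_communities number of relation-disjoint communities (>= 1)
#' @param complex_depth maximum complex nesting distance (>= 1)
#' @param seed integer seed; everything downstream is deterministic in it
#' @return a `fixture_spec` list
#' @export
fixture_spec <- function(n_proteins = 150L,
                         relation_density = 0.8,
                         type_weights = NULL,
                         group_sizes = c(8L, 5L),
                         n_communities = 1L,
                         complex_depth = 3L,
                         seed = 1L) {
  types <- rel_type_names()
  if (is.null(type_weights)) {
    type_weights <- stats::setNames(rep(1 / length(types), length(types)),
                                    types)
  }
  stopifnot(abs(sum(type_weights) - 1) < 1e-8,
            setequal(names(type_weights), types),
            n_communities >= 1, complex_depth >= 1,
            relation_density >= 0)
  if (sum(group_sizes) > n_proteins - 4L * n_communities) {
    stop("infeasible fixture: planted group sizes leave too few background proteins")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 relation_density = relation_density,
                 type_weights = type_weights,
                 group_sizes = as.integer(group_sizes),
                 n_communities = as.integer(n_communities),
                 complex_depth = as.integer(complex_depth),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

fixture_protein_names <- function(n) sprintf("P%04d", seq_len(n))

#' Generate a synthetic pathway network
#'
#' Background relations are sampled independently per unordered pair and
#' type with probability `relation_density * type_weights[type]`; directed
#' types get a random direction.  Members of each planted group receive one
#' shared relation profile over a handful of background proteins (same
#' types, same directions) and no relations to each other or elsewhere, so
#' their structural equivalence is exact and noise-free.  With more than one
#' community, relations never cross community boundaries, so the relation
#' graph has at least `n_communities` connected components.
#'
#' @param spec a [fixture_spec()]
#' @return a `pathway_network`; attributes `planted_groups` (list of member
#'   name vectors) and `communities` (named community index per protein)
#' @export
generate_network <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_proteins
    prot <- fixture_protein_names(n)
    types <- names(spec$type_weights)
    directed <- rel_type_directed()
    # carve out planted members, assign everyone a community
    n_plant <- sum(spec$group_sizes)
    planted_idx <- if (n_plant > 0) sample.int(n, n_plant) else integer(0)
    planted <- prot[planted_idx]
    background <- setdiff(prot, planted)
    comm <- stats::setNames(integer(n), prot)
    comm[background] <- rep_len(seq_len(spec$n_communities),
                                length(background))
    groups <- list()
    ptr <- 0L
    for (gi in seq_along(spec$group_sizes)) {
      sz <- spec$group_sizes[gi]
      members <- planted[(ptr + 1L):(ptr + sz)]
      ptr <- ptr + sz
      comm[members] <- 1L + (gi - 1L) %% spec$n_communities
      groups[[gi]] <- members
    }
    src <- character(0); typ <- character(0); tgt <- character(0)
    # background relations within communities
    if (length(background) > 1) {
      for (a in seq_len(length(background) - 1L)) {
        for (b in (a + 1L):length(background)) {
          p <- background[a]; q <- background[b]
          if (comm[[p]] != comm[[q]]) next
          hit <- stats::runif(length(types)) <
            spec$relation_density * spec$type_weights
          for (t in types[hit]) {
            if (directed[[t]] && stats::runif(1) < 0.5) {
              src <- c(src, q); typ <- c(typ, t); tgt <- c(tgt, p)
            } else {
              src <- c(src, p); typ <- c(typ, t); tgt <- c(tgt, q)
            }
          }
        }
      }
    }
    # planted groups: one shared external profile per group
    for (gi in seq_along(groups)) {
      members <- groups[[gi]]
      pool <- background[comm[background] == comm[[members[1]]]]
      n_targets <- min(length(pool), sample(3:6, 1))
      targets <- sample(pool, n_targets)
      for (tg in targets) {
        k_types <- sample(types, sample(1:2, 1))
        for (t in k_types) {
          outward <- !directed[[t]] || stats::runif(1) < 0.5
          for (m in members) {
            if (outward) {
              src <- c(src, m); typ <- c(typ, t); tgt <- c(tgt, tg)
            } else {
              src <- c(src, tg); typ <- c(typ, t); tgt <- c(tgt, m)
            }
          }
        }
      }
    }
    net <- pathway_network(data.frame(source = src, type = typ,
                                      target = tgt,
                                      stringsAsFactors = FALSE))
    # isolated proteins are still part of the pathway
    net$proteins <- canon_set(c(net$proteins, prot))
    attr(net, "planted_groups") <- groups
    attr(net, "communities") <- comm
    net
  })
}

#' Generate a nested complex hierarchy over the fixture proteins
#'
#' Builds `complex_depth + 1` levels of complexes: bottom-level complexes
#' contain proteins only; each higher-level complex contains one or two
#' complexes from the level immediately below plus a few proteins.  A
#' guaranteed chain through all levels makes the maximum ancestor-descendant
#' nesting distance exactly `complex_depth`.  Deterministic given the spec
#' seed.
#'
#' @param spec a [fixture_spec()]
#' @return list of complex records (as from [read_complexes()])
#' @export
generate_hierarchy <- function(spec) {
  with_seed(spec$seed + 1000L, {
    prot <- fixture_protein_names(spec$n_proteins)
    n_levels <- spec$complex_depth + 1L
    recs <- list()
    per_level <- pmax(rev(seq_len(n_levels)), 2L) # more leaves than roots
    prev_level_ids <- character(0)
    cnum <- 0L
    for (lvl in seq_len(n_levels)) {
      ids <- character(0)
      for (i in seq_len(per_level[lvl])) {
        cnum <- cnum + 1L
        cid <- sprintf("CPLX%02d", cnum)
        members <- sample(prot, sample(2:5, 1))
        if (lvl > 1) {
          # always include the chain predecessor for the first complex of
          # the level; others may pick any lower complex
          nested <- if (i == 1) prev_level_ids[1] else
            sample(prev_level_ids, min(length(prev_level_ids),
                                       sample(1:2, 1)))
          members <- c(nested, members)
        }
        recs[[cid]] <- list(complex_id = cid, members = canon_set(members))
        ids <- c(ids, cid)
      }
      prev_level_ids <- ids
    }
    validate_complexes(recs)
    recs
  })
}

#' Write a fixture to disk as SIF + complexes TSV
#'
#' Files carry a comment header recording the seed.
#'
#' @param spec a [fixture_spec()]
#' @param sif_path,complexes_path output paths
#' @return the generated network, invisibly
#' @export
write_fixture <- function(spec, sif_path, complexes_path = NULL) {
  net <- generate_network(spec)
  write_sif(net, sif_path)
  header <- sprintf("# synthetic fixture, seed %d", spec$seed)
  body <- readLines(sif_path)
  writeLines(c(header, body), sif_path)
  if (!is.null(complexes_path)) {
    recs <- generate_hierarchy(spec)
    write_complexes(recs, complexes_path)
    body <- readLines(complexes_path)
    writeLines(c(header, body), complexes_path)
  }
  invisible(net)
}
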