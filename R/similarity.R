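#' Common relations of two relation sets
#'
#' The intersection C = r1 ∩ r2 of two relation-element sets, the building
#' block of the protein dissimilarity measure.
#'
#' @param r1,r2 character vectors of relation elements
#' @return the intersection, canonically sorted
#' @export
common_relations <- function(r1, r2) {
  canon_set(intersect(r1, r2))
}

#' Size of the uncommon-relation set
#'
#' |U| = |r1| + |r2| - 2|r1 ∩ r2|, which equals the cardinality of the
#' symmetric difference of the two sets.
#'
#' @param r1,r2 character vectors of relation elements (sets: no duplicates)
#' @return non-negative integer
#' @export
uncommon_count <- function(r1, r2) {
  length(r1) + length(r2) - 2L * length(intersect(r1, r2))
}

#' Dissimilarity between two proteins
#'
#' For proteins i and j in a network with proteins P_1..P_n,
#' \deqn{Dis(P_i, P_j) = \sum_{k=1}^{n} (|U_{ijk}| - w |C_{ijk}|)}
#' where C_ijk = R_ik ∩ R_jk is the set of relations i and j hold in common
#' with respect to the third protein k, and U_ijk is the symmetric difference
#' (their uncommon relations).  The sum runs over all n proteins including
#' k = i and k = j; the self sets R_ii and R_jj are empty, so these two terms
#' each contribute |R_ij| to the uncommon part.
#'
#' The weight `w` (non-negative integer, default 1) controls the importance
#' of common relations: with w = 0 the measure is the pure uncommon-relation
#' count; with large w proteins sharing many relations score very negative
#' (i.e. very similar).  The value can be negative whenever the shared
#' relations outweigh the uncommon ones.
#'
#' @param network a `pathway_network`
#' @param i,j protein names
#' @param w non-negative integer weight on common relations
#' @return integer, symmetric in (i, j)
#' @export
dissimilarity <- function(network, i, j, w = 1L) {
  if (!(i %in% network$proteins)) stop("unknown protein: ", i)
  if (!(j %in% network$proteins)) stop("unknown protein: ", j)
  stopifnot(w >= 0)
  total <- 0L
  for (k in network$proteins) {
    rik <- rel_set(network, i, k)
    rjk <- rel_set(network, j, k)
    cc <- length(intersect(rik, rjk))
    u <- length(rik) + length(rjk) - 2L * cc
    total <- total + u - w * cc
  }
  as.integer(total)
}

# All possible relation elements: 2 orientations per directed type plus
# one per undirected type (13 codes).
rel_element_universe <- function() {
  tt <- relation_types()
  c(rbind(rel_element(tt$name[tt$directed], "out"),
          rel_element(tt$name[tt$directed], "in")),
    rel_element(tt$name[!tt$directed], "none"))
}

#' Full pairwise dissimilarity matrix
#'
#' Symmetric integer matrix of `dissimilarity()` over all protein pairs.
#' The diagonal equals -w * sum_k |R_ik| (with R_iik = R_ik both common and
#' never uncommon against itself).
#'
#' Computed via the substituted form
#' `sum_k(|R_ik| + |R_jk| - (2 + w)|C_ijk|)`: with `M` the binary incidence
#' of proteins over (third protein, relation element) pairs,
#' `sum_k |C_ijk|` is the inner product of rows i and j of `M`, so the whole
#' matrix is one sparse cross-product.  Results are identical to the scalar
#' definition.
#'
#' @param network a `pathway_network`
#' @param w non-negative integer weight
#' @return integer matrix with protein names as dimnames
#' @export
dissimilarity_matrix <- function(network, w = 1L) {
  prot <- network$proteins
  n <- length(prot)
  m <- matrix(0L, n, n, dimnames = list(prot, prot))
  if (n == 0) return(m)
  universe <- rel_element_universe()
  ne <- length(universe)
  code <- stats::setNames(seq_len(ne), universe)
  idx <- stats::setNames(seq_len(n), prot)
  keys <- names(network$relations)
  if (length(keys) > 0) {
    counts <- lengths(network$relations)
    pq <- matrix(unlist(strsplit(keys, "\t", fixed = TRUE)),
                 ncol = 2, byrow = TRUE)
    rows <- rep(idx[pq[, 1]], counts)
    kcol <- rep(idx[pq[, 2]], counts)
    els <- unlist(network$relations, use.names = FALSE)
    M <- Matrix::sparseMatrix(i = rows,
                              j = (kcol - 1L) * ne + code[els],
                              x = 1, dims = c(n, n * ne))
  } else {
    M <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n * ne))
  }
  tot <- Matrix::rowSums(M)
  overlap <- as.matrix(Matrix::tcrossprod(M))
  m <- outer(tot, tot, "+") - (2 + w) * overlap
  storage.mode(m) <- "integer"
  dimnames(m) <- list(prot, prot)
  m
}

#' Export a dissimilarity matrix as TSV
#'
#' Header row and first column carry protein names; cells are integers.
#'
#' @param m matrix from [dissimilarity_matrix()]
#' @param path output path
#' @export
write_dissimilarity_tsv <- function(m, path) {
  utils::write.table(m, file = path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(NULL)
}
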