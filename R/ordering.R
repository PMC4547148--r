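#' Order proteins lexicographically by name
#'
#' Case-insensitive primary key with a case-sensitive tiebreak, so protein
#' families with shared name stems land together regardless of capitalisation.
#'
#' @param network a `pathway_network`
#' @return a `protein_ordering` (list with `sequence`, `method`)
#' @export
order_by_name <- function(network) {
  p <- network$proteins
  o <- order(tolower(p), p, method = "radix")
  structure(list(sequence = p[o], method = "name", w = NA_integer_,
                 start = NA_character_),
            class = "protein_ordering")
}

#' Greedy similarity ordering (nearest-neighbour seriation)
#'
#' Builds a chain: the first position holds `start` (`"auto"` picks the
#' lexicographically first protein; a `seed` instead picks a uniformly random
#' start); every subsequent position holds the not-yet-placed protein with
#' the minimum dissimilarity to the most recently placed protein, ties broken
#' lexicographically.  Deterministic given (network, w, start/seed).
#'
#' @param network a `pathway_network`
#' @param w non-negative integer weight passed to [dissimilarity_matrix()]
#' @param start a protein name, or `"auto"` for the lexicographically first
#' @param seed optional integer; when supplied, the start protein is drawn
#'   at random under this seed (overrides `start`)
#' @return a `protein_ordering`
#' @export
order_by_similarity <- function(network, w = 1L, start = "auto",
                                seed = NULL) {
  prot <- network$proteins
  n <- length(prot)
  if (n == 0) {
    return(structure(list(sequence = character(0), method = "similarity",
                          w = as.integer(w), start = start),
                     class = "protein_ordering"))
  }
  if (!is.null(seed)) {
    start <- local({
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
      prot[sample.int(n, 1)]
    })
  } else if (identical(start, "auto")) {
    start <- prot[1]
  } else if (!(start %in% prot)) {
    stop("unknown start protein: ", start)
  }
  d <- dissimilarity_matrix(network, w)
  placed <- character(n)
  placed[1] <- start
  remaining <- setdiff(prot, start)
  for (pos in seq_len(n - 1)) {
    last <- placed[pos]
    dv <- d[last, remaining]
    # ties broken lexicographically: remaining is kept sorted
    nxt <- remaining[which.min(dv)]
    placed[pos + 1] <- nxt
    remaining <- setdiff(remaining, nxt)
  }
  structure(list(sequence = placed, method = "similarity",
                 w = as.integer(w), start = start),
            class = "protein_ordering")
}

#' @export
print.protein_ordering <- function(x, ...) {
  cat(sprintf("<protein_ordering: %d proteins, method=%s>\n",
              length(x$sequence), x$method))
  invisible(x)
}

#' Write an ordering as a one-column text file
#'
#' @param ordering a `protein_ordering`
#' @param path output path
#' @export
write_ordering <- function(ordering, path) {
  writeLines(ordering$sequence, path)
  invisible(NULL)
}
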