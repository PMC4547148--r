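#' Relation-type frequencies and co-occurrence over protein pairs
#'
#' Counts, for each relation type, the number of unordered protein pairs
#' whose relation set contains that type (a type present in both directions
#' still counts once), and for each unordered pair of types the number of
#' protein pairs carrying both.  These drive the area-proportional Venn
#' summary: circle area ~ frequency, pairwise overlap area ~ co-occurrence.
#'
#' @param network a `pathway_network`
#' @return a `relation_summary`: list with `counts` (named integer vector
#'   over all 8 types) and `cooccurrence` (symmetric 8x8 integer matrix)
#' @export
summarize_relations <- function(network) {
  types <- rel_type_names()
  counts <- stats::setNames(integer(length(types)), types)
  cooc <- matrix(0L, length(types), length(types),
                 dimnames = list(types, types))
  seen <- character(0)
  for (k in names(network$relations)) {
    pq <- strsplit(k, "\t", fixed = TRUE)[[1]]
    if (pq[1] >= pq[2]) next # visit each unordered pair once
    present <- unique(rel_element_type(network$relations[[k]]))
    counts[present] <- counts[present] + 1L
    if (length(present) > 1) {
      for (a in seq_along(present)) {
        for (b in seq_along(present)) {
          if (a < b) {
            cooc[present[a], present[b]] <-
              cooc[present[a], present[b]] + 1L
            cooc[present[b], present[a]] <-
              cooc[present[b], present[a]] + 1L
          }
        }
      }
    }
  }
  structure(list(counts = counts, cooccurrence = cooc),
            class = "relation_summary")
}

#' Intersection area of two circles
#'
#' Closed-form lens area for circles of radius `r1`, `r2` with centers `d`
#' apart: 0 when disjoint or tangent, the smaller circle's full area when
#' contained, the standard two-segment lens formula otherwise.  Vectorised
#' over its arguments.
#'
#' @param r1,r2 radii (> 0)
#' @param d center distance (>= 0)
#' @return intersection area
#' @export
circle_intersection_area <- function(r1, r2, d) {
  n <- max(length(r1), length(r2), length(d))
  r1 <- rep_len(r1, n); r2 <- rep_len(r2, n); d <- rep_len(d, n)
  stopifnot(all(r1 > 0), all(r2 > 0), all(d >= 0))
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (d[i] >= r1[i] + r2[i]) {
      out[i] <- 0
    } else if (d[i] <= abs(r1[i] - r2[i])) {
      out[i] <- pi * min(r1[i], r2[i])^2
    } else {
      x1 <- (d[i]^2 + r1[i]^2 - r2[i]^2) / (2 * d[i])
      x2 <- d[i] - x1
      out[i] <- r1[i]^2 * acos(pmin(pmax(x1 / r1[i], -1), 1)) -
        x1 * sqrt(max(r1[i]^2 - x1^2, 0)) +
        r2[i]^2 * acos(pmin(pmax(x2 / r2[i], -1), 1)) -
        x2 * sqrt(max(r2[i]^2 - x2^2, 0))
    }
  }
  out
}

# d(lens area)/d(distance): minus the chord length in the partial-overlap
# regime, zero when disjoint or contained (area locally constant).
lens_area_ddist <- function(r1, r2, d) {
  if (d >= r1 + r2 || d <= abs(r1 - r2) || d == 0) return(0)
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  -2 * sqrt(max(r1^2 - x1^2, 0))
}

#' Area-proportional circle layout of relation co-occurrence
#'
#' A stress-minimising approximation to the (computationally hard) exact
#' overlap problem.  Radii are fixed analytically so that each circle's area
#' equals its pair count (area-per-count factor 1); only the centers are
#' optimised.  The stress is the sum over type pairs of the squared
#' difference between the target overlap area (co-occurrence count on the
#' same scale) and the achieved lens area.  Optimisation is gradient descent
#' with analytic chord-length gradients and backtracking line search from a
#' seeded circular initial arrangement; it terminates at `max_iter` or when
#' the stress improvement falls below `tol`.  Deterministic given `seed`.
#'
#' @param summary a `relation_summary`
#' @param seed integer seed for the initial arrangement
#' @param max_iter maximum gradient steps
#' @param tol convergence threshold on stress improvement
#' @return a `venn_layout`: list with `circles` (data.frame `type`, `x`,
#'   `y`, `r`, `color`), `stress` (final residual) and `trace` (stress per
#'   accepted iteration)
#' @export
layout_venn <- function(summary, seed = 1L, max_iter = 1000L, tol = 1e-9) {
  counts <- summary$counts[summary$counts > 0]
  if (length(counts) == 0) stop("all relation counts are zero; nothing to lay out")
  types <- names(counts)
  k <- length(types)
  r <- sqrt(counts / pi)
  targets <- summary$cooccurrence[types, types, drop = FALSE]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ang <- 2 * pi * (seq_len(k) - 1) / k + stats::runif(k, -0.1, 0.1)
  rad0 <- mean(r)
  cx <- rad0 * cos(ang)
  cy <- rad0 * sin(ang)
  stress_of <- function(cx, cy) {
    s <- 0
    if (k < 2) return(0)
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      d <- sqrt((cx[a] - cx[b])^2 + (cy[a] - cy[b])^2)
      s <- s + (targets[a, b] - circle_intersection_area(r[a], r[b], d))^2
    }
    s
  }
  grad_of <- function(cx, cy) {
    gx <- numeric(k); gy <- numeric(k)
    if (k < 2) return(list(gx = gx, gy = gy))
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      dx <- cx[a] - cx[b]; dy <- cy[a] - cy[b]
      d <- sqrt(dx^2 + dy^2)
      if (d < 1e-12) { dx <- 1e-6; dy <- 0; d <- 1e-6 }
      A <- circle_intersection_area(r[a], r[b], d)
      dA <- lens_area_ddist(r[a], r[b], d)
      coef <- 2 * (A - targets[a, b]) * dA / d
      gx[a] <- gx[a] + coef * dx; gy[a] <- gy[a] + coef * dy
      gx[b] <- gx[b] - coef * dx; gy[b] <- gy[b] - coef * dy
    }
    list(gx = gx, gy = gy)
  }
  s <- stress_of(cx, cy)
  trace <- s
  step0 <- max(r)
  for (it in seq_len(max_iter)) {
    g <- grad_of(cx, cy)
    gn <- sqrt(sum(g$gx^2 + g$gy^2))
    if (gn < 1e-14) break
    step <- step0 / gn
    improved <- FALSE
    for (bt in 1:30) {
      nx <- cx - step * g$gx
      ny <- cy - step * g$gy
      ns <- stress_of(nx, ny)
      if (ns < s) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) break
    gain <- s - ns
    cx <- nx; cy <- ny; s <- ns
    trace <- c(trace, s)
    if (gain < tol) break
  }
  colors <- rel_type_color()[types]
  structure(list(
    circles = data.frame(type = types, x = cx, y = cy, r = unname(r),
                         color = unname(colors), stringsAsFactors = FALSE),
    stress = s, trace = trace
  ), class = "venn_layout")
}

#' Export a Venn layout as JSON
#'
#' One object per circle: type, x, y, r, color.
#'
#' @param layout a `venn_layout`
#' @param path output path
#' @export
write_venn_json <- function(layout, path) {
  jsonlite::write_json(layout$circles, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
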