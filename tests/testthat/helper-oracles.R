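# Independent oracles and small random-input builders used across the suite.
# These deliberately avoid the code paths they check: the dissimilarity
# oracle materialises U as an explicit union of set differences, the chain
# oracle re-scans all unplaced proteins at every step, and counting oracles
# are plain double/triple loops.

# Random edge-list network built directly with base R (independent of the
# fixtures module).
random_net <- function(n, seed, density = 0.25) {
  set.seed(seed)
  prot <- sprintf("X%02d", seq_len(n))
  types <- relation_types()
  src <- character(0); typ <- character(0); tgt <- character(0)
  if (n >= 2) {
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      for (ti in seq_len(nrow(types))) {
        if (runif(1) < density / nrow(types) * 8) {
          if (types$directed[ti] && runif(1) < 0.5) {
            src <- c(src, prot[b]); tgt <- c(tgt, prot[a])
          } else {
            src <- c(src, prot[a]); tgt <- c(tgt, prot[b])
          }
          typ <- c(typ, types$name[ti])
        }
      }
    }
  }
  net <- pathway_network(data.frame(source = src, type = typ, target = tgt,
                                    stringsAsFactors = FALSE))
  net$proteins <- sort(unique(c(net$proteins, prot)), method = "radix")
  net
}

# Verbatim dissimilarity: U built element-by-element as
# (R_ik - R_jk) union (R_jk - R_ik), C as the intersection.
oracle_dis <- function(net, i, j, w) {
  total <- 0
  for (k in net$proteins) {
    rik <- rel_set(net, i, k)
    rjk <- rel_set(net, j, k)
    u <- union(setdiff(rik, rjk), setdiff(rjk, rik))
    cc <- intersect(rik, rjk)
    total <- total + length(u) - w * length(cc)
  }
  total
}

# Nearest-neighbour chain recomputing the argmin by scanning all unplaced
# proteins at each step; lexicographic tie-break.
oracle_chain <- function(net, w, start) {
  prot <- net$proteins
  placed <- start
  while (length(placed) < length(prot)) {
    last <- placed[length(placed)]
    rest <- sort(setdiff(prot, placed), method = "radix")
    best <- NULL; bestd <- Inf
    for (p in rest) {
      d <- oracle_dis(net, last, p, w)
      if (d < bestd) { bestd <- d; best <- p }
    }
    placed <- c(placed, best)
  }
  placed
}

# Monte-Carlo estimate of two-circle intersection area.
mc_lens_area <- function(r1, r2, d, n = 1e6, seed = 42) {
  set.seed(seed)
  # sample within the smaller circle, count points inside the other
  if (r2 < r1) { tmp <- r1; r1 <- r2; r2 <- tmp }
  theta <- runif(n, 0, 2 * pi)
  rad <- r1 * sqrt(runif(n))
  x <- rad * cos(theta); y <- rad * sin(theta)
  inside <- (x - d)^2 + y^2 <= r2^2
  pi * r1^2 * mean(inside)
}

# Exhaustive per-pair relation-type counting.
oracle_summary <- function(net) {
  types <- relation_types()$name
  counts <- setNames(integer(length(types)), types)
  cooc <- matrix(0L, length(types), length(types),
                 dimnames = list(types, types))
  prot <- net$proteins
  n <- length(prot)
  if (n >= 2) {
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      r <- rel_set(net, prot[a], prot[b])
      present <- unique(sub("\\|[a-z]+$", "", r))
      counts[present] <- counts[present] + 1L
      for (s in present) for (t in present) {
        if (s < t) {
          cooc[s, t] <- cooc[s, t] + 1L
          cooc[t, s] <- cooc[t, s] + 1L
        }
      }
    }
  }
  list(counts = counts, cooccurrence = cooc)
}

# Hand fixture from the grouping examples: 5 proteins sharing one planted
# profile (identical relations to HUB1/HUB2) plus 3 distinct proteins.
planted_group_net <- function() {
  edges <- rbind(
    cbind(sprintf("GRP%d", 1:5), "neighbor-of", "HUB1"),
    cbind(sprintf("GRP%d", 1:5), "controls-phosphorylation-of", "HUB2"),
    c("HUB1", "in-complex-with", "HUB2"),
    c("ODD1", "controls-expression-of", "HUB1"))
  pathway_network(data.frame(source = edges[, 1], type = edges[, 2],
                             target = edges[, 3], stringsAsFactors = FALSE))
}

sif_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".sif",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
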