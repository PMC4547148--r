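test_that("relation summaries count unordered pairs once per type", {
  s0 <- summarize_relations(pathway_network())
  expect_true(all(s0$counts == 0))

  net <- read_sif(sif_file(c("A\tneighbor-of\tB",
                             "A\tin-complex-with\tB")))
  s <- summarize_relations(net)
  expect_equal(unname(s$counts["neighbor-of"]), 1L)
  expect_equal(unname(s$counts["in-complex-with"]), 1L)
  expect_equal(s$cooccurrence["neighbor-of", "in-complex-with"], 1L)
  expect_equal(sum(s$counts), 2L)
})

test_that("summaries match the exhaustive double-loop oracle", {
  for (seed in c(4, 9, 23)) {
    net <- random_net(12, seed = seed, density = 0.4)
    s <- summarize_relations(net)
    o <- oracle_summary(net)
    expect_equal(s$counts, o$counts)
    expect_equal(s$cooccurrence, o$cooccurrence)
    expect_equal(s$cooccurrence, t(s$cooccurrence))
    # co-occurrence can never exceed either marginal count
    for (a in rownames(s$cooccurrence)) for (b in colnames(s$cooccurrence)) {
      expect_lte(s$cooccurrence[a, b], min(s$counts[a], s$counts[b]))
    }
  }
})

test_that("circle intersection area covers the degenerate regimes", {
  expect_equal(circle_intersection_area(2, 2, 0), pi * 4)
  expect_equal(circle_intersection_area(1, 2, 3), 0)   # tangent
  expect_equal(circle_intersection_area(1, 2, 5), 0)   # disjoint
  expect_equal(circle_intersection_area(1, 3, 1.5), pi) # contained
})

test_that("circle intersection area agrees with Monte-Carlo", {
  set.seed(31)
  for (i in 1:12) {
    r1 <- runif(1, 0.5, 3); r2 <- runif(1, 0.5, 3)
    d <- runif(1, 0, r1 + r2 + 0.5)
    exact <- circle_intersection_area(r1, r2, d)
    mc <- mc_lens_area(r1, r2, d, n = 1e6, seed = 1000 + i)
    if (exact > 1e-3) {
      expect_lt(abs(mc - exact) / exact, 0.01)
    } else {
      expect_lt(mc, pi * min(r1, r2)^2 * 0.01)
    }
  }
})

test_that("radii are analytic: circle areas exactly proportional to counts", {
  net <- random_net(14, seed = 8, density = 0.5)
  s <- summarize_relations(net)
  lay <- layout_venn(s, seed = 1)
  counts <- s$counts[lay$circles$type]
  areas <- pi * lay$circles$r^2
  expect_equal(unname(areas), unname(as.numeric(counts)))
})

test_that("a single relation type yields one circle with zero stress", {
  net <- read_sif(sif_file("A\tneighbor-of\tB"))
  lay <- layout_venn(summarize_relations(net), seed = 1)
  expect_equal(nrow(lay$circles), 1)
  expect_equal(lay$stress, 0)
  expect_error(layout_venn(summarize_relations(pathway_network())),
               "all relation counts are zero")
})

test_that("attainable two-circle targets converge: disjoint and containment", {
  # disjoint: two types never co-occurring
  net_d <- read_sif(sif_file(c("A\tneighbor-of\tB",
                               "C\tin-complex-with\tD",
                               "E\tneighbor-of\tF",
                               "G\tin-complex-with\tH")))
  s <- summarize_relations(net_d)
  lay <- layout_venn(s, seed = 2)
  r <- setNames(lay$circles$r, lay$circles$type)
  d <- sqrt(diff(lay$circles$x)^2 + diff(lay$circles$y)^2)
  achieved <- circle_intersection_area(r[1], r[2], d)
  expect_lte(achieved, 0.01 * pi * min(r)^2)

  # containment: every pair carrying the rarer type also carries the other
  lines <- c(paste0("N", 1:3, "\tneighbor-of\tM", 1:3),
             paste0("N", 1:8, "\tin-complex-with\tM", 1:8))
  net_c <- read_sif(sif_file(lines))
  s2 <- summarize_relations(net_c)
  expect_equal(unname(s2$counts["neighbor-of"]), 3L)
  expect_equal(unname(s2$counts["in-complex-with"]), 8L)
  expect_equal(s2$cooccurrence["neighbor-of", "in-complex-with"], 3L)
  lay2 <- layout_venn(s2, seed = 3)
  rs <- setNames(lay2$circles$r, lay2$circles$type)
  d2 <- sqrt(diff(lay2$circles$x)^2 + diff(lay2$circles$y)^2)
  achieved2 <- circle_intersection_area(rs[1], rs[2], d2)
  target <- pi * min(rs)^2
  expect_lt(abs(achieved2 - target) / target, 0.05)
})

test_that("half-overlap targets converge within 5% relative area error", {
  # two types each on 6 pairs, co-occurring on 3
  lines <- c(paste0("A", 1:3, "\tneighbor-of\tB", 1:3),
             paste0("A", 1:3, "\tinteracts-with\tB", 1:3),
             paste0("C", 1:3, "\tneighbor-of\tD", 1:3),
             paste0("E", 1:3, "\tinteracts-with\tF", 1:3))
  s <- summarize_relations(read_sif(sif_file(lines)))
  lay <- layout_venn(s, seed = 5)
  rs <- lay$circles$r
  d <- sqrt(diff(lay$circles$x)^2 + diff(lay$circles$y)^2)
  achieved <- circle_intersection_area(rs[1], rs[2], d)
  expect_lt(abs(achieved - 3) / 3, 0.05)
})

test_that("stress is non-increasing along the recorded trace", {
  net <- random_net(14, seed = 17, density = 0.6)
  lay <- layout_venn(summarize_relations(net), seed = 4)
  expect_gte(lay$stress, 0)
  expect_true(all(diff(lay$trace) <= 0))
  # deterministic given the seed
  lay2 <- layout_venn(summarize_relations(net), seed = 4)
  expect_identical(lay$circles, lay2$circles)
})

test_that("layouts export circle geometry as JSON", {
  net <- read_sif(sif_file(c("A\tneighbor-of\tB", "B\tinteracts-with\tC")))
  lay <- layout_venn(summarize_relations(net), seed = 1)
  p <- withr::local_tempfile(fileext = ".json")
  write_venn_json(lay, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_setequal(names(back), c("type", "x", "y", "r", "color"))
  expect_equal(nrow(back), 2)
})
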