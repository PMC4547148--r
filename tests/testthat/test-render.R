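test_that("the bifocal lens conserves extent on the worked 10-cell example", {
  edges <- seq(0, 100, by = 10)
  out <- apply_lens(edges, 4:5, 3)
  w <- diff(out)
  expect_equal(w[4:5], c(30, 30))
  expect_equal(w[-(4:5)], rep(5, 8)) # (100 - 2*30) / 8
  expect_equal(out[11], 100)
  expect_equal(apply_lens(edges, 4:5, 1), edges) # magnification 1 = identity
})

test_that("lens conservation and monotonicity hold on random configurations", {
  set.seed(55)
  for (i in 1:300) {
    n <- sample(3:40, 1)
    edges <- c(0, cumsum(runif(n, 0.5, 3)))
    a <- sample(n, 1); b <- min(n, a + sample(0:4, 1))
    mag <- runif(1, 1.05, 4)
    out <- suppressWarnings(apply_lens(edges, a:b, mag))
    expect_lt(abs(out[n + 1] - edges[n + 1]), 1e-9)
    expect_equal(out[1], 0)
    expect_true(all(diff(out) > 0))
  }
})

test_that("over-magnification clamps outside cells with a warning", {
  edges <- seq(0, 10, by = 1)
  expect_warning(out <- apply_lens(edges, 5:6, 100),
                 "clamped")
  expect_equal(out[11], 10)
  expect_true(all(diff(out) > 0))
})

test_that("scenes place directed sectors by row-source and mirror undirected", {
  net <- read_sif(sif_file("RAF1\tcontrols-phosphorylation-of\tMEK1"))
  ord <- order_by_name(net)
  sc <- build_scene(net, ord)
  g <- sc$glyphs
  expect_equal(nrow(g), 1)
  # RAF1 is row 2, MEK1 column 1 under name order
  expect_equal(g$row, 2)
  expect_equal(g$col, 1)
  expect_equal(g$type, "controls-phosphorylation-of")

  net2 <- read_sif(sif_file("A\tneighbor-of\tB"))
  sc2 <- build_scene(net2, order_by_name(net2))
  g2 <- sc2$glyphs
  expect_equal(nrow(g2), 2)
  expect_setequal(paste(g2$row, g2$col), c("1 2", "2 1"))

  bad <- order_by_name(net)
  expect_error(build_scene(net2, bad), "does not cover")
})

test_that("per-cell sector sets equal the relation sets under the convention", {
  net <- random_net(9, seed = 41, density = 0.5)
  ord <- order_by_similarity(net, w = 1L)
  sc <- build_scene(net, ord)
  idx <- setNames(seq_along(ord$sequence), ord$sequence)
  slots <- setNames(relation_types()$slot, relation_types()$name)
  for (k in names(net$relations)) {
    pq <- strsplit(k, "\t", fixed = TRUE)[[1]]
    els <- net$relations[[k]]
    visible <- els[!grepl("\\|in$", els)]
    cell <- sc$glyphs[sc$glyphs$row == idx[pq[1]] &
                        sc$glyphs$col == idx[pq[2]], ]
    expect_setequal(cell$slot,
                    unname(slots[sub("\\|[a-z]+$", "", visible)]))
  }
  # slot/color constancy: one (slot, color) per type across all cells
  tab <- unique(sc$glyphs[, c("type", "slot", "color")])
  expect_equal(nrow(tab), length(unique(tab$type)))
})

test_that("matrix SVG is well-formed with one sector path per glyph", {
  net <- random_net(8, seed = 12, density = 0.4)
  ord <- order_by_similarity(net, w = 1L)
  sc <- build_scene(net, ord, lens = lens_config(2:3, 2:3, 2))
  svg <- render_svg(sc)
  doc <- xml2::read_xml(svg)
  sectors <- xml2::xml_find_all(doc, "//*[@class='sector']")
  expect_length(sectors, nrow(sc$glyphs))
  fills <- unique(xml2::xml_attr(sectors, "fill"))
  expect_true(all(fills %in% relation_types()$color))

  # empty scene still yields a parsable frame
  empty <- build_scene(pathway_network(),
                       order_by_name(pathway_network()))
  expect_no_error(xml2::read_xml(render_svg(empty)))

  # overlay rectangles appear beneath glyphs when a grid is supplied
  ov <- matrix(0L, 8, 8); ov[1:2, 1:2] <- 1L
  sc_ov <- build_scene(net, ord, overlay = ov)
  doc2 <- xml2::read_xml(render_svg(sc_ov))
  rects <- xml2::xml_find_all(doc2, "//*[@class='overlay']")
  expect_length(rects, 4)
})

test_that("a 1-cell scene renders exactly one sector in the type color", {
  net <- read_sif(sif_file("RAF1\tcontrols-phosphorylation-of\tMEK1"))
  sc <- build_scene(net, order_by_name(net))
  doc <- xml2::read_xml(render_svg(sc))
  sectors <- xml2::xml_find_all(doc, "//*[@class='sector']")
  expect_length(sectors, 1)
  col <- relation_types()
  expect_equal(xml2::xml_attr(sectors, "fill"),
               col$color[col$name == "controls-phosphorylation-of"])
})

test_that("Venn SVG carries one circle per type in the taxonomy colors", {
  lines <- c("A\tneighbor-of\tB", "A\tin-complex-with\tB",
             "C\tcontrols-state-change-of\tD",
             "C\tcontrols-transport-of\tE")
  lay <- layout_venn(summarize_relations(read_sif(sif_file(lines))),
                     seed = 1)
  doc <- xml2::read_xml(render_venn(lay))
  circles <- xml2::xml_find_all(doc, "//*[@class='venn']")
  expect_length(circles, 4)
  fills <- xml2::xml_attr(circles, "fill")
  expect_setequal(fills, c("#377EB8", "#00CED1", "#E41A1C", "#FFD92F"))
  # rendered radii preserve area ~ count proportionality (all counts 1)
  rr <- as.numeric(xml2::xml_attr(circles, "r"))
  expect_equal(max(rr) / min(rr), 1)
})

test_that("arc SVG draws one path per arc with level-decayed opacity", {
  h <- complex_hierarchy(read_complexes(sif_file(
    c("C1\tC2", "C1\tp1", "C2\tC3", "C2\tp2", "C3\tp3", "C3\tp4"))))
  lst <- ordered_listing(h)
  arcs <- descendant_arcs(h, "C1", lst)
  doc <- xml2::read_xml(render_arcs(lst, arcs))
  paths <- xml2::xml_find_all(doc, "//*[@class='arc']")
  expect_length(paths, nrow(arcs))
  ops <- sort(as.numeric(xml2::xml_attr(paths, "stroke-opacity")),
              decreasing = TRUE)
  expect_equal(ops, c(1.0, 0.6))
  # no arcs -> labels only, still valid XML
  doc0 <- xml2::read_xml(render_arcs(lst, arcs[0, ]))
  expect_length(xml2::xml_find_all(doc0, "//*[@class='arc']"), 0)
  expect_length(xml2::xml_find_all(doc0, "//*[@class='listing']"),
                length(lst))
})
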