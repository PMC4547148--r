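# SVG output. Scenes are resolved to plain geometry first (cell edges after
# lensing, one glyph record per visible sector), then serialised; the text
# documents are well-formed SVG 1.1 and are parsed back in the test suite.

svg_header <- function(width, height) {
  sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
    'width="%g" height="%g" viewBox="0 0 %g %g">\n'),
    width, height, width, height)
}

num <- function(x) formatC(x, format = "fg", digits = 10)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Bifocal lens transform of cell edges
#'
#' Magnifies the cells in `focus` (an inclusive index range) by
#' `magnification` and compresses all remaining cells by a single common
#' factor so that the total extent is exactly conserved.  Output edges are
#' strictly increasing.  If the requested magnification would drive the
#' outside cells to non-positive width, outside cells are clamped to a
#' minimum width (0.1% of the extent) with a warning and the focus absorbs
#' the remainder.
#'
#' @param edges strictly increasing numeric vector of n+1 cell edges
#' @param focus integer vector; `range(focus)` is the focused cell range
#' @param magnification factor > 0 applied to focused cell widths
#' @return transformed edge vector, same endpoints
#' @export
apply_lens <- function(edges, focus, magnification) {
  n <- length(edges) - 1L
  stopifnot(n >= 1, all(diff(edges) > 0), length(focus) >= 1)
  f1 <- max(1L, min(focus)); f2 <- min(n, max(focus))
  if (magnification == 1) return(edges)
  w <- diff(edges)
  total <- sum(w)
  infocus <- seq_len(n) >= f1 & seq_len(n) <= f2
  wf <- sum(w[infocus]); wo <- sum(w[!infocus])
  new_w <- w
  if (wo == 0) return(edges) # everything focused: conservation forces identity
  scale_out <- (total - magnification * wf) / wo
  min_w <- total * 1e-3
  if (any(w[!infocus] * scale_out <= min_w)) {
    warning("magnification too large; outside cells clamped to minimum width")
    new_w[!infocus] <- min_w
    new_w[infocus] <- w[infocus] * (total - sum(new_w[!infocus])) / wf
  } else {
    new_w[infocus] <- w[infocus] * magnification
    new_w[!infocus] <- w[!infocus] * scale_out
  }
  c(edges[1], edges[1] + cumsum(new_w))
}

#' Lens configuration
#'
#' @param focus_rows,focus_cols integer index ranges (inclusive) to magnify
#' @param magnification factor > 1
#' @param enabled logical
#' @return a `lens_config` list
#' @export
lens_config <- function(focus_rows, focus_cols = focus_rows,
                        magnification = 3, enabled = TRUE) {
  stopifnot(is.finite(magnification), magnification > 0)
  structure(list(focus_rows = focus_rows, focus_cols = focus_cols,
                 magnification = magnification, enabled = enabled),
            class = "lens_config")
}

#' Resolve a matrix scene from a network and an ordering
#'
#' Cell (row i, col j) shows a 45-degree circular sector for relation type t
#' when t is directed and protein i -> j holds (row = source, column =
#' target), or t is undirected and the pair carries it (mirrored into both
#' cells).  Each type's sector sits at its fixed angular slot in every cell,
#' so type identity is readable from angle as well as color.  An optional
#' bifocal lens distorts the cell edges; an optional overlay grid (e.g. from
#' [membership_overlay()]) darkens cells; optional group sizes darken labels.
#'
#' @param network a `pathway_network` (possibly a collapsed group network)
#' @param ordering a `protein_ordering` covering exactly the network's nodes
#' @param lens optional `lens_config`
#' @param overlay optional integer matrix in matrix order
#' @param label_sizes optional named integer vector (node -> group size)
#' @param cell_px nominal cell size in user units
#' @return a `matrix_scene`
#' @export
build_scene <- function(network, ordering, lens = NULL, overlay = NULL,
                        label_sizes = NULL, cell_px = 24) {
  seqn <- ordering$sequence
  if (!setequal(seqn, network$proteins) ||
      length(seqn) != length(network$proteins)) {
    stop("ordering does not cover the network's nodes")
  }
  n <- length(seqn)
  edges <- seq(0, n * cell_px, by = cell_px)
  ex <- ey <- edges
  if (!is.null(lens) && isTRUE(lens$enabled)) {
    ey <- apply_lens(edges, lens$focus_rows, lens$magnification)
    ex <- apply_lens(edges, lens$focus_cols, lens$magnification)
  }
  if (!is.null(overlay)) {
    stopifnot(nrow(overlay) == n, ncol(overlay) == n)
  }
  slots <- rel_type_slot()
  colors <- rel_type_color()
  gr <- integer(0); gc <- integer(0); gslot <- integer(0)
  gcol <- character(0); gtype <- character(0)
  idx <- stats::setNames(seq_len(n), seqn)
  for (k in names(network$relations)) {
    pq <- strsplit(k, "\t", fixed = TRUE)[[1]]
    i <- idx[[pq[1]]]; j <- idx[[pq[2]]]
    for (el in network$relations[[k]]) {
      o <- rel_element_orientation(el)
      if (o == "in") next # visible from the mirror cell's "out"
      t <- rel_element_type(el)
      gr <- c(gr, i); gc <- c(gc, j)
      gslot <- c(gslot, slots[[t]]); gcol <- c(gcol, colors[[t]])
      gtype <- c(gtype, t)
    }
  }
  structure(list(
    ordering = ordering,
    cell_edges_x = ex, cell_edges_y = ey,
    glyphs = data.frame(row = gr, col = gc, slot = gslot, color = gcol,
                        type = gtype, stringsAsFactors = FALSE),
    overlay = overlay,
    labels = seqn,
    label_sizes = label_sizes
  ), class = "matrix_scene")
}

# Pie-sector path: 45-degree wedge at the type's slot, centred in the cell.
sector_path <- function(cx, cy, radius, slot) {
  a0 <- slot * pi / 4 - pi / 2 # slot 0 points up, clockwise like a clock
  a1 <- a0 + pi / 4
  x0 <- cx + radius * cos(a0); y0 <- cy + radius * sin(a0)
  x1 <- cx + radius * cos(a1); y1 <- cy + radius * sin(a1)
  sprintf("M %s %s L %s %s A %s %s 0 0 1 %s %s Z",
          num(cx), num(cy), num(x0), num(y0),
          num(radius), num(radius), num(x1), num(y1))
}

#' Serialise a matrix scene to SVG
#'
#' Overlay cells are drawn first as translucent dark rectangles, then one
#' `<path class="sector">` per glyph, then the grid frame and labels (label
#' darkness maps group size when sizes are present).
#'
#' @param scene a `matrix_scene`
#' @return SVG document as a single string
#' @export
render_svg <- function(scene) {
  ex <- scene$cell_edges_x; ey <- scene$cell_edges_y
  n <- length(ey) - 1L
  margin <- 90
  width <- ex[length(ex)] + margin
  height <- ey[length(ey)] + margin
  parts <- svg_header(width, height)
  parts <- c(parts, sprintf('<g transform="translate(%g,%g)">\n',
                            margin, margin))
  if (!is.null(scene$overlay)) {
    mx <- max(scene$overlay)
    if (mx > 0) {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        v <- scene$overlay[i, j]
        if (v > 0) {
          parts <- c(parts, sprintf(
            '<rect class="overlay" x="%s" y="%s" width="%s" height="%s" fill="#1A1A2E" fill-opacity="%s"/>\n',
            num(ex[j]), num(ey[i]), num(ex[j + 1] - ex[j]),
            num(ey[i + 1] - ey[i]), num(0.15 + 0.55 * v / mx)))
        }
      }
    }
  }
  g <- scene$glyphs
  if (nrow(g) > 0) {
    for (a in seq_len(nrow(g))) {
      i <- g$row[a]; j <- g$col[a]
      cx <- (ex[j] + ex[j + 1]) / 2
      cy <- (ey[i] + ey[i + 1]) / 2
      radius <- 0.45 * min(ex[j + 1] - ex[j], ey[i + 1] - ey[i])
      parts <- c(parts, sprintf(
        '<path class="sector" d="%s" fill="%s"/>\n',
        sector_path(cx, cy, radius, g$slot[a]), g$color[a]))
    }
  }
  # frame
  parts <- c(parts, sprintf(
    '<rect class="frame" x="0" y="0" width="%s" height="%s" fill="none" stroke="#888" stroke-width="0.5"/>\n',
    num(ex[length(ex)]), num(ey[length(ey)])))
  sizes <- scene$label_sizes
  maxs <- if (!is.null(sizes)) max(sizes) else 1L
  fs <- if (n > 0) max(4, min(10, (ey[length(ey)] / max(n, 1)) * 0.5)) else 10
  for (i in seq_len(n)) {
    lab <- xml_escape(scene$labels[i])
    dark <- if (!is.null(sizes)) {
      s <- sizes[[scene$labels[i]]]
      grDevices::gray(0.65 - 0.65 * s / max(maxs, 1))
    } else "#333333"
    cy <- (ey[i] + ey[i + 1]) / 2
    cx <- (ex[i] + ex[i + 1]) / 2
    parts <- c(parts, sprintf(
      '<text class="rowlabel" x="-4" y="%s" font-size="%g" text-anchor="end" dominant-baseline="middle" fill="%s">%s</text>\n',
      num(cy), fs, dark, lab))
    parts <- c(parts, sprintf(
      '<text class="collabel" x="%s" y="-4" font-size="%g" text-anchor="start" fill="%s" transform="rotate(-60 %s -4)">%s</text>\n',
      num(cx), fs, dark, num(cx), lab))
  }
  parts <- c(parts, "</g>\n</svg>\n")
  paste(parts, collapse = "")
}

#' Serialise a Venn layout to SVG
#'
#' One translucent circle per relation type in its taxonomy color, plus a
#' legend of type names; the color coding matches the matrix sectors.
#'
#' @param layout a `venn_layout`
#' @return SVG document as a single string
#' @export
render_venn <- function(layout) {
  circ <- layout$circles
  pad <- max(circ$r) * 0.2 + 10
  x0 <- min(circ$x - circ$r) - pad
  y0 <- min(circ$y - circ$r) - pad
  x1 <- max(circ$x + circ$r) + pad
  legend_h <- 16 * nrow(circ) + 10
  y1 <- max(circ$y + circ$r) + pad + legend_h
  w <- x1 - x0; h <- y1 - y0
  parts <- svg_header(w, h)
  parts <- c(parts, sprintf('<g transform="translate(%g,%g)">\n', -x0, -y0))
  for (i in seq_len(nrow(circ))) {
    parts <- c(parts, sprintf(
      '<circle class="venn" cx="%s" cy="%s" r="%s" fill="%s" fill-opacity="0.45" stroke="%s"/>\n',
      num(circ$x[i]), num(circ$y[i]), num(circ$r[i]),
      circ$color[i], circ$color[i]))
  }
  ly <- max(circ$y + circ$r) + pad / 2
  for (i in seq_len(nrow(circ))) {
    parts <- c(parts, sprintf(
      '<rect class="legend-swatch" x="%s" y="%s" width="10" height="10" fill="%s"/>\n',
      num(min(circ$x - circ$r)), num(ly + 16 * (i - 1)), circ$color[i]))
    parts <- c(parts, sprintf(
      '<text class="legend" x="%s" y="%s" font-size="10">%s</text>\n',
      num(min(circ$x - circ$r) + 14), num(ly + 16 * (i - 1) + 9),
      xml_escape(circ$type[i])))
  }
  parts <- c(parts, "</g>\n</svg>\n")
  paste(parts, collapse = "")
}

#' Serialise a complex listing and its arcs to SVG
#'
#' A vertical size-ordered list of complex labels with semicircular arcs to
#' its right; stroke width is proportional to the sub-complex protein count
#' and stroke opacity carries the level-decay saturation.
#'
#' @param listing character vector of complex ids in display order
#' @param arcs data.frame from [descendant_arcs()]
#' @param row_h vertical spacing per list entry
#' @return SVG document as a single string
#' @export
render_arcs <- function(listing, arcs, row_h = 18) {
  n <- length(listing)
  label_w <- 8 * (max(c(nchar(listing), 0)) + 1) + 10
  max_span <- if (nrow(arcs) > 0) {
    max(abs(arcs$to_index - arcs$from_index)) * row_h / 2
  } else 0
  w <- label_w + max_span + 30
  h <- max(n * row_h + 20, 40)
  parts <- svg_header(w, h)
  ypos <- function(i) 10 + (i - 0.5) * row_h
  for (i in seq_len(n)) {
    parts <- c(parts, sprintf(
      '<text class="listing" x="%s" y="%s" font-size="11" text-anchor="end" dominant-baseline="middle">%s</text>\n',
      num(label_w - 6), num(ypos(i)), xml_escape(listing[i])))
  }
  if (nrow(arcs) > 0) {
    maxth <- max(arcs$thickness)
    for (a in seq_len(nrow(arcs))) {
      y1 <- ypos(arcs$from_index[a]); y2 <- ypos(arcs$to_index[a])
      r <- abs(y2 - y1) / 2
      sw <- 1 + 4 * arcs$thickness[a] / max(maxth, 1)
      sweep <- if (y2 > y1) 1 else 0
      parts <- c(parts, sprintf(
        '<path class="arc" d="M %s %s A %s %s 0 0 %d %s %s" fill="none" stroke="#2C5F8A" stroke-width="%s" stroke-opacity="%s"/>\n',
        num(label_w), num(y1), num(r), num(r), sweep, num(label_w), num(y2),
        num(sw), num(arcs$saturation[a])))
    }
  }
  parts <- c(parts, "</svg>\n")
  paste(parts, collapse = "")
}
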