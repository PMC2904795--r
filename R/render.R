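#' Rendering style for symbol-notation output
#'
#' @param set symbol set: `"cfg"` (CFG colour, the default), `"cfg-bw"`
#'   (same shapes, black outlines with solid/empty/hatched fills),
#'   `"uoxf"` (Oxford-style black-and-white shape vocabulary; only the
#'   symbol set is supported, not the full Oxford linkage-angle system) or
#'   `"text"` (text tokens instead of shapes).
#' @param magnification positive scalar; all coordinates, spacings and the
#'   linkage pen width scale linearly with it.
#' @param x_spacing fixed horizontal distance between residue columns, in
#'   px at magnification 1.
#' @param y_spacing vertical distance between sibling rows, in px at
#'   magnification 1.
#' @param symbol_size symbol bounding-box side, in px at magnification 1.
#' @param show_key draw a key listing each monosaccharide used, to the
#'   right of the structure.
#' @param margin canvas margin in px at magnification 1.
#' @param font_size base font size in px at magnification 1.
#' @return An object of class `symbol_style`.
#' @export
symbol_style <- function(set = c("cfg", "cfg-bw", "uoxf", "text"),
                         magnification = 1, x_spacing = 40, y_spacing = 44,
                         symbol_size = 20, show_key = FALSE, margin = 30,
                         font_size = 12) {
  if (is.character(set) && length(set) >= 1L && !set[1L] %in% c("cfg", "cfg-bw", "uoxf", "text"))
    glycan_error(sprintf("unsupported symbol set %s", dQuote(set[1L], '"')),
                 "glycan_config_error")
  set <- match.arg(set)
  stopifnot(is.numeric(magnification), magnification > 0)
  structure(list(set = set, magnification = magnification,
                 x_spacing = x_spacing, y_spacing = y_spacing,
                 symbol_size = symbol_size, show_key = show_key,
                 margin = margin, font_size = font_size),
            class = "symbol_style")
}

# shape and fill per monosaccharide, per symbol set.  CFG colours follow
# the published CFG/SNFG palette.
symbol_palette <- function(set) {
  switch(set,
    "cfg" = list(
      GlcNAc = list(shape = "square",   fill = "#0072BC"),
      Man    = list(shape = "circle",   fill = "#00A651"),
      Gal    = list(shape = "circle",   fill = "#FFD400"),
      NeuAc  = list(shape = "diamond",  fill = "#A54399"),
      Fuc    = list(shape = "triangle", fill = "#ED1C24")),
    "cfg-bw" = list(
      GlcNAc = list(shape = "square",   fill = "#000000"),
      Man    = list(shape = "circle",   fill = "#FFFFFF"),
      Gal    = list(shape = "circle",   fill = "url(#hatch)"),
      NeuAc  = list(shape = "diamond",  fill = "#808080"),
      Fuc    = list(shape = "triangle", fill = "#FFFFFF")),
    "uoxf" = list(
      GlcNAc = list(shape = "square",   fill = "#000000"),
      Man    = list(shape = "circle",   fill = "#BFBFBF"),
      Gal    = list(shape = "circle",   fill = "#FFFFFF"),
      NeuAc  = list(shape = "diamond",  fill = "#000000"),
      Fuc    = list(shape = "triangle", fill = "#FFFFFF")),
    glycan_error(sprintf("unsupported symbol set %s", dQuote(set, '"')),
                 "glycan_config_error"))
}

#' Lay out a glycan tree right-to-left
#'
#' Residues are placed on a fixed horizontal grid of columns indexed by
#' depth, with the asparagine rightmost.  Vertical positions come from
#' post-order subtree centering with the alpha1-6 arm above the alpha1-3
#' arm; the core fucose is dropped below the reducing GlcNAc and the
#' bisecting GlcNAc sits on the beta-mannose column axis, above it.
#'
#' @param tree a [build_tree()] result.
#' @param style a [symbol_style()].
#' @return A list with `nodes` (data frame: `id`, `mono`, `depth`,
#'   `col`, `x`, `y`), `edges` (data frame: `child`, `parent`, `x1`, `y1`,
#'   `x2`, `y2`), and scalars `width`, `height` (px at the style's
#'   magnification).
#' @export
layout_tree <- function(tree, style = symbol_style()) {
  stopifnot(inherits(tree, "glycan_tree"), inherits(style, "symbol_style"))
  n <- length(tree$mono)
  kids <- tree_children(tree)
  # special nodes: core fucose (Fuc on reducing GlcNAc), bisecting GlcNAc
  # (GlcNAc child of the beta-mannose, node 4 by construction)
  fuc_i <- which(tree$mono == "Fuc" & tree$parent == 2L)
  bis_i <- which(tree$mono == "GlcNAc" & tree$parent == 4L)
  special <- c(fuc_i, bis_i)
  lower_man <- 5L  # alpha1-3 core mannose, node 5 by construction

  rowy <- rep(NA_real_, n)
  next_row <- 0
  assign_rows <- function(i) {
    ks <- setdiff(kids[[i]], special)
    if (length(ks) == 0L) {
      rowy[i] <<- next_row
      next_row <<- next_row + 1
      return(invisible())
    }
    p <- suppressWarnings(as.integer(tree$pos[ks])); p[is.na(p)] <- 0L
    ord <- if (i == lower_man) order(p, tree$anomer[ks])
           else order(-p, tree$anomer[ks])
    for (k in ks[ord]) assign_rows(k)
    rowy[i] <<- mean(rowy[ks])
    invisible()
  }
  assign_rows(1L)
  if (length(fuc_i)) rowy[fuc_i] <- rowy[2L] + 1
  if (length(bis_i)) rowy[bis_i] <- rowy[4L] - 1

  col <- tree$depth
  if (length(fuc_i)) col[fuc_i] <- tree$depth[2L]  # same column as reducing GlcNAc
  if (length(bis_i)) col[bis_i] <- tree$depth[4L]  # beta-mannose column axis

  mag <- style$magnification
  xsp <- style$x_spacing * mag
  ysp <- style$y_spacing * mag
  margin <- style$margin * mag
  maxcol <- max(col)
  ymin <- min(rowy)
  x <- margin + (maxcol - col) * xsp
  y <- margin + (rowy - ymin) * ysp
  width <- 2 * margin + maxcol * xsp
  if (isTRUE(style$show_key) && style$set != "text")
    width <- width + 110 * mag
  height <- 2 * margin + (max(rowy) - ymin) * ysp
  nodes <- data.frame(id = seq_len(n), mono = tree$mono, depth = tree$depth,
                      col = col, x = x, y = y, stringsAsFactors = FALSE)
  e <- seq_len(n)[-1L]
  edges <- data.frame(child = e, parent = tree$parent[e],
                      x1 = x[e], y1 = y[e],
                      x2 = x[tree$parent[e]], y2 = y[tree$parent[e]])
  list(nodes = nodes, edges = edges, width = width, height = height)
}

# residue label for text-only rendering
residue_label <- function(tree, i) {
  if (tree$mono[i] == "Asn") return("Asn")
  anom <- c(a = "α", b = "β")[[tree$anomer[i]]]
  acarbon <- if (tree$mono[i] == "NeuAc") "2" else "1"
  p <- tree$pos[i]
  paste0(tree$mono[i], anom, acarbon, "-", if (p == "N") "" else p)
}

#' Render a glycan tree as an SVG document
#'
#' One shape element per sugar residue (or one text token per residue in
#' text mode), one text element for the asparagine, one line per glycosidic
#' linkage, and an optional key.  The linkage pen width grows linearly with
#' magnification, with a floor of 1 px.
#'
#' @param tree a [build_tree()] result.
#' @param style a [symbol_style()].
#' @return An object of class `glycan_svg`: element data frames `shapes`,
#'   `lines`, `texts`, canvas `width`/`height`, and the SVG 1.1 source in
#'   `$svg` (also returned by `as.character()`).
#' @examples
#' doc <- render_svg(build_tree(parse_code("300000000")))
#' nrow(doc$shapes)  # 5 sugar residues
#' @export
render_svg <- function(tree, style = symbol_style()) {
  stopifnot(inherits(tree, "glycan_tree"), inherits(style, "symbol_style"))
  lay <- layout_tree(tree, style)
  mag <- style$magnification
  lwd <- max(1, 1.5 * mag)
  fs <- style$font_size * mag
  sym <- style$symbol_size * mag

  lines <- data.frame(x1 = lay$edges$x1, y1 = lay$edges$y1,
                      x2 = lay$edges$x2, y2 = lay$edges$y2, lwd = lwd)
  shapes <- data.frame(x = numeric(0), y = numeric(0), shape = character(0),
                       fill = character(0), stroke = character(0),
                       size = numeric(0), mono = character(0),
                       stringsAsFactors = FALSE)
  texts <- data.frame(x = numeric(0), y = numeric(0), label = character(0),
                      size = numeric(0), anchor = character(0),
                      stringsAsFactors = FALSE)
  sugars <- which(tree$mono != "Asn")
  if (style$set == "text") {
    texts <- data.frame(
      x = lay$nodes$x, y = lay$nodes$y,
      label = vapply(seq_along(tree$mono), function(i) residue_label(tree, i),
                     character(1L)),
      size = fs, anchor = "middle", stringsAsFactors = FALSE)
  } else {
    pal <- symbol_palette(style$set)
    shapes <- data.frame(
      x = lay$nodes$x[sugars], y = lay$nodes$y[sugars],
      shape = vapply(tree$mono[sugars], function(m) pal[[m]]$shape, character(1L)),
      fill = vapply(tree$mono[sugars], function(m) pal[[m]]$fill, character(1L)),
      stroke = "#000000", size = sym, mono = tree$mono[sugars],
      stringsAsFactors = FALSE)
    texts <- data.frame(x = lay$nodes$x[1L], y = lay$nodes$y[1L] + 0.35 * fs,
                        label = "Asn", size = fs, anchor = "middle",
                        stringsAsFactors = FALSE)
    if (isTRUE(style$show_key)) {
      used <- intersect(c("Man", "GlcNAc", "Gal", "NeuAc", "Fuc"),
                        unique(tree$mono[sugars]))
      kx <- lay$width - 95 * mag
      for (k in seq_along(used)) {
        ky <- style$margin * mag + (k - 1) * 1.4 * sym
        m <- used[k]
        shapes <- rbind(shapes, data.frame(
          x = kx, y = ky, shape = pal[[m]]$shape, fill = pal[[m]]$fill,
          stroke = "#000000", size = 0.7 * sym, mono = m,
          stringsAsFactors = FALSE))
        texts <- rbind(texts, data.frame(
          x = kx + 0.9 * sym, y = ky + 0.3 * fs, label = m,
          size = 0.85 * fs, anchor = "start", stringsAsFactors = FALSE))
      }
    }
  }
  svg <- svg_document(shapes, lines, texts, lay$width, lay$height)
  structure(list(shapes = shapes, lines = lines, texts = texts,
                 width = lay$width, height = lay$height, style = style,
                 svg = svg),
            class = "glycan_svg")
}

#' @export
as.character.glycan_svg <- function(x, ...) x$svg

#' @export
print.glycan_svg <- function(x, ...) {
  cat(sprintf("<glycan_svg> %g x %g px, %d shapes, %d lines, %d text elements\n",
              x$width, x$height, nrow(x$shapes), nrow(x$lines), nrow(x$texts)))
  invisible(x)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

fmt_num <- function(x) formatC(x, format = "fg", digits = 7, width = 1)

# assemble an SVG 1.1 document from element data frames
svg_document <- function(shapes, lines, texts, width, height) {
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt_num(width), fmt_num(height), fmt_num(width), fmt_num(height)),
    '<defs><pattern id="hatch" patternUnits="userSpaceOnUse" width="6" height="6"><path d="M0,6 L6,0" stroke="#000000" stroke-width="1"/></pattern></defs>')
  if (nrow(lines))
    out <- c(out, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="%s"/>',
                          fmt_num(lines$x1), fmt_num(lines$y1),
                          fmt_num(lines$x2), fmt_num(lines$y2), fmt_num(lines$lwd)))
  if (nrow(shapes)) {
    r <- shapes$size / 2
    el <- character(nrow(shapes))
    for (i in seq_len(nrow(shapes))) {
      x <- shapes$x[i]; y <- shapes$y[i]; ri <- r[i]
      el[i] <- switch(shapes$shape[i],
        circle = sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="%s" stroke-width="1"/>',
                         fmt_num(x), fmt_num(y), fmt_num(ri), shapes$fill[i], shapes$stroke[i]),
        square = sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s" stroke-width="1"/>',
                         fmt_num(x - ri), fmt_num(y - ri), fmt_num(2 * ri), fmt_num(2 * ri),
                         shapes$fill[i], shapes$stroke[i]),
        diamond = sprintf('<polygon points="%s,%s %s,%s %s,%s %s,%s" fill="%s" stroke="%s" stroke-width="1"/>',
                          fmt_num(x), fmt_num(y - ri), fmt_num(x + ri), fmt_num(y),
                          fmt_num(x), fmt_num(y + ri), fmt_num(x - ri), fmt_num(y),
                          shapes$fill[i], shapes$stroke[i]),
        triangle = sprintf('<polygon points="%s,%s %s,%s %s,%s" fill="%s" stroke="%s" stroke-width="1"/>',
                           fmt_num(x), fmt_num(y - ri), fmt_num(x + ri), fmt_num(y + ri),
                           fmt_num(x - ri), fmt_num(y + ri),
                           shapes$fill[i], shapes$stroke[i]),
        glycan_error(sprintf("unknown shape %s", shapes$shape[i]), "glycan_config_error"))
    }
    out <- c(out, el)
  }
  if (nrow(texts))
    out <- c(out, sprintf('<text x="%s" y="%s" font-size="%s" text-anchor="%s" font-family="Helvetica, Arial, sans-serif">%s</text>',
                          fmt_num(texts$x), fmt_num(texts$y), fmt_num(texts$size),
                          texts$anchor, xml_escape(texts$label)))
  paste(c(out, "</svg>"), collapse = "\n")
}

#' Write an SVG document to a file
#'
#' @param x a `glycan_svg` (or grid) object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(x, path) {
  stopifnot(inherits(x, "glycan_svg"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(x$svg, con, useBytes = FALSE)
  invisible(path)
}

#' Export a rendered document as a raster image
#'
#' Draws the same element model onto a PNG, JPEG or BMP device.  Pixel
#' dimensions are the canvas size times `scale`.
#'
#' @param x a `glycan_svg` (or grid) object.
#' @param path output file path.
#' @param format `"png"`, `"jpeg"` or `"bmp"`; defaults to the file
#'   extension.
#' @param scale positive scalar multiplying the pixel dimensions.
#' @return `path`, invisibly; attributes `width`/`height` give the pixel
#'   dimensions written.
#' @export
export_raster <- function(x, path, format = NULL, scale = 1) {
  stopifnot(inherits(x, "glycan_svg"), is.numeric(scale), scale > 0)
  if (is.null(format)) {
    format <- tolower(sub(".*\\.", "", path))
    if (format == "jpg") format <- "jpeg"
  }
  w <- round(x$width * scale); h <- round(x$height * scale)
  dev <- switch(format,
    png = function() grDevices::png(path, width = w, height = h),
    jpeg = function() grDevices::jpeg(path, width = w, height = h, quality = 95),
    bmp = function() grDevices::bmp(path, width = w, height = h),
    glycan_error(sprintf("unsupported raster format %s", dQuote(format, '"')),
                 "glycan_config_error"))
  dev()
  on.exit(grDevices::dev.off())
  graphics::par(mar = rep(0, 4))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, x$width), ylim = c(x$height, 0),
                        xaxs = "i", yaxs = "i")
  graphics::rect(0, x$height, x$width, 0, col = "white", border = NA)
  if (nrow(x$lines))
    graphics::segments(x$lines$x1, x$lines$y1, x$lines$x2, x$lines$y2,
                       lwd = x$lines$lwd * scale)
  if (nrow(x$shapes)) {
    fill <- ifelse(grepl("^url", x$shapes$fill), "grey70", x$shapes$fill)
    for (i in seq_len(nrow(x$shapes))) {
      cx <- x$shapes$x[i]; cy <- x$shapes$y[i]; r <- x$shapes$size[i] / 2
      switch(x$shapes$shape[i],
        circle = graphics::symbols(cx, cy, circles = r, inches = FALSE,
                                   add = TRUE, bg = fill[i], fg = "black"),
        square = graphics::rect(cx - r, cy + r, cx + r, cy - r,
                                col = fill[i], border = "black"),
        diamond = graphics::polygon(c(cx, cx + r, cx, cx - r),
                                    c(cy - r, cy, cy + r, cy),
                                    col = fill[i], border = "black"),
        triangle = graphics::polygon(c(cx, cx + r, cx - r),
                                     c(cy - r, cy + r, cy + r),
                                     col = fill[i], border = "black"))
    }
  }
  if (nrow(x$texts))
    graphics::text(x$texts$x, x$texts$y, labels = x$texts$label,
                   cex = x$texts$size / 12,
                   adj = ifelse(x$texts$anchor == "start", 0, 0.5))
  invisible(structure(path, width = w, height = h))
}
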