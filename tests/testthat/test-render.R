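test_that("the core lays out in five residue columns with Asn rightmost", {
  lay <- layout_tree(build_tree(parse_code("300000000")))
  expect_identical(nrow(lay$nodes), 6L)          # Asn + 5 sugars
  expect_identical(max(lay$nodes$col), 4L)       # 5 columns, 0-indexed
  expect_identical(lay$nodes$x[1L], max(lay$nodes$x))  # Asn rightmost
  # x strictly decreases with column depth
  expect_true(all(diff(tapply(lay$nodes$x, lay$nodes$col, unique)) < 0))
})

test_that("the deepest antenna drives the canvas width", {
  lay <- layout_tree(build_tree(parse_code("310333553")))
  expect_identical(max(lay$nodes$col), 8L)
})

test_that("the alpha1-6 arm is drawn above the alpha1-3 arm", {
  tree <- build_tree(parse_code("300000000"))
  lay <- layout_tree(tree)
  upper <- which(tree$anomer == "a" & tree$pos == "6")
  lower <- which(tree$anomer == "a" & tree$pos == "3")
  expect_lt(lay$nodes$y[upper], lay$nodes$y[lower])  # smaller y = higher
})

test_that("fucose sits below the reducing GlcNAc and the bisect on the beta-mannose axis", {
  tree <- build_tree(parse_code("311000000"))
  lay <- layout_tree(tree)
  fuc <- which(tree$mono == "Fuc")
  expect_identical(lay$nodes$x[fuc], lay$nodes$x[2L])
  expect_gt(lay$nodes$y[fuc], lay$nodes$y[2L])
  bis <- which(tree$mono == "GlcNAc" & tree$parent == 4L)
  expect_identical(lay$nodes$x[bis], lay$nodes$x[4L])
  expect_lt(lay$nodes$y[bis], lay$nodes$y[4L])
})

test_that("no two symbol bounding boxes overlap across random codes", {
  style <- symbol_style()
  for (id in sample_codes(40L, seed = 51L)) {
    tree <- suppressWarnings(build_tree(suppressWarnings(parse_code(id))))
    lay <- layout_tree(tree, style)
    expect_identical(
      overlap_count(lay$nodes$x, lay$nodes$y, style$symbol_size), 0L)
  }
})

test_that("SVG output contains one shape per sugar and the CFG palette", {
  doc <- render_svg(build_tree(parse_code("300000000")))
  expect_identical(nrow(doc$shapes), 5L)
  expect_identical(sum(doc$shapes$shape == "circle"), 3L)  # 3 Man
  expect_identical(sum(doc$shapes$shape == "square"), 2L)  # 2 GlcNAc
  expect_identical(nrow(doc$lines), 5L)  # one line per linkage incl. the Asn link
  expect_identical(doc$texts$label, "Asn")
  expect_true(all(doc$shapes$fill[doc$shapes$mono == "Man"] == "#00A651"))

  doc2 <- render_svg(build_tree(parse_code("310033333")))
  expect_identical(nrow(doc2$shapes), 15L)
  expect_identical(sum(doc2$shapes$shape == "diamond"), 3L)  # NeuAc count
  expect_identical(sum(doc2$shapes$shape == "triangle"), 1L) # core fucose
})

test_that("SVG source is well-formed XML", {
  skip_if_not_installed("xml2")
  doc <- render_svg(build_tree(parse_code("310333553")),
                    symbol_style(show_key = TRUE))
  x <- xml2::read_xml(doc$svg)
  expect_identical(xml2::xml_name(x), "svg")
})

test_that("shape count equals the residue census on random codes", {
  for (id in sample_codes(60L, seed = 52L)) {
    tree <- suppressWarnings(build_tree(suppressWarnings(parse_code(id))))
    doc <- render_svg(tree)
    expect_identical(nrow(doc$shapes), sum(census(tree)))
  }
})

test_that("text-only mode emits text tokens and no shapes", {
  tree <- build_tree(parse_code("300000000"))
  doc <- render_svg(tree, symbol_style(set = "text"))
  expect_identical(nrow(doc$shapes), 0L)
  expect_identical(nrow(doc$texts), length(tree$mono))
})

test_that("magnification rescales the whole document linearly", {
  tree <- build_tree(parse_code("310033333"))
  d1 <- render_svg(tree, symbol_style(magnification = 1))
  d2 <- render_svg(tree, symbol_style(magnification = 2))
  expect_equal(d2$width, 2 * d1$width)
  expect_equal(d2$height, 2 * d1$height)
  expect_equal(d2$shapes$x, 2 * d1$shapes$x)
  expect_equal(d2$shapes$y, 2 * d1$shapes$y)
  expect_equal(d2$lines$lwd, rep(3, nrow(d2$lines)))  # pen width scales, floor 1
  expect_equal(unique(render_svg(tree, symbol_style(magnification = 0.25))$lines$lwd), 1)
})

test_that("the alternative symbol sets keep their own shape/fill vocabulary", {
  tree <- build_tree(parse_code("310033333"))
  bw <- render_svg(tree, symbol_style(set = "cfg-bw"))
  expect_true(all(bw$shapes$fill %in%
                  c("#000000", "#FFFFFF", "url(#hatch)", "#808080")))
  ox <- render_svg(tree, symbol_style(set = "uoxf"))
  expect_true(all(ox$shapes$fill %in% c("#000000", "#FFFFFF", "#BFBFBF")))
  expect_setequal(unique(ox$shapes$shape[ox$shapes$mono == "GlcNAc"]), "square")
  expect_error(symbol_style(set = "snfg"), class = "glycan_config_error")
})

test_that("the key lists each monosaccharide used once", {
  tree <- build_tree(parse_code("310033333"))  # 5 distinct monosaccharides
  plain <- render_svg(tree, symbol_style())
  keyed <- render_svg(tree, symbol_style(show_key = TRUE))
  expect_identical(nrow(keyed$shapes) - nrow(plain$shapes), 5L)
  expect_identical(nrow(keyed$texts) - nrow(plain$texts), 5L)
  expect_gt(keyed$width, plain$width)
})

test_that("raster export writes decodable files at the canvas dimensions", {
  skip_if_not_installed("png")
  tree <- build_tree(parse_code("300000000"))
  doc <- render_svg(tree)
  tmp <- withr::local_tempdir()
  p <- export_raster(doc, file.path(tmp, "core.png"))
  img <- png::readPNG(file.path(tmp, "core.png"))
  expect_identical(dim(img)[2L], as.integer(round(doc$width)))
  expect_identical(dim(img)[1L], as.integer(round(doc$height)))

  # doubling magnification doubles the pixel dimensions
  doc2 <- render_svg(tree, symbol_style(magnification = 2))
  export_raster(doc2, file.path(tmp, "core2.png"))
  img2 <- png::readPNG(file.path(tmp, "core2.png"))
  expect_identical(dim(img2)[1:2], 2L * dim(img)[1:2])

  # scale behaves the same way
  export_raster(doc, file.path(tmp, "core_s2.png"), scale = 2)
  imgs <- png::readPNG(file.path(tmp, "core_s2.png"))
  expect_identical(dim(imgs)[1:2], 2L * dim(img)[1:2])

  # BMP and JPEG share the canvas dimensions
  export_raster(doc, file.path(tmp, "core.bmp"))
  expect_identical(bmp_dims(file.path(tmp, "core.bmp")),
                   as.integer(round(c(doc$width, doc$height))))
  export_raster(doc, file.path(tmp, "core.jpg"))
  expect_gt(file.size(file.path(tmp, "core.jpg")), 0)
  expect_error(export_raster(doc, file.path(tmp, "core.gif")),
               class = "glycan_config_error")
})
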