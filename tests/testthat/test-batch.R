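test_that("code files read with blanks preserved and comments skipped", {
  f <- withr::local_tempfile(lines = c("300000000", "", "# a comment",
                                       "310333553"))
  got <- read_code_file(f)
  expect_identical(got, c("300000000", NA, "310333553"))

  empty <- withr::local_tempfile(lines = character(0))
  expect_identical(read_code_file(empty), character(0))

  bad <- withr::local_tempfile(lines = c("300000000", "oops", "310333553"))
  expect_warning(got2 <- read_code_file(bad), class = "glycan_skipped_warning")
  expect_identical(got2, c("300000000", NA, "310333553"))
  expect_error(read_code_file(bad, strict = TRUE), "line 2",
               class = "glycan_validation_error")
  expect_error(read_code_file(file.path(tempdir(), "no-such-file.txt")),
               class = "glycan_io_error")

  # identifiers are normalized on read (digits 8-9 recomputed)
  fixme <- withr::local_tempfile(lines = "310333599")
  expect_identical(read_code_file(fixme), "310333553")
})

test_that("grids fill column-major in the default 22 x 13 geometry", {
  codes <- random_codes(fixture_spec(seed = 3L, n = 45L))
  g <- build_grid(codes)
  expect_identical(c(g$rows, g$cols), c(22L, 13L))
  occupancy <- colSums(!is.na(g$cells))
  expect_equal(occupancy[1:3], c(22, 22, 1), ignore_attr = TRUE)
  expect_true(all(occupancy[-(1:3)] == 0L))
  expect_identical(g$cells[1:22, 1L], codes[1:22])   # top-to-bottom
  expect_identical(g$cells[1:22, 2L], codes[23:44])
  expect_identical(g$cells[1L, 3L], codes[45L])
})

test_that("blank entries occupy their cells and overflow is policed", {
  entries <- c("300000000", NA, "310333553")
  g <- build_grid(entries, rows = 2L, cols = 2L)
  expect_identical(g$cells[2L, 1L], NA_character_)
  expect_identical(g$cells[1L, 2L], "310333553")

  too_many <- rep("300000000", 287L)
  expect_error(build_grid(too_many), class = "glycan_overflow_error")
  pages <- build_grid(too_many, paging = TRUE)
  expect_length(pages, 2L)
  expect_identical(sum(!is.na(pages[[1L]]$cells)), 286L)
  expect_identical(sum(!is.na(pages[[2L]]$cells)), 1L)
})

test_that("grid rendering draws every occupied cell, captions optional", {
  codes <- random_codes(fixture_spec(seed = 9L, n = 8L))
  entries <- c(codes[1:4], NA, codes[5:8])
  style <- symbol_style(magnification = 0.6)
  g <- build_grid(entries, rows = 3L, cols = 3L)
  doc <- render_grid_svg(g, style)
  expect_identical(doc$n_rendered, 8L)
  expect_identical(sum(doc$texts$label %in% codes), 8L)  # one caption per cell

  g2 <- build_grid(entries, rows = 3L, cols = 3L, show_codes = FALSE)
  doc2 <- render_grid_svg(g2, style)
  expect_identical(sum(doc2$texts$label %in% codes), 0L)
  # shape totals match the summed censuses
  total <- sum(vapply(codes, function(id) {
    sum(census(suppressWarnings(build_tree(suppressWarnings(parse_code(id))))))
  }, integer(1L)))
  expect_identical(nrow(doc$shapes), total)
  expect_error(render_grid_svg(g, symbol_style(set = "text")),
               class = "glycan_config_error")
})

test_that("aligning two code sets pads each to the sorted superset", {
  tmp <- withr::local_tempdir()
  write_code_file(c("300000000", "310033333"), file.path(tmp, "A.txt"))
  write_code_file(c("310033333", "310333553"), file.path(tmp, "B.txt"))
  res <- align_code_sets(file.path(tmp, c("A.txt", "B.txt")),
                         out_dir = file.path(tmp, "out"))
  expect_identical(res$superset, c("300000000", "310033333", "310333553"))
  expect_identical(res$aligned$A.txt, c("300000000", "310033333", NA))
  expect_identical(res$aligned$B.txt, c(NA, "310033333", "310333553"))
  # files round-trip
  expect_identical(read_code_file(file.path(tmp, "out", "A_aligned.txt")),
                   res$aligned$A.txt)
  expect_identical(read_code_file(file.path(tmp, "out", "superset.txt")),
                   res$superset)
  expect_error(align_code_sets(file.path(tmp, "A.txt")),
               class = "glycan_usage_error")
})

test_that("alignment edge cases: identical and disjoint inputs", {
  tmp <- withr::local_tempdir()
  same <- c("310333553", "300000000")
  write_code_file(same, file.path(tmp, "s1.txt"))
  write_code_file(rev(same), file.path(tmp, "s2.txt"))
  res <- align_code_sets(file.path(tmp, c("s1.txt", "s2.txt")), tmp)
  expect_identical(res$aligned$s1.txt, sort(same))
  expect_false(anyNA(res$aligned$s2.txt))

  a <- random_codes(fixture_spec(seed = 71L, n = 6L))
  b <- setdiff(random_codes(fixture_spec(seed = 72L, n = 9L)), a)
  write_code_file(a, file.path(tmp, "d1.txt"))
  write_code_file(b, file.path(tmp, "d2.txt"))
  res2 <- align_code_sets(file.path(tmp, c("d1.txt", "d2.txt")), tmp)
  expect_length(res2$superset, length(a) + length(b))
  expect_identical(sum(is.na(res2$aligned$d1.txt)), length(b))
  expect_identical(sum(is.na(res2$aligned$d2.txt)), length(a))
})

test_that("alignment postconditions hold on randomized inputs with blanks and duplicates", {
  tmp <- withr::local_tempdir()
  paths <- character(3L)
  sets <- list()
  for (i in 1:3) {
    paths[i] <- file.path(tmp, sprintf("set%d.txt", i))
    spec <- fixture_spec(seed = 100L + i, n = 20L + 5L * i, blank_rate = 0.15)
    random_code_file(spec, paths[i])
    sets[[i]] <- unique(random_codes(spec))
  }
  res <- suppressWarnings(align_code_sets(paths, file.path(tmp, "out")))
  expect_false(is.unsorted(as.numeric(res$superset)))
  for (i in 1:3) {
    al <- res$aligned[[i]]
    expect_length(al, length(res$superset))
    expect_identical(al[!is.na(al)], res$superset[!is.na(al)])
    expect_setequal(al[!is.na(al)], sets[[i]])
  }
})
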