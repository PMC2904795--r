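# Code-list files, multi-structure grids, and set alignment.

#' Read a code-list file
#'
#' One identifier per line; blank lines are significant (they become blank
#' grid cells) and are returned as `NA`.  Lines starting with `#` are
#' comments and skipped entirely.  Invalid lines are reported with their
#' line numbers and treated as blanks in lenient mode, or raise an error
#' in strict mode.
#'
#' @param path path to a UTF-8 text file.
#' @param strict logical; error on invalid lines instead of warning.
#' @return Character vector of normalized nine-digit identifiers, with
#'   `NA` for blank lines.
#' @export
read_code_file <- function(path, strict = FALSE) {
  if (!file.exists(path))
    glycan_error(sprintf("cannot read %s", dQuote(path, '"')), "glycan_io_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines)
  lines <- lines[keep]
  lineno <- seq_along(keep)[keep]
  out <- rep(NA_character_, length(lines))
  bad <- integer(0)
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    code <- tryCatch(suppressWarnings(parse_code(lines[i], strict = strict)),
                     glycanid_error = function(e) e)
    if (inherits(code, "glycanid_error")) {
      if (strict)
        glycan_error(sprintf("line %d: %s", lineno[i], conditionMessage(code)),
                     "glycan_validation_error")
      bad <- c(bad, lineno[i])
    } else {
      out[i] <- format_code(code)
    }
  }
  if (length(bad))
    warning(warningCondition(
      sprintf("treated %d invalid line(s) as blank: line(s) %s",
              length(bad), paste(utils::head(bad, 10L), collapse = ", ")),
      class = c("glycan_skipped_warning", "glycanid_warning")))
  out
}

#' Write a code-list file
#'
#' @param entries character vector of identifiers; `NA` or `""` entries
#'   are written as blank lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_code_file <- function(entries, path) {
  entries[is.na(entries)] <- ""
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(entries, con)
  invisible(path)
}

#' Arrange codes in a display grid
#'
#' Cells are filled one column at a time, top to bottom, starting at the
#' left; blank entries occupy cells, preserving their positions.  The
#' default geometry is 22 rows by 13 columns.
#'
#' @param entries character vector of identifiers (`NA` = blank cell),
#'   e.g. from [read_code_file()].
#' @param rows,cols grid geometry.
#' @param show_codes print each identifier beneath its structure when
#'   rendered.
#' @param paging if `TRUE`, entries beyond `rows * cols` spill onto
#'   additional pages and a list of grids is returned; otherwise overflow
#'   is an error.
#' @return An object of class `glycan_grid` (or a list of them when
#'   paging): `rows`, `cols`, `show_codes` and a `rows` x `cols` character
#'   matrix `cells`.
#' @export
build_grid <- function(entries, rows = 22L, cols = 13L, show_codes = TRUE,
                       paging = FALSE) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 1L, cols >= 1L)
  capacity <- rows * cols
  if (length(entries) > capacity) {
    if (!paging)
      glycan_error(sprintf("%d entries exceed the %d x %d grid capacity of %d (enable paging to split pages)",
                           length(entries), rows, cols, capacity),
                   "glycan_overflow_error")
    pages <- split(entries, (seq_along(entries) - 1L) %/% capacity)
    return(lapply(pages, build_grid, rows = rows, cols = cols,
                  show_codes = show_codes, paging = FALSE))
  }
  cells <- matrix(NA_character_, nrow = rows, ncol = cols)
  cells[seq_along(entries)] <- entries  # column-major fill
  structure(list(rows = rows, cols = cols, cells = cells,
                 show_codes = isTRUE(show_codes)),
            class = "glycan_grid")
}

#' @export
print.glycan_grid <- function(x, ...) {
  cat(sprintf("<glycan_grid> %d x %d, %d structures%s\n", x$rows, x$cols,
              sum(!is.na(x$cells)), if (x$show_codes) ", codes shown" else ""))
  invisible(x)
}

#' Render a grid of structures as one SVG document
#'
#' Every occupied cell is rendered with the given style into a uniform
#' cell box (sized to the largest structure), with the identifier printed
#' beneath when the grid's `show_codes` is set.  The canvas is trimmed to
#' the occupied rows and columns.
#'
#' @param grid a [build_grid()] result.
#' @param style a [symbol_style()]; `"text"` is not supported for grids.
#' @return An object of class `c("glycan_grid_svg", "glycan_svg")`, with
#'   the combined element data frames, `n_rendered`, and the SVG source in
#'   `$svg`.  Usable with [write_svg()] and [export_raster()].
#' @export
render_grid_svg <- function(grid, style = symbol_style()) {
  stopifnot(inherits(grid, "glycan_grid"), inherits(style, "symbol_style"))
  if (style$set == "text")
    glycan_error("text-only rendering is not supported for grids",
                 "glycan_config_error")
  mag <- style$magnification
  occupied <- which(!is.na(grid$cells), arr.ind = TRUE)
  if (nrow(occupied) == 0L)
    glycan_error("grid has no structures to render", "glycan_validation_error")
  docs <- apply(occupied, 1L, function(rc) {
    code <- suppressWarnings(parse_code(grid$cells[rc[1L], rc[2L]]))
    tree <- suppressWarnings(build_tree(code))
    render_svg(tree, style)
  })
  caption_h <- if (grid$show_codes) 20 * mag else 0
  cell_w <- max(vapply(docs, `[[`, numeric(1L), "width"))
  cell_h <- max(vapply(docs, `[[`, numeric(1L), "height")) + caption_h
  shapes <- NULL; lines <- NULL; texts <- NULL
  for (k in seq_len(nrow(occupied))) {
    r <- occupied[k, 1L]; cc <- occupied[k, 2L]
    d <- docs[[k]]
    ox <- (cc - 1L) * cell_w + (cell_w - d$width) / 2
    oy <- (r - 1L) * cell_h
    s <- d$shapes; s$x <- s$x + ox; s$y <- s$y + oy
    l <- d$lines; l$x1 <- l$x1 + ox; l$x2 <- l$x2 + ox
    l$y1 <- l$y1 + oy; l$y2 <- l$y2 + oy
    t <- d$texts; t$x <- t$x + ox; t$y <- t$y + oy
    if (grid$show_codes)
      t <- rbind(t, data.frame(
        x = (cc - 1L) * cell_w + cell_w / 2,
        y = oy + cell_h - 6 * mag,
        label = grid$cells[r, cc], size = 0.85 * style$font_size * mag,
        anchor = "middle", stringsAsFactors = FALSE))
    shapes <- rbind(shapes, s); lines <- rbind(lines, l); texts <- rbind(texts, t)
  }
  width <- max(occupied[, 2L]) * cell_w
  height <- max(occupied[, 1L]) * cell_h
  svg <- svg_document(shapes, lines, texts, width, height)
  structure(list(shapes = shapes, lines = lines, texts = texts,
                 width = width, height = height, style = style, svg = svg,
                 n_rendered = nrow(occupied),
                 rows = grid$rows, cols = grid$cols),
            class = c("glycan_grid_svg", "glycan_svg"))
}

#' Align several code files for visual comparison
#'
#' Builds the superset of all input code sets, sorts it in ascending
#' numeric order, and writes one output file per input of exactly the
#' superset's length, with blank lines where a superset code is missing
#' from that input.  Loading the aligned files as grids therefore places
#' each structure at the same cell position in every file.
#'
#' @param paths two or more code-list files.
#' @param out_dir directory for the aligned outputs (created if needed).
#' @return Invisibly, a list with `superset` (character vector), `aligned`
#'   (named list of character vectors with `NA` blanks) and `files` (paths
#'   written: one `*_aligned.txt` per input plus `superset.txt`).
#' @export
align_code_sets <- function(paths, out_dir = ".") {
  if (length(paths) < 2L)
    glycan_error("at least two code files are required", "glycan_usage_error")
  sets <- lapply(paths, function(p) {
    codes <- read_code_file(p)
    codes <- codes[!is.na(codes)]
    dup <- unique(codes[duplicated(codes)])
    if (length(dup))
      warning(warningCondition(
        sprintf("%s: duplicate code(s) collapsed: %s", basename(p),
                paste(dup, collapse = ", ")),
        class = c("glycan_duplicate_warning", "glycanid_warning")))
    unique(codes)
  })
  names(sets) <- basename(paths)
  superset <- sort(unique(unlist(sets)))  # 9-digit strings sort numerically
  aligned <- lapply(sets, function(s) ifelse(superset %in% s, superset, NA_character_))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(aligned)) {
    base <- sub("\\.[^.]*$", "", names(sets)[i])
    f <- file.path(out_dir, paste0(base, "_aligned.txt"))
    write_code_file(aligned[[i]], f)
    files <- c(files, f)
  }
  sf <- file.path(out_dir, "superset.txt")
  write_code_file(superset, sf)
  invisible(list(superset = superset, aligned = aligned,
                 files = c(files, sf)))
}
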