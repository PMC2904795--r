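#' Construct a validated nine-digit N-glycan code
#'
#' The nine-digit encoding describes a mammalian N-glycan built on the
#' trimannosyl core: digit 1 is the total number of mannoses (3-6), digit 2
#' flags a core fucose, digit 3 a bisecting GlcNAc, digits 4-7 give the
#' extension level (0-6) of each of up to four antennae, and digits 8-9 --
#' the galactose and N-acetylneuraminic acid totals -- are always derived
#' from the branch levels, never set directly.
#'
#' @param man integer, total mannose count including the core (3-6).
#' @param fucose 0 or 1, core fucose on the reducing-end GlcNAc.
#' @param bisect 0 or 1, bisecting GlcNAc on the beta-mannose.
#' @param branches integer vector of length 4, extension level 0-6 of
#'   branches 1-4 (branch 1 = beta1-2 on the alpha1-3 mannose, branch 2 =
#'   beta1-4 on the alpha1-3 mannose, branch 3 = beta1-2 on the alpha1-6
#'   mannose, branch 4 = beta1-6 on the alpha1-6 mannose).
#' @return An object of class `glycan_code`: a list with elements `man`,
#'   `fucose`, `bisect`, `branches`, and the derived `gal` and `neuac`.
#' @examples
#' glycan_code(3, 1, 0, c(3, 3, 3, 5))  # A4G4FLac1S3, code 310333553
#' @seealso [parse_code()], [format_code()], [compute_composition()]
#' @export
glycan_code <- function(man, fucose = 0L, bisect = 0L, branches = c(0L, 0L, 0L, 0L)) {
  man <- as.integer(man); fucose <- as.integer(fucose); bisect <- as.integer(bisect)
  branches <- as.integer(branches)
  if (length(branches) != 4L)
    glycan_error("`branches` must have length 4", "glycan_validation_error")
  digits <- c(man, fucose, bisect, branches)
  if (anyNA(digits))
    glycan_error("digits must be integers", "glycan_validation_error")
  check_digit_ranges(digits)
  comp <- compute_composition(branches)
  structure(
    list(man = man, fucose = fucose, bisect = bisect, branches = branches,
         gal = unname(comp["gal"]), neuac = unname(comp["neuac"])),
    class = "glycan_code")
}

# Range checks on digits 1-7; errors name the offending digit.
check_digit_ranges <- function(digits7) {
  if (digits7[1L] < 3L || digits7[1L] > 6L)
    glycan_error(sprintf("digit 1 (mannose count) is %d, allowed range 3-6", digits7[1L]),
                 "glycan_validation_error")
  for (i in 2:3) {
    if (!digits7[i] %in% c(0L, 1L))
      glycan_error(sprintf("digit %d (%s) is %d, allowed values 0-1",
                           i, c("core fucose", "bisecting GlcNAc")[i - 1L], digits7[i]),
                   "glycan_validation_error")
  }
  for (i in 4:7) {
    if (digits7[i] < 0L || digits7[i] > 6L)
      glycan_error(sprintf("digit %d (branch %d extension level) is %d, allowed range 0-6",
                           i, i - 3L, digits7[i]),
                   "glycan_validation_error")
  }
  invisible(TRUE)
}

#' Derive galactose and sialic-acid totals from branch extension levels
#'
#' Digits 8 and 9 of an identifier are sums of fixed per-level increments:
#' one Gal for levels 2-4, two for levels 5-6; one NeuAc for levels 3 and 6
#' (the sialylated levels).  They are recomputed whenever digits 4-7 change.
#'
#' @param branch_levels integer vector of extension levels, each 0-6
#'   (normally length 4).
#' @return Named integer vector `c(gal = , neuac = )`.
#' @examples
#' compute_composition(c(3, 3, 3, 5))  # gal 5, neuac 3
#' @export
compute_composition <- function(branch_levels) {
  lv <- as.integer(branch_levels)
  if (anyNA(lv) || any(lv < 0L | lv > 6L))
    glycan_error("branch extension levels must be integers in 0-6",
                 "glycan_validation_error")
  c(gal = sum(GAL_INCREMENT[lv + 1L]), neuac = sum(NEUAC_INCREMENT[lv + 1L]))
}

#' Parse a nine- or seven-digit N-glycan identifier
#'
#' Accepts 7 or 9 decimal digits, optionally separated by single spaces,
#' with any number of flanking spaces; no other characters are allowed.
#' Only the first seven digits determine the structure: digits 8-9 are
#' recomputed from the branch levels, and supplied values that disagree are
#' corrected with a warning (or rejected when `strict = TRUE`).
#'
#' @param text a single identifier string, e.g. `"310333553"` or
#'   `"3 1 0 0 3 3 3 3 3"`.
#' @param strict logical; if `TRUE`, a nine-digit input whose last two
#'   digits disagree with the recomputed composition is an error rather
#'   than a warning.
#' @return A [glycan_code()] object.
#' @examples
#' parse_code("3 1 0 0 3 3 3 3 3")
#' parse_code("310333599")  # last two digits corrected to 53 with a warning
#' @export
parse_code <- function(text, strict = FALSE) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    glycan_error("`text` must be a single character string", "glycan_parse_error")
  s <- trimws(text)
  if (!grepl("^[0-9]( ?[0-9])*$", s))
    glycan_error(sprintf("not a valid identifier: %s", dQuote(text, '"')),
                 "glycan_parse_error")
  digits <- as.integer(strsplit(gsub(" ", "", s, fixed = TRUE), "", fixed = TRUE)[[1L]])
  if (!length(digits) %in% c(7L, 9L))
    glycan_error(sprintf("identifier must have 7 or 9 digits, got %d", length(digits)),
                 "glycan_parse_error")
  check_digit_ranges(digits[1:7])
  code <- glycan_code(digits[1L], digits[2L], digits[3L], digits[4:7])
  if (length(digits) == 9L && (digits[8L] != code$gal || digits[9L] != code$neuac)) {
    msg <- sprintf("digits 8-9 of %s recomputed as %d%d (supplied %d%d)",
                   gsub(" ", "", s, fixed = TRUE), code$gal, code$neuac,
                   digits[8L], digits[9L])
    if (strict) glycan_error(msg, "glycan_validation_error")
    warning(warningCondition(msg, class = c("glycan_corrected_warning", "glycanid_warning")))
  }
  code
}

#' Format a glycan code as its identifier string
#'
#' @param code a [glycan_code()] object.
#' @param spaced logical; insert a single space between digits.
#' @return A 9-character (or 17 with spaces) identifier string.
#' @examples
#' format_code(glycan_code(3, 1, 0, c(0, 3, 3, 3)), spaced = TRUE)
#' @export
format_code <- function(code, spaced = FALSE) {
  stopifnot(inherits(code, "glycan_code"))
  d <- c(code$man, code$fucose, code$bisect, code$branches, code$gal, code$neuac)
  paste(d, collapse = if (spaced) " " else "")
}

#' @export
as.character.glycan_code <- function(x, ...) format_code(x)

#' @export
format.glycan_code <- function(x, ...) format_code(x)

#' @export
print.glycan_code <- function(x, ...) {
  cls <- classify(x)
  q <- attr(cls, "qualifier")
  cat(sprintf("<glycan_code %s> %s%s: Man%d%s%s, branches (%s), Gal %d, NeuAc %d\n",
              format_code(x), cls, if (!is.null(q)) paste0(" (", q, ")") else "",
              x$man, if (x$fucose) " +coreFuc" else "",
              if (x$bisect) " +bisect" else "",
              paste(x$branches, collapse = ","), x$gal, x$neuac))
  invisible(x)
}

#' @export
`==.glycan_code` <- function(e1, e2) {
  inherits(e1, "glycan_code") && inherits(e2, "glycan_code") &&
    format_code(e1) == format_code(e2)
}

#' Classify a code as oligomannose, hybrid or complex
#'
#' Oligomannose: more than three mannoses and no antennae.  Hybrid: extra
#' mannoses alongside at least one antenna.  Complex: the Man3 core with
#' antennae.  The bare trimannosyl core is reported as complex with a
#' `"core-only"` qualifier attribute.
#'
#' @param code a [glycan_code()] object.
#' @return One of `"oligomannose"`, `"hybrid"`, `"complex"` (character),
#'   possibly with attribute `qualifier = "core-only"`.
#' @examples
#' classify(parse_code("500000000"))  # oligomannose
#' @export
classify <- function(code) {
  stopifnot(inherits(code, "glycan_code"))
  branched <- any(code$branches > 0L)
  if (code$man > 3L) {
    if (branched) "hybrid" else "oligomannose"
  } else if (branched) {
    "complex"
  } else {
    structure("complex", qualifier = "core-only")
  }
}

#' Extract every valid identifier from free text
#'
#' Tokens are delimited by newlines, tabs, or runs of two or more spaces; a
#' single interior space acts as a digit separator, so `"3 1 0 0 3 3 3 3 3"`
#' is one token.  Tokens containing any character other than digits and
#' single spaces are skipped with a warning.
#'
#' @param text an arbitrary character string (may span multiple lines).
#' @param quiet logical; suppress the warning listing skipped tokens.
#' @return A list of [glycan_code()] objects in order of appearance
#'   (empty list if none).
#' @examples
#' extract_codes_from_text("300000000\n310333553")
#' @export
extract_codes_from_text <- function(text, quiet = FALSE) {
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  tokens <- strsplit(text, "\r\n|\r|\n|\t| {2,}")[[1L]]
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  out <- list()
  skipped <- character()
  for (tok in tokens) {
    code <- tryCatch(suppressWarnings(parse_code(tok)),
                     glycanid_error = function(e) NULL)
    if (is.null(code)) skipped <- c(skipped, tok) else out[[length(out) + 1L]] <- code
  }
  if (length(skipped) && !quiet)
    warning(warningCondition(
      sprintf("skipped %d invalid token(s): %s", length(skipped),
              paste(utils::head(skipped, 5L), collapse = ", ")),
      class = c("glycan_skipped_warning", "glycanid_warning")))
  out
}

#' Enumerate the full space of valid identifiers
#'
#' All 4 x 2 x 2 x 7^4 = 38,416 valid codes (digits 8-9 derived), as
#' identifier strings in ascending numeric order.  The table behind it is
#' cached for the session.
#'
#' @return Character vector of 38,416 nine-digit identifiers.
#' @export
code_space <- function() code_table()$id

# Full code-space table: digit matrix, derived composition, identifier
# strings and GlycoBase names, in ascending numeric order.  Cached.
code_table <- function() {
  tbl <- .glycanid_cache$code_table
  if (!is.null(tbl)) return(tbl)
  g <- expand.grid(b4 = 0:6, b3 = 0:6, b2 = 0:6, b1 = 0:6,
                   bis = 0:1, fuc = 0:1, man = 3:6, KEEP.OUT.ATTRS = FALSE)
  d <- cbind(man = g$man, fuc = g$fuc, bis = g$bis,
             b1 = g$b1, b2 = g$b2, b3 = g$b3, b4 = g$b4)
  storage.mode(d) <- "integer"
  B <- d[, 4:7, drop = FALSE]
  gal <- GAL_INCREMENT[B[, 1L] + 1L] + GAL_INCREMENT[B[, 2L] + 1L] +
    GAL_INCREMENT[B[, 3L] + 1L] + GAL_INCREMENT[B[, 4L] + 1L]
  neuac <- NEUAC_INCREMENT[B[, 1L] + 1L] + NEUAC_INCREMENT[B[, 2L] + 1L] +
    NEUAC_INCREMENT[B[, 3L] + 1L] + NEUAC_INCREMENT[B[, 4L] + 1L]
  id <- paste0(d[, 1L], d[, 2L], d[, 3L], d[, 4L], d[, 5L], d[, 6L], d[, 7L],
               gal, neuac)
  # lac branches (level >= 4) must form a suffix of the branch positions for
  # a code to be canonical under the highest-position LacNAc convention
  lacbits <- (B[, 1L] >= 4L) * 8L + (B[, 2L] >= 4L) * 4L +
    (B[, 3L] >= 4L) * 2L + (B[, 4L] >= 4L)
  canonical <- lacbits %in% c(0L, 1L, 3L, 7L, 15L)
  tbl <- list(digits = d, gal = as.integer(gal), neuac = as.integer(neuac),
              id = id, canonical = canonical,
              name = glycobase_name_vec(d, gal, neuac))
  .glycanid_cache$code_table <- tbl
  tbl
}
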