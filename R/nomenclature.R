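# GlycoBase-style abbreviations: A<antennae> G<branches carrying terminal-
# region Gal> F (core fucose) B (bisect) Lac<branches with a LacNAc repeat>
# S<sialic acids>, zero-valued tokens omitted.  Oligomannose codes are
# "M<n>"; hybrids are written "M<n>-<antenna tokens>" as an extension.

# token string for complex-style components (vectorized)
glycobase_tokens <- function(A, G, fuc, bis, Lac, S) {
  paste0("A", A,
         ifelse(G > 0L, paste0("G", G), ""),
         ifelse(fuc == 1L, "F", ""),
         ifelse(bis == 1L, "B", ""),
         ifelse(Lac > 0L, paste0("Lac", Lac), ""),
         ifelse(S > 0L, paste0("S", S), ""))
}

# vectorized naming over a digit matrix (used by the cached code table)
glycobase_name_vec <- function(d, gal, neuac) {
  B <- d[, 4:7, drop = FALSE]
  A <- rowSums(B >= 1L)
  G <- rowSums(B == 2L | B == 3L | B == 5L | B == 6L)
  Lac <- rowSums(B >= 4L)
  branched <- A > 0L
  tok <- glycobase_tokens(A, G, d[, 2L], d[, 3L], Lac, neuac)
  mn <- paste0("M", d[, 1L],
               ifelse(d[, 2L] == 1L, "-F", ""),
               ifelse(d[, 3L] == 1L, "-B", ""))
  out <- character(nrow(d))
  complex <- branched & d[, 1L] == 3L
  hybrid <- branched & d[, 1L] > 3L
  out[complex] <- tok[complex]
  out[hybrid] <- paste0("M", d[hybrid, 1L], "-", tok[hybrid])
  out[!branched] <- mn[!branched]
  out
}

#' Convert a glycan code to its GlycoBase-style abbreviation
#'
#' For complex glycans (Man3 with antennae): `A` counts branches at level
#' 1 or above, `G` counts branches whose terminal region carries a
#' galactose (levels 2, 3, 5, 6), `F` and `B` flag core fucose and
#' bisecting GlcNAc, `Lac` counts branches bearing a LacNAc repeat (level
#' 4 or above) and `S` is the sialic-acid total (digit 9).  Unbranched
#' codes give `"M<n>"` (with `-F`/`-B` suffixes when decorated); hybrid
#' codes give `"M<n>-<antenna tokens>"`, an extension beyond the complex
#' convention.
#'
#' @param code a [glycan_code()] object.
#' @return An object of class `glycobase_name`; its `format()`/`print()`
#'   give the abbreviation string, e.g. `"A4G4FLac1S3"`.
#' @examples
#' to_glycobase(parse_code("310333553"))  # A4G4FLac1S3
#' @export
to_glycobase <- function(code) {
  stopifnot(inherits(code, "glycan_code"))
  B <- code$branches
  name <- list(
    man = code$man,
    antennae = sum(B >= 1L),
    terminal_gal = sum(B %in% c(2L, 3L, 5L, 6L)),
    fucose = code$fucose,
    bisect = code$bisect,
    lac_repeats = sum(B >= 4L),
    sialic = code$neuac)
  d <- matrix(c(code$man, code$fucose, code$bisect, B), nrow = 1L)
  name$string <- glycobase_name_vec(d, code$gal, code$neuac)
  structure(name, class = "glycobase_name")
}

#' @export
format.glycobase_name <- function(x, ...) x$string

#' @export
as.character.glycobase_name <- function(x, ...) x$string

#' @export
print.glycobase_name <- function(x, ...) {
  cat(sprintf("<glycobase_name> %s (A%d G%d F%d B%d Lac%d S%d)\n", x$string,
              x$antennae, x$terminal_gal, x$fucose, x$bisect,
              x$lac_repeats, x$sialic))
  invisible(x)
}

#' Parse a GlycoBase-style abbreviation string
#'
#' Accepts complex-style token strings (`"A4G4FLac1S3"`, explicit zeros
#' such as `"A1G0S0"` allowed), oligomannose forms (`"M5"`, `"M3-F"`) and
#' the hybrid extension (`"M4-A1G1S1"`).
#'
#' @param text abbreviation string.
#' @return A `glycobase_name` object.
#' @export
parse_glycobase <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  man <- NA_integer_
  m <- regmatches(s, regexec("^M([0-9]+)", s))[[1L]]
  rest <- s
  if (length(m)) {
    man <- as.integer(m[2L])
    rest <- substring(s, nchar(m[1L]) + 1L)
    rest <- sub("^-", "", rest)
  }
  rest <- gsub("-", "", rest)  # tolerate "F-B" suffix joins
  pat <- "^(?:A([0-9]+))?(?:G([0-9]+))?(F)?(B)?(?:Lac([0-9]+))?(?:S([0-9]+))?$"
  g <- regmatches(rest, regexec(pat, rest))[[1L]]
  if (length(g) == 0L)
    glycan_error(sprintf("cannot parse abbreviation %s", dQuote(text, '"')),
                 "glycan_parse_error")
  num <- function(x) if (nzchar(x)) as.integer(x) else 0L
  name <- list(man = if (is.na(man)) NULL else man,
               antennae = num(g[2L]), terminal_gal = num(g[3L]),
               fucose = as.integer(nzchar(g[4L])),
               bisect = as.integer(nzchar(g[5L])),
               lac_repeats = num(g[6L]), sialic = num(g[7L]))
  if (is.null(name$man)) name$man <- 3L
  check_glycobase_consistency(name)
  name$string <- glycobase_string(name)
  structure(name, class = "glycobase_name")
}

# canonical abbreviation string from name components
glycobase_string <- function(name) {
  if (name$antennae == 0L) {
    paste0("M", name$man,
           if (name$fucose == 1L) "-F" else "",
           if (name$bisect == 1L) "-B" else "")
  } else {
    tok <- glycobase_tokens(name$antennae, name$terminal_gal, name$fucose,
                            name$bisect, name$lac_repeats, name$sialic)
    if (name$man == 3L) tok else paste0("M", name$man, "-", tok)
  }
}

check_glycobase_consistency <- function(name) {
  if (name$antennae > 4L)
    glycan_error("at most 4 antennae are encodable", "glycan_validation_error")
  if (name$terminal_gal > name$antennae)
    glycan_error("G cannot exceed the antenna count", "glycan_validation_error")
  if (name$lac_repeats > name$antennae)
    glycan_error("Lac cannot exceed the antenna count", "glycan_validation_error")
  if (name$sialic > name$terminal_gal)
    glycan_error("S cannot exceed the number of Gal-terminated branches",
                 "glycan_validation_error")
  if (name$man < 3L || name$man > 6L)
    glycan_error("mannose count out of range 3-6", "glycan_validation_error")
  invisible(TRUE)
}

#' Enumerate all identifiers matching a GlycoBase-style abbreviation
#'
#' Because an abbreviation does not fix which antenna carries each
#' decoration, several identifiers can share one abbreviation; sialylation
#' placement in particular is often unresolved experimentally.  This
#' enumerates every valid code whose abbreviation matches, restricted by
#' default to the canonical convention that LacNAc-repeat-bearing branches
#' occupy the highest-numbered branch positions.
#'
#' @param name abbreviation string or `glycobase_name` object.
#' @param canonical_only logical; keep only codes whose LacNAc branches
#'   sit at the highest-numbered positions (default `TRUE`).
#' @return Character vector of nine-digit identifiers in ascending numeric
#'   order (possibly empty).
#' @examples
#' enumerate_codes("A4G4FLac1S3")
#' # "310233653" "310323653" "310332653" "310333553"
#' @export
enumerate_codes <- function(name, canonical_only = TRUE) {
  if (is.character(name)) name <- parse_glycobase(name)
  stopifnot(inherits(name, "glycobase_name"))
  check_glycobase_consistency(name)
  tbl <- code_table()
  target <- name$string
  sel <- tbl$name == target
  if (canonical_only) sel <- sel & tbl$canonical
  tbl$id[sel]
}
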