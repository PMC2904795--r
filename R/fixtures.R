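# Reproducible synthetic corpora of valid codes, for testing and demos.

#' Specification for a synthetic code corpus
#'
#' @param seed integer RNG seed; the same spec always yields the same
#'   corpus.
#' @param n number of codes to generate.
#' @param class_mix named proportions for `oligomannose`, `hybrid` and
#'   `complex` codes; normalised to sum to one.  The default leans
#'   complex, reflecting mature mammalian secreted glycoproteins.
#' @param blank_rate probability of inserting a blank line before each
#'   code when writing a file with [random_code_file()].
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n = 100L,
                         class_mix = c(oligomannose = 0.2, hybrid = 0.2,
                                       complex = 0.6),
                         blank_rate = 0) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 0L)
  req <- c("oligomannose", "hybrid", "complex")
  if (is.null(names(class_mix)) || !setequal(names(class_mix), req) ||
      any(class_mix < 0) || sum(class_mix) <= 0)
    glycan_error("class_mix must be non-negative proportions named oligomannose, hybrid, complex",
                 "glycan_validation_error")
  if (blank_rate < 0 || blank_rate >= 1)
    glycan_error("blank_rate must be in [0, 1)", "glycan_validation_error")
  structure(list(seed = as.integer(seed), n = n,
                 class_mix = class_mix[req] / sum(class_mix),
                 blank_rate = blank_rate),
            class = "fixture_spec")
}

# run expr with the RNG seeded from spec, restoring global RNG state
with_spec_seed <- function(spec, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(spec$seed)
  expr
}

# assumes the RNG is already seeded; exact class counts by largest remainder
generate_codes <- function(spec) {
  n <- spec$n
  if (n == 0L) return(character(0))
  raw <- spec$class_mix * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0L) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1L
  }
  compose <- function(man, fuc, bis, B) {
    gal <- GAL_INCREMENT[B[, 1L] + 1L] + GAL_INCREMENT[B[, 2L] + 1L] +
      GAL_INCREMENT[B[, 3L] + 1L] + GAL_INCREMENT[B[, 4L] + 1L]
    neu <- NEUAC_INCREMENT[B[, 1L] + 1L] + NEUAC_INCREMENT[B[, 2L] + 1L] +
      NEUAC_INCREMENT[B[, 3L] + 1L] + NEUAC_INCREMENT[B[, 4L] + 1L]
    paste0(man, fuc, bis, B[, 1L], B[, 2L], B[, 3L], B[, 4L], gal, neu)
  }
  out <- character(0)
  if (k[["oligomannose"]] > 0L) {
    m <- k[["oligomannose"]]
    out <- c(out, paste0(sample(4:6, m, replace = TRUE), "00000000"))
  }
  if (k[["hybrid"]] > 0L) {
    m <- k[["hybrid"]]
    b1 <- sample(0:6, m, replace = TRUE)
    b2 <- sample(0:6, m, replace = TRUE)
    dead <- b1 == 0L & b2 == 0L
    b1[dead] <- sample(1:6, sum(dead), replace = TRUE)
    out <- c(out, compose(sample(4:6, m, replace = TRUE),
                          stats::rbinom(m, 1L, 0.3), stats::rbinom(m, 1L, 0.1),
                          cbind(b1, b2, 0L, 0L)))
  }
  if (k[["complex"]] > 0L) {
    m <- k[["complex"]]
    B <- matrix(sample(0:6, 4L * m, replace = TRUE), ncol = 4L)
    dead <- rowSums(B) == 0L
    B[dead, 1L] <- sample(1:6, sum(dead), replace = TRUE)
    out <- c(out, compose(3L, stats::rbinom(m, 1L, 0.5),
                          stats::rbinom(m, 1L, 0.15), B))
  }
  sample(out)  # shuffle class blocks together
}

#' Generate random valid codes
#'
#' Deterministic for a given [fixture_spec()]: class counts are allocated
#' exactly by largest remainder, branch levels are sampled uniformly
#' (hybrid antennae restricted to the alpha1-3 arm), and the result is
#' shuffled.  The caller's RNG state is preserved.
#'
#' @param spec a [fixture_spec()].
#' @return Character vector of `spec$n` nine-digit identifiers.
#' @examples
#' random_codes(fixture_spec(seed = 7, n = 5))
#' @export
random_codes <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_spec_seed(spec, generate_codes(spec))
}

#' Write a random code-list file
#'
#' Generates codes per the spec and writes them one per line, inserting a
#' blank line before each code with probability `spec$blank_rate`.
#'
#' @param spec a [fixture_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
random_code_file <- function(spec, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  lines <- with_spec_seed(spec, {
    codes <- generate_codes(spec)
    if (spec$blank_rate > 0 && length(codes)) {
      blanks <- stats::runif(length(codes)) < spec$blank_rate
      unlist(lapply(seq_along(codes),
                    function(i) if (blanks[i]) c("", codes[i]) else codes[i]))
    } else codes
  })
  write_code_file(lines, path)
}

#' Worked-example codes
#'
#' The small corpus of structures used throughout the documentation: the
#' bare trimannosyl core, a fucosylated triantennary trisialylated
#' structure (A3G3FS3), and the four sialylation-placement variants of the
#' tetraantennary A4G4FLac1S3 structure.
#'
#' @return Named character vector of six nine-digit identifiers.
#' @examples
#' reference_codes()
#' @export
reference_codes <- function() {
  c(core          = "300000000",
    a3g3fs3       = "310033333",
    a4g4flac1s3_1 = "310333553",
    a4g4flac1s3_2 = "310332653",
    a4g4flac1s3_3 = "310323653",
    a4g4flac1s3_4 = "310233653")
}
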