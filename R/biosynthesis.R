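# Single-enzyme transitions between codes: each of the eleven mammalian
# glycosyltransferase/mannosidase activities in the encoding is a guarded
# one-digit transformation adding or removing exactly one residue (the
# 1,3-1,6-alpha-mannosidase is modelled as two single-residue steps).

GUARD_FLAGS <- c(
  "gnt1_max_man5",        # GnT-I acts only after trimming to Man5 or below
  "man2_requires_branch1",# alpha-mannosidase II acts only after GnT-I
  "complex_requires_man3",# GnT-II/IV/V act only on the fully trimmed core
  "gnt4_requires_branch1",# GnT-IV needs branch 1 initiated
  "gnt5_requires_branch3")# GnT-V needs branch 3 initiated

#' The eleven enzyme activities as code-transition rules
#'
#' Each rule carries its EC number, the digit it transforms, the
#' from/to transitions, the branch positions it may act on, and a guard.
#' Substrate-order guards (classical CHO pathway ordering) are named flags
#' that can be relaxed individually via `relax`.
#'
#' @param relax character vector of guard flags to disable; any of
#'   `"gnt1_max_man5"`, `"man2_requires_branch1"`,
#'   `"complex_requires_man3"`, `"gnt4_requires_branch1"`,
#'   `"gnt5_requires_branch3"`.
#' @return A list of 11 objects of class `enzyme_rule` with fields `ec`,
#'   `enzyme`, `abbrev`, `target` (`"man"`, `"fucose"`, `"bisect"` or
#'   `"branch"`), `transitions` (list of `c(from, to)` pairs), `branches`
#'   (positions a branch rule may act on), `residue_delta` and `guard`
#'   (a predicate on the seven digit values).
#' @export
rule_set <- function(relax = character()) {
  bad <- setdiff(relax, GUARD_FLAGS)
  if (length(bad))
    glycan_error(sprintf("unknown guard flag(s): %s", paste(bad, collapse = ", ")),
                 "glycan_config_error")
  on_ <- function(flag) !(flag %in% relax)
  rule <- function(ec, enzyme, abbrev, target, transitions, branches = integer(0),
                   delta = 1L, guard = function(d) TRUE) {
    structure(list(ec = ec, enzyme = enzyme, abbrev = abbrev, target = target,
                   transitions = transitions, branches = branches,
                   residue_delta = delta, guard = guard),
              class = "enzyme_rule")
  }
  list(
    rule("2.4.1.38", "beta-N-acetylglucosaminylglycopeptide beta-1,4-galactosyltransferase",
         "GalT", "branch", list(c(1L, 2L), c(4L, 5L)), 1:4),
    rule("2.4.1.68", "glycoprotein 6-alpha-L-fucosyltransferase",
         "FucT8", "fucose", list(c(0L, 1L))),
    rule("2.4.1.101", "alpha-1,3-mannosyl-glycoprotein 2-beta-N-acetylglucosaminyltransferase",
         "GnT-I", "branch", list(c(0L, 1L)), 1L,
         guard = function(d) !on_("gnt1_max_man5") || d[1L] <= 5L),
    rule("2.4.1.143", "alpha-1,6-mannosyl-glycoprotein 2-beta-N-acetylglucosaminyltransferase",
         "GnT-II", "branch", list(c(0L, 1L)), 3L,
         guard = function(d) !on_("complex_requires_man3") || d[1L] == 3L),
    rule("2.4.1.144", "beta-1,4-mannosyl-glycoprotein 4-beta-N-acetylglucosaminyltransferase",
         "GnT-III", "bisect", list(c(0L, 1L))),
    rule("2.4.1.145", "alpha-1,3-mannosyl-glycoprotein 4-beta-N-acetylglucosaminyltransferase",
         "GnT-IV", "branch", list(c(0L, 1L)), 2L,
         guard = function(d) (!on_("complex_requires_man3") || d[1L] == 3L) &&
                             (!on_("gnt4_requires_branch1") || d[4L] >= 1L)),
    rule("2.4.1.149", "N-acetyllactosaminide beta-1,3-N-acetylglucosaminyltransferase",
         "iGnT", "branch", list(c(2L, 4L)), 1:4),
    rule("2.4.1.155", "alpha-1,6-mannosyl-glycoprotein 6-beta-N-acetylglucosaminyltransferase",
         "GnT-V", "branch", list(c(0L, 1L)), 4L,
         guard = function(d) (!on_("complex_requires_man3") || d[1L] == 3L) &&
                             (!on_("gnt5_requires_branch3") || d[6L] >= 1L)),
    rule("2.4.99.6", "N-acetyllactosaminide alpha-2,3-sialyltransferase",
         "ST3", "branch", list(c(2L, 3L), c(5L, 6L)), 1:4),
    rule("3.2.1.113", "mannosyl-oligosaccharide 1,2-alpha-mannosidase",
         "Man-I", "man", list(c(6L, 5L)), delta = -1L),
    rule("3.2.1.114", "mannosyl-oligosaccharide 1,3-1,6-alpha-mannosidase",
         "Man-II", "man", list(c(5L, 4L), c(4L, 3L)), delta = -1L,
         guard = function(d) !on_("man2_requires_branch1") || d[4L] >= 1L))
}

#' @export
print.enzyme_rule <- function(x, ...) {
  tr <- paste(vapply(x$transitions, function(t) paste0(t[1L], "→", t[2L]),
                     character(1L)), collapse = ", ")
  cat(sprintf("<enzyme_rule %s> %s (%s): %s %s%s\n", x$abbrev, x$ec, x$enzyme,
              x$target, tr,
              if (length(x$branches)) paste0(" on branch(es) ",
                                             paste(x$branches, collapse = ",")) else ""))
  invisible(x)
}

# digits 1-7 of a code as an integer vector
code_digits7 <- function(code) {
  if (is.character(code)) code <- suppressWarnings(parse_code(code))
  stopifnot(inherits(code, "glycan_code"))
  c(code$man, code$fucose, code$bisect, code$branches)
}

# identifier string from digits 1-7 (composition recomputed)
digits7_to_id <- function(d) {
  comp <- c(sum(GAL_INCREMENT[d[4:7] + 1L]), sum(NEUAC_INCREMENT[d[4:7] + 1L]))
  paste(c(d, comp), collapse = "")
}

#' Enumerate all single-enzyme products of a code
#'
#' Applies every rule whose guard and from-value are satisfied, at every
#' admissible branch position, and returns the resulting codes with their
#' compositions recomputed.
#'
#' @param code a [glycan_code()] or identifier string.
#' @param rules a [rule_set()].
#' @return A data frame with one row per applicable (rule, site):
#'   columns `ec`, `abbrev`, `enzyme`, `site` (branch position or `NA`)
#'   and `product` (nine-digit identifier).
#' @examples
#' successors("300000000")  # FucT8, GnT-I, GnT-III
#' @export
successors <- function(code, rules = rule_set()) {
  d <- code_digits7(code)
  ec <- character(0); ab <- character(0); en <- character(0)
  site <- integer(0); prod <- character(0)
  for (r in rules) {
    if (!r$guard(d)) next
    slot <- switch(r$target, man = 1L, fucose = 2L, bisect = 3L, branch = NA_integer_)
    for (tr in r$transitions) {
      if (r$target == "branch") {
        for (b in r$branches) {
          if (d[3L + b] != tr[1L]) next
          d2 <- d; d2[3L + b] <- tr[2L]
          ec <- c(ec, r$ec); ab <- c(ab, r$abbrev); en <- c(en, r$enzyme)
          site <- c(site, b); prod <- c(prod, digits7_to_id(d2))
        }
      } else {
        if (d[slot] != tr[1L]) next
        d2 <- d; d2[slot] <- tr[2L]
        ec <- c(ec, r$ec); ab <- c(ab, r$abbrev); en <- c(en, r$enzyme)
        site <- c(site, NA_integer_); prod <- c(prod, digits7_to_id(d2))
      }
    }
  }
  data.frame(ec = ec, abbrev = ab, enzyme = en, site = site, product = prod,
             stringsAsFactors = FALSE)
}

#' Shortest enzyme path between two codes
#'
#' Breadth-first search over single-enzyme transitions.  Mannose count
#' never increases and branch levels never decrease along any path, so the
#' search space is finite.
#'
#' @param from,to codes or identifier strings.
#' @param rules a [rule_set()].
#' @return A data frame of steps (`step`, `ec`, `abbrev`, `enzyme`,
#'   `site`, `code` after the step); zero rows when `from == to`; `NULL`
#'   when unreachable.
#' @examples
#' nrow(reachable("600000000", "310333553"))
#' @export
reachable <- function(from, to, rules = rule_set()) {
  from_id <- format_code(if (is.character(from)) suppressWarnings(parse_code(from)) else from)
  to_id <- format_code(if (is.character(to)) suppressWarnings(parse_code(to)) else to)
  empty <- data.frame(step = integer(0), ec = character(0), abbrev = character(0),
                      enzyme = character(0), site = integer(0), code = character(0),
                      stringsAsFactors = FALSE)
  if (from_id == to_id) return(empty)
  prev <- new.env(parent = emptyenv())  # product -> list(from, row)
  queue <- from_id
  assign(from_id, NULL, envir = prev)
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    succ <- successors(cur, rules)
    for (i in seq_len(nrow(succ))) {
      p <- succ$product[i]
      if (exists(p, envir = prev, inherits = FALSE)) next
      assign(p, list(from = cur, row = succ[i, , drop = FALSE]), envir = prev)
      if (p == to_id) {
        # reconstruct
        steps <- list()
        node <- to_id
        while (node != from_id) {
          rec <- get(node, envir = prev)
          steps[[length(steps) + 1L]] <- rec$row
          node <- rec$from
        }
        steps <- rev(steps)
        out <- do.call(rbind, steps)
        return(data.frame(step = seq_len(nrow(out)), ec = out$ec,
                          abbrev = out$abbrev, enzyme = out$enzyme,
                          site = out$site, code = out$product,
                          stringsAsFactors = FALSE))
      }
      queue <- c(queue, p)
    }
  }
  NULL
}
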