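#' Expand a glycan code into an explicit residue/linkage tree
#'
#' Builds the rooted tree anchored at the asparagine: the
#' Asn-GlcNAc-GlcNAc-Man core with its alpha1-3 and alpha1-6 mannoses,
#' extra mannoses for codes Man4-Man6, core fucose (alpha1-6 on the
#' reducing GlcNAc), bisecting GlcNAc (beta1-4 on the beta-mannose) and the
#' four antennae grown per their extension levels.  Extra mannoses follow
#' the processing-intermediate topology: Man4 adds Man(a1-3) on the
#' alpha1-6 core mannose, Man5 adds Man(a1-6) there, Man6 adds Man(a1-2)
#' on the alpha1-3 core mannose.
#'
#' A warning is raised when branches 3 or 4 (on the alpha1-6 mannose) are
#' non-zero while extra mannoses are present, since those positions are
#' occupied in vivo; the tree is still built.
#'
#' @param code a [glycan_code()] object.
#' @return An object of class `glycan_tree`: a list of parallel vectors
#'   `mono`, `anomer` (`"a"`, `"b"` or `""`), `pos` (attachment position on
#'   the parent; `"N"` for the Asn link), `parent` (index, 0 for the root)
#'   and `depth` (Asn = 0), plus the originating `code`.
#' @examples
#' build_tree(parse_code("300000000"))
#' @export
build_tree <- function(code) {
  stopifnot(inherits(code, "glycan_code"))
  if (code$man > 3L && any(code$branches[3:4] > 0L))
    warning(warningCondition(
      sprintf("code %s: branches 3-4 on the alpha1-6 mannose are biologically implausible when extra mannoses are present",
              format_code(code)),
      class = c("glycan_implausible_warning", "glycanid_warning")))
  # core: Asn(1) - GlcNAc(2) - GlcNAc(3) - betaMan(4) - Man a1-3(5), Man a1-6(6)
  mono <- c("Asn", "GlcNAc", "GlcNAc", "Man", "Man", "Man")
  anomer <- c("", "b", "b", "b", "a", "a")
  pos <- c("", "N", "4", "4", "3", "6")
  parent <- c(0L, 1L, 2L, 3L, 4L, 4L)
  depth <- c(0L, 1L, 2L, 3L, 4L, 4L)
  if (code$man >= 4L) {
    mono <- c(mono, "Man"); anomer <- c(anomer, "a"); pos <- c(pos, "3")
    parent <- c(parent, 6L); depth <- c(depth, 5L)
  }
  if (code$man >= 5L) {
    mono <- c(mono, "Man"); anomer <- c(anomer, "a"); pos <- c(pos, "6")
    parent <- c(parent, 6L); depth <- c(depth, 5L)
  }
  if (code$man >= 6L) {
    mono <- c(mono, "Man"); anomer <- c(anomer, "a"); pos <- c(pos, "2")
    parent <- c(parent, 5L); depth <- c(depth, 5L)
  }
  if (code$fucose == 1L) {
    mono <- c(mono, "Fuc"); anomer <- c(anomer, "a"); pos <- c(pos, "6")
    parent <- c(parent, 2L); depth <- c(depth, 2L)
  }
  if (code$bisect == 1L) {
    mono <- c(mono, "GlcNAc"); anomer <- c(anomer, "b"); pos <- c(pos, "4")
    parent <- c(parent, 4L); depth <- c(depth, 4L)
  }
  arm_node <- c(5L, 5L, 6L, 6L)
  for (b in 1:4) {
    lev <- code$branches[b]
    if (lev == 0L) next
    chain <- branch_chain(lev, BRANCH_POS[b])
    k <- length(chain)
    n0 <- length(mono)
    mono <- c(mono, vapply(chain, `[[`, character(1L), 1L))
    anomer <- c(anomer, vapply(chain, `[[`, character(1L), 2L))
    pos <- c(pos, vapply(chain, function(s) as.character(s[[3L]]), character(1L)))
    parent <- c(parent, c(arm_node[b], n0 + seq_len(k - 1L)))
    depth <- c(depth, 4L + seq_len(k))
  }
  structure(list(mono = mono, anomer = anomer, pos = pos, parent = parent,
                 depth = depth, code = code),
            class = "glycan_tree")
}

#' Residue census of a glycan tree
#'
#' Counts per monosaccharide (the Asn anchor is not a sugar and is not
#' counted).  For a tree built from a code, the census reproduces the
#' code's digits: Man = digit 1, Fuc = digit 2, Gal = digit 8, NeuAc =
#' digit 9, and GlcNAc = 2 + digit 3 + the summed per-level GlcNAc
#' increments of the branches.
#'
#' @param tree a [build_tree()] result.
#' @return Named integer vector with elements `Man`, `GlcNAc`, `Gal`,
#'   `NeuAc`, `Fuc`.
#' @export
census <- function(tree) {
  stopifnot(inherits(tree, "glycan_tree"))
  monos <- c("Man", "GlcNAc", "Gal", "NeuAc", "Fuc")
  out <- tabulate(match(tree$mono, monos), nbins = 5L)
  names(out) <- monos
  out
}

#' @export
print.glycan_tree <- function(x, ...) {
  cs <- census(x)
  cat(sprintf("<glycan_tree %s> %d residues: %s\n  %s\n",
              format_code(x$code), sum(cs),
              paste(sprintf("%s %d", names(cs)[cs > 0L], cs[cs > 0L]), collapse = ", "),
              to_condensed_text(x)))
  invisible(x)
}

# children indices of each node, as a list indexed by node
tree_children <- function(tree) {
  n <- length(tree$mono)
  unname(split(seq_len(n)[-1L],
               factor(tree$parent[-1L], levels = seq_len(n))))
}

# sort child indices by ascending linkage position, alpha before beta on ties
order_children_condensed <- function(tree, kids) {
  p <- suppressWarnings(as.integer(tree$pos[kids]))
  p[is.na(p)] <- 0L
  kids[order(p, tree$anomer[kids])]
}

#' Serialize a glycan tree as condensed linear text
#'
#' Deterministic IUPAC-style condensed form, written from the non-reducing
#' end towards the asparagine: at every branching node children are taken
#' in ascending linkage-position order, the first written bare and the
#' remainder parenthesized, e.g.
#' `"Manα1-3(Manα1-6)Manβ1-4GlcNAcβ1-4GlcNAcβ1-Asn"`
#' for the trimannosyl core.
#'
#' @param tree a [build_tree()] result.
#' @return A single character string.
#' @export
to_condensed_text <- function(tree) {
  stopifnot(inherits(tree, "glycan_tree"))
  kids <- tree_children(tree)
  lab <- paste0(tree$mono,
                c("α", "β", "")[match(tree$anomer, c("a", "b"), nomatch = 3L)],
                ifelse(tree$mono == "NeuAc", "2-", "1-"),
                ifelse(tree$pos == "N", "", tree$pos))
  lab[tree$mono == "Asn"] <- "Asn"
  ser <- function(i) {
    ks <- kids[[i]]
    if (length(ks) == 0L) return(lab[i])
    ks <- order_children_condensed(tree, ks)
    parts <- vapply(ks, ser, character(1L))
    if (length(parts) > 1L)
      parts[-1L] <- paste0("(", parts[-1L], ")")
    paste0(paste(parts, collapse = ""), lab[i])
  }
  ser(1L)
}

#' Export a glycan tree as an adjacency listing
#'
#' @param tree a [build_tree()] result.
#' @return A data frame with columns `child`, `parent`, `mono`, `anomer`,
#'   `pos` (one row per node; the Asn root has parent 0).
#' @export
tree_adjacency <- function(tree) {
  stopifnot(inherits(tree, "glycan_tree"))
  data.frame(child = seq_along(tree$mono), parent = tree$parent,
             mono = tree$mono, anomer = tree$anomer, pos = tree$pos,
             stringsAsFactors = FALSE)
}
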