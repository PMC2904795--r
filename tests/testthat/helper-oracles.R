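# Independent oracles and small utilities shared across tests.

# Residue chains per extension level, written out explicitly (independent of
# the package's increment tables): composition oracle counts names directly.
oracle_level_chain <- list(
  `0` = character(0),
  `1` = c("GlcNAc"),
  `2` = c("Gal", "GlcNAc"),
  `3` = c("NeuAc", "Gal", "GlcNAc"),
  `4` = c("GlcNAc", "Gal", "GlcNAc"),
  `5` = c("Gal", "GlcNAc", "Gal", "GlcNAc"),
  `6` = c("NeuAc", "Gal", "GlcNAc", "Gal", "GlcNAc"))

oracle_composition <- function(levels) {
  res <- unlist(oracle_level_chain[as.character(levels)])
  c(gal = sum(res == "Gal"), neuac = sum(res == "NeuAc"))
}

# all 7^4 branch-level tuples as a matrix
all_branch_tuples <- function() {
  as.matrix(expand.grid(b1 = 0:6, b2 = 0:6, b3 = 0:6, b4 = 0:6,
                        KEEP.OUT.ATTRS = FALSE))
}

# axis-aligned bounding-box overlap count among symbol centres
overlap_count <- function(x, y, side) {
  n <- length(x)
  if (n < 2L) return(0L)
  cnt <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (abs(x[i] - x[j]) < side && abs(y[i] - y[j]) < side) cnt <- cnt + 1L
    }
  }
  cnt
}

# width/height of a BMP file, from its header
bmp_dims <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 18L)
  dims <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  abs(dims)
}

# deterministic sample of identifiers from the full code space
sample_codes <- function(n, seed = 42L) {
  ids <- code_space()
  withr::with_seed(seed, sample(ids, n))
}
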