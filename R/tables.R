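# Internal lookup tables shared across modules.

# Per-level residue increments for one branch (antenna), extension levels 0-6.
# Level semantics: 0 = absent; 1 = GlcNAc; 2 = Gal-GlcNAc (LacNAc);
# 3 = NeuAc-Gal-GlcNAc; 4 = GlcNAc-Gal-GlcNAc (LacNAc + repeat-initiating
# GlcNAc); 5 = Gal-GlcNAc-Gal-GlcNAc (one full LacNAc repeat);
# 6 = NeuAc-Gal-GlcNAc-Gal-GlcNAc.  Index with level + 1.
GAL_INCREMENT    <- c(0L, 0L, 1L, 1L, 1L, 2L, 2L)
NEUAC_INCREMENT  <- c(0L, 0L, 0L, 1L, 0L, 0L, 1L)
GLCNAC_INCREMENT <- c(0L, 1L, 1L, 1L, 2L, 2L, 2L)

# Branch attachment geometry: branches 1-2 sit on the "lower" alpha-1,3 core
# mannose (beta-1,2 and beta-1,4), branches 3-4 on the "upper" alpha-1,6 core
# mannose (beta-1,2 and beta-1,6).
BRANCH_ARM <- c("a3", "a3", "a6", "a6")
BRANCH_POS <- c(2L, 4L, 2L, 6L)

# Outward residue chain grown on a branch at a given extension level.
# Returns a list of (mono, anomer, pos) steps, innermost first; `pos` of the
# first step is the attachment position on the core mannose.
branch_chain <- function(level, attach_pos) {
  steps <- list()
  if (level >= 1L) steps[[1L]] <- list("GlcNAc", "b", attach_pos)
  if (level >= 2L) steps[[2L]] <- list("Gal", "b", 4L)
  if (level == 3L) steps[[3L]] <- list("NeuAc", "a", 3L)
  if (level >= 4L) steps[[3L]] <- list("GlcNAc", "b", 3L)
  if (level >= 5L) steps[[4L]] <- list("Gal", "b", 4L)
  if (level == 6L) steps[[5L]] <- list("NeuAc", "a", 3L)
  steps
}

# Package-level cache (full code-space table, built lazily).
.glycanid_cache <- new.env(parent = emptyenv())

glycan_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "glycanid_error")))
}
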