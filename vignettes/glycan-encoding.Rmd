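---
title: "The nine-digit N-glycan encoding: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nine-digit N-glycan encoding: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycanid)
```

## The encoding

Mammalian *N*-glycans are built on an invariant pentasaccharide core,
Manα1-3(Manα1-6)Manβ1-4GlcNAcβ1-4GlcNAcβ1-Asn, and elaborated by a small,
bond-specific enzyme repertoire. Under that constraint a structure is
identified by nine digits: mannose total (3–6), core-fucose flag,
bisecting-GlcNAc flag, four branch extension levels (0–6), then a derived
galactose total (0–8) and sialic-acid total (0–4). Branch positions are
fixed — branches 1 and 2 attach β1-2 and β1-4 to the α1-3 core mannose,
branches 3 and 4 attach β1-2 and β1-6 to the α1-6 core mannose — so a
branch is described entirely by how far it has been extended:

| level | chain grown outward | +Gal | +GlcNAc | +NeuAc |
|-------|--------------------------------|----|----|----|
| 0 | — | 0 | 0 | 0 |
| 1 | GlcNAc | 0 | 1 | 0 |
| 2 | Gal-GlcNAc | 1 | 1 | 0 |
| 3 | NeuAc-Gal-GlcNAc | 1 | 1 | 1 |
| 4 | GlcNAc-Gal-GlcNAc | 1 | 2 | 0 |
| 5 | Gal-GlcNAc-Gal-GlcNAc | 2 | 2 | 0 |
| 6 | NeuAc-Gal-GlcNAc-Gal-GlcNAc | 2 | 2 | 1 |

Levels 4–6 replay levels 1–3 beyond one β1-3-linked LacNAc repeat; levels
3 and 6 carry an α2-3-linked NeuAc on the terminal galactose. Digits 8–9
are the column sums of this table over the four branches. They are
therefore *derived*: `parse_code()` recomputes them whenever digits 1–7
are given, and a nine-digit input whose trailing digits disagree is
corrected with a warning by default. A `strict = TRUE` mode turns the
correction into an error for pipelines that must not accept inconsistent
records; lenient correction is the default because identifiers in the
wild frequently circulate with stale composition digits. Seven-digit
input is accepted outright, since the first seven digits specify the
structure uniquely.

The full space of valid codes is small — 4 × 2 × 2 × 7⁴ = 38,416 — which
makes exhaustive verification practical: the test suite checks
parse/format identity, census/digit agreement and serialization
injectivity over the entire space, and the acceptance script re-derives
the galactose ceiling (8) and sialic-acid ceiling (4) by enumerating all
2,401 branch-level tuples.

## Classification

Codes are labelled by the standard three-way classification:
`oligomannose` (extra mannoses, no antennae), `hybrid` (extra mannoses
alongside at least one antenna) and `complex` (antennae on the trimmed
Man3 core). The encoding names these classes without fixing a decision
rule, so the rule above — the field's conventional usage — is a package
convention. The bare core is reported as `complex` with a `"core-only"`
qualifier rather than given a fourth class.

Digit ranges are the only validation the codec enforces. Biologically
odd-but-encodable states (say, branch 2 extended while branch 1 is empty)
pass validation, because display tools must accept any code that printed
sources contain. One plausibility check lives in `build_tree()` instead:
branches 3–4 on the α1-6 mannose warn when extra mannoses occupy that arm
(the positions clash in vivo), but the tree is still built.

## Tree expansion choices

The encoding does not pin down where extra mannoses sit. The package uses
the processing-intermediate topology implied by the two mannosidase
activities it models: Man4 adds Man(α1-3) on the α1-6 core mannose, Man5
adds Man(α1-6) there (the classical Man5 intermediate), Man6 adds
Man(α1-2) on the α1-3 core mannose. These choices affect drawing and
serialization only — no digit arithmetic depends on them.

Condensed text is serialized deterministically: at every branching node
children are ordered by ascending linkage position (α before β on ties),
the first child is written bare and the rest parenthesized, which yields
the conventional form `Manα1-3(Manα1-6)Manβ1-4…` for the core. The
Asn linkage is written `GlcNAcβ1-Asn`, without a position number.

## Abbreviations and enumeration

GlycoBase-style abbreviations compress a complex structure to antenna
counts: `A` branches initiated, `G` branches whose terminal region
carries a galactose (levels 2, 3, 5, 6), `F`/`B` the fucose and bisect
flags, `Lac` branches bearing a repeat (level ≥ 4), `S` total sialic
acids. Zero tokens are omitted. An abbreviation does not say *which*
branch carries each decoration, so several codes share one name;
`enumerate_codes()` inverts the map by filtering the full code space.

Two conventions close gaps the abbreviation grammar leaves open:

* **Canonical LacNAc placement.** Repeat-bearing branches are required to
  occupy the highest-numbered branch positions. Under this convention the
  tetraantennary name `A4G4FLac1S3` enumerates to exactly four
  identifiers (310233653, 310323653, 310332653, 310333553) — the
  sialylation-placement variants — rather than sixteen positional
  permutations. `canonical_only = FALSE` lifts the restriction.
* **Oligomannose and hybrid names.** Unbranched codes render as `M<n>`
  (decorated cores as `M3-F` etc.) and hybrids as `M<n>-<antenna
  tokens>`. These are package extensions, chosen so that every code has
  exactly one printable name; the complex-type grammar itself covers
  neither.

## Rendering

Layout is right-to-left from the asparagine: columns are tree depth with
a fixed horizontal spacing (40 px at magnification 1), vertical positions
come from post-order subtree centering with a 44 px row pitch, and the
α1-6 arm is drawn above the α1-3 arm, with branch 4 topmost within the
upper arm (β1-6 above β1-2) and branch 1 above branch 2 within the lower
arm — the arrangement of conventional tetraantennary figures. The core
fucose drops one row below the reducing GlcNAc in the same column; the
bisecting GlcNAc sits on the β-mannose column axis one row above it. The
row pitch exceeds twice the symbol size (20 px), which is what guarantees
the non-overlap property the tests assert.

Every distance scales linearly with the magnification factor, and the
linkage pen width is `max(1, 1.5 × magnification)` — linear with a 1 px
floor, since the encoding's rendering description fixes only that the
width follows magnification. One line is drawn per linkage, including the
GlcNAc–Asn bond, so a structure with *n* sugars has *n* line elements and
*n* shape elements plus a text label for Asn.

Symbol sets: CFG colour uses the published CFG/SNFG palette (GlcNAc
#0072BC square, Man #00A651 circle, Gal #FFD400 circle, NeuAc #A54399
diamond, Fuc #ED1C24 triangle); CFG black-and-white keeps the shapes and
distinguishes same-shape residues by fill (solid, empty, hatched); the
Oxford (UOXF) set is supported at the level of its shape/fill vocabulary
only — the full Oxford system of linkage angles and line styles is out of
scope. Text-only mode emits one text token per residue and no shapes.
SVG 1.1 is generated directly from the element model (shapes, lines,
texts), which keeps the output countable and testable; raster export
draws the same element model onto PNG/JPEG/BMP devices at
`canvas × scale` pixels.

## Grids and set alignment

Code-list files are one identifier per line; blank lines are meaningful
and become blank cells, and `#` comment lines (a package extension) are
skipped. The default grid is 22 rows × 13 columns, filled one column at a
time, top to bottom, from the left — so 45 entries occupy columns 1–3 as
22/22/1. Overflow beyond the geometry is an error unless paging is
enabled, in which case successive pages are emitted.

`align_code_sets()` implements superset alignment for visual comparison:
the union of all input sets is sorted in ascending numeric order (the
nine-digit string's integer value; fixed-width strings sort identically),
and each input is rewritten to the superset's length with blanks where a
code is absent, so the same structure lands in the same grid cell in
every output. Duplicates within one input are collapsed to set semantics
with a warning, the natural reading of a set comparison.

## Enzyme transitions

Eleven EC-numbered activities — four branch-initiating GlcNAc
transferases, the bisecting transferase, the core fucosyltransferase, the
β1-4 galactosyltransferase, the β1-3 GlcNAc transferase that starts a
LacNAc repeat, the α2-3 sialyltransferase, and two trimming mannosidases
— are expressed as guarded one-digit transitions, each adding or removing
exactly one residue (the 1,3-1,6-α-mannosidase is split into 5→4 and 4→3
steps to preserve that invariant). Bond specificity falls out of the
level table: GalT maps levels 1→2 and 4→5, ST3 caps terminal Gal-GlcNAc
groups at levels 2→3 and 5→6, iGnT opens the repeat at 2→4.

The encoding lists activities, not substrate prerequisites, so pathway
ordering is a set of package-level guards reflecting the classical
mammalian route: GnT-I requires trimming to Man5 and an empty branch 1;
mannosidase II requires GnT-I to have acted; GnT-II, -IV and -V require
the fully trimmed Man3 core; GnT-IV needs branch 1 initiated and GnT-V
branch 3. Each guard is a named flag that `rule_set(relax = …)` disables
individually, because these assumptions are conventions, not encodings.
Under the rules, mannose count is non-increasing and branch levels,
galactose and sialic acid non-decreasing along any path, which makes the
transition graph acyclic and `reachable()`'s breadth-first search finite;
the shortest route from Man6 to the fucosylated tetraantennary structure
310333553 takes 17 steps (3 trims plus 14 single-residue additions).

Note one consequence of taking bond specificity at face value: a level-5
branch ends in an unsialylated Gal-GlcNAc group, so the sialyltransferase
*does* act on 310333553 (branch 4, 5→6) alongside the bisecting
transferase — terminal completeness is a property of levels 3 and 6 only.

## Synthetic corpora

`fixture_spec()`/`random_codes()` generate reproducible corpora for tests
and demos. Class proportions are allocated exactly (largest remainder)
rather than sampled, so a 200-code corpus at the default 20/20/60 mix
contains exactly 40/40/120 oligomannose/hybrid/complex codes. Branch
levels are sampled uniformly; hybrid antennae are placed on the α1-3 arm
only, matching the plausibility warning above; decoration probabilities
(fucose 0.5 on complex, 0.3 on hybrid; bisect 0.15/0.1) are rough
reflections of how common those features are in mammalian secreted
glycoproteins, chosen once for realism rather than fit to any dataset.
The generator emulates *valid identifier corpora* — it does not emulate
any real sample's abundance distribution, analytical ambiguity or
measurement noise, so passing tests demonstrate correctness of the code
manipulations, not agreement with experimental glycomics.

Test problem sizes are the package's own choices: exhaustive loops where
the space is small enough (38,416 codes for codec/structure/biosynthesis
properties), 500 random codes for renderer census checks, and a few
hundred sampled cases for the remaining property suites.

## Known limitations

Deliberately outside the encoding and therefore outside the package:
Neu5Gc capping, α2-6 sialylation, antenna or Lewis-type fucosylation,
more than one LacNAc repeat per branch, pentaantennary structures, plant
Xyl/Ara residues, O-glycans, GlycoCT/WURCS/Linear Code serialization, GU
values, and the full Oxford linkage-angle notation. The Man4 and Man6
isomer topologies are conventions (above), and the hybrid/oligomannose
abbreviation forms are extensions; both are flagged where they appear.
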