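# glycanid

Tools for the nine-digit numeric encoding of mammalian *N*-glycans.

Asparagine-linked glycans of mammalian (classically CHO-cell) glycoproteins
share an invariant trimannosyl core,
Manα1-3(Manα1-6)Manβ1-4GlcNAcβ1-4GlcNAcβ1-Asn, decorated by a constrained
repertoire of glycosyltransferases and mannosidases. That regularity lets a
structure be captured by nine digits:

| digit | range | meaning |
|-------|-------|---------|
| 1 | 3–6 | total mannose residues (core included) |
| 2 | 0–1 | core fucose (α1-6 on the reducing GlcNAc) |
| 3 | 0–1 | bisecting GlcNAc (β1-4 on the β-mannose) |
| 4–7 | 0–6 | extension level of branches 1–4 |
| 8 | 0–8 | galactose count — derived |
| 9 | 0–4 | *N*-acetylneuraminic acid count — derived |

Branches 1–2 sit β1-2/β1-4 on the α1-3 core mannose, branches 3–4 β1-2/β1-6
on the α1-6 core mannose. Extension levels grow a branch outward: 1 =
GlcNAc, 2 = Gal-GlcNAc (LacNAc), 3 = NeuAc-Gal-GlcNAc, 4–6 repeat the
pattern after one β1-3-linked LacNAc repeat; levels 3 and 6 carry an
α2-3-linked sialic acid. Digits 8–9 are always recomputed from digits 4–7,
never set directly.

The package provides, for anyone who works with these identifiers
(glycomics, systems biology of glycosylation, bioprocess engineering):

* **codec** — parsing, validation, normalisation, free-text extraction,
  oligomannose/hybrid/complex classification (`parse_code()`,
  `format_code()`, `compute_composition()`, `extract_codes_from_text()`,
  `classify()`, `code_space()`);
* **structure** — expansion into an explicit residue/linkage tree and
  IUPAC-style condensed text (`build_tree()`, `census()`,
  `to_condensed_text()`);
* **nomenclature** — GlycoBase-style abbreviations and the reverse
  enumeration of all identifiers consistent with one (`to_glycobase()`,
  `enumerate_codes()`);
* **render** — right-to-left symbol-notation layout and export to SVG,
  PNG, JPEG and BMP in CFG colour, CFG black-and-white, Oxford (UOXF)
  or text-only styles (`render_svg()`, `export_raster()`);
* **batch** — code-list files, 22 × 13 column-major display grids, and
  alignment of several code sets on their sorted superset so matching
  structures occupy matching cells (`build_grid()`, `align_code_sets()`);
* **biosynthesis** — the eleven EC-numbered enzyme activities of the
  encoding as guarded one-digit transitions, with successor listing and
  shortest-path search (`rule_set()`, `successors()`, `reachable()`);
* **fixtures** — reproducible random corpora (`fixture_spec()`,
  `random_codes()`), plus a command-line front-end (`glycan_cli()`,
  `inst/cli/glycanid`).

## Worked example

```r
library(glycanid)

code <- parse_code("3 1 0 0 3 3 3 3 3")
code
#> <glycan_code 310033333> complex: Man3 +coreFuc, branches (0,3,3,3), Gal 3, NeuAc 3
```

The spaced form is accepted, digits 8–9 (here 3 and 3) are recomputed from
the branch levels, and the structure is complex: a Man3 core with three
sialylated antennae and a core fucose.

```r
to_glycobase(code)
#> <glycobase_name> A3G3FS3 (A3 G3 F1 B0 Lac0 S3)

to_condensed_text(build_tree(code))
#> NeuAcα2-3Galβ1-4GlcNAcβ1-4Manα1-3(NeuAcα2-3Galβ1-4GlcNAcβ1-2(
#>   NeuAcα2-3Galβ1-4GlcNAcβ1-6)Manα1-6)Manβ1-4GlcNAcβ1-4(Fucα1-6)GlcNAcβ1-Asn
```

(line broken here for display; the function returns one string).

An abbreviation does not fix where each sialic acid sits, so several
identifiers can share one name — the tetraantennary, fucosylated,
trisialylated structure with one LacNAc repeat has four:

```r
enumerate_codes("A4G4FLac1S3")
#> [1] "310233653" "310323653" "310332653" "310333553"
```

Single-enzyme transitions from the bare core:

```r
successors("300000000")[, c("abbrev", "product")]
#>    abbrev   product
#> 1   FucT8 310000000
#> 2   GnT-I 300100000
#> 3  GnT-II 300001000
#> 4 GnT-III 301000000
```

Rendering and batch figures:

```r
doc <- render_svg(build_tree(code))      # 15 symbols, CFG colours
doc
#> <glycan_svg> 340 x 159 px, 15 shapes, 15 lines, 1 text elements
write_svg(doc, "a3g3fs3.svg")
export_raster(doc, "a3g3fs3.png", scale = 2)

grid <- build_grid(random_codes(fixture_spec(seed = 1, n = 45)))
write_svg(render_grid_svg(grid, symbol_style(magnification = 0.6)), "grid.svg")
```

The same operations are scriptable from a shell via the front-end in
`inst/cli/glycanid` (subcommands `validate`, `draw`, `grid`, `align`,
`reactions`, `enumerate`, `fixtures`).

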