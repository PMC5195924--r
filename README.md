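# ChemHarvest

Computational-chemistry articles routinely deposit their optimized 3D
structures — the actually re-usable result of the work — as tables of
Cartesian coordinates inside supplementary-information PDFs, interleaved
with prose, energies, page numbers and running headers. Stored that way,
the molecular data is effectively lost to computation: nothing downstream
can dock, re-optimize or profile a molecule that exists only as typeset
text. ChemHarvest is an R package for chemists and cheminformaticians that
digs those molecules back out and emits ready-to-compute files.

## What it does

Given a PDF (simple, single-column) or its plain-text export, ChemHarvest

1. extracts page-aware text lines and normalizes typography
   (non-breaking spaces, Unicode minus signs);
2. classifies every line against a strict coordinate grammar —
   an element symbol *or* atomic number, then x, y, z in ångströms —
   in space-, comma- and tab-delimited dialects, auto-detecting the
   dialect;
3. assembles maximal runs of coordinate lines into molecule blocks,
   healing page breaks that would otherwise split a molecule (blank lines,
   bare page numbers and recurring headers/footers inside a run are
   skipped when coordinates resume within 5 lines);
4. reconstructs covalent connectivity with the classical distance rule

   bonded(i, j)  ⇔  d(i, j) ≤ r_cov(i) + r_cov(j) + t,   t = 0.35 Å

   using Cordero et al. (2008) covalent radii (Z = 1–96), with bond order
   fixed at 1 and distances strictly above the cutoff treated as
   non-bonding;
5. validates each recreated molecule (bond lengths, valence angles, signed
   dihedrals; warnings for isolated atoms, sub-0.4 Å clashes and
   hypervalent degrees); and
6. writes a multi-record **SDF** (MDL V2000), one **Gaussian job file** per
   molecule, an **XYZ** file, a plain-text **bond matrix** report and the
   **residual text** (everything that was *not* a molecule), plus a JSON
   run report.

The two regular expressions published with the original extraction tool
are shipped verbatim (`paperPattern()`, `matchPaperPattern()`) as a
fidelity reference; the pipeline itself uses the stricter canonical
grammar, which accepts only lines the published patterns also accept.

A deterministic fixture generator (`generateDocument()`) fabricates
supplementary-style documents — coordinate runs in any dialect, element
symbols or atomic numbers, 1–10 decimals, noise lines, pagination breaks
mid-molecule, optionally rendered to PDF — together with a ground-truth
manifest, so the whole pipeline is testable without downloading anything.

## Worked example

```r
library(ChemHarvest)

# fabricate a 2-molecule supplementary PDF, then treat it as found data
fx  <- generateDocument(seed = 7, nMolecules = 2, delimiter = "space",
                        renderPdf = TRUE, pdfPath = "si_demo.pdf")
res <- runExtract("si_demo.pdf", outDir = "si_out", verbose = TRUE)
#> read 2 page(s), 24 line(s) from si_demo.pdf
#> resolved delimiter: space
#> blocks: 2, atoms: 13, coordinate lines: 13
#> wrote: si_demo.sdf, si_demo_mol1.gjf, si_demo_mol2.gjf, si_demo.xyz,
#>        si_demo_bonds.txt, si_demo_residual.txt, si_demo_report.json

res$report
#> ExtractionReport: delimiter=space lines=24 coordinate-lines=13 blocks=2 atoms=13

res$blocks[[1]]
#> MoleculeBlock 1: 8 atoms (C,H)  label: Mol ID 1  ethane  (B3LYP/6-31G(d))

bonds(res$bondMatrices[[1]])
#>   i j distance
#> 1 1 2 1.536029
#> 2 1 3 1.091842
#> ...
```

Of the 24 lines in the document, 13 were coordinate records; they form 2
blocks (an 8-atom ethane and a 5-atom methane), and the perceived C–C
(1.54 Å) and C–H (1.09 Å) distances sit well inside the 0.35 Å-padded
radius sums. The `si_demo_bonds.txt` report prints the same connectivity
per molecule ("Mol ID 1  atoms=8  bonds=7" followed by one `i j elem_i
elem_j distance` line per bond), and `si_demo_residual.txt` holds the 11
non-molecular lines under per-page markers.

## Command line

```sh
Rscript inst/scripts/chemharvest.R extract --input si.pdf --out-dir out \
    --delimiter auto --tolerance 0.35 --formats sdf,gjf,bonds,residual
Rscript inst/scripts/chemharvest.R fixture --seed 5 --molecules 3 \
    --delimiter comma --pdf --out-dir fixtures
```

`extract` exits 0 iff at least one molecule was extracted (or the
document had no coordinate lines and `--allow-empty` was given); a
directory input is processed in batch, one failure not aborting the rest.

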