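---
title: "Harvesting 3D molecular structures from supplementary documents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harvesting 3D molecular structures from supplementary documents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChemHarvest)
```

## The problem

Supplementary-information (SI) documents of computational-chemistry
articles carry the field's most directly re-usable artifact — optimized
Cartesian geometries — as typeset text inside PDFs. Each molecule appears
as a run of lines, one atom per line: a first column holding an element
symbol or an atomic number (authors interchange the two freely), then x,
y, z in ångströms, separated by spaces, commas or tabs depending on the
publisher and the author's export habits. Around the runs sit titles,
energy statements, thermochemistry tables, page numbers and running
headers; page breaks fall wherever the typesetting puts them, including
mid-molecule. ChemHarvest turns such a document back into computable
molecules: SDF/MOL connection tables, Gaussian job files and XYZ, plus a
bond-matrix report and the residual (non-molecular) text.

This vignette explains the models and procedures behind each stage, the
tunable parameters and the reasoning behind their defaults, what the
synthetic-fixture generator does and does not emulate, and the package's
known limitations.

## Document ingestion

`readDocument()` produces a page-aware line sequence from either input
path. Plain text is read as UTF-8 with a latin-1 fallback; form feeds
(`\f`) delimit pages, otherwise the file is one page. PDF text is
recovered by the package's own extractor, which replays the text
operators of each page's content stream (inflating FlateDecode with base
R's decompressor) and orders strings top-to-bottom, left-to-right. The
extractor targets simple single-column text PDFs — which is what
coordinate-bearing SI documents overwhelmingly are — and deliberately
does not attempt multi-column layout analysis, CID/Type0 font decoding or
OCR. Encrypted or unextractable PDFs raise a dedicated condition
(`pdfIngestError`) whose message names the standard workaround: export
the PDF to plain text with any external viewer and run the text path.
Treating the text export as a first-class input, rather than an
afterthought, reflects how practitioners actually cope with the
zoo of PDF producers.

`normalizeLines()` maps Unicode space variants to ASCII spaces and
typographic minus/hyphen variants to `-`, and strips trailing whitespace.
PDF extractors commonly emit U+00A0 and U+2212 where the coordinate
grammar expects ASCII; nothing else is touched. Tabs are preserved
because they *are* the tab dialect's delimiter. The operation is
idempotent and shape-preserving, so it can be applied defensively.

## Line classification

Two classifiers coexist, on purpose.

The **verbatim reference patterns** (`paperPattern()`,
`matchPaperPattern()`) are the two regular expressions published with the
original extraction tool for the space and comma dialects, kept
byte-identical and evaluated with full-string (anchored) semantics. They
contain permissive `.{1,2}` wildcards where a sign or decimal point is
plainly intended. We do not repair them: quoted artifacts are only useful
as a fidelity baseline if they stay verbatim, and any repair would be a
guess about intent. One measurable consequence of the anchored semantics
is that the space pattern cannot match a first coordinate with two or
more integer digits (the mandatory whitespace after its `[0-9]{1,8}` run
can never be reached), i.e. it presumes molecules within a
single-digit-ångström box — a realistic assumption for small-molecule SI
tables and one the fixture generator respects.

The **canonical grammar** (`parseCoordinateLine()`) is what the pipeline
uses: first token ≤ 3 characters normalizing to an element
(`normalizeElement()`: all-digit tokens are atomic numbers mapped for
1 ≤ Z ≤ 118; alphabetic tokens are case-normalized and checked against
the periodic table; mixed tokens are rejected), then at least three
fixed-decimal numeric fields (optional sign, digits, optional decimal
point with 1–10 fractional digits). The first three numeric fields are
x, y, z; a trailing tail is tolerated only if purely numeric, which
admits the `symbol  Z  x y z` layout some programs emit. Two-field lines
(a Gaussian charge/multiplicity line like `0 1`) are rejected, as is
scientific notation by default (`allowScientific = TRUE` enables it; the
published patterns could never match it, so it is off unless asked for).
Classification is total — any line, however malformed, yields "not a
coordinate" rather than an error. On every well-formed line the canonical
grammar accepts, the published pattern of the same dialect also matches;
the test suite checks this subset property over thousands of generated
lines.

`detectDelimiter()` resolves the `auto` dialect by counting canonical
acceptances under each concrete delimiter and taking the maximum, ties
broken space > comma > tab (space is the overwhelmingly common dialect,
so it wins degenerate ties, including the all-zero case).

## Block assembly

A molecule block is a maximal run of coordinate lines. The delicate part
is pagination: a page break inside a run injects furniture — a blank
line, a bare page number, a running header — and a naive segmenter would
split the molecule, carrying a few atoms into the next block. The healing
rule: a run is not terminated by an *ignorable interruption*, defined as
empty lines, bare-integer lines, and lines whose text recurs on at least
3 distinct pages (the operational signature of a running header or
footer), provided coordinates resume within 5 non-coordinate lines. Any
other non-coordinate line ends the block. The three thresholds are our
operationalization of a subroutine the original tool describes only by
its effect; they are deliberately conservative (real page furniture is
1–3 lines) and configurable in source. Blocks whose pages differ are
flagged `spans_pages`.

Two screens drop pathological runs, each recorded as a warning in the
`ExtractionReport`: runs shorter than `minAtoms` (default 2 — a single
free atom is chemically possible but indistinguishable from a stray
numeric table row; set 1 to keep them), and runs whose first-column
tokens are exactly the ascending sequence 1, 2, 3, … (a serial-numbered
data table masquerading as H, He, Li, …).

`attachLabels()` captures the nearest preceding non-empty,
non-coordinate, non-ignorable line within 3 lines of the block start
(truncated to 80 characters) — SI documents conventionally title each
coordinate table on the line above it. Labels are best-effort metadata: a
page break can push the title beyond the window, in which case the block
simply has none; atoms are never affected.

Adjacent coordinate runs with no separator at all cannot be split — the
text gives no boundary signal — and this is out of scope by design.

## Bond perception

Connectivity is reconstructed with the classical covalent-radius distance
rule: atoms i and j are bonded iff

$$d_{ij} \le r_i + r_j + t$$

with t = 0.35 Å by default and boundary equality counting as bonded
(only distances strictly greater are non-bonding). All pairs are
evaluated; there is no early exit, no neighbor-list approximation.

Choices worth stating:

* **Radii set.** Cordero et al. (2008) single-bond covalent radii, one
  value per element, Z = 1–96, shipped as a plain-text two-column file
  and loaded by `covalentRadii()`. The set is published, complete over
  the relevant elements, and widely used; user tables in the same format
  plug in via a file path. Looking up an uncovered element (Z ≥ 97) is an
  explicit error naming the element — silent defaults would fabricate
  chemistry.
* **One radius per element.** No hybridization-specific carbon radii; the
  0.35 Å tolerance absorbs that spread (sp–sp³ carbon radii differ by
  ~0.07 Å, well inside it).
* **Bond order is always 1.** The distance rule recovers *connectivity*;
  assigning multiplicities (or Wiberg-type QM bond orders) is a
  documented non-goal, so SDF output writes order-1 bonds only.
* **Tolerance is monotone.** Raising t can only add bonds; the t = 0 bond
  set is a subset of the default's. The test suite asserts this, along
  with permutation equivariance and exact agreement with an
  independently coded brute-force oracle on random atom clouds.

`validateGeometry()` then reports every bond length, every valence angle
at atoms of degree ≥ 2, and every signed dihedral along bonded 4-atom
paths, with warnings for degree-0 atoms in multi-atom blocks (the
signature of a pagination fragment), pairs closer than 0.4 Å (typeset
coordinate corruption), and degrees above per-element maxima (H 1, C 4,
N 4, O 3, S 6, halogens 1, others 8). Dihedrals use the IUPAC sign
convention, computed as atan2((n₁×n₂)·b̂₂, n₁·n₂) for the plane normals
n₁, n₂ about the central bond b₂, yielding values in (−180°, 180°];
paths whose defining planes are degenerate (collinear triples) are
omitted from the dihedral list, while direct calls to `dihedralAngle()`
on such input raise an explicit degenerate-geometry error.

## Output formats

`writeSDF()`/`writeMol()` emit MDL V2000 — chosen over V3000 for maximal
interoperability — with coordinates at the format's canonical 4 decimal
places, no stereo/charge/isotope fields, and an explicit error for blocks
beyond the 999-atom connection-table ceiling. `writeGJF()` writes route
(default a bare `#`, configurable — no universal route exists), title,
`charge multiplicity` (defaults `0 1`) and coordinates at 8 decimal
places; `writeXYZ()` the same precision. Eight decimals preserves
everything the coordinate grammar can carry and round-trips through the
canonical parser at 10⁻⁸ Å. One GJF per molecule (rather than one
combined file) keeps each job independently submittable.
`writeBondMatrixText()` and `writeResidualText()` complete the three-file
contract: molecules, bond matrix, and the non-molecular text (all
unconsumed lines under per-page markers — available for downstream text
mining). All writers are timestamp-free, so identical inputs give
byte-identical files.

`runExtract()` binds the stages and writes the bundle plus a JSON report;
`inst/scripts/chemharvest.R` wraps it for the shell with the exit-code
policy described in the README.

## The fixture generator, and what passing tests mean

`generateDocument()` fabricates an SI-style document from idealized
geometries (`toyMoleculeLibrary()`: water, methane, ethane, benzene,
dimethyl sulfide, built from standard bond lengths/angles), each randomly
rotated and translated within a single-digit-ångström box, rendered in a
chosen dialect, decimal count (1–10) and first-column style (symbols,
atomic numbers, or a per-atom mix including lower-case symbols), with a
label line above each molecule, interleaved prose/energy noise, and
pagination that inserts a blank line and bare page number at each break
plus a recurring header once the document reaches 3 pages — so breaks
land inside coordinate runs and exercise the healing rule. Everything is
recorded in a manifest (per-line roles, exact coordinate text, expected
counts), generation is byte-deterministic under the seed, and the same
pages can be rendered to a real PDF through the package's writer to
exercise the PDF path end to end.

What the generator does *not* emulate: publisher-specific typography and
multi-column layouts, scanned/raster pages, Z-matrix or fractional
crystallographic coordinate blocks, ligature and hyphenation artifacts,
and coordinate tables with boundary signals weaker than a separating text
line. Noise text is synthesized from the content classes real SI
documents contain (method statements, energies, thermochemistry), not
copied from any published supplement. Consequently, green tests certify
the pipeline's contracts — recovery, healing, conservation, round-trips —
on documents with these structural features; they do not certify any
particular publisher's PDF quirks, and badly mangled real-world exports
can still require manual text export first.

Validation scales, chosen to keep the default suite fast while covering
the parameter space: 50 seeded fixtures spanning all three dialects ×
three element styles × decimals {2,4,6,8} × page lengths 5–18; 100 random
3–40-atom blocks against the brute-force bond oracle; ≥ 1000 generated
lines for the pattern-fidelity subset property; cross-toolkit
connectivity checks of the five library molecules against OpenBabel
(via ChemmineOB), which agrees exactly on all five; SDF re-read through
ChemmineR as the independent reader. The complete suite runs in well
under a minute.

## Numerical and edge-case choices

* Boundary equality at the cutoff is bonded (strictly-greater is
  non-bonding).
* Coordinates are parsed by R's decimal reader and re-rendered exactly at
  the source's digit count; parsed magnitudes are capped at 10⁶ Å as a
  sanity bound.
* Angles clamp the cosine into [−1, 1] before `acos` to absorb rounding;
  zero-length vectors are explicit errors, not NaNs.
* Empty documents are valid inputs everywhere (one page, zero lines;
  empty reports; empty output files), not errors.
* The generator restores the caller's RNG state, so fixture creation
  inside an analysis never perturbs the surrounding stream.

## Limitations

Beyond the generator's stated non-goals: the PDF extractor handles the
simple single-column class only; molecules split by anything other than
the modelled page furniture (e.g. a figure caption inside a run) will
fragment, surfacing as `isolated_atom`/short-block warnings rather than
silent corruption; connectivity is single-bond only and protonation/charge
states are not inferred; and documents whose coordinate tables are images
rather than text are entirely out of reach — those need OCR, which this
package deliberately does not attempt.
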