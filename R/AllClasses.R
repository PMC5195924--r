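#' @import methods
NULL

#' DocumentText: a page-aware sequence of text lines
#'
#' Ordered pages of ordered lines extracted from a PDF or plain-text file,
#' with every line addressable by its (page, line) position. Line order
#' follows the visual top-to-bottom order of the source.
#'
#' @slot sourceKind `"pdf"` or `"text"`.
#' @slot pages list of character vectors, one per page, in page order.
#'   Page numbers are implicit 1-based positions; no line contains an
#'   end-of-line character.
#' @export
setClass("DocumentText",
  representation(sourceKind = "character", pages = "list"))

setValidity("DocumentText", function(object) {
  msg <- character(0)
  if (length(object@sourceKind) != 1L ||
      !object@sourceKind %in% c("pdf", "text"))
    msg <- c(msg, "sourceKind must be 'pdf' or 'text'")
  if (!all(vapply(object@pages, is.character, logical(1))))
    msg <- c(msg, "pages must be a list of character vectors")
  if (any(vapply(object@pages, function(p) any(grepl("[\r\n]", p)),
                 logical(1))))
    msg <- c(msg, "lines must not contain end-of-line characters")
  if (length(msg)) msg else TRUE
})

#' MoleculeBlock: one candidate molecule
#'
#' A maximal run of coordinate lines recovered from a document, in document
#' order, with an optional label captured from the preceding text.
#'
#' @slot blockId 1-based integer position in document order.
#' @slot atoms data.frame with columns `element`, `x`, `y`, `z`,
#'   `token` (the raw first-column text), `page`, `line`, `text`
#'   (the raw source line); one row per atom, in document order.
#' @slot label length-0 or length-1 character.
#' @slot flags character vector, subset of
#'   `c("spans_pages", "suspicious_serial_elements")`.
#' @export
setClass("MoleculeBlock",
  representation(blockId = "integer", atoms = "data.frame",
                 label = "character", flags = "character"))

setValidity("MoleculeBlock", function(object) {
  msg <- character(0)
  need <- c("element", "x", "y", "z", "token", "page", "line", "text")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:",
                        paste(need, collapse = ", ")))
  if (nrow(object@atoms) < 1L) msg <- c(msg, "atoms must be non-empty")
  if (length(object@label) > 1L) msg <- c(msg, "label must be length 0 or 1")
  bad <- setdiff(object@flags,
                 c("spans_pages", "suspicious_serial_elements"))
  if (length(bad)) msg <- c(msg, paste("unknown flags:", paste(bad, collapse = ",")))
  if (length(msg)) msg else TRUE
})

#' BondMatrix: distance-perceived covalent connectivity
#'
#' Symmetric 0/1 adjacency over the atoms of one [MoleculeBlock-class],
#' with the per-bond interatomic distances and the tolerance that was added
#' to the covalent-radii sums.
#'
#' @slot n atom count.
#' @slot adjacency n-by-n symmetric 0/1 integer matrix, zero diagonal.
#' @slot bonds data.frame with columns `i`, `j` (1-based atom indices,
#'   i < j) and `distance` (angstrom).
#' @slot tolerance the tolerance (angstrom) used, default 0.35.
#' @export
setClass("BondMatrix",
  representation(n = "integer", adjacency = "matrix", bonds = "data.frame",
                 tolerance = "numeric"))

setValidity("BondMatrix", function(object) {
  msg <- character(0)
  a <- object@adjacency
  if (!all(dim(a) == object@n)) msg <- c(msg, "adjacency must be n x n")
  else {
    if (any(diag(a) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    if (!isTRUE(all.equal(a, t(a)))) msg <- c(msg, "adjacency must be symmetric")
    if (!all(a %in% c(0, 1))) msg <- c(msg, "adjacency must be 0/1")
    b <- object@bonds
    if (nrow(b)) {
      if (any(b$i >= b$j)) msg <- c(msg, "bonds must have i < j")
      if (any(a[cbind(b$i, b$j)] != 1))
        msg <- c(msg, "bonds list and adjacency disagree")
    }
    if (sum(a) != 2L * nrow(object@bonds))
      msg <- c(msg, "bond count and adjacency disagree")
  }
  if (length(msg)) msg else TRUE
})

#' GeometryReport: bond lengths, angles, dihedrals and consistency warnings
#'
#' @slot lengths data.frame `i`, `j`, `distance` (angstrom).
#' @slot angles data.frame `i`, `apex`, `k`, `degrees`; apex is the central
#'   atom, angles in \[0, 180\].
#' @slot dihedrals data.frame `i`, `j`, `k`, `l`, `degrees`; signed,
#'   in (-180, 180\].
#' @slot warnings data.frame `type` (`isolated_atom`, `atom_clash`,
#'   `hypervalent`), `atoms` (comma-joined 1-based indices), `detail`.
#' @export
setClass("GeometryReport",
  representation(lengths = "data.frame", angles = "data.frame",
                 dihedrals = "data.frame", warnings = "data.frame"))

#' CovalentRadiiTable: named per-element covalent radii
#'
#' @slot name identifier of the radii set.
#' @slot radii named numeric vector, element symbol -> radius (angstrom).
#'   Looking up an uncovered element is an explicit error, never a default.
#' @export
setClass("CovalentRadiiTable",
  representation(name = "character", radii = "numeric"))

setValidity("CovalentRadiiTable", function(object) {
  msg <- character(0)
  r <- object@radii
  if (is.null(names(r)) || any(!nzchar(names(r))))
    msg <- c(msg, "radii must be a named vector")
  if (any(r <= 0 | r >= 3.0))
    msg <- c(msg, "all radii must be > 0 and < 3.0 angstrom")
  want <- elementSymbol(1:96)
  miss <- setdiff(want, names(r))
  if (length(miss))
    msg <- c(msg, paste("radii must cover Z=1..96; missing:",
                        paste(miss, collapse = ",")))
  if (length(msg)) msg else TRUE
})

#' ExtractionReport: counts and warnings for one extraction run
#'
#' @slot delimiter the concrete delimiter used.
#' @slot nLines,nCoordinateLines,nBlocks,nAtoms document-level counts.
#' @slot blockAtomCounts integer vector, atoms per kept block.
#' @slot warnings character vector (dropped runs, serial-element blocks, ...).
#' @export
setClass("ExtractionReport",
  representation(delimiter = "character", nLines = "integer",
                 nCoordinateLines = "integer", nBlocks = "integer",
                 nAtoms = "integer", blockAtomCounts = "integer",
                 warnings = "character"))

setValidity("ExtractionReport", function(object) {
  msg <- character(0)
  if (sum(object@blockAtomCounts) != object@nAtoms)
    msg <- c(msg, "sum of per-block atom counts must equal nAtoms")
  if (any(c(object@nLines, object@nCoordinateLines, object@nBlocks,
            object@nAtoms) < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' FixtureManifest: ground truth for a generated document
#'
#' Everything needed to check an extraction against the generator's intent:
#' per-line roles, the exact coordinate text of every molecule, and the
#' expected block/atom counts.
#'
#' @slot seed integer seed that reproduces the fixture byte-identically.
#' @slot delimiter `"space"`, `"comma"` or `"tab"`.
#' @slot decimals fractional digits used for coordinates (1..10).
#' @slot elementStyle `"symbol"`, `"atomic_number"` or `"mixed"`.
#' @slot molecules list; each element has `label`, `name`, `elements`,
#'   `coordText` (exact emitted lines) and `xyz` (the rounded numeric
#'   coordinates those lines encode).
#' @slot lineTable data.frame `page`, `line`, `text`, `role`
#'   (coordinate/label/noise/header/pagenum/blank), `mol` (molecule index
#'   or NA).
#' @slot pageLength content lines per page used at pagination.
#' @slot expectedBlocks,expectedAtoms expected extraction counts.
#' @export
setClass("FixtureManifest",
  representation(seed = "integer", delimiter = "character",
                 decimals = "integer", elementStyle = "character",
                 molecules = "list", lineTable = "data.frame",
                 pageLength = "integer", expectedBlocks = "integer",
                 expectedAtoms = "integer"))

setValidity("FixtureManifest", function(object) {
  msg <- character(0)
  if (object@expectedBlocks != length(object@molecules))
    msg <- c(msg, "expectedBlocks must equal number of molecules")
  na <- sum(vapply(object@molecules, function(m) length(m$elements),
                   integer(1)))
  if (object@expectedAtoms != na)
    msg <- c(msg, "expectedAtoms inconsistent with molecule list")
  if (length(msg)) msg else TRUE
})
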