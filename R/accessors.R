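#' @rdname DocumentText-class
#' @param doc a [DocumentText-class].
#' @export
docPages <- function(doc) doc@pages

#' Number of pages / lines of a document
#' @rdname DocumentText-class
#' @export
nPages <- function(doc) length(doc@pages)

#' @rdname DocumentText-class
#' @export
nLines <- function(doc) sum(lengths(doc@pages))

#' Flatten a document to a (page, line, text) table
#'
#' @param doc a [DocumentText-class].
#' @return data.frame with columns `page`, `line`, `text`, one row per line
#'   in document order.
#' @export
docLines <- function(doc) {
  n <- lengths(doc@pages)
  data.frame(page = rep.int(seq_along(doc@pages), n),
             line = unlist(lapply(n, seq_len), use.names = FALSE),
             text = unlist(doc@pages, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Retrieve one line by (page, line) address
#' @rdname docLines
#' @param page,line 1-based page and within-page line numbers.
#' @export
docLine <- function(doc, page, line) {
  stopifnot(page >= 1L, page <= nPages(doc))
  p <- doc@pages[[page]]
  stopifnot(line >= 1L, line <= length(p))
  p[[line]]
}

#' @rdname MoleculeBlock-class
#' @param block a [MoleculeBlock-class].
#' @export
blockAtoms <- function(block) block@atoms

#' @rdname MoleculeBlock-class
#' @export
blockId <- function(block) block@blockId

#' @rdname MoleculeBlock-class
#' @export
blockLabel <- function(block)
  if (length(block@label)) block@label else NA_character_

#' @rdname MoleculeBlock-class
#' @export
blockFlags <- function(block) block@flags

#' First and last source address of a block
#' @rdname MoleculeBlock-class
#' @return `blockSpan`: data.frame of two rows (`first`, `last`) with
#'   columns `page`, `line`.
#' @export
blockSpan <- function(block) {
  a <- block@atoms
  data.frame(page = c(a$page[1L], a$page[nrow(a)]),
             line = c(a$line[1L], a$line[nrow(a)]),
             row.names = c("first", "last"))
}

#' @rdname BondMatrix-class
#' @param bm a [BondMatrix-class].
#' @export
bonds <- function(bm) bm@bonds

#' @rdname BondMatrix-class
#' @export
adjacency <- function(bm) bm@adjacency

#' @rdname BondMatrix-class
#' @export
nBonds <- function(bm) nrow(bm@bonds)

setMethod("show", "DocumentText", function(object) {
  cat(sprintf("DocumentText (%s): %d page(s), %d line(s)\n",
              object@sourceKind, nPages(object), nLines(object)))
})

setMethod("show", "MoleculeBlock", function(object) {
  lab <- if (length(object@label)) object@label else "<no label>"
  cat(sprintf("MoleculeBlock %d: %d atoms (%s)  label: %s\n",
              object@blockId, nrow(object@atoms),
              paste(unique(object@atoms$element), collapse = ","), lab))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "BondMatrix", function(object) {
  cat(sprintf("BondMatrix: %d atoms, %d bonds (tolerance %.2f A)\n",
              object@n, nrow(object@bonds), object@tolerance))
})

setMethod("show", "CovalentRadiiTable", function(object) {
  cat(sprintf("CovalentRadiiTable '%s': %d elements (%.2f..%.2f A)\n",
              object@name, length(object@radii),
              min(object@radii), max(object@radii)))
})

setMethod("show", "ExtractionReport", function(object) {
  cat(sprintf(
    "ExtractionReport: delimiter=%s lines=%d coordinate-lines=%d blocks=%d atoms=%d\n",
    object@delimiter, object@nLines, object@nCoordinateLines,
    object@nBlocks, object@nAtoms))
  if (length(object@warnings))
    cat("  warnings:\n", paste("   -", object@warnings, collapse = "\n"), "\n")
})

setMethod("show", "FixtureManifest", function(object) {
  cat(sprintf(
    "FixtureManifest: seed=%d %s/%s decimals=%d, %d molecule(s), %d atom(s)\n",
    object@seed, object@delimiter, object@elementStyle, object@decimals,
    object@expectedBlocks, object@expectedAtoms))
})
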