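# Grouping coordinate lines into molecule blocks, healing page-break
# interruptions, and attaching nearby text labels.

# Per-line classification shared by segmentation, labelling and reporting.
# "Ignorable" lines are the page furniture that may interrupt a molecule's
# coordinate run without splitting it: empty lines, bare integers (page
# numbers) and running headers/footers, operationalized as a line whose
# text recurs on >= 3 distinct pages.
.classifyLines <- function(doc, delim) {
  flat <- docLines(doc)
  p <- .parseLines(flat$text, delim)
  flat$isCoord <- p$ok
  flat$element <- p$element
  flat$x <- p$x; flat$y <- p$y; flat$z <- p$z
  flat$token <- p$token
  flat$isBlank <- grepl("^[ \t]*$", flat$text)
  flat$isBareInt <- grepl("^ *[0-9]+ *$", flat$text) & !flat$isCoord
  recur <- character(0)
  if (nrow(flat)) {
    keyed <- flat[!flat$isBlank, c("page", "text")]
    if (nrow(keyed)) {
      keyed <- unique(keyed)
      cnt <- table(keyed$text)
      recur <- names(cnt)[cnt >= 3L]
    }
  }
  flat$isRecurring <- flat$text %in% recur & !flat$isCoord
  flat$isIgnorable <- !flat$isCoord &
    (flat$isBlank | flat$isBareInt | flat$isRecurring)
  flat
}

#' Segment a document into molecule blocks
#'
#' A block is a maximal run of coordinate lines. A run is not terminated by
#' an ignorable interruption -- empty lines, bare-integer page numbers, and
#' running headers/footers (text recurring on >= 3 distinct pages) --
#' provided coordinates resume within 5 non-coordinate lines; any other
#' non-coordinate line ends the block. This heals molecules split by page
#' breaks (the pagination failure mode where a few atoms carry forward into
#' the next molecule). Runs shorter than `minAtoms` are dropped and
#' recorded as warnings, as are runs whose first-column tokens form the
#' ascending serial sequence 1, 2, 3, ... (numeric-table noise, not
#' elements).
#'
#' @param doc a normalized [DocumentText-class].
#' @param delim concrete delimiter: `"space"`, `"comma"` or `"tab"`.
#' @param minAtoms minimum atoms per kept block (default 2; single free
#'   atoms are indistinguishable from numeric-table noise).
#' @return list of [MoleculeBlock-class] with contiguous `blockId` from 1,
#'   carrying attributes `warnings` (character) and `nCoordinateLines`
#'   (all coordinate lines seen, kept or dropped).
#' @export
segmentBlocks <- function(doc, delim = c("space", "comma", "tab"),
                          minAtoms = 2L) {
  delim <- match.arg(delim)
  stopifnot(minAtoms >= 1L)
  cls <- .classifyLines(doc, delim)
  N <- nrow(cls)
  runs <- list()
  cur <- integer(0)
  i <- 1L
  while (i <= N) {
    if (cls$isCoord[i]) { cur <- c(cur, i); i <- i + 1L; next }
    if (length(cur)) {
      j <- i; gap <- 0L; healable <- TRUE
      while (j <= N && !cls$isCoord[j]) {
        gap <- gap + 1L
        if (gap > 5L || !cls$isIgnorable[j]) { healable <- FALSE; break }
        j <- j + 1L
      }
      if (healable && j <= N && cls$isCoord[j]) { i <- j; next }
      runs[[length(runs) + 1L]] <- cur
      cur <- integer(0)
    }
    i <- i + 1L
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur

  blocks <- list()
  warnings <- character(0)
  for (run in runs) {
    a <- cls[run, c("element", "x", "y", "z", "token", "page", "line",
                    "text")]
    rownames(a) <- NULL
    n <- nrow(a)
    at <- sprintf("page %d line %d", a$page[1L], a$line[1L])
    serial <- all(grepl("^[0-9]+$", a$token)) &&
      identical(a$token, as.character(seq_len(n)))
    if (serial) {
      warnings <- c(warnings, sprintf(
        "dropped %d-line run at %s: first-column tokens are the ascending serial sequence 1..%d (flag: suspicious_serial_elements)",
        n, at, n))
      next
    }
    if (n < minAtoms) {
      warnings <- c(warnings, sprintf(
        "dropped %d-atom run at %s: fewer than min_atoms=%d", n, at,
        minAtoms))
      next
    }
    flags <- character(0)
    if (a$page[1L] != a$page[n]) flags <- c(flags, "spans_pages")
    blocks[[length(blocks) + 1L]] <-
      new("MoleculeBlock", blockId = length(blocks) + 1L, atoms = a,
          label = character(0), flags = flags)
  }
  attr(blocks, "warnings") <- warnings
  attr(blocks, "nCoordinateLines") <- sum(cls$isCoord)
  attr(blocks, "delimiter") <- delim
  blocks
}

#' Attach labels to molecule blocks
#'
#' The label is the nearest preceding non-empty, non-coordinate,
#' non-ignorable line within 3 lines of the block start (in document
#' order), truncated to 80 characters; absent if no such line exists.
#' Labels never alter atoms.
#'
#' @param blocks list of [MoleculeBlock-class] from [segmentBlocks()].
#' @param doc the same normalized [DocumentText-class].
#' @param delim the delimiter used at segmentation (defaults to the
#'   attribute stored on `blocks`).
#' @return the blocks, with labels filled where found.
#' @export
attachLabels <- function(blocks, doc, delim = attr(blocks, "delimiter")) {
  if (is.null(delim)) stop("delim is required when blocks carry no attribute")
  cls <- .classifyLines(doc, delim)
  key <- paste(cls$page, cls$line)
  for (b in seq_along(blocks)) {
    a <- blocks[[b]]@atoms
    idx <- match(paste(a$page[1L], a$line[1L]), key)
    if (idx <= 1L) next
    cand <- rev(seq.int(max(1L, idx - 3L), idx - 1L))
    for (k in cand) {
      if (!cls$isBlank[k] && !cls$isCoord[k] && !cls$isIgnorable[k]) {
        blocks[[b]]@label <- substr(cls$text[k], 1L, 80L)
        break
      }
    }
  }
  blocks
}

#' Aggregate an extraction report
#'
#' @param doc the normalized [DocumentText-class].
#' @param delim concrete delimiter used.
#' @param blocks blocks from [segmentBlocks()] (their attributes supply the
#'   dropped-run warnings and the total coordinate-line count).
#' @return an [ExtractionReport-class].
#' @export
buildReport <- function(doc, delim, blocks) {
  counts <- vapply(blocks, function(b) nrow(b@atoms), integer(1))
  nCoord <- attr(blocks, "nCoordinateLines")
  if (is.null(nCoord)) nCoord <- sum(.classifyLines(doc, delim)$isCoord)
  w <- attr(blocks, "warnings")
  if (is.null(w)) w <- character(0)
  new("ExtractionReport", delimiter = delim, nLines = nLines(doc),
      nCoordinateLines = as.integer(nCoord), nBlocks = length(blocks),
      nAtoms = as.integer(sum(counts)), blockAtomCounts = counts,
      warnings = w)
}

#' Serialize an ExtractionReport
#'
#' @param report an [ExtractionReport-class].
#' @return `reportText()`: a character vector of plain-text lines;
#'   `reportJSON()`: a JSON string.
#' @export
reportText <- function(report) {
  c(sprintf("delimiter: %s", report@delimiter),
    sprintf("lines: %d", report@nLines),
    sprintf("coordinate lines: %d", report@nCoordinateLines),
    sprintf("blocks: %d", report@nBlocks),
    sprintf("atoms: %d", report@nAtoms),
    sprintf("block %d: %d atoms", seq_along(report@blockAtomCounts),
            report@blockAtomCounts),
    if (length(report@warnings)) paste("warning:", report@warnings))
}

#' @rdname reportText
#' @export
reportJSON <- function(report) {
  jsonlite::toJSON(list(
    delimiter = report@delimiter,
    lines = report@nLines,
    coordinate_lines = report@nCoordinateLines,
    blocks = report@nBlocks,
    atoms = report@nAtoms,
    block_atom_counts = report@blockAtomCounts,
    warnings = report@warnings), auto_unbox = TRUE, pretty = TRUE)
}
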