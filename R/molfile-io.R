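# Serialization of extracted molecules: MDL SDF/MOL V2000, Gaussian job
# files, XYZ, and the plain-text bond-matrix and residual-text reports that
# complete the three-file output contract (molecule files, bond matrix,
# non-molecular text). All writers are deterministic: identical inputs give
# byte-identical text (no timestamps).

.blockTitle <- function(block) {
  if (length(block@label) && nzchar(block@label)) block@label
  else sprintf("Mol ID %d", block@blockId)
}

.molRecord <- function(block, bm) {
  a <- block@atoms
  n <- nrow(a)
  if (n > 999L)
    stop(sprintf(
      "block %d has %d atoms; the V2000 connection table is limited to 999",
      block@blockId, n))
  b <- bm@bonds
  c(.blockTitle(block),
    "  ChemHarvest",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            a$x, a$y, a$z, a$element),
    if (nrow(b)) sprintf("%3d%3d  1  0  0  0  0", b$i, b$j),
    "M  END")
}

#' Write molecules as a multi-record MDL SDF (V2000)
#'
#' One V2000 connection table per block, in `blockId` order, title line =
#' block label or `"Mol ID <id>"`, coordinates at the format's canonical 4
#' decimal places in 10-column fields, all bonds order 1, records closed by
#' `"$$$$"`. No stereo, charge or isotope fields are set.
#'
#' @param blocks list of [MoleculeBlock-class].
#' @param bondMatrices list of [BondMatrix-class], one per block.
#' @param path optional file path; when given the text is also written.
#' @return the SDF text as a single string (invisibly when `path` given).
#' @export
writeSDF <- function(blocks, bondMatrices, path = NULL) {
  stopifnot(length(blocks) == length(bondMatrices))
  recs <- unlist(lapply(seq_along(blocks), function(i)
    c(.molRecord(blocks[[i]], bondMatrices[[i]]), "$$$$")))
  .emitText(recs, path)
}

#' Write one molecule as an MDL MOL (V2000) record
#'
#' @param block a [MoleculeBlock-class].
#' @param bonds its [BondMatrix-class].
#' @inheritParams writeSDF
#' @return the MOL text (single record, no `"$$$$"` terminator).
#' @export
writeMol <- function(block, bonds, path = NULL) {
  .emitText(.molRecord(block, bonds), path)
}

#' Write one molecule as a Gaussian job file
#'
#' Route line (default a bare `"#"`), blank line, title, blank line,
#' `"<charge> <multiplicity>"`, one `element x y z` line per atom with 8
#' decimal places, terminated by a blank line.
#'
#' @param block a [MoleculeBlock-class].
#' @param route route section text.
#' @param charge integer molecular charge.
#' @param multiplicity spin multiplicity, >= 1.
#' @inheritParams writeSDF
#' @return the GJF text.
#' @export
writeGJF <- function(block, route = "#", charge = 0L, multiplicity = 1L,
                     path = NULL) {
  stopifnot(multiplicity >= 1L)
  a <- block@atoms
  .emitText(c(route, "", .blockTitle(block), "",
              sprintf("%d %d", as.integer(charge), as.integer(multiplicity)),
              sprintf("%-2s  %14.8f %14.8f %14.8f",
                      a$element, a$x, a$y, a$z),
              ""), path)
}

#' Write the plain-text bond-matrix report
#'
#' Per molecule: a header `"Mol ID <id>  atoms=<n>  bonds=<m>"`, then one
#' line per bond: `i j elem_i elem_j distance` with the distance at 3
#' decimal places.
#'
#' @inheritParams writeSDF
#' @return the report text.
#' @export
writeBondMatrixText <- function(blocks, bondMatrices, path = NULL) {
  stopifnot(length(blocks) == length(bondMatrices))
  out <- unlist(lapply(seq_along(blocks), function(k) {
    a <- blocks[[k]]@atoms
    b <- bondMatrices[[k]]@bonds
    c(sprintf("Mol ID %d  atoms=%d  bonds=%d", blocks[[k]]@blockId,
              nrow(a), nrow(b)),
      if (nrow(b)) sprintf("%3d %3d  %-2s %-2s  %.3f", b$i, b$j,
                           a$element[b$i], a$element[b$j], b$distance))
  }))
  if (is.null(out)) out <- character(0)
  .emitText(out, path)
}

#' Write the non-molecular residual text
#'
#' Every document line not consumed into any kept block, in document
#' order, under `"--- page N ---"` markers (one marker per page).
#'
#' @param doc the [DocumentText-class] the blocks came from.
#' @inheritParams writeSDF
#' @return the residual text.
#' @export
writeResidualText <- function(doc, blocks, path = NULL) {
  consumed <- character(0)
  for (b in blocks)
    consumed <- c(consumed, paste(b@atoms$page, b@atoms$line))
  out <- character(0)
  for (p in seq_along(doc@pages)) {
    out <- c(out, sprintf("--- page %d ---", p))
    lines <- doc@pages[[p]]
    keep <- !(paste(p, seq_along(lines)) %in% consumed)
    out <- c(out, lines[keep])
  }
  .emitText(out, path)
}

#' Write molecules in XYZ format
#'
#' Per block: atom-count line, comment line (label or `"Mol ID <id>"`),
#' then `element x y z` with 8 decimal places; blocks concatenated.
#'
#' @inheritParams writeSDF
#' @return the XYZ text.
#' @export
writeXYZ <- function(blocks, path = NULL) {
  out <- unlist(lapply(blocks, function(b) {
    a <- b@atoms
    c(sprintf("%d", nrow(a)), .blockTitle(b),
      sprintf("%-2s %14.8f %14.8f %14.8f", a$element, a$x, a$y, a$z))
  }))
  if (is.null(out)) out <- character(0)
  .emitText(out, path)
}

.emitText <- function(lines, path) {
  txt <- paste0(paste(lines, collapse = "\n"),
                if (length(lines)) "\n" else "")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (nzchar(txt)) writeChar(txt, con, eos = NULL)
    return(invisible(txt))
  }
  txt
}
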