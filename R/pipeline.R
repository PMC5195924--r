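# End-to-end extraction: ingest -> normalize -> delimiter resolution ->
# segmentation -> bond perception -> geometry validation -> output files.

.FORMATS <- c("sdf", "gjf", "xyz", "bonds", "residual")

#' Run the full extraction pipeline on one document
#'
#' Reads a PDF or text file, normalizes it, resolves the delimiter
#' (unless given concretely), segments molecule blocks, perceives bonds
#' with the distance rule, validates geometry, and writes the requested
#' output files next to a JSON machine report:
#' `<stem>.sdf`, `<stem>_mol<id>.gjf`, `<stem>.xyz`, `<stem>_bonds.txt`,
#' `<stem>_residual.txt`, `<stem>_report.json`.
#'
#' @param input input file path.
#' @param kind `"auto"`, `"pdf"` or `"text"`.
#' @param delimiter `"auto"` (default) or a concrete delimiter.
#' @param tolerance bond-perception tolerance in angstrom (default 0.35).
#' @param radii radii set name or file (see [covalentRadii()]).
#' @param minAtoms minimum atoms per block (default 2).
#' @param outDir output directory (created if missing).
#' @param formats subset of `c("sdf", "gjf", "xyz", "bonds", "residual")`.
#' @param route,charge,multiplicity Gaussian job header fields.
#' @param verbose log progress to stderr.
#' @return invisibly, a list with `report` ([ExtractionReport-class]),
#'   `blocks`, `bondMatrices`, `geometry` (per-block
#'   [GeometryReport-class]) and `files` (paths written).
#' @export
runExtract <- function(input, kind = c("auto", "pdf", "text"),
                       delimiter = c("auto", "space", "comma", "tab"),
                       tolerance = 0.35, radii = "cordero2008",
                       minAtoms = 2L, outDir = ".",
                       formats = .FORMATS, route = "#", charge = 0L,
                       multiplicity = 1L, verbose = FALSE) {
  kind <- match.arg(kind)
  delimiter <- match.arg(delimiter)
  stopifnot(tolerance >= 0, minAtoms >= 1L, multiplicity >= 1L)
  formats <- match.arg(formats, .FORMATS, several.ok = TRUE)
  if (!length(formats)) stop("formats must be a non-empty subset")
  say <- function(...) if (verbose) message(sprintf(...))

  doc <- normalizeLines(readDocument(input, kind))
  say("read %d page(s), %d line(s) from %s", nPages(doc), nLines(doc), input)
  if (delimiter == "auto") {
    delimiter <- detectDelimiter(doc)
    say("resolved delimiter: %s", delimiter)
  }
  table <- covalentRadii(radii)
  blocks <- segmentBlocks(doc, delimiter, minAtoms = minAtoms)
  blocks <- attachLabels(blocks, doc, delimiter)
  bondMatrices <- lapply(blocks, perceiveBonds, table = table,
                         tolerance = tolerance)
  geometry <- lapply(seq_along(blocks), function(i)
    validateGeometry(blocks[[i]], bondMatrices[[i]]))
  report <- buildReport(doc, delimiter, blocks)
  say("blocks: %d, atoms: %d, coordinate lines: %d", report@nBlocks,
      report@nAtoms, report@nCoordinateLines)

  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  stem <- tools::file_path_sans_ext(basename(input))
  files <- character(0)
  out <- function(name) file.path(outDir, name)
  if ("sdf" %in% formats) {
    writeSDF(blocks, bondMatrices, out(paste0(stem, ".sdf")))
    files <- c(files, out(paste0(stem, ".sdf")))
  }
  if ("gjf" %in% formats) for (b in seq_along(blocks)) {
    p <- out(sprintf("%s_mol%d.gjf", stem, blocks[[b]]@blockId))
    writeGJF(blocks[[b]], route = route, charge = charge,
             multiplicity = multiplicity, path = p)
    files <- c(files, p)
  }
  if ("xyz" %in% formats) {
    writeXYZ(blocks, out(paste0(stem, ".xyz")))
    files <- c(files, out(paste0(stem, ".xyz")))
  }
  if ("bonds" %in% formats) {
    writeBondMatrixText(blocks, bondMatrices, out(paste0(stem, "_bonds.txt")))
    files <- c(files, out(paste0(stem, "_bonds.txt")))
  }
  if ("residual" %in% formats) {
    writeResidualText(doc, blocks, out(paste0(stem, "_residual.txt")))
    files <- c(files, out(paste0(stem, "_residual.txt")))
  }
  rp <- out(paste0(stem, "_report.json"))
  writeLines(reportJSON(report), rp)
  files <- c(files, rp)
  say("wrote: %s", paste(basename(files), collapse = ", "))

  invisible(list(report = report, blocks = blocks,
                 bondMatrices = bondMatrices, geometry = geometry,
                 files = files))
}
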