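# Synthetic supplementary-style documents with ground-truth manifests.
# Every pipeline stage is testable against these without downloading any
# real article supplement: the generator emulates the structure such
# documents share -- labelled Cartesian coordinate runs in several
# delimiter dialects, interleaved with prose, energy statements, page
# numbers and running headers, with page breaks that may fall inside a
# molecule's coordinate run. Noise text is synthesized from those content
# classes, never copied from any published supplement.

# place 3 hydrogens tetrahedrally on carbon `C`, pointing away from `from`
.methylH <- function(C, from, phase = 0, L = 1.09) {
  u <- C - from; u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .cross3(u, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross3(u, e1)
  t(vapply(phase + c(0, 120, 240) * pi / 180, function(phi)
    C + L * (u / 3 + sqrt(8) / 3 * (cos(phi) * e1 + sin(phi) * e2)),
    numeric(3)))
}

#' Idealized small-molecule geometries
#'
#' A toy library built from standard bond lengths and angles: water,
#' methane, ethane, benzene and dimethyl sulfide. Each entry carries the
#' bond count expected under default distance-rule perception.
#'
#' @return named list; each element has `elements` (symbols), `xyz`
#'   (n x 3 matrix, angstrom) and `expectedBonds` (integer).
#' @examples
#' lib <- toyMoleculeLibrary()
#' names(lib)
#' lib$water$expectedBonds
#' @export
toyMoleculeLibrary <- function() {
  out <- list()

  th <- 104.52 * pi / 180
  out$water <- list(
    elements = c("O", "H", "H"),
    xyz = rbind(c(0, 0, 0), c(0.9572, 0, 0),
                0.9572 * c(cos(th), sin(th), 0)),
    expectedBonds = 2L)

  h <- 1.089 / sqrt(3)
  out$methane <- list(
    elements = c("C", rep("H", 4)),
    xyz = rbind(c(0, 0, 0), h * c(1, 1, 1), h * c(1, -1, -1),
                h * c(-1, 1, -1), h * c(-1, -1, 1)),
    expectedBonds = 4L)

  c1 <- c(0, 0, 0); c2 <- c(0, 0, 1.536)
  out$ethane <- list(
    elements = c("C", "C", rep("H", 6)),
    xyz = rbind(c1, c2,
                .methylH(c1, c2, phase = 0, L = 1.091),
                .methylH(c2, c1, phase = pi / 3, L = 1.091)),
    expectedBonds = 7L)

  ang <- seq(0, 300, by = 60) * pi / 180
  out$benzene <- list(
    elements = c(rep("C", 6), rep("H", 6)),
    xyz = rbind(1.396 * cbind(cos(ang), sin(ang), 0),
                (1.396 + 1.087) * cbind(cos(ang), sin(ang), 0)),
    expectedBonds = 12L)

  s <- c(0, 0, 0)
  csc <- 98.9 * pi / 180
  cA <- 1.81 * c(1, 0, 0)
  cB <- 1.81 * c(cos(csc), sin(csc), 0)
  out$`dimethyl sulfide` <- list(
    elements = c("S", "C", "C", rep("H", 6)),
    xyz = rbind(s, cA, cB, .methylH(cA, s), .methylH(cB, s, phase = pi / 5)),
    expectedBonds = 8L)

  out
}

#' Curated near-miss lines for parser hardening
#'
#' Lines drawn from the failure sources real supplements exhibit --
#' two-field charge/multiplicity lines, serial-number rows, energy
#' statements, ragged decimal counts, atomic-number first columns -- each
#' tagged with whether the canonical space-dialect parser accepts it as a
#' coordinate record. (A serial row like `"1 2 3 4"` is a valid record at
#' line level; the serial-sequence screen at block level is what rejects
#' such tables.)
#'
#' @return data.frame with columns `line`, `accept`, `note`.
#' @export
adversarialNoiseBank <- function() {
  data.frame(
    line = c("0 1",
             "E = -115.2",
             "E(RHF) = -115.123456",
             "Gibbs free energy = -234.567",
             "1 2 3 4",
             "N 0.1 -0.22 3.123456789",
             "C 6 0.000000 0.000000 0.000000",
             "C 0.1 0.2",
             "C 0.1 0.2 0.3 au",
             "Xx 1.0 2.0 3.0",
             "cl 0.1 0.2 0.3",
             "C 1.0E2 0.0 0.0",
             "119 0.0 0.0 0.0",
             "12",
             "S14 0.1 0.2 0.3"),
    accept = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
               FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    note = c("two numeric fields only (charge/multiplicity)",
             "first token not an element",
             "energy statement",
             "prose with a number",
             "serial row: H at (2,3,4) at line level; screened at block level",
             "ragged decimals, 9 fractional digits: valid",
             "atomic-number second column: numeric tail accepted",
             "only two coordinates",
             "non-numeric trailing text",
             "not a periodic-table symbol",
             "case-normalized Cl",
             "scientific notation rejected by default",
             "Z=119 outside the periodic table",
             "bare integer (page number)",
             "mixed alphanumeric token"),
    stringsAsFactors = FALSE)
}

.NOISE_POOL <- c(
  "Computed at the B3LYP/6-31G(d) level of theory.",
  "Optimized geometries and single point energies follow.",
  "Cartesian coordinates are given in angstroms.",
  "Thermochemical corrections were evaluated at 298.15 K.",
  "Frequency analysis confirmed each stationary point.",
  "All electronic structure calculations used a pruned integration grid.",
  "Relative energies are reported in kcal/mol.",
  "Solvent effects were modeled with a polarizable continuum.")

.noiseLine <- function() {
  k <- sample.int(length(.NOISE_POOL) + 3L, 1L)
  if (k <= length(.NOISE_POOL)) return(.NOISE_POOL[k])
  switch(k - length(.NOISE_POOL),
         sprintf("E(RHF) = %.6f hartree", -stats::runif(1, 100, 700)),
         sprintf("Zero-point correction = %.6f", stats::runif(1)),
         sprintf("Sum of electronic and thermal free energies = %.6f",
                 -stats::runif(1, 100, 700)))
}

.randomRotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

.fieldSep <- function(delimiter, padded) {
  switch(delimiter, space = " ", comma = ",", tab = "\t")
}

#' Generate a synthetic supplementary-style document
#'
#' Emits labelled coordinate runs for molecules drawn from
#' [toyMoleculeLibrary()] (randomly rotated and translated inside a
#' single-digit-angstrom box), interleaved with prose and energy noise
#' lines, paginated with running page furniture (blank line and bare page
#' number at each break, a recurring header when the document has at least
#' 3 pages), so that page breaks can fall inside a molecule's run. The
#' manifest records every line's role and the exact coordinate text, and
#' is the ground truth the extraction pipeline is tested against.
#' Deterministic: the same seed reproduces the document byte-identically.
#'
#' @param seed integer seed.
#' @param nMolecules number of molecules (>= 0).
#' @param delimiter `"space"`, `"comma"` or `"tab"`.
#' @param decimals fractional digits for coordinates (1..10); default
#'   drawn from 2..8.
#' @param elementStyle first-column style: `"symbol"`, `"atomic_number"`
#'   or `"mixed"` (per-atom mix, including occasional lower-case symbols).
#' @param pageLength content lines per page (>= 4); default drawn from
#'   12..22.
#' @param renderPdf also render the document as a single-column PDF.
#' @param pdfPath where to put the PDF (default: a tempfile).
#' @return list with `document` (a [DocumentText-class]), `text` (the
#'   full text with form-feed page breaks), `manifest` (a
#'   [FixtureManifest-class]) and `pdfPath` (or `NULL`).
#' @export
generateDocument <- function(seed, nMolecules = 3L,
                             delimiter = c("space", "comma", "tab"),
                             decimals = NULL,
                             elementStyle = c("symbol", "atomic_number",
                                              "mixed"),
                             pageLength = NULL, renderPdf = FALSE,
                             pdfPath = NULL) {
  delimiter <- match.arg(delimiter)
  elementStyle <- match.arg(elementStyle)
  stopifnot(nMolecules >= 0L)
  oldSeed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        envir = globalenv()))
  set.seed(as.integer(seed))

  if (is.null(decimals)) decimals <- sample(2:8, 1L)
  decimals <- as.integer(decimals)
  stopifnot(decimals >= 1L, decimals <= 10L)
  if (is.null(pageLength)) pageLength <- sample(12:22, 1L)
  pageLength <- as.integer(pageLength)
  if (pageLength < 4L)
    stop("pageLength must be at least 4 (room for a coordinate run plus furniture)")

  lib <- toyMoleculeLibrary()
  rightAlign <- delimiter == "space" && stats::runif(1) < 0.5

  fmtNum <- function(v) {
    if (rightAlign)
      formatC(v, width = decimals + 4L, digits = decimals, format = "f")
    else sprintf("%.*f", decimals, v)
  }

  content <- character(0); role <- character(0); mol <- integer(0)
  addLine <- function(text, r, m = NA_integer_) {
    content <<- c(content, text); role <<- c(role, r); mol <<- c(mol, m)
  }
  for (k in seq_len(sample(1:3, 1L))) addLine(.noiseLine(), "noise")

  molecules <- list()
  for (m in seq_len(nMolecules)) {
    name <- sample(names(lib), 1L)
    entry <- lib[[name]]
    xyz <- entry$xyz %*% .randomRotation() +
      matrix(stats::runif(3, -3, 3), nrow(entry$xyz), 3, byrow = TRUE)
    tokens <- switch(elementStyle,
      symbol = entry$elements,
      atomic_number = as.character(atomicNumber(entry$elements)),
      mixed = vapply(entry$elements, function(e) {
        u <- stats::runif(1)
        if (u < 0.4) e
        else if (u < 0.7) as.character(atomicNumber(e))
        else tolower(e)
      }, character(1)))
    sep <- .fieldSep(delimiter)
    xs <- fmtNum(xyz[, 1]); ys <- fmtNum(xyz[, 2]); zs <- fmtNum(xyz[, 3])
    lines <- paste(tokens, xs, ys, zs, sep = sep)
    label <- sprintf("Mol ID %d  %s  (B3LYP/6-31G(d))", m, name)
    for (k in seq_len(sample(0:2, 1L))) addLine(.noiseLine(), "noise")
    addLine(label, "label", m)
    for (k in seq_along(lines)) addLine(lines[k], "coordinate", m)
    molecules[[m]] <- list(
      label = label, name = name, elements = entry$elements,
      tokens = unname(tokens), coordText = lines,
      xyz = cbind(x = as.numeric(xs), y = as.numeric(ys),
                  z = as.numeric(zs)))
  }
  for (k in seq_len(sample(1:2, 1L))) addLine(.noiseLine(), "noise")

  # paginate: pages of `pageLength` content lines; furniture is a blank
  # line plus a bare page number at the bottom of each page, and a
  # recurring header at the top once the document is >= 3 pages
  nPages <- max(1L, ceiling(length(content) / pageLength))
  useHeader <- nPages >= 3L
  header <- "Supporting Information"
  pages <- list(); tab <- list()
  for (p in seq_len(nPages)) {
    idx <- seq.int((p - 1L) * pageLength + 1L,
                   min(p * pageLength, length(content)))
    ptext <- character(0); prole <- character(0); pmol <- integer(0)
    add <- function(t, r, m = NA_integer_) {
      ptext <<- c(ptext, t); prole <<- c(prole, r); pmol <<- c(pmol, m)
    }
    if (useHeader) add(header, "header")
    for (i in idx) add(content[i], role[i], mol[i])
    add("", "blank")
    add(as.character(p), "pagenum")
    pages[[p]] <- ptext
    tab[[p]] <- data.frame(page = p, line = seq_along(ptext), text = ptext,
                           role = prole, mol = pmol,
                           stringsAsFactors = FALSE)
  }
  lineTable <- do.call(rbind, tab)
  rownames(lineTable) <- NULL

  manifest <- new("FixtureManifest", seed = as.integer(seed),
                  delimiter = delimiter, decimals = decimals,
                  elementStyle = elementStyle, molecules = molecules,
                  lineTable = lineTable, pageLength = pageLength,
                  expectedBlocks = as.integer(nMolecules),
                  expectedAtoms = sum(vapply(molecules, function(m)
                    length(m$elements), integer(1))))

  text <- paste(vapply(pages, paste, character(1), collapse = "\n"),
                collapse = "\f")
  doc <- new("DocumentText", sourceKind = "text", pages = pages)
  pdf <- NULL
  if (renderPdf) {
    pdf <- if (is.null(pdfPath)) tempfile(fileext = ".pdf") else pdfPath
    renderFixturePDF(pages, pdf)
  }
  list(document = doc, text = text, manifest = manifest, pdfPath = pdf)
}

#' Serialize a FixtureManifest as JSON
#'
#' @param manifest a [FixtureManifest-class].
#' @return a JSON string.
#' @export
manifestJSON <- function(manifest) {
  jsonlite::toJSON(list(
    seed = manifest@seed, delimiter = manifest@delimiter,
    decimals = manifest@decimals, element_style = manifest@elementStyle,
    page_length = manifest@pageLength,
    expected_blocks = manifest@expectedBlocks,
    expected_atoms = manifest@expectedAtoms,
    molecules = lapply(manifest@molecules, function(m)
      list(label = m$label, name = m$name, elements = m$elements,
           coord_text = m$coordText)),
    lines = manifest@lineTable), auto_unbox = TRUE, pretty = TRUE)
}
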