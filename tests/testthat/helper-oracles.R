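# Independent oracles, written separately from the package internals.

# brute-force distance-rule bond perception: explicit pair loop, no
# vectorization shared with the implementation
oracleRadii <- local({
  tab <- read.table(system.file("extdata", "cordero2008_radii.txt",
                                package = "ChemHarvest"),
                    comment.char = "#", stringsAsFactors = FALSE)
  setNames(tab[[2]], tab[[1]])
})

oracleBonds <- function(elements, xyz, tolerance = 0.35) {
  n <- length(elements)
  out <- character(0)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((xyz[i, 1] - xyz[j, 1])^2 + (xyz[i, 2] - xyz[j, 2])^2 +
              (xyz[i, 3] - xyz[j, 3])^2)
    if (d <= oracleRadii[[elements[i]]] + oracleRadii[[elements[j]]] +
        tolerance)
      out <- c(out, paste(i, j, sep = "-"))
  }
  sort(out)
}

bondPairs <- function(bm) {
  b <- bonds(bm)
  sort(paste(b$i, b$j, sep = "-"))
}

# independent signed-dihedral formula (projection form)
oracleCross <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

oracleDihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  atan2(sum(oracleCross(b1, v) * w), sum(v * w)) * 180 / pi
}

# random block in a 10 A box, elements from the common organic set
randomBlock <- function(n) {
  data.frame(element = sample(c("H", "C", "N", "O", "S", "P", "F", "Cl"),
                              n, replace = TRUE),
             x = runif(n, -5, 5), y = runif(n, -5, 5), z = runif(n, -5, 5),
             stringsAsFactors = FALSE)
}

toyBlock <- function(entry, id = 1L) {
  a <- data.frame(element = entry$elements, x = entry$xyz[, 1],
                  y = entry$xyz[, 2], z = entry$xyz[, 3],
                  token = entry$elements,
                  page = 1L, line = seq_along(entry$elements),
                  text = "", stringsAsFactors = FALSE)
  new("MoleculeBlock", blockId = id, atoms = a, label = character(0),
      flags = character(0))
}

writeTextFixture <- function(text, path = tempfile(fileext = ".txt")) {
  con <- file(path, open = "wb")
  if (nzchar(text)) writeChar(text, con, eos = NULL)
  close(con)
  path
}

docFromLines <- function(..., kind = "text") {
  new("DocumentText", sourceKind = kind, pages = list(...))
}

# full recovery check of one generated fixture against its manifest
checkRecovery <- function(fx) {
  doc <- normalizeLines(fx$document)
  man <- fx$manifest
  delim <- detectDelimiter(doc)
  if (delim != man@delimiter) return(sprintf("delimiter %s != %s", delim,
                                             man@delimiter))
  blocks <- attachLabels(segmentBlocks(doc, delim), doc)
  if (length(blocks) != man@expectedBlocks)
    return(sprintf("blocks %d != %d", length(blocks), man@expectedBlocks))
  for (m in seq_along(blocks)) {
    a <- blockAtoms(blocks[[m]])
    mol <- man@molecules[[m]]
    if (nrow(a) != length(mol$elements)) return("atom count mismatch")
    if (!identical(a$element, mol$elements)) return("element mismatch")
    if (!identical(a$text, mol$coordText)) return("coordinate text mismatch")
    if (!isTRUE(all.equal(unname(as.matrix(a[, c("x", "y", "z")])),
                          unname(mol$xyz), tolerance = 1e-12)))
      return("coordinate value mismatch")
    # labels are best-effort (a page break may separate label and run
    # beyond the 3-line capture window); when captured they must be right
    lab <- blockLabel(blocks[[m]])
    if (!is.na(lab) && !identical(lab, mol$label))
      return("wrong label")
  }
  TRUE
}
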