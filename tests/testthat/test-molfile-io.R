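waterBlock <- function(id = 1L) toyBlock(toyMoleculeLibrary()$water, id)

test_that("V2000 records have correct counts, atom and bond blocks", {
  he <- new("MoleculeBlock", blockId = 1L,
            atoms = data.frame(element = "He", x = 0, y = 0, z = 0,
                               token = "He", page = 1L, line = 1L,
                               text = "He 0 0 0"),
            label = character(0), flags = character(0))
  txt <- writeMol(he, perceiveBonds(he))
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(lines[1], "Mol ID 1")
  expect_match(lines[4], "^  1  0")
  expect_match(lines[5], "^    0\\.0000    0\\.0000    0\\.0000 He")
  expect_identical(lines[6], "M  END")
  expect_false(any(lines == "$$$$"))

  w <- waterBlock()
  bm <- perceiveBonds(w)
  lines <- strsplit(writeMol(w, bm), "\n")[[1]]
  expect_match(lines[4], "^  3  2")
  bondLines <- grep("^  1  [23]  1  0", lines, value = TRUE)
  expect_length(bondLines, 2L)

  sdf <- writeSDF(list(waterBlock(1L), waterBlock(2L), waterBlock(3L)),
                  list(bm, bm, bm))
  expect_equal(sum(strsplit(sdf, "\n")[[1]] == "$$$$"), 3L)

  big <- new("MoleculeBlock", blockId = 1L,
             atoms = data.frame(element = "C", x = 3 * seq_len(1000),
                                y = 0, z = 0, token = "C", page = 1L,
                                line = seq_len(1000), text = "x"),
             label = character(0), flags = character(0))
  expect_error(writeMol(big, perceiveBonds(big)), "999")
})

test_that("an independent SDF reader recovers elements, coordinates and bonds", {
  fx <- generateDocument(seed = 77, nMolecules = 4, delimiter = "space")
  doc <- normalizeLines(fx$document)
  blocks <- attachLabels(segmentBlocks(doc, "space"), doc)
  bms <- lapply(blocks, perceiveBonds)
  f <- tempfile(fileext = ".sdf")
  writeSDF(blocks, bms, f)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(f))
  expect_equal(length(sdfs), length(blocks))
  for (k in seq_along(blocks)) {
    ab <- ChemmineR::atomblock(sdfs[[k]])
    a <- blockAtoms(blocks[[k]])
    expect_identical(gsub("_.*", "", rownames(ab)), a$element)
    expect_lt(max(abs(unname(ab[, 1:3]) -
                      as.matrix(a[, c("x", "y", "z")]))), 5.001e-5)
    bb <- ChemmineR::bondblock(sdfs[[k]])
    got <- sort(paste(pmin(bb[, 1], bb[, 2]), pmax(bb[, 1], bb[, 2]),
                      sep = "-"))
    expect_identical(got, bondPairs(bms[[k]]))
    expect_true(all(bb[, 3] == 1))
  }
})

test_that("Gaussian job files have the documented layout and round-trip", {
  w <- waterBlock()
  txt <- writeGJF(w)
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(lines[1], "#")
  expect_identical(lines[5], "0 1")
  expect_equal(sum(grepl("^[A-Z]", lines[6:8])), 3L)
  expect_identical(strsplit(writeGJF(w, charge = -1L,
                                     multiplicity = 2L), "\n")[[1]][5],
                   "-1 2")
  expect_error(writeGJF(w, multiplicity = 0L))

  # round trip through the canonical parser at 1e-8
  coords <- lines[6:8]
  for (k in seq_along(coords)) {
    r <- parseCoordinateLine(coords[k], "space")
    expect_identical(r$element, blockAtoms(w)$element[k])
    expect_equal(c(r$x, r$y, r$z),
                 as.numeric(blockAtoms(w)[k, c("x", "y", "z")]),
                 tolerance = 1e-8)
  }
})

test_that("XYZ output is count/comment/atoms and round-trips", {
  blocks <- list(waterBlock(1L), toyBlock(toyMoleculeLibrary()$methane, 2L))
  txt <- writeXYZ(blocks)
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(lines[1], "3")
  expect_identical(lines[2], "Mol ID 1")
  expect_identical(lines[6], "5")
  expect_identical(writeXYZ(list()), "")
  for (k in 3:5) {
    r <- parseCoordinateLine(lines[k], "space")
    expect_equal(c(r$x, r$y, r$z),
                 as.numeric(blockAtoms(blocks[[1]])[k - 2, c("x", "y", "z")]),
                 tolerance = 1e-8)
  }
})

test_that("the bond-matrix report is ordered i<j and atom-order-symmetric", {
  w <- waterBlock()
  txt <- writeBondMatrixText(list(w), list(perceiveBonds(w)))
  lines <- strsplit(txt, "\n")[[1]]
  expect_match(lines[1], "^Mol ID 1  atoms=3  bonds=2$")
  expect_length(lines, 3L)
  expect_identical(writeBondMatrixText(list(), list()), "")

  # swapping atom order reports the same distances with i<j kept
  a <- blockAtoms(w)
  rev <- new("MoleculeBlock", blockId = 1L, atoms = a[3:1, ],
             label = character(0), flags = character(0))
  d1 <- sort(regmatches(txt, gregexpr("[0-9]+\\.[0-9]{3}", txt))[[1]])
  t2 <- writeBondMatrixText(list(rev), list(perceiveBonds(rev)))
  d2 <- sort(regmatches(t2, gregexpr("[0-9]+\\.[0-9]{3}", t2))[[1]])
  expect_identical(d1, d2)
  b2 <- bonds(perceiveBonds(rev))
  expect_true(all(b2$i < b2$j))
})

test_that("residual text is exactly the unconsumed lines under page markers", {
  # all-coordinate document: only page markers remain
  doc <- docFromLines(sprintf("C %.3f 0.0 0.0", 3 * 1:5))
  blocks <- segmentBlocks(doc, "space")
  expect_identical(writeResidualText(doc, blocks), "--- page 1 ---\n")

  # no coordinates: the full text is reproduced
  doc <- docFromLines(c("just", "prose"), c("two", "pages"))
  txt <- writeResidualText(doc, segmentBlocks(doc, "space"))
  expect_identical(strsplit(txt, "\n")[[1]],
                   c("--- page 1 ---", "just", "prose",
                     "--- page 2 ---", "two", "pages"))

  # fixture: residual equals the manifest's non-coordinate lines exactly
  fx <- generateDocument(seed = 55, nMolecules = 3, delimiter = "tab")
  doc <- normalizeLines(fx$document)
  blocks <- segmentBlocks(doc, "tab")
  res <- strsplit(writeResidualText(doc, blocks), "\n")[[1]]
  res <- res[!grepl("^--- page [0-9]+ ---$", res)]
  tab <- fx$manifest@lineTable
  expect_identical(res, tab$text[tab$role != "coordinate"])
})

test_that("writers are deterministic and conserve atoms across formats", {
  fx <- generateDocument(seed = 91, nMolecules = 3, delimiter = "comma")
  doc <- normalizeLines(fx$document)
  blocks <- attachLabels(segmentBlocks(doc, "comma"), doc)
  bms <- lapply(blocks, perceiveBonds)
  expect_identical(writeSDF(blocks, bms), writeSDF(blocks, bms))
  expect_identical(writeXYZ(blocks), writeXYZ(blocks))

  report <- buildReport(doc, "comma", blocks)
  sdfAtoms <- sum(as.integer(substr(
    grep(" V2000$", strsplit(writeSDF(blocks, bms), "\n")[[1]],
         value = TRUE), 1, 3)))
  xyzAtoms <- sum(as.integer(grep("^[0-9]+$",
    strsplit(writeXYZ(blocks), "\n")[[1]], value = TRUE)))
  expect_equal(sdfAtoms, report@nAtoms)
  expect_equal(xyzAtoms, report@nAtoms)

  res <- strsplit(writeResidualText(doc, blocks), "\n")[[1]]
  nResidual <- sum(!grepl("^--- page [0-9]+ ---$", res))
  expect_equal(nResidual + report@nAtoms, nLines(doc))
})
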