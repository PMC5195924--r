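test_that("interatomic distances are Euclidean and symmetric", {
  expect_equal(interatomicDistance(c(0, 0, 0), c(1, 0, 0)), 1.0)
  expect_equal(interatomicDistance(c(2, 3, 4), c(2, 3, 4)), 0.0)
  expect_equal(interatomicDistance(c(1, 2, 3), c(4, 6, 3)), 5.0)
  set.seed(8)
  for (k in 1:20) {
    a <- runif(3, -5, 5); b <- runif(3, -5, 5)
    expect_identical(interatomicDistance(a, b), interatomicDistance(b, a))
  }
})

test_that("cutoffs are radius sums plus the scaling factor, erroring when uncovered", {
  tab <- covalentRadii()
  expect_equal(bondCutoff("C", "C", tab, tolerance = 0),
               2 * covalentRadius(tab, "C"))
  expect_equal(bondCutoff("H", "H", tab), 0.97)
  expect_equal(bondCutoff("C", "O", tab), 1.77)
  expect_identical(bondCutoff("C", "O", tab), bondCutoff("O", "C", tab))
  expect_error(covalentRadius(tab, "Bk"), "Bk")
  expect_error(covalentRadius(tab, "Bk"), "cordero2008")
  # user tables load from the same two-column format
  f <- tempfile()
  writeLines(paste(elementSymbol(1:96), 1.0), f)
  expect_equal(covalentRadius(covalentRadii(f), "C"), 1.0)
})

test_that("distance-rule perception finds the chemically expected bonds", {
  water <- data.frame(element = c("O", "H", "H"),
                      x = c(0, 0.9572, -0.2399), y = c(0, 0, 0.9266),
                      z = 0)
  bm <- perceiveBonds(water)
  expect_equal(bondPairs(bm), c("1-2", "1-3"))

  one <- data.frame(element = "He", x = 0, y = 0, z = 0)
  expect_equal(nBonds(perceiveBonds(one)), 0L)

  far <- data.frame(element = c("He", "He"), x = c(0, 10), y = 0, z = 0)
  expect_equal(nBonds(perceiveBonds(far)), 0L)

  # boundary: distance exactly at the cutoff is bonded
  cut <- bondCutoff("C", "C")
  pair <- data.frame(element = c("C", "C"), x = c(0, cut), y = 0, z = 0)
  expect_equal(nBonds(perceiveBonds(pair)), 1L)
  pair$x[2] <- cut + 1e-9
  expect_equal(nBonds(perceiveBonds(pair)), 0L)
})

test_that("perception agrees with the brute-force oracle on random blocks", {
  set.seed(17)
  for (k in 1:25) {
    blk <- randomBlock(sample(3:40, 1))
    bm <- perceiveBonds(blk)
    expect_identical(bondPairs(bm),
                     oracleBonds(blk$element, as.matrix(blk[, 2:4])))
    # adjacency and bond list encode the same set
    expect_equal(sum(adjacency(bm)), 2L * nBonds(bm))
  }
})

test_that("perception is monotone in tolerance and permutation-equivariant", {
  set.seed(23)
  for (k in 1:10) {
    blk <- randomBlock(sample(3:25, 1))
    b0 <- bondPairs(perceiveBonds(blk, tolerance = 0))
    b35 <- bondPairs(perceiveBonds(blk, tolerance = 0.35))
    b60 <- bondPairs(perceiveBonds(blk, tolerance = 0.60))
    expect_true(all(b0 %in% b35))
    expect_true(all(b35 %in% b60))

    p <- sample(nrow(blk))
    bmP <- perceiveBonds(blk[p, , drop = FALSE])
    bm <- perceiveBonds(blk)
    expect_identical(adjacency(bm)[p, p], adjacency(bmP))
  }
})

test_that("connectivity matches an independent cheminformatics toolkit on the toy library", {
  lib <- toyMoleculeLibrary()
  for (nm in names(lib)) {
    e <- lib[[nm]]
    xyz <- paste0(length(e$elements), "\n", nm, "\n",
                  paste(sprintf("%s %.6f %.6f %.6f", e$elements,
                                e$xyz[, 1], e$xyz[, 2], e$xyz[, 3]),
                        collapse = "\n"), "\n")
    sdf <- strsplit(ChemmineOB::convertFormat("XYZ", "SDF", xyz), "\n")[[1]]
    na <- as.integer(substr(sdf[4], 1, 3))
    nb <- as.integer(substr(sdf[4], 4, 6))
    obPairs <- sort(vapply(sdf[(4 + na + 1):(4 + na + nb)], function(l)
      paste(sort(c(as.integer(substr(l, 1, 3)),
                   as.integer(substr(l, 4, 6)))), collapse = "-"),
      character(1), USE.NAMES = FALSE))
    bm <- perceiveBonds(data.frame(element = e$elements, x = e$xyz[, 1],
                                   y = e$xyz[, 2], z = e$xyz[, 3]))
    expect_identical(bondPairs(bm), obPairs, info = nm)
  }
})

test_that("angles and dihedrals follow standard vector geometry", {
  lin <- data.frame(element = "C", x = c(0, 1, 2), y = 0, z = 0)
  expect_equal(bondAngle(lin, 1, 2, 3), 180)
  ra <- data.frame(element = "C", x = c(1, 0, 0), y = c(0, 0, 1), z = 0)
  expect_equal(bondAngle(ra, 1, 2, 3), 90)

  water <- toyMoleculeLibrary()$water
  wb <- data.frame(element = water$elements, x = water$xyz[, 1],
                   y = water$xyz[, 2], z = water$xyz[, 3])
  expect_equal(bondAngle(wb, 2, 1, 3), 104.52, tolerance = 1e-6)

  dih <- data.frame(element = "C", x = c(0, 0, 1, 1), y = c(1, 0, 0, 0),
                    z = c(0, 0, 0, 1))
  expect_equal(dihedralAngle(dih, 1, 2, 3, 4), 90)
  expect_equal(dihedralAngle(dih, 1, 2, 3, 4),
               oracleDihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 0, 1)))
  # random paths agree with the independent projection formula
  set.seed(41)
  for (k in 1:25) {
    p <- matrix(runif(12, -3, 3), 4)
    blk <- data.frame(element = "C", x = p[, 1], y = p[, 2], z = p[, 3])
    got <- tryCatch(dihedralAngle(blk, 1, 2, 3, 4), error = function(e) NA)
    if (!is.na(got))
      expect_equal(got, oracleDihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                   tolerance = 1e-9)
  }
  # degenerate geometry is an explicit error
  expect_error(bondAngle(lin, 1, 1, 2))
  expect_error(dihedralAngle(lin, 1, 2, 3, 3))
  coll <- data.frame(element = "C", x = 0:3, y = 0, z = 0)
  expect_error(dihedralAngle(coll, 1, 2, 3, 4), "degenerate")
  same <- data.frame(element = "C", x = c(0, 0, 1), y = 0, z = 0)
  expect_error(bondAngle(same, 1, 2, 3), "degenerate")
})

test_that("geometry validation lists lengths/angles/dihedrals and flags problems", {
  water <- toyMoleculeLibrary()$water
  blk <- toyBlock(water)
  bm <- perceiveBonds(blk)
  g <- validateGeometry(blk, bm)
  expect_equal(nrow(g@lengths), 2L)
  expect_equal(nrow(g@angles), 1L)
  expect_equal(g@angles$degrees, 104.52, tolerance = 1e-6)
  expect_equal(nrow(g@dihedrals), 0L)
  expect_equal(nrow(g@warnings), 0L)

  stray <- data.frame(element = c("O", "H", "H", "He"),
                      x = c(0, 0.9572, -0.2399, 15), y = c(0, 0, 0.9266, 0),
                      z = 0)
  g <- validateGeometry(stray, perceiveBonds(stray))
  expect_true("isolated_atom" %in% g@warnings$type)

  clash <- data.frame(element = c("C", "C"), x = c(0, 0.1), y = 0, z = 0)
  g <- validateGeometry(clash, perceiveBonds(clash))
  expect_true("atom_clash" %in% g@warnings$type)

  hyper <- data.frame(element = c("C", rep("H", 5)),
                      x = c(0, 1, -1, 0, 0, 0), y = c(0, 0, 0, 1, -1, 0),
                      z = c(0, 0, 0, 0, 0, 1))
  g <- validateGeometry(hyper, perceiveBonds(hyper))
  expect_true("hypervalent" %in% g@warnings$type)

  # ethane has the full dihedral complement (9 H-C-C-H paths)
  eth <- toyBlock(toyMoleculeLibrary()$ethane)
  g <- validateGeometry(eth, perceiveBonds(eth))
  expect_equal(nrow(g@dihedrals), 9L)
  expect_true(all(g@angles$degrees >= 0 & g@angles$degrees <= 180))
  expect_true(all(g@dihedrals$degrees > -180 & g@dihedrals$degrees <= 180))
})
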