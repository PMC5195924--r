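# Distance-rule bond perception: two atoms are covalently bonded iff their
# separation does not exceed the sum of their covalent radii plus a fixed
# tolerance (default 0.35 angstrom). Distances strictly above the cutoff
# are non-bonding. Bond order is always 1: the rule recovers connectivity,
# not bond multiplicity.

#' Load a covalent-radii table
#'
#' The default set is the Cordero et al. (2008) single-bond covalent radii
#' (one value per element, Z = 1..96), shipped as a plain-text two-column
#' file (symbol, radius in angstrom). A user table in the same format can
#' be given as a file path. Hybridization-specific radii are deliberately
#' not used; the perception tolerance absorbs that variation.
#'
#' @param name name of a packaged set (`"cordero2008"`) or path to a
#'   two-column text file.
#' @return a [CovalentRadiiTable-class].
#' @examples
#' tab <- covalentRadii()
#' covalentRadius(tab, c("H", "C", "O"))
#' @export
covalentRadii <- function(name = "cordero2008") {
  path <- if (file.exists(name)) name
          else system.file("extdata", paste0(name, "_radii.txt"),
                           package = "ChemHarvest")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown radii set and no such file: ", name)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("symbol", "radius"),
                           stringsAsFactors = FALSE)
  radii <- stats::setNames(tab$radius, tab$symbol)
  new("CovalentRadiiTable",
      name = if (file.exists(name)) tools::file_path_sans_ext(basename(name))
             else name,
      radii = radii)
}

#' Look up covalent radii, erroring on uncovered elements
#'
#' @param table a [CovalentRadiiTable-class].
#' @param element character vector of canonical symbols.
#' @return numeric vector of radii (angstrom). An uncovered element is an
#'   explicit error naming the element, never a silent default.
#' @export
covalentRadius <- function(table, element) {
  stopifnot(is(table, "CovalentRadiiTable"))
  r <- table@radii[element]
  if (anyNA(r))
    stop("element(s) not covered by radii table '", table@name, "': ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Euclidean distance between two atoms
#'
#' @param a,b numeric xyz triples (angstrom), or one-row data.frames with
#'   `x`, `y`, `z` columns (e.g. rows of [blockAtoms()]).
#' @return distance in angstrom.
#' @export
interatomicDistance <- function(a, b) {
  a <- .xyz(a); b <- .xyz(b)
  sqrt(sum((a - b)^2))
}

.xyz <- function(p) {
  if (is.data.frame(p)) as.numeric(p[1L, c("x", "y", "z")])
  else { stopifnot(is.numeric(p), length(p) == 3L); as.numeric(p) }
}

#' Bonding cutoff distance for an element pair
#'
#' `radius(e1) + radius(e2) + tolerance`; symmetric in its element
#' arguments. A pair at exactly the cutoff counts as bonded (only
#' distances strictly greater are non-bonding).
#'
#' @param e1,e2 canonical element symbols.
#' @param table a [CovalentRadiiTable-class].
#' @param tolerance added scaling factor in angstrom (default 0.35).
#' @return cutoff distance in angstrom.
#' @examples
#' bondCutoff("C", "O")  # 0.76 + 0.66 + 0.35
#' @export
bondCutoff <- function(e1, e2, table = covalentRadii(), tolerance = 0.35) {
  stopifnot(tolerance >= 0)
  covalentRadius(table, e1) + covalentRadius(table, e2) + tolerance
}

#' Perceive covalent bonds in a molecule block
#'
#' All-pairs evaluation of the distance rule: atoms i and j are bonded iff
#' their distance is less than or equal to
#' `bondCutoff(element_i, element_j, table, tolerance)`.
#'
#' @param block a [MoleculeBlock-class] (or a data.frame with `element`,
#'   `x`, `y`, `z` columns).
#' @param table a [CovalentRadiiTable-class].
#' @param tolerance angstrom, default 0.35.
#' @return a [BondMatrix-class].
#' @export
perceiveBonds <- function(block, table = covalentRadii(), tolerance = 0.35) {
  a <- if (is(block, "MoleculeBlock")) block@atoms else block
  stopifnot(nrow(a) >= 1L, tolerance >= 0)
  n <- nrow(a)
  r <- covalentRadius(table, a$element)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(r, r, "+") + tolerance
  adj <- (d <= cut) * 1L
  diag(adj) <- 0L
  dimnames(adj) <- NULL
  ut <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  b <- data.frame(i = as.integer(ut[, 1L]), j = as.integer(ut[, 2L]),
                  distance = d[ut])
  b <- b[order(b$i, b$j), , drop = FALSE]
  rownames(b) <- NULL
  new("BondMatrix", n = n, adjacency = adj, bonds = b,
      tolerance = tolerance)
}
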