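# Vector geometry on molecule blocks: bond lengths, valence angles, signed
# dihedrals, and the consistency checks applied to every recreated
# molecule.

.blockXYZ <- function(block) {
  a <- if (is(block, "MoleculeBlock")) block@atoms else block
  as.matrix(a[, c("x", "y", "z")])
}

.cross3 <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

#' Valence angle at an apex atom
#'
#' Angle between the vectors apex->i and apex->k, in degrees, in
#' \[0, 180\]. The middle index `j` is the apex.
#'
#' @param block a [MoleculeBlock-class] or atoms data.frame.
#' @param i,j,k distinct 1-based atom indices; `j` is the apex.
#' @return degrees.
#' @examples
#' atoms <- data.frame(element = c("H", "O", "H"),
#'                     x = c(1, 0, 0), y = c(0, 0, 1), z = 0)
#' bondAngle(atoms, 1, 2, 3)  # 90
#' @export
bondAngle <- function(block, i, j, k) {
  xyz <- .blockXYZ(block)
  stopifnot(length(unique(c(i, j, k))) == 3L,
            all(c(i, j, k) %in% seq_len(nrow(xyz))))
  u <- xyz[i, ] - xyz[j, ]
  v <- xyz[k, ] - xyz[j, ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    stop("degenerate geometry: coincident atoms give a zero vector")
  cosA <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosA))) * 180 / pi
}

#' Signed dihedral angle along a 4-atom path
#'
#' Signed angle between the planes (i, j, k) and (j, k, l) in degrees, in
#' (-180, 180\], with the IUPAC sign convention (clockwise rotation of the
#' far bond viewed along j->k is positive).
#'
#' @param block a [MoleculeBlock-class] or atoms data.frame.
#' @param i,j,k,l distinct 1-based atom indices along the path.
#' @return degrees.
#' @export
dihedralAngle <- function(block, i, j, k, l) {
  xyz <- .blockXYZ(block)
  stopifnot(length(unique(c(i, j, k, l))) == 4L,
            all(c(i, j, k, l) %in% seq_len(nrow(xyz))))
  b1 <- xyz[j, ] - xyz[i, ]
  b2 <- xyz[k, ] - xyz[j, ]
  b3 <- xyz[l, ] - xyz[k, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10 || nb2 < 1e-12)
    stop("degenerate geometry: collinear atoms leave a dihedral undefined")
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# per-element maximum degree before a hypervalent warning
.MAX_DEGREE_DEFAULT <- 8L
.MAX_DEGREE <- c(H = 1L, C = 4L, N = 4L, O = 3L, S = 6L,
                 F = 1L, Cl = 1L, Br = 1L, I = 1L, At = 1L, Ts = 1L)

#' Validate the geometry of a perceived molecule
#'
#' Lists every bond length, every valence angle at atoms with two or more
#' bonds, and every dihedral along bonded 4-atom paths, then flags
#' consistency problems: `isolated_atom` (degree-0 atom in a block of >= 2
#' atoms, the signature of a pagination fragment), `atom_clash` (any pair
#' closer than 0.4 angstrom) and `hypervalent` (degree above a per-element
#' maximum: H 1, C 4, N 4, O 3, S 6, halogens 1, others 8). Dihedrals whose
#' defining planes are degenerate (collinear atoms) are omitted from the
#' list.
#'
#' @param block a [MoleculeBlock-class] or atoms data.frame.
#' @param bonds the [BondMatrix-class] computed from `block`.
#' @return a [GeometryReport-class].
#' @export
validateGeometry <- function(block, bonds) {
  a <- if (is(block, "MoleculeBlock")) block@atoms else block
  stopifnot(is(bonds, "BondMatrix"), nrow(a) == bonds@n)
  n <- bonds@n
  adj <- bonds@adjacency
  deg <- as.integer(rowSums(adj))
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] == 1L))

  lengths <- bonds@bonds

  angles <- list()
  for (apex in seq_len(n)) {
    nb <- nbrs[[apex]]
    if (length(nb) < 2L) next
    pr <- utils::combn(nb, 2L)
    for (c2 in seq_len(ncol(pr)))
      angles[[length(angles) + 1L]] <- data.frame(
        i = pr[1L, c2], apex = apex, k = pr[2L, c2],
        degrees = bondAngle(a, pr[1L, c2], apex, pr[2L, c2]))
  }
  angles <- if (length(angles)) do.call(rbind, angles)
            else data.frame(i = integer(0), apex = integer(0),
                            k = integer(0), degrees = numeric(0))

  dihedrals <- list()
  if (nrow(bonds@bonds)) for (r in seq_len(nrow(bonds@bonds))) {
    bj <- bonds@bonds$i[r]; bk <- bonds@bonds$j[r]
    for (i in setdiff(nbrs[[bj]], bk)) for (l in setdiff(nbrs[[bk]], bj)) {
      if (i == l) next
      deg. <- tryCatch(dihedralAngle(a, i, bj, bk, l),
                       error = function(e) NA_real_)
      if (is.na(deg.)) next
      dihedrals[[length(dihedrals) + 1L]] <-
        data.frame(i = i, j = bj, k = bk, l = l, degrees = deg.)
    }
  }
  dihedrals <- if (length(dihedrals)) do.call(rbind, dihedrals)
               else data.frame(i = integer(0), j = integer(0),
                               k = integer(0), l = integer(0),
                               degrees = numeric(0))

  warn <- list()
  addWarn <- function(type, atoms, detail)
    warn[[length(warn) + 1L]] <<- data.frame(
      type = type, atoms = paste(atoms, collapse = ","), detail = detail)
  if (n >= 2L) {
    for (i in which(deg == 0))
      addWarn("isolated_atom", i,
              sprintf("atom %d (%s) has no bonds", i, a$element[i]))
    d <- as.matrix(stats::dist(.blockXYZ(a)))
    cl <- which(upper.tri(d) & d < 0.4, arr.ind = TRUE)
    if (nrow(cl)) for (r in seq_len(nrow(cl)))
      addWarn("atom_clash", cl[r, ],
              sprintf("atoms %d and %d are %.3f A apart",
                      cl[r, 1L], cl[r, 2L], d[cl[r, , drop = FALSE]]))
  }
  maxdeg <- .MAX_DEGREE[a$element]
  maxdeg[is.na(maxdeg)] <- .MAX_DEGREE_DEFAULT
  for (i in which(deg > maxdeg))
    addWarn("hypervalent", i,
            sprintf("atom %d (%s) has degree %d > %d", i, a$element[i],
                    deg[i], maxdeg[i]))
  warn <- if (length(warn)) do.call(rbind, warn)
          else data.frame(type = character(0), atoms = character(0),
                          detail = character(0))

  new("GeometryReport", lengths = lengths, angles = angles,
      dihedrals = dihedrals, warnings = warn)
}
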