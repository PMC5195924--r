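# Periodic table, Z = 1..118, IUPAC symbols.
.ELEMENT_SYMBOLS <- c(
  "H",  "He", "Li", "Be", "B",  "C",  "N",  "O",  "F",  "Ne",
  "Na", "Mg", "Al", "Si", "P",  "S",  "Cl", "Ar", "K",  "Ca",
  "Sc", "Ti", "V",  "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y",  "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I",  "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W",  "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U",  "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' Element symbol for an atomic number
#'
#' @param z integer atomic number(s) in 1..118.
#' @return character vector of symbols; `NA` outside 1..118.
#' @examples
#' elementSymbol(c(1, 6, 16))
#' @export
elementSymbol <- function(z) {
  z <- as.integer(z)
  out <- rep(NA_character_, length(z))
  ok <- !is.na(z) & z >= 1L & z <= 118L
  out[ok] <- .ELEMENT_SYMBOLS[z[ok]]
  out
}

#' Atomic number for an element symbol
#'
#' @param symbol canonical element symbol(s).
#' @return integer vector; `NA` for unknown symbols.
#' @export
atomicNumber <- function(symbol) {
  m <- match(symbol, .ELEMENT_SYMBOLS)
  as.integer(m)
}

#' Normalize a first-column token to an element symbol
#'
#' Coordinate tables interchange element symbols and atomic numbers in the
#' first column, with inconsistent letter case. An all-digit token is read
#' as an atomic number and mapped to its symbol if 1 <= Z <= 118; an
#' alphabetic token is case-normalized (first letter upper, rest lower) and
#' accepted iff it is a periodic-table symbol; anything else (mixed tokens,
#' tokens longer than 3 characters) yields `NA`.
#'
#' @param token character vector of raw first-column tokens.
#' @return character vector of canonical symbols, `NA` where the token is
#'   not an element.
#' @examples
#' normalizeElement(c("C", "6", "cl", "Xx", "119"))
#' @export
normalizeElement <- function(token) {
  token <- as.character(token)
  out <- rep(NA_character_, length(token))
  n <- nchar(token)
  ok <- !is.na(token) & n >= 1L & n <= 3L
  isNum <- ok & grepl("^[0-9]+$", token)
  out[isNum] <- elementSymbol(as.integer(token[isNum]))
  isAlpha <- ok & !isNum & grepl("^[A-Za-z]+$", token)
  if (any(isAlpha)) {
    t2 <- token[isAlpha]
    t2 <- paste0(toupper(substr(t2, 1L, 1L)), tolower(substring(t2, 2L)))
    t2[!(t2 %in% .ELEMENT_SYMBOLS)] <- NA_character_
    out[isAlpha] <- t2
  }
  out
}
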