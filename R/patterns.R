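# Line classification: the published reference patterns (kept verbatim as a
# fidelity baseline) and the canonical coordinate-line grammar that the
# pipeline actually uses.

# Reference regular expressions, byte-identical to the published ones (the
# host-language doubled backslashes collapsed to single regex backslashes).
# The permissive ".{1,2}" wildcards are intentionally NOT repaired: these
# strings are quotable artifacts, and the strict grammar lives in
# parseCoordinateLine() instead.
.PAPER_PATTERNS <- c(
  space_dialect =
    "^[A-Za-z0-9]{1,2}\\s+-{0,1}.{1,2}[0-9]{1,8}\\s+-{0,1}.{1,2}[0-9]{1,8}.{1,}",
  comma_dialect =
    "^[A-Za-z0-9]{1,2}\\,[0]{0,1}[\\,]{0,1}-{0,1}.{1,2}[0-9]{1,10}\\,-{0,1}.{1,2}[0-9]{1,10}.{1,}")

#' The verbatim reference patterns for coordinate lines
#'
#' Two regular expressions published with the original extraction tool, one
#' per delimiter dialect, preserved byte-identically as a fidelity
#' reference. They are deliberately permissive (`.{1,2}` wildcards where a
#' sign/decimal point is expected); the strict canonical grammar is
#' [parseCoordinateLine()].
#'
#' @param patternId `"space_dialect"` or `"comma_dialect"`.
#' @return the regular-expression string.
#' @export
paperPattern <- function(patternId = c("space_dialect", "comma_dialect")) {
  patternId <- match.arg(patternId)
  unname(.PAPER_PATTERNS[patternId])
}

#' Match a line against a verbatim reference pattern
#'
#' Applies the published pattern with full-string (anchored) match
#' semantics, i.e. the whole line must match, exactly as a
#' `String.matches()`-style engine would evaluate it.
#'
#' @param line character vector of normalized lines.
#' @param patternId `"space_dialect"` or `"comma_dialect"`.
#' @return logical vector.
#' @examples
#' matchPaperPattern("C 1.46988100 -0.00902000 0.00000000", "space_dialect")
#' @export
matchPaperPattern <- function(line,
                              patternId = c("space_dialect", "comma_dialect")) {
  patternId <- match.arg(patternId)
  pat <- paste0("^(?:", .PAPER_PATTERNS[patternId], ")$")
  grepl(pat, line, perl = TRUE)
}

# fixed-decimal numeric field: optional sign, digits, optionally a decimal
# point with 1-10 fractional digits; scientific notation excluded
.NUM_FIELD <- "^[+-]?[0-9]+(\\.[0-9]{1,10})?$"
.NUM_FIELD_SCI <- "^[+-]?[0-9]+(\\.[0-9]{1,10})?([eE][+-]?[0-9]{1,3})?$"

.splitFields <- function(line, delim) {
  switch(delim,
    space = strsplit(sub("^ +", "", line), " +"),
    comma = lapply(strsplit(line, ",", fixed = TRUE),
                   function(f) gsub("^[ \t]+|[ \t]+$", "", f)),
    tab   = lapply(strsplit(line, "\t+"),
                   function(f) gsub("^ +| +$", "", f)),
    stop("delim must be 'space', 'comma' or 'tab'"))
}

# Vectorized canonical classification. Returns a data.frame with one row
# per line: ok, element, x, y, z, token.
.parseLines <- function(lines, delim, allowScientific = FALSE) {
  numRe <- if (allowScientific) .NUM_FIELD_SCI else .NUM_FIELD
  fields <- .splitFields(lines, delim)
  n <- length(lines)
  out <- data.frame(ok = logical(n),
                    element = rep(NA_character_, n),
                    x = rep(NA_real_, n), y = rep(NA_real_, n),
                    z = rep(NA_real_, n),
                    token = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    f <- f[nzchar(f)]
    if (length(f) < 4L) next
    el <- normalizeElement(f[1L])
    if (is.na(el)) next
    rest <- f[-1L]
    if (!all(grepl(numRe, rest, perl = TRUE))) next
    xyz <- as.numeric(rest[1:3])
    if (any(!is.finite(xyz)) || any(abs(xyz) >= 1e6)) next
    out$ok[i] <- TRUE
    out$element[i] <- el
    out$x[i] <- xyz[1L]; out$y[i] <- xyz[2L]; out$z[i] <- xyz[3L]
    out$token[i] <- f[1L]
  }
  out
}

#' Parse one line as an atomic-coordinate record
#'
#' The canonical grammar: a first token that normalizes to an element
#' (symbol or atomic number, see [normalizeElement()]), then at least three
#' numeric fields in fixed-decimal form (optional sign, digits, optional
#' decimal point with 1-10 fractional digits), separated by the given
#' delimiter. Runs of spaces collapse in the space dialect; spaces around
#' commas/tabs are tolerated. The first three numeric fields are x, y, z
#' (angstrom); any extra trailing fields must also be numeric (e.g. a
#' symbol + atomic-number + x y z layout), otherwise the line is rejected.
#' Lines with only two numeric fields (a charge/multiplicity line such as
#' `"0 1"`) are rejected. Total: never raises on any input line.
#'
#' @param line a single normalized line.
#' @param delim `"space"`, `"comma"` or `"tab"`.
#' @param allowScientific accept scientific-notation coordinates
#'   (default `FALSE`; the published patterns cannot match them).
#' @return a one-row data.frame with columns `element`, `x`, `y`, `z`,
#'   `token`, or `NULL` if the line is not a coordinate record.
#' @examples
#' parseCoordinateLine("C 0.00000000 0.00000000 0.00000000", "space")
#' parseCoordinateLine("16,0.0,-1.2345678,2.3456789", "comma")
#' parseCoordinateLine("Gibbs free energy = -234.567", "space")
#' @export
parseCoordinateLine <- function(line, delim = c("space", "comma", "tab"),
                                allowScientific = FALSE) {
  delim <- match.arg(delim)
  stopifnot(length(line) == 1L)
  p <- .parseLines(line, delim, allowScientific)
  if (!p$ok) return(NULL)
  p[, c("element", "x", "y", "z", "token")]
}

#' Resolve the delimiter dialect of a document
#'
#' Tries each concrete delimiter, counts the lines the canonical parser
#' accepts under it, and returns the delimiter with the maximal count.
#' Ties break by the fixed priority space > comma > tab; a document with no
#' coordinate lines resolves to `"space"`.
#'
#' @param doc a [DocumentText-class] (normalized).
#' @return `"space"`, `"comma"` or `"tab"`.
#' @export
detectDelimiter <- function(doc) {
  stopifnot(is(doc, "DocumentText"))
  lines <- docLines(doc)$text
  counts <- vapply(c("space", "comma", "tab"),
                   function(d) sum(.parseLines(lines, d)$ok), integer(1))
  c("space", "comma", "tab")[which.max(counts)]
}
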