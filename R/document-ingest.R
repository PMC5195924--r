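#' Read a PDF or plain-text file into a DocumentText
#'
#' Plain text is read as UTF-8 with a latin-1 fallback; the whole file is a
#' single page unless form-feed characters (`\\f`) delimit pages, in which
#' case each segment becomes its own page. PDFs are read with the built-in
#' single-column text extractor: text is recovered from the content streams
#' in top-to-bottom reading order, one extractor line per rendered line.
#' Encrypted or otherwise unextractable PDFs raise a condition of class
#' `"pdfIngestError"` whose message points at the standard workaround:
#' export the PDF to plain text externally and feed the text file in.
#'
#' @param path file path.
#' @param kind `"pdf"`, `"text"`, or `"auto"` (resolve by extension:
#'   `.pdf` is PDF, everything else text).
#' @return a [DocumentText-class]. An empty file yields one page with zero
#'   lines, not an error.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("a", "b", "c"), f)
#' readDocument(f)
#' @export
readDocument <- function(path, kind = c("auto", "pdf", "text")) {
  kind <- match.arg(kind)
  if (!file.exists(path) || dir.exists(path))
    stop("file does not exist or is not readable: ", path)
  if (kind == "auto")
    kind <- if (grepl("\\.pdf$", path, ignore.case = TRUE)) "pdf" else "text"
  pages <- if (kind == "pdf") .readPDFLines(path) else .readTextPages(path)
  new("DocumentText", sourceKind = kind, pages = pages)
}

.readTextPages <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  txt <- rawToChar(raw)
  if (!all(validUTF8(txt))) {
    txt <- iconv(rawToChar(raw), from = "latin1", to = "UTF-8")
  } else {
    Encoding(txt) <- "UTF-8"
  }
  txt <- gsub("\r\n", "\n", txt, fixed = TRUE)
  txt <- gsub("\r", "\n", txt, fixed = TRUE)
  segments <- strsplit(txt, "\f", fixed = TRUE)[[1L]]
  if (length(segments) == 0L) segments <- ""
  lapply(segments, function(s) strsplit(s, "\n", fixed = TRUE)[[1L]])
}

#' Normalize the lines of a document
#'
#' PDF extractors commonly emit non-breaking spaces and typographic minus
#' signs; the coordinate grammar assumes ASCII. This replaces Unicode space
#' variants with ordinary spaces, maps Unicode minus/hyphen variants to
#' ASCII `-`, and strips trailing whitespace. Tab characters are preserved
#' (they carry the tab-delimiter dialect). Line and page structure are
#' unchanged, and the operation is idempotent.
#'
#' @param doc a [DocumentText-class].
#' @return a [DocumentText-class] with the same shape and normalized text.
#' @export
normalizeLines <- function(doc) {
  stopifnot(is(doc, "DocumentText"))
  doc@pages <- lapply(doc@pages, .normalizeText)
  doc
}

# NBSP, ogham, en/em and friends, narrow NBSP, math space, ideographic, BOM
.UNICODE_SPACES <- "(*UTF)[\\x{00A0}\\x{1680}\\x{2000}-\\x{200B}\\x{202F}\\x{205F}\\x{3000}\\x{FEFF}]"
# minus sign, hyphen variants, en/em dashes, horizontal bar
.UNICODE_MINUS <- "(*UTF)[\\x{2212}\\x{2010}-\\x{2015}]"

.normalizeText <- function(x) {
  x <- enc2utf8(x)
  x <- gsub(.UNICODE_SPACES, " ", x, perl = TRUE)
  x <- gsub(.UNICODE_MINUS, "-", x, perl = TRUE)
  sub("[ \t]+$", "", x)
}
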