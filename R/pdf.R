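# Minimal single-column PDF support.
#
# The writer renders fixture pages (one text line per rendered line,
# Helvetica, uncompressed content streams) and exists so that the PDF input
# path can be exercised end to end without any external renderer. The
# reader recovers text from simple, single-column, text-operator PDFs:
# it scans indirect objects, inflates FlateDecode streams, replays the
# Tm/Td/TD/T*/Tj/TJ text operators of each page's content stream, and
# groups strings into lines by their y position (top to bottom, then left
# to right). Multi-column layout, CID fonts, OCR and encrypted files are
# out of scope; encrypted input raises a "pdfIngestError" pointing at the
# export-to-text fallback.

.pdfEscape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("(", "\\(", x, fixed = TRUE)
  x <- gsub(")", "\\)", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

#' Render text pages as a simple single-column PDF
#'
#' One rendered line per input line, in reading order; empty lines are
#' rendered as empty strings so that line structure survives extraction.
#' Used by the fixture generator; deterministic (no timestamps or IDs).
#'
#' @param pages list of character vectors, one vector per page.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
renderFixturePDF <- function(pages, path) {
  stopifnot(is.list(pages))
  nP <- length(pages)
  # object numbering: 1 catalog, 2 pages, 3 font, then per page i:
  # page object 3+2i-1, content object 3+2i
  objs <- character(3 + 2L * nP)
  kids <- paste(sprintf("%d 0 R", 3 + 2L * seq_len(nP) - 1L),
                collapse = " ")
  objs[1] <- "<< /Type /Catalog /Pages 2 0 R >>"
  objs[2] <- sprintf("<< /Type /Pages /Kids [%s] /Count %d >>", kids, nP)
  objs[3] <- "<< /Type /Font /Subtype /Type1 /BaseFont /Helvetica >>"
  body <- character(length(objs))
  for (i in seq_len(nP)) {
    lines <- pages[[i]]
    y <- 770 - 13 * (seq_along(lines) - 1L)
    content <- c("BT", "/F1 9 Tf",
                 sprintf("1 0 0 1 56 %d Tm (%s) Tj", y, .pdfEscape(lines)),
                 "ET")
    stream <- paste(content, collapse = "\n")
    pgObj <- 3 + 2L * i - 1L
    ctObj <- 3 + 2L * i
    objs[pgObj] <- paste0(
      "<< /Type /Page /Parent 2 0 R /MediaBox [0 0 612 792] ",
      sprintf("/Resources << /Font << /F1 3 0 R >> >> /Contents %d 0 R >>",
              ctObj))
    objs[ctObj] <- sprintf("<< /Length %d >>\nstream\n%s\nendstream",
                           nchar(stream, type = "bytes"), stream)
  }
  header <- "%PDF-1.4\n"
  offsets <- integer(length(objs))
  pos <- nchar(header, type = "bytes")
  for (k in seq_along(objs)) {
    body[k] <- sprintf("%d 0 obj\n%s\nendobj\n", k, objs[k])
    offsets[k] <- pos
    pos <- pos + nchar(body[k], type = "bytes")
  }
  xrefPos <- pos
  xref <- c(sprintf("xref\n0 %d", length(objs) + 1L),
            "0000000000 65535 f ",
            sprintf("%010d 00000 n ", offsets),
            sprintf("trailer\n<< /Size %d /Root 1 0 R >>", length(objs) + 1L),
            sprintf("startxref\n%d\n%%%%EOF", xrefPos))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(paste0(header, paste(body, collapse = ""),
                   paste(xref, collapse = "\n"), "\n"),
            con, eos = NULL)
  invisible(path)
}

.pdfError <- function(msg) {
  stop(errorCondition(
    paste0(msg, "; if the file is valid, save/export it as plain text ",
           "externally and re-run with kind = \"text\""),
    class = c("pdfIngestError", "error", "condition")))
}

# Read a PDF into a list of character vectors (one per page).
.readPDFLines <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 5 || rawToChar(raw[1:5]) != "%PDF-")
    .pdfError(paste0("not a PDF file: ", path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "bytes"
  objs <- .pdfObjects(txt, raw)
  if (any(grepl("/Encrypt", vapply(objs, `[[`, "", "dict"), fixed = TRUE)) ||
      grepl("/Encrypt", .pdfTrailer(txt), fixed = TRUE))
    .pdfError(paste0("encrypted PDF cannot be extracted: ", path))
  pageOrder <- .pdfPageOrder(objs)
  if (!length(pageOrder))
    .pdfError(paste0("no page tree found in PDF: ", path))
  lapply(pageOrder, function(pg) {
    contRef <- .pdfRef(objs[[pg]]$dict, "/Contents")
    if (is.na(contRef)) return(character(0))
    co <- objs[[as.character(contRef)]]
    if (is.null(co)) return(character(0))
    stream <- .pdfStreamData(co)
    .pdfTextLines(stream)
  })
}

.pdfTrailer <- function(txt) {
  m <- gregexpr("trailer", txt, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) return("")
  substring(txt, m[length(m)], nchar(txt))
}

# Locate "<n> 0 obj ... endobj" spans; honour /Length for stream bodies so
# binary stream content cannot confuse the scan.
.pdfObjects <- function(txt, raw) {
  out <- list()
  pos <- 1L
  n <- nchar(txt)
  while (pos <= n) {
    m <- regexpr("(\\d+)\\s+\\d+\\s+obj", substring(txt, pos), perl = TRUE)
    if (m == -1L) break
    start <- pos + as.integer(m) - 1L
    hdr <- regmatches(substring(txt, pos), m)
    num <- sub("^(\\d+).*", "\\1", hdr)
    after <- start + attr(m, "match.length")
    # dictionary runs until 'stream' or 'endobj'
    rest <- substring(txt, after)
    sM <- regexpr("stream\r?\n", rest, perl = TRUE)
    eM <- regexpr("endobj", rest, fixed = TRUE)
    hasStream <- sM != -1L && (eM == -1L || sM < eM)
    if (hasStream) {
      dict <- substring(rest, 1L, as.integer(sM) - 1L)
      dataStart <- after + as.integer(sM) + attr(sM, "match.length") - 1L
      len <- suppressWarnings(as.integer(
        sub(".*?/Length\\s+(\\d+).*", "\\1", dict, perl = TRUE)))
      if (is.na(len)) {
        endM <- regexpr("endstream", substring(txt, dataStart), fixed = TRUE)
        len <- if (endM == -1L) 0L else as.integer(endM) - 2L
      }
      data <- raw[seq.int(dataStart, length.out = len)]
      tail <- substring(txt, dataStart + len)
      eM2 <- regexpr("endobj", tail, fixed = TRUE)
      endPos <- if (eM2 == -1L) n else dataStart + len + as.integer(eM2) + 5L
      out[[num]] <- list(dict = dict, data = data)
      pos <- endPos + 1L
    } else {
      endPos <- if (eM == -1L) n else after + as.integer(eM) + 5L
      dict <- substring(rest, 1L, if (eM == -1L) nchar(rest)
                        else as.integer(eM) - 1L)
      out[[num]] <- list(dict = dict, data = NULL)
      pos <- endPos + 1L
    }
  }
  out
}

.pdfStreamData <- function(obj) {
  data <- obj$data
  if (is.null(data)) return("")
  if (grepl("/FlateDecode", obj$dict, fixed = TRUE)) {
    data <- tryCatch(memDecompress(data, type = "gzip"),
                     error = function(e)
                       .pdfError("failed to inflate a content stream"))
  }
  txt <- rawToChar(data)
  Encoding(txt) <- "bytes"
  txt
}

.pdfRef <- function(dict, key) {
  m <- regmatches(dict, regexpr(
    paste0(key, "\\s+(\\d+)\\s+\\d+\\s+R"), dict, perl = TRUE))
  if (!length(m)) return(NA_integer_)
  as.integer(sub(paste0(key, "\\s+(\\d+).*"), "\\1", m, perl = TRUE))
}

.pdfPageOrder <- function(objs) {
  dicts <- vapply(objs, `[[`, "", "dict")
  pagesIdx <- which(grepl("/Type\\s*/Pages", dicts, perl = TRUE))
  kids <- character(0)
  for (i in pagesIdx) {
    m <- regmatches(dicts[i], regexpr("/Kids\\s*\\[([^]]*)\\]", dicts[i],
                                      perl = TRUE))
    if (!length(m)) next
    refs <- regmatches(m, gregexpr("(\\d+)\\s+\\d+\\s+R", m, perl = TRUE))[[1L]]
    kids <- c(kids, sub("^(\\d+).*", "\\1", refs))
  }
  kids <- kids[kids %in% names(objs)]
  # resolve nested page-tree nodes recursively (flat trees in practice)
  out <- character(0)
  for (k in kids) {
    if (grepl("/Type\\s*/Pages", objs[[k]]$dict, perl = TRUE))
      out <- c(out, .pdfPageOrder(objs[k]))
    else out <- c(out, k)
  }
  out
}

# Replay text operators of one content stream; returns lines top-to-bottom.
.pdfTextLines <- function(stream) {
  toks <- .pdfTokens(stream)
  x <- 0; y <- 0; leading <- 0
  pieces <- list()
  pending <- list()  # operand stack (strings and numbers as tokens)
  emit <- function(s) {
    pieces[[length(pieces) + 1L]] <<- list(x = x, y = y, text = s)
  }
  for (tk in toks) {
    if (tk$type %in% c("string", "number", "array", "name")) {
      pending[[length(pending) + 1L]] <- tk
      next
    }
    op <- tk$value
    nums <- function(k) {
      vals <- unlist(lapply(pending, function(t)
        if (t$type == "number") as.numeric(t$value)))
      if (length(vals) >= k) utils::tail(vals, k) else numeric(0)
    }
    if (op == "Tm") {
      v <- nums(6); if (length(v) == 6) { x <- v[5]; y <- v[6] }
    } else if (op %in% c("Td", "TD")) {
      v <- nums(2)
      if (length(v) == 2) { x <- x + v[1]; y <- y + v[2] }
      if (op == "TD" && length(v) == 2) leading <- -v[2]
    } else if (op == "TL") {
      v <- nums(1); if (length(v)) leading <- v[1]
    } else if (op == "T*") {
      y <- y - leading
    } else if (op %in% c("Tj", "'", "\"")) {
      strs <- Filter(function(t) t$type == "string", pending)
      if (length(strs)) emit(strs[[length(strs)]]$value)
    } else if (op == "TJ") {
      arrs <- Filter(function(t) t$type == "array", pending)
      if (length(arrs))
        emit(paste(arrs[[length(arrs)]]$value, collapse = ""))
    }
    pending <- list()
  }
  if (!length(pieces)) return(character(0))
  px <- vapply(pieces, `[[`, numeric(1), "x")
  py <- vapply(pieces, `[[`, numeric(1), "y")
  pt <- vapply(pieces, `[[`, character(1), "text")
  key <- round(py, 1)
  rows <- sort(unique(key), decreasing = TRUE)
  vapply(rows, function(r) {
    idx <- which(key == r)
    idx <- idx[order(px[idx])]
    paste(pt[idx], collapse = "")
  }, character(1))
}

.pdfUnescape <- function(s) {
  out <- character(0)
  i <- 1L; n <- nchar(s)
  buf <- character(0)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "\\" && i < n) {
      nx <- substr(s, i + 1L, i + 1L)
      map <- c(n = "\n", r = "\r", t = "\t", b = "\b", f = "\f",
               "(" = "(", ")" = ")", "\\" = "\\")
      if (nx %in% names(map)) {
        buf <- c(buf, map[[nx]]); i <- i + 2L
      } else if (grepl("[0-7]", nx)) {
        oct <- regmatches(substring(s, i + 1L),
                          regexpr("^[0-7]{1,3}", substring(s, i + 1L)))
        buf <- c(buf, intToUtf8(strtoi(oct, base = 8L)))
        i <- i + 1L + nchar(oct)
      } else { buf <- c(buf, nx); i <- i + 2L }
    } else { buf <- c(buf, ch); i <- i + 1L }
  }
  paste(buf, collapse = "")
}

# Tokenize a content stream into strings, numbers, names, arrays, operators.
.pdfTokens <- function(stream) {
  toks <- list()
  i <- 1L; n <- nchar(stream)
  push <- function(type, value)
    toks[[length(toks) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    ch <- substr(stream, i, i)
    if (grepl("[ \t\r\n]", ch)) { i <- i + 1L; next }
    if (ch == "(") {
      depth <- 1L; j <- i + 1L; buf <- character(0)
      while (j <= n && depth > 0L) {
        cj <- substr(stream, j, j)
        if (cj == "\\") { buf <- c(buf, substr(stream, j, j + 1L)); j <- j + 2L; next }
        if (cj == "(") depth <- depth + 1L
        if (cj == ")") { depth <- depth - 1L; if (depth == 0L) break }
        buf <- c(buf, cj); j <- j + 1L
      }
      push("string", .pdfUnescape(paste(buf, collapse = "")))
      i <- j + 1L
    } else if (ch == "[") {
      # array: collect contained strings (TJ form)
      depth <- 1L; j <- i + 1L; strs <- character(0)
      while (j <= n && depth > 0L) {
        cj <- substr(stream, j, j)
        if (cj == "(") {
          d2 <- 1L; k <- j + 1L; buf <- character(0)
          while (k <= n && d2 > 0L) {
            ck <- substr(stream, k, k)
            if (ck == "\\") { buf <- c(buf, substr(stream, k, k + 1L)); k <- k + 2L; next }
            if (ck == "(") d2 <- d2 + 1L
            if (ck == ")") { d2 <- d2 - 1L; if (d2 == 0L) break }
            buf <- c(buf, ck); k <- k + 1L
          }
          strs <- c(strs, .pdfUnescape(paste(buf, collapse = "")))
          j <- k + 1L
          next
        }
        if (cj == "[") depth <- depth + 1L
        if (cj == "]") depth <- depth - 1L
        j <- j + 1L
      }
      push("array", strs)
      i <- j
    } else if (ch == "/") {
      m <- regexpr("^/[^ \t\r\n/\\[\\]()<>]*", substring(stream, i), perl = TRUE)
      push("name", regmatches(substring(stream, i), m))
      i <- i + attr(m, "match.length")
    } else if (grepl("[0-9+.-]", ch)) {
      m <- regexpr("^[+-]?[0-9]*\\.?[0-9]+", substring(stream, i), perl = TRUE)
      if (m == -1L) { i <- i + 1L; next }
      push("number", regmatches(substring(stream, i), m))
      i <- i + attr(m, "match.length")
    } else {
      m <- regexpr("^[^ \t\r\n()\\[\\]/]+", substring(stream, i), perl = TRUE)
      op <- regmatches(substring(stream, i), m)
      push("operator", op)
      i <- i + attr(m, "match.length")
    }
  }
  toks
}
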