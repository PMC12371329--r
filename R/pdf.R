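# Minimal PDF support.
#
# Writing: single-page text-layer PDFs (Helvetica, one Tj per line,
# uncompressed content stream) — enough to emulate supplementary PDFs whose
# text is stored as actual characters.
#
# Reading: locates content streams in the raw bytes (inflating FlateDecode
# streams when present) and collects the literal strings fed to the
# text-showing operators Tj / TJ / ' / ". Scanned-image PDFs therefore
# yield empty text: OCR of embedded page images is deliberately not
# attempted.

pdf_escape_string <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("(", "\\(", x, fixed = TRUE)
  gsub(")", "\\)", x, fixed = TRUE)
}

# Write `lines` as a one-page PDF with an uncompressed text content stream.
write_pdf_min <- function(path, lines) {
  content <- paste0("BT\n/F1 10 Tf\n72 760 Td\n12 TL\n",
                    paste0("(", pdf_escape_string(lines), ") Tj T*\n", collapse = ""),
                    "ET")
  objs <- c(
    "<< /Type /Catalog /Pages 2 0 R >>",
    "<< /Type /Pages /Kids [3 0 R] /Count 1 >>",
    paste0("<< /Type /Page /Parent 2 0 R /MediaBox [0 0 612 792] ",
           "/Resources << /Font << /F1 4 0 R >> >> /Contents 5 0 R >>"),
    "<< /Type /Font /Subtype /Type1 /BaseFont /Helvetica >>",
    paste0("<< /Length ", nchar(content, type = "bytes"), " >>\nstream\n",
           content, "\nendstream"))
  out <- "%PDF-1.4\n"
  off <- integer(length(objs))
  for (i in seq_along(objs)) {
    off[i] <- nchar(out, type = "bytes")
    out <- paste0(out, i, " 0 obj\n", objs[i], "\nendobj\n")
  }
  xref <- nchar(out, type = "bytes")
  out <- paste0(out, "xref\n0 ", length(objs) + 1, "\n0000000000 65535 f \n",
                paste0(formatC(off, width = 10, flag = "0"), " 00000 n \n",
                       collapse = ""),
                "trailer\n<< /Size ", length(objs) + 1, " /Root 1 0 R >>\n",
                "startxref\n", xref, "\n%%EOF\n")
  writeBin(charToRaw(out), path)
  invisible(path)
}

# Split raw PDF bytes into decoded content-stream strings (latin1-mapped).
pdf_content_streams <- function(raw) {
  starts <- grepRaw("stream", raw, all = TRUE, fixed = TRUE)
  ends <- grepRaw("endstream", raw, all = TRUE, fixed = TRUE)
  if (!length(starts)) return(character())
  starts <- setdiff(starts, ends + 3L)  # "stream" inside "endstream"
  out <- character()
  used_end <- 0L
  for (s in starts) {
    e <- ends[ends > s]
    if (!length(e)) next
    e <- e[1]
    if (e <= used_end) next
    used_end <- e
    from <- s + 6L
    # skip the EOL that terminates the "stream" keyword
    while (from <= length(raw) && raw[from] %in% as.raw(c(0x0d, 0x0a))) from <- from + 1L
    to <- e - 1L
    while (to >= from && raw[to] %in% as.raw(c(0x0d, 0x0a))) to <- to - 1L
    if (to < from) next
    bytes <- raw[from:to]
    # dictionary preceding this stream decides the filter
    dict_from <- max(1L, s - 400L)
    dict <- rawToChar(raw[dict_from:(s - 1L)], multiple = FALSE)
    Encoding(dict) <- "latin1"
    if (grepl("FlateDecode", dict, fixed = TRUE)) {
      bytes <- tryCatch(memDecompress(bytes, type = "gzip"),
                        error = function(e) NULL)
      if (is.null(bytes)) next
    }
    txt <- rawToChar(bytes)
    Encoding(txt) <- "latin1"
    out <- c(out, txt)
  }
  out
}

# Parse one content stream: collect literal strings shown by Tj/TJ/'/",
# inserting newlines at the line-advance operators (T*, Td, TD).
pdf_stream_text <- function(content) {
  chars <- strsplit(content, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  pieces <- character()
  pending <- NULL  # last literal string, awaiting its operator
  flush_op <- function(op) {
    if (op %in% c("Tj", "'", "\"") && !is.null(pending)) {
      pieces <<- c(pieces, pending)
    }
    if (op %in% c("T*", "Td", "TD", "ET") && length(pieces) &&
        pieces[length(pieces)] != "\n") {
      pieces <<- c(pieces, "\n")
    }
    pending <<- NULL
  }
  read_literal <- function(i) {
    depth <- 1L
    buf <- character()
    i <- i + 1L
    while (i <= n && depth > 0L) {
      ch <- chars[i]
      if (ch == "\\") {
        nxt <- if (i + 1L <= n) chars[i + 1L] else ""
        if (nxt %in% c("(", ")", "\\")) { buf <- c(buf, nxt); i <- i + 2L; next }
        if (nxt == "n") { buf <- c(buf, "\n"); i <- i + 2L; next }
        if (nxt == "r") { buf <- c(buf, "\r"); i <- i + 2L; next }
        if (nxt == "t") { buf <- c(buf, "\t"); i <- i + 2L; next }
        if (grepl("[0-7]", nxt)) {  # octal escape, up to 3 digits
          oct <- ""
          j <- i + 1L
          while (j <= n && nchar(oct) < 3 && grepl("[0-7]", chars[j])) {
            oct <- paste0(oct, chars[j]); j <- j + 1L
          }
          buf <- c(buf, rawToChar(as.raw(strtoi(oct, base = 8L))))
          i <- j
          next
        }
        i <- i + 2L
        next
      }
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") { depth <- depth - 1L; if (depth == 0L) { i <- i + 1L; break } }
      if (depth > 0L) buf <- c(buf, ch)
      i <- i + 1L
    }
    list(text = paste(buf, collapse = ""), next_i = i)
  }
  in_array <- FALSE
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      lit <- read_literal(i)
      if (in_array) pieces <- c(pieces, lit$text) else pending <- lit$text
      i <- lit$next_i
      next
    }
    if (ch == "[") { in_array <- TRUE; i <- i + 1L; next }
    if (ch == "]") { in_array <- FALSE; i <- i + 1L; next }
    if (grepl("[A-Za-z*'\"]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z*'\"]", chars[j])) j <- j + 1L
      flush_op(paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
      next
    }
    i <- i + 1L
  }
  paste(pieces, collapse = "")
}

# Extract the character text of a PDF given its raw bytes.
# Returns NULL when the bytes are not a PDF (no %PDF header).
pdf_extract_text <- function(raw) {
  if (length(raw) < 5L || !identical(raw[1:5], charToRaw("%PDF-"))) return(NULL)
  streams <- pdf_content_streams(raw)
  if (!length(streams)) return("")
  txt <- paste(vapply(streams, pdf_stream_text, character(1)), collapse = "\n")
  sub("\n+$", "", gsub(" *\n", "\n", txt))
}
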