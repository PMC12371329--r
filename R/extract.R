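# Text extraction from supplementary files.
#
# All extractors serialize to plain text with "\t" between row cells and
# "\n" between rows/paragraphs, so a downstream match can never span a cell
# or line boundary (both separators are outside the word alphabet).

extraction_result <- function(doc_id, status, text = "", failure_reason = "") {
  tibble::tibble(doc_id = doc_id, status = status, text = text,
                 n_chars = nchar(text), failure_reason = failure_reason)
}

ok_or_empty <- function(doc_id, text) {
  extraction_result(doc_id, if (nchar(text) > 0) "ok" else "ok_empty", text)
}

# Decode raw bytes under the permitted encodings: UTF-8 first, then
# Latin-1. Embedded NULs or bytes in the undefined C1 range fail both.
decode_bytes <- function(raw) {
  if (any(raw == as.raw(0))) stop("embedded NUL byte")
  txt <- rawToChar(raw)
  if (all(validUTF8(txt))) {
    Encoding(txt) <- "UTF-8"
    return(txt)
  }
  if (any(raw >= as.raw(0x80) & raw <= as.raw(0x9f))) {
    stop("bytes undecodable as UTF-8 or Latin-1")
  }
  Encoding(txt) <- "latin1"
  enc2utf8(txt)
}

split_lines <- function(txt) strsplit(txt, "\r\n|\r|\n")[[1]]

extract_spreadsheet <- function(raw, ext) {
  tmp <- tempfile(fileext = paste0(".", ext))
  on.exit(unlink(tmp), add = TRUE)
  writeBin(raw, tmp)
  reader <- if (ext == "xls") readxl::read_xls else readxl::read_xlsx
  sheets <- readxl::excel_sheets(tmp)
  chunks <- character()
  for (s in sheets) {
    df <- suppressMessages(reader(tmp, sheet = s, col_names = FALSE,
                                  col_types = "text"))
    chunks <- c(chunks, paste0("## sheet: ", s))
    if (nrow(df)) {
      m <- as.matrix(df)
      m[is.na(m)] <- ""
      chunks <- c(chunks, apply(m, 1, paste, collapse = "\t"))
    }
  }
  # a workbook with no cell content at all is an empty extraction
  body <- chunks[!startsWith(chunks, "## sheet: ")]
  if (!length(body) || !any(nzchar(body))) return("")
  paste(chunks, collapse = "\n")
}

extract_delimited <- function(raw, sep) {
  txt <- decode_bytes(raw)
  lines <- split_lines(txt)
  if (!is.null(sep)) {
    lines <- vapply(lines, function(l) {
      paste(strsplit(l, sep, fixed = TRUE)[[1]], collapse = "\t")
    }, character(1), USE.NAMES = FALSE)
  }
  paste(lines, collapse = "\n")
}

extract_markup <- function(raw, html) {
  txt <- decode_bytes(raw)
  doc <- if (html) xml2::read_html(txt) else xml2::read_xml(txt)
  xp <- if (html) "//text()[not(ancestor::script) and not(ancestor::style)]" else "//text()"
  nodes <- xml2::xml_find_all(doc, xp)
  vals <- trimws(vapply(nodes, xml2::xml_text, character(1)))
  paste(vals[nzchar(vals)], collapse = "\n")
}

#' OCR with rotation search
#'
#' Wrapper contract for pluggable OCR of JPG supplementary figures: the
#' image is offered at rotations of 0, 90, 180 and 270 degrees and the
#' orientation yielding the most recognized characters wins, so vertical
#' text is still captured. The OCR engine itself is supplied by the caller
#' as a function `image array -> character(1)`.
#'
#' @param img Numeric image array (height x width, optionally x channels),
#'   e.g. from `jpeg::readJPEG()`.
#' @param ocr_fun Function taking an image array and returning recognized
#'   text.
#' @return The text of the best-scoring orientation.
#' @export
ocr_with_rotation <- function(img, ocr_fun) {
  rot90 <- function(a) {
    if (length(dim(a)) == 2) return(t(a[nrow(a):1, , drop = FALSE]))
    aperm(a[dim(a)[1]:1, , , drop = FALSE], c(2, 1, 3))
  }
  best <- ""
  cur <- img
  for (k in 1:4) {
    txt <- ocr_fun(cur)
    if (nchar(gsub("\\s", "", txt)) > nchar(gsub("\\s", "", best))) best <- txt
    cur <- rot90(cur)
  }
  best
}

extract_jpg <- function(raw, ocr_enabled, ocr_fun) {
  if (!isTRUE(ocr_enabled) || is.null(ocr_fun)) return(NULL)  # skipped
  if (!requireNamespace("jpeg", quietly = TRUE)) return(NULL)
  img <- jpeg::readJPEG(raw)
  ocr_with_rotation(img, ocr_fun)
}

#' Extract plain text from one classified file
#'
#' Dispatches on the record's filetype: spreadsheets (xlsx, xls) are
#' serialized cell-by-cell in row-major order (tab between cells, newline
#' between rows, a `## sheet:` break line between sheets, values read as
#' text so numeric display formats can never mangle an identifier);
#' delimited text (csv, txt) is decoded under UTF-8 then Latin-1; docx
#' yields paragraph and table text; pdf yields only text stored as actual
#' characters (no OCR of scanned pages); html/xml are tag-stripped; jpg is
#' OCRed only when enabled and an engine is plugged in, otherwise skipped.
#' Unreadable or corrupt content is reported as a failure, never raised:
#' sub-100% success rates are an expected property of real supplementary
#' data.
#'
#' @param record One classification row (see [classify_bundle()]); must be
#'   of category `supplementary` or `manuscript_figure`.
#' @param content Raw vector with the file bytes.
#' @param ocr_enabled Attempt OCR for jpg files.
#' @param ocr_fun Pluggable OCR engine (see [ocr_with_rotation()]).
#' @param doc_enabled Capability flag for legacy Word (.doc) extraction;
#'   without it, .doc files are `skipped_unsupported` rather than failed.
#' @return One-row tibble: `doc_id`, `status` (`ok`, `ok_empty`, `failed`,
#'   `skipped_unsupported`), `text`, `n_chars`, `failure_reason`.
#' @export
extract_text <- function(record, content, ocr_enabled = FALSE, ocr_fun = NULL,
                         doc_enabled = FALSE) {
  if (!record$category %in% c("supplementary", "manuscript_figure")) {
    stop("extract_text expects a supplementary or manuscript_figure record, got ",
         record$category, call. = FALSE)
  }
  stopifnot(is.raw(content))
  doc_id <- record$doc_id
  ext <- record$filetype
  out <- tryCatch({
    txt <- switch(ext,
      xlsx = extract_spreadsheet(content, "xlsx"),
      xls = extract_spreadsheet(content, "xls"),
      csv = extract_delimited(content, ","),
      txt = extract_delimited(content, NULL),
      docx = docx_extract_text(content),
      doc = if (doc_enabled) docx_extract_text(content) else NULL,
      pdf = {
        t0 <- pdf_extract_text(content)
        if (is.null(t0)) stop("not a PDF (missing %PDF header)")
        t0
      },
      html = ,
      htm = extract_markup(content, html = TRUE),
      xml = extract_markup(content, html = FALSE),
      jpg = ,
      jpeg = extract_jpg(content, ocr_enabled, ocr_fun),
      NULL)
    if (is.null(txt)) {
      extraction_result(doc_id, "skipped_unsupported")
    } else {
      ok_or_empty(doc_id, txt)
    }
  }, error = function(e) {
    extraction_result(doc_id, "failed",
                      failure_reason = conditionMessage(e))
  })
  out
}

#' Extract text from every extractable file of a corpus directory
#'
#' @param records Classification tibble (all articles concatenated).
#' @param corpus_dir Directory holding one subdirectory per article, named
#'   by PMCID.
#' @inheritParams extract_text
#' @return Tibble of extraction results, one row per supplementary or
#'   manuscript-figure file.
#' @export
extract_bundle_files <- function(records, corpus_dir, ocr_enabled = FALSE,
                                 ocr_fun = NULL, doc_enabled = FALSE) {
  todo <- records[records$category %in% c("supplementary", "manuscript_figure"), ,
                  drop = FALSE]
  parts <- lapply(seq_len(nrow(todo)), function(i) {
    rec <- todo[i, , drop = FALSE]
    path <- file.path(corpus_dir, rec$pmcid, rec$filename)
    content <- readBin(path, "raw", n = file.size(path))
    extract_text(rec, content, ocr_enabled = ocr_enabled, ocr_fun = ocr_fun,
                 doc_enabled = doc_enabled)
  })
  do.call(rbind, c(list(extraction_result(character(0), character(0),
                                          character(0), character(0))), parts))
}

#' Per-filetype extraction accounting
#'
#' Aggregates extraction outcomes per filetype: number of files attempted,
#' number succeeding (`ok` plus `ok_empty` — an extraction that ran and
#' produced no text still succeeded), the success rate, and the mean
#' character count over non-empty successes (`ok_empty` files contribute no
#' characters and are excluded from the mean). Files skipped for lack of a
#' capability are not attempts and do not appear. Rows are ordered by
#' descending file count, then filetype.
#'
#' @param results Extraction-result tibble from [extract_text()] /
#'   [extract_bundle_files()].
#' @param records Matching classification tibble; every result `doc_id`
#'   must resolve to exactly one record.
#' @return Tibble with columns `filetype`, `n_files`, `n_ok`,
#'   `success_rate`, `mean_chars`.
#' @export
build_extraction_report <- function(results, records) {
  if (!all(results$doc_id %in% records$doc_id)) {
    bad <- setdiff(results$doc_id, records$doc_id)
    stop("extraction results reference unknown doc_id(s): ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  att <- results[results$status != "skipped_unsupported", , drop = FALSE]
  if (!nrow(att)) {
    return(tibble::tibble(filetype = character(), n_files = integer(),
                          n_ok = integer(), success_rate = numeric(),
                          mean_chars = numeric()))
  }
  ft <- records$filetype[match(att$doc_id, records$doc_id)]
  types <- unique(ft)
  rows <- lapply(types, function(t) {
    sel <- ft == t
    n <- sum(sel)
    ok <- sum(att$status[sel] %in% c("ok", "ok_empty"))
    chars <- att$n_chars[sel][att$status[sel] == "ok"]
    tibble::tibble(filetype = t, n_files = n, n_ok = ok,
                   success_rate = ok / n,
                   mean_chars = if (length(chars)) mean(chars) else 0)
  })
  rep <- do.call(rbind, rows)
  rep[order(-rep$n_files, rep$filetype), , drop = FALSE]
}

#' Write an extraction report as delimited text
#' @param report Tibble from [build_extraction_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extraction_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
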