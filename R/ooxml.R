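# Minimal OOXML writers (xlsx spreadsheets, docx word-processor files) used
# by the synthetic-corpus generator, and the docx reader used by the
# extractor. Spreadsheet cells are written as inline strings so no value is
# ever coerced through a numeric display format (an accession stored as
# text must survive byte-for-byte).

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

ooxml_zip <- function(path, staging) {
  entries <- list.files(staging, full.names = TRUE, all.files = TRUE,
                        no.. = TRUE, include.dirs = TRUE)
  zip::zipr(path, entries, include_directories = FALSE)
  invisible(path)
}

ct_header <- '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>'

# sheets: named list of character matrices (or vectors treated as one row).
write_xlsx_min <- function(path, sheets) {
  if (!is.list(sheets)) sheets <- list(Sheet1 = sheets)
  if (is.null(names(sheets)) || any(!nzchar(names(sheets)))) {
    names(sheets) <- paste0("Sheet", seq_along(sheets))
  }
  d <- tempfile("xlsx_stage")
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  dir.create(file.path(d, "_rels"), recursive = TRUE)
  dir.create(file.path(d, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(d, "xl", "worksheets"), recursive = TRUE)

  n <- length(sheets)
  overrides <- paste0(
    '<Override PartName="/xl/worksheets/sheet', seq_len(n),
    '.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    collapse = "")
  writeLines(c(ct_header, paste0(
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    overrides, "</Types>")), file.path(d, "[Content_Types].xml"))
  writeLines(c(ct_header, paste0(
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>")), file.path(d, "_rels", ".rels"))
  sheet_tags <- paste0('<sheet name="', xml_escape(names(sheets)), '" sheetId="',
                       seq_len(n), '" r:id="rId', seq_len(n), '"/>', collapse = "")
  writeLines(c(ct_header, paste0(
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    "<sheets>", sheet_tags, "</sheets></workbook>")),
    file.path(d, "xl", "workbook.xml"))
  rels <- paste0('<Relationship Id="rId', seq_len(n),
                 '" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet',
                 seq_len(n), '.xml"/>', collapse = "")
  writeLines(c(ct_header, paste0(
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    rels, "</Relationships>")), file.path(d, "xl", "_rels", "workbook.xml.rels"))

  col_letter <- function(j) {
    # spreadsheet column letters, 1 -> A
    out <- ""
    while (j > 0) { r <- (j - 1) %% 26; out <- paste0(LETTERS[r + 1], out); j <- (j - 1) %/% 26 }
    out
  }
  for (k in seq_len(n)) {
    m <- sheets[[k]]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    rows <- character(nrow(m))
    for (i in seq_len(nrow(m))) {
      cells <- character(ncol(m))
      for (j in seq_len(ncol(m))) {
        v <- m[i, j]
        if (is.na(v) || !nzchar(v)) { cells[j] <- ""; next }
        cells[j] <- paste0('<c r="', col_letter(j), i, '" t="inlineStr"><is><t xml:space="preserve">',
                           xml_escape(v), "</t></is></c>")
      }
      rows[i] <- paste0('<row r="', i, '">', paste(cells, collapse = ""), "</row>")
    }
    writeLines(c(ct_header, paste0(
      '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main"><sheetData>',
      paste(rows, collapse = ""), "</sheetData></worksheet>")),
      file.path(d, "xl", "worksheets", paste0("sheet", k, ".xml")))
  }
  ooxml_zip(path, d)
}

# paragraphs: character vector; table_rows: optional character matrix
# rendered as a w:tbl (one w:p per cell).
write_docx_min <- function(path, paragraphs, table_rows = NULL) {
  d <- tempfile("docx_stage")
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  dir.create(file.path(d, "_rels"), recursive = TRUE)
  dir.create(file.path(d, "word"), recursive = TRUE)
  writeLines(c(ct_header, paste0(
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/word/document.xml" ContentType="application/vnd.openxmlformats-officedocument.wordprocessingml.document.main+xml"/>',
    "</Types>")), file.path(d, "[Content_Types].xml"))
  writeLines(c(ct_header, paste0(
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="word/document.xml"/>',
    "</Relationships>")), file.path(d, "_rels", ".rels"))
  p_tag <- function(x) paste0('<w:p><w:r><w:t xml:space="preserve">',
                              xml_escape(x), "</w:t></w:r></w:p>")
  body <- paste(vapply(paragraphs, p_tag, character(1)), collapse = "")
  if (!is.null(table_rows)) {
    if (is.null(dim(table_rows))) table_rows <- matrix(table_rows, nrow = 1)
    trs <- character(nrow(table_rows))
    for (i in seq_len(nrow(table_rows))) {
      tcs <- paste0("<w:tc>", vapply(table_rows[i, ], p_tag, character(1)), "</w:tc>",
                    collapse = "")
      trs[i] <- paste0("<w:tr>", tcs, "</w:tr>")
    }
    body <- paste0(body, "<w:tbl>", paste(trs, collapse = ""), "</w:tbl>")
  }
  writeLines(c(ct_header, paste0(
    '<w:document xmlns:w="http://schemas.openxmlformats.org/wordprocessingml/2006/main"><w:body>',
    body, "</w:body></w:document>")), file.path(d, "word", "document.xml"))
  ooxml_zip(path, d)
}

# Read the paragraph and table text of a docx given its raw bytes.
# Each w:p becomes one line, so cell values never run together.
docx_extract_text <- function(raw) {
  tmp <- tempfile(fileext = ".docx")
  on.exit(unlink(tmp), add = TRUE)
  writeBin(raw, tmp)
  exdir <- tempfile("docx_x")
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  zip::unzip(tmp, files = "word/document.xml", exdir = exdir)
  docpath <- file.path(exdir, "word", "document.xml")
  if (!file.exists(docpath)) stop("no word/document.xml in docx archive")
  doc <- xml2::read_xml(docpath)
  ps <- xml2::xml_find_all(doc, "//w:p", xml2::xml_ns(doc))
  paste(vapply(ps, xml2::xml_text, character(1)), collapse = "\n")
}
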