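supp_record <- function(filename, pmcid = "PMC1") {
  classify_bundle(pmcid, c("a.nxml", filename), "a.nxml")[2, , drop = FALSE]
}

read_raw <- function(path) readBin(path, "raw", n = file.size(path))

test_that("planted tokens survive extraction verbatim for every format", {
  tokens <- c("TP53", "GO:0005737", "CHEBL-free", "R-HSA-2168880")
  dir <- withr::local_tempdir()

  # xlsx, two sheets, value that a numeric coercion would mangle
  xp <- file.path(dir, "t.xlsx")
  suppminer:::write_xlsx_min(xp, list(
    data = rbind(c("gene", "go"), c("TP53", "GO:0005737"), c("1e+06", "0005737")),
    extra = matrix(c("R-HSA-2168880", "note"), nrow = 1)))
  r <- extract_text(supp_record("t.xlsx"), read_raw(xp))
  expect_identical(r$status, "ok")
  for (tok in c("TP53", "GO:0005737", "1e+06", "0005737", "R-HSA-2168880")) {
    expect_true(grepl(tok, r$text, fixed = TRUE), label = tok)
  }
  expect_true(grepl("## sheet: extra", r$text, fixed = TRUE))
  # cells are tab-separated, rows newline-separated
  expect_true(grepl("TP53\tGO:0005737", r$text, fixed = TRUE))

  # csv with comma cells -> tab-joined
  cp <- file.path(dir, "t.csv")
  writeLines(c("id,term", "IPR013770,domain"), cp)
  r <- extract_text(supp_record("t.csv"), read_raw(cp))
  expect_identical(r$status, "ok")
  expect_true(grepl("IPR013770\tdomain", r$text, fixed = TRUE))

  # txt passthrough
  tp <- file.path(dir, "t.txt")
  writeLines(c("line one GCST90017001", "line two"), tp)
  r <- extract_text(supp_record("t.txt"), read_raw(tp))
  expect_true(grepl("GCST90017001", r$text, fixed = TRUE))

  # docx paragraphs and table cells
  dp <- file.path(dir, "t.docx")
  suppminer:::write_docx_min(dp, c("first paragraph", "ZDB-GENE-030820-3 seen"),
                             table_rows = rbind(c("FBgn0003074", "wing")))
  r <- extract_text(supp_record("t.docx"), read_raw(dp))
  expect_true(grepl("ZDB-GENE-030820-3", r$text, fixed = TRUE))
  expect_true(grepl("FBgn0003074", r$text, fixed = TRUE))

  # pdf text layer, including escaped characters
  pp <- file.path(dir, "t.pdf")
  suppminer:::write_pdf_min(pp, c("table (with) GO: 0005737", "and \\ backslash"))
  r <- extract_text(supp_record("t.pdf"), read_raw(pp))
  expect_identical(r$status, "ok")
  expect_true(grepl("table (with) GO: 0005737", r$text, fixed = TRUE))
  expect_true(grepl("and \\ backslash", r$text, fixed = TRUE))

  # html: tag-stripped, adjacent cells cannot run together
  hp <- file.path(dir, "t.html")
  writeLines(c("<html><body><table><tr><td>GO:0005737</td><td>term</td></tr>",
               "</table><p>PA444801</p><script>var x=1;</script></body></html>"), hp)
  r <- extract_text(supp_record("t.html"), read_raw(hp))
  expect_true(grepl("GO:0005737", r$text, fixed = TRUE))
  expect_false(grepl("GO:0005737term", r$text, fixed = TRUE))
  expect_false(grepl("var x", r$text, fixed = TRUE))
  expect_true(grepl("PA444801", r$text, fixed = TRUE))

  # xml
  mp <- file.path(dir, "t.xml")
  writeLines(c("<r><rec><id>CVCL_0030</id><d>hela</d></rec></r>"), mp)
  r <- extract_text(supp_record("t.xml"), read_raw(mp))
  expect_true(grepl("CVCL_0030", r$text, fixed = TRUE))
  expect_false(grepl("CVCL_0030hela", r$text, fixed = TRUE))
})

test_that("extraction outcomes and the report follow the stated conventions", {
  dir <- withr::local_tempdir()
  # an all-empty workbook ran fine but yielded nothing
  ep <- file.path(dir, "e.xlsx")
  suppminer:::write_xlsx_min(ep, list(empty = matrix("", 1, 1)))
  r <- extract_text(supp_record("e.xlsx"), read_raw(ep))
  expect_identical(r$status, "ok_empty")
  expect_identical(r$n_chars, 0L)

  # a pdf with no text operators (image-only shape), no OCR -> empty, not failed
  gp <- file.path(dir, "g.pdf")
  writeBin(charToRaw("%PDF-1.4\n1 0 obj\n<< /Type /Catalog >>\nendobj\n%%EOF\n"), gp)
  r <- extract_text(supp_record("g.pdf"), read_raw(gp))
  expect_identical(r$status, "ok_empty")

  # jpg without an OCR engine is skipped, not failed
  r <- extract_text(supp_record("s1.jpg"), as.raw(c(0xff, 0xd8, 0xff)))
  expect_identical(r$status, "skipped_unsupported")
  # legacy doc without the capability flag likewise
  r <- extract_text(supp_record("old.doc"), as.raw(1:10))
  expect_identical(r$status, "skipped_unsupported")

  # corrupt spreadsheet bytes fail with a reason
  r <- extract_text(supp_record("bad.xls"), as.raw(rep(7, 64)))
  expect_identical(r$status, "failed")
  expect_true(nzchar(r$failure_reason))

  # undecodable csv bytes fail under both permitted encodings
  r <- extract_text(supp_record("bad.csv"), as.raw(c(0x61, 0x2c, 0x81, 0xff, 0x00)))
  expect_identical(r$status, "failed")
  # latin1 (but not utf-8) text is decoded, not failed
  r <- extract_text(supp_record("l1.csv"), c(charToRaw("caf"), as.raw(0xe9),
                                             charToRaw(",x")))
  expect_identical(r$status, "ok")
  expect_true(grepl("café\tx", r$text, fixed = TRUE))
})

test_that("the extraction report accounts per-filetype attempts and successes", {
  recs <- do.call(rbind, lapply(
    c("a.xlsx", "b.xlsx", "c.xlsx", "d.xlsx", "e.jpg", "f.jpg"), supp_record))
  results <- rbind(
    suppminer:::extraction_result("PMC1_a.xlsx", "ok", strrep("x", 10)),
    suppminer:::extraction_result("PMC1_b.xlsx", "ok", strrep("x", 20)),
    suppminer:::extraction_result("PMC1_c.xlsx", "ok", strrep("x", 30)),
    suppminer:::extraction_result("PMC1_d.xlsx", "failed", failure_reason = "broken"),
    suppminer:::extraction_result("PMC1_e.jpg", "ok_empty"),
    suppminer:::extraction_result("PMC1_f.jpg", "ok_empty"))
  rep <- build_extraction_report(results, recs)
  xlsx <- rep[rep$filetype == "xlsx", ]
  expect_identical(xlsx$n_files, 4L)
  expect_equal(xlsx$success_rate, 0.75)
  expect_equal(xlsx$mean_chars, 20)
  jpg <- rep[rep$filetype == "jpg", ]
  expect_equal(jpg$success_rate, 1)   # empty output still counts as success
  expect_equal(jpg$mean_chars, 0)     # ...but contributes no characters
  expect_identical(rep$filetype, c("xlsx", "jpg"))  # descending n_files
  expect_identical(sum(rep$n_files), nrow(results))

  empty <- build_extraction_report(results[0, ], recs)
  expect_identical(nrow(empty), 0L)
  expect_error(build_extraction_report(
    suppminer:::extraction_result("PMCZ_q.csv", "ok", "t"), recs), "unknown doc_id")
})

test_that("no extractor raises past the dispatcher on arbitrary bytes", {
  withr::with_seed(99, {
    exts <- c("xlsx", "xls", "csv", "txt", "docx", "pdf", "html", "xml")
    for (k in 1:24) {
      ext <- sample(exts, 1)
      blob <- as.raw(sample.int(256, sample(c(3, 64, 512), 1), replace = TRUE) - 1L)
      r <- extract_text(supp_record(paste0("fuzz.", ext)), blob)
      expect_true(r$status %in% c("ok", "ok_empty", "failed"),
                  label = paste("fuzz", ext, "->", r$status))
    }
  })
})

test_that("extraction is deterministic and refuses non-extractable categories", {
  dir <- withr::local_tempdir()
  cp <- file.path(dir, "t.csv")
  writeLines("a,b", cp)
  r1 <- extract_text(supp_record("t.csv"), read_raw(cp))
  r2 <- extract_text(supp_record("t.csv"), read_raw(cp))
  expect_identical(r1, r2)
  man <- classify_bundle("PMC1", "a.nxml", "a.nxml")
  expect_error(extract_text(man, as.raw(1)), "supplementary")
})

test_that("the OCR wrapper picks the rotation with the most recognized text", {
  img <- matrix(0, nrow = 2, ncol = 5)  # landscape
  fake_ocr <- function(a) if (ncol(a) >= nrow(a)) "wide text here" else "x"
  expect_identical(ocr_with_rotation(img, fake_ocr), "wide text here")
  fake_ocr_tall <- function(a) if (nrow(a) > ncol(a)) "vertical caption" else ""
  expect_identical(ocr_with_rotation(img, fake_ocr_tall), "vertical caption")
})
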