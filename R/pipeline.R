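# End-to-end pipeline: classify -> extract -> match -> aggregate.

read_corpus_manifest <- function(corpus_dir) {
  mp <- file.path(corpus_dir, "manifest.json")
  if (!file.exists(mp)) {
    stop("no articles found: missing manifest.json under ", corpus_dir,
         call. = FALSE)
  }
  manifest <- read_manifest(mp)
  if (!length(manifest$articles)) {
    stop("no articles found in ", corpus_dir, call. = FALSE)
  }
  manifest
}

#' Run the full mining pipeline over a corpus directory
#'
#' Composes the module operations in sequence: bundle classification, text
#' extraction, name and accession matching, and the three aggregate
#' reports (articles per resource per collection tier, accession
#' occurrences per tier, year-by-filetype occurrence matrix with the
#' per-year article series). The corpus directory must hold one
#' subdirectory per article plus a `manifest.json` supplying, per article,
#' its identifier, publication year, manuscript XML name, referenced
#' figure names, and the abstract / full-text stand-in documents. Only
#' those descriptive fields are read; any ground-truth annotations in the
#' manifest are ignored by the pipeline.
#'
#' Extraction failures are data, not crashes: the pipeline completes,
#' logs every failed document with its reason, and reports per-type
#' success rates.
#'
#' @param corpus_dir Corpus directory.
#' @param out_dir Output directory for reports (created if needed); `NULL`
#'   to skip writing.
#' @param reg A [registry()].
#' @param ocr_enabled Attempt OCR for jpg files (requires `ocr_fun`).
#' @param ocr_fun Pluggable OCR engine (see [ocr_with_rotation()]).
#' @param doc_enabled Capability flag for legacy Word (.doc) files.
#' @param min_year Articles published before this year are excluded from
#'   the reports.
#' @param formats Report formats to write, subset of `c("tsv", "json")`.
#' @return Invisibly, a list: `classification`, `extraction_results`
#'   (texts included), `extraction_report`, `mentions`, `docsets`,
#'   `name_report`, `accession_report`, `year_report`.
#' @export
run_pipeline <- function(corpus_dir, out_dir = NULL, reg = default_registry(),
                         ocr_enabled = FALSE, ocr_fun = NULL,
                         doc_enabled = FALSE, min_year = 2000,
                         formats = c("tsv", "json")) {
  manifest <- read_corpus_manifest(corpus_dir)

  classification <- do.call(rbind, lapply(manifest$articles, function(art) {
    files <- list.files(file.path(corpus_dir, art$pmcid))
    classify_bundle(art$pmcid, files, art$nxml,
                    nxml_figure_names = unlist(art$figures) %||% character())
  }))

  results <- extract_bundle_files(classification, corpus_dir,
                                  ocr_enabled = ocr_enabled, ocr_fun = ocr_fun,
                                  doc_enabled = doc_enabled)
  report <- build_extraction_report(results, classification)

  texts <- character()
  for (art in manifest$articles) {
    if (!is.null(art$abstract)) texts[abstract_doc_id(art$article_key)] <- art$abstract
    if (!is.null(art$fulltext)) texts[fulltext_doc_id(art$article_key)] <- art$fulltext
  }
  ok <- results$status %in% c("ok")
  supp_texts <- results$text[ok]
  names(supp_texts) <- results$doc_id[ok]
  texts <- c(texts, supp_texts)

  mentions <- find_mentions(texts, reg)

  docsets <- lapply(manifest$articles, function(art) {
    mine <- classification[classification$pmcid == art$pmcid, , drop = FALSE]
    article_docset(art$article_key, art$year, abstract = art$abstract,
                   fulltext = art$fulltext,
                   supp_docs = mine$doc_id[mine$category == "supplementary"],
                   figure_docs = mine$doc_id[mine$category == "manuscript_figure"])
  })

  name_report <- count_name_articles(docsets, mentions, reg = reg,
                                     min_year = min_year)
  accession_report <- count_accessions(docsets, mentions, reg = reg,
                                       min_year = min_year)
  year_report <- year_filetype_matrix(docsets, mentions, classification,
                                      min_year = min_year)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jp <- function(x) if ("json" %in% formats) file.path(out_dir, x) else NULL
    if ("tsv" %in% formats || "json" %in% formats) {
      write_classification(classification, file.path(out_dir, "classification.tsv"))
      write_extraction_report(report, file.path(out_dir, "extraction_report.tsv"))
      write_mentions_jsonl(mentions, file.path(out_dir, "mentions.jsonl"))
      write_count_report(name_report, file.path(out_dir, "name_counts.tsv"),
                         jp("name_counts.json"))
      write_count_report(accession_report,
                         file.path(out_dir, "accession_counts.tsv"),
                         jp("accession_counts.json"))
      write_count_report(year_report, file.path(out_dir, "year_filetype.tsv"),
                         jp("year_filetype.json"))
      utils::write.table(year_report$articles,
                         file.path(out_dir, "articles_per_year.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    # structured log of every failed extraction
    log_con <- file(file.path(out_dir, "extraction_log.jsonl"), "wt",
                    encoding = "UTF-8")
    fails <- results[results$status == "failed", , drop = FALSE]
    if (nrow(fails)) {
      writeLines(vapply(seq_len(nrow(fails)), function(i) {
        jsonlite::toJSON(list(doc_id = fails$doc_id[i], status = "failed",
                              reason = fails$failure_reason[i]),
                         auto_unbox = TRUE)
      }, character(1)), log_con)
    }
    close(log_con)
  }

  invisible(list(classification = classification, extraction_results = results,
                 extraction_report = report, mentions = mentions,
                 docsets = docsets, name_report = name_report,
                 accession_report = accession_report, year_report = year_report))
}
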