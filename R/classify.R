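#' @importFrom tools file_ext file_path_sans_ext
NULL

# File types with a text extractor. "doc" legacy Word is listed because the
# extractor surface exists (behind a capability flag); tif/png/zip and
# multimedia types are deliberately absent (unprocessed image/archive/video
# formats).
extractable_filetypes <- function() {
  c("xlsx", "xls", "csv", "txt", "docx", "doc", "pdf", "html", "htm",
    "xml", "jpg", "jpeg")
}

filetype_of <- function(filename) {
  tolower(tools::file_ext(filename))
}

#' Classify the files of one article bundle
#'
#' Partitions a PMC-style article bundle into manuscript and supplementary
#' material. The manuscript XML and the PDF rendition of the manuscript
#' (same stem as the XML) are set aside, as their text is already in the
#' full-text collection; JPG figures referenced by the manuscript are
#' flagged `manuscript_figure` (still extractable, but indexed apart); GIF
#' images are excluded outright (thumbnails and equation glyphs);
#' extensions with no extractor are `unsupported`; everything else is
#' supplementary material.
#'
#' @param pmcid Article identifier (`"PMC"` + digits).
#' @param filenames Character vector of base names within the bundle.
#' @param nxml_name Name of the manuscript XML file (must be among
#'   `filenames`).
#' @param nxml_figure_names Figure file names referenced by the manuscript.
#' @return A tibble with one row per input file: `pmcid`, `filename`,
#'   `doc_id` (`pmcid` + `"_"` + `filename`), `category` (one of
#'   `manuscript_xml`, `manuscript_pdf`, `manuscript_figure`,
#'   `supplementary`, `excluded_gif`, `unsupported`) and `filetype`
#'   (lowercased final extension).
#' @export
classify_bundle <- function(pmcid, filenames, nxml_name,
                            nxml_figure_names = character()) {
  if (!length(filenames)) stop("empty filename list for ", pmcid, call. = FALSE)
  if (!nxml_name %in% filenames) {
    stop("manuscript XML '", nxml_name, "' is not among the bundle files of ",
         pmcid, call. = FALSE)
  }
  stem <- function(x) tolower(tools::file_path_sans_ext(x))
  nxml_stem <- stem(nxml_name)
  ft <- vapply(filenames, filetype_of, character(1), USE.NAMES = FALSE)
  category <- character(length(filenames))
  for (i in seq_along(filenames)) {
    f <- filenames[i]
    category[i] <-
      if (f == nxml_name) "manuscript_xml"
      else if (ft[i] == "pdf" && stem(f) == nxml_stem) "manuscript_pdf"
      else if (ft[i] %in% c("jpg", "jpeg") && f %in% nxml_figure_names) "manuscript_figure"
      else if (ft[i] == "gif") "excluded_gif"
      else if (!ft[i] %in% extractable_filetypes()) "unsupported"
      else "supplementary"
  }
  tibble::tibble(pmcid = pmcid, filename = filenames,
                 doc_id = paste0(pmcid, "_", filenames),
                 category = category, filetype = ft)
}

#' Write a classification table as delimited text
#' @param records Classification tibble from [classify_bundle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
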