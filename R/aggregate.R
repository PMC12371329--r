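# Article-level counting across the three collections.
#
# Each article is a three-collection view keyed by one deduplication
# identifier (PMCID preferred over PMID): its MEDLINE rendition (title +
# abstract), its full text, and its supplementary documents. Name searches
# count articles (once per article per tier); accession searches count
# occurrences, with the title+abstract shared between the MEDLINE and
# full-text renditions counted once.

#' Build one article's document set
#'
#' @param article_key PMCID when available, else `"PMID:"` + pmid; the
#'   article-level deduplication identifier.
#' @param year Publication year (integer).
#' @param abstract Abstract text (MEDLINE collection), or `NULL`.
#' @param fulltext Full-text (PMC collection), or `NULL`. In real corpora
#'   the full text contains the title and abstract again; the counting
#'   rules below assume so and never count that shared region twice.
#' @param supp_docs Character vector of supplementary document ids
#'   belonging to this article.
#' @param figure_docs Document ids of OCRed manuscript figures; their
#'   mentions count in the supplementary tier (that is where their text is
#'   indexed), but they are not supplementary data files when measuring
#'   the share of articles with supplementary material.
#' @return An object of class `article_docset`.
#' @export
article_docset <- function(article_key, year, abstract = NULL, fulltext = NULL,
                           supp_docs = character(), figure_docs = character()) {
  stopifnot(is_string(article_key), nzchar(article_key))
  structure(list(article_key = article_key, year = as.integer(year),
                 abstract = abstract, fulltext = fulltext,
                 supp_docs = as.character(supp_docs),
                 figure_docs = as.character(figure_docs)),
            class = "article_docset")
}

#' Collection document id of an article's abstract / full text
#' @param article_key Article deduplication key.
#' @return Document id string.
#' @export
abstract_doc_id <- function(article_key) paste0(article_key, "#abstract")

#' @rdname abstract_doc_id
#' @export
fulltext_doc_id <- function(article_key) paste0(article_key, "#fulltext")

# doc_id -> (article_key, collection) lookup for a docset list.
docset_lookup <- function(docsets) {
  keys <- vapply(docsets, function(d) d$article_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate article_key in docsets: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(docsets, function(d) {
    ids <- character(); coll <- character()
    if (!is.null(d$abstract)) { ids <- c(ids, abstract_doc_id(d$article_key)); coll <- c(coll, "abstract") }
    if (!is.null(d$fulltext)) { ids <- c(ids, fulltext_doc_id(d$article_key)); coll <- c(coll, "fulltext") }
    supp_all <- c(d$supp_docs, d$figure_docs %||% character())
    if (length(supp_all)) { ids <- c(ids, supp_all); coll <- c(coll, rep("supp", length(supp_all))) }
    tibble::tibble(doc_id = ids, article_key = d$article_key,
                   year = d$year, collection = coll)
  })
  do.call(rbind, rows)
}

resolve_mentions <- function(docsets, mentions, min_year) {
  lk <- docset_lookup(docsets)
  i <- match(mentions$doc_id, lk$doc_id)
  if (anyNA(i)) {
    stop("mention(s) reference unknown doc_id(s): ",
         paste(utils::head(unique(mentions$doc_id[is.na(i)]), 3), collapse = ", "),
         call. = FALSE)
  }
  m <- mentions
  m$article_key <- lk$article_key[i]
  m$year <- lk$year[i]
  m$collection <- lk$collection[i]
  m[m$year >= min_year, , drop = FALSE]
}

report_resources <- function(reg, mentions, names_only) {
  if (!is.null(reg)) {
    keep <- vapply(reg$resources, function(r) {
      if (names_only) !r$name_excluded else !is.null(r$accession_pattern)
    }, logical(1))
    vapply(reg$resources[keep], function(r) r$resource_id, character(1))
  } else sort(unique(mentions$resource_id))
}

#' Count articles citing each resource, per collection tier
#'
#' For resource names the unit is the article: a citation is counted once
#' per article no matter how often or where it appears. The three columns
#' are cumulative — articles found searching MEDLINE abstracts alone;
#' adding the full texts; adding the supplementary files — so an article
#' whose mention sits in both the abstract and the full text still counts
#' once in every tier it reaches. The gain column is the extra yield of the
#' supplementary collection over MEDLINE + full text. The `any_of_them` row
#' deduplicates across resources (one article can mention several, so it is
#' not the column sum).
#'
#' @param docsets List of [article_docset()] objects.
#' @param mentions Mention tibble (name mentions are used).
#' @param reg Optional [registry()]; fixes row order and includes
#'   zero-count rows for non-excluded resources.
#' @param min_year Articles published before this year are ignored.
#' @return A `count_report` (kind `"names"`): tibble with `resource_id`,
#'   `n_medline`, `n_medline_pmc`, `n_all`, `gain` (raw ratio) and
#'   `gain_pct` (rounded percent, `NA` when undefined).
#' @export
count_name_articles <- function(docsets, mentions, reg = NULL, min_year = 2000) {
  m <- resolve_mentions(docsets, mentions, min_year)
  m <- m[m$mention_kind == "name", , drop = FALSE]
  resources <- report_resources(reg, m, names_only = TRUE)
  tier_sets <- function(sel) {
    a <- unique(m$article_key[sel & m$collection == "abstract"])
    f <- unique(m$article_key[sel & m$collection == "fulltext"])
    s <- unique(m$article_key[sel & m$collection == "supp"])
    c(n1 = length(a), n2 = length(union(a, f)), n3 = length(union(union(a, f), s)))
  }
  rows <- lapply(resources, function(r) {
    n <- tier_sets(m$resource_id == r)
    tibble::tibble(resource_id = r, n_medline = n[["n1"]],
                   n_medline_pmc = n[["n2"]], n_all = n[["n3"]])
  })
  any_n <- tier_sets(rep(TRUE, nrow(m)))
  rows <- c(rows, list(tibble::tibble(resource_id = "any_of_them",
                                      n_medline = any_n[["n1"]],
                                      n_medline_pmc = any_n[["n2"]],
                                      n_all = any_n[["n3"]])))
  tab <- do.call(rbind, rows)
  tab$gain <- ifelse(tab$n_medline_pmc > 0,
                     (tab$n_all - tab$n_medline_pmc) / tab$n_medline_pmc, NA_real_)
  tab$gain_pct <- ifelse(is.na(tab$gain), NA_real_, round(100 * tab$gain))
  structure(list(kind = "names", table = tab, min_year = min_year),
            class = "count_report")
}

#' Count accession-number occurrences, per collection tier
#'
#' For accession numbers the unit is the occurrence, so the prevalence of
#' identifiers in supplementary files can be compared directly with the
#' manuscripts. Both the MEDLINE and the full-text renditions of an
#' article contain the title and abstract, so for the MEDLINE + full-text
#' tier each identifier's occurrences are counted as the larger of its
#' abstract and full-text counts, never the sum of the two renditions.
#' Supplementary occurrences then add on top. `pct_only_supp` is the
#' percentage of all occurrences found exclusively in the supplementary
#' files.
#'
#' @inheritParams count_name_articles
#' @return A `count_report` (kind `"accessions"`): tibble with
#'   `resource_id`, `n_occ_medline`, `n_occ_medline_pmc`, `n_occ_all`,
#'   `pct_only_supp` (raw) and a `total` row.
#' @export
count_accessions <- function(docsets, mentions, reg = NULL, min_year = 2000) {
  m <- resolve_mentions(docsets, mentions, min_year)
  m <- m[m$mention_kind == "accession", , drop = FALSE]
  resources <- report_resources(reg, m, names_only = FALSE)
  occ_counts <- function(sel) {
    mm <- m[sel, , drop = FALSE]
    key <- paste(mm$article_key, mm$resource_id, mm$normalized_id, sep = "\r")
    a <- table(key[mm$collection == "abstract"])
    f <- table(key[mm$collection == "fulltext"])
    s <- table(key[mm$collection == "supp"])
    keys <- unique(key)
    av <- as.integer(a[keys]); av[is.na(av)] <- 0L
    fv <- as.integer(f[keys]); fv[is.na(fv)] <- 0L
    sv <- as.integer(s[keys]); sv[is.na(sv)] <- 0L
    n1 <- sum(av)
    n2 <- sum(pmax(av, fv))
    c(n1 = n1, n2 = n2, n3 = n2 + sum(sv))
  }
  rows <- lapply(resources, function(r) {
    n <- occ_counts(m$resource_id == r)
    tibble::tibble(resource_id = r, n_occ_medline = n[["n1"]],
                   n_occ_medline_pmc = n[["n2"]], n_occ_all = n[["n3"]])
  })
  tab <- do.call(rbind, rows)
  tot <- tibble::tibble(resource_id = "total",
                        n_occ_medline = sum(tab$n_occ_medline),
                        n_occ_medline_pmc = sum(tab$n_occ_medline_pmc),
                        n_occ_all = sum(tab$n_occ_all))
  tab <- rbind(tab, tot)
  tab$pct_only_supp <- ifelse(tab$n_occ_all > 0,
                              100 * (tab$n_occ_all - tab$n_occ_medline_pmc) / tab$n_occ_all,
                              NA_real_)
  structure(list(kind = "accessions", table = tab, min_year = min_year),
            class = "count_report")
}

#' @export
print.count_report <- function(x, ...) {
  cat("<count_report kind=", x$kind, ", articles from ", x$min_year, ">\n", sep = "")
  print(x$table, n = Inf)
  invisible(x)
}

#' Accession occurrences by publication year and file type
#'
#' Cross-tabulates supplementary-collection accession occurrences by the
#' publishing article's year and the carrying file's type, with row and
#' column totals; also derives the per-year article series: article count
#' and percentage of articles with at least one supplementary file.
#'
#' @inheritParams count_name_articles
#' @param file_records Classification tibble mapping every supplementary
#'   `doc_id` to its `filetype`.
#' @return List of class `year_filetype_report`: `matrix` (wide tibble,
#'   filetype rows, one column per year, plus `total`), `cells` (long
#'   tibble), `articles` (tibble `year`, `n_articles`, `pct_with_supp`),
#'   and `total_occ`.
#' @export
year_filetype_matrix <- function(docsets, mentions, file_records,
                                 min_year = 2000) {
  m <- resolve_mentions(docsets, mentions, min_year)
  m <- m[m$mention_kind == "accession" & m$collection == "supp", , drop = FALSE]
  i <- match(m$doc_id, file_records$doc_id)
  if (anyNA(i)) {
    stop("supplementary doc_id(s) missing from file records: ",
         paste(utils::head(unique(m$doc_id[is.na(i)]), 3), collapse = ", "),
         call. = FALSE)
  }
  m$filetype <- file_records$filetype[i]

  years <- vapply(docsets, function(d) d$year, integer(1))
  keep <- years >= min_year
  yr_range <- if (any(keep)) sort(unique(years[keep])) else integer()
  arts <- tibble::tibble(
    year = yr_range,
    n_articles = vapply(yr_range, function(y) sum(years[keep] == y), integer(1)),
    pct_with_supp = vapply(yr_range, function(y) {
      sel <- keep & years == y
      100 * mean(vapply(docsets[sel], function(d) length(d$supp_docs) > 0, logical(1)))
    }, numeric(1)))

  cells <- if (nrow(m)) {
    tab <- as.data.frame(table(filetype = m$filetype, year = m$year),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, , drop = FALSE]
    tibble::tibble(filetype = tab$filetype, year = as.integer(tab$year),
                   n_occ = as.integer(tab$Freq))
  } else tibble::tibble(filetype = character(), year = integer(), n_occ = integer())

  ft_order <- unique(cells$filetype[order(-vapply(
    cells$filetype, function(t) sum(cells$n_occ[cells$filetype == t]), integer(1)))])
  wide <- tibble::tibble(filetype = ft_order)
  for (y in yr_range) {
    wide[[as.character(y)]] <- vapply(ft_order, function(t) {
      v <- cells$n_occ[cells$filetype == t & cells$year == y]
      if (length(v)) v else 0L
    }, integer(1))
  }
  wide$total <- if (length(ft_order)) {
    vapply(ft_order, function(t) sum(cells$n_occ[cells$filetype == t]), integer(1))
  } else integer()

  structure(list(matrix = wide, cells = cells, articles = arts,
                 total_occ = sum(cells$n_occ), min_year = min_year),
            class = "year_filetype_report")
}

#' @export
print.year_filetype_report <- function(x, ...) {
  cat("<year_filetype_report> ", x$total_occ,
      " supplementary accession occurrences\n", sep = "")
  print(x$matrix, n = Inf)
  invisible(x)
}

#' Write a count report (TSV plus a machine-readable JSON twin)
#'
#' @param report A `count_report` or `year_filetype_report`.
#' @param path_tsv TSV output path.
#' @param path_json Optional JSON output path.
#' @return `path_tsv`, invisibly.
#' @export
write_count_report <- function(report, path_tsv, path_json = NULL) {
  tab <- if (inherits(report, "year_filetype_report")) report$matrix else report$table
  utils::write.table(tab, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(path_json)) {
    payload <- if (inherits(report, "year_filetype_report")) {
      list(matrix = report$matrix, cells = report$cells,
           articles = report$articles, total_occ = report$total_occ,
           min_year = report$min_year)
    } else {
      list(kind = report$kind, table = report$table, min_year = report$min_year)
    }
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path_tsv)
}
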