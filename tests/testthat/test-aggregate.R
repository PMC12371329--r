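mk_mention <- function(doc_id, resource_id, kind = "name",
                       nid = if (kind == "name") resource_id else "ID1") {
  tibble::tibble(doc_id = doc_id, resource_id = resource_id,
                 mention_kind = kind, surface = nid, start = 0L, end = 1L,
                 normalized_id = nid)
}

test_that("an article counts once per tier wherever its mention sits", {
  d <- article_docset("PMC1", 2020, abstract = "a", fulltext = "f")
  m <- rbind(mk_mention(abstract_doc_id("PMC1"), "rhea"),
             mk_mention(fulltext_doc_id("PMC1"), "rhea"))
  rep <- count_name_articles(list(d), m)
  row <- rep$table[rep$table$resource_id == "rhea", ]
  expect_identical(c(row$n_medline, row$n_medline_pmc, row$n_all), c(1L, 1L, 1L))
})

test_that("cumulative tiers and gain reproduce the worked example", {
  # 2 abstract-only, 5 fulltext-only, 3 supp-only articles
  docsets <- lapply(1:10, function(i) {
    article_docset(paste0("PMC", i), 2021, abstract = "a", fulltext = "f",
                   supp_docs = paste0("PMC", i, "_s.xlsx"))
  })
  m <- rbind(
    do.call(rbind, lapply(1:2, function(i) mk_mention(abstract_doc_id(paste0("PMC", i)), "rhea"))),
    do.call(rbind, lapply(3:7, function(i) mk_mention(fulltext_doc_id(paste0("PMC", i)), "rhea"))),
    do.call(rbind, lapply(8:10, function(i) mk_mention(paste0("PMC", i, "_s.xlsx"), "rhea"))))
  rep <- count_name_articles(docsets, m)
  row <- rep$table[rep$table$resource_id == "rhea", ]
  expect_identical(c(row$n_medline, row$n_medline_pmc, row$n_all), c(2L, 7L, 10L))
  expect_identical(row$gain_pct, 43)

  empty <- count_name_articles(docsets, m[0, ])
  expect_true(all(empty$table$n_all == 0L))
  expect_true(all(is.na(empty$table$gain_pct)))
})

test_that("the any_of_them row deduplicates across resources", {
  docsets <- list(article_docset("PMC1", 2020, abstract = "a"),
                  article_docset("PMC2", 2020, abstract = "a"))
  m <- rbind(mk_mention(abstract_doc_id("PMC1"), "rhea"),
             mk_mention(abstract_doc_id("PMC1"), "gene_ontology"),
             mk_mention(abstract_doc_id("PMC2"), "rhea"))
  tab <- count_name_articles(docsets, m)$table
  per_res <- sum(tab$n_medline[tab$resource_id != "any_of_them"])
  any_row <- tab$n_medline[tab$resource_id == "any_of_them"]
  expect_identical(per_res, 3L)
  expect_identical(any_row, 2L)
})

test_that("the shared title+abstract region is never counted twice", {
  d <- article_docset("PMC1", 2020, abstract = "a", fulltext = "f")
  m <- rbind(mk_mention(abstract_doc_id("PMC1"), "gene_ontology", "accession", "GO:0005737"),
             mk_mention(fulltext_doc_id("PMC1"), "gene_ontology", "accession", "GO:0005737"))
  tab <- count_accessions(list(d), m)$table
  row <- tab[tab$resource_id == "gene_ontology", ]
  expect_identical(c(row$n_occ_medline, row$n_occ_medline_pmc, row$n_occ_all),
                   c(1L, 1L, 1L))
})

test_that("pct_only_supp follows its arithmetic definition", {
  d <- article_docset("PMC1", 2020, fulltext = "f",
                      supp_docs = "PMC1_s.xlsx")
  m <- rbind(mk_mention("PMC1_s.xlsx", "chebi", "accession", "CHEBI:1"),
             mk_mention("PMC1_s.xlsx", "chebi", "accession", "CHEBI:2"),
             mk_mention("PMC1_s.xlsx", "chebi", "accession", "CHEBI:3"),
             mk_mention(fulltext_doc_id("PMC1"), "chebi", "accession", "CHEBI:9"))
  tab <- count_accessions(list(d), m)$table
  row <- tab[tab$resource_id == "chebi", ]
  expect_identical(row$n_occ_all, 4L)
  expect_equal(row$pct_only_supp, 75)
  expect_identical(nrow(count_accessions(list(d), m[0, ])$table[
    count_accessions(list(d), m[0, ])$table$n_occ_all > 0, ]), 0L)
})

test_that("counting equals brute-force enumeration on random corpora", {
  resources <- c("rhea", "gene_ontology", "chebi", "uniprot")
  for (seed in c(11, 12, 13, 14)) {
    fx <- random_docsets_and_mentions(10, resources, seed)
    got_n <- count_name_articles(fx$docsets, fx$mentions)$table
    exp_n <- oracle_name_counts(fx$docsets, fx$mentions,
                                sort(unique(fx$mentions$resource_id[
                                  fx$mentions$mention_kind == "name"])))
    for (r in exp_n$resource_id) {
      g <- got_n[got_n$resource_id == r, c("n_medline", "n_medline_pmc", "n_all")]
      e <- exp_n[exp_n$resource_id == r, c("n_medline", "n_medline_pmc", "n_all")]
      expect_identical(as.integer(unlist(g)), as.integer(unlist(e)),
                       label = paste("names", r, "seed", seed))
    }
    got_a <- count_accessions(fx$docsets, fx$mentions)$table
    exp_a <- oracle_accession_counts(fx$docsets, fx$mentions,
                                     sort(unique(fx$mentions$resource_id[
                                       fx$mentions$mention_kind == "accession"])))
    for (r in exp_a$resource_id) {
      g <- got_a[got_a$resource_id == r,
                 c("n_occ_medline", "n_occ_medline_pmc", "n_occ_all")]
      e <- exp_a[exp_a$resource_id == r,
                 c("n_occ_medline", "n_occ_medline_pmc", "n_occ_all")]
      expect_identical(as.integer(unlist(g)), as.integer(unlist(e)),
                       label = paste("accessions", r, "seed", seed))
    }
    # cumulative nesting holds on every row of both reports
    expect_true(all(got_n$n_medline <= got_n$n_medline_pmc &
                      got_n$n_medline_pmc <= got_n$n_all))
    expect_true(all(got_a$n_occ_medline <= got_a$n_occ_medline_pmc &
                      got_a$n_occ_medline_pmc <= got_a$n_occ_all))
  }
})

test_that("input order never changes any report", {
  fx <- random_docsets_and_mentions(12, c("rhea", "chebi", "gene_ontology"), 77)
  perm_m <- fx$mentions[withr::with_seed(1, sample(nrow(fx$mentions))), ]
  perm_d <- fx$docsets[withr::with_seed(2, sample(length(fx$docsets)))]
  expect_equal(count_name_articles(perm_d, perm_m)$table,
               count_name_articles(fx$docsets, fx$mentions)$table)
  expect_equal(count_accessions(perm_d, perm_m)$table,
               count_accessions(fx$docsets, fx$mentions)$table)
  recs <- tibble::tibble(doc_id = unlist(lapply(fx$docsets, function(d) d$supp_docs)))
  recs$filetype <- "xlsx"
  expect_equal(year_filetype_matrix(perm_d, perm_m, recs)$matrix,
               year_filetype_matrix(fx$docsets, fx$mentions, recs)$matrix)
})

test_that("articles published before the cutoff year are excluded", {
  docsets <- list(article_docset("PMC1", 1999, abstract = "a"),
                  article_docset("PMC2", 2001, abstract = "a"))
  m <- rbind(mk_mention(abstract_doc_id("PMC1"), "rhea"),
             mk_mention(abstract_doc_id("PMC2"), "rhea"))
  tab <- count_name_articles(docsets, m)$table
  expect_identical(tab$n_medline[tab$resource_id == "rhea"], 1L)
  tab_all <- count_name_articles(docsets, m, min_year = 1990)$table
  expect_identical(tab_all$n_medline[tab_all$resource_id == "rhea"], 2L)
})

test_that("the year-filetype matrix tabulates and conserves totals", {
  docsets <- list(
    article_docset("PMC1", 2022, fulltext = "f",
                   supp_docs = c("PMC1_a.xlsx", "PMC1_b.csv")),
    article_docset("PMC2", 2023, fulltext = "f", supp_docs = "PMC2_a.csv"),
    article_docset("PMC3", 2023, fulltext = "f"))
  recs <- tibble::tibble(doc_id = c("PMC1_a.xlsx", "PMC1_b.csv", "PMC2_a.csv"),
                         filetype = c("xlsx", "csv", "csv"))
  m <- rbind(mk_mention("PMC1_a.xlsx", "chebi", "accession", "CHEBI:1"),
             mk_mention("PMC1_a.xlsx", "chebi", "accession", "CHEBI:2"),
             mk_mention("PMC2_a.csv", "chebi", "accession", "CHEBI:3"),
             mk_mention(fulltext_doc_id("PMC1"), "chebi", "accession", "CHEBI:9"))
  yr <- year_filetype_matrix(docsets, m, recs)
  expect_identical(yr$cells$n_occ[yr$cells$filetype == "xlsx" & yr$cells$year == 2022], 2L)
  expect_identical(yr$cells$n_occ[yr$cells$filetype == "csv" & yr$cells$year == 2023], 1L)
  expect_identical(yr$total_occ, 3L)

  # conservation against the occurrence report: matrix total == supp-only occurrences
  acc <- count_accessions(docsets, m)$table
  tot <- acc[acc$resource_id == "total", ]
  expect_identical(yr$total_occ, tot$n_occ_all - tot$n_occ_medline_pmc)

  # article series: share of articles with supplementary files
  arts <- yr$articles
  expect_equal(arts$pct_with_supp[arts$year == 2022], 100)
  expect_equal(arts$pct_with_supp[arts$year == 2023], 50)
  expect_error(year_filetype_matrix(docsets, m, recs[1:2, ]), "missing")
})

test_that("unknown documents and duplicate article keys are validation errors", {
  d <- article_docset("PMC1", 2020, abstract = "a")
  expect_error(count_name_articles(list(d), mk_mention("PMC9_s.xlsx", "rhea")),
               "unknown doc_id")
  expect_error(
    count_name_articles(list(article_docset("PMC1", 2020, abstract = "a"),
                             article_docset("PMC1", 2021, abstract = "a")),
                        mk_mention(abstract_doc_id("PMC1"), "rhea")),
    "duplicate article_key")
})
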