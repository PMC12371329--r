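test_that("name matching uses lowercasing, word boundaries and exclusions", {
  reg <- mini_registry()
  m <- find_name_mentions("Data from the Rhea knowledgebase", reg)
  expect_identical(nrow(m), 1L)
  expect_identical(m$resource_id, "rhea")
  expect_identical(m$surface, "Rhea")
  expect_identical(substr("Data from the Rhea knowledgebase", m$start + 1, m$end),
                   "Rhea")

  expect_identical(nrow(find_name_mentions("at the spearhead of research", reg)), 0L)
  expect_identical(nrow(find_name_mentions("transferred to the cath lab", reg)), 0L)
  expect_identical(nrow(find_name_mentions("", reg)), 0L)
  # case-insensitive, punctuation boundaries
  m2 <- find_name_mentions("see RHEA, and rhea; but not rheab", reg)
  expect_identical(nrow(m2), 2L)
})

test_that("accession matching honors namespace-space tolerance and normalization", {
  reg <- default_registry()
  m <- find_accession_mentions("localized to GO: 0005739 compartment", reg)
  expect_identical(nrow(m), 1L)
  expect_identical(m$resource_id, "gene_ontology")
  expect_identical(m$normalized_id, "GO:0005739")
  expect_identical(m$surface, "GO: 0005739")
  # offsets address the original text
  expect_identical(substr("localized to GO: 0005739 compartment",
                          m$start + 1, m$end), m$surface)

  expect_identical(nrow(find_accession_mentions("tagged GO:123 here", reg)), 0L)
  expect_identical(nrow(find_accession_mentions("", reg)), 0L)
})

test_that("prefix forcing admits the prefixed form and only it", {
  reg <- default_registry()
  m <- find_accession_mentions("UniProt:Q8VRN4 was studied", reg)
  expect_identical(m$resource_id, "uniprot")
  expect_identical(m$normalized_id, "Q8VRN4")
  expect_identical(nrow(find_accession_mentions("the protein Q8VRN4 was studied",
                                                reg)), 0L)
  expect_identical(
    find_accession_mentions("uniprot: q19724 appears lowercased", reg)$resource_id,
    "uniprot")
  m2 <- find_accession_mentions("known in col:4QHKG only", reg)
  expect_identical(m2$resource_id, "col")
  expect_identical(m2$normalized_id, "4QHKG")
  # a bare whitespace separator is not accepted
  expect_identical(nrow(find_accession_mentions("UniProt Q8VRN4", reg)), 0L)
})

test_that("every published exemplar accession resolves to its resource", {
  reg <- default_registry()
  exemplars <- c(flybase = "FBgn0003074", ensembl = "ENSG00000176261.11",
                 interpro = "IPR013770", chembl = "CHEMBL1148970",
                 reactome = "R-HSA-2168880", zfin = "ZDB-GENE-030820-3",
                 chebi = "chebi: 18034", gwas_catalog = "GCST90017001",
                 pharmgkb = "PA444801", rgd = "RGD: 69310",
                 gene_ontology = "GO: 0005737", bgee = "FBgn0036915",
                 human_protein_atlas = "ENSG00000122862")
  for (rid in names(exemplars)) {
    text <- paste("as listed under", exemplars[[rid]], "in the table")
    m <- find_accession_mentions(text, reg)
    expect_identical(sum(m$resource_id == rid), 1L, label = rid)
    hit <- m[m$resource_id == rid, ]
    expect_identical(hit$normalized_id, gsub(" ", "", exemplars[[rid]], fixed = TRUE))
  }
})

test_that("shared identifier schemes coexist at overlapping offsets", {
  reg <- default_registry()
  m <- find_accession_mentions("gene ENSG00000176261.11 was assayed", reg)
  expect_setequal(unique(m$resource_id), c("ensembl", "human_protein_atlas", "bgee"))
  # leftmost-longest within one resource: ensembl takes the versioned span
  expect_identical(m$normalized_id[m$resource_id == "ensembl"], "ENSG00000176261.11")
  expect_identical(m$normalized_id[m$resource_id == "human_protein_atlas"],
                   "ENSG00000176261")
  # the truncated identifier of the published audit error is Bgee-only
  m2 <- find_accession_mentions("listed as FBgn003202 in the table", reg)
  expect_identical(unique(m2$resource_id), "bgee")
})

test_that("mentions never touch adjacent word characters and stay pattern-valid", {
  reg <- default_registry()
  texts <- c("xGO:0005737 GO:0005737x GO:0005737",
             "CHEMBL1148970CHEMBL GCST90017001.5 IPR013770_x",
             "see ENSG00000176261.11, FBgn0003074; PA444801!")
  ci <- stringi::stri_opts_regex(case_insensitive = TRUE)
  for (text in texts) {
    m <- rbind(find_name_mentions(text, reg), find_accession_mentions(text, reg))
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(m))) {
      if (m$start[i] > 0) expect_false(grepl("[a-zA-Z0-9_]", chars[m$start[i]]))
      if (m$end[i] < length(chars)) {
        expect_false(grepl("[a-zA-Z0-9_]", chars[m$end[i] + 1]))
      }
      if (m$mention_kind[i] == "accession") {
        pat <- registry_resource(reg, m$resource_id[i])$accession_pattern
        expect_true(stringi::stri_detect_regex(
          m$normalized_id[i], paste0("^(?:", pat, ")$"), opts_regex = ci),
          label = paste(m$resource_id[i], m$normalized_id[i]))
      }
    }
  }
  # only the first GO token in the boundary text is free-standing
  m <- find_accession_mentions(texts[1], reg)
  expect_identical(nrow(m), 1L)
  expect_identical(m$start, 24L)
})

test_that("appending text preserves existing mentions and their offsets", {
  reg <- default_registry()
  base <- "study of GO:0005737 with UniProt:Q8VRN4 and the Rhea knowledgebase"
  m0 <- rbind(find_name_mentions(base, reg), find_accession_mentions(base, reg))
  grown <- paste(base, "further text with CHEMBL1148970 and spearhead decoys")
  m1 <- rbind(find_name_mentions(grown, reg), find_accession_mentions(grown, reg))
  m1_prefix <- m1[m1$end <= nchar(base), names(m0)]
  expect_identical(sort_by_pos(m1_prefix), sort_by_pos(m0))
  expect_true(nrow(m1) > nrow(m0))
})

test_that("matcher output equals the brute-force scanner on random texts", {
  reg <- default_registry()
  texts <- withr::with_seed(1234, replicate(20, random_match_text()))
  for (text in texts) {
    expect_matches_oracle(text, reg)
  }
})

test_that("the audit sampler is deterministic and counts planted corruption", {
  reg <- mini_registry()
  ids <- sprintf("GO:%07d", 1:100)
  ids[37] <- "GO:0000000"  # corrupted: not in the known-identifier list
  mentions <- tibble::tibble(doc_id = "d", resource_id = "gene_ontology",
                             mention_kind = "accession", surface = ids,
                             start = 0L, end = 1L, normalized_id = ids)
  known <- sprintf("GO:%07d", 1:100)
  audit <- audit_sample(mentions, n = 100, seed = 5,
                        validator = function(id) id %in% known)
  expect_identical(attr(audit, "n_total"), 100L)
  expect_identical(sum(audit$n_correct), 99L)
  expect_equal(attr(audit, "accuracy"), 0.99)

  audit2 <- audit_sample(mentions, n = 100, seed = 5,
                         validator = function(id) id %in% known)
  expect_identical(audit, audit2)

  all_ok <- audit_sample(mentions[1:10, ], n = 10, seed = 1,
                         validator = function(id) TRUE)
  expect_identical(all_ok$n_correct, all_ok$n_sampled)
  expect_error(audit_sample(mentions[0, ], 5, 1, function(id) TRUE),
               "no accession mentions")
})
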