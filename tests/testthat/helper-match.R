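# Helpers for comparing the matcher against the brute-force oracle.

sort_by_pos <- function(m) {
  m <- m[order(m$start, m$resource_id, m$normalized_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Random text mixing filler, genuine accessions, names, decoys, and noisy
# near-miss tokens; uses the generator's samplers under the ambient seed.
random_match_text <- function(n_tokens = NULL) {
  if (is.null(n_tokens)) n_tokens <- sample(40:120, 1)
  rids <- suppminer:::plantable_resources()
  noise <- c("GO:123", "GO:12345678", "IPR13770", "ens", "fb", "Q8VRN4",
             "uniprot:Z9ZZZ9", "col 4QHKG", "cath lab", "spearhead",
             "R-HSA-", "ZDB-GENE-1-1", "CVCL_12", "stringdb")
  names_pool <- c("Gene ontology", "UniProt", "Rhea", "FlyBase",
                  "Catalogue of life", "STRING", "CATH", "Human protein atlas")
  toks <- replicate(n_tokens, {
    u <- runif(1)
    if (u < 0.70) sample(suppminer:::filler_words(), 1)
    else if (u < 0.85) suppminer:::sample_accession(sample(rids, 1),
                                                    spaced = runif(1) < 0.2)
    else if (u < 0.93) sample(noise, 1)
    else sample(names_pool, 1)
  })
  paste(toks, collapse = " ")
}

expect_matches_oracle <- function(text, reg) {
  cols <- c("resource_id", "start", "end", "normalized_id")
  got_n <- find_name_mentions(text, reg)
  exp_n <- naive_name_scan(text, reg)
  expect_identical(as.data.frame(sort_by_pos(got_n[, cols])),
                   as.data.frame(sort_by_pos(exp_n[, cols])),
                   label = paste("names on:", substr(text, 1, 60)))
  got_a <- find_accession_mentions(text, reg)
  exp_a <- naive_accession_scan(text, reg)
  expect_identical(as.data.frame(sort_by_pos(got_a[, cols])),
                   as.data.frame(sort_by_pos(exp_a[, cols])),
                   label = paste("accessions on:", substr(text, 1, 60)))
  invisible(NULL)
}
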