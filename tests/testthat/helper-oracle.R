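# Independent brute-force oracles: a character-by-character scanner for the
# matcher and a plain enumeration for the counting logic. Both reimplement
# the documented rules from scratch (substring enumeration + anchored
# full-match tests) so they share no scanning code with the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# doc ids of files the generator deliberately corrupted
corrupted_doc_ids <- function(man) {
  out <- character()
  for (a in man$articles) {
    for (f in a$files) {
      if (isTRUE(f$corrupted)) out <- c(out, paste0(a$pmcid, "_", f$filename))
    }
  }
  out
}

.is_word_chr <- function(ch) grepl("^[a-z0-9_]$", tolower(ch))

# all word-boundary start positions of a text (1-based)
.word_starts <- function(chars) {
  n <- length(chars)
  if (!n) return(integer())
  w <- vapply(chars, .is_word_chr, logical(1))
  which(w & !c(FALSE, w[-n]))
}

naive_name_scan <- function(text, reg) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tl <- tolower(text)
  out <- list()
  for (res in reg$resources) {
    if (res$name_excluded) next
    for (v in unique(c(res$display_name, res$name_variants))) {
      vl <- tolower(v)
      L <- nchar(vl)
      if (L > n) next
      starts <- 1:(n - L + 1)
      hits <- starts[stringi::stri_sub(tl, starts, starts + L - 1) == vl]
      for (s in hits) {
        left_ok <- s == 1 || !.is_word_chr(chars[s - 1])
        right_ok <- s + L - 1 == n || !.is_word_chr(chars[s + L])
        if (left_ok && right_ok) {
          out[[length(out) + 1L]] <- data.frame(
            resource_id = res$resource_id, start = s - 1L, end = s + L - 1L,
            normalized_id = vl, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(resource_id = character(), start = integer(),
                      end = integer(), normalized_id = character()))
  }
  d <- do.call(rbind, out)
  d[order(d$start, d$resource_id), , drop = FALSE]
}

naive_accession_scan <- function(text, reg, max_len = 40L) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  starts <- .word_starts(chars)
  if (!length(starts)) {
    return(data.frame(resource_id = character(), start = integer(),
                      end = integer(), normalized_id = character()))
  }
  # candidate substrings: word-boundary start, all lengths, right-bounded
  cand <- do.call(rbind, lapply(starts, function(s) {
    e <- s:min(n, s + max_len - 1L)
    ok <- vapply(e, function(x) x == n || !.is_word_chr(chars[x + 1]), logical(1))
    if (!any(ok)) return(NULL)
    data.frame(s = s, e = e[ok])
  }))
  cand$str <- stringi::stri_sub(text, cand$s, cand$e)
  # one space after a colon is tolerated, and removed for the match test
  cand$probe <- gsub(": ", ":", cand$str, fixed = TRUE)
  out <- list()
  ci <- stringi::stri_opts_regex(case_insensitive = TRUE)
  for (res in reg$resources) {
    if (is.null(res$accession_pattern)) next
    full <- paste0("^(?:", res$accession_pattern, ")$")
    hit <- stringi::stri_detect_regex(cand$probe, full, opts_regex = ci)
    if (res$prefix_required) {
      hit <- hit & vapply(seq_len(nrow(cand)), function(i) {
        if (!hit[i]) return(FALSE)
        ctx <- stringi::stri_sub(text, max(1L, cand$s[i] - 20L), cand$s[i] - 1L)
        toks <- paste(tolower(res$prefix_tokens), collapse = "|")
        grepl(paste0("(^|[^a-z0-9_])(", toks, "): ?$"), ctx,
              ignore.case = TRUE, perl = TRUE)
      }, logical(1))
    }
    hits <- cand[hit, , drop = FALSE]
    if (!nrow(hits)) next
    # leftmost-longest, non-overlapping within one resource
    hits <- hits[order(hits$s, -(hits$e - hits$s)), , drop = FALSE]
    taken_end <- 0L
    for (i in seq_len(nrow(hits))) {
      if (hits$s[i] <= taken_end) next
      taken_end <- hits$e[i]
      out[[length(out) + 1L]] <- data.frame(
        resource_id = res$resource_id, start = hits$s[i] - 1L, end = hits$e[i],
        normalized_id = gsub("[ \t\r\n]+", "", hits$str[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(resource_id = character(), start = integer(),
                      end = integer(), normalized_id = character()))
  }
  d <- do.call(rbind, out)
  d <- d[order(d$start, d$resource_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# ---- counting enumeration -------------------------------------------------

oracle_name_counts <- function(docsets, mentions, resources, min_year = 2000) {
  m <- mentions[mentions$mention_kind == "name", , drop = FALSE]
  tier <- function(rid_filter) {
    n1 <- n2 <- n3 <- 0L
    for (d in docsets) {
      if (d$year < min_year) next
      sel <- if (is.null(rid_filter)) rep(TRUE, nrow(m)) else m$resource_id == rid_filter
      in_abs <- !is.null(d$abstract) &&
        any(sel & m$doc_id == abstract_doc_id(d$article_key))
      in_ful <- !is.null(d$fulltext) &&
        any(sel & m$doc_id == fulltext_doc_id(d$article_key))
      in_sup <- any(sel & m$doc_id %in% c(d$supp_docs, d$figure_docs))
      n1 <- n1 + in_abs
      n2 <- n2 + (in_abs || in_ful)
      n3 <- n3 + (in_abs || in_ful || in_sup)
    }
    c(n1, n2, n3)
  }
  rows <- lapply(resources, function(r) c(list(r), as.list(tier(r))))
  rows <- c(rows, list(c(list("any_of_them"), as.list(tier(NULL)))))
  do.call(rbind, lapply(rows, function(x)
    data.frame(resource_id = x[[1]], n_medline = x[[2]], n_medline_pmc = x[[3]],
               n_all = x[[4]], stringsAsFactors = FALSE)))
}

oracle_accession_counts <- function(docsets, mentions, resources,
                                    min_year = 2000) {
  m <- mentions[mentions$mention_kind == "accession", , drop = FALSE]
  rows <- lapply(resources, function(r) {
    n1 <- n2 <- n3 <- 0L
    for (d in docsets) {
      if (d$year < min_year) next
      sel <- m$resource_id == r
      abs_m <- m$normalized_id[sel & m$doc_id == abstract_doc_id(d$article_key)]
      ful_m <- m$normalized_id[sel & m$doc_id == fulltext_doc_id(d$article_key)]
      sup_m <- m$normalized_id[sel & m$doc_id %in% c(d$supp_docs, d$figure_docs)]
      ids <- unique(c(abs_m, ful_m, sup_m))
      for (id in ids) {
        a <- sum(abs_m == id); f <- sum(ful_m == id); s <- sum(sup_m == id)
        n1 <- n1 + a
        n2 <- n2 + max(a, f)
        n3 <- n3 + max(a, f) + s
      }
    }
    data.frame(resource_id = r, n_occ_medline = n1, n_occ_medline_pmc = n2,
               n_occ_all = n3, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- shared fixtures ------------------------------------------------------

# small registry exercising every matching rule without the full roster
mini_registry <- function() {
  registry(list(
    resource_definition("gene_ontology", "Gene ontology",
                        accession_pattern = "GO:\\d{7}"),
    resource_definition("rhea", "Rhea", accession_pattern = "RHEA:\\d{5}"),
    resource_definition("uniprot", "UniProt",
                        accession_pattern = "[OPQ][0-9][A-Z0-9]{3}[0-9]",
                        prefix_required = TRUE, prefix_tokens = "uniprot"),
    resource_definition("cath", "CATH", accession_pattern = "[1-6]\\.\\d+\\.\\d+\\.\\d+",
                        name_excluded = TRUE,
                        name_exclusion_reason = "catheter abbreviation")),
    version_label = "mini")
}

# random mention tibble over a set of synthetic docsets (no texts involved;
# counting operates on mentions + docsets alone)
random_docsets_and_mentions <- function(n_articles, resources, seed) {
  withr::with_seed(seed, {
    docsets <- lapply(seq_len(n_articles), function(i) {
      article_docset(sprintf("PMC%07d", i),
                     year = sample(1998:2023, 1),
                     abstract = if (runif(1) < 0.9) "a" else NULL,
                     fulltext = if (runif(1) < 0.8) "f" else NULL,
                     supp_docs = if (runif(1) < 0.7) {
                       sprintf("PMC%07d_supp%d.xlsx", i, seq_len(sample(2, 1)))
                     } else character())
    })
    rows <- list()
    for (d in docsets) {
      slots <- c(if (!is.null(d$abstract)) abstract_doc_id(d$article_key),
                 if (!is.null(d$fulltext)) fulltext_doc_id(d$article_key),
                 d$supp_docs)
      if (!length(slots)) next
      for (k in seq_len(sample(0:6, 1))) {
        rid <- sample(resources, 1)
        kind <- sample(c("name", "accession"), 1)
        nid <- if (kind == "accession") paste0("ID", sample(5, 1)) else tolower(rid)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          doc_id = sample(slots, 1), resource_id = rid, mention_kind = kind,
          surface = nid, start = 0L, end = 1L, normalized_id = nid)
      }
    }
    mentions <- do.call(rbind, c(list(tibble::tibble(
      doc_id = character(), resource_id = character(), mention_kind = character(),
      surface = character(), start = integer(), end = integer(),
      normalized_id = character())), rows))
    list(docsets = docsets, mentions = mentions)
  })
}
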