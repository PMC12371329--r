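# Synthetic article-bundle corpus with a ground-truth manifest.
#
# The generator emulates PMC OA article bundles: one manuscript XML stub per
# article plus supplementary files in the supported formats, with planted
# resource names, planted accession numbers (reverse-sampled from the
# registry patterns), decoy strings that must never match, and optional
# deliberately corrupted files. The manifest records every planted mention,
# so pipeline recall and precision are measurable exactly.

# Filler vocabulary. Chosen so that no word, and no pair of adjacent words,
# can collide with a registry name or accession pattern (no digits, no
# resource-name words); verified by test.
filler_words <- function() {
  c("the", "of", "and", "in", "measured", "samples", "analysis", "results",
    "values", "control", "treated", "cells", "growth", "assay", "binding",
    "observed", "significant", "increase", "decrease", "method", "buffer",
    "solution", "replicate", "median", "cluster", "pathway", "signal",
    "expression", "tissue", "mouse", "variant", "sequence", "alignment",
    "domain", "fold", "change", "annotation", "curation", "dataset",
    "figure", "experiment", "condition", "temperature", "supernatant",
    "lysate", "incubation", "dilution", "fraction")
}

filler <- function(n) paste(sample(filler_words(), n, replace = TRUE), collapse = " ")

rand_digits <- function(n, first_nonzero = FALSE) {
  d <- sample(0:9, n, replace = TRUE)
  if (first_nonzero) d[1] <- sample(1:9, 1)
  paste(d, collapse = "")
}

rand_upper <- function(n) paste(sample(LETTERS, n, replace = TRUE), collapse = "")

# Reverse-sample one accession for a resource. Digit-run lengths are chosen
# so that a sampled identifier never creates an isolated four-character
# digit-led token (which would collide with the Protein Data Bank pattern).
# `spaced` plants the namespace-colon variant with one space ("GO: 0005737").
sample_accession <- function(resource_id, spaced = FALSE) {
  tok <- switch(resource_id,
    gene_ontology = paste0("GO:", rand_digits(7)),
    chebi = paste0("CHEBI:", rand_digits(5)),
    ensembl = paste0("ENSG", rand_digits(11)),
    human_protein_atlas = paste0("ENSG", rand_digits(11)),
    flybase = paste0("FBgn", rand_digits(7)),
    bgee = paste0("FBgn", rand_digits(6)),  # truncated FlyBase shape: Bgee-only
    interpro = paste0("IPR", rand_digits(6)),
    chembl = paste0("CHEMBL", rand_digits(7)),
    reactome = paste0("R-HSA-", rand_digits(7, TRUE)),
    zfin = paste0("ZDB-GENE-", rand_digits(6), "-", rand_digits(1, TRUE)),
    gwas_catalog = paste0("GCST", rand_digits(8)),
    pharmgkb = paste0("PA", rand_digits(6, TRUE)),
    rgd = paste0("RGD:", rand_digits(5, TRUE)),
    uniprot = paste0("UniProt:Q", sample(0:9, 1), rand_upper(3), sample(0:9, 1)),
    col = paste0("col:", paste(sample(strsplit("23456789BCDFGHJKLMNPQRSTVWXYZ", "")[[1]],
                                      5, replace = TRUE), collapse = "")),
    cellosaurus = paste0("CVCL_", rand_digits(4)),
    imex = paste0("IM-", rand_digits(5, TRUE)),
    proteomexchange = paste0("PXD", rand_digits(6)),
    sgd = paste0("S", rand_digits(9)),
    wormbase = paste0("WBGene", rand_digits(8)),
    panther = paste0("PTHR", rand_digits(5)),
    lipid_maps = paste0("LMFA", rand_digits(8)),
    rhea = paste0("RHEA:", rand_digits(5)),
    bacdive = paste0("BACDIVE:", rand_digits(6, TRUE)),
    pombase = paste0("SP", sample(c("AC", "BC", "CC"), 1), rand_digits(4), ".",
                     rand_digits(2)),
    pdb = paste0(sample(1:9, 1), rand_upper(3)),
    brenda = paste0("7.", sample(1:9, 1), ".", sample(1:9, 1), ".", sample(1:99, 1)),
    cath = paste0(sample(1:6, 1), ".", sample(10:99, 1), ".", sample(1:9, 1), ".",
                  sample(10:99, 1)),
    string = paste0(rand_digits(5, TRUE), ".ENSP", rand_digits(11)),
    civic = paste0("civic.vid:", sample(10:999, 1)),
    stop("no accession sampler for resource '", resource_id, "'", call. = FALSE))
  if (spaced && grepl(":", tok, fixed = TRUE) && !grepl("^UniProt|^col", tok)) {
    tok <- sub(":", ": ", tok, fixed = TRUE)
  }
  tok
}

# Resources whose sampled identifiers are, by construction, also valid
# identifiers of other resources (Bgee and the Human Protein Atlas reuse
# Ensembl/FlyBase identifiers; CATH superfamily codes are shaped like EC
# numbers; STRING qualifies Ensembl protein ids with a taxon).
cross_resources <- function(resource_id) {
  switch(resource_id,
    ensembl = c("ensembl", "human_protein_atlas", "bgee"),
    human_protein_atlas = c("human_protein_atlas", "ensembl", "bgee"),
    flybase = c("flybase", "bgee"),
    string = c("string", "ensembl", "bgee"),
    cath = c("cath", "brenda"),
    resource_id)
}

plantable_resources <- function() {
  c("gene_ontology", "chebi", "ensembl", "human_protein_atlas", "flybase",
    "bgee", "interpro", "chembl", "reactome", "zfin", "gwas_catalog",
    "pharmgkb", "rgd", "uniprot", "col", "cellosaurus", "imex",
    "proteomexchange", "sgd", "wormbase", "panther", "lipid_maps", "rhea",
    "bacdive", "pombase", "pdb", "brenda", "cath", "string", "civic")
}

decoy_strings <- function() c("spearhead", "cath lab", "Q8VRN4", "GO:123")

#' Specify a synthetic corpus
#'
#' The defaults describe the study conditions the generator emulates:
#' publication years of the later open-access era, roughly 80% of articles
#' carrying supplementary files, a file-type mix dominated by spreadsheets,
#' and accession numbers placed overwhelmingly in the supplementary files
#' with only a small minority in abstracts or full-text bodies.
#'
#' @param n_articles Number of articles.
#' @param year_range Inclusive pair of publication years.
#' @param supp_prob Probability an article has supplementary files.
#' @param max_supp_files Maximum supplementary files per article.
#' @param filetype_weights Named sampling weights over the generated
#'   supplementary file types.
#' @param accessions_per_file Inclusive range of accessions planted per
#'   supplementary file.
#' @param acc_resources Resources to draw planted accessions from (must all
#'   carry patterns).
#' @param name_resources Resources whose names are planted in abstracts,
#'   full texts and supplementary files.
#' @param p_name_abstract,p_name_body,p_name_supp Per-article probabilities
#'   of planting one resource name in the given slot.
#' @param p_acc_abstract,p_acc_body Per-article probabilities of one
#'   accession occurring in the abstract / full-text body (kept small: in
#'   real corpora almost all accession occurrences sit in the
#'   supplementary files).
#' @param p_spaced Probability a namespace-prefixed accession is planted
#'   with one space after the colon ("GO: 0005737").
#' @param n_decoys Total decoy strings planted across the corpus.
#' @param corruption Named list, filetype -> number of files of that type
#'   to corrupt deliberately.
#' @param seed Integer seed; a fixed seed gives a byte-identical manifest.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_articles = 200,
                        year_range = c(2018, 2023),
                        supp_prob = 0.8,
                        max_supp_files = 3,
                        filetype_weights = c(xlsx = 0.40, csv = 0.12, txt = 0.10,
                                             docx = 0.12, pdf = 0.11, html = 0.08,
                                             xml = 0.07),
                        accessions_per_file = c(2, 8),
                        acc_resources = plantable_resources(),
                        name_resources = c("gene_ontology", "uniprot", "ensembl",
                                           "reactome", "rhea", "flybase", "chebi",
                                           "human_protein_atlas", "cellosaurus",
                                           "interpro"),
                        p_name_abstract = 0.35, p_name_body = 0.5, p_name_supp = 0.25,
                        p_acc_abstract = 0.04, p_acc_body = 0.15,
                        p_spaced = 0.05,
                        n_decoys = 60,
                        corruption = list(),
                        seed = 1L) {
  stopifnot(n_articles >= 1, length(year_range) == 2, year_range[1] <= year_range[2],
            supp_prob >= 0, supp_prob <= 1, max_supp_files >= 1,
            all(filetype_weights >= 0), length(accessions_per_file) == 2,
            accessions_per_file[1] >= 0,
            accessions_per_file[1] <= accessions_per_file[2],
            n_decoys >= 0)
  structure(list(n_articles = as.integer(n_articles),
                 year_range = as.integer(year_range), supp_prob = supp_prob,
                 max_supp_files = as.integer(max_supp_files),
                 filetype_weights = filetype_weights,
                 accessions_per_file = as.integer(accessions_per_file),
                 acc_resources = acc_resources, name_resources = name_resources,
                 p_name_abstract = p_name_abstract, p_name_body = p_name_body,
                 p_name_supp = p_name_supp, p_acc_abstract = p_acc_abstract,
                 p_acc_body = p_acc_body, p_spaced = p_spaced,
                 n_decoys = as.integer(n_decoys), corruption = corruption,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

# ---- file content builders ------------------------------------------------

build_supp_file <- function(path, filetype, acc_tokens, name_tokens, decoy_tokens) {
  w <- function(k) filler(k)
  extra <- c(name_tokens, decoy_tokens)
  switch(filetype,
    xlsx = {
      rows <- rbind(c("identifier", "annotation", "note"),
                    t(vapply(acc_tokens, function(a) c(a, w(1), w(2)),
                             character(3))))
      sheets <- list(data = rows)
      if (length(extra)) {
        sheets$notes <- cbind(extra, vapply(seq_along(extra), function(i) w(2),
                                            character(1)))
      }
      write_xlsx_min(path, sheets)
    },
    csv = {
      lines <- c("identifier,annotation,note",
                 vapply(acc_tokens, function(a) paste(a, w(1), w(2), sep = ","),
                        character(1)),
                 vapply(extra, function(e) paste(e, w(1), w(1), sep = ","),
                        character(1)))
      writeLines(lines, path, useBytes = TRUE)
    },
    txt = {
      lines <- c(vapply(acc_tokens, function(a) paste(w(3), a, w(3)), character(1)),
                 vapply(extra, function(e) paste(w(2), e, w(2)), character(1)))
      writeLines(lines, path, useBytes = TRUE)
    },
    docx = {
      # when accessions are planted, at least one sits inside a document table
      n_tab <- min(2L, length(acc_tokens))
      in_tab <- acc_tokens[seq_len(n_tab)]
      in_par <- if (n_tab) acc_tokens[-seq_len(n_tab)] else character()
      paragraphs <- c(w(8),
                      vapply(in_par, function(a) paste(w(4), a, w(4)), character(1)),
                      vapply(extra, function(e) paste(w(2), e, w(2)), character(1)))
      tab <- if (n_tab) t(vapply(in_tab, function(a) c(a, w(2)), character(2)))
             else NULL
      write_docx_min(path, paragraphs, table_rows = tab)
    },
    pdf = {
      lines <- c(w(6),
                 vapply(acc_tokens, function(a) paste(w(2), a, w(2)), character(1)),
                 vapply(extra, function(e) paste(w(2), e, w(1)), character(1)))
      write_pdf_min(path, lines)
    },
    html = {
      tr <- vapply(acc_tokens, function(a)
        paste0("<tr><td>", xml_escape(a), "</td><td>", w(2), "</td></tr>"),
        character(1))
      ps <- vapply(extra, function(e)
        paste0("<p>", xml_escape(paste(w(2), e, w(2))), "</p>"), character(1))
      writeLines(c("<html><head><title>supplementary table</title></head><body>",
                   paste0("<p>", w(6), "</p>"),
                   "<table>", tr, "</table>", ps, "</body></html>"),
                 path, useBytes = TRUE)
    },
    xml = {
      recs <- vapply(acc_tokens, function(a)
        paste0("<record><id>", xml_escape(a), "</id><desc>", w(3), "</desc></record>"),
        character(1))
      notes <- vapply(extra, function(e)
        paste0("<note>", xml_escape(paste(w(1), e, w(1))), "</note>"), character(1))
      writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
                   "<records>", recs, notes, "</records>"), path, useBytes = TRUE)
    },
    stop("no builder for filetype '", filetype, "'", call. = FALSE))
  invisible(path)
}

# ---- corruption -----------------------------------------------------------

default_corrupt_mode <- function(filetype) {
  switch(filetype,
    # truncation destroys the archive's central directory; damaging only the
    # first local header is not enough for readers that trust the directory
    xlsx = , docx = "truncate",
    csv = , txt = , html = "badbytes",
    xml = "truncate",
    pdf = "garbage",
    "truncate")
}

#' Deliberately corrupt a generated file
#'
#' Produces a deterministically corrupted variant that the extractor must
#' classify as `failed`: truncation, invalid-encoding byte injection for
#' delimited text, archive-header damage for OOXML containers, or header
#' garbage for PDF. Emulates the formatting and encoding defects observed
#' in real supplementary files.
#'
#' @param path File to corrupt in place.
#' @param filetype Lowercase extension token.
#' @param mode One of `"auto"` (type-appropriate default), `"truncate"`,
#'   `"badbytes"`, `"zipdamage"`, `"garbage"`, `"none"`.
#' @param seed Integer seed driving the randomized modes.
#' @return The corrupted bytes, invisibly (also written back to `path`).
#' @export
corrupt_file <- function(path, filetype, mode = "auto", seed = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  modes <- c("auto", "truncate", "badbytes", "zipdamage", "garbage", "none")
  if (!mode %in% modes) {
    stop("unknown corruption mode '", mode, "'", call. = FALSE)
  }
  if (mode == "auto") mode <- default_corrupt_mode(filetype)
  raw <- readBin(path, "raw", n = file.size(path))
  out <- withr::with_seed(seed, switch(mode,
    none = raw,
    truncate = raw[seq_len(max(1L, length(raw) %/% 2L))],
    badbytes = {
      at <- if (length(raw) > 4) sample.int(length(raw) - 1L, 1) else 1L
      append(raw, as.raw(c(0xff, 0xfe, 0x81, 0x00)), after = at)
    },
    zipdamage = { raw[1:4] <- as.raw(0); raw },
    garbage = as.raw(sample.int(256, max(64L, length(raw) %/% 4L), replace = TRUE) - 1L)
  ))
  writeBin(out, path)
  invisible(out)
}

# ---- generation -----------------------------------------------------------

#' Generate a synthetic article-bundle corpus
#'
#' Writes one directory per article (named by PMCID) containing a
#' manuscript XML stub and supplementary files with planted content, plus a
#' `manifest.json` ground-truth manifest recording every planted mention
#' (including the coincidental cross-resource identities of shared
#' identifier schemes), every decoy, and every corrupted file. With a fixed
#' seed the manifest and all planted content are reproduced identically.
#'
#' @param spec A [corpus_spec()].
#' @param reg A [registry()] supplying patterns for the planted accessions.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (class `corpus_manifest`); also written
#'   to `file.path(out_dir, "manifest.json")`.
#' @export
generate_corpus <- function(spec, reg = default_registry(), out_dir) {
  stopifnot(inherits(spec, "corpus_spec"))
  for (r in spec$acc_resources) {
    res <- registry_resource(reg, r)
    if (is.null(res)) stop("unknown resource in acc_resources: '", r, "'", call. = FALSE)
    if (is.null(res$accession_pattern)) {
      stop("resource '", r, "' has no accession pattern; cannot plant accessions",
           call. = FALSE)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create corpus directory: ", out_dir, call. = FALSE)

  manifest <- withr::with_seed(spec$seed, generate_corpus_impl(spec, reg, out_dir))
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

generate_corpus_impl <- function(spec, reg, out_dir) {
  years <- seq(spec$year_range[1], spec$year_range[2])
  ftypes <- names(spec$filetype_weights)
  articles <- vector("list", spec$n_articles)

  # pre-assign decoys to (article, slot)
  decoy_at <- if (spec$n_decoys > 0) {
    tibble::tibble(article = sample.int(spec$n_articles, spec$n_decoys, replace = TRUE),
                   decoy = sample(decoy_strings(), spec$n_decoys, replace = TRUE),
                   slot = sample(c("abstract", "body", "supp"), spec$n_decoys,
                                 replace = TRUE, prob = c(0.3, 0.4, 0.3)))
  } else tibble::tibble(article = integer(), decoy = character(), slot = character())

  plant_name <- function(p) {
    if (length(spec$name_resources) && runif(1) < p) sample(spec$name_resources, 1) else NULL
  }
  name_string <- function(rid) registry_resource(reg, rid)$display_name

  for (i in seq_len(spec$n_articles)) {
    pmcid <- sprintf("PMC9%06d", i)
    year <- sample(years, 1)
    art_decoys <- decoy_at[decoy_at$article == i, , drop = FALSE]

    mention_rows <- list()
    note <- function(doc_id, resource_id, kind, normalized_id) {
      mention_rows[[length(mention_rows) + 1L]] <<-
        list(doc_id = doc_id, resource_id = resource_id, mention_kind = kind,
             normalized_id = normalized_id)
    }
    note_accession <- function(doc_id, rid, token) {
      norm <- compact_ws(sub("^(UniProt|col):\\s?", "", token))
      for (r in cross_resources(rid)) {
        # a STRING identifier's Ensembl/Bgee identity is the protein id
        # without the taxon qualifier
        sub_norm <- if (rid == "string" && r != "string") {
          sub("^\\d+\\.", "", norm)
        } else norm
        note(doc_id, r, "accession", sub_norm)
      }
      # a namespace prefix that is itself a searchable resource name
      # ("CHEBI: 18034", "UniProt:Q8VRN4") is a bounded word and therefore
      # also a legitimate name mention
      if (rid %in% c("chebi", "rhea", "bacdive", "uniprot")) {
        note(doc_id, rid, "name",
             tolower(registry_resource(reg, rid)$display_name))
      }
    }

    abs_id <- abstract_doc_id(pmcid)
    ful_id <- fulltext_doc_id(pmcid)

    # abstract: filler + optional name + rare accession + assigned decoys
    abs_parts <- c(filler(25))
    nm <- plant_name(spec$p_name_abstract)
    if (!is.null(nm)) {
      abs_parts <- c(abs_parts, paste(filler(2), name_string(nm), filler(2)))
      note(abs_id, nm, "name", tolower(name_string(nm)))
    }
    abs_acc <- NULL
    if (runif(1) < spec$p_acc_abstract) {
      rid <- sample(spec$acc_resources, 1)
      abs_acc <- list(rid = rid, tok = sample_accession(rid, runif(1) < spec$p_spaced))
      abs_parts <- c(abs_parts, paste(filler(1), abs_acc$tok, filler(1)))
      note_accession(abs_id, abs_acc$rid, abs_acc$tok)
    }
    abs_parts <- c(abs_parts, art_decoys$decoy[art_decoys$slot == "abstract"])
    abstract <- paste(abs_parts, collapse = " ")

    # full text = abstract + body (the shared title+abstract region is
    # repeated, as in real PMC renditions)
    body_parts <- c(filler(60))
    nm2 <- plant_name(spec$p_name_body)
    body_name_notes <- list()
    if (!is.null(nm2)) {
      body_parts <- c(body_parts, paste(filler(2), name_string(nm2), filler(2)))
      body_name_notes <- c(body_name_notes, nm2)
    }
    body_accs <- list()
    if (runif(1) < spec$p_acc_body) {
      rid <- sample(spec$acc_resources, 1)
      tok <- sample_accession(rid, runif(1) < spec$p_spaced)
      body_accs <- c(body_accs, list(list(rid = rid, tok = tok)))
      body_parts <- c(body_parts, paste(filler(1), tok, filler(1)))
    }
    body_parts <- c(body_parts, art_decoys$decoy[art_decoys$slot == "body"])
    fulltext <- paste(c(abstract, body_parts), collapse = " ")
    # fulltext rendition repeats every abstract mention, then adds its own
    if (!is.null(nm)) note(ful_id, nm, "name", tolower(name_string(nm)))
    if (!is.null(abs_acc)) note_accession(ful_id, abs_acc$rid, abs_acc$tok)
    for (nmx in body_name_notes) note(ful_id, nmx, "name", tolower(name_string(nmx)))
    for (ba in body_accs) note_accession(ful_id, ba$rid, ba$tok)

    # supplementary files
    n_supp <- if (runif(1) < spec$supp_prob) sample.int(spec$max_supp_files, 1) else 0L
    supp_decoys <- art_decoys$decoy[art_decoys$slot == "supp"]
    files <- list()
    art_dir <- file.path(out_dir, pmcid)
    dir.create(art_dir, showWarnings = FALSE)
    writeLines(c('<?xml version="1.0"?>', "<article><front><article-title>",
                 filler(5), "</article-title></front></article>"),
               file.path(art_dir, "article.nxml"), useBytes = TRUE)
    figures <- character()
    if (runif(1) < 0.15) {  # manuscript PDF rendition, same stem as the XML
      write_pdf_min(file.path(art_dir, "article.pdf"), filler(10))
      files <- c(files, list(list(filename = "article.pdf", filetype = "pdf",
                                  corrupted = FALSE)))
    }
    if (runif(1) < 0.10) {  # figure referenced by the manuscript
      writeBin(as.raw(c(0xff, 0xd8, 0xff, 0xe0, sample.int(256, 32, TRUE) - 1L)),
               file.path(art_dir, "fig1.jpg"))
      figures <- "fig1.jpg"
      files <- c(files, list(list(filename = "fig1.jpg", filetype = "jpg",
                                  corrupted = FALSE)))
    }
    if (runif(1) < 0.08) {  # web thumbnail, excluded outright
      writeBin(c(charToRaw("GIF89a"), as.raw(sample.int(256, 16, TRUE) - 1L)),
               file.path(art_dir, "thumb.gif"))
      files <- c(files, list(list(filename = "thumb.gif", filetype = "gif",
                                  corrupted = FALSE)))
    }
    if (runif(1) < 0.06) {  # multimedia, no extractor
      writeBin(as.raw(sample.int(256, 48, TRUE) - 1L),
               file.path(art_dir, "movie.mp4"))
      files <- c(files, list(list(filename = "movie.mp4", filetype = "mp4",
                                  corrupted = FALSE)))
    }
    supp_ids <- character()
    for (j in seq_len(n_supp)) {
      ft <- sample(ftypes, 1, prob = spec$filetype_weights)
      fn <- sprintf("supp%02d.%s", j, ft)
      doc_id <- paste0(pmcid, "_", fn)
      k <- sample(seq(spec$accessions_per_file[1], spec$accessions_per_file[2]), 1)
      accs <- lapply(seq_len(k), function(x) {
        rid <- sample(spec$acc_resources, 1)
        list(rid = rid, tok = sample_accession(rid, runif(1) < spec$p_spaced))
      })
      nm3 <- plant_name(spec$p_name_supp)
      nm3_tokens <- character()
      if (!is.null(nm3)) {
        nm3_tokens <- name_string(nm3)
        note(doc_id, nm3, "name", tolower(nm3_tokens))
      }
      dec <- if (j == 1L) supp_decoys else character()
      build_supp_file(file.path(art_dir, fn), ft,
                      acc_tokens = vapply(accs, function(a) a$tok, character(1)),
                      name_tokens = nm3_tokens, decoy_tokens = dec)
      for (a in accs) note_accession(doc_id, a$rid, a$tok)
      files <- c(files, list(list(filename = fn, filetype = ft, corrupted = FALSE)))
      supp_ids <- c(supp_ids, doc_id)
    }
    if (n_supp == 0L && length(supp_decoys)) {
      # decoys assigned to a supp slot of an article without files fall back
      # to the body; texts are already written, so keep them in the manifest
      fulltext <- paste(c(fulltext, supp_decoys), collapse = " ")
    }

    articles[[i]] <- list(
      article_key = pmcid, pmcid = pmcid, year = year, nxml = "article.nxml",
      figures = as.list(figures), abstract = abstract, fulltext = fulltext,
      files = files, supp_doc_ids = as.list(supp_ids),
      mentions = mention_rows,
      decoys = as.list(art_decoys$decoy))
  }

  # corruption plan: corrupt the requested number of files per type
  for (ft in names(spec$corruption)) {
    want <- spec$corruption[[ft]]
    if (want <= 0) next
    cand <- list()
    for (i in seq_along(articles)) {
      for (k in seq_along(articles[[i]]$files)) {
        f <- articles[[i]]$files[[k]]
        if (f$filetype == ft && startsWith(f$filename, "supp")) {
          cand <- c(cand, list(c(i, k)))
        }
      }
    }
    if (length(cand) < want) {
      stop("corruption plan wants ", want, " ", ft, " files but the corpus has ",
           length(cand), call. = FALSE)
    }
    pick <- sample.int(length(cand), want)
    for (p in pick) {
      i <- cand[[p]][1]; k <- cand[[p]][2]
      f <- articles[[i]]$files[[k]]
      corrupt_file(file.path(out_dir, articles[[i]]$pmcid, f$filename),
                   ft, mode = "auto", seed = spec$seed + i)
      articles[[i]]$files[[k]]$corrupted <- TRUE
    }
  }

  structure(list(format_version = 1L, seed = spec$seed,
                 registry_version = reg$version_label,
                 n_articles = spec$n_articles, articles = articles),
            class = "corpus_manifest")
}

# ---- manifest accessors ---------------------------------------------------

#' Ground-truth mentions recorded in a corpus manifest
#'
#' @param manifest A `corpus_manifest` (from [generate_corpus()] or read
#'   back from `manifest.json`).
#' @param include_corrupted Keep mentions planted in files that were then
#'   deliberately corrupted (unrecoverable by design).
#' @return Tibble with `doc_id`, `resource_id`, `mention_kind`,
#'   `normalized_id`.
#' @export
manifest_mentions <- function(manifest, include_corrupted = FALSE) {
  rows <- list()
  for (art in manifest$articles) {
    bad <- vapply(art$files, function(f) isTRUE(f$corrupted), logical(1))
    bad_ids <- paste0(art$pmcid, "_",
                      vapply(art$files[bad], function(f) f$filename, character(1)),
                      recycle0 = TRUE)
    for (m in art$mentions) {
      if (!include_corrupted && m$doc_id %in% bad_ids) next
      rows[[length(rows) + 1L]] <- m
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(doc_id = character(), resource_id = character(),
                          mention_kind = character(), normalized_id = character()))
  }
  tibble::tibble(
    doc_id = vapply(rows, `[[`, character(1), "doc_id"),
    resource_id = vapply(rows, `[[`, character(1), "resource_id"),
    mention_kind = vapply(rows, `[[`, character(1), "mention_kind"),
    normalized_id = vapply(rows, `[[`, character(1), "normalized_id"))
}

#' Article document sets described by a corpus manifest
#' @param manifest A `corpus_manifest`.
#' @return List of [article_docset()] objects.
#' @export
manifest_docsets <- function(manifest) {
  lapply(manifest$articles, function(art) {
    figs <- unlist(art$figures) %||% character()
    article_docset(art$article_key, art$year, abstract = art$abstract,
                   fulltext = art$fulltext,
                   supp_docs = unlist(art$supp_doc_ids) %||% character(),
                   figure_docs = if (length(figs)) paste0(art$pmcid, "_", figs)
                                 else character())
  })
}

#' Read a corpus manifest back from disk
#' @param path Path to a `manifest.json`.
#' @return A `corpus_manifest`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path)
  structure(m, class = "corpus_manifest")
}

#' Compare found mentions against a ground truth
#'
#' Multiset comparison on (`doc_id`, `resource_id`, `mention_kind`,
#' `normalized_id`): each expected occurrence must be found exactly as
#' often as planted.
#'
#' @param found Mention tibble from the pipeline.
#' @param expected Tibble from [manifest_mentions()].
#' @return List with `precision`, `recall`, `n_found`, `n_expected`,
#'   `false_positives` and `false_negatives` (tibbles of unmatched keys).
#' @export
compare_mentions <- function(found, expected) {
  key <- function(x) paste(x$doc_id, x$resource_id, x$mention_kind,
                           x$normalized_id, sep = "\r")
  tf <- table(key(found))
  te <- table(key(expected))
  keys <- union(names(tf), names(te))
  nf <- as.integer(tf[keys]); nf[is.na(nf)] <- 0L
  ne <- as.integer(te[keys]); ne[is.na(ne)] <- 0L
  hit <- sum(pmin(nf, ne))
  unkey <- function(k, n) {
    if (!length(k)) {
      return(tibble::tibble(doc_id = character(), resource_id = character(),
                            mention_kind = character(), normalized_id = character(),
                            count = integer()))
    }
    parts <- do.call(rbind, strsplit(k, "\r", fixed = TRUE))
    tibble::tibble(doc_id = parts[, 1], resource_id = parts[, 2],
                   mention_kind = parts[, 3], normalized_id = parts[, 4],
                   count = n)
  }
  fp <- nf > ne
  fn <- ne > nf
  list(precision = if (sum(nf)) hit / sum(nf) else NA_real_,
       recall = if (sum(ne)) hit / sum(ne) else NA_real_,
       n_found = sum(nf), n_expected = sum(ne),
       false_positives = unkey(keys[fp], (nf - ne)[fp]),
       false_negatives = unkey(keys[fn], (ne - nf)[fn]))
}
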