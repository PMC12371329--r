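#' @import tibble
NULL

# Empty mention table with the canonical column set.
mention_tbl <- function() {
  tibble::tibble(doc_id = character(), resource_id = character(),
                 mention_kind = character(), surface = character(),
                 start = integer(), end = integer(),
                 normalized_id = character())
}

as_mention_tbl <- function(doc_id, resource_id, mention_kind, surface,
                           start, end, normalized_id) {
  tibble::tibble(doc_id = doc_id, resource_id = resource_id,
                 mention_kind = mention_kind, surface = surface,
                 start = as.integer(start), end = as.integer(end),
                 normalized_id = normalized_id)
}

sort_mentions <- function(m) m[order(m$start, m$resource_id), , drop = FALSE]

# Insert an optional-single-space tolerance after every literal namespace
# colon in a pattern source string: "GO:\d{7}" is compiled so that it also
# matches "GO: 0005737". Colons that are regex syntax ("(?:", "(?<" ...)
# or sit inside a character class are left untouched.
tolerate_colon_space <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  out <- character(0)
  in_class <- FALSE
  escaped <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    out <- c(out, ch)
    if (escaped) { escaped <- FALSE; next }
    if (ch == "\\") { escaped <- TRUE; next }
    if (ch == "[" && !in_class) { in_class <- TRUE; next }
    if (ch == "]" && in_class) { in_class <- FALSE; next }
    if (ch == ":" && !in_class) {
      prev2 <- if (i >= 3) paste0(chars[i - 2], chars[i - 1]) else ""
      if (prev2 != "(?") out <- c(out, " ?")
    }
  }
  paste(out, collapse = "")
}

# Compile one resource's accession pattern into a scan-ready ICU regex.
# The accession body is capture group 1; word-boundary lookarounds anchor
# both ends; prefix-forced resources additionally require one of their
# prefix tokens plus ":" (optionally followed by a single space).
compile_accession_regex <- function(res) {
  body <- tolerate_colon_space(res$accession_pattern)
  if (res$prefix_required) {
    toks <- paste(vapply(tolower(res$prefix_tokens), regex_quote, character(1)),
                  collapse = "|")
    paste0(.left_boundary(), "(?:", toks, "): ?(", body, ")", .right_boundary())
  } else {
    paste0(.left_boundary(), "(", body, ")", .right_boundary())
  }
}

#' Find resource-name mentions in a text
#'
#' Dictionary matching of resource display names and name variants:
#' comparison is case-insensitive and a candidate is accepted only when both
#' ends fall on word boundaries (a transition between `[a-z0-9_]` and
#' anything else, or a string edge), so that e.g. Rhea is not recognized
#' inside the word "spearhead". Resources flagged `name_excluded` yield no
#' mentions.
#'
#' @param text Character scalar (may be empty).
#' @param reg A [registry()].
#' @param doc_id Document identifier stamped on the returned mentions.
#' @return A tibble of mentions with columns `doc_id`, `resource_id`,
#'   `mention_kind` (`"name"`), `surface`, `start`, `end` (0-based,
#'   half-open character offsets) and `normalized_id` (the lowercased
#'   variant that matched), sorted by (`start`, `resource_id`).
#' @export
find_name_mentions <- function(text, reg, doc_id = NA_character_) {
  stopifnot(is_string(text) || (is.character(text) && length(text) == 1))
  out <- list(mention_tbl())
  for (res in reg$resources) {
    if (res$name_excluded) next
    variants <- unique(c(res$display_name, res$name_variants))
    for (v in variants) {
      rx <- paste0(.left_boundary(), regex_quote(v), .right_boundary())
      loc <- stringi::stri_locate_all_regex(text, rx, opts_regex = .regex_opts())[[1]]
      if (nrow(loc) == 0 || is.na(loc[1, 1])) next
      out[[length(out) + 1L]] <- as_mention_tbl(
        doc_id = doc_id, resource_id = res$resource_id, mention_kind = "name",
        surface = stringi::stri_sub(text, loc[, 1], loc[, 2]),
        start = loc[, 1] - 1L, end = loc[, 2],
        normalized_id = tolower(v))
    }
  }
  sort_mentions(do.call(rbind, out))
}

#' Find accession-number mentions in a text
#'
#' Scans the text with each pattern-bearing resource's compiled Local
#' Unique Identifier regular expression. Matching is case-insensitive;
#' both ends of a match must fall on word boundaries; one optional space is
#' tolerated after a literal namespace colon inside the pattern (so
#' `"GO: 0005739"` is found by `GO:\\d{7}`). Resources with
#' `prefix_required` match only when the accession is immediately preceded
#' by a prefix token plus `":"` and an optional single space
#' (`"UniProt:Q8VRN4"`, never bare `"Q8VRN4"`). Overlapping candidates for
#' the same resource resolve leftmost-longest; matches for different
#' resources may coexist at overlapping offsets.
#'
#' @inheritParams find_name_mentions
#' @return A tibble of mentions (see [find_name_mentions()]);
#'   `mention_kind` is `"accession"` and `normalized_id` is the matched
#'   identifier with internal whitespace removed. The forcing prefix of a
#'   `prefix_required` resource is context, not part of the mention.
#' @export
find_accession_mentions <- function(text, reg, doc_id = NA_character_) {
  stopifnot(is.character(text) && length(text) == 1)
  out <- list(mention_tbl())
  for (res in reg$resources) {
    if (is.null(res$accession_pattern)) next
    rx <- compile_accession_regex(res)
    loc <- stringi::stri_locate_all_regex(text, rx, capture_groups = TRUE,
                                          opts_regex = .regex_opts())[[1]]
    if (nrow(loc) == 0 || is.na(loc[1, 1])) next
    grp <- attr(loc, "capture_groups")[[1]]
    out[[length(out) + 1L]] <- as_mention_tbl(
      doc_id = doc_id, resource_id = res$resource_id, mention_kind = "accession",
      surface = stringi::stri_sub(text, grp[, 1], grp[, 2]),
      start = grp[, 1] - 1L, end = grp[, 2],
      normalized_id = compact_ws(stringi::stri_sub(text, grp[, 1], grp[, 2])))
  }
  sort_mentions(do.call(rbind, out))
}

#' Find all mentions (names and accessions) in a set of documents
#'
#' @param texts Named character vector; names are document identifiers.
#' @param reg A [registry()].
#' @return A single mention tibble covering all documents.
#' @export
find_mentions <- function(texts, reg) {
  stopifnot(is.character(texts), !is.null(names(texts)), all(nzchar(names(texts))))
  parts <- lapply(names(texts), function(id) {
    rbind(find_name_mentions(texts[[id]], reg, doc_id = id),
          find_accession_mentions(texts[[id]], reg, doc_id = id))
  })
  do.call(rbind, c(list(mention_tbl()), parts))
}

#' Precision audit of accession mentions
#'
#' Draws a uniform random sample of accession mentions (without replacement
#' when the sample size allows) and checks each sampled identifier with a
#' user-supplied validator, e.g. membership in a list of identifiers known
#' to exist in the resource. Mirrors a manual audit of a random sample of
#' matched accession numbers.
#'
#' @param mentions A mention tibble; only `mention_kind == "accession"` rows
#'   are eligible.
#' @param n Sample size (capped at the number of accession mentions).
#' @param seed Integer seed; fixed seed gives an identical sample on reruns.
#' @param validator Function `normalized_id -> logical(1)`.
#' @return A tibble with one row per sampled resource: `resource_id`,
#'   `n_sampled`, `n_correct`; total sample size and accuracy are attached
#'   as attributes `n_total` and `accuracy`.
#' @export
audit_sample <- function(mentions, n, seed, validator) {
  stopifnot(n >= 1, is.function(validator))
  acc <- mentions[mentions$mention_kind == "accession", , drop = FALSE]
  if (nrow(acc) == 0) stop("no accession mentions to audit", call. = FALSE)
  n_take <- as.integer(min(n, nrow(acc)))
  idx <- withr::with_seed(seed, sample.int(nrow(acc), n_take, replace = FALSE))
  smp <- acc[idx, , drop = FALSE]
  ok <- vapply(smp$normalized_id, function(id) isTRUE(validator(id)), logical(1))
  res_ids <- sort(unique(smp$resource_id))
  tab <- tibble::tibble(
    resource_id = res_ids,
    n_sampled = vapply(res_ids, function(r) sum(smp$resource_id == r), integer(1)),
    n_correct = vapply(res_ids, function(r) sum(ok[smp$resource_id == r]), integer(1)))
  attr(tab, "n_total") <- n_take
  attr(tab, "accuracy") <- sum(ok) / n_take
  tab
}

#' Write mentions as JSON Lines
#'
#' One mention per line with fields `doc_id`, `resource_id`,
#' `mention_kind`, `surface`, `start`, `end`, `normalized_id`.
#'
#' @param mentions A mention tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mentions_jsonl <- function(mentions, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(mentions)) {
    lines <- vapply(seq_len(nrow(mentions)), function(i) {
      jsonlite::toJSON(as.list(mentions[i, , drop = FALSE]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}
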