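#' Define a single biodata resource
#'
#' A `resource_definition` describes one Global Core Biodata Resource (GCBR)
#' entry: the searchable name strings, the accession-number pattern (an
#' identifiers.org-style Local Unique Identifier regular expression, when one
#' exists), and the false-positive controls applied to it during matching.
#'
#' @param resource_id Short, stable, unique token (e.g. `"gene_ontology"`).
#' @param display_name Exact resource name as listed by the Global Biodata
#'   Coalition; searched case-insensitively with word boundaries.
#' @param name_variants Character vector of additional searchable name
#'   strings (may be empty).
#' @param accession_pattern Regular-expression source string for the Local
#'   Unique Identifier, or `NULL` when the resource has no usable pattern.
#'   Stored uncompiled so the registry remains language-neutral data.
#' @param prefix_required When `TRUE`, an accession matches only if the
#'   pattern occurrence is immediately preceded by one of `prefix_tokens`
#'   plus `":"` (optionally followed by one space), e.g. `"UniProt:Q8VRN4"`.
#'   Used to tame over-general patterns.
#' @param prefix_tokens Character vector of forcing tokens (e.g. `"uniprot"`).
#' @param name_excluded When `TRUE` the resource is skipped in name search
#'   (its name is too ambiguous in running text); accession search is not
#'   affected.
#' @param name_exclusion_reason Free-text reason, required when
#'   `name_excluded` is `TRUE`.
#' @param example_accession Optional example identifier known to match
#'   `accession_pattern`; used for validation and by the synthetic-corpus
#'   samplers.
#'
#' @return An object of class `resource_definition`.
#' @seealso [registry()], [default_registry()]
#' @export
resource_definition <- function(resource_id,
                                display_name,
                                name_variants = character(),
                                accession_pattern = NULL,
                                prefix_required = FALSE,
                                prefix_tokens = character(),
                                name_excluded = FALSE,
                                name_exclusion_reason = "",
                                example_accession = NULL) {
  res <- structure(
    list(
      resource_id = as.character(resource_id),
      display_name = as.character(display_name),
      name_variants = as.character(name_variants %||% character()),
      accession_pattern = if (is.null(accession_pattern)) NULL else as.character(accession_pattern),
      prefix_required = isTRUE(prefix_required),
      prefix_tokens = as.character(prefix_tokens %||% character()),
      name_excluded = isTRUE(name_excluded),
      name_exclusion_reason = as.character(name_exclusion_reason %||% ""),
      example_accession = if (is.null(example_accession)) NULL else as.character(example_accession)
    ),
    class = "resource_definition"
  )
  errs <- validate_resource(res)
  if (length(errs)) {
    stop("invalid resource definition '", res$resource_id, "': ",
         paste(errs, collapse = "; "), call. = FALSE)
  }
  res
}

# Returns a character vector of violation messages (empty when valid).
validate_resource <- function(res) {
  errs <- character()
  if (!length(res$resource_id) || is.na(res$resource_id) || !nzchar(res$resource_id)) {
    errs <- c(errs, "resource_id must be non-empty")
  }
  if (!length(res$display_name) || !nzchar(res$display_name)) {
    errs <- c(errs, "display_name must be non-empty")
  }
  if (res$prefix_required && !length(res$prefix_tokens)) {
    errs <- c(errs, "prefix_required is true but prefix_tokens is empty")
  }
  if (!is.null(res$accession_pattern)) {
    ok <- tryCatch({
      stringi::stri_detect_regex("probe", res$accession_pattern)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) errs <- c(errs, paste0("accession_pattern does not compile: '",
                                    res$accession_pattern, "'"))
  }
  if (res$name_excluded && !nzchar(res$name_exclusion_reason)) {
    errs <- c(errs, "name_excluded is true but name_exclusion_reason is empty")
  }
  errs
}

#' Build a resource registry
#'
#' A registry is an ordered collection of [resource_definition()] entries;
#' iteration order is preserved so that all downstream reports are
#' deterministic.
#'
#' @param resources List of [resource_definition()] objects.
#' @param version_label Free-text label for the registry revision.
#'
#' @return An object of class `gcbr_registry`.
#' @export
registry <- function(resources = list(), version_label = "") {
  ids <- vapply(resources, function(r) r$resource_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate resource_id in registry: ",
         paste(sQuote(dup), collapse = ", "), call. = FALSE)
  }
  for (r in resources) {
    errs <- validate_resource(r)
    if (length(errs)) {
      stop("invalid resource '", r$resource_id, "': ",
           paste(errs, collapse = "; "), call. = FALSE)
    }
  }
  structure(list(resources = resources, version_label = as.character(version_label)),
            class = "gcbr_registry")
}

#' @export
print.gcbr_registry <- function(x, ...) {
  n_pat <- sum(vapply(x$resources, function(r) !is.null(r$accession_pattern), logical(1)))
  n_exc <- sum(vapply(x$resources, function(r) r$name_excluded, logical(1)))
  cat("<gcbr_registry> ", length(x$resources), " resources (",
      n_pat, " with accession patterns, ", n_exc, " name-excluded)",
      if (nzchar(x$version_label)) paste0(" [", x$version_label, "]"), "\n", sep = "")
  invisible(x)
}

#' @export
length.gcbr_registry <- function(x) length(x$resources)

#' Look up one resource by id
#'
#' @param reg A [registry()].
#' @param resource_id Resource id to retrieve.
#' @return The matching [resource_definition()], or `NULL`.
#' @export
registry_resource <- function(reg, resource_id) {
  for (r in reg$resources) if (r$resource_id == resource_id) return(r)
  NULL
}

#' Resource ids of a registry, in registry order
#' @param reg A [registry()].
#' @param pattern_only Keep only resources carrying an accession pattern.
#' @return Character vector of resource ids.
#' @export
registry_ids <- function(reg, pattern_only = FALSE) {
  keep <- if (pattern_only) {
    vapply(reg$resources, function(r) !is.null(r$accession_pattern), logical(1))
  } else rep(TRUE, length(reg$resources))
  vapply(reg$resources[keep], function(r) r$resource_id, character(1))
}

# One registry record <-> plain list, for the YAML config format.
resource_to_record <- function(r) {
  rec <- list(resource_id = r$resource_id, display_name = r$display_name)
  if (length(r$name_variants)) rec$name_variants <- as.list(r$name_variants)
  if (!is.null(r$accession_pattern)) rec$accession_pattern <- r$accession_pattern
  if (!is.null(r$example_accession)) rec$example_accession <- r$example_accession
  if (r$prefix_required) {
    rec$prefix_required <- TRUE
    rec$prefix_tokens <- as.list(r$prefix_tokens)
  }
  if (r$name_excluded) {
    rec$name_excluded <- TRUE
    rec$name_exclusion_reason <- r$name_exclusion_reason
  }
  rec
}

record_to_resource <- function(rec) {
  allowed <- c("resource_id", "display_name", "name_variants", "accession_pattern",
               "prefix_required", "prefix_tokens", "name_excluded",
               "name_exclusion_reason", "example_accession")
  extra <- setdiff(names(rec), allowed)
  if (length(extra)) {
    stop("unknown registry key(s) ", paste(sQuote(extra), collapse = ", "),
         " in entry '", rec$resource_id %||% "?", "'", call. = FALSE)
  }
  resource_definition(
    resource_id = rec$resource_id %||% "",
    display_name = rec$display_name %||% "",
    name_variants = unlist(rec$name_variants) %||% character(),
    accession_pattern = rec$accession_pattern,
    prefix_required = isTRUE(rec$prefix_required),
    prefix_tokens = unlist(rec$prefix_tokens) %||% character(),
    name_excluded = isTRUE(rec$name_excluded),
    name_exclusion_reason = rec$name_exclusion_reason %||% "",
    example_accession = rec$example_accession
  )
}

#' Load a resource registry from a YAML config file
#'
#' The config is a single human-editable YAML document with a
#' `version_label` and a `resources` sequence; each record may carry the
#' keys `resource_id`, `display_name`, `name_variants`, `accession_pattern`,
#' `example_accession`, `prefix_required`, `prefix_tokens`, `name_excluded`
#' and `name_exclusion_reason`. Malformed entries (duplicate ids, invalid
#' regular expressions, missing exclusion reasons) are rejected with an
#' error naming the offending entry, never silently dropped.
#'
#' @param path Path to the YAML registry config.
#' @return A [registry()].
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop("registry config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("registry config does not parse as a mapping: ", path, call. = FALSE)
  recs <- raw$resources %||% list()
  resources <- lapply(recs, function(rec) {
    tryCatch(record_to_resource(rec),
             error = function(e) stop("in registry config '", path, "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  registry(resources, version_label = raw$version_label %||% "")
}

#' Write a resource registry to a YAML config file
#'
#' Inverse of [load_registry()]: `load_registry(write_registry(reg, path))`
#' reproduces `reg`.
#'
#' @param reg A [registry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(reg, path) {
  doc <- list(version_label = reg$version_label,
              resources = lapply(reg$resources, resource_to_record))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' The bundled Global Core Biodata Resource registry
#'
#' Returns the registry shipped with the package: the 52 GCBR names of the
#' 2024 roster, with accession patterns for the 30 resources that have a
#' usable identifiers.org Local Unique Identifier pattern. Four resources
#' (BRENDA, SILVA, CATH, STRING) are flagged `name_excluded` because their
#' names are dominated by false positives in running text (person names,
#' "cath lab", the common noun "string"); prefix forcing is set for
#' Catalogue of Life and UniProt, whose bare patterns are too general.
#'
#' @return A [registry()].
#' @export
default_registry <- function() {
  path <- system.file("extdata", "gcbr_registry.yaml", package = "suppminer",
                      mustWork = TRUE)
  load_registry(path)
}
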