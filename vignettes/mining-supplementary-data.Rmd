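---
title: "Mining biodata-resource mentions from supplementary data files"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining biodata-resource mentions from supplementary data files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Literature search engines index titles, abstracts and, for open-access
articles, full text — but not the supplementary data files published
alongside the manuscript. Those files (spreadsheets, Word documents, PDFs,
delimited text, markup, figures) carry a large and growing share of the
concrete biological evidence in a paper, in particular *accession
numbers*: the stable identifiers of entries in biological databases such
as the Gene Ontology (`GO:0005739` = "mitochondrion"). An accession
occurring in a supplementary table is invisible to an abstract or
full-text search, so curation pipelines that link databases to literature
systematically under-retrieve.

`suppminer` implements the full measurement pipeline for this problem:

1. **classify** — partition a PMC-style article bundle into manuscript
   parts and genuine supplementary material;
2. **extract** — pull plain text out of each supported file format,
   accounting for per-format success rates;
3. **match** — find mentions of Global Core Biodata Resource (GCBR) names
   and accession numbers, with explicit false-positive controls;
4. **aggregate** — count at the article level across three nested
   collections (MEDLINE abstracts; + full texts; + supplementary files),
   deduplicating by PMCID;
5. **synth** — generate a fully self-contained synthetic corpus with a
   ground-truth manifest, so the whole pipeline is verifiable end to end
   without downloading anything.

## The registry

The bundled registry (`default_registry()`) holds the 52 GCBR resources of
the 2024 roster. Thirty carry an accession pattern — an
identifiers.org-style *Local Unique Identifier* regular expression. The
registry stores pattern **source strings**; compilation happens in the
matcher, so the config (`inst/extdata/gcbr_registry.yaml`) is
language-neutral data that users can edit or replace (`load_registry()`).

Two classes of resources get special treatment, mirroring the behaviour
of dictionary matching in running text:

* **Name exclusion.** BRENDA and SILVA collide with person names, CATH
  with "cath lab" (catheterization laboratory), STRING with the common
  noun. Their names are skipped in name search (`name_excluded`), with the
  reason recorded; their accession patterns still apply.
* **Prefix forcing.** The Catalogue of Life pattern (one to six
  consonants/digits) and the UniProt pattern match far too much English.
  These resources match only as `col:4QHKG` / `UniProt:Q8VRN4` — the
  token, a colon, at most one space, then the identifier. Bare `Q8VRN4`
  never matches. This deliberately trades recall for precision.

Where a public LUI pattern is unusable bare in free text (BacDive, RGD and
Rhea are bare digit runs; the public STRING and PomBase patterns match
almost any token), the registry records a conservative equivalent — the
namespace-prefixed or properly narrowed form — with a comment on the
entry. Bgee has no identifier scheme of its own: it reuses Ensembl and
FlyBase gene identifiers, so its pattern accepts those stems with an open
digit count. A consequence worth knowing: a truncated FlyBase identifier
(e.g. `FBgn003202`, six digits) is still a syntactically valid Bgee match
— exactly the kind of extraction artefact a precision audit surfaces.

## Matching rules

All matching is case-insensitive on an ASCII word-boundary alphabet
(`[a-z0-9_]`): a match is accepted only when both ends sit on a transition
between word and non-word characters (or a string edge). This is what
keeps *Rhea* out of "spearhead". The same boundary rule is applied to
accession patterns — without it, `GO:\d{7}` would fire inside longer digit
runs.

Authors often put a space after the namespace colon (`GO: 0005739`,
`chebi: 18034`). The matcher tolerates exactly one space after a literal
colon inside a pattern and removes internal whitespace in the
`normalized_id`, so both spellings normalize to `GO:0005739`. The
mention's surface and offsets always address the original text.

Overlaps within one resource resolve leftmost-longest (so
`ENSG00000176261.11` is taken with its version suffix). Overlaps *across*
resources are all kept: an `ENSG...` identifier genuinely is an Ensembl
gene, a Human Protein Atlas entry and a Bgee gene at once, and counting is
per resource.

`audit_sample()` reproduces the precision-audit protocol: a seeded uniform
sample of matched accessions is checked by a user-supplied validator
(e.g. membership in a list of identifiers known to exist in the resource),
reported per resource.

## Extraction

Every extractor serializes to plain text with `\t` between row cells and
`\n` between rows, paragraphs or sheet sections, so a match can never span
a cell boundary. Spreadsheet cells are read as text — never through a
numeric display format — because one mangled cell (`1e+06`, a truncated
identifier) is precisely the failure mode that corrupts accession data.
Multi-sheet workbooks are concatenated in stored order with a
`## sheet: <name>` break line (the choice of including sheet names is
ours; nothing downstream depends on it).

Delimited text is decoded as UTF-8 first, then Latin-1; bytes invalid
under both (embedded NULs, C1-range bytes) make the file `failed`. PDF
extraction reads only text stored as actual characters (the `Tj`/`TJ`
operators of the content streams, inflating FlateDecode streams when
present); scanned-image PDFs therefore come back `ok_empty`, which is an
honest outcome, not an error. HTML/XML are reduced to their text nodes,
one node per line, so adjacent table cells cannot run together. JPG OCR is
pluggable: the engine is a function argument, and the wrapper offers the
image at four rotations and keeps the orientation with the most recognized
characters; without an engine, jpg files are skipped, not failed.

Failures are expected data. `extract_text()` never lets a reader error
escape: corrupt content yields `status = "failed"` with a reason, and
`build_extraction_report()` accounts per filetype for attempts, successes
(`ok` + `ok_empty`), the success rate, and the mean character count of
non-empty successes (`ok_empty` files are excluded from the mean — whether
to include them is a convention; we exclude and say so).

## Counting

Articles are deduplicated by PMCID (PMID fallback), and only articles
published from 2000 are counted by default. Three nested collection tiers
are reported: MEDLINE (abstract), MEDLINE + PMC (adding full text),
and + supplementary data.

* **Names count articles.** A resource citation counts once per article
  per tier, no matter where or how often it appears. The *gain* column is
  the percentage of additional articles contributed by the supplementary
  tier; the `any_of_them` row deduplicates across resources.
* **Accessions count occurrences.** The full-text rendition of an article
  contains its title and abstract again, so at the MEDLINE + PMC tier each
  (article, resource, identifier) contributes
  `max(abstract occurrences, full-text occurrences)` — never the sum of
  the two renditions. This reproduces the single-count behaviour for the
  shared region, and has the useful property that cumulative nesting
  (`n_medline <= n_medline_pmc <= n_all`) holds on any input, including
  adversarial ones where a full text lacks its abstract's identifier.
  `pct_only_supp` is the share of all occurrences found exclusively in
  supplementary files.

`year_filetype_matrix()` cross-tabulates supplementary accession
occurrences by publication year and carrying filetype, and derives the
per-year article series (article count, share of articles with
supplementary files). Its cell total equals the supplementary-only
occurrence count of the accession report by construction — the two views
conserve.

OCRed manuscript figures are indexed in the supplementary collection, so
their mentions count in the supplementary tier; they are *not* counted as
supplementary data files in the per-year share, since they belong to the
manuscript.

## The synthetic corpus

`generate_corpus()` writes one directory per article — a manuscript XML
stub plus supplementary files in xlsx, csv, txt, docx (with at least one
accession inside a document table), pdf (text layer), html and xml — and a
`manifest.json` recording every planted mention, every decoy and every
deliberately corrupted file. Planted accessions are reverse-sampled from
the registry patterns; digit-run lengths are chosen so a sampled
identifier can never create a free-standing four-character digit-led token
(which would collide with the Protein Data Bank pattern). The manifest
also records the *coincidental* identities of shared identifier schemes
(an ENSG identifier is Ensembl + Human Protein Atlas + Bgee; a
taxon-qualified STRING identifier contains an Ensembl protein id; CATH
codes are shaped like EC numbers) and the name mention induced when a
namespace prefix is itself a searchable name (`CHEBI: 18034` contains the
bounded word "chebi"). Without this bookkeeping, a 100% precision/recall
check would be measuring manifest gaps rather than pipeline behaviour.

The defaults are the study conditions the generator emulates, chosen once:
200 articles over 2018–2023, 80% of articles with 1–3 supplementary files,
an xlsx-dominated filetype mix, accessions planted overwhelmingly in
supplementary files (abstract/body planting probabilities 0.04/0.15 per
article, a handful per supplementary file), 60 decoys
("spearhead", "cath lab", bare "Q8VRN4", "GO:123"), and a filler
vocabulary verified by test to be collision-free against the whole
registry. Under these conditions roughly 97% of accession occurrences are
supplementary-only — the qualitative shape of real corpora — but no claim
is made that synthetic counts reproduce any published corpus-scale value:
real supplementary files are messier (merged cells, scanned pages,
thousand-row tables, encodings in the wild), and passing the closed loop
here demonstrates correctness of the machinery, not field recall.

Deliberate corruption is part of the generator: truncation for OOXML
containers (destroying the zip central directory — damaging only the first
local header is *not* enough for readers that trust the directory),
invalid-byte injection for delimited text, header garbage for PDF. The
extraction report's success rates must then equal the corruption plan's
arithmetic exactly.

Determinism: all generation randomness derives from the spec's single
seed; a fixed seed reproduces the manifest and all planted content
byte-for-byte.

## Numerical and design choices

* Word alphabet is ASCII letters/digits/underscore on case-folded text —
  the simplest testable reading of "lowercasing and word boundaries".
* Normalization removes whitespace but preserves the surface's case
  (`chebi: 18034` → `chebi:18034`); patterns are case-insensitive, so
  case-folding identifiers would add nothing and would lose information.
* The prefix separator for forced resources is `token:` plus at most one
  space; a bare whitespace separator (`UniProt Q8VRN4`) is not accepted.
* Mention sort order is (start offset, resource id); reports iterate the
  registry in config order — both choices exist purely so that every
  output is reproducible to the byte.
* Problem sizes in the test-suite and acceptance script (200-article
  corpora, 100 oracle texts of up to ten thousand characters) were chosen
  as the smallest sizes at which every rule — cross-resource overlap,
  prefix forcing, corruption accounting, dedup tiers — is exercised many
  times over.

## Known limitations

* Name search is exact dictionary matching: no synonyms, abbreviations or
  contextual disambiguation, so "Orphadata Science" does not match texts
  that write "Orphadata". This is faithful to the method being modelled;
  the counts inherit its false negatives.
* Prefix forcing certainly misses bare identifiers of UniProt and the
  Catalogue of Life; that is the accepted cost of precision.
* Table structure is not reconstructed: a column spread across
  non-consecutive PDF pages stays broken. Extraction recovers characters,
  not semantics.
* Legacy `.doc` support is a capability flag (off by default) and jpg OCR
  requires plugging in an engine; neither format is produced by the
  generator, so their code paths are covered by corruption/fuzz tests
  rather than round trips.
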