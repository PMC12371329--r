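`%||%` <- function(a, b) if (is.null(a)) b else a

# ASCII word alphabet used for all boundary decisions, applied to
# case-folded text: a boundary is any transition between [a-z0-9_] and
# anything else, or a string edge.
.word_class <- "[a-z0-9_]"

.left_boundary <- function() paste0("(?<!", .word_class, ")")
.right_boundary <- function() paste0("(?!", .word_class, ")")

.regex_opts <- function() stringi::stri_opts_regex(case_insensitive = TRUE)

# Escape a literal string for embedding in an ICU regular expression.
regex_quote <- function(x) stringi::stri_replace_all_regex(x, "([\\\\.^$|()\\[\\]{}*+?/-])", "\\\\$1")

compact_ws <- function(x) gsub("[ \t\r\n]+", "", x)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
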