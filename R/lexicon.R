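#' Load and validate a domain lexicon
#'
#' The lexicon is the single knowledge source driving every matching step:
#' cancer-concept identification, modifier search, kinship/experiencer
#' attribution, section-heading recognition and negation detection. It holds
#' eleven categories in a YAML file, one top-level key per category, a list of
#' phrases per key. The packaged default (`lexicon_path()`) transcribes the
#' full five-category domain lexicon used by the classifier; user configs may
#' extend or override any category.
#'
#' Entries are stored lowercase, except `cancer_acronyms`, which are kept in
#' original case and matched exact-case against raw tokens (so the determiner
#' "all" never matches the leukemia acronym "ALL"). Heading categories are
#' stored normalized: lowercase, no trailing colon.
#'
#' @param source path to a YAML lexicon file, or `NULL` for the packaged
#'   default.
#' @return an object of class `hx_lexicon`: a named list of character vectors,
#'   one per category.
#' @export
#' @examples
#' lex <- load_lexicon()
#' phrase_in(lex, "negation_phrases", c("no", "history", "of"))
load_lexicon <- function(source = NULL) {
  if (is.null(source)) source <- lexicon_path()
  raw <- tryCatch(
    # keep bare "no"/"yes" as words, not YAML booleans — "no" is a negation phrase
    yaml::read_yaml(source, handlers = list(
      "bool#yes" = function(x) x, "bool#no" = function(x) x
    )),
    error = function(e) stop("cannot parse lexicon config: ", conditionMessage(e), call. = FALSE)
  )
  if (!is.list(raw) || is.null(names(raw))) {
    stop("lexicon config must be a mapping of category -> phrase list", call. = FALSE)
  }
  unknown <- setdiff(names(raw), LEXICON_CATEGORIES)
  if (length(unknown) > 0) {
    stop("unknown lexicon categories: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  lex <- stats::setNames(vector("list", length(LEXICON_CATEGORIES)), LEXICON_CATEGORIES)
  for (cat in LEXICON_CATEGORIES) {
    entries <- raw[[cat]]
    if (is.null(entries)) entries <- character(0)
    entries <- as.character(unlist(entries))
    if (any(!nzchar(trimws(entries)))) {
      stop("empty phrase in category '", cat, "'", call. = FALSE)
    }
    entries <- trimws(gsub("\\s+", " ", entries))
    if (cat != "cancer_acronyms") entries <- tolower(entries)
    lex[[cat]] <- unique(entries)
  }
  structure(lex, class = "hx_lexicon", source = source) |> validate_lexicon()
}

LEXICON_CATEGORIES <- c(
  "noncancer_oma_terms", "cancer_acronyms", "unique_cancers",
  "modifier_descriptors", "cancer_as_adjective_nouns",
  "kinship_fdr", "kinship_other", "nonrelatives",
  "family_history_headings", "nonsubjective_headings", "negation_phrases"
)

#' Path to the packaged default lexicon file
#' @return file path of the default YAML lexicon shipped with the package.
#' @export
lexicon_path <- function() {
  system.file("extdata", "lexicon.yaml", package = "cancerhx", mustWork = TRUE)
}

# Mutually exclusive category pairs: a phrase in both is a configuration error.
EXCLUSIVE_PAIRS <- list(
  c("kinship_fdr", "nonrelatives"),
  c("kinship_other", "nonrelatives"),
  c("modifier_descriptors", "negation_phrases"),
  c("family_history_headings", "nonsubjective_headings")
)

validate_lexicon <- function(lex) {
  for (pair in EXCLUSIVE_PAIRS) {
    clash <- intersect(lex[[pair[1]]], lex[[pair[2]]])
    if (length(clash) > 0) {
      stop(
        "lexicon validation: '", paste(clash, collapse = "', '"),
        "' listed under both ", pair[1], " and ", pair[2], call. = FALSE
      )
    }
  }
  lex
}

#' @export
print.hx_lexicon <- function(x, ...) {
  cat("<hx_lexicon> ", length(LEXICON_CATEGORIES), " categories\n", sep = "")
  for (cat in LEXICON_CATEGORIES) {
    cat(sprintf("  %-26s %4d entries\n", cat, length(x[[cat]])))
  }
  invisible(x)
}

#' Write a lexicon back to YAML
#'
#' Round-trips losslessly: reloading the written file yields identical
#' category sets.
#'
#' @param lex an `hx_lexicon`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "hx_lexicon"))
  out <- lapply(unclass(lex)[LEXICON_CATEGORIES], as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Test membership of a token sequence in a lexicon category
#'
#' The token sequence, joined on single spaces, is looked up in the category.
#' Lookup is case-insensitive for all categories except `cancer_acronyms`,
#' which compares the raw tokens exact-case.
#'
#' @param lex an `hx_lexicon`.
#' @param category category name.
#' @param tokens character vector of tokens (normalized lowercase for all
#'   categories but `cancer_acronyms`).
#' @return `TRUE` or `FALSE`.
#' @export
phrase_in <- function(lex, category, tokens) {
  if (!category %in% LEXICON_CATEGORIES) {
    stop("unknown lexicon category: ", category, call. = FALSE)
  }
  if (length(tokens) == 0) return(FALSE)
  phrase <- paste(tokens, collapse = " ")
  if (category != "cancer_acronyms") phrase <- tolower(phrase)
  phrase %in% lex[[category]]
}

#' Can a token run be segmented entirely into modifier descriptors?
#'
#' A window of tokens "matches the lexicon" when it can be partitioned into
#' one or more contiguous runs, each a `modifier_descriptors` entry — e.g.
#' `c("small", "cell", "lung")` segments as "small cell" + "lung". Solved by
#' dynamic programming over split points (descriptor entries are 1-4 tokens
#' long).
#'
#' @param lex an `hx_lexicon`.
#' @param tokens non-empty character vector of lowercase tokens.
#' @return `TRUE` if an exact partition exists, else `FALSE`.
#' @export
segmentable_as_modifiers <- function(lex, tokens) {
  !is.null(segment_modifiers(lex, tokens))
}

# Returns the descriptor-phrase partition of `tokens` (longest-first at each
# position), or NULL if no exact partition exists.
segment_modifiers <- function(lex, tokens) {
  n <- length(tokens)
  if (n == 0) return(NULL)
  max_len <- max(lengths(strsplit(lex$modifier_descriptors, " ", fixed = TRUE)), 1L)
  # reachable[i]: tokens[1..i-1] fully segmented; back-pointers rebuild phrases
  reachable <- c(TRUE, rep(FALSE, n))
  back <- integer(n + 1)
  for (i in seq_len(n)) {
    if (!reachable[i]) next
    for (len in seq_len(min(max_len, n - i + 1))) {
      j <- i + len
      if (reachable[j]) next
      if (phrase_in(lex, "modifier_descriptors", tokens[i:(j - 1)])) {
        reachable[j] <- TRUE
        back[j] <- i
      }
    }
  }
  if (!reachable[n + 1]) return(NULL)
  phrases <- character(0)
  j <- n + 1
  while (j > 1) {
    i <- back[j]
    phrases <- c(paste(tokens[i:(j - 1)], collapse = " "), phrases)
    j <- i
  }
  phrases
}
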