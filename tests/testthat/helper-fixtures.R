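# Shared fixtures and independent oracles for the window-search tests.

default_lex <- load_lexicon()

make_sentence <- function(text) {
  structure(list(text = text, tokens = tokenize(text)), class = "hx_sentence")
}

make_report <- function(..., lex = default_lex, report_id = "1") {
  parse_report(paste(..., sep = "\n"), lex, report_id = report_id)
}

single_hotspot <- function(text, lex = default_lex) {
  s <- make_sentence(text)
  hs <- find_hotspots(s, lex)
  stopifnot(length(hs) >= 1)
  list(sentence = s, hotspot = hs[[1]])
}

# Brute-force partition check: can `tokens` be split into descriptor phrases?
# Recursive enumeration of all prefix splits — independent of the DP route.
brute_segmentable <- function(lex, tokens) {
  if (length(tokens) == 0) return(TRUE)
  for (k in seq_along(tokens)) {
    if (phrase_in(lex, "modifier_descriptors", tokens[seq_len(k)]) &&
      brute_segmentable(lex, tokens[-seq_len(k)])) {
      return(TRUE)
    }
  }
  FALSE
}

# Brute-force window searches: enumerate the contiguous token runs ending at
# the anchor, longest first (length <= 5), checking each in full.
brute_modifier_window <- function(lex, norms, anchor_start) {
  for (len in rev(seq_len(min(5, anchor_start)))) {
    w <- norms[(anchor_start - len + 1):anchor_start]
    if (brute_segmentable(lex, w)) return(len)
  }
  NA_integer_
}

brute_negation_window <- function(lex, norms, anchor_start) {
  for (len in rev(seq_len(min(5, anchor_start)))) {
    w <- norms[(anchor_start - len + 1):anchor_start]
    if (paste(w, collapse = " ") %in% lex$negation_phrases) return(len)
  }
  NA_integer_
}

# Random sentences assembled from lexicon material around a "cancer" anchor.
random_lexicon_sentence <- function(lex) {
  filler <- c(
    "the", "patient", "has", "a", "of", "her", "his", "was", "with",
    "history", "noted", "in", "record", "for", "and", "or", "recent"
  )
  neg_tokens <- unlist(strsplit(lex$negation_phrases, " ", fixed = TRUE))
  desc_tokens <- unlist(strsplit(sample(lex$modifier_descriptors, 10), " ", fixed = TRUE))
  n_before <- sample(0:8, 1)
  before <- sample(c(filler, neg_tokens, desc_tokens), n_before, replace = TRUE)
  after <- sample(filler, sample(0:4, 1), replace = TRUE)
  tokens <- c(before, "cancer", after)
  list(
    sentence = make_sentence(paste(tokens, collapse = " ")),
    anchor_start = n_before # 0-based index of the anchor token
  )
}
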