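#' Window configuration for the Dynamic-Window engine
#'
#' The modifier search walks backward windows in descending size order
#' (default 5, 4, 3, 2, 1 tokens); if none matches, it looks forward at
#' single-token offsets 1-3 to catch "cancer of the <location>". The negation
#' search reuses the backward sizes only.
#'
#' @param backward_sizes strictly descending positive integers.
#' @param forward_look_offsets positive integer offsets for the forward look.
#' @param forward_window_size size of each forward window (single token).
#' @return an object of class `hx_window_config`.
#' @export
window_config <- function(backward_sizes = c(5L, 4L, 3L, 2L, 1L),
                          forward_look_offsets = c(1L, 2L, 3L),
                          forward_window_size = 1L) {
  backward_sizes <- as.integer(backward_sizes)
  forward_look_offsets <- as.integer(forward_look_offsets)
  stopifnot(
    length(backward_sizes) > 0, all(backward_sizes >= 1),
    all(diff(backward_sizes) < 0),
    all(forward_look_offsets >= 1), forward_window_size >= 1
  )
  structure(
    list(
      backward_sizes = backward_sizes,
      forward_look_offsets = forward_look_offsets,
      forward_window_size = as.integer(forward_window_size)
    ),
    class = "hx_window_config"
  )
}

#' Locate cancer-concept hot-spots in a sentence
#'
#' Rule cascade: (a) every token ending in "-oma"/"-omas" whose norm is not a
#' known non-cancer ("hematoma" etc.); (b) only when no "-oma" term was found,
#' every token "cancer"; (c) unconditionally, tokens matching the unique
#' cancer words (hodgkin, leukemia, neoplasm, tumor); (d) unconditionally,
#' raw tokens matching a cancer acronym exact-case (so the determiner "all"
#' never matches "ALL"). A candidate immediately followed by a noun that uses
#' cancer as an adjective ("tumor markers", "cancer conference") is
#' suppressed. Hits are deduplicated by token position.
#'
#' @param sentence an `hx_sentence`.
#' @param lex an `hx_lexicon`.
#' @return list of hot-spots, each
#'   `list(token_start, token_end, term, rule, expanded)` with 0-based
#'   half-open token indices.
#' @export
find_hotspots <- function(sentence, lex) {
  toks <- sentence$tokens
  n <- nrow(toks)
  if (n == 0) return(list())
  hits <- list()
  add <- function(i, rule, term) {
    hits[[length(hits) + 1]] <<- list(
      token_start = i - 1L, token_end = i, term = term, rule = rule, expanded = FALSE
    )
  }
  oma <- which(
    grepl("omas?$", toks$norm) & !(toks$norm %in% lex$noncancer_oma_terms)
  )
  for (i in oma) add(i, "oma_suffix", toks$norm[i])
  if (length(oma) == 0) {
    for (i in which(toks$norm == "cancer")) add(i, "cancer_word", "cancer")
  }
  for (i in which(toks$norm %in% lex$unique_cancers)) add(i, "unique_cancer", toks$norm[i])
  for (i in which(toks$raw_clean %in% lex$cancer_acronyms)) add(i, "acronym", toks$raw_clean[i])
  if (length(hits) == 0) return(list())
  # suppress "<concept> markers/conference/..." and dedupe by token span
  keep <- vapply(hits, function(h) {
    j <- h$token_end + 1L
    !(j <= n && toks$norm[j] %in% lex$cancer_as_adjective_nouns)
  }, logical(1))
  hits <- hits[keep]
  starts <- vapply(hits, `[[`, integer(1), "token_start")
  hits <- hits[!duplicated(starts)]
  hits[order(vapply(hits, `[[`, integer(1), "token_start"))]
}

#' Backward window of tokens before an anchor
#'
#' Up to `size` token norms immediately preceding `anchor_start`, truncated at
#' the sentence start; never crosses the sentence boundary.
#'
#' @param tokens token data.frame of a sentence (from [tokenize()]).
#' @param anchor_start 0-based index of the anchor token.
#' @param size window size (tokens).
#' @return character vector of token norms (possibly shorter than `size`).
#' @export
window_before <- function(tokens, anchor_start, size) {
  stopifnot(size >= 1)
  from <- max(0L, anchor_start - size)
  if (from >= anchor_start) return(character(0))
  tokens$norm[(from + 1L):anchor_start]
}

#' Variable-size window search for modifier phrases
#'
#' Backward windows are tried in the configured descending order; the first
#' full window exactly segmentable into modifier descriptors wins. Only full
#' windows count — near the sentence start a size that cannot be filled is
#' skipped, so the effective sizes are `min(5, available) ... 1`. If no
#' backward window matches, each forward offset's single token is tested
#' against the descriptors ("cancer of the lung" matches at offset 3).
#'
#' @param sentence an `hx_sentence`.
#' @param hotspot a hot-spot from [find_hotspots()].
#' @param lex an `hx_lexicon`.
#' @param cfg an `hx_window_config`.
#' @return `NULL` if nothing matched, else
#'   `list(phrases, direction, window_size)` where `phrases` keeps
#'   lexicon-phrase units whole and `direction` is "backward" or "forward"
#'   (for forward matches `window_size` is the matching offset).
#' @export
search_modifiers <- function(sentence, hotspot, lex, cfg = window_config()) {
  toks <- sentence$tokens
  for (size in cfg$backward_sizes) {
    w <- window_before(toks, hotspot$token_start, size)
    if (length(w) != size) next
    seg <- segment_modifiers(lex, w)
    if (!is.null(seg)) {
      return(list(phrases = seg, direction = "backward", window_size = size))
    }
  }
  n <- nrow(toks)
  for (off in cfg$forward_look_offsets) {
    j <- hotspot$token_end + off # 1-based index of the token `off` places ahead
    if (j > n) break
    if (phrase_in(lex, "modifier_descriptors", toks$norm[j])) {
      return(list(phrases = toks$norm[j], direction = "forward", window_size = off))
    }
  }
  NULL
}

#' Expand a hot-spot over its backward modifiers
#'
#' After a backward modifier match the hot-spot grows to cover the whole
#' unified concept ("cancer" becomes "small cell lung cancer"), so that the
#' negation search starts from the front of the phrase. A forward match, or no
#' match, leaves the hot-spot unchanged.
#'
#' @param hotspot a hot-spot.
#' @param modifier_match result of [search_modifiers()] (may be `NULL`).
#' @return the (possibly expanded) hot-spot.
#' @export
expand_hotspot <- function(hotspot, modifier_match) {
  if (is.null(modifier_match) || modifier_match$direction != "backward") {
    return(hotspot)
  }
  hotspot$token_start <- hotspot$token_start - modifier_match$window_size
  hotspot$expanded <- TRUE
  hotspot
}

#' Backward window search for a negation phrase
#'
#' Windows of the configured sizes are tried in descending order from the
#' start of the (possibly expanded) hot-spot; the first full window whose
#' token sequence is exactly a lexicon negation phrase wins. There is no
#' forward look. A negation farther back than the largest window — as in
#' "there is no family history of diabetes or cancer", where "of diabetes or"
#' intervenes — is missed by design; that reach limit is a documented property
#' of the engine.
#'
#' @param sentence an `hx_sentence`.
#' @param hotspot a hot-spot, expanded if a backward modifier matched.
#' @param lex an `hx_lexicon`.
#' @param cfg an `hx_window_config`.
#' @return `list(phrase, window_size)` or `NULL`.
#' @export
search_negation <- function(sentence, hotspot, lex, cfg = window_config()) {
  toks <- sentence$tokens
  for (size in cfg$backward_sizes) {
    w <- window_before(toks, hotspot$token_start, size)
    if (length(w) != size) next
    if (phrase_in(lex, "negation_phrases", w)) {
      return(list(phrase = paste(w, collapse = " "), window_size = size))
    }
  }
  NULL
}

#' Determine who experiences the mention
#'
#' Default patient. Rule A: a sentence inside a family-history section is
#' attributed to "unknown_family". Rule B: a sentence containing the phrase
#' "family history" is likewise "unknown_family". If either rule fired, the
#' sentence is scanned for specific kinship terms (first-degree relatives
#' first, then other relatives; leftmost match wins) to replace
#' "unknown_family". If neither fired, the kinship scan runs directly: a
#' nonrelative (husband, wife, spouse) discards the frame, a relative becomes
#' the experiencer, otherwise the patient keeps it.
#'
#' @param sentence an `hx_sentence`.
#' @param section the enclosing `hx_section`.
#' @param lex an `hx_lexicon`.
#' @return the experiencer string, or `NA_character_` for a discarded frame.
#' @export
determine_experiencer <- function(sentence, section, lex) {
  norms <- sentence$tokens$norm
  family_context <- section$is_family_history ||
    !is.null(find_phrase(norms, "family history"))
  if (family_context) {
    kin <- scan_kinship(norms, lex)
    return(if (is.null(kin)) "unknown_family" else kin)
  }
  if (!is.null(scan_phrases(norms, lex$nonrelatives))) {
    return(NA_character_) # nonrelative: discard
  }
  kin <- scan_kinship(norms, lex)
  if (is.null(kin)) "patient" else kin
}

# First position (1-based) where `phrase` occurs as contiguous norms, or NULL.
find_phrase <- function(norms, phrase) {
  p <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  k <- length(p)
  if (k == 0 || length(norms) < k) return(NULL)
  for (i in seq_len(length(norms) - k + 1)) {
    if (all(norms[i:(i + k - 1)] == p)) return(i)
  }
  NULL
}

# Leftmost occurrence of any phrase in `phrases`; returns the phrase or NULL.
scan_phrases <- function(norms, phrases) {
  best_pos <- Inf
  best <- NULL
  for (ph in phrases) {
    pos <- find_phrase(norms, ph)
    if (!is.null(pos) && pos < best_pos) {
      best_pos <- pos
      best <- ph
    }
  }
  best
}

scan_kinship <- function(norms, lex) {
  fdr <- scan_phrases(norms, lex$kinship_fdr)
  if (!is.null(fdr)) return(fdr)
  scan_phrases(norms, lex$kinship_other)
}

#' Build cancer frames with the Dynamic-Window engine
#'
#' For every sentence of every subjective section, each hot-spot is run
#' through the five-step pipeline: hot-spot identification, variable-size
#' bi-directional modifier search, hot-spot expansion, backward negation
#' search, and experiencer determination. Frames with a nonrelative
#' experiencer are discarded; the rest are emitted in document order.
#'
#' @param report a parsed `hx_report`.
#' @param lex an `hx_lexicon`.
#' @param cfg an `hx_window_config`.
#' @return list of `hx_frame` objects.
#' @export
build_frames_dynamic_window <- function(report, lex, cfg = window_config()) {
  frames <- list()
  for (ctx in subjective_sentences(report)) {
    sent <- ctx$sentence
    for (hs in find_hotspots(sent, lex)) {
      mods <- search_modifiers(sent, hs, lex, cfg)
      hs_exp <- expand_hotspot(hs, mods)
      neg <- search_negation(sent, hs_exp, lex, cfg)
      exp <- determine_experiencer(sent, ctx$section, lex)
      if (is.na(exp)) next
      frames[[length(frames) + 1]] <- cancer_frame(
        report_id = report$report_id,
        cancer_term = hs$term,
        modifiers = if (is.null(mods)) character(0) else mods$phrases,
        experiencer = exp,
        negation_terms = if (is.null(neg)) character(0) else neg$phrase,
        section_location = section_location(ctx$section),
        sentence_text = sent$text
      )
    }
  }
  frames
}
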