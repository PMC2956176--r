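#' Compile lexicon entries into ConText-style triggers
#'
#' The trigger/scope engine is configured entirely from the domain lexicon:
#' negation phrases become negation triggers (each carrying its own phrase as
#' the scoped value); "family history (of)" and the
#' kinship terms become experiencer triggers carrying their own value;
#' nonrelative terms become experiencer triggers valued `"DISCARD"` (a frame
#' in their scope is dropped). Bare "negative" and "unremarkable" are
#' excluded: on their own they follow the concept they negate ("EKG was
#' negative") and a forward scope would misfire — their pre-concept use is
#' covered by the "negative for"/"unremarkable for" entries.
#'
#' @param lex an `hx_lexicon`.
#' @return list of triggers `list(phrase = token vector, axis, value)`.
#' @export
compile_triggers <- function(lex) {
  triggers <- list()
  add <- function(phrase, axis, value) {
    triggers[[length(triggers) + 1]] <<- list(
      phrase = strsplit(phrase, " ", fixed = TRUE)[[1]], axis = axis, value = value
    )
  }
  post_only <- c("negative", "unremarkable")
  for (ph in setdiff(lex$negation_phrases, post_only)) add(ph, "negation", ph)
  add("family history of", "experiencer", "unknown_family")
  add("family history", "experiencer", "unknown_family")
  for (ph in c(lex$kinship_fdr, lex$kinship_other)) add(ph, "experiencer", ph)
  for (ph in lex$nonrelatives) add(ph, "experiencer", "DISCARD")
  triggers
}

#' Assign trigger scopes over a sentence
#'
#' Each trigger occurrence opens a forward scope from the token after the
#' trigger to the end of the sentence. A scope closes early at a termination
#' token ("but", "however", "although"); a later trigger on the same axis
#' re-opens the scope with its own value. Where several triggers start at the
#' same token, the longest phrase wins (so "no family history of" beats
#' "no"). Only pre-concept (forward-scoping) triggers exist in this engine.
#'
#' @param sentence an `hx_sentence`.
#' @param triggers from [compile_triggers()].
#' @param termination tokens that close an open scope.
#' @return list with per-token value vectors `negation` and `experiencer`
#'   (NA outside any scope), and `spans`, the matched trigger occurrences.
#' @export
assign_scopes <- function(sentence, triggers,
                          termination = c("but", "however", "although")) {
  norms <- sentence$tokens$norm
  n <- length(norms)
  spans <- list()
  # axes are independent: a negation trigger must not mask an experiencer
  # trigger nested inside it ("no family history of" contains "family
  # history of"), so each axis gets its own scan
  scan_axis <- function(axis) {
    axis_triggers <- Filter(function(t) t$axis == axis, triggers)
    values <- rep(NA_character_, n)
    open <- NA_character_
    i <- 1L
    while (i <= n) {
      if (norms[i] %in% termination) {
        open <- NA_character_
        i <- i + 1L
        next
      }
      hit <- NULL # longest trigger starting at i; a match consumes its tokens
      for (tr in axis_triggers) {
        k <- length(tr$phrase)
        if (i + k - 1L > n) next
        if (all(norms[i:(i + k - 1L)] == tr$phrase)) {
          if (is.null(hit) || k > length(hit$phrase)) hit <- tr
        }
      }
      if (!is.null(hit)) {
        open <- hit$value
        spans[[length(spans) + 1]] <<- list(
          axis = axis, value = hit$value,
          token_start = i - 1L, token_end = i - 1L + length(hit$phrase)
        )
        i <- i + length(hit$phrase)
        next
      }
      values[i] <- open
      i <- i + 1L
    }
    values
  }
  list(
    negation = scan_axis("negation"),
    experiencer = scan_axis("experiencer"),
    spans = spans
  )
}

#' Sentence-wide modifier attachment
#'
#' Unlike the windowed search, this engine attaches every modifier descriptor
#' found anywhere in the sentence outside the hot-spot span: the run of
#' descriptors immediately preceding the hot-spot first (kept in text order),
#' then remaining matches by increasing token distance. The long reach is
#' deliberate and reproduces the engine's documented over-attachment — in
#' "patient underwent tumor debulking ... ultrasound of the liver" the
#' trailing "liver" attaches to "tumor". Set `scope = "window"` to restrict
#' attachment to the windowed search instead.
#'
#' @param sentence an `hx_sentence`.
#' @param hotspot a hot-spot from [find_hotspots()].
#' @param lex an `hx_lexicon`.
#' @param scope `"sentence"` (default) or `"window"`.
#' @param cfg window configuration, used when `scope = "window"`.
#' @return character vector of modifier phrases (possibly empty).
#' @export
attach_modifiers_sentencewide <- function(sentence, hotspot, lex,
                                          scope = c("sentence", "window"),
                                          cfg = window_config()) {
  scope <- match.arg(scope)
  if (scope == "window") {
    m <- search_modifiers(sentence, hotspot, lex, cfg)
    return(if (is.null(m)) character(0) else m$phrases)
  }
  norms <- sentence$tokens$norm
  n <- length(norms)
  max_len <- max(lengths(strsplit(lex$modifier_descriptors, " ", fixed = TRUE)), 1L)
  in_hotspot <- function(i) i > hotspot$token_start && i <= hotspot$token_end
  matches <- list() # greedy longest-match scan, left to right
  i <- 1L
  while (i <= n) {
    if (in_hotspot(i)) {
      i <- i + 1L
      next
    }
    hit_len <- 0L
    for (len in rev(seq_len(min(max_len, n - i + 1L)))) {
      if (any(vapply(i:(i + len - 1L), in_hotspot, logical(1)))) next
      if (phrase_in(lex, "modifier_descriptors", norms[i:(i + len - 1L)])) {
        hit_len <- len
        break
      }
    }
    if (hit_len > 0L) {
      matches[[length(matches) + 1]] <- list(
        phrase = paste(norms[i:(i + hit_len - 1L)], collapse = " "),
        token_start = i - 1L, token_end = i - 1L + hit_len
      )
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  if (length(matches) == 0) return(character(0))
  ends <- vapply(matches, `[[`, integer(1), "token_end")
  starts <- vapply(matches, `[[`, integer(1), "token_start")
  # contiguous descriptor run ending at the hot-spot start, in text order
  adjacent <- logical(length(matches))
  bound <- hotspot$token_start
  for (j in rev(seq_along(matches))) {
    if (ends[j] == bound) {
      adjacent[j] <- TRUE
      bound <- starts[j]
    }
  }
  dist <- pmin(abs(starts - hotspot$token_end), abs(hotspot$token_start - ends))
  order_rest <- setdiff(order(dist), which(adjacent))
  phrases <- c(
    vapply(matches[adjacent], `[[`, character(1), "phrase"),
    vapply(matches[order_rest], `[[`, character(1), "phrase")
  )
  phrases
}

#' Build cancer frames with the ConText-style engine
#'
#' Hot-spot identification is shared with the Dynamic-Window engine; negation
#' and experiencer come from trigger scopes ([assign_scopes()]); modifiers
#' attach sentence-wide by default. A sentence inside a family-history
#' section still defaults its experiencer to "unknown_family" when no
#' experiencer scope covers the concept. Frames scoped to a nonrelative are
#' discarded. Frames are emitted in document order.
#'
#' @param report a parsed `hx_report`.
#' @param lex an `hx_lexicon`.
#' @param modifier_scope `"sentence"` (documented default) or `"window"`.
#' @param cfg window configuration, used for `modifier_scope = "window"`.
#' @return list of `hx_frame` objects.
#' @export
build_frames_context <- function(report, lex,
                                 modifier_scope = c("sentence", "window"),
                                 cfg = window_config()) {
  modifier_scope <- match.arg(modifier_scope)
  triggers <- compile_triggers(lex)
  frames <- list()
  for (ctx in subjective_sentences(report)) {
    sent <- ctx$sentence
    hotspots <- find_hotspots(sent, lex)
    if (length(hotspots) == 0) next
    scopes <- assign_scopes(sent, triggers)
    for (hs in hotspots) {
      idx <- hs$token_start + 1L # 1-based index of the concept token
      neg_phrase <- scopes$negation[idx]
      exp <- scopes$experiencer[idx]
      if (is.na(exp)) {
        exp <- if (ctx$section$is_family_history) "unknown_family" else "patient"
      }
      if (identical(exp, "DISCARD")) next
      mods <- attach_modifiers_sentencewide(sent, hs, lex, scope = modifier_scope, cfg = cfg)
      frames[[length(frames) + 1]] <- cancer_frame(
        report_id = report$report_id,
        cancer_term = hs$term,
        modifiers = mods,
        experiencer = exp,
        negation_terms = if (is.na(neg_phrase)) character(0) else neg_phrase,
        section_location = section_location(ctx$section),
        sentence_text = sent$text
      )
    }
  }
  frames
}
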