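#' Does a frame name a specific cancer?
#'
#' A frame is unspecified when it captured only a generic concept word —
#' "cancer", "tumor" or "neoplasm" — with no modifiers ("The cancer was
#' excised 6 months ago"). Any modifier ("lung cancer") or any other term
#' ("adenocarcinoma") makes it specified.
#'
#' @param frame an `hx_frame`.
#' @return `TRUE` or `FALSE`.
#' @export
is_specified <- function(frame) {
  !(frame$cancer_term %in% c("cancer", "tumor", "neoplasm") &&
    length(frame$modifiers) == 0)
}

#' Resolve a generic cancer mention against earlier frames
#'
#' Generic mentions ("the cancer") are resolved by searching the report's
#' previous frames in reverse order for the nearest specified cancer; if none
#' exists the mention is taken to be the patient's known mesothelioma.
#' Negated specified frames still serve as antecedents: the antecedent
#' restriction is on specificity only.
#'
#' @param frame an unspecified `hx_frame`.
#' @param prior_frames frames earlier in the same report, document order.
#' @return the resolved cancer phrase (a [full_phrase()] or "mesothelioma").
#' @export
resolve_reference <- function(frame, prior_frames) {
  if (is_specified(frame)) {
    stop("resolve_reference() called on a specified frame", call. = FALSE)
  }
  for (f in rev(prior_frames)) {
    if (is_specified(f)) return(full_phrase(f))
  }
  "mesothelioma"
}

# A resolved phrase counts as the known mesothelioma iff it contains the
# token "mesothelioma" ("malignant mesothelioma" is still the known cancer).
is_mesothelioma_phrase <- function(phrase) {
  "mesothelioma" %in% strsplit(tolower(phrase), "[^a-z-]+")[[1]]
}

# Resolved identity of any frame: own phrase if specified, else antecedent.
resolved_cancer <- function(frame, prior_frames) {
  if (is_specified(frame)) full_phrase(frame) else resolve_reference(frame, prior_frames)
}

#' Classify a report for personal history of ancillary cancer (Q1)
#'
#' Positive iff some frame is attributed to the patient, is not negated, and
#' resolves to a cancer other than the known mesothelioma. Frames resolving
#' to mesothelioma are excluded — the patient is known to have it.
#'
#' @param frames the report's frames, in document order.
#' @return `list(positive, supporting)` where `supporting` is the list of
#'   frames satisfying the predicate.
#' @export
classify_q1 <- function(frames) {
  supporting <- list()
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (is_family(f) || is_negated(f)) next
    resolved <- resolved_cancer(f, frames[seq_len(i - 1)])
    if (is_mesothelioma_phrase(resolved)) next
    supporting[[length(supporting) + 1]] <- f
  }
  list(positive = length(supporting) > 0, supporting = supporting)
}

#' Classify a report for family history of any cancer (Q2)
#'
#' Positive iff some non-negated frame is attributed to a family member —
#' any cancer concept counts, mesothelioma included.
#'
#' @param frames the report's frames, in document order.
#' @return `list(positive, supporting)`.
#' @export
classify_q2 <- function(frames) {
  keep <- vapply(frames, function(f) is_family(f) && !is_negated(f), logical(1))
  supporting <- frames[keep]
  list(positive = length(supporting) > 0, supporting = supporting)
}

#' Classify one report's frames on both questions
#'
#' @param frames the report's frames, in document order.
#' @param report_id report id (defaults to the frames' id).
#' @return an `hx_classification`:
#'   `list(report_id, q1_personal_ancillary, q2_family_any, supporting)`.
#' @export
classify_report <- function(frames, report_id = NULL) {
  if (is.null(report_id)) {
    report_id <- if (length(frames) > 0) frames[[1]]$report_id else NA_character_
  }
  q1 <- classify_q1(frames)
  q2 <- classify_q2(frames)
  structure(
    list(
      report_id = report_id,
      q1_personal_ancillary = q1$positive,
      q2_family_any = q2$positive,
      supporting = list(q1 = q1$supporting, q2 = q2$supporting)
    ),
    class = "hx_classification"
  )
}

#' Run an engine over a parsed corpus and classify every report
#'
#' @param reports list of parsed `hx_report` objects.
#' @param lex an `hx_lexicon`.
#' @param engine `"dynamic-window"` or `"context"`.
#' @param cfg an `hx_window_config`.
#' @param modifier_scope modifier scoping for the context engine.
#' @return list with `classifications` (data.frame: report_id, q1, q2) and
#'   `frames` (all frames, document order).
#' @export
classify_corpus <- function(reports, lex, engine = c("dynamic-window", "context"),
                            cfg = window_config(),
                            modifier_scope = c("sentence", "window")) {
  engine <- match.arg(engine)
  modifier_scope <- match.arg(modifier_scope)
  all_frames <- list()
  rows <- lapply(reports, function(rep) {
    frames <- switch(engine,
      "dynamic-window" = build_frames_dynamic_window(rep, lex, cfg),
      "context" = build_frames_context(rep, lex, modifier_scope = modifier_scope, cfg = cfg)
    )
    all_frames <<- c(all_frames, frames)
    cls <- classify_report(frames, report_id = rep$report_id)
    data.frame(
      report_id = rep$report_id,
      q1 = cls$q1_personal_ancillary,
      q2 = cls$q2_family_any,
      stringsAsFactors = FALSE
    )
  })
  classifications <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(report_id = character(0), q1 = logical(0), q2 = logical(0))
  }
  list(classifications = classifications, frames = all_frames)
}

#' Summarize per-report classifications over a corpus
#'
#' @param classifications data.frame with columns `report_id`, `q1`, `q2`.
#' @return an `hx_summary`: positive report ids and counts per question,
#'   ids sorted for stable output.
#' @export
summarize_classifications <- function(classifications) {
  q1_ids <- sort(classifications$report_id[classifications$q1])
  q2_ids <- sort(classifications$report_id[classifications$q2])
  structure(
    list(
      n_reports = nrow(classifications),
      q1_positive_ids = q1_ids, q1_positive = length(q1_ids),
      q2_positive_ids = q2_ids, q2_positive = length(q2_ids)
    ),
    class = "hx_summary"
  )
}

#' @export
print.hx_summary <- function(x, ...) {
  cat("Corpus summary:", x$n_reports, "reports\n")
  cat(
    "  Q1 personal history of ancillary cancer:", x$q1_positive, "positive\n",
    if (x$q1_positive > 0) paste("   ", paste(x$q1_positive_ids, collapse = ", "), "\n") else ""
  )
  cat(
    "  Q2 family history of any cancer:", x$q2_positive, "positive\n",
    if (x$q2_positive > 0) paste("   ", paste(x$q2_positive_ids, collapse = ", "), "\n") else ""
  )
  invisible(x)
}

#' Write a per-report results table
#'
#' Tab-separated with columns report_id, q1, q2, q1_evidence, q2_evidence
#' (evidence: the supporting frames' full phrases, "; "-joined).
#'
#' @param reports parsed reports (as in [classify_corpus()]).
#' @param lex an `hx_lexicon`.
#' @param path output path.
#' @param ... passed to [classify_corpus()].
#' @return the classifications data.frame, invisibly.
#' @export
write_results <- function(reports, lex, path, ...) {
  res <- classify_corpus(reports, lex, ...)
  by_report <- split(res$frames, vapply(res$frames, `[[`, character(1), "report_id"))
  evidence <- function(rid, q) {
    frames <- by_report[[rid]]
    if (is.null(frames)) return("")
    cls <- classify_report(frames, rid)
    paste(vapply(cls$supporting[[q]], full_phrase, character(1)), collapse = "; ")
  }
  tab <- res$classifications
  tab$q1_evidence <- vapply(tab$report_id, evidence, character(1), q = "q1")
  tab$q2_evidence <- vapply(tab$report_id, evidence, character(1), q = "q2")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res$classifications)
}
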