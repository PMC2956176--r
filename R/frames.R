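#' Construct a seven-slot cancer frame
#'
#' A cancer frame is the central record of the system: one per cancer-concept
#' mention, holding everything classification needs. Its seven slots are the
#' report id, the located cancer term (e.g. "cancer", "mesothelioma"), the
#' modifier phrases attached to it, the experiencer ("patient",
#' "unknown_family", or a specific kinship term), any matched negation
#' phrases, the section location (heading or "preamble") and the raw sentence
#' text.
#'
#' Frames whose experiencer would be a nonrelative (spouse etc.) are never
#' constructed — the engines discard them, since such mentions concern neither
#' the patient nor a blood relative.
#'
#' @param report_id report identifier.
#' @param cancer_term located concept term.
#' @param modifiers character vector of modifier phrases, text order;
#'   lexicon-phrase units are kept whole ("small cell" is one element).
#' @param experiencer "patient", "unknown_family" or a kinship term.
#' @param negation_terms character vector of matched negation phrases.
#' @param section_location section heading or "preamble".
#' @param sentence_text the sentence the mention came from.
#' @return an object of class `hx_frame`.
#' @export
cancer_frame <- function(report_id, cancer_term, modifiers = character(0),
                         experiencer = "patient", negation_terms = character(0),
                         section_location = "preamble", sentence_text = "") {
  stopifnot(
    nzchar(report_id), nzchar(cancer_term), nzchar(section_location),
    length(experiencer) == 1
  )
  structure(
    list(
      report_id = report_id,
      cancer_term = cancer_term,
      modifiers = as.character(modifiers),
      experiencer = experiencer,
      negation_terms = as.character(negation_terms),
      section_location = section_location,
      sentence_text = sentence_text
    ),
    class = "hx_frame"
  )
}

#' @export
print.hx_frame <- function(x, ...) {
  cat(
    "<hx_frame> [", x$report_id, "] ", full_phrase(x),
    if (is_negated(x)) " (negated)" else "",
    " | experiencer: ", x$experiencer,
    " | section: ", x$section_location, "\n",
    sep = ""
  )
  invisible(x)
}

#' Unified concept phrase of a frame
#'
#' Modifiers in text order followed by the cancer term, joined with spaces:
#' modifiers `c("small cell", "lung")` with term `"cancer"` give
#' `"small cell lung cancer"`.
#'
#' @param frame an `hx_frame`.
#' @return single string.
#' @export
full_phrase <- function(frame) {
  paste(c(frame$modifiers, frame$cancer_term), collapse = " ")
}

#' Is a frame negated?
#' @param frame an `hx_frame`.
#' @return `TRUE` iff the negation slot is non-empty.
#' @export
is_negated <- function(frame) length(frame$negation_terms) > 0

#' Is a frame attributed to a family member?
#' @param frame an `hx_frame`.
#' @return `TRUE` iff the experiencer is not the patient.
#' @export
is_family <- function(frame) !identical(frame$experiencer, "patient")

FRAME_COLUMNS <- c(
  "report_id", "cancer_term", "modifiers", "experiencer",
  "negation_terms", "section_location", "sentence_text"
)

#' Convert frames to a seven-column table
#'
#' Multi-valued slots (modifiers, negation terms) are joined with `"; "`.
#'
#' @param frames list of `hx_frame` objects.
#' @return data.frame with one row per frame, columns in slot order.
#' @export
frames_to_table <- function(frames) {
  rows <- lapply(frames, function(f) {
    data.frame(
      report_id = f$report_id,
      cancer_term = f$cancer_term,
      modifiers = paste(f$modifiers, collapse = "; "),
      experiencer = f$experiencer,
      negation_terms = paste(f$negation_terms, collapse = "; "),
      section_location = f$section_location,
      sentence_text = f$sentence_text,
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0) {
    return(stats::setNames(
      data.frame(matrix(character(0), nrow = 0, ncol = 7), stringsAsFactors = FALSE),
      FRAME_COLUMNS
    ))
  }
  do.call(rbind, rows)
}

#' Write a frame dump
#'
#' Tab-separated, one frame per line, header included, columns in the
#' seven-slot order. [read_frames()] round-trips the dump losslessly.
#'
#' @param frames list of `hx_frame` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  utils::write.table(frames_to_table(frames), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a frame dump written by [write_frames()]
#' @param path path to a tab-separated frame dump.
#' @return list of `hx_frame` objects.
#' @export
read_frames <- function(path) {
  tab <- utils::read.table(path,
    sep = "\t", header = TRUE, quote = "",
    colClasses = "character", stringsAsFactors = FALSE
  )
  if (!identical(names(tab), FRAME_COLUMNS)) {
    stop("frame dump columns do not match the seven-slot order", call. = FALSE)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    split_multi <- function(x) if (nzchar(x)) strsplit(x, "; ", fixed = TRUE)[[1]] else character(0)
    cancer_frame(
      report_id = tab$report_id[i],
      cancer_term = tab$cancer_term[i],
      modifiers = split_multi(tab$modifiers[i]),
      experiencer = tab$experiencer[i],
      negation_terms = split_multi(tab$negation_terms[i]),
      section_location = tab$section_location[i],
      sentence_text = tab$sentence_text[i]
    )
  })
}
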