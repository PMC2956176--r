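#' Split a corpus file into individual reports
#'
#' A corpus is plain text holding one or more history-and-physical style
#' reports separated by a delimiter line. Each block becomes one report; a
#' leading `REPORT_ID: <id>` line inside a block sets its id, otherwise ids
#' are sequential (`"1"`, `"2"`, ...). Empty blocks are skipped with a
#' warning.
#'
#' @param text corpus text (single string, possibly multi-line).
#' @param delimiter regular expression a full delimiter line must match.
#' @return list of `hx_report` objects (see [parse_report()]); sections are
#'   not yet populated.
#' @export
split_corpus <- function(text, delimiter = "^=====END_OF_REPORT=====\\s*$") {
  stopifnot(is.character(text), length(text) == 1, nzchar(text))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("\r$", "", lines)
  is_delim <- grepl(delimiter, lines)
  block_id <- cumsum(is_delim)
  reports <- list()
  seq_id <- 0L
  for (b in unique(block_id)) {
    block <- lines[block_id == b & !is_delim]
    if (all(!nzchar(trimws(block)))) {
      # trailing emptiness after a final delimiter is normal; interior blanks are not
      if (b < max(block_id)) warning("empty report block skipped", call. = FALSE)
      next
    }
    seq_id <- seq_id + 1L
    id_line <- grep("^REPORT_ID:\\s*\\S", block)
    if (length(id_line) > 0) {
      rid <- trimws(sub("^REPORT_ID:\\s*", "", block[id_line[1]]))
      block <- block[-id_line[1]]
    } else {
      rid <- as.character(seq_id)
    }
    reports[[length(reports) + 1]] <- new_report(rid, paste(block, collapse = "\n"))
  }
  reports
}

new_report <- function(report_id, raw_text) {
  structure(
    list(report_id = report_id, raw_text = raw_text, sections = list()),
    class = "hx_report"
  )
}

#' @export
print.hx_report <- function(x, ...) {
  cat("<hx_report> id=", x$report_id, ", ", length(x$sections), " sections, ",
    nchar(x$raw_text), " chars\n",
    sep = ""
  )
  invisible(x)
}

#' Parse one report: sections, sentences, tokens
#'
#' Convenience wrapper running [segment_sections()] and [split_sentences()]
#' over every section.
#'
#' @param report an `hx_report` from [split_corpus()], or a raw text string.
#' @param lex an `hx_lexicon`.
#' @param report_id id used when `report` is raw text.
#' @return the report with sections, sentences and tokens populated.
#' @export
parse_report <- function(report, lex, report_id = "1") {
  if (is.character(report)) report <- new_report(report_id, report)
  report <- segment_sections(report, lex)
  report$sections <- lapply(report$sections, split_sentences)
  report
}

#' Segment a report into heading-delimited sections
#'
#' Clinical notes follow the subjective-objective-assessment-plan layout:
#' history sections carry patient-reported narrative, while exam/assessment
#' sections carry clinician findings. A new section starts at each line whose
#' leading text (case-insensitive, tolerant of a trailing colon, at most 60
#' characters before the colon) matches a heading in the lexicon — family
#' history variants, non-subjective headings, or the configurable subjective
#' heading list. Text before the first heading forms a heading-less preamble
#' treated as subjective. A section is subjective unless its heading matched
#' `nonsubjective_headings`; frame building only ever sees subjective
#' sections.
#'
#' @param report an `hx_report`.
#' @param lex an `hx_lexicon`.
#' @param subjective_headings extra headings that open (subjective) sections,
#'   beyond the lexicon's family-history and non-subjective lists.
#' @return the report with `$sections` populated (sentences not yet split).
#' @export
segment_sections <- function(report, lex, subjective_headings = DEFAULT_SUBJECTIVE_HEADINGS) {
  stopifnot(inherits(report, "hx_report"))
  lines <- strsplit(report$raw_text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0) lines <- ""
  sections <- list()
  cur_heading <- NA_character_
  cur_lines <- character(0)
  flush <- function() {
    if (is.na(cur_heading) && all(!nzchar(trimws(cur_lines)))) return()
    sections[[length(sections) + 1]] <<- new_section(cur_heading, cur_lines, lex)
  }
  for (line in lines) {
    hit <- match_heading(line, lex, subjective_headings)
    if (!is.null(hit)) {
      flush()
      cur_heading <- hit$heading
      cur_lines <- if (nzchar(trimws(hit$rest))) hit$rest else character(0)
    } else {
      cur_lines <- c(cur_lines, line)
    }
  }
  flush()
  if (length(sections) == 0) sections <- list(new_section(NA_character_, "", lex))
  report$sections <- sections
  report
}

DEFAULT_SUBJECTIVE_HEADINGS <- c(
  "chief complaint", "cc", "history of present illness", "hpi",
  "past medical history", "pmh", "past surgical history", "psh",
  "social history", "sh", "review of systems", "ros",
  "medications", "allergies", "hospital course"
)

norm_heading <- function(x) {
  x <- tolower(trimws(x))
  x <- sub(":$", "", x)
  trimws(gsub("\\s+", " ", x))
}

# Returns list(heading, rest) if the line opens a section, else NULL.
match_heading <- function(line, lex, subjective_headings) {
  known <- c(
    lex$family_history_headings, lex$nonsubjective_headings,
    norm_heading(subjective_headings)
  )
  colon <- regexpr(":", line, fixed = TRUE)
  if (colon > 0 && colon <= 60) {
    cand <- norm_heading(substr(line, 1, colon - 1))
    if (cand %in% known) {
      return(list(heading = trimws(substr(line, 1, colon)), rest = substr(line, colon + 1, nchar(line))))
    }
  }
  cand <- norm_heading(line)
  if (nzchar(cand) && cand %in% known) {
    return(list(heading = trimws(line), rest = ""))
  }
  NULL
}

new_section <- function(heading, lines, lex) {
  h <- if (is.na(heading)) NA_character_ else heading
  hn <- if (is.na(heading)) "" else norm_heading(heading)
  structure(
    list(
      heading = h,
      is_family_history = hn %in% lex$family_history_headings,
      is_subjective = !(hn %in% lex$nonsubjective_headings),
      text = paste(lines, collapse = "\n"),
      sentences = list()
    ),
    class = "hx_section"
  )
}

#' Section display label
#' @param section an `hx_section`.
#' @return the heading, or `"preamble"` for the heading-less lead-in.
#' @export
section_location <- function(section) {
  if (is.na(section$heading)) "preamble" else section$heading
}

#' Split a section's text into sentences
#'
#' Sentences end at terminal punctuation (`.`, `!`, `?`) followed by
#' whitespace and a capital letter, or at end of text. A hard line break whose
#' line does not end in terminal punctuation also closes a sentence: clinical
#' notes frequently omit sentence-final periods, and without this rule a whole
#' unpunctuated section would be swallowed into one run-on "sentence" that
#' lets scope searches roam far too wide.
#'
#' @param section an `hx_section`.
#' @return the section with `$sentences` populated; each sentence carries its
#'   token spans from [tokenize()].
#' @export
split_sentences <- function(section) {
  stopifnot(inherits(section, "hx_section"))
  sentences <- character(0)
  for (line in strsplit(section$text, "\n", fixed = TRUE)[[1]]) {
    if (!nzchar(trimws(line))) next
    parts <- strsplit(line, "(?<=[.!?])\\s+(?=[A-Z\"'(])", perl = TRUE)[[1]]
    sentences <- c(sentences, trimws(parts))
  }
  sentences <- sentences[nzchar(sentences)]
  section$sentences <- lapply(sentences, function(s) {
    structure(list(text = s, tokens = tokenize(s)), class = "hx_sentence")
  })
  section
}

#' Tokenize sentence text into positioned tokens
#'
#' Tokens are maximal runs of non-whitespace. Each token records: `raw` (the
#' exact substring), `norm` (lowercase, leading/trailing punctuation
#' stripped, internal punctuation such as hyphens kept), `raw_clean` (edge
#' punctuation stripped but case preserved — used for exact-case acronym
#' matching), and 0-based half-open character offsets `start`/`end` into the
#' sentence. Tokens whose `norm` is empty (pure punctuation) are dropped.
#'
#' @param text sentence text.
#' @return data.frame with columns `raw`, `norm`, `raw_clean`, `start`, `end`.
#' @export
tokenize <- function(text) {
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1) {
    return(data.frame(
      raw = character(0), norm = character(0), raw_clean = character(0),
      start = integer(0), end = integer(0), stringsAsFactors = FALSE
    ))
  }
  raw <- regmatches(text, gregexpr("\\S+", text))[[1]]
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  raw_clean <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", raw)
  # keep internal hyphens: only edge punctuation is stripped ("T-PLL," -> "T-PLL")
  norm <- tolower(raw_clean)
  keep <- nzchar(norm)
  data.frame(
    raw = raw[keep], norm = norm[keep], raw_clean = raw_clean[keep],
    start = start[keep], end = end[keep], stringsAsFactors = FALSE
  )
}

#' Parse a whole corpus
#'
#' @param text corpus text or a file path (detected by [file.exists()]).
#' @param lex an `hx_lexicon`.
#' @param delimiter report delimiter regex, passed to [split_corpus()].
#' @return list of fully parsed `hx_report` objects.
#' @export
parse_corpus <- function(text, lex, delimiter = "^=====END_OF_REPORT=====\\s*$") {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  lapply(split_corpus(text, delimiter), parse_report, lex = lex)
}

# All subjective sentences of a parsed report, with their enclosing section.
subjective_sentences <- function(report) {
  out <- list()
  for (section in report$sections) {
    if (!section$is_subjective) next
    for (sent in section$sentences) {
      out[[length(out) + 1]] <- list(sentence = sent, section = section)
    }
  }
  out
}
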