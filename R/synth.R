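#' Catalogue of synthetic sentence patterns
#'
#' Every rule and every documented engine limitation is exercised by a
#' pattern: a sentence template with a known gold-label contribution and a
#' declared expected outcome per engine. Easy patterns are ones both engines
#' handle correctly; hard patterns reproduce the documented failure modes —
#' a negation pushed out of the backward window's five-token reach by an
#' intervening prepositional phrase, sentence-wide modifier over-attachment
#' ("liver tumor"), and the inconclusive either/or construction that fools
#' both engines.
#'
#' @return data.frame with columns `id`, `role` (which question slot the
#'   pattern fills), `hardness`, gold contributions `q1_gold`/`q2_gold`, and
#'   expected per-engine contributions `dw_q1`, `dw_q2`, `ctx_q1`, `ctx_q2`.
#' @export
pattern_inventory <- function() {
  p <- function(id, role, hardness, q1, q2, dw_q1 = q1, dw_q2 = q2,
                ctx_q1 = q1, ctx_q2 = q2) {
    data.frame(
      id = id, role = role, hardness = hardness,
      q1_gold = q1, q2_gold = q2,
      dw_q1 = dw_q1, dw_q2 = dw_q2, ctx_q1 = ctx_q1, ctx_q2 = ctx_q2,
      stringsAsFactors = FALSE
    )
  }
  rbind(
    p("specified_personal", "q1_pos", "easy", TRUE, FALSE),
    p("specified_personal_oma", "q1_pos", "easy", TRUE, FALSE),
    p("generic_reference_personal", "q1_pos", "easy", TRUE, FALSE),
    p("forward_location_personal", "q1_pos", "easy", TRUE, FALSE),
    p("negated_personal", "q1_neg", "easy", FALSE, FALSE),
    p("denies_personal", "q1_neg", "easy", FALSE, FALSE),
    p("meso_personal", "q1_neg", "easy", FALSE, FALSE),
    p("generic_meso_reference", "q1_neg", "easy", FALSE, FALSE),
    p("family_fdr_specified", "q2_pos", "easy", FALSE, TRUE),
    p("family_other_nonfh", "q2_pos", "easy", FALSE, TRUE),
    p("family_unknown", "q2_pos", "easy", FALSE, TRUE),
    p("family_meso", "q2_pos", "easy", FALSE, TRUE),
    p("negated_family", "q2_neg", "easy", FALSE, FALSE),
    p("nonrelative", "q2_neg", "easy", FALSE, FALSE),
    p("decoy_tumor_markers", "decoy", "easy", FALSE, FALSE),
    p("decoy_cancer_conference", "decoy", "easy", FALSE, FALSE),
    p("decoy_hematoma", "decoy", "easy", FALSE, FALSE),
    p("decoy_nonsubjective", "decoy", "easy", FALSE, FALSE),
    # documented engine limitations
    p("neg_distance_6", "q2_neg", "hard", FALSE, FALSE, dw_q2 = TRUE),
    p("sentencewide_modifier_trap", "q1_neg", "hard", FALSE, FALSE, ctx_q1 = TRUE),
    p("either_or", "q1_neg", "hard", FALSE, FALSE, dw_q1 = TRUE, ctx_q1 = TRUE),
    p("runon_lines", "q1_neg", "hard", FALSE, FALSE)
  )
}

# Verbatim hard sentences: the window-reach negation miss and the
# sentence-wide modifier trap.
SENT_NEG_DISTANCE_6 <- "There is no family history of diabetes or cancer."
SENT_MODIFIER_TRAP <- paste(
  "Patient underwent tumor debulking with chemoperfusion, splenectomy,",
  "omentectomy and interoperative ultrasound of the liver."
)
SENT_EITHER_OR <- paste(
  "The pathology was consistent with either mesothelioma versus",
  "signet-ring cell adenocarcinoma."
)

SITE_SINGLE <- c(
  "colon", "breast", "lung", "prostate", "ovarian", "bladder",
  "gastric", "thyroid", "renal", "pancreatic"
)
SITE_ANY <- c(SITE_SINGLE, "small cell lung", "squamous cell", "basal cell")
KIN_FDR <- c("mother", "father", "sister", "brother", "daughter", "son")
KIN_OTHER <- c("uncle", "aunt", "grandfather", "grandmother", "cousin")
NONREL <- c("husband", "wife", "spouse")

# Instantiate one pattern: returns list(sentences, section) where section is
# "hpi", "pmh", "fh", or "any".
instantiate_pattern <- function(id) {
  site <- sample(SITE_ANY, 1)
  site1 <- sample(SITE_SINGLE, 1)
  switch(id,
    specified_personal = list(
      sentences = sprintf("The patient was previously treated for %s cancer.", site),
      section = "pmh"
    ),
    specified_personal_oma = list(
      sentences = sprintf("She was diagnosed with adenocarcinoma in %d.", sample(1985:2005, 1)),
      section = "pmh"
    ),
    generic_reference_personal = list(
      sentences = c(
        sprintf("The patient was treated for %s cancer in %d.", site1, sample(1990:2008, 1)),
        "The tumor was subsequently resected."
      ),
      section = "pmh"
    ),
    forward_location_personal = list(
      sentences = sprintf("Imaging raised concern for cancer of the %s.", site1),
      section = "hpi"
    ),
    negated_personal = list(
      sentences = sprintf("The patient has no history of %s cancer.", site),
      section = "pmh"
    ),
    denies_personal = list(
      sentences = sprintf("He denies any history of %s cancer.", site),
      section = "pmh"
    ),
    meso_personal = list(
      sentences = "The patient carries a diagnosis of malignant mesothelioma.",
      section = "hpi"
    ),
    generic_meso_reference = list(
      sentences = "The tumor has remained stable since the last visit.",
      section = "hpi"
    ),
    family_fdr_specified = list(
      sentences = sprintf(
        "%s was diagnosed with %s cancer.",
        tools_toupper_first(sample(KIN_FDR, 1)), site1
      ),
      section = "fh"
    ),
    family_other_nonfh = list(
      sentences = sprintf("His %s had %s cancer.", sample(KIN_OTHER, 1), site1),
      section = "hpi"
    ),
    family_unknown = list(
      sentences = sprintf("There is a family history of %s cancer.", site1),
      section = "fh"
    ),
    family_meso = list(
      sentences = sprintf(
        "Her %s was diagnosed with mesothelioma.", sample(KIN_FDR, 1)
      ),
      section = "fh"
    ),
    negated_family = list(
      sentences = sample(c(
        "There is no family history of cancer.",
        "The patient denies any family history of cancer."
      ), 1),
      section = "fh"
    ),
    nonrelative = list(
      sentences = sprintf("Her %s has %s cancer.", sample(NONREL, 1), site1),
      section = "hpi"
    ),
    decoy_tumor_markers = list(
      sentences = "Tumor markers were within normal limits.",
      section = "any"
    ),
    decoy_cancer_conference = list(
      sentences = "Her case was reviewed at the cancer conference.",
      section = "any"
    ),
    decoy_hematoma = list(
      sentences = "A small hematoma was noted on the left thigh.",
      section = "any"
    ),
    decoy_nonsubjective = list(
      sentences = "There is a firm mass suspicious for carcinoma.",
      section = "pe"
    ),
    neg_distance_6 = list(sentences = SENT_NEG_DISTANCE_6, section = "fh"),
    sentencewide_modifier_trap = list(sentences = SENT_MODIFIER_TRAP, section = "hpi"),
    either_or = list(sentences = SENT_EITHER_OR, section = "hpi"),
    runon_lines = list(
      sentences = sprintf(
        "no history of %s cancer\nfollowed for hypertension\nchronic low back pain",
        site1
      ),
      section = "pmh"
    ),
    stop("unknown pattern id: ", id, call. = FALSE)
  )
}

tools_toupper_first <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

FILLER <- list(
  cc = c("Shortness of breath.", "Increasing chest discomfort.", "Scheduled follow-up visit."),
  hpi = c(
    "The patient reports mild dyspnea on exertion.",
    "Symptoms began approximately three weeks ago.",
    "Pain is adequately controlled with the current regimen.",
    "Appetite and weight have been stable."
  ),
  pmh = c(
    "Hypertension and hyperlipidemia.",
    "Type 2 diabetes managed with metformin.",
    "Appendectomy in childhood."
  ),
  sh = c(
    "The patient worked as an insulator for many years.",
    "Remote asbestos exposure is documented.",
    "He quit smoking ten years ago.",
    "Lives at home with adequate support."
  ),
  fh = c(
    "Parents are deceased of natural causes.",
    "No other significant conditions were reported."
  ),
  ros = c(
    "Review of systems is otherwise noncontributory.",
    "Denies fevers, chills, or night sweats."
  ),
  pe = c(
    "Blood pressure 128/76, pulse 82, afebrile.",
    "Lungs with decreased breath sounds at the right base.",
    "Abdomen soft and nontender."
  ),
  ap = c(
    "Continue the current treatment plan.",
    "Repeat imaging in three months."
  )
)

SECTION_HEADINGS <- c(
  cc = "CHIEF COMPLAINT:", hpi = "HISTORY OF PRESENT ILLNESS:",
  pmh = "PAST MEDICAL HISTORY:", sh = "SOCIAL HISTORY:",
  fh = "FAMILY HISTORY:", ros = "REVIEW OF SYSTEMS:",
  pe = "PHYSICAL EXAMINATION:", ap = "ASSESSMENT AND PLAN:"
)

#' Specification for a synthetic corpus
#'
#' Defaults mirror the study conditions the generator emulates: 300-report
#' test corpora with 20% of reports positive for personal history of
#' ancillary cancer and 27% positive for family history of any cancer, at
#' most 10 reports per synthetic patient.
#'
#' @param n_reports number of reports.
#' @param q1_prevalence,q2_prevalence planted positive fractions.
#' @param hardness `"easy"` (both engines correct by construction),
#'   `"documented_limitations"` (hard failure-mode patterns planted, each at
#'   least once), or `"mixed"`.
#' @param construct_mix optional named non-negative weights over pattern ids,
#'   applied within each role when sampling.
#' @param seed integer RNG seed; all sampling flows through one stream.
#' @return an `hx_synth_spec` list.
#' @export
synth_spec <- function(n_reports = 300, q1_prevalence = 0.20, q2_prevalence = 0.27,
                       hardness = c("easy", "documented_limitations", "mixed"),
                       construct_mix = NULL, seed = 1L) {
  hardness <- match.arg(hardness)
  stopifnot(
    n_reports >= 0,
    q1_prevalence >= 0, q1_prevalence <= 1,
    q2_prevalence >= 0, q2_prevalence <= 1
  )
  if (!is.null(construct_mix)) {
    stopifnot(!is.null(names(construct_mix)), all(construct_mix >= 0))
    unknown <- setdiff(names(construct_mix), pattern_inventory()$id)
    if (length(unknown) > 0) stop("unknown pattern ids in construct_mix: ", paste(unknown, collapse = ", "))
  }
  structure(
    list(
      n_reports = as.integer(n_reports),
      q1_prevalence = q1_prevalence, q2_prevalence = q2_prevalence,
      hardness = hardness, construct_mix = construct_mix, seed = as.integer(seed)
    ),
    class = "hx_synth_spec"
  )
}

# Sample an easy pattern for a role; hard patterns are planted separately.
sample_pattern <- function(role, inv, spec) {
  pool <- inv$id[inv$role == role & inv$hardness == "easy"]
  w <- rep(1, length(pool))
  if (!is.null(spec$construct_mix)) {
    w <- ifelse(pool %in% names(spec$construct_mix), spec$construct_mix[pool], 1)
  }
  if (length(pool) == 0 || sum(w) == 0) {
    stop("construct_mix leaves no usable pattern for role '", role, "'", call. = FALSE)
  }
  sample(pool, 1, prob = w)
}

#' Generate a synthetic clinical-note corpus with known ground truth
#'
#' Emits delimiter-separated, section-headed history-and-physical style
#' reports. Each report plants at most one cancer-bearing construct per
#' question (so the gold label is sound by construction and no generic
#' mention can accidentally resolve against a construct planted for the other
#' question), plus decoy sentences ("tumor markers", "hematoma", exam-section
#' mentions) that must produce no frames. At `documented_limitations`
#' hardness, the hard patterns replace their easy counterparts in a fraction
#' of label-negative reports, and each hard pattern is forced to appear at
#' least once; the gold table then also carries each engine's expected labels.
#'
#' @param spec an `hx_synth_spec`.
#' @return list with `text` (the corpus, one string) and `gold`, a data.frame
#'   with columns `report_id`, `patient_id`, `q1`, `q2`, `expected_dw_q1`,
#'   `expected_dw_q2`, `expected_ctx_q1`, `expected_ctx_q2`, `patterns`
#'   (";"-joined planted construct ids).
#' @export
generate_corpus <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "hx_synth_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  inv <- pattern_inventory()
  n <- spec$n_reports
  if (n == 0) {
    warning("generating an empty corpus", call. = FALSE)
    return(list(text = "", gold = empty_gold()))
  }
  if (spec$q1_prevalence > 0 &&
    !any(inv$role == "q1_pos" & pattern_usable(inv, spec))) {
    stop("q1_prevalence > 0 but construct_mix admits no positive pattern", call. = FALSE)
  }
  if (spec$q2_prevalence > 0 &&
    !any(inv$role == "q2_pos" & pattern_usable(inv, spec))) {
    stop("q2_prevalence > 0 but construct_mix admits no positive pattern", call. = FALSE)
  }

  # patients: 1-10 reports each, in order
  patient_sizes <- integer(0)
  while (sum(patient_sizes) < n) {
    patient_sizes <- c(patient_sizes, sample(1:10, 1, prob = c(2, 3, 4, 3, 2, 1, 1, 1, 0.5, 0.5)))
  }
  patient_of <- rep(seq_along(patient_sizes), patient_sizes)[seq_len(n)]

  q1_gold_plan <- stats::runif(n) < spec$q1_prevalence
  q2_gold_plan <- stats::runif(n) < spec$q2_prevalence
  # force each hard pattern into at least one label-negative report
  forced <- rep(NA_character_, n)
  if (spec$hardness != "easy") {
    neg_q1 <- which(!q1_gold_plan)
    neg_q2 <- which(!q2_gold_plan)
    if (length(neg_q2) > 0) forced[neg_q2[1]] <- "neg_distance_6"
    q1_slots <- setdiff(neg_q1, neg_q2[1])
    hard_q1 <- c("sentencewide_modifier_trap", "either_or", "runon_lines")
    for (k in seq_along(hard_q1)) {
      if (k <= length(q1_slots)) forced[q1_slots[k]] <- hard_q1[k]
    }
  }

  blocks <- character(n)
  gold_rows <- vector("list", n)
  for (i in seq_len(n)) {
    planted <- character(0)
    q1_pat <- q2_pat <- NULL
    if (q1_gold_plan[i]) {
      q1_pat <- sample_pattern("q1_pos", inv, spec)
    } else if (!is.na(forced[i]) && forced[i] %in% inv$id[inv$role == "q1_neg"]) {
      q1_pat <- forced[i]
    } else if (spec$hardness != "easy" && stats::runif(1) < 0.25) {
      q1_pat <- sample(inv$id[inv$role == "q1_neg" & inv$hardness == "hard"], 1)
    } else if (stats::runif(1) < 0.6) {
      q1_pat <- sample_pattern_easy("q1_neg", inv, spec)
    }
    if (q2_gold_plan[i]) {
      q2_pat <- sample_pattern("q2_pos", inv, spec)
    } else if (!is.na(forced[i]) && forced[i] == "neg_distance_6") {
      q2_pat <- forced[i]
    } else if (spec$hardness != "easy" && stats::runif(1) < 0.25) {
      q2_pat <- "neg_distance_6"
    } else if (stats::runif(1) < 0.5) {
      q2_pat <- sample_pattern_easy("q2_neg", inv, spec)
    }
    decoys <- sample(inv$id[inv$role == "decoy"], sample(0:2, 1))
    planted <- c(q1_pat, q2_pat, decoys)

    blocks[i] <- render_report(i, q1_pat, q2_pat, decoys)

    expected <- pattern_expectations(planted, inv)
    gold_rows[[i]] <- data.frame(
      report_id = sprintf("R%04d", i),
      patient_id = sprintf("P%03d", patient_of[i]),
      q1 = any_contribution(planted, inv, "q1_gold"),
      q2 = any_contribution(planted, inv, "q2_gold"),
      expected_dw_q1 = unname(expected["dw_q1"]), expected_dw_q2 = unname(expected["dw_q2"]),
      expected_ctx_q1 = unname(expected["ctx_q1"]), expected_ctx_q2 = unname(expected["ctx_q2"]),
      patterns = paste(planted, collapse = ";"),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  gold <- do.call(rbind, gold_rows)
  list(
    text = paste(blocks, collapse = "\n=====END_OF_REPORT=====\n"),
    gold = gold
  )
}

pattern_usable <- function(inv, spec) {
  if (is.null(spec$construct_mix)) return(rep(TRUE, nrow(inv)))
  ifelse(inv$id %in% names(spec$construct_mix), spec$construct_mix[inv$id] > 0, TRUE)
}

sample_pattern_easy <- function(role, inv, spec) {
  spec_easy <- spec
  spec_easy$hardness <- "easy"
  sample_pattern(role, inv, spec_easy)
}

any_contribution <- function(ids, inv, col) {
  if (length(ids) == 0) return(FALSE)
  any(inv[[col]][match(ids, inv$id)])
}

pattern_expectations <- function(ids, inv) {
  cols <- c("dw_q1", "dw_q2", "ctx_q1", "ctx_q2")
  vapply(cols, function(col) any_contribution(ids, inv, col), logical(1))
}

render_report <- function(i, q1_pat, q2_pat, decoys) {
  by_section <- list(cc = character(0), hpi = character(0), pmh = character(0),
                     sh = character(0), fh = character(0), ros = character(0),
                     pe = character(0), ap = character(0))
  place <- function(id) {
    inst <- instantiate_pattern(id)
    sec <- inst$section
    if (sec == "any") sec <- sample(c("hpi", "pmh", "sh"), 1)
    by_section[[sec]] <<- c(by_section[[sec]], inst$sentences)
  }
  for (id in c(q1_pat, q2_pat, decoys)) place(id)

  core <- c("hpi", "pmh", "pe") # always present
  optional <- setdiff(names(SECTION_HEADINGS), core)
  used <- names(by_section)[lengths(by_section) > 0]
  extra <- sample(setdiff(optional, used), sample(1:3, 1))
  keep <- names(SECTION_HEADINGS)[names(SECTION_HEADINGS) %in% union(core, union(used, extra))]

  lines <- c(sprintf("REPORT_ID: R%04d", i))
  for (sec in keep) {
    lines <- c(lines, SECTION_HEADINGS[[sec]])
    filler <- sample(FILLER[[sec]], min(sample(1:2, 1), length(FILLER[[sec]])))
    body <- c(filler, by_section[[sec]])
    # planted sentences after filler, order deterministic given the stream
    lines <- c(lines, body)
  }
  paste(lines, collapse = "\n")
}

empty_gold <- function() {
  data.frame(
    report_id = character(0), patient_id = character(0),
    q1 = logical(0), q2 = logical(0),
    expected_dw_q1 = logical(0), expected_dw_q2 = logical(0),
    expected_ctx_q1 = logical(0), expected_ctx_q2 = logical(0),
    patterns = character(0), stringsAsFactors = FALSE
  )
}

#' Write a synthetic corpus and its gold table to disk
#'
#' @param spec an `hx_synth_spec`.
#' @param corpus_path output path for the corpus text.
#' @param gold_path output path for the tab-separated gold table.
#' @return the gold data.frame, invisibly.
#' @export
write_synth_corpus <- function(spec, corpus_path, gold_path) {
  out <- generate_corpus(spec)
  writeLines(out$text, corpus_path)
  utils::write.table(out$gold, gold_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out$gold)
}
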