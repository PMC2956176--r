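frame <- function(term, mods = character(0), exp = "patient", neg = character(0)) {
  cancer_frame("R1", term, modifiers = mods, experiencer = exp, negation_terms = neg)
}

test_that("specificity separates generic from specific mentions", {
  expect_true(is_specified(frame("adenocarcinoma")))
  expect_true(is_specified(frame("cancer", mods = "lung")))
  expect_false(is_specified(frame("cancer")))
  expect_false(is_specified(frame("tumor")))
  expect_false(is_specified(frame("neoplasm")))
  expect_true(is_specified(frame("mesothelioma")))
})

test_that("reference resolution walks prior frames in reverse, defaulting to mesothelioma", {
  generic <- frame("cancer")
  expect_identical(resolve_reference(generic, list(frame("adenocarcinoma"))), "adenocarcinoma")
  expect_identical(resolve_reference(generic, list()), "mesothelioma")
  expect_identical(
    resolve_reference(generic, list(frame("cancer", mods = "lung"), frame("melanoma"))),
    "melanoma"
  )
  # intervening unspecified frames are skipped, not resolved transitively
  expect_identical(
    resolve_reference(generic, list(frame("melanoma"), frame("tumor"))),
    "melanoma"
  )
  expect_error(resolve_reference(frame("melanoma"), list()), "specified frame")
})

test_that("resolution depends only on frames before the target", {
  generic <- frame("cancer")
  prior <- list(frame("melanoma"))
  with_later <- c(prior, list(frame("adenocarcinoma")))
  expect_identical(
    resolve_reference(generic, prior),
    resolve_reference(generic, prior) # later frames never enter the call
  )
  expect_identical(resolve_reference(generic, with_later), "adenocarcinoma")
})

test_that("Q1 requires a non-negated, patient, non-mesothelioma resolution", {
  expect_false(classify_q1(list(
    frame("cancer", mods = c("small cell", "lung"), neg = "no history of")
  ))$positive)
  expect_false(classify_q1(list(frame("mesothelioma")))$positive)
  expect_false(classify_q1(list(frame("mesothelioma", mods = "malignant")))$positive)
  expect_true(classify_q1(list(frame("adenocarcinoma")))$positive)
  expect_false(classify_q1(list(frame("adenocarcinoma", exp = "mother")))$positive)
  # generic mention resolving to an earlier ancillary cancer counts
  expect_true(classify_q1(list(frame("melanoma", neg = "no"), frame("tumor")))$positive)
  # generic mention with no antecedent is the known mesothelioma
  expect_false(classify_q1(list(frame("tumor")))$positive)
  expect_length(classify_q1(list(frame("adenocarcinoma")))$supporting, 1)
})

test_that("Q2 accepts any non-negated family frame, mesothelioma included", {
  expect_true(classify_q2(list(frame("mesothelioma", exp = "father")))$positive)
  expect_false(classify_q2(list(
    frame("cancer", exp = "unknown_family", neg = "no family history of")
  ))$positive)
  expect_false(classify_q2(list(frame("adenocarcinoma")))$positive)
  expect_true(classify_q2(list(frame("cancer", exp = "unknown_family")))$positive)
})

test_that("a report of only mesothelioma-resolving or negated frames is never Q1-positive", {
  frames <- list(
    frame("mesothelioma"),
    frame("cancer"), # resolves to mesothelioma
    frame("melanoma", neg = "no history of"),
    frame("mesothelioma", mods = "malignant")
  )
  expect_false(classify_q1(frames)$positive)
})

test_that("adding a non-negated family frame never turns Q2 off", {
  set.seed(5)
  pool <- list(
    frame("cancer", exp = "mother"), frame("mesothelioma", exp = "uncle"),
    frame("melanoma", neg = "no"), frame("tumor"), frame("adenocarcinoma")
  )
  for (i in 1:25) {
    frames <- sample(pool, sample(0:4, 1), replace = TRUE)
    before <- classify_q2(frames)$positive
    augmented <- c(frames, list(frame("cancer", exp = "unknown_family")))
    expect_true(classify_q2(augmented)$positive || !before)
    expect_true(classify_q2(augmented)$positive) # the added frame alone suffices
  }
})

test_that("classify_report and the corpus summary aggregate correctly", {
  cls <- classify_report(list(frame("adenocarcinoma"), frame("cancer", exp = "mother")))
  expect_true(cls$q1_personal_ancillary)
  expect_true(cls$q2_family_any)
  expect_identical(cls$report_id, "R1")

  tab <- data.frame(
    report_id = c("R3", "R1", "R2"),
    q1 = c(FALSE, TRUE, FALSE),
    q2 = c(TRUE, FALSE, TRUE)
  )
  s <- summarize_classifications(tab)
  expect_identical(s$q1_positive_ids, "R1")
  expect_identical(s$q2_positive_ids, c("R2", "R3"))
  expect_identical(s$n_reports, 3L)

  empty <- summarize_classifications(tab[0, ])
  expect_identical(empty$q1_positive, 0L)
  expect_identical(empty$q2_positive_ids, character(0))
})

test_that("results tables carry evidence phrases", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rep <- make_report(
    "PAST MEDICAL HISTORY:", "She was treated for colon cancer.",
    "FAMILY HISTORY:", "Mother had breast cancer."
  )
  write_results(list(rep), default_lex, path)
  tab <- utils::read.delim(path)
  expect_identical(tab$q1_evidence, "colon cancer")
  expect_identical(tab$q2_evidence, "breast cancer")
})
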