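test_that("triggers compile from every relevant lexicon category", {
  triggers <- compile_triggers(default_lex)
  phrases <- vapply(triggers, function(t) paste(t$phrase, collapse = " "), character(1))
  axes <- vapply(triggers, `[[`, character(1), "axis")
  values <- vapply(triggers, `[[`, character(1), "value")

  expect_true("denies any family history of" %in% phrases[axes == "negation"])
  expect_true("no history of" %in% phrases[axes == "negation"])
  expect_identical(values[phrases == "mother"], "mother")
  expect_identical(values[phrases == "spouse"], "DISCARD")
  expect_identical(unique(values[phrases %in% c("family history", "family history of")]), "unknown_family")
  # bare post-concept cues are not forward triggers
  expect_false("negative" %in% phrases)
  expect_true("negative for" %in% phrases)

  empty_neg <- default_lex
  empty_neg$negation_phrases <- character(0)
  expect_length(Filter(function(t) t$axis == "negation", compile_triggers(empty_neg)), 0)
})

test_that("scopes run from trigger to sentence end and close at terminators", {
  triggers <- compile_triggers(default_lex)
  s <- make_sentence("no history of small cell lung cancer in her record")
  sc <- assign_scopes(s, triggers)
  cancer_idx <- which(s$tokens$norm == "cancer")
  expect_identical(sc$negation[cancer_idx], "no history of")

  # the long trigger wins over its "no" prefix, and both axes fire
  s2 <- make_sentence("there is no family history of diabetes or cancer")
  sc2 <- assign_scopes(s2, triggers)
  i <- which(s2$tokens$norm == "cancer")
  expect_identical(sc2$negation[i], "no family history of")
  expect_identical(sc2$experiencer[i], "unknown_family")

  # "but" closes an open scope
  s3 <- make_sentence("no history of melanoma but she has lung cancer")
  sc3 <- assign_scopes(s3, triggers)
  expect_true(is.na(sc3$negation[which(s3$tokens$norm == "cancer")]))
  expect_identical(sc3$negation[which(s3$tokens$norm == "melanoma")], "no history of")

  expect_length(assign_scopes(make_sentence("nothing to see here"), triggers)$spans, 0)
  # scope containment: spans never exceed the sentence
  for (sp in sc2$spans) {
    expect_gte(sp$token_start, 0)
    expect_lte(sp$token_end, nrow(s2$tokens))
  }
})

test_that("sentence-wide modifier attachment reaches across the sentence", {
  trap <- paste(
    "patient underwent tumor debulking with chemoperfusion, splenectomy,",
    "omentectomy and interoperative ultrasound of the liver"
  )
  sh <- single_hotspot(trap)
  expect_identical(sh$hotspot$term, "tumor")
  expect_identical(
    attach_modifiers_sentencewide(sh$sentence, sh$hotspot, default_lex), "liver"
  )

  near <- single_hotspot("small cell lung cancer")
  expect_identical(
    attach_modifiers_sentencewide(near$sentence, near$hotspot, default_lex),
    c("small cell", "lung")
  )

  plain <- single_hotspot("the cancer was excised")
  expect_identical(
    attach_modifiers_sentencewide(plain$sentence, plain$hotspot, default_lex),
    character(0)
  )

  # opting into windowed scope suppresses the long reach
  expect_identical(
    attach_modifiers_sentencewide(sh$sentence, sh$hotspot, default_lex, scope = "window"),
    character(0)
  )
})

test_that("context engine reproduces its documented frame behaviors", {
  trap_rep <- make_report(
    "HISTORY OF PRESENT ILLNESS:",
    paste(
      "Patient underwent tumor debulking with chemoperfusion, splenectomy,",
      "omentectomy and interoperative ultrasound of the liver."
    )
  )
  frames <- build_frames_context(trap_rep, default_lex)
  expect_length(frames, 1)
  expect_identical(full_phrase(frames[[1]]), "liver tumor")
  expect_false(is_negated(frames[[1]]))
  expect_identical(frames[[1]]$experiencer, "patient")

  ex_rep <- make_report(
    "HISTORY OF PRESENT ILLNESS:",
    "The patient has no history of small cell lung cancer in her record."
  )
  f <- build_frames_context(ex_rep, default_lex)
  expect_length(f, 1)
  expect_true(is_negated(f[[1]]))
  expect_identical(f[[1]]$experiencer, "patient")

  nonrel <- make_report("Her spouse has lung cancer.")
  expect_length(build_frames_context(nonrel, default_lex), 0)
  expect_length(build_frames_context(make_report(""), default_lex), 0)

  # family-history section still defaults the experiencer without a trigger
  fh <- make_report("FAMILY HISTORY:", "Significant for breast cancer.")
  ff <- build_frames_context(fh, default_lex)
  expect_identical(ff[[1]]$experiencer, "unknown_family")
})

test_that("engines agree on easy sentences and diverge exactly on the hard ones", {
  easy <- c(
    "The patient has no history of colon cancer.",
    "His mother had breast cancer.",
    "She was previously treated for lung cancer.",
    "There is no family history of cancer."
  )
  for (text in easy) {
    rep <- make_report("HISTORY OF PRESENT ILLNESS:", text)
    dw <- build_frames_dynamic_window(rep, default_lex)
    ctx <- build_frames_context(rep, default_lex)
    expect_identical(length(dw), length(ctx), info = text)
    for (k in seq_along(dw)) {
      expect_identical(dw[[k]]$cancer_term, ctx[[k]]$cancer_term, info = text)
      expect_identical(is_negated(dw[[k]]), is_negated(ctx[[k]]), info = text)
      expect_identical(dw[[k]]$experiencer, ctx[[k]]$experiencer, info = text)
    }
  }

  # divergence 1: negation out of the window's reach is caught by scopes
  r113 <- make_report("FAMILY HISTORY:", "There is no family history of diabetes or cancer.")
  expect_false(is_negated(build_frames_dynamic_window(r113, default_lex)[[1]]))
  expect_true(is_negated(build_frames_context(r113, default_lex)[[1]]))

  # divergence 2: only the sentence-wide engine builds "liver tumor"
  trap <- make_report(
    "HISTORY OF PRESENT ILLNESS:",
    paste(
      "Patient underwent tumor debulking with chemoperfusion, splenectomy,",
      "omentectomy and interoperative ultrasound of the liver."
    )
  )
  expect_identical(full_phrase(build_frames_dynamic_window(trap, default_lex)[[1]]), "tumor")
  expect_identical(full_phrase(build_frames_context(trap, default_lex)[[1]]), "liver tumor")
})
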