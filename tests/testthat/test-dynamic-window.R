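example_sentence <- "The patient has no history of small cell lung cancer in her record."

test_that("hot-spot identification follows the rule cascade", {
  hs <- find_hotspots(make_sentence(example_sentence), default_lex)
  expect_length(hs, 1)
  expect_identical(hs[[1]]$term, "cancer")
  expect_identical(hs[[1]]$rule, "cancer_word")
  expect_identical(hs[[1]]$token_start, 9L)

  expect_length(find_hotspots(make_sentence("a hematoma on her leg"), default_lex), 0)
  expect_length(find_hotspots(make_sentence("tumor markers were normal"), default_lex), 0)
  expect_length(find_hotspots(make_sentence("seen at the cancer conference"), default_lex), 0)

  two <- find_hotspots(
    make_sentence("mesothelioma versus signet-ring cell adenocarcinoma"), default_lex
  )
  expect_length(two, 2)
  expect_setequal(vapply(two, `[[`, character(1), "term"), c("mesothelioma", "adenocarcinoma"))

  # "cancer" is only a fallback when no -oma term is present
  with_oma <- find_hotspots(make_sentence("melanoma but no word for ca"), default_lex)
  expect_identical(vapply(with_oma, `[[`, character(1), "rule"), "oma_suffix")
  expect_length(
    find_hotspots(make_sentence("melanoma and cancer were discussed"), default_lex), 1
  )

  # acronyms are exact-case on the raw token
  expect_length(find_hotspots(make_sentence("treated for CLL previously"), default_lex), 1)
  expect_length(find_hotspots(make_sentence("she did it all herself"), default_lex), 0)

  # unique-cancer and -oma hits on the same token collapse to one hot-spot
  expect_length(find_hotspots(make_sentence("a neoplasm was found"), default_lex), 1)
})

test_that("backward windows truncate at the sentence start and never cross it", {
  toks <- tokenize(example_sentence)
  expect_identical(
    window_before(toks, 9L, 5L),
    c("history", "of", "small", "cell", "lung")
  )
  expect_identical(window_before(toks, 9L, 3L), c("small", "cell", "lung"))
  expect_identical(window_before(toks, 0L, 4L), character(0))
  expect_length(window_before(toks, 2L, 5L), 2)
})

test_that("modifier search walks sizes 5..1 then looks forward", {
  sh <- single_hotspot(example_sentence)
  m <- search_modifiers(sh$sentence, sh$hotspot, default_lex)
  expect_identical(m$direction, "backward")
  expect_identical(m$window_size, 3L)
  expect_identical(m$phrases, c("small cell", "lung"))

  fwd <- single_hotspot("cancer of the lung")
  mf <- search_modifiers(fwd$sentence, fwd$hotspot, default_lex)
  expect_identical(mf$direction, "forward")
  expect_identical(mf$window_size, 3L)
  expect_identical(mf$phrases, "lung")

  none <- single_hotspot("The cancer was excised 6 months ago")
  expect_null(search_modifiers(none$sentence, none$hotspot, default_lex))
})

test_that("hot-spots expand backward only", {
  sh <- single_hotspot(example_sentence)
  m <- search_modifiers(sh$sentence, sh$hotspot, default_lex)
  he <- expand_hotspot(sh$hotspot, m)
  expect_true(he$expanded)
  expect_identical(he$token_start, 6L) # now starts at "small"

  fwd <- single_hotspot("cancer of the lung")
  mf <- search_modifiers(fwd$sentence, fwd$hotspot, default_lex)
  expect_identical(expand_hotspot(fwd$hotspot, mf), fwd$hotspot)
  expect_identical(expand_hotspot(sh$hotspot, NULL), sh$hotspot)
})

test_that("negation search is backward-only from the expanded span", {
  sh <- single_hotspot(example_sentence)
  he <- expand_hotspot(sh$hotspot, search_modifiers(sh$sentence, sh$hotspot, default_lex))
  neg <- search_negation(sh$sentence, he, default_lex)
  expect_identical(neg$phrase, "no history of")
  expect_identical(neg$window_size, 3L)

  # the documented out-of-reach miss: "of diabetes or" pushes the negation
  # beyond the largest window
  far <- single_hotspot("there is no family history of diabetes or cancer")
  expect_null(search_negation(far$sentence, far$hotspot, default_lex))

  start <- single_hotspot("cancer was found")
  expect_null(search_negation(start$sentence, start$hotspot, default_lex))
})

test_that("experiencer rules: section, phrase, kinship, nonrelative", {
  fh_rep <- make_report("FAMILY HISTORY:", "No one has been ill.")
  fh_sec <- fh_rep$sections[[1]]
  expect_identical(
    determine_experiencer(fh_sec$sentences[[1]], fh_sec, default_lex),
    "unknown_family"
  )

  pre <- make_report("There is a family history of illness.")$sections[[1]]
  expect_identical(
    determine_experiencer(pre$sentences[[1]], pre, default_lex), "unknown_family"
  )

  kin <- make_report("His mother had breast cancer.")$sections[[1]]
  expect_identical(determine_experiencer(kin$sentences[[1]], kin, default_lex), "mother")

  # kinship refines the family-history context
  both <- make_report("FAMILY HISTORY:", "His uncle had breast cancer.")$sections[[1]]
  expect_identical(determine_experiencer(both$sentences[[1]], both, default_lex), "uncle")

  nonrel <- make_report("His wife has lung cancer.")$sections[[1]]
  expect_identical(
    determine_experiencer(nonrel$sentences[[1]], nonrel, default_lex), NA_character_
  )

  plain <- make_report("The patient has lung cancer.")$sections[[1]]
  expect_identical(determine_experiencer(plain$sentences[[1]], plain, default_lex), "patient")
})

test_that("full frame build reproduces the worked example end to end", {
  rep <- make_report("HISTORY OF PRESENT ILLNESS:", example_sentence)
  frames <- build_frames_dynamic_window(rep, default_lex)
  expect_length(frames, 1)
  f <- frames[[1]]
  expect_identical(f$cancer_term, "cancer")
  expect_identical(f$modifiers, c("small cell", "lung"))
  expect_identical(f$negation_terms, "no history of")
  expect_identical(f$experiencer, "patient")
  expect_identical(full_phrase(f), "small cell lung cancer")

  # nonsubjective sections are never searched
  pe <- make_report("PHYSICAL EXAMINATION:", "mass suspicious for carcinoma")
  expect_length(build_frames_dynamic_window(pe, default_lex), 0)

  nonrel <- make_report("Her spouse has lung cancer.")
  expect_length(build_frames_dynamic_window(nonrel, default_lex), 0)

  empty <- make_report("")
  expect_length(build_frames_dynamic_window(empty, default_lex), 0)
})

test_that("frame building is deterministic", {
  rep <- make_report(
    "HISTORY OF PRESENT ILLNESS:", example_sentence,
    "FAMILY HISTORY:", "His mother had breast cancer."
  )
  a <- build_frames_dynamic_window(rep, default_lex)
  b <- build_frames_dynamic_window(rep, default_lex)
  expect_identical(a, b)
})

test_that("windowed searches agree with brute-force enumeration", {
  set.seed(101)
  n_checked <- 0
  for (i in 1:400) {
    rs <- random_lexicon_sentence(default_lex)
    norms <- rs$sentence$tokens$norm
    anchor <- rs$anchor_start
    hs <- list(
      token_start = anchor, token_end = anchor + 1L,
      term = "cancer", rule = "cancer_word", expanded = FALSE
    )
    m <- search_modifiers(rs$sentence, hs, default_lex)
    expected_m <- brute_modifier_window(default_lex, norms, anchor)
    if (is.na(expected_m)) {
      expect_true(is.null(m) || m$direction == "forward")
    } else {
      expect_identical(m$window_size, expected_m)
      expect_identical(m$direction, "backward")
    }
    neg <- search_negation(rs$sentence, hs, default_lex)
    expected_n <- brute_negation_window(default_lex, norms, anchor)
    if (is.na(expected_n)) {
      expect_null(neg)
    } else {
      expect_identical(neg$window_size, expected_n)
    }
    n_checked <- n_checked + 1
  }
  expect_identical(n_checked, 400)
})
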