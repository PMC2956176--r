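---
title: "Classifying cancer history from clinical free text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cancer history from clinical free text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cancerhx)
```

## The problem

Tissue banks and registries that track mesothelioma patients need two facts
that usually live only in narrative history-and-physical (H&P) notes: does
the patient have a personal history of any cancer *other than* the known
mesothelioma (Q1), and is there a family history of any cancer (Q2)?
`cancerhx` answers both questions per report with rule-based information
extraction. Everything the classifier knows is held in an editable
five-category domain lexicon (cancer identification terms, modifiers,
kinship terms, section headings, negation phrases), so curation of the
lexicon — the dominant improvement path in this style of system — never
requires touching code.

The unit of information is the **cancer frame**: one record per
cancer-concept mention, with seven slots — report id, cancer term, modifier
phrases, experiencer, negation terms, section location, sentence text. Two
interchangeable engines fill the slots; everything upstream (parsing) and
downstream (frame evaluation, classification) is shared, which makes the
engines directly comparable.

## Report parsing

A corpus file is split into reports on a delimiter line (default
`=====END_OF_REPORT=====`; the export format of any record system can be
accommodated by changing the regex). Reports are segmented into sections at
lines whose leading text matches a heading in the lexicon, case-insensitive
and colon-tolerant, with at most 60 characters before the colon — the length
cap keeps a mid-sentence "family history" from opening a section; that case
is instead handled by the experiencer phrase rule. Clinical notes follow the
subjective/objective/assessment/plan convention, and only *subjective*
sections are searched for frames. Because no exhaustive list of subjective
headings exists, the policy is the implementable complement: every section
is subjective unless its heading is in the non-subjective list (physical
examination, assessment, impression, ...). Text before the first heading is
a subjective preamble.

Sentences end at terminal punctuation followed by whitespace and a capital,
*or* at a hard line break without terminal punctuation. The line-break rule
is a deliberate mitigation: dictated notes frequently drop sentence-final
periods, and a splitter that waits for punctuation hands a scope engine a
run-on "sentence" spanning half a section. The cost is that a sentence
wrapped mid-clause across lines is split in two; for frame building this is
the safer error, since windows and scopes never cross sentence boundaries.

Tokens are whitespace-delimited; each keeps its raw form, a case-preserved
copy with edge punctuation stripped (for exact-case acronym matching), and a
lowercase norm. Internal punctuation survives, so "T-PLL," normalizes to
"t-pll" with raw form "T-PLL".

## Hot-spots

Both engines share concept identification. The cascade: every token ending
in *-oma/-omas* that is not a known non-cancer (hematoma, glaucoma, coma,
...); only if no *-oma* token exists, the word "cancer"; unconditionally,
the unique cancer words (hodgkin, leukemia, neoplasm, tumor) and the cancer
acronyms, matched exact-case on the raw token so the determiner "all" never
fires the leukemia acronym "ALL". A candidate immediately followed by a noun
that uses cancer as an adjective ("tumor *markers*", "cancer *conference*")
is suppressed. "melanoma" appears both as an *-oma* concept and as a
modifier descriptor (it modifies in phrases like "melanoma in situ
excision"); we keep it in both roles and flag the dual listing to lexicon
curators.

## Engine 1: Dynamic-Window

From each hot-spot, a variable-size backward window search runs at sizes 5,
4, 3, 2, 1: the first window *exactly partitionable* into modifier
descriptors wins. Partitionability is the right reading of "the entire
window matches the lexicon" because descriptors are 1-3 token phrases:
"small cell lung" is the two entries "small cell" + "lung". Only full
windows are tested, so near the sentence start the effective sizes are
`min(5, available) ... 1`. If no backward window matches, a forward look at
single-token offsets 1-3 catches "cancer of the *location*". A backward
match expands the hot-spot over the modifiers ("cancer" becomes "small cell
lung cancer"); a forward match does not expand.

Negation then runs the same backward search (no forward look) from the
*expanded* span start, requiring the whole window to equal a negation
phrase. The expansion is what lets "no history of" be found three tokens
before "small cell lung cancer" even though it sits six tokens before
"cancer" itself. The reach limit is real and kept: in "there is no family
history of diabetes or cancer" the intervening "of diabetes or" pushes the
negation beyond the largest window and the frame is (wrongly) built
non-negated. That miss is asserted in the test suite as expected behavior —
it is a documented property of fixed window sizes, and the window
configuration is exposed (`window_config()`) precisely so users can
experiment with larger sizes.

The experiencer defaults to the patient. A family-history section or the
phrase "family history" in the sentence switches it to "unknown_family",
refined to a specific relative if a kinship term is present (first-degree
relatives scanned before other relatives, leftmost match winning, for
determinism). Outside family context, a kinship term sets the experiencer
directly and a nonrelative term (husband, wife, spouse) discards the frame
entirely — neither the patient nor a blood relative.

## Engine 2: ConText-style trigger scopes

The second engine compiles the same lexicon into forward-scoping triggers in
the NegEx/ConText tradition: each trigger occurrence opens a scope from the
token after the trigger to the sentence end, closed early by a termination
token ("but", "however", "although" — a conventional set, chosen here
because no inventory is fixed by the classification task) or re-opened by a
later trigger on the same axis. The negation and experiencer axes are
scanned independently, because triggers nest across axes: "no family
history of" (negation) contains "family history of" (experiencer) and both
must fire. At each position the longest trigger wins its axis. Bare
"negative" and "unremarkable" are not forward triggers — alone they follow
the concept ("EKG was negative"); their pre-concept use is covered by the
"negative for"/"unremarkable for" entries.

Modifiers attach sentence-wide: every descriptor outside the hot-spot span,
nearest first, with the descriptor run immediately preceding the hot-spot
kept in text order. This long reach is deliberately retained together with
its documented failure — in "patient underwent tumor debulking ...
ultrasound of the liver" the trailing "liver" attaches and an errant "liver
tumor" frame is built. A `modifier_scope = "window"` flag opts into windowed
attachment for users who want the fix rather than fidelity.

The two engines agree on easy sentences (negation adjacent to the concept,
no intervening material) and diverge exactly where documented: the scope
engine catches the out-of-reach negation the window engine misses, and the
window engine avoids the sentence-wide modifier trap the scope engine falls
into. Both build two frames for inconclusive either/or sentences
("... either mesothelioma versus signet-ring cell adenocarcinoma"), which
misclassifies such reports under both engines — neither models uncertainty.

## Frame evaluation

A frame is *specified* if it names a cancer beyond a bare generic word
("cancer"/"tumor"/"neoplasm" with no modifiers). Generic frames are resolved
by searching previous frames of the report in reverse for the nearest
specified cancer; with no antecedent the mention is taken to be the known
mesothelioma. Negated specified frames still serve as antecedents — the
antecedent condition is specificity; whether a negated antecedent should be
barred is genuinely open, and we chose the permissive reading because "the
cancer" most often refers back to whatever cancer was last *named*,
negated or not. Resolution is per-report; reports of the same patient are
classified independently.

Q1 is positive iff some frame is patient-attributed, non-negated, and
resolves to a phrase not containing the token "mesothelioma" (the token test
keeps "malignant mesothelioma" excluded). Q2 is positive iff some
non-negated frame belongs to a family member — mesothelioma counts there,
since familial mesothelioma is family history of cancer.

## Evaluation layer

`confusion()` and the four standard measures (accuracy, precision, recall,
F) score predictions against a gold table; zero denominators return 0 with a
warning rather than NaN so corpus-level summaries stay finite. Agreement
between annotators uses observed agreement, positive/negative specific
agreement (2a/(2a+b+c) and its complement form), and Cohen's kappa; with two
categories weighted kappa reduces to unweighted kappa, so a single
implementation covers both descriptions. The three-annotator mode reports
all pairwise statistics, their averages, and the 2-of-3 majority vote used
as the reference standard — including its known blind spot: a label two
annotators miss is lost even when the third is right. Confidence intervals
use the Wilson score method, a package choice (the interval method behind
published tables of this kind is rarely stated); Wilson is preferred over
Wald for proportions near 1, where these accuracies live. Presentation
rounding is half-up at three decimals.

## Synthetic corpora

Real H&P reports are PHI-restricted, so the package ships a seeded generator
(`generate_corpus()`) instead of data. Defaults emulate the study conditions
this classifier targets: 300-report corpora, 20% Q1-positive and 27%
Q2-positive, at most 10 reports per synthetic patient, 4-8 headed sections
per report. Every planted sentence comes from a pattern inventory that
declares its gold contribution *and* each engine's expected behavior, so a
corpus carries both gold labels and per-engine expected labels. Each report
plants at most one cancer-bearing construct per question — this makes gold
labels sound by construction and prevents a generic mention from
accidentally resolving against a construct planted for the other question —
plus decoys ("tumor markers", "hematoma", exam-section mentions) that must
yield no frames. All sampling flows through one RNG stream keyed by the
seed; generation is byte-reproducible.

Hardness `"easy"` uses only constructs both engines handle, and both engines
must recover gold exactly (accuracy 1.0) — that is a regression gate, not a
performance claim. Hardness `"documented_limitations"` additionally plants
the hard constructs, each at least once, verbatim where a specific sentence
is documented; each engine must then err exactly on the reports whose
patterns predict its error and nowhere else. What passing these suites shows
is that the *rules are implemented faithfully*; it does not show performance
on real clinical text, whose misspellings, transcription noise, idiosyncratic
headings and unbounded vocabulary the generator deliberately does not model.

Test problem sizes are the package's own choices: 300-report easy and
150-report hard corpora in the acceptance suite, 1000 randomized sentences
for the oracle-equivalence property (windowed searches against brute-force
enumeration of all contiguous preceding runs of length at most 5).

## Numerical and degenerate-input choices

Tokenization drops pure-punctuation tokens; empty sections and empty reports
yield empty frame lists, never errors. Window searches skip truncated
windows rather than padding. Ties in kinship scanning break leftmost-first.
`pairwise_agreement()` on constant raters (chance agreement 1) defines kappa
as 1 for perfect agreement and 0 otherwise, with a warning. The generator
rejects impossible specifications (positive prevalence with all positive
patterns weighted to zero). An empty requested corpus is a warning, not an
error.

## Known limitations

- No syntactic parsing: negation scope is purely lexical; prepositional
  phrases defeat the window engine and long sentences over-extend the scope
  engine.
- Either/or constructions build frames for both alternatives; uncertainty is
  not represented.
- No temporality axis: "history of" and current disease are not
  distinguished beyond the negation lexicon.
- Lexicon coverage bounds recall; terms absent from the lexicon are
  invisible. The lexicon file is the intended extension point.
- Reference resolution never crosses report boundaries.
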