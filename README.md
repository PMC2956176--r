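# cancerhx

Rule-based classification of cancer history from free-text clinical notes.

Registries and tissue banks that follow mesothelioma patients must abstract
two facts from narrative history-and-physical (H&P) reports: **Q1** — does
the patient have a personal history of *ancillary* cancer (any malignancy
other than the known mesothelioma)? and **Q2** — is there a family history
of any cancer? `cancerhx` answers both questions per report by building
**seven-slot semantic cancer frames** (report id, cancer term, modifiers,
experiencer, negation terms, section location, sentence text) from the
subjective sections of each note, then evaluating the frames.

Two interchangeable frame-building engines share one domain lexicon, one
parser and one evaluation layer:

- **Dynamic-Window** — hot-spots on cancer concepts (``-oma`` suffixes, the
  word "cancer", unique cancer words, exact-case acronyms), then a
  variable-size backward window search (sizes 5, 4, 3, 2, 1) for modifier
  phrases with a 3-offset forward look for "cancer of the *location*",
  hot-spot expansion over matched modifiers, a backward-only window search
  for negation phrases, and rule-based experiencer attribution
  (family-history section → unknown family → specific relative; nonrelative
  mentions discarded).
- **ConText-style** — the same hot-spots under NegEx/ConText-style forward
  trigger scopes for negation and experiencer, with sentence-wide modifier
  attachment.

Generic mentions ("the cancer") are resolved against the nearest earlier
specified frame, defaulting to mesothelioma. Q1 requires a non-negated,
patient-attributed frame resolving to a non-mesothelioma cancer; Q2 requires
a non-negated family-attributed frame (mesothelioma included).

The package also provides the evaluation side — confusion counts, accuracy,
precision, recall, F-measure (harmonic mean `2PR/(P+R)`), observed and
positive/negative specific agreement `2a/(2a+b+c)`, Cohen's kappa
`(po−pe)/(1−pe)`, three-annotator majority vote — and a seeded synthetic
H&P corpus generator with known ground truth for testing without clinical
data.

## Worked example

```r
library(cancerhx)
lex <- load_lexicon()

report <- parse_report(paste(
  "HISTORY OF PRESENT ILLNESS:",
  "The patient has no history of small cell lung cancer in her record.",
  "FAMILY HISTORY:",
  "His mother had breast cancer.",
  sep = "\n"), lex, report_id = "example")

frames <- build_frames_dynamic_window(report, lex)
for (f in frames) print(f)
#> <hx_frame> [example] small cell lung cancer (negated) | experiencer: patient | section: HISTORY OF PRESENT ILLNESS:
#> <hx_frame> [example] breast cancer | experiencer: mother | section: FAMILY HISTORY:

cls <- classify_report(frames)
cat("Q1:", cls$q1_personal_ancillary, " Q2:", cls$q2_family_any, "\n")
#> Q1: FALSE  Q2: TRUE
```

In the first sentence the backward modifier search matches at window size 3
("small cell lung"), the hot-spot expands to "small cell lung cancer", and
the negation search then matches "no history of" — also at window size 3 —
so the frame is negated and does not count toward Q1. The second frame is a
non-negated breast-cancer mention attributed to the patient's mother, so the
report is Q2-positive.

Corpus-level use with the synthetic generator:

```r
out <- generate_corpus(synth_spec(n_reports = 10, seed = 42))
res <- classify_corpus(parse_corpus(out$text, lex), lex, engine = "context")
print(summarize_classifications(res$classifications))
#> Corpus summary: 10 reports
#>   Q1 personal history of ancillary cancer: 1 positive
#>      R0006
#>   Q2 family history of any cancer: 3 positive
#>      R0002, R0006, R0010
```

A command-line interface wraps the same functions
(`exec/hx classify|evaluate|synth`), e.g.:

```sh
Rscript exec/hx synth --corpus corpus.txt --gold gold.tsv --n 300 --seed 1
Rscript exec/hx classify --input corpus.txt --engine dynamic-window --output pred.tsv
Rscript exec/hx evaluate --pred pred.tsv --gold gold.tsv
```

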