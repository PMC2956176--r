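#' Confusion counts between predictions and gold labels
#'
#' @param pred logical vector of system calls.
#' @param gold logical vector of reference-standard labels, aligned with
#'   `pred`.
#' @return an `hx_confusion`: `list(tp, fp, tn, fn)`.
#' @export
confusion <- function(pred, gold) {
  if (length(pred) != length(gold)) {
    stop("pred and gold differ in length (", length(pred), " vs ", length(gold), ")",
      call. = FALSE
    )
  }
  stopifnot(is.logical(pred), is.logical(gold), !anyNA(pred), !anyNA(gold))
  structure(
    list(
      tp = sum(pred & gold), fp = sum(pred & !gold),
      tn = sum(!pred & !gold), fn = sum(!pred & gold)
    ),
    class = "hx_confusion"
  )
}

#' @export
print.hx_confusion <- function(x, ...) {
  cat(sprintf(
    "<hx_confusion> tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
    x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn
  ))
  invisible(x)
}

total_n <- function(c) c$tp + c$fp + c$tn + c$fn

ratio0 <- function(num, den, what) {
  if (den == 0) {
    warning(what, ": zero denominator, returning 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Classification performance measures
#'
#' Accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' F-measure `2PR/(P+R)` — the harmonic mean of precision and recall. A zero
#' denominator yields 0 with a warning.
#'
#' @param c an `hx_confusion`.
#' @return a proportion in `[0, 1]`.
#' @name performance
NULL

#' @rdname performance
#' @export
accuracy <- function(c) ratio0(c$tp + c$tn, total_n(c), "accuracy")

#' @rdname performance
#' @export
precision <- function(c) ratio0(c$tp, c$tp + c$fp, "precision")

#' @rdname performance
#' @export
recall <- function(c) ratio0(c$tp, c$tp + c$fn, "recall")

#' @rdname performance
#' @export
f_measure <- function(c) harmonic_f(precision(c), recall(c))

#' @rdname performance
#' @param p precision.
#' @param r recall.
#' @export
harmonic_f <- function(p, r) {
  if (p + r == 0) {
    warning("f-measure: zero denominator, returning 0", call. = FALSE)
    return(0)
  }
  2 * p * r / (p + r)
}

#' All four performance measures at once
#' @param c an `hx_confusion`.
#' @return named numeric vector: accuracy, precision, recall, f_measure.
#' @export
performance_measures <- function(c) {
  p <- precision(c)
  r <- recall(c)
  c(accuracy = accuracy(c), precision = p, recall = r, f_measure = harmonic_f(p, r))
}

#' Pairwise agreement between two annotators
#'
#' From the pair's 2x2 table (a = both positive, d = both negative, b/c =
#' disagreements): observed agreement `(a+d)/n`; positive specific agreement
#' `2a/(2a+b+c)`; negative specific agreement `2d/(2d+b+c)`; Cohen's kappa
#' `(po - pe)/(1 - pe)` with chance agreement `pe` from the marginals. With
#' two categories, weighted kappa reduces to this unweighted kappa, so one
#' statistic covers both. If `pe = 1` (both raters constant), kappa is 1 when
#' agreement is perfect and 0 otherwise, with a warning.
#'
#' @param a,b logical vectors of the two annotators' answers, aligned.
#' @return an `hx_agreement`: `list(observed, pos_specific, neg_specific,
#'   kappa)`.
#' @export
pairwise_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("annotation vectors differ in length", call. = FALSE)
  n <- length(a)
  if (n == 0) stop("cannot compute agreement on empty annotations", call. = FALSE)
  stopifnot(is.logical(a), is.logical(b), !anyNA(a), !anyNA(b))
  both_pos <- sum(a & b)
  both_neg <- sum(!a & !b)
  dis <- n - both_pos - both_neg
  observed <- (both_pos + both_neg) / n
  pos_specific <- if (2 * both_pos + dis == 0) 0 else 2 * both_pos / (2 * both_pos + dis)
  neg_specific <- if (2 * both_neg + dis == 0) 0 else 2 * both_neg / (2 * both_neg + dis)
  pe <- (sum(a) / n) * (sum(b) / n) + (sum(!a) / n) * (sum(!b) / n)
  kappa <- if (pe == 1) {
    warning("degenerate marginals (pe = 1); kappa set to ",
      if (observed == 1) 1 else 0,
      call. = FALSE
    )
    if (observed == 1) 1 else 0
  } else {
    (observed - pe) / (1 - pe)
  }
  structure(
    list(
      observed = observed, pos_specific = pos_specific,
      neg_specific = neg_specific, kappa = kappa
    ),
    class = "hx_agreement"
  )
}

#' @export
print.hx_agreement <- function(x, ...) {
  cat(sprintf(
    "<hx_agreement> observed=%.3f Ppos=%.3f Pneg=%.3f kappa=%.3f\n",
    x$observed, x$pos_specific, x$neg_specific, x$kappa
  ))
  invisible(x)
}

#' Majority-vote reference standard from three annotators
#'
#' Per-position 2-of-3 consensus. A label two annotators miss is lost from
#' the reference standard even if the third annotator is right — the vote is
#' the definition of truth here, not a correction of it.
#'
#' @param a1,a2,a3 logical vectors, aligned.
#' @return logical vector of consensus labels.
#' @export
majority_vote <- function(a1, a2, a3) {
  if (length(a1) != length(a2) || length(a2) != length(a3)) {
    stop("annotator vectors differ in length", call. = FALSE)
  }
  (a1 + a2 + a3) >= 2
}

#' Agreement table for three annotators
#'
#' All three pairwise comparisons plus their average, per question.
#'
#' @param a1,a2,a3 logical vectors, aligned.
#' @return data.frame: pair, observed, pos_specific, neg_specific, kappa,
#'   with an "average" row.
#' @export
agreement_table <- function(a1, a2, a3) {
  pairs <- list(`1 vs 2` = list(a1, a2), `1 vs 3` = list(a1, a3), `2 vs 3` = list(a2, a3))
  rows <- lapply(names(pairs), function(nm) {
    g <- pairwise_agreement(pairs[[nm]][[1]], pairs[[nm]][[2]])
    data.frame(
      pair = nm, observed = g$observed, pos_specific = g$pos_specific,
      neg_specific = g$neg_specific, kappa = g$kappa, stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  avg <- data.frame(
    pair = "average", observed = mean(tab$observed),
    pos_specific = mean(tab$pos_specific), neg_specific = mean(tab$neg_specific),
    kappa = mean(tab$kappa), stringsAsFactors = FALSE
  )
  rbind(tab, avg)
}

#' Wilson score interval for a proportion
#'
#' Used for the confidence intervals accompanying accuracy, precision and
#' recall. The score interval behaves well for proportions near 0 or 1,
#' where the Wald interval degenerates.
#'
#' @param successes number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(successes, n, conf = 0.95) {
  stopifnot(n > 0, successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Round half-up to a fixed number of decimals
#'
#' Presentation rounding for result tables (base `round()` rounds half to
#' even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 3) {
  # small guard against binary representation error (0.9275 * 1000 = 927.49..)
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}
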