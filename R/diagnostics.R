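#' Confusion counts for a scalar index at a cutoff
#'
#' Tabulates predicted failure (the score meets the cutoff in the stated
#' direction, threshold inclusive) against a dichotomous criterion.
#'
#' @param scores Numeric vector of index values.
#' @param truth Logical vector: `TRUE` = criterion-positive (non-credible /
#'   criterion failed).
#' @param cutoff Numeric threshold.
#' @param fail_direction `"at_or_above"` (scores `>=` cutoff fail, e.g. an
#'   EI total) or `"at_or_below"` (scores `<=` cutoff fail, e.g. TOMM-1).
#' @return List of class `"confusion_counts"` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_cutoff <- function(scores, truth, cutoff,
                                fail_direction = c("at_or_above", "at_or_below")) {
  fail_direction <- match.arg(fail_direction)
  if (length(scores) == 0L) stop("empty input", call. = FALSE)
  if (length(scores) != length(truth))
    stop("scores and truth must have equal length", call. = FALSE)
  truth <- as.logical(truth)
  if (anyNA(scores) || anyNA(truth))
    stop("missing values in scores or truth", call. = FALSE)
  pred <- if (fail_direction == "at_or_above") scores >= cutoff else scores <= cutoff
  structure(list(tp = sum(pred & truth), fp = sum(pred & !truth),
                 tn = sum(!pred & !truth), fn = sum(!pred & truth)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, OCC, and base rate of failure from counts
#'
#' Standard signal-detection rates: sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, overall correct classification (OCC) `(tp+tn)/N`, and the
#' base rate of failure `(tp+fp)/N` (the proportion flagged, which upper-
#' bounds the false-positive rate). All at full precision; rounding is a
#' display concern (see [fmt_prop()]).
#'
#' @param counts A `confusion_counts` object or list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @return List with `sensitivity`, `specificity`, `occ`, `br_fail`.
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    n <- tp + fp + tn + fn
    if (n == 0L) stop("empty confusion table", call. = FALSE)
    if (tp + fn == 0L) stop("no criterion-positive cases: sensitivity undefined",
                            call. = FALSE)
    if (tn + fp == 0L) stop("no criterion-negative cases: specificity undefined",
                            call. = FALSE)
    list(sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         occ = (tp + tn) / n,
         br_fail = (tp + fp) / n)
  })
}

#' Base rate of failure at a cutoff
#'
#' Proportion of all scores meeting the failure condition; no external
#' criterion is involved.
#'
#' @inheritParams confusion_at_cutoff
#' @return Proportion in \[0, 1\].
#' @export
base_rate_fail <- function(scores, cutoff,
                           fail_direction = c("at_or_above", "at_or_below")) {
  fail_direction <- match.arg(fail_direction)
  if (length(scores) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(scores)) stop("missing values in scores", call. = FALSE)
  if (fail_direction == "at_or_above") mean(scores >= cutoff)
  else mean(scores <= cutoff)
}

#' Cutoff sweep of classification accuracy
#'
#' One row per cutoff: base rate of failure plus sensitivity, specificity,
#' and OCC against the criterion — the layout of a classification-accuracy
#' table swept from liberal to conservative cutoffs.
#'
#' @inheritParams confusion_at_cutoff
#' @param cutoffs Numeric vector of cutoffs, liberal to conservative.
#' @return Data frame with columns `cutoff`, `br_fail`, `sensitivity`,
#'   `specificity`, `occ`.
#' @examples
#' set.seed(1)
#' s <- sample(0:8, 40, TRUE); tr <- s + rnorm(40) > 4
#' roc_sweep(s, tr, 1:7)
#' @export
roc_sweep <- function(scores, truth, cutoffs,
                      fail_direction = c("at_or_above", "at_or_below")) {
  fail_direction <- match.arg(fail_direction)
  if (length(cutoffs) == 0L) stop("no cutoffs supplied", call. = FALSE)
  rows <- lapply(cutoffs, function(cu) {
    m <- classification_metrics(confusion_at_cutoff(scores, truth, cu,
                                                    fail_direction))
    data.frame(cutoff = cu, br_fail = base_rate_fail(scores, cu, fail_direction),
               sensitivity = m$sensitivity, specificity = m$specificity,
               occ = m$occ)
  })
  do.call(rbind, rows)
}

#' Nonparametric AUC with Hanley--McNeil confidence interval
#'
#' Area under the ROC curve estimated as the Mann--Whitney probability that
#' a randomly chosen criterion-positive case scores more extremely (in the
#' failure direction) than a randomly chosen negative case, with ties
#' credited one half. The standard error and 95% CI use the Hanley--McNeil
#' normal approximation, with the CI truncated to \[0, 1\].
#'
#' @inheritParams confusion_at_cutoff
#' @return List with `auc`, `se`, `ci_lo`, `ci_hi`, `n_pos`, `n_neg`.
#' @export
auc_mann_whitney <- function(scores, truth,
                             fail_direction = c("at_or_above", "at_or_below")) {
  fail_direction <- match.arg(fail_direction)
  truth <- as.logical(truth)
  if (length(scores) != length(truth))
    stop("scores and truth must have equal length", call. = FALSE)
  if (anyNA(scores) || anyNA(truth))
    stop("missing values in scores or truth", call. = FALSE)
  n1 <- sum(truth); n2 <- sum(!truth)
  if (n1 == 0L || n2 == 0L)
    stop("need at least one positive and one negative case", call. = FALSE)
  x <- if (fail_direction == "at_or_above") scores else -scores
  # midranks give the tie-corrected Mann-Whitney statistic directly
  r <- rank(x, ties.method = "average")
  auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  z <- stats::qnorm(0.975)
  list(auc = auc, se = se,
       ci_lo = max(0, auc - z * se), ci_hi = min(1, auc + z * se),
       n_pos = n1, n_neg = n2)
}

#' Likelihood ratio as a quotient of base rates
#'
#' In the cross-range analyses a likelihood ratio is the base rate of
#' criterion failure in one index range divided by that in another (e.g.,
#' Fail over Pass). Both arguments must be on the same scale (both
#' proportions or both percentages).
#'
#' @param br_numerator,br_denominator Base rates on a common scale.
#' @return The quotient, full precision.
#' @export
likelihood_ratio <- function(br_numerator, br_denominator) {
  if (any(br_denominator == 0))
    stop("zero denominator base rate", call. = FALSE)
  br_numerator / br_denominator
}

#' Base rates of criterion failure across classification ranges
#'
#' For each criterion measure, the base rate of failure within each index
#' band (Pass / Borderline / Fail), the derived likelihood ratios
#' Borderline/Pass, Fail/Borderline, and Fail/Pass, and the column means
#' across criteria. `NA` criterion flags are dropped per criterion (a
#' criterion administered to a subsample keeps its own n).
#'
#' @param bands Factor or character vector of band labels per examinee
#'   (levels Pass, Borderline, Fail).
#' @param criterion_fails Named list of logical vectors, aligned with
#'   `bands`; each entry is one criterion measure's fail flag.
#' @return List of class `"range_br_table"`: `br` (data frame, percent
#'   scale, one row per criterion plus band ns), `lr` (data frame with
#'   columns `b_over_p`, `f_over_b`, `f_over_p` and a `mean` row appended).
#' @export
range_br_analysis <- function(bands, criterion_fails) {
  bands <- factor(as.character(bands), levels = band_levels)
  if (anyNA(bands)) stop("bands must be Pass/Borderline/Fail", call. = FALSE)
  if (!is.list(criterion_fails) || is.null(names(criterion_fails)) ||
      any(!nzchar(names(criterion_fails))))
    stop("criterion_fails must be a named list of logical vectors", call. = FALSE)
  if (any(table(bands) == 0L))
    stop("every band must contain at least one examinee", call. = FALSE)
  br <- t(vapply(criterion_fails, function(fl) {
    if (length(fl) != length(bands))
      stop("criterion vector length mismatch", call. = FALSE)
    fl <- as.logical(fl)
    vapply(band_levels, function(b) {
      sel <- bands == b & !is.na(fl)
      if (!any(sel)) return(NA_real_)
      100 * mean(fl[sel])
    }, numeric(1))
  }, numeric(3)))
  br_df <- data.frame(criterion = rownames(br),
                      pass = br[, "Pass"], borderline = br[, "Borderline"],
                      fail = br[, "Fail"], row.names = NULL)
  lr_df <- data.frame(
    criterion = br_df$criterion,
    b_over_p = likelihood_ratio(br_df$borderline, br_df$pass),
    f_over_b = likelihood_ratio(br_df$fail, br_df$borderline),
    f_over_p = likelihood_ratio(br_df$fail, br_df$pass))
  lr_df <- rbind(lr_df,
                 data.frame(criterion = "mean",
                            b_over_p = mean(lr_df$b_over_p),
                            f_over_b = mean(lr_df$f_over_b),
                            f_over_p = mean(lr_df$f_over_p)))
  structure(list(br = br_df, lr = lr_df,
                 band_n = stats::setNames(as.integer(table(bands)), band_levels)),
            class = "range_br_table")
}

#' @export
print.range_br_table <- function(x, ...) {
  cat("Base rate of criterion failure (%) by classification range\n")
  cat(sprintf("  n: Pass %d / Borderline %d / Fail %d\n",
              x$band_n["Pass"], x$band_n["Borderline"], x$band_n["Fail"]))
  b <- x$br; b[-1] <- lapply(b[-1], round, 1)
  print(b, row.names = FALSE)
  cat("Likelihood ratios\n")
  l <- x$lr; l[-1] <- lapply(l[-1], round, 2)
  print(l, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio profile across individual index values
#'
#' Base rate of criterion failure at each index value, expressed as a
#' likelihood ratio relative to the zero-score baseline — the per-value
#' rather than per-band view of how risk grows with the index.
#'
#' @param scores Integer index values per examinee.
#' @param criterion_fails Named list of logical vectors aligned with
#'   `scores`.
#' @param values Index values to profile; defaults to every observed value.
#'   The baseline value 0 must be observed.
#' @return Data frame: `value`, then one base-rate (%) and one LR column per
#'   criterion.
#' @export
value_lr_profile <- function(scores, criterion_fails,
                             values = sort(unique(scores))) {
  if (!any(scores == 0))
    stop("no examinees at the zero-score baseline", call. = FALSE)
  out <- data.frame(value = values)
  for (nm in names(criterion_fails)) {
    fl <- as.logical(criterion_fails[[nm]])
    if (length(fl) != length(scores))
      stop("criterion vector length mismatch", call. = FALSE)
    br <- vapply(values, function(v) {
      sel <- scores == v & !is.na(fl)
      if (!any(sel)) return(NA_real_)
      100 * mean(fl[sel])
    }, numeric(1))
    base <- 100 * mean(fl[scores == 0 & !is.na(fl)])
    out[[paste0("br_", nm)]] <- br
    out[[paste0("lr_", nm)]] <- if (base > 0) br / base else NA_real_
  }
  out
}

#' Cohen's d from group means and standard deviations
#'
#' Standardized mean difference. The default denominator is the square root
#' of the unweighted average of the two variances,
#' `sqrt((sd1^2 + sd2^2)/2)`; a df-weighted pooled denominator is available
#' via `pooled = TRUE` (then `n1`, `n2` are required). The absolute
#' difference is reported.
#'
#' @param mean1,sd1,mean2,sd2 Group summary statistics (`sd > 0`).
#' @param pooled Use the df-weighted pooled SD instead of the
#'   average-variance denominator.
#' @param n1,n2 Group sizes, required when `pooled = TRUE`.
#' @return Nonnegative effect size d.
#' @examples
#' cohens_d(284.5, 20.4, 237.8, 40.0)  # 1.47
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2, pooled = FALSE,
                     n1 = NULL, n2 = NULL) {
  if (any(c(sd1, sd2) <= 0)) stop("standard deviations must be positive",
                                  call. = FALSE)
  denom <- if (pooled) {
    if (is.null(n1) || is.null(n2))
      stop("pooled = TRUE requires n1 and n2", call. = FALSE)
    sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  } else {
    sqrt((sd1^2 + sd2^2) / 2)
  }
  abs(mean1 - mean2) / denom
}

#' Phi-squared effect size from a chi-square statistic
#'
#' `phi^2 = chi^2 / N`, the proportion-of-association effect size attached
#' to contingency-table tests.
#'
#' @param chi2 Pearson chi-square statistic.
#' @param n Sample size underlying the table.
#' @return Phi-squared.
#' @examples
#' phi_squared(90.0, 452)
#' @export
phi_squared <- function(chi2, n) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(chi2 < 0)) stop("chi2 must be non-negative", call. = FALSE)
  chi2 / n
}

#' Pearson chi-square statistic for an r x c table
#'
#' Thin wrapper around [stats::chisq.test()] without continuity correction,
#' returning just the statistic for use with [phi_squared()].
#'
#' @param counts Matrix or table of non-negative counts with positive
#'   margins.
#' @return The X-squared statistic.
#' @export
chi2_rxc <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in counts table", call. = FALSE)
  unname(suppressWarnings(stats::chisq.test(counts, correct = FALSE))$statistic)
}

#' Round half away from zero at display precision
#'
#' All computation in the package is full precision; this is the single
#' display-rounding rule (half away from zero, the convention of printed
#' clinical tables, unlike [round()]'s round-half-even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
fmt_prop <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
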