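#' Aggregate three free-standing PVT outcomes into the G-3 composite
#'
#' The G-3 composite summarizes the Word Memory Test, Medical Symptom
#' Validity Test, and Non-Verbal MSVT at their standard cutoffs: passing all
#' three is an overall Pass; failing two or more is an overall Fail; exactly
#' one failure is Indeterminate (a single failure is insufficient to deem a
#' profile invalid, and such cases are excluded from dichotomous criterion
#' grouping).
#'
#' @param fail_flags Logical vector of length three (`TRUE` = failed that
#'   PVT at its standard cutoff).
#' @return List with `n_fails` (0--3) and `label` (factor Pass /
#'   Indeterminate / Fail).
#' @examples
#' g3_outcome(c(TRUE, FALSE, FALSE))$label
#' @export
g3_outcome <- function(fail_flags) {
  if (length(fail_flags) != 3L || !is.logical(fail_flags) || anyNA(fail_flags))
    stop("fail_flags must be exactly three non-missing logicals", call. = FALSE)
  n <- sum(fail_flags)
  label <- if (n == 0L) "Pass" else if (n == 1L) "Indeterminate" else "Fail"
  list(n_fails = as.integer(n),
       label = factor(label, levels = c("Pass", "Indeterminate", "Fail")))
}

#' Dichotomize the G-3 at a chosen failure count
#'
#' Table-style dichotomies `G-3 >= m`: an examinee fails when at least
#' `min_fails` of the three component PVTs are failed. `min_fails = 2` is
#' the standard Fail definition; `min_fails = 1` is the liberal variant.
#'
#' @param fail_flags Logical vector of length three.
#' @param min_fails Integer in 1--3.
#' @return `TRUE` if the composite is failed.
#' @export
g3_dichotomy <- function(fail_flags, min_fails = 2L) {
  if (length(fail_flags) != 3L || !is.logical(fail_flags) || anyNA(fail_flags))
    stop("fail_flags must be exactly three non-missing logicals", call. = FALSE)
  min_fails <- as.integer(min_fails)
  if (length(min_fails) != 1L || is.na(min_fails) || min_fails < 1L || min_fails > 3L)
    stop("min_fails must be 1, 2, or 3", call. = FALSE)
  sum(fail_flags) >= min_fails
}

#' Trichotomize the WMT from its three main subtest percentages
#'
#' The Word Memory Test three-way outcome from the Immediate Recognition,
#' Delayed Recognition, and Consistency subtests (percent correct): Pass if
#' all three exceed the cutoff; Borderline if none is below it but at least
#' one equals it (the manual's "Warning"); Fail if any falls below it.
#' Inputs are compared at one-decimal precision, mirroring the printed
#' "85.0%" convention.
#'
#' @param ir,dr,cns Subtest percentages in \[0, 100\].
#' @param cutoff Percentage cutoff, default 85.0.
#' @return Factor with levels Pass, Borderline, Fail.
#' @examples
#' wmt_trichotomize(85.0, 90, 95)  # Borderline
#' @export
wmt_trichotomize <- function(ir, dr, cns, cutoff = 85.0) {
  x <- c(ir, dr, cns)
  if (length(x) != 3L || !is.numeric(x) || anyNA(x) ||
      any(x < 0 | x > 100))
    stop("ir, dr, cns must be single percentages in [0, 100]", call. = FALSE)
  x <- round(x, 1L)
  cutoff <- round(cutoff, 1L)
  band <- if (any(x < cutoff)) "Fail"
          else if (any(x == cutoff)) "Borderline"
          else "Pass"
  factor(band, levels = c("Pass", "Borderline", "Fail"))
}

#' Cross two dichotomous validity classifiers
#'
#' Joint outcome of a criterion composite (e.g., G-3) and the index band,
#' both already dichotomized (Borderline / Indeterminate cases excluded
#' upstream): passed both, mixed (passed one, failed the other), or failed
#' both.
#'
#' @param g3_label,ei_band Character or factor scalars, each `"Pass"` or
#'   `"Fail"`.
#' @return Factor with levels passed_both, mixed, failed_both.
#' @export
joint_outcome <- function(g3_label, ei_band) {
  a <- as.character(g3_label); b <- as.character(ei_band)
  if (length(a) != 1L || length(b) != 1L ||
      !a %in% c("Pass", "Fail") || !b %in% c("Pass", "Fail"))
    stop("both labels must be 'Pass' or 'Fail' (dichotomize upstream)",
         call. = FALSE)
  out <- if (a == "Pass" && b == "Pass") "passed_both"
         else if (a == "Fail" && b == "Fail") "failed_both"
         else "mixed"
  factor(out, levels = c("passed_both", "mixed", "failed_both"))
}

#' Row-wise G-3 labels for a cohort
#'
#' Convenience wrapper applying [g3_outcome()] over the `wmt_fail`,
#' `msvt_fail`, and `nvmsvt_fail` columns of a cohort table.
#'
#' @param cohort Data frame with logical (or 0/1) columns `wmt_fail`,
#'   `msvt_fail`, `nvmsvt_fail`.
#' @return Factor vector (Pass / Indeterminate / Fail), one per row.
#' @export
g3_label_cohort <- function(cohort) {
  cols <- c("wmt_fail", "msvt_fail", "nvmsvt_fail")
  absent <- setdiff(cols, names(cohort))
  if (length(absent))
    stop("cohort lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  flags <- vapply(cols, function(cn) as.logical(cohort[[cn]]),
                  logical(nrow(cohort)))
  if (nrow(cohort) == 1L) flags <- matrix(flags, nrow = 1L)
  n <- rowSums(flags)
  if (anyNA(n)) stop("missing criterion PVT flag(s)", call. = FALSE)
  factor(ifelse(n == 0L, "Pass", ifelse(n == 1L, "Indeterminate", "Fail")),
         levels = c("Pass", "Indeterminate", "Fail"))
}

#' Dichotomize TOMM-1 trial-1 scores
#'
#' Convenience wrapper over the generic cutoff machinery with
#' `fail_direction = "at_or_below"`. The default Fail cutoff is <= 42, the
#' more commonly cited calibration; some summaries use <= 43 instead, so
#' the cutoff is an explicit argument rather than a fixed rule.
#'
#' @param scores Integer trial-1 scores in 0--50.
#' @param cutoff Fail cutoff (score at or below fails). Default 42.
#' @return Logical vector: `TRUE` = failed.
#' @export
tomm1_fail <- function(scores, cutoff = 42) {
  if (any(!is.na(scores) & (scores < 0 | scores > 50)))
    stop("TOMM-1 scores must lie in 0..50", call. = FALSE)
  scores <= cutoff
}
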