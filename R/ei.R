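#' Sum recoded failure levels into the index total
#'
#' The index total is the plain, unweighted sum of the component failure
#' levels; for a k-component battery it ranges from 0 (all components passed
#' at the most liberal cutoff) to 3k (all failed at the most conservative
#' cutoff).
#'
#' @param levels Integer vector with every element in `0:3`.
#' @return Integer total.
#' @export
ei_total <- function(levels) {
  levels <- as.integer(levels)
  if (length(levels) == 0L) stop("empty level vector", call. = FALSE)
  if (anyNA(levels) || any(levels < 0L | levels > 3L))
    stop("levels must all lie in 0..3", call. = FALSE)
  sum(levels)
}

band_levels <- c("Pass", "Borderline", "Fail")

#' Classify an index total into Pass / Borderline / Fail
#'
#' @param total Integer total(s) in `0:(3k)`.
#' @param battery A [battery_config()] supplying `pass_max` and
#'   `borderline_max`.
#' @return Factor with levels Pass, Borderline, Fail.
#' @examples
#' classify_total(0:5, ei5_battery())
#' @export
classify_total <- function(total, battery) {
  stopifnot(inherits(battery, "battery_config"))
  total <- as.integer(total)
  kmax <- 3L * length(battery$components)
  if (anyNA(total) || any(total < 0L | total > kmax))
    stop(sprintf("total out of range 0..%d", kmax), call. = FALSE)
  band <- ifelse(total <= battery$pass_max, "Pass",
                 ifelse(total <= battery$borderline_max, "Borderline", "Fail"))
  factor(band, levels = band_levels)
}

#' Score a cohort: recode, total, and band every examinee
#'
#' Takes a cohort data frame holding one column per battery component (raw
#' scores) and appends, for each component, a `lvl_<name>` column with the
#' recoded level, plus `ei_total` and `ei_band`. Under
#' `missing_policy = "error"` any `NA` in a component column aborts with the
#' offending row and component; under `"complete_case"` such rows are
#' dropped and the drop count is recorded in `attr(result, "n_dropped")`
#' (and reported via `message()`).
#'
#' @param cohort Data frame with one row per examinee.
#' @param battery A [battery_config()].
#' @return The retained rows with level, total, and band columns appended.
#' @examples
#' coh <- data.frame(CD = c(10, 6, 4), RCFT_Copy = c(32, 29, 24.5),
#'                   FMS_WCST = c(0, 3, 5), RDS = c(10, 8, 7),
#'                   RH_CVLT = c(15, 13, 13))
#' score_cohort(coh, ei5_battery())$ei_total
#' @export
score_cohort <- function(cohort, battery) {
  stopifnot(is.data.frame(cohort), inherits(battery, "battery_config"))
  nms <- names(battery$components)
  absent <- setdiff(nms, names(cohort))
  if (length(absent))
    stop("cohort lacks component column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  n0 <- nrow(cohort)
  if (n0 == 0L) {
    out <- cohort
    for (nm in nms) out[[paste0("lvl_", nm)]] <- integer(0)
    out$ei_total <- integer(0)
    out$ei_band <- factor(character(0), levels = band_levels)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  na_mat <- vapply(nms, function(nm) is.na(cohort[[nm]]), logical(n0))
  if (n0 == 1L) na_mat <- matrix(na_mat, nrow = 1L, dimnames = list(NULL, nms))
  any_na <- rowSums(na_mat) > 0L
  if (any(any_na)) {
    if (battery$missing_policy == "error") {
      i <- which(any_na)[1L]
      stop(sprintf("missing score in row %d, component %s (missing_policy = 'error')",
                   i, nms[which(na_mat[i, ])[1L]]), call. = FALSE)
    }
    message(sprintf("score_cohort: dropped %d of %d rows with missing component scores",
                    sum(any_na), n0))
  }
  keep <- !any_na
  out <- cohort[keep, , drop = FALSE]
  lvl <- vapply(nms, function(nm)
    recode_score(out[[nm]], battery$components[[nm]]), integer(nrow(out)))
  if (nrow(out) == 1L) lvl <- matrix(lvl, nrow = 1L, dimnames = list(NULL, nms))
  for (nm in nms) out[[paste0("lvl_", nm)]] <- as.integer(lvl[, nm])
  out$ei_total <- as.integer(rowSums(lvl))
  out$ei_band <- classify_total(out$ei_total, battery)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(any_na)
  out
}

#' Exhaustively enumerate every level vector of a battery
#'
#' Brute-force oracle over all `4^k` level vectors: counts how many vectors
#' fall in each band and finds the minimum number of failing components
#' needed to reach the Fail band when every nonzero component sits at a
#' single stated level. For the default EI-5 bands this recovers the two
#' headline facts of the scale: at least four marginal (level-1) failures,
#' or at least two conservative (level-2) failures, are needed to Fail.
#'
#' @param battery A [battery_config()]; `k <= 10` is enforced (the scan is
#'   exhaustive).
#' @return List with `band_counts` (named integer vector over the three
#'   bands, summing to `4^k`), `min_level1_only_components_for_fail`, and
#'   `min_level2_only_components_for_fail` (NA if unattainable).
#' @export
enumerate_fail_combinations <- function(battery) {
  stopifnot(inherits(battery, "battery_config"))
  k <- length(battery$components)
  if (k > 10L)
    stop("k too large for exhaustive enumeration (k <= 10)", call. = FALSE)
  grid <- as.matrix(expand.grid(rep(list(0:3), k)))
  totals <- rowSums(grid)
  bands <- classify_total(totals, battery)
  band_counts <- table(bands)
  fail_min <- battery$borderline_max + 1L
  min_at_level <- function(lv) {
    # vectors whose nonzero entries are all == lv; minimal count reaching Fail
    ok <- apply(grid, 1L, function(v) all(v %in% c(0L, lv)) && any(v == lv))
    cand <- grid[ok & totals >= fail_min, , drop = FALSE]
    if (nrow(cand) == 0L) return(NA_integer_)
    as.integer(min(rowSums(cand > 0L)))
  }
  list(band_counts = stats::setNames(as.integer(band_counts), names(band_counts)),
       min_level1_only_components_for_fail = min_at_level(1L),
       min_level2_only_components_for_fail = min_at_level(2L))
}
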