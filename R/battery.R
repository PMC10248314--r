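#' Declare an embedded validity indicator and its failure-level cutoffs
#'
#' A component specification describes one embedded validity indicator (EVI):
#' the direction in which scores become non-credible and the three cutoffs
#' that split its scale into ordinal failure levels 0--3. Level 0 is an
#' unequivocal pass; level 1 corresponds to the most liberal published cutoff
#' (specificity at or above .84); levels 2 and 3 correspond to progressively
#' more conservative cutoffs (base rates of failure near 10% and 5%).
#'
#' For a `low_fails` indicator the cutoffs must be strictly decreasing
#' (`c1 > c2 > c3`); scores at or below a cutoff reach that level. For a
#' `high_fails` indicator they must be strictly increasing and scores at or
#' above a cutoff reach the level. The "failing" comparison is always
#' inclusive of the printed threshold.
#'
#' @param name Short identifier, e.g. `"CD"`.
#' @param direction `"low_fails"` (low scores are non-credible) or
#'   `"high_fails"`.
#' @param cuts Numeric vector of three cutoffs `(c1, c2, c3)` ordered by
#'   increasing severity.
#' @param valid_range Closed numeric interval `c(lo, hi)` of admissible raw
#'   scores.
#' @param units Free-text score metric, e.g. `"ACSS"` or `"raw"`.
#' @param granularity Optional positive step size of the score scale (e.g.
#'   `0.5` for figure-copy scores). When set, off-grid raw scores are snapped
#'   to the nearest grid point before recoding, with exact midpoints resolved
#'   toward the failure direction.
#'
#' @return A validated object of class `"component_spec"`.
#' @seealso [recode_score()], [battery_config()]
#' @examples
#' cd <- component_spec("CD", "low_fails", c(6, 5, 4), c(1, 19), units = "ACSS")
#' recode_score(5, cd)
#' @export
component_spec <- function(name, direction = c("low_fails", "high_fails"),
                           cuts, valid_range, units = "raw",
                           granularity = NULL) {
  direction <- match.arg(direction)
  spec <- structure(
    list(name = as.character(name), direction = direction,
         cuts = as.numeric(cuts), valid_range = as.numeric(valid_range),
         units = as.character(units),
         granularity = if (is.null(granularity)) NULL else as.numeric(granularity)),
    class = "component_spec")
  validate_component_spec(spec)
}

#' Validate a component specification
#'
#' Checks the structural invariants of a [component_spec()]: strict cutoff
#' ordering in the failure direction, cutoffs inside the valid range, a
#' non-degenerate range, and a positive granularity when one is declared.
#'
#' @param spec A `component_spec`.
#' @return The spec, unchanged, if valid; otherwise an error whose message
#'   names the violated invariant.
#' @export
validate_component_spec <- function(spec) {
  stopifnot(inherits(spec, "component_spec"))
  if (!nzchar(spec$name)) stop("component name must be non-empty", call. = FALSE)
  if (length(spec$cuts) != 3L || anyNA(spec$cuts) || !all(is.finite(spec$cuts)))
    stop(sprintf("component '%s': exactly three finite cuts required", spec$name),
         call. = FALSE)
  ord_ok <- if (spec$direction == "low_fails")
    spec$cuts[1] > spec$cuts[2] && spec$cuts[2] > spec$cuts[3]
  else
    spec$cuts[1] < spec$cuts[2] && spec$cuts[2] < spec$cuts[3]
  if (!ord_ok)
    stop(sprintf("component '%s': cuts must be strictly %s for %s",
                 spec$name,
                 if (spec$direction == "low_fails") "decreasing" else "increasing",
                 spec$direction),
         call. = FALSE)
  if (length(spec$valid_range) != 2L || anyNA(spec$valid_range) ||
      spec$valid_range[1] >= spec$valid_range[2])
    stop(sprintf("component '%s': valid_range must be a proper interval (lo < hi)",
                 spec$name), call. = FALSE)
  if (any(spec$cuts < spec$valid_range[1] | spec$cuts > spec$valid_range[2]))
    stop(sprintf("component '%s': cuts outside valid_range", spec$name),
         call. = FALSE)
  if (!is.null(spec$granularity) &&
      (length(spec$granularity) != 1L || !is.finite(spec$granularity) ||
       spec$granularity <= 0))
    stop(sprintf("component '%s': granularity must be a positive number",
                 spec$name), call. = FALSE)
  spec
}

#' @export
print.component_spec <- function(x, ...) {
  cat(sprintf("<component_spec> %s (%s, %s)\n", x$name, x$units, x$direction))
  cat(sprintf("  cuts: %s | range: [%g, %g]%s\n",
              paste(x$cuts, collapse = " / "),
              x$valid_range[1], x$valid_range[2],
              if (is.null(x$granularity)) ""
              else sprintf(" | grid: %g", x$granularity)))
  invisible(x)
}

# Snap a raw score to the component's grid. Midpoint ties are resolved toward
# the failure direction so a boundary case never escapes a level it would
# reach under the inclusive-threshold convention.
snap_to_grid <- function(raw, spec) {
  g <- spec$granularity
  if (is.null(g)) return(raw)
  lo <- spec$valid_range[1]
  k <- (raw - lo) / g
  kf <- floor(k)
  frac <- k - kf
  eps <- sqrt(.Machine$double.eps)
  down <- frac < 0.5 - eps |
    (abs(frac - 0.5) <= eps & spec$direction == "low_fails")
  lo + ifelse(down, kf, kf + 1) * g
}

#' Recode a raw score onto the 0--3 ordinal failure scale
#'
#' Maps a raw score to an Erdodi Index failure level using the component's
#' three cutoffs. For a `low_fails` component: level 0 if `raw > c1`, 1 if
#' `c2 < raw <= c1`, 2 if `c3 < raw <= c2`, 3 if `raw <= c3`. For
#' `high_fails` the comparisons mirror with `>=`. Scores on a declared
#' granularity grid are compared as-is; off-grid scores are first snapped to
#' the grid (midpoints toward failure), so every admissible score maps to
#' exactly one level.
#'
#' @param raw Numeric vector of raw scores within the component's
#'   `valid_range`.
#' @param spec A [component_spec()].
#' @return Integer vector of failure levels in `0:3`.
#' @examples
#' rcft <- component_spec("RCFT", "low_fails", c(29, 25, 22), c(0, 36),
#'                        units = "raw", granularity = 0.5)
#' recode_score(c(30.5, 27, 24.5, 21), rcft)
#' @export
recode_score <- function(raw, spec) {
  validate_component_spec(spec)
  if (length(raw) == 0L) return(integer(0))
  if (!is.numeric(raw) || anyNA(raw) || !all(is.finite(raw)))
    stop(sprintf("component '%s': raw scores must be finite numbers", spec$name),
         call. = FALSE)
  if (any(raw < spec$valid_range[1] | raw > spec$valid_range[2]))
    stop(sprintf("component '%s': raw score outside valid_range [%g, %g]",
                 spec$name, spec$valid_range[1], spec$valid_range[2]),
         call. = FALSE)
  x <- snap_to_grid(raw, spec)
  cuts <- spec$cuts
  if (spec$direction == "low_fails")
    as.integer((x <= cuts[1]) + (x <= cuts[2]) + (x <= cuts[3]))
  else
    as.integer((x >= cuts[1]) + (x >= cuts[2]) + (x >= cuts[3]))
}

#' Assemble a battery of components with classification bands
#'
#' A battery is an ordered set of component specifications plus the total-score
#' bands that trichotomize the summed index: totals at or below `pass_max`
#' are a Pass, totals above `pass_max` up to `borderline_max` are Borderline,
#' and higher totals are a Fail. The default bands (1, 3) reproduce the
#' standard EI-5 convention Pass <= 1 / Borderline 2--3 / Fail >= 4.
#'
#' @param components List of [component_spec()] objects (unique names).
#' @param pass_max Highest total still classified Pass (non-negative integer).
#' @param borderline_max Highest total still classified Borderline
#'   (`>= pass_max`); a Fail must remain attainable, i.e.
#'   `borderline_max + 1 <= 3k`.
#' @param name Battery label.
#' @param missing_policy `"error"` (default: a missing component score is an
#'   error) or `"complete_case"` (rows with missing scores are dropped and
#'   counted).
#' @return An object of class `"battery_config"`.
#' @examples
#' bat <- ei5_battery()
#' bat$pass_max; bat$borderline_max
#' @export
battery_config <- function(components, pass_max = 1L, borderline_max = 3L,
                           name = "battery",
                           missing_policy = c("error", "complete_case")) {
  missing_policy <- match.arg(missing_policy)
  if (!is.list(components) || length(components) < 1L ||
      !all(vapply(components, inherits, logical(1), "component_spec")))
    stop("components must be a non-empty list of component_spec objects",
         call. = FALSE)
  lapply(components, validate_component_spec)
  nms <- vapply(components, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("component names must be unique", call. = FALSE)
  pass_max <- as.integer(pass_max)
  borderline_max <- as.integer(borderline_max)
  k <- length(components)
  if (pass_max < 0L) stop("pass_max must be non-negative", call. = FALSE)
  if (borderline_max < pass_max)
    stop("borderline_max must be >= pass_max", call. = FALSE)
  if (borderline_max + 1L > 3L * k)
    stop(sprintf("Fail unattainable: borderline_max + 1 = %d exceeds 3k = %d",
                 borderline_max + 1L, 3L * k), call. = FALSE)
  names(components) <- nms
  structure(list(name = name, components = components,
                 pass_max = pass_max, borderline_max = borderline_max,
                 missing_policy = missing_policy),
            class = "battery_config")
}

#' @export
print.battery_config <- function(x, ...) {
  k <- length(x$components)
  cat(sprintf("<battery_config> %s: %d components, bands Pass <=%d / Borderline %d-%d / Fail >=%d\n",
              x$name, k, x$pass_max, x$pass_max + 1L, x$borderline_max,
              x$borderline_max + 1L))
  for (s in x$components)
    cat(sprintf("  %-10s %-10s cuts %s\n", s$name, s$direction,
                paste(s$cuts, collapse = "/")))
  invisible(x)
}

#' The default five-component EI-5 battery
#'
#' The standard EI-5 configuration: Digit-Symbol Coding (WAIS-R age-corrected
#' scaled score), the Rey Complex Figure Test copy trial (raw, 0.5-point
#' grid), failures to maintain set on the Wisconsin Card Sorting Test,
#' Reliable Digit Span, and CVLT Yes/No recognition hits, with bands
#' Pass <= 1 / Borderline 2--3 / Fail >= 4.
#'
#' @param missing_policy Passed through to [battery_config()].
#' @return A `battery_config` with `k = 5`.
#' @export
ei5_battery <- function(missing_policy = c("error", "complete_case")) {
  missing_policy <- match.arg(missing_policy)
  battery_config(
    list(
      component_spec("CD",        "low_fails",  c(6, 5, 4),          c(1, 19),  units = "ACSS", granularity = 1),
      component_spec("RCFT_Copy", "low_fails",  c(29.0, 25.0, 22.0), c(0, 36),  units = "raw",  granularity = 0.5),
      component_spec("FMS_WCST",  "high_fails", c(3, 4, 5),          c(0, 30),  units = "raw",  granularity = 1),
      component_spec("RDS",       "low_fails",  c(7, 6, 5),          c(0, 20),  units = "raw",  granularity = 1),
      component_spec("RH_CVLT",   "low_fails",  c(12, 11, 10),       c(0, 16),  units = "raw",  granularity = 1)
    ),
    pass_max = 1L, borderline_max = 3L, name = "EI-5",
    missing_policy = missing_policy)
}

#' Recode one examinee's raw scores against a battery
#'
#' Applies [recode_score()] component-wise, in battery order.
#'
#' @param raw_scores Named numeric vector or list mapping component name to
#'   raw score. Must cover every battery component (the `missing_policy` of
#'   the battery governs gaps when scoring whole cohorts; here a missing or
#'   unknown name is always an error).
#' @param battery A [battery_config()].
#' @return Named integer vector of levels, length `k`, in battery order.
#' @examples
#' recode_profile(c(CD = 5, RCFT_Copy = 30.5, FMS_WCST = 0, RDS = 8,
#'                  RH_CVLT = 13), ei5_battery())
#' @export
recode_profile <- function(raw_scores, battery) {
  stopifnot(inherits(battery, "battery_config"))
  raw_scores <- unlist(raw_scores)
  nms <- names(battery$components)
  unknown <- setdiff(names(raw_scores), nms)
  if (length(unknown))
    stop("unknown component name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(nms, names(raw_scores))
  if (length(missing))
    stop("missing component score(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- vapply(nms, function(nm)
    recode_score(as.numeric(raw_scores[[nm]]), battery$components[[nm]]),
    integer(1))
  names(out) <- nms
  out
}
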