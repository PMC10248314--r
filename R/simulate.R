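#' Parameters for the synthetic-cohort generator
#'
#' Assembles and validates the knobs of the generative model used to test
#' the scoring and diagnostics pipeline end-to-end: a latent credibility
#' state (non-credible with probability `prevalence`) drives correlated
#' deficits on the embedded indicators via a single shared severity factor,
#' and the free-standing criterion PVTs observe that state imperfectly
#' through per-PVT sensitivity/specificity. The generative model is
#' invented for testability — it emulates the broad statistical shape of a
#' mixed clinical/forensic referral cohort, not any real dataset.
#'
#' @param n Cohort size. Default 452, a typical consecutive-referral series.
#' @param prevalence Probability an examinee is non-credible. Default 0.20,
#'   the middle of the 15--25% range usually cited for mixed
#'   clinical/forensic settings.
#' @param noncredible_shift Mean shift of non-credible examinees toward the
#'   failure direction, in within-group SD units, applied to every
#'   component. Default 1.5 (free-standing PVTs separate groups with
#'   d well above 1).
#' @param sd_multiplier SD inflation of the non-credible group (invalid
#'   performance is reliably more variable). Default 1.5.
#' @param rho Shared-factor correlation of deficit severity across
#'   components, in \[0, 1). Default 0.30.
#' @param component_means,component_sds Named numeric vectors (one entry per
#'   battery component) giving the credible-state location and spread on
#'   each component's native scale. Defaults cover the EI-5 battery.
#' @param criterion Named list of `c(sensitivity, specificity)` pairs, one
#'   per simulated free-standing PVT fail flag.
#' @param tomm1 `c(mean, sd, shift)` for the simulated TOMM-1 trial-1 score
#'   (0--50, lower fails), or `NULL` to omit.
#' @param wmt_subscales `c(mean, sd, shift)` for the simulated WMT
#'   IR/DR/CNS percentages, or `NULL` to omit.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return List of class `"sim_params"`.
#' @export
sim_params <- function(n = 452L, prevalence = 0.20, noncredible_shift = 1.5,
                       sd_multiplier = 1.5, rho = 0.30,
                       component_means = c(CD = 10, RCFT_Copy = 32,
                                           FMS_WCST = 1, RDS = 10, RH_CVLT = 14.5),
                       component_sds = c(CD = 3, RCFT_Copy = 3.5,
                                         FMS_WCST = 1.2, RDS = 2, RH_CVLT = 1.5),
                       criterion = list(wmt = c(0.80, 0.92),
                                        msvt = c(0.75, 0.95),
                                        nvmsvt = c(0.70, 0.95)),
                       tomm1 = c(mean = 48, sd = 2.5, shift = 3.0),
                       wmt_subscales = c(mean = 96, sd = 4, shift = 3.0),
                       seed = 1L) {
  stopifnot(n >= 1, prevalence >= 0, prevalence <= 1,
            noncredible_shift >= 0, sd_multiplier > 0,
            rho >= 0, rho < 1, all(component_sds > 0))
  if (!identical(sort(names(component_means)), sort(names(component_sds))))
    stop("component_means and component_sds must cover the same names",
         call. = FALSE)
  for (cr in criterion)
    if (length(cr) != 2L || any(cr < 0 | cr > 1))
      stop("each criterion entry must be c(sensitivity, specificity) in [0,1]",
           call. = FALSE)
  structure(list(n = as.integer(n), prevalence = prevalence,
                 noncredible_shift = noncredible_shift,
                 sd_multiplier = sd_multiplier, rho = rho,
                 component_means = component_means,
                 component_sds = component_sds,
                 criterion = criterion, tomm1 = tomm1,
                 wmt_subscales = wmt_subscales, seed = as.integer(seed)),
            class = "sim_params")
}

# one shared-factor draw on a component's native scale, shifted toward the
# failure direction for non-credible rows and SD-inflated for them
draw_component <- function(f, noncred, mu, sigma, dir_sign, shift, sd_mult, rho) {
  e <- stats::rnorm(length(f))
  z <- sqrt(rho) * f + sqrt(1 - rho) * e
  z <- z * ifelse(noncred, sd_mult, 1) + shift * noncred
  mu + sigma * dir_sign * z
}

clip_snap <- function(x, spec) {
  x <- pmin(pmax(x, spec$valid_range[1]), spec$valid_range[2])
  snap_to_grid(x, spec)
}

#' Simulate a cohort with a latent credibility state
#'
#' Draws a cohort table matching the schema consumed by [score_cohort()],
#' [g3_label_cohort()], and the diagnostics: raw scores for every battery
#' component (discretized to each component's grid and clipped to its valid
#' range), fail flags for the simulated free-standing criterion PVTs,
#' optional TOMM-1 and WMT subscale scores, the latent truth flag
#' `noncredible`, and referral-source / incentive covariates. The deficit
#' severity of an examinee is one latent Gaussian factor shared across
#' components (correlation `rho`), so validity indicators co-fail the way
#' embedded indicators do in practice.
#'
#' @param params A [sim_params()] object.
#' @param battery The [battery_config()] whose components are simulated;
#'   defaults to [ei5_battery()]. Every battery component must have an
#'   entry in `params$component_means`.
#' @return Data frame with `params$n` rows; deterministic given
#'   `params$seed`.
#' @examples
#' coh <- simulate_cohort(sim_params(n = 100, seed = 7))
#' table(score_cohort(coh, ei5_battery())$ei_band)
#' @export
simulate_cohort <- function(params = sim_params(), battery = ei5_battery()) {
  stopifnot(inherits(params, "sim_params"), inherits(battery, "battery_config"))
  nms <- names(battery$components)
  absent <- setdiff(nms, names(params$component_means))
  if (length(absent))
    stop("no simulation distribution for component(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  n <- params$n
  noncred <- stats::runif(n) < params$prevalence
  f <- stats::rnorm(n)  # shared deficit-severity factor

  out <- data.frame(id = seq_len(n))
  for (nm in nms) {
    spec <- battery$components[[nm]]
    dir_sign <- if (spec$direction == "low_fails") -1 else 1
    x <- draw_component(f, noncred, params$component_means[[nm]],
                        params$component_sds[[nm]], dir_sign,
                        params$noncredible_shift, params$sd_multiplier,
                        params$rho)
    out[[nm]] <- clip_snap(x, spec)
  }

  for (nm in names(params$criterion)) {
    sens <- params$criterion[[nm]][1]; spec <- params$criterion[[nm]][2]
    p_fail <- ifelse(noncred, sens, 1 - spec)
    out[[paste0(nm, "_fail")]] <- stats::runif(n) < p_fail
  }

  if (!is.null(params$tomm1)) {
    t1 <- draw_component(f, noncred, params$tomm1[["mean"]],
                         params$tomm1[["sd"]], -1, params$tomm1[["shift"]],
                         params$sd_multiplier, params$rho)
    out$tomm1 <- as.integer(pmin(50, pmax(0, round(t1))))
  }
  if (!is.null(params$wmt_subscales)) {
    ws <- params$wmt_subscales
    for (sub in c("wmt_ir", "wmt_dr", "wmt_cns")) {
      x <- draw_component(f, noncred, ws[["mean"]], ws[["sd"]], -1,
                          ws[["shift"]], params$sd_multiplier, params$rho)
      out[[sub]] <- round(pmin(100, pmax(0, x)), 1)
    }
  }

  sources <- c("IME", "Clinical", "M-LEG", "W-COM")
  out$referral_source <- sample(sources, n, replace = TRUE,
                                prob = c(0.458, 0.302, 0.095, 0.088))
  out$incentive <- ifelse(out$referral_source == "Clinical",
                          "negative", "positive")
  out$noncredible <- noncred
  out
}

#' Recover the planted signal from a simulated cohort
#'
#' Runs the full pipeline — recode, total, band, diagnostics — on a
#' simulated cohort against its latent truth flag and against the simulated
#' criterion PVTs, summarizing how well the index recovers the planted
#' credibility state.
#'
#' @param cohort A cohort from [simulate_cohort()] (must carry
#'   `noncredible`).
#' @param battery A [battery_config()].
#' @return List: `auc` (index total vs latent truth, [auc_mann_whitney()]),
#'   `fail_cutoff_metrics` (sens/spec/OCC/BR at the battery's Fail
#'   threshold vs truth), `band_prevalence` (planted non-credible
#'   prevalence per band), `range_br` (a [range_br_analysis()] against the
#'   simulated criterion flags), `n`, `band_counts`.
#' @export
recovery_report <- function(cohort, battery = ei5_battery()) {
  if (is.null(cohort$noncredible))
    stop("cohort carries no latent truth flag ('noncredible')", call. = FALSE)
  scored <- score_cohort(cohort, battery)
  truth <- as.logical(scored$noncredible)
  auc <- auc_mann_whitney(scored$ei_total, truth, "at_or_above")
  fail_min <- battery$borderline_max + 1L
  m <- classification_metrics(
    confusion_at_cutoff(scored$ei_total, truth, fail_min, "at_or_above"))
  band_prev <- tapply(truth, scored$ei_band, mean)
  crit_cols <- grep("_fail$", names(scored), value = TRUE)
  crit <- stats::setNames(lapply(crit_cols, function(cn) as.logical(scored[[cn]])),
                          sub("_fail$", "", crit_cols))
  rng <- if (length(crit) && !any(table(scored$ei_band) == 0L))
    range_br_analysis(scored$ei_band, crit) else NULL
  list(auc = auc, fail_cutoff_metrics = m,
       band_prevalence = band_prev, range_br = rng,
       n = nrow(scored),
       band_counts = stats::setNames(as.integer(table(scored$ei_band)),
                                     band_levels))
}
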