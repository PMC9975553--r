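#' Model specification for activity--outcome regressions
#'
#' Describes one of the three model families:
#' \describe{
#'   \item{single}{outcome on one activity plus covariates — the effect of
#'     *adding* that activity, ignoring the rest of the day.}
#'   \item{partition}{outcome on all four activities plus covariates (no
#'     total-time term) — each coefficient is an addition effect holding
#'     the other three activities fixed.}
#'   \item{ism}{outcome on all activities *except one*, plus total
#'     activity time and covariates — each retained coefficient is the
#'     effect of substituting that activity for the dropped one at fixed
#'     total time, and equals the difference of the two partition
#'     coefficients.}
#' }
#' Exposures enter the design divided by `exposure_unit` minutes, so a
#' coefficient is the outcome change per `exposure_unit`-minute
#' reallocation (10 min/day by default, the smallest unit with
#' established health relevance).
#'
#' @param model_kind `"single"`, `"partition"` or `"ism"`.
#' @param dropped_activity for ISM only: the activity removed from the
#'   design (`"sb"`, `"lpa"`, `"mpa"` or `"vpa"`), i.e. the one being
#'   displaced.
#' @param exposure_unit minutes per coefficient unit (> 0).
#' @param covariates character vector of adjustment columns; default
#'   gender, age and resting energy expenditure.
#' @param outcome name of the outcome column (default `delta_cmr_z`, the
#'   change in the composite risk score).
#' @param alpha two-sided type-I level for the confidence intervals
#'   (default 0.05 → 95% CIs).
#' @return object of class `ism_spec`.
#' @export
ism_spec <- function(model_kind = c("partition", "single", "ism"),
                     dropped_activity = NULL, exposure_unit = 10,
                     covariates = c("gender", "age", "ree"),
                     outcome = "delta_cmr_z", alpha = 0.05) {
  model_kind <- match.arg(model_kind)
  if (exposure_unit <= 0) stop("exposure_unit must be > 0", call. = FALSE)
  if (model_kind == "ism") {
    if (is.null(dropped_activity)) {
      stop("ISM requires a dropped_activity", call. = FALSE)
    }
    dropped_activity <- match.arg(tolower(dropped_activity), ACTIVITY_COLS)
  } else if (!is.null(dropped_activity)) {
    stop("dropped_activity is only meaningful for model_kind = 'ism'",
         call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1)
  structure(list(model_kind = model_kind, dropped_activity = dropped_activity,
                 exposure_unit = exposure_unit, covariates = covariates,
                 outcome = outcome, alpha = alpha),
            class = "ism_spec")
}

# shared design assembly + lm fit + tidy coefficient extraction
fit_ols <- function(data, exposure_cols, spec, model_kind, dropped = NULL) {
  need <- c(spec$outcome, exposure_cols, spec$covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- data[, need, drop = FALSE]
  if (anyNA(df)) stop("missing values in model columns", call. = FALSE)
  for (a in intersect(exposure_cols, c(ACTIVITY_COLS, "tpa"))) {
    df[[a]] <- df[[a]] / spec$exposure_unit
  }
  fml <- stats::as.formula(paste(
    spec$outcome, "~",
    paste(c(exposure_cols, spec$covariates), collapse = " + ")))
  fit <- lm(fml, data = df)

  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; aliased columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X <- model.matrix(fit)
  kp <- kappa(X, exact = TRUE)
  if (kp > 1e8) {
    warning(sprintf("near-collinear design (condition number %.3g)", kp),
            call. = FALSE)
  }
  # summary.lm warns "essentially perfect fit" at zero residual variance;
  # we replace that with a single targeted warning below
  quiet_perfect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  s <- quiet_perfect(summary(fit))
  if (s$sigma < 1e-10) {
    warning("residual variance ~ 0; p-values are degenerate (reported as 0)",
            call. = FALSE)
  }
  ci <- quiet_perfect(confint(fit, level = 1 - spec$alpha))
  tab <- data.frame(
    term = rownames(s$coefficients),
    beta = s$coefficients[, "Estimate"],
    se = s$coefficients[, "Std. Error"],
    ci_low = ci[, 1], ci_high = ci[, 2],
    p_value = s$coefficients[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(model_kind = model_kind, dropped_activity = dropped,
                 spec = spec, coefficients = tab, lm_fit = fit,
                 n = nrow(df)),
            class = "ism_fit")
}

#' @export
print.ism_fit <- function(x, digits = 3, ...) {
  label <- switch(x$model_kind, single = "Single model",
                  partition = "Partition model",
                  ism = sprintf("Isotemporal substitution model (dropped: %s)",
                                toupper(x$dropped_activity)))
  cat(label, sprintf(" [n = %d, per %g min]\n", x$n, x$spec$exposure_unit))
  tab <- x$coefficients
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Extract activity-term effects from a fitted model
#'
#' @param fit an `ism_fit`.
#' @return the coefficient rows for the activity exposures only.
#' @export
activity_effects <- function(fit) {
  stopifnot(inherits(fit, "ism_fit"))
  fit$coefficients[fit$coefficients$term %in% ACTIVITY_COLS, , drop = FALSE]
}

#' Single model: one activity plus covariates
#'
#' OLS of the outcome on one activity exposure (per `exposure_unit`
#' minutes) and the covariates, with classical t-based confidence
#' intervals.
#'
#' @param data analysis table: one row per participant with the outcome,
#'   activity minutes and covariates (see [analysis_table()]).
#' @param activity which activity to enter (`"sb"`, `"lpa"`, `"mpa"`,
#'   `"vpa"`).
#' @param spec an [ism_spec()]; its `model_kind` is overridden to
#'   `"single"`.
#' @return an `ism_fit`.
#' @export
fit_single <- function(data, activity, spec = ism_spec("single")) {
  activity <- match.arg(tolower(activity), ACTIVITY_COLS)
  stopifnot(inherits(spec, "ism_spec"))
  if (any(data[[activity]] < 0)) {
    stop("activity minutes must be non-negative", call. = FALSE)
  }
  fit_ols(data, activity, spec, "single")
}

#' Partition model: all four activities plus covariates
#'
#' OLS on SB, LPA, MPA and VPA simultaneously (no total-time column);
#' each coefficient is the effect of adding `exposure_unit` minutes of
#' that activity while the other three are held fixed (total time grows).
#'
#' @inheritParams fit_single
#' @return an `ism_fit`.
#' @export
fit_partition <- function(data, spec = ism_spec("partition")) {
  stopifnot(inherits(spec, "ism_spec"))
  if ("tpa" %in% c(spec$covariates)) {
    stop("the partition model must not include total activity time",
         call. = FALSE)
  }
  fit_ols(data, ACTIVITY_COLS, spec, "partition")
}

#' Isotemporal substitution model
#'
#' OLS of the outcome on the three retained activities plus total
#' activity time (TPA) and covariates, all per `exposure_unit` minutes.
#' Holding TPA fixed, increasing a retained activity necessarily
#' displaces the dropped one, so the coefficient of retained activity k
#' is the effect of substituting `exposure_unit` minutes of k for the
#' dropped activity. Algebraically it equals the difference of partition
#' coefficients, beta_k − beta_dropped (same column space); the test
#' suite asserts this identity to 1e-8.
#'
#' TPA is recomputed internally as the exact sum of the four activity
#' columns; if the input carries a `tpa` column that disagrees beyond
#' 1e-9 the fit is refused, because the substitution reading of the
#' coefficients depends on that exact linear dependence.
#'
#' @inheritParams fit_single
#' @param spec an [ism_spec()] with `model_kind = "ism"` and a
#'   `dropped_activity`.
#' @return an `ism_fit`.
#' @export
fit_ism <- function(data, spec) {
  stopifnot(inherits(spec, "ism_spec"))
  if (spec$model_kind != "ism" || is.null(spec$dropped_activity)) {
    stop("spec must have model_kind = 'ism' and a dropped_activity",
         call. = FALSE)
  }
  miss <- setdiff(ACTIVITY_COLS, names(data))
  if (length(miss)) {
    stop("data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tpa_exact <- data$sb + data$lpa + data$mpa + data$vpa
  if ("tpa" %in% names(data) &&
      max(abs(data$tpa - tpa_exact)) > 1e-9) {
    stop("tpa column is not the exact sum of sb+lpa+mpa+vpa; ",
         "the substitution interpretation requires exact closure",
         call. = FALSE)
  }
  data$tpa <- tpa_exact
  retained <- setdiff(ACTIVITY_COLS, spec$dropped_activity)
  fit_ols(data, c(retained, "tpa"), spec, "ism", spec$dropped_activity)
}

#' Full pairwise substitution-effect matrix
#'
#' Fits the ISM once per choice of dropped activity and collects every
#' ordered (replaced, replacing) pair as a `SubstitutionEffect` row. The
#' matrix is antisymmetric: effect(j replaced by k) = −effect(k replaced
#' by j), to numerical precision.
#'
#' @inheritParams fit_single
#' @param spec an [ism_spec()]; `model_kind`/`dropped_activity` are
#'   managed internally.
#' @return data.frame of class `substitution_effects`: `replaced`,
#'   `replacing`, `duration` (minutes), `beta`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @export
substitution_matrix <- function(data, spec = ism_spec("partition")) {
  stopifnot(inherits(spec, "ism_spec"))
  rows <- lapply(ACTIVITY_COLS, function(j) {
    sp <- ism_spec("ism", dropped_activity = j,
                   exposure_unit = spec$exposure_unit,
                   covariates = spec$covariates, outcome = spec$outcome,
                   alpha = spec$alpha)
    eff <- activity_effects(fit_ism(data, sp))
    data.frame(replaced = toupper(j), replacing = toupper(eff$term),
               duration = spec$exposure_unit, beta = eff$beta,
               ci_low = eff$ci_low, ci_high = eff$ci_high,
               p_value = eff$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("substitution_effects", "data.frame")
  out
}

#' Rescale substitution effects to another duration
#'
#' A substitution effect is a linear contrast of regression coefficients,
#' so substituting `d` minutes instead of the fitted `duration` scales
#' the point estimate and both CI limits by `d / duration`; the p-value
#' (and the CI's coverage) is unchanged by a positive linear rescaling.
#'
#' @param effect a `substitution_effects` data.frame (or any data.frame
#'   with `duration`, `beta`, `ci_low`, `ci_high` columns).
#' @param duration target substitution duration in minutes (> 0).
#' @return the rescaled effects, `duration` updated.
#' @examples
#' eff <- data.frame(replaced = "SB", replacing = "VPA", duration = 10,
#'                   beta = -0.39, ci_low = -0.66, ci_high = -0.12,
#'                   p_value = 0.01)
#' scale_effect(eff, 60)$beta  # -2.34
#' @export
scale_effect <- function(effect, duration) {
  stopifnot(is.data.frame(effect),
            all(c("duration", "beta", "ci_low", "ci_high") %in% names(effect)))
  if (length(duration) != 1 || !is.finite(duration) || duration <= 0) {
    stop("duration must be a single positive number of minutes",
         call. = FALSE)
  }
  k <- duration / effect$duration
  effect$beta <- effect$beta * k
  effect$ci_low <- effect$ci_low * k
  effect$ci_high <- effect$ci_high * k
  effect$duration <- duration
  effect
}

#' Assemble a three-model summary table
#'
#' Stacks the single-model row (one fit per activity), the partition row
#' and the ISM block (one row per dropped activity) into one long table,
#' the shape of the usual published model-comparison table.
#'
#' @inheritParams fit_single
#' @param spec an [ism_spec()] supplying unit, covariates, outcome, alpha.
#' @return data.frame: `model` (`SM`/`PM`/`ISM`), `replaced` (ISM rows
#'   only), `activity`, `beta`, `ci_low`, `ci_high`, `p_value`.
#' @export
model_table <- function(data, spec = ism_spec("partition")) {
  sm <- do.call(rbind, lapply(ACTIVITY_COLS, function(a) {
    sp <- ism_spec("single", exposure_unit = spec$exposure_unit,
                   covariates = spec$covariates, outcome = spec$outcome,
                   alpha = spec$alpha)
    eff <- activity_effects(fit_single(data, a, sp))
    data.frame(model = "SM", replaced = NA_character_,
               activity = toupper(a), beta = eff$beta, ci_low = eff$ci_low,
               ci_high = eff$ci_high, p_value = eff$p_value)
  }))
  pm_fit <- fit_partition(data, ism_spec("partition",
                                         exposure_unit = spec$exposure_unit,
                                         covariates = spec$covariates,
                                         outcome = spec$outcome,
                                         alpha = spec$alpha))
  pm_eff <- activity_effects(pm_fit)
  pm <- data.frame(model = "PM", replaced = NA_character_,
                   activity = toupper(pm_eff$term), beta = pm_eff$beta,
                   ci_low = pm_eff$ci_low, ci_high = pm_eff$ci_high,
                   p_value = pm_eff$p_value)
  sub <- substitution_matrix(data, spec)
  ism <- data.frame(model = "ISM", replaced = sub$replaced,
                    activity = sub$replacing, beta = sub$beta,
                    ci_low = sub$ci_low, ci_high = sub$ci_high,
                    p_value = sub$p_value)
  out <- rbind(sm, pm, ism)
  rownames(out) <- NULL
  out
}
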