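#' Configuration for the synthetic cohort generator
#'
#' Bundles every distributional assumption of the simulated study world:
#' cohort size and demographics, the marginal activity-minute
#' distributions, the baseline cardiometabolic panel, and the planted
#' linear model tying the change in cardiometabolic risk score (CMR-z,
#' post minus pre) to per-10-minute activity exposures and covariates.
#' Defaults emulate a 4-week summer-camp cohort of 196 obese children and
#' adolescents wearing a waist accelerometer 09:00--21:00.
#'
#' @param n_participants cohort size.
#' @param prop_male proportion of boys.
#' @param age_mean_sd mean and SD of age in years.
#' @param height_mean_sd,weight_mean_sd anthropometrics, cm and kg.
#' @param ree_male_mean_sd,ree_female_mean_sd resting energy expenditure
#'   (kcal/day) by gender; REE is a model covariate, so its gender gap is
#'   kept.
#' @param activity_mean_sd named list `sb`, `lpa`, `mpa`, `vpa`, each a
#'   `c(mean, sd)` of daily minutes.
#' @param tpa_mean_sd mean and SD of total daily monitored activity
#'   minutes; each participant's category minutes are closed to a draw
#'   from this distribution (capped at `total_wear_minutes`).
#' @param total_wear_minutes length of the daily wear window (720 min,
#'   09:00--21:00); hard upper bound on a participant's activity total.
#' @param panel_mean_sd data.frame of baseline panel distributions with
#'   columns `variable`, `mean`, `sd` (see [default_panel_stats()]).
#' @param panel_change_mean_sd data.frame of mean and SD of
#'   post-minus-pre changes per panel variable
#'   (see [default_panel_changes()]).
#' @param true_partition_coefs named numeric, the planted partition-model
#'   coefficients: change in CMR-z per additional 10 min/day of each
#'   activity, other activities held fixed.
#' @param covariate_coefs named numeric `c(age=, gender=, ree=)`: planted
#'   covariate effects on the CMR-z change (per year, for boys vs girls,
#'   and per kcal/day).
#' @param delta_cmr_mean planted mean CMR-z change at the configured
#'   covariate and activity means.
#' @param noise_sd residual SD of the CMR-z change.
#' @param seed integer RNG seed; the generated cohort is a deterministic
#'   function of the config (seed included).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 196,
                          prop_male = 106 / 196,
                          age_mean_sd = c(13.44, 1.71),
                          height_mean_sd = c(163.56, 8.66),
                          weight_mean_sd = c(81.97, 15.16),
                          ree_male_mean_sd = c(1864.50, 232.36),
                          ree_female_mean_sd = c(1632.67, 197.41),
                          activity_mean_sd = list(sb = c(274, 53),
                                                  lpa = c(241, 46),
                                                  mpa = c(38, 14),
                                                  vpa = c(35, 16)),
                          tpa_mean_sd = c(588, 67),
                          total_wear_minutes = 720,
                          panel_mean_sd = default_panel_stats(),
                          panel_change_mean_sd = default_panel_changes(),
                          true_partition_coefs = c(sb = 0.05, lpa = -0.05,
                                                   mpa = -0.27, vpa = -0.34),
                          covariate_coefs = c(age = 0.02, gender = -0.10,
                                              ree = 1e-4),
                          delta_cmr_mean = -2.78,
                          noise_sd = 2.2,
                          seed = 20230215L) {
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop("n_participants must be a positive count", call. = FALSE)
  }
  if (prop_male < 0 || prop_male > 1) {
    stop("prop_male must be in [0, 1]", call. = FALSE)
  }
  stopifnot(identical(sort(names(activity_mean_sd)), sort(ACTIVITY_COLS)))
  sds <- c(age_mean_sd[2], height_mean_sd[2], weight_mean_sd[2],
           ree_male_mean_sd[2], ree_female_mean_sd[2], tpa_mean_sd[2],
           vapply(activity_mean_sd, `[`, numeric(1), 2),
           panel_mean_sd$sd, panel_change_mean_sd$sd)
  if (any(sds <= 0)) stop("all SDs must be > 0", call. = FALSE)
  stopifnot(all(ACTIVITY_COLS %in% names(true_partition_coefs)),
            all(c("age", "gender", "ree") %in% names(covariate_coefs)),
            noise_sd >= 0, total_wear_minutes > 0,
            tpa_mean_sd[1] <= total_wear_minutes)
  structure(list(
    n_participants = as.integer(n_participants), prop_male = prop_male,
    age_mean_sd = age_mean_sd, height_mean_sd = height_mean_sd,
    weight_mean_sd = weight_mean_sd, ree_male_mean_sd = ree_male_mean_sd,
    ree_female_mean_sd = ree_female_mean_sd,
    activity_mean_sd = activity_mean_sd, tpa_mean_sd = tpa_mean_sd,
    total_wear_minutes = total_wear_minutes,
    panel_mean_sd = panel_mean_sd,
    panel_change_mean_sd = panel_change_mean_sd,
    true_partition_coefs = true_partition_coefs[ACTIVITY_COLS],
    covariate_coefs = covariate_coefs,
    delta_cmr_mean = delta_cmr_mean, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Baseline cardiometabolic panel distributions
#'
#' Mean and SD at baseline for each panel variable: fasting insulin
#' (mIU/L), fasting plasma glucose (mmol/L), waist circumference (cm),
#' total cholesterol (mmol/L), HDL cholesterol (mmol/L), systolic and
#' diastolic blood pressure (mmHg), plus descriptive-only variables
#' (triglycerides, body weight, BMI, hip circumference).
#'
#' @return data.frame with columns `variable`, `mean`, `sd`.
#' @export
default_panel_stats <- function() {
  data.frame(
    variable = c("fins", "fpg", "wc", "tc", "hdl", "sbp", "dbp",
                 "tg", "weight", "bmi", "hc"),
    mean = c(13.67, 4.74, 99.50, 4.71, 1.15, 113.27, 68.75,
             1.24, 81.97, 30.52, 107.25),
    sd = c(8.68, 0.79, 12.00, 1.02, 0.24, 10.53, 8.74,
           0.58, 15.52, 4.22, 9.43),
    stringsAsFactors = FALSE
  )
}

#' Post-minus-pre change distributions for the panel
#'
#' Mean and SD of the 4-week change (post minus pre) per panel variable,
#' used to construct post-intervention panels consistent with the planted
#' CMR-z change.
#'
#' @return data.frame with columns `variable`, `mean`, `sd`.
#' @export
default_panel_changes <- function() {
  data.frame(
    variable = c("fins", "fpg", "wc", "tc", "hdl", "sbp", "dbp",
                 "tg", "weight", "bmi", "hc"),
    mean = c(-3.01, -0.07, -7.93, -0.97, -0.01, -7.62, -5.71,
             -0.45, -7.49, -2.81, -6.06),
    sd = c(7.58, 0.92, 4.40, 0.72, 0.23, 9.45, 8.67,
           0.50, 2.97, 1.15, 2.99),
    stringsAsFactors = FALSE
  )
}

# exact truncated-normal draws by rejection (cheap at these scales)
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

# round non-negative values to integers preserving their (integer) sum
round_preserve_sum <- function(x, target) {
  f <- floor(x)
  short <- as.integer(round(target)) - sum(f)
  if (short > 0) {
    top_up <- order(x - f, decreasing = TRUE)[seq_len(short)]
    f[top_up] <- f[top_up] + 1
  }
  as.integer(f)
}

#' Generate a synthetic cohort
#'
#' Draws participants (demographics, daily activity minutes, pre/post
#' cardiometabolic panels) with a planted linear effect of activity
#' composition on the change in CMR-z. Category minutes come from
#' truncated-normal marginals and are proportionally rescaled (then
#' integer-rounded, preserving the sum) so that SB + LPA + MPA + VPA
#' equals the participant's total monitored minutes exactly.
#'
#' The planted outcome is
#' `delta_cmr_z = intercept + sum(beta_a * minutes_a / 10) + covariate
#' effects + N(0, noise_sd)`, with the intercept chosen so the expected
#' change at the configured means equals `delta_cmr_mean`. Post panels are
#' built from pre panels by distributing each participant's CMR-z change
#' across the six score components proportionally to the configured mean
#' change magnitudes (so the panel-derived score change tracks, but does
#' not exactly equal, the planted one).
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: list with `participants`
#'   (one row per participant: id, gender (0 = girl, 1 = boy), age,
#'   height, weight, ree, sb/lpa/mpa/vpa/tpa daily minutes, planted
#'   delta_cmr_z), `panels` (long pre/post panel table) and the `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_participants = 20, seed = 1))
#' head(coh$participants)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants

  gender <- rbinom(n, 1, config$prop_male)  # 1 = boy, 0 = girl
  age <- rtrunc_norm(n, config$age_mean_sd[1], config$age_mean_sd[2],
                     lower = 6, upper = 19)
  height <- rtrunc_norm(n, config$height_mean_sd[1], config$height_mean_sd[2],
                        lower = 100)
  weight <- rtrunc_norm(n, config$weight_mean_sd[1], config$weight_mean_sd[2],
                        lower = 25)
  ree <- ifelse(gender == 1,
                rtrunc_norm(n, config$ree_male_mean_sd[1],
                            config$ree_male_mean_sd[2], lower = 500),
                rtrunc_norm(n, config$ree_female_mean_sd[1],
                            config$ree_female_mean_sd[2], lower = 500))

  # activity composition: truncated-normal marginals closed to a
  # participant-specific total, integer minutes
  raw <- matrix(unlist(lapply(ACTIVITY_COLS, function(a) {
    ms <- config$activity_mean_sd[[a]]
    rtrunc_norm(n, ms[1], ms[2], lower = 0)
  })), nrow = n, dimnames = list(NULL, ACTIVITY_COLS))
  tpa_target <- rtrunc_norm(n, config$tpa_mean_sd[1], config$tpa_mean_sd[2],
                            lower = 4, upper = config$total_wear_minutes)
  tpa_target <- round(tpa_target)
  scaled <- raw * tpa_target / rowSums(raw)
  minutes <- t(vapply(seq_len(n),
                      function(i) round_preserve_sum(scaled[i, ], tpa_target[i]),
                      integer(4)))
  colnames(minutes) <- ACTIVITY_COLS

  # planted outcome
  beta <- config$true_partition_coefs
  cov_beta <- config$covariate_coefs
  act_means <- vapply(config$activity_mean_sd, `[`, numeric(1), 1)
  ree_mean <- config$prop_male * config$ree_male_mean_sd[1] +
    (1 - config$prop_male) * config$ree_female_mean_sd[1]
  intercept <- config$delta_cmr_mean -
    sum(beta * act_means[ACTIVITY_COLS] / 10) -
    cov_beta["age"] * config$age_mean_sd[1] -
    cov_beta["gender"] * config$prop_male -
    cov_beta["ree"] * ree_mean
  delta_cmr_z <- as.numeric(
    intercept + minutes %*% (beta / 10) +
      cov_beta["age"] * age + cov_beta["gender"] * gender +
      cov_beta["ree"] * ree +
      rnorm(n, 0, config$noise_sd)
  )

  participants <- data.frame(
    id = sprintf("P%04d", seq_len(n)), gender = gender, age = age,
    height = height, weight = weight, ree = ree,
    sb = minutes[, "sb"], lpa = minutes[, "lpa"],
    mpa = minutes[, "mpa"], vpa = minutes[, "vpa"],
    stringsAsFactors = FALSE
  )
  participants$tpa <- with(participants, sb + lpa + mpa + vpa)
  participants$delta_cmr_z <- delta_cmr_z

  panels <- build_synthetic_panels(participants, config)
  structure(list(participants = participants, panels = panels,
                 config = config),
            class = "synthetic_cohort")
}

# pre panel from baseline marginals; post panel = pre + mean change +
# participant's CMR-z deviation spread over the six score components in
# proportion to the z-unit magnitude of the configured mean changes, plus
# small component-level noise
build_synthetic_panels <- function(participants, config) {
  n <- nrow(participants)
  ps <- config$panel_mean_sd
  chg <- config$panel_change_mean_sd
  stats_of <- function(tbl, v) unlist(tbl[tbl$variable == v, c("mean", "sd")])

  pre <- list(participant_id = participants$id, occasion = "pre")
  for (v in ps$variable) {
    s <- stats_of(ps, v)
    pre[[v]] <- rtrunc_norm(n, s["mean"], s["sd"], lower = s["mean"] / 10)
  }
  # keep pulse pressure physiological
  narrow <- which(pre$sbp - pre$dbp < 10)
  while (length(narrow)) {
    s1 <- stats_of(ps, "sbp"); s2 <- stats_of(ps, "dbp")
    pre$sbp[narrow] <- rtrunc_norm(length(narrow), s1["mean"], s1["sd"],
                                   lower = s1["mean"] / 10)
    pre$dbp[narrow] <- rtrunc_norm(length(narrow), s2["mean"], s2["sd"],
                                   lower = s2["mean"] / 10)
    narrow <- narrow[pre$sbp[narrow] - pre$dbp[narrow] < 10]
  }
  pre <- as.data.frame(pre, stringsAsFactors = FALSE)

  # six CMR-z components; MAP change is split between SBP and DBP in
  # proportion to their configured mean changes
  comp <- c("fins", "fpg", "wc", "tc", "hdl", "map")
  comp_sign <- c(fins = 1, fpg = 1, wc = 1, tc = 1, hdl = -1, map = 1)
  map_chg <- mean(c(stats_of(chg, "sbp")["mean"], stats_of(chg, "dbp")["mean"]))
  map_sd <- sqrt(mean(c(stats_of(ps, "sbp")["sd"], stats_of(ps, "dbp")["sd"])^2))
  comp_mean_chg <- c(vapply(comp[1:5], function(v) stats_of(chg, v)[["mean"]],
                            numeric(1)), map = map_chg)
  comp_pre_sd <- c(vapply(comp[1:5], function(v) stats_of(ps, v)[["sd"]],
                          numeric(1)), map = map_sd)
  w <- abs(comp_mean_chg / comp_pre_sd)
  w <- w / sum(w)

  dev <- participants$delta_cmr_z - mean(participants$delta_cmr_z)
  post <- pre
  post$occasion <- "post"
  for (i in seq_along(comp)) {
    v <- comp[i]
    delta_v <- comp_mean_chg[i] +
      comp_sign[v] * dev * w[i] * comp_pre_sd[i] +
      rnorm(n, 0, 0.3 * comp_pre_sd[i] * w[i])
    if (v == "map") {
      sbp_share <- stats_of(chg, "sbp")["mean"] /
        (stats_of(chg, "sbp")["mean"] + stats_of(chg, "dbp")["mean"])
      post$sbp <- pre$sbp + 2 * delta_v * sbp_share
      post$dbp <- pre$dbp + 2 * delta_v * (1 - sbp_share)
    } else {
      post[[v]] <- pre[[v]] + delta_v
    }
  }
  for (v in c("tg", "weight", "bmi", "hc")) {
    s <- stats_of(chg, v)
    post[[v]] <- pre[[v]] + rnorm(n, s["mean"], s["sd"])
  }
  # floor at small positive values; keep sbp > dbp
  for (v in ps$variable) post[[v]] <- pmax(post[[v]], 0.05)
  bad <- which(post$sbp <= post$dbp + 5)
  post$dbp[bad] <- post$sbp[bad] - 5

  rbind(pre, post)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$participants
  cat(sprintf("Synthetic cohort: %d participants (%d boys, %d girls)\n",
              nrow(p), sum(p$gender == 1), sum(p$gender == 0)))
  cat(sprintf("  mean daily minutes: SB %.0f, LPA %.0f, MPA %.0f, VPA %.0f (TPA %.0f)\n",
              mean(p$sb), mean(p$lpa), mean(p$mpa), mean(p$vpa), mean(p$tpa)))
  cat(sprintf("  planted mean CMR-z change: %.2f\n", mean(p$delta_cmr_z)))
  invisible(x)
}

#' Analysis table of a synthetic cohort
#'
#' One row per participant with the regression outcome, the four activity
#' exposures (mean daily minutes) and the covariates — the shape consumed
#' by [fit_single()], [fit_partition()] and [fit_ism()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param outcome_source `"planted"` uses the generator's exact CMR-z
#'   change; `"panel"` recomputes it from the pre/post panels via
#'   [build_cmr_z()] with pooled standardization (the route real data
#'   would take).
#' @return data.frame with columns `id`, `delta_cmr_z`, `sb`, `lpa`,
#'   `mpa`, `vpa`, `gender`, `age`, `ree`.
#' @export
analysis_table <- function(cohort, outcome_source = c("planted", "panel")) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  outcome_source <- match.arg(outcome_source)
  at <- cohort$participants[, c("id", "delta_cmr_z", ACTIVITY_COLS,
                                "gender", "age", "ree")]
  if (outcome_source == "panel") {
    z <- build_cmr_z(cohort$panels, standardization = "pooled")
    pre <- z[z$occasion == "pre", c("participant_id", "cmr_z")]
    post <- z[z$occasion == "post", c("participant_id", "cmr_z")]
    m <- merge(pre, post, by = "participant_id", suffixes = c("_pre", "_post"))
    at$delta_cmr_z <- m$cmr_z_post[match(at$id, m$participant_id)] -
      m$cmr_z_pre[match(at$id, m$participant_id)]
  }
  at
}

#' Generate a 60-s epoch count stream for one participant
#'
#' Emits one epoch per minute of the participant's day, as contiguous
#' blocks of SB, then LPA, MPA, VPA (the substitution models consume only
#' daily totals, so bout structure is deliberately simple). Axis counts
#' are drawn so that each epoch's vector magnitude lies inside its band:
#' classifying the stream with the same cut points recovers the planted
#' daily minutes exactly.
#'
#' @param participant one-row data.frame (or list) with `id` and daily
#'   minutes `sb`, `lpa`, `mpa`, `vpa`.
#' @param seed integer seed for the stream.
#' @param cut_points a [cut_points()] object.
#' @param date day of the stream (used for the first day).
#' @param n_days number of identical-composition days to emit.
#' @param start_hour wear-window start (09:00 by default).
#' @param total_wear_minutes wear-window length; the participant's minutes
#'   must not exceed it.
#' @return data.frame with columns `id`, `timestamp`, `axis1`, `axis2`,
#'   `axis3`, one row per 60-s epoch.
#' @export
generate_epoch_stream <- function(participant, seed,
                                  cut_points = isotempo::cut_points(),
                                  date = as.Date("2021-07-01"), n_days = 1,
                                  start_hour = 9, total_wear_minutes = 720) {
  mins <- vapply(ACTIVITY_COLS, function(a) as.numeric(participant[[a]]),
                 numeric(1))
  if (anyNA(mins) || any(mins < 0) || any(mins != round(mins))) {
    stop("participant daily minutes must be non-negative integers",
         call. = FALSE)
  }
  if (sum(mins) > total_wear_minutes) {
    stop("daily minutes exceed the wear window (",
         sum(mins), " > ", total_wear_minutes, ")", call. = FALSE)
  }
  set.seed(seed)
  lo <- c(0, cut_points$sb_max + 1, cut_points$lpa_max + 1,
          cut_points$mpa_max + 1)
  hi <- c(cut_points$sb_max, cut_points$lpa_max, cut_points$mpa_max,
          cut_points$mpa_max + 2500)  # open VPA band: bounded draw range

  one_day <- function(day_date) {
    band_idx <- rep(seq_along(ACTIVITIES), times = mins)
    m <- length(band_idx)
    if (m == 0) return(NULL)
    target <- runif(m, lo[band_idx] + 0.5, hi[band_idx] - 0.5)
    u <- matrix(abs(rnorm(3 * m)), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    axes <- round(u * target)
    vm <- sqrt(rowSums(axes^2))
    ok <- as.integer(classify_intensity(vm, cut_points)) == band_idx
    if (any(!ok)) {
      # fallback: put an exactly in-band integer on one axis
      idx <- which(!ok)
      axes[idx, 1] <- floor(runif(length(idx), lo[band_idx[idx]],
                                  hi[band_idx[idx]] + 1))
      axes[idx, 2] <- 0
      axes[idx, 3] <- 0
    }
    ts <- as.POSIXct(paste(day_date, sprintf("%02d:00:00", start_hour)),
                     tz = "UTC") + 60 * (seq_len(m) - 1)
    data.frame(id = participant$id, timestamp = ts,
               axis1 = as.integer(axes[, 1]), axis2 = as.integer(axes[, 2]),
               axis3 = as.integer(axes[, 3]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(n_days) - 1,
                               function(d) one_day(date + d)))
  if (is.null(out)) {
    out <- data.frame(id = character(), timestamp = as.POSIXct(character()),
                      axis1 = integer(), axis2 = integer(), axis3 = integer())
  }
  out
}

#' Write cohort tables to CSV
#'
#' Writes `participants.csv`, `panels.csv` and the config (as JSON) to a
#' directory.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    participants = file.path(dir, "participants.csv"),
    panels = file.path(dir, "panels.csv"),
    config = file.path(dir, "cohort_config.json")
  )
  write.csv(cohort$participants, paths["participants"], row.names = FALSE)
  write.csv(cohort$panels, paths["panels"], row.names = FALSE)
  jsonlite::write_json(unclass(cohort$config), paths["config"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
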