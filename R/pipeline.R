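#' Minimum sample size for a multiple regression
#'
#' Rule-of-thumb floor for regression sample size: `n > 50 + 8 m`, with
#' `m` the number of independent variables (Tabachnick & Fidell). With
#' the seven predictors of the full substitution analysis the floor is
#' 106.
#'
#' @param n_predictors number of independent variables, >= 1.
#' @return the required minimum sample size `50 + 8 * n_predictors`.
#' @examples
#' minimum_sample_size(7)  # 106
#' @export
minimum_sample_size <- function(n_predictors) {
  if (length(n_predictors) != 1 || !is.finite(n_predictors) ||
      n_predictors < 1 || n_predictors != round(n_predictors)) {
    stop("n_predictors must be a positive integer", call. = FALSE)
  }
  50 + 8 * n_predictors
}

#' Pipeline configuration
#'
#' Options for the end-to-end run: simulate a cohort, emit and classify
#' epoch streams, score the panels, fit the three model families, and
#' write report tables. All randomness flows from the single `seed`
#' (split deterministically per stage).
#'
#' @param out_dir output directory for report CSVs and the manifest.
#' @param cohort a [cohort_config()]; its own seed is overridden by
#'   `seed`.
#' @param cut_points a [cut_points()] object.
#' @param standardization passed to [build_cmr_z()].
#' @param durations substitution durations (minutes) for the scaled
#'   effects table.
#' @param exposure_unit,covariates,alpha model options, see [ism_spec()].
#' @param outcome_source `"panel"` (score the simulated panels, the
#'   real-data route) or `"planted"` (the generator's exact outcome).
#' @param seed root RNG seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            cohort = cohort_config(),
                            cut_points = isotempo::cut_points(),
                            standardization = "pooled",
                            durations = c(10, 20, 30, 40, 50, 60),
                            exposure_unit = 10,
                            covariates = c("gender", "age", "ree"),
                            alpha = 0.05,
                            outcome_source = c("panel", "planted"),
                            seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(cut_points, "cut_points"))
  if (any(durations <= 0) || any(durations != round(durations))) {
    stop("durations must be positive whole minutes", call. = FALSE)
  }
  structure(list(out_dir = out_dir, cohort = cohort,
                 cut_points = cut_points,
                 standardization = standardization, durations = durations,
                 exposure_unit = exposure_unit, covariates = covariates,
                 alpha = alpha, outcome_source = match.arg(outcome_source),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(root, stage) {
  # deterministic per-stage split, kept within 32-bit integer range
  (root * 7919L + stage * 104729L) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' simulate → classify → score → fit → report. Writes tidy CSVs in the
#' shape of the usual study tables (baseline descriptives, activity by
#' gender, pre/post changes, change--activity correlations, the
#' SM/PM/ISM model table), a long substitution-by-duration table, and a
#' JSON run manifest (config hash, package version, row counts). Two
#' runs with the same config and seed produce byte-identical numeric
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  res <- tryCatch({
    # -- simulate -----------------------------------------------------
    ccfg <- config$cohort
    ccfg$seed <- stage_seed(config$seed, 1L)
    cohort <- generate_cohort(ccfg)
    write_cohort_csv(cohort, config$out_dir)

    # -- classify -----------------------------------------------------
    stage <- "classify"
    streams <- do.call(rbind, lapply(seq_len(nrow(cohort$participants)),
      function(i) {
        generate_epoch_stream(cohort$participants[i, ],
                              seed = stage_seed(config$seed, 2L) + i,
                              cut_points = config$cut_points)
      }))
    summaries <- summarize_days(streams, cut_points = config$cut_points,
                                min_valid_days = 1)
    means <- summaries$participant_means

    # -- score --------------------------------------------------------
    stage <- "score"
    desc <- describe_changes(cohort$panels,
                             standardization = config$standardization)
    z <- build_cmr_z(cohort$panels, standardization = config$standardization)
    pre <- cohort$panels[cohort$panels$occasion == "pre", ]
    post <- cohort$panels[cohort$panels$occasion == "post", ]
    post <- post[match(pre$participant_id, post$participant_id), ]
    zd <- z[z$occasion == "post", "cmr_z"][
      match(pre$participant_id,
            z$participant_id[z$occasion == "post"])] -
      z[z$occasion == "pre", "cmr_z"][
        match(pre$participant_id, z$participant_id[z$occasion == "pre"])]
    deltas <- data.frame(
      participant_id = pre$participant_id,
      d_fins = post$fins - pre$fins, d_fpg = post$fpg - pre$fpg,
      d_map = mean_arterial_pressure(post$sbp, post$dbp) -
        mean_arterial_pressure(pre$sbp, pre$dbp),
      d_tc = post$tc - pre$tc, d_wc = post$wc - pre$wc,
      d_hdl = post$hdl - pre$hdl, d_cmr_z = zd,
      stringsAsFactors = FALSE
    )
    act <- means
    names(act)[names(act) == "participant_id"] <- "participant_id"
    cors <- correlation_table(deltas, act)

    # -- fit ----------------------------------------------------------
    stage <- "fit"
    at <- cohort$participants[, c("id", ACTIVITY_COLS, "gender", "age", "ree")]
    at$delta_cmr_z <- if (config$outcome_source == "panel") {
      deltas$d_cmr_z[match(at$id, deltas$participant_id)]
    } else cohort$participants$delta_cmr_z
    spec <- ism_spec("partition", exposure_unit = config$exposure_unit,
                     covariates = config$covariates, alpha = config$alpha)
    models <- model_table(at, spec)
    sub <- substitution_matrix(at, spec)
    scaled <- do.call(rbind, lapply(config$durations,
                                    function(d) scale_effect(sub, d)))

    # -- report -------------------------------------------------------
    stage <- "report"
    p <- cohort$participants
    table1 <- do.call(rbind, lapply(
      list(c("age", "Age (years)"), c("weight", "Body weight (kg)"),
           c("height", "Height (cm)"), c("ree", "REE (kcal/d)")),
      function(v) data.frame(
        variable = v[2],
        total_mean = mean(p[[v[1]]]), total_sd = sd(p[[v[1]]]),
        boys_mean = mean(p[[v[1]]][p$gender == 1]),
        boys_sd = sd(p[[v[1]]][p$gender == 1]),
        girls_mean = mean(p[[v[1]]][p$gender == 0]),
        girls_sd = sd(p[[v[1]]][p$gender == 0]))))
    table2 <- do.call(rbind, lapply(c(ACTIVITY_COLS, "tpa"), function(a) {
      data.frame(activity = toupper(a),
                 total_mean = mean(p[[a]]), total_sd = sd(p[[a]]),
                 boys_mean = mean(p[[a]][p$gender == 1]),
                 boys_sd = sd(p[[a]][p$gender == 1]),
                 girls_mean = mean(p[[a]][p$gender == 0]),
                 girls_sd = sd(p[[a]][p$gender == 0]))
    }))

    paths <- c(
      baseline = "table_baseline.csv", activity = "table_activity.csv",
      changes = "table_changes.csv", correlations = "table_correlations.csv",
      models = "table_models.csv",
      substitutions = "substitution_by_duration.csv",
      daily = "daily_summaries.csv"
    )
    paths <- file.path(config$out_dir, paths)
    names(paths) <- c("baseline", "activity", "changes", "correlations",
                      "models", "substitutions", "daily")
    write.csv(table1, paths["baseline"], row.names = FALSE)
    write.csv(table2, paths["activity"], row.names = FALSE)
    write.csv(desc$table, paths["changes"], row.names = FALSE)
    write.csv(cors, paths["correlations"], row.names = FALSE)
    write.csv(models, paths["models"], row.names = FALSE)
    write.csv(scaled, paths["substitutions"], row.names = FALSE)
    write.csv(summaries$days, paths["daily"], row.names = FALSE)

    cfg_path <- file.path(config$out_dir, "pipeline_config.json")
    jsonlite::write_json(
      list(seed = config$seed, standardization = config$standardization,
           durations = config$durations, exposure_unit = config$exposure_unit,
           covariates = config$covariates, alpha = config$alpha,
           outcome_source = config$outcome_source,
           cohort = unclass(config$cohort),
           cut_points = unclass(config$cut_points)),
      cfg_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("isotempo")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      config_md5 = unname(tools::md5sum(cfg_path)),
      seed = config$seed,
      n_participants = nrow(cohort$participants),
      n_epochs = nrow(streams),
      n_days = nrow(summaries$days),
      n_model_rows = nrow(models),
      n_substitution_rows = nrow(scaled)
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    list(cohort = cohort, summaries = summaries, descriptives = desc,
         correlations = cors, models = models, substitutions = sub,
         scaled = scaled, manifest = manifest, paths = paths)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
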