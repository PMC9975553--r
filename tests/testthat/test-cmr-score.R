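test_that("MAP is the midpoint of systolic and diastolic pressure", {
  expect_equal(mean_arterial_pressure(113.27, 68.75), 91.01)
  expect_equal(round(mean_arterial_pressure(105.65, 63.04), 2), 84.34)
  expect_error(mean_arterial_pressure(100, 100), "exceed")
  expect_error(mean_arterial_pressure(90, 100), "exceed")
  expect_error(mean_arterial_pressure(100, -5), "> 0")
})

test_that("CMR-z components standardize correctly and sum exactly", {
  panels <- tiny_panels(n = 40, seed = 9,
                        post_shift = list(fins = -3, wc = -8, tc = -1,
                                          sbp = -7, dbp = -5, hdl = 0.02))
  z <- build_cmr_z(panels, standardization = "pooled")
  zcols <- c("z_fins", "z_fpg", "z_wc", "z_tc", "z_hdl_flipped", "z_map")
  # each component has mean 0 / SD 1 over the standardizing population
  for (col in zcols) {
    expect_lt(abs(mean(z[[col]])), 1e-9)
    expect_lt(abs(sd(z[[col]]) - 1), 1e-9)
  }
  # the score is exactly the component sum
  expect_lt(max(abs(z$cmr_z - rowSums(z[, zcols]))), 1e-12)
  # baseline standardization: pre rows are the reference population
  zb <- build_cmr_z(panels, standardization = "baseline")
  pre_rows <- zb[zb$occasion == "pre", ]
  for (col in zcols) expect_lt(abs(mean(pre_rows[[col]])), 1e-9)
})

test_that("HDL sign flip equals negating the HDL z-score, and is protective", {
  panels <- tiny_panels(n = 25, seed = 21,
                        post_shift = list(fins = -2, hdl = 0.05))
  z <- build_cmr_z(panels)
  # standardizing (-hdl) == -(standardized hdl): recompute directly
  m <- mean(panels$hdl); s <- sd(panels$hdl)
  expect_equal(z$z_hdl_flipped, -((panels$hdl - m) / s))
  # raising HDL alone strictly lowers the score
  bumped <- panels
  bumped$hdl[1] <- bumped$hdl[1] + 0.2
  z2 <- build_cmr_z(bumped)
  expect_lt(z2$cmr_z[1] - (z2$z_hdl_flipped[1] - z$z_hdl_flipped[1]) -
              z$cmr_z[1], 1e-9)  # only the HDL component moved it
  expect_lt(z2$z_hdl_flipped[1], z$z_hdl_flipped[1])
})

test_that("pooled centering makes pre and post group means exactly opposite", {
  panels <- tiny_panels(n = 30, seed = 33,
                        post_shift = list(fins = -3, fpg = -0.1, wc = -8,
                                          tc = -1, hdl = 0.01, sbp = -8,
                                          dbp = -6))
  for (sd_type in c("sample", "population")) {
    z <- build_cmr_z(panels, standardization = "pooled", sd_type = sd_type)
    expect_lt(abs(mean(z$cmr_z[z$occasion == "pre"]) +
                    mean(z$cmr_z[z$occasion == "post"])), 1e-9)
  }
})

test_that("a participant at the population mean scores zero; zero-SD factors are named", {
  panels <- tiny_panels(n = 20, seed = 44,
                        post_shift = list(fins = -1, tc = -0.5))
  # append a synthetic participant sitting at the pooled mean of each factor
  mean_row <- panels[1, ]
  mean_row$participant_id <- "MEAN"
  mean_row$occasion <- "pre"
  for (v in c("fins", "fpg", "wc", "tc", "hdl", "sbp", "dbp")) {
    mean_row[[v]] <- mean(panels[[v]])
  }
  # adding a row that equals the pooled mean leaves the mean unchanged,
  # so that participant's every z-score (hence the sum) is exactly zero
  withmean <- rbind(panels, mean_row)
  z <- build_cmr_z(withmean, standardization = "pooled")
  zm <- z[z$participant_id == "MEAN", ]
  expect_lt(abs(zm$cmr_z), 1e-9)

  flat <- panels
  flat$fpg <- 4.7
  expect_error(build_cmr_z(flat), "fpg")
})

test_that("change table reports paired deltas, ANOVA p and normality flag", {
  # no change at all: deltas zero, p undefined and reported as NA
  same <- tiny_panels(n = 10, seed = 3)
  d0 <- describe_changes(same, include_cmr_z = FALSE)
  expect_true(all(d0$table$change_mean == 0))
  expect_true(all(is.na(d0$table$p_anova)))

  # planted exact weight change with no noise is recovered exactly
  shifted <- tiny_panels(n = 16, seed = 8,
                         post_shift = list(weight = -7.49, fins = -3))
  dt <- describe_changes(shifted, include_cmr_z = FALSE)$table
  expect_equal(dt$change_mean[dt$variable == "weight"], -7.49)
  expect_equal(dt$change_sd[dt$variable == "weight"], 0)

  # two-group one-way ANOVA p equals the equal-variance two-sample t test
  set.seed(15)
  noisy <- tiny_panels(n = 30, seed = 15)
  noisy$fins[noisy$occasion == "post"] <-
    noisy$fins[noisy$occasion == "post"] + rnorm(30, -3, 2)
  dtab <- describe_changes(noisy, include_cmr_z = FALSE)$table
  tt <- t.test(noisy$fins[noisy$occasion == "pre"],
               noisy$fins[noisy$occasion == "post"], var.equal = TRUE)
  expect_equal(dtab$p_anova[dtab$variable == "fins"], tt$p.value,
               tolerance = 1e-12)

  # unpaired participants are excluded with a warning
  unpaired <- shifted[-1, ]
  expect_warning(res <- describe_changes(unpaired, include_cmr_z = FALSE),
                 "unpaired")
  expect_equal(res$unpaired, shifted$participant_id[1])
})

test_that("correlation table matches a from-scratch Pearson and flags exact linearity", {
  set.seed(12)
  n <- 20
  act <- data.frame(participant_id = sprintf("Q%02d", 1:n),
                    sb = runif(n, 200, 350), lpa = runif(n, 150, 300),
                    mpa = runif(n, 10, 70), vpa = runif(n, 5, 60))
  deltas <- data.frame(participant_id = act$participant_id,
                       d_cmr_z = -0.04 * act$vpa,   # exact negative linear
                       d_fins = rnorm(n))
  tab <- correlation_table(deltas, act)
  expect_equal(tab$r[tab$activity == "VPA" & tab$variable == "d_cmr_z"], -1)
  # every r equals the covariance-over-SDs oracle
  for (i in seq_len(nrow(tab))) {
    a <- tolower(tab$activity[i]); v <- tab$variable[i]
    expect_equal(tab$r[i], oracle_pearson(act[[a]], deltas[[v]]),
                 tolerance = 1e-12)
  }
  # star coding follows the two-sided p-value
  expect_true(all(tab$stars[!is.na(tab$p) & tab$p < 0.01] == "**"))
  expect_true(all(tab$stars[!is.na(tab$p) & tab$p >= 0.05] == ""))
  # constant columns are reported as missing, not errors
  act2 <- act
  act2$sb <- 274
  expect_warning(
    tab2 <- correlation_table(deltas[, c("participant_id", "d_cmr_z")], act2),
    "constant")
  expect_true(all(is.na(tab2$r[tab2$activity == "SB"])))
})

test_that("under permutation the change-activity correlations are null-calibrated", {
  set.seed(20230215)
  coh <- generate_cohort(cohort_config(seed = 20230215))
  at <- analysis_table(coh)
  n_perm <- 500
  sig <- logical(n_perm)
  for (i in seq_len(n_perm)) {
    shuffled <- sample(at$delta_cmr_z)
    ct <- cor.test(shuffled, at$vpa)
    sig[i] <- ct$p.value < 0.05
  }
  # non-significant in at least 94% of permutations at n = 196
  expect_gte(mean(!sig), 0.94)
})
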