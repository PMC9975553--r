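test_that("single model recovers a noise-free planted addition effect exactly", {
  set.seed(31)
  at <- random_analysis_table(60, coefs = c(sb = 0.12, lpa = 0, mpa = 0,
                                            vpa = 0),
                              with_covariates = FALSE)
  fit <- suppressWarnings(fit_single(at, "sb",
                                     ism_spec("single", covariates = NULL)))
  eff <- activity_effects(fit)
  expect_equal(eff$beta, 0.12, tolerance = 1e-8)
  # degenerate design: a constant activity column is refused
  at$lpa <- 300
  expect_error(fit_single(at, "lpa", ism_spec("single", covariates = NULL)),
               "rank-deficient")
})

test_that("OLS estimates, intervals and p-values match a normal-equations oracle", {
  set.seed(55)
  at <- random_analysis_table(30, noise_sd = 0.8)
  fit <- fit_partition(at)
  X <- cbind(1, at$sb / 10, at$lpa / 10, at$mpa / 10, at$vpa / 10,
             at$gender, at$age, at$ree)
  o <- oracle_ols(at$delta_cmr_z, X)
  tab <- fit$coefficients
  expect_equal(tab$beta, o$beta, tolerance = 1e-8)
  expect_equal(tab$se, o$se, tolerance = 1e-8)
  expect_equal(tab$ci_low, o$ci_low, tolerance = 1e-8)
  expect_equal(tab$ci_high, o$ci_high, tolerance = 1e-8)
  expect_equal(tab$p_value, o$p, tolerance = 1e-8)

  # single model against the same oracle with one exposure
  fs <- fit_single(at, "vpa")
  Xs <- cbind(1, at$vpa / 10, at$gender, at$age, at$ree)
  os <- oracle_ols(at$delta_cmr_z, Xs)
  expect_equal(fs$coefficients$beta, os$beta, tolerance = 1e-8)
  expect_equal(fs$coefficients$ci_low, os$ci_low, tolerance = 1e-8)
})

test_that("partition model recovers planted coefficients exactly at zero noise", {
  set.seed(8)
  truth <- c(sb = 0.05, lpa = -0.05, mpa = -0.27, vpa = -0.34)
  at <- random_analysis_table(100, coefs = truth)
  fit <- suppressWarnings(fit_partition(at))
  eff <- activity_effects(fit)
  expect_equal(setNames(eff$beta, eff$term), truth, tolerance = 1e-8)
  # identical activity columns across participants are refused
  flat <- at
  flat$sb <- flat$lpa
  expect_error(suppressWarnings(fit_partition(flat)), "rank-deficient")
})

test_that("ISM coefficients equal partition-coefficient differences (the central identity)", {
  set.seed(99)
  for (rep in 1:5) {
    for (covs in list(c("gender", "age", "ree"), NULL)) {
      at <- random_analysis_table(70, noise_sd = 1,
                                  with_covariates = !is.null(covs))
      pm <- activity_effects(fit_partition(
        at, ism_spec("partition", covariates = covs)))
      pb <- setNames(pm$beta, pm$term)
      for (dropped in c("sb", "lpa", "mpa", "vpa")) {
        ism <- activity_effects(fit_ism(
          at, ism_spec("ism", dropped_activity = dropped,
                       covariates = covs)))
        for (k in ism$term) {
          expect_lt(abs(ism$beta[ism$term == k] - (pb[k] - pb[dropped])),
                    1e-8)
        }
      }
    }
  }
})

test_that("ISM refuses an inconsistent total-activity column", {
  set.seed(2)
  at <- random_analysis_table(40, noise_sd = 0.5)
  at$tpa <- at$sb + at$lpa + at$mpa + at$vpa + 0.5
  expect_error(fit_ism(at, ism_spec("ism", dropped_activity = "sb")),
               "exact closure")
  at$tpa <- at$sb + at$lpa + at$mpa + at$vpa
  expect_s3_class(fit_ism(at, ism_spec("ism", dropped_activity = "sb")),
                  "ism_fit")
  expect_error(ism_spec("ism"), "dropped_activity")
  expect_error(ism_spec("partition", dropped_activity = "sb"),
               "only meaningful")
})

test_that("substitution matrix is antisymmetric with no diagonal", {
  set.seed(64)
  at <- random_analysis_table(80, noise_sd = 0.7)
  sub <- substitution_matrix(at)
  expect_equal(nrow(sub), 12)                      # 4 x 3 ordered pairs
  expect_true(all(sub$replaced != sub$replacing))  # no j -> j entries
  for (i in seq_len(nrow(sub))) {
    mirror <- sub[sub$replaced == sub$replacing[i] &
                    sub$replacing == sub$replaced[i], ]
    expect_lt(abs(sub$beta[i] + mirror$beta), 1e-8)
    # CI limits swap and flip sign under reversal
    expect_lt(abs(sub$ci_low[i] + mirror$ci_high), 1e-8)
    expect_lt(abs(sub$p_value[i] - mirror$p_value), 1e-8)
  }
})

test_that("exposure-unit rescaling is exactly equivariant", {
  set.seed(41)
  at <- random_analysis_table(60, noise_sd = 0.6)
  per10 <- activity_effects(fit_partition(at, ism_spec("partition")))
  per1 <- activity_effects(fit_partition(
    at, ism_spec("partition", exposure_unit = 1)))
  expect_equal(per10$beta, per1$beta * 10, tolerance = 1e-10)
  expect_equal(per10$ci_low, per1$ci_low * 10, tolerance = 1e-10)
  expect_equal(per10$p_value, per1$p_value, tolerance = 1e-10)
})

test_that("duration scaling multiplies estimate and CI, leaving p alone", {
  eff <- data.frame(replaced = c("SB", "SB"), replacing = c("MPA", "VPA"),
                    duration = 10, beta = c(-0.32, -0.39),
                    ci_low = c(-0.63, -0.66), ci_high = c(-0.01, -0.12),
                    p_value = c(0.04, 0.01))
  s30 <- scale_effect(eff[1, ], 30)
  expect_equal(s30$beta, -0.96)
  expect_equal(s30$ci_low, -1.89)
  expect_equal(s30$p_value, 0.04)
  s60 <- scale_effect(eff[2, ], 60)
  expect_equal(s60$beta, -2.34)
  expect_equal(s60$duration, 60)
  # identity scaling changes nothing
  expect_equal(scale_effect(eff, 10), eff)
  expect_error(scale_effect(eff, 0), "positive")
  expect_error(scale_effect(eff, -10), "positive")
})

test_that("zero-noise fits warn that p-values are degenerate", {
  set.seed(9)
  at <- random_analysis_table(50)
  expect_warning(fit_partition(at), "degenerate")
})

test_that("the stacked model table carries SM, PM and ISM blocks", {
  set.seed(21)
  at <- random_analysis_table(90, noise_sd = 0.8)
  tab <- model_table(at)
  expect_equal(sum(tab$model == "SM"), 4)
  expect_equal(sum(tab$model == "PM"), 4)
  expect_equal(sum(tab$model == "ISM"), 12)
  # the ISM block is consistent with the PM block by the identity
  pm <- setNames(tab$beta[tab$model == "PM"], tab$activity[tab$model == "PM"])
  ism <- tab[tab$model == "ISM", ]
  for (i in seq_len(nrow(ism))) {
    expect_lt(abs(ism$beta[i] - (pm[ism$activity[i]] - pm[ism$replaced[i]])),
              1e-8)
  }
})
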