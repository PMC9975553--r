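# Independent oracles and small fixture builders, deliberately written
# without reusing the package's own code paths.

# brute-force OLS via the normal equations, with classical t intervals
oracle_ols <- function(y, X, alpha = 0.05) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  n <- nrow(X); p <- ncol(X)
  sigma2 <- sum(resid^2) / (n - p)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tcrit <- qt(1 - alpha / 2, df = n - p)
  tval <- beta / se
  list(beta = as.numeric(beta), se = as.numeric(se),
       ci_low = as.numeric(beta - tcrit * se),
       ci_high = as.numeric(beta + tcrit * se),
       p = as.numeric(2 * pt(-abs(tval), df = n - p)))
}

# from-scratch Pearson correlation (covariance over product of SDs)
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# per-epoch scalar classification by explicit if-chains
oracle_classify <- function(vm, sb_max = 99, lpa_max = 3686, mpa_max = 5246) {
  vapply(vm, function(v) {
    b <- floor(v)
    if (b <= sb_max) "SB"
    else if (b <= lpa_max) "LPA"
    else if (b <= mpa_max) "MPA"
    else "VPA"
  }, character(1))
}

# random analysis table with a known linear outcome; exact (no noise)
# unless noise_sd > 0
random_analysis_table <- function(n, coefs = c(sb = 0.05, lpa = -0.05,
                                               mpa = -0.27, vpa = -0.34),
                                  noise_sd = 0, with_covariates = TRUE,
                                  cov_coefs = c(gender = -0.1, age = 0.02,
                                                ree = 1e-4)) {
  at <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    sb = round(runif(n, 150, 400)), lpa = round(runif(n, 120, 350)),
    mpa = round(runif(n, 10, 80)), vpa = round(runif(n, 5, 80)),
    gender = rbinom(n, 1, 0.5), age = runif(n, 10, 17),
    ree = runif(n, 1300, 2300)
  )
  mu <- with(at, coefs["sb"] * sb / 10 + coefs["lpa"] * lpa / 10 +
               coefs["mpa"] * mpa / 10 + coefs["vpa"] * vpa / 10)
  if (with_covariates) {
    mu <- mu + with(at, cov_coefs["gender"] * gender +
                      cov_coefs["age"] * age + cov_coefs["ree"] * ree)
  }
  at$delta_cmr_z <- as.numeric(mu) + rnorm(n, 0, noise_sd)
  at
}

# minimal paired pre/post panel table
tiny_panels <- function(n = 12, seed = 7, post_shift = NULL) {
  set.seed(seed)
  pre <- data.frame(
    participant_id = sprintf("Q%02d", seq_len(n)), occasion = "pre",
    fins = rnorm(n, 13.7, 4), fpg = rnorm(n, 4.7, 0.5),
    wc = rnorm(n, 99, 8), tc = rnorm(n, 4.7, 0.7),
    hdl = rnorm(n, 1.15, 0.2), sbp = rnorm(n, 113, 8),
    dbp = rnorm(n, 69, 6), weight = rnorm(n, 82, 10),
    stringsAsFactors = FALSE
  )
  pre$dbp <- pmin(pre$dbp, pre$sbp - 10)
  post <- pre
  post$occasion <- "post"
  if (!is.null(post_shift)) {
    for (v in names(post_shift)) post[[v]] <- post[[v]] + post_shift[[v]]
  }
  rbind(pre, post)
}
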