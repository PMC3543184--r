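# Enrichment tests, correlations, covariance models.

test_that("hypergeometric enrichment uses the strictly-greater tail", {
  # n2=10, m=4, n1=5: P(N > 3) = P(N = 4) = C(4,4) C(6,1) / C(10,5) = 6/252
  res <- hypergeometric_enrichment(n1 = 5, n2 = 10, m = 4, n_obs = 3)
  expect_equal(res$p_value, 6 / 252, tolerance = 1e-12)
  # nothing strictly greater than the maximum attainable count
  expect_equal(hypergeometric_enrichment(5, 10, 4, 4)$p_value, 0)
  # trait-free universe
  expect_equal(hypergeometric_enrichment(5, 10, 0, 0)$p_value, 0)
  expect_error(hypergeometric_enrichment(5, 10, 4, 5), "n_obs")
  expect_error(hypergeometric_enrichment(11, 10, 4, 2), "universe")
  expect_error(hypergeometric_enrichment(5, 10, -1, 0), "nonnegative")
})

test_that("enrichment p-values match subset enumeration for small universes", {
  for (n2 in c(5, 8, 10)) {
    for (n1 in 1:n2) {
      for (m in 0:n2) {
        for (n_obs in 0:min(n1, m)) {
          expect_equal(
            hypergeometric_enrichment(n1, n2, m, n_obs)$p_value,
            enum_hyper_pvalue(n1, n2, m, n_obs),
            tolerance = 1e-10,
            info = sprintf("n1=%d n2=%d m=%d n_obs=%d", n1, n2, m, n_obs))
        }
      }
    }
  }
})

test_that("pearson correlation handles exact and degenerate cases", {
  x <- 1:20
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(1, 20)), "zero-variance")
  expect_error(pearson_correlation(1:2, 1:2), "length")
  # independent variables: |r| < 0.05 at n = 10^4
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    abs(pearson_correlation(rnorm(1e4), rnorm(1e4))$r) < 0.05
  }, logical(1))
  expect_true(all(ok))
})

test_that("a noiseless single-covariate response is recovered exactly", {
  set.seed(5)
  df <- data.frame(a = rlnorm(100), b = rlnorm(100), c = rnorm(100))
  z <- as.numeric(scale(log(df$a)))
  # log response is the standardized covariate (up to negligible noise that
  # keeps the least-squares problem non-degenerate)
  df$resp <- exp(z + rnorm(100, 0, 1e-8))
  # step() warns that selection on a near-perfect fit is pointless; that is
  # exactly the scenario being checked here
  fit <- suppressWarnings(
    fit_covariance_model(df, "resp",
                         covariates = list(a = "log", b = "log",
                                           c = "raw")))
  expect_identical(fit$selected, "a")
  expect_equal(fit$coefficients$estimate, 1, tolerance = 1e-6)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-6)
})

test_that("standardization makes fits invariant to affine covariate rescaling", {
  set.seed(6)
  df <- data.frame(a = rlnorm(200), g = rnorm(200))
  df$resp <- exp(0.5 * scale(log(df$a)) + 0.3 * scale(df$g) +
                   rnorm(200, 0, 0.6))
  f1 <- fit_covariance_model(df, "resp",
                             covariates = list(a = "log", g = "raw"))
  df2 <- df
  df2$g <- 100 * df$g - 7            # affine rescale of a raw covariate
  f2 <- fit_covariance_model(df2, "resp",
                             covariates = list(a = "log", g = "raw"))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-9)
  expect_equal(f1$adjusted_r2, f2$adjusted_r2, tolerance = 1e-12)
})

test_that("adjusted R^2 matches its closed form", {
  set.seed(8)
  df <- data.frame(a = rlnorm(150), b = rnorm(150))
  df$resp <- exp(0.4 * scale(log(df$a)) + rnorm(150, 0, 0.9))
  fit <- fit_covariance_model(df, "resp",
                              covariates = list(a = "log", b = "raw"))
  sm <- summary(fit$fit)
  n <- fit$n_used
  p <- length(fit$selected)
  expect_equal(fit$adjusted_r2,
               1 - (1 - sm$r.squared) * (n - 1) / (n - p - 1),
               tolerance = 1e-12)
})

test_that("AIC selection retains noise covariates at the chi-square rate, not more", {
  # With the AIC penalty of 2 per parameter, a pure-noise covariate survives
  # selection with asymptotic probability P(chisq_1 > 2) ~ 0.157; the
  # selected model should therefore be far sparser than the full model but
  # is not expected to be empty every time.
  set.seed(77)
  kept <- integer(25)
  for (s in 1:25) {
    df <- data.frame(matrix(rnorm(400 * 6), 400, 6))
    names(df) <- paste0("x", 1:6)
    df$resp <- exp(rnorm(400))
    cov <- as.list(setNames(rep("raw", 6), names(df)[1:6]))
    fit <- fit_covariance_model(df, "resp", covariates = cov)
    kept[s] <- length(fit$selected)
  }
  rate <- mean(kept) / 6
  expect_lt(rate, 0.30)              # sparse relative to the full model
  expect_lt(abs(rate - 0.157), 0.12) # consistent with the chi-square rate
})

test_that("exhaustive and stepwise selection agree on simple designs", {
  set.seed(13)
  df <- data.frame(a = rlnorm(120), b = rlnorm(120), c = rnorm(120))
  df$resp <- exp(0.6 * scale(log(df$a)) + rnorm(120, 0, 0.5))
  cov <- list(a = "log", b = "log", c = "raw")
  f1 <- fit_covariance_model(df, "resp", covariates = cov,
                             selection = "stepwise")
  f2 <- fit_covariance_model(df, "resp", covariates = cov,
                             selection = "exhaustive")
  expect_identical(sort(f1$selected), sort(f2$selected))
  expect_equal(f1$adjusted_r2, f2$adjusted_r2, tolerance = 1e-10)
})

test_that("covariance-model preconditions are enforced", {
  df <- data.frame(a = rlnorm(30), resp = rlnorm(30))
  df$resp[1] <- -1
  expect_error(fit_covariance_model(df, "resp",
                                    covariates = list(a = "log")),
               "strictly positive")
  df2 <- data.frame(a = rlnorm(10), resp = rlnorm(10))
  expect_error(fit_covariance_model(df2, "resp",
                                    covariates = list(a = "log")),
               "complete cases")
  set.seed(1)
  df3 <- data.frame(a = rlnorm(50), resp = rlnorm(50))
  df3$b <- df3$a * 3                 # exactly collinear after standardization
  expect_error(fit_covariance_model(df3, "resp",
                                    covariates = list(a = "log", b = "log")),
               "collinear")
})

test_that("protein models improve with a true occupancy effect and not without", {
  set.seed(21)
  n <- 200
  df <- data.frame(mrna = rlnorm(n), cai = rlnorm(n),
                   occupancy = rlnorm(n, log(0.66), 0.1),
                   density = rlnorm(n, log(1.2), 0.4))
  df$protein_level <- exp(0.4 * scale(log(df$mrna)) + 0.5 * scale(log(df$cai)) +
                            0.4 * scale(log(df$occupancy)) + rnorm(n, 0, 0.6))
  fits <- protein_level_model(df, covariates = list(mrna = "log", cai = "log"))
  expect_gt(fits$with$adjusted_r2, fits$without$adjusted_r2)
  expect_true("occupancy" %in% fits$with$selected)

  # no occupancy effect: model II should not gain and AIC usually drops it
  dropped <- vapply(1:20, function(s) {
    set.seed(100 + s)
    d <- data.frame(mrna = rlnorm(n), cai = rlnorm(n),
                    occupancy = rlnorm(n, log(0.66), 0.1),
                    density = rlnorm(n, log(1.2), 0.4))
    d$protein_level <- exp(0.4 * scale(log(d$mrna)) +
                             0.5 * scale(log(d$cai)) + rnorm(n, 0, 0.6))
    f <- protein_level_model(d, covariates = list(mrna = "log", cai = "log"))
    !"occupancy" %in% f$with$selected
  }, logical(1))
  expect_gte(mean(dropped), 0.7)

  # deterministic protein = CAI term only
  d2 <- data.frame(mrna = rlnorm(50), cai = rlnorm(50),
                   occupancy = rlnorm(50, log(0.66), 0.1),
                   density = rlnorm(50, log(1.2), 0.4))
  d2$protein_level <- exp(as.numeric(scale(log(d2$cai))) + rnorm(50, 0, 1e-8))
  f2 <- suppressWarnings(
    protein_level_model(d2, covariates = list(mrna = "log", cai = "log")))
  expect_identical(f2$without$selected, "cai")
  expect_equal(f2$without$coefficients$estimate, 1, tolerance = 1e-6)
})
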