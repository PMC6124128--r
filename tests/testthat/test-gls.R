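test_that("covariance assembly is exact matrix arithmetic", {
  fx <- fixture_taxonomy()
  tree <- build_hierarchy(fx$taxonomy, fx$clades)
  P <- phylo_similarity(tree)
  set.seed(5)
  coords <- data.frame(society_id = rownames(P),
                       lat = runif(6, -60, 60), lon = runif(6, -170, 170))
  D <- distance_matrix(coords)
  S <- gaussian_similarity(D, 2000, repair = FALSE)

  # pure white noise and pure phylogenetic structure
  expect_equal(assemble_covariance(P, S, cov_model(0, 0, 2000), repair = FALSE),
               diag(6), ignore_attr = TRUE)
  expect_equal(assemble_covariance(P, S, cov_model(1, 0, 2000), repair = FALSE),
               P, ignore_attr = TRUE)
  # hand-computed mixture
  V <- assemble_covariance(P, S, cov_model(0.3, 0.5, 2000), repair = FALSE)
  expect_equal(V, 0.3 * P + 0.5 * S + 0.2 * diag(6), ignore_attr = TRUE)
  expect_equal(diag(V), rep(1, 6), tolerance = 1e-9, ignore_attr = TRUE)
  # paper mode: no identity component
  Vp <- assemble_covariance(P, S, cov_model(0.3, 0.7, 2000, mode = "paper"),
                            repair = FALSE)
  expect_equal(Vp, 0.3 * P + 0.7 * S, ignore_attr = TRUE)
  # simplex violations rejected
  expect_error(cov_model(0.7, 0.5, 2000), "simplex")
  expect_error(cov_model(-0.1, 0.5, 2000), "non-negative")
  expect_error(cov_model(0.3, 0.5, 2000, mode = "paper"), "equal 1")
  expect_error(assemble_covariance(P, S[1:5, 1:5], cov_model(0.2, 0.2, 2000)),
               "dimension mismatch")
})

test_that("profile GLS with V = I reproduces OLS/ML exactly", {
  # 100 random small datasets against the lm() oracle
  for (seed in 1:100) {
    n <- sample(10:25, 1)
    d <- random_dataset(n, k = 2, seed = seed)
    fit <- gls_profile_loglik(d$y, d$X, diag(n))
    lmfit <- lm(d$y ~ d$X - 1)
    expect_equal(unname(fit$beta), unname(coef(lmfit)), tolerance = 1e-8)
    expect_equal(fit$logLik, as.numeric(logLik(lmfit)), tolerance = 1e-8)
    # ML standard errors = lm (REML-flavoured) s.e. scaled by sqrt((n-k)/n)
    k <- ncol(d$X)
    se_lm <- summary(lmfit)$coefficients[, "Std. Error"]
    expect_equal(unname(fit$se), unname(se_lm * sqrt((n - k) / n)),
                 tolerance = 1e-8)
  }
})

test_that("the GLS log-likelihood equals a direct MVN density evaluation", {
  for (seed in 1:20) {
    n <- sample(6:10, 1)
    d <- random_dataset(n, k = 1, seed = 100 + seed)
    V <- random_spd(n, seed = 200 + seed)
    fit <- gls_profile_loglik(d$y, d$X, V)
    mu <- as.numeric(d$X %*% fit$beta)
    ll <- oracle_mvn_loglik(d$y, mu, fit$sigma2 * V)
    expect_equal(fit$logLik, ll, tolerance = 1e-8)
  }
})

test_that("exact fits hit the variance floor with a warning", {
  x <- 1:12
  y <- 2 * x
  X <- cbind(x = x)
  expect_warning(fit <- gls_profile_loglik(y, X, diag(12)), "floor")
  expect_equal(unname(fit$beta), 2, tolerance = 1e-9)
})

test_that("collinear and degenerate designs are rejected", {
  set.seed(9)
  x <- rnorm(15)
  X <- cbind("(Intercept)" = 1, a = x, b = x)
  expect_error(gls_profile_loglik(rnorm(15), X, diag(15)), "collinear")
  expect_error(gls_profile_loglik(rnorm(3), cbind(1, rnorm(3), rnorm(3), rnorm(3)),
                                  diag(3)), "more observations")
})

test_that("log-likelihood is invariant to simultaneous row permutation", {
  n <- 12
  d <- random_dataset(n, k = 1, seed = 31)
  V <- random_spd(n, seed = 32)
  f1 <- gls_profile_loglik(d$y, d$X, V)
  set.seed(33)
  perm <- sample(n)
  f2 <- gls_profile_loglik(d$y[perm], d$X[perm, ], V[perm, perm])
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-9)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
})

test_that("fit_ols recovers noiseless coefficients and ignores row order", {
  set.seed(41)
  x <- rnorm(20)
  tr <- data.frame(society_id = sprintf("s%02d", 1:20), y = 3 + 0.5 * x, x = x)
  expect_warning(f <- fit_ols(model_spec("y", "x"), tr), "floor")
  expect_equal(f$coefficients$beta, c(3, 0.5), tolerance = 1e-8)
  set.seed(42)
  tr2 <- data.frame(society_id = sprintf("s%02d", 1:20),
                    y = 1 + 2 * x + rnorm(20), x = x)
  f1 <- fit_ols(model_spec("y", "x"), tr2)
  f2 <- fit_ols(model_spec("y", "x"), tr2[sample(20), ])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-10)
  # degrees of freedom reported as n - k
  expect_equal(f1$df, 20 - 2)
})

test_that("fixing all covariance parameters reduces to one profile call", {
  b <- simulate_benchmark_suite(sim_config(n_societies = 30, n_clades = 5,
                                           seed = 8, scenario = "null"))
  fx <- list(w_p = 0.25, w_s = 0.35, sigma_s = 1500)
  f <- fit_gls(model_spec("C1", "PAR"), b$traits, b$P, b$D, fix = fx)
  S <- gaussian_similarity(b$D, 1500, repair = FALSE)
  ids <- f$ids
  V <- assemble_covariance(b$P[ids, ids], S[ids, ids],
                           cov_model(0.25, 0.35, 1500), repair = FALSE)
  dat <- crosscult:::.build_design(model_spec("C1", "PAR"), b$traits)
  ref <- gls_profile_loglik(dat$y, dat$X, V)
  expect_equal(f$logLik, ref$logLik, tolerance = 1e-9)
  expect_equal(f$coefficients$beta, unname(ref$beta), tolerance = 1e-9)
  expect_equal(f$cov$w_p, 0.25)
  expect_equal(f$cov$sigma_s, 1500)
})

test_that("corrected ML log-likelihood dominates OLS in nugget mode", {
  # OLS is nested at w_p = w_s = 0, so the optimized fit cannot be worse
  for (seed in c(2, 13)) {
    b <- simulate_benchmark_suite(sim_config(n_societies = 40, n_clades = 6,
                                             seed = seed, scenario = "direct"))
    u <- fit_ols(model_spec("C1", "PAR"), b$traits)
    g <- fit_gls(model_spec("C1", "PAR"), b$traits, b$P, b$D, mode = "nugget")
    expect_gte(g$logLik, u$logLik - 1e-6)
  }
})

test_that("paper-mode fits keep the weights on the constraint w_p + w_s = 1", {
  b <- simulate_benchmark_suite(sim_config(n_societies = 40, n_clades = 6,
                                           seed = 63, scenario = "null"))
  g <- fit_gls(model_spec("C1", "PAR"), b$traits, b$P, b$D, mode = "paper")
  expect_equal(g$cov$w_p + g$cov$w_s, 1, tolerance = 1e-9)
  expect_equal(g$cov$mode, "paper")
  # one fewer free covariance parameter than nugget mode
  expect_equal(g$AIC, 2 * (g$k + 3) - 2 * g$logLik, tolerance = 1e-10)
  # OLS is not nested here, so the contribution statistic may take
  # either sign; it must still be finite and well-defined
  u <- fit_ols(model_spec("C1", "PAR"), b$traits)
  expect_true(is.finite(autocorrelation_contribution(g, u)))
})

test_that("the contribution statistic matches its definition and edge cases", {
  expect_equal(round(autocorrelation_contribution(-13.202, -17.734), 3), 0.256)
  expect_equal(round(autocorrelation_contribution(-58.308, -46.469), 3), -0.255)
  expect_equal(autocorrelation_contribution(-10, -10), 0)
  expect_error(autocorrelation_contribution(-5, 0), "undefined")
})

test_that("AIC bookkeeping matches the definition", {
  set.seed(51)
  tr <- data.frame(society_id = sprintf("s%02d", 1:20),
                   y = rnorm(20), x = rnorm(20))
  u <- fit_ols(model_spec("y", "x"), tr)
  # OLS free parameters: k coefficients + sigma2
  expect_equal(u$AIC, 2 * (u$k + 1) - 2 * u$logLik, tolerance = 1e-10)
  b <- simulate_benchmark_suite(sim_config(n_societies = 30, n_clades = 5,
                                           seed = 52, scenario = "null"))
  g <- fit_gls(model_spec("C1", "PAR"), b$traits, b$P, b$D)
  # nugget-mode free covariance parameters: sigma2, w_p, w_s, sigma_s
  expect_equal(g$AIC, 2 * (g$k + 4) - 2 * g$logLik, tolerance = 1e-10)
})
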