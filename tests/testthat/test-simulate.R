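test_that("simulated taxonomies are valid, reproducible and sized right", {
  t1 <- simulate_taxonomy(6, 2, seed = 1)
  t2 <- simulate_taxonomy(6, 2, seed = 1)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$taxonomy), 6)
  expect_equal(nrow(t1$clades), 2)
  # generated taxonomies always pass hierarchy validation
  for (seed in 1:50) {
    tax <- simulate_taxonomy(sample(10:30, 1), sample(2:6, 1), seed = seed)
    tree <- suppressWarnings(build_hierarchy(tax$taxonomy, tax$clades))
    depths <- ape::node.depth.edgelength(tree)
    expect_lt(max(abs(depths[seq_along(tree$tip.label)] - 1)), 1e-9)
  }
  # all-singleton clades force an identity similarity matrix
  tax <- simulate_taxonomy(12, 12, seed = 3)
  tree <- suppressWarnings(build_hierarchy(tax$taxonomy, tax$clades))
  P <- phylo_similarity(tree)
  expect_equal(P, diag(12), ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(simulate_taxonomy(5, 6), "exceed")
})

test_that("simulated coordinates are in range and cluster by clade", {
  co <- simulate_coordinates(50, seed = 2, clustered = FALSE)
  expect_true(all(co$lat >= -90 & co$lat <= 90))
  expect_true(all(co$lon > -180 & co$lon <= 180))
  expect_identical(co, simulate_coordinates(50, seed = 2, clustered = FALSE))
  # clustered mode: within-clade distances smaller than between-clade
  ratios <- numeric(20)
  for (seed in 1:20) {
    tax <- simulate_taxonomy(30, 5, seed = seed)
    co <- simulate_coordinates(30, seed = seed,
                               clade_ids = tax$taxonomy$clade_id)
    D <- distance_matrix(co)
    same <- outer(tax$taxonomy$clade_id, tax$taxonomy$clade_id, "==")
    ut <- upper.tri(D)
    ratios[seed] <- mean(D[ut & same]) / mean(D[ut & !same])
  }
  expect_lt(mean(ratios), 1)
  expect_true(mean(ratios < 1) >= 0.9)
})

test_that("trait simulation reproduces the requested covariance", {
  # white-noise case: mean ~ 0, variance ~ 1
  tax <- simulate_taxonomy(20, 4, seed = 5)
  tree <- suppressWarnings(build_hierarchy(tax$taxonomy, tax$clades))
  ids <- tax$taxonomy$tip_id
  P <- phylo_similarity(tree)[ids, ids] # align with taxonomy order
  co <- simulate_coordinates(20, seed = 5)
  S <- gaussian_similarity(distance_matrix(co), 2000)
  cv0 <- cov_model(0, 0, 2000, 1)
  draws <- vapply(1:50, function(i)
    simulate_trait(NULL, NULL, P, S, cv0, seed = i), numeric(20))
  expect_lt(abs(mean(draws)), 0.1)
  expect_lt(abs(stats::var(as.vector(draws)) - 1), 0.1)

  # Monte-Carlo covariance check at n = 8: empirical covariance within
  # 10% Frobenius error of sigma2 * V
  tax8 <- simulate_taxonomy(8, 2, seed = 6)
  tree8 <- suppressWarnings(build_hierarchy(tax8$taxonomy, tax8$clades))
  P8 <- phylo_similarity(tree8)[tax8$taxonomy$tip_id, tax8$taxonomy$tip_id]
  co8 <- simulate_coordinates(8, seed = 6,
                              clade_ids = tax8$taxonomy$clade_id)
  S8 <- gaussian_similarity(distance_matrix(co8), 2000)
  cv <- cov_model(0.4, 0.3, 2000, 1.5)
  V <- 1.5 * assemble_covariance(P8, S8, cv)
  E <- vapply(1:2000, function(i)
    simulate_trait(NULL, NULL, P8, S8, cv, seed = 10000 + i), numeric(8))
  emp <- tcrossprod(E - rowMeans(E)) / (ncol(E) - 1)
  frob <- function(M) sqrt(sum(M^2))
  expect_lt(frob(emp - V) / frob(V), 0.10)

  # pure phylogenetic structure: between-clade variance exceeds within
  cv_p <- cov_model(1, 0, 2000, 1)
  reps <- vapply(1:200, function(i)
    simulate_trait(NULL, NULL, P, S, cv_p, seed = 500 + i), numeric(20))
  cl <- tax$taxonomy$clade_id
  within_ms <- mean(apply(reps, 2, function(y)
    mean(tapply(y, cl, function(v) if (length(v) > 1) stats::var(v) else NA),
         na.rm = TRUE)))
  between_ms <- mean(apply(reps, 2, function(y)
    stats::var(tapply(y, cl, mean))))
  expect_gt(between_ms, within_ms)
})

test_that("benchmark truth records mirror the scenario wiring", {
  b_null <- simulate_benchmark_suite(sim_config(seed = 9, scenario = "null"))
  expect_equal(sum(b_null$truth$edges$from == "PAR"), 0)
  b_dir <- simulate_benchmark_suite(sim_config(seed = 9, scenario = "direct"))
  expect_true(any(b_dir$truth$edges$from == "PAR" &
                    b_dir$truth$edges$to == "C1"))
  b_cov <- simulate_benchmark_suite(sim_config(seed = 9,
                                               scenario = "covariation"))
  expect_true(any(b_cov$truth$edges$from == "C1" &
                    b_cov$truth$edges$to == "C2"))
  b_con <- simulate_benchmark_suite(sim_config(seed = 9,
                                               scenario = "confounded"))
  expect_false(any(b_con$truth$edges$from == "PAR"))
  expect_true(all(c("PAR", "C1") %in%
                    b_con$truth$edges$to[b_con$truth$edges$from == "LATG"]))
  # determinism: identical config -> identical dataset
  b2 <- simulate_benchmark_suite(sim_config(seed = 9, scenario = "direct"))
  expect_identical(b_dir$traits, b2$traits)
  # missingness injected at the stated rate, roughly
  bm <- simulate_benchmark_suite(sim_config(seed = 9, scenario = "null",
                                            missing_rate = 0.1))
  rate <- mean(is.na(as.matrix(bm$traits[, -1])))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.2)
})

test_that("confounding induces spurious marginal correlation", {
  # the latitudinal confound makes OLS find a PAR-C1 association that the
  # truth record does not contain
  sig <- logical(25)
  for (i in 1:25) {
    b <- simulate_benchmark_suite(sim_config(seed = 300 + i,
                                             scenario = "confounded"))
    u <- fit_ols(model_spec("C1", "PAR"), b$traits)
    sig[i] <- u$coefficients$p[u$coefficients$term == "PAR"] < 0.05
  }
  expect_gt(mean(sig), 0.5)
})
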