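#!/usr/bin/env Rscript
# Calibration study: on null data whose residuals carry phylogenetic and
# spatial structure (w_p = 0.5, w_s = 0.3), how often does each test
# reject a true-null slope at nominal alpha = 0.05?  The uncorrected test
# treats societies as independent and over-rejects; the corrected test
# should stay near the nominal rate.  Also: recovery of the phylogenetic
# weight when the truth is w_p = 0.6, w_s = 0.  (200 replicates here;
# the test suite runs the full-size version.)

suppressPackageStartupMessages(library(crosscult))
seed <- 20260924
nrep <- 200
b <- simulate_benchmark_suite(sim_config(seed = seed, scenario = "null"))
cv <- cov_model(0.5, 0.3, 2000, 1)
ids <- b$traits$society_id

rej_u <- rej_c <- logical(nrep)
for (i in seq_len(nrep)) {
  tr <- data.frame(
    society_id = ids,
    x = simulate_trait(NULL, NULL, b$P, b$S, cv, seed = seed + 20000 + i),
    y = simulate_trait(NULL, NULL, b$P, b$S, cv, seed = seed + 60000 + i))
  u <- fit_ols(model_spec("y", "x"), tr)
  g <- fit_gls(model_spec("y", "x"), tr, b$P, b$D)
  rej_u[i] <- u$coefficients$p[u$coefficients$term == "x"] < 0.05
  rej_c[i] <- g$coefficients$p[g$coefficients$term == "x"] < 0.05
}

cv6 <- cov_model(0.6, 0, 2000, 1)
wp_hat <- numeric(50)
set.seed(seed)
for (i in 1:50) {
  tr <- data.frame(society_id = ids, x = rnorm(length(ids)),
                   y = simulate_trait(NULL, NULL, b$P, b$S, cv6,
                                      seed = seed + 90000 + i))
  wp_hat[i] <- fit_gls(model_spec("y", "x"), tr, b$P, b$D)$cov$w_p
}

tab <- data.frame(
  quantity = c("ols_type1_rate", "gls_type1_rate", "wp_hat_mean",
               "wp_true"),
  value = c(mean(rej_u), mean(rej_c), mean(wp_hat), 0.6),
  n = c(nrep, nrep, 50, NA))
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/calibration.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Uncorrected type-I rate: %.3f (nominal 0.05)\n", mean(rej_u)))
cat(sprintf("Corrected type-I rate:   %.3f\n", mean(rej_c)))
cat(sprintf("Mean fitted w_p:         %.3f (truth 0.6)\n", mean(wp_hat)))
cat("The inflation of the uncorrected rate is the quantitative core of\n")
cat("the case for modelling relatedness and proximity in the residuals.\n")
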