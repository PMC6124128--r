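#' Likelihood-ratio test between nested fits
#'
#' `LR = 2 (logLik_full - logLik_nested)` compared against a chi-squared
#' upper tail with `df` degrees of freedom (`df` = number of added
#' regression coefficients; covariance parameters are re-estimated in both
#' models and not counted).  Small negative LR values (optimizer slack,
#' within 1e-6) are clamped to zero; larger negatives indicate misuse on
#' non-nested fits and raise an error.
#'
#' @param logLik_nested,logLik_full log-likelihoods (numbers or
#'   `cc_gls_fit` objects).
#' @param df integer >= 1, number of constrained parameters.
#' @param bonferroni_m number of tests behind the Bonferroni flag
#'   (default 16, giving the threshold p < 0.003 used alongside the
#'   nominal 0.05).
#' @return object of class `cc_lr_test` with `LR`, `df`, `p` and
#'   significance flags.
#' @export
#' @examples
#' lr_test(-54.021, -54.015, df = 1)  # LR = 0.012
lr_test <- function(logLik_nested, logLik_full, df, bonferroni_m = 16) {
  ln <- if (inherits(logLik_nested, "cc_gls_fit"))
    logLik_nested$logLik else logLik_nested
  lf <- if (inherits(logLik_full, "cc_gls_fit"))
    logLik_full$logLik else logLik_full
  if (!is.numeric(df) || df < 1) stop("df must be a positive integer")
  lr <- 2 * (lf - ln)
  if (lr < 0) {
    if (lr > -1e-6) lr <- 0
    else stop("negative likelihood ratio (", format(lr),
              "): models are not nested or fits did not converge")
  }
  p <- pchisq(lr, df = df, lower.tail = FALSE)
  structure(list(LR = lr, df = as.integer(df), p = p,
                 significant_05 = p < 0.05,
                 significant_bonferroni = p < 0.05 / bonferroni_m),
            class = "cc_lr_test")
}

#' @export
print.cc_lr_test <- function(x, ...) {
  cat(sprintf("LR = %.3f, df = %d, p = %.4g%s\n", x$LR, x$df, x$p,
              if (x$significant_05) " *" else ""))
  invisible(x)
}

#' Rank fits by AIC
#'
#' AIC is `2 (k + free covariance parameters) - 2 logLik`.  All fits must
#' be on the same response and the same complete-case set, otherwise
#' AIC values are not comparable.  A fit is flagged as better than
#' another when its AIC is lower by more than `threshold` (default 2);
#' pairs within the threshold have equivalent explanatory power.
#'
#' @param fits named list of `cc_gls_fit` objects.
#' @param threshold delta-AIC decision threshold (default 2).
#' @return list with `table` (model, AIC, delta to best) and `better`
#'   (logical matrix: row model fits better than column model).
#' @export
aic_rank <- function(fits, threshold = 2) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "cc_gls_fit")))
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  resp <- unique(vapply(fits, function(f) f$spec$response, ""))
  if (length(resp) != 1) stop("fits are on different responses")
  id_sets <- lapply(fits, function(f) sort(f$ids))
  if (!all(vapply(id_sets, identical, TRUE, id_sets[[1]]))) {
    stop("fits use different complete-case sets; AIC not comparable")
  }
  aic <- vapply(fits, `[[`, 0, "AIC")
  d <- outer(aic, aic, `-`) # d[i, j] = AIC_i - AIC_j
  better <- t(d) > threshold # i better than j when AIC_j - AIC_i > threshold
  diag(better) <- FALSE
  delta <- aic - min(aic)
  list(table = data.frame(model = names(fits), AIC = aic, delta = delta,
                          worse_than_best = delta > threshold,
                          row.names = NULL),
       better = better, threshold = threshold)
}

#' Pairwise Kendall correlation screen
#'
#' Tie-corrected Kendall's tau-b with normal-approximation statistic and
#' two-sided p for every pair of the given variables, over pairwise
#' complete observations.  Pairs with fewer than `min_pairs` complete
#' observations, or with a constant variable, are reported as missing
#' with a warning.
#'
#' @param traits trait table.
#' @param variables character vector of column names.
#' @param min_pairs minimum complete pairs per cell (default 8).
#' @return object of class `cc_corr_screen`: matrices `tau`, `statistic`,
#'   `p`.
#' @export
kendall_screen <- function(traits, variables, min_pairs = 8) {
  stopifnot(all(variables %in% names(traits)), length(variables) >= 2)
  m <- length(variables)
  tau <- stat <- p <- matrix(NA_real_, m, m,
                             dimnames = list(variables, variables))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      x <- as.numeric(traits[[variables[i]]])
      y <- as.numeric(traits[[variables[j]]])
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < min_pairs) {
        warning("fewer than ", min_pairs, " complete pairs for ",
                variables[i], " / ", variables[j])
        next
      }
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warning("constant variable in pair ", variables[i], " / ",
                variables[j], "; tau undefined")
        next
      }
      ct <- suppressWarnings(
        cor.test(x[ok], y[ok], method = "kendall", exact = FALSE))
      tau[i, j] <- tau[j, i] <- unname(ct$estimate)
      stat[i, j] <- stat[j, i] <- unname(ct$statistic)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(tau = tau, statistic = stat, p = p), class = "cc_corr_screen")
}

#' @export
print.cc_corr_screen <- function(x, ...) {
  cat("Kendall tau-b screen (upper: tau, p in brackets)\n")
  print(round(x$tau, 3))
  invisible(x)
}
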