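# Staged hypothesis winnowing: (1) univariate corrected/uncorrected
# screens of each focal ("cultural") variable against each exposure
# ("parasite") measure; (2) covariation tests among focal variables;
# (3) races against external covariate sets (environment, biodiversity,
# population).  A variable dropped at any stage never re-enters.

# subset a trait table to the complete cases of a set of variables so
# nested fits share the same case set (a requirement for LRT/AIC)
.complete_subset <- function(traits, vars, id_col = "society_id") {
  keep <- complete.cases(traits[, vars, drop = FALSE])
  traits[keep, , drop = FALSE]
}

.fit_nested_pair <- function(traits, P, D, y, base_preds, added, mode) {
  vars <- unique(c(y, base_preds, added))
  sub <- .complete_subset(traits, vars)
  m1 <- fit_gls(model_spec(y, base_preds), sub, P, D, mode = mode)
  m2 <- fit_gls(model_spec(y, c(base_preds, added)), sub, P, D, mode = mode)
  list(m1 = m1, m2 = m2,
       lrt = lr_test(m1, m2, df = length(added)))
}

#' Stage 1: univariate associations with each exposure measure
#'
#' For each focal variable and each exposure (parasite-load) measure, an
#' uncorrected (OLS) and a corrected (phylogenetic + spatial GLS) simple
#' regression is fitted and the contribution of autocorrelation
#' (`1 - logLik_c / logLik_u`) computed.  Focal variables with no
#' corrected association significant at `alpha` against any exposure
#' measure are dropped.
#'
#' @param traits trait table.
#' @param P,D phylogenetic similarity and distance matrices.
#' @param cultural_vars,parasite_vars character vectors of column names.
#' @param alpha retention threshold on the corrected slope p (default
#'   0.05).
#' @param bonferroni_m number of tests for the Bonferroni flag; defaults
#'   to the number of (focal, exposure) pairs.
#' @param mode covariance mode for the corrected fits.
#' @return list with `table` (one row per pair), `retained`, `dropped`,
#'   and `significant_pairs` (data.frame of y/x combinations significant
#'   at `alpha`, consumed by later stages).
#' @export
stage1_univariate <- function(traits, P, D, cultural_vars, parasite_vars,
                              alpha = 0.05, bonferroni_m = NULL,
                              mode = "nugget") {
  if (is.null(bonferroni_m)) {
    bonferroni_m <- length(cultural_vars) * length(parasite_vars)
  }
  rows <- list()
  for (y in cultural_vars) {
    for (x in parasite_vars) {
      row <- data.frame(y = y, x = x, n = NA_integer_,
                        beta_u = NA_real_, se_u = NA_real_, t_u = NA_real_,
                        p_u = NA_real_, logLik_u = NA_real_,
                        beta_c = NA_real_, se_c = NA_real_, t_c = NA_real_,
                        p_c = NA_real_, logLik_c = NA_real_,
                        contribution = NA_real_,
                        significant_05 = FALSE, significant_bonferroni = FALSE,
                        error = NA_character_)
      res <- tryCatch({
        sub <- .complete_subset(traits, c(y, x))
        u <- fit_ols(model_spec(y, x), sub)
        c_ <- fit_gls(model_spec(y, x), sub, P, D, mode = mode)
        cu <- u$coefficients[u$coefficients$term == x, ]
        cc_ <- c_$coefficients[c_$coefficients$term == x, ]
        row$n <- u$n
        row[c("beta_u", "se_u", "t_u", "p_u")] <-
          cu[c("beta", "se", "t", "p")]
        row$logLik_u <- u$logLik
        row[c("beta_c", "se_c", "t_c", "p_c")] <-
          cc_[c("beta", "se", "t", "p")]
        row$logLik_c <- c_$logLik
        row$contribution <- autocorrelation_contribution(c_, u)
        row$significant_05 <- row$p_c < alpha
        row$significant_bonferroni <- row$p_c < 0.05 / bonferroni_m
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  sig <- tab[!is.na(tab$p_c) & tab$p_c < alpha, c("y", "x"), drop = FALSE]
  retained <- intersect(cultural_vars, unique(sig$y))
  list(table = tab, retained = retained,
       dropped = setdiff(cultural_vars, retained),
       significant_pairs = sig, alpha = alpha, bonferroni_m = bonferroni_m)
}

#' Stage 2: does the exposure explain focal variation beyond covariation?
#'
#' For each retained focal variable, Model 1 is a corrected GLS on its
#' significantly correlated focal covariates (from the Kendall screen);
#' Model 2 adds the exposure measure.  A likelihood-ratio test (df = 1)
#' decides whether the exposure adds explanatory power.  Only
#' combinations already significant at stage 1 (and in the screen) are
#' tested; a variable with no significant focal covariates passes through
#' untested.
#'
#' @inheritParams stage1_univariate
#' @param retained_vars focal variables surviving stage 1.
#' @param screen a [kendall_screen()] over the focal variables.
#' @param significant_pairs stage-1 `significant_pairs` data.frame.
#' @param screen_alpha significance gate on the screen (default 0.05).
#' @return list with `table`, `retained`, `dropped`,
#'   `significant_pairs` (surviving y/x combinations).
#' @export
stage2_covariation <- function(traits, P, D, retained_vars, parasite_vars,
                               screen, significant_pairs, alpha = 0.05,
                               screen_alpha = 0.05, mode = "nugget") {
  rows <- list()
  surviving <- list()
  for (y in retained_vars) {
    others <- setdiff(retained_vars, y)
    covs <- others[!is.na(screen$p[y, others]) &
                     screen$p[y, others] < screen_alpha]
    xs <- significant_pairs$x[significant_pairs$y == y]
    if (length(covs) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        y = y, x = NA_character_, covariates = "", n = NA_integer_,
        logLik_m1 = NA_real_, logLik_m2 = NA_real_, LR = NA_real_,
        p = NA_real_, significant = NA, note = "no covariates; untested")
      surviving[[y]] <- data.frame(y = y, x = xs)
      next
    }
    any_sig <- FALSE
    kept_x <- character(0)
    for (x in xs) {
      res <- tryCatch(
        .fit_nested_pair(traits, P, D, y, covs, x, mode),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          y = y, x = x, covariates = paste(covs, collapse = "+"),
          n = NA_integer_, logLik_m1 = NA_real_, logLik_m2 = NA_real_,
          LR = NA_real_, p = NA_real_, significant = NA,
          note = conditionMessage(res))
        next
      }
      sig <- res$lrt$p < alpha
      rows[[length(rows) + 1]] <- data.frame(
        y = y, x = x, covariates = paste(covs, collapse = "+"),
        n = res$m1$n, logLik_m1 = res$m1$logLik, logLik_m2 = res$m2$logLik,
        LR = res$lrt$LR, p = res$lrt$p, significant = sig, note = "")
      if (isTRUE(sig)) {
        any_sig <- TRUE
        kept_x <- c(kept_x, x)
      }
    }
    if (any_sig) surviving[[y]] <- data.frame(y = y, x = kept_x)
  }
  tab <- do.call(rbind, rows)
  retained <- names(surviving)
  sig <- if (length(surviving)) do.call(rbind, surviving) else
    data.frame(y = character(0), x = character(0))
  rownames(sig) <- NULL
  list(table = tab, retained = retained,
       dropped = setdiff(retained_vars, retained),
       significant_pairs = sig, alpha = alpha)
}

#' Stage 3: races against external covariate sets
#'
#' Two configurable races per retained focal variable and exposure
#' measure: (a) a likelihood-ratio test of covariates-only versus
#' covariates + exposure, and (b) an AIC comparison of the covariate-link
#' model (`y ~ covariates`) against the direct exposure-link model
#' (`y ~ exposure`), with delta-AIC computed as
#' `AIC(exposure model) - AIC(covariate model)` so values above
#' `aic_threshold` favour the covariate explanation.  The verdict per
#' focal variable is `"parasite retained"` only if, for some exposure
#' measure, no covariate set explains the association under either race;
#' otherwise `"explained by <set>"`.  Pairs whose best race is within the
#' AIC threshold are flagged as having equivalent explanatory power.
#'
#' @inheritParams stage2_covariation
#' @param covariate_sets named list of character vectors (each a set of
#'   covariate column names); an empty list reduces the stage to the
#'   incoming result (all exposures retained).
#' @param aic_threshold delta-AIC decision threshold (default 2).
#' @return list with `lrt_table`, `aic_table`, `verdicts` (data.frame
#'   y / verdict / detail).
#' @export
stage3_external <- function(traits, P, D, retained_vars, parasite_vars,
                            significant_pairs, covariate_sets,
                            alpha = 0.05, aic_threshold = 2,
                            mode = "nugget") {
  lrt_rows <- list()
  aic_rows <- list()
  verdicts <- list()
  for (y in retained_vars) {
    xs <- unique(significant_pairs$x[significant_pairs$y == y])
    if (length(covariate_sets) == 0) {
      verdicts[[y]] <- data.frame(
        y = y, verdict = "parasite retained",
        detail = "no covariate sets configured", equivalent = FALSE)
      next
    }
    x_explained <- setNames(rep(FALSE, length(xs)), xs)
    x_detail <- setNames(rep("", length(xs)), xs)
    x_equiv <- setNames(rep(FALSE, length(xs)), xs)
    for (x in xs) {
      for (set_name in names(covariate_sets)) {
        covs <- covariate_sets[[set_name]]
        # (a) LRT: does the exposure add signal beyond the covariates?
        res <- tryCatch(
          .fit_nested_pair(traits, P, D, y, covs, x, mode),
          error = function(e) e)
        if (!inherits(res, "error")) {
          sig <- res$lrt$p < alpha
          lrt_rows[[length(lrt_rows) + 1]] <- data.frame(
            y = y, x = x, covariate_set = set_name,
            covariates = paste(covs, collapse = "+"), n = res$m1$n,
            logLik_m1 = res$m1$logLik, logLik_m2 = res$m2$logLik,
            LR = res$lrt$LR, p = res$lrt$p, significant = sig)
          if (!sig && !x_explained[x]) {
            x_explained[x] <- TRUE
            x_detail[x] <- paste0("explained by ", set_name, " (LRT)")
          }
        }
        # (b) AIC race: covariate-link vs exposure-link model
        aic_res <- tryCatch({
          vars <- unique(c(y, covs, x))
          sub <- .complete_subset(traits, vars)
          m_cov <- fit_gls(model_spec(y, covs), sub, P, D, mode = mode)
          m_par <- fit_gls(model_spec(y, x), sub, P, D, mode = mode)
          d_aic <- m_par$AIC - m_cov$AIC
          data.frame(y = y, x = x, covariate_set = set_name,
                     covariates = paste(covs, collapse = "+"), n = m_cov$n,
                     AIC_cov = m_cov$AIC, AIC_par = m_par$AIC,
                     delta_AIC = d_aic,
                     covariate_better = d_aic > aic_threshold,
                     equivalent = abs(d_aic) <= aic_threshold)
        }, error = function(e) NULL)
        if (!is.null(aic_res)) {
          aic_rows[[length(aic_rows) + 1]] <- aic_res
          if (aic_res$covariate_better && !x_explained[x]) {
            x_explained[x] <- TRUE
            x_detail[x] <- paste0("explained by ", set_name, " (AIC)")
          }
          if (aic_res$equivalent) x_equiv[x] <- TRUE
        }
      }
    }
    if (all(x_explained)) {
      verdicts[[y]] <- data.frame(
        y = y, verdict = "explained by covariates",
        detail = paste(unique(x_detail[x_detail != ""]), collapse = "; "),
        equivalent = any(x_equiv))
    } else {
      kept <- names(x_explained)[!x_explained]
      verdicts[[y]] <- data.frame(
        y = y, verdict = "parasite retained",
        detail = paste0("retained for ", paste(kept, collapse = ", ")),
        equivalent = any(x_equiv[kept]))
    }
  }
  list(lrt_table = if (length(lrt_rows)) do.call(rbind, lrt_rows) else NULL,
       aic_table = if (length(aic_rows)) do.call(rbind, aic_rows) else NULL,
       verdicts = if (length(verdicts)) do.call(rbind, verdicts) else
         data.frame(y = character(0), verdict = character(0),
                    detail = character(0), equivalent = logical(0)),
       alpha = alpha, aic_threshold = aic_threshold)
}

#' Prune covariates of the exposure variable itself
#'
#' Fits `exposure ~ base + extras` and tests, by likelihood ratio,
#' whether removing each extra (or all extras) significantly decreases
#' the fit — i.e. whether the covariate explains variation in the
#' exposure beyond the base gradient (typically latitude).
#'
#' @inheritParams stage1_univariate
#' @param exposure exposure (parasite-load) column name.
#' @param base character vector, always-included covariates.
#' @param extras character vector of candidate covariates to prune.
#' @return data.frame with one LRT row per removal.
#' @export
prune_covariates <- function(traits, P, D, exposure, base, extras,
                             alpha = 0.05, mode = "nugget") {
  rows <- list()
  vars <- unique(c(exposure, base, extras))
  sub <- .complete_subset(traits, vars)
  full <- fit_gls(model_spec(exposure, c(base, extras)), sub, P, D,
                  mode = mode)
  drops <- c(list(all = extras), as.list(setNames(extras, extras)))
  for (nm in names(drops)) {
    rem <- setdiff(c(base, extras), drops[[nm]])
    red <- fit_gls(model_spec(exposure, rem), sub, P, D, mode = mode)
    lrt <- lr_test(red, full, df = length(drops[[nm]]))
    rows[[length(rows) + 1]] <- data.frame(
      removed = nm, model_full = paste(c(base, extras), collapse = "+"),
      model_reduced = paste(rem, collapse = "+"), n = full$n,
      logLik_full = full$logLik, logLik_reduced = red$logLik,
      LR = lrt$LR, df = lrt$df, p = lrt$p, significant = lrt$p < alpha)
  }
  do.call(rbind, rows)
}

#' Run the full winnowing pipeline
#'
#' Executes stages 1-3 with the drop-forward rule: a variable dropped at
#' any stage is never fitted again.  Deterministic given its inputs.
#'
#' @param config named list with elements `traits`, `P`, `D`,
#'   `cultural_vars`, `parasite_vars`, `covariate_sets` (named list;
#'   may be empty), and optionally `alpha` (0.05), `screen_alpha` (0.05),
#'   `bonferroni_m`, `aic_threshold` (2), `mode` ("nugget").
#' @return object of class `cc_winnow_report`: per-stage tables, a status
#'   trail with one row per focal variable, and the final retained set.
#' @export
run_winnow <- function(config) {
  need <- c("traits", "P", "D", "cultural_vars", "parasite_vars")
  if (!all(need %in% names(config))) {
    stop("config must contain: ", paste(need, collapse = ", "))
  }
  alpha <- config$alpha %||% 0.05
  screen_alpha <- config$screen_alpha %||% 0.05
  aic_threshold <- config$aic_threshold %||% 2
  mode <- config$mode %||% "nugget"
  covariate_sets <- config$covariate_sets %||% list()
  cultural <- config$cultural_vars
  parasite <- config$parasite_vars

  nvar <- length(cultural)
  trail <- data.frame(variable = as.character(cultural),
                      status = rep("retained", nvar),
                      stage_dropped = rep(NA_integer_, nvar),
                      dropped_by = rep(NA_character_, nvar),
                      verdict = rep(NA_character_, nvar))
  if (length(cultural) == 0) {
    return(structure(list(stage1 = NULL, screen = NULL, stage2 = NULL,
                          stage3 = NULL, trail = trail,
                          retained = character(0), config = config),
                     class = "cc_winnow_report"))
  }

  s1 <- stage1_univariate(config$traits, config$P, config$D, cultural,
                          parasite, alpha = alpha,
                          bonferroni_m = config$bonferroni_m, mode = mode)
  trail$status[trail$variable %in% s1$dropped] <- "dropped"
  trail$stage_dropped[trail$variable %in% s1$dropped] <- 1L
  trail$dropped_by[trail$variable %in% s1$dropped] <-
    "no significant corrected association"

  screen <- if (length(s1$retained) >= 2) {
    kendall_screen(config$traits, s1$retained)
  } else NULL

  s2 <- if (length(s1$retained) >= 1 && !is.null(screen)) {
    stage2_covariation(config$traits, config$P, config$D, s1$retained,
                       parasite, screen, s1$significant_pairs,
                       alpha = alpha, screen_alpha = screen_alpha,
                       mode = mode)
  } else if (length(s1$retained) == 1) {
    # single survivor: nothing to covary with, passes through untested
    list(table = NULL, retained = s1$retained,
         dropped = character(0),
         significant_pairs = s1$significant_pairs)
  } else {
    list(table = NULL, retained = character(0), dropped = character(0),
         significant_pairs = s1$significant_pairs[0, ])
  }
  trail$status[trail$variable %in% s2$dropped] <- "dropped"
  trail$stage_dropped[trail$variable %in% s2$dropped] <- 2L
  trail$dropped_by[trail$variable %in% s2$dropped] <-
    "explained by covariation with other focal variables"

  s3 <- if (length(s2$retained) >= 1) {
    stage3_external(config$traits, config$P, config$D, s2$retained,
                    parasite, s2$significant_pairs, covariate_sets,
                    alpha = alpha, aic_threshold = aic_threshold,
                    mode = mode)
  } else {
    list(lrt_table = NULL, aic_table = NULL,
         verdicts = data.frame(y = character(0), verdict = character(0),
                               detail = character(0),
                               equivalent = logical(0)))
  }
  for (i in seq_len(nrow(s3$verdicts))) {
    v <- s3$verdicts[i, ]
    trail$verdict[trail$variable == v$y] <- v$verdict
    if (v$verdict != "parasite retained") {
      trail$status[trail$variable == v$y] <- "dropped"
      trail$stage_dropped[trail$variable == v$y] <- 3L
      trail$dropped_by[trail$variable == v$y] <- v$detail
    }
  }
  retained <- trail$variable[trail$status == "retained"]

  structure(list(stage1 = s1, screen = screen, stage2 = s2, stage3 = s3,
                 trail = trail, retained = retained, config = config),
            class = "cc_winnow_report")
}

#' @export
print.cc_winnow_report <- function(x, ...) {
  cat("Winnowing report\n")
  print(x$trail)
  cat("final retained:",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
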