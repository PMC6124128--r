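#' Specify a regression model
#'
#' Light-weight container naming the response and predictors of a single
#' regression on the trait table.
#'
#' @param response character, response variable name.
#' @param predictors character vector of predictor names (may be empty
#'   for an intercept-only model).
#' @param intercept logical, include an intercept (default TRUE).
#' @return an object of class `cc_model_spec`.
#' @export
model_spec <- function(response, predictors = character(0), intercept = TRUE) {
  stopifnot(is.character(response), length(response) == 1)
  predictors <- as.character(predictors)
  if (response %in% predictors) {
    stop("response '", response, "' cannot also be a predictor")
  }
  structure(list(response = response, predictors = predictors,
                 intercept = isTRUE(intercept)),
            class = "cc_model_spec")
}

#' Covariance model for GLS residuals
#'
#' The residual covariance is `sigma2 * V` with
#' `V = w_p P + w_s S + (1 - w_p - w_s) I` in `"nugget"` mode (white-noise
#' component completes the mixture, so ordinary least squares is nested at
#' `w_p = w_s = 0`), or `V = w_p P + (1 - w_p) S` in `"paper"` mode (no
#' identity component; the two structured similarities exhaust the
#' mixture, and the corrected model is *not* nested over OLS).
#'
#' @param w_p phylogenetic weight, >= 0.
#' @param w_s spatial weight, >= 0 (in `"paper"` mode forced to
#'   `1 - w_p`).
#' @param sigma_s spatial length-scale, km.
#' @param sigma2 residual scale.
#' @param mode `"nugget"` (default) or `"paper"`.
#' @return an object of class `cc_cov_model`.
#' @export
cov_model <- function(w_p, w_s, sigma_s, sigma2 = 1, mode = c("nugget", "paper")) {
  mode <- match.arg(mode)
  if (w_p < 0 || w_s < 0) stop("weights must be non-negative")
  if (mode == "nugget") {
    if (w_p + w_s > 1 + 1e-12) {
      stop("weights outside simplex: w_p + w_s must be <= 1 in nugget mode")
    }
  } else {
    if (abs(w_p + w_s - 1) > 1e-9) {
      stop("in paper mode w_p + w_s must equal 1")
    }
  }
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (sigma_s <= 0) stop("sigma_s must be > 0")
  structure(list(w_p = w_p, w_s = w_s, sigma_s = sigma_s,
                 sigma2 = sigma2, mode = mode),
            class = "cc_cov_model")
}

#' Assemble the residual correlation-structure matrix
#'
#' Mixes phylogenetic similarity `P`, spatial kernel `S` and (in nugget
#' mode) the identity, according to a [cov_model()].
#'
#' @param P phylogenetic similarity matrix.
#' @param S spatial kernel matrix (same societies, same order).
#' @param cov a [cov_model()].
#' @param repair logical; eigenvalue-floor repair if indefinite.
#' @return correlation-structure matrix with unit diagonal.
#' @export
assemble_covariance <- function(P, S, cov, repair = TRUE) {
  stopifnot(inherits(cov, "cc_cov_model"))
  if (!all(dim(P) == dim(S))) stop("dimension mismatch between P and S")
  n <- nrow(P)
  if (cov$mode == "nugget") {
    w_n <- 1 - cov$w_p - cov$w_s
    V <- cov$w_p * P + cov$w_s * S + diag(w_n, n)
  } else {
    V <- cov$w_p * P + (1 - cov$w_p) * S
  }
  if (repair) {
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      V <- psd_repair(V)
      if (isTRUE(attr(V, "psd_repaired"))) V <- stats::cov2cor(V)
    }
  }
  dimnames(V) <- dimnames(P)
  V
}

#' Profile (concentrated) GLS log-likelihood
#'
#' For fixed correlation structure `V`, the ML estimates are available in
#' closed form: `beta = (X'V^-1 X)^-1 X'V^-1 y`, `sigma2 = r'V^-1 r / n`
#' (ML, not REML), and the log-likelihood is the multivariate-normal log
#' density at `(beta, sigma2 V)`.  Standard errors are
#' `sqrt(sigma2 * diag((X'V^-1 X)^-1))`, t statistics `beta / se`, and
#' two-sided p-values use `n - k` degrees of freedom.
#'
#' @param y numeric response vector (no missing values).
#' @param X design matrix, `n x k`.
#' @param V correlation-structure matrix (repaired SPD).
#' @return list with `beta`, `se`, `t`, `p`, `sigma2`, `logLik`, `n`, `k`.
#' @export
gls_profile_loglik <- function(y, X, V) {
  n <- length(y)
  X <- as.matrix(X)
  k <- ncol(X)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  if (n <= k) stop("need more observations than coefficients (n > k)")
  ch <- .chol_or_repair(V) # upper triangular, V = t(ch) %*% ch
  A <- forwardsolve(t(ch), X)
  b <- forwardsolve(t(ch), y)
  qa <- qr(A)
  if (qa$rank < k) {
    bad <- colnames(X)[-seq_len(qa$rank)]
    stop("design matrix is collinear (rank ", qa$rank, " < ", k,
         "); check columns: ", paste(bad, collapse = ", "))
  }
  R <- qr.R(qa)
  if (kappa(R, exact = FALSE) > 1e10) {
    stop("design matrix is ill-conditioned; check columns: ",
         paste(colnames(X), collapse = ", "))
  }
  beta <- qr.coef(qa, b)
  r <- b - A %*% beta
  rss <- sum(r^2)
  sigma2 <- rss / n
  if (sigma2 < 1e-12) {
    warning("residual scale at floor (near-exact fit); log-likelihood is ",
            "evaluated at sigma2 = 1e-12")
    sigma2 <- 1e-12
  }
  logdetV <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetV + rss / sigma2)
  XtViX_inv <- chol2inv(R)
  se <- sqrt(pmax(sigma2 * diag(XtViX_inv), 0))
  tval <- as.numeric(beta) / se
  pval <- .t_pvalue(tval, n - k)
  list(beta = setNames(as.numeric(beta), colnames(X)),
       se = setNames(se, colnames(X)),
       t = setNames(tval, colnames(X)),
       p = setNames(pval, colnames(X)),
       sigma2 = sigma2, logLik = ll, n = n, k = k)
}

# lean profile log-likelihood for the inner optimization loop: no
# standard errors, no condition diagnostics (the final fit re-evaluates
# through gls_profile_loglik, which has them)
.profile_ll_fast <- function(y, X, V) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    V <- psd_repair(V)
    ch <- chol(V + diag(1e-10, n))
  }
  A <- backsolve(ch, X, transpose = TRUE)
  b <- backsolve(ch, y, transpose = TRUE)
  M <- crossprod(A)
  beta <- tryCatch(solve(M, crossprod(A, b)), error = function(e) NULL)
  if (is.null(beta)) return(-Inf)
  r <- b - A %*% beta
  sigma2 <- max(sum(r^2) / n, 1e-12)
  -0.5 * (n * log(2 * pi) + n * log(sigma2) + 2 * sum(log(diag(ch))) +
            sum(r^2) / sigma2)
}

# --- internal: build y, X and aligned matrices from a trait table -------

.build_design <- function(spec, traits, id_col = "society_id") {
  stopifnot(inherits(spec, "cc_model_spec"))
  vars <- c(spec$response, spec$predictors)
  missing_vars <- setdiff(vars, names(traits))
  if (length(missing_vars)) {
    stop("variables not in trait table: ", paste(missing_vars, collapse = ", "))
  }
  sub <- traits[, c(id_col, vars), drop = FALSE]
  keep <- complete.cases(sub)
  sub <- sub[keep, , drop = FALSE]
  y <- as.numeric(sub[[spec$response]])
  if (length(spec$predictors)) {
    f <- as.formula(paste("~", paste(spec$predictors, collapse = " + ")))
    X <- model.matrix(f, data = sub)
    if (!spec$intercept) X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  } else {
    X <- matrix(1, nrow(sub), 1, dimnames = list(NULL, "(Intercept)"))
    if (!spec$intercept) stop("model with no predictors needs an intercept")
  }
  list(y = y, X = X, ids = as.character(sub[[id_col]]))
}

# fixed multi-start grid over (structured weight u, phylo share v,
# length-scale fraction f); a quasi-spread design, not random
.start_grid <- matrix(c(
  0.50, 0.50, 0.50,
  0.25, 0.75, 0.25,
  0.75, 0.25, 0.75,
  0.20, 0.20, 0.85,
  0.85, 0.80, 0.15
), ncol = 3, byrow = TRUE, dimnames = list(NULL, c("u", "v", "f")))

#' Fit a GLS regression with phylogenetic + spatial residual covariance
#'
#' Maximizes the profile log-likelihood over the covariance parameters
#' (`w_p`, `w_s`, spatial length-scale `sigma_s`) with a derivative-free
#' simplex search (Nelder-Mead) restarted from five fixed grid points over
#' the weight simplex and a log-spaced length-scale range
#' `[1, 2 * max(D)]` km.  Coefficients and residual scale are profiled
#' out in closed form at every step.  Rows with missing response or
#' predictors are dropped listwise.
#'
#' @param spec a [model_spec()].
#' @param traits trait table (data.frame with `society_id` column).
#' @param P phylogenetic similarity matrix (dimnames = society ids).
#' @param D great-circle distance matrix in km (dimnames = society ids).
#' @param mode `"nugget"` or `"paper"` (see [cov_model()]).
#' @param fix optional named list fixing any of `w_p`, `w_s`, `sigma_s`;
#'   if all three are fixed no optimization is performed.
#' @param n_starts number of multi-starts (default 5).
#' @param control passed to [stats::optim()] (defaults: `reltol = 1e-8`,
#'   `maxit = 1000`).
#' @param min_n minimum complete cases (default 10).
#' @return object of class `cc_gls_fit`: coefficient table, `logLik`,
#'   `AIC`, fitted [cov_model()], convergence record.
#' @export
fit_gls <- function(spec, traits, P, D, mode = c("nugget", "paper"),
                    fix = NULL, n_starts = 5, control = list(), min_n = 10) {
  mode <- match.arg(mode)
  dat <- .build_design(spec, traits)
  n <- length(dat$y)
  if (n < min_n) {
    stop("only ", n, " complete cases; need at least ", min_n)
  }
  if (!all(dat$ids %in% rownames(P)) || !all(dat$ids %in% rownames(D))) {
    stop("society ids in trait table missing from P or D")
  }
  Psub <- P[dat$ids, dat$ids]
  Dsub <- D[dat$ids, dat$ids]
  max_d <- max(Dsub)
  s_lo <- 1
  s_hi <- max(2 * max_d, 2)
  ctrl <- modifyList(list(reltol = 1e-8, maxit = 1000), control)

  fix <- as.list(fix)
  fixed_all <- all(c("w_p", "w_s", "sigma_s") %in% names(fix))

  # parameter transforms: u = total structured weight, v = phylo share
  par_to_cov <- function(z) {
    if (mode == "nugget") {
      u <- stats::plogis(z[1])
      v <- stats::plogis(z[2])
      w_p <- u * v
      w_s <- u * (1 - v)
    } else {
      w_p <- stats::plogis(z[2])
      w_s <- 1 - w_p
    }
    sig <- s_lo * (s_hi / s_lo)^stats::plogis(z[3])
    if (!is.null(fix$w_p)) w_p <- fix$w_p
    if (!is.null(fix$w_s)) w_s <- fix$w_s
    if (!is.null(fix$sigma_s)) sig <- fix$sigma_s
    if (mode == "nugget" && w_p + w_s > 1) { # can occur with partial fixing
      tot <- w_p + w_s
      w_p <- w_p / tot
      w_s <- w_s / tot
    }
    list(w_p = unname(w_p), w_s = unname(w_s), sigma_s = unname(sig))
  }
  build_V <- function(cv) {
    S <- exp(-(Dsub / cv$sigma_s)^2)
    if (mode == "nugget") {
      cv$w_p * Psub + cv$w_s * S + diag(1 - cv$w_p - cv$w_s, n)
    } else {
      cv$w_p * Psub + (1 - cv$w_p) * S
    }
  }
  eval_at <- function(cv) gls_profile_loglik(dat$y, dat$X, build_V(cv))
  neg_ll <- function(z) {
    cv <- par_to_cov(z)
    ll <- tryCatch(.profile_ll_fast(dat$y, dat$X, build_V(cv)),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  if (fixed_all) {
    cv <- par_to_cov(c(0, 0, 0))
    best <- list(par = c(0, 0, 0), value = -Inf)
    restarts <- data.frame(start = 0L, value = NA_real_, convergence = 0L)
  } else {
    starts <- .start_grid[seq_len(min(n_starts, nrow(.start_grid))), ,
                          drop = FALSE]
    best <- NULL
    restarts <- data.frame(start = integer(0), value = numeric(0),
                           convergence = integer(0))
    for (i in seq_len(nrow(starts))) {
      z0 <- c(stats::qlogis(starts[i, "u"]), stats::qlogis(starts[i, "v"]),
              stats::qlogis(starts[i, "f"]))
      opt <- tryCatch(
        optim(z0, neg_ll, method = "Nelder-Mead", control = ctrl),
        error = function(e) NULL)
      if (is.null(opt)) next
      restarts <- rbind(restarts,
                        data.frame(start = i, value = -opt$value,
                                   convergence = opt$convergence))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (is.null(best) || !is.finite(best$value) || best$value >= 1e10) {
      stop("all restarts failed to converge; best objective: ",
           if (is.null(best)) "none" else -best$value)
    }
    cv <- par_to_cov(best$par)
  }

  res <- eval_at(cv)
  n_cov_free <- 1 + # sigma2
    (if (mode == "nugget") 3 else 2) -
    sum(c("w_p", "w_s", "sigma_s") %in% names(fix) &
          c(TRUE, mode == "nugget", TRUE))
  aic <- 2 * (res$k + n_cov_free) - 2 * res$logLik
  structure(list(
    spec = spec,
    coefficients = data.frame(term = names(res$beta), beta = res$beta,
                              se = res$se, t = res$t, p = res$p,
                              row.names = NULL),
    n = res$n, k = res$k, df = res$n - res$k,
    logLik = res$logLik, AIC = aic, n_cov_free = n_cov_free,
    cov = cov_model(cv$w_p, cv$w_s, cv$sigma_s, res$sigma2, mode),
    corrected = TRUE, ids = dat$ids,
    restarts = restarts
  ), class = "cc_gls_fit")
}

#' Ordinary least squares (uncorrected) fit
#'
#' The `V = I` special case: every society treated as an independent
#' observation.  Variance is the ML estimate (divide by `n`), so the
#' log-likelihood is directly comparable with [fit_gls()].
#'
#' @inheritParams fit_gls
#' @return object of class `cc_gls_fit` with `corrected = FALSE`.
#' @export
fit_ols <- function(spec, traits, min_n = NULL) {
  dat <- .build_design(spec, traits)
  n <- length(dat$y)
  k <- ncol(dat$X)
  if (is.null(min_n)) min_n <- k + 2
  if (n < min_n) stop("only ", n, " complete cases; need at least ", min_n)
  res <- gls_profile_loglik(dat$y, dat$X, diag(n))
  aic <- 2 * (res$k + 1) - 2 * res$logLik
  structure(list(
    spec = spec,
    coefficients = data.frame(term = names(res$beta), beta = res$beta,
                              se = res$se, t = res$t, p = res$p,
                              row.names = NULL),
    n = res$n, k = res$k, df = res$n - res$k,
    logLik = res$logLik, AIC = aic, n_cov_free = 1,
    cov = NULL, corrected = FALSE, ids = dat$ids,
    restarts = NULL
  ), class = "cc_gls_fit")
}

#' @export
print.cc_gls_fit <- function(x, ...) {
  cat(if (x$corrected) "Corrected (phylo + spatial) GLS fit"
      else "Uncorrected (OLS) fit",
      sprintf("  [n = %d, logLik = %.3f, AIC = %.3f]\n", x$n, x$logLik, x$AIC))
  cat(sprintf("%s ~ %s\n", x$spec$response,
              if (length(x$spec$predictors))
                paste(x$spec$predictors, collapse = " + ") else "1"))
  print(x$coefficients, digits = 4)
  if (!is.null(x$cov)) {
    cat(sprintf("covariance (%s): w_p = %.3f, w_s = %.3f, sigma_s = %.0f km, sigma2 = %.4g\n",
                x$cov$mode, x$cov$w_p, x$cov$w_s, x$cov$sigma_s, x$cov$sigma2))
  }
  invisible(x)
}

#' Contribution of autocorrelation to model fit
#'
#' `1 - logLik(corrected) / logLik(uncorrected)`.  Positive values mean
#' the corrected model fits better (log-likelihoods are negative in
#' practice); negative values indicate a worse fit of the constrained
#' covariance, which can occur in `"paper"` mode where OLS is not nested.
#'
#' @param logLik_corrected,logLik_uncorrected log-likelihoods (numbers or
#'   `cc_gls_fit` objects).
#' @return dimensionless statistic.
#' @export
#' @examples
#' autocorrelation_contribution(-13.202, -17.734) # 0.256
autocorrelation_contribution <- function(logLik_corrected, logLik_uncorrected) {
  lc <- if (inherits(logLik_corrected, "cc_gls_fit"))
    logLik_corrected$logLik else logLik_corrected
  lu <- if (inherits(logLik_uncorrected, "cc_gls_fit"))
    logLik_uncorrected$logLik else logLik_uncorrected
  if (lu == 0) stop("uncorrected log-likelihood is zero; statistic undefined")
  1 - lc / lu
}
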