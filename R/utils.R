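# Internal numerical helpers shared by the similarity/covariance code.

# Floor used when repairing indefinite similarity matrices.  Gaussian
# kernels of geodesic (great-circle) distance are not guaranteed positive
# definite on the sphere, and tree matrices with near-tied tips can be close
# to singular; eigenvalues below this are raised to it.
.psd_floor <- 1e-8

#' Repair a symmetric matrix to positive semi-definiteness
#'
#' Eigenvalues below a small floor are raised to the floor and the matrix
#' reassembled.  Used on the spatial kernel and on assembled residual
#' correlation matrices before Cholesky factorization; the repair is a
#' numerical safeguard, not a model component, and is recorded via the
#' `"psd_repaired"` attribute so callers can log it.
#'
#' @param M symmetric numeric matrix.
#' @param floor eigenvalue floor (default 1e-8).
#' @return the repaired matrix, with attribute `psd_repaired = TRUE` when a
#'   repair actually happened (and `min_eigen`, the offending eigenvalue).
#' @export
psd_repair <- function(M, floor = .psd_floor) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= floor) {
    return(M)
  }
  vals <- pmax(e$values, floor)
  R <- e$vectors %*% (vals * t(e$vectors))
  R <- (R + t(R)) / 2
  attr(R, "psd_repaired") <- TRUE
  attr(R, "min_eigen") <- min(e$values)
  R
}

# Cheap positive-definiteness gate: try Cholesky, fall back to the
# eigenvalue repair only when it fails.  Returns the Cholesky factor.
.chol_or_repair <- function(V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    V <- psd_repair(V, floor = .psd_floor)
    # after flooring the matrix is PD up to roundoff; nudge if needed
    ch <- tryCatch(chol(V), error = function(e) chol(V + diag(1e-10, nrow(V))))
  }
  ch
}

# stable two-sided t-test p-value
.t_pvalue <- function(tval, df) 2 * pt(abs(tval), df = df, lower.tail = FALSE)
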