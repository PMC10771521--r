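#' Fisher r-to-z transformation
#'
#' Transforms Pearson correlations to the variance-stabilising z scale,
#' \code{z = atanh(r)}. Correlations at or beyond +/-1 (possible for, e.g.,
#' noise-free agreement between identical rating vectors) are clipped to
#' +/-(1 - 1e-12) with a warning, so the transform stays finite.
#'
#' @param r numeric vector of correlations, |r| <= 1.
#' @return numeric vector of z values.
#' @seealso [fisher_z_inverse()]
#' @export
fisher_z <- function(r) {
  stopifnot(is.numeric(r))
  if (any(abs(r[is.finite(r)]) > 1 + 1e-8)) {
    stop("fisher_z: |r| > 1")
  }
  clip <- is.finite(r) & abs(r) >= 1
  if (any(clip)) {
    warning(sprintf("fisher_z: %d correlation(s) at |r| = 1 clipped", sum(clip)))
    r[clip] <- sign(r[clip]) * (1 - 1e-12)
  }
  atanh(r)
}

#' Inverse Fisher transformation
#'
#' @param z numeric vector of Fisher z values.
#' @return correlations, \code{tanh(z)}.
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Expected overlap of two random samples from a finite registry
#'
#' For two samples of sizes \code{n1} and \code{n2} drawn at random without
#' replacement from the same population of size \code{N}, the number of
#' individuals present in both samples is hypergeometric with expectation
#' \code{n1 * n2 / N}. Used to argue that two twin samples drawn from a large
#' registry are unlikely to overlap much.
#'
#' @param n1,n2 sample sizes.
#' @param N population size, \code{N >= max(n1, n2)}.
#' @return expected number of shared individuals.
#' @export
expected_sample_overlap <- function(n1, n2, N) {
  stopifnot(n1 >= 0, n2 >= 0, N >= n1, N >= n2, N > 0)
  n1 * n2 / N
}

# Symmetry / PSD checks used by simulation configs and model specs.
check_psd <- function(m, name = "matrix", tol = 1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    stop(sprintf("%s must be symmetric", name))
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop(sprintf("%s is not positive semi-definite (min eigenvalue %.3g)", name, min(ev)))
  }
  invisible(TRUE)
}

# Correlation matrix from a covariance matrix; tolerates zero variances.
cov2cor_safe <- function(m) {
  s <- sqrt(diag(m))
  s[s == 0] <- NA_real_
  m / tcrossprod(s)
}
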