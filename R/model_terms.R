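#' First-order autoregressive correlation matrix
#'
#' Entry (i, j) is `rho^|i - j|` — the separable building block of the
#' AR1xAR1 spatial residual structure along field rows and columns.
#'
#' @param n dimension (number of rows or columns).
#' @param rho autocorrelation, strictly inside `(-1, 1)`.
#' @return n x n positive-definite correlation matrix.
#' @export
ar1_correlation <- function(n, rho) {
  stopifnot(n >= 1)
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  idx <- seq_len(n)
  rho^abs(outer(idx, idx, "-"))
}

#' Factor-analytic covariance matrix
#'
#' The between-environment genetic covariance `Go = Lambda Lambda' +
#' diag(Psi)`, with environment loadings `Lambda` on `m` latent factors and
#' environment-specific variances `Psi`.
#'
#' @param Lambda k x m loading matrix (a vector is taken as one column).
#' @param Psi length-k vector of nonnegative specific variances.
#' @return k x k symmetric positive semi-definite matrix.
#' @export
fa_covariance <- function(Lambda, Psi) {
  Lambda <- as.matrix(Lambda)
  if (length(Psi) != nrow(Lambda)) stop("Psi length must equal nrow(Lambda)")
  if (any(Psi < 0)) stop("Psi must be nonnegative")
  tcrossprod(Lambda) + diag(as.numeric(Psi), nrow(Lambda))
}

#' Genetic correlation matrix from a genetic covariance matrix
#'
#' @param Go k x k genetic covariance matrix with positive diagonal.
#' @return k x k correlation matrix with unit diagonal.
#' @export
genetic_correlations <- function(Go) {
  Go <- as.matrix(Go)
  d <- diag(Go)
  if (any(d <= 0)) stop("Go has a zero or negative diagonal entry")
  R <- Go / sqrt(outer(d, d))
  diag(R) <- 1
  R
}

#' Plot-level heritability of an environment
#'
#' `h2_k = sigma2_g(k) / (sigma2_g(k) + sigma2_e(k))`, with the genetic
#' variance taken from the diagonal of the fitted between-environment
#' covariance and the residual (spatial) variance of the same environment.
#'
#' @param varcomp variance components of a [megblup()] fit (`fit$varcomp`),
#'   or any list with elements `Go` and `resid_var`.
#' @param env environment name or index; `NULL` returns all environments.
#' @return named vector of heritabilities in `[0, 1]`.
#' @export
plot_heritability <- function(varcomp, env = NULL) {
  if (inherits(varcomp, "megblup")) varcomp <- varcomp$varcomp
  g <- diag(as.matrix(varcomp$Go))
  e <- varcomp$resid_var
  if (length(e) == 1) e <- rep(e, length(g))
  denom <- g + e
  h2 <- ifelse(denom > 0, g / denom, 0)
  if (any(denom == 0)) warning("zero total variance; heritability set to 0")
  names(h2) <- colnames(varcomp$Go) %||% names(e)
  if (!is.null(env)) h2 <- h2[env]
  h2
}
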