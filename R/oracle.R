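# Direct dense reference implementation of the model likelihood.
#
# These functions build the full n x n phenotypic covariance matrix
# explicitly from the model definition and evaluate (or brute-force
# maximize) the error-contrast (REML) normal log-likelihood with generic
# dense linear algebra.  They share no code with the production engine and
# exist as an independent cross-check: on small instances the engine must
# reproduce these values.  They scale as O(n^3) per evaluation and are only
# meant for validation-sized problems.

#' Directly evaluated REML log-likelihood (dense reference implementation)
#'
#' Builds `V = sum_i sigma2_i Z_i Z_i' + Z_g (Go %x% K) Z_g' + R` as a dense
#' matrix from the plot table and evaluates the REML log-likelihood
#' `-[log|V| + log|X'V^-1 X| + y'Py + (n-p) log 2pi] / 2`.  Independent of
#' the fitting engine; use for validation on small datasets.
#'
#' @param pheno plot-record data frame.
#' @param kinship relationship matrix covering the phenotyped lines.
#' @param varcomp list with `sigma2` (named iid design-term variances, any of
#'   `env`, `trial`, `rep_trial`, `block`), `Go` (between-environment genetic
#'   covariance, a 1 x 1 matrix for a single environment), `resid_var`
#'   (per-environment or pooled), and optionally `spatial_rho`
#'   (environments x 2 matrix of column/row AR1 correlations).
#' @param model one of `"multi_env"`, `"multi_env_year"`, `"single_env"`.
#' @param env_effect `"random"` or `"fixed"` environment main effect.
#' @return the REML log-likelihood (numeric scalar).
#' @export
reml_direct <- function(pheno, kinship, varcomp,
                        model = c("multi_env", "multi_env_year",
                                  "single_env"),
                        env_effect = c("random", "fixed")) {
  model <- match.arg(model)
  env_effect <- match.arg(env_effect)
  pieces <- direct_pieces(pheno, kinship, model, env_effect)
  direct_ll(pieces, varcomp)
}

direct_pieces <- function(pheno, kinship, model, env_effect) {
  ph <- as.data.frame(pheno)
  for (cn in c("line", "env", "trial", "rep", "block")) {
    ph[[cn]] <- as.character(ph[[cn]])
  }
  envg <- if (model == "multi_env_year") paste(ph$env, ph$year, sep = ":")
          else ph$env
  ord <- order(envg, ph$line, ph$rep)
  ph <- ph[ord, ]; envg <- envg[ord]
  env_levels <- sort(unique(envg))
  k <- length(env_levels)
  n <- nrow(ph)
  ids <- rownames(kinship)
  Km <- as.matrix(kinship)
  # fixed effects
  rep_f <- factor(ph$rep)
  envg_f <- factor(envg, levels = env_levels)
  X <- if (env_effect == "fixed" && k > 1) {
    stats::model.matrix(~ envg_f + rep_f,
                        contrasts.arg = list(rep_f = "contr.sum"))
  } else if (nlevels(rep_f) > 1) {
    stats::model.matrix(~ rep_f, contrasts.arg = list(rep_f = "contr.sum"))
  } else {
    matrix(1, n, 1)
  }
  qx <- qr(X)
  X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  dummy <- function(key) {
    lev <- sort(unique(key))
    out <- matrix(0, n, length(lev))
    out[cbind(seq_len(n), match(key, lev))] <- 1
    out
  }
  Zs <- list(env = dummy(envg),
             trial = dummy(paste(envg, ph$trial)),
             rep_trial = dummy(paste(envg, ph$trial, ph$rep)),
             block = dummy(paste(envg, ph$trial, ph$rep, ph$block)))
  if (env_effect == "fixed" || model == "single_env") Zs$env <- NULL
  Zs <- Zs[vapply(Zs, ncol, 1L) >= 2]
  # genetic incidence onto (environment, line) cells in kinship order
  li <- match(ph$line, ids)
  ei <- match(envg, env_levels)
  Zg <- matrix(0, n, length(ids) * k)
  Zg[cbind(seq_len(n), (ei - 1L) * length(ids) + li)] <- 1
  list(X = X, Zs = Zs, Zg = Zg, Km = Km, env_levels = env_levels,
       envg = envg, ph = ph, n = n, k = k)
}

direct_ll <- function(pieces, varcomp) {
  n <- pieces$n; k <- pieces$k
  V <- matrix(0, n, n)
  for (nm in names(pieces$Zs)) {
    s2 <- varcomp$sigma2[[nm]]
    if (is.null(s2) || is.na(s2)) s2 <- 0
    V <- V + s2 * tcrossprod(pieces$Zs[[nm]])
  }
  Go <- as.matrix(varcomp$Go)
  V <- V + pieces$Zg %*% kronecker(Go, pieces$Km) %*% t(pieces$Zg)
  s2e <- varcomp$resid_var
  if (length(s2e) == 1) s2e <- rep(s2e, k)
  for (i in seq_len(k)) {
    idx <- which(pieces$envg == pieces$env_levels[i])
    rho <- if (!is.null(varcomp$spatial_rho)) varcomp$spatial_rho[i, ]
           else c(0, 0)
    if (any(rho != 0)) {
      ci <- pieces$ph$col[idx]; ri <- pieces$ph$row[idx]
      Cc <- outer(ci, ci, function(a, b) rho[1]^abs(a - b)) *
        outer(ri, ri, function(a, b) rho[2]^abs(a - b))
      V[idx, idx] <- V[idx, idx] + s2e[i] * Cc
    } else {
      diag(V)[idx] <- diag(V)[idx] + s2e[i]
    }
  }
  X <- pieces$X
  p <- ncol(X)
  U <- chol(V)
  ldV <- 2 * sum(log(diag(U)))
  Xs <- backsolve(U, X, transpose = TRUE)
  ys <- backsolve(U, pieces$ph$value, transpose = TRUE)
  XVX <- crossprod(Xs)
  UX <- chol(XVX)
  ldX <- 2 * sum(log(diag(UX)))
  XVy <- crossprod(Xs, ys)
  beta <- backsolve(UX, backsolve(UX, XVy, transpose = TRUE))
  yPy <- sum(ys^2) - sum(XVy * beta)
  as.numeric(-0.5 * (ldV + ldX + yPy + (n - p) * log(2 * pi)))
}

#' Brute-force REML maximization with a generic optimizer (reference)
#'
#' Maximizes the directly evaluated error-contrast log-likelihood
#' ([reml_direct()]) over an unstructured between-environment genetic
#' covariance (log-Cholesky parameterized), iid design-term variances and
#' per-environment residual variances, using Nelder-Mead followed by BFGS
#' from several neutral starting points.  This is the independent oracle
#' against which the fitting engine is validated on small instances; it is
#' far too slow for production use.
#'
#' @inheritParams reml_direct
#' @param terms which iid design terms to include (subset of `env`, `trial`,
#'   `rep_trial`, `block` present in the data).
#' @param n_starts number of starting points.
#' @return list with `ll` (maximized log-likelihood), `Go`, `sigma2`,
#'   `resid_var`.
#' @export
reml_direct_fit <- function(pheno, kinship,
                            model = c("multi_env", "multi_env_year",
                                      "single_env"),
                            env_effect = c("random", "fixed"),
                            terms = NULL, n_starts = 3) {
  model <- match.arg(model)
  env_effect <- match.arg(env_effect)
  pieces <- direct_pieces(pheno, kinship, model, env_effect)
  if (!is.null(terms)) pieces$Zs <- pieces$Zs[intersect(names(pieces$Zs), terms)]
  k <- pieces$k
  nms <- names(pieces$Zs)
  n_iid <- length(nms)
  n_chol <- k * (k + 1) / 2
  lowidx <- which(lower.tri(matrix(0, k, k), diag = TRUE))
  unpack <- function(theta) {
    s2 <- stats::setNames(exp(theta[seq_len(n_iid)]), nms)
    Lg <- matrix(0, k, k)
    Lg[lowidx] <- theta[n_iid + seq_len(n_chol)]
    diag(Lg) <- exp(diag(Lg))
    Go <- tcrossprod(Lg)
    s2e <- exp(theta[n_iid + n_chol + seq_len(k)])
    list(sigma2 = as.list(s2), Go = Go, resid_var = s2e)
  }
  nll <- function(theta) {
    vc <- unpack(theta)
    ll <- tryCatch(direct_ll(pieces, vc), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  vy <- stats::var(pieces$ph$value)
  pack_chol <- function(M) {
    Lc <- t(chol(M))
    diag(Lc) <- log(diag(Lc))
    Lc[lowidx]
  }
  best <- NULL
  for (st in seq_len(n_starts)) {
    frac <- c(0.3, 0.6, 0.1)[(st - 1) %% 3 + 1]
    M0 <- frac * vy * (0.9 * diag(k) + 0.1)
    th0 <- c(rep(log(0.1 * vy), n_iid), pack_chol(M0),
             rep(log((1 - frac) * vy * 0.8), k))
    op <- stats::optim(th0, nll, method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-12))
    op <- stats::optim(op$par, nll, method = "BFGS",
                       control = list(maxit = 300, reltol = 1e-12))
    if (is.null(best) || op$value < best$value) best <- op
  }
  vc <- unpack(best$par)
  list(ll = -best$value, Go = vc$Go, sigma2 = vc$sigma2,
       resid_var = vc$resid_var)
}
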