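# REML engine for the multi-environment mixed model.
#
# The phenotype model is y = X b + sum_i Z_i u_i + e with u_i ~ N(0, D_i):
# D_i = sigma2_i I for the iid design terms and D_g = Go %x% K for the
# line-by-environment genetic term (Go = Lambda Lambda' + diag(Psi)), and
# e block-diagonal over environments with variance sigma2_k (optionally an
# AR1xAR1 correlation over the field grid).  All likelihood quantities are
# obtained through the Woodbury identity
#   V^-1 = R^-1 - R^-1 Z L (I + L' Z'R^-1 Z L)^-1 L' Z' R^-1,
# where D = L L', so the only large factorization is a q x q Cholesky in the
# total number of random-effect levels q.  Gradients of the REML
# log-likelihood are analytic in all variance parameters; the spatial
# autocorrelations are profiled in an outer loop.

# ---- parameter map ----------------------------------------------------------

make_pmap <- function(terms, k_env, fa_order, resid_by_env) {
  pos <- 0L
  pmap <- list(iid = integer(0), lambda = NULL, lsigma_g = NULL, psi = NULL,
               resid = NULL, k = k_env)
  for (nm in names(terms)) {
    if (terms[[nm]]$type == "iid") {
      pos <- pos + 1L
      pmap$iid[nm] <- pos
    }
  }
  if (!is.null(terms$genetic)) {
    kg <- terms$genetic$k
    if (kg == 1L) {
      pos <- pos + 1L
      pmap$lsigma_g <- pos
    } else {
      m <- min(fa_order, kg)
      lam <- matrix(0L, kg, m)
      for (j in seq_len(m)) for (e in j:kg) {
        pos <- pos + 1L
        lam[e, j] <- pos
      }
      pmap$lambda <- lam
      pmap$psi <- pos + seq_len(kg)
      pos <- pos + kg
    }
  }
  nres <- if (resid_by_env) k_env else 1L
  pmap$resid <- pos + seq_len(nres)
  pos <- pos + nres
  pmap$n_par <- pos
  pmap
}

theta_to_comps <- function(theta, pmap, terms) {
  comps <- list(sigma2 = exp(theta[pmap$iid]))
  names(comps$sigma2) <- names(pmap$iid)
  if (!is.null(terms$genetic)) {
    kg <- terms$genetic$k
    if (kg == 1L) {
      comps$Lambda <- matrix(sqrt(exp(theta[pmap$lsigma_g])), 1, 1)
      comps$Psi <- 0
    } else {
      m <- ncol(pmap$lambda)
      Lam <- matrix(0, kg, m)
      Lam[pmap$lambda > 0] <- theta[pmap$lambda[pmap$lambda > 0]]
      comps$Lambda <- Lam
      comps$Psi <- exp(theta[pmap$psi])
    }
    comps$Go <- fa_covariance(comps$Lambda, comps$Psi)
  }
  comps$resid_var <- exp(theta[pmap$resid])
  comps
}

comps_to_theta <- function(comps, pmap, terms) {
  theta <- numeric(pmap$n_par)
  theta[pmap$iid] <- log(pmax(comps$sigma2, 1e-10))
  if (!is.null(terms$genetic)) {
    if (terms$genetic$k == 1L) {
      theta[pmap$lsigma_g] <- log(max(comps$Go[1, 1], 1e-10))
    } else {
      can <- canonical_loadings(comps$Lambda, comps$Psi, ncol(pmap$lambda))
      theta[pmap$lambda[pmap$lambda > 0]] <- can$Lambda[pmap$lambda > 0]
      theta[pmap$psi] <- log(pmax(can$Psi, 1e-8))
    }
  }
  theta[pmap$resid] <- log(pmax(comps$resid_var, 1e-10))
  theta
}

# Rotate a loading matrix to the canonical lower-triangular form with a
# positive leading loading per factor.  The rotation leaves Lambda Lambda'
# (and hence the likelihood) unchanged: the triangular factor is the partial
# Cholesky of Lambda Lambda', guarded against rank deficiency.
canonical_loadings <- function(Lambda, Psi, m) {
  Lambda <- as.matrix(Lambda)
  k <- nrow(Lambda)
  M <- tcrossprod(Lambda)
  C <- matrix(0, k, m)
  for (j in seq_len(m)) {
    pj <- M[j, j] - sum(C[j, seq_len(j - 1)]^2)
    if (pj > 1e-12) {
      C[j, j] <- sqrt(pj)
      if (j < k) {
        for (e in (j + 1):k) {
          C[e, j] <- (M[e, j] - sum(C[e, seq_len(j - 1)] * C[j, seq_len(j - 1)])) /
            C[j, j]
        }
      }
    } else {
      C[j, j] <- 1e-6
    }
  }
  list(Lambda = C, Psi = pmax(Psi, 1e-8))
}

# ---- engine construction ----------------------------------------------------

make_engine <- function(design, K = NULL) {
  terms <- design$terms
  gen <- terms$genetic
  eng <- new.env(parent = emptyenv())
  eng$design <- design
  eng$terms <- terms
  eng$K <- K
  if (!is.null(gen)) {
    stopifnot(!is.null(K), nrow(K) == gen$N,
              identical(rownames(K), gen$line_ids))
    eng$Km <- as.matrix(K)
    eng$UK <- chol(eng$Km)
  }
  eng$qs <- vapply(terms, function(t) ncol(t$Z), integer(1))
  eng$q <- sum(eng$qs)
  off <- cumsum(c(0L, eng$qs))
  eng$rows <- lapply(seq_along(terms), function(i) (off[i] + 1L):off[i + 1L])
  names(eng$rows) <- names(terms)
  eng$Z <- do.call(cbind, lapply(terms, `[[`, "Z"))
  eng$B <- cbind(design$X, design$y)
  eng$n_env <- lengths(design$env_idx)
  eng$rho <- matrix(0, length(design$env_levels), 2,
                    dimnames = list(design$env_levels, c("col", "row")))
  eng$cache_key <- NULL
  set_env_pieces(eng)
  eng
}

# Per-environment crossproducts against the residual correlation inverse;
# recomputed only when the spatial autocorrelations change (optionally for a
# single environment).
set_env_pieces <- function(eng, only = NULL) {
  design <- eng$design
  spatial <- design$spec$spatial
  if (is.null(eng$Ek) || is.null(only)) {
    eng$Ek <- vector("list", length(design$env_levels))
    eng$Fk <- eng$Ck <- eng$Ccor <- eng$Ucor <- eng$Ek
    eng$ldetC <- numeric(length(design$env_levels))
    only <- NULL
  }
  todo <- only %||% seq_along(design$env_levels)
  for (i in todo) {
    idx <- design$env_idx[[i]]
    Zi <- eng$Z[idx, , drop = FALSE]
    Bi <- eng$B[idx, , drop = FALSE]
    if (!spatial || (eng$rho[i, 1] == 0 && eng$rho[i, 2] == 0)) {
      eng$Ek[[i]] <- Matrix::crossprod(Zi)
      eng$Fk[[i]] <- as.matrix(Matrix::crossprod(Zi, Bi))
      eng$Ck[[i]] <- crossprod(Bi)
      eng$ldetC[i] <- 0
      eng$Ccor[i] <- list(NULL); eng$Ucor[i] <- list(NULL)
    } else {
      ph <- design$pheno[idx, ]
      Cc <- outer(ph$col, ph$col, function(a, b) eng$rho[i, 1]^abs(a - b)) *
        outer(ph$row, ph$row, function(a, b) eng$rho[i, 2]^abs(a - b))
      Uc <- chol(Cc)
      Zs <- backsolve(Uc, as.matrix(Zi), transpose = TRUE)
      Bs <- backsolve(Uc, Bi, transpose = TRUE)
      eng$Ek[[i]] <- crossprod(Zs)
      eng$Fk[[i]] <- crossprod(Zs, Bs)
      eng$Ck[[i]] <- crossprod(Bs)
      eng$ldetC[i] <- 2 * sum(log(diag(Uc)))
      eng$Ccor[[i]] <- Cc; eng$Ucor[[i]] <- Uc
    }
  }
  eng$cache_key <- NULL
  invisible(eng)
}

# (Uo %x% Al) %*% B for B with N*k rows, exploiting the Kronecker structure.
kron_mult <- function(Ao, Al, B) {
  B <- as.matrix(B)
  N <- nrow(Al); k <- nrow(Ao); r <- ncol(B)
  s1 <- Al %*% matrix(B, N, k * r)
  tmp <- aperm(array(s1, c(N, k, r)), c(2, 1, 3))
  s2 <- Ao %*% matrix(tmp, k, N * r)
  matrix(aperm(array(s2, c(k, N, r)), c(2, 1, 3)), N * k, r)
}

# t(L) %*% B using the block structure of L (diagonal blocks per iid term,
# Kronecker factor for the genetic block).
blk_lt_mult <- function(eng, st, B) {
  B <- as.matrix(B)
  out <- B
  for (nm in names(eng$terms)) {
    rws <- eng$rows[[nm]]
    if (eng$terms[[nm]]$type == "iid") {
      out[rws, ] <- sqrt(st$sigma2[[nm]]) * B[rws, , drop = FALSE]
    } else {
      out[rws, ] <- kron_mult(st$Uo, eng$UK, B[rws, , drop = FALSE])
    }
  }
  out
}

# expand per-environment residual variances according to resid_by_env
resid_vec <- function(eng, comps) {
  k <- length(eng$design$env_levels)
  if (length(comps$resid_var) == k) comps$resid_var else
    rep(comps$resid_var[1], k)
}

# ---- REML evaluation --------------------------------------------------------

# Core evaluation: REML log-likelihood and, when requested, the pieces needed
# for analytic gradients and EM updates.
eval_reml <- function(eng, comps, want = c("ll")) {
  design <- eng$design
  n <- design$n; p <- design$p
  q <- eng$q
  k <- length(design$env_levels)
  s2e <- resid_vec(eng, comps)
  st <- list(sigma2 = comps$sigma2)
  if (!is.null(eng$terms$genetic)) {
    Go <- comps$Go
    st$Uo <- tryCatch(chol(Go), error = function(e)
      chol(Go + (1e-8 + 1e-6 * mean(diag(Go))) * diag(nrow(Go))))
  }
  # assemble weighted crossproducts
  A <- eng$Ek[[1]] / s2e[1]
  FB <- eng$Fk[[1]] / s2e[1]
  CB <- eng$Ck[[1]] / s2e[1]
  ldR <- eng$n_env[1] * log(s2e[1]) + eng$ldetC[1]
  if (k > 1) for (i in 2:k) {
    A <- A + eng$Ek[[i]] / s2e[i]
    FB <- FB + eng$Fk[[i]] / s2e[i]
    CB <- CB + eng$Ck[[i]] / s2e[i]
    ldR <- ldR + eng$n_env[i] * log(s2e[i]) + eng$ldetC[i]
  }
  FB <- as.matrix(FB)
  CB <- as.matrix(CB)
  # L as an explicit dense matrix (block diagonal)
  L <- matrix(0, q, q)
  for (nm in names(eng$terms)) {
    rws <- eng$rows[[nm]]
    if (eng$terms[[nm]]$type == "iid") {
      diag(L)[rws] <- sqrt(st$sigma2[[nm]])
    } else {
      L[rws, rws] <- kronecker(t(st$Uo), t(eng$UK))
    }
  }
  W <- as.matrix(A %*% L)
  M <- blk_lt_mult(eng, st, W)
  diag(M) <- diag(M) + 1
  M <- (M + t(M)) / 2
  U <- tryCatch(chol(M), error = function(e) chol(M + 1e-8 * diag(q)))
  ldV <- ldR + 2 * sum(log(diag(U)))
  T1 <- blk_lt_mult(eng, st, FB)              # L' Z'R^-1 [X y]
  S1 <- backsolve(U, T1, transpose = TRUE)
  VB <- CB - crossprod(S1)                    # [X y]' V^-1 [X y]
  XVX <- VB[seq_len(p), seq_len(p), drop = FALSE]
  XVy <- VB[seq_len(p), p + 1]
  yVy <- VB[p + 1, p + 1]
  UX <- tryCatch(chol(XVX), error = function(e)
    stop("singular fixed-effect structure", call. = FALSE))
  beta <- backsolve(UX, backsolve(UX, XVy, transpose = TRUE))
  yPy <- yVy - sum(XVy * beta)
  ldXVX <- 2 * sum(log(diag(UX)))
  ll <- -0.5 * (ldV + ldXVX + yPy + (n - p) * log(2 * pi))
  out <- list(ll = ll, beta = beta, comps = comps, s2e = s2e)
  if (identical(want, c("ll"))) return(out)

  # ---- shared gradient / EM pieces ----
  Minv <- chol2inv(U)
  XVXinv <- chol2inv(UX)
  zr <- FB[, p + 1] - FB[, seq_len(p), drop = FALSE] %*% beta   # Z'R^-1 r
  ltzr <- blk_lt_mult(eng, st, zr)
  w <- as.numeric(zr - W %*% (Minv %*% ltzr))                   # Z'Py
  ZVX <- FB[, seq_len(p), drop = FALSE] -
    W %*% (Minv %*% T1[, seq_len(p), drop = FALSE])             # Z'V^-1 X
  WU <- backsolve(U, t(W), transpose = TRUE)
  ZVZ <- as.matrix(A) - crossprod(WU)
  Szz <- ZVZ - ZVX %*% XVXinv %*% t(ZVX)                        # Z'PZ
  # residual-space vectors: Py and V^-1 X
  r <- design$y - design$X %*% beta
  ZL <- as.matrix(eng$Z %*% L)                                  # n x q
  Rr <- numeric(n); RX <- matrix(0, n, p); RZL <- matrix(0, n, q)
  for (i in seq_len(k)) {
    idx <- design$env_idx[[i]]
    if (is.null(eng$Ucor[[i]])) {
      Rr[idx] <- r[idx] / s2e[i]
      RX[idx, ] <- design$X[idx, , drop = FALSE] / s2e[i]
      RZL[idx, ] <- ZL[idx, , drop = FALSE] / s2e[i]
    } else {
      Uc <- eng$Ucor[[i]]
      sol <- function(b) backsolve(Uc, backsolve(Uc, b, transpose = TRUE))
      Rr[idx] <- sol(r[idx]) / s2e[i]
      RX[idx, ] <- sol(design$X[idx, , drop = FALSE]) / s2e[i]
      RZL[idx, ] <- sol(ZL[idx, , drop = FALSE]) / s2e[i]
    }
  }
  Py <- Rr - RZL %*% (Minv %*% ltzr)
  H <- RX - RZL %*% (Minv %*% T1[, seq_len(p), drop = FALSE])   # V^-1 X
  # genetic summaries
  gen <- eng$terms$genetic
  T_tr <- NULL; Qw <- NULL; W2 <- NULL
  if (!is.null(gen)) {
    rg <- eng$rows$genetic
    N <- gen$N; kg <- gen$k
    S22 <- Szz[rg, rg, drop = FALSE]
    Km <- eng$Km
    T_tr <- matrix(0, kg, kg)
    for (e in seq_len(kg)) for (f in e:kg) {
      blk <- S22[(e - 1) * N + seq_len(N), (f - 1) * N + seq_len(N)]
      T_tr[e, f] <- T_tr[f, e] <- sum(Km * blk)
    }
    W2 <- matrix(w[rg], N, kg)
    KW2 <- Km %*% W2
    Qw <- crossprod(W2, KW2)
  }
  # residual traces: tr(P C_k) per environment
  trPC <- numeric(k); quadC <- numeric(k)
  for (i in seq_len(k)) {
    idx <- design$env_idx[[i]]
    EkL <- as.matrix(eng$Ek[[i]] %*% L)
    LEL <- blk_lt_mult(eng, st, EkL)
    Hk <- H[idx, , drop = FALSE]
    Pyk <- Py[idx]
    if (is.null(eng$Ccor[[i]])) {
      CH <- Hk; CPy <- Pyk
    } else {
      CH <- eng$Ccor[[i]] %*% Hk; CPy <- eng$Ccor[[i]] %*% Pyk
    }
    trPC[i] <- eng$n_env[i] / s2e[i] - sum(Minv * LEL) / s2e[i]^2 -
      sum(XVXinv * crossprod(Hk, CH))
    quadC[i] <- sum(Pyk * CPy)
  }
  out <- c(out, list(Minv = Minv, XVXinv = XVXinv, w = w, Szz = Szz, Py = Py,
                     H = H, T_tr = T_tr, Qw = Qw, W2 = W2, trPC = trPC,
                     quadC = quadC, st = st))
  out
}

# analytic gradient of the REML log-likelihood w.r.t. the transformed theta
reml_gradient <- function(eng, comps, pmap, ev) {
  g <- numeric(pmap$n_par)
  for (nm in names(pmap$iid)) {
    rws <- eng$rows[[nm]]
    s2 <- comps$sigma2[[nm]]
    trS <- sum(diag(ev$Szz)[rws])
    quad <- sum(ev$w[rws]^2)
    g[pmap$iid[nm]] <- -0.5 * s2 * (trS - quad)
  }
  gen <- eng$terms$genetic
  if (!is.null(gen)) {
    if (gen$k == 1L) {
      s2g <- comps$Go[1, 1]
      g[pmap$lsigma_g] <- -0.5 * s2g * (ev$T_tr[1, 1] - ev$Qw[1, 1])
    } else {
      TL <- ev$T_tr %*% comps$Lambda
      QL <- ev$Qw %*% comps$Lambda
      sel <- pmap$lambda > 0
      g[pmap$lambda[sel]] <- -(TL[sel] - QL[sel])
      g[pmap$psi] <- -0.5 * comps$Psi *
        (diag(ev$T_tr) - diag(ev$Qw))
    }
  }
  s2e <- ev$s2e
  if (length(comps$resid_var) == length(s2e)) {
    for (i in seq_along(s2e)) {
      g[pmap$resid[i]] <- -0.5 * s2e[i] * (ev$trPC[i] - ev$quadC[i])
    }
  } else {
    g[pmap$resid[1]] <- -0.5 * s2e[1] * sum(ev$trPC - ev$quadC)
  }
  g
}

# ---- EM updates -------------------------------------------------------------

# One REML-EM update of all variance parameters from the current E-step.
em_update <- function(eng, comps, ev, fa_order) {
  new <- comps
  for (nm in names(comps$sigma2)) {
    rws <- eng$rows[[nm]]
    s2 <- comps$sigma2[[nm]]
    qi <- length(rws)
    u <- s2 * ev$w[rws]
    trS <- sum(diag(ev$Szz)[rws])
    new$sigma2[[nm]] <- max((sum(u^2) + s2 * qi - s2^2 * trS) / qi, 1e-10)
  }
  gen <- eng$terms$genetic
  if (!is.null(gen)) {
    N <- gen$N; kg <- gen$k
    Go <- comps$Go
    Uhat <- eng$Km %*% ev$W2 %*% Go
    KiU <- backsolve(eng$UK, backsolve(eng$UK, Uhat, transpose = TRUE))
    Smat <- (crossprod(Uhat, KiU) + N * Go - Go %*% ev$T_tr %*% Go) / N
    Smat <- (Smat + t(Smat)) / 2
    if (kg == 1L) {
      new$Lambda <- matrix(sqrt(max(Smat[1, 1], 1e-10)), 1, 1)
      new$Psi <- 0
    } else {
      m <- min(fa_order, kg)
      if (m >= kg) {
        Uo <- tryCatch(chol(Smat - 1e-8 * diag(kg)), error = function(e)
          chol(Smat + 1e-6 * mean(diag(Smat)) * diag(kg)))
        new$Lambda <- t(Uo)
        new$Psi <- rep(1e-8, kg)
      } else {
        fa <- fa_fit(Smat, m, comps$Lambda, comps$Psi, iter = 40)
        new$Lambda <- fa$Lambda
        new$Psi <- fa$Psi
      }
    }
    new$Go <- fa_covariance(new$Lambda, new$Psi)
  }
  s2e <- ev$s2e
  k <- length(s2e)
  newres <- numeric(k)
  for (i in seq_len(k)) {
    nk <- eng$n_env[i]
    newres[i] <- (s2e[i]^2 * ev$quadC[i] + s2e[i] * nk -
                    s2e[i]^2 * ev$trPC[i]) / nk
  }
  newres <- pmax(newres, 1e-10)
  new$resid_var <- if (length(comps$resid_var) == k) newres else
    sum(newres * eng$n_env) / sum(eng$n_env)
  new
}

# Maximize -N/2 (log|Go| + tr(Go^-1 S)) over the factor-analytic structure
# Go = Lambda Lambda' + diag(Psi) by the Rubin-Thayer EM iteration, started
# from the current parameters (ascent property preserved).
fa_fit <- function(S, m, Lambda0 = NULL, Psi0 = NULL, iter = 50,
                   floor_psi = 1e-8) {
  k <- nrow(S)
  if (is.null(Lambda0) || ncol(as.matrix(Lambda0)) != m) {
    es <- eigen(S, symmetric = TRUE)
    ev <- pmax(es$values[seq_len(m)], 1e-6)
    Lambda0 <- es$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(ev * 0.9), m)
    Psi0 <- pmax(diag(S) - rowSums(Lambda0^2), 0.05 * mean(diag(S)))
  }
  Lam <- as.matrix(Lambda0); Psi <- pmax(Psi0, floor_psi)
  for (it in seq_len(iter)) {
    Go <- tcrossprod(Lam) + diag(Psi, k)
    B <- t(solve(Go, Lam))                 # m x k
    Eff <- diag(m) - B %*% Lam + B %*% S %*% t(B)
    Exf <- S %*% t(B)
    Lam_new <- Exf %*% solve((Eff + t(Eff)) / 2)
    Psi_new <- pmax(diag(S - Lam_new %*% t(Exf)), floor_psi)
    delta <- max(abs(Lam_new - Lam), abs(Psi_new - Psi))
    Lam <- Lam_new; Psi <- Psi_new
    if (delta < 1e-8) break
  }
  list(Lambda = Lam, Psi = Psi)
}

# ---- initialization ---------------------------------------------------------

init_comps <- function(eng, fa_order) {
  design <- eng$design
  y <- design$y
  vtot <- stats::var(y)
  k <- length(design$env_levels)
  # residual: within line-by-environment-cell variance where replicated
  s2e <- numeric(k)
  for (i in seq_len(k)) {
    idx <- design$env_idx[[i]]
    cell <- paste(design$pheno$line[idx], design$pheno$trial[idx])
    wv <- tapply(y[idx], cell, function(v)
      if (length(v) > 1) stats::var(v) else NA_real_)
    s2e[i] <- stats::median(wv, na.rm = TRUE)
    if (!is.finite(s2e[i])) s2e[i] <- 0.5 * stats::var(y[idx])
    s2e[i] <- max(s2e[i], 0.02 * vtot)
  }
  comps <- list(sigma2 = stats::setNames(
    rep(0.05 * vtot, sum(names(eng$terms) != "genetic")),
    setdiff(names(eng$terms), "genetic")))
  gen <- eng$terms$genetic
  if (!is.null(gen)) {
    # moment start for Go from per-environment line means
    N <- gen$N
    Ym <- matrix(NA_real_, N, k)
    reps <- matrix(1, N, k)
    for (i in seq_len(k)) {
      idx <- design$env_idx[[i]]
      li <- match(design$pheno$line[idx], gen$line_ids)
      mn <- tapply(y[idx], li, mean)
      ct <- tapply(y[idx], li, length)
      Ym[as.integer(names(mn)), i] <- mn
      reps[as.integer(names(ct)), i] <- ct
    }
    Ym <- sweep(Ym, 2, colMeans(Ym, na.rm = TRUE))
    dg <- numeric(k)
    for (i in seq_len(k)) {
      vi <- stats::var(Ym[, i], na.rm = TRUE)
      if (!is.finite(vi)) vi <- 0.3 * vtot
      dg[i] <- max(vi - s2e[i] / stats::median(reps[, i]), 0.05 * vtot)
    }
    Cm <- suppressWarnings(stats::cor(Ym, use = "pairwise.complete.obs"))
    Cm[!is.finite(Cm)] <- 0
    diag(Cm) <- 1
    Cm <- pmin(pmax(Cm, -0.95), 0.95)
    Go0 <- Cm * sqrt(outer(dg, dg))
    es <- eigen((Go0 + t(Go0)) / 2, symmetric = TRUE)
    Go0 <- es$vectors %*% diag(pmax(es$values, 1e-4 * vtot), k) %*% t(es$vectors)
    if (gen$k == 1L) {
      comps$Lambda <- matrix(sqrt(Go0[1, 1]), 1, 1)
      comps$Psi <- 1e-8
    } else {
      m <- min(fa_order, k)
      fa <- fa_fit((Go0 + t(Go0)) / 2, m, iter = 60)
      comps$Lambda <- fa$Lambda
      comps$Psi <- fa$Psi
    }
    comps$Go <- fa_covariance(comps$Lambda, comps$Psi)
  }
  comps$resid_var <- if (design$spec$resid_by_env) s2e else
    sum(s2e * eng$n_env) / sum(eng$n_env)
  comps
}

# ---- driver -----------------------------------------------------------------

# Full REML fit at fixed spatial autocorrelations: EM warm-up then L-BFGS-B
# with analytic gradients.  Returns the converged components and trace.
reml_fit_inner <- function(eng, fa_order, comps0 = NULL, em_iter = 8,
                           max_iter = 200, tol = 1e-8, optimize = TRUE) {
  design <- eng$design
  pmap <- make_pmap(eng$terms, length(design$env_levels), fa_order,
                    design$spec$resid_by_env)
  comps <- comps0 %||% init_comps(eng, fa_order)
  em_trace <- numeric(0)
  if (optimize && em_iter > 0) {
    for (it in seq_len(em_iter)) {
      ev <- eval_reml(eng, comps, want = "grad")
      em_trace <- c(em_trace, ev$ll)
      comps <- em_update(eng, comps, ev, fa_order)
    }
  }
  theta <- comps_to_theta(comps, pmap, eng$terms)
  n_eval <- 0L
  cache <- new.env(parent = emptyenv())
  getev <- function(th) {
    key <- paste(format(th, digits = 17), collapse = ",")
    if (!identical(cache$key, key)) {
      cache$key <- key
      cache$ev <- eval_reml(eng, theta_to_comps(th, pmap, eng$terms),
                            want = "grad")
      n_eval <<- n_eval + 1L
    }
    cache$ev
  }
  if (optimize) {
    fn <- function(th) -getev(th)$ll
    gr <- function(th) -reml_gradient(eng, theta_to_comps(th, pmap, eng$terms),
                                      pmap, getev(th))
    lower <- rep(-25, pmap$n_par); upper <- rep(25, pmap$n_par)
    if (!is.null(pmap$lambda)) {
      sel <- pmap$lambda[pmap$lambda > 0]
      lower[sel] <- -1e3; upper[sel] <- 1e3
    }
    ctl <- list(maxit = max_iter, factr = max(tol / 1e-15, 10))
    opt <- stats::optim(theta, fn, gr, method = "L-BFGS-B",
                        lower = lower, upper = upper, control = ctl)
    # a fresh restart clears the limited-memory Hessian and recovers the
    # occasional premature line-search stall at negligible cost
    opt2 <- stats::optim(opt$par, fn, gr, method = "L-BFGS-B",
                         lower = lower, upper = upper, control = ctl)
    if (opt2$value <= opt$value) opt <- opt2
    theta <- opt$par
    convergence <- opt$convergence
    message_opt <- opt$message %||% ""
    iterations <- opt$counts[1]
  } else {
    convergence <- 0L; message_opt <- "evaluation only"; iterations <- 0L
  }
  comps <- theta_to_comps(theta, pmap, eng$terms)
  ev <- eval_reml(eng, comps, want = "grad")
  grad <- if (optimize) reml_gradient(eng, comps, pmap, ev) else numeric(0)
  list(comps = comps, ev = ev, ll = ev$ll, pmap = pmap, em_trace = em_trace,
       convergence = convergence, message = message_opt,
       iterations = iterations, grad_norm = if (length(grad)) max(abs(grad)) else NA_real_,
       n_eval = n_eval)
}

# Profile the spatial autocorrelations environment by environment: coarse
# grid search then simplex refinement of (rho_col, rho_row) at the current
# variance parameters, alternated with inner REML fits.
fit_spatial <- function(eng, fa_order, em_iter, max_iter, tol, n_outer = 2,
                        rho_grid = c(-0.6, -0.3, 0, 0.3, 0.6)) {
  fit <- reml_fit_inner(eng, fa_order, em_iter = em_iter,
                        max_iter = max_iter, tol = tol)
  k <- length(eng$design$env_levels)
  for (round in seq_len(n_outer)) {
    for (i in seq_len(k)) {
      obj <- function(rr) {
        rr <- pmin(pmax(rr, -0.95), 0.95)
        eng$rho[i, ] <- rr
        set_env_pieces(eng, only = i)
        -eval_reml(eng, fit$comps, want = "ll")$ll
      }
      best <- eng$rho[i, ]; bestv <- obj(best)
      for (rc in rho_grid) for (rw in rho_grid) {
        v <- obj(c(rc, rw))
        if (v < bestv - 1e-10) { bestv <- v; best <- c(rc, rw) }
      }
      op <- stats::optim(best, obj, method = "Nelder-Mead",
                         control = list(maxit = 40, reltol = 1e-6))
      eng$rho[i, ] <- pmin(pmax(op$par, -0.95), 0.95)
      set_env_pieces(eng, only = i)
    }
    fit <- reml_fit_inner(eng, fa_order, comps0 = fit$comps, em_iter = 0,
                          max_iter = max_iter, tol = tol)
  }
  fit
}
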