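# Shared fixtures, all generated in code.

# Small multi-environment dataset: n_lines test lines, optional checks.
small_dataset <- function(n_lines = 12, k = 2, n_trials = 1, checks = 0,
                          seed = 1, Lambda = NULL, Psi = NULL,
                          resid_var = NULL, reps = 2, block_size = 6,
                          spatial_rho = c(0, 0), n_selfing = 3,
                          trial_var = 0.05, rep_var = 0.05,
                          block_var = 0.05, env_main_var = 0.2,
                          direct_mvn = FALSE) {
  if (is.null(Lambda)) Lambda <- matrix(seq(0.8, 0.4, length.out = k), k, 1)
  if (is.null(Psi)) Psi <- rep(0.15, k)
  if (is.null(resid_var)) resid_var <- rep(0.5, k)
  pop <- population_spec(n_founders = max(6, n_lines %/% 2),
                         n_markers = 300, n_crosses = max(4, n_lines %/% 2),
                         n_selfing = n_selfing, seed = seed)
  des <- trial_design_spec(n_environments = k, n_trials_per_env = n_trials,
                           entries_per_trial = ceiling(n_lines / n_trials),
                           checks_per_trial = checks, n_replicates = reps,
                           grid_cols = 5, block_size = block_size)
  arch <- genetic_architecture(Lambda = Lambda, Psi = Psi,
                               resid_var = resid_var,
                               env_main_var = env_main_var,
                               trial_var = trial_var, rep_var = rep_var,
                               block_var = block_var,
                               spatial_rho_col = spatial_rho[1],
                               spatial_rho_row = spatial_rho[2])
  dat <- sim_breeding_dataset(pop, des, arch, n_lines = n_lines, seed = seed,
                              direct_mvn = direct_mvn)
  dat$K <- if (checks > 0) {
    block_diagonal_kinship(compute_G(dat$geno),
                           setdiff(unique(dat$pheno$line),
                                   rownames(dat$geno)))
  } else {
    compute_G(dat$geno)
  }
  dat$arch <- arch
  dat
}

# Direct dense GLS solve used as a BLUE oracle: X fixed cells, V from
# components, computed with plain base algebra.
gls_blues_oracle <- function(pheno, varcomp) {
  ph <- pheno[order(pheno$env, pheno$line, pheno$rep), ]
  cell <- paste(ph$line, ph$env, sep = "\r")
  lev <- sort(unique(cell))
  X <- matrix(0, nrow(ph), length(lev))
  X[cbind(seq_len(nrow(ph)), match(cell, lev))] <- 1
  rep_f <- factor(ph$rep)
  if (nlevels(rep_f) > 1) {
    Xr <- stats::model.matrix(~rep_f, contrasts.arg = list(rep_f = "contr.sum"))
    X <- cbind(X, Xr[, -1, drop = FALSE])
  }
  n <- nrow(ph)
  V <- matrix(0, n, n)
  add_term <- function(key, s2) {
    Z <- outer(key, unique(key), "==") * 1
    V <<- V + s2 * tcrossprod(Z)
  }
  envg <- ph$env
  if (!is.null(varcomp$sigma2)) {
    if (!is.na(varcomp$sigma2["trial"] %||% NA)) {
      add_term(paste(envg, ph$trial), varcomp$sigma2[["trial"]])
    }
    if (!is.na(varcomp$sigma2["rep_trial"] %||% NA)) {
      add_term(paste(envg, ph$trial, ph$rep), varcomp$sigma2[["rep_trial"]])
    }
    if (!is.na(varcomp$sigma2["block"] %||% NA)) {
      add_term(paste(envg, ph$trial, ph$rep, ph$block),
               varcomp$sigma2[["block"]])
    }
  }
  s2e <- varcomp$resid_var
  envs <- sort(unique(envg))
  if (length(s2e) == 1) s2e <- rep(s2e, length(envs))
  diag(V) <- diag(V) + s2e[match(envg, envs)]
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% ph$value)
  parts <- strsplit(lev, "\r", fixed = TRUE)
  data.frame(line = vapply(parts, `[`, "", 1),
             env = vapply(parts, `[`, "", 2),
             blue = beta[seq_along(lev)], stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
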