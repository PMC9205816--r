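# Validation of the REML engine against direct dense computation and
# closed-form mixed-model algebra.

fixed_vc <- function(k, seed = 1) {
  set.seed(seed)
  Lam <- matrix(seq(0.9, 0.4, length.out = k), k, 1)
  Psi <- seq(0.1, 0.3, length.out = k)
  list(sigma2 = c(env = 0.12, trial = 0.07, rep_trial = 0.04, block = 0.06),
       Lambda = Lam, Psi = Psi, Go = fa_covariance(Lam, Psi),
       resid_var = seq(0.4, 0.6, length.out = k))
}

test_that("engine log-likelihood equals the dense reference, all variants", {
  dat <- small_dataset(n_lines = 10, k = 2, seed = 41, checks = 0)
  vc <- fixed_vc(2)
  # multi-environment (iid residual)
  f1 <- megblup(dat$pheno, dat$K, model = "multi_env",
                varcomp_init = vc, estimate = FALSE)
  expect_identical(f1$design$n, 40L)
  llo <- reml_direct(dat$pheno, stabilize_kinship(dat$K), vc, "multi_env")
  expect_lt(abs(f1$loglik - llo), 1e-8)
  # multi-environment with spatial residual correlation
  vc_sp <- vc
  vc_sp$spatial_rho <- matrix(c(0.5, -0.3, 0.2, 0.4), 2, 2)
  f2 <- megblup(dat$pheno, dat$K, model = "multi_env", spatial = TRUE,
                varcomp_init = vc_sp, estimate = FALSE)
  llo2 <- reml_direct(dat$pheno, stabilize_kinship(dat$K), vc_sp, "multi_env")
  expect_lt(abs(f2$loglik - llo2), 1e-6)
  # multi-year: same environments in two years
  ph20 <- dat$pheno; ph20$year <- 2020
  ph20$value <- ph20$value + rnorm(nrow(ph20), 0, 0.3)
  ph2 <- rbind(dat$pheno, ph20)
  vc4 <- fixed_vc(4)
  f3 <- megblup(ph2, dat$K, model = "multi_env_year",
                varcomp_init = vc4, estimate = FALSE)
  llo3 <- reml_direct(ph2, stabilize_kinship(dat$K), vc4, "multi_env_year")
  expect_lt(abs(f3$loglik - llo3), 1e-8)
  # single environment
  ph_1 <- dat$pheno[dat$pheno$env == "SE1", ]
  vc1 <- list(sigma2 = c(rep_trial = 0.04, block = 0.06),
              Go = matrix(0.5), Lambda = matrix(sqrt(0.5)), Psi = 0,
              resid_var = 0.45)
  f4 <- suppressMessages(
    megblup(ph_1, dat$K, model = "single_env", varcomp_init = vc1,
            estimate = FALSE))
  llo4 <- reml_direct(ph_1, stabilize_kinship(dat$K), vc1, "single_env")
  expect_lt(abs(f4$loglik - llo4), 1e-8)
})

test_that("balanced and general engines are numerically identical", {
  dat <- small_dataset(n_lines = 15, k = 3, seed = 42, n_trials = 1,
                       trial_var = 0, rep_var = 0.03, block_var = 0,
                       env_main_var = 0.2)
  vc <- list(Lambda = matrix(c(0.8, 0.6, 0.3), 3, 1), Psi = c(0.1, 0.1, 0.3),
             Go = fa_covariance(matrix(c(0.8, 0.6, 0.3), 3, 1),
                                c(0.1, 0.1, 0.3)),
             sigma2 = setNames(numeric(0), character(0)),
             resid_var = c(0.4, 0.5, 0.6))
  fg <- megblup(dat$pheno, dat$K, env_effect = "fixed",
                random_terms = character(0), engine = "general",
                varcomp_init = vc, estimate = FALSE)
  fb <- megblup(dat$pheno, dat$K, env_effect = "fixed",
                random_terms = character(0), engine = "balanced",
                varcomp_init = vc, estimate = FALSE)
  expect_lt(abs(fg$loglik - fb$loglik), 1e-9)
  expect_lt(max(abs(fg$gblups - fb$gblups)), 1e-9)
  # and the optimized fits agree once both explore from the same start
  # (the two engines share one likelihood but not one starting strategy)
  ob <- megblup(dat$pheno, dat$K, env_effect = "fixed",
                random_terms = character(0), engine = "balanced",
                max_iter = 300, tol = 1e-10)
  og <- megblup(dat$pheno, dat$K, env_effect = "fixed",
                random_terms = character(0), engine = "general",
                max_iter = 300, tol = 1e-10,
                varcomp_init = ob$varcomp)
  expect_lt(abs(og$loglik - ob$loglik), 1e-4)
  expect_lt(max(abs(og$varcomp$Go - ob$varcomp$Go)), 5e-3)
})

test_that("zero-genetic-variance data drive the genetic term to the boundary", {
  # under the null the REML genetic variance is a boundary-censored
  # half-normal, so individual realizations scatter; the median over a few
  # fixed seeds sits essentially at zero
  g_frac <- u_frac <- numeric(0)
  for (sd in 50:53) {
    arch0 <- genetic_architecture(Lambda = matrix(0, 2, 1), Psi = c(0, 0),
                                  resid_var = c(0.5, 0.5), env_main_var = 0.1,
                                  trial_var = 0, rep_var = 0.05,
                                  block_var = 0.05)
    des <- trial_design_spec(n_environments = 2, n_trials_per_env = 1,
                             entries_per_trial = 125, checks_per_trial = 0,
                             n_replicates = 2, grid_cols = 15,
                             block_size = 10)
    pop <- population_spec(n_founders = 125, n_markers = 2000, seed = sd)
    geno <- simulate_founder_genotypes(pop)
    lay <- assign_trial_layout(rownames(geno), des, seed = sd,
                               envs = c("SE1", "SE2"))
    ph <- simulate_phenotypes(geno, lay, arch0, seed = sd)
    fit <- megblup(ph, compute_G(geno), max_iter = 150, tol = 1e-8)
    g_frac <- c(g_frac, max(diag(fit$varcomp$Go)) / var(ph$value))
    u_frac <- c(u_frac, mean(abs(fit$gblups)) / sd(ph$value))
  }
  expect_lt(median(g_frac), 0.02)
  expect_lt(median(u_frac), 0.05)
})

test_that("predictions follow the kinship information flow", {
  # one-record-per-line toy with an explicit G: engine matches the direct
  # mixed-model-equations solve, an unrelated line predicts exactly 0, and
  # kinship twins get equal predictions
  K <- matrix(c(1, 1, 0.3, 0,
                1, 1, 0.3, 0,
                0.3, 0.3, 1, 0,
                0, 0, 0, 1), 4, 4,
              dimnames = list(c("T1", "T2", "P3", "U4"),
                              c("T1", "T2", "P3", "U4")))
  ph <- data.frame(line = c("T1", "P3"), env = "E1", trial = "T",
                   rep = c("R1", "R1"), block = "B", value = c(2.0, -1.0))
  vc <- list(sigma2 = setNames(numeric(0), character(0)),
             Lambda = matrix(1), Psi = 0, Go = matrix(1),
             resid_var = 0.5)
  fit <- suppressMessages(
    megblup(ph, K, model = "single_env", random_terms = character(0),
            varcomp_init = vc, estimate = FALSE))
  # direct solve: u_all = s2g K[, obs] V^-1 (y - mu), V = s2g K_obs + R
  Ks <- K + 1e-6 * diag(4) # engine stabilization
  Vo <- Ks[c("T1", "P3"), c("T1", "P3")] + 0.5 * diag(2)
  X <- matrix(1, 2, 1)
  mu <- solve(t(X) %*% solve(Vo, X), t(X) %*% solve(Vo, c(2, -1)))
  u_direct <- Ks[, c("T1", "P3")] %*%
    solve(Vo, c(2, -1) - as.numeric(mu))
  expect_lt(max(abs(predict(fit)[, 1] - u_direct)), 1e-8)
  # unphenotyped, unrelated line: exactly zero
  expect_identical(unname(predict(fit, lines = "U4")[1, 1]), 0)
  # twins: identical kinship rows (up to the stabilizing ridge), one tested
  expect_lt(abs(predict(fit)["T1", 1] - predict(fit)["T2", 1]), 1e-5)
  expect_error(predict(fit, lines = "nope"), "not in the kinship")
})

test_that("GBLUP shrinks between the BLUE deviation and zero", {
  ph <- expand.grid(line = paste0("L", 1:4), rep = c("R1", "R2"),
                    stringsAsFactors = FALSE)
  ph$env <- "E1"; ph$trial <- "T"; ph$block <- "B"
  line_mu <- c(L1 = 1, L2 = -0.5, L3 = 0.2, L4 = 2)
  set.seed(9)
  ph$value <- line_mu[ph$line] + rnorm(8, 0, 0.2)
  K <- diag(4); dimnames(K) <- list(paste0("L", 1:4), paste0("L", 1:4))
  base_vc <- list(sigma2 = setNames(numeric(0), character(0)),
                  Lambda = matrix(1), Psi = 0, resid_var = 0.04)
  strong <- weak <- base_vc
  strong$Go <- matrix(1e6); strong$Lambda <- matrix(1e3)
  weak$Go <- matrix(1e-8); weak$Lambda <- matrix(1e-4)
  f_strong <- suppressMessages(
    megblup(ph, K, model = "single_env", random_terms = character(0),
            varcomp_init = strong, estimate = FALSE))
  f_weak <- suppressMessages(
    megblup(ph, K, model = "single_env", random_terms = character(0),
            varcomp_init = weak, estimate = FALSE))
  lm_means <- tapply(ph$value, ph$line, mean)
  dev <- lm_means - mean(lm_means)
  expect_lt(max(abs(predict(f_strong)[names(dev), 1] - dev)), 1e-3)
  expect_lt(max(abs(predict(f_weak))), 1e-5)
})

test_that("converged solutions satisfy the mixed-model equations", {
  dat <- small_dataset(n_lines = 12, k = 2, seed = 43)
  fit <- megblup(dat$pheno, dat$K, max_iter = 150, tol = 1e-9)
  design <- fit$design
  vc <- fit$varcomp
  Zs <- lapply(design$terms, function(t) as.matrix(t$Z))
  Z <- do.call(cbind, Zs)
  u <- unlist(lapply(names(design$terms), function(nm) as.numeric(fit$u[[nm]])))
  X <- design$X
  k <- length(design$env_levels)
  rvec <- vc$resid_var[match(as.character(design$envg), names(vc$resid_var))]
  Rinv <- diag(1 / rvec)
  Dinvs <- lapply(names(design$terms), function(nm) {
    if (design$terms[[nm]]$type == "iid") {
      diag(ncol(Zs[[nm]])) / vc$sigma2[[nm]]
    } else {
      solve(kronecker(vc$Go, as.matrix(fit$K)))
    }
  })
  Dinv <- as.matrix(Matrix::bdiag(Dinvs))
  C <- rbind(cbind(t(X) %*% Rinv %*% X, t(X) %*% Rinv %*% Z),
             cbind(t(Z) %*% Rinv %*% X, t(Z) %*% Rinv %*% Z + Dinv))
  rhs <- c(t(X) %*% Rinv %*% design$y, t(Z) %*% Rinv %*% design$y)
  sol <- c(fit$fixed, u)
  resid <- C %*% sol - rhs
  expect_lt(max(abs(resid)) / max(abs(rhs)), 1e-6)
})

test_that("EM warm-up iterations never decrease the REML log-likelihood", {
  dat <- small_dataset(n_lines = 14, k = 3, seed = 44)
  fit <- megblup(dat$pheno, dat$K, em_iter = 15, max_iter = 10, tol = 1e-6)
  expect_gte(length(fit$em_trace), 15)
  expect_true(all(diff(fit$em_trace) > -1e-6))
})

test_that("richer factor structures never fit worse than nested ones", {
  dat <- small_dataset(n_lines = 16, k = 3, seed = 45)
  f1 <- megblup(dat$pheno, dat$K, fa_order = 1, max_iter = 300, tol = 1e-9)
  f2 <- megblup(dat$pheno, dat$K, fa_order = 2, max_iter = 300, tol = 1e-9,
                varcomp_init = f1$varcomp)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
})

test_that("BLUEs match balanced means, translation and a GLS oracle", {
  # balanced two-replicate data with (near) zero design variance: the BLUE
  # is the plot mean per cell
  ph <- expand.grid(line = paste0("L", 1:5), rep = c("R1", "R2"),
                    env = c("E1", "E2"), stringsAsFactors = FALSE)
  ph$trial <- "T"; ph$block <- "B"
  set.seed(11)
  ph$value <- rnorm(nrow(ph))
  vc0 <- list(sigma2 = c(trial = 1e-9, rep_trial = 1e-9, block = 1e-9),
              resid_var = c(1, 1))
  bl <- suppressMessages(compute_blues(ph, varcomp = vc0))
  means <- tapply(ph$value, paste(ph$line, ph$env, sep = "\r"), mean)
  expect_lt(max(abs(bl$blue - means[paste(bl$line, bl$env, sep = "\r")])),
            1e-6)
  # translation equivariance: shifting one environment shifts its BLUEs
  ph2 <- ph; ph2$value[ph2$env == "E2"] <- ph2$value[ph2$env == "E2"] + 5
  bl2 <- suppressMessages(compute_blues(ph2, varcomp = vc0))
  expect_lt(max(abs((bl2$blue - bl$blue)[bl$env == "E2"] - 5)), 1e-8)
  expect_lt(max(abs((bl2$blue - bl$blue)[bl$env == "E1"])), 1e-8)
  # unbalanced data with block effects: agree with a direct GLS solve
  dat <- small_dataset(n_lines = 8, k = 2, seed = 46)
  keep <- !(dat$pheno$line == rownames(dat$geno)[1] & dat$pheno$env == "SE2")
  ph3 <- dat$pheno[keep, ]
  vc <- list(sigma2 = c(trial = 0.05, rep_trial = 0.03, block = 0.08),
             resid_var = c(0.5, 0.6))
  bl3 <- suppressMessages(compute_blues(ph3, varcomp = vc))
  orc <- gls_blues_oracle(ph3, vc)
  m <- match(paste(bl3$line, bl3$env), paste(orc$line, orc$env))
  expect_lt(max(abs(bl3$blue - orc$blue[m])), 1e-6)
})

test_that("spatial autocorrelations are recovered on a gridded trial", {
  arch <- genetic_architecture(Lambda = matrix(sqrt(0.4), 1, 1), Psi = 0,
                               resid_var = 1, env_main_var = 0,
                               trial_var = 0, rep_var = 0.05, block_var = 0,
                               spatial_rho_col = 0.5, spatial_rho_row = 0.35)
  des <- trial_design_spec(n_environments = 1, n_trials_per_env = 1,
                           entries_per_trial = 150, checks_per_trial = 0,
                           n_replicates = 2, grid_cols = 15, block_size = 10)
  pop <- population_spec(n_founders = 30, n_markers = 500, seed = 47)
  dat <- sim_breeding_dataset(pop, des, arch, n_lines = 150, seed = 47)
  fit <- suppressMessages(
    megblup(dat$pheno, compute_G(dat$geno), model = "single_env",
            spatial = TRUE, max_iter = 60, tol = 1e-6))
  rho <- fit$varcomp$spatial_rho
  expect_lt(abs(rho[1, "col"] - 0.5), 0.15)
  expect_lt(abs(rho[1, "row"] - 0.35), 0.15)
})
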