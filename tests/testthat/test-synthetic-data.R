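test_that("founder genotypes respect range, frequency and seed", {
  spec <- population_spec(n_founders = 50, n_markers = 1000,
                          maf_range = c(0.05, 0.5), seed = 1)
  g <- simulate_founder_genotypes(spec)
  expect_equal(dim(g), c(50, 1000))
  expect_true(all(g %in% 0:2))
  expect_identical(simulate_founder_genotypes(spec), g)
  # at fixed frequency 0.5 the expected dosage mean is 1 (within 3 SE)
  spec5 <- population_spec(n_founders = 200, n_markers = 500,
                           maf_range = c(0.5, 0.5), seed = 2)
  mm <- colMeans(simulate_founder_genotypes(spec5))
  se3 <- 3 * sd(mm) / sqrt(length(mm))
  expect_lt(abs(mean(mm) - 1), max(se3, 0.01))
  expect_error(population_spec(maf_range = c(0, 0.6)), "maf_range")
})

test_that("families follow Mendelian expectations and drawn sizes", {
  founders <- rbind(F1 = rep(c(0, 2), 5), F2 = rep(c(0, 0), 5))
  colnames(founders) <- paste0("M", 1:10)
  spec0 <- population_spec(n_founders = 2, n_markers = 10, n_crosses = 3,
                           family_size_range = c(4, 4), n_selfing = 0,
                           seed = 3)
  fam <- simulate_families(founders, spec0)
  # homozygous-0 loci in both parents -> progeny dosage 0
  expect_true(all(fam$geno[, founders["F1", ] + founders["F2", ] == 0] == 0))
  # 2 x 0 loci -> all F1 progeny dosage 1 (no selfing)
  expect_true(all(fam$geno[, founders["F1", ] == 2 & founders["F2", ] == 0] == 1))
  expect_identical(nrow(fam$geno), nrow(fam$pedigree))
  # total progeny equals the sum of drawn family sizes (fixed-size recount)
  spec3 <- population_spec(n_founders = 10, n_markers = 50, n_crosses = 45,
                           family_size_range = c(3, 3), seed = 4)
  f2 <- simulate_families(simulate_founder_genotypes(spec3), spec3)
  expect_identical(nrow(f2$geno), 45L * 3L)
  expect_identical(nrow(f2$pedigree), 45L * 3L)
  # variable sizes stay within the requested range in total
  specv <- population_spec(n_founders = 10, n_markers = 50, n_crosses = 45,
                           family_size_range = c(1, 9), seed = 4)
  fv <- simulate_families(simulate_founder_genotypes(specv), specv)
  expect_true(nrow(fv$geno) >= 45 && nrow(fv$geno) <= 45 * 9)
  expect_identical(nrow(fv$geno), nrow(fv$pedigree))
  expect_error(simulate_families(founders[1, , drop = FALSE], spec0),
               "at least 2")
})

test_that("trial layout reproduces the expected plot counts and structure", {
  des <- trial_design_spec(n_environments = 6, n_trials_per_env = 5,
                           entries_per_trial = 56, checks_per_trial = 4,
                           n_replicates = 2, grid_cols = 15, block_size = 8)
  lines <- sprintf("L%03d", 1:280)
  lay <- assign_trial_layout(lines, des, seed = 1)
  # 5 trials x (56 + 4) entries x 2 reps = 600 plots per environment
  expect_identical(as.integer(table(lay$env)), rep(600L, 6))
  # unique (env, row, col)
  expect_false(any(duplicated(lay[, c("env", "row", "col")])))
  # each test line appears once per replicate in exactly one trial per env
  cnt <- table(lay$line[!lay$is_check], lay$env[!lay$is_check])
  expect_true(all(cnt == 2))
  tr <- tapply(lay$trial[!lay$is_check], lay$line[!lay$is_check],
               function(x) length(unique(x)))
  expect_true(all(tr == 1))
  # checks appear in every trial of every environment
  chk <- lay[lay$is_check, ]
  expect_identical(nrow(unique(chk[, c("env", "trial")])), 30L)
  # blocks nested in replicate: each block belongs to one (trial, rep)
  expect_identical(nrow(unique(lay[, c("block", "trial", "rep")])),
                   length(unique(lay$block)))
  # determinism
  expect_identical(assign_trial_layout(lines, des, seed = 1), lay)
  # minimal case: 1 line, 1 trial, 1 rep -> 1 + checks plots
  des1 <- trial_design_spec(n_environments = 1, n_trials_per_env = 1,
                            entries_per_trial = 1, checks_per_trial = 2,
                            n_replicates = 1, grid_cols = 3, block_size = 3)
  expect_identical(nrow(assign_trial_layout("L1", des1, seed = 1)), 3L)
  # an undersized grid errors with the deficit
  des_small <- trial_design_spec(n_environments = 1, n_trials_per_env = 1,
                                 entries_per_trial = 10, checks_per_trial = 0,
                                 n_replicates = 2, grid_cols = 5,
                                 grid_rows = 2, block_size = 5)
  expect_error(assign_trial_layout(sprintf("L%02d", 1:10), des_small, seed = 1),
               "too small")
})

test_that("phenotypes decompose as designed", {
  # perfect correlation: no specific variance, equal loadings
  dat <- small_dataset(n_lines = 20, k = 3, seed = 5,
                       Lambda = matrix(1, 3, 1), Psi = rep(0, 3),
                       resid_var = rep(0.5, 3))
  tv <- attr(dat$pheno, "true_values")
  expect_lt(max(abs(tv[, 1] - tv[, 2])), 1e-10)
  expect_lt(max(abs(tv[, 1] - tv[, 3])), 1e-10)
  # null genetics: phenotypic variance equals design + residual variance
  arch0 <- genetic_architecture(Lambda = matrix(0, 2, 1), Psi = c(0, 0),
                                resid_var = c(0.6, 0.6), env_main_var = 0,
                                trial_var = 0, rep_var = 0.1, block_var = 0.1)
  des0 <- trial_design_spec(n_environments = 2, n_trials_per_env = 1,
                            entries_per_trial = 150, checks_per_trial = 0,
                            n_replicates = 2, grid_cols = 15, block_size = 10)
  pop0 <- population_spec(n_founders = 30, n_markers = 100, seed = 6)
  d0 <- sim_breeding_dataset(pop0, des0, arch0, n_lines = 150, seed = 6)
  expect_lt(abs(var(d0$pheno$value) / (0.6 + 0.1 + 0.1) - 1), 0.15)
  expect_true(all(attr(d0$pheno, "true_values") == 0))
})

test_that("factor-analytic identity sets the genetic correlation", {
  # k = 2, Lambda = (1, 0.5), Psi = (0, 0.75): corr = 0.5 / sqrt(1) = 0.5
  dat <- small_dataset(n_lines = 500, k = 2, seed = 7,
                       Lambda = matrix(c(1, 0.5), 2, 1), Psi = c(0, 0.75),
                       resid_var = c(0.5, 0.5), n_selfing = 0)
  tv <- attr(dat$pheno, "true_values")
  tv <- tv[rownames(dat$geno), ] # test lines only
  expect_lt(abs(cor(tv[, 1], tv[, 2]) - 0.5), 0.08)
})

test_that("realized genetic covariance approaches the target", {
  # unrelated panel (the kinship diagonal is near 1), averaged over a few
  # marker-effect draws: the line-marginal covariance of the true genetic
  # values converges to Lambda Lambda' + Psi
  Lam <- matrix(c(0.9, 0.7, 0.5), 3, 1)
  Psi <- c(0.1, 0.3, 0.5)
  pop <- population_spec(n_founders = 2000, n_markers = 2000, seed = 8)
  des <- trial_design_spec(n_environments = 3, n_trials_per_env = 1,
                           entries_per_trial = 2000, checks_per_trial = 0,
                           n_replicates = 1, grid_cols = 50, block_size = 10)
  arch <- genetic_architecture(Lambda = Lam, Psi = Psi,
                               resid_var = rep(0.5, 3))
  geno <- simulate_founder_genotypes(pop)
  layout <- assign_trial_layout(rownames(geno), des, seed = 8, envs = paste0("SE", 1:3))
  Go_emp <- matrix(0, 3, 3)
  for (sd in 1:3) {
    ph <- simulate_phenotypes(geno, layout, arch, seed = 8 + sd)
    Go_emp <- Go_emp + cov(attr(ph, "true_values")) / 3
  }
  Go_true <- fa_covariance(Lam, Psi)
  expect_lt(max(abs(Go_emp - Go_true)) / max(diag(Go_true)), 0.05)
  # plot heritability identity on the simulation truth
  h2_emp <- diag(Go_emp) / (diag(Go_emp) + arch$resid_var)
  h2_target <- diag(Go_true) / (diag(Go_true) + arch$resid_var)
  expect_lt(max(abs(h2_emp - h2_target)), 0.05)
})

test_that("spatial noise shows the targeted lag-1 autocorrelations", {
  arch <- genetic_architecture(Lambda = matrix(0, 1, 1), Psi = 0,
                               resid_var = 1, env_main_var = 0,
                               trial_var = 0, rep_var = 0, block_var = 0,
                               spatial_rho_col = 0.6, spatial_rho_row = 0.4)
  des <- trial_design_spec(n_environments = 1, n_trials_per_env = 1,
                           entries_per_trial = 5000, checks_per_trial = 0,
                           n_replicates = 2, grid_cols = 100,
                           block_size = 20)
  pop <- population_spec(n_founders = 100, n_markers = 60, seed = 9)
  dat <- sim_breeding_dataset(pop, des, arch, n_lines = 5000, seed = 9)
  ph <- dat$pheno
  fld <- matrix(NA_real_, max(ph$row), max(ph$col))
  fld[cbind(ph$row, ph$col)] <- ph$value
  lag_row <- cor(as.vector(fld[-1, ]), as.vector(fld[-nrow(fld), ]),
                 use = "complete.obs")
  lag_col <- cor(as.vector(fld[, -1]), as.vector(fld[, -ncol(fld)]),
                 use = "complete.obs")
  expect_lt(abs(lag_row - 0.4), 0.05)
  expect_lt(abs(lag_col - 0.6), 0.05)
})

test_that("the full simulation is a pure function of spec and seed", {
  d1 <- small_dataset(n_lines = 10, k = 2, seed = 12, checks = 1)
  d2 <- small_dataset(n_lines = 10, k = 2, seed = 12, checks = 1)
  expect_identical(d1$pheno, d2$pheno)
  expect_identical(d1$geno, d2$geno)
  d3 <- small_dataset(n_lines = 10, k = 2, seed = 13, checks = 1)
  expect_false(identical(d1$pheno$value, d3$pheno$value))
})
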