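#' Specification of a simulated breeding population
#'
#' @param n_founders number of founder lines.
#' @param n_markers number of biallelic markers.
#' @param maf_range range of founder allele frequencies, within `(0, 0.5]`.
#' @param n_crosses number of biparental crosses.
#' @param family_size_range range of progeny per cross (inclusive), within
#'   `[1, 50]`; sizes are drawn uniformly.
#' @param n_selfing generations of selfing applied to each progeny after the
#'   cross, approximating the near-homozygosity of F4-derived lines.
#' @param seed integer seed.
#' @return validated list of class `population_spec`.
#' @export
population_spec <- function(n_founders = 60, n_markers = 2000,
                            maf_range = c(0.05, 0.5), n_crosses = 56,
                            family_size_range = c(1, 9), n_selfing = 3,
                            seed = 1) {
  stopifnot(n_founders >= 2, n_markers >= 1, n_crosses >= 1, n_selfing >= 0)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be within (0, 0.5] with min <= max")
  }
  if (length(family_size_range) != 2 || family_size_range[1] < 1 ||
      family_size_range[2] > 50 || family_size_range[1] > family_size_range[2]) {
    stop("family_size_range must be within [1, 50] with min <= max")
  }
  structure(list(n_founders = as.integer(n_founders),
                 n_markers = as.integer(n_markers), maf_range = maf_range,
                 n_crosses = as.integer(n_crosses),
                 family_size_range = as.integer(family_size_range),
                 n_selfing = as.integer(n_selfing), seed = as.integer(seed)),
            class = "population_spec")
}

#' Specification of a multi-environment trial design
#'
#' Emulates the structure of early-stage variety trials: in every environment
#' the test lines are grouped into trials of fixed entry count, each trial is
#' grown with repeated checks in all replicates, and plots sit on a
#' row-by-column grid so spatially correlated field trends can be simulated
#' and modelled.  Incomplete blocks of near-equal size are nested within
#' replicate and trial.
#'
#' @param n_environments number of selection environments.
#' @param n_trials_per_env trials per environment.
#' @param entries_per_trial test entries per trial.
#' @param checks_per_trial check entries repeated in every trial.
#' @param n_replicates replicates per trial.
#' @param grid_cols field columns of each environment's grid.
#' @param grid_rows field rows; `NULL` sizes the grid to the plot count.
#' @param block_size target incomplete-block size (blocks are `block_size` or
#'   `block_size - 1` plots so each replicate is covered exactly).
#' @return validated list of class `trial_design_spec`.
#' @export
trial_design_spec <- function(n_environments = 6, n_trials_per_env = 5,
                              entries_per_trial = 56, checks_per_trial = 4,
                              n_replicates = 2, grid_cols = 15,
                              grid_rows = NULL, block_size = 8) {
  stopifnot(n_environments >= 1, n_trials_per_env >= 1, entries_per_trial >= 1,
            checks_per_trial >= 0, n_replicates >= 1, grid_cols >= 1,
            block_size >= 2)
  structure(list(n_environments = as.integer(n_environments),
                 n_trials_per_env = as.integer(n_trials_per_env),
                 entries_per_trial = as.integer(entries_per_trial),
                 checks_per_trial = as.integer(checks_per_trial),
                 n_replicates = as.integer(n_replicates),
                 grid_cols = as.integer(grid_cols),
                 grid_rows = if (is.null(grid_rows)) NULL else as.integer(grid_rows),
                 block_size = as.integer(block_size)),
            class = "trial_design_spec")
}

#' Genetic architecture of the simulated trait
#'
#' The between-environment covariance of true genetic values is the
#' factor-analytic matrix `Lambda %*% t(Lambda) + diag(Psi)`.  Genetic values
#' are built from sampled marker effects (`n_qtl` markers per latent factor)
#' so genomic prediction has a mechanistic target; design effects and the
#' separable AR1xAR1 spatial residual are layered on top.
#'
#' @param Lambda k x m matrix of environment loadings on the latent factors.
#' @param Psi length-k vector of environment-specific genetic variances.
#' @param resid_var length-k vector of residual (spatial) variances.
#' @param n_qtl markers sampled as causal per latent factor.
#' @param mean overall trait mean (e.g. grain yield in t/ha).
#' @param env_main_var,trial_var,rep_var,block_var design-effect variances.
#' @param spatial_rho_col,spatial_rho_row AR1 correlations along field
#'   columns and rows, in `(-1, 1)`; zero gives independent plot errors.
#' @return validated list of class `genetic_architecture`.
#' @export
genetic_architecture <- function(Lambda, Psi, resid_var, n_qtl = 300,
                                 mean = 6, env_main_var = 0.2,
                                 trial_var = 0.05, rep_var = 0.05,
                                 block_var = 0.05, spatial_rho_col = 0,
                                 spatial_rho_row = 0) {
  Lambda <- as.matrix(Lambda)
  k <- nrow(Lambda)
  stopifnot(length(Psi) == k, length(resid_var) == k, n_qtl >= 1)
  if (any(Psi < 0) || any(resid_var < 0) ||
      any(c(env_main_var, trial_var, rep_var, block_var) < 0)) {
    stop("variances must be nonnegative")
  }
  if (abs(spatial_rho_col) >= 1 || abs(spatial_rho_row) >= 1) {
    stop("spatial correlations must lie in (-1, 1)")
  }
  Go <- tcrossprod(Lambda) + diag(Psi, k)
  if (min(eigen(Go, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("target genetic covariance is not positive semi-definite")
  }
  structure(list(Lambda = Lambda, Psi = as.numeric(Psi),
                 resid_var = as.numeric(resid_var), n_qtl = as.integer(n_qtl),
                 mean = mean, env_main_var = env_main_var,
                 trial_var = trial_var, rep_var = rep_var,
                 block_var = block_var, spatial_rho_col = spatial_rho_col,
                 spatial_rho_row = spatial_rho_row, Go = Go),
            class = "genetic_architecture")
}

#' Simulate founder genotypes
#'
#' Draws each marker's allele frequency uniformly from `maf_range` and each
#' line's dosage as Binomial(2, p) in linkage equilibrium (loci unlinked).
#'
#' @param spec a [population_spec()].
#' @return lines x markers dosage matrix in \{0, 1, 2\}.
#' @export
simulate_founder_genotypes <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  local_rng(spec$seed)
  p <- stats::runif(spec$n_markers, spec$maf_range[1], spec$maf_range[2])
  g <- matrix(stats::rbinom(spec$n_founders * spec$n_markers, 2,
                            rep(p, each = spec$n_founders)),
              nrow = spec$n_founders,
              dimnames = list(sprintf("F%03d", seq_len(spec$n_founders)),
                              sprintf("M%05d", seq_len(spec$n_markers))))
  g
}

#' Simulate biparental families
#'
#' Crosses random founder pairs, draws family sizes uniformly from
#' `family_size_range`, and generates progeny by independent-locus Mendelian
#' sampling (one gamete per parent, loci unlinked), followed by `n_selfing`
#' generations of selfing of each progeny.
#'
#' @param founders founder dosage matrix from [simulate_founder_genotypes()].
#' @param spec a [population_spec()].
#' @param n_progeny optional total progeny count; when given, families are
#'   drawn until the total is reached (the last family is trimmed) and
#'   `spec$n_crosses` is ignored.
#' @return list with `geno` (progeny dosage matrix) and `pedigree`
#'   (data frame `id`, `parent1`, `parent2`, one row per progeny).
#' @export
simulate_families <- function(founders, spec, n_progeny = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (nrow(founders) < 2) stop("need at least 2 founder lines to cross")
  local_rng(spec$seed + 1L)
  fam_lo <- spec$family_size_range[1]; fam_hi <- spec$family_size_range[2]
  draw_sizes <- function(n) {
    fam_lo + sample.int(fam_hi - fam_lo + 1L, n, replace = TRUE) - 1L
  }
  sizes <- integer(0)
  if (is.null(n_progeny)) {
    sizes <- draw_sizes(spec$n_crosses)
  } else {
    while (sum(sizes) < n_progeny) {
      sizes <- c(sizes, draw_sizes(1))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_progeny)
    sizes <- sizes[sizes > 0]
  }
  n_cross <- length(sizes)
  parents <- t(vapply(seq_len(n_cross),
                      function(i) sample.int(nrow(founders), 2),
                      integer(2)))
  total <- sum(sizes)
  geno <- matrix(0, total, ncol(founders),
                 dimnames = list(NULL, colnames(founders)))
  ped <- data.frame(id = character(total), parent1 = character(total),
                    parent2 = character(total), stringsAsFactors = FALSE)
  row <- 0L
  for (i in seq_len(n_cross)) {
    g1 <- founders[parents[i, 1], ]; g2 <- founders[parents[i, 2], ]
    for (j in seq_len(sizes[i])) {
      row <- row + 1L
      d <- gamete(g1) + gamete(g2)
      for (s in seq_len(spec$n_selfing)) d <- gamete(d) + gamete(d)
      geno[row, ] <- d
      ped$id[row] <- sprintf("L%04d", row)
      ped$parent1[row] <- rownames(founders)[parents[i, 1]]
      ped$parent2[row] <- rownames(founders)[parents[i, 2]]
    }
  }
  rownames(geno) <- ped$id
  list(geno = geno, pedigree = ped)
}

# One gamete from an unphased dosage vector under linkage equilibrium:
# hom loci transmit deterministically, het loci transmit a Bernoulli(1/2).
gamete <- function(d) {
  out <- d / 2
  het <- d == 1
  out[het] <- stats::rbinom(sum(het), 1, 0.5)
  out
}

#' Assign lines to a multi-environment trial layout
#'
#' Groups the test lines into trials (the same grouping in every
#' environment), adds the checks to every trial, replicates each trial, and
#' places plots on the environment's row-by-column grid.  Replicates occupy
#' consecutive row bands within their trial; incomplete blocks of near-equal
#' size are nested within replicate.  Entry-to-plot randomization is
#' independent per environment, trial and replicate.
#'
#' @param lines character vector of test line ids.
#' @param design a [trial_design_spec()].
#' @param seed integer seed.
#' @param envs optional environment labels (default `SE1 ... SEk`).
#' @param year year label stored with each plot.
#' @return plot-record data frame with columns `line`, `env`, `year`,
#'   `trial`, `rep`, `block`, `row`, `col`, `value` (NA) and `is_check`.
#' @export
assign_trial_layout <- function(lines, design, seed = 1, envs = NULL,
                                year = 2021L) {
  stopifnot(inherits(design, "trial_design_spec"))
  lines <- as.character(lines)
  n <- length(lines)
  cap <- design$entries_per_trial * design$n_trials_per_env
  if (n > cap) {
    stop(sprintf("%d lines exceed trial capacity %d (= %d trials x %d entries)",
                 n, cap, design$n_trials_per_env, design$entries_per_trial))
  }
  local_rng(seed)
  if (is.null(envs)) envs <- sprintf("SE%d", seq_len(design$n_environments))
  checks <- if (design$checks_per_trial > 0)
    sprintf("CHK%d", seq_len(design$checks_per_trial)) else character(0)
  # trial grouping of entries, shared across environments
  perm <- sample(lines)
  nt <- design$n_trials_per_env
  sizes <- rep(n %/% nt, nt)
  if (n %% nt > 0) sizes[seq_len(n %% nt)] <- sizes[seq_len(n %% nt)] + 1L
  groups <- split(perm, rep(seq_len(nt), times = sizes))
  plots_per_rep <- vapply(groups, length, integer(1)) + length(checks)
  rows_per_rep <- ceiling(plots_per_rep / design$grid_cols)
  rows_needed <- sum(rows_per_rep * design$n_replicates)
  grid_rows <- design$grid_rows %||% rows_needed
  if (grid_rows * design$grid_cols <
      sum(plots_per_rep) * design$n_replicates ||
      grid_rows < rows_needed) {
    stop(sprintf("grid of %d rows x %d cols too small: need %d rows for %d plots",
                 grid_rows, design$grid_cols, rows_needed,
                 sum(plots_per_rep) * design$n_replicates))
  }
  out <- vector("list", design$n_environments)
  for (e in seq_along(envs)) {
    rows_e <- list(); row_offset <- 0L
    for (t in seq_along(groups)) {
      entries <- c(groups[[t]], checks)
      for (r in seq_len(design$n_replicates)) {
        np <- length(entries)
        ord <- sample(entries)
        nb <- max(1L, round(np / design$block_size))
        block_id <- sort(rep(seq_len(nb), length.out = np))
        pos <- seq_len(np) - 1L
        rows_e[[length(rows_e) + 1L]] <- data.frame(
          line = ord, env = envs[e], year = year,
          trial = sprintf("T%d", t), rep = sprintf("R%d", r),
          block = sprintf("T%d.R%d.B%d", t, r, block_id),
          row = row_offset + pos %/% design$grid_cols + 1L,
          col = pos %% design$grid_cols + 1L,
          value = NA_real_,
          is_check = ord %in% checks,
          stringsAsFactors = FALSE)
        row_offset <- row_offset + rows_per_rep[t]
      }
    }
    out[[e]] <- do.call(rbind, rows_e)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "grid") <- c(rows = grid_rows, cols = design$grid_cols)
  attr(out, "seed") <- seed
  out
}

#' Simulate phenotypes on a trial layout
#'
#' Builds each plot value as overall mean + environment + trial +
#' replicate-in-trial + incomplete-block effects + the line-by-environment
#' genetic value + spatially correlated residual noise.  Genetic values of
#' genotyped lines are constructed from `n_qtl` sampled marker effects per
#' latent factor (standardized factor scores), so their covariance across
#' environments matches `Lambda Lambda' + diag(Psi)`; check lines receive
#' fixed true values drawn from the same covariance and replicated across
#' trials.  With `direct_mvn = TRUE` the genetic values are instead drawn
#' directly from a matrix normal with row covariance G (from the markers)
#' and column covariance `Go` — the distributional assumption of the
#' multi-environment model, useful as a simulation oracle.
#'
#' @param geno dosage matrix of the test lines (no missing values).
#' @param layout plot-record table from [assign_trial_layout()].
#' @param arch a [genetic_architecture()].
#' @param seed integer seed.
#' @param direct_mvn draw genetic values directly from the model MVN instead
#'   of through marker effects.
#' @return the layout with `value` filled; the true genetic values are
#'   attached as `attr(, "true_values")` (lines x environments matrix).
#' @export
simulate_phenotypes <- function(geno, layout, arch, seed = 1,
                                direct_mvn = FALSE) {
  stopifnot(inherits(arch, "genetic_architecture"))
  if (anyNA(layout$row) || anyNA(layout$col)) stop("layout is incomplete")
  if (anyNA(geno)) stop("genotypes contain missing values")
  local_rng(seed)
  envs <- unique(layout$env)
  k <- length(envs)
  if (nrow(arch$Lambda) != k) {
    stop(sprintf("architecture has %d environments, layout has %d",
                 nrow(arch$Lambda), k))
  }
  test_lines <- rownames(geno)
  layout_lines <- unique(layout$line)
  checks <- setdiff(layout_lines, test_lines)
  N <- length(test_lines)
  # genetic values of genotyped lines
  # Genetic values live on the scale of the model distribution
  # u ~ N(0, Go %x% K): variances are per unit of genomic relationship, so a
  # line's marginal variance is diag(K) * diag(Go).
  need_K <- direct_mvn || any(arch$Psi > 0)
  if (need_K) {
    K <- stabilize_kinship(compute_G(geno))
    LK <- t(chol(K))
  }
  if (direct_mvn) {
    U <- matrix(stats::rnorm(N * k), N, k)
    g_test <- LK %*% U %*% chol_psd(arch$Go) # row cov K, col cov Go
  } else {
    m <- ncol(arch$Lambda)
    p <- colMeans(geno) / 2
    W <- sweep(geno, 2, 2 * p, "-")
    Fscore <- matrix(0, N, m)
    for (j in seq_len(m)) {
      qtl <- sample.int(ncol(W), min(arch$n_qtl, ncol(W)))
      denom <- 2 * sum(p[qtl] * (1 - p[qtl]))
      # Cov(W beta) = G (VanRaden scale) when Var(beta) = 1 / denom
      beta <- stats::rnorm(length(qtl), 0, sqrt(1 / denom))
      Fscore[, j] <- W[, qtl, drop = FALSE] %*% beta
    }
    spec_dev <- if (any(arch$Psi > 0)) {
      LK %*% matrix(stats::rnorm(N * k), N, k)
    } else {
      matrix(0, N, k)
    }
    g_test <- Fscore %*% t(arch$Lambda) +
      sweep(spec_dev, 2, sqrt(arch$Psi), "*")
  }
  rownames(g_test) <- test_lines
  g_chk <- matrix(0, length(checks), k, dimnames = list(checks, envs))
  if (length(checks)) {
    Z <- matrix(stats::rnorm(length(checks) * k), length(checks), k)
    g_chk <- Z %*% chol_psd(arch$Go)
    rownames(g_chk) <- checks
  }
  gmat <- rbind(g_test, g_chk)
  colnames(gmat) <- envs
  # design effects
  env_eff <- stats::setNames(stats::rnorm(k, 0, sqrt(arch$env_main_var)), envs)
  key_trial <- unique(paste(layout$env, layout$trial))
  trial_eff <- stats::setNames(stats::rnorm(length(key_trial), 0,
                                            sqrt(arch$trial_var)), key_trial)
  key_rep <- unique(paste(layout$env, layout$trial, layout$rep))
  rep_eff <- stats::setNames(stats::rnorm(length(key_rep), 0,
                                          sqrt(arch$rep_var)), key_rep)
  key_blk <- unique(paste(layout$env, layout$block))
  blk_eff <- stats::setNames(stats::rnorm(length(key_blk), 0,
                                          sqrt(arch$block_var)), key_blk)
  # spatial / residual noise per environment over the full field grid
  grid <- attr(layout, "grid")
  nr <- max(layout$row); nc <- max(layout$col)
  noise <- numeric(nrow(layout))
  for (e in seq_along(envs)) {
    idx <- which(layout$env == envs[e])
    s2 <- arch$resid_var[e]
    if (arch$spatial_rho_col == 0 && arch$spatial_rho_row == 0) {
      noise[idx] <- stats::rnorm(length(idx), 0, sqrt(s2))
    } else {
      Lr <- t(chol(ar1_correlation(nr, arch$spatial_rho_row)))
      Lc <- chol(ar1_correlation(nc, arch$spatial_rho_col))
      Efield <- sqrt(s2) * (Lr %*% matrix(stats::rnorm(nr * nc), nr, nc) %*% Lc)
      noise[idx] <- Efield[cbind(layout$row[idx], layout$col[idx])]
    }
  }
  value <- arch$mean + env_eff[layout$env] +
    trial_eff[paste(layout$env, layout$trial)] +
    rep_eff[paste(layout$env, layout$trial, layout$rep)] +
    blk_eff[paste(layout$env, layout$block)] +
    gmat[cbind(match(layout$line, rownames(gmat)),
               match(layout$env, envs))] +
    noise
  out <- layout
  out$value <- as.numeric(value)
  attr(out, "true_values") <- gmat
  attr(out, "grid") <- grid
  attr(out, "seed") <- seed
  out
}

#' Simulate a complete breeding dataset
#'
#' One-call wrapper tying the population, trial-design and architecture
#' pieces together: founders are crossed into families until the trial
#' capacity is filled, markers are taken as-is (no QC needed on simulated
#' data), the layout is generated and phenotypes are simulated.
#'
#' @param pop a [population_spec()].
#' @param design a [trial_design_spec()].
#' @param arch a [genetic_architecture()].
#' @param n_lines number of test lines (default: full trial capacity).
#' @param seed integer seed controlling all stages.
#' @param envs,year,direct_mvn passed through to the layout/phenotype steps.
#' @return list with `pheno` (plot records), `geno` (test-line dosages),
#'   `pedigree`, and `true_values`.
#' @export
sim_breeding_dataset <- function(pop, design, arch,
                                 n_lines = design$entries_per_trial *
                                   design$n_trials_per_env,
                                 seed = pop$seed, envs = NULL, year = 2021L,
                                 direct_mvn = FALSE) {
  pop$seed <- as.integer(seed)
  founders <- simulate_founder_genotypes(pop)
  fam <- simulate_families(founders, pop, n_progeny = n_lines)
  layout <- assign_trial_layout(fam$pedigree$id, design, seed = seed + 2L,
                                envs = envs, year = year)
  pheno <- simulate_phenotypes(fam$geno, layout, arch, seed = seed + 3L,
                               direct_mvn = direct_mvn)
  list(pheno = pheno, geno = fam$geno, pedigree = fam$pedigree,
       true_values = attr(pheno, "true_values"))
}

# Upper Cholesky factor tolerating a semi-definite matrix.
chol_psd <- function(S, eps = 1e-10) {
  chol(S + eps * mean(diag(S)) * diag(nrow(S)))
}

#' Canonical six-environment demo architecture
#'
#' A single-factor genetic architecture emulating the structure of a
#' six-selection-environment wheat yield-testing stage: five moderately to
#' highly correlated environments (pairwise genetic correlations about
#' 0.67-0.86) plus one weakly, slightly negatively correlated low-heritability
#' environment (an early-heat-stress analogue with plot heritability 0.18).
#' Plot-level heritabilities span 0.18-0.6 against a unit residual variance.
#' Used throughout the package's examples, tests and acceptance script as
#' the standard simulation truth.
#'
#' @param h2 plot-level heritabilities per environment.
#' @param factor_cor signed correlation of each environment with the latent
#'   factor.
#' @param ... further arguments passed to [genetic_architecture()]
#'   (e.g. design-effect variances, spatial correlations, `n_qtl`).
#' @return list with `arch` (a [genetic_architecture()]), `h2_true` and
#'   `corr_true` (the implied between-environment genetic correlations).
#' @export
demo_architecture <- function(h2 = c(0.5, 0.45, 0.6, 0.4, 0.18, 0.35),
                              factor_cor = c(0.93, 0.9, 0.92, 0.85,
                                             -0.08, 0.8),
                              ...) {
  stopifnot(length(h2) == length(factor_cor), all(h2 > 0), all(h2 < 1),
            all(abs(factor_cor) <= 1))
  sg <- sqrt(h2 / (1 - h2)) # residual variance 1 per environment
  Lambda <- matrix(factor_cor * sg, length(h2), 1)
  Psi <- sg^2 * (1 - factor_cor^2)
  arch <- genetic_architecture(Lambda = Lambda, Psi = Psi,
                               resid_var = rep(1, length(h2)), ...)
  list(arch = arch, h2_true = h2,
       corr_true = genetic_correlations(arch$Go))
}
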