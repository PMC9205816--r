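#' Fit a multi-environment genomic/pedigree BLUP mixed model by REML
#'
#' Fits the plot-level linear mixed model of a multi-environment (or single
#' environment) variety trial with a factor-analytic between-environment
#' genetic covariance: the phenotype is modelled as overall mean + fixed
#' replicate effect (+ optional fixed or random environment main effect) +
#' random trial, replicate-within-trial and incomplete-block effects + a
#' line-by-environment genetic effect `u ~ N(0, Go %x% K)` with
#' `Go = Lambda Lambda' + diag(Psi)`, and independent per-environment
#' residuals, optionally with separable AR1xAR1 spatial correlation over the
#' field grid.  Variance parameters are estimated by REML (EM warm-up
#' followed by quasi-Newton iterations with analytic gradients); genetic
#' effects of every line in the kinship matrix — phenotyped or not — are the
#' empirical BLUP solutions of the mixed-model equations at the converged
#' components.
#'
#' @param pheno plot-record data frame (columns `line`, `env`, `trial`,
#'   `rep`, `block`, `value`; `year` for `model = "multi_env_year"`; `row`
#'   and `col` when `spatial = TRUE`).
#' @param kinship genomic ([compute_G()]) or pedigree ([compute_A()])
#'   relationship matrix.  Its line set defines the prediction targets; all
#'   phenotyped lines must be present (see [block_diagonal_kinship()] for
#'   partially genotyped data).
#' @param model,fa_order,env_effect,spatial,random_terms,resid_by_env model
#'   structure, see [model_spec()].
#' @param engine `"general"` (any design), `"balanced"` (fast path for
#'   complete line x environment tables with two replicates, iid residuals
#'   and no design variance components) or `"auto"` (balanced when
#'   applicable).
#' @param em_iter EM warm-up iterations before the quasi-Newton phase.
#' @param max_iter maximum quasi-Newton iterations.
#' @param tol absolute convergence tolerance on the REML log-likelihood.
#' @param varcomp_init optional starting values (a `varcomp`-like list with
#'   `Lambda`, `Psi`, `sigma2`, `resid_var`).
#' @param estimate set to `FALSE` to skip estimation and solve the
#'   mixed-model equations at `varcomp_init` (which is then required).
#' @return object of class `megblup` with components `varcomp` (loadings,
#'   specific variances, `Go`, design-term variances, residual variances,
#'   spatial correlations, log-likelihood, boundary flags), `gblups`
#'   (lines x environments matrix), `fixed` (estimates), `u` (all random
#'   effect solutions), `fitted`, `residuals` and `convergence`.
#' @seealso [predict.megblup()], [compute_blues()], [plot_heritability()],
#'   [genetic_correlations()]
#' @examples
#' set.seed(1)
#' pop <- population_spec(n_founders = 10, n_markers = 200, n_crosses = 8,
#'                        seed = 42)
#' des <- trial_design_spec(n_environments = 2, n_trials_per_env = 1,
#'                          entries_per_trial = 40, checks_per_trial = 0)
#' arch <- genetic_architecture(Lambda = matrix(c(0.8, 0.6), 2, 1),
#'                              Psi = c(0.1, 0.2), resid_var = c(0.5, 0.5))
#' dat <- sim_breeding_dataset(pop, des, arch, n_lines = 30, seed = 42)
#' K <- compute_G(dat$geno)
#' fit <- megblup(dat$pheno, K, model = "multi_env", max_iter = 50)
#' summary(fit)
#' @export
megblup <- function(pheno, kinship,
                    model = c("multi_env", "multi_env_year", "single_env"),
                    fa_order = 1, env_effect = c("random", "fixed"),
                    spatial = FALSE, random_terms = NULL, resid_by_env = TRUE,
                    engine = c("auto", "general", "balanced"),
                    em_iter = 8, max_iter = 200, tol = 1e-8,
                    varcomp_init = NULL, estimate = TRUE) {
  model <- match.arg(model)
  env_effect <- match.arg(env_effect)
  engine <- match.arg(engine)
  spec <- model_spec(model, fa_order = fa_order, env_effect = env_effect,
                     spatial = spatial, random_terms = random_terms,
                     resid_by_env = resid_by_env)
  K <- stabilize_kinship(kinship)
  design <- build_design(pheno, spec, line_ids = rownames(K))
  use_balanced <- FALSE
  if (engine != "general") {
    ok <- balanced_applicable(design)
    if (engine == "balanced" && !ok) {
      stop("balanced engine requires a complete line x environment table ",
           "with two replicates, no design variance components, fixed ",
           "environment means and iid residuals")
    }
    use_balanced <- ok
  }
  if (use_balanced) {
    fit <- fit_balanced(design, K, fa_order = fa_order, tol = tol,
                        max_iter = max_iter, varcomp_init = varcomp_init,
                        estimate = estimate)
  } else {
    fit <- fit_general(design, K, em_iter = em_iter, max_iter = max_iter,
                       tol = tol, varcomp_init = varcomp_init,
                       estimate = estimate)
  }
  fit$call <- match.call()
  fit
}

# Is the balanced fast path exact for this design?
balanced_applicable <- function(design) {
  spec <- design$spec
  if (spec$spatial || spec$env_effect != "fixed" || !spec$resid_by_env) {
    return(FALSE)
  }
  if (any(names(design$terms) != "genetic")) return(FALSE)
  k <- length(design$env_levels)
  if (k < 2) return(FALSE)
  ph <- design$pheno
  if (length(unique(ph$rep)) != 2) return(FALSE)
  tab <- table(ph$line, droplevels(design$envg))
  N <- length(design$line_ids)
  nrow(tab) == N && all(tab == 2) &&
    all(table(ph$line, ph$rep) == k)
}

# ---- general-engine driver --------------------------------------------------

fit_general <- function(design, K, em_iter, max_iter, tol, varcomp_init,
                        estimate) {
  eng <- make_engine(design, K)
  spec <- design$spec
  comps0 <- NULL
  if (!is.null(varcomp_init)) comps0 <- varcomp_to_comps(varcomp_init, design)
  if (!estimate && is.null(comps0)) {
    stop("estimate = FALSE requires varcomp_init")
  }
  if (spec$spatial && estimate) {
    res <- fit_spatial(eng, spec$fa_order, em_iter = em_iter,
                       max_iter = max_iter, tol = tol)
  } else {
    if (!is.null(varcomp_init) && !is.null(varcomp_init$spatial_rho) &&
        spec$spatial) {
      eng$rho <- varcomp_init$spatial_rho
      set_env_pieces(eng)
    }
    res <- reml_fit_inner(eng, spec$fa_order, comps0 = comps0,
                          em_iter = if (is.null(comps0)) em_iter else 0,
                          max_iter = max_iter, tol = tol,
                          optimize = estimate)
  }
  build_fit(design, K, eng, res)
}

build_fit <- function(design, K, eng, res) {
  comps <- res$comps
  ev <- res$ev
  gen <- design$terms$genetic
  k <- length(design$env_levels)
  env_names <- design$env_levels
  # random-effect solutions u = D Z'Py per term
  u <- list()
  for (nm in names(design$terms)) {
    rws <- eng$rows[[nm]]
    if (design$terms[[nm]]$type == "iid") {
      u[[nm]] <- stats::setNames(comps$sigma2[[nm]] * ev$w[rws],
                                 design$terms[[nm]]$levels)
    } else {
      U <- eng$Km %*% ev$W2 %*% comps$Go
      dimnames(U) <- list(gen$line_ids, gen$env_levels)
      u[[nm]] <- U
    }
  }
  beta <- stats::setNames(as.numeric(ev$beta), colnames(design$X))
  fitted <- as.numeric(design$X %*% ev$beta)
  for (nm in names(design$terms)) {
    fitted <- fitted + as.numeric(design$terms[[nm]]$Z %*% as.numeric(u[[nm]]))
  }
  vtot <- stats::var(design$y)
  boundary <- c(comps$sigma2 < 1e-6 * vtot,
                genetic = !is.null(gen) && max(diag(comps$Go)) < 1e-6 * vtot)
  varcomp <- make_varcomp(comps, design, eng, res)
  structure(list(
    varcomp = varcomp,
    gblups = if (!is.null(gen)) u$genetic else NULL,
    fixed = beta,
    u = u,
    fitted = fitted,
    residuals = design$y - fitted,
    loglik = res$ll,
    convergence = list(converged = res$convergence == 0,
                       iterations = res$iterations,
                       grad_norm = res$grad_norm,
                       message = res$message, n_eval = res$n_eval,
                       boundary = boundary),
    em_trace = res$em_trace,
    engine = "general",
    design = design, K = K),
    class = "megblup")
}

make_varcomp <- function(comps, design, eng, res) {
  gen <- design$terms$genetic
  env_names <- if (!is.null(gen)) gen$env_levels else design$env_levels
  Lambda <- comps$Lambda
  Psi <- comps$Psi
  Go <- comps$Go
  if (!is.null(Go)) {
    # canonical sign convention: leading loading of each factor positive
    for (j in seq_len(ncol(Lambda))) {
      lead <- which(abs(Lambda[, j]) > 1e-10)[1]
      if (!is.na(lead) && Lambda[lead, j] < 0) Lambda[, j] <- -Lambda[, j]
    }
    rownames(Lambda) <- env_names
    names(Psi) <- env_names
    dimnames(Go) <- list(env_names, env_names)
  }
  rv <- comps$resid_var
  names(rv) <- if (length(rv) == length(design$env_levels))
    design$env_levels else "pooled"
  list(Lambda = Lambda, Psi = Psi, Go = Go, sigma2 = comps$sigma2,
       resid_var = rv,
       spatial_rho = if (design$spec$spatial && !is.null(eng)) eng$rho else NULL,
       loglik = res$ll)
}

varcomp_to_comps <- function(vc, design) {
  comps <- list(sigma2 = vc$sigma2)
  nm_iid <- setdiff(names(design$terms), "genetic")
  if (is.null(comps$sigma2)) comps$sigma2 <- stats::setNames(
    rep(0.05 * stats::var(design$y), length(nm_iid)), nm_iid)
  comps$sigma2 <- comps$sigma2[nm_iid]
  if (!is.null(design$terms$genetic)) {
    if (!is.null(vc$Lambda)) {
      comps$Lambda <- as.matrix(vc$Lambda)
      comps$Psi <- vc$Psi %||% rep(1e-8, nrow(comps$Lambda))
    } else if (!is.null(vc$Go)) {
      k <- nrow(vc$Go)
      fa <- fa_fit(as.matrix(vc$Go), min(design$spec$fa_order, k), iter = 200)
      comps$Lambda <- fa$Lambda; comps$Psi <- fa$Psi
    } else stop("varcomp_init must carry Lambda/Psi or Go")
    comps$Go <- fa_covariance(comps$Lambda, comps$Psi)
  }
  comps$resid_var <- vc$resid_var
  if (design$spec$resid_by_env &&
      length(comps$resid_var) != length(design$env_levels)) {
    comps$resid_var <- rep(comps$resid_var[1], length(design$env_levels))
  }
  comps
}

# ---- balanced fast path -----------------------------------------------------

# Exact REML for the complete two-replicate line x environment layout with
# fixed environment means, a fixed replicate contrast, the genetic term and
# iid heterogeneous residuals.  The plot data decompose orthogonally into
# cell means and within-cell replicate differences; rotating the cell-mean
# matrix by the eigenvectors of K turns the likelihood into a product of N
# independent k-variate normals, making each evaluation O(N k^3).
fit_balanced <- function(design, K, fa_order, tol, max_iter, varcomp_init,
                         estimate) {
  gen <- design$terms$genetic
  N <- gen$N; k <- gen$k
  line_ids <- gen$line_ids; env_names <- gen$env_levels
  ph <- design$pheno
  reps <- sort(unique(ph$rep))
  li <- match(ph$line, line_ids); ei <- match(design$envg, env_names)
  Y <- matrix(0, N, k); Dif <- matrix(0, N, k)
  sel1 <- ph$rep == reps[1]
  Y1 <- matrix(NA_real_, N, k); Y2 <- matrix(NA_real_, N, k)
  Y1[cbind(li[sel1], ei[sel1])] <- design$y[sel1]
  Y2[cbind(li[!sel1], ei[!sel1])] <- design$y[!sel1]
  Y <- (Y1 + Y2) / 2
  Dif <- Y2 - Y1
  es <- eigen(as.matrix(K), symmetric = TRUE)
  Q <- es$vectors; s <- pmax(es$values, 1e-10)
  Yt <- crossprod(Q, Y)
  cvec <- as.numeric(crossprod(Q, rep(1, N)))
  pmap <- make_pmap(design$terms, k, fa_order, TRUE)
  nll <- function(theta) {
    comps <- theta_to_comps(theta, pmap, design$terms)
    -balanced_ll(comps, Yt, Dif, cvec, s, N, k)$ll
  }
  # moment start
  s2e0 <- pmax(apply(Dif, 2, stats::var) / 2, 1e-6)
  Ym <- sweep(Y, 2, colMeans(Y))
  Go0 <- stats::cov(Ym) - diag(s2e0 / 2, k)
  eg <- eigen((Go0 + t(Go0)) / 2, symmetric = TRUE)
  Go0 <- eg$vectors %*% diag(pmax(eg$values, 1e-4 * mean(s2e0)), k) %*%
    t(eg$vectors)
  m <- min(fa_order, k)
  fa0 <- if (!is.null(varcomp_init) && !is.null(varcomp_init$Lambda)) {
    list(Lambda = as.matrix(varcomp_init$Lambda),
         Psi = varcomp_init$Psi %||% rep(1e-8, k))
  } else {
    fa_fit(Go0, m, iter = 100)
  }
  comps0 <- list(sigma2 = stats::setNames(numeric(0), character(0)),
                 Lambda = fa0$Lambda, Psi = fa0$Psi,
                 Go = fa_covariance(fa0$Lambda, fa0$Psi),
                 resid_var = varcomp_init$resid_var %||% s2e0)
  theta <- comps_to_theta(comps0, pmap, design$terms)
  if (estimate) {
    ctl <- list(maxit = max_iter, factr = max(tol / 1e-15, 10),
                ndeps = rep(1e-5, pmap$n_par))
    opt <- stats::optim(theta, nll, method = "L-BFGS-B",
                        lower = rep(-25, pmap$n_par),
                        upper = rep(25, pmap$n_par), control = ctl)
    # evaluations are cheap here; restart once to escape finite-difference
    # gradient stalls near the optimum
    opt2 <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                         control = list(maxit = 500, reltol = 1e-12))
    opt3 <- stats::optim(opt2$par, nll, method = "L-BFGS-B",
                         lower = rep(-25, pmap$n_par),
                         upper = rep(25, pmap$n_par), control = ctl)
    opt <- if (opt3$value <= opt$value) opt3 else opt
    theta <- opt$par
    convergence <- opt$convergence; iterations <- opt$counts[1]
  } else {
    convergence <- 0L; iterations <- 0L
  }
  comps <- theta_to_comps(theta, pmap, design$terms)
  bl <- balanced_ll(comps, Yt, Dif, cvec, s, N, k, want_blup = TRUE)
  U <- Q %*% bl$Ut
  dimnames(U) <- list(line_ids, env_names)
  fitted_cells <- matrix(rep(bl$mu, each = N), N, k) + U
  # map back to plots (rep contrast delta on replicate 2)
  fitted <- fitted_cells[cbind(li, ei)] +
    ifelse(ph$rep == reps[1], -bl$delta / 2, bl$delta / 2)
  res <- list(comps = comps, ll = bl$ll, convergence = convergence,
              iterations = iterations, grad_norm = NA_real_,
              message = "", n_eval = NA_integer_, em_trace = numeric(0))
  varcomp <- make_varcomp(comps, design, NULL, res)
  structure(list(
    varcomp = varcomp, gblups = U,
    fixed = c(stats::setNames(bl$mu, paste0("mean:", env_names)),
              rep_contrast = bl$delta),
    u = list(genetic = U),
    fitted = fitted, residuals = design$y - fitted,
    loglik = bl$ll,
    convergence = list(converged = convergence == 0,
                       iterations = iterations, grad_norm = NA_real_,
                       message = "", n_eval = NA_integer_,
                       boundary = c(genetic = max(diag(comps$Go)) <
                                      1e-6 * stats::var(design$y))),
    em_trace = numeric(0), engine = "balanced",
    design = design, K = K), class = "megblup")
}

# REML log-likelihood of the balanced layout (see fit_balanced); the
# constant aligns the implicit fixed-effect coding with the general
# engine's (intercept + sum-to-zero replicate contrast) parameterization.
# The per-line covariances s_i * Go + diag(s2e / 2) are simultaneously
# diagonalized by whitening with the residual diagonal, so the whole
# evaluation is a handful of k x k eigen/matrix operations plus elementwise
# arithmetic over the N x k table.
balanced_ll <- function(comps, Yt, Dif, cvec, s, N, k, want_blup = FALSE) {
  Go <- comps$Go
  s2e <- comps$resid_var
  de <- sqrt(s2e / 2)
  B <- Go / outer(de, de)
  eB <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- eB$vectors; th <- pmax(eB$values, 0)
  # whitened, rotated responses: row i has independent components with
  # variance s_i * th_j + 1 (times the residual scale absorbed below)
  Yw <- sweep(Yt, 2, de, "/") %*% P                 # N x k
  Dwt <- 1 + outer(s, th)                           # N x k
  ldA <- N * sum(log(s2e / 2)) + sum(log(Dwt))
  Yq <- Yw / Dwt
  quadA_full <- sum(Yw * Yq)
  aj <- colSums(cvec^2 / Dwt)                       # k
  bj <- colSums(cvec * Yq)                          # k
  # back-transform the GLS normal equations for the environment means
  Tm <- sweep(P, 2, sqrt(aj), "*")
  Amu <- Tm %*% t(Tm) / outer(de, de)
  bmu <- (P %*% bj) / de
  UA <- chol(Amu)
  mu <- backsolve(UA, backsolve(UA, bmu, transpose = TRUE))
  quadA <- quadA_full - sum(bmu * mu)
  ldXA <- 2 * sum(log(diag(UA)))
  # replicate-difference component: d_ik ~ N(delta, 2 sigma2_k)
  Adel <- sum(N / (2 * s2e))
  bdel <- sum(colSums(Dif) / (2 * s2e))
  delta <- bdel / Adel
  quadB <- sum(sweep(Dif^2, 2, 2 * s2e, "/")) - bdel * delta
  ldB <- sum(N * log(2 * s2e))
  n <- 2 * N * k; p <- k + 1
  # parameterization constant: the general engine codes the replicate
  # contrast sum-to-zero on plots; the mean/difference coding differs by a
  # factor 2 in that column (|det T| = 2 per the REML invariance rule).
  ll <- -0.5 * (ldA + quadA + ldXA + ldB + quadB + log(Adel) +
                  (n - p) * log(2 * pi)) - log(2)
  out <- list(ll = ll, mu = mu, delta = delta)
  if (want_blup) {
    Rt <- Yt - tcrossprod(cvec, as.numeric(mu))
    Rq <- (sweep(Rt, 2, de, "/") %*% P) / Dwt
    Sir <- sweep(Rq %*% t(P), 2, de, "/")          # Sigma_i^-1 r_i by row
    out$Ut <- (Sir %*% Go) * s
  }
  out
}
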