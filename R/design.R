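#' Mixed-model specification
#'
#' Chooses the model equation and covariance structure fitted by
#' [megblup()]:
#' * `"multi_env"` — plots from several selection environments in one year;
#'   fixed overall mean and replicate effect; random environment main effect,
#'   trial, replicate-within-trial and block effects (each iid), and the
#'   line-by-environment genetic effect with covariance `Go %x% K`, where
#'   `Go` is factor-analytic and `K` a genomic or pedigree relationship
#'   matrix.
#' * `"multi_env_year"` — the multi-year extension: environment levels are
#'   environment-by-year combinations and the replicate/block terms are
#'   nested within year as well.
#' * `"single_env"` — one environment; random genetic effect with covariance
#'   `sigma2_g K`, plus trial, replicate-within-trial and block terms.
#'
#' The residual is independent between environments with per-environment
#' variance, optionally with a separable AR1xAR1 correlation across field
#' columns and rows within each environment.
#'
#' @param formula_kind model equation, see above.
#' @param fa_order number of latent factors `m` of the factor-analytic
#'   genetic covariance (`1 <= m <= k`); identifiability is imposed by fixing
#'   loadings above the diagonal to zero and the leading loading of each
#'   factor to a positive sign.
#' @param env_effect treat the environment main effect as `"random"` (iid
#'   variance component) or absorb it into fixed per-environment means.
#' @param spatial fit the AR1xAR1 spatial residual correlation (requires
#'   `row` and `col` plot coordinates).
#' @param random_terms subset of `c("env", "trial", "rep_trial", "block")`
#'   to retain as iid design components; `NULL` keeps all that apply to the
#'   equation.  Terms with fewer than two levels in the data are dropped
#'   with a message.
#' @param resid_by_env heterogeneous residual variance per environment
#'   (`TRUE`, the default) or a single pooled residual variance.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(formula_kind = c("multi_env", "multi_env_year",
                                        "single_env"),
                       fa_order = 1, env_effect = c("random", "fixed"),
                       spatial = FALSE, random_terms = NULL,
                       resid_by_env = TRUE) {
  formula_kind <- match.arg(formula_kind)
  env_effect <- match.arg(env_effect)
  stopifnot(fa_order >= 1)
  structure(list(formula_kind = formula_kind, fa_order = as.integer(fa_order),
                 env_effect = env_effect, spatial = spatial,
                 random_terms = random_terms, resid_by_env = resid_by_env),
            class = "model_spec")
}

#' Build design structures for the mixed model
#'
#' Validates the plot table against a [model_spec()], sorts plots within
#' environment by field column and row, and constructs the fixed-effect
#' matrix and sparse incidence matrices of every random term, including the
#' line-by-environment genetic term whose columns follow the kinship line
#' order.  Level orderings are lexicographic and stable across calls.
#'
#' @param pheno plot-record data frame (columns `line`, `env`, `trial`,
#'   `rep`, `block`, `value`; `year` for the multi-year model; `row`, `col`
#'   for spatial residuals).
#' @param spec a [model_spec()].
#' @param line_ids line identifiers defining the genetic-term column order,
#'   normally `rownames(K)`; defaults to the sorted lines present.
#' @return list of class `megblup_design` (data vector, fixed-effect matrix,
#'   random-term incidences, environment index).
#' @export
build_design <- function(pheno, spec, line_ids = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  pheno <- as.data.frame(pheno)
  need <- c("line", "env", "trial", "rep", "block", "value")
  if (spec$formula_kind == "multi_env_year") need <- c(need, "year")
  if (spec$spatial) need <- c(need, "row", "col")
  for (cn in need) {
    if (!cn %in% names(pheno)) {
      stop(sprintf("model '%s' requires column '%s' in the plot table",
                   spec$formula_kind, cn))
    }
  }
  for (cn in c("line", "env", "trial", "rep", "block")) {
    pheno[[cn]] <- as.character(pheno[[cn]])
  }
  envg <- if (spec$formula_kind == "multi_env_year") {
    paste(pheno$env, pheno$year, sep = ":")
  } else {
    pheno$env
  }
  if (spec$formula_kind == "single_env" && length(unique(envg)) > 1) {
    stop("single_env model given data from more than one environment")
  }
  ord <- if (spec$spatial) {
    order(envg, pheno$col, pheno$row)
  } else {
    order(envg, pheno$line, pheno$rep)
  }
  pheno <- pheno[ord, , drop = FALSE]
  envg <- envg[ord]
  env_levels <- sort(unique(envg))
  k <- length(env_levels)
  if (is.null(line_ids)) line_ids <- sort(unique(pheno$line))
  missing_lines <- setdiff(unique(pheno$line), line_ids)
  if (length(missing_lines)) {
    stop("phenotyped lines absent from the kinship line set: ",
         paste(utils::head(missing_lines, 5), collapse = ", "),
         if (length(missing_lines) > 5) " ..." else "")
  }
  n <- nrow(pheno)
  # fixed effects: overall mean + replicate; per-environment means when the
  # environment main effect is fixed
  rep_f <- factor(pheno$rep, levels = sort(unique(pheno$rep)))
  envg_f <- factor(envg, levels = env_levels)
  if (spec$env_effect == "fixed" && k > 1) {
    X <- stats::model.matrix(~ envg_f + rep_f,
                             contrasts.arg = list(rep_f = "contr.sum"))
  } else if (nlevels(rep_f) > 1) {
    X <- stats::model.matrix(~ rep_f,
                             contrasts.arg = list(rep_f = "contr.sum"))
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  # random design terms (iid variance components)
  keys <- list(
    env = envg,
    trial = paste(envg, pheno$trial, sep = ":"),
    rep_trial = paste(envg, pheno$trial, pheno$rep, sep = ":"),
    block = paste(envg, pheno$trial, pheno$rep, pheno$block, sep = ":"))
  applicable <- c(if (spec$env_effect == "random" &&
                      spec$formula_kind != "single_env") "env",
                  "trial", "rep_trial", "block")
  wanted <- spec$random_terms %||% applicable
  wanted <- intersect(applicable, wanted)
  terms <- list()
  for (tm in wanted) {
    lev <- sort(unique(keys[[tm]]))
    if (length(lev) < 2) {
      message(sprintf("dropping random term '%s': fewer than 2 levels", tm))
      next
    }
    terms[[tm]] <- list(name = tm, type = "iid",
                        Z = incidence_matrix(keys[[tm]], lev), levels = lev)
  }
  # genetic term: line x environment cells, column index (env - 1) * N + line
  N <- length(line_ids)
  li <- match(pheno$line, line_ids)
  ei <- match(envg, env_levels)
  Zg <- Matrix::sparseMatrix(i = seq_len(n), j = (ei - 1L) * N + li,
                             x = 1, dims = c(n, N * k))
  terms[["genetic"]] <- list(name = "genetic", type = "genetic", Z = Zg,
                             line_ids = line_ids, k = k, N = N,
                             env_levels = env_levels)
  structure(list(y = as.numeric(pheno$value), X = X, n = n, p = ncol(X),
                 terms = terms, envg = envg_f, env_levels = env_levels,
                 env_idx = split(seq_len(n), envg_f),
                 pheno = pheno, spec = spec, line_ids = line_ids),
            class = "megblup_design")
}

incidence_matrix <- function(key, levels) {
  Matrix::sparseMatrix(i = seq_along(key), j = match(key, levels), x = 1,
                       dims = c(length(key), length(levels)))
}

#' @export
print.megblup_design <- function(x, ...) {
  cat(sprintf("mixed-model design: %d plots, %d fixed effects, %d environments\n",
              x$n, x$p, length(x$env_levels)))
  for (tm in x$terms) {
    cat(sprintf("  random %-10s %5d levels (%s)\n", tm$name, ncol(tm$Z), tm$type))
  }
  invisible(x)
}
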