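#' Best linear unbiased estimates of line-by-environment values
#'
#' Estimates each phenotyped (line, environment) cell as a fixed effect —
#' the companion of the BLUP model in which line effects are shrunk — with
#' the design terms (trial, replicate-within-trial, incomplete block) kept
#' random and the same residual structure as the parent model.  The
#' replicate contrast is coded sum-to-zero, so the estimates are on the
#' data scale and average to the overall mean.
#'
#' Variance components of the nuisance terms can either be estimated by
#' REML under the line-fixed model (`varcomp = NULL`) or reused from a
#' fitted [megblup()] model, which is much faster and customary when BLUEs
#' and BLUPs are reported from the same dataset.
#'
#' @param pheno plot-record data frame.
#' @param model,spatial,random_terms,resid_by_env model structure as in
#'   [megblup()] (the genetic and environment-main terms are absorbed by the
#'   fixed cells).
#' @param varcomp `NULL`, a `varcomp` list, or a `megblup` fit whose design
#'   variance components are reused.
#' @param max_iter REML iteration cap when estimating nuisance components.
#' @return data frame of class `blue_table` with columns `line`, `env`,
#'   `blue`, `se`; inestimable cells are `NA`.
#' @export
compute_blues <- function(pheno, model = c("multi_env", "multi_env_year",
                                           "single_env"),
                          spatial = FALSE, random_terms = NULL,
                          resid_by_env = TRUE, varcomp = NULL,
                          max_iter = 100) {
  model <- match.arg(model)
  if (inherits(varcomp, "megblup")) varcomp <- varcomp$varcomp
  spec <- model_spec(model, fa_order = 1, env_effect = "fixed",
                     spatial = spatial,
                     random_terms = random_terms %||%
                       c("trial", "rep_trial", "block"),
                     resid_by_env = resid_by_env)
  design <- build_design(pheno, spec)
  design$terms$genetic <- NULL
  # replace the fixed-effect matrix: one dummy per line-by-environment cell
  # plus the sum-to-zero replicate contrast
  ph <- design$pheno
  envg <- as.character(design$envg)
  cell <- paste(ph$line, envg, sep = "\r")
  cell_levels <- sort(unique(cell))
  Xc <- as.matrix(incidence_matrix(cell, cell_levels))
  colnames(Xc) <- cell_levels
  rep_f <- factor(ph$rep)
  X <- if (nlevels(rep_f) > 1) {
    Xr <- stats::model.matrix(~rep_f, contrasts.arg = list(rep_f = "contr.sum"))
    cbind(Xc, Xr[, -1, drop = FALSE])
  } else Xc
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- intersect(colnames(X)[-keep], cell_levels)
    X <- X[, keep, drop = FALSE]
  }
  design$X <- X
  design$p <- ncol(X)
  eng <- make_engine(design, NULL)
  if (is.null(varcomp)) {
    res <- reml_fit_inner(eng, fa_order = 1, em_iter = 5,
                          max_iter = max_iter, tol = 1e-8)
  } else {
    comps <- varcomp_to_comps(varcomp, design)
    res <- reml_fit_inner(eng, fa_order = 1, comps0 = comps, em_iter = 0,
                          optimize = FALSE)
  }
  ev <- eval_reml(eng, res$comps, want = "grad")
  beta <- stats::setNames(as.numeric(ev$beta), colnames(X))
  se <- stats::setNames(sqrt(pmax(diag(ev$XVXinv), 0)), colnames(X))
  parts <- strsplit(cell_levels, "\r", fixed = TRUE)
  out <- data.frame(line = vapply(parts, `[`, "", 1),
                    env = vapply(parts, `[`, "", 2),
                    blue = beta[cell_levels],
                    se = se[cell_levels],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (length(dropped)) {
    out$blue[cell_levels %in% dropped] <- NA_real_
    out$se[cell_levels %in% dropped] <- NA_real_
    warning(sprintf("%d inestimable cell(s) flagged NA", length(dropped)))
  }
  class(out) <- c("blue_table", "data.frame")
  attr(out, "varcomp") <- res$comps
  attr(out, "loglik") <- res$ll
  out
}
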