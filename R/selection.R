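#' Smith-Hazel selection index coefficients
#'
#' Classic multi-trait index weights `b = P^{-1} G w`, where `P` is the
#' phenotypic variance-covariance matrix of the index traits (here typically
#' environment-wise genetic values on a line-mean basis), `G` the genetic
#' variance-covariance matrix and `w` the vector of economic weights.
#'
#' @param G genetic covariance matrix (k x k, symmetric).
#' @param P phenotypic covariance matrix (k x k, symmetric positive definite).
#' @param w numeric vector of economic weights, length k.
#' @param ridge optional nonnegative ridge added to `diag(P)` when `P` is
#'   numerically singular.
#' @return numeric vector `b` of index coefficients.
#' @references Smith, H.F. (1936); Hazel, L.N. (1943).
#' @export
smith_hazel_weights <- function(G, P, w, ridge = 0) {
  G <- as.matrix(G); P <- as.matrix(P); w <- as.numeric(w)
  k <- length(w)
  stopifnot(nrow(G) == k, ncol(G) == k, nrow(P) == k, ncol(P) == k)
  if (ridge > 0) diag(P) <- diag(P) + ridge
  b <- tryCatch(solve(P, G %*% w), error = function(e)
    stop("P is singular; consider the `ridge` argument", call. = FALSE))
  drop(b)
}

#' Index scores for a table of line values
#'
#' Linear combination `score_i = sum_k b_k * value_ik` of per-environment
#' (or per-trait) values.
#'
#' @param values numeric matrix, lines x environments, with line ids as
#'   row names; no missing cells.
#' @param b index coefficients, length `ncol(values)`.
#' @return named numeric vector of scores.
#' @export
index_scores <- function(values, b) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells in the value table")
  stopifnot(length(b) == ncol(values))
  drop(values %*% as.numeric(b))
}

#' Select the top fraction of lines by score
#'
#' Picks the `ceiling(fraction * n)` highest-scoring lines.  Ties at the
#' cutoff are broken by line id order, making the selection reproducible.
#'
#' @param scores named numeric vector of scores (names are line ids).
#' @param fraction selected fraction in `(0, 1]`.
#' @return object of class `selection_set`: character vector of selected ids
#'   with attributes `fraction` and `n_total`.
#' @export
select_top <- function(scores, fraction = 0.20) {
  stopifnot(fraction > 0, fraction <= 1)
  if (length(scores) == 0) stop("empty score vector")
  if (is.null(names(scores))) names(scores) <- paste0("L", seq_along(scores))
  n_sel <- ceiling(fraction * length(scores))
  ord <- order(-scores, names(scores))
  structure(names(scores)[ord[seq_len(n_sel)]],
            fraction = fraction, n_total = length(scores),
            class = "selection_set")
}

#' Proportion of lines shared by two selection sets
#'
#' The selection-intersection accuracy used to mirror advancement decisions:
#' the fraction of lines selected under one criterion (e.g. GBLUP from the
#' full data) that are also selected under another (e.g. GBLUP from a sparse
#' prediction model).  Both sets must be the same size.
#'
#' @param a,b selection sets ([select_top()]) or plain id vectors of equal
#'   length.
#' @return fraction in `[0, 1]`.
#' @export
intersection_accuracy <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) == 0 || length(b) == 0) stop("empty selection set")
  if (length(a) != length(b)) stop("selection sets have different sizes")
  length(intersect(a, b)) / length(a)
}

#' Predictive ability
#'
#' Pearson correlation between predicted genetic values and reference values
#' (typically BLUEs from the full data) over the common lines.
#'
#' @param predicted named numeric vector of predictions.
#' @param reference named numeric vector of reference values.
#' @return Pearson correlation, or `NA` with a warning when fewer than three
#'   common lines exist or either vector is constant.
#' @export
predictive_ability <- function(predicted, reference) {
  common <- intersect(names(predicted), names(reference))
  if (length(common) < 3) {
    warning("fewer than 3 common lines; predictive ability undefined")
    return(NA_real_)
  }
  x <- predicted[common]; y <- reference[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; predictive ability undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' @export
print.selection_set <- function(x, ...) {
  cat(sprintf("selection set: top %.0f%% = %d of %d lines\n",
              100 * attr(x, "fraction"), length(x), attr(x, "n_total")))
  if (length(x) <= 20) cat(" ", paste(x, collapse = ", "), "\n")
  invisible(x)
}

#' Smith-Hazel index inputs from a fitted multi-environment model
#'
#' Convenience constructor for the index covariances: the genetic covariance
#' is the fitted between-environment matrix `Go`; the phenotypic covariance
#' adds the per-environment residual variance divided by the number of
#' replicates, i.e. the covariance of line means.
#'
#' @param fit a [megblup()] fit.
#' @param n_reps replicate count used to put residual variance on a line-mean
#'   basis.
#' @return list with elements `G` and `P`.
#' @export
index_covariances <- function(fit, n_reps = 2) {
  stopifnot(inherits(fit, "megblup"))
  Go <- fit$varcomp$Go
  P <- Go + diag(fit$varcomp$resid_var / n_reps, nrow(Go))
  dimnames(P) <- dimnames(Go)
  list(G = Go, P = P)
}
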