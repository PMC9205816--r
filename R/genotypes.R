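#' Filter SNP markers on missingness and minor allele frequency
#'
#' Applies the standard pre-analysis marker quality control: markers with a
#' missing-call fraction above `max_missing` or a minor allele frequency (MAF)
#' below `min_maf` are dropped.  MAF is computed on non-missing calls only.
#' Thresholds are inclusive: a marker with missingness exactly `max_missing`
#' or MAF exactly `min_maf` is kept.
#'
#' @param geno numeric matrix of allele dosages in \{0, 1, 2\} with `NA` for
#'   missing calls; rows are lines, columns are markers. Row and column names
#'   identify lines and markers.
#' @param max_missing maximum tolerated fraction of missing calls per marker.
#' @param min_maf minimum minor allele frequency per marker.
#' @return the dosage matrix restricted to passing markers, original marker
#'   order preserved.  A warning is raised if no marker passes.
#' @examples
#' g <- matrix(c(0, 1, 2, 0, NA, 2, 0, 0, 0, 1), nrow = 5)
#' filter_snps(g, max_missing = 0.2, min_maf = 0.05)
#' @export
filter_snps <- function(geno, max_missing = 0.20, min_maf = 0.05) {
  geno <- as_dosage_matrix(geno)
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  miss <- colMeans(is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0 # all-missing marker: caught by missingness filter
  maf <- pmin(p, 1 - p)
  keep <- miss <= max_missing & maf >= min_maf
  if (!any(keep)) {
    warning("no marker passed the missingness/MAF filters")
  }
  geno[, keep, drop = FALSE]
}

#' Impute missing marker calls
#'
#' Stand-in for haplotype-based imputation: fills each missing call with a
#' simple per-marker statistic.  Fractional dosages are permitted downstream
#' (they only enter through the genomic relationship matrix).
#'
#' @inheritParams filter_snps
#' @param method imputation rule; only `"marker_mean"` (the per-marker mean
#'   dosage over non-missing calls) is implemented.
#' @return a complete dosage matrix; non-missing entries are unchanged.
#' @export
impute_missing <- function(geno, method = c("marker_mean")) {
  method <- match.arg(method)
  geno <- as_dosage_matrix(geno)
  nmiss <- colSums(is.na(geno))
  if (!any(nmiss > 0)) return(geno)
  allmiss <- nmiss == nrow(geno)
  if (any(allmiss)) {
    stop("marker(s) with no non-missing call: ",
         paste(colnames(geno)[allmiss], collapse = ", "))
  }
  mu <- colMeans(geno, na.rm = TRUE)
  idx <- which(is.na(geno), arr.ind = TRUE)
  geno[idx] <- mu[idx[, 2]]
  geno
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = W W' / (2 * sum p_j (1 - p_j)), where W is the dosage matrix centered
#' by twice the observed allele frequency p_j of each marker.  The mean
#' diagonal of G is approximately 1 plus the mean inbreeding coefficient of
#' the panel.
#'
#' @param geno complete (no missing calls) dosage matrix, lines x markers.
#' @return a symmetric lines x lines matrix of class `kinship` with
#'   `attr(, "kind") == "genomic"`.
#' @references VanRaden, P.M. (2008) Efficient methods to compute genomic
#'   predictions. J. Dairy Sci. 91:4414-4423.
#' @examples
#' g <- matrix(c(0, 2, 2, 0), nrow = 2, dimnames = list(c("A", "B"), NULL))
#' compute_G(g)
#' @export
compute_G <- function(geno) {
  geno <- as_dosage_matrix(geno, allow_fractional = TRUE)
  if (anyNA(geno)) stop("missing dosages: impute before computing G")
  p <- colMeans(geno) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: G denominator is zero")
  W <- sweep(geno, 2, 2 * p, "-")
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  new_kinship(G, kind = "genomic")
}

#' Pedigree (numerator) relationship matrix by the tabular method
#'
#' Builds the additive relationship matrix A from a three-column pedigree
#' using the classic recursion: for individual i with parents s and d,
#' A[i, i] = 1 + A[s, d] / 2 and A[i, j] = (A[j, s] + A[j, d]) / 2 for any
#' earlier individual j.  Founders (unknown parents) are taken as unrelated
#' and non-inbred.  Individuals are topologically sorted first, so the input
#' order is free; a pedigree cycle is an error.
#'
#' @param ped data frame with columns `id`, `parent1`, `parent2` (character;
#'   `NA` or `"0"` for unknown parents).
#' @return a symmetric matrix of class `kinship` with
#'   `attr(, "kind") == "pedigree"`, rows/columns in the input id order.
#' @export
compute_A <- function(ped) {
  ped <- as.data.frame(ped)
  names(ped)[1:3] <- c("id", "parent1", "parent2")
  ids <- as.character(ped$id)
  if (anyDuplicated(ids)) stop("duplicate ids in pedigree")
  p1 <- normalize_parent(ped$parent1, ids)
  p2 <- normalize_parent(ped$parent2, ids)
  ord <- pedigree_order(ids, p1, p2)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  pos <- seq_len(n)
  names(pos) <- ids
  for (i in ord) {
    s <- p1[i]; d <- p2[i]
    si <- if (is.na(s)) NA_integer_ else pos[[s]]
    di <- if (is.na(d)) NA_integer_ else pos[[d]]
    aij <- numeric(n)
    if (!is.na(si)) aij <- aij + A[si, ] / 2
    if (!is.na(di)) aij <- aij + A[di, ] / 2
    A[i, ] <- aij
    A[, i] <- aij
    f <- if (!is.na(si) && !is.na(di)) A[si, di] / 2 else 0
    A[i, i] <- 1 + f
  }
  new_kinship(A, kind = "pedigree")
}

#' Block-diagonal extension of a kinship matrix
#'
#' Combines a genotyped (or pedigreed) block with an identity block for lines
#' that carry no marker or pedigree information, as used when historical
#' phenotype records of ungenotyped lines augment a calibration set.  The two
#' blocks have zero covariance.
#'
#' @param k a `kinship` (or plain symmetric) matrix with line ids as dimnames.
#' @param extra_ids character vector of additional line ids, disjoint from the
#'   ids already in `k`.
#' @return the extended `kinship` matrix.
#' @export
block_diagonal_kinship <- function(k, extra_ids) {
  extra_ids <- as.character(extra_ids)
  if (length(extra_ids) == 0) return(k)
  ids <- rownames(k)
  if (any(extra_ids %in% ids)) {
    stop("extra_ids overlap the kinship line set: ",
         paste(intersect(extra_ids, ids), collapse = ", "))
  }
  if (anyDuplicated(extra_ids)) stop("duplicate extra_ids")
  n1 <- nrow(k); n2 <- length(extra_ids)
  out <- matrix(0, n1 + n2, n1 + n2,
                dimnames = list(c(ids, extra_ids), c(ids, extra_ids)))
  out[1:n1, 1:n1] <- as.matrix(k)
  diag(out)[(n1 + 1):(n1 + n2)] <- 1
  new_kinship(out, kind = attr(k, "kind") %||% "genomic")
}

#' Stabilize a kinship matrix for factorization
#'
#' Adds a small ridge to the diagonal so that Cholesky factorization succeeds
#' even for singular relationship matrices (e.g. clones or a G computed from
#' few markers).  An optional blend with the identity is available but off by
#' default.
#'
#' @param k kinship matrix.
#' @param eps diagonal ridge added before factorization.
#' @param blend weight on the identity in the blend `(1 - blend) * K +
#'   blend * I`; `0` disables blending.
#' @return the stabilized matrix (attributes preserved).
#' @export
stabilize_kinship <- function(k, eps = 1e-6, blend = 0) {
  kind <- attr(k, "kind")
  m <- as.matrix(k)
  if (blend > 0) m <- (1 - blend) * m + blend * diag(nrow(m))
  diag(m) <- diag(m) + eps
  new_kinship(m, kind = kind %||% "genomic")
}

# ---- internal helpers -------------------------------------------------------

new_kinship <- function(m, kind) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  structure(m, kind = kind, class = c("kinship", "matrix", "array"))
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("%s relationship matrix: %d lines (mean diagonal %.3f)\n",
              attr(x, "kind"), nrow(x), mean(diag(x))))
  invisible(x)
}

as_dosage_matrix <- function(geno, allow_fractional = FALSE) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  if (is.null(rownames(geno))) rownames(geno) <- paste0("L", seq_len(nrow(geno)))
  if (is.null(colnames(geno))) colnames(geno) <- paste0("M", seq_len(ncol(geno)))
  if (anyDuplicated(rownames(geno))) stop("duplicate line ids")
  if (anyDuplicated(colnames(geno))) stop("duplicate marker ids")
  if (any(!is.na(geno))) {
    rng <- range(geno, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  }
  if (!allow_fractional && !all(geno %in% c(0, 1, 2, NA))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  geno
}

normalize_parent <- function(p, ids) {
  p <- as.character(p)
  p[p %in% c("0", "", "NA")] <- NA_character_
  bad <- !is.na(p) & !(p %in% ids)
  if (any(bad)) stop("unknown parent id(s): ", paste(unique(p[bad]), collapse = ", "))
  names(p) <- ids
  p
}

# Kahn topological sort; errors on a cycle, reporting one offending chain.
pedigree_order <- function(ids, p1, p2) {
  n <- length(ids)
  pos <- seq_len(n); names(pos) <- ids
  self_parent <- !is.na(p1) & p1 == ids | !is.na(p2) & p2 == ids
  if (any(self_parent)) stop("individual is its own parent: ", ids[self_parent][1])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(p1[i], p2[i])) {
      if (!is.na(p)) {
        j <- pos[[p]]
        indeg[i] <- indeg[i] + 1L
        children[[j]] <- c(children[[j]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stop("pedigree cycle involving: ",
         paste(ids[indeg > 0][seq_len(min(5, sum(indeg > 0)))], collapse = " -> "))
  }
  ord
}

`%||%` <- function(a, b) if (is.null(a)) b else a
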