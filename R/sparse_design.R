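#' Number of lines overlapping across environments for a target fraction
#'
#' Sparse-testing designs with a partially overlapping calibration set place
#' `x` lines in every environment and split the remaining `n - x` lines into
#' equal-sized sets unique to each environment.  So that the unique sets are
#' exactly equal, `x` is the smallest count at least `fraction * n_lines` such
#' that `n_lines - x` is divisible by `n_envs`.  For 280 lines and six
#' environments this yields 28, 58, 88, 112 and 142 overlapping lines at
#' fractions 0.1 to 0.5.
#'
#' @param n_lines total number of test lines.
#' @param n_envs number of environments (at least 2).
#' @param fraction target overlap fraction in `[0, 1)`.
#' @return integer overlap count; `0` when `fraction` is `0`.
#' @export
overlap_count <- function(n_lines, n_envs, fraction) {
  stopifnot(n_lines >= 1, n_envs >= 2, fraction >= 0, fraction < 1)
  if (fraction == 0) return(0L)
  x <- ceiling(fraction * n_lines)
  x <- x + (n_lines - x) %% n_envs
  if (x >= n_lines) stop("overlap fraction leaves no unique lines")
  as.integer(x)
}

#' Allocate lines to environments with no overlap
#'
#' Randomly partitions the lines into `length(env_ids)` sets whose sizes
#' differ by at most one; each set is the calibration set of exactly one
#' environment, so no line is phenotyped in more than one environment.
#' Which environments receive the larger sets is randomized.
#'
#' @param line_ids character vector of line ids.
#' @param env_ids character vector of environment ids.
#' @param seed integer seed making the allocation reproducible.
#' @return an `allocation_plan`: a list with elements `tested` (named list,
#'   environments a line is phenotyped in), `unique_sets`, `overlap_set`
#'   (empty here), `overlap_fraction`, `repeat_index` and `seed`.
#' @export
allocate_nonoverlap <- function(line_ids, env_ids, seed) {
  line_ids <- as.character(line_ids); env_ids <- as.character(env_ids)
  k <- length(env_ids)
  stopifnot(length(line_ids) >= k, k >= 1)
  rng <- local_rng(seed)
  perm <- sample(line_ids)
  sizes <- rep(length(line_ids) %/% k, k)
  extra <- length(line_ids) %% k
  if (extra > 0) sizes[sample.int(k, extra)] <- sizes[1] + 1L
  splits <- split(perm, rep(seq_len(k), times = sizes))
  names(splits) <- env_ids
  new_allocation_plan(unique_sets = splits, overlap_set = character(0),
                      env_ids = env_ids, fraction = 0, seed = seed)
}

#' Allocate lines to environments with a fixed overlap fraction
#'
#' Draws [overlap_count()] lines at random to be phenotyped in every
#' environment; the remaining lines are partitioned into exactly equal-sized
#' sets unique to each environment.  The per-environment calibration size is
#' `overlap + (n - overlap) / k`.
#'
#' @inheritParams allocate_nonoverlap
#' @param fraction overlap fraction in `(0, 1)`.
#' @export
allocate_overlap <- function(line_ids, env_ids, fraction, seed) {
  line_ids <- as.character(line_ids); env_ids <- as.character(env_ids)
  stopifnot(fraction > 0)
  k <- length(env_ids)
  x <- overlap_count(length(line_ids), k, fraction)
  rng <- local_rng(seed)
  perm <- sample(line_ids)
  overlap_set <- perm[seq_len(x)]
  rest <- perm[-seq_len(x)]
  splits <- split(rest, rep(seq_len(k), each = length(rest) / k))
  names(splits) <- env_ids
  new_allocation_plan(unique_sets = splits, overlap_set = overlap_set,
                      env_ids = env_ids, fraction = fraction, seed = seed)
}

#' Generate repeated allocation plans
#'
#' Re-randomizes an allocation a number of times (30 repeats in a typical
#' cross-validation), deriving the seed of repeat `i` as `base_seed + i - 1`.
#'
#' @param allocator function `(seed) -> allocation_plan`, e.g. a closure over
#'   [allocate_overlap()] with fixed lines, environments and fraction.
#' @param n_repeats number of repeats.
#' @param base_seed seed of the first repeat.
#' @return list of plans carrying `repeat_index` `0 ... n_repeats - 1`.
#' @export
replicate_plans <- function(allocator, n_repeats = 30, base_seed = 1) {
  stopifnot(n_repeats >= 1)
  lapply(seq_len(n_repeats), function(i) {
    plan <- allocator(base_seed + i - 1L)
    plan$repeat_index <- i - 1L
    plan
  })
}

#' Mask phenotypes according to an allocation plan
#'
#' Splits a plot table into the training records (plots whose line is
#' phenotyped in that plot's environment under the plan) and the list of
#' masked (line, environment) cells whose genetic values are to be predicted.
#' Lines absent from the plan (e.g. checks) are kept in training everywhere.
#'
#' @param pheno plot-record data frame with at least columns `line`, `env`.
#' @param plan an `allocation_plan`.
#' @return list with elements `training` (data frame) and `truth_cells`
#'   (data frame of unique masked line/env pairs).
#' @export
mask_phenotypes <- function(pheno, plan) {
  stopifnot(inherits(plan, "allocation_plan"))
  plan_lines <- plan_line_ids(plan)
  missing <- setdiff(plan_lines, unique(as.character(pheno$line)))
  if (length(missing)) {
    stop("plan lines absent from phenotype table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  line <- as.character(pheno$line); env <- as.character(pheno$env)
  keep <- rep(TRUE, nrow(pheno))
  in_plan <- line %in% plan_lines
  tested <- mapply(function(l, e) e %in% plan$tested[[l]],
                   line[in_plan], env[in_plan])
  keep[in_plan] <- tested
  masked <- unique(data.frame(line = line[!keep], env = env[!keep],
                              stringsAsFactors = FALSE))
  masked <- masked[order(masked$line, masked$env), , drop = FALSE]
  rownames(masked) <- NULL
  list(training = pheno[keep, , drop = FALSE], truth_cells = masked)
}

#' Calibration and prediction set sizes of a plan
#'
#' @param plan an `allocation_plan`.
#' @return data frame with one row per environment: calibration (tested) and
#'   prediction (untested) line counts.
#' @export
plan_sizes <- function(plan) {
  n <- length(plan_line_ids(plan))
  calib <- vapply(plan$env_ids, function(e)
    length(plan$overlap_set) + length(plan$unique_sets[[e]]), integer(1))
  data.frame(env = plan$env_ids, calibration = as.integer(calib),
             prediction = as.integer(n - calib), row.names = NULL)
}

#' Serialize allocation plans to a TSV file
#'
#' Writes one row per (line, environment) combination with a `tested` flag,
#' preceded by commented YAML header lines recording fraction, seed and
#' per-environment counts.
#'
#' @param plans list of `allocation_plan` objects (or a single plan).
#' @param path output file path.
#' @export
write_plans <- function(plans, path) {
  if (inherits(plans, "allocation_plan")) plans <- list(plans)
  hdr <- lapply(plans, function(p)
    list(repeat_index = p$repeat_index, overlap_fraction = p$overlap_fraction,
         seed = p$seed, calibration = as.list(stats::setNames(
           plan_sizes(p)$calibration, plan_sizes(p)$env))))
  yml <- strsplit(yaml::as.yaml(list(plans = hdr)), "\n")[[1]]
  rows <- do.call(rbind, lapply(plans, function(p) {
    lines <- plan_line_ids(p)
    do.call(rbind, lapply(lines, function(l)
      data.frame(line = l, env = p$env_ids,
                 tested = as.integer(p$env_ids %in% p$tested[[l]]),
                 repeat_index = p$repeat_index)))
  }))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", yml), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- internals --------------------------------------------------------------

new_allocation_plan <- function(unique_sets, overlap_set, env_ids, fraction,
                                seed, repeat_index = 0L) {
  tested <- list()
  for (e in env_ids) for (l in unique_sets[[e]]) tested[[l]] <- e
  for (l in overlap_set) tested[[l]] <- env_ids
  structure(list(tested = tested, unique_sets = unique_sets,
                 overlap_set = overlap_set, env_ids = env_ids,
                 overlap_fraction = fraction, seed = seed,
                 repeat_index = repeat_index),
            class = "allocation_plan")
}

plan_line_ids <- function(plan) {
  c(plan$overlap_set, unlist(plan$unique_sets, use.names = FALSE))
}

#' @export
print.allocation_plan <- function(x, ...) {
  sz <- plan_sizes(x)
  cat(sprintf(
    "sparse-testing allocation: %d lines, %d environments, overlap %.0f%% (%d lines)\n",
    length(plan_line_ids(x)), length(x$env_ids), 100 * x$overlap_fraction,
    length(x$overlap_set)))
  cat(sprintf("  calibration per environment: %s\n",
              paste(sz$calibration, collapse = ", ")))
  invisible(x)
}

# Seed a private RNG stream for the calling function, restoring the caller's
# RNG state when that function exits.
local_rng <- function(seed, envir = parent.frame()) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  expr <- if (is.null(old)) {
    quote(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(expr, TRUE), envir = envir)
  invisible(seed)
}
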