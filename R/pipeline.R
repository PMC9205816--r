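#' Run a sparse-testing genomic-prediction experiment
#'
#' End-to-end evaluation of sparse-testing strategies on a multi-environment
#' dataset: for each overlap strategy and repeat, lines are allocated to
#' environments ([allocate_nonoverlap()] / [allocate_overlap()]), phenotypes
#' of untested cells are masked, the multi-environment model is refitted on
#' the training records (optionally augmented with historical data), masked
#' genetic values are predicted, and two accuracies are scored against
#' full-data references: the per-environment predictive ability (Pearson
#' correlation of predicted genetic effects with full-data BLUEs over the
#' prediction set) and the Smith-Hazel selection-intersection accuracy
#' (proportion of the top `sh_fraction` selected from full-data GBLUPs that
#' are re-selected from the prediction model).
#'
#' Full-data references are computed once and reused across strategies and
#' repeats; when several kinship matrices are supplied (e.g. genomic and
#' pedigree), all models are evaluated on the same allocation plans so the
#' comparison is paired.
#'
#' @param pheno plot-record data frame of the current dataset.
#' @param kinships a kinship matrix, or a named list of kinship matrices
#'   (names become the model labels, e.g. `list(GBLUP = G, PBLUP = A)`).
#' @param strategies overlap fractions, `0` meaning no overlap.
#' @param n_repeats allocation repeats per strategy.
#' @param base_seed seed from which all allocation seeds derive.
#' @param sh_fraction selected fraction for the intersection accuracy.
#' @param sh_weights economic weights of the Smith-Hazel index (default:
#'   the six-environment weight vector `0.25, 0.1, 0.3, 0.2, 0.1, 0.05`,
#'   positionally bound to the sorted environment labels; equal weights for
#'   other environment counts).
#' @param checks line ids always phenotyped everywhere and excluded from the
#'   accuracy sets; defaults to lines flagged by an `is_check` column, if
#'   present.
#' @param history optional historical plot records for augmentation.
#' @param augmentation `"none"`, `"single_env_history"` (historical records
#'   from one environment appended as an additional correlated environment)
#'   or `"multi_year_history"` (prior-year multi-environment records; the
#'   model switches to year-nested terms).
#' @param model,fa_order,env_effect,spatial,engine,em_iter,max_iter model
#'   options passed to [megblup()].
#' @param verbose print progress.
#' @return object of class `accuracy_report`: list with `predictive`
#'   (strategy x repeat x environment x model rows), `sh` (strategy x
#'   repeat x model rows), `summary`, `failures` and `config`.
#' @export
run_sparse_experiment <- function(pheno, kinships,
                                  strategies = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                                  n_repeats = 30, base_seed = 1,
                                  sh_fraction = 0.2, sh_weights = NULL,
                                  checks = NULL, history = NULL,
                                  augmentation = c("none",
                                                   "single_env_history",
                                                   "multi_year_history"),
                                  model = "multi_env", fa_order = 1,
                                  env_effect = "random", spatial = FALSE,
                                  engine = "general", em_iter = 6,
                                  max_iter = 200, verbose = FALSE) {
  augmentation <- match.arg(augmentation)
  if (length(strategies) == 0) stop("strategies must be nonempty")
  if (any(strategies < 0 | strategies >= 1)) {
    stop("overlap fractions must lie in [0, 1)")
  }
  if (is.matrix(kinships) || inherits(kinships, "kinship")) {
    kinships <- stats::setNames(
      list(kinships),
      if ((attr(kinships, "kind") %||% "genomic") == "pedigree") "PBLUP"
      else "GBLUP")
  }
  if (is.null(names(kinships))) {
    names(kinships) <- paste0("model", seq_along(kinships))
  }
  if (is.null(checks) && "is_check" %in% names(pheno)) {
    checks <- unique(pheno$line[pheno$is_check])
  }
  envs <- sort(unique(pheno$env))
  k <- length(envs)
  test_lines <- sort(setdiff(unique(pheno$line), checks))
  if (is.null(sh_weights)) {
    sh_weights <- if (k == 6) c(0.25, 0.1, 0.3, 0.2, 0.1, 0.05)
                  else rep(1 / k, k)
  }
  config <- list(strategies = strategies, n_repeats = n_repeats,
                 base_seed = base_seed, sh_fraction = sh_fraction,
                 sh_weights = sh_weights, augmentation = augmentation,
                 model = model, fa_order = fa_order,
                 env_effect = env_effect, spatial = spatial,
                 n_lines = length(test_lines), n_envs = k,
                 models = names(kinships))
  # ---- full-data references, one per kinship ----
  refs <- list()
  for (mn in names(kinships)) {
    K <- kinships[[mn]]
    full_fit <- megblup(pheno, K, model = model, fa_order = fa_order,
                        env_effect = env_effect, spatial = spatial,
                        engine = engine, em_iter = em_iter,
                        max_iter = max_iter)
    blues <- compute_blues(pheno, model = model, spatial = spatial,
                           varcomp = full_fit)
    idx <- index_covariances(full_fit,
                             n_reps = length(unique(pheno$rep)))
    b <- smith_hazel_weights(idx$G, idx$P, sh_weights)
    scores <- index_scores(full_fit$gblups[test_lines, envs, drop = FALSE], b)
    refs[[mn]] <- list(fit = full_fit, blues = blues, sh_b = b,
                       top = select_top(scores, sh_fraction))
  }
  pred_rows <- list(); sh_rows <- list(); failures <- list()
  for (si in seq_along(strategies)) {
    frac <- strategies[si]
    for (r in seq_len(n_repeats)) {
      seed_r <- base_seed + 1000L * (si - 1L) + (r - 1L)
      plan <- if (frac == 0) {
        allocate_nonoverlap(test_lines, envs, seed = seed_r)
      } else {
        allocate_overlap(test_lines, envs, frac, seed = seed_r)
      }
      plan$repeat_index <- r - 1L
      masked <- mask_phenotypes(pheno, plan)
      train <- masked$training
      model_r <- model
      for (mn in names(kinships)) {
        K <- kinships[[mn]]
        train_m <- train
        if (augmentation != "none") {
          aug <- augment_training(train, history, mode = augmentation,
                                  kinship = K)
          train_m <- aug$pheno
          model_r <- aug$model
          K <- aug$kinship
        }
        fit <- tryCatch(
          megblup(train_m, K, model = model_r, fa_order = fa_order,
                  env_effect = env_effect, spatial = spatial,
                  engine = "general", em_iter = em_iter,
                  max_iter = max_iter),
          error = function(e) e)
        if (inherits(fit, "error")) {
          failures[[length(failures) + 1L]] <-
            data.frame(strategy = frac, rep = r - 1L, model = mn,
                       reason = conditionMessage(fit))
          next
        }
        ref <- refs[[mn]]
        for (e in envs) {
          cells <- masked$truth_cells
          ml <- cells$line[cells$env == e]
          ml <- intersect(ml, test_lines)
          pa <- NA_real_
          if (length(ml) >= 3) {
            pred <- fit$gblups[ml, e]
            refv <- ref$blues$blue[match(paste(ml, e),
                                         paste(ref$blues$line, ref$blues$env))]
            names(refv) <- ml
            pa <- suppressWarnings(predictive_ability(pred, refv))
          }
          pred_rows[[length(pred_rows) + 1L]] <-
            data.frame(strategy = frac, rep = r - 1L, env = e, model = mn,
                       augmentation = augmentation,
                       predictive_ability = pa)
        }
        scores_r <- index_scores(fit$gblups[test_lines, envs, drop = FALSE],
                                 ref$sh_b)
        top_r <- select_top(scores_r, sh_fraction)
        sh_rows[[length(sh_rows) + 1L]] <-
          data.frame(strategy = frac, rep = r - 1L, model = mn,
                     augmentation = augmentation,
                     sh_accuracy = intersection_accuracy(ref$top, top_r))
      }
      if (verbose) {
        message(sprintf("strategy %.0f%% repeat %d done", 100 * frac, r))
      }
    }
  }
  predictive <- do.call(rbind, pred_rows)
  sh <- do.call(rbind, sh_rows)
  summary_pa <- stats::aggregate(predictive_ability ~ strategy + env + model,
                                 data = predictive, FUN = mean,
                                 na.rm = TRUE, na.action = stats::na.pass)
  summary_sh <- stats::aggregate(sh_accuracy ~ strategy + model, data = sh,
                                 FUN = mean, na.rm = TRUE,
                                 na.action = stats::na.pass)
  structure(list(predictive = predictive, sh = sh,
                 summary = list(predictive = summary_pa, sh = summary_sh),
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 refs = refs, config = config),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "sparse-testing accuracy report: %d strategies x %d repeats, %d environments\n",
    length(x$config$strategies), x$config$n_repeats, x$config$n_envs))
  cat("\nMean predictive ability by strategy (over environments and repeats):\n")
  pa <- stats::aggregate(predictive_ability ~ strategy + model,
                         data = x$predictive, FUN = mean, na.rm = TRUE)
  print(pa, row.names = FALSE)
  cat("\nMean Smith-Hazel intersection accuracy:\n")
  print(x$summary$sh, row.names = FALSE)
  if (!is.null(x$failures)) {
    cat(sprintf("\n%d model fit(s) failed and were excluded\n",
                nrow(x$failures)))
  }
  invisible(x)
}

#' @export
plot.accuracy_report <- function(x, ...) {
  pa <- x$predictive[!is.na(x$predictive$predictive_ability), ]
  graphics::boxplot(predictive_ability ~ strategy, data = pa,
                    xlab = "overlap fraction",
                    ylab = "predictive ability",
                    main = "Predictive ability by sparse-testing strategy")
  invisible(x)
}

#' Augment a training set with historical records
#'
#' * `single_env_history`: appends records of a single historical
#'   environment, relabelled with a `*` suffix, so it enters the
#'   multi-environment model as an additional correlated environment.
#' * `multi_year_history`: appends a full prior-year multi-environment
#'   table and switches the model to the year-nested equation, in which
#'   environment levels are environment-by-year combinations.
#'
#' History lines without rows in the kinship matrix are added as an
#' identity block ([block_diagonal_kinship()]): their records still inform
#' the environmental and variance structure without claiming relatedness.
#'
#' @param current training plot records (must carry `year`).
#' @param history historical plot records with year labels distinct from
#'   the current data.
#' @param mode augmentation mode, see above.
#' @param kinship optional kinship matrix to extend for ungenotyped history
#'   lines.
#' @return list with `pheno`, `model` and (if supplied) `kinship`.
#' @export
augment_training <- function(current, history,
                             mode = c("none", "single_env_history",
                                      "multi_year_history"),
                             kinship = NULL) {
  mode <- match.arg(mode)
  if (mode == "none" || is.null(history)) {
    return(list(pheno = current, model = "multi_env", kinship = kinship))
  }
  if (!"year" %in% names(current) || !"year" %in% names(history)) {
    stop("augmentation requires a 'year' column in both tables")
  }
  clash <- intersect(unique(current$year), unique(history$year))
  if (length(clash)) {
    stop("year collision between current and historical data: ",
         paste(clash, collapse = ", "))
  }
  history <- as.data.frame(history)
  if (mode == "single_env_history") {
    if (length(unique(history$env)) != 1) {
      stop("single_env_history expects a one-environment historical table")
    }
    history$env <- paste0(history$env, "*")
    model <- "multi_env"
  } else {
    model <- "multi_env_year"
  }
  cols <- intersect(names(current), names(history))
  out <- rbind(current[, cols, drop = FALSE], history[, cols, drop = FALSE])
  if (!is.null(kinship)) {
    extra <- setdiff(unique(history$line), rownames(kinship))
    if (length(extra)) kinship <- block_diagonal_kinship(kinship, extra)
  }
  list(pheno = out, model = model, kinship = kinship)
}

#' Compare stage-1 and stage-2 selection metrics
#'
#' Quantifies how well a first-stage (single-environment) selection metric
#' anticipates the second-stage (multi-environment) value of the same
#' lines: the Pearson correlation between the stage-wise values over common
#' lines, and for each selected fraction the proportion of overlap between
#' the stage-wise top sets.  Applied to GBLUPs and to BLUEs, this contrasts
#' relationship-aware and independence-assuming advancement metrics.
#'
#' @param stage1,stage2 named numeric vectors of line values (e.g. GBLUPs or
#'   BLUEs; a lines x environments matrix is averaged over environments).
#' @param fractions selected fractions to evaluate.
#' @return list with `correlation` and a data frame `overlap` (fraction,
#'   proportion).
#' @export
stage_advancement <- function(stage1, stage2,
                              fractions = seq(0.1, 0.5, by = 0.1)) {
  if (is.matrix(stage1)) stage1 <- rowMeans(stage1)
  if (is.matrix(stage2)) stage2 <- rowMeans(stage2)
  common <- intersect(names(stage1), names(stage2))
  if (length(common) < 3) stop("fewer than 3 common lines between stages")
  s1 <- stage1[common]; s2 <- stage2[common]
  ov <- vapply(fractions, function(f) {
    intersection_accuracy(select_top(s1, f), select_top(s2, f))
  }, numeric(1))
  list(correlation = stats::cor(s1, s2),
       overlap = data.frame(fraction = fractions, proportion = ov),
       n_common = length(common))
}

#' Write an accuracy report to disk
#'
#' Writes the raw per-repeat rows and the summaries as TSV files plus a YAML
#' run manifest (configuration, seeds, package version) that can be
#' re-loaded to reproduce the run.
#'
#' @param report an `accuracy_report` from [run_sparse_experiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "accuracy_report"))
  if (length(report$config$strategies) == 0) {
    stop("report has an empty strategy list")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    predictive = file.path(dir, "predictive_ability.tsv"),
    sh = file.path(dir, "sh_accuracy.tsv"),
    summary_pa = file.path(dir, "summary_predictive.tsv"),
    summary_sh = file.path(dir, "summary_sh.tsv"),
    manifest = file.path(dir, "manifest.yaml"))
  utils::write.table(report$predictive, paths["predictive"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$sh, paths["sh"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$summary$predictive, paths["summary_pa"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$summary$sh, paths["summary_sh"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- c(report$config,
                list(package_version =
                       as.character(utils::packageVersion("sparsegp")),
                     r_version = R.version.string,
                     n_failures = if (is.null(report$failures)) 0L
                                  else nrow(report$failures)))
  yaml::write_yaml(manifest, paths["manifest"])
  invisible(paths)
}

#' @rdname write_report
#' @param path path to a written manifest.
#' @export
read_report_manifest <- function(path) {
  yaml::read_yaml(path)
}
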