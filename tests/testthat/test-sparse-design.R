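test_that("overlap_count reproduces the printed allocation arithmetic", {
  # 280 lines, 6 environments: 10..50% overlap
  expect_identical(overlap_count(280, 6, 0.10), 28L)
  expect_identical(overlap_count(280, 6, 0.20), 58L)
  expect_identical(overlap_count(280, 6, 0.30), 88L)
  expect_identical(overlap_count(280, 6, 0.40), 112L)
  expect_identical(overlap_count(280, 6, 0.50), 142L)
  expect_identical(overlap_count(280, 6, 0), 0L)
  # the remainder always splits exactly across environments
  for (f in c(0.1, 0.25, 0.37, 0.5)) {
    x <- overlap_count(280, 6, f)
    expect_identical((280L - x) %% 6L, 0L)
    expect_gte(x, f * 280)
  }
  expect_error(overlap_count(10, 6, 0.95), "no unique lines")
})

test_that("non-overlapping allocation partitions lines into near-equal sets", {
  ids <- sprintf("L%03d", 1:280)
  envs <- paste0("SE", 1:6)
  plan <- allocate_nonoverlap(ids, envs, seed = 3)
  sizes <- sort(plan_sizes(plan)$calibration)
  expect_identical(sizes, c(46L, 46L, 47L, 47L, 47L, 47L))
  expect_identical(sort(plan_sizes(plan)$prediction, decreasing = TRUE),
                   c(234L, 234L, 233L, 233L, 233L, 233L))
  all_sets <- unlist(plan$unique_sets, use.names = FALSE)
  expect_identical(sort(all_sets), ids)        # partition: union, no overlap
  expect_length(plan$overlap_set, 0)
  # one line per environment when counts match
  p1 <- allocate_nonoverlap(ids[1:6], envs, seed = 1)
  expect_true(all(plan_sizes(p1)$calibration == 1))
  # determinism
  p2 <- allocate_nonoverlap(ids, envs, seed = 3)
  expect_identical(plan$unique_sets, p2$unique_sets)
})

test_that("overlapping allocation yields the printed calibration sizes", {
  ids <- sprintf("L%03d", 1:280)
  envs <- paste0("SE", 1:6)
  expected_calib <- c("0.1" = 70L, "0.2" = 95L, "0.3" = 120L,
                      "0.4" = 140L, "0.5" = 165L)
  expected_pred <- c("0.1" = 210L, "0.2" = 185L, "0.3" = 160L,
                     "0.4" = 140L, "0.5" = 115L)
  for (f in names(expected_calib)) {
    plan <- allocate_overlap(ids, envs, as.numeric(f), seed = 5)
    sz <- plan_sizes(plan)
    expect_true(all(sz$calibration == expected_calib[[f]]))
    expect_true(all(sz$prediction == expected_pred[[f]]))
    expect_identical(sort(c(plan$overlap_set,
                            unlist(plan$unique_sets, use.names = FALSE))),
                     ids)
  }
  expect_error(allocate_overlap(ids[1:6], envs, 0.9, seed = 1))
})

test_that("replicate_plans derives seeds and repeat indices", {
  ids <- sprintf("L%02d", 1:30)
  alloc <- function(seed) allocate_overlap(ids, paste0("SE", 1:3), 0.1, seed)
  plans <- replicate_plans(alloc, n_repeats = 30, base_seed = 7)
  expect_length(plans, 30)
  expect_identical(vapply(plans, `[[`, 0L, "repeat_index"), 0:29)
  expect_identical(plans[[1]]$overlap_set, alloc(7)$overlap_set)
  # different base seeds give different partitions
  plans2 <- replicate_plans(alloc, n_repeats = 1, base_seed = 99)
  expect_false(identical(plans[[1]]$unique_sets, plans2[[1]]$unique_sets))
})

test_that("mask_phenotypes splits plots and lists masked cells once", {
  dat <- small_dataset(n_lines = 12, k = 3, seed = 8)
  plan <- allocate_overlap(rownames(dat$geno), sort(unique(dat$pheno$env)),
                           0.25, seed = 2)
  out <- mask_phenotypes(dat$pheno, plan)
  # conservation: every original plot is either in training or masked
  masked_plots <- paste(dat$pheno$line, dat$pheno$env) %in%
    paste(out$truth_cells$line, out$truth_cells$env)
  expect_identical(nrow(out$training) + sum(masked_plots), nrow(dat$pheno))
  # every masked cell is unique and truly absent from training
  expect_false(any(duplicated(out$truth_cells)))
  expect_false(any(paste(out$truth_cells$line, out$truth_cells$env) %in%
                     paste(out$training$line, out$training$env)))
  # checks sit outside the plan and stay in training everywhere
  expect_true(all(dat$pheno$line[dat$pheno$is_check] %in% out$training$line))
  expect_error(mask_phenotypes(dat$pheno[dat$pheno$line != plan$overlap_set[1], ],
                               plan), "absent")
})

test_that("non-overlap masked line counts per environment match 233/234", {
  ids <- sprintf("L%03d", 1:280)
  envs <- paste0("SE", 1:6)
  plan <- allocate_nonoverlap(ids, envs, seed = 10)
  pheno <- expand.grid(line = ids, env = envs, rep = c("R1", "R2"),
                       stringsAsFactors = FALSE)
  pheno$value <- 0
  out <- mask_phenotypes(pheno, plan)
  masked_per_env <- table(out$truth_cells$env)
  expect_true(all(masked_per_env %in% c(233L, 234L)))
  expect_identical(nrow(out$training) + 2L * nrow(out$truth_cells),
                   nrow(pheno))
})

test_that("plans serialize with their YAML header", {
  ids <- sprintf("L%02d", 1:20)
  plan <- allocate_overlap(ids, paste0("SE", 1:2), 0.2, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_plans(plan, path)
  lines <- readLines(path)
  expect_true(any(grepl("overlap_fraction", lines)))
  body <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  expect_identical(nrow(body), 40L)
  expect_setequal(unique(body$line), ids)
})
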