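test_that("filter_snps applies missingness and MAF rules inclusively", {
  g <- rbind(c(0, 0, 0), c(1, NA, 0), c(2, 2, 0), c(0, 0, 1))
  colnames(g) <- c("A", "B", "C"); rownames(g) <- paste0("L", 1:4)
  # marker B: 25% missing > 20% -> removed; C: MAF 1/8 = 0.125 >= 0.05 kept
  out <- filter_snps(g, max_missing = 0.20, min_maf = 0.05)
  expect_identical(colnames(out), c("A", "C"))
  expect_identical(rownames(out), rownames(g))
  # thresholds are inclusive and the identity setting keeps everything
  expect_identical(colnames(filter_snps(g, max_missing = 1, min_maf = 0)),
                   colnames(g))
  expect_identical(colnames(filter_snps(g, max_missing = 0.25, min_maf = 0)),
                   colnames(g))
  # idempotence
  expect_identical(filter_snps(out), out)
  expect_warning(filter_snps(g, max_missing = 0, min_maf = 0.49),
                 "no marker passed")
})

test_that("impute_missing fills marker means and leaves the rest unchanged", {
  g <- cbind(m1 = c(0, 2, NA), m2 = c(1, 0, 2), m3 = c(2, 2, NA))
  rownames(g) <- paste0("L", 1:3)
  out <- impute_missing(g)
  expect_equal(out[3, "m1"], 1.0)
  expect_equal(out[3, "m3"], 2.0)
  expect_equal(out[, "m2"], g[, "m2"])
  complete <- impute_missing(g[1:2, ])
  expect_equal(complete, g[1:2, ])
  allmiss <- cbind(m1 = c(NA_real_, NA_real_))
  expect_error(impute_missing(allmiss), "m1")
})

test_that("compute_G matches the VanRaden hand calculation", {
  g <- matrix(c(0, 2, 2, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("m1", "m2")))
  G <- compute_G(g)
  # p = (0.5, 0.5), W = [[-1, 1], [1, -1]], denominator 1
  expect_equal(unclass(G), matrix(c(2, -2, -2, 2), 2,
                                  dimnames = list(c("A", "B"), c("A", "B"))),
               ignore_attr = TRUE)
  expect_lt(max(abs(G - t(G))), 1e-10)
  # identical fully homozygous lines share diagonal and off-diagonal entries
  g2 <- rbind(L1 = c(0, 2, 0, 2), L2 = c(0, 2, 0, 2), L3 = c(2, 0, 2, 0))
  G2 <- compute_G(g2)
  expect_equal(G2["L1", "L2"], G2["L1", "L1"])
  expect_error(compute_G(matrix(2, 3, 4)), "monomorphic")
})

test_that("compute_A reproduces textbook numerator relationships", {
  # founders only -> identity
  ped0 <- data.frame(id = c("A", "B"), parent1 = NA, parent2 = NA)
  expect_equal(unclass(compute_A(ped0)), diag(2), ignore_attr = TRUE)
  # full sibs from unrelated parents: A_sibs = 0.5; parent-offspring 0.5
  ped <- data.frame(id = c("A", "B", "S1", "S2"),
                    parent1 = c(NA, NA, "A", "A"),
                    parent2 = c(NA, NA, "B", "B"))
  A <- compute_A(ped)
  expect_equal(A["S1", "S2"], 0.5)
  expect_equal(A["A", "S1"], 0.5)
  expect_equal(A["S1", "S1"], 1)
  # selfed offspring of a non-inbred parent: F = 0.5, diagonal 1.5
  peds <- data.frame(id = c("A", "X"), parent1 = c(NA, "A"),
                     parent2 = c(NA, "A"))
  expect_equal(compute_A(peds)["X", "X"], 1.5)
  # order-independence: shuffled input gives the same values
  A2 <- compute_A(ped[c(3, 1, 4, 2), ])
  expect_equal(A2[rownames(A), colnames(A)], unclass(A), ignore_attr = TRUE)
  # cycles are rejected
  pedc <- data.frame(id = c("A", "B"), parent1 = c("B", "A"),
                     parent2 = c(NA, NA))
  expect_error(compute_A(pedc), "cycle")
})

test_that("block_diagonal_kinship appends an identity block", {
  K <- compute_G(rbind(L1 = c(0, 2, 1), L2 = c(2, 0, 1), L3 = c(0, 0, 2)))
  out <- block_diagonal_kinship(K, c("H1", "H2"))
  expect_equal(dim(out), c(5, 5))
  expect_equal(out[4:5, 4:5], diag(2), ignore_attr = TRUE)
  expect_true(all(out[1:3, 4:5] == 0) && all(out[4:5, 1:3] == 0))
  expect_identical(block_diagonal_kinship(K, character(0)), K)
  expect_error(block_diagonal_kinship(K, c("L1")), "overlap")
})

test_that("G is centered near zero off-diagonal for unrelated founders", {
  spec <- population_spec(n_founders = 80, n_markers = 5000, seed = 11)
  g <- simulate_founder_genotypes(spec)
  G <- compute_G(g)
  off <- G[upper.tri(G)]
  expect_lt(abs(mean(off)), 0.02)
})

test_that("genomic and pedigree relationships agree in expectation", {
  spec <- population_spec(n_founders = 40, n_markers = 5000, n_crosses = 60,
                          family_size_range = c(2, 5), n_selfing = 0,
                          seed = 21)
  founders <- simulate_founder_genotypes(spec)
  fam <- simulate_families(founders, spec, n_progeny = 200)
  ped <- rbind(data.frame(id = rownames(founders), parent1 = NA_character_,
                          parent2 = NA_character_),
               fam$pedigree)
  A <- compute_A(ped)[rownames(fam$geno), rownames(fam$geno)]
  G <- compute_G(fam$geno)
  off <- upper.tri(A)
  expect_lt(mean(abs(A[off] - G[off])), 0.05)
  # both kinds are PSD after stabilization
  for (K in list(stabilize_kinship(G), stabilize_kinship(compute_A(ped)))) {
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("VCF import converts GT to dosage and skips multi-allelic sites", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "L1", "L2", sep = "\t"),
    paste("1", "100", "m1", "A", "T", ".", "PASS", ".", "GT", "0/0", "0/1",
          sep = "\t"),
    paste("1", "200", "m2", "G", "C,A", ".", "PASS", ".", "GT", "0/0", "1/1",
          sep = "\t"),
    paste("1", "300", "m3", "A", "G", ".", "PASS", ".", "GT", "1|1", "./.",
          sep = "\t"))
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_message(d <- read_vcf_dosage(path), "multi-allelic")
  expect_equal(dim(d), c(2, 2))
  expect_equal(unname(d["L1", ]), c(0, 2))
  expect_equal(unname(d["L2", "m1"]), 1)
  expect_true(is.na(d["L2", "m3"]))
})
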