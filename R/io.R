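#' Read and write plot-record tables
#'
#' Plot records are stored as tab-separated text with a header line and
#' optional leading `#`-prefixed YAML metadata (seed, grid dimensions).
#'
#' @param pheno plot-record data frame.
#' @param path file path.
#' @return `read_plot_records` returns the data frame with any metadata in
#'   `attr(, "meta")`.
#' @export
write_plot_records <- function(pheno, path) {
  meta <- list(seed = attr(pheno, "seed"),
               grid = as.list(attr(pheno, "grid")))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  con <- file(path, "w"); on.exit(close(con))
  if (length(meta)) {
    writeLines(paste0("# ", strsplit(yaml::as.yaml(meta), "\n")[[1]]), con)
  }
  utils::write.table(pheno, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plot_records
#' @export
read_plot_records <- function(path) {
  lines <- readLines(path)
  metal <- grep("^#", lines)
  meta <- NULL
  if (length(metal)) {
    meta <- yaml::yaml.load(paste(sub("^# ?", "", lines[metal]),
                                  collapse = "\n"))
  }
  out <- utils::read.table(text = lines[setdiff(seq_along(lines), metal)],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  attr(out, "meta") <- meta
  out
}

#' Read and write dosage matrices
#'
#' Delimited text with marker ids in the header and line ids in the first
#' column; missing calls are `NA`.
#'
#' @param geno dosage matrix.
#' @param path file path.
#' @export
write_dosage <- function(geno, path) {
  df <- data.frame(line = rownames(geno), as.data.frame(geno),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read and write pedigree tables
#'
#' Three-column text (`id`, `parent1`, `parent2`); unknown parents are `NA`
#' or `0`.
#'
#' @param ped pedigree data frame.
#' @param path file path.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped[, c("id", "parent1", "parent2")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character"))
}

#' Write a kinship matrix as delimited text
#'
#' @param k kinship matrix.
#' @param path file path.
#' @export
write_kinship <- function(k, path) {
  df <- data.frame(line = rownames(k), as.data.frame(as.matrix(k)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  m <- read_dosage(path)
  new_kinship(m, kind = "genomic")
}

#' Import allele dosages from a VCF file
#'
#' Converts the GT field to alternate-allele dosage (0/1/2, `NA` for missing
#' calls).  Multi-allelic sites are skipped with a message reporting the
#' count.  Requires the `vcfR` package.
#'
#' @param path VCF file path (plain or gzipped).
#' @return lines x markers dosage matrix.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF import requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt %||% "")
  if (any(multi)) {
    message(sprintf("skipping %d multi-allelic site(s)", sum(multi)))
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
  })
  t(dose) # lines x markers
}
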