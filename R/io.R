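#' Read a genotype matrix from TSV or VCF
#'
#' TSV layout: a header row whose first field names the sample-id column and
#' whose remaining fields are SNP ids; one row per sample; cells in
#' `{0, 1, 2, NA}` (additive minor-allele dosage coding). VCF: biallelic
#' sites are converted to ALT-allele dosage from the GT field; multiallelic
#' sites are skipped with a logged count. Missing genotypes are imputed to
#' the column mean (required before standardization) with a logged count,
#' or rows with missing values dropped under `missing = "complete-case"`.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @param missing Missing-genotype policy: `"mean-impute"` (default) or
#'   `"complete-case"`.
#' @return An object of class `genotype_table`: `sample_ids`, `snp_ids`,
#'   `values` (numeric n x p matrix), `missing_mask` (logical matrix on the
#'   retained rows), `n_missing`, `n_multiallelic_skipped`.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"),
                           missing = c("mean-impute", "complete-case")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path)
  gt <- if (format == "tsv") read_genotypes_tsv(path)
        else read_genotypes_vcf(path)
  mask <- is.na(gt$values)
  n_missing <- sum(mask)
  if (n_missing > 0) {
    if (missing == "complete-case") {
      keep <- rowSums(mask) == 0L
      message("dropping ", sum(!keep), " sample(s) with missing genotypes")
      gt$values <- gt$values[keep, , drop = FALSE]
      gt$sample_ids <- gt$sample_ids[keep]
      mask <- mask[keep, , drop = FALSE]
    } else {
      message("imputing ", n_missing,
              " missing genotype(s) to column means")
      cm <- colMeans(gt$values, na.rm = TRUE)
      idx <- which(mask, arr.ind = TRUE)
      gt$values[idx] <- cm[idx[, 2L]]
    }
  }
  structure(list(sample_ids = gt$sample_ids, snp_ids = gt$snp_ids,
                 values = gt$values, missing_mask = mask,
                 n_missing = n_missing,
                 n_multiallelic_skipped = gt$n_multiallelic_skipped %||% 0L),
            class = "genotype_table")
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop("malformed genotype TSV (need sample-id column plus >= 1 SNP): ",
         path)
  sample_ids <- df[[1L]]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  snp_ids <- colnames(df)[-1L]
  if (anyDuplicated(snp_ids))
    stop("duplicate SNP id(s) in header")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  na_cells <- is.na(vals) | vals == "NA" | vals == ""
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  valid <- !is.na(num) & (num == 0 | num == 1 | num == 2)
  bad <- !na_cells & !valid
  if (any(bad)) {
    bad_idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "invalid genotype cell at line %d, column '%s' (value '%s'): must be 0, 1, 2 or NA",
      bad_idx[1L] + 1L, snp_ids[bad_idx[2L]], vals[bad_idx[1L], bad_idx[2L]]))
  }
  num[na_cells] <- NA_real_
  dimnames(num) <- list(sample_ids, snp_ids)
  list(sample_ids = sample_ids, snp_ids = snp_ids, values = num)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  n_skip <- sum(multi)
  if (n_skip > 0) {
    message("skipping ", n_skip, " multiallelic site(s)")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids) || any(ids == ".")) {
    fix <- vcfR::getFIX(v)
    ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                  paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"])
  }
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  })
  values <- t(dose)  # samples x SNPs
  colnames(values) <- ids
  list(sample_ids = rownames(values), snp_ids = ids, values = values,
       n_multiallelic_skipped = n_skip)
}

#' Read a binary phenotype file aligned to a genotype table
#'
#' Two-column TSV (`sample_id`, `status` in 0/1). When a `genotype_table`
#' is supplied the phenotypes are reordered to its sample order; samples
#' present on only one side are an error.
#'
#' @param path Phenotype TSV path.
#' @param genotypes Optional `genotype_table` to align against.
#' @return Named integer vector of 0/1 status values.
#' @export
read_phenotype <- function(path, genotypes = NULL) {
  df <- utils::read.delim(path, colClasses = "character")
  if (ncol(df) < 2L) stop("phenotype file must have two columns")
  ids <- df[[1L]]
  status <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(status) || !all(status %in% c(0, 1)))
    stop("non-binary status value(s) in ", path)
  if (anyDuplicated(ids)) stop("duplicate sample id(s) in phenotype file")
  y <- stats::setNames(as.integer(status), ids)
  if (!is.null(genotypes)) {
    extra <- setdiff(ids, genotypes$sample_ids)
    miss <- setdiff(genotypes$sample_ids, ids)
    if (length(extra) || length(miss))
      stop("sample mismatch between phenotype and genotypes; ",
           if (length(extra)) paste0("extra in phenotype: ",
                                     paste(extra, collapse = ", "), "; "),
           if (length(miss)) paste0("missing from phenotype: ",
                                    paste(miss, collapse = ", ")))
    y <- y[genotypes$sample_ids]
  }
  y
}

#' Write a genotype matrix as TSV
#'
#' @param values Matrix of genotype values (or a `genotype_table`).
#' @param sample_ids Sample ids (ignored when `values` is a
#'   `genotype_table`).
#' @param path Output path.
#' @export
write_genotypes <- function(values, sample_ids = NULL, path) {
  if (inherits(values, "genotype_table")) {
    sample_ids <- values$sample_ids
    values <- values$values
  }
  df <- data.frame(sample_id = sample_ids, values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phenotype vector as two-column TSV
#'
#' @param y Binary status vector.
#' @param sample_ids Sample ids.
#' @param path Output path.
#' @export
write_phenotype <- function(y, sample_ids, path) {
  utils::write.table(data.frame(sample_id = sample_ids, status = y), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minor-allele-frequency filter
#'
#' Drops SNP columns whose minor allele frequency (under additive 0/1/2
#' coding, MAF = min(f, 1 - f) with f = mean(dosage)/2) falls below the
#' threshold.
#'
#' @param gt A `genotype_table`.
#' @param maf Threshold (default 0.05).
#' @return The filtered `genotype_table`.
#' @export
maf_filter <- function(gt, maf = 0.05) {
  stopifnot(inherits(gt, "genotype_table"))
  f <- colMeans(gt$values) / 2
  keep <- pmin(f, 1 - f) >= maf
  subset_genotypes(gt, keep)
}

#' Hardy-Weinberg equilibrium filter
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of the genotype
#' counts against Hardy-Weinberg proportions computed from the allele
#' frequency; SNPs with p-value below `p_cutoff` are dropped. Dosages are
#' rounded to the nearest genotype level for counting.
#'
#' @param gt A `genotype_table`.
#' @param p_cutoff Significance cutoff (default 1e-3).
#' @return The filtered `genotype_table`.
#' @export
hwe_filter <- function(gt, p_cutoff = 1e-3) {
  stopifnot(inherits(gt, "genotype_table"))
  pvals <- apply(gt$values, 2L, function(x) {
    g <- round(x)
    n0 <- sum(g == 0); n1 <- sum(g == 1); n2 <- sum(g == 2)
    n <- n0 + n1 + n2
    if (n == 0) return(0)
    f <- (2 * n2 + n1) / (2 * n)
    e <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
    if (any(e == 0)) return(1)
    stat <- sum((c(n0, n1, n2) - e)^2 / e)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  })
  subset_genotypes(gt, pvals >= p_cutoff)
}

subset_genotypes <- function(gt, keep) {
  gt$values <- gt$values[, keep, drop = FALSE]
  gt$snp_ids <- gt$snp_ids[keep]
  gt$missing_mask <- gt$missing_mask[, keep, drop = FALSE]
  gt
}

run_config_fields <- c(
  "n", "p", "cluster_size", "structure", "rho", "data_type",
  "effect_fraction", "effect_bounds", "n_replicates", "methods", "seed",
  "alpha", "c", "nlambda1", "lambda2_grid", "gamma", "tol", "max_iter")

#' Read and validate a benchmark run configuration
#'
#' YAML mapping with the scenario, tuning and benchmark settings; unknown
#' keys are rejected before any computation. Required keys: `n`, `p`,
#' `cluster_size`, `structure`, `rho`, `n_replicates`, `seed`. Everything
#' else defaults to the package defaults.
#'
#' @param path YAML file path.
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  # keep bare keys like "n" and "y" as strings (YAML 1.1 would read them
  # as booleans)
  cfg <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) x, "bool#no" = function(x) x))
  if (!is.list(cfg)) stop("run config must be a YAML mapping")
  unknown <- setdiff(names(cfg), run_config_fields)
  if (length(unknown))
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  req <- c("n", "p", "cluster_size", "structure", "rho", "n_replicates",
           "seed")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("missing required run-config key(s): ",
         paste(miss, collapse = ", "))
  defaults <- list(data_type = "snp", effect_fraction = 0.10,
                   effect_bounds = c(0.25, 0.75),
                   methods = c("network", "mcp", "enet", "lasso"),
                   alpha = 5, c = 1.96, nlambda1 = 20,
                   lambda2_grid = c(0, 0.01, 0.1, 1, 10), gamma = 4.5,
                   tol = 1e-4, max_iter = 500)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  structure(cfg, class = "run_config")
}
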