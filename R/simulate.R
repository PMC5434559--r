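#' Simulation scenario configuration
#'
#' Describes one scenario of the clustered synthetic-data design: `p`
#' predictors in clusters of `cluster_size`, within-cluster correlation
#' `rho` under an AR (`rho^|i-j|`) or block (compound-symmetric) structure,
#' clusters mutually independent. A fraction `effect_fraction` of the
#' predictors carry nonzero coefficients, allocated as whole clusters, drawn
#' from `Unif(effect_bounds)`. With `data_type = "snp"` the latent
#' expression values are trichotomized at their empirical quartiles into
#' 0/1/2 genotypes.
#'
#' @param n Training sample size.
#' @param p Number of predictors; must be divisible by `cluster_size`.
#' @param cluster_size Predictors per cluster.
#' @param structure `"ar"` or `"block"`.
#' @param rho Within-cluster correlation in `[0, 1)`.
#' @param effect_fraction Fraction of predictors with nonzero effects
#'   (default 0.10), allocated as whole clusters.
#' @param effect_bounds Lower/upper bound of the uniform effect-size
#'   distribution (default `c(0.25, 0.75)`).
#' @param data_type `"snp"` (quartile-trichotomized genotypes) or
#'   `"expression"` (continuous).
#' @param seed Master seed; every artifact of the scenario is a pure
#'   function of the configuration including this seed.
#' @param n_validation,n_test Sizes of the independent validation/test
#'   draws; default: validation of size `n`, no test set.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 500, p = 750, cluster_size = 5,
                       structure = c("ar", "block"), rho = 0.9,
                       effect_fraction = 0.10,
                       effect_bounds = c(0.25, 0.75),
                       data_type = c("snp", "expression"), seed = 1,
                       n_validation = n, n_test = 0) {
  structure_ <- match.arg(structure)
  data_type <- match.arg(data_type)
  stopifnot(n >= 4, p >= 1, cluster_size >= 1)
  if (p %% cluster_size != 0)
    stop("p must be divisible by cluster_size")
  stopifnot(rho >= 0, rho < 1)
  stopifnot(effect_fraction >= 0, effect_fraction <= 1)
  stopifnot(length(effect_bounds) == 2L, effect_bounds[1] <= effect_bounds[2])
  structure(list(n = as.integer(n), p = as.integer(p),
                 cluster_size = as.integer(cluster_size),
                 structure = structure_, rho = rho,
                 effect_fraction = effect_fraction,
                 effect_bounds = effect_bounds, data_type = data_type,
                 seed = as.integer(seed),
                 n_validation = as.integer(n_validation),
                 n_test = as.integer(n_test)),
            class = "sim_config")
}

cluster_chol <- function(config) {
  s <- config$cluster_size
  if (s == 1L) return(matrix(1, 1, 1))
  S <- if (config$structure == "ar") {
    config$rho^abs(outer(seq_len(s), seq_len(s), "-"))
  } else {
    m <- matrix(config$rho, s, s); diag(m) <- 1; m
  }
  chol(S)
}

#' Simulate clustered multivariate-normal expression values
#'
#' Draws an `n x p` matrix of marginally standardized (mean 0, variance 1)
#' normal values; predictors within a cluster follow the configured AR or
#' compound-symmetric correlation, clusters are independent.
#'
#' @param config A [sim_config()].
#' @param n Number of rows to draw (defaults to `config$n`).
#' @note Uses the current RNG state; callers wanting reproducibility should
#'   `set.seed()` first (as [make_dataset()] does).
#' @export
simulate_expression <- function(config, n = config$n) {
  stopifnot(inherits(config, "sim_config"))
  U <- cluster_chol(config)
  s <- config$cluster_size
  ncl <- config$p %/% s
  X <- matrix(NA_real_, n, config$p)
  for (b in seq_len(ncl)) {
    Z <- matrix(stats::rnorm(n * s), n, s)
    X[, ((b - 1L) * s + 1L):(b * s)] <- Z %*% U
  }
  colnames(X) <- paste0("snp", seq_len(config$p))
  X
}

#' Trichotomize expression values into genotype levels
#'
#' Per column, values above the empirical 3rd quartile become 2 (AA), values
#' in (Q1, Q3] become 1 (Aa), and values at or below the 1st quartile become
#' 0 (aa), yielding level frequencies of about (0.25, 0.50, 0.25) and an
#' implied allele frequency of 1/2. The upper tail is mapped to 2; the
#' orientation is immaterial after standardization but fixed for
#' reproducibility.
#'
#' @param expr Numeric matrix of expression values, `n >= 4`.
#' @return Integer matrix of the same shape with values in `{0, 1, 2}`.
#' @export
dichotomize_to_snps <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 4L) stop("need at least 4 observations for quartiles")
  out <- apply(expr, 2L, function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    as.integer(x > q[1]) + as.integer(x > q[2])
  })
  dimnames(out) <- dimnames(expr)
  out
}

#' Draw the true coefficient vector
#'
#' Selects `round(effect_fraction * p / cluster_size)` clusters uniformly at
#' random (so the number of nonzero coefficients is `effect_fraction * p`)
#' and draws every coefficient inside a selected cluster independently from
#' `Unif(effect_bounds)`; all other coefficients are exactly zero.
#'
#' @param config A [sim_config()].
#' @param seed Seed for the cluster choice and effect draws; defaults to the
#'   scenario's master seed.
#' @return Numeric vector `beta_true` of length `p`.
#' @export
assign_effects <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  s <- config$cluster_size
  ncl <- config$p %/% s
  beta <- numeric(config$p)
  if (config$effect_fraction > 0) {
    k <- max(1L, as.integer(round(config$effect_fraction * config$p / s)))
    k <- min(k, ncl)
    chosen <- sample.int(ncl, k)
    for (b in chosen) {
      idx <- ((b - 1L) * s + 1L):(b * s)
      beta[idx] <- stats::runif(s, config$effect_bounds[1],
                                config$effect_bounds[2])
    }
  }
  beta
}

#' Simulate the binary response through the logistic link
#'
#' `y_i ~ Bernoulli(logistic(x_i' beta))` independently, with the design
#' standardized (columns centered, `n^{-1}||X_m||^2 = 1`) before the product
#' so that genotype levels enter on the same scale the solver uses.
#'
#' @param X Design matrix (genotype levels or expression values).
#' @param beta_true True coefficient vector.
#' @param seed Optional seed.
#' @return Integer vector of 0/1 responses.
#' @export
simulate_response <- function(X, beta_true, seed = NULL) {
  if (ncol(X) != length(beta_true)) stop("dimension mismatch")
  if (!is.null(seed)) set.seed(seed)
  Xs <- standardize_design(X)
  pi <- stats::plogis(drop(Xs %*% beta_true))
  stats::rbinom(nrow(X), 1L, pi)
}

#' Simulate a train / validation (/ test) dataset triple
#'
#' All roles share the same true coefficient vector and cluster assignment;
#' the draws are independent, with seeds derived deterministically from the
#' scenario's master seed, so the whole triple is a pure function of the
#' configuration.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements `train`,
#'   `validation` (and `test` when `n_test > 0`) — each a list with `X`,
#'   `y`, `role` — plus `beta_true`, `support_true` and `config`.
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  beta_true <- assign_effects(config, seed = derive_seed(config$seed, 1L))
  roles <- list(train = config$n, validation = config$n_validation)
  if (config$n_test > 0) roles$test <- config$n_test
  out <- list()
  for (j in seq_along(roles)) {
    nm <- names(roles)[j]
    set.seed(derive_seed(config$seed, 10L + j))
    X <- simulate_expression(config, n = roles[[j]])
    if (config$data_type == "snp") X <- dichotomize_to_snps(X)
    y <- simulate_response(X, beta_true,
                           seed = derive_seed(config$seed, 100L + j))
    out[[nm]] <- list(X = X, y = y, role = nm)
  }
  out$beta_true <- beta_true
  out$support_true <- which(beta_true != 0)
  out$config <- config
  class(out) <- "sim_dataset"
  out
}

#' Write a simulated dataset to delimited files
#'
#' Writes, for each role, the genotype/expression TSV and phenotype TSV in
#' the formats the package's readers accept, plus a JSON sidecar with the
#' configuration, seed and true support.
#'
#' @param ds A `sim_dataset` from [make_dataset()].
#' @param prefix Output path prefix; files are
#'   `<prefix>_<role>_genotypes.tsv`, `<prefix>_<role>_phenotype.tsv` and
#'   `<prefix>_meta.json`.
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(ds, prefix) {
  stopifnot(inherits(ds, "sim_dataset"))
  files <- character(0)
  for (nm in intersect(c("train", "validation", "test"), names(ds))) {
    role <- ds[[nm]]
    sample_ids <- sprintf("s%04d", seq_len(nrow(role$X)))
    fg <- paste0(prefix, "_", nm, "_genotypes.tsv")
    fp <- paste0(prefix, "_", nm, "_phenotype.tsv")
    write_genotypes(role$X, sample_ids, fg)
    write_phenotype(role$y, sample_ids, fp)
    files <- c(files, fg, fp)
  }
  meta <- list(config = unclass(ds$config),
               beta_true = ds$beta_true,
               support_true = ds$support_true)
  fm <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, fm, auto_unbox = TRUE, digits = NA)
  invisible(c(files, fm))
}
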