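#' Configuration for the LD power-adjacency network
#'
#' Bundles the parameters that define the SNP-SNP network: the power-adjacency
#' exponent `alpha`, the standard-normal threshold constant `c` used by the
#' Fisher-transform significance cutoff, and the sample size `n_obs` the
#' cutoff is computed for.
#'
#' @param alpha Positive exponent of the power adjacency; default 5. Raising
#'   `alpha` shrinks weak edge weights toward zero but never changes which
#'   edges exist (that is controlled by `c`).
#' @param c Nonnegative standard-normal quantile used to threshold
#'   `sqrt(n - 3) * z` where `z` is the Fisher transform of a correlation;
#'   default 1.96 (two-sided 5%).
#' @param n_obs Integer sample count used for the cutoff; must be at least 4
#'   (the Fisher cutoff needs `n - 3 > 0`).
#' @return An object of class `network_config`.
#' @seealso [build_adjacency()], [correlation_cutoff()]
#' @export
network_config <- function(alpha = 5, c = 1.96, n_obs) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  stopifnot(is.numeric(c), length(c) == 1L, c >= 0)
  if (!is.numeric(n_obs) || length(n_obs) != 1L || n_obs < 4)
    stop("n_obs must be a single integer >= 4 (Fisher cutoff needs n - 3 > 0)")
  structure(list(alpha = alpha, c = c, n_obs = as.integer(n_obs)),
            class = "network_config")
}

#' Pearson correlation matrix of a design matrix
#'
#' Column-wise Pearson correlations, with a hard error on constant columns
#' (for which the correlation is undefined) naming the offending column.
#'
#' @param X Numeric matrix (n samples x p predictors), n >= 2.
#' @return Symmetric p x p correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 observations to correlate")
  v <- apply(X, 2L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    lbl <- if (!is.null(colnames(X))) colnames(X)[bad[1L]] else bad[1L]
    stop("constant column (zero variance): ", lbl)
  }
  R <- stats::cor(X)
  R[R > 1] <- 1
  R[R < -1] <- -1
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R
}

#' Fisher z-transformation of a correlation
#'
#' `z = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing transform of a
#' Pearson correlation; under zero true correlation `sqrt(n - 3) * z` is
#' approximately standard normal.
#'
#' @param r Numeric vector of correlations with `|r| < 1`.
#' @return The transformed values (an odd function of `r`).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z is only defined for |r| < 1")
  0.5 * log((1 + r) / (1 - r))
}

#' Correlation cutoff from the Fisher-transform normal approximation
#'
#' Inverts the Fisher transform at the normal threshold `c`:
#' `r_c = (exp(2c / sqrt(n - 3)) - 1) / (exp(2c / sqrt(n - 3)) + 1)`,
#' equivalently `tanh(c / sqrt(n - 3))`. Correlations with `|r| <= r_c` are
#' treated as noise and receive no network edge.
#'
#' @param n_obs Integer sample count, at least 4.
#' @param c Nonnegative normal threshold constant.
#' @return The cutoff `r_c` in `[0, 1)`.
#' @export
correlation_cutoff <- function(n_obs, c) {
  if (!is.numeric(n_obs) || length(n_obs) != 1L || n_obs < 4)
    stop("n_obs must be a single integer >= 4")
  stopifnot(is.numeric(c), length(c) == 1L, c >= 0)
  e <- exp(2 * c / sqrt(n_obs - 3))
  (e - 1) / (e + 1)
}

#' Build the signed sparse power-adjacency network
#'
#' Edge weights are `a_mk = sgn(r_mk) * |r_mk|^alpha` whenever
#' `|r_mk| > r_c`, and 0 otherwise; the diagonal is zero. The signed power
#' preserves the sign of the correlation for any exponent. The result is
#' stored as a general sparse matrix (both triangles) for fast column access
#' in the solver.
#'
#' @param R Symmetric correlation matrix with unit diagonal.
#' @param config A [network_config()].
#' @return An object of class `adjacency_network` with elements `weights`
#'   (sparse symmetric p x p \code{\link[Matrix]{dgCMatrix-class}}), `r_c`,
#'   `config` and `snp_ids`.
#' @export
build_adjacency <- function(R, config) {
  stopifnot(inherits(config, "network_config"))
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8)
    stop("R must be a symmetric correlation matrix")
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop("R must have unit diagonal")
  r_c <- correlation_cutoff(config$n_obs, config$c)
  W <- sign(R) * abs(R)^config$alpha
  W[abs(R) <= r_c] <- 0
  diag(W) <- 0
  ids <- colnames(R)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(R)))
  weights <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                                     "generalMatrix"), "CsparseMatrix")
  dimnames(weights) <- list(ids, ids)
  structure(list(weights = weights, r_c = r_c, config = config,
                 snp_ids = ids),
            class = "adjacency_network")
}

#' Build the LD network directly from a design matrix
#'
#' Convenience wrapper: Pearson correlations of the columns of `X`, the
#' Fisher-transform cutoff at sample size `nrow(X)`, then the signed power
#' adjacency.
#'
#' @inheritParams pearson_matrix
#' @inheritParams network_config
#' @return An `adjacency_network`; see [build_adjacency()].
#' @export
ld_network <- function(X, alpha = 5, c = 1.96) {
  cfg <- network_config(alpha = alpha, c = c, n_obs = nrow(X))
  build_adjacency(pearson_matrix(X), cfg)
}

#' @export
#' @method print adjacency_network
print.adjacency_network <- function(x, ...) {
  p <- ncol(x$weights)
  ne <- Matrix::nnzero(x$weights) / 2
  cat(sprintf("LD power-adjacency network: %d nodes, %d edges (r_c = %.4g",
              p, ne, x$r_c))
  if (!is.null(x$config))
    cat(sprintf(", alpha = %g, c = %g", x$config$alpha, x$config$c))
  cat(")\n")
  invisible(x)
}

#' Write a network as a three-column edge list
#'
#' One undirected edge per line: `snp_id_a`, `snp_id_b`, signed `weight`,
#' tab-separated with a header.
#'
#' @param net An `adjacency_network`.
#' @param path Output file path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "adjacency_network"))
  W <- Matrix::triu(net$weights, k = 1)
  tri <- Matrix::summary(methods::as(W, "TsparseMatrix"))
  df <- data.frame(snp_id_a = net$snp_ids[tri$i],
                   snp_id_b = net$snp_ids[tri$j],
                   weight = tri$x, stringsAsFactors = FALSE)
  df <- df[df$weight != 0, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge list written by [write_edge_list()]
#'
#' @param path Path to a three-column TSV (`snp_id_a`, `snp_id_b`, `weight`).
#' @param snp_ids Character vector fixing the node set and its order; must
#'   cover every id appearing in the file.
#' @return An `adjacency_network` (with `r_c` and `config` set to `NA`/`NULL`
#'   since the construction parameters are not stored in the edge list).
#' @export
read_edge_list <- function(path, snp_ids) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id_a", "snp_id_b", "weight")
  if (!all(need %in% names(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  ia <- match(as.character(df$snp_id_a), snp_ids)
  ib <- match(as.character(df$snp_id_b), snp_ids)
  if (anyNA(ia) || anyNA(ib)) {
    missing <- unique(c(df$snp_id_a[is.na(ia)], df$snp_id_b[is.na(ib)]))
    stop("edge list references unknown SNP ids: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  p <- length(snp_ids)
  weights <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                                  x = c(df$weight, df$weight),
                                  dims = c(p, p),
                                  dimnames = list(snp_ids, snp_ids))
  weights <- methods::as(methods::as(weights, "generalMatrix"),
                         "CsparseMatrix")
  structure(list(weights = weights, r_c = NA_real_, config = NULL,
                 snp_ids = snp_ids),
            class = "adjacency_network")
}
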