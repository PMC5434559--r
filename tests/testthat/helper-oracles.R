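# Shared fixtures and independent oracles used across test files.

# Random standardized logistic instance with a sparse true signal.
rand_instance <- function(n = 50, p = 10, k = 3, effect = 1.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(rep(effect, k), rep(0, p - k))
  y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  list(X = standardize_design(X), y = y, beta_true = beta)
}

# Random signed sparse symmetric adjacency with zero diagonal, wrapped as
# the package's network object.
rand_network <- function(p, density = 0.3, seed = 1) {
  set.seed(seed)
  W <- matrix(0, p, p)
  for (m in seq_len(p - 1)) {
    for (k in (m + 1):p) {
      if (runif(1) < density) {
        w <- runif(1, 0.1, 0.9) * sample(c(-1, 1), 1)
        W[m, k] <- w
        W[k, m] <- w
      }
    }
  }
  weights <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                                     "generalMatrix"), "CsparseMatrix")
  structure(list(weights = weights, r_c = 0, config = NULL,
                 snp_ids = paste0("snp", seq_len(p))),
            class = "adjacency_network")
}

# Value of the one-dimensional coordinate surrogate at beta_m = b, computed
# directly from the data with literal loops: the fixed-weight quadratic term
# plus the penalty in the solver's parametrization. The coordinate update
# must minimize this function.
surrogate_value <- function(b, m, beta, residual, X, net = NULL, spec,
                            method) {
  n <- nrow(X)
  quad <- sum((residual - X[, m] * (b - beta[m]))^2) / (8 * n)
  pen <- if (method %in% c("network", "mcp")) {
    mcp_penalty(b, spec$lambda1, spec$gamma)
  } else if (method == "lasso") {
    spec$lambda1 * abs(b)
  } else {
    spec$lambda1 * abs(b) + spec$lambda2 / 2 * b^2
  }
  if (method == "network" && spec$lambda2 > 0) {
    lap <- 0
    for (k in seq_len(length(beta))) {
      a <- net$weights[k, m]
      if (k != m && a != 0)
        lap <- lap + abs(a) * (b - sign(a) * beta[k])^2
    }
    pen <- pen + spec$lambda2 / 2 * lap
  }
  quad + pen
}

# Small deterministic simulated scenario for cheap end-to-end tests.
tiny_scenario <- function(seed = 5) {
  sim_config(n = 80, p = 20, cluster_size = 4, structure = "ar", rho = 0.5,
             effect_fraction = 0.2, data_type = "snp", seed = seed)
}
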