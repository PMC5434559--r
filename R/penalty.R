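#' Penalty specification for the network-constrained fit
#'
#' Holds the three regularization parameters: `lambda1` (MCP level,
#' sparsity), `lambda2` (network smoothness level) and `gamma` (MCP concavity
#' parameter). With the fixed IRLS weight bound `w = 1/4`, `gamma` must
#' exceed `1/w = 4` for the coordinate subproblem to stay convex; the default
#' is 4.5.
#'
#' @param lambda1 Nonnegative MCP level.
#' @param lambda2 Nonnegative Laplacian (network) level.
#' @param gamma MCP concavity parameter, strictly greater than 4.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(lambda1, lambda2 = 0, gamma = 4.5) {
  stopifnot(is.numeric(lambda1), length(lambda1) == 1L, lambda1 >= 0)
  stopifnot(is.numeric(lambda2), length(lambda2) == 1L, lambda2 >= 0)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 4)
    stop("gamma must exceed 4 (the reciprocal of the fixed IRLS weight 1/4)")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, gamma = gamma),
            class = "penalty_spec")
}

#' Minimax concave penalty (MCP)
#'
#' `rho(t; lambda1, gamma) = lambda1 * integral_0^{|t|} (1 - x/(gamma*lambda1))_+ dx`,
#' i.e. `lambda1*|t| - t^2/(2*gamma)` for `|t| <= gamma*lambda1` and the
#' saturated value `gamma*lambda1^2/2` beyond. Applies lasso-like shrinkage
#' near zero and none for large coefficients.
#'
#' @param t Numeric vector of coefficient values.
#' @param lambda1 Nonnegative penalty level.
#' @param gamma Concavity parameter (> 4 in this package's fits).
#' @return Penalty values, even and nondecreasing in `|t|`.
#' @export
mcp_penalty <- function(t, lambda1, gamma = 4.5) {
  stopifnot(lambda1 >= 0, gamma > 0)
  ifelse(abs(t) <= gamma * lambda1,
         lambda1 * abs(t) - t^2 / (2 * gamma),
         gamma * lambda1^2 / 2)
}

#' Soft-thresholding operator
#'
#' `S(u, lam) = sgn(u) * (|u| - lam)_+`, the closed-form solution of the
#' univariate lasso problem.
#'
#' @param u Numeric vector.
#' @param lam Nonnegative threshold.
#' @export
soft_threshold <- function(u, lam) {
  stopifnot(lam >= 0)
  sign(u) * pmax(abs(u) - lam, 0)
}

#' Signed Laplacian smoothness penalty
#'
#' `lambda2 * sum_{m<k} |a_mk| * (beta_m - sgn(a_mk) * beta_k)^2` over the
#' network edges: positively connected predictors are pulled toward equal
#' coefficients, negatively connected ones toward opposite coefficients.
#' Zero iff `beta_m = sgn(a_mk) * beta_k` on every edge.
#'
#' Note on conventions: the coordinate update used by [ldnet_fit()] (quadratic
#' coefficient `t_m = 1/4 + lambda2 * sum |a_mk|`) corresponds to a Laplacian
#' weight of `lambda2/2` in this sum; [penalized_objective()] accounts for
#' that factor so that it is the exact objective the solver descends.
#'
#' @param beta Coefficient vector of length p.
#' @param net An `adjacency_network` on the same p predictors.
#' @param lambda2 Nonnegative level.
#' @return A nonnegative scalar.
#' @export
laplacian_penalty <- function(beta, net, lambda2) {
  stopifnot(inherits(net, "adjacency_network"), lambda2 >= 0)
  if (length(beta) != ncol(net$weights))
    stop("beta length (", length(beta), ") does not match network dimension (",
         ncol(net$weights), ")")
  if (lambda2 == 0) return(0)
  tri <- Matrix::summary(methods::as(Matrix::triu(net$weights, k = 1),
                                     "TsparseMatrix"))
  if (nrow(tri) == 0L) return(0)
  a <- tri$x
  d <- beta[tri$i] - sign(a) * beta[tri$j]
  lambda2 * sum(abs(a) * d^2)
}

#' Penalized logistic objective
#'
#' The mean negative log-likelihood of the no-intercept logistic model plus
#' the MCP and (for the network method) the Laplacian penalty, in the
#' parametrization the coordinate-descent update exactly minimizes (the
#' Laplacian sum enters with weight `lambda2/2`; see [laplacian_penalty()]).
#' Probabilities are clipped to `[1e-10, 1 - 1e-10]` before taking logs so
#' the loss stays finite.
#'
#' @param beta Coefficient vector.
#' @param X Design matrix (standardized, as passed to the solver).
#' @param y Binary response in `{0, 1}`.
#' @param net An `adjacency_network`, or `NULL` when `spec$lambda2 == 0`.
#' @param spec A [penalty_spec()].
#' @return A finite scalar for finite `beta`.
#' @export
penalized_objective <- function(beta, X, y, net = NULL, spec) {
  stopifnot(inherits(spec, "penalty_spec"))
  if (!all(y %in% c(0, 1))) stop("y must be binary in {0, 1}")
  eta <- drop(as.matrix(X) %*% beta)
  pi <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
  loss <- -mean(y * log(pi) + (1 - y) * log(1 - pi))
  pen <- sum(mcp_penalty(beta, spec$lambda1, spec$gamma))
  if (spec$lambda2 > 0) {
    if (is.null(net)) stop("lambda2 > 0 requires a network")
    pen <- pen + laplacian_penalty(beta, net, spec$lambda2 / 2)
  }
  loss + pen
}

#' Working quantities of the fixed-weight IRLS majorization
#'
#' With the fixed weight `w = 1/4`, recomputes the linear predictor
#' `eta = X beta`, the probabilities `pi = logistic(eta)` (overflow-safe,
#' clipped), the working response `ytilde = eta + 4*(y - pi)` and the
#' surrogate residual \code{r = 4*(y - pi)}.
#'
#' @inheritParams penalized_objective
#' @return A list with `eta`, `pi`, `working_response`, `residual` and the
#'   scalar `weight = 1/4`.
#' @export
working_quantities <- function(beta, X, y) {
  eta <- drop(as.matrix(X) %*% beta)
  pi <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
  r <- 4 * (y - pi)
  list(eta = eta, pi = pi, working_response = eta + r, residual = r,
       weight = 0.25)
}

#' Single coordinate-descent update (reference implementation)
#'
#' Pure-R version of the closed-form coordinate update, used as a readable
#' reference and as the object of the exact-minimizer property checks. Given
#' the surrogate residual `r` (from [working_quantities()] at the current
#' `beta`), computes
#' `z_m = (1/4) * (n^{-1} X_m' r + beta_m)`,
#' `u_m = z_m + lambda2 * sum_{k != m} a_mk beta_k`,
#' `t_m = 1/4 + lambda2 * sum_{k != m} |a_mk|`,
#' and returns `S(u_m, lambda1) / (t_m - 1/gamma)` when
#' `|u_m| <= t_m * gamma * lambda1`, else `u_m / t_m`. The sign-aware
#' symmetric sums are the default; `update_rule = "triangular"` reproduces
#' the unsigned upper-triangle variant (sums over `k > m` only).
#'
#' @param m Coordinate index (1-based).
#' @param beta Current coefficient vector.
#' @param residual Current surrogate residual `r`.
#' @param X Standardized design matrix (`n^{-1} ||X_m||^2 = 1`).
#' @param net `adjacency_network` or `NULL`.
#' @param spec A [penalty_spec()].
#' @param method One of `"network"`, `"mcp"`, `"lasso"`, `"enet"`.
#' @param update_rule `"symmetric"` (default) or `"triangular"`.
#' @return The updated value of `beta[m]`.
#' @export
coordinate_update <- function(m, beta, residual, X, net = NULL, spec,
                              method = c("network", "mcp", "lasso", "enet"),
                              update_rule = c("symmetric", "triangular")) {
  method <- match.arg(method)
  update_rule <- match.arg(update_rule)
  stopifnot(inherits(spec, "penalty_spec"))
  n <- nrow(X)
  z <- 0.25 * (sum(X[, m] * residual) / n + beta[m])
  u <- z
  t_m <- 0.25
  if (method == "network" && spec$lambda2 > 0) {
    a <- as.numeric(net$weights[, m])
    a[m] <- 0
    if (update_rule == "triangular") {
      keep <- seq_along(a) > m
      u <- z + spec$lambda2 * sum(abs(a[keep]) * beta[keep])
      t_m <- 0.25 + spec$lambda2 * sum(abs(a[keep]))
    } else {
      u <- z + spec$lambda2 * sum(a * beta)
      t_m <- 0.25 + spec$lambda2 * sum(abs(a))
    }
  } else if (method == "enet") {
    t_m <- 0.25 + spec$lambda2
  }
  if (method %in% c("network", "mcp")) {
    if (t_m - 1 / spec$gamma <= 0)
      stop("t_m - 1/gamma <= 0: increase gamma above ", 1 / t_m)
    if (abs(u) <= t_m * spec$gamma * spec$lambda1)
      soft_threshold(u, spec$lambda1) / (t_m - 1 / spec$gamma)
    else
      u / t_m
  } else {
    soft_threshold(u, spec$lambda1) / t_m
  }
}
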