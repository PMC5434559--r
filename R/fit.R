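#' Standardize a design matrix for the solver
#'
#' Centers each column and scales it so that `n^{-1} * ||X_m||^2 = 1`
#' (population standard deviation), the normalization under which the
#' coordinate update's quadratic coefficient is exactly the fixed weight 1/4.
#'
#' @param X Numeric matrix.
#' @return The standardized matrix with attributes `center` and `scale`.
#' @export
standardize_design <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  scl <- sqrt(colMeans(Xc^2))
  if (any(scl == 0)) {
    bad <- which(scl == 0)
    lbl <- if (!is.null(colnames(X))) colnames(X)[bad[1L]] else bad[1L]
    stop("constant column (zero variance): ", lbl)
  }
  Xs <- sweep(Xc, 2L, scl, "/")
  attr(Xs, "center") <- ctr
  attr(Xs, "scale") <- scl
  Xs
}

#' Smallest lambda1 that zeroes every coefficient
#'
#' At `beta = 0` the probabilities are all 1/2 and the coordinate update's
#' argument is `z_m = n^{-1} X_m'(y - 1/2)`; every coordinate stays at zero
#' iff `lambda1 >= max_m |z_m|`.
#'
#' @param X Standardized design matrix.
#' @param y Binary response.
#' @return The scalar `lambda_max`.
#' @export
lambda_max <- function(X, y) {
  max(abs(crossprod(as.matrix(X), y - 0.5))) / nrow(X)
}

#' Geometric lambda1 ladder
#'
#' Decreasing geometric sequence from `lmax` down to `min_ratio * lmax`,
#' the default grid for tuning the sparsity level.
#'
#' @param lmax Upper end, typically [lambda_max()].
#' @param nlambda Number of grid points (default 20).
#' @param min_ratio Ratio of smallest to largest value (default 0.01).
#' @export
lambda1_ladder <- function(lmax, nlambda = 20, min_ratio = 0.01) {
  stopifnot(lmax > 0, nlambda >= 1, min_ratio > 0, min_ratio <= 1)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

method_code <- function(method) {
  match(method, c("network", "mcp", "lasso", "enet")) - 1L
}

adjacency_slots <- function(net, p, method, lambda2) {
  if (method == "network" && lambda2 > 0) {
    if (is.null(net)) stop("method 'network' with lambda2 > 0 needs a network")
    W <- net$weights
    if (ncol(W) != p)
      stop("network dimension (", ncol(W), ") does not match p (", p, ")")
    list(p = W@p, i = W@i, x = W@x)
  } else {
    list(p = integer(0), i = integer(0), x = numeric(0))
  }
}

#' Fit the network-constrained penalized logistic regression
#'
#' Minimizes the mean negative logistic log-likelihood plus the MCP and
#' signed-Laplacian network penalty by cyclic coordinate descent inside an
#' IRLS majorization with the exact Hessian bound `w = 1/4`. Each full sweep
#' refreshes the working quantities at the current linear predictor; after a
#' full sweep the solver iterates on the current active set until it
#' stabilizes, then re-checks all coordinates. Convergence is declared when
#' the L2 change of `beta` over a full sweep drops below `tol`. The model has
#' no intercept by default (an optional unpenalized intercept is available
#' for unbalanced real data).
#'
#' The comparator methods are special cases of the same update:
#' `"mcp"` is the fit with `lambda2 = 0`; `"lasso"` drops the MCP branch
#' (pure soft-threshold update, the `gamma -> Inf` limit); `"enet"` uses the
#' soft-threshold update with a ridge term (`t_m = 1/4 + lambda2`).
#'
#' @param X Design matrix (n x p). Standardized internally unless
#'   `standardize = FALSE`, in which case columns must already satisfy
#'   `n^{-1} ||X_m||^2 = 1` after centering.
#' @param y Binary response in `{0, 1}`.
#' @param net An `adjacency_network` (required for `method = "network"` with
#'   `lambda2 > 0`).
#' @param lambda1 Nonnegative MCP / L1 level.
#' @param lambda2 Nonnegative network (or ridge, for `"enet"`) level.
#' @param gamma MCP concavity parameter (> 4); default 4.5.
#' @param method One of `"network"`, `"mcp"`, `"lasso"`, `"enet"`.
#' @param tol Convergence tolerance on the L2 change of `beta` per full
#'   sweep; default `1e-4`.
#' @param max_iter Maximum number of coordinate sweeps; default 500.
#' @param standardize Standardize `X` internally (default `TRUE`).
#' @param intercept Fit an unpenalized intercept (default `FALSE`).
#' @param beta_init Optional warm start for `beta`.
#' @param loss_floor Separation guard: iteration stops (with
#'   `separated = TRUE` and `converged = FALSE`) once the mean negative
#'   log-likelihood falls below this value, since a perfectly separated
#'   training fit gives the saturated MCP objective no finite minimizer and
#'   further sweeps only inflate the coefficients. Set to 0 to disable.
#' @param update_rule `"symmetric"` (sign-aware, order-independent; default)
#'   or `"triangular"` (literal unsigned upper-triangle sums, provided for
#'   compatibility; no descent guarantee).
#' @param track_objective Record the penalized objective after every sweep.
#' @return An object of class `ldnet_fit` with elements `beta` (on the
#'   standardized scale), `beta0`, `support`, `converged`, `n_iterations`,
#'   `objective`, `objective_initial`, `objective_trace`, the penalty
#'   parameters, and the standardization `center`/`scale` used.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(100 * 10), 100, 10)
#' y <- rbinom(100, 1, plogis(X[, 1] - X[, 2]))
#' fit <- ldnet_fit(X, y, lambda1 = 0.05, method = "mcp")
#' fit$support
#' @export
ldnet_fit <- function(X, y, net = NULL, lambda1, lambda2 = 0, gamma = 4.5,
                      method = c("network", "mcp", "lasso", "enet"),
                      tol = 1e-4, max_iter = 500, standardize = TRUE,
                      intercept = FALSE, beta_init = NULL,
                      update_rule = c("symmetric", "triangular"),
                      track_objective = FALSE, loss_floor = 1e-3) {
  method <- match.arg(method)
  update_rule <- match.arg(update_rule)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary in {0, 1}")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  if (method %in% c("network", "mcp") && gamma <= 4)
    stop("gamma must exceed 4 (reciprocal of the fixed IRLS weight 1/4)")
  if (method %in% c("mcp", "lasso")) lambda2 <- 0

  if (standardize) {
    Xs <- standardize_design(X)
    ctr <- attr(Xs, "center"); scl <- attr(Xs, "scale")
  } else {
    Xs <- X
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  p <- ncol(Xs)
  if (is.null(beta_init)) beta_init <- numeric(p)
  stopifnot(length(beta_init) == p)

  A <- adjacency_slots(net, p, method, lambda2)
  res <- sls_fit_cpp(Xs, y, A$p, A$i, A$x, lambda1, lambda2, gamma,
                     method_code(method), tol, as.integer(max_iter),
                     as.numeric(beta_init), 0.0, intercept,
                     if (update_rule == "triangular") 1L else 0L,
                     track_objective, loss_floor)
  beta <- res$beta
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("snp", seq_len(p))
  names(beta) <- ids
  structure(list(beta = beta,
                 beta0 = if (intercept) res$b0 else 0,
                 support = which(beta != 0),
                 converged = res$converged,
                 separated = res$separated,
                 n_iterations = res$n_iterations,
                 objective = res$objective,
                 objective_initial = res$objective_initial,
                 objective_trace = if (track_objective) res$objective_trace,
                 lambda1 = lambda1, lambda2 = lambda2, gamma = gamma,
                 method = method, intercept = intercept,
                 center = ctr, scale = scl, snp_ids = ids),
            class = "ldnet_fit")
}

#' Fit a comparator method
#'
#' Thin wrapper over [ldnet_fit()] selecting one of the three alternative
#' penalties: `"mcp"` (network term disabled), `"lasso"` (L1 only) or
#' `"enet"` (L1 + ridge).
#'
#' @param method One of `"lasso"`, `"mcp"`, `"enet"`.
#' @inheritParams ldnet_fit
#' @param ... Passed on to [ldnet_fit()].
#' @export
fit_comparator <- function(method, X, y, lambda1, lambda2 = 0, ...) {
  if (!method %in% c("lasso", "mcp", "enet"))
    stop("unknown comparator method: ", method)
  ldnet_fit(X, y, net = NULL, lambda1 = lambda1, lambda2 = lambda2,
            method = method, ...)
}

#' @export
#' @method print ldnet_fit
print.ldnet_fit <- function(x, ...) {
  cat(sprintf(
    "ldnet fit (%s): %d/%d nonzero, lambda1 = %.4g, lambda2 = %.4g, %s in %d sweeps\n",
    x$method, length(x$support), length(x$beta), x$lambda1, x$lambda2,
    if (x$converged) "converged" else "NOT converged", x$n_iterations))
  invisible(x)
}

#' @export
#' @method coef ldnet_fit
coef.ldnet_fit <- function(object, ...) object$beta

#' Predict from a fitted model
#'
#' New data are standardized with the training centers/scales stored in the
#' fit. Class prediction uses the fixed rule `yhat = 1` iff `pi > 1/2`.
#'
#' @param object An `ldnet_fit`.
#' @param newx Matrix of predictors on the original scale of the training
#'   data.
#' @param type `"link"`, `"response"` or `"class"`.
#' @param ... Unused.
#' @export
predict.ldnet_fit <- function(object, newx,
                              type = c("link", "response", "class"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  Xs <- sweep(sweep(newx, 2L, object$center), 2L, object$scale, "/")
  eta <- drop(Xs %*% object$beta) + object$beta0
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         class = as.integer(stats::plogis(eta) > 0.5))
}

#' Warm-started solution path over a decreasing lambda1 ladder
#'
#' Fits every value of `lambda1` (sorted decreasing) at a fixed `lambda2`,
#' warm-starting each fit at the previous solution.
#'
#' @inheritParams ldnet_fit
#' @param lambda1 Numeric vector of MCP/L1 levels.
#' @param warm_start Use the previous solution as starting value (default
#'   `TRUE`).
#' @return A list of `ldnet_fit` objects, ordered by decreasing `lambda1`.
#' @export
ldnet_path <- function(X, y, net = NULL, lambda1, lambda2 = 0, gamma = 4.5,
                       method = "network", tol = 1e-4, max_iter = 500,
                       standardize = TRUE, warm_start = TRUE, ...) {
  lambda1 <- sort(lambda1, decreasing = TRUE)
  if (standardize) X <- standardize_design(X)
  fits <- vector("list", length(lambda1))
  beta <- NULL
  for (j in seq_along(lambda1)) {
    fits[[j]] <- ldnet_fit(X, y, net = net, lambda1 = lambda1[j],
                           lambda2 = lambda2, gamma = gamma, method = method,
                           tol = tol, max_iter = max_iter,
                           standardize = FALSE,
                           beta_init = if (warm_start) beta, ...)
    # carry the training standardization so predictions work on raw data
    fits[[j]]$center <- attr(X, "center") %||% fits[[j]]$center
    fits[[j]]$scale <- attr(X, "scale") %||% fits[[j]]$scale
    beta <- fits[[j]]$beta
  }
  fits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tune the penalty levels on a validation set
#'
#' Fits every pair on a two-dimensional grid of `(lambda1, lambda2)` values
#' (warm-started along decreasing `lambda1` within each `lambda2`), records
#' the validation misclassification of the rule `yhat = I(pi > 1/2)`, and
#' returns the pair minimizing it. Ties are broken toward the sparser model:
#' larger `lambda1` first, then larger `lambda2`. For methods `"mcp"` and
#' `"lasso"` the `lambda2` grid collapses to `{0}`.
#'
#' @param X_train,y_train Training data (raw scale; standardized internally).
#' @param X_val,y_val Validation data, disjoint from training; standardized
#'   with the training centers/scales.
#' @param net `adjacency_network` built on the training predictors.
#' @param method One of `"network"`, `"mcp"`, `"lasso"`, `"enet"`.
#' @param lambda1 Optional ladder; default geometric 20-point ladder from
#'   [lambda_max()] down to 1% of it.
#' @param lambda2 Grid of network/ridge levels; default
#'   `c(0, 0.01, 0.1, 1, 10)`.
#' @param nlambda1 Ladder length when `lambda1` is `NULL`.
#' @param gamma,tol,max_iter As in [ldnet_fit()].
#' @param warm_start Warm-start along the ladder (default `TRUE`).
#' @return An object of class `ldnet_tune`: `grid` (data frame of
#'   `lambda1`, `lambda2`, `val_misclassification`), `best_lambda1`,
#'   `best_lambda2`, `best_fit`, and `degenerate_validation` flag.
#' @export
ldnet_tune <- function(X_train, y_train, X_val, y_val, net = NULL,
                       method = c("network", "mcp", "lasso", "enet"),
                       lambda1 = NULL, lambda2 = c(0, 0.01, 0.1, 1, 10),
                       nlambda1 = 20, gamma = 4.5, tol = 1e-4,
                       max_iter = 500, warm_start = TRUE) {
  method <- match.arg(method)
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  y_val <- as.numeric(y_val)
  Xs <- standardize_design(X_train)
  if (is.null(lambda1))
    lambda1 <- lambda1_ladder(lambda_max(Xs, y_train), nlambda = nlambda1)
  lambda1 <- sort(unique(lambda1), decreasing = TRUE)
  if (method %in% c("mcp", "lasso")) lambda2 <- 0
  lambda2 <- sort(unique(lambda2))
  if (length(lambda1) == 0L || length(lambda2) == 0L)
    stop("tuning grid must be nonempty")
  degenerate <- length(unique(y_val)) < 2L
  if (degenerate)
    warning("validation labels are all one class; accuracy still computed")
  Xv <- sweep(sweep(X_val, 2L, attr(Xs, "center")), 2L,
              attr(Xs, "scale"), "/")

  rows <- list(); fits <- list(); k <- 0L
  for (l2 in lambda2) {
    path <- ldnet_path(Xs, y_train, net = net, lambda1 = lambda1,
                       lambda2 = l2, gamma = gamma, method = method,
                       tol = tol, max_iter = max_iter, standardize = FALSE,
                       warm_start = warm_start)
    for (j in seq_along(path)) {
      k <- k + 1L
      eta <- drop(Xv %*% path[[j]]$beta) + path[[j]]$beta0
      mis <- mean(as.integer(stats::plogis(eta) > 0.5) != y_val)
      rows[[k]] <- data.frame(lambda1 = path[[j]]$lambda1, lambda2 = l2,
                              val_misclassification = mis)
      fits[[k]] <- path[[j]]
    }
  }
  grid <- do.call(rbind, rows)
  best <- order(grid$val_misclassification, -grid$lambda1, -grid$lambda2)[1L]
  best_fit <- fits[[best]]
  best_fit$center <- attr(Xs, "center")
  best_fit$scale <- attr(Xs, "scale")
  structure(list(grid = grid,
                 best_lambda1 = grid$lambda1[best],
                 best_lambda2 = grid$lambda2[best],
                 best_misclassification = grid$val_misclassification[best],
                 best_fit = best_fit,
                 method = method,
                 degenerate_validation = degenerate),
            class = "ldnet_tune")
}

#' @export
#' @method print ldnet_tune
print.ldnet_tune <- function(x, ...) {
  cat(sprintf(
    "ldnet tuning (%s): best lambda1 = %.4g, lambda2 = %.4g, val misclassification = %.4f (%d grid points)\n",
    x$method, x$best_lambda1, x$best_lambda2, x$best_misclassification,
    nrow(x$grid)))
  invisible(x)
}

#' Write fitted coefficients as TSV
#'
#' Columns: `snp_id`, `beta`, `selected` (0/1 flag for nonzero).
#'
#' @param fit An `ldnet_fit`.
#' @param path Output path.
#' @export
write_coefficients <- function(fit, path) {
  df <- data.frame(snp_id = fit$snp_ids, beta = fit$beta,
                   selected = as.integer(fit$beta != 0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write fit metadata as JSON
#'
#' Records the penalty parameters, iteration count, convergence flag and
#' final objective.
#'
#' @inheritParams write_coefficients
#' @export
write_fit_metadata <- function(fit, path) {
  meta <- list(method = fit$method, lambda1 = fit$lambda1,
               lambda2 = fit$lambda2, gamma = fit$gamma,
               n_iterations = fit$n_iterations, converged = fit$converged,
               objective = fit$objective,
               n_selected = length(fit$support))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
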