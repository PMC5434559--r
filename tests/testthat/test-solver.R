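test_that("coordinate update hits the closed-form branches", {
  # isolated coordinate, lambda2 = 0, |u| above the MCP branch point:
  # the update is u / t = 4 * u
  n <- 20
  set.seed(41)
  X <- standardize_design(matrix(rnorm(n * 2), n, 2))
  spec <- penalty_spec(lambda1 = 0.01, lambda2 = 0, gamma = 4.5)
  beta <- c(2, 0)
  r <- rnorm(n, mean = 3)
  z <- 0.25 * (sum(X[, 1] * r) / n + beta[1])
  stopifnot(abs(z) > spec$gamma * spec$lambda1 / 4)
  expect_equal(coordinate_update(1, beta, r, X, spec = spec, method = "mcp"),
               4 * z, tolerance = 1e-12)
  # u = 0 gives an exact zero
  beta0 <- c(0, 0)
  r0 <- rep(0, n)
  expect_identical(
    coordinate_update(1, beta0, r0, X, spec = spec, method = "mcp"), 0)
})

test_that("coordinate update minimizes its 1-D surrogate (grid oracle)", {
  grid <- seq(-4, 4, length.out = 8001)
  methods <- c("network", "mcp", "lasso", "enet")
  for (case in 1:100) {
    set.seed(1000 + case)
    n <- 25; p <- 6
    X <- standardize_design(matrix(rnorm(n * p), n, p))
    net <- rand_network(p, density = 0.5, seed = 2000 + case)
    spec <- penalty_spec(lambda1 = runif(1, 0.01, 0.5),
                         lambda2 = sample(c(0, 0.5, 2), 1),
                         gamma = runif(1, 4.1, 9))
    beta <- rnorm(p, sd = 1)
    r <- rnorm(n, sd = 2)
    m <- sample.int(p, 1)
    method <- methods[(case %% 4) + 1]
    b_hat <- coordinate_update(m, beta, r, X, net = net, spec = spec,
                               method = method)
    vals <- vapply(grid, function(b) {
      surrogate_value(b, m, beta, r, X, net, spec, method)
    }, numeric(1))
    expect_lte(surrogate_value(b_hat, m, beta, r, X, net, spec, method),
               min(vals) + 1e-8)
  }
})

test_that("one full C++ sweep equals the R reference sweep", {
  inst <- rand_instance(n = 30, p = 8, seed = 51)
  net <- rand_network(8, density = 0.4, seed = 52)
  for (method in c("network", "mcp", "lasso", "enet")) {
    spec <- penalty_spec(0.05, if (method %in% c("mcp", "lasso")) 0 else 0.8,
                         4.5)
    set.seed(53)
    beta <- rnorm(8, sd = 0.2)
    fit <- ldnet_fit(inst$X, inst$y, net = net, lambda1 = spec$lambda1,
                     lambda2 = spec$lambda2, gamma = spec$gamma,
                     method = method, standardize = FALSE, max_iter = 1,
                     beta_init = beta, tol = 1e-12)
    # reference: refresh working quantities, then cycle coordinates once
    wq <- working_quantities(beta, inst$X, inst$y)
    r <- wq$residual
    b <- beta
    for (m in seq_along(b)) {
      bnew <- coordinate_update(m, b, r, inst$X, net = net, spec = spec,
                                method = method)
      r <- r - inst$X[, m] * (bnew - b[m])
      b[m] <- bnew
    }
    expect_equal(unname(fit$beta), b, tolerance = 1e-12)
  }
})

test_that("a lambda1 above lambda_max yields the null model", {
  inst <- rand_instance(n = 60, p = 10, seed = 61)
  lmax <- lambda_max(inst$X, inst$y)
  fit <- ldnet_fit(inst$X, inst$y, lambda1 = lmax * 1.01, method = "mcp",
                   standardize = FALSE)
  expect_true(all(fit$beta == 0))
  expect_true(fit$converged)
  fit2 <- ldnet_fit(inst$X, inst$y, lambda1 = lmax * 0.5, method = "mcp",
                    standardize = FALSE)
  expect_gt(length(fit2$support), 0)
})

test_that("the LASSO special case agrees with an independent convex solver", {
  inst <- rand_instance(n = 50, p = 20, k = 4, seed = 71)
  g <- glmnet::glmnet(inst$X, inst$y, family = "binomial", alpha = 1,
                      lambda = 0.04, standardize = FALSE, intercept = FALSE,
                      thresh = 1e-14)
  ref <- as.numeric(g$beta)
  f_lasso <- ldnet_fit(inst$X, inst$y, lambda1 = 0.04, method = "lasso",
                       standardize = FALSE, tol = 1e-9, max_iter = 5000,
                       loss_floor = 0)
  expect_lt(max(abs(f_lasso$beta - ref)), 1e-4)
  # gamma -> infinity limit of the MCP fit is the LASSO
  f_limit <- ldnet_fit(inst$X, inst$y, lambda1 = 0.04, method = "mcp",
                       gamma = 1e8, standardize = FALSE, tol = 1e-9,
                       max_iter = 5000, loss_floor = 0)
  expect_lt(max(abs(f_limit$beta - ref)), 1e-4)
  expect_lt(max(abs(f_limit$beta - f_lasso$beta)), 1e-4)
})

test_that("comparator special-case reductions are exact", {
  inst <- rand_instance(n = 60, p = 12, seed = 81)
  net <- rand_network(12, density = 0.3, seed = 82)
  # network fit with lambda2 = 0 is exactly the MCP comparator
  f_net0 <- ldnet_fit(inst$X, inst$y, net = net, lambda1 = 0.05,
                      lambda2 = 0, method = "network", standardize = FALSE)
  f_mcp <- fit_comparator("mcp", inst$X, inst$y, lambda1 = 0.05,
                          standardize = FALSE)
  expect_identical(unname(f_net0$beta), unname(f_mcp$beta))
  # elastic net with lambda2 = 0 is exactly the LASSO
  f_en0 <- fit_comparator("enet", inst$X, inst$y, lambda1 = 0.05,
                          lambda2 = 0, standardize = FALSE)
  f_las <- fit_comparator("lasso", inst$X, inst$y, lambda1 = 0.05,
                          standardize = FALSE)
  expect_identical(unname(f_en0$beta), unname(f_las$beta))
  expect_error(fit_comparator("scad", inst$X, inst$y, lambda1 = 0.1),
               "unknown comparator")
})

test_that("every sweep decreases the penalized objective", {
  inst <- rand_instance(n = 80, p = 15, seed = 91)
  net <- rand_network(15, density = 0.3, seed = 92)
  for (method in c("network", "mcp", "lasso", "enet")) {
    fit <- ldnet_fit(inst$X, inst$y, net = net, lambda1 = 0.03,
                     lambda2 = if (method %in% c("mcp", "lasso")) 0 else 0.5,
                     method = method, standardize = FALSE,
                     track_objective = TRUE)
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
    expect_lte(fit$objective, fit$objective_initial)
    expect_true(is.finite(fit$objective))
  }
  # the monitored objective agrees with the exported objective function
  spec <- penalty_spec(0.03, 0.5, 4.5)
  fit <- ldnet_fit(inst$X, inst$y, net = net, lambda1 = 0.03, lambda2 = 0.5,
                   method = "network", standardize = FALSE)
  expect_equal(fit$objective,
               penalized_objective(fit$beta, inst$X, inst$y, net, spec),
               tolerance = 1e-10)
})

test_that("network smoothing pulls duplicated predictors together", {
  set.seed(101)
  n <- 120
  x1 <- rnorm(n)
  X <- cbind(x1, x1, matrix(rnorm(n * 4), n, 4))
  colnames(X) <- paste0("s", 1:6)
  y <- rbinom(n, 1, plogis(1.5 * scale(x1)[, 1]))
  Xs <- standardize_design(X)
  net <- ld_network(Xs, alpha = 5, c = 1.96)
  expect_equal(as.matrix(net$weights)[1, 2], 1)  # duplicated pair, r = 1
  gaps <- sapply(c(0, 0.1, 1, 10), function(l2) {
    f <- ldnet_fit(Xs, y, net = net, lambda1 = 0.02, lambda2 = l2,
                   method = "network", standardize = FALSE, tol = 1e-8,
                   max_iter = 2000)
    abs(f$beta[1] - f$beta[2])
  })
  expect_true(all(diff(gaps) <= 1e-8))
  expect_lt(gaps[4], gaps[1] + 1e-12)
})

test_that("column permutation permutes the solution", {
  inst <- rand_instance(n = 70, p = 10, seed = 111)
  net <- rand_network(10, density = 0.4, seed = 112)
  fit <- ldnet_fit(inst$X, inst$y, net = net, lambda1 = 0.03, lambda2 = 0.7,
                   method = "network", standardize = FALSE, tol = 1e-10,
                   max_iter = 5000, loss_floor = 0)
  set.seed(113)
  perm <- sample(10)
  netp <- net
  netp$weights <- net$weights[perm, perm]
  netp$snp_ids <- net$snp_ids[perm]
  fitp <- ldnet_fit(inst$X[, perm], inst$y, net = netp, lambda1 = 0.03,
                    lambda2 = 0.7, method = "network", standardize = FALSE,
                    tol = 1e-10, max_iter = 5000, loss_floor = 0)
  expect_equal(unname(fitp$beta), unname(fit$beta[perm]), tolerance = 1e-6)
})

test_that("a strong predictor is recovered with the right sign", {
  hits <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    set.seed(3000 + r)
    n <- 500; p <- 5
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, plogis(2 * X[, 1]))
    f <- ldnet_fit(X, y, lambda1 = 0.05, method = "mcp")
    if (f$beta[1] > 0) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("invalid concavity and responses are rejected", {
  inst <- rand_instance(n = 20, p = 4, seed = 121)
  expect_error(ldnet_fit(inst$X, inst$y, lambda1 = 0.1, gamma = 3,
                         method = "mcp"), "gamma")
  expect_error(penalty_spec(0.1, 0, gamma = 4), "gamma")
  expect_error(ldnet_fit(inst$X, c(inst$y[-1], 5), lambda1 = 0.1,
                         method = "mcp"), "binary")
})

test_that("the optional unpenalized intercept tracks class imbalance", {
  set.seed(131)
  n <- 400
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, plogis(-1.5 + X[, 1]))
  f <- ldnet_fit(X, y, lambda1 = 0.05, method = "mcp", intercept = TRUE)
  expect_lt(f$beta0, -0.5)
  p_hat <- mean(predict(f, X, type = "response"))
  expect_equal(p_hat, mean(y), tolerance = 0.05)
})

test_that("tuning selects the misclassification argmin with sparse ties", {
  cfg <- tiny_scenario(seed = 141)
  ds <- make_dataset(cfg)
  tuned <- ldnet_tune(ds$train$X, ds$train$y, ds$validation$X,
                      ds$validation$y, method = "mcp", nlambda1 = 8)
  expect_true(all(tuned$best_misclassification <=
                    tuned$grid$val_misclassification))
  at_min <- tuned$grid[tuned$grid$val_misclassification ==
                         tuned$best_misclassification, ]
  expect_equal(tuned$best_lambda1, max(at_min$lambda1))
  # single-point grid returns that point
  one <- ldnet_tune(ds$train$X, ds$train$y, ds$validation$X,
                    ds$validation$y, method = "mcp",
                    lambda1 = 0.05, lambda2 = 0)
  expect_equal(one$best_lambda1, 0.05)
  expect_equal(nrow(one$grid), 1L)
  # degenerate validation labels warn but still produce a result
  expect_warning(
    ldnet_tune(ds$train$X, ds$train$y, ds$validation$X,
               rep(1, length(ds$validation$y)), method = "lasso",
               nlambda1 = 4),
    "one class")
})

test_that("warm-started tuning matches exhaustive cold refits", {
  cfg <- tiny_scenario(seed = 151)
  ds <- make_dataset(cfg)
  net <- ld_network(standardize_design(ds$train$X), c = 1.0)
  l1 <- lambda1_ladder(lambda_max(standardize_design(ds$train$X),
                                  ds$train$y), nlambda = 3)
  l2 <- c(0, 0.1, 1)
  warm <- ldnet_tune(ds$train$X, ds$train$y, ds$validation$X,
                     ds$validation$y, net = net, method = "network",
                     lambda1 = l1, lambda2 = l2, warm_start = TRUE)
  cold <- ldnet_tune(ds$train$X, ds$train$y, ds$validation$X,
                     ds$validation$y, net = net, method = "network",
                     lambda1 = l1, lambda2 = l2, warm_start = FALSE)
  expect_equal(warm$best_lambda1, cold$best_lambda1)
  expect_equal(warm$best_lambda2, cold$best_lambda2)
  expect_equal(warm$grid$val_misclassification,
               cold$grid$val_misclassification, tolerance = 0.02)
})
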