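test_that("simulated expression matches the target correlation structure", {
  n <- 5000
  cfg <- sim_config(n = n, p = 10, cluster_size = 5, structure = "ar",
                    rho = 0.5, data_type = "expression", seed = 1)
  set.seed(1)
  X <- simulate_expression(cfg)
  expect_equal(dim(X), c(n, 10))
  expect_true(all(abs(colMeans(X)) < 4 / sqrt(n)))
  expect_true(all(abs(apply(X, 2, var) - 1) < 0.1))
  # AR: corr(gene1, gene3) = rho^2 within 3 Monte-Carlo standard errors
  se <- (1 - 0.25^2) / sqrt(n - 3)
  expect_lt(abs(cor(X[, 1], X[, 3]) - 0.25), 3 * se)
  expect_lt(abs(cor(X[, 1], X[, 2]) - 0.5), 3 * (1 - 0.5^2) / sqrt(n - 3))
  # clusters are independent
  expect_lt(abs(cor(X[, 1], X[, 6])), 4 / sqrt(n))

  cfgb <- sim_config(n = n, p = 10, cluster_size = 5, structure = "block",
                     rho = 0.6, data_type = "expression", seed = 2)
  set.seed(2)
  Xb <- simulate_expression(cfgb)
  offdiag <- cor(Xb[, 1:5])[upper.tri(diag(5))]
  # 10 simultaneous pairwise checks: allow 4 standard errors each
  expect_true(all(abs(offdiag - 0.6) < 4 * (1 - 0.36) / sqrt(n - 3)))

  cfg0 <- sim_config(n = n, p = 6, cluster_size = 3, structure = "ar",
                     rho = 0, data_type = "expression", seed = 3)
  set.seed(3)
  X0 <- simulate_expression(cfg0)
  cors <- cor(X0)[upper.tri(diag(6))]
  expect_true(all(abs(cors) < 4 / sqrt(n)))
})

test_that("quartile trichotomization yields (0.25, 0.50, 0.25) genotypes", {
  set.seed(11)
  expr <- matrix(rnorm(100 * 6), 100, 6)
  G <- dichotomize_to_snps(expr)
  expect_true(all(G %in% 0:2))
  for (j in 1:6) {
    freq <- tabulate(G[, j] + 1L, 3L) / 100
    expect_equal(freq, c(0.25, 0.50, 0.25))
    # implied allele frequency is 1/2
    expect_equal((2 * freq[3] + freq[2]) / 2, 0.5)
    # levels are monotone in the underlying value
    ord <- order(expr[, j])
    expect_true(all(diff(G[ord, j]) >= 0))
  }
  # positively correlated expressions give positively correlated genotypes
  cfg <- sim_config(n = 2000, p = 4, cluster_size = 2, structure = "ar",
                    rho = 0.5, data_type = "snp", seed = 12)
  set.seed(12)
  Gp <- dichotomize_to_snps(simulate_expression(cfg))
  expect_gt(cor(Gp[, 1], Gp[, 2]), 0)
  expect_error(dichotomize_to_snps(matrix(rnorm(6), 3, 2)), "at least 4")
})

test_that("effect assignment selects whole clusters at the right size", {
  cfg <- sim_config(n = 100, p = 750, cluster_size = 5, seed = 21)
  beta <- assign_effects(cfg)
  expect_equal(sum(beta != 0), 75)  # effect_fraction * p
  nz <- beta != 0
  expect_true(all(beta[nz] >= 0.25 & beta[nz] <= 0.75))
  # nonzero entries come as complete clusters
  cl <- matrix(nz, nrow = 5)
  expect_true(all(colSums(cl) %in% c(0L, 5L)))
  # p = 1500 with clusters of 10 gives 150 nonzero
  cfg2 <- sim_config(n = 100, p = 1500, cluster_size = 10, seed = 22)
  expect_equal(sum(assign_effects(cfg2) != 0), 150)
  cfg0 <- sim_config(n = 100, p = 40, cluster_size = 4,
                     effect_fraction = 0, seed = 23)
  expect_equal(assign_effects(cfg0), numeric(40))
  # deterministic given the seed
  expect_identical(assign_effects(cfg), assign_effects(cfg))
})

test_that("response simulation is balanced under the null and reproducible", {
  set.seed(31)
  X <- matrix(rnorm(2000 * 4), 2000, 4)
  y0 <- simulate_response(X, numeric(4), seed = 32)
  expect_true(all(y0 %in% 0:1))
  expect_lt(abs(mean(y0) - 0.5), 3 * 0.5 / sqrt(2000))
  expect_identical(simulate_response(X, c(1, 0, 0, 0), seed = 33),
                   simulate_response(X, c(1, 0, 0, 0), seed = 33))
  expect_error(simulate_response(X, numeric(3)), "mismatch")
})

test_that("dataset triples share truth, differ in draws, and reproduce", {
  cfg <- sim_config(n = 50, p = 40, cluster_size = 4, rho = 0.5,
                    data_type = "snp", seed = 41, n_test = 30)
  ds <- make_dataset(cfg)
  expect_named(ds, c("train", "validation", "test", "beta_true",
                     "support_true", "config"))
  expect_equal(nrow(ds$train$X), 50)
  expect_equal(nrow(ds$test$X), 30)
  expect_false(identical(ds$train$X, ds$validation$X))
  expect_identical(ds$support_true, which(ds$beta_true != 0))
  expect_equal(length(ds$support_true),
               round(0.1 * 40))  # effect_fraction * p
  ds2 <- make_dataset(cfg)
  expect_identical(ds, ds2)
  cfg2 <- cfg; cfg2$seed <- 42L
  expect_false(identical(make_dataset(cfg2)$train$y, ds$train$y))
})

test_that("scenario configuration is validated", {
  expect_error(sim_config(p = 10, cluster_size = 3), "divisible")
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(effect_bounds = c(1, 0.5)))
})
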