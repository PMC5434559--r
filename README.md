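# ldnet

Network-constrained regularized logistic regression for SNP selection in
case–control association studies.

## The problem

In a case–control study with high-dimensional SNP genotypes (additive
0/1/2 coding, p ≫ n), linkage disequilibrium (LD) makes neighbouring SNPs
strongly correlated. Penalties that treat predictors independently — LASSO,
MCP — typically keep one arbitrary SNP per correlated block and drop the
rest, losing most of a block that shares true signal. `ldnet` selects SNPs
with a penalized logistic regression whose penalty couples correlated SNPs
through a weighted LD network, so correlated blocks are recovered together.

## Model

For binary disease status *y* and linear predictor η = Xβ (standardized
design, no intercept), `ldnet` minimizes

    Q(β) = −(1/n) Σᵢ [ yᵢ log πᵢ + (1−yᵢ) log(1−πᵢ) ]
           + Σₘ ρ(βₘ; λ₁, γ)
           + (λ₂/2) Σ_{m<k} |a_mk| (βₘ − sgn(a_mk) βₖ)²

where ρ is the minimax concave penalty (MCP) and A = (a_mk) is a signed
sparse LD network built from Pearson correlations:
a_mk = sgn(r_mk)·|r_mk|⁵ when |r_mk| exceeds the Fisher-transform cutoff
r_c = tanh(c/√(n−3)), else 0. The MCP term gives sparsity without biasing
large effects; the Laplacian term pulls positively correlated SNPs toward
equal coefficients (negatively correlated toward opposite ones).

Optimization is cyclic coordinate descent inside an IRLS majorization with
the exact Hessian bound w = 1/4, giving a closed-form update per
coordinate, monotone descent of Q, and exact zeros in the solution. LASSO,
elastic net and plain MCP are available as special cases of the same
update (`method = "lasso" / "enet" / "mcp"`). Penalty levels (λ₁, λ₂) are
tuned by misclassification on an independent validation set over a 2-D
grid. See the vignette (`vignettes/network-regularized-logistic.Rmd`) for
the full account.

## Worked example

Simulate a clustered SNP design (60 SNPs in clusters of 5, within-cluster
AR correlation 0.8, one 5-SNP cluster carrying effects), build the LD
network, and tune the network-constrained fit:

```r
library(ldnet)

cfg <- sim_config(n = 300, p = 60, cluster_size = 5, structure = "ar",
                  rho = 0.8, data_type = "snp", seed = 7)
ds  <- make_dataset(cfg)
ds$support_true
#> [1] 56 57 58 59 60

net <- ld_network(standardize_design(ds$train$X))
net
#> LD power-adjacency network: 60 nodes, 201 edges (r_c = 0.1132, alpha = 5, c = 1.96)

tuned <- ldnet_tune(ds$train$X, ds$train$y, ds$validation$X,
                    ds$validation$y, net = net, method = "network")
tuned
#> ldnet tuning (network): best lambda1 = 0.02547, lambda2 = 10, val misclassification = 0.1667 (100 grid points)

selection_metrics(tuned$best_fit$beta, ds$support_true)
#> $tp
#> [1] 5
#> $fp
#> [1] 16
```

The network method recovers the full 5-SNP effect cluster (tp = 5). The
plain MCP comparator on the same data keeps only part of it:

```r
mcp <- ldnet_tune(ds$train$X, ds$train$y, ds$validation$X,
                  ds$validation$y, method = "mcp")
selection_metrics(mcp$best_fit$beta, ds$support_true)
#> $tp
#> [1] 3
#> $fp
#> [1] 6
```

At realistic problem sizes (n = 500, p = 750, strong LD) the contrast is
much sharper; `run_benchmark()` reproduces those scenarios replicate by
replicate, and the false-positive count of the network method drops to a
handful while it recovers essentially the whole support.

A command-line interface wrapping the same functions (subcommands
`simulate`, `network`, `fit`, `tune`, `benchmark`, `evaluate`) is installed
at `system.file("cli", "ldnet.R", package = "ldnet")`.

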