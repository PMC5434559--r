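#' Selection true/false positive counts
#'
#' Counts selected predictors (exactly nonzero coefficients — the
#' thresholding update produces exact zeros, so no epsilon cutoff is used)
#' inside and outside the true support.
#'
#' @param beta_hat Estimated coefficient vector.
#' @param support_true Integer indices of the truly nonzero coefficients.
#' @return A list with integer `tp` and `fp`; always
#'   `tp + fp == sum(beta_hat != 0)`.
#' @export
selection_metrics <- function(beta_hat, support_true) {
  sel <- which(beta_hat != 0)
  list(tp = length(intersect(sel, support_true)),
       fp = length(setdiff(sel, support_true)))
}

#' Misclassification rate of the plug-in classifier
#'
#' `mean(yhat != y)` with `yhat = I(logistic(X beta) > 1/2)`; a predicted
#' probability of exactly 1/2 is classified as 0.
#'
#' @param beta_hat Coefficient vector (on the scale of `X`).
#' @param X Design matrix.
#' @param y Binary response.
#' @export
misclassification_rate <- function(beta_hat, X, y) {
  if (!all(y %in% c(0, 1))) stop("y must be binary in {0, 1}")
  pi <- stats::plogis(drop(as.matrix(X) %*% beta_hat))
  mean(as.integer(pi > 0.5) != y)
}

#' Selection-space ROC points along a lambda1 path
#'
#' For each fit on a path of decreasing `lambda1` (shared `lambda2` and
#' `gamma`), computes the selection true-positive rate
#' `TPR = tp / |support_true|` and false-positive rate
#' `FPR = fp / (p - |support_true|)`; points are sorted by FPR (then TPR)
#' with (0,0) prepended and (1,1) appended.
#'
#' @param path_fits Nonempty list of `ldnet_fit` objects along a lambda1
#'   ladder.
#' @param support_true True support indices.
#' @return A data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(path_fits, support_true) {
  if (length(path_fits) == 0L) stop("empty path")
  p <- length(path_fits[[1L]]$beta)
  s <- length(support_true)
  pts <- t(vapply(path_fits, function(f) {
    m <- selection_metrics(f$beta, support_true)
    c(fpr = if (p - s > 0) m$fp / (p - s) else 0,
      tpr = if (s > 0) m$tp / s else 0)
  }, numeric(2)))
  pts <- pts[order(pts[, "fpr"], pts[, "tpr"]), , drop = FALSE]
  out <- rbind(c(0, 0), pts, c(1, 1))
  data.frame(fpr = out[, 1], tpr = out[, 2], row.names = NULL)
}

run_one_replicate <- function(config, methods, alpha, c, nlambda1,
                              lambda2_grid, gamma, tol, max_iter) {
  ds <- make_dataset(config)
  Xtr <- ds$train$X
  net <- if ("network" %in% methods) {
    ld_network(standardize_design(Xtr), alpha = alpha, c = c)
  }
  out <- list()
  for (method in methods) {
    tuned <- ldnet_tune(Xtr, ds$train$y, ds$validation$X, ds$validation$y,
                        net = if (method == "network") net,
                        method = method, nlambda1 = nlambda1,
                        lambda2 = lambda2_grid, gamma = gamma, tol = tol,
                        max_iter = max_iter)
    m <- selection_metrics(tuned$best_fit$beta, ds$support_true)
    out[[method]] <- data.frame(
      method = method, tp = m$tp, fp = m$fp,
      lambda1 = tuned$best_lambda1, lambda2 = tuned$best_lambda2,
      val_misclassification = tuned$best_misclassification,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

scenario_label <- function(config) {
  sprintf("%s_rho%g_%s_n%d_p%d", config$structure, config$rho,
          config$data_type, config$n, config$p)
}

#' Replicate-level selection benchmark
#'
#' For each scenario and replicate: simulate train/validation data, build
#' the LD network on the standardized training predictors, tune each method
#' on its grid by validation misclassification, and record the selection
#' true/false positives of the tuned fit; then aggregate mean and sd per
#' scenario and method. Replicate seeds are `master_seed + replicate index`,
#' so any subset of replicates is reproducible independently, and the whole
#' table is a pure function of its arguments.
#'
#' @param scenarios A [sim_config()] or list of them.
#' @param methods Character subset of
#'   `c("network", "mcp", "enet", "lasso")`.
#' @param n_replicates Replicates per scenario (>= 1).
#' @param master_seed Integer master seed.
#' @param alpha,c Network construction parameters (see [ld_network()]).
#' @param nlambda1,lambda2_grid,gamma,tol,max_iter Tuning/solver settings
#'   (see [ldnet_tune()]).
#' @param verbose Print per-replicate progress.
#' @return An object of class `ldnet_benchmark`: `replicates` (long data
#'   frame, one row per scenario x replicate x method), `summary`
#'   (mean/sd aggregates with `n_replicates`), and `n_failed` (replicates
#'   whose fit failed, excluded from aggregation). With a single replicate
#'   the sd columns are reported as 0 and flagged via the
#'   `single_replicate` column.
#' @export
run_benchmark <- function(scenarios, methods = c("network", "mcp", "enet",
                                                 "lasso"),
                          n_replicates, master_seed = 1, alpha = 5,
                          c = 1.96, nlambda1 = 20,
                          lambda2_grid = c(0, 0.01, 0.1, 1, 10),
                          gamma = 4.5, tol = 1e-4, max_iter = 500,
                          verbose = FALSE) {
  if (inherits(scenarios, "sim_config")) scenarios <- list(scenarios)
  stopifnot(n_replicates >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  reps <- list(); k <- 0L; n_failed <- 0L
  for (sc in scenarios) {
    lbl <- scenario_label(sc)
    for (r in seq_len(n_replicates)) {
      cfg <- sc
      cfg$seed <- as.integer((master_seed + r) %% 2147483647)
      res <- tryCatch(
        run_one_replicate(cfg, methods, alpha, c, nlambda1, lambda2_grid,
                          gamma, tol, max_iter),
        error = function(e) {
          message("replicate ", r, " of scenario ", lbl, " failed: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(res)) { n_failed <- n_failed + 1L; next }
      res$scenario <- lbl
      res$structure <- sc$structure; res$rho <- sc$rho
      res$data_type <- sc$data_type; res$n <- sc$n; res$p <- sc$p
      res$replicate_id <- r
      k <- k + 1L
      reps[[k]] <- res
      if (verbose)
        message(sprintf("[%s] replicate %d/%d done", lbl, r, n_replicates))
    }
  }
  if (k == 0L) stop("all replicates failed")
  long <- do.call(rbind, reps)
  rownames(long) <- NULL
  agg <- do.call(rbind, lapply(
    split(long, list(long$scenario, long$method), drop = TRUE),
    function(d) {
      single <- nrow(d) == 1L
      data.frame(scenario = d$scenario[1L], structure = d$structure[1L],
                 rho = d$rho[1L], data_type = d$data_type[1L],
                 n = d$n[1L], p = d$p[1L], method = d$method[1L],
                 tp_mean = mean(d$tp),
                 tp_sd = if (single) 0 else stats::sd(d$tp),
                 fp_mean = mean(d$fp),
                 fp_sd = if (single) 0 else stats::sd(d$fp),
                 n_replicates = nrow(d), single_replicate = single,
                 stringsAsFactors = FALSE)
    }))
  rownames(agg) <- NULL
  structure(list(replicates = long, summary = agg, n_failed = n_failed),
            class = "ldnet_benchmark")
}

#' @export
#' @method print ldnet_benchmark
print.ldnet_benchmark <- function(x, ...) {
  cat("ldnet benchmark:",
      length(unique(x$summary$scenario)), "scenario(s),",
      max(x$summary$n_replicates), "replicate(s),",
      x$n_failed, "failed\n")
  s <- x$summary
  s$TP <- sprintf("%.2f(%.2f)", s$tp_mean, s$tp_sd)
  s$FP <- sprintf("%.2f(%.2f)", s$fp_mean, s$fp_sd)
  print(s[, c("scenario", "method", "TP", "FP", "n_replicates")],
        row.names = FALSE)
  invisible(x)
}

#' Write benchmark tables as TSV
#'
#' Writes a wide table (one row per scenario, `mean(sd)` cells per method
#' for TP and FP) and a tidy long table of the per-replicate counts.
#'
#' @param bench An `ldnet_benchmark`.
#' @param path_wide,path_long Output paths (either may be `NULL` to skip).
#' @export
write_benchmark_table <- function(bench, path_wide = NULL,
                                  path_long = NULL) {
  stopifnot(inherits(bench, "ldnet_benchmark"))
  if (!is.null(path_long))
    utils::write.table(bench$replicates, path_long, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(path_wide)) {
    s <- bench$summary
    s$cell_tp <- sprintf("%.2f(%.2f)", s$tp_mean, s$tp_sd)
    s$cell_fp <- sprintf("%.2f(%.2f)", s$fp_mean, s$fp_sd)
    wide <- NULL
    for (m in unique(s$method)) {
      sm <- s[s$method == m, c("scenario", "cell_tp", "cell_fp")]
      names(sm)[2:3] <- paste0(m, c("_TP", "_FP"))
      wide <- if (is.null(wide)) sm else merge(wide, sm, by = "scenario")
    }
    utils::write.table(wide, path_wide, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(bench)
}

#' Write ROC points as TSV
#'
#' @param roc Data frame from [roc_points()].
#' @param path Output path.
#' @export
write_roc_points <- function(roc, path) {
  utils::write.table(roc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
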