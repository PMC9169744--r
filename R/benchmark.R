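.BAYES_METHODS <- c("JZS", "g-sqrt-n", "hyper-g", "EB-local", "UIP", "g-1",
                    "benchmark", "BIC", "AIC")
.PENALIZED_METHODS <- c("LASSO", "LASSO-1se", "ElasticNet")

#' Benchmark configuration
#'
#' Bundles the study-design constants of a method comparison: which methods
#' run, how many bootstrap replicates and train-test splits, the train
#' fraction, the interval level, the MC3 chain length, the number of
#' posterior draws behind each interval, and the reference method every
#' metric is standardized against.
#'
#' @param methods character vector of method labels; Bayesian labels are
#'   `"JZS"`, `"g-sqrt-n"`, `"hyper-g"`, `"EB-local"`, `"UIP"`, `"g-1"`,
#'   `"benchmark"`, `"BIC"`, `"AIC"`; penalized ones `"LASSO"`,
#'   `"LASSO-1se"`, `"ElasticNet"`.
#' @param n_bootstrap bootstrap replicates per dataset (default 100).
#' @param n_splits random 75-25 train-test splits per replicate (default 100).
#' @param train_fraction train fraction (default 0.75).
#' @param alpha interval miscoverage level (default 0.05).
#' @param mcmc_iterations MC3 chain length (default 10000).
#' @param n_draws posterior draws per interval summary (default 10000).
#' @param reference_method label the relative table divides by (default
#'   `"JZS"`); must be among `methods`.
#' @param seed master seed; every stage derives its own stream from it.
#' @return Object of class `"benchmark_config"`.
#' @export
benchmark_config <- function(methods = c("JZS", "g-sqrt-n", "hyper-g",
                                         "EB-local", "LASSO"),
                             n_bootstrap = 100, n_splits = 100,
                             train_fraction = 0.75, alpha = 0.05,
                             mcmc_iterations = 10000, n_draws = 10000,
                             reference_method = "JZS", seed = 1) {
  unknown <- setdiff(methods, c(.BAYES_METHODS, .PENALIZED_METHODS))
  if (length(unknown)) stop("unregistered method label(s): ",
                            paste(unknown, collapse = ", "))
  if (!reference_method %in% methods)
    stop("reference_method must be among methods")
  if (n_bootstrap < 1 || n_splits < 1) stop("counts must be >= 1")
  structure(list(methods = methods, n_bootstrap = n_bootstrap,
                 n_splits = n_splits, train_fraction = train_fraction,
                 alpha = alpha, mcmc_iterations = mcmc_iterations,
                 n_draws = n_draws, reference_method = reference_method,
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

# one method on one replicate: full-data metrics + split-averaged prediction
.eval_bayes <- function(label, X, y, truth, splits, config, seed,
                        with_bms = FALSE) {
  n_iter <- config$mcmc_iterations
  nd <- config$n_draws
  al <- config$alpha
  fit <- bma_lm(X, y, prior = label, method = "mc3", n_iter = n_iter,
                seed = derive_seed(seed, "full"))
  variants <- list(BMA = fit)
  if (with_bms) variants$BMS <- bms(fit)
  est <- lapply(variants, function(f)
    bma_coefficients(f, alpha = al, n_draws = nd,
                     seed = derive_seed(seed, "coef")))
  pred <- lapply(variants, function(f)
    list(r2 = numeric(0), rmse = numeric(0), mis = numeric(0)))
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    trfit <- bma_lm(X[sp$train, , drop = FALSE], y[sp$train], prior = label,
                    method = "mc3", n_iter = n_iter,
                    seed = derive_seed(seed, paste0("split", si)))
    tr_variants <- list(BMA = trfit)
    if (with_bms) tr_variants$BMS <- bms(trfit)
    for (v in names(tr_variants)) {
      pr <- bma_predict(tr_variants[[v]], X[sp$test, , drop = FALSE],
                        alpha = al, n_draws = nd,
                        seed = derive_seed(seed, paste0("pred", si, v)))
      yt <- y[sp$test]
      tm <- mean(y[sp$train])
      pred[[v]]$r2 <- c(pred[[v]]$r2, r2_test(yt, pr$point, tm))
      pred[[v]]$rmse <- c(pred[[v]]$rmse, sqrt(mean((yt - pr$point)^2)))
      pred[[v]]$mis <- c(pred[[v]]$mis,
                         mean_interval_score(pr$lower, pr$upper, yt, al))
    }
  }
  lapply(stats::setNames(names(variants), names(variants)), function(v) {
    cs <- est[[v]]
    f <- variants[[v]]
    list(point_est_rmse = rmse_coefficients(truth$beta_DG, cs$mean),
         int_est_mis = mean_interval_score(cs$lower, cs$upper, truth$beta_DG,
                                           al),
         inference_one_minus_auprc =
           1 - auprc(truth$support, scores = cs$inclusion_prob),
         prediction_r2test = mean(pred[[v]]$r2),
         prediction_rmse = mean(pred[[v]]$rmse),
         int_pred_mis = mean(pred[[v]]$mis),
         n_vars = if (v == "BMS") sum(map_model(f$posterior))
                  else average_model_size(f$posterior))
  })
}

.eval_penalized <- function(label, X, y, truth, splits, config, seed) {
  method <- switch(label, LASSO = "lasso", `LASSO-1se` = "lasso-1se",
                   ElasticNet = "elastic-net")
  data <- regression_data(X, y)
  fit <- fit_penalized(data, method, seed = derive_seed(seed, "full"))
  path <- coefficient_path(data, if (method == "elastic-net")
    "elastic-net" else "lasso")
  r2s <- rmses <- numeric(0)
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    dtr <- regression_data(X[sp$train, , drop = FALSE], y[sp$train])
    trfit <- fit_penalized(dtr, method,
                           seed = derive_seed(seed, paste0("split", si)))
    pp <- predict(trfit, X[sp$test, , drop = FALSE], data = dtr)
    yt <- y[sp$test]
    r2s <- c(r2s, r2_test(yt, pp, mean(y[sp$train])))
    rmses <- c(rmses, sqrt(mean((yt - pp)^2)))
  }
  list(BMA = list(point_est_rmse = rmse_coefficients(truth$beta_DG,
                                                     fit$coefficients),
                  int_est_mis = NA_real_,
                  inference_one_minus_auprc =
                    1 - auprc(truth$support, path = support_path(path)),
                  prediction_r2test = mean(r2s),
                  prediction_rmse = mean(rmses),
                  int_pred_mis = NA_real_,
                  n_vars = sum(fit$coefficients != 0)))
}

#' Run the benchmark
#'
#' For every dataset x replicate x method: fit on the full replicate for
#' the estimation, interval-estimation, inference (support recovery) and
#' model-size metrics; fit on random train-test splits for the prediction
#' and interval-prediction metrics (split-averaged within replicate).
#' Fully seeded; a failing method on one replicate is recorded as missing
#' rather than aborting the run.
#'
#' @param config a [benchmark_config()].
#' @param suites a `"benchmark_dataset"` or list of them.
#' @param with_bms also compute MAP-model (selection) versions of each
#'   Bayesian method (default `FALSE`).
#' @return Data frame of class `"metric_records"`, one row per (dataset,
#'   method, variant, replicate), with the five metrics plus `n_vars`,
#'   `prediction_rmse`, and an `error` flag.
#' @export
run_benchmark <- function(config, suites, with_bms = FALSE) {
  if (inherits(suites, "benchmark_dataset")) suites <- list(suites)
  rows <- list()
  for (suite in suites) {
    nrep <- min(config$n_bootstrap, ncol(suite$Y))
    for (r in seq_len(nrep)) {
      y <- suite$Y[, r]
      rep_seed <- derive_seed(config$seed, paste0(suite$name, r))
      splits <- train_test_split(suite$spec$n, config$train_fraction,
                                 config$n_splits, seed = rep_seed)
      for (m in config$methods) {
        res <- tryCatch({
          if (m %in% .BAYES_METHODS)
            .eval_bayes(m, suite$X, y, suite$truth, splits, config,
                        derive_seed(rep_seed, m), with_bms = with_bms)
          else .eval_penalized(m, suite$X, y, suite$truth, splits, config,
                               derive_seed(rep_seed, m))
        }, error = function(e) {
          warning("method ", m, " failed on ", suite$name, " replicate ", r,
                  ": ", conditionMessage(e))
          NULL
        })
        if (is.null(res)) {
          rows[[length(rows) + 1L]] <- data.frame(
            dataset = suite$name, method = m, variant = "BMA", replicate = r,
            point_est_rmse = NA_real_, int_est_mis = NA_real_,
            inference_one_minus_auprc = NA_real_,
            prediction_r2test = NA_real_, prediction_rmse = NA_real_,
            int_pred_mis = NA_real_, n_vars = NA_real_, error = TRUE)
          next
        }
        for (v in names(res)) {
          rows[[length(rows) + 1L]] <- data.frame(
            dataset = suite$name, method = m, variant = v, replicate = r,
            as.data.frame(res[[v]]), error = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metric_records", "data.frame")
  out
}

.METRIC_COLS <- c(PointEst = "point_est_rmse", IntEst = "int_est_mis",
                  Inference = "inference_one_minus_auprc",
                  Prediction = "prediction_rmse", IntPred = "int_pred_mis")

#' Relative ranking table
#'
#' Averages each metric over replicates within a dataset, divides by the
#' reference method's value for that dataset, then averages the ratios
#' across datasets with equal weight. `Score` is the mean of the five
#' relative metrics; methods lacking intervals get `PartScore`, the mean of
#' the three available ones (PointEst, Inference, Prediction). Methods are
#' ranked by Score, with PartScore-only methods interleaved as highly as
#' possible without disturbing the Score order. The relative Prediction
#' column uses the test-set prediction RMSE (a loss, so lower is better
#' throughout); the raw `R2test` average is reported alongside.
#'
#' @param records a `"metric_records"` data frame (BMA variant rows are
#'   used).
#' @param reference reference method label (default `"JZS"`).
#' @return Data frame of class `"ranked_table"`, one row per method,
#'   ordered by rank.
#' @export
relative_score_table <- function(records, reference = "JZS") {
  rec <- records[records$variant == "BMA" & !records$error, , drop = FALSE]
  if (!nrow(rec)) stop("no usable records")
  if (!reference %in% rec$method) stop("reference method absent from records")
  datasets <- unique(rec$dataset)
  methods <- unique(rec$method)
  agg <- function(m, ds, col)
    mean(rec[rec$method == m & rec$dataset == ds, col], na.rm = TRUE)
  rel <- sapply(names(.METRIC_COLS), function(metric) {
    col <- .METRIC_COLS[[metric]]
    sapply(methods, function(m) {
      ratios <- vapply(datasets, function(ds) {
        ref <- agg(reference, ds, col)
        if (!is.finite(ref) || ref == 0)
          stop("reference metric is zero or missing for dataset ", ds)
        agg(m, ds, col) / ref
      }, numeric(1))
      mean(ratios)
    })
  })
  rel <- matrix(rel, nrow = length(methods),
                dimnames = list(methods, names(.METRIC_COLS)))
  nvars <- vapply(methods, function(m)
    mean(vapply(datasets, function(ds) agg(m, ds, "n_vars"), numeric(1))),
    numeric(1))
  r2raw <- vapply(methods, function(m)
    mean(vapply(datasets, function(ds) agg(m, ds, "prediction_r2test"),
                numeric(1))), numeric(1))
  has_all <- apply(is.finite(rel), 1L, all)
  score <- ifelse(has_all, rowMeans(rel), NA_real_)
  part <- rowMeans(rel[, c("PointEst", "Inference", "Prediction"),
                       drop = FALSE])
  sort_key <- ifelse(has_all, score, part)
  out <- data.frame(method = methods, rel,
                    Score = score, PartScore = part,
                    NVars = nvars, R2test = r2raw, row.names = NULL)
  out <- out[order(sort_key), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ranked_table", "data.frame")
  out
}

#' @export
#' @method print ranked_table
print.ranked_table <- function(x, digits = 3, ...) {
  cat("Relative performance (reference = 1; lower is better)\n")
  print.data.frame(format(as.data.frame(x), digits = digits),
                   row.names = FALSE)
  invisible(x)
}

#' Paired BMA versus MAP-model-selection comparison
#'
#' Reruns the benchmark computing, from the same posteriors, both the
#' model-averaged and the MAP-model-conditioned version of each requested
#' Bayesian method, and tabulates their relative metrics side by side with
#' a sign summary of the BMA - BMS differences (negative mean differences
#' mean averaging beats selection, since all metrics are losses).
#'
#' @param config a [benchmark_config()]; its Bayesian methods are compared.
#' @param suites dataset suite(s) as in [run_benchmark()].
#' @return List with `records` (full metric rows), `table` (per method and
#'   variant the dataset-averaged relative metrics) and `bma_minus_bms`
#'   (matrix of mean metric differences, BMA minus BMS, on the raw metric
#'   scale so the comparison stays defined when the reference attains a
#'   perfect inference score).
#' @export
compare_bma_bms <- function(config, suites) {
  records <- run_benchmark(config, suites, with_bms = TRUE)
  ref <- config$reference_method
  rec <- records[!records$error, , drop = FALSE]
  datasets <- unique(rec$dataset)
  relrow <- function(m, v) {
    vapply(names(.METRIC_COLS), function(metric) {
      col <- .METRIC_COLS[[metric]]
      mean(vapply(datasets, function(ds) {
        refv <- mean(rec[rec$method == ref & rec$variant == "BMA" &
                           rec$dataset == ds, col], na.rm = TRUE)
        mean(rec[rec$method == m & rec$variant == v & rec$dataset == ds, col],
             na.rm = TRUE) / refv
      }, numeric(1)))
    }, numeric(1))
  }
  rawrow <- function(m, v) {
    vapply(names(.METRIC_COLS), function(metric) {
      col <- .METRIC_COLS[[metric]]
      mean(vapply(datasets, function(ds)
        mean(rec[rec$method == m & rec$variant == v & rec$dataset == ds, col],
             na.rm = TRUE), numeric(1)))
    }, numeric(1))
  }
  meths <- intersect(config$methods, .BAYES_METHODS)
  tab <- do.call(rbind, lapply(meths, function(m) {
    data.frame(method = m, variant = c("BMA", "BMS"),
               rbind(relrow(m, "BMA"), relrow(m, "BMS")), row.names = NULL)
  }))
  diffs <- t(vapply(meths, function(m)
    rawrow(m, "BMA") - rawrow(m, "BMS"), numeric(length(.METRIC_COLS))))
  list(records = records, table = tab, bma_minus_bms = diffs)
}

#' Write metric records to CSV
#'
#' @param records a `"metric_records"` data frame.
#' @param file output path.
#' @export
write_metric_records_csv <- function(records, file) {
  utils::write.csv(as.data.frame(records), file, row.names = FALSE)
  invisible(file)
}
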