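# probing: MLP probes and the downstream metric battery.

test_that("probes fit separable data, are deterministic, and beat nulls", {
  n <- 60
  X <- modalign:::with_seed(1, matrix(stats::rnorm(n * 4), n, 4))
  y <- as.integer(X[, 1] + X[, 2] > 0)
  rownames(X) <- paste0("p", seq_len(n))
  names(y) <- rownames(X)
  pr <- fit_probe(X, y, "binary", probe_config(hidden = 16, epochs = 300),
                  seed = 1)
  acc <- mean(as.integer(predict_probe(pr, X) > 0.5) == y)
  expect_equal(acc, 1.0)

  pr2 <- fit_probe(X, y, "binary", probe_config(hidden = 16, epochs = 300),
                   seed = 1)
  expect_identical(predict_probe(pr, X), predict_probe(pr2, X))

  # signal vs permuted-label null, margin over across-seed sd
  Xte <- modalign:::with_seed(2, matrix(stats::rnorm(n * 4), n, 4))
  rownames(Xte) <- paste0("q", seq_len(n))
  yte <- as.integer(Xte[, 1] + Xte[, 2] > 0)
  accs <- function(labels) {
    vapply(1:4, function(s) {
      p <- fit_probe(X, labels, "binary",
                     probe_config(hidden = 16, epochs = 200), seed = s)
      mean(as.integer(predict_probe(p, Xte) > 0.5) == yte)
    }, 1.0)
  }
  real <- accs(y)
  ynull <- stats::setNames(modalign:::with_seed(3, sample(y)), names(y))
  null <- accs(ynull)
  expect_gt(mean(real) - mean(null), 3 * max(stats::sd(real), 0.01))

  expect_error(fit_probe(X, unname(y), "binary"), "mismatch")
  expect_error(fit_probe(X, y, "binary",
                         probe_config(hidden = 1e6)), "budget")
})

test_that("spearman_rho matches the rank-difference oracle", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)), -1)
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 4)
  d <- rank(x) - rank(y)
  oracle <- 1 - 6 * sum(d^2) / (4 * (16 - 1))
  expect_equal(spearman_rho(x, y), 0.8)
  expect_equal(spearman_rho(x, y), oracle)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_rho(1, 2), "n >= 2")
})

test_that("roc_auc equals exhaustive pair counting and a threshold sweep", {
  expect_equal(roc_auc(c(5, 6), c(1, 2)), 1)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.6), c(0.7, 0.1)), 0.75)

  sweep_auc <- function(pos, neg) {
    thr <- sort(unique(c(pos, neg, -Inf, Inf)), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(pos >= t), 1.0)
    fpr <- vapply(thr, function(t) mean(neg >= t), 1.0)
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  for (i in 1:8) {
    pos <- modalign:::with_seed(i, round(stats::runif(7), 2))
    neg <- modalign:::with_seed(i + 30, round(stats::runif(9), 2))
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(roc_auc(pos, neg), mean(pairs), tolerance = 1e-12)
    expect_equal(roc_auc(pos, neg), sweep_auc(pos, neg), tolerance = 1e-9)
  }
  expect_error(roc_auc(numeric(0), 1), "nonempty")
})

test_that("fmax matches the worked example and a dense-grid oracle", {
  truth <- rbind(c(1, 0), c(0, 1))
  scores <- rbind(c(0.9, 0.2), c(0.7, 0.6))
  res <- fmax(truth, scores)
  expect_equal(res$fmax, 6 / 7, tolerance = 1e-12)

  expect_equal(fmax(truth, truth)$fmax, 1) # perfect predictor

  grid_fmax <- function(truth, scores) {
    taus <- seq(0, 1, length.out = 10001)
    best <- 0
    for (tau in taus) {
      pred <- scores > tau
      TP <- rowSums(pred & truth == 1)
      npred <- rowSums(pred)
      prec <- ifelse(npred > 0, TP / npred, 0)
      rec <- TP / pmax(rowSums(truth == 1), 1)
      P <- mean(prec)
      R <- mean(rec)
      f <- if (P + R > 0) 2 * P * R / (P + R) else 0
      best <- max(best, f)
    }
    best
  }
  for (i in 1:5) {
    tr <- modalign:::with_seed(i, matrix(rbinom(24, 1, 0.4), 4, 6))
    tr[1, 1] <- 1 # ensure some positives
    sc <- modalign:::with_seed(i + 7, matrix(round(stats::runif(24), 3), 4, 6))
    expect_equal(fmax(tr, sc)$fmax, grid_fmax(tr, sc), tolerance = 1e-9)
    # invariance to strictly monotone transforms of scores
    expect_equal(fmax(tr, sc)$fmax, fmax(tr, sc^3)$fmax, tolerance = 1e-9)
  }
  expect_error(fmax(truth, scores * 2), "0, 1")
})

test_that("aupr_per_class matches exhaustive threshold enumeration", {
  y <- c(1, 1, 0, 0, 0)
  s <- c(0.9, 0.8, 0.3, 0.2, 0.1)
  expect_equal(aupr_per_class(y, s), 1)

  # all-same scores: area = prevalence
  expect_equal(aupr_per_class(c(1, 0, 0, 1), rep(0.5, 4)), 0.5)

  brute <- function(y, s) {
    thr <- sort(unique(s), decreasing = TRUE)
    tp <- vapply(thr, function(t) sum(y == 1 & s >= t), 1.0)
    fp <- vapply(thr, function(t) sum(y == 0 & s >= t), 1.0)
    prec <- tp / (tp + fp)
    rec <- tp / sum(y == 1)
    sum(diff(c(0, rec)) * prec)
  }
  y6 <- c(1, 0, 1, 0, 0, 1)
  s6 <- c(0.95, 0.9, 0.6, 0.55, 0.3, 0.2)
  expect_equal(aupr_per_class(y6, s6), brute(y6, s6), tolerance = 1e-12)
  for (i in 1:5) {
    yy <- modalign:::with_seed(i, rbinom(12, 1, 0.4))
    yy[1] <- 1
    ss <- modalign:::with_seed(i + 20, round(stats::runif(12), 2))
    expect_equal(aupr_per_class(yy, ss), brute(yy, ss), tolerance = 1e-12)
  }
  expect_error(aupr_per_class(c(0, 0), c(0.1, 0.2)), "no positive")
})

test_that("metrics agree that perfect predictors score 1 and nulls chance", {
  n <- 200
  y <- modalign:::with_seed(1, rbinom(n, 1, 0.5))
  s_perfect <- y
  expect_equal(roc_auc(s_perfect[y == 1], s_perfect[y == 0]), 1)
  s_null <- modalign:::with_seed(2, stats::runif(n))
  auc_null <- roc_auc(s_null[y == 1], s_null[y == 0])
  expect_lt(abs(auc_null - 0.5), 3 / sqrt(n))
})

test_that("the downstream suite emits a complete metric table", {
  tt <- toy_trained()
  recs <- tt$corpus$records
  ids <- names(recs)
  E1 <- ma_embed_all(tt$model, recs, "sequence")
  embs <- list(modelA = E1, modelB = E1)
  cls <- stats::setNames(vapply(recs, function(r) r$labels$class, 1), ids)
  reg <- stats::setNames(vapply(recs, function(r) r$labels$regression, 1), ids)
  ml <- do.call(rbind, lapply(recs, function(r) r$labels$multilabel))
  rownames(ml) <- ids
  tasks <- list(
    loc = list(kind = "multiclass", labels = cls, metric = "accuracy"),
    thermo = list(kind = "regression", labels = reg, metric = "spearman"),
    go = list(kind = "multilabel", labels = ml, metric = "fmax")
  )
  split <- list(train = tt$split$train, test = tt$split$test)
  mt <- run_downstream_suite(embs, tasks, split, n_runs = 2, seed = 1,
                             config = probe_config(hidden = 16, epochs = 60))
  expect_identical(nrow(mt), 2L * 3L * 2L)
  # identical embeddings under two names -> identical per-seed metrics
  a <- mt[mt$model == "modelA", ]
  b <- mt[mt$model == "modelB", ]
  expect_equal(a$value, b$value)
  s <- summarize_metric_table(mt)
  expect_identical(nrow(s), 6L)
  expect_true(all(s$n_runs == 2))
  # single run: sd is NA
  mt1 <- run_downstream_suite(embs["modelA"], tasks["loc"], split,
                              n_runs = 1, seed = 1,
                              config = probe_config(hidden = 8, epochs = 30))
  expect_true(is.na(summarize_metric_table(mt1)$sd))
})
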