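# Frozen-embedding downstream evaluation: MLP probes plus the full metric
# battery (Spearman, ROC AUC, Fmax, per-class AUPR).

#' Probe configuration
#'
#' @param hidden hidden width of the MLP probe.
#' @param epochs full-batch training epochs.
#' @param lr Adam learning rate.
#' @param max_params parameter budget for the probe (lightweight
#'   fine-tuning cap).
#' @return settings list.
#' @export
probe_config <- function(hidden = 64, epochs = 200, lr = 0.01,
                         max_params = 1.5e6) {
  list(hidden = hidden, epochs = epochs, lr = lr, max_params = max_params)
}

#' Fit a small MLP probe on frozen embeddings
#'
#' One rectified hidden layer; the task kind picks the loss (squared error
#' for regression, logistic / softmax cross-entropy for binary / multiclass,
#' per-label binary cross-entropy for multilabel). Embeddings are never
#' updated. Deterministic given the seed.
#'
#' @param embeddings n x l matrix with rownames = ids.
#' @param labels task labels: numeric vector (regression/binary), integer
#'   class vector (multiclass), or binary matrix (multilabel); names /
#'   rownames must cover the embedding ids.
#' @param kind task kind: "regression", "binary", "multiclass", "multilabel".
#' @param config a [probe_config()].
#' @param seed integer seed.
#' @return an `ma_probe` object.
#' @export
fit_probe <- function(embeddings, labels, kind = c("regression", "binary",
                                                   "multiclass", "multilabel"),
                      config = probe_config(), seed = 1) {
  kind <- match.arg(kind)
  ids <- rownames(embeddings)
  if (kind == "multilabel") {
    if (is.null(rownames(labels)) || !all(ids %in% rownames(labels))) {
      stop("label/id mismatch")
    }
    Y <- labels[ids, , drop = FALSE]
  } else {
    if (is.null(names(labels)) || !all(ids %in% names(labels))) {
      stop("label/id mismatch")
    }
    Y <- labels[ids]
  }
  X <- embeddings
  n <- nrow(X); d <- ncol(X); h <- config$hidden
  out_dim <- switch(kind,
                    regression = 1L, binary = 1L,
                    multiclass = as.integer(max(Y)),
                    multilabel = ncol(Y))
  n_par <- d * h + h + h * out_dim + out_dim
  if (n_par > config$max_params) stop("probe exceeds the parameter budget")

  params <- with_seed(derive_seed(seed, "probe"), list(
    W1 = matrix(stats::rnorm(d * h, sd = 1 / sqrt(d)), d, h),
    b1 = numeric(h),
    W2 = matrix(stats::rnorm(h * out_dim, sd = 1 / sqrt(h)), h, out_dim),
    b2 = numeric(out_dim)
  ))
  if (kind == "multiclass") {
    T1 <- matrix(0, n, out_dim)
    T1[cbind(seq_len(n), Y)] <- 1
    Y_target <- T1
  } else {
    Y_target <- matrix(as.numeric(Y), nrow = n)
  }

  opt <- optimizer_config("adam", lr = config$lr)
  st <- NULL
  for (ep in seq_len(config$epochs)) {
    pre1 <- sweep(X %*% params$W1, 2, params$b1, "+")
    H <- pmax(pre1, 0)
    O <- sweep(H %*% params$W2, 2, params$b2, "+")
    dO <- switch(kind,
                 regression = 2 * (O - Y_target) / n,
                 binary = (stats::plogis(O) - Y_target) / n,
                 multilabel = (stats::plogis(O) - Y_target) / n,
                 multiclass = (row_softmax(O) - Y_target) / n)
    g <- list(W1 = NULL, b1 = NULL, W2 = t(H) %*% dO, b2 = colSums(dO))
    dH <- dO %*% t(params$W2)
    dpre1 <- dH * (pre1 > 0)
    g$W1 <- t(X) %*% dpre1
    g$b1 <- colSums(dpre1)
    u <- opt_update(params, g, st, opt, t = ep)
    params <- u$params; st <- u$state
  }
  structure(list(params = params, kind = kind, out_dim = out_dim),
            class = "ma_probe")
}

#' Predict scores from a fitted probe
#'
#' @param probe an `ma_probe`.
#' @param embeddings n x l matrix.
#' @return regression: numeric predictions; binary: probabilities;
#'   multiclass / multilabel: n x K probability matrix.
#' @export
predict_probe <- function(probe, embeddings) {
  H <- pmax(sweep(embeddings %*% probe$params$W1, 2, probe$params$b1, "+"), 0)
  O <- sweep(H %*% probe$params$W2, 2, probe$params$b2, "+")
  out <- switch(probe$kind,
                regression = drop(O),
                binary = drop(stats::plogis(O)),
                multilabel = stats::plogis(O),
                multiclass = row_softmax(O))
  if (!is.null(rownames(embeddings)) && !is.null(dim(out))) {
    rownames(out) <- rownames(embeddings)
  }
  out
}

#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of average ranks (ties get midranks).
#'
#' @param x,y paired numeric observations (n >= 2, non-constant).
#' @return value in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) stop("need n >= 2 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: rank standard deviation undefined")
  }
  stats::cor(rank(x), rank(y))
}

#' ROC AUC via the normalized Mann-Whitney U statistic
#'
#' Ties between a positive and a negative score count one half; equals the
#' area under the threshold-sweep ROC curve.
#'
#' @param scores_pos scores of positive instances.
#' @param scores_neg scores of negative instances.
#' @return value in [0, 1].
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0 || length(scores_neg) == 0) {
    stop("both groups must be nonempty")
  }
  r <- rank(c(scores_pos, scores_neg))
  n1 <- length(scores_pos)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U / (n1 * length(scores_neg))
}

#' Protein-centric Fmax for multilabel prediction
#'
#' For every threshold tau, labels scoring strictly above tau are predicted.
#' Per-protein precision and recall are averaged over all N proteins
#' (a protein with zero predictions contributes precision 0), and Fmax is
#' the maximum harmonic mean over the scan set (all distinct scores plus
#' 0 and 1 — sufficient because the metric is piecewise constant between
#' consecutive scores).
#'
#' @param true_labels n x K binary matrix of true label sets.
#' @param scores n x K score matrix in [0, 1].
#' @param all_protein_precision average precision over all proteins (the
#'   default); FALSE averages only over proteins with >= 1 prediction
#'   (CAFA convention).
#' @return list(fmax, threshold).
#' @export
fmax <- function(true_labels, scores, all_protein_precision = TRUE) {
  stopifnot(all(dim(true_labels) == dim(scores)))
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  taus <- sort(unique(c(0, 1, as.numeric(scores))))
  best <- 0; best_tau <- 0
  N <- nrow(true_labels)
  for (tau in taus) {
    pred <- scores > tau
    TP <- rowSums(pred & true_labels == 1)
    npred <- rowSums(pred)
    ntrue <- rowSums(true_labels == 1)
    prec_i <- ifelse(npred > 0, TP / npred, 0)
    rec_i <- ifelse(ntrue > 0, TP / ntrue, 0)
    P <- if (all_protein_precision) mean(prec_i) else {
      if (any(npred > 0)) mean(prec_i[npred > 0]) else 0
    }
    R <- mean(rec_i)
    F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
    if (F1 > best) {
      best <- F1
      best_tau <- tau
    }
  }
  list(fmax = best, threshold = best_tau)
}

#' Area under the precision-recall curve for one class
#'
#' One-vs-rest labels; step-wise (non-interpolated) area over the threshold
#' sweep, i.e. sum over recall increments of the precision at that point.
#'
#' @param true_labels binary vector (>= 1 positive) for the class.
#' @param scores numeric scores for the class.
#' @return value in [0, 1].
#' @export
aupr_per_class <- function(true_labels, scores) {
  true_labels <- as.integer(true_labels)
  if (sum(true_labels) == 0) stop("class has no positive instances")
  ord <- order(scores, decreasing = TRUE)
  y <- true_labels[ord]
  s <- scores[ord]
  # process score groups (ties enter together)
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last_of_grp <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last_of_grp]; fp <- fp[last_of_grp]
  P <- sum(true_labels)
  prec <- tp / (tp + fp)
  rec <- tp / P
  prev_rec <- c(0, rec[-length(rec)])
  sum((rec - prev_rec) * prec)
}

#' Run the frozen-embedding downstream suite
#'
#' For every (model, task), trains `n_runs` MLP probes with different
#' random initialisations on frozen embeddings and reports the
#' task-appropriate metric per run plus mean and standard deviation.
#'
#' @param embeddings_by_model named list: model name -> (n x l embedding
#'   matrix with rownames).
#' @param tasks named list of tasks: each a list(kind, labels, metric) where
#'   metric is one of "spearman", "accuracy", "auc", "fmax".
#' @param split list(train, test) of id vectors.
#' @param n_runs independent probe fits per (model, task).
#' @param seed base seed.
#' @param config a [probe_config()].
#' @return `ma_metric_table`: data.frame(model, task, run, metric, value)
#'   plus aggregated mean/sd rows accessible via [summarize_metric_table()].
#' @export
run_downstream_suite <- function(embeddings_by_model, tasks, split,
                                 n_runs = 6, seed = 1,
                                 config = probe_config()) {
  rows <- list()
  for (mname in names(embeddings_by_model)) {
    E <- embeddings_by_model[[mname]]
    for (tname in names(tasks)) {
      task <- tasks[[tname]]
      tr_ids <- intersect(split$train, rownames(E))
      te_ids <- intersect(split$test, rownames(E))
      if (length(tr_ids) == 0 || length(te_ids) == 0) {
        stop("missing embeddings for task '", tname, "'")
      }
      for (run in seq_len(n_runs)) {
        # seed depends on (task, run) only, so identical embeddings under
        # two model names give identical per-seed metrics
        pr <- fit_probe(E[tr_ids, , drop = FALSE], task$labels, task$kind,
                        config, seed = derive_seed(seed, paste(tname, run)))
        sc <- predict_probe(pr, E[te_ids, , drop = FALSE])
        val <- probe_metric(task, sc, te_ids)
        rows[[length(rows) + 1]] <- data.frame(
          model = mname, task = tname, run = run, metric = task$metric,
          value = val, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ma_metric_table", "data.frame")
  out
}

probe_metric <- function(task, scores, ids) {
  kind <- task$kind
  metric <- task$metric
  if (kind == "multilabel") {
    truth <- task$labels[ids, , drop = FALSE]
  } else {
    truth <- task$labels[ids]
  }
  switch(metric,
         spearman = spearman_rho(scores, truth),
         accuracy = {
           pred <- if (kind == "binary") as.integer(scores > 0.5)
           else max.col(scores)
           mean(pred == truth)
         },
         auc = roc_auc(scores[truth == 1], scores[truth == 0]),
         fmax = fmax(truth, scores)$fmax,
         stop("unknown metric: ", metric))
}

#' Aggregate a metric table over runs
#'
#' @param table an `ma_metric_table`.
#' @return data.frame(model, task, metric, mean, sd, n_runs); the sd column
#'   is NA for single runs.
#' @export
summarize_metric_table <- function(table) {
  agg <- stats::aggregate(value ~ model + task + metric, data = table,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(model = agg$model, task = agg$task, metric = agg$metric,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n_runs = agg$value[, "n"], stringsAsFactors = FALSE)
  out
}
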