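# Model-comparison machinery: rank-sum tests, quartile/outlier summaries,
# normalized performance drop, ablation orchestration.

#' Two-sample Wilcoxon rank-sum test
#'
#' Average ranks for ties; exact null enumeration when n_x + n_y <= 12 and
#' the pooled sample is tie-free, otherwise the normal approximation with
#' tie and continuity corrections. `alternative = "greater"` tests whether
#' y tends to exceed x.
#'
#' @param x,y numeric samples (nonempty).
#' @param alternative "greater" (one-sided, y > x) or "two.sided".
#' @return `ma_comparison`: list(p_value, statistic, alternative, exact).
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    y, x, alternative = if (alternative == "greater") "greater" else "two.sided",
    exact = exact, correct = TRUE))
  structure(list(p_value = wt$p.value, statistic = unname(wt$statistic),
                 alternative = alternative, exact = exact),
            class = "ma_comparison")
}

#' Five-number/IQR summary with low-side outlier count
#'
#' Quartiles by linear interpolation of order statistics (R type 7).
#' Outliers are counted strictly below Q1 - 1.5 IQR (the low side, matching
#' how per-class AUPR outliers are reported); the high-side count is
#' returned as well but kept separate.
#'
#' @param values numeric sample (n >= 1).
#' @return list(min, q1, median, q3, max, iqr, outliers_low, outliers_high).
#' @export
iqr_summary <- function(values) {
  if (length(values) == 0) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  list(min = min(values), q1 = q[1], median = q[2], q3 = q[3],
       max = max(values), iqr = iqr,
       outliers_low = sum(values < q[1] - 1.5 * iqr),
       outliers_high = sum(values > q[3] + 1.5 * iqr))
}

#' Normalized performance drop
#'
#' Delta_{x,y} = (Perf_y - Perf_x) / Perf_x; negative values mean model y is
#' inferior to model x.
#'
#' @param perf_x reference performance (nonzero).
#' @param perf_y compared performance.
#' @return the relative change.
#' @export
normalized_drop <- function(perf_x, perf_y) {
  if (perf_x == 0) stop("reference performance is zero")
  (perf_y - perf_x) / perf_x
}

#' Pairwise drop matrix for a set of models on one task
#'
#' @param perfs named numeric vector of per-model performances.
#' @return square matrix D with D[y, x] = normalized_drop(perf_x, perf_y);
#'   the diagonal is exactly zero.
#' @export
drop_matrix <- function(perfs) {
  k <- length(perfs)
  D <- matrix(0, k, k, dimnames = list(names(perfs), names(perfs)))
  for (x in seq_len(k)) {
    for (y in seq_len(k)) {
      if (x != y) D[y, x] <- normalized_drop(perfs[x], perfs[y])
    }
  }
  D
}

#' Write / read a heatmap matrix (round-trip stable)
#'
#' @param D labelled square matrix.
#' @param path file path.
#' @export
write_heatmap <- function(D, path) {
  df <- data.frame(model = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_heatmap
#' @export
read_heatmap <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  D <- as.matrix(df[, -1, drop = FALSE])
  rownames(D) <- df$model
  D
}

#' Enumerate modality subsets for exhaustive ablations
#'
#' Every nonempty subset of the m optional modalities, each combined with
#' the anchor: 2^m - 1 models.
#'
#' @param optional character vector of non-anchor modalities.
#' @param anchor anchor modality.
#' @return list of modality vectors (anchor always included).
#' @export
ablation_subsets <- function(optional, anchor = "sequence") {
  optional <- unique(optional)
  m <- length(optional)
  subsets <- list()
  for (bits in seq_len(2^m - 1)) {
    sel <- optional[bitwAnd(bits, 2^(seq_len(m) - 1)) > 0]
    subsets[[length(subsets) + 1]] <- c(anchor, sel)
  }
  subsets
}

#' Exhaustive modality ablation run
#'
#' Trains one alignment model per modality subset (shared seeds), evaluates
#' retrieval and the downstream probe suite for each, and assembles the
#' pairwise normalized-drop matrix plus Wilcoxon comparisons per task.
#'
#' @param subsets list of modality subsets (each must contain the anchor;
#'   duplicates are removed with a warning).
#' @param corpus an `ma_corpus`.
#' @param split list(train, validation, test) id sets.
#' @param tasks downstream task list (see [run_downstream_suite()]).
#' @param steps,batch_size,opt training schedule.
#' @param n_runs probe repetitions per task.
#' @param seed shared seed.
#' @param l,d,n_layers model size settings.
#' @return list(metrics = `ma_metric_table`, retrieval = per-model reports,
#'   drops = per-task drop matrices, comparisons = pairwise Wilcoxon
#'   results).
#' @export
ablation_run <- function(subsets, corpus, split, tasks, steps = 200,
                         batch_size = 8, opt = optimizer_config(),
                         n_runs = 3, seed = 1, l = 32, d = 16,
                         d_anchor = 2 * d, n_layers = 1) {
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = "+"), "")
  if (anyDuplicated(keys)) {
    warning("duplicate modality subsets removed")
    subsets <- subsets[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
  }
  anchor <- "sequence"
  for (s in subsets) if (!anchor %in% s) stop("subset without anchor modality")

  emb_by_model <- list()
  retrieval <- list()
  for (si in seq_along(subsets)) {
    mods <- subsets[[si]]
    name <- paste(setdiff(mods, anchor), collapse = "+")
    if (name == "") name <- anchor
    model <- alignment_model(mods, l = l, seed = seed, d = d,
                             d_anchor = d_anchor, n_layers = n_layers,
                             gen_config = corpus$config)
    pd <- list()
    for (m in setdiff(mods, anchor)) {
      pd[[m]] <- pair_dataset(model, corpus, m, ids = split$train)
    }
    tr <- ma_train(model, pd, steps = steps, batch_size = batch_size,
                   seed = seed, opt = opt)
    test_recs <- corpus$records[split$test]
    retrieval[[name]] <- evaluate_alignment(tr$model, test_recs,
                                            modalities = mods,
                                            k_values = c(1, 10))
    emb_by_model[[name]] <- ma_embed_all(tr$model, corpus$records, anchor)
  }

  metrics <- run_downstream_suite(emb_by_model, tasks, split,
                                  n_runs = n_runs, seed = seed)
  summ <- summarize_metric_table(metrics)
  drops <- list()
  comparisons <- list()
  model_names <- names(emb_by_model)
  for (tname in unique(summ$task)) {
    st <- summ[summ$task == tname, ]
    perfs <- stats::setNames(st$mean, st$model)[model_names]
    drops[[tname]] <- drop_matrix(perfs)
    for (a in model_names) {
      for (b in model_names) {
        if (a == b) next
        va <- metrics$value[metrics$model == a & metrics$task == tname]
        vb <- metrics$value[metrics$model == b & metrics$task == tname]
        comparisons[[paste(tname, a, ">", b)]] <-
          wilcoxon_rank_sum(vb, va, "greater")
      }
    }
  }
  list(metrics = metrics, retrieval = retrieval, drops = drops,
       comparisons = comparisons)
}
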