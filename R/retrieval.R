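# Cross-modal retrieval metrics: R@k and median rank over trained and
# emergent modality pairs.

#' Enumerate retrieval tasks for a modality set
#'
#' Trained tasks are both directions between the anchor and every other
#' modality (2(n-1) of them); emergent tasks are all ordered pairs of
#' non-anchor modalities ((n-1)(n-2)), which were never co-trained.
#'
#' @param modalities character vector of n >= 2 distinct modalities.
#' @param anchor anchor modality (must be in `modalities`).
#' @return data.frame(query, candidate, trained).
#' @export
enumerate_tasks <- function(modalities, anchor = "sequence") {
  if (anyDuplicated(modalities)) stop("duplicate modalities")
  if (!anchor %in% modalities) stop("anchor not in modality list")
  if (length(modalities) < 2) stop("need at least two modalities")
  others <- setdiff(modalities, anchor)
  trained <- rbind(
    data.frame(query = anchor, candidate = others, stringsAsFactors = FALSE),
    data.frame(query = others, candidate = anchor, stringsAsFactors = FALSE)
  )
  trained$trained <- TRUE
  emergent <- expand.grid(query = others, candidate = others,
                          stringsAsFactors = FALSE)
  emergent <- emergent[emergent$query != emergent$candidate, , drop = FALSE]
  emergent$trained <- logical(nrow(emergent))
  out <- rbind(trained, emergent)
  rownames(out) <- NULL
  out
}

#' Rank of the true candidate by cosine similarity
#'
#' Optimistic tie rule: rank = 1 + number of candidates strictly more
#' similar than the true one, so pure ties give rank 1 and the random
#' baseline analysis is exact.
#'
#' @param query unit vector.
#' @param candidates N x l matrix of unit vectors.
#' @param true_index row of the true counterpart.
#' @param tol unit-norm tolerance.
#' @return integer rank in 1..N.
#' @export
rank_of_match <- function(query, candidates, true_index, tol = 1e-6) {
  if (is.null(dim(candidates))) candidates <- matrix(candidates, nrow = 1)
  N <- nrow(candidates)
  if (true_index < 1 || true_index > N) stop("true index out of range")
  if (abs(sqrt(sum(query^2)) - 1) > tol) stop("query must be unit-norm")
  check_unit_rows(candidates, tol)
  sims <- drop(candidates %*% query)
  1L + sum(sims > sims[true_index])
}

#' Recall at k
#'
#' @param ranks integer ranks (>= 1).
#' @param k cutoff.
#' @return fraction of ranks <= k.
#' @export
recall_at_k <- function(ranks, k) {
  if (length(ranks) == 0) stop("empty rank list")
  mean(ranks <= k)
}

#' Median rank
#'
#' @param ranks integer ranks (>= 1); even counts average the two central
#'   values.
#' @return numeric median.
#' @export
median_rank <- function(ranks) {
  if (length(ranks) == 0) stop("empty rank list")
  stats::median(ranks)
}

# ranks of all matched pairs for one (query matrix, candidate matrix) task;
# rows are id-paired.
task_ranks <- function(Q, C) {
  stopifnot(nrow(Q) == nrow(C))
  S <- Q %*% t(C)
  true_sims <- diag(S)
  as.integer(1L + rowSums(S > true_sims))
}

#' Evaluate cross-modal alignment of a trained model
#'
#' Embeds every held-out protein in each modality, computes the rank of the
#' true counterpart for every query in every task direction, and aggregates
#' R@k and the median rank per task.
#'
#' @param model an `ma_model`.
#' @param records named list of held-out protein records.
#' @param modalities modality subset to evaluate (default: all registered).
#' @param k_values recall cutoffs.
#' @return `ma_retrieval_report`: data.frame with query, candidate, trained,
#'   N, median_rank and one `R@k` column per cutoff.
#' @export
evaluate_alignment <- function(model, records,
                               modalities = names(model$modalities),
                               k_values = c(1, 10, 100)) {
  tasks <- enumerate_tasks(modalities, model$anchor)
  emb <- lapply(stats::setNames(modalities, modalities), function(m) {
    ma_embed_all(model, records, m)
  })
  rows <- vector("list", nrow(tasks))
  for (t in seq_len(nrow(tasks))) {
    qm <- tasks$query[t]; cm <- tasks$candidate[t]
    ids <- intersect(rownames(emb[[qm]]), rownames(emb[[cm]]))
    if (length(ids) == 0) {
      stop("no protein carries both '", qm, "' and '", cm, "'")
    }
    ranks <- task_ranks(emb[[qm]][ids, , drop = FALSE],
                        emb[[cm]][ids, , drop = FALSE])
    row <- data.frame(query = qm, candidate = cm, trained = tasks$trained[t],
                      N = length(ids), median_rank = median_rank(ranks),
                      stringsAsFactors = FALSE)
    for (k in k_values) row[[paste0("R@", k)]] <- recall_at_k(ranks, k)
    rows[[t]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ma_retrieval_report", "data.frame")
  out
}

#' Serialize a retrieval report (tab-delimited + radar-plot data)
#'
#' @param report an `ma_retrieval_report`.
#' @param path base path; writes `<path>.tsv` and `<path>_radar.tsv` (one
#'   axis per task, vertices R@1/R@10/R@100).
#' @export
write_retrieval_report <- function(report, path) {
  utils::write.table(report, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  kcols <- grep("^R@", colnames(report), value = TRUE)
  radar <- data.frame(axis = paste(report$query, report$candidate, sep = "->"),
                      trained = report$trained, report[, kcols],
                      check.names = FALSE)
  utils::write.table(radar, paste0(path, "_radar.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
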