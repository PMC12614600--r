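# Zero-shot analyses: evolutionary relatedness in embedding space and
# binding-site pair discrimination.

#' Hamming distance between aligned strings
#'
#' Column-by-column symbol mismatch count; the gap character '-' is treated
#' as a distinct 21st symbol.
#'
#' @param a,b aligned strings of equal length.
#' @return integer mismatch count.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned strings must have equal length")
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  sum(va != vb)
}

#' Rank an MSA family into similar / divergent / unrelated groups
#'
#' Aligned members are sorted by Hamming distance to the reference (ties
#' broken by input order); the lowest `n_similar` form the similar group and
#' the highest `n_divergent` the divergent group. Unrelated members are
#' passed through as the control group.
#'
#' @param family an `ma_msa_family`.
#' @param n_similar,n_divergent group sizes.
#' @return list(reference, similar, divergent, unrelated) of member ids.
#' @export
rank_family <- function(family, n_similar = 50, n_divergent = 50) {
  aligned <- names(family$members)[family$groups != "unrelated"]
  unrelated <- names(family$members)[family$groups == "unrelated"]
  if (length(aligned) < n_similar + n_divergent) {
    stop("family has too few aligned members for the requested groups")
  }
  d <- vapply(aligned, function(id) {
    hamming_distance(family$members[[id]], family$reference)
  }, 1L)
  ord <- order(d) # stable: ties keep input order
  list(reference = "reference",
       similar = aligned[utils::head(ord, n_similar)],
       divergent = aligned[utils::tail(ord, n_divergent)],
       unrelated = unrelated)
}

#' Cosine-similarity samples per relatedness group
#'
#' Computes the cosine similarity of the reference embedding to every member
#' of each group and the separation margin
#' median(divergent) - median(unrelated). An alternative min-gap margin
#' (min(divergent) - max(unrelated)) is also returned.
#'
#' @param embeddings matrix with rownames covering the reference and all
#'   member ids.
#' @param groups a [rank_family()] result; the reference embedding row is
#'   named by `groups$reference`.
#' @return `ma_cosine_groups`: list(similar, divergent, unrelated numeric
#'   samples; margin; margin_min_gap).
#' @export
cosine_groups <- function(embeddings, groups) {
  need <- c(groups$reference, groups$similar, groups$divergent,
            groups$unrelated)
  missing <- setdiff(need, rownames(embeddings))
  if (length(missing)) stop("missing embedding for id '", missing[1], "'")
  ref <- embeddings[groups$reference, ]
  sims_to <- function(ids) {
    vapply(ids, function(id) cosine_sim(ref, embeddings[id, ]), 1.0)
  }
  sim <- sims_to(groups$similar)
  div <- sims_to(groups$divergent)
  unr <- sims_to(groups$unrelated)
  structure(list(similar = sim, divergent = div, unrelated = unr,
                 margin = stats::median(div) - stats::median(unr),
                 margin_min_gap = min(div) - max(unr)),
            class = "ma_cosine_groups")
}

#' Write per-group cosine-similarity samples (violin-plot data)
#'
#' @param cg an `ma_cosine_groups`.
#' @param path output path (tab-delimited: group, similarity).
#' @export
write_cosine_groups <- function(cg, path) {
  df <- data.frame(
    group = rep(c("similar", "divergent", "unrelated"),
                c(length(cg$similar), length(cg$divergent),
                  length(cg$unrelated))),
    similarity = c(cg$similar, cg$divergent, cg$unrelated))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binding-site pair discrimination AUC
#'
#' Scores every labelled pair by the cosine similarity of its two
#' embeddings, then measures how well that score separates similar from
#' dissimilar pairs via ROC AUC (threshold sweep equivalent).
#'
#' @param embeddings matrix with rownames covering all pair members.
#' @param pairs data.frame(id_a, id_b, label) with label in
#'   {"similar", "dissimilar"}; unordered pairs must be unique.
#' @return list(auc, similarities = per-pair scores, roc = ROC points).
#' @export
pair_auc <- function(embeddings, pairs) {
  key <- apply(cbind(pmin(pairs$id_a, pairs$id_b),
                     pmax(pairs$id_a, pairs$id_b)), 1, paste, collapse = "|")
  if (anyDuplicated(key)) stop("duplicate unordered pair")
  if (!all(c("similar", "dissimilar") %in% pairs$label)) {
    stop("need at least one similar and one dissimilar pair")
  }
  sims <- vapply(seq_len(nrow(pairs)), function(i) {
    cosine_sim(embeddings[pairs$id_a[i], ], embeddings[pairs$id_b[i], ])
  }, 1.0)
  pos <- sims[pairs$label == "similar"]
  neg <- sims[pairs$label == "dissimilar"]
  thr <- sort(unique(c(-1, sims, 1)), decreasing = TRUE)
  roc <- t(vapply(thr, function(t) {
    c(fpr = mean(neg >= t), tpr = mean(pos >= t))
  }, c(fpr = 0, tpr = 0)))
  list(auc = roc_auc(pos, neg), similarities = sims, roc = as.data.frame(roc))
}
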