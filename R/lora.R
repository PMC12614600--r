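# Low-rank adaptation and masked-language-model objective.

#' Construct a LoRA adapter for a frozen weight matrix
#'
#' The effective weight is W' = W + (alpha / r) * A B. Only A and B receive
#' gradient updates; W stays bit-identical throughout training. A is
#' initialised to zero (standard practice), so the adapter starts as an
#' exact identity perturbation.
#'
#' @param n,m dimensions of the base matrix W (n x m).
#' @param r adapter rank; must satisfy r < min(n, m).
#' @param alpha scale parameter.
#' @param seed integer seed for the B factor.
#' @return a `lora_adapter` list with fields A (n x r), B (r x m), r, alpha.
#' @export
lora_adapter <- function(n, m, r = 4, alpha = 8, seed = 1) {
  if (r >= min(n, m)) stop("rank must satisfy r < min(n, m)")
  with_seed(derive_seed(seed, "lora"), {
    structure(list(A = matrix(0, n, r),
                   B = matrix(stats::rnorm(r * m, sd = 1 / sqrt(r)), r, m),
                   r = r, alpha = alpha),
              class = "lora_adapter")
  })
}

#' LoRA forward map
#'
#' @param adapter a [lora_adapter()].
#' @param W frozen base matrix (n x m).
#' @param x input row vector (length n) or matrix (batch x n).
#' @return x W + (alpha/r) x A B.
#' @export
lora_forward <- function(adapter, W, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  out <- x %*% W + (adapter$alpha / adapter$r) * (x %*% adapter$A) %*% adapter$B
  if (nrow(out) == 1) drop(out) else out
}

# Attach LoRA adapters to the attention Wq/Wv matrices of every layer of a
# transformer (the conventional placement).
attach_lora <- function(state, r = 4, alpha = 8, seed = 1) {
  d <- state$config$d
  state$lora <- list(layers = lapply(seq_len(state$config$n_layers), function(l) {
    list(Wq = lora_adapter(d, d, r, alpha, derive_seed(seed, paste0("q", l))),
         Wv = lora_adapter(d, d, r, alpha, derive_seed(seed, paste0("v", l))))
  }))
  state
}

#' Masked-language-model loss
#'
#' Sum over masked positions of the negative log-probability assigned to the
#' true token (set `mean_per_token = TRUE` for the mean variant).
#'
#' @param pred_probs matrix (n_masked x vocab) of normalized distributions,
#'   one row per masked position.
#' @param true_tokens integer vector of the original tokens at the masked
#'   positions.
#' @param mean_per_token average instead of sum.
#' @return nonnegative scalar.
#' @export
mlm_loss <- function(pred_probs, true_tokens, mean_per_token = FALSE) {
  if (length(true_tokens) == 0) stop("empty masked-position set")
  if (is.null(dim(pred_probs))) pred_probs <- matrix(pred_probs, nrow = 1)
  stopifnot(nrow(pred_probs) == length(true_tokens))
  p <- pred_probs[cbind(seq_along(true_tokens), true_tokens)]
  nll <- -log(pmax(p, 1e-300))
  if (mean_per_token) mean(nll) else sum(nll)
}

#' One MLM pretraining step for a transformer encoder
#'
#' Masks a random subset of positions (replacing them with `mask_token`),
#' predicts the original tokens through a tied-embedding output head, and
#' applies one gradient step to all parameters.
#'
#' @param state a `transformer_state`.
#' @param tokens integer token sequence.
#' @param mask_token token id used as the mask symbol.
#' @param mask_frac fraction of positions to mask (at least one is masked).
#' @param lr learning rate.
#' @param seed integer seed for the mask draw.
#' @return list(state = updated state, loss = MLM loss value).
#' @export
mlm_step <- function(state, tokens, mask_token, mask_frac = 0.15, lr = 0.05,
                     seed = 1) {
  n <- length(tokens)
  masked <- with_seed(seed, sort(sample.int(n, max(1, floor(mask_frac * n)))))
  x <- tokens
  x[masked] <- mask_token
  fw <- transformer_encode(x, state, need_cache = TRUE)
  H <- fw$out
  logits <- H[masked, , drop = FALSE] %*% t(state$params$E)
  P <- row_softmax(logits)
  loss <- mlm_loss(P, tokens[masked])
  dlogits <- P
  dlogits[cbind(seq_along(masked), tokens[masked])] <-
    dlogits[cbind(seq_along(masked), tokens[masked])] - 1
  dH <- matrix(0, n, state$config$d)
  dH[masked, ] <- dlogits %*% state$params$E
  grads <- transformer_backward(dH, state, fw$cache)
  # tied output head contribution to E
  grads$params$E <- grads$params$E + t(dlogits) %*% H[masked, , drop = FALSE]
  state$params <- tree_map2(state$params, grads$params,
                            function(p, g) p - lr * g)
  list(state = state, loss = loss)
}
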