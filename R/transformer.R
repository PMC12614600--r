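# Transformer encoder (sequence / structure-token / text modalities).
#
# Layer = multi-head scaled dot-product attention (keys masked to valid
# positions), concatenation, output matrix, then a position-wise
# rectifier FFN. Both sublayers carry the standard residual connection of
# the underlying pretrained architectures (without it a from-scratch stack
# is untrainable; see the methods vignette). Gradients are hand-derived
# and verified against finite differences in the tests.

#' Transformer configuration
#'
#' @param vocab_size token vocabulary size (token ids are 1..vocab_size).
#' @param d model width; must equal n_heads * d_k.
#' @param n_layers number of layers (0 gives the embedding stack only).
#' @param n_heads attention head count.
#' @param d_ff feed-forward width.
#' @param max_len maximum sequence length (positional table size).
#' @return a `transformer_config` list.
#' @export
transformer_config <- function(vocab_size, d = 32, n_layers = 2, n_heads = 2,
                               d_ff = 64, max_len = 128) {
  if (d %% n_heads != 0) stop("d must be divisible by n_heads")
  stopifnot(vocab_size >= 1, n_layers >= 0, n_heads >= 1, d_ff >= 1)
  structure(list(vocab_size = vocab_size, d = d, n_layers = n_layers,
                 n_heads = n_heads, d_k = d %/% n_heads, d_ff = d_ff,
                 max_len = max_len),
            class = "transformer_config")
}

#' Sinusoidal positional encoding table
#'
#' Classic interleaved sine/cosine table. The multi-frequency phase
#' structure lets even an untrained encoder expose position-weighted
#' composition statistics to the pooling head, which a random table cannot.
#'
#' @param max_len table length.
#' @param d model width.
#' @param base frequency base.
#' @return max_len x d matrix.
#' @export
sinusoidal_positions <- function(max_len, d, base = 100) {
  P <- matrix(0, max_len, d)
  pos <- seq_len(max_len)
  for (i in seq_len(max(d %/% 2, 1))) {
    f <- 1 / (base^(2 * (i - 1) / d))
    P[, 2 * i - 1] <- sin(f * pos)
    if (2 * i <= d) P[, 2 * i] <- cos(f * pos)
  }
  P
}

#' Initialize transformer parameters
#'
#' The positional table starts sinusoidal (it may still train under a
#' "full" policy); all other parameters are Gaussian.
#'
#' @param config a [transformer_config()].
#' @param seed integer seed; equal seeds give bit-identical parameters.
#' @return a `transformer_state` list (config + parameter arrays).
#' @export
transformer_init <- function(config, seed = 1) {
  with_seed(derive_seed(seed, "transformer"), {
    d <- config$d
    sd0 <- 1 / sqrt(d)
    rand <- function(nr, nc, s = sd0) matrix(stats::rnorm(nr * nc, sd = s), nr, nc)
    layers <- lapply(seq_len(config$n_layers), function(l) {
      list(Wq = rand(d, d), Wk = rand(d, d), Wv = rand(d, d), Wo = rand(d, d),
           W1 = rand(d, config$d_ff), b1 = numeric(config$d_ff),
           W2 = rand(config$d_ff, d), b2 = numeric(d))
    })
    structure(list(config = config,
                   params = list(E = rand(config$vocab_size, d, 0.5),
                                 P = sinusoidal_positions(config$max_len, d),
                                 layers = layers),
                   lora = NULL),
              class = "transformer_state")
  })
}

# effective weight of a possibly LoRA-adapted matrix
lora_effective <- function(W, ad) {
  if (is.null(ad)) W else W + (ad$alpha / ad$r) * (ad$A %*% ad$B)
}

#' Transformer forward pass
#'
#' @param tokens integer token ids (1..vocab_size).
#' @param state a `transformer_state`.
#' @param mask logical vector marking valid positions (default all valid).
#' @param need_cache keep intermediate activations for the backward pass.
#' @return list(out = length x d feature matrix, cache = forward cache).
#' @export
transformer_encode <- function(tokens, state, mask = NULL, need_cache = FALSE) {
  cfg <- state$config
  n <- length(tokens)
  if (any(tokens < 1 | tokens > cfg$vocab_size)) stop("token id out of range")
  if (n > cfg$max_len) stop("sequence exceeds maximum length")
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n)
  H <- state$params$E[tokens, , drop = FALSE] +
    state$params$P[seq_len(n), , drop = FALSE]
  cache <- list(tokens = tokens, mask = mask, H = list(H))
  p <- cfg$n_heads; dk <- cfg$d_k
  scale <- 1 / sqrt(dk)
  key_mask <- ifelse(mask, 0, -Inf)
  for (l in seq_len(cfg$n_layers)) {
    ly <- state$params$layers[[l]]
    ad <- if (is.null(state$lora)) NULL else state$lora$layers[[l]]
    Wq <- lora_effective(ly$Wq, ad$Wq)
    Wv <- lora_effective(ly$Wv, ad$Wv)
    Q <- H %*% Wq; K <- H %*% ly$Wk; V <- H %*% Wv
    O <- matrix(0, n, cfg$d)
    A_list <- vector("list", p)
    for (h in seq_len(p)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) * scale
      S <- sweep(S, 2, key_mask, "+")
      A <- row_softmax(S)
      A_list[[h]] <- A
      O[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    M <- H + O %*% ly$Wo # residual around attention
    pre1 <- sweep(M %*% ly$W1, 2, ly$b1, "+")
    Z <- pmax(pre1, 0)
    Hn <- M + sweep(Z %*% ly$W2, 2, ly$b2, "+") # residual around FFN
    if (need_cache) {
      cache[[paste0("layer", l)]] <- list(Q = Q, K = K, V = V, O = O, M = M,
                                          pre1 = pre1, Z = Z, A = A_list)
      cache$H[[l + 1]] <- Hn
    }
    H <- Hn
  }
  list(out = H, cache = if (need_cache) cache else NULL)
}

# Backward pass. dH is the gradient at the output (n x d). Returns
# gradients for all parameters (same shape tree as state$params) plus, when
# LoRA adapters are attached, gradients for the adapter factors.
transformer_backward <- function(dH, state, cache) {
  cfg <- state$config
  n <- length(cache$tokens)
  p <- cfg$n_heads; dk <- cfg$d_k
  scale <- 1 / sqrt(dk)
  g <- zeros_like(state$params)
  glora <- if (is.null(state$lora)) NULL else zeros_like(state$lora)
  for (l in rev(seq_len(cfg$n_layers))) {
    ly <- state$params$layers[[l]]
    ad <- if (is.null(state$lora)) NULL else state$lora$layers[[l]]
    cc <- cache[[paste0("layer", l)]]
    Hin <- cache$H[[l]]
    # FFN (residual: dM gets dH directly plus the FFN path)
    dZ <- dH %*% t(ly$W2)
    g$layers[[l]]$W2 <- t(cc$Z) %*% dH
    g$layers[[l]]$b2 <- colSums(dH)
    dpre1 <- dZ * (cc$pre1 > 0)
    g$layers[[l]]$W1 <- t(cc$M) %*% dpre1
    g$layers[[l]]$b1 <- colSums(dpre1)
    dM <- dH + dpre1 %*% t(ly$W1)
    # output projection (residual: input gradient carries dM onward)
    g$layers[[l]]$Wo <- t(cc$O) %*% dM
    dO <- dM %*% t(ly$Wo)
    dQ <- matrix(0, n, cfg$d); dK <- matrix(0, n, cfg$d); dV <- matrix(0, n, cfg$d)
    for (h in seq_len(p)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      A <- cc$A[[h]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- cc$V[, cols, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dV[, cols] <- t(A) %*% dOh
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- (dS %*% cc$K[, cols, drop = FALSE]) * scale
      dK[, cols] <- (t(dS) %*% cc$Q[, cols, drop = FALSE]) * scale
    }
    Wq_eff <- lora_effective(ly$Wq, ad$Wq %||% NULL)
    Wv_eff <- lora_effective(ly$Wv, ad$Wv %||% NULL)
    dWq <- t(Hin) %*% dQ
    dWk <- t(Hin) %*% dK
    dWv <- t(Hin) %*% dV
    g$layers[[l]]$Wq <- dWq
    g$layers[[l]]$Wk <- dWk
    g$layers[[l]]$Wv <- dWv
    if (!is.null(glora) && !is.null(ad)) {
      for (nm in c("Wq", "Wv")) {
        if (!is.null(ad[[nm]])) {
          dW <- if (nm == "Wq") dWq else dWv
          s <- ad[[nm]]$alpha / ad[[nm]]$r
          glora$layers[[l]][[nm]]$A <- s * (dW %*% t(ad[[nm]]$B))
          glora$layers[[l]][[nm]]$B <- s * (t(ad[[nm]]$A) %*% dW)
        }
      }
    }
    dH <- dM + dQ %*% t(Wq_eff) + dK %*% t(ly$Wk) + dV %*% t(Wv_eff)
  }
  # embedding + positional tables
  for (t in seq_len(n)) {
    g$E[cache$tokens[t], ] <- g$E[cache$tokens[t], ] + dH[t, ]
    g$P[t, ] <- g$P[t, ] + dH[t, ]
  }
  list(params = g, lora = glora)
}
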