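# Pooling and projection heads mapping per-position encoder outputs into
# the shared unit sphere.

#' Valid 1D convolution (cross-correlation form)
#'
#' y[t, j] = sum_i sum_{k=0..K-1} w[j, i, k] * x[t + k, i]; only positions
#' where the whole kernel fits are produced, so the output has
#' length - K + 1 rows.
#'
#' @param x length x C_in input matrix.
#' @param w filter array of dim (C_out, C_in, K).
#' @return (length - K + 1) x C_out matrix.
#' @export
conv1d <- function(x, w) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  K <- dim(w)[3]
  L <- nrow(x)
  if (L < K) stop("input length shorter than kernel")
  C_out <- dim(w)[1]
  out <- matrix(0, L - K + 1, C_out)
  for (k in seq_len(K)) {
    # w[, , k] is C_out x C_in; x rows t+k-1
    out <- out + x[(k):(L - K + k), , drop = FALSE] %*% t(matrix(w[, , k], dim(w)[1], dim(w)[2]))
  }
  out
}

#' Masked valid 1D convolution
#'
#' Zeroes masked positions of the input before convolving; with an all-ones
#' mask this equals [conv1d()] exactly.
#'
#' @param x length x C_in input matrix.
#' @param mask binary vector of length nrow(x).
#' @param w filter array of dim (C_out, C_in, K).
#' @return (length - K + 1) x C_out matrix.
#' @export
masked_conv1d <- function(x, mask, w) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (length(mask) != nrow(x)) stop("mask length must equal input length")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  conv1d(x * as.numeric(mask), w)
}

# --- pooler constructors -----------------------------------------------

pooler_init <- function(kind, d, seed = 1) {
  kind <- match.arg(kind, c("attention", "mean", "cls"))
  params <- if (kind == "attention") {
    with_seed(derive_seed(seed, "pooler"), {
      list(w = array(stats::rnorm(d, sd = 1 / sqrt(d)), dim = c(1, d, 1)))
    })
  } else {
    list()
  }
  structure(list(kind = kind, params = params), class = "ma_pooler")
}

#' Attention pooling over valid positions
#'
#' A masked K=1 convolution produces one scalar score per position; a
#' softmax over the valid positions turns scores into convex weights, and
#' the output is the weighted sum of the per-position features. Invalid
#' positions get exactly zero weight.
#'
#' @param features length x d feature matrix.
#' @param mask logical/binary vector of valid positions (>= 1 valid).
#' @param params list with filter `w` of dim (1, d, 1).
#' @return list(out = length-d vector, weights = per-position weights).
#' @export
attention1d_pool <- function(features, mask, params) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("attention pooling needs at least one valid position")
  scores <- drop(masked_conv1d(features, as.numeric(mask), params$w))
  s <- scores
  s[!mask] <- -Inf
  wts <- softmax_vec_masked(s)
  list(out = drop(crossprod(features, wts)), weights = wts)
}

softmax_vec_masked <- function(s) {
  m <- max(s[is.finite(s)])
  e <- exp(s - m)
  e[!is.finite(s)] <- 0
  e / sum(e)
}

#' Mean pooling over valid positions
#'
#' @param features length x d matrix.
#' @param mask logical/binary vector of valid positions.
#' @return length-d vector.
#' @export
mean_pool <- function(features, mask) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("mean pooling needs at least one valid position")
  colMeans(features[mask, , drop = FALSE])
}

#' First-position (CLS) pooling
#'
#' @param features length x d matrix (length >= 1).
#' @return length-d vector (the first row).
#' @export
cls_pool <- function(features) {
  if (nrow(features) < 1) stop("cls pooling needs at least one position")
  features[1, ]
}

pool_forward <- function(pooler, features, mask) {
  switch(pooler$kind,
         attention = attention1d_pool(features, mask, pooler$params),
         mean = list(out = mean_pool(features, mask), weights = NULL),
         cls = list(out = cls_pool(features), weights = NULL))
}

# backward through the pooler: dout (d) -> list(dfeatures, dparams)
pool_backward <- function(pooler, features, mask, pool_out, dout) {
  mask <- as.logical(mask)
  d <- ncol(features)
  if (pooler$kind == "mean") {
    k <- sum(mask)
    dfeat <- matrix(0, nrow(features), d)
    dfeat[mask, ] <- matrix(rep(dout / k, each = k), k, d)
    return(list(dfeatures = dfeat, dparams = list()))
  }
  if (pooler$kind == "cls") {
    dfeat <- matrix(0, nrow(features), d)
    dfeat[1, ] <- dout
    return(list(dfeatures = dfeat, dparams = list()))
  }
  # attention: out = F^T wts, wts = softmax(scores), scores = F w (masked)
  wts <- pool_out$weights
  dwts <- drop(features %*% dout)
  # softmax backward over valid positions
  dscores <- wts * (dwts - sum(dwts * wts))
  wvec <- drop(pooler$params$w)
  dfeat <- outer(wts, dout) + outer(dscores * as.numeric(mask), wvec)
  dw <- colSums(features * (dscores * as.numeric(mask)))
  list(dfeatures = dfeat, dparams = list(w = array(dw, dim = c(1, d, 1))))
}

# --- projection heads ---------------------------------------------------

projection_init <- function(kind, d_in, l, seed = 1) {
  kind <- match.arg(kind, c("linear", "mlp"))
  with_seed(derive_seed(seed, "proj"), {
    if (kind == "linear") {
      params <- list(W = matrix(stats::rnorm(d_in * l, sd = 1 / sqrt(d_in)),
                                d_in, l),
                     b = numeric(l))
    } else {
      params <- list(W1 = matrix(stats::rnorm(d_in * l, sd = 1 / sqrt(d_in)),
                                 d_in, l),
                     b1 = numeric(l),
                     W2 = matrix(stats::rnorm(l * l, sd = 1 / sqrt(l)), l, l),
                     b2 = numeric(l))
    }
    structure(list(kind = kind, params = params, l = l), class = "ma_projection")
  })
}

#' Project a pooled vector into the shared space
#'
#' Linear heads compute v W + b; MLP heads apply one rectified hidden layer
#' of width l before the linear output.
#'
#' @param v pooled feature vector.
#' @param proj a projection head (see internals).
#' @return list(out = length-l vector, cache).
#' @export
project <- function(v, proj) {
  if (proj$kind == "linear") {
    out <- drop(v %*% proj$params$W) + proj$params$b
    return(list(out = out, cache = list(v = v)))
  }
  pre <- drop(v %*% proj$params$W1) + proj$params$b1
  h <- pmax(pre, 0)
  out <- drop(h %*% proj$params$W2) + proj$params$b2
  list(out = out, cache = list(v = v, pre = pre, h = h))
}

project_backward <- function(proj, cache, dout) {
  if (proj$kind == "linear") {
    dparams <- list(W = outer(cache$v, dout), b = dout)
    dv <- drop(proj$params$W %*% dout)
    return(list(dv = dv, dparams = dparams))
  }
  dh <- drop(proj$params$W2 %*% dout)
  dparams <- list(W1 = NULL, b1 = NULL,
                  W2 = outer(cache$h, dout), b2 = dout)
  dpre <- dh * (cache$pre > 0)
  dparams$W1 <- outer(cache$v, dpre)
  dparams$b1 <- dpre
  dv <- drop(proj$params$W1 %*% dpre)
  list(dv = dv, dparams = dparams)
}

# backward through y = v / ||v||
l2_normalize_backward <- function(v, dy) {
  nrm <- sqrt(sum(v^2))
  y <- v / nrm
  (dy - y * sum(y * dy)) / nrm
}
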