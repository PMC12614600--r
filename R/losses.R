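# InfoNCE contrastive objective and its gradient.

check_unit_rows <- function(M, tol = 1e-6) {
  if (is.null(dim(M))) M <- matrix(M, nrow = 1)
  nrm <- sqrt(rowSums(M^2))
  if (any(abs(nrm - 1) > tol)) stop("rows must be unit-norm")
  M
}

#' InfoNCE loss for one modality direction
#'
#' L = -(1/n) sum_i log[ exp(a_i.b_i / tau) / sum_j exp(a_i.b_j / tau) ];
#' matched pairs sit on the diagonal, all other in-batch pairs act as
#' negatives. Numerically stabilised by row-max subtraction.
#'
#' @param A n x l matrix of unit query embeddings.
#' @param B n x l matrix of unit candidate embeddings (row i pairs row i of A).
#' @param tau temperature (> 0).
#' @return nonnegative scalar.
#' @export
info_nce_loss <- function(A, B, tau = 0.07) {
  if (tau <= 0) stop("temperature must be positive")
  A <- check_unit_rows(A)
  B <- check_unit_rows(B)
  n <- nrow(A)
  S <- (A %*% t(B)) / tau
  m <- apply(S, 1, max)
  lse <- m + log(rowSums(exp(S - m)))
  mean(lse - diag(S))
}

#' Symmetric (bidirectional) contrastive loss
#'
#' L_total = L(A, B) + L(B, A): the model learns to retrieve either modality
#' from the other.
#'
#' @inheritParams info_nce_loss
#' @return nonnegative scalar.
#' @export
symmetric_loss <- function(A, B, tau = 0.07) {
  info_nce_loss(A, B, tau) + info_nce_loss(B, A, tau)
}

# Gradient of the symmetric loss with respect to A and B (rows assumed
# unit-norm; the normalisation Jacobian is applied by the caller).
symmetric_loss_grad <- function(A, B, tau = 0.07) {
  n <- nrow(A)
  S <- (A %*% t(B)) / tau
  P1 <- row_softmax(S)        # queries A over candidates B
  P2 <- row_softmax(t(S))     # queries B over candidates A
  I <- diag(n)
  dS <- (P1 - I) / n + t((P2 - I) / n)
  loss <- {
    m1 <- apply(S, 1, max); lse1 <- m1 + log(rowSums(exp(S - m1)))
    St <- t(S)
    m2 <- apply(St, 1, max); lse2 <- m2 + log(rowSums(exp(St - m2)))
    mean(lse1 - diag(S)) + mean(lse2 - diag(St))
  }
  list(loss = loss, dA = (dS %*% B) / tau, dB = (t(dS) %*% A) / tau)
}
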