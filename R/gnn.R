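# Hierarchical geometric message-passing encoder (structure and pocket
# modalities). Node features are updated per layer as
#   v_i <- UPDATE(v_i, sum_{j in N_i} MESSAGE(v_j, e_ij, F(G)))
# where MESSAGE and UPDATE are small rectifier MLPs; UPDATE adds a residual.
# All geometric inputs are invariant (distances and angles), so the encoder
# is invariant to rigid motions and node permutations by construction.

#' GNN configuration
#'
#' @param width node feature width.
#' @param n_layers message-passing layers.
#' @param level hierarchy level: "amino_acid", "backbone" or "all_atom";
#'   determines which geometric features enter MESSAGE.
#' @param cutoff edge cutoff radius in Angstrom.
#' @return a `gnn_config` list.
#' @export
gnn_config <- function(width = 32, n_layers = 2,
                       level = c("all_atom", "backbone", "amino_acid"),
                       cutoff = 10) {
  level <- match.arg(level)
  structure(list(width = width, n_layers = n_layers, level = level,
                 cutoff = cutoff, g = geom_width(level)),
            class = "gnn_config")
}

#' Initialize GNN parameters
#'
#' @param config a [gnn_config()].
#' @param seed integer seed.
#' @return a `gnn_state` list.
#' @export
gnn_init <- function(config, seed = 1) {
  w <- config$width; g <- config$g
  with_seed(derive_seed(seed, "gnn"), {
    rand <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
    layers <- lapply(seq_len(config$n_layers), function(l) {
      list(msg_W1 = rand(w + g, w), msg_b1 = numeric(w),
           msg_W2 = rand(w, w), msg_b2 = numeric(w),
           upd_W1 = rand(2 * w, w), upd_b1 = numeric(w),
           upd_W2 = rand(w, w), upd_b2 = numeric(w))
    })
    structure(list(config = config,
                   params = list(Emb = rand(21, w), layers = layers)),
              class = "gnn_state")
  })
}

#' GNN forward pass
#'
#' @param graph a [build_protein_graph()] result (level must match config).
#' @param state a `gnn_state`.
#' @param need_cache keep activations for the backward pass.
#' @return list(out = graph-level feature vector (mean over nodes),
#'   node_features = n x width matrix, cache).
#' @export
gnn_encode <- function(graph, state, need_cache = FALSE) {
  cfg <- state$config
  if (graph$n == 0) stop("empty graph")
  if (!identical(graph$level, cfg$level)) {
    stop("graph level '", graph$level, "' does not match config '",
         cfg$level, "'")
  }
  V <- state$params$Emb[graph$aa_idx, , drop = FALSE]
  src <- graph$edges[, 1]; dst <- graph$edges[, 2]
  cache <- list(V = list(V))
  for (l in seq_len(cfg$n_layers)) {
    ly <- state$params$layers[[l]]
    if (nrow(graph$edges) > 0) {
      msg_in <- cbind(V[src, , drop = FALSE], graph$geom)
      pre_h <- sweep(msg_in %*% ly$msg_W1, 2, ly$msg_b1, "+")
      h <- pmax(pre_h, 0)
      msg <- sweep(h %*% ly$msg_W2, 2, ly$msg_b2, "+")
      agg <- matrix(0, graph$n, cfg$width)
      rs <- rowsum(msg, group = dst)
      agg[as.integer(rownames(rs)), ] <- rs
    } else {
      msg_in <- NULL; pre_h <- NULL; h <- NULL
      agg <- matrix(0, graph$n, cfg$width)
    }
    upd_in <- cbind(V, agg)
    pre_u <- sweep(upd_in %*% ly$upd_W1, 2, ly$upd_b1, "+")
    u <- pmax(pre_u, 0)
    Vn <- V + sweep(u %*% ly$upd_W2, 2, ly$upd_b2, "+")
    if (need_cache) {
      cache[[paste0("layer", l)]] <- list(msg_in = msg_in, pre_h = pre_h,
                                          h = h, upd_in = upd_in,
                                          pre_u = pre_u, u = u)
      cache$V[[l + 1]] <- Vn
    }
    V <- Vn
  }
  list(out = colMeans(V), node_features = V,
       cache = if (need_cache) cache else NULL)
}

# Backward pass from the graph-level gradient dout (length width).
gnn_backward <- function(dout, graph, state, cache) {
  cfg <- state$config
  w <- cfg$width
  n <- graph$n
  src <- graph$edges[, 1]; dst <- graph$edges[, 2]
  g <- zeros_like(state$params)
  dV <- matrix(rep(dout / n, each = n), n, w)
  for (l in rev(seq_len(cfg$n_layers))) {
    ly <- state$params$layers[[l]]
    cc <- cache[[paste0("layer", l)]]
    du <- dV %*% t(ly$upd_W2)
    g$layers[[l]]$upd_W2 <- t(cc$u) %*% dV
    g$layers[[l]]$upd_b2 <- colSums(dV)
    dpre_u <- du * (cc$pre_u > 0)
    g$layers[[l]]$upd_W1 <- t(cc$upd_in) %*% dpre_u
    g$layers[[l]]$upd_b1 <- colSums(dpre_u)
    d_updin <- dpre_u %*% t(ly$upd_W1)
    dV_new <- dV + d_updin[, seq_len(w), drop = FALSE]  # residual + v_i path
    dagg <- d_updin[, w + seq_len(w), drop = FALSE]
    if (nrow(graph$edges) > 0) {
      dmsg <- dagg[dst, , drop = FALSE]
      g$layers[[l]]$msg_W2 <- t(cc$h) %*% dmsg
      g$layers[[l]]$msg_b2 <- colSums(dmsg)
      dh <- dmsg %*% t(ly$msg_W2)
      dpre_h <- dh * (cc$pre_h > 0)
      g$layers[[l]]$msg_W1 <- t(cc$msg_in) %*% dpre_h
      g$layers[[l]]$msg_b1 <- colSums(dpre_h)
      dmsg_in <- dpre_h %*% t(ly$msg_W1)
      dsrc <- rowsum(dmsg_in[, seq_len(w), drop = FALSE], group = src)
      idx <- as.integer(rownames(dsrc))
      dV_new[idx, ] <- dV_new[idx, , drop = FALSE] + dsrc
    }
    dV <- dV_new
  }
  emb_g <- rowsum(dV, group = graph$aa_idx)
  g$Emb[as.integer(rownames(emb_g)), ] <- emb_g
  g
}
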