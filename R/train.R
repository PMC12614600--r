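# Anchor-paired sequential contrastive training.

#' Optimizer settings
#'
#' Plain stochastic gradient descent with momentum is the default; Adam is
#' available as a pluggable alternative.
#'
#' @param kind "sgd" or "adam".
#' @param lr learning rate.
#' @param momentum SGD momentum coefficient.
#' @param beta1,beta2,eps Adam coefficients.
#' @param weight_decay decoupled weight decay (AdamW-style: parameters
#'   shrink by lr * weight_decay * p each update).
#' @return an `ma_optimizer` settings list.
#' @export
optimizer_config <- function(kind = c("sgd", "adam"), lr = 0.1,
                             momentum = 0.9, beta1 = 0.9, beta2 = 0.999,
                             eps = 1e-8, weight_decay = 0) {
  kind <- match.arg(kind)
  structure(list(kind = kind, lr = lr, momentum = momentum, beta1 = beta1,
                 beta2 = beta2, eps = eps, weight_decay = weight_decay),
            class = "ma_optimizer")
}

# one optimizer update over a parameter tree; state carries momentum/Adam
# buffers with the same shape.
opt_update <- function(params, grads, state, opt, t = 1) {
  if (is.null(params) || is.null(grads)) {
    return(list(params = params, state = state))
  }
  if (is.null(state)) {
    state <- if (opt$kind == "sgd") list(v = zeros_like(params))
    else list(m = zeros_like(params), v = zeros_like(params))
  }
  if (opt$kind == "sgd") {
    state$v <- tree_map2(state$v, grads, function(v, g) opt$momentum * v + g)
    params <- tree_map2(params, state$v, function(p, v) p - opt$lr * v)
  } else {
    state$m <- tree_map2(state$m, grads,
                         function(m, g) opt$beta1 * m + (1 - opt$beta1) * g)
    state$v <- tree_map2(state$v, grads,
                         function(v, g) opt$beta2 * v + (1 - opt$beta2) * g^2)
    bc1 <- 1 - opt$beta1^t
    bc2 <- 1 - opt$beta2^t
    upd <- tree_map2(state$m, state$v, function(m, v) {
      (m / bc1) / (sqrt(v / bc2) + opt$eps)
    })
    params <- tree_map2(params, upd, function(p, u) p - opt$lr * u)
  }
  if (opt$weight_decay > 0) {
    # decay weight matrices/filters only (not biases or adapter scalars)
    params <- tree_map(params, function(p) {
      if (!is.null(dim(p))) p * (1 - opt$lr * opt$weight_decay) else p
    })
  }
  list(params = params, state = state)
}

# accumulate gradient trees (handles NULL)
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  tree_map2(a, b, `+`)
}

#' Build an aligned pair dataset for one non-anchor modality
#'
#' Keeps only proteins that carry the modality; prepares encoder inputs once
#' (graph construction, tokenisation) and caches the frozen anchor encoder's
#' per-position features so they are not recomputed every step.
#'
#' @param model an `ma_model`.
#' @param corpus an `ma_corpus`.
#' @param modality non-anchor modality name.
#' @param ids optional id subset (e.g. a training split).
#' @return an `ma_pair_data` list: ids, anchor_inputs, other_inputs,
#'   anchor_feats (cached features or NULL), modality.
#' @export
pair_dataset <- function(model, corpus, modality, ids = NULL) {
  if (modality == model$anchor) stop("pair dataset needs a non-anchor modality")
  recs <- corpus$records
  if (!is.null(ids)) recs <- recs[intersect(ids, names(recs))]
  anchor_mod <- model$modalities[[model$anchor]]
  anchor_inputs <- list(); other_inputs <- list(); anchor_feats <- list()
  cache_anchor <- anchor_mod$policy == "freeze"
  for (id in names(recs)) {
    oth <- prepare_input(model, recs[[id]], modality)
    if (is.null(oth)) next
    anc <- prepare_input(model, recs[[id]], model$anchor)
    anchor_inputs[[id]] <- anc
    other_inputs[[id]] <- oth
    if (cache_anchor) {
      anchor_feats[[id]] <- transformer_encode(anc, anchor_mod$encoder)$out
    }
  }
  if (length(other_inputs) == 0) stop("no records carry modality '", modality, "'")
  structure(list(ids = names(other_inputs), anchor_inputs = anchor_inputs,
                 other_inputs = other_inputs,
                 anchor_feats = if (cache_anchor) anchor_feats else NULL,
                 modality = modality),
            class = "ma_pair_data")
}

#' One contrastive training step on a batch of pairs
#'
#' Encodes both sides, evaluates the symmetric InfoNCE loss, and applies one
#' optimizer update. Gradients reach only parameters whose training policy
#' permits (freeze: none; lora: adapter factors only; full: all), plus both
#' branches' poolers and projection heads.
#'
#' @param model an `ma_model`.
#' @param batch list with `modality`, `ids`, and parallel `anchor_inputs`,
#'   `other_inputs` lists (optionally `anchor_feats` cached features).
#' @param opt an [optimizer_config()].
#' @param opt_state optimizer state (NULL on the first call).
#' @param step step counter (Adam bias correction).
#' @return list(model, loss, opt_state).
#' @export
train_step <- function(model, batch, opt = optimizer_config(),
                       opt_state = NULL, step = 1) {
  modality <- batch$modality
  mod_o <- model$modalities[[modality]]
  if (is.null(mod_o)) stop("unregistered modality: ", modality)
  mod_a <- model$modalities[[model$anchor]]
  n <- length(batch$ids)
  if (n < 2) stop("contrastive training needs n >= 2 pairs")

  fwd_a <- vector("list", n); fwd_o <- vector("list", n)
  need_a <- mod_a$policy != "freeze"
  for (i in seq_len(n)) {
    id <- batch$ids[i]
    af <- if (is.null(batch$anchor_feats)) NULL else batch$anchor_feats[[id]]
    fwd_a[[i]] <- branch_forward(mod_a, batch$anchor_inputs[[id]],
                                 need_cache = need_a,
                                 enc_features = af)
    fwd_o[[i]] <- branch_forward(mod_o, batch$other_inputs[[id]],
                                 need_cache = mod_o$policy != "freeze")
  }
  A <- do.call(rbind, lapply(fwd_a, `[[`, "emb"))
  B <- do.call(rbind, lapply(fwd_o, `[[`, "emb"))
  lg <- symmetric_loss_grad(A, B, model$tau)

  ga <- list(proj = NULL, pooler = NULL, encoder = NULL, lora = NULL)
  go <- list(proj = NULL, pooler = NULL, encoder = NULL, lora = NULL)
  for (i in seq_len(n)) {
    id <- batch$ids[i]
    gi <- branch_backward(mod_a, batch$anchor_inputs[[id]], fwd_a[[i]],
                          lg$dA[i, ])
    ga <- list(proj = acc_grads(ga$proj, gi$proj),
               pooler = acc_grads(ga$pooler, gi$pooler),
               encoder = acc_grads(ga$encoder, gi$encoder),
               lora = acc_grads(ga$lora, gi$lora))
    gi <- branch_backward(mod_o, batch$other_inputs[[id]], fwd_o[[i]],
                          lg$dB[i, ])
    go <- list(proj = acc_grads(go$proj, gi$proj),
               pooler = acc_grads(go$pooler, gi$pooler),
               encoder = acc_grads(go$encoder, gi$encoder),
               lora = acc_grads(go$lora, gi$lora))
  }

  if (is.null(opt_state)) opt_state <- list()
  upd_branch <- function(mod, g, key) {
    st <- opt_state[[key]] %||% list(proj = NULL, pooler = NULL,
                                     encoder = NULL, lora = NULL)
    u <- opt_update(mod$proj$params, g$proj, st$proj, opt, step)
    mod$proj$params <- u$params; st$proj <- u$state
    if (!is.null(mod$pooler) && length(mod$pooler$params) > 0 &&
        !is.null(g$pooler) && length(g$pooler) > 0) {
      u <- opt_update(mod$pooler$params, g$pooler, st$pooler, opt, step)
      mod$pooler$params <- u$params; st$pooler <- u$state
    }
    if (mod$policy == "full" && !is.null(g$encoder)) {
      u <- opt_update(mod$encoder$params, g$encoder, st$encoder, opt, step)
      mod$encoder$params <- u$params; st$encoder <- u$state
    }
    if (mod$policy == "lora" && !is.null(g$lora)) {
      # only the A/B factors move; r and alpha carry zero gradients
      u <- opt_update(mod$encoder$lora, g$lora, st$lora, opt, step)
      mod$encoder$lora <- u$params; st$lora <- u$state
    }
    opt_state[[key]] <<- st
    mod
  }
  model$modalities[[model$anchor]] <- upd_branch(mod_a, ga, model$anchor)
  model$modalities[[modality]] <- upd_branch(mod_o, go, modality)
  list(model = model, loss = lg$loss, opt_state = opt_state)
}

#' Train the alignment model (round-robin over pair datasets)
#'
#' Visits the pair datasets in fixed registration order; each visit draws
#' the next batch from that dataset's independently cycling (seeded,
#' reshuffled per epoch) order, and applies one sequential update. This
#' mirrors anchor-paired training where differently sized modality datasets
#' are all consumed repeatedly.
#'
#' @param model an `ma_model`.
#' @param pair_data named list of [pair_dataset()] objects (non-anchor
#'   modalities).
#' @param steps total optimizer steps.
#' @param batch_size pairs per batch.
#' @param seed integer seed controlling batch order.
#' @param opt an [optimizer_config()].
#' @return list(model, log = data.frame(step, modality, loss)).
#' @export
ma_train <- function(model, pair_data, steps = 500, batch_size = 16,
                     seed = 1, opt = optimizer_config()) {
  if (length(pair_data) == 0) stop("need at least one pair dataset")
  # fixed registration order
  order_mods <- intersect(names(model$modalities), names(pair_data))
  cursors <- stats::setNames(rep(1L, length(order_mods)), order_mods)
  epochs <- stats::setNames(rep(0L, length(order_mods)), order_mods)
  orders <- lapply(stats::setNames(order_mods, order_mods), function(m) {
    with_seed(derive_seed(seed, paste0("order-", m, "-0")),
              sample(pair_data[[m]]$ids))
  })
  opt_state <- NULL
  log <- vector("list", steps)
  for (s in seq_len(steps)) {
    m <- order_mods[((s - 1) %% length(order_mods)) + 1]
    pd <- pair_data[[m]]
    bsz <- min(batch_size, length(pd$ids))
    take <- cursors[m]:(cursors[m] + bsz - 1)
    if (max(take) > length(pd$ids)) { # wrap: reshuffle a fresh epoch
      epochs[m] <- epochs[m] + 1L
      orders[[m]] <- with_seed(
        derive_seed(seed, paste0("order-", m, "-", epochs[m])),
        sample(pd$ids))
      cursors[m] <- 1L
      take <- 1:bsz
    }
    ids <- orders[[m]][take]
    cursors[m] <- cursors[m] + bsz
    batch <- list(modality = m, ids = ids,
                  anchor_inputs = pd$anchor_inputs,
                  other_inputs = pd$other_inputs,
                  anchor_feats = pd$anchor_feats)
    res <- train_step(model, batch, opt, opt_state, step = s)
    model <- res$model
    opt_state <- res$opt_state
    log[[s]] <- data.frame(step = s, modality = m, loss = res$loss)
  }
  list(model = model, log = do.call(rbind, log))
}
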