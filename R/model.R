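# Multi-modal alignment model: one encoder + pooler + projection head per
# modality, all mapping into a shared unit sphere of dimension l.
#
# Default training policies mirror the reference recipe: the anchor
# (sequence) encoder is frozen with an attention pooler and linear head;
# graph encoders (structure, pocket) train fully with a mean readout and
# linear head; the structure-token transformer trains fully with mean
# pooling; the text transformer is LoRA-adapted with CLS pooling and an
# MLP head.

MODALITY_DEFAULTS <- list(
  sequence = list(type = "transformer", policy = "freeze",
                  pooler = "attention", proj = "linear"),
  structure = list(type = "gnn", policy = "full", pooler = "graph",
                   proj = "linear"),
  tokens = list(type = "transformer", policy = "full", pooler = "mean",
                proj = "linear"),
  pocket = list(type = "gnn", policy = "full", pooler = "graph",
                proj = "linear"),
  text = list(type = "transformer", policy = "lora", pooler = "cls",
              proj = "mlp")
)

#' Build a multi-modal alignment model
#'
#' @param modalities character vector of modalities to register; must
#'   include the anchor "sequence". Known modalities: sequence, structure,
#'   tokens, pocket, text.
#' @param l shared latent dimension (>= 2).
#' @param tau InfoNCE temperature (> 0), fixed by default.
#' @param seed integer seed for all parameter initialisation.
#' @param d encoder width for non-anchor modalities.
#' @param d_anchor width of the (frozen, feature-cached) anchor sequence
#'   encoder; wider than `d` by default since its cost is paid once.
#' @param n_layers encoder depth (transformer layers / message-passing
#'   rounds).
#' @param gen_config generator settings defining the vocabularies
#'   (structure-token bins, text vocabulary).
#' @param gnn_level hierarchy level for graph encoders.
#' @param cutoff graph edge cutoff radius in Angstrom.
#' @return an `ma_model` object.
#' @export
alignment_model <- function(modalities = c("sequence", "structure", "tokens",
                                           "pocket", "text"),
                            l = 64, tau = 0.07, seed = 1, d = 32,
                            d_anchor = 64, n_layers = 2,
                            gen_config = generator_config(),
                            gnn_level = "all_atom", cutoff = 10) {
  if (!"sequence" %in% modalities) stop("anchor modality 'sequence' required")
  if (anyDuplicated(modalities)) stop("duplicate modalities")
  unknown <- setdiff(modalities, names(MODALITY_DEFAULTS))
  if (length(unknown)) stop("unregistered modality: ", unknown[1])
  if (l < 2) stop("shared dimension must be >= 2")
  if (tau <= 0) stop("temperature must be positive")
  # keep registration order canonical: anchor first, then spec order
  modalities <- intersect(names(MODALITY_DEFAULTS), modalities)

  mods <- list()
  for (m in modalities) {
    def <- MODALITY_DEFAULTS[[m]]
    sd_m <- derive_seed(seed, paste0("mod-", m))
    if (def$type == "transformer") {
      vocab <- switch(m,
                      sequence = 20L,
                      tokens = gen_config$token_bins,
                      text = gen_config$text_vocab + 2L) # + CLS + MASK
      d_m <- if (m == "sequence") d_anchor else d
      enc <- transformer_init(
        transformer_config(vocab, d = d_m, n_layers = n_layers,
                           n_heads = 2, d_ff = 2 * d_m, max_len = 256),
        seed = sd_m)
      if (def$policy == "lora") enc <- attach_lora(enc, r = 4, alpha = 8,
                                                   seed = sd_m)
      pooler <- if (def$pooler %in% c("attention", "mean", "cls")) {
        pooler_init(def$pooler, d_m, seed = sd_m)
      } else NULL
    } else {
      enc <- gnn_init(gnn_config(width = d, n_layers = n_layers,
                                 level = gnn_level, cutoff = cutoff),
                      seed = sd_m)
      pooler <- NULL # graph readout (mean over nodes) is built in
      d_m <- d
    }
    proj <- projection_init(def$proj, d_m, l, seed = sd_m)
    mods[[m]] <- list(name = m, type = def$type, policy = def$policy,
                      encoder = enc, pooler = pooler, proj = proj)
  }
  structure(list(modalities = mods, anchor = "sequence", l = l, tau = tau,
                 d = d, gen_config = gen_config, gnn_level = gnn_level,
                 cutoff = cutoff, seed = seed),
            class = "ma_model")
}

#' @export
print.ma_model <- function(x, ...) {
  cat(sprintf("ma_model: %d modalities -> shared dim %d (tau = %g)\n",
              length(x$modalities), x$l, x$tau))
  for (m in x$modalities) {
    cat(sprintf("  %-10s %-12s policy=%-7s pooler=%s proj=%s\n", m$name,
                m$type, m$policy,
                if (is.null(m$pooler)) "graph-mean" else m$pooler$kind,
                m$proj$kind))
  }
  invisible(x)
}

#' Prepare a raw protein record as encoder input for one modality
#'
#' @param model an `ma_model`.
#' @param record a protein record from [generate_corpus()].
#' @param modality registered modality name.
#' @return encoder-ready input (integer token vector or `protein_graph`),
#'   or NULL when the record lacks the modality.
#' @export
prepare_input <- function(model, record, modality) {
  mod <- model$modalities[[modality]]
  if (is.null(mod)) stop("unregistered modality: ", modality)
  switch(
    modality,
    sequence = {
      idx <- match(strsplit(record$sequence, "")[[1]], AA_ALPHABET)
      if (anyNA(idx)) stop("illegal residue in sequence of ", record$id)
      idx
    },
    tokens = {
      if (is.null(record$tokens)) return(NULL)
      as.integer(record$tokens)
    },
    text = {
      if (is.null(record$text)) return(NULL)
      kw <- as.integer(sub("^kw", "", record$text))
      cls <- model$gen_config$text_vocab + 1L
      c(cls, kw)
    },
    structure = {
      if (is.null(record$structure)) return(NULL)
      build_protein_graph(record$structure, cutoff = model$cutoff,
                          level = model$gnn_level)
    },
    pocket = {
      if (is.null(record$pocket)) return(NULL)
      if (length(unique(record$pocket$structure$res_index)) < 2) return(NULL)
      build_protein_graph(record$pocket$structure, cutoff = model$cutoff,
                          level = model$gnn_level)
    }
  )
}

# Forward pass of one modality branch for one prepared input.
# Returns the unit embedding plus (optionally) every cache needed for the
# backward pass.
branch_forward <- function(mod, input, need_cache = FALSE,
                           enc_features = NULL) {
  if (mod$type == "transformer") {
    if (is.null(enc_features)) {
      fw <- transformer_encode(input, mod$encoder, need_cache = need_cache)
      feats <- fw$out
      enc_cache <- fw$cache
    } else {
      feats <- enc_features
      enc_cache <- NULL
    }
    mask <- rep(TRUE, nrow(feats))
    pl <- pool_forward(mod$pooler, feats, mask)
    pooled <- pl$out
  } else {
    fw <- gnn_encode(input, mod$encoder, need_cache = need_cache)
    feats <- fw$node_features
    enc_cache <- fw$cache
    pl <- NULL
    pooled <- fw$out
  }
  pj <- project(pooled, mod$proj)
  emb <- l2_normalize(pj$out)
  list(emb = emb, feats = feats, enc_cache = enc_cache, pool = pl,
       pooled = pooled, proj_cache = pj$cache, proj_out = pj$out)
}

# Backward pass of one branch. demb is the gradient at the unit embedding.
# Returns gradients: proj, pooler, encoder (params/lora trees or NULL when
# the policy blocks encoder updates).
branch_backward <- function(mod, input, fwd, demb) {
  dproj_out <- l2_normalize_backward(fwd$proj_out, demb)
  pb <- project_backward(mod$proj, fwd$proj_cache, dproj_out)
  dpooled <- pb$dv
  out <- list(proj = pb$dparams, pooler = NULL, encoder = NULL, lora = NULL)
  if (mod$type == "transformer") {
    mask <- rep(TRUE, nrow(fwd$feats))
    plb <- pool_backward(mod$pooler, fwd$feats, mask, fwd$pool, dpooled)
    out$pooler <- plb$dparams
    if (mod$policy != "freeze") {
      tb <- transformer_backward(plb$dfeatures, mod$encoder, fwd$enc_cache)
      if (mod$policy == "full") out$encoder <- tb$params
      if (mod$policy == "lora") out$lora <- tb$lora
    }
  } else {
    if (mod$policy != "freeze") {
      out$encoder <- gnn_backward(dpooled, input, mod$encoder, fwd$enc_cache)
    }
  }
  out
}

#' Embed a protein record (or prepared input) for one modality
#'
#' @param model an `ma_model`.
#' @param sample a protein record, or an already prepared input.
#' @param modality registered modality name.
#' @return unit-norm numeric vector of length `model$l` with attributes
#'   `modality` (and `id` when the sample is a record).
#' @export
ma_embed <- function(model, sample, modality) {
  mod <- model$modalities[[modality]]
  if (is.null(mod)) stop("unregistered modality: ", modality)
  id <- NULL
  if (is.list(sample) && !inherits(sample, "protein_graph") &&
      !is.null(sample$id)) {
    id <- sample$id
    sample <- prepare_input(model, sample, modality)
    if (is.null(sample)) stop("record lacks modality '", modality, "'")
  }
  emb <- branch_forward(mod, sample)$emb
  attr(emb, "modality") <- modality
  if (!is.null(id)) attr(emb, "id") <- id
  emb
}

#' Embed many records for one modality
#'
#' @param model an `ma_model`.
#' @param records named list of protein records (or prepared inputs).
#' @param modality registered modality name.
#' @return matrix (n x l) with rownames = ids; records lacking the modality
#'   are skipped.
#' @export
ma_embed_all <- function(model, records, modality) {
  rows <- list()
  for (id in names(records)) {
    inp <- records[[id]]
    if (is.list(inp) && !inherits(inp, "protein_graph") && !is.null(inp$id)) {
      inp <- prepare_input(model, inp, modality)
    }
    if (is.null(inp)) next
    rows[[id]] <- branch_forward(model$modalities[[modality]], inp)$emb
  }
  M <- do.call(rbind, rows)
  rownames(M) <- names(rows)
  M
}

# --- checkpoints --------------------------------------------------------

#' Save a model checkpoint as JSON text
#'
#' Deterministic save/load round trip at full double precision.
#'
#' @param model an `ma_model`.
#' @param path output path.
#' @export
save_checkpoint <- function(model, path) {
  jsonlite::write_json(serialize_tree(unclass(model)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint path.
#' @return an `ma_model`.
#' @export
load_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(deserialize_tree(raw), class = "ma_model")
}

serialize_tree <- function(x) {
  if (is.matrix(x)) {
    return(list(".matrix" = TRUE, dim = dim(x), data = as.numeric(x)))
  }
  if (is.array(x)) {
    return(list(".array" = TRUE, dim = dim(x), data = as.numeric(x)))
  }
  if (is.list(x)) return(lapply(x, serialize_tree))
  x
}

deserialize_tree <- function(x) {
  if (is.list(x)) {
    if (isTRUE(x[[".matrix"]][[1]]) || isTRUE(x[[".array"]][[1]])) {
      return(array(as.numeric(unlist(x$data)),
                   dim = as.integer(unlist(x$dim))))
    }
    if (length(x) == 0) return(NULL)
    out <- lapply(x, deserialize_tree)
    # unwrap length-1 unnamed scalars produced by simplify = FALSE
    if (is.null(names(x))) {
      if (all(vapply(out, function(v) is.atomic(v) && length(v) == 1, TRUE))) {
        return(unlist(out))
      }
    }
    return(out)
  }
  x
}
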