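# Masked-language-model pretraining of the text encoder.
#
# The reference recipe LoRA-adapts a *pretrained* biomedical language
# model; at desk scale the stand-in is a short MLM pretraining phase on the
# corpus keyword annotations (full-parameter updates) before the base is
# frozen and only LoRA factors move during alignment.

#' MLM-pretrain the text encoder of an alignment model
#'
#' Runs `steps` single-sequence MLM updates over the keyword annotations of
#' the given records (cycling in seeded order). The mask symbol is the last
#' token of the text vocabulary. All encoder parameters are updated here;
#' alignment training afterwards touches only the LoRA factors (policy
#' "lora").
#'
#' @param model an `ma_model` with a registered text modality.
#' @param corpus an `ma_corpus`.
#' @param ids id subset to pretrain on (e.g. the training split).
#' @param steps MLM update steps.
#' @param lr learning rate.
#' @param seed integer seed.
#' @return list(model, losses).
#' @export
pretrain_text_mlm <- function(model, corpus, ids = NULL, steps = 500,
                              lr = 0.002, seed = 1) {
  mod <- model$modalities$text
  if (is.null(mod)) stop("model has no text modality")
  recs <- corpus$records
  if (!is.null(ids)) recs <- recs[intersect(ids, names(recs))]
  inputs <- list()
  for (id in names(recs)) {
    inp <- prepare_input(model, recs[[id]], "text")
    if (!is.null(inp)) inputs[[id]] <- inp
  }
  if (length(inputs) == 0) stop("no records carry text")
  mask_token <- model$gen_config$text_vocab + 2L
  ord <- with_seed(derive_seed(seed, "mlm-order"),
                   sample(rep_len(seq_along(inputs), steps)))
  losses <- numeric(steps)
  enc <- mod$encoder
  for (s in seq_len(steps)) {
    res <- mlm_step(enc, inputs[[ord[s]]], mask_token, mask_frac = 0.3,
                    lr = lr, seed = derive_seed(seed, paste0("mlm-", s)))
    enc <- res$state
    losses[s] <- res$loss
  }
  model$modalities$text$encoder <- enc
  list(model = model, losses = losses)
}
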