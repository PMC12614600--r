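# Shared fixtures, built in code and memoized for the test session.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

full_config <- function() {
  cfg <- generator_config()
  cfg$missing_pocket <- 0
  cfg$missing_text <- 0
  cfg
}

# small fully-covered corpus for unit tests
tiny_corpus <- function() {
  memo("tiny_corpus", generate_corpus(30, d_z = 8, seed = 42,
                                      config = full_config()))
}

# a small trained model (sequence anchor + structure + text), shared by the
# alignment-property, retrieval-improvement and zero-shot tests
toy_trained <- function() {
  memo("toy_trained", {
    corpus <- generate_corpus(200, d_z = 8, seed = 7, config = full_config())
    split <- split_by_identity(corpus, 0.5, seed = 7,
                               fractions = c(train = 0.7, validation = 0.1,
                                             test = 0.2))
    model <- alignment_model(c("sequence", "structure", "pocket"),
                             l = 16, seed = 7, d = 16, d_anchor = 32,
                             n_layers = 1)
    pd <- list(
      structure = pair_dataset(model, corpus, "structure", ids = split$train),
      pocket = pair_dataset(model, corpus, "pocket", ids = split$train)
    )
    tr <- ma_train(model, pd, steps = 600, batch_size = 16, seed = 7,
                   opt = optimizer_config("adam", lr = 0.003))
    list(model = tr$model, corpus = corpus, split = split, log = tr$log,
         untrained = model)
  })
}

random_unit_rows <- function(n, l, seed = 1) {
  M <- modalign:::with_seed(seed, matrix(stats::rnorm(n * l), n, l))
  l2_normalize(M)
}

# a tiny deterministic CA-only structure (straight-ish chain)
line_structure <- function(n, spacing = 3.8) {
  data.frame(atom = "CA", res_name = "ALA", res_index = seq_len(n),
             x = spacing * seq_len(n), y = 0, z = 0, element = "C",
             stringsAsFactors = FALSE)
}
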