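# modalign

Multi-modal protein representation alignment at desk scale.

Protein function is written in several "languages" at once: the amino-acid
sequence, the 3D fold, discrete structure tokens, the ligand-binding
pocket, and curated text annotations. `modalign` binds an encoder for each
of these modalities into **one shared unit-sphere latent space** using
anchor-paired contrastive training: every training pair couples the
sequence modality (the anchor, present for every protein) with one other
modality, and the symmetric InfoNCE objective

L = L_FE + L_EF,  with  L_FE = −(1/n) Σᵢ log [ exp(aᵢᵀbᵢ/τ) / Σⱼ exp(aᵢᵀbⱼ/τ) ]

pulls matched cross-modal pairs together and pushes in-batch mismatches
apart. Because all modalities are tied to the same anchor, modalities never
paired during training still align — *emergent alignment* — and the package
ships the full evaluation battery to measure it: cross-modal retrieval
(R@1/R@10/R@100, median rank) over trained and emergent directions,
frozen-embedding MLP probing (Spearman ρ, accuracy, ROC AUC, Fmax,
per-class AUPR), Wilcoxon rank-sum model comparison, normalized
performance-drop heatmaps over exhaustive modality ablations, and
zero-shot analyses (evolutionary-relatedness separation via Hamming-ranked
MSA groups, binding-site pair discrimination AUC).

Everything runs on one CPU in minutes, with no downloads: a latent-driven
synthetic generator emits corpora in which every modality (FASTA sequence,
minimal-PDB Cα structure, structure-token string, pocket residue set,
keyword list, task labels) is a noisy view of one hidden latent vector per
protein — the statistical structure the method assumes. Encoders are
implemented from scratch in base R (transformer, geometric message-passing
GNN, LoRA adapters, attention/mean/CLS pooling, projection heads) with
hand-derived gradients verified against finite differences in the test
suite.

Who this is for: anyone studying contrastive multi-modal alignment
mechanics — emergent retrieval, modality ablations, pooling and adapter
policies — who wants a fully inspectable, deterministic, dependency-light
reference implementation rather than a GPU training stack.

## Worked example

```r
library(modalign)

cfg <- generator_config()
cfg$missing_pocket <- 0; cfg$missing_text <- 0
corpus <- generate_corpus(500, d_z = 8, seed = 1, config = cfg)
split  <- split_by_identity(corpus, threshold = 0.5, seed = 1)

model <- alignment_model(c("sequence", "structure", "tokens", "pocket"),
                         l = 32, seed = 1, d = 32, d_anchor = 64)
pairs <- lapply(setNames(c("structure", "tokens", "pocket"),
                         c("structure", "tokens", "pocket")),
                function(m) pair_dataset(model, corpus, m, ids = split$train))
fit <- ma_train(model, pairs, steps = 2000, batch_size = 16, seed = 1,
                opt = optimizer_config("adam", lr = 0.003))
report <- evaluate_alignment(fit$model, corpus$records[split$test],
                             modalities = names(model$modalities))
print(report[, c("query", "candidate", "trained", "median_rank", "R@1", "R@10")])
```

Output from this exact run (seed 1, ~3 minutes on one CPU):

```
       query candidate trained median_rank  R@1 R@10
1   sequence structure    TRUE         1.0 0.62 0.98
2   sequence    tokens    TRUE         7.5 0.16 0.62
3   sequence    pocket    TRUE         2.5 0.34 0.84
4  structure  sequence    TRUE         1.0 0.54 0.94
5     tokens  sequence    TRUE         8.5 0.18 0.64
6     pocket  sequence    TRUE         2.5 0.38 0.84
7     tokens structure   FALSE        19.0 0.04 0.28
8     pocket structure   FALSE         2.0 0.38 0.90
9  structure    tokens   FALSE        23.0 0.10 0.28
10    pocket    tokens   FALSE        17.0 0.02 0.38
11 structure    pocket   FALSE         2.0 0.38 0.88
12    tokens    pocket   FALSE        17.0 0.04 0.28
```

Reading it: trained directions (sequence paired with each modality during
training) retrieve the true counterpart at median rank 1–8.5 out of 50
held-out proteins. The *emergent* structure↔pocket directions — never
paired during training — reach median rank 2 purely because both were
anchored to sequence; the random-baseline median rank would be 25. Emergent
pairs involving the token modality stay weaker (median rank 17–23); the
methods vignette (`vignettes/methods.Rmd`) analyses why the synthetic
world limits those pairs.

Downstream probing on the frozen embeddings:

```r
emb <- list(modalign = ma_embed_all(fit$model, corpus$records, "sequence"))
cls <- setNames(vapply(corpus$records, function(r) r$labels$class, 1),
                names(corpus$records))
tasks <- list(localization = list(kind = "multiclass", labels = cls,
                                  metric = "accuracy"))
mt <- run_downstream_suite(emb, tasks, split, n_runs = 6, seed = 1)
summarize_metric_table(mt)
```

## Command line

```sh
inst/cli/modalign generate --n 50 --seed 1 --out run1
inst/cli/modalign train --n 200 --steps 300 --seed 1 --out run1
inst/cli/modalign eval-retrieval --n 200 --steps 300 --seed 1 --out run1
```

Subcommands: `generate`, `train`, `eval-retrieval`, `probe`, `ablate`,
`evolve`, `pair-auc`, `report`. Every run directory contains the frozen
effective configuration and a timestamped log; one `--seed` reproduces a
run bit-for-bit.

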