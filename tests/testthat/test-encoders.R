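# encoders: dihedrals, graphs, transformer, GNN, LoRA, MLM.

test_that("dihedral matches the two-normal atan2 oracle and its symmetries", {
  d <- dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1))
  expect_true(d$valid)
  expect_equal(d$angle, pi / 2, tolerance = 1e-12)

  # planar trans zigzag -> magnitude pi
  z <- dihedral(c(0, 1, 0), c(1, 0, 0), c(2, 1, 0), c(3, 0, 0))
  expect_equal(abs(z$angle), pi, tolerance = 1e-12)

  # reversal keeps the angle; mirroring flips the sign
  for (i in 1:10) {
    pts <- modalign:::with_seed(i, matrix(stats::rnorm(12), 4, 3))
    a <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    b <- dihedral(pts[4, ], pts[3, ], pts[2, ], pts[1, ])
    m <- pts
    m[, 3] <- -m[, 3]
    c0 <- dihedral(m[1, ], m[2, ], m[3, ], m[4, ])
    expect_equal(a$angle, b$angle, tolerance = 1e-9)
    expect_equal(a$angle, -c0$angle, tolerance = 1e-9)
  }

  # degenerate geometry is flagged, not thrown
  bad <- dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_false(bad$valid)
})

test_that("protein graphs match the brute-force distance oracle", {
  s2 <- line_structure(2, spacing = 5)
  g <- build_protein_graph(s2, cutoff = 10)
  expect_identical(nrow(g$edges), 2L) # one undirected edge, both directions

  s2b <- line_structure(2, spacing = 12)
  g2 <- build_protein_graph(s2b, cutoff = 10)
  expect_identical(nrow(g2$edges), 0L)

  r <- tiny_corpus()$records[[2]]
  g3 <- build_protein_graph(r$structure, cutoff = 10)
  P <- modalign:::ca_trace(r$structure)
  D <- as.matrix(dist(P))
  want <- which(D <= 10 & row(D) != col(D), arr.ind = TRUE)
  got <- g3$edges
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_identical(key(got), key(want))
  # symmetry, no self-edges, all edge lengths within cutoff
  expect_identical(key(got), key(got[, 2:1, drop = FALSE]))
  expect_true(all(g3$edges[, 1] != g3$edges[, 2]))
  expect_true(all(D[g3$edges] <= 10))
  expect_error(build_protein_graph(line_structure(1)), "at least 2")
})

test_that("transformer honors the L = 0 and masking contracts", {
  cfg <- transformer_config(8, d = 8, n_layers = 0, n_heads = 2, d_ff = 16,
                            max_len = 32)
  st <- transformer_init(cfg, seed = 1)
  toks <- c(3L, 1L, 5L)
  out <- transformer_encode(toks, st)$out
  expect_equal(out, st$params$E[toks, ] + st$params$P[1:3, ],
               ignore_attr = TRUE)

  cfg2 <- transformer_config(8, d = 8, n_layers = 2, n_heads = 2, d_ff = 16,
                             max_len = 32)
  st2 <- transformer_init(cfg2, seed = 2)
  o1 <- transformer_encode(toks, st2)$out
  padded <- c(toks, 2L, 2L)
  o2 <- transformer_encode(padded, st2,
                           mask = c(TRUE, TRUE, TRUE, FALSE, FALSE))$out
  expect_lt(max(abs(o1 - o2[1:3, ])), 1e-6)

  expect_error(transformer_encode(c(1L, 99L), st2), "out of range")
  expect_error(transformer_encode(rep(1L, 33), st2), "maximum length")
  # determinism of initialization
  expect_identical(st2$params, transformer_init(cfg2, seed = 2)$params)
})

test_that("single transformer layer matches a hand-computed oracle", {
  # one layer, d = 2, one head, hand-set parameters, 2-token input
  cfg <- transformer_config(4, d = 2, n_layers = 1, n_heads = 1, d_ff = 2,
                            max_len = 4)
  st <- transformer_init(cfg, seed = 1)
  st$params$E <- matrix(c(1, 0,
                          0, 1,
                          1, 1,
                          0, 0), 4, 2, byrow = TRUE)
  st$params$P <- matrix(0, 4, 2)
  ly <- list(Wq = diag(2), Wk = diag(2), Wv = matrix(c(0, 1, 1, 0), 2, 2),
             Wo = diag(2), W1 = diag(2), b1 = c(0, 0), W2 = diag(2),
             b2 = c(0.5, -0.5))
  st$params$layers[[1]] <- ly
  x <- c(1L, 2L)
  H <- st$params$E[x, ]                       # rows (1,0), (0,1)
  Q <- H %*% ly$Wq; K <- H %*% ly$Wk; V <- H %*% ly$Wv
  S <- Q %*% t(K) / sqrt(2)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  M <- H + (A %*% V) %*% ly$Wo                # residual
  Z <- pmax(M %*% ly$W1 + matrix(ly$b1, 2, 2, byrow = TRUE), 0)
  expect_ref <- M + Z %*% ly$W2 + matrix(ly$b2, 2, 2, byrow = TRUE)
  got <- transformer_encode(x, st)$out
  expect_equal(got, expect_ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GNN zero-message case reduces to mean of initial node features", {
  r <- tiny_corpus()$records[[3]]
  g <- build_protein_graph(r$structure, cutoff = 10)
  st <- gnn_init(gnn_config(width = 8, n_layers = 2), seed = 1)
  # MESSAGE zeroed and UPDATE forced to the residual pass-through
  for (l in 1:2) {
    st$params$layers[[l]]$msg_W2[] <- 0
    st$params$layers[[l]]$msg_b2[] <- 0
    st$params$layers[[l]]$upd_W2[] <- 0
    st$params$layers[[l]]$upd_b2[] <- 0
  }
  out <- gnn_encode(g, st)$out
  expect_equal(out, colMeans(st$params$Emb[g$aa_idx, ]), tolerance = 1e-12)
})

test_that("GNN output is invariant to rigid motions and node permutations", {
  r <- tiny_corpus()$records[[5]]
  st <- gnn_init(gnn_config(width = 8, n_layers = 2), seed = 3)
  g <- build_protein_graph(r$structure, cutoff = 10)
  base <- gnn_encode(g, st)$out
  for (i in 1:5) {
    # random rotation (QR of a Gaussian) + translation
    R <- modalign:::with_seed(i, qr.Q(qr(matrix(stats::rnorm(9), 3))))
    tr <- modalign:::with_seed(i + 50, stats::rnorm(3, sd = 20))
    s2 <- r$structure
    xyz <- as.matrix(s2[, c("x", "y", "z")]) %*% R
    s2$x <- xyz[, 1] + tr[1]
    s2$y <- xyz[, 2] + tr[2]
    s2$z <- xyz[, 3] + tr[3]
    g2 <- build_protein_graph(s2, cutoff = 10)
    expect_lt(max(abs(gnn_encode(g2, st)$out - base)), 1e-5)
  }
  # permuting atom record order changes nothing (nodes are residue-sorted)
  s3 <- r$structure[modalign:::with_seed(9, sample(nrow(r$structure))), ]
  g3 <- build_protein_graph(s3, cutoff = 10)
  expect_lt(max(abs(gnn_encode(g3, st)$out - base)), 1e-12)
})

test_that("one GNN layer matches hand-computed message/update arithmetic", {
  # two nodes, one undirected edge, scalar-ish hand-set parameters
  s <- line_structure(2, spacing = 5)
  g <- build_protein_graph(s, cutoff = 10, level = "amino_acid")
  st <- gnn_init(gnn_config(width = 2, n_layers = 1, level = "amino_acid"),
                 seed = 1)
  w <- 2; gdim <- ncol(g$geom)
  st$params$Emb[] <- 0
  st$params$Emb[g$aa_idx[1], ] <- c(1, 0) # ALA row
  ly <- st$params$layers[[1]]
  ly$msg_W1 <- matrix(1, w + gdim, w)
  ly$msg_b1 <- c(0, 0)
  ly$msg_W2 <- diag(w)
  ly$msg_b2 <- c(0, 0)
  ly$upd_W1 <- rbind(diag(w), diag(w)) # [v, agg] summed
  ly$upd_b1 <- c(0, 0)
  ly$upd_W2 <- 0.5 * diag(w)
  ly$upd_b2 <- c(0, 0)
  st$params$layers[[1]] <- ly
  V <- st$params$Emb[g$aa_idx, ]
  msg_in <- cbind(V[g$edges[, 1], ], g$geom)
  msg <- pmax(msg_in %*% ly$msg_W1, 0) %*% ly$msg_W2
  agg <- rowsum(msg, g$edges[, 2])
  u <- pmax(V + agg, 0)
  Vn <- V + u %*% ly$upd_W2
  expect_equal(gnn_encode(g, st)$out, colMeans(Vn), tolerance = 1e-12)
  expect_error(gnn_encode(structure(list(n = 0), class = "protein_graph"), st),
               "empty|level")
})

test_that("LoRA forward obeys its closed forms and freezes W", {
  W <- diag(2)
  ad <- lora_adapter(2, 2, r = 1, alpha = 2, seed = 1)
  ad$A <- matrix(c(1, 0), 2, 1)
  ad$B <- matrix(c(0, 1), 1, 2)
  expect_equal(lora_forward(ad, W, c(1, 0)), c(1, 2))

  ad0 <- ad
  ad0$alpha <- 0
  expect_equal(lora_forward(ad0, W, c(3, 4)), c(3, 4))
  adz <- ad
  adz$A[] <- 0
  expect_equal(lora_forward(adz, W, c(3, 4)), c(3, 4))
  expect_error(lora_adapter(2, 2, r = 2), "rank")

  # merged-weight evaluation equals factored evaluation
  for (i in 1:5) {
    ad2 <- lora_adapter(6, 4, r = 2, alpha = 3, seed = i)
    ad2$A <- modalign:::with_seed(i, matrix(stats::rnorm(12), 6, 2))
    W2 <- modalign:::with_seed(i + 10, matrix(stats::rnorm(24), 6, 4))
    x <- modalign:::with_seed(i + 20, stats::rnorm(6))
    merged <- W2 + (ad2$alpha / ad2$r) * ad2$A %*% ad2$B
    expect_lt(max(abs(lora_forward(ad2, W2, x) - drop(x %*% merged))), 1e-6)
  }
})

test_that("mlm_loss evaluates its closed forms", {
  V <- 7
  expect_equal(mlm_loss(matrix(1 / V, 1, V), 3L), log(V))
  P <- matrix(1e-12, 2, 4)
  P[1, 2] <- 1
  P[2, 4] <- 1
  expect_equal(mlm_loss(P, c(2L, 4L)), 0, tolerance = 1e-9)
  P2 <- rbind(c(0.5, 0.5, 0, 0), c(0.25, 0.25, 0.25, 0.25))
  expect_equal(mlm_loss(P2, c(1L, 3L)), log(2) + log(4))
  expect_error(mlm_loss(P2, integer(0)), "empty")
})

test_that("mlm_step reduces loss on a repeated sequence", {
  cfg <- transformer_config(10, d = 8, n_layers = 1, n_heads = 2, d_ff = 16,
                            max_len = 16)
  st <- transformer_init(cfg, seed = 1)
  toks <- c(1L, 2L, 3L, 4L, 5L, 1L, 2L, 3L)
  first <- NULL
  for (i in 1:60) {
    res <- mlm_step(st, toks, mask_token = 10L, lr = 0.01, seed = i %% 7 + 1)
    st <- res$state
    if (i == 1) first <- res$loss
  }
  expect_lt(res$loss, first)
})

test_that("checkpoints round trip through JSON text", {
  model <- alignment_model(c("sequence", "structure"), l = 8, seed = 2,
                           d = 8, d_anchor = 8, n_layers = 1)
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  r <- tiny_corpus()$records[[1]]
  e1 <- ma_embed(model, r, "sequence")
  e2 <- ma_embed(back, r, "sequence")
  expect_equal(as.numeric(e1), as.numeric(e2), tolerance = 1e-12)
  g1 <- ma_embed(model, r, "structure")
  g2 <- ma_embed(back, r, "structure")
  expect_equal(as.numeric(g1), as.numeric(g2), tolerance = 1e-12)
})
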