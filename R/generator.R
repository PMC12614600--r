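# Latent-driven synthetic multi-modal protein generator.
#
# Every protein owns a hidden latent vector z; all modalities (sequence,
# CA-trace structure, structure tokens, binding pocket, text keywords) and
# all task labels are noisy views of that z. This statistical linkage is
# exactly what anchor-paired contrastive training assumes, so emergent
# cross-modal alignment is recoverable from these corpora.

#' Default generator settings
#'
#' Missing-modality fractions mirror the coverage imbalance of a real
#' multi-modal protein corpus (pocket is the scarcest modality, text next);
#' structure and tokens are always present.
#'
#' @return named list of generator settings.
#' @export
generator_config <- function() {
  list(
    seq_len_range = c(30L, 60L),   # residues
    structure_noise = 0.3,         # Angstrom, sd of coordinate noise
    pocket_radius = 12,            # Angstrom, CA distance to pseudo-ligand
    text_vocab = 40L,              # keyword vocabulary size
    n_keywords = 5L,               # keywords per protein
    token_bins = 16L,              # structure-token vocabulary size
    n_segments = 6L,               # secondary-structure segments per chain
    missing_pocket = 0.67,         # fraction of records lacking a pocket
    missing_text = 0.48,           # fraction of records lacking text
    n_classes = 10L,               # multiclass label width
    n_multilabel = 8L,             # multilabel vector width
    regression_noise = 0.1
  )
}

# CA pseudo-geometry per secondary-structure state:
# (pseudo bond angle theta, pseudo torsion alpha), radians.
SS_GEOM <- list(
  H = c(theta = 91 * pi / 180, alpha = 50 * pi / 180),    # helix
  E = c(theta = 124 * pi / 180, alpha = -170 * pi / 180), # strand
  C = c(theta = 105 * pi / 180, alpha = 80 * pi / 180)    # coil
)

# Place a chain of n CA atoms from per-residue (theta, alpha) internal
# coordinates, bond length 3.8 A (NeRF-style extension).
build_ca_chain <- function(thetas, alphas, bond = 3.8) {
  n <- length(thetas)
  P <- matrix(0, n, 3)
  P[1, ] <- c(0, 0, 0)
  if (n >= 2) P[2, ] <- c(bond, 0, 0)
  if (n >= 3) P[3, ] <- P[2, ] + bond * c(-cos(pi - thetas[3]), sin(pi - thetas[3]), 0)
  if (n >= 4) {
    for (t in 4:n) {
      a <- P[t - 3, ]; b <- P[t - 2, ]; c0 <- P[t - 1, ]
      bc <- c0 - b
      bc <- bc / sqrt(sum(bc^2))
      ab <- b - a
      nvec <- c(ab[2] * bc[3] - ab[3] * bc[2],
                ab[3] * bc[1] - ab[1] * bc[3],
                ab[1] * bc[2] - ab[2] * bc[1])
      nn <- sqrt(sum(nvec^2))
      if (nn < 1e-8) nvec <- c(0, 0, 1) else nvec <- nvec / nn
      mvec <- c(nvec[2] * bc[3] - nvec[3] * bc[2],
                nvec[3] * bc[1] - nvec[1] * bc[3],
                nvec[1] * bc[2] - nvec[2] * bc[1])
      th <- thetas[t]; al <- alphas[t]
      d2 <- c(-bond * cos(pi - th),
              bond * sin(pi - th) * cos(al),
              bond * sin(pi - th) * sin(al))
      P[t, ] <- c0 + d2[1] * bc + d2[2] * mvec + d2[3] * nvec
    }
  }
  P
}

# Corpus-level parameter set drawn once per (d_z, seed, config).
gen_params <- function(d_z, config, seed) {
  with_seed(derive_seed(seed, "gen-params"), {
    list(
      B1 = matrix(stats::rnorm(20 * d_z), 20, d_z),
      B2 = matrix(stats::rnorm(20 * d_z), 20, d_z),
      seg_dirs = l2_normalize(matrix(stats::rnorm(config$n_segments * d_z),
                                     config$n_segments, d_z)),
      topic = matrix(stats::rnorm(config$text_vocab * d_z), config$text_vocab, d_z),
      pocket_dir = l2_normalize(stats::rnorm(d_z)),
      class_map = matrix(stats::rnorm(config$n_classes * d_z), config$n_classes, d_z),
      multilabel_map = matrix(stats::rnorm(config$n_multilabel * d_z),
                              config$n_multilabel, d_z),
      reg_w = l2_normalize(stats::rnorm(d_z)),
      bin_w = l2_normalize(stats::rnorm(d_z))
    )
  })
}

generate_one <- function(id, z, params, config, seed) {
  with_seed(seed, {
    lo <- config$seq_len_range[1]; hi <- config$seq_len_range[2]
    n <- sample(lo:hi, 1)

    # sequence: position-specific residue distributions from z
    omega <- 2 * pi / 25
    seq_idx <- integer(n)
    for (t in seq_len(n)) {
      logits <- 2 * as.numeric((params$B1 * cos(omega * t) +
                                params$B2 * sin(omega * t)) %*% z)
      seq_idx[t] <- sample.int(20, 1, prob = softmax_vec(logits))
    }
    sequence <- paste0(AA_ALPHABET[seq_idx], collapse = "")

    # secondary-structure states per segment, selected by z
    nseg <- config$n_segments
    seg_of <- pmin(floor((seq_len(n) - 1) / n * nseg) + 1, nseg)
    proj <- as.numeric(params$seg_dirs %*% z)
    states <- ifelse(proj > 0.25, "H", ifelse(proj < -0.25, "E", "C"))[seg_of]
    geom <- do.call(rbind, SS_GEOM[states])
    P <- build_ca_chain(geom[, "theta"], geom[, "alpha"])
    P <- P + matrix(stats::rnorm(3 * n, sd = config$structure_noise), n, 3)
    structure <- data.frame(
      atom = "CA",
      res_name = aa3(AA_ALPHABET[seq_idx]),
      res_index = seq_len(n),
      x = round(P[, 1], 3), y = round(P[, 2], 3), z = round(P[, 3], 3),
      element = "C", stringsAsFactors = FALSE
    )

    # tokens: deterministic discretization of the emitted coordinates
    tokens <- tokenize_structure(structure, config$token_bins)

    # pocket: residues near a z-placed pseudo-ligand point
    a_idx <- 1 + floor(stats::plogis(2 * sum(params$pocket_dir * z)) * (n - 1))
    Pr <- as.matrix(structure[, c("x", "y", "z")])
    lig <- Pr[a_idx, ] + c(2, 2, 2)
    d2lig <- sqrt(rowSums((Pr - matrix(lig, n, 3, byrow = TRUE))^2))
    pocket_res <- which(d2lig <= config$pocket_radius)
    pocket <- list(indices = pocket_res,
                   structure = structure[structure$res_index %in% pocket_res, ,
                                         drop = FALSE])

    # text keywords from a z-dependent topic distribution
    kw_p <- softmax_vec(as.numeric(params$topic %*% z))
    kw <- sample.int(config$text_vocab, min(config$n_keywords, config$text_vocab),
                     prob = kw_p)
    text <- sprintf("kw%02d", sort(kw))

    labels <- list(
      class = which.max(as.numeric(params$class_map %*% z)),
      binary = as.integer(sum(params$bin_w * z) > 0),
      multilabel = as.integer(as.numeric(params$multilabel_map %*% z) > 0),
      regression = sum(params$reg_w * z) +
        stats::rnorm(1, sd = config$regression_noise)
    )

    list(id = id, sequence = sequence, structure = structure, tokens = tokens,
         pocket = pocket, text = text, labels = labels)
  })
}

aa3 <- function(aa1) {
  map <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  unname(map[aa1])
}

#' Generate a synthetic multi-modal protein corpus
#'
#' Each record derives all modalities from a hidden latent vector z; see the
#' methods vignette for the generative model. Identical (inputs, seed) give
#' byte-identical corpora.
#'
#' @param n number of proteins (>= 1).
#' @param d_z latent dimension (>= 1).
#' @param seed integer seed.
#' @param config generator settings, see [generator_config()].
#' @return object of class `ma_corpus`: list with `records` (named list of
#'   protein records), `latents` (n x d_z matrix), `config`, `params`.
#' @export
generate_corpus <- function(n, d_z = 8, seed = 1, config = generator_config()) {
  if (n < 1) stop("n must be >= 1")
  if (d_z < 1) stop("d_z must be >= 1")
  for (f in c("missing_pocket", "missing_text")) {
    if (config[[f]] < 0 || config[[f]] > 1) {
      stop(f, " must lie in [0, 1]")
    }
  }
  params <- gen_params(d_z, config, seed)
  ids <- sprintf("P%04d", seq_len(n))
  Z <- with_seed(derive_seed(seed, "latents"),
                 matrix(stats::rnorm(n * d_z), n, d_z))
  rownames(Z) <- ids
  records <- vector("list", n)
  for (i in seq_len(n)) {
    records[[i]] <- generate_one(ids[i], Z[i, ], params, config,
                                 derive_seed(seed, paste0("rec-", i)))
  }
  names(records) <- ids

  # missing-modality fractions, honored exactly (rounded down)
  drop_mod <- function(records, field, frac, tag) {
    k <- floor(n * frac)
    if (k > 0) {
      idx <- with_seed(derive_seed(seed, tag), sample.int(n, k))
      for (i in idx) records[[i]][[field]] <- NULL
    }
    records
  }
  records <- drop_mod(records, "pocket", config$missing_pocket, "miss-pocket")
  records <- drop_mod(records, "text", config$missing_text, "miss-text")

  structure(list(records = records, latents = Z, config = config,
                 params = params, seed = seed),
            class = "ma_corpus")
}

#' @export
print.ma_corpus <- function(x, ...) {
  n <- length(x$records)
  has <- function(f) sum(vapply(x$records, function(r) !is.null(r[[f]]), TRUE))
  cat(sprintf("ma_corpus: %d proteins (d_z = %d)\n", n, ncol(x$latents)))
  cat(sprintf("  modality coverage: structure %d, tokens %d, pocket %d, text %d\n",
              has("structure"), has("tokens"), has("pocket"), has("text")))
  invisible(x)
}

#' Simulate an MSA family around a reference sequence
#'
#' Similar/divergent members substitute the reference per site at the stated
#' rates (substitutions are uniform over the 20 letters, so the expected
#' mismatch fraction is rate * 19/20); unrelated members are independent of
#' the reference. Gap insertion (gap symbol '-', replacing the site) is off
#' by default.
#'
#' @param length alignment length.
#' @param n_similar,n_divergent,n_unrelated group sizes (defaults 50/50/1000).
#' @param rate_similar,rate_divergent per-site substitution probabilities,
#'   with rate_similar < rate_divergent.
#' @param seed integer seed.
#' @param gap_rate per-site gap probability (applied to similar/divergent).
#' @return object of class `ma_msa_family` with fields `reference`,
#'   `members` (named character vector), `groups` (similar/divergent/unrelated
#'   tag per member).
#' @export
generate_msa_family <- function(length, n_similar = 50, n_divergent = 50,
                                n_unrelated = 1000, rate_similar = 0.05,
                                rate_divergent = 0.3, seed = 1, gap_rate = 0) {
  if (n_similar < 0 || n_divergent < 0 || n_unrelated < 0) {
    stop("group counts must be non-negative")
  }
  if (rate_similar < 0 || rate_similar > 1 || rate_divergent < 0 ||
      rate_divergent > 1) stop("rates must lie in [0, 1]")
  if (rate_similar >= rate_divergent) {
    stop("rate_similar must be < rate_divergent")
  }
  with_seed(derive_seed(seed, "msa"), {
    ref <- sample(AA_ALPHABET, length, replace = TRUE)
    mutate <- function(rate) {
      s <- ref
      hit <- stats::runif(length) < rate
      if (any(hit)) s[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
      if (gap_rate > 0) {
        g <- stats::runif(length) < gap_rate
        s[g] <- GAP_CHAR
      }
      paste0(s, collapse = "")
    }
    members <- c(
      vapply(seq_len(n_similar), function(i) mutate(rate_similar), ""),
      vapply(seq_len(n_divergent), function(i) mutate(rate_divergent), ""),
      vapply(seq_len(n_unrelated), function(i) {
        paste0(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
      }, "")
    )
    groups <- rep(c("similar", "divergent", "unrelated"),
                  c(n_similar, n_divergent, n_unrelated))
    names(members) <- sprintf("m%04d", seq_along(members))
    structure(list(reference = paste0(ref, collapse = ""),
                   members = members, groups = groups),
              class = "ma_msa_family")
  })
}

# Positional sequence identity: matches over the first min(la, lb) positions
# divided by min(la, lb). Alignment-free by design (desk scale).
seq_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  m <- min(la, lb)
  va <- strsplit(substr(a, 1, m), "")[[1]]
  vb <- strsplit(substr(b, 1, m), "")[[1]]
  sum(va == vb) / m
}

#' Split a corpus into train/validation/test by sequence identity clusters
#'
#' Greedy single-linkage clustering on pairwise positional identity; whole
#' clusters land in exactly one split so no near-duplicate sequences straddle
#' a split boundary.
#'
#' @param corpus an `ma_corpus`.
#' @param threshold identity threshold in (0, 1); pairs at or above it are
#'   linked.
#' @param seed integer seed (cluster-to-split assignment order).
#' @param fractions named numeric vector of split targets, summing to 1.
#' @return list of id character vectors: `train`, `validation`, `test`.
#' @export
split_by_identity <- function(corpus, threshold = 0.5, seed = 1,
                              fractions = c(train = 0.8, validation = 0.1,
                                            test = 0.1)) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  recs <- corpus$records
  if (length(recs) == 0) stop("empty corpus")
  ids <- names(recs)
  n <- length(ids)
  seqs <- vapply(recs, `[[`, "", "sequence")

  # union-find single linkage
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (seq_identity(seqs[i], seqs[j]) >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  clusters <- split(seq_len(n), roots)

  order_idx <- with_seed(derive_seed(seed, "split"),
                         sample.int(length(clusters)))
  sizes <- stats::setNames(numeric(length(fractions)), names(fractions))
  assign_to <- stats::setNames(vector("list", length(fractions)),
                               names(fractions))
  for (ci in order_idx) {
    cl <- clusters[[ci]]
    # most underfilled split relative to its target
    deficit <- fractions - sizes / n
    k <- names(which.max(deficit))
    assign_to[[k]] <- c(assign_to[[k]], cl)
    sizes[k] <- sizes[k] + length(cl)
  }
  lapply(assign_to, function(ix) ids[sort(ix)])
}

#' Write a corpus to disk through the io_formats layer
#'
#' Emits FASTA sequences, per-protein minimal PDB files, token/text/label
#' tables, and a manifest of per-protein modality availability.
#'
#' @param corpus an `ma_corpus`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "pdb"), showWarnings = FALSE)
  recs <- corpus$records
  write_fasta(lapply(recs, `[[`, "sequence"), file.path(dir, "sequences.fasta"))
  for (r in recs) {
    if (!is.null(r$structure)) {
      write_pdb_min(r$structure, file.path(dir, "pdb", paste0(r$id, ".pdb")))
    }
  }
  tok <- data.frame(id = names(recs), stringsAsFactors = FALSE)
  tok$tokens <- lapply(recs, function(r) r$tokens %||% integer(0))
  write_table_schema(tok, file.path(dir, "tokens.tsv"),
                     c(id = "string", tokens = "int_list"))
  txt <- data.frame(id = names(recs), stringsAsFactors = FALSE)
  txt$keywords <- lapply(recs, function(r) r$text %||% character(0))
  write_table_schema(txt, file.path(dir, "text.tsv"),
                     c(id = "string", keywords = "str_list"))
  pock <- data.frame(id = names(recs), stringsAsFactors = FALSE)
  pock$residues <- lapply(recs, function(r) {
    if (is.null(r$pocket)) integer(0) else r$pocket$indices
  })
  write_table_schema(pock, file.path(dir, "pockets.tsv"),
                     c(id = "string", residues = "int_list"))
  lab <- data.frame(
    id = names(recs),
    class = vapply(recs, function(r) r$labels$class, 1),
    binary = vapply(recs, function(r) r$labels$binary, 1L),
    regression = vapply(recs, function(r) r$labels$regression, 1),
    stringsAsFactors = FALSE
  )
  lab$multilabel <- lapply(recs, function(r) r$labels$multilabel)
  write_table_schema(lab, file.path(dir, "labels.tsv"),
                     c(id = "string", class = "real", binary = "integer",
                       regression = "real", multilabel = "int_list"))
  manifest <- data.frame(
    id = names(recs),
    sequence = 1L,
    structure = vapply(recs, function(r) as.integer(!is.null(r$structure)), 1L),
    tokens = vapply(recs, function(r) as.integer(!is.null(r$tokens)), 1L),
    pocket = vapply(recs, function(r) as.integer(!is.null(r$pocket)), 1L),
    text = vapply(recs, function(r) as.integer(!is.null(r$text)), 1L),
    stringsAsFactors = FALSE
  )
  write_table_schema(manifest, file.path(dir, "manifest.tsv"),
                     c(id = "string", sequence = "integer",
                       structure = "integer", tokens = "integer",
                       pocket = "integer", text = "integer"))
  invisible(dir)
}
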