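#' @keywords internal
"_PACKAGE"

# Amino-acid alphabet used throughout (standard 20 letters).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"

#' Derive a child seed from a base seed
#'
#' Expands one user-facing seed into independent per-component seeds so a
#' single integer reproduces a whole pipeline. Kept below 2^31 - 1.
#'
#' @param seed base integer seed.
#' @param tag character tag naming the consumer.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587L + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Row-wise softmax with -Inf support; numerically stabilised.
row_softmax <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E[is.na(E)] <- 0 # rows that are all -Inf
  E / pmax(rowSums(E), .Machine$double.eps)
}

softmax_vec <- function(x) {
  m <- max(x)
  e <- exp(x - m)
  e / sum(e)
}

#' L2-normalize a vector or the rows of a matrix
#'
#' @param v numeric vector, or matrix whose rows are normalized.
#' @return unit-norm vector/matrix (Euclidean norm 1 per row).
#' @export
l2_normalize <- function(v) {
  if (is.matrix(v)) {
    nrm <- sqrt(rowSums(v^2))
    if (any(nrm == 0)) stop("cannot normalize a zero vector (undefined direction)")
    return(v / nrm)
  }
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("cannot normalize a zero vector (undefined direction)")
  v / nrm
}

cosine_sim <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))

# map a function over two parallel nested lists of numeric arrays
tree_map2 <- function(x, y, f) {
  if (is.null(x)) return(NULL)
  if (is.list(x)) {
    out <- x
    for (k in seq_along(x)) out[[k]] <- tree_map2(x[[k]], y[[k]], f)
    return(out)
  }
  f(x, y)
}

tree_map <- function(x, f) {
  if (is.null(x)) return(NULL)
  if (is.list(x)) {
    out <- x
    for (k in seq_along(x)) out[[k]] <- tree_map(x[[k]], f)
    return(out)
  }
  f(x)
}

# sum of all elements across a nested numeric list (used for checksums)
tree_checksum <- function(x) {
  s <- 0
  walk <- function(v) {
    if (is.list(v)) lapply(v, walk) else s <<- s + sum(as.numeric(v))
    invisible(NULL)
  }
  walk(x)
  s
}

zeros_like <- function(x) tree_map(x, function(a) {
  a[] <- 0
  a
})

# Gaussian radial basis expansion of distances (edge featurisation)
rbf_expand <- function(d, centers, width) {
  outer(d, centers, function(x, c) exp(-((x - c)^2) / (2 * width^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
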