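# Protein graph construction with invariant geometric features.

AA3_TO_IDX <- stats::setNames(seq_along(AA_ALPHABET),
                              c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY",
                                "HIS", "ILE", "LYS", "LEU", "MET", "ASN",
                                "PRO", "GLN", "ARG", "SER", "THR", "VAL",
                                "TRP", "TYR"))

# side-chain torsion atom quadruples (chi1..chi4)
CHI_ATOMS <- list(c("N", "CA", "CB", "CG"),
                  c("CA", "CB", "CG", "CD"),
                  c("CB", "CG", "CD", "CE"),
                  c("CG", "CD", "CE", "CZ"))

#' Build a residue-level protein graph
#'
#' Nodes are residues (each must carry a CA atom); an undirected edge links
#' residues whose CA-CA distance is at most `cutoff`. Geometric features are
#' all rigid-motion invariant: an RBF expansion of the edge distance, Euler
#' angles between the residue frames of the endpoints (backbone level and
#' up), and side-chain torsion angles chi1..chi4 of the source residue
#' (all-atom level). Residues with insufficient atoms get validity flags
#' FALSE and zeroed angle features rather than fabricated values.
#'
#' @param structure minimal structure data.frame (see [read_pdb_min()]).
#' @param cutoff edge cutoff radius in Angstrom.
#' @param level one of "amino_acid", "backbone", "all_atom".
#' @return a `protein_graph` list: n, aa_idx, pos (n x 3), edges (m x 2
#'   directed pairs), geom (m x g invariant feature matrix), level, cutoff.
#' @export
build_protein_graph <- function(structure, cutoff = 10,
                                level = c("all_atom", "backbone",
                                          "amino_acid")) {
  level <- match.arg(level)
  res_ids <- sort(unique(structure$res_index))
  n <- length(res_ids)
  if (n < 2) stop("graph needs at least 2 residues")
  P <- ca_trace(structure)
  if (nrow(P) != n) stop("every residue needs a CA atom")
  aa_idx <- vapply(res_ids, function(ri) {
    nm <- structure$res_name[structure$res_index == ri][1]
    idx <- AA3_TO_IDX[nm]
    if (is.na(idx)) 21L else as.integer(idx)
  }, 1L)

  D <- as.matrix(stats::dist(P))
  adj <- D <= cutoff & upper.tri(D)
  und <- which(adj, arr.ind = TRUE)
  edges <- rbind(und, und[, 2:1, drop = FALSE])
  colnames(edges) <- c("src", "dst")
  m <- nrow(edges)
  if (m == 0) {
    return(structure(list(n = n, aa_idx = aa_idx, pos = P,
                          edges = matrix(integer(0), 0, 2),
                          geom = matrix(0, 0, geom_width(level)),
                          level = level, cutoff = cutoff),
                     class = "protein_graph"))
  }

  # residue frames: (N, CA, C) when available, else consecutive CA triples
  frames <- vector("list", n)
  by_res <- split(structure, structure$res_index)
  for (i in seq_len(n)) {
    r <- by_res[[as.character(res_ids[i])]]
    atom_of <- function(a) {
      k <- which(r$atom == a)
      if (length(k) == 0) NULL else as.numeric(r[k[1], c("x", "y", "z")])
    }
    Na <- atom_of("N"); Ca <- atom_of("CA"); Cc <- atom_of("C")
    fr <- NULL
    if (!is.null(Na) && !is.null(Ca) && !is.null(Cc)) {
      fr <- residue_frame(Na, Ca, Cc)
    }
    if (is.null(fr) && i > 1 && i < n) {
      fr <- residue_frame(P[i - 1, ], P[i, ], P[i + 1, ])
    }
    frames[i] <- list(fr) # keep NULL slots (terminal residues)
  }

  # chi torsions per residue (all-atom level)
  chi <- matrix(0, n, 4)
  chi_valid <- matrix(FALSE, n, 4)
  if (level == "all_atom") {
    for (i in seq_len(n)) {
      r <- by_res[[as.character(res_ids[i])]]
      for (k in seq_len(4)) {
        pts <- lapply(CHI_ATOMS[[k]], function(a) {
          j <- which(r$atom == a)
          if (length(j) == 0) NULL else as.numeric(r[j[1], c("x", "y", "z")])
        })
        if (!any(vapply(pts, is.null, TRUE))) {
          dd <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
          if (dd$valid) {
            chi[i, k] <- dd$angle
            chi_valid[i, k] <- TRUE
          }
        }
      }
    }
  }

  rbf_centers <- seq(0, cutoff, length.out = 8)
  dvec <- D[edges]
  G <- rbf_expand(dvec, rbf_centers, cutoff / 8)
  if (level %in% c("backbone", "all_atom")) {
    EU <- matrix(0, m, 6)
    for (e in seq_len(m)) {
      fi <- frames[[edges[e, 1]]]; fj <- frames[[edges[e, 2]]]
      if (!is.null(fi) && !is.null(fj)) {
        tau <- euler_between(fi, fj)
        EU[e, ] <- c(sin(tau), cos(tau))
      }
    }
    G <- cbind(G, EU)
  }
  if (level == "all_atom") {
    CH <- cbind(sin(chi) * chi_valid, cos(chi) * chi_valid)[edges[, 1], ,
                                                           drop = FALSE]
    G <- cbind(G, CH)
  }
  structure(list(n = n, aa_idx = aa_idx, pos = P, edges = edges, geom = G,
                 level = level, cutoff = cutoff),
            class = "protein_graph")
}

geom_width <- function(level) {
  switch(level, amino_acid = 8, backbone = 14, all_atom = 22)
}
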