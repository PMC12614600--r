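# Geometric primitives: signed dihedrals, residue frames, Euler angles,
# and the dihedral-bin structure tokenizer.

#' Signed dihedral angle of four points
#'
#' Standard two-normal atan2 construction with the right-handed sign
#' convention; the angle lies in (-pi, pi]. Degenerate geometry (coincident
#' consecutive points or three collinear points) yields a flagged-invalid
#' result rather than an error.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return list(angle = numeric, valid = logical).
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-10 || sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    return(list(angle = NA_real_, valid = FALSE))
  }
  m1 <- cross(n1, b2 / nb2)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  if (ang <= -pi) ang <- ang + 2 * pi
  list(angle = ang, valid = TRUE)
}

# Orthonormal residue frame. Built from (N, CA, C) when all three atoms are
# present, else from the consecutive CA triple (prev, this, next). Returns a
# 3x3 matrix with rows = frame axes, or NULL when undefined.
residue_frame <- function(ca_prev, ca_this, ca_next) {
  u <- ca_next - ca_this
  v <- ca_prev - ca_this
  nu <- sqrt(sum(u^2))
  if (nu < 1e-10) return(NULL)
  e1 <- u / nu
  w <- v - sum(v * e1) * e1
  nw <- sqrt(sum(w^2))
  if (nw < 1e-10) return(NULL)
  e2 <- w / nw
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  rbind(e1, e2, e3)
}

# ZYZ Euler angles (tau1, tau2, tau3) of the rotation carrying frame A onto
# frame B; both are 3x3 row-axis matrices. Rigid-motion invariant because
# only the relative rotation A %*% t(B) enters.
euler_between <- function(A, B) {
  R <- A %*% t(B)
  # ZYZ extraction
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (abs(sin(beta)) < 1e-8) {
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
  } else {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  }
  c(alpha, beta, gamma)
}

# Extract the CA trace (n x 3 matrix, ordered by residue index) from a
# minimal structure data.frame. Every residue must carry a CA atom.
ca_trace <- function(structure) {
  ca <- structure[structure$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$res_index), , drop = FALSE]
  if (anyDuplicated(ca$res_index)) stop("duplicate CA atom for a residue")
  as.matrix(ca[, c("x", "y", "z")])
}

#' Discretize local backbone geometry into structure tokens
#'
#' Token t is the bin index (1..n_bins) of the pseudo-dihedral defined by
#' CA atoms (t-1, t, t+1, t+2). Terminal residues, where that dihedral is
#' undefined, receive token 1 by convention. Tokens are a deterministic
#' function of the coordinates, so they regenerate exactly from an emitted
#' structure.
#'
#' @param structure minimal structure data.frame (needs CA atoms).
#' @param n_bins token vocabulary size.
#' @return integer vector of tokens, one per residue.
#' @export
tokenize_structure <- function(structure, n_bins = 16) {
  P <- ca_trace(structure)
  n <- nrow(P)
  tok <- rep(1L, n)
  if (n >= 4) {
    for (t in 2:(n - 2)) {
      d <- dihedral(P[t - 1, ], P[t, ], P[t + 1, ], P[t + 2, ])
      if (d$valid) {
        # map (-pi, pi] -> bin 1..n_bins
        b <- floor((d$angle + pi) / (2 * pi) * n_bins) + 1L
        tok[t] <- min(max(b, 1L), n_bins)
      }
    }
  }
  tok
}
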