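# Independent test oracles.  These deliberately avoid the package's
# production code paths (igraph components, sparse propagation, the im2col
# convolution) so that agreement between the two routes is informative.

# Flood-fill count of 8-connected components of a binary matrix.
ff_components <- function(mask) {
  m <- mask != 0
  P <- nrow(m); Q <- ncol(m)
  seen <- matrix(FALSE, P, Q)
  ncomp <- 0L
  for (start in which(m & !seen)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0L) {
      k <- queue[[1L]]; queue <- queue[-1L]
      i <- (k - 1L) %% P + 1L
      j <- (k - 1L) %/% P + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > P || jj < 1 || jj > Q) next
        if (m[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue <- c(queue, (jj - 1L) * P + ii)
        }
      }
    }
  }
  ncomp
}

# O(N^2) brute-force 8-connectivity edge enumeration over all pixel pairs.
# Returns an M x 2 matrix of 0-based row-major node ids (lo < hi), sorted.
brute_edges <- function(mask) {
  m <- mask != 0
  P <- nrow(m); Q <- ncol(m)
  ids <- which(m)  # column-major 1-based
  coord <- cbind((ids - 1L) %% P + 1L, (ids - 1L) %/% P + 1L)
  out <- matrix(integer(0), 0L, 2L)
  n <- nrow(coord)
  if (n >= 2L) {
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      di <- abs(coord[a, 1L] - coord[b, 1L])
      dj <- abs(coord[a, 2L] - coord[b, 2L])
      if (di <= 1L && dj <= 1L) {
        na <- (coord[a, 1L] - 1L) * Q + (coord[a, 2L] - 1L)
        nb <- (coord[b, 1L] - 1L) * Q + (coord[b, 2L] - 1L)
        out <- rbind(out, c(min(na, nb), max(na, nb)))
      }
    }
  }
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

# Dense spectral Chebyshev oracle: eigendecompose the rescaled Laplacian and
# apply the polynomial filter in the spectral domain, U g(Lambda) U^T X.
cheb_spectral_oracle <- function(X, A, theta_k, lambda_max = 2) {
  A <- as.matrix(A)
  N <- nrow(A)
  d <- rowSums(A)
  dis <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(N) - diag(dis) %*% A %*% diag(dis)
  L_hat <- (2 / lambda_max) * L - diag(N)
  eg <- eigen(L_hat, symmetric = TRUE)
  U <- eg$vectors
  lam <- eg$values
  K <- length(theta_k) - 1L
  # Chebyshev polynomials of the eigenvalues, scalar recurrence
  Tk <- matrix(0, N, K + 1L)
  Tk[, 1L] <- 1
  if (K >= 1L) Tk[, 2L] <- lam
  if (K >= 2L) for (k in 2:K) Tk[, k + 1L] <- 2 * lam * Tk[, k] - Tk[, k - 1L]
  Y <- matrix(0, N, ncol(theta_k[[1L]]))
  for (k in 0:K) {
    Mk <- U %*% (Tk[, k + 1L] * t(U))   # U diag(T_k(lam)) U^T
    Y <- Y + Mk %*% X %*% theta_k[[k + 1L]]
  }
  Y
}

# Random sparse symmetric adjacency on n nodes (zero diagonal).
random_adjacency <- function(n, p = 0.25) {
  Au <- matrix(stats::runif(n * n) < p, n, n)
  Au[lower.tri(Au, diag = TRUE)] <- FALSE
  Ad <- Au | t(Au)
  methods::as(Matrix::Matrix(Ad * 1, sparse = TRUE), "generalMatrix")
}

# Random connected adjacency: chain backbone plus random extras.
random_connected_adjacency <- function(n, p = 0.2) {
  A <- as.matrix(random_adjacency(n, p))
  for (i in seq_len(n - 1L)) A[i, i + 1L] <- A[i + 1L, i] <- 1
  methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix")
}

# Tiny planted two-blob labeled graph for learning-sanity tests: two
# rectangles of vessel pixels (artery and vein) on a small canvas with
# class-separable node features.
planted_two_class_graph <- function(P = 16L, Q = 16L, n_feat = 8L,
                                    noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  labels <- matrix(vesseltopo:::LBL_BACKGROUND, P, Q)
  labels[3:6, 2:14] <- vesseltopo:::LBL_ARTERY
  labels[10:13, 2:14] <- vesseltopo:::LBL_VEIN
  mask <- labels != vesseltopo:::LBL_BACKGROUND
  means <- rbind(
    background = rep(0, n_feat),
    artery = c(rep(2, n_feat %/% 2), rep(0, n_feat - n_feat %/% 2)),
    crossing = rep(1, n_feat),
    vein = c(rep(0, n_feat %/% 2), rep(2, n_feat - n_feat %/% 2))
  )
  labv <- as.integer(vesseltopo:::rm_flatten(labels))
  X <- means[labv + 1L, , drop = FALSE] +
    matrix(stats::rnorm(P * Q * n_feat, 0, noise_sd), P * Q, n_feat)
  feats <- array(0, c(P, Q, n_feat))
  for (k in seq_len(n_feat)) feats[, , k] <- vesseltopo:::rm_unflatten(X[, k], P, Q)
  build_vessel_graph(feats = feats, image = NULL, mask = mask,
                     labels = labels, feature_mode = "cnn")
}

# Vectorized variant of the brute-force oracle for larger sweeps: still
# tests every pixel pair for 8-adjacency and joint foreground membership,
# via outer differences instead of an explicit double loop.
brute_edges_vec <- function(mask) {
  m <- mask != 0
  P <- nrow(m); Q <- ncol(m)
  ids <- which(m)
  n <- length(ids)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  r <- (ids - 1L) %% P + 1L
  cc <- (ids - 1L) %/% P + 1L
  nid <- (r - 1L) * Q + (cc - 1L)
  dr <- abs(outer(r, r, "-"))
  dc <- abs(outer(cc, cc, "-"))
  adj <- dr <= 1L & dc <= 1L & upper.tri(dr)
  idx <- which(adj, arr.ind = TRUE)
  e <- cbind(pmin(nid[idx[, 1L]], nid[idx[, 2L]]),
             pmax(nid[idx[, 1L]], nid[idx[, 2L]]))
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}
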