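#' Binarize a class-probability map into a vessel mask
#'
#' A pixel is foreground iff its argmax class is any vessel class (artery,
#' crossing/unknown, or vein), i.e. the argmax is not background.  Ties at
#' the argmax are broken toward the lowest class index, so an exact tie with
#' background yields background.
#'
#' @param probs `P x Q x 4` probability array (classes ordered background,
#'   artery, crossing/unknown, vein).
#' @return logical `P x Q` matrix.
#' @export
binarize <- function(probs) {
  d <- dim(probs)
  if (length(d) != 3L) stop("probs must be a P x Q x CL array")
  m <- matrix(probs, d[1L] * d[2L], d[3L])
  am <- max.col(m, ties.method = "first")
  matrix(am != 1L, d[1L], d[2L])
}

#' Dilate a binary mask with a disk structuring element
#'
#' The structuring element is the lattice Euclidean ball
#' `{(di, dj) : di^2 + dj^2 <= r^2}`; `r = 0` is the identity and the output
#' always contains the input.
#'
#' @param mask binary matrix.
#' @param r integer radius >= 0.
#' @return logical matrix of the same shape.
#' @export
dilate <- function(mask, r) {
  if (length(r) != 1L || !is.finite(r) || r < 0) {
    stop("dilation radius r must be a single integer >= 0")
  }
  if (r != round(r)) stop("dilation radius r must be an integer")
  m <- mask != 0
  if (r == 0) return(m)
  out <- m
  offs <- disk_offsets(r)
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    if (di == 0L && dj == 0L) next
    out <- out | shift_mask(m, di, dj)
  }
  out
}

#' Build 8-connectivity edges among foreground pixels
#'
#' Every pixel of the `P x Q` raster is a node (row-major, 0-based ids:
#' `id = (row - 1) * Q + (col - 1)`).  An undirected edge joins two pixels
#' iff they are 8-neighbours and both are foreground; background pixels stay
#' isolated nodes.
#'
#' @param mask binary `P x Q` matrix.
#' @return list with `edges` (`M x 2` integer matrix of 0-based node ids,
#'   first column < second column), `A` (sparse symmetric 0/1 adjacency with
#'   zero diagonal, `Matrix` package), and `n_nodes`.
#' @export
build_edges <- function(mask) {
  P <- nrow(mask); Q <- ncol(mask)
  if (is.null(P) || P == 0L || Q == 0L) stop("empty raster: mask has no pixels")
  m <- mask != 0
  id <- matrix(seq_len(P * Q) - 1L, P, Q, byrow = TRUE)  # row-major 0-based
  from <- integer(0); to <- integer(0)
  # four forward directions cover each undirected 8-neighbour pair once
  for (off in list(c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))) {
    di <- off[1L]; dj <- off[2L]
    i0 <- max(1L, 1L - di); i1 <- min(P, P - di)
    j0 <- max(1L, 1L - dj); j1 <- min(Q, Q - dj)
    if (i0 > i1 || j0 > j1) next
    a <- m[i0:i1, j0:j1, drop = FALSE]
    b <- m[(i0 + di):(i1 + di), (j0 + dj):(j1 + dj), drop = FALSE]
    hit <- which(a & b)
    if (length(hit) == 0L) next
    ia <- id[i0:i1, j0:j1, drop = FALSE]
    ib <- id[(i0 + di):(i1 + di), (j0 + dj):(j1 + dj), drop = FALSE]
    from <- c(from, ia[hit]); to <- c(to, ib[hit])
  }
  lo <- pmin(from, to); hi <- pmax(from, to)
  o <- order(lo, hi)
  edges <- cbind(lo, hi)[o, , drop = FALSE]
  dimnames(edges) <- NULL
  N <- P * Q
  if (nrow(edges) > 0L) {
    A <- Matrix::sparseMatrix(i = edges[, 1L] + 1L, j = edges[, 2L] + 1L,
                              x = 1, dims = c(N, N), symmetric = TRUE)
    A <- methods::as(A, "generalMatrix")
  } else {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(N, N))
  }
  list(edges = edges, A = A, n_nodes = N)
}

#' Assemble node features from CNN features and image channels
#'
#' Node `k` (row-major pixel order) gets the concatenation of that pixel's
#' CNN feature vector and its image channels (`mode = "cnn+rgb"`, width
#' `H + CH`), or the respective subset (`"cnn"` / `"rgb"`).  No spatial
#' resampling is performed.
#'
#' @param feats `P x Q x H` CNN feature array (may be NULL for mode "rgb").
#' @param image `P x Q x CH` image array (may be NULL for mode "cnn").
#' @param mode one of `"cnn+rgb"`, `"cnn"`, `"rgb"`.
#' @return `N x C` numeric matrix, `N = P * Q`.
#' @export
assemble_features <- function(feats, image, mode = c("cnn+rgb", "cnn", "rgb")) {
  mode <- match.arg(mode)
  parts <- list()
  if (mode %in% c("cnn+rgb", "cnn")) {
    if (is.null(feats)) stop("feats is required for mode ", mode)
    parts$cnn <- rm_flatten(feats)
  }
  if (mode %in% c("cnn+rgb", "rgb")) {
    if (is.null(image)) stop("image is required for mode ", mode)
    parts$rgb <- rm_flatten(image)
  }
  if (length(parts) == 2L && nrow(parts$cnn) != nrow(parts$rgb)) {
    stop("feats and image must share the same P x Q canvas")
  }
  do.call(cbind, unname(parts))
}

#' Symmetric renormalized propagation matrix
#'
#' Adds self-loops and rescales: `A_hat = A + I`, `D_hat_ii = sum_j
#' A_hat_ij`, `S = D_hat^(-1/2) A_hat D_hat^(-1/2)`.  All eigenvalues of `S`
#' lie in `[-1, 1]`; an isolated node has `S[i, i] = 1` and no off-diagonal
#' entries.
#'
#' @param A sparse symmetric adjacency with zero diagonal.
#' @return list of class `normalized_adjacency` with `S` (sparse), `d_hat`
#'   (degree vector of `A_hat`), and `n_nodes`.
#' @export
normalize_adjacency <- function(A) {
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  if (!Matrix::isSymmetric(A)) stop("adjacency matrix must be symmetric")
  if (any(Matrix::diag(A) != 0)) stop("adjacency matrix must have a zero diagonal")
  N <- nrow(A)
  A_hat <- A + Matrix::Diagonal(N)
  d_hat <- Matrix::rowSums(A_hat)
  Dis <- Matrix::Diagonal(N, 1 / sqrt(d_hat))
  S <- Dis %*% A_hat %*% Dis
  structure(list(S = methods::as(S, "generalMatrix"), d_hat = d_hat,
                 n_nodes = N),
            class = "normalized_adjacency")
}

#' Build the topology-preserving vessel graph for one image
#'
#' Combines the stages: binarize the CNN probability map (unless a mask is
#' supplied), optionally dilate it with a disk of radius `dilation_r`,
#' create 8-connectivity edges among foreground pixels, and assemble node
#' features from the CNN feature map and the image channels.  Background
#' pixels are kept as isolated nodes by default; `keep_isolated = FALSE`
#' drops them and reindexes (ablation variant).  Labels for dilated-but-
#' background pixels remain whatever the ground truth says (typically
#' background): features and labels are read from the pixel-aligned rasters.
#'
#' @param feats `P x Q x H` CNN features (NULL allowed for mode "rgb").
#' @param image `P x Q x 3` image.
#' @param probs CNN probability map (used when `mask` is NULL).
#' @param mask optional binary vessel mask overriding `binarize(probs)`.
#' @param labels optional `P x Q` integer ground-truth label matrix.
#' @param dilation_r disk dilation radius applied to the mask before edge
#'   construction.
#' @param feature_mode one of `"cnn+rgb"`, `"cnn"`, `"rgb"`.
#' @param keep_isolated keep background pixels as isolated nodes (default).
#' @return list of class `vessel_graph`: `N`, `X`, `edges`, `A`, `y`
#'   (or NULL), `index_map` (0-based pixel id per node), `P`, `Q`, `mask`
#'   (the possibly dilated mask), `feature_mode`, `keep_isolated`.
#' @export
build_vessel_graph <- function(feats, image, probs = NULL, mask = NULL,
                               labels = NULL, dilation_r = 0L,
                               feature_mode = "cnn+rgb",
                               keep_isolated = TRUE) {
  if (is.null(mask)) {
    if (is.null(probs)) stop("either probs or mask must be supplied")
    mask <- binarize(probs)
  }
  mask <- dilate(mask, dilation_r)
  P <- nrow(mask); Q <- ncol(mask)
  eg <- build_edges(mask)
  X <- assemble_features(feats, image, feature_mode)
  if (nrow(X) != P * Q) stop("feature rasters do not match the mask canvas")
  y <- if (!is.null(labels)) as.integer(rm_flatten(labels)) else NULL
  edges <- eg$edges
  A <- eg$A
  index_map <- seq_len(P * Q) - 1L
  if (!keep_isolated) {
    keep <- which(rm_flatten(mask))            # 1-based node ids of foreground
    remap <- integer(P * Q); remap[keep] <- seq_along(keep)
    X <- X[keep, , drop = FALSE]
    if (!is.null(y)) y <- y[keep]
    edges <- cbind(remap[edges[, 1L] + 1L] - 1L, remap[edges[, 2L] + 1L] - 1L)
    dimnames(edges) <- NULL
    A <- A[keep, keep, drop = FALSE]
    index_map <- keep - 1L
  }
  structure(list(
    N = nrow(X), X = X, edges = edges, A = A, y = y,
    index_map = index_map, P = P, Q = Q, mask = mask,
    feature_mode = feature_mode, keep_isolated = keep_isolated
  ), class = "vessel_graph")
}

#' Write a vessel graph's edge list and arrays to disk
#'
#' The edge list goes to a two-column CSV of 0-based node ids; node
#' features, labels, mask and index metadata go to a compressed serialized
#' container (RDS).
#'
#' @param graph a `vessel_graph`.
#' @param edges_csv path for the edge-list CSV.
#' @param arrays_rds path for the array container.
#' @return invisibly, the paths.
#' @export
write_vessel_graph <- function(graph, edges_csv, arrays_rds) {
  utils::write.csv(data.frame(from = graph$edges[, 1L], to = graph$edges[, 2L]),
                   edges_csv, row.names = FALSE)
  saveRDS(graph[c("N", "X", "y", "index_map", "P", "Q", "mask",
                  "feature_mode", "keep_isolated", "edges")],
          arrays_rds, compress = "gzip")
  invisible(c(edges_csv, arrays_rds))
}
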