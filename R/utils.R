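# Internal helpers shared across modules.

# Label codes for the four-class artery/vein scheme.  Probability maps use
# the same ordering along their class dimension (background first).
LBL_BACKGROUND <- 0L
LBL_ARTERY <- 1L
LBL_CROSSING <- 2L
LBL_VEIN <- 3L
N_CLASSES <- 4L

LABEL_NAMES <- c("background", "artery", "crossing_unknown", "vein")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that package functions never leak
#' random state into the caller's session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Shift a logical/numeric P x Q matrix by (di, dj):
# out[i, j] = m[i + di, j + dj], FALSE outside the canvas.
shift_mask <- function(m, di, dj) {
  P <- nrow(m); Q <- ncol(m)
  out <- matrix(FALSE, P, Q)
  i0 <- max(1L, 1L - di); i1 <- min(P, P - di)
  j0 <- max(1L, 1L - dj); j1 <- min(Q, Q - dj)
  if (i0 <= i1 && j0 <= j1) {
    out[i0:i1, j0:j1] <- m[(i0 + di):(i1 + di), (j0 + dj):(j1 + dj)] != 0
  }
  out
}

# Row-wise softmax of a numeric matrix, numerically stabilised.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Softmax over the 3rd dimension of a P x Q x K array.
softmax_channels <- function(a) {
  d <- dim(a)
  m <- matrix(a, d[1L] * d[2L], d[3L])
  array(softmax_rows(m), d)
}

# Row-major (English reading order) pixel <-> node mapping.  Node ids are
# 0-based: id = (row - 1) * Q + (col - 1).
rm_flatten <- function(a) {
  if (length(dim(a)) == 2L) return(as.vector(t(a)))
  d <- dim(a)
  out <- matrix(0, d[1L] * d[2L], d[3L])
  for (k in seq_len(d[3L])) out[, k] <- as.vector(t(a[, , k]))
  out
}

rm_unflatten <- function(v, P, Q) {
  matrix(v, P, Q, byrow = TRUE)
}

# Number of 8-connected components of a binary mask (production path; the
# test suite cross-checks it against an independent flood-fill oracle).
n_components_8 <- function(mask) {
  mask <- mask != 0
  fg <- which(rm_flatten(mask))
  if (length(fg) == 0L) return(0L)
  eg <- build_edges(mask)
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(eg$edges + 1L),
    directed = FALSE,
    vertices = data.frame(name = fg)
  )
  igraph::components(g)$no
}

# Deterministic, dependency-free checksum of a config list for manifests.
config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = 10, force = TRUE))
  b <- utf8ToInt(s)
  h <- sum(b * (seq_along(b) %% 97 + 1)) %% 2147483647
  sprintf("%x-%d", as.integer(h), length(b))
}
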