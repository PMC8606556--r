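#' Parameters for the two-layer graph convolutional classifier
#'
#' The classifier is `softmax(S . relu(S X Theta1) . Theta2)` with dropout
#' on the hidden activations during training.  `S` is the renormalized
#' propagation matrix from [normalize_adjacency()].
#'
#' @param n_features input feature width `C` (e.g. `H + CH`).
#' @param n_hidden hidden width `H'` (default 32).
#' @param n_classes output classes (default 4).
#' @param dropout_rate dropout probability in `[0, 1)` (default 0.5; the
#'   rate is a package choice, applied between the two graph convolutions).
#' @param seed integer seed for Glorot-uniform initialization.
#' @return list of class `gcn_params` with `Theta1`, `Theta2`,
#'   `dropout_rate`.
#' @export
gcn_params <- function(n_features, n_hidden = 32L, n_classes = 4L,
                       dropout_rate = 0.5, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  glorot <- function(fi, fo) {
    lim <- sqrt(6 / (fi + fo))
    matrix(stats::runif(fi * fo, -lim, lim), fi, fo)
  }
  with_seed(seed, {
    structure(list(
      Theta1 = glorot(n_features, n_hidden),
      Theta2 = glorot(n_hidden, n_classes),
      dropout_rate = dropout_rate
    ), class = "gcn_params")
  })
}

#' First-order spectral graph convolution
#'
#' Computes `Y = S X Theta` with sparse propagation, where `S` is the
#' renormalized propagation matrix.  An isolated node's output row is its
#' own feature row times `Theta` (self-loop only).
#'
#' @param X `N x C` node feature matrix.
#' @param S sparse `N x N` propagation matrix (or a `normalized_adjacency`).
#' @param Theta `C x F` filter parameter matrix.
#' @return dense `N x F` matrix.
#' @export
gcn_layer <- function(X, S, Theta) {
  if (inherits(S, "normalized_adjacency")) S <- S$S
  X <- as.matrix(X); Theta <- as.matrix(Theta)
  if (nrow(X) != nrow(S)) stop("X rows must match S dimension")
  if (ncol(X) != nrow(Theta)) stop("Theta rows must match X columns")
  as.matrix(S %*% (X %*% Theta))
}

#' Coefficients for a Chebyshev spectral filter
#'
#' @param theta_k list of `K + 1` coefficient matrices (`C x F` each).
#' @param lambda_max largest Laplacian eigenvalue used for rescaling
#'   (default 2, the standard surrogate).
#' @return list of class `cheb_params` with `K`, `theta_k`, `lambda_max`.
#' @export
cheb_params <- function(theta_k, lambda_max = 2) {
  if (length(theta_k) < 1L) stop("theta_k must contain at least one matrix (K >= 0)")
  structure(list(K = length(theta_k) - 1L, theta_k = theta_k,
                 lambda_max = lambda_max),
            class = "cheb_params")
}

# Symmetric normalized Laplacian L = I - D^(-1/2) A D^(-1/2); zero-degree
# nodes take D^(-1/2) = 0, so L acts as the identity on them.
normalized_laplacian <- function(A) {
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  N <- nrow(A)
  d <- Matrix::rowSums(A)
  dis <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dis <- Matrix::Diagonal(N, dis)
  Matrix::Diagonal(N) - Dis %*% A %*% Dis
}

#' Chebyshev-polynomial spectral graph convolution
#'
#' Computes `sum_{k=0..K} T_k(L_hat) X theta_k` with the recurrence
#' `T_0 = I`, `T_1 = L_hat`, `T_k = 2 L_hat T_{k-1} - T_{k-2}`, where
#' `L_hat = (2 / lambda_max) L - I` and `L` is the symmetric normalized
#' Laplacian.  Zero-degree nodes use a zero inverse square-root degree, so
#' `L` is the identity on them.
#'
#' @param X `N x C` node feature matrix.
#' @param A sparse symmetric adjacency (zero diagonal).
#' @param params a [cheb_params()].
#' @return dense `N x F` matrix.
#' @export
cheb_layer <- function(X, A, params) {
  if (params$K < 0L) stop("Chebyshev order K must be >= 0")
  X <- as.matrix(X)
  L <- normalized_laplacian(A)
  N <- nrow(L)
  L_hat <- (2 / params$lambda_max) * L - Matrix::Diagonal(N)
  Tprev <- X                       # T_0(L_hat) X
  Y <- Tprev %*% params$theta_k[[1L]]
  if (params$K >= 1L) {
    Tcur <- as.matrix(L_hat %*% X) # T_1(L_hat) X
    Y <- Y + Tcur %*% params$theta_k[[2L]]
    if (params$K >= 2L) {
      for (k in 2:params$K) {
        Tnext <- as.matrix(2 * (L_hat %*% Tcur)) - Tprev
        Y <- Y + Tnext %*% params$theta_k[[k + 1L]]
        Tprev <- Tcur; Tcur <- Tnext
      }
    }
  }
  Y
}

#' Check the first-order Chebyshev / single-parameter identity
#'
#' With `theta0 = theta` and `theta1 = -theta`, the K = 1 Chebyshev filter
#' `theta0 x - theta1 D^(-1/2) A D^(-1/2) x` equals the single-parameter
#' form `theta (I + D^(-1/2) A D^(-1/2)) x`.  This verifies the numerical
#' path; pass a different `theta1` to see the identity fail.
#'
#' @param A adjacency with no isolated nodes (`D` must be invertible).
#' @param x `N x C` feature matrix (or vector).
#' @param theta `C x F` matrix (or scalar).
#' @param theta1 second coefficient; defaults to `-theta`.
#' @param tol agreement tolerance.
#' @return TRUE/FALSE.
#' @export
first_order_identity_check <- function(A, x, theta, theta1 = NULL, tol = 1e-10) {
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  d <- Matrix::rowSums(A)
  if (any(d == 0)) {
    stop("graph has isolated nodes: degree matrix D is not invertible")
  }
  x <- as.matrix(x)
  theta <- as.matrix(theta)
  if (is.null(theta1)) theta1 <- -theta else theta1 <- as.matrix(theta1)
  N <- nrow(A)
  Dis <- Matrix::Diagonal(N, 1 / sqrt(d))
  Sn <- Dis %*% A %*% Dis
  lhs <- x %*% theta - as.matrix(Sn %*% x) %*% theta1
  rhs <- (x + as.matrix(Sn %*% x)) %*% theta
  max(abs(lhs - rhs)) < tol
}

#' Two-layer GCN forward pass
#'
#' `relu` after the first graph convolution, dropout (inverted, applied only
#' when `training = TRUE`), a second graph convolution, then per-node
#' softmax.
#'
#' @param X `N x C` node features (or a `vessel_graph`).
#' @param S propagation matrix from [normalize_adjacency()].
#' @param params a [gcn_params()].
#' @param training apply dropout (uses the current RNG state).
#' @param return_logits also return pre-softmax logits.
#' @return `N x n_classes` probability matrix (or a list with `probs`,
#'   `logits` when `return_logits = TRUE`).
#' @export
gcn_forward <- function(X, S, params, training = FALSE, return_logits = FALSE) {
  if (inherits(X, "vessel_graph")) X <- X$X
  if (inherits(S, "normalized_adjacency")) S <- S$S
  H1 <- pmax(gcn_layer(X, S, params$Theta1), 0)
  if (training && params$dropout_rate > 0) {
    keep <- 1 - params$dropout_rate
    mask <- matrix(stats::runif(length(H1)) < keep, nrow(H1), ncol(H1)) / keep
    H1 <- H1 * mask
  }
  logits <- gcn_layer(H1, S, params$Theta2)
  probs <- softmax_rows(logits)
  if (return_logits) list(probs = probs, logits = logits) else probs
}

#' Training configuration for the GCN
#'
#' Defaults follow the published schedule for the public dataset: Adam at
#' initial learning rate 0.003, reduced to 1/100th every 30 epochs, 200
#' epochs, full-graph gradient steps.
#'
#' @param learning_rate initial Adam learning rate.
#' @param lr_decay_factor multiplicative decay (0 < factor <= 1).
#' @param lr_decay_interval epochs between decays.
#' @param total_epochs training epochs (>= 0).
#' @param n_hidden hidden width `H'`.
#' @param dropout_rate dropout probability.
#' @param loss_nodes `"all"` (background nodes contribute with their label)
#'   or `"vessel"` (restrict the loss to non-background nodes).
#' @param seed integer seed.
#' @return list of class `gcn_train_config`.
#' @export
gcn_train_config <- function(learning_rate = 0.003, lr_decay_factor = 0.01,
                             lr_decay_interval = 30L, total_epochs = 200L,
                             n_hidden = 32L, dropout_rate = 0.5,
                             loss_nodes = c("all", "vessel"), seed = 1L) {
  if (total_epochs < 0) stop("total_epochs must be >= 0")
  if (lr_decay_factor <= 0 || lr_decay_factor > 1) {
    stop("lr_decay_factor must lie in (0, 1]")
  }
  structure(list(
    learning_rate = learning_rate, lr_decay_factor = lr_decay_factor,
    lr_decay_interval = as.integer(lr_decay_interval),
    total_epochs = as.integer(total_epochs),
    n_hidden = as.integer(n_hidden), dropout_rate = dropout_rate,
    loss_nodes = match.arg(loss_nodes), seed = as.integer(seed)
  ), class = "gcn_train_config")
}

#' Train the two-layer GCN on labeled vessel graphs
#'
#' Minimizes node-wise cross-entropy over the four classes with Adam
#' (beta1 = 0.9, beta2 = 0.999, eps = 1e-8).  One epoch is one full-graph
#' gradient step per training graph, cycled in fixed order.  The learning
#' rate is multiplied by `lr_decay_factor` every `lr_decay_interval` epochs.
#'
#' @param graphs list of `vessel_graph` objects with labels `y` for every
#'   node.
#' @param config a [gcn_train_config()].
#' @param params optional initial [gcn_params()] (otherwise initialized from
#'   `config$seed`).
#' @return list with `params` (trained), `history`
#'   (data.frame: epoch, loss, lr).
#' @export
train_gcn <- function(graphs, config = gcn_train_config(), params = NULL) {
  if (length(graphs) < 1L) stop("at least one training graph is required")
  for (g in graphs) {
    if (is.null(g$y) || length(g$y) != g$N) {
      stop("every training graph must carry labels for all nodes")
    }
  }
  C <- ncol(graphs[[1L]]$X)
  if (is.null(params)) {
    params <- gcn_params(C, config$n_hidden, N_CLASSES,
                         config$dropout_rate, config$seed)
  }
  history <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  if (config$total_epochs == 0L) return(list(params = params, history = history))
  # precompute propagation and S X per graph
  prep <- lapply(graphs, function(g) {
    S <- normalize_adjacency(g$A)$S
    lab <- if (config$loss_nodes == "vessel") which(g$y != LBL_BACKGROUND) else seq_len(g$N)
    if (length(lab) == 0L) stop("no labeled nodes available for the loss")
    list(S = S, SX = as.matrix(S %*% g$X), X = g$X, y = g$y, lab = lab)
  })
  state <- adam_init(params[c("Theta1", "Theta2")])
  th <- params[c("Theta1", "Theta2")]
  keep <- 1 - params$dropout_rate
  with_seed(config$seed, {
    for (ep in seq_len(config$total_epochs)) {
      lr <- config$learning_rate *
        config$lr_decay_factor^((ep - 1L) %/% config$lr_decay_interval)
      losses <- numeric(length(prep))
      for (gi in seq_along(prep)) {
        pg <- prep[[gi]]
        Z1 <- pg$SX %*% th$Theta1
        H1 <- pmax(Z1, 0)
        if (params$dropout_rate > 0) {
          dmask <- matrix(stats::runif(length(H1)) < keep, nrow(H1), ncol(H1)) / keep
          H1d <- H1 * dmask
        } else {
          dmask <- NULL
          H1d <- H1
        }
        Z2 <- as.matrix(pg$S %*% (H1d %*% th$Theta2))
        probs <- softmax_rows(Z2)
        nl <- length(pg$lab)
        p_true <- pmax(probs[cbind(pg$lab, pg$y[pg$lab] + 1L)], 1e-12)
        loss <- -mean(log(p_true))
        if (!is.finite(loss)) {
          stop("non-finite GCN loss at epoch ", ep, ", graph ", gi)
        }
        losses[gi] <- loss
        dZ2 <- probs
        dZ2[cbind(pg$lab, pg$y[pg$lab] + 1L)] <-
          dZ2[cbind(pg$lab, pg$y[pg$lab] + 1L)] - 1
        if (nl < nrow(dZ2)) {
          zero_rows <- setdiff(seq_len(nrow(dZ2)), pg$lab)
          dZ2[zero_rows, ] <- 0
        }
        dZ2 <- dZ2 / nl
        SdZ2 <- as.matrix(pg$S %*% dZ2)
        gTheta2 <- crossprod(H1d, SdZ2)
        dH1 <- tcrossprod(SdZ2, th$Theta2)
        if (!is.null(dmask)) dH1 <- dH1 * dmask
        dZ1 <- dH1 * (Z1 > 0)
        gTheta1 <- crossprod(pg$SX, dZ1)
        upd <- adam_step(th, list(Theta1 = gTheta1, Theta2 = gTheta2), state, lr)
        th <- upd$params; state <- upd$state
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = mean(losses), lr = lr))
    }
  })
  params$Theta1 <- th$Theta1
  params$Theta2 <- th$Theta2
  list(params = params, history = history)
}

#' Predict node class probabilities for a vessel graph
#'
#' Deterministic inference (dropout off).
#'
#' @param graph a `vessel_graph`.
#' @param params trained [gcn_params()].
#' @return `N x 4` probability matrix.
#' @export
gcn_predict <- function(graph, params) {
  S <- normalize_adjacency(graph$A)$S
  gcn_forward(graph$X, S, params, training = FALSE)
}
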