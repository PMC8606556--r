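test_that("gcn_layer matches hand examples and the dense oracle", {
  # single isolated node: y = x Theta
  A1 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(1, 1))
  S1 <- normalize_adjacency(A1)
  x <- matrix(c(2, -1), 1, 2)
  Th <- matrix(c(1, 0, 2, 1, 1, 3), 2, 3)
  expect_equal(gcn_layer(x, S1, Th), x %*% Th)
  # two-node complete graph with identity filter averages the rows
  A2 <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(2, 2), symmetric = TRUE)
  S2 <- normalize_adjacency(A2)
  X2 <- matrix(c(1, 3, 2, 6), 2, 2)
  Y2 <- gcn_layer(X2, S2, diag(2))
  expect_equal(Y2, matrix(colMeans(X2), 2, 2, byrow = TRUE))
  # random graphs vs dense S X Theta
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:32, 1)
    A <- random_adjacency(n)
    S <- normalize_adjacency(A)
    X <- matrix(rnorm(n * 4), n, 4)
    Th <- matrix(rnorm(4 * 3), 4, 3)
    dense <- as.matrix(S$S) %*% X %*% Th
    expect_lt(max(abs(gcn_layer(X, S, Th) - dense)), 1e-10)
  }
  expect_error(gcn_layer(matrix(0, 3, 2), S2, Th), "match S dimension")
})

test_that("cheb_layer matches closed forms and the eigendecomposition oracle", {
  set.seed(17)
  n <- 10
  A <- random_adjacency(n)
  X <- matrix(rnorm(n * 3), n, 3)
  th0 <- matrix(rnorm(6), 3, 2)
  # K = 0: Y = X theta0
  expect_equal(cheb_layer(X, A, cheb_params(list(th0))), X %*% th0)
  # K = 1, lambda_max = 2: Y = X theta0 + (L - I) X theta1
  th1 <- matrix(rnorm(6), 3, 2)
  L <- as.matrix(vesseltopo:::normalized_laplacian(A))
  manual <- X %*% th0 + (L - diag(n)) %*% X %*% th1
  expect_lt(max(abs(cheb_layer(X, A, cheb_params(list(th0, th1))) - manual)), 1e-12)
  # K = 3 vs spectral oracle on random graphs (including isolated nodes)
  for (rep in 1:8) {
    m <- sample(6:20, 1)
    Am <- random_adjacency(m, runif(1, 0.1, 0.4))
    Xm <- matrix(rnorm(m * 3), m, 3)
    tk <- lapply(1:4, function(i) matrix(rnorm(6), 3, 2))
    got <- cheb_layer(Xm, Am, cheb_params(tk))
    want <- cheb_spectral_oracle(Xm, Am, tk)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("the single-parameter first-order identity holds (and fails on a sign flip)", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(4:16, 1)
    A <- random_connected_adjacency(n)
    x <- matrix(rnorm(n * 2), n, 2)
    th <- matrix(rnorm(2 * 3), 2, 3)
    expect_true(first_order_identity_check(A, x, th))
    expect_true(first_order_identity_check(A, x, th * 0))    # both sides zero
    expect_false(first_order_identity_check(A, x, th, theta1 = th))
  }
  iso <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(3, 3), symmetric = TRUE)
  expect_error(first_order_identity_check(iso, matrix(0, 3, 1), matrix(1)),
               "isolated nodes")
})

test_that("forward: zero filters give uniform probabilities; inference deterministic; 67-32-4 dims", {
  set.seed(41)
  n <- 30
  A <- random_adjacency(n)
  S <- normalize_adjacency(A)
  X <- matrix(rnorm(n * 67), n, 67)
  p <- gcn_params(67, 32, 4, seed = 2)
  expect_identical(dim(p$Theta1), c(67L, 32L))
  expect_identical(dim(p$Theta2), c(32L, 4L))
  pz <- p; pz$Theta1[] <- 0; pz$Theta2[] <- 0
  out <- gcn_forward(X, S, pz)
  expect_equal(out, matrix(0.25, n, 4))
  expect_identical(gcn_forward(X, S, p), gcn_forward(X, S, p))
})

test_that("forward is permutation-equivariant", {
  set.seed(53)
  n <- 18
  A <- random_adjacency(n)
  S <- normalize_adjacency(A)$S
  X <- matrix(rnorm(n * 5), n, 5)
  p <- gcn_params(5, 7, 4, seed = 9)
  out <- gcn_forward(X, S, p)
  perm <- sample(n)
  Sp <- S[perm, perm]
  outp <- gcn_forward(X[perm, ], Sp, p)
  expect_lt(max(abs(outp - out[perm, ])), 1e-8)
})

test_that("averaged training-mode logits converge to inference logits", {
  set.seed(61)
  n <- 12
  A <- random_adjacency(n)
  S <- normalize_adjacency(A)$S
  X <- matrix(rnorm(n * 4), n, 4)
  p <- gcn_params(4, 6, 4, dropout_rate = 0.5, seed = 13)
  ref <- gcn_forward(X, S, p, return_logits = TRUE)$logits
  acc <- 0
  R <- 1500
  for (i in seq_len(R)) {
    acc <- acc + gcn_forward(X, S, p, training = TRUE, return_logits = TRUE)$logits
  }
  # dropout is inverted, so logits are unbiased; allow Monte-Carlo error
  expect_lt(max(abs(acc / R - ref)), 0.15 * max(abs(ref)) + 0.05)
})

test_that("train_gcn: zero epochs is the identity and the decay schedule is honoured", {
  g <- planted_two_class_graph(seed = 2)
  cfg0 <- gcn_train_config(total_epochs = 0, seed = 4)
  fit0 <- train_gcn(list(g), cfg0)
  expect_identical(fit0$params, gcn_params(ncol(g$X), cfg0$n_hidden, 4L,
                                           cfg0$dropout_rate, cfg0$seed))
  cfg <- gcn_train_config(total_epochs = 8, lr_decay_interval = 3,
                          lr_decay_factor = 0.5, learning_rate = 0.003, seed = 4)
  fit <- train_gcn(list(g), cfg)
  expect_equal(fit$history$lr, 0.003 * c(1, 1, 1, 0.5, 0.5, 0.5, 0.25, 0.25))
  gu <- g; gu$y <- NULL
  expect_error(train_gcn(list(gu)), "labels for all nodes")
})

test_that("train_gcn separates a planted two-class graph", {
  g <- planted_two_class_graph(seed = 7)
  cfg <- gcn_train_config(learning_rate = 0.01, lr_decay_factor = 0.1,
                          lr_decay_interval = 60, total_epochs = 100, seed = 5)
  fit <- train_gcn(list(g), cfg)
  probs <- gcn_predict(g, fit$params)
  acc <- mean(max.col(probs) - 1L == g$y)
  expect_gte(acc, 0.99)
})
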