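test_that("binarize uses the argmax-not-background rule with first-index ties", {
  probs <- array(0, c(2, 2, 4))
  probs[1, 1, ] <- c(0.7, 0.1, 0.1, 0.1)   # background
  probs[1, 2, ] <- c(0.1, 0.6, 0.2, 0.1)   # artery -> foreground
  probs[2, 1, ] <- c(0.25, 0.25, 0.25, 0.25)  # tie -> lowest index = background
  probs[2, 2, ] <- c(0.1, 0.1, 0.1, 0.7)   # vein -> foreground
  expect_identical(binarize(probs),
                   matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  allbg <- array(rep(c(1, 0, 0, 0), each = 9), c(3, 3, 4))
  expect_true(all(!binarize(allbg)))
})

test_that("dilate implements the lattice Euclidean disk", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_identical(dilate(m, 0), m)
  expect_identical(sum(dilate(m, 1)), 5L)    # center + 4-neighbours
  expect_identical(sum(dilate(m, 2)), 13L)
  expect_error(dilate(m, -1), "r must be")
  # monotone in r and always contains the input
  set.seed(42)
  rm <- matrix(runif(15 * 12) < 0.2, 15, 12)
  d1 <- dilate(rm, 1); d2 <- dilate(rm, 2)
  expect_true(all(!rm | d1))
  expect_true(all(!d1 | d2))
})

test_that("build_edges matches hand examples", {
  m <- matrix(FALSE, 2, 2); m[1, 1] <- TRUE; m[1, 2] <- TRUE
  eg <- build_edges(m)
  expect_identical(nrow(eg$edges), 1L)
  expect_identical(eg$edges[1, ], c(0L, 1L))
  # 3x3 all-foreground has 20 undirected edges
  eg3 <- build_edges(matrix(TRUE, 3, 3))
  expect_identical(nrow(eg3$edges), 20L)
  # diagonals count: foreground only at (0,0) and (1,1)
  md <- matrix(FALSE, 2, 2); md[1, 1] <- TRUE; md[2, 2] <- TRUE
  expect_identical(build_edges(md)$edges, cbind(0L, 3L))
  expect_error(build_edges(matrix(logical(0), 0, 0)), "empty raster")
})

test_that("build_edges matches the O(N^2) brute-force oracle on random masks", {
  set.seed(7)
  for (rep in 1:25) {
    P <- sample(3:16, 1); Q <- sample(3:16, 1)
    m <- matrix(runif(P * Q) < runif(1, 0.1, 0.7), P, Q)
    eg <- build_edges(m)
    bo <- brute_edges(m)
    expect_identical(unname(eg$edges), unname(bo))
    # adjacency agrees: symmetric, 2M nonzeros, zero diagonal
    expect_identical(Matrix::nnzero(eg$A), 2L * nrow(eg$edges))
    expect_true(Matrix::isSymmetric(eg$A))
    expect_true(all(Matrix::diag(eg$A) == 0))
    # every background pixel has degree zero
    deg <- Matrix::rowSums(eg$A)
    bg <- which(!vesseltopo:::rm_flatten(m))
    expect_true(all(deg[bg] == 0))
  }
})

test_that("assemble_features concatenates per-pixel features in row-major order", {
  P <- 2L; Q <- 3L; H <- 4L
  feats <- array(seq_len(P * Q * H), c(P, Q, H))
  image <- array(seq_len(P * Q * 3) / 100, c(P, Q, 3L))
  X <- assemble_features(feats, image, "cnn+rgb")
  expect_identical(dim(X), c(P * Q, H + 3L))
  expect_identical(ncol(assemble_features(feats, NULL, "cnn")), H)
  expect_identical(ncol(assemble_features(NULL, image, "rgb")), 3L)
  # node 0 is pixel (1,1); node 1 is pixel (1,2) under row-major ids
  expect_equal(X[1, ], c(feats[1, 1, ], image[1, 1, ]))
  expect_equal(X[2, ], c(feats[1, 2, ], image[1, 2, ]))
  expect_equal(X[Q + 1, ], c(feats[2, 1, ], image[2, 1, ]))
  expect_error(assemble_features(feats, array(0, c(5, 5, 3)), "cnn+rgb"),
               "share the same")
})

test_that("normalize_adjacency matches hand computations", {
  A1 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(1, 1))
  expect_equal(as.matrix(normalize_adjacency(A1)$S), matrix(1, 1, 1))
  A2 <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(2, 2),
                             symmetric = TRUE)
  expect_equal(as.matrix(normalize_adjacency(A2)$S),
               matrix(0.5, 2, 2))
  # 3-node path 0-1-2: D_hat = diag(2, 3, 2)
  A3 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 3), x = 1, dims = c(3, 3),
                             symmetric = TRUE)
  S3 <- as.matrix(normalize_adjacency(A3)$S)
  expect_equal(S3[1, 1], 1 / 2)
  expect_equal(S3[2, 2], 1 / 3)
  expect_equal(S3[1, 2], 1 / sqrt(6))
  expect_equal(S3[1, 3], 0)
  asym <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(2, 2))
  expect_error(normalize_adjacency(asym), "symmetric")
})

test_that("propagation matrix is symmetric with spectrum in [-1, 1]; isolated nodes self-loop", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(2:32, 1)
    A <- random_adjacency(n, runif(1, 0.05, 0.5))
    na <- normalize_adjacency(A)
    S <- as.matrix(na$S)
    expect_true(isSymmetric(S, tol = 1e-12))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-10)
    iso <- which(Matrix::rowSums(A) == 0)
    for (i in iso) {
      expect_equal(S[i, i], 1)
      expect_true(all(S[i, -i] == 0))
    }
  }
})

test_that("build_vessel_graph assembles nodes, labels and masks consistently", {
  li <- generate_labeled_image(synth_config(height = 32, width = 32,
                                            trees_per_class = 1, seed = 3))
  feats <- array(rnorm(32 * 32 * 5), c(32, 32, 5))
  g <- build_vessel_graph(feats, li$image, mask = li$labels != 0L,
                          labels = li$labels)
  expect_s3_class(g, "vessel_graph")
  expect_identical(g$N, 32L * 32L)
  expect_identical(ncol(g$X), 8L)
  expect_identical(g$y, as.integer(vesseltopo:::rm_flatten(li$labels)))
  # dropping isolated nodes keeps exactly the foreground pixels
  g2 <- build_vessel_graph(feats, li$image, mask = li$labels != 0L,
                           labels = li$labels, keep_isolated = FALSE)
  expect_identical(g2$N, sum(li$labels != 0L))
  expect_true(all(g2$y != 0L))
  expect_identical(nrow(g2$edges), nrow(g$edges))
  # edge endpoints remain valid after reindexing
  expect_true(all(g2$edges >= 0 & g2$edges < g2$N))
  # index_map points back to the original row-major pixel ids
  full_y <- as.integer(vesseltopo:::rm_flatten(li$labels))
  expect_identical(full_y[g2$index_map + 1L], g2$y)
})

test_that("dilated graphs read features from the same rasters", {
  li <- generate_labeled_image(synth_config(height = 32, width = 32,
                                            trees_per_class = 1, seed = 4))
  feats <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
  g0 <- build_vessel_graph(feats, li$image, mask = li$labels != 0L,
                           labels = li$labels, dilation_r = 0)
  g1 <- build_vessel_graph(feats, li$image, mask = li$labels != 0L,
                           labels = li$labels, dilation_r = 1)
  expect_gte(nrow(g1$edges), nrow(g0$edges))
  expect_identical(g0$X, g1$X)  # features are pixel-aligned, mask-independent
})
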