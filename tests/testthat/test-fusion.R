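mk_probs <- function(P, Q, seed) {
  set.seed(seed)
  a <- array(runif(P * Q * 4), c(P, Q, 4))
  s <- apply(a, c(1, 2), sum)
  for (k in 1:4) a[, , k] <- a[, , k] / s
  a
}

test_that("agreement fusion follows the voting rule", {
  cnn <- array(0, c(1, 2, 4)); gcn <- matrix(0, 2, 4)
  # pixel 1: both argmax artery -> artery
  cnn[1, 1, ] <- c(0.1, 0.6, 0.2, 0.1); gcn[1, ] <- c(0.2, 0.5, 0.2, 0.1)
  # pixel 2: CNN artery, GCN vein -> disagreement -> background
  cnn[1, 2, ] <- c(0.1, 0.6, 0.2, 0.1); gcn[2, ] <- c(0.1, 0.2, 0.2, 0.5)
  fused <- fuse_agreement(cnn, gcn)
  expect_identical(fused, matrix(c(1L, 0L), 1, 2))
  # identical inputs agree everywhere
  p <- mk_probs(6, 7, 1)
  pm <- matrix(aperm(p, c(2, 1, 3)), 42, 4)
  expect_identical(fuse_agreement(p, pm), vesseltopo:::argmax_labels(p))
  # optional mapping of disagreements to the crossing/unknown class
  fused2 <- fuse_agreement(cnn, gcn, config = fusion_config(
    disagreement = "crossing_unknown"))
  expect_identical(fused2[1, 2], 2L)
})

test_that("agreement fusion equals per-class set intersection (property)", {
  for (seed in 1:20) {
    p1 <- mk_probs(8, 9, seed)
    p2 <- mk_probs(8, 9, seed + 100)
    p2m <- matrix(aperm(p2, c(2, 1, 3)), 72, 4)
    fused <- fuse_agreement(p1, p2m)
    l1 <- vesseltopo:::argmax_labels(p1)
    l2 <- vesseltopo:::argmax_labels(p2)
    for (cls in 0:3) {
      want <- (l1 == cls) & (l2 == cls)
      if (cls == 0L) want <- want | (l1 != l2)  # disagreements land in background
      expect_identical(fused == cls, want)
    }
  }
})

test_that("weighted fusion thresholds convex combinations", {
  # degenerate weights reproduce the thresholded single source
  for (seed in 1:10) {
    p1 <- mk_probs(7, 5, seed)
    p2 <- mk_probs(7, 5, seed + 50)
    p2m <- matrix(aperm(p2, c(2, 1, 3)), 35, 4)
    f_cnn <- fuse_weighted(p1, p2m, config = fusion_config("weighted", 1, 0))
    f_gcn <- fuse_weighted(p1, p2m, config = fusion_config("weighted", 0, 1))
    thresh_lab <- function(p) {
      m <- matrix(aperm(p, c(2, 1, 3)), 35, 4)  # row-major pixel order
      am <- max.col(m, ties.method = "first")
      ifelse(m[cbind(1:35, am)] > 0.5, am - 1L, 0L)
    }
    expect_identical(as.vector(t(f_cnn)), as.integer(thresh_lab(p1)))
    expect_identical(as.vector(t(f_gcn)),
                     as.integer(ifelse(p2m[cbind(1:35, max.col(p2m, "first"))] > 0.5,
                                       max.col(p2m, "first") - 1L, 0L)))
    # convexity: fused class probabilities lie within [min, max] of the sources
    fusedp <- 0.3 * p1 + 0.7 * p2
    expect_true(all(fusedp >= pmin(p1, p2) - 1e-12 & fusedp <= pmax(p1, p2) + 1e-12))
  }
  # arithmetic example: artery 0.6 and 0.5 -> 0.55 > 0.5 -> artery
  cnn <- array(c(0.3, 0.6, 0.05, 0.05), c(1, 1, 4))
  gcn <- matrix(c(0.4, 0.5, 0.05, 0.05), 1, 4)
  expect_identical(fuse_weighted(cnn, gcn,
    config = fusion_config("weighted", 0.5, 0.5))[1, 1], 1L)
  # nothing exceeds the threshold -> background
  cnn0 <- array(0.25, c(1, 1, 4)); gcn0 <- matrix(0.25, 1, 4)
  expect_identical(fuse_weighted(cnn0, gcn0,
    config = fusion_config("weighted", 0.5, 0.5))[1, 1], 0L)
  expect_error(fusion_config("weighted", 0.5, 0.6), "must equal 1")
  expect_error(fusion_config("weighted", -0.2, 1.2), ">= 0")
})

test_that("evaluate_av reproduces the definitional metric formulas", {
  # perfect prediction
  gt <- matrix(c(1L, 3L, 1L, 3L, 0L, 2L), 2, 3)
  mr <- evaluate_av(gt, gt)
  expect_equal(mr$accuracy, 1)
  expect_equal(mr$sensitivity, 1)
  expect_equal(mr$specificity, 1)
  expect_identical(mr$support, 4L)  # crossing and background excluded
  # constructed confusion: TP=90 FN=10 TN=80 FP=20 -> Sen .90 Spe .80 Acc .85
  gt2 <- matrix(c(rep(1L, 100), rep(3L, 100)), 10, 20)
  pred2 <- gt2
  pred2[91:100] <- 0L         # 10 arteries predicted background -> FN
  pred2[101:120] <- 1L        # 20 veins predicted artery -> FP
  mr2 <- evaluate_av(pred2, gt2)
  expect_identical(c(mr2$TP, mr2$FN, mr2$TN, mr2$FP), c(90L, 10L, 80L, 20L))
  expect_equal(mr2$sensitivity, 0.90)
  expect_equal(mr2$specificity, 0.80)
  expect_equal(mr2$accuracy, 0.85)
  # all-vein predictor: sensitivity 0, specificity 1
  pred3 <- matrix(3L, 10, 20)
  mr3 <- evaluate_av(pred3, gt2)
  expect_equal(mr3$sensitivity, 0)
  expect_equal(mr3$specificity, 1)
  # accuracy is the prevalence-weighted convex combination of sen and spe
  prev <- (mr2$TP + mr2$FN) / mr2$support
  expect_equal(mr2$accuracy, prev * mr2$sensitivity + (1 - prev) * mr2$specificity)
  # pred-and-gt support drops unassigned pixels
  mr4 <- evaluate_av(pred2, gt2, eval_set = "pred_and_gt")
  expect_identical(mr4$support, 190L)
  expect_error(evaluate_av(matrix(0L, 2, 2), gt2), "same shape")
})

test_that("topology diagnostics count multi-class segments and fragmentation", {
  gt <- matrix(0L, 9, 20)
  gt[3, 2:19] <- 1L        # one artery segment
  gt[7, 2:19] <- 3L        # one vein segment
  expect_identical(topology_diagnostics(gt, gt),
                   list(multiclass_segment_count = 0L, fragmentation_ratio = 1))
  # half of the artery segment predicted vein -> one multi-class segment
  pred <- gt
  pred[3, 11:19] <- 3L
  td <- topology_diagnostics(pred, gt)
  expect_identical(td$multiclass_segment_count, 1L)
  expect_equal(td$fragmentation_ratio, 1)
  # a gap splitting one component in two doubles the fragmentation ratio
  pred2 <- gt
  pred2[3, 10] <- 0L
  gt1 <- gt; gt1[7, ] <- 0L
  pred2[7, ] <- 0L
  td2 <- topology_diagnostics(pred2, gt1)
  expect_equal(td2$fragmentation_ratio, 2)
})

test_that("node probabilities map back through a partial index_map", {
  # graph with isolated nodes dropped: unmapped pixels become background
  li <- generate_labeled_image(synth_config(height = 32, width = 32,
                                            trees_per_class = 1, seed = 13))
  feats <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  g <- build_vessel_graph(feats, li$image, mask = li$labels != 0L,
                          labels = li$labels, keep_isolated = FALSE)
  p <- gcn_params(ncol(g$X), 6, 4, seed = 3)
  probs <- gcn_predict(g, p)
  expect_identical(dim(probs), c(g$N, 4L))
  ras <- gcn_probs_to_raster(probs, g$index_map, g$P, g$Q)
  # mapped pixels carry the node rows, all others are pure background
  flat <- vesseltopo:::rm_flatten(ras)
  expect_equal(flat[g$index_map + 1L, ], probs)
  off <- setdiff(seq_len(g$P * g$Q), g$index_map + 1L)
  expect_true(all(flat[off, 1L] == 1))
  lab <- vesseltopo:::argmax_labels(ras)
  expect_true(all(lab[!g$mask] == 0L))
})
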