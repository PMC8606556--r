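#' Fusion configuration
#'
#' @param mode `"agreement"` (per-class intersection voting; the proposed
#'   default) or `"weighted"` (convex combination of class probabilities).
#' @param w_cnn,w_gcn non-negative weights; in weighted mode they must sum
#'   to 1.
#' @param threshold probability threshold for asserting a class in weighted
#'   mode; comparison is strict (`>`), so an exact 0.5/0.5 two-class tie
#'   asserts nothing.
#' @param disagreement label assigned where the two sources disagree in
#'   agreement mode: `"background"` (default, no assignment) or
#'   `"crossing_unknown"`.
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(mode = c("agreement", "weighted"),
                          w_cnn = 0.2, w_gcn = 0.8, threshold = 0.5,
                          disagreement = c("background", "crossing_unknown")) {
  mode <- match.arg(mode)
  if (w_cnn < 0 || w_gcn < 0) stop("fusion weights must be >= 0")
  if (mode == "weighted" && abs(w_cnn + w_gcn - 1) > 1e-9) {
    stop("in weighted mode w_cnn + w_gcn must equal 1")
  }
  structure(list(mode = mode, w_cnn = w_cnn, w_gcn = w_gcn,
                 threshold = threshold,
                 disagreement = match.arg(disagreement)),
            class = "fusion_config")
}

#' Spread GCN node probabilities back onto the pixel raster
#'
#' Nodes map to pixels through `index_map` (0-based row-major pixel ids).
#' Pixels without a node (possible when isolated nodes were dropped) get
#' probability 1 for background.
#'
#' @param gcn_probs `N x 4` node probability matrix.
#' @param index_map 0-based pixel id per node.
#' @param P,Q raster size.
#' @return `P x Q x 4` array.
#' @export
gcn_probs_to_raster <- function(gcn_probs, index_map, P, Q) {
  M <- matrix(0, P * Q, ncol(gcn_probs))
  M[, LBL_BACKGROUND + 1L] <- 1
  M[index_map + 1L, ] <- gcn_probs
  out <- array(0, c(P, Q, ncol(gcn_probs)))
  for (k in seq_len(ncol(gcn_probs))) out[, , k] <- rm_unflatten(M[, k], P, Q)
  out
}

argmax_labels <- function(probs) {
  d <- dim(probs)
  m <- matrix(probs, d[1L] * d[2L], d[3L])
  matrix(max.col(m, ties.method = "first") - 1L, d[1L], d[2L])
}

#' Agreement-voting fusion of CNN and GCN outputs
#'
#' Each source contributes its argmax label per pixel; only agreement
#' permits a class assignment, disagreements are ignored (assigned the
#' background / no-assignment label by default).
#'
#' @param cnn_probs `P x Q x 4` CNN probability map.
#' @param gcn_probs `N x 4` GCN node probabilities.
#' @param index_map 0-based pixel ids of the graph nodes (defaults to the
#'   full raster in row-major order).
#' @param config a [fusion_config()] (only `disagreement` is used).
#' @return `P x Q` integer label map.
#' @export
fuse_agreement <- function(cnn_probs, gcn_probs,
                           index_map = NULL, config = fusion_config()) {
  d <- dim(cnn_probs); P <- d[1L]; Q <- d[2L]
  if (is.null(index_map)) {
    if (nrow(gcn_probs) != P * Q) {
      stop("gcn_probs rows must equal P * Q when no index_map is given")
    }
    index_map <- seq_len(P * Q) - 1L
  }
  gr <- gcn_probs_to_raster(gcn_probs, index_map, P, Q)
  cnn_lab <- argmax_labels(cnn_probs)
  gcn_lab <- argmax_labels(gr)
  fused <- matrix(
    if (config$disagreement == "background") LBL_BACKGROUND else LBL_CROSSING,
    P, Q)
  agree <- cnn_lab == gcn_lab
  fused[agree] <- cnn_lab[agree]
  fused
}

#' Weighted-probability fusion of CNN and GCN outputs
#'
#' Per class `i`, `fused_i = w_cnn * p_cnn_i + w_gcn * p_gcn_i`.  A class is
#' asserted where its fused probability strictly exceeds the threshold; if
#' several classes exceed it, the maximum wins; if none does, the pixel is
#' background.
#'
#' @inheritParams fuse_agreement
#' @param config a [fusion_config()] with mode `"weighted"` (weights and
#'   threshold are taken from it).
#' @return `P x Q` integer label map.
#' @export
fuse_weighted <- function(cnn_probs, gcn_probs,
                          index_map = NULL,
                          config = fusion_config("weighted")) {
  if (config$w_cnn < 0 || config$w_gcn < 0 ||
      abs(config$w_cnn + config$w_gcn - 1) > 1e-9) {
    stop("weighted fusion requires non-negative weights summing to 1")
  }
  d <- dim(cnn_probs); P <- d[1L]; Q <- d[2L]
  if (is.null(index_map)) {
    if (nrow(gcn_probs) != P * Q) {
      stop("gcn_probs rows must equal P * Q when no index_map is given")
    }
    index_map <- seq_len(P * Q) - 1L
  }
  gr <- gcn_probs_to_raster(gcn_probs, index_map, P, Q)
  fusedp <- config$w_cnn * cnn_probs + config$w_gcn * gr
  m <- matrix(fusedp, P * Q, d[3L])
  am <- max.col(m, ties.method = "first")
  best <- m[cbind(seq_len(P * Q), am)]
  lab <- ifelse(best > config$threshold, am - 1L, LBL_BACKGROUND)
  matrix(as.integer(lab), P, Q)
}

#' Artery-vs-vein evaluation metrics
#'
#' Evaluation is restricted to pixels whose ground truth is artery or vein
#' (the combined crossing/uncertain class and background are excluded);
#' with `eval_set = "pred_and_gt"` it is further restricted to pixels whose
#' prediction is also artery or vein.  Artery is the positive class and
#' vein the negative class; inside the evaluation support, a predicted
#' crossing or background pixel counts as a misclassification of its
#' ground-truth class (an artery pixel not predicted artery is a false
#' negative, a vein pixel not predicted vein is a false positive).
#'
#' @param pred `P x Q` integer label map (0..3).
#' @param gt `P x Q` integer ground-truth label map (0..3).
#' @param eval_set `"gt_vessels"` (default) or `"pred_and_gt"`.
#' @return list of class `metrics_report`: `accuracy`, `sensitivity`,
#'   `specificity`, confusion counts `TP`, `FP`, `TN`, `FN`, `support`
#'   (number of evaluated pixels) and `eval_set`.
#' @export
evaluate_av <- function(pred, gt, eval_set = c("gt_vessels", "pred_and_gt")) {
  eval_set <- match.arg(eval_set)
  if (!all(dim(pred) == dim(gt))) stop("pred and gt must share the same shape")
  sel <- gt == LBL_ARTERY | gt == LBL_VEIN
  if (eval_set == "pred_and_gt") {
    sel <- sel & (pred == LBL_ARTERY | pred == LBL_VEIN)
  }
  g <- gt[sel]; p <- pred[sel]
  TP <- sum(g == LBL_ARTERY & p == LBL_ARTERY)
  FN <- sum(g == LBL_ARTERY & p != LBL_ARTERY)
  TN <- sum(g == LBL_VEIN & p == LBL_VEIN)
  FP <- sum(g == LBL_VEIN & p != LBL_VEIN)
  tot <- TP + FN + TN + FP
  structure(list(
    accuracy = if (tot > 0) (TP + TN) / tot else NA_real_,
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    TP = TP, FP = FP, TN = TN, FN = FN,
    support = tot, eval_set = eval_set
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "A/V metrics (support %d px, eval set %s): Acc %.4f  Sen %.4f  Spe %.4f\n",
    x$support, x$eval_set, x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d\n", x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

# Split ground-truth vessel pixels of a single class into segments between
# branch points: branch points (vessel pixels with >= 3 vessel neighbours)
# are removed, the 8-connected components of the remainder are segments.
gt_segments <- function(gt) {
  vessel <- gt != LBL_BACKGROUND
  nb <- matrix(0L, nrow(gt), ncol(gt))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- nb + shift_mask(vessel, di, dj)
  }
  branch <- vessel & nb >= 3L
  segs <- list()
  for (cls in c(LBL_ARTERY, LBL_VEIN)) {
    m <- (gt == cls) & !branch
    if (!any(m)) next
    ids <- which(rm_flatten(m))
    eg <- build_edges(m)
    g <- igraph::graph_from_data_frame(as.data.frame(eg$edges + 1L),
                                       directed = FALSE,
                                       vertices = data.frame(name = ids))
    comp <- igraph::components(g)$membership
    pix <- as.integer(names(comp))
    segs <- c(segs, unname(split(pix, comp)))
  }
  segs
}

#' Topology diagnostics for a predicted label map
#'
#' Quantifies the two failure modes of pixel-wise vessel classifiers:
#' `multiclass_segment_count` is the number of ground-truth vessel segments
#' (single-class runs between branch points) whose pixels receive more than
#' one predicted artery/vein class, and `fragmentation_ratio` is the number
#' of 8-connected components of the predicted vessels divided by the number
#' for the ground-truth vessels (1 is ideal; larger means broken vessels).
#'
#' @param pred,gt `P x Q` integer label maps.
#' @return list with `multiclass_segment_count` and `fragmentation_ratio`.
#' @export
topology_diagnostics <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("pred and gt must share the same shape")
  segs <- gt_segments(gt)
  multi <- 0L
  predv <- rm_flatten(pred)
  for (pix in segs) {
    cls <- unique(predv[pix])
    cls <- cls[cls %in% c(LBL_ARTERY, LBL_VEIN)]
    if (length(cls) > 1L) multi <- multi + 1L
  }
  n_gt <- n_components_8(gt != LBL_BACKGROUND)
  n_pred <- n_components_8(pred != LBL_BACKGROUND)
  list(multiclass_segment_count = multi,
       fragmentation_ratio = if (n_gt > 0) n_pred / n_gt else NA_real_)
}
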