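#' Configuration for the synthetic fundus generator
#'
#' Builds a validated configuration for [generate_labeled_image()].  The
#' generator draws artery and vein trees as biased random walks with
#' stochastic branching, rasterised with disk brushes, on a fundus-like
#' background.  Crossing pixels (artery and vein overlap) receive the
#' combined crossing/uncertain label, mirroring how public artery/vein
#' datasets annotate crossings.
#'
#' @param height,width canvas size in pixels (at least 32).
#' @param trees_per_class number of vascular trees per class (>= 1).
#' @param branch_probability probability of spawning a side branch at each
#'   growth step, in `[0, 1]`.
#' @param vessel_radius_range numeric length-2, min and max brush radius in
#'   pixels.
#' @param color_means list with RGB triples (values in `[0, 1]`) named
#'   `background`, `artery`, `vein`.  Crossing pixels take the mean of the
#'   artery and vein colors.
#' @param noise_sd standard deviation of i.i.d. Gaussian RGB noise (>= 0).
#' @param seed integer seed; all randomness of the module flows from it.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(height = 128L, width = 128L,
                         trees_per_class = 3L,
                         branch_probability = 0.04,
                         vessel_radius_range = c(1, 2.5),
                         color_means = list(
                           background = c(0.72, 0.45, 0.30),
                           artery = c(0.93, 0.35, 0.30),
                           vein = c(0.45, 0.12, 0.15)
                         ),
                         noise_sd = 0.04,
                         seed = 1L) {
  if (height < 32 || width < 32) {
    stop("canvas too small: height and width must both be >= 32 pixels")
  }
  if (trees_per_class < 1) stop("trees_per_class must be >= 1")
  if (branch_probability < 0 || branch_probability > 1) {
    stop("branch_probability must lie in [0, 1]")
  }
  if (length(vessel_radius_range) != 2L || any(vessel_radius_range <= 0) ||
      vessel_radius_range[1L] > vessel_radius_range[2L]) {
    stop("vessel_radius_range must be positive c(min, max) with min <= max")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  for (nm in c("background", "artery", "vein")) {
    cm <- color_means[[nm]]
    if (is.null(cm) || length(cm) != 3L || any(cm < 0) || any(cm > 1)) {
      stop("color_means$", nm, " must be an RGB triple in [0, 1]")
    }
  }
  structure(list(
    height = as.integer(height), width = as.integer(width),
    trees_per_class = as.integer(trees_per_class),
    branch_probability = branch_probability,
    vessel_radius_range = as.numeric(vessel_radius_range),
    color_means = color_means,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Disk brush offsets for a given radius (Euclidean ball on the lattice).
disk_offsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(di = -ri:ri, dj = -ri:ri)
  g[g$di^2 + g$dj^2 <= r^2, , drop = FALSE]
}

# Paint a disk of radius r centred at (i, j) onto a logical matrix.
paint_disk <- function(mask, i, j, offs) {
  P <- nrow(mask); Q <- ncol(mask)
  ii <- round(i) + offs$di
  jj <- round(j) + offs$dj
  ok <- ii >= 1 & ii <= P & jj >= 1 & jj <= Q
  mask[cbind(ii[ok], jj[ok])] <- TRUE
  mask
}

# Grow one vascular tree as a biased random walk with stochastic branching.
# Step length < 1 px and disk brushes of radius >= 1 guarantee each tree is
# one 8-connected (in fact 4-connected) raster component.
grow_tree <- function(P, Q, branch_probability, radius_range) {
  mask <- matrix(FALSE, P, Q)
  side <- sample.int(4L, 1L)
  pos <- switch(side,
    c(1 + runif(1) * 2, runif(1, 2, Q - 1)),                             # top
    c(P - runif(1) * 2, runif(1, 2, Q - 1)),                             # bottom
    c(runif(1, 2, P - 1), 1 + runif(1) * 2),                             # left
    c(runif(1, 2, P - 1), Q - runif(1) * 2)                              # right
  )
  ang <- switch(side,
    runif(1, pi / 4, 3 * pi / 4),        # heading down
    runif(1, -3 * pi / 4, -pi / 4),      # heading up
    runif(1, -pi / 4, pi / 4),           # heading right
    runif(1, 3 * pi / 4, 5 * pi / 4)     # heading left
  )
  r0 <- runif(1, radius_range[1L], radius_range[2L])
  step <- 0.7
  max_steps <- 3L * max(P, Q)
  max_walkers <- 8L
  # walker: (i, j, angle, radius, steps left)
  stack <- list(c(pos[1L], pos[2L], ang, r0, max_steps))
  n_spawned <- 1L
  while (length(stack) > 0L) {
    w <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- w[1L]; j <- w[2L]; a <- w[3L]; r <- w[4L]; left <- w[5L]
    offs <- disk_offsets(r)
    while (left > 0 && i >= 1 && i <= P && j >= 1 && j <= Q) {
      mask <- paint_disk(mask, i, j, offs)
      a <- a + rnorm(1, 0, 0.15)
      i <- i + step * sin(a) * 1  # rows grow downward for angle pi/2
      j <- j + step * cos(a)
      left <- left - 1
      if (n_spawned < max_walkers && runif(1) < branch_probability) {
        child_a <- a + sample(c(-1, 1), 1L) * runif(1, 0.5, 1.0)
        child_r <- max(radius_range[1L], r * 0.85)
        stack[[length(stack) + 1L]] <- c(i, j, child_a, child_r, left)
        n_spawned <- n_spawned + 1L
      }
    }
  }
  mask
}

#' Generate a synthetic labeled fundus-like image
#'
#' Renders `trees_per_class` artery trees and vein trees on a noisy
#' background.  Pixels covered by both classes are labeled
#' `crossing_unknown`; everything else keeps its single class or the
#' background label.  The output is a deterministic function of
#' `config$seed`.
#'
#' @param config a [synth_config()].
#' @return a list of class `labeled_image` with elements `image`
#'   (`P x Q x 3` array in `[0, 1]`), `labels` (`P x Q` integer matrix with
#'   values 0 = background, 1 = artery, 2 = crossing/unknown, 3 = vein),
#'   `trees` (per-tree logical masks, split by class) and `config`.
#' @export
generate_labeled_image <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  with_seed(config$seed, {
    P <- config$height; Q <- config$width
    trees <- list(artery = list(), vein = list())
    class_mask <- list(
      artery = matrix(FALSE, P, Q),
      vein = matrix(FALSE, P, Q)
    )
    for (cls in c("artery", "vein")) {
      for (t in seq_len(config$trees_per_class)) {
        tm <- grow_tree(P, Q, config$branch_probability, config$vessel_radius_range)
        trees[[cls]][[t]] <- tm
        class_mask[[cls]] <- class_mask[[cls]] | tm
      }
    }
    labels <- matrix(LBL_BACKGROUND, P, Q)
    labels[class_mask$artery] <- LBL_ARTERY
    labels[class_mask$vein] <- LBL_VEIN
    labels[class_mask$artery & class_mask$vein] <- LBL_CROSSING
    cm <- config$color_means
    cross_col <- (cm$artery + cm$vein) / 2
    image <- array(0, c(P, Q, 3L))
    for (ch in 1:3) {
      plane <- matrix(cm$background[ch], P, Q)
      plane[labels == LBL_ARTERY] <- cm$artery[ch]
      plane[labels == LBL_VEIN] <- cm$vein[ch]
      plane[labels == LBL_CROSSING] <- cross_col[ch]
      image[, , ch] <- plane
    }
    if (config$noise_sd > 0) {
      image <- image + rnorm(length(image), 0, config$noise_sd)
      image[image < 0] <- 0
      image[image > 1] <- 1
    }
    structure(list(image = image, labels = labels, trees = trees,
                   config = config),
              class = "labeled_image")
  })
}

#' Break a binary vessel mask at random sites
#'
#' Simulates segmentation errors ("broken vessels") by erasing short runs of
#' foreground.  Break sites are drawn among interior foreground pixels (>= 2
#' foreground 8-neighbours); a site is accepted only if erasing the disk of
#' diameter `gap_length` around it increases the local 8-connected component
#' count in a window around the site, so accepted breaks actually sever the
#' vessel locally.  If fewer than `break_count` feasible sites exist, all
#' feasible ones are applied.  Foreground is only ever removed, never added.
#'
#' @param mask binary matrix (vessel = TRUE/1).
#' @param break_count maximum number of breaks (>= 0).
#' @param gap_length approximate erased run length in pixels.
#' @param seed integer seed.
#' @return logical matrix of the same shape.
#' @export
corrupt_mask <- function(mask, break_count, gap_length, seed = 1L) {
  if (break_count < 0) stop("break_count must be >= 0")
  m <- mask != 0
  if (break_count == 0 || !any(m)) return(m)
  with_seed(seed, {
    P <- nrow(m); Q <- ncol(m)
    nb <- matrix(0L, P, Q)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- nb + shift_mask(m, di, dj)
    }
    cand <- which(m & nb >= 2L)
    if (length(cand) == 0L) return(m)
    cand <- cand[sample.int(length(cand))]
    offs <- disk_offsets(gap_length / 2)
    win <- as.integer(gap_length) + 2L
    applied <- 0L
    for (k in cand) {
      if (applied >= break_count) break
      i <- (k - 1L) %% P + 1L
      j <- (k - 1L) %/% P + 1L
      if (!m[i, j]) next
      # local window before/after comparison
      wi <- max(1L, i - win):min(P, i + win)
      wj <- max(1L, j - win):min(Q, j + win)
      local_before <- m[wi, wj, drop = FALSE]
      erased <- m
      ii <- i + offs$di; jj <- j + offs$dj
      ok <- ii >= 1 & ii <= P & jj >= 1 & jj <= Q
      erased[cbind(ii[ok], jj[ok])] <- FALSE
      local_after <- erased[wi, wj, drop = FALSE]
      if (!any(local_after)) next
      if (n_components_8(local_after) > n_components_8(local_before)) {
        m <- erased
        applied <- applied + 1L
      }
    }
    m
  })
}
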