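#' Configuration for the encoder-decoder pixel classifier
#'
#' The backbone is a small U-Net style encoder-decoder: `depth` levels of
#' 3x3 convolution + rectifier + 2x2 max-pooling, a bottleneck, and a
#' mirrored decoder with nearest-neighbour upsampling and skip
#' concatenation.  Its last decoder stage emits `hidden_features` (H)
#' channels which feed exactly one 1x1 convolution to `num_classes` followed
#' by a per-pixel softmax; those H channels are the representative CNN
#' features handed to the graph stage.
#'
#' Defaults mirror a GPU-scale recipe (learning rate 2e-5 halved every 10k
#' epochs for 20k epochs); tests and the bundled pipeline use drastically
#' reduced desk-scale schedules.
#'
#' @param depth number of down/up levels (>= 1).
#' @param base_channels channels of the first encoder level.
#' @param hidden_features H, channels entering the final 1x1 classifier.
#' @param num_classes output classes (4 for the artery/vein task).
#' @param learning_rate initial Adam learning rate.
#' @param lr_halving_interval epochs between halvings of the learning rate.
#' @param total_epochs training epochs (one pass over the training set each).
#' @param augmentation list of logical toggles `flip`, `rotate` (rotations
#'   are 90-degree multiples and require square images).
#' @param seed integer seed for initialization and augmentation.
#' @return list of class `backbone_config`.
#' @export
backbone_config <- function(depth = 2L, base_channels = 8L,
                            hidden_features = 16L, num_classes = 4L,
                            learning_rate = 2e-5,
                            lr_halving_interval = 10000L,
                            total_epochs = 20000L,
                            augmentation = list(flip = TRUE, rotate = TRUE),
                            seed = 1L) {
  if (depth < 1) stop("depth must be >= 1")
  if (hidden_features < 1) stop("hidden_features must be >= 1")
  if (num_classes < 2) stop("num_classes must be >= 2")
  structure(list(
    depth = as.integer(depth), base_channels = as.integer(base_channels),
    hidden_features = as.integer(hidden_features),
    num_classes = as.integer(num_classes),
    learning_rate = learning_rate,
    lr_halving_interval = as.integer(lr_halving_interval),
    total_epochs = as.integer(total_epochs),
    augmentation = augmentation,
    seed = as.integer(seed)
  ), class = "backbone_config")
}

## ---- primitive layers (arrays are P x Q x C) --------------------------------

# The 3x3 convolutions work on an im2col matrix (pixels x 9*Cin) built with
# contiguous flat-index shifts (column-major pixel index k = i + (j-1)*P:
# shifting by (di, dj) is a shift by di + dj*P with the wrapped boundary rows
# zeroed).  One BLAS matmul then computes all kernel offsets at once; the
# columns are cached for the backward pass.

conv_im2col <- function(x) {
  d <- dim(x); P <- d[1L]; Q <- d[2L]; C <- d[3L]
  n <- P * Q
  Xm <- x; dim(Xm) <- c(n, C)
  cols <- matrix(0, n, 9L * C)
  o <- 0L
  for (bb in 1:3) for (a in 1:3) {
    di <- a - 2L; dj <- bb - 2L
    s <- di + dj * P
    blk <- matrix(0, n, C)
    if (s >= 0L) {
      if (s < n) blk[1:(n - s), ] <- Xm[(s + 1L):n, ]
    } else {
      blk[(1L - s):n, ] <- Xm[1:(n + s), ]
    }
    if (di == 1L) blk[seq.int(P, n, P), ] <- 0
    if (di == -1L) blk[seq.int(1L, n, P), ] <- 0
    cols[, o * C + seq_len(C)] <- blk
    o <- o + 1L
  }
  cols
}

w_big <- function(W) {
  Cin <- dim(W)[3L]; Cout <- dim(W)[4L]
  Wb <- matrix(0, 9L * Cin, Cout)
  o <- 0L
  for (bb in 1:3) for (a in 1:3) {
    Wb[o * Cin + seq_len(Cin), ] <- matrix(W[a, bb, , , drop = FALSE], Cin, Cout)
    o <- o + 1L
  }
  Wb
}

w_from_big <- function(Wb, Cin, Cout) {
  W <- array(0, c(3L, 3L, Cin, Cout))
  o <- 0L
  for (bb in 1:3) for (a in 1:3) {
    W[a, bb, , ] <- Wb[o * Cin + seq_len(Cin), , drop = FALSE]
    o <- o + 1L
  }
  W
}

conv_fwd <- function(x, W, b, cols = NULL) {
  d <- dim(x); P <- d[1L]; Q <- d[2L]
  Cout <- dim(W)[4L]
  if (is.null(cols)) cols <- conv_im2col(x)
  out <- cols %*% w_big(W)
  out <- out + rep(b, each = P * Q)
  dim(out) <- c(P, Q, Cout)
  list(out = out, cols = cols, P = P, Q = Q)
}

conv_bwd <- function(cols, P, Q, W, dout) {
  Cin <- dim(W)[3L]; Cout <- dim(W)[4L]
  n <- P * Q
  doutM <- dout; dim(doutM) <- c(n, Cout)
  dWb <- crossprod(cols, doutM)
  db <- colSums(doutM)
  dcols <- tcrossprod(doutM, w_big(W))
  dxM <- matrix(0, n, Cin)
  o <- 0L
  for (bb in 1:3) for (a in 1:3) {
    di <- a - 2L; dj <- bb - 2L
    s <- di + dj * P
    blk <- dcols[, o * Cin + seq_len(Cin), drop = FALSE]
    if (di == 1L) blk[seq.int(P, n, P), ] <- 0
    if (di == -1L) blk[seq.int(1L, n, P), ] <- 0
    if (s >= 0L) {
      if (s < n) dxM[(s + 1L):n, ] <- dxM[(s + 1L):n, ] + blk[1:(n - s), , drop = FALSE]
    } else {
      dxM[1:(n + s), ] <- dxM[1:(n + s), ] + blk[(1L - s):n, , drop = FALSE]
    }
    o <- o + 1L
  }
  list(dx = array(dxM, c(P, Q, Cin)), dW = w_from_big(dWb, Cin, Cout), db = db)
}

maxpool2 <- function(x) {
  d <- dim(x); P <- d[1L]; Q <- d[2L]
  io <- seq(1L, P, 2L); ie <- seq(2L, P, 2L)
  jo <- seq(1L, Q, 2L); je <- seq(2L, Q, 2L)
  a <- x[io, jo, , drop = FALSE]; b <- x[ie, jo, , drop = FALSE]
  cc <- x[io, je, , drop = FALSE]; dd <- x[ie, je, , drop = FALSE]
  wa <- (a >= b) & (a >= cc) & (a >= dd)
  wb <- !wa & (b >= cc) & (b >= dd)
  wc <- !wa & !wb & (cc >= dd)
  wd <- !(wa | wb | wc)
  out <- a * wa + b * wb + cc * wc + dd * wd
  list(out = out, w = list(wa, wb, wc, wd))
}

maxpool2_bwd <- function(dout, w, P, Q) {
  C <- dim(dout)[3L]
  dx <- array(0, c(P, Q, C))
  io <- seq(1L, P, 2L); ie <- seq(2L, P, 2L)
  jo <- seq(1L, Q, 2L); je <- seq(2L, Q, 2L)
  dx[io, jo, ] <- dout * w[[1L]]
  dx[ie, jo, ] <- dout * w[[2L]]
  dx[io, je, ] <- dout * w[[3L]]
  dx[ie, je, ] <- dout * w[[4L]]
  dx
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , drop = FALSE]
}

upsample2_bwd <- function(dout) {
  d <- dim(dout); P <- d[1L]; Q <- d[2L]
  io <- seq(1L, P, 2L); ie <- seq(2L, P, 2L)
  jo <- seq(1L, Q, 2L); je <- seq(2L, Q, 2L)
  dout[io, jo, , drop = FALSE] + dout[ie, jo, , drop = FALSE] +
    dout[io, je, , drop = FALSE] + dout[ie, je, , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1L], da[2L], da[3L] + db[3L]))
}

## ---- model ------------------------------------------------------------------

backbone_channels <- function(cfg) {
  D <- cfg$depth; base <- cfg$base_channels
  enc_in <- c(3L, base * 2L^(seq_len(D - 1L) - 1L))
  enc_out <- base * 2L^(seq_len(D) - 1L)
  dec_in <- base * 2L^seq_len(D) + base * 2L^(seq_len(D) - 1L)
  dec_out <- c(cfg$hidden_features, if (D > 1L) base * 2L^(seq(2L, D) - 1L))
  list(enc_in = enc_in, enc_out = enc_out,
       bott_in = base * 2L^(D - 1L), bott_out = base * 2L^D,
       dec_in = dec_in, dec_out = dec_out)
}

he_conv <- function(Cin, Cout) {
  array(stats::rnorm(9L * Cin * Cout, 0, sqrt(2 / (9 * Cin))), c(3L, 3L, Cin, Cout))
}

#' Build an encoder-decoder pixel classifier
#'
#' Parameters are drawn with He initialization, deterministically in
#' `config$seed`.  The final stage is exactly one 1x1 convolution from
#' `hidden_features` to `num_classes` channels followed by per-pixel softmax.
#'
#' @param config a [backbone_config()].
#' @return list of class `vt_backbone` with elements `config` and `params`.
#' @export
build_backbone <- function(config) {
  ch <- backbone_channels(config)
  D <- config$depth
  params <- with_seed(config$seed, {
    p <- list()
    for (d in seq_len(D)) {
      p[[paste0("enc", d, "_W")]] <- he_conv(ch$enc_in[d], ch$enc_out[d])
      p[[paste0("enc", d, "_b")]] <- numeric(ch$enc_out[d])
    }
    p$bott_W <- he_conv(ch$bott_in, ch$bott_out)
    p$bott_b <- numeric(ch$bott_out)
    for (d in seq_len(D)) {
      p[[paste0("dec", d, "_W")]] <- he_conv(ch$dec_in[d], ch$dec_out[d])
      p[[paste0("dec", d, "_b")]] <- numeric(ch$dec_out[d])
    }
    H <- config$hidden_features
    p$head_W <- matrix(stats::rnorm(H * config$num_classes, 0, sqrt(2 / H)),
                       H, config$num_classes)
    p$head_b <- numeric(config$num_classes)
    p
  })
  structure(list(config = config, params = params), class = "vt_backbone")
}

check_canvas <- function(cfg, P, Q) {
  f <- 2L^cfg$depth
  if (P %% f != 0L || Q %% f != 0L) {
    stop("canvas ", P, "x", Q, " is incompatible with depth ", cfg$depth,
         ": both sides must be divisible by ", f)
  }
}

backbone_forward <- function(params, cfg, x, want_cache = FALSE) {
  d <- dim(x); P <- d[1L]; Q <- d[2L]
  check_canvas(cfg, P, Q)
  D <- cfg$depth
  cache <- list(enc_cols = vector("list", D), enc_pre = vector("list", D),
                pool_w = vector("list", D), pool_dim = vector("list", D),
                dec_cols = vector("list", D), dec_pre = vector("list", D),
                up_ch = integer(D))
  h <- x
  skips <- vector("list", D)
  for (d_ in seq_len(D)) {
    cv <- conv_fwd(h, params[[paste0("enc", d_, "_W")]], params[[paste0("enc", d_, "_b")]])
    z <- cv$out
    if (want_cache) {
      cache$enc_cols[[d_]] <- cv$cols
      cache$enc_pre[[d_]] <- z
    }
    h <- pmax(z, 0)
    skips[[d_]] <- h
    mp <- maxpool2(h)
    if (want_cache) {
      cache$pool_w[[d_]] <- mp$w
      cache$pool_dim[[d_]] <- dim(h)[1:2]
    }
    h <- mp$out
  }
  cv <- conv_fwd(h, params$bott_W, params$bott_b)
  z <- cv$out
  if (want_cache) {
    cache$bott_cols <- cv$cols
    cache$bott_dim <- dim(h)[1:2]
    cache$bott_pre <- z
  }
  h <- pmax(z, 0)
  for (d_ in rev(seq_len(D))) {
    up <- upsample2(h)
    cache$up_ch[d_] <- dim(up)[3L]
    hin <- concat_ch(up, skips[[d_]])
    cv <- conv_fwd(hin, params[[paste0("dec", d_, "_W")]], params[[paste0("dec", d_, "_b")]])
    z <- cv$out
    if (want_cache) {
      cache$dec_cols[[d_]] <- cv$cols
      cache$dec_dim[[d_]] <- dim(hin)[1:2]
      cache$dec_pre[[d_]] <- z
    }
    h <- pmax(z, 0)
  }
  feats <- h
  H <- cfg$hidden_features
  featsM <- matrix(feats, P * Q, H)
  logits <- sweep(featsM %*% params$head_W, 2L, params$head_b, "+")
  probs <- array(softmax_rows(logits), c(P, Q, cfg$num_classes))
  list(feats = feats, probs = probs, cache = if (want_cache) cache else NULL)
}

backbone_backward <- function(params, cfg, fw, dlogitsM) {
  cache <- fw$cache
  feats <- fw$feats
  d <- dim(feats); P <- d[1L]; Q <- d[2L]
  D <- cfg$depth
  grads <- list()
  featsM <- matrix(feats, P * Q, cfg$hidden_features)
  grads$head_W <- crossprod(featsM, dlogitsM)
  grads$head_b <- colSums(dlogitsM)
  dh <- array(tcrossprod(dlogitsM, params$head_W), dim(feats))
  dskip <- vector("list", D)
  # decoder ran d = D..1, so reverse order is d = 1..D
  for (d_ in seq_len(D)) {
    dz <- dh * (cache$dec_pre[[d_]] > 0)
    dd <- cache$dec_dim[[d_]]
    cb <- conv_bwd(cache$dec_cols[[d_]], dd[1L], dd[2L],
                   params[[paste0("dec", d_, "_W")]], dz)
    grads[[paste0("dec", d_, "_W")]] <- cb$dW
    grads[[paste0("dec", d_, "_b")]] <- cb$db
    cu <- cache$up_ch[d_]
    dup <- cb$dx[, , seq_len(cu), drop = FALSE]
    dskip[[d_]] <- cb$dx[, , (cu + 1L):dim(cb$dx)[3L], drop = FALSE]
    dh <- upsample2_bwd(dup)
  }
  dz <- dh * (cache$bott_pre > 0)
  bd <- cache$bott_dim
  cb <- conv_bwd(cache$bott_cols, bd[1L], bd[2L], params$bott_W, dz)
  grads$bott_W <- cb$dW
  grads$bott_b <- cb$db
  dh <- cb$dx
  # encoder ran d = 1..D, so reverse order is d = D..1
  for (d_ in rev(seq_len(D))) {
    pd <- cache$pool_dim[[d_]]
    dpool <- maxpool2_bwd(dh, cache$pool_w[[d_]], pd[1L], pd[2L])
    dz <- (dpool + dskip[[d_]]) * (cache$enc_pre[[d_]] > 0)
    cb <- conv_bwd(cache$enc_cols[[d_]], pd[1L], pd[2L],
                   params[[paste0("enc", d_, "_W")]], dz)
    grads[[paste0("enc", d_, "_W")]] <- cb$dW
    grads[[paste0("enc", d_, "_b")]] <- cb$db
    dh <- cb$dx
  }
  grads
}

## ---- optimizer --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## ---- training ---------------------------------------------------------------

rot90_arr <- function(a, k) {
  k <- k %% 4L
  if (k == 0L) return(a)
  for (i in seq_len(k)) {
    d <- dim(a)
    if (length(d) == 2L) {
      a <- t(a)[d[2L]:1, , drop = FALSE]
    } else {
      a <- aperm(a, c(2L, 1L, 3L))[d[2L]:1, , , drop = FALSE]
    }
  }
  a
}

flip_arr <- function(a, horizontal) {
  d <- dim(a)
  if (length(d) == 2L) {
    if (horizontal) a[, d[2L]:1, drop = FALSE] else a[d[1L]:1, , drop = FALSE]
  } else {
    if (horizontal) a[, d[2L]:1, , drop = FALSE] else a[d[1L]:1, , , drop = FALSE]
  }
}

augment_pair <- function(image, labels, aug) {
  if (isTRUE(aug$flip)) {
    if (stats::runif(1) < 0.5) { image <- flip_arr(image, TRUE); labels <- flip_arr(labels, TRUE) }
    if (stats::runif(1) < 0.5) { image <- flip_arr(image, FALSE); labels <- flip_arr(labels, FALSE) }
  }
  if (isTRUE(aug$rotate) && nrow(labels) == ncol(labels)) {
    k <- sample(0:3, 1L)
    image <- rot90_arr(image, k); labels <- rot90_arr(labels, k)
  }
  list(image = image, labels = labels)
}

cross_entropy_pixels <- function(probsM, labels_vec, n_classes) {
  idx <- cbind(seq_along(labels_vec), labels_vec + 1L)
  p <- pmax(probsM[idx], 1e-12)
  -mean(log(p))
}

#' Train the pixel classifier
#'
#' Minimizes unweighted per-pixel cross-entropy over the four classes with
#' Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8).  One epoch is one pass
#' over the training images with a full-image gradient step per image.  The
#' learning rate is halved every `lr_halving_interval` epochs.  Random flip
#' and 90-degree rotation augmentation is applied when enabled.
#'
#' @param model a `vt_backbone` from [build_backbone()].
#' @param images list of `labeled_image` (or lists with `image`, `labels`).
#' @param config optional [backbone_config()] overriding `model$config` for
#'   the training schedule.
#' @return list with `model` (trained) and `history`
#'   (data.frame: epoch, loss, lr).
#' @export
train_backbone <- function(model, images, config = model$config) {
  if (length(images) < 1L) stop("at least one training image is required")
  params <- model$params
  cfg <- model$config
  n_ep <- config$total_epochs
  history <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  if (n_ep == 0L) {
    return(list(model = model, history = history))
  }
  state <- adam_init(params)
  with_seed(config$seed, {
    for (ep in seq_len(n_ep)) {
      lr <- config$learning_rate * 0.5^((ep - 1L) %/% config$lr_halving_interval)
      losses <- numeric(length(images))
      for (k in seq_along(images)) {
        li <- images[[k]]
        pair <- augment_pair(li$image, li$labels, config$augmentation)
        fw <- backbone_forward(params, cfg, pair$image, want_cache = TRUE)
        P <- dim(pair$image)[1L]; Q <- dim(pair$image)[2L]
        probsM <- matrix(fw$probs, P * Q, cfg$num_classes)
        yv <- as.vector(pair$labels)
        loss <- cross_entropy_pixels(probsM, yv, cfg$num_classes)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", ep, ", image ", k,
               "; reduce the learning rate")
        }
        losses[k] <- loss
        onehot <- matrix(0, P * Q, cfg$num_classes)
        onehot[cbind(seq_len(P * Q), yv + 1L)] <- 1
        dlogitsM <- (probsM - onehot) / (P * Q)
        grads <- backbone_backward(params, cfg, fw, dlogitsM)
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params; state <- upd$state
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = mean(losses), lr = lr))
    }
  })
  model$params <- params
  list(model = model, history = history)
}

#' Extract CNN features and class probabilities for an image
#'
#' Returns the tensor entering the final 1x1 classifier (the representative
#' CNN features, `P x Q x H`) together with the softmax class probabilities
#' (`P x Q x num_classes`).  Inference is deterministic: no augmentation or
#' dropout is applied.
#'
#' @param model a `vt_backbone`.
#' @param image `P x Q x 3` array (or a `labeled_image`).
#' @return list with `feats` and `probs`.
#' @export
extract_features <- function(model, image) {
  if (inherits(image, "labeled_image")) image <- image$image
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    stop("image must be a P x Q x 3 array")
  }
  fw <- backbone_forward(model$params, model$config, image, want_cache = FALSE)
  list(feats = fw$feats, probs = fw$probs)
}
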