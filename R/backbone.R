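#' Backbone configuration
#'
#' Describes the randomly initialized convolutional backbone whose penultimate
#' fully connected layer provides the image features. `scale = "full"` is the
#' standard VGG16-D layout with the last fully connected layer removed:
#' thirteen 3x3 convolutions in five pooled blocks, then two 4096-unit fully
#' connected layers, the second of which emits the 4096-dimensional feature
#' vector. `scale = "tiny"` is a three-block analogue (8/16/32 channels)
#' preserving the conv-stack -> penultimate-FC structure at desk scale.
#'
#' @param scale `"tiny"` or `"full"`.
#' @param input_size square input side in pixels. Must be a multiple of 8
#'   (tiny) or 32 (full); defaults 64 and 224.
#' @param feature_dim feature dimension of the penultimate FC layer; defaults
#'   128 (tiny, must be <= 512) and 4096 (full).
#' @param init_seed seed for the random weight initialization.
#' @param sobel_preprocess replace RGB input by a 2-channel Sobel gradient
#'   image (off by default).
#' @return object of class `backbone_config`.
#' @export
backbone_config <- function(scale = c("tiny", "full"), input_size = NULL,
                            feature_dim = NULL, init_seed = 1,
                            sobel_preprocess = FALSE) {
  scale <- match.arg(scale)
  input_size <- as.integer(input_size %||% if (scale == "tiny") 64L else 224L)
  feature_dim <- as.integer(feature_dim %||% if (scale == "tiny") 128L else 4096L)
  if (feature_dim <= 0) stop_input("feature_dim must be positive")
  stride <- if (scale == "tiny") 8L else 32L
  if (input_size < 32 || input_size %% stride != 0) {
    stop_input(sprintf("input_size must be >= 32 and a multiple of %d for scale '%s'",
                       stride, scale))
  }
  if (scale == "tiny" && feature_dim > 512) {
    stop_input("tiny backbones are capped at feature_dim 512")
  }
  structure(list(scale = scale, input_size = input_size,
                 feature_dim = feature_dim, init_seed = as.integer(init_seed),
                 sobel_preprocess = isTRUE(sobel_preprocess)),
            class = "backbone_config")
}

# Channel plans; "P" marks a 2x2 max-pool.
conv_plan <- function(scale) {
  if (scale == "tiny") list(8L, "P", 16L, "P", 32L, "P")
  else list(64L, 64L, "P", 128L, 128L, "P", 256L, 256L, 256L, "P",
            512L, 512L, 512L, "P", 512L, 512L, 512L, "P")
}

he_init <- function(n_out, n_in) {
  matrix(rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in)
}

#' Build a randomly initialized backbone
#'
#' Instantiates the convolutional filters and fully connected weights (He
#' initialization, deterministic for a fixed `init_seed`). The conv filters
#' stay fixed at their random initialization throughout; pseudo-label training
#' updates the fully connected layers (see [train_epoch()]).
#'
#' @param config a [backbone_config()].
#' @return object of class `rc_backbone` with elements `config`, `conv`
#'   (list of conv-layer weights), and `fc` (list of dense layers, the last of
#'   which is the `feature_dim`-unit penultimate FC layer).
#' @export
build_backbone <- function(config) {
  stopifnot(inherits(config, "backbone_config"))
  in_ch <- if (config$sobel_preprocess) 2L else 3L
  plan <- conv_plan(config$scale)
  with_rng_seed(config$init_seed, {
    conv <- list()
    spatial <- config$input_size
    ch <- in_ch
    for (item in plan) {
      if (identical(item, "P")) {
        conv[[length(conv) + 1L]] <- list(type = "pool")
        spatial <- spatial %/% 2L
      } else {
        conv[[length(conv) + 1L]] <- list(type = "conv", in_ch = ch, out_ch = item,
                                          W = he_init(item, 9L * ch),
                                          b = numeric(item))
        ch <- item
      }
    }
    flat_dim <- spatial * spatial * ch
    fc_dims <- if (config$scale == "tiny") c(flat_dim, config$feature_dim)
               else c(flat_dim, 4096L, config$feature_dim)
    fc <- list()
    for (j in seq_len(length(fc_dims) - 1L)) {
      nu <- fc_dims[j + 1L]
      # batch-normalized FC layers: BN keeps per-unit activation variance at 1
      # during pseudo-label training, which prevents the representation from
      # collapsing to a point; running stats make evaluation deterministic.
      fc[[j]] <- list(W = he_init(nu, fc_dims[j]), b = numeric(nu),
                      gamma = rep(1, nu), beta = numeric(nu),
                      run_mean = numeric(nu), run_var = rep(1, nu))
    }
    structure(list(config = config, conv = conv, fc = fc,
                   flat_dim = flat_dim,
                   conv_out_shape = c(spatial, spatial, ch)),
              class = "rc_backbone")
  })
}

#' @export
print.rc_backbone <- function(x, ...) {
  cat(sprintf("<rc_backbone scale=%s input=%dpx features=%d seed=%d>\n",
              x$config$scale, x$config$input_size, x$config$feature_dim,
              x$config$init_seed))
  invisible(x)
}

# ---- forward primitives -----------------------------------------------------

# im2col index cache: for an [H, W, C] input (3x3 kernel, pad 1, stride 1)
# returns a (9C x HW) matrix of linear indices into the zero-padded array.
.im2col_cache <- new.env(parent = emptyenv())

im2col_indices <- function(h, w, c) {
  key <- paste(h, w, c, sep = "_")
  idx <- .im2col_cache[[key]]
  if (!is.null(idx)) return(idx)
  hp <- h + 2L; wp <- w + 2L
  # output centers (i, j) at padded coords (i+1, j+1); patch offsets -1..1
  out_i <- rep(seq_len(h), times = w)
  out_j <- rep(seq_len(w), each = h)
  base <- (out_i + 1L) + (out_j) * hp  # linear index of center, channel 1
  offs <- as.vector(outer(-1:1, (-1:1) * hp, `+`))          # 9 in-plane offsets
  chan <- (seq_len(c) - 1L) * (hp * wp)
  patch <- as.vector(outer(offs, chan, `+`))                # 9C offsets
  idx <- matrix(rep(base, each = length(patch)), nrow = length(patch)) +
    patch
  storage.mode(idx) <- "integer"
  .im2col_cache[[key]] <- idx
  idx
}

conv3x3_forward <- function(x, layer) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; c <- d[3]
  xpad <- array(0, c(h + 2L, w + 2L, c))
  xpad[2:(h + 1L), 2:(w + 1L), ] <- x
  idx <- im2col_indices(h, w, c)
  col <- matrix(xpad[idx], nrow = nrow(idx))
  out <- layer$W %*% col + layer$b
  out[out < 0] <- 0
  array(t(out), c(h, w, layer$out_ch))
}

maxpool2_forward <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  pmax(x[i1, j1, , drop = FALSE], x[i2, j1, , drop = FALSE],
       x[i1, j2, , drop = FALSE], x[i2, j2, , drop = FALSE])
}

sobel_channels <- function(x) {
  gray <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
  d <- dim(gray)
  gp <- matrix(0, d[1] + 2L, d[2] + 2L)
  gp[2:(d[1] + 1L), 2:(d[2] + 1L)] <- gray
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dx (columns)
  ky <- t(kx)
  gx <- gy <- matrix(0, d[1], d[2])
  for (a in 1:3) for (b in 1:3) {
    sub <- gp[a:(a + d[1] - 1L), b:(b + d[2] - 1L)]
    gx <- gx + kx[a, b] * sub
    gy <- gy + ky[a, b] * sub
  }
  array(c(gx, gy), c(d[1], d[2], 2L))
}

# 0..255 integer pixels -> standardized float tensor at the configured size.
preprocess_image <- function(img, config) {
  px <- if (inherits(img, "fruit_image")) img$pixels else img
  d <- dim(px)
  if (length(d) != 3L || d[3] != 3L) stop_input("images must be HxWx3 arrays")
  x <- px / 255
  if (d[1] != config$input_size || d[2] != config$input_size) {
    x <- EBImage::resize(x, w = config$input_size, h = config$input_size)
    x <- array(x, c(config$input_size, config$input_size, 3L))
  }
  x <- (x - 0.5) / 0.25
  if (config$sobel_preprocess) x <- sobel_channels(x)
  x
}

# Conv-stack forward; returns the flattened conv output (and optionally the
# last conv block's [h, w, c] activation tensor for Grad-CAM).
conv_stack_forward <- function(backbone, img, keep_maps = FALSE) {
  x <- preprocess_image(img, backbone$config)
  for (layer in backbone$conv) {
    x <- if (layer$type == "pool") maxpool2_forward(x) else conv3x3_forward(x, layer)
  }
  if (keep_maps) list(flat = as.vector(x), maps = x) else as.vector(x)
}

# Conv features for a set of images: N x flat_dim matrix.
extract_conv_features <- function(backbone, images) {
  n <- length(images)
  out <- matrix(0, n, backbone$flat_dim)
  for (i in seq_len(n)) out[i, ] <- conv_stack_forward(backbone, images[[i]])
  rownames(out) <- image_ids(images)
  out
}

image_ids <- function(images) {
  vapply(seq_along(images), function(i) {
    images[[i]]$sample_id %||% sprintf("img%04d", i)
  }, character(1))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Dense stack forward (rows = samples): each layer is
# relu(gamma * BN(X W' + b) + beta). Evaluation mode (default) uses the
# stored running statistics, so results are independent of batching;
# training mode uses batch statistics and reports updated running stats.
# keep_cache returns per-layer inputs and pre/post-BN pre-activations.
fc_forward <- function(fc, X, keep_cache = FALSE, training = FALSE) {
  acts <- list(X)
  zs <- list(); xhats <- list(); ss <- list(); mus <- list(); vars <- list()
  A <- X
  for (j in seq_along(fc)) {
    l <- fc[[j]]
    Z <- sweep(A %*% t(l$W), 2L, l$b, `+`)
    if (training) {
      mu <- colMeans(Z)
      v <- colMeans(sweep(Z, 2L, mu)^2)
      fc[[j]]$run_mean <- (1 - BN_MOMENTUM) * l$run_mean + BN_MOMENTUM * mu
      fc[[j]]$run_var <- (1 - BN_MOMENTUM) * l$run_var + BN_MOMENTUM * v
    } else {
      mu <- l$run_mean
      v <- l$run_var
    }
    xhat <- sweep(sweep(Z, 2L, mu), 2L, sqrt(v + BN_EPS), `/`)
    S <- sweep(sweep(xhat, 2L, l$gamma, `*`), 2L, l$beta, `+`)
    A <- pmax(S, 0)
    if (keep_cache) {
      zs[[j]] <- Z; xhats[[j]] <- xhat; ss[[j]] <- S
      mus[[j]] <- mu; vars[[j]] <- v
      acts[[j + 1L]] <- A
    }
  }
  if (keep_cache) {
    list(out = A, acts = acts, zs = zs, xhats = xhats, ss = ss,
         mus = mus, vars = vars, fc = fc)
  } else A
}

#' Extract penultimate-FC features
#'
#' Runs images through the conv stack and fully connected layers and returns
#' the activations of the penultimate fully connected layer, one row per
#' image. A pure function of (weights, preprocessed image): batching has no
#' effect beyond floating-point round-off, and no stochastic layers exist.
#'
#' @param backbone an [build_backbone()] object.
#' @param images non-empty list of `fruit_image`s (or HxWx3 arrays) of
#'   uniform size.
#' @param batch_size images per processing batch.
#' @return `N x feature_dim` numeric matrix, rownames = image ids.
#' @export
extract_features <- function(backbone, images, batch_size = 32) {
  stopifnot(inherits(backbone, "rc_backbone"))
  if (length(images) == 0L) stop_input("no images supplied")
  dims <- vapply(images, function(im) {
    d <- dim(if (inherits(im, "fruit_image")) im$pixels else im)
    paste(d, collapse = "x")
  }, character(1))
  if (length(unique(dims)) != 1L) stop_input("images must have uniform size")
  batch_size <- max(1L, as.integer(batch_size))
  n <- length(images)
  out <- matrix(0, n, backbone$config$feature_dim)
  for (start in seq(1L, n, by = batch_size)) {
    sel <- start:min(n, start + batch_size - 1L)
    cf <- extract_conv_features(backbone, images[sel])
    out[sel, ] <- fc_forward(backbone$fc, cf)
  }
  rownames(out) <- image_ids(images)
  if (any(!is.finite(out))) stop_input("non-finite feature values")
  out
}

# Quick deterministic checksum of the first conv layer (used by tests/logs).
backbone_checksum <- function(backbone) {
  sum(backbone$conv[[1]]$W) + sum(backbone$fc[[1]]$W[1, ])
}
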