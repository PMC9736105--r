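# Bilinear upsampling of a matrix to h_out x w_out (align-corners mapping).
bilinear_upsample <- function(m, h_out, w_out) {
  h_in <- nrow(m); w_in <- ncol(m)
  if (h_in == h_out && w_in == w_out) return(m)
  ri <- if (h_out == 1L) rep(1, h_out) else 1 + (seq_len(h_out) - 1) * (h_in - 1) / (h_out - 1)
  ci <- if (w_out == 1L) rep(1, w_out) else 1 + (seq_len(w_out) - 1) * (w_in - 1) / (w_out - 1)
  r0 <- pmin(floor(ri), h_in - 1L); r0[h_in == 1L] <- 1L
  c0 <- pmin(floor(ci), w_in - 1L); c0[w_in == 1L] <- 1L
  if (h_in == 1L) r0 <- rep(1L, h_out)
  if (w_in == 1L) c0 <- rep(1L, w_out)
  fr <- ri - r0; fc <- ci - c0
  r1 <- pmin(r0 + 1L, h_in); c1 <- pmin(c0 + 1L, w_in)
  m00 <- m[r0, c0, drop = FALSE]; m10 <- m[r1, c0, drop = FALSE]
  m01 <- m[r0, c1, drop = FALSE]; m11 <- m[r1, c1, drop = FALSE]
  wr <- matrix(fr, h_out, w_out); wc <- matrix(fc, h_out, w_out, byrow = TRUE)
  m00 * (1 - wr) * (1 - wc) + m10 * wr * (1 - wc) +
    m01 * (1 - wr) * wc + m11 * wr * wc
}

#' Grad-CAM heatmap for a stage prediction
#'
#' Gradient-weighted class activation mapping: the gradient of the target
#' stage's logit with respect to the last convolutional block's output maps is
#' spatially averaged into per-channel weights; the rectified weighted sum of
#' the maps, upsampled bilinearly to the input size and min-max normalized,
#' shows which image regions drive the prediction. A map whose rectified sum
#' is identically zero is returned as all zeros and flagged rather than
#' renormalized.
#'
#' @param model an `rc_model` (or a list with `backbone` and `head`).
#' @param image a `fruit_image` or HxWx3 pixel array.
#' @param target_stage target class: integer cluster id, or a stage name when
#'   the model carries a stage map; default is the predicted class.
#' @return object of class `rc_heatmap`: `values` (HxW in `[0, 1]` aligned to
#'   the input), `target`, `score` (raw logit), `all_zero` flag, `weights`
#'   (per-channel gradient weights).
#' @export
gradcam_heatmap <- function(model, image, target_stage = NULL) {
  backbone <- model$backbone
  head <- model$head
  if (is.null(backbone) || is.null(head)) stop_input("model must carry backbone and head")
  if (!any(vapply(backbone$conv, function(l) l$type == "conv", logical(1)))) {
    stop_input("unsupported architecture: no convolutional layer")
  }
  fwd <- conv_stack_forward(backbone, image, keep_maps = TRUE)
  maps <- fwd$maps
  X <- matrix(fwd$flat, 1L)
  fc_out <- fc_forward(backbone$fc, X, keep_cache = TRUE)
  logits <- as.vector(head$W %*% t(fc_out$out)) + head$b
  if (is.null(target_stage)) {
    target <- which.max(logits)
  } else if (is.character(target_stage)) {
    if (is.null(model$stage_map)) stop_input("model has no stage map; use a cluster id")
    target <- which(model$stage_map == target_stage)
    if (length(target) != 1L) stop_input("unknown target stage")
  } else {
    target <- as.integer(target_stage)
    if (target < 1L || target > length(logits)) stop_input("target stage out of range")
  }
  # gradient of the target logit w.r.t. the flattened conv output
  # (evaluation mode: BN is a fixed per-unit affine map)
  g <- head$W[target, , drop = FALSE]
  for (j in rev(seq_along(backbone$fc))) {
    l <- backbone$fc[[j]]
    scale <- l$gamma / sqrt(l$run_var + BN_EPS)
    g <- (g * (fc_out$ss[[j]] > 0) * rep(scale, each = nrow(g))) %*% l$W
  }
  grad_maps <- array(as.vector(g), dim(maps))
  w <- apply(grad_maps, 3L, mean)
  cam <- matrix(0, dim(maps)[1], dim(maps)[2])
  for (ch in seq_along(w)) cam <- cam + w[ch] * maps[, , ch]
  cam[cam < 0] <- 0
  px <- if (inherits(image, "fruit_image")) image$pixels else image
  cam_up <- bilinear_upsample(cam, dim(px)[1], dim(px)[2])
  all_zero <- max(cam_up) <= 0
  values <- if (all_zero) cam_up * 0 else {
    (cam_up - min(cam_up)) / (max(cam_up) - min(cam_up))
  }
  structure(list(values = values, target = target, score = logits[target],
                 all_zero = all_zero, weights = w),
            class = "rc_heatmap")
}

#' @export
print.rc_heatmap <- function(x, ...) {
  cat(sprintf("<rc_heatmap %dx%d target=%d score=%.4g%s>\n",
              nrow(x$values), ncol(x$values), x$target, x$score,
              if (x$all_zero) ", all-zero" else ""))
  invisible(x)
}

#' Fraction of top-decile heat inside a bounding box
#'
#' Localization statistic: the share of total heat carried by the hottest 10%
#' of pixels that falls inside `bbox` (`c(x0, x1, y0, y1)`, e.g. the rendered
#' crack region of a synthetic image).
#'
#' @param heatmap an `rc_heatmap` (or plain matrix).
#' @param bbox integer vector `c(x0, x1, y0, y1)` in pixel coordinates.
#' @return fraction in `[0, 1]` (`NA` for an all-zero map).
#' @export
heat_in_bbox <- function(heatmap, bbox) {
  v <- if (inherits(heatmap, "rc_heatmap")) heatmap$values else heatmap
  if (max(v) <= 0) return(NA_real_)
  thr <- stats::quantile(v, 0.9)
  top <- v >= thr
  inside <- matrix(FALSE, nrow(v), ncol(v))
  inside[bbox[3]:bbox[4], bbox[1]:bbox[2]] <- TRUE
  sum(v[top & inside]) / sum(v[top])
}

#' Overlay a heatmap on its image
#'
#' Alpha-blends a warm-to-cold colormap over the image, with per-pixel opacity
#' proportional to the heat, so that a zero map returns the original image
#' unchanged.
#'
#' @param image `fruit_image` or HxWx3 array (0..255).
#' @param heatmap `rc_heatmap` or HxW matrix in `[0, 1]` of matching size.
#' @param alpha maximum blend opacity.
#' @param file optional path; when given the overlay is written as PNG.
#' @return HxWx3 numeric array in 0..255.
#' @export
heatmap_overlay <- function(image, heatmap, alpha = 0.6, file = NULL) {
  px <- if (inherits(image, "fruit_image")) image$pixels else image
  v <- if (inherits(heatmap, "rc_heatmap")) heatmap$values else heatmap
  if (!all(dim(px)[1:2] == dim(v))) stop_input("image and heatmap dimensions differ")
  ramp <- grDevices::colorRamp(c("navy", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(v))
  out <- array(0, dim(px))
  a <- alpha * v
  for (ch in 1:3) {
    out[, , ch] <- (1 - a) * px[, , ch] + a * matrix(cols[, ch], nrow(v), ncol(v))
  }
  out[out < 0] <- 0
  out[out > 255] <- 255
  if (!is.null(file)) {
    EBImage::writeImage(EBImage::Image(aperm(out / 255, c(2, 1, 3)),
                                       colormode = "Color"), file)
  }
  out
}
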