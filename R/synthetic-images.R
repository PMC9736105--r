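#' Stage phenotype parameters
#'
#' Parameterizes how a maturity stage expresses itself in a rendered fruit
#' image: peel hue (degrees on the HSV wheel), peel texture roughness, the
#' fraction of the fruit area opened by a peel crack, and the fraction of the
#' fruit area showing exposed seeds through that crack. Unripe fruit have a
#' sleek, closed (indehiscent) peel; ripe fruit a slightly cracked peel;
#' overripe fruit a rough, clearly cracked peel with exposed seeds.
#'
#' @param stage one of `"unripe"`, `"ripe"`, `"overripe"`.
#' @param peel_hue mean peel hue in degrees (0-360).
#' @param peel_hue_jitter standard deviation of the per-image hue draw, degrees.
#' @param peel_roughness texture-noise amplitude in `[0, 1]`.
#' @param crack_fraction crack area as a fraction of fruit area in `[0, 1]`.
#'   Must be 0 for unripe fruit (their peel never opens).
#' @param seed_exposure exposed-seed area as a fraction of fruit area; cannot
#'   exceed `crack_fraction` (seeds are only visible through the crack).
#' @return an object of class `stage_phenotype`.
#' @export
stage_phenotype <- function(stage, peel_hue, peel_hue_jitter = 6,
                            peel_roughness = 0.1, crack_fraction = 0,
                            seed_exposure = 0) {
  stage <- match.arg(stage, MATURITY_STAGES)
  assert_scalar_number(peel_hue, "peel_hue", 0, 360)
  assert_scalar_number(peel_hue_jitter, "peel_hue_jitter", 0, 90)
  assert_scalar_number(peel_roughness, "peel_roughness", 0, 1)
  assert_scalar_number(crack_fraction, "crack_fraction", 0, 1)
  assert_scalar_number(seed_exposure, "seed_exposure", 0, 1)
  if (stage == "unripe" && crack_fraction > 0) {
    stop_input("unripe fruit are indehiscent: crack_fraction must be 0")
  }
  if (seed_exposure > crack_fraction) {
    stop_input("seed_exposure cannot exceed crack_fraction")
  }
  structure(list(stage = stage, peel_hue = peel_hue,
                 peel_hue_jitter = peel_hue_jitter,
                 peel_roughness = peel_roughness,
                 crack_fraction = crack_fraction,
                 seed_exposure = seed_exposure),
            class = "stage_phenotype")
}

#' Default phenotypes for the three maturity stages
#'
#' The three stages are separated mainly by peel hue (green -> yellow-brown ->
#' brown), with texture roughness, crack opening and seed exposure increasing
#' with maturity. `separation` in `[0, 1]` shrinks the hue bands toward their
#' common center and widens the per-image jitter, so that adjacent stages
#' overlap slightly at moderate values (as real maturity classes do) and are
#' cleanly separable at `separation = 1`.
#'
#' @param separation stage-separability knob in `[0, 1]`; default 0.7.
#' @return named list of [stage_phenotype()] objects.
#' @export
default_phenotypes <- function(separation = 0.7) {
  assert_scalar_number(separation, "separation", 0, 1)
  hue_center <- 65
  hues <- hue_center + (c(unripe = 105, ripe = 65, overripe = 25) - hue_center) * separation
  jitter <- 6 + 10 * (1 - separation)
  list(
    unripe   = stage_phenotype("unripe", hues[["unripe"]], jitter, 0.05, 0,    0),
    ripe     = stage_phenotype("ripe", hues[["ripe"]], jitter, 0.15, 0.06, 0.02),
    overripe = stage_phenotype("overripe", hues[["overripe"]], jitter, 0.35, 0.15, 0.08)
  )
}

# Half-width t (in unit-disk coordinates) of a band through the center of an
# ellipse covering `frac` of its area: solves (2/pi)(t sqrt(1-t^2) + asin t) = frac.
crack_band_halfwidth <- function(frac) {
  if (frac <= 0) return(0)
  if (frac >= 1) return(1)
  f <- function(t) (2 / pi) * (t * sqrt(1 - t^2) + asin(t)) - frac
  stats::uniroot(f, c(0, 1), tol = 1e-10)$root
}

# Smooth low-frequency noise field, H x W, sd ~ amp.
smooth_noise <- function(h, w, amp, cells = 8) {
  coarse <- matrix(rnorm(cells * cells, 0, amp), cells, cells)
  bilinear_upsample(coarse, h, w)
}

#' Render a synthetic fruit image
#'
#' Draws an elliptical fruit on a textured soil-colored background. The peel
#' hue is drawn from the stage's hue band; texture roughness modulates the
#' brightness channel; if `crack_fraction > 0` a dark band (the opened peel
#' crack) is cut across the fruit with area exactly `crack_fraction` of the
#' fruit area, and seed-colored blobs are placed inside it until they cover
#' `seed_exposure` of the fruit area. Additive Gaussian pixel noise is applied
#' last. Rendering is bit-deterministic for a fixed `rng_seed`.
#'
#' @param phenotype a [stage_phenotype()].
#' @param size image side in pixels (square), at least 32.
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @param noise_sd additive pixel-noise standard deviation (0-255 scale).
#' @param sample_id optional identifier carried on the image.
#' @param keep_masks if `TRUE`, attach logical fruit/crack/seed masks (used by
#'   rendering diagnostics and localization tests).
#' @return a `fruit_image`: list with `pixels` (`size x size x 3` integer array
#'   in 0..255), `truth_stage`, `sample_id`, `crack_bbox` (`c(x0, x1, y0, y1)`
#'   in pixel coordinates, or `NULL` when no crack is rendered).
#' @export
generate_image <- function(phenotype, size = 64, rng_seed = NULL, noise_sd = 4,
                           sample_id = NULL, keep_masks = FALSE) {
  stopifnot(inherits(phenotype, "stage_phenotype"))
  assert_scalar_number(size, "size", 32)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  size <- as.integer(size)
  with_rng_seed(rng_seed, {
    h <- w <- size
    xg <- matrix(rep(seq_len(w), each = h), h, w)   # column index
    yg <- matrix(rep(seq_len(h), times = w), h, w)  # row index

    # fruit ellipse with mild geometric jitter
    cx <- w / 2 + runif(1, -0.03, 0.03) * w
    cy <- h / 2 + runif(1, -0.03, 0.03) * h
    a <- 0.40 * w * (1 + runif(1, -0.05, 0.05))
    b <- 0.36 * h * (1 + runif(1, -0.05, 0.05))
    xi <- (xg - cx) / a
    eta <- (yg - cy) / b
    r2 <- xi^2 + eta^2
    fruit <- r2 <= 1

    # background: litter-brown with low-frequency mottle
    bg_base <- c(125, 112, 88)
    mottle <- smooth_noise(h, w, 18)
    px <- array(0, c(h, w, 3))
    for (ch in 1:3) px[, , ch] <- bg_base[ch] + mottle + rnorm(h * w, 0, 6)

    # peel color from the stage hue band
    hue <- (phenotype$peel_hue + rnorm(1, 0, phenotype$peel_hue_jitter)) %% 360
    peel_rgb <- grDevices::col2rgb(grDevices::hsv(hue / 360, 0.72, 0.62))[, 1]
    shade <- 1 - 0.30 * r2          # radial shading for a rounded look
    rough <- 1 + phenotype$peel_roughness *
      (0.8 * smooth_noise(h, w, 0.5, cells = 12) + rnorm(h * w, 0, 0.25))
    for (ch in 1:3) {
      layer <- px[, , ch]
      layer[fruit] <- (peel_rgb[ch] * shade * rough)[fruit]
      px[, , ch] <- layer
    }

    # crack: band through the fruit center covering crack_fraction of its area
    crack <- matrix(FALSE, h, w)
    seeds <- matrix(FALSE, h, w)
    crack_bbox <- NULL
    if (phenotype$crack_fraction > 0) {
      t_half <- crack_band_halfwidth(phenotype$crack_fraction)
      phi <- runif(1, 0, pi)
      proj <- xi * cos(phi) + eta * sin(phi)
      crack <- fruit & (abs(proj) <= t_half)
      crack_col <- c(62, 42, 30)
      cr_noise <- rnorm(h * w, 0, 8)
      for (ch in 1:3) {
        layer <- px[, , ch]
        layer[crack] <- (crack_col[ch] + cr_noise)[crack]
        px[, , ch] <- layer
      }
      # seed blobs inside the crack
      target <- phenotype$seed_exposure * sum(fruit)
      if (target >= 1 && any(crack)) {
        idx <- which(crack)
        seed_r <- max(2, 0.045 * size)
        tries <- 0
        while (sum(seeds) < target && tries < 400) {
          ctr <- idx[sample.int(length(idx), 1)]
          scy <- (ctr - 1) %% h + 1
          scx <- (ctr - 1) %/% h + 1
          rx <- seed_r * runif(1, 0.8, 1.3)
          ry <- seed_r * runif(1, 0.8, 1.3)
          blob <- (((xg - scx) / rx)^2 + ((yg - scy) / ry)^2) <= 1
          seeds <- seeds | (blob & crack)
          tries <- tries + 1
        }
        seed_col <- c(152, 106, 58)
        sd_noise <- rnorm(h * w, 0, 10)
        for (ch in 1:3) {
          layer <- px[, , ch]
          layer[seeds] <- (seed_col[ch] + sd_noise)[seeds]
          px[, , ch] <- layer
        }
      }
      if (any(crack)) {
        cols <- range(xg[crack]); rows <- range(yg[crack])
        crack_bbox <- c(x0 = cols[1], x1 = cols[2], y0 = rows[1], y1 = rows[2])
      }
    }

    if (noise_sd > 0) px <- px + array(rnorm(h * w * 3, 0, noise_sd), c(h, w, 3))
    px <- array(as.integer(pmin(255, pmax(0, round(px)))), c(h, w, 3))

    img <- structure(list(pixels = px,
                          truth_stage = phenotype$stage,
                          sample_id = sample_id,
                          crack_bbox = crack_bbox),
                     class = "fruit_image")
    if (keep_masks) img$masks <- list(fruit = fruit, crack = crack, seeds = seeds)
    img
  })
}

#' @export
print.fruit_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fruit_image %dx%d, stage: %s, id: %s%s>\n", d[1], d[2],
              x$truth_stage %||% "unknown", x$sample_id %||% "-",
              if (is.null(x$crack_bbox)) "" else ", cracked"))
  invisible(x)
}

#' Generate a labelled synthetic image set
#'
#' Renders `n_per_stage` images per maturity stage (or stage-specific counts),
#' with per-image jitter of the crack/seed/roughness parameters around the
#' stage phenotype, and returns them in shuffled order with truth labels.
#'
#' @param n_per_stage a single count, or a named vector with entries
#'   `unripe`, `ripe`, `overripe`.
#' @param size image side in pixels.
#' @param rng_seed integer seed controlling every draw.
#' @param separation stage-separability knob passed to [default_phenotypes()].
#' @param phenotypes optional named list of [stage_phenotype()]s overriding
#'   the defaults.
#' @param noise_sd additive pixel-noise SD.
#' @param keep_masks attach rendering masks to each image.
#' @return list of `fruit_image` objects with `truth_stage` and `sample_id` set.
#' @export
generate_dataset <- function(n_per_stage, size = 64, rng_seed = NULL,
                             separation = 0.7, phenotypes = NULL,
                             noise_sd = 4, keep_masks = FALSE) {
  if (length(n_per_stage) == 1L) {
    counts <- stats::setNames(rep(as.integer(n_per_stage), 3), MATURITY_STAGES)
  } else {
    if (!all(MATURITY_STAGES %in% names(n_per_stage))) {
      stop_input("n_per_stage must be a single count or named for all three stages")
    }
    counts <- as.integer(n_per_stage[MATURITY_STAGES])
    names(counts) <- MATURITY_STAGES
  }
  if (any(counts < 1)) stop_input("need at least one image per stage")
  phenotypes <- phenotypes %||% default_phenotypes(separation)
  with_rng_seed(rng_seed, {
    images <- list()
    i <- 0
    for (stage in MATURITY_STAGES) {
      ph <- phenotypes[[stage]]
      for (j in seq_len(counts[[stage]])) {
        i <- i + 1
        jit <- stage_phenotype(
          stage = ph$stage,
          peel_hue = ph$peel_hue,
          peel_hue_jitter = ph$peel_hue_jitter,
          peel_roughness = min(1, max(0, ph$peel_roughness * runif(1, 0.8, 1.2))),
          crack_fraction = if (ph$crack_fraction > 0)
            min(1, ph$crack_fraction * runif(1, 0.75, 1.25)) else 0,
          seed_exposure = 0  # set below, capped by the jittered crack
        )
        if (ph$seed_exposure > 0) {
          jit$seed_exposure <- min(jit$crack_fraction,
                                   ph$seed_exposure * runif(1, 0.75, 1.25))
        }
        images[[i]] <- generate_image(jit, size = size, rng_seed = NULL,
                                      noise_sd = noise_sd,
                                      sample_id = sprintf("s%04d", i),
                                      keep_masks = keep_masks)
      }
    }
    images[sample.int(length(images))]
  })
}

#' Truth stages of a generated image set
#' @param images list of `fruit_image` objects.
#' @return character vector (NA where an image carries no truth label).
#' @export
truth_stages <- function(images) {
  vapply(images, function(im) im$truth_stage %||% NA_character_, character(1))
}

# Mean HSV hue (degrees) of the central fruit region; used by sanity checks.
mean_fruit_hue <- function(img) {
  px <- img$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  rows <- seq(round(h * 0.4), round(h * 0.6))
  cols <- seq(round(w * 0.4), round(w * 0.6))
  if (!is.null(img$masks)) {
    m <- img$masks$fruit & !img$masks$crack
  } else {
    m <- matrix(FALSE, h, w); m[rows, cols] <- TRUE
  }
  r <- mean(px[, , 1][m]); g <- mean(px[, , 2][m]); b <- mean(px[, , 3][m])
  hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 255)
  hsv[1, 1] * 360
}
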