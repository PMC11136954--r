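# Offline augmentations. Geometric ops transform image and mask through one
# shared inverse coordinate map -- bilinear sampling for the image, nearest
# neighbour for the mask (no label bleeding), background fill outside the
# source frame. Photometric ops (blur, sharpen, brightness) leave the mask
# untouched. Pixel coordinates are 0-based (row, col) with the origin at
# the top-left; positive rotation angles turn counter-clockwise.

AUG_OPS <- c("horizontal_flip", "vertical_flip", "rotate", "translate",
             "crop_and_pad", "rotate_and_crop", "gaussian_blur", "sharpen",
             "brightness")

#' Augmentation specification
#'
#' @param op one of `"horizontal_flip"`, `"vertical_flip"`, `"rotate"`,
#'   `"translate"`, `"crop_and_pad"`, `"rotate_and_crop"`,
#'   `"gaussian_blur"`, `"sharpen"`, `"brightness"`.
#' @param params named list of op parameters; unset parameters are drawn
#'   from their documented default ranges using `seed`. Recognized:
#'   `angle` (degrees, rotate ops, default range ±25), `dx`/`dy`
#'   (translate fractions, ±0.1), `scale` (crop fraction, 0.8-1),
#'   `sigma` (blur, 0.5-1.5), `alpha` (sharpen, 0.5-1), `delta`
#'   (brightness, ±0.2).
#' @param seed integer controlling any randomly drawn parameters.
#' @return object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(op, params = list(), seed = 1L) {
  op <- match.arg(op, AUG_OPS)
  structure(list(op = op, params = params, seed = as.integer(seed)),
            class = "augmentation_spec")
}

# Hard validity limits per parameter; the narrower default ranges are only
# used when a value is drawn randomly.
AUG_LIMITS <- list(angle = c(-180, 180), dx = c(-0.5, 0.5), dy = c(-0.5, 0.5),
                   scale = c(0.5, 1), sigma = c(0.1, 5), alpha = c(0, 2),
                   delta = c(-0.5, 0.5))

aug_param <- function(spec, name, range) {
  if (!is.null(spec$params[[name]])) {
    v <- spec$params[[name]]
    lim <- AUG_LIMITS[[name]]
    if (v < lim[1] - 1e-9 || v > lim[2] + 1e-9)
      stop("augment: parameter '", name, "' = ", v,
           " outside the allowed range [", lim[1], ", ", lim[2], "]")
    return(v)
  }
  with_seed(spec$seed, stats::runif(1, range[1], range[2]))
}

# ---- samplers ---------------------------------------------------------------

# Inverse-map warp. inv(r, c) returns source (row, col) 0-based matrices for
# the 0-based destination grid. Image: bilinear with background fill;
# mask: nearest with background fill (class 0).
warp_pair <- function(image, mask, inv) {
  H <- nrow(mask); W <- ncol(mask)
  g <- expand.grid(r = 0:(H - 1), c = 0:(W - 1))
  src <- inv(g$r, g$c)
  sr <- src$r; sc <- src$c
  # nearest for the mask
  nr <- round(sr); nc <- round(sc)
  valid <- nr >= 0 & nr <= H - 1 & nc >= 0 & nc <= W - 1
  m <- integer(H * W)
  m[valid] <- mask[cbind(nr[valid] + 1, nc[valid] + 1)]
  new_mask <- matrix(m, H, W)
  # bilinear for the image
  r0 <- pmin(pmax(floor(sr), 0), H - 1); c0 <- pmin(pmax(floor(sc), 0), W - 1)
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  fr <- pmin(pmax(sr - r0, 0), 1); fc <- pmin(pmax(sc - c0, 0), 1)
  out <- array(0, dim = dim(image))
  for (ch in seq_len(dim(image)[3])) {
    pl <- image[, , ch]
    v <- (1 - fr) * (1 - fc) * pl[cbind(r0 + 1, c0 + 1)] +
      fr * (1 - fc) * pl[cbind(r1 + 1, c0 + 1)] +
      (1 - fr) * fc * pl[cbind(r0 + 1, c1 + 1)] +
      fr * fc * pl[cbind(r1 + 1, c1 + 1)]
    v[!valid] <- 0
    out[, , ch] <- matrix(v, H, W)
  }
  list(image = out, mask = new_mask)
}

# Separable Gaussian blur with replicate padding, per channel.
blur_gaussian <- function(image, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k <- k / sum(k)
  H <- dim(image)[1]; W <- dim(image)[2]; C <- dim(image)[3]
  # replicate-pad then valid convolution; channels ride the batch dim
  ri <- c(rep(1, rad), 1:H, rep(H, rad))
  ci <- c(rep(1, rad), 1:W, rep(W, rad))
  xp <- array(image[ri, ci, ], dim = c(H + 2 * rad, W + 2 * rad, 1, C))
  kv <- array(k, dim = c(2 * rad + 1, 1, 1, 1))
  kh <- array(k, dim = c(1, 2 * rad + 1, 1, 1))
  y <- conv2d_fwd_cpp(xp, kv, numeric(0), 1L, 1L, 0L, 0L, 1L, 1L)
  y <- conv2d_fwd_cpp(y, kh, numeric(0), 1L, 1L, 0L, 0L, 1L, 1L)
  array(y, dim = c(H, W, C))
}

resize_nearest_mask <- function(mask, H2, W2) {
  H <- nrow(mask); W <- ncol(mask)
  ri <- pmin(pmax(floor(((0:(H2 - 1)) + 0.5) * H / H2), 0), H - 1) + 1
  ci <- pmin(pmax(floor(((0:(W2 - 1)) + 0.5) * W / W2), 0), W - 1) + 1
  mask[ri, ci, drop = FALSE]
}

resize_bilinear_image <- function(image, H2, W2) {
  x <- array(image, dim = c(dim(image)[1:2], 1, dim(image)[3]))
  y <- upsample_bilinear_fwd_cpp(x, as.integer(H2), as.integer(W2))
  array(y, dim = c(H2, W2, dim(image)[3]))
}

# ---- the nine ops -----------------------------------------------------------

#' Apply one augmentation to a sample pair
#'
#' Geometric ops move image and mask identically; photometric ops leave
#' the mask bitwise unchanged. Output size always equals input size.
#'
#' @param pair a `sample_pair`.
#' @param spec an [augmentation_spec()].
#' @return a new `sample_pair` with the op name appended to the id.
#' @export
augment_pair <- function(pair, spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  img <- pair$image; mask <- pair$mask
  H <- nrow(mask); W <- ncol(mask)
  res <- switch(spec$op,
    horizontal_flip = list(image = img[, W:1, , drop = FALSE],
                           mask = mask[, W:1, drop = FALSE]),
    vertical_flip = list(image = img[H:1, , , drop = FALSE],
                         mask = mask[H:1, , drop = FALSE]),
    rotate = {
      th <- aug_param(spec, "angle", c(-25, 25)) * pi / 180
      cy <- (H - 1) / 2; cx <- (W - 1) / 2
      warp_pair(img, mask, function(r, c) {
        list(r = cos(th) * (r - cy) - sin(th) * (c - cx) + cy,
             c = sin(th) * (r - cy) + cos(th) * (c - cx) + cx)
      })
    },
    translate = {
      dy <- round(aug_param(spec, "dy", c(-0.1, 0.1)) * H)
      dx <- round(aug_param(spec, "dx", c(-0.1, 0.1)) * W)
      warp_pair(img, mask, function(r, c) list(r = r - dy, c = c - dx))
    },
    crop_and_pad = {
      sc <- aug_param(spec, "scale", c(0.8, 1))
      h2 <- max(1L, round(sc * H)); w2 <- max(1L, round(sc * W))
      r0 <- with_seed(spec$seed + 1L, sample.int(H - h2 + 1L, 1L)) - 1L
      c0 <- with_seed(spec$seed + 2L, sample.int(W - w2 + 1L, 1L)) - 1L
      pr <- (H - h2) %/% 2L; pc <- (W - w2) %/% 2L
      im2 <- array(0, dim = dim(img)); mk2 <- matrix(0L, H, W)
      im2[pr + 1:h2, pc + 1:w2, ] <- img[r0 + 1:h2, c0 + 1:w2, , drop = FALSE]
      mk2[pr + 1:h2, pc + 1:w2] <- mask[r0 + 1:h2, c0 + 1:w2]
      list(image = im2, mask = mk2)
    },
    rotate_and_crop = {
      th <- aug_param(spec, "angle", c(-25, 25))
      rot <- augment_pair(pair, augmentation_spec("rotate",
                                                  list(angle = th),
                                                  spec$seed))
      keep <- 0.85
      h2 <- max(1L, round(keep * H)); w2 <- max(1L, round(keep * W))
      r0 <- (H - h2) %/% 2L; c0 <- (W - w2) %/% 2L
      list(image = resize_bilinear_image(
             rot$image[r0 + 1:h2, c0 + 1:w2, , drop = FALSE], H, W),
           mask = resize_nearest_mask(rot$mask[r0 + 1:h2, c0 + 1:w2,
                                               drop = FALSE], H, W))
    },
    gaussian_blur = {
      sg <- aug_param(spec, "sigma", c(0.5, 1.5))
      list(image = blur_gaussian(img, sg), mask = mask)
    },
    sharpen = {
      al <- aug_param(spec, "alpha", c(0.5, 1))
      sm <- blur_gaussian(img, 1)
      list(image = pmin(pmax(img + al * (img - sm), 0), 1), mask = mask)
    },
    brightness = {
      dl <- aug_param(spec, "delta", c(-0.2, 0.2))
      list(image = pmin(pmax(img * (1 + dl), 0), 1), mask = mask)
    })
  new_sample_pair(res$image, res$mask, paste0(pair$id, "_", spec$op))
}

#' Default set of the nine offline augmentations
#' @param seed base seed; op k uses `seed + k`.
#' @return list of nine [augmentation_spec()]s, one per op.
#' @export
default_augmentations <- function(seed = 1L) {
  lapply(seq_along(AUG_OPS), function(k)
    augmentation_spec(AUG_OPS[k], seed = seed + k))
}

#' Offline dataset expansion (training split only)
#'
#' Returns the original pairs plus one augmented copy per spec per pair
#' (nine specs by default: a tenfold expansion). Augmented ids record the
#' source id and op, so split membership remains traceable and no
#' augmented copy can leak out of the training split.
#'
#' @param pairs training-split `sample_pair`s.
#' @param specs list of [augmentation_spec()]s.
#' @param seed base seed; pair i / spec k uses `seed + 1000*k + i` so the
#'   expansion is reproducible.
#' @return list of `(1 + length(specs)) * length(pairs)` pairs.
#' @export
expand_offline <- function(pairs, specs = default_augmentations(), seed = 1L) {
  out <- pairs
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    for (i in seq_along(pairs)) {
      spi <- augmentation_spec(sp$op, sp$params, seed + 1000L * k + i)
      out[[length(out) + 1L]] <- augment_pair(pairs[[i]], spi)
    }
  }
  out
}
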