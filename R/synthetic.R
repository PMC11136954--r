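# Deterministic synthetic crop/weed scene generator. Scenes emulate the
# structure of field imagery used for seedling/weed segmentation: a
# textured soil background under uneven illumination, broad-leaved bean
# seedlings drawn as clusters of overlapping ellipse "leaves" (class 1),
# and weeds drawn as thin random-walk polylines or small ragged blobs
# (class 2). The mask is the exact rasterization of the drawn shapes, so
# image and label are pixel-co-registered by construction. The shapes
# deliberately stress leaf-edge handling (touching leaves) and small-object
# recognition (thin weeds).

#' Synthetic scene specification
#'
#' Defaults describe the fixture-scale study condition used throughout the
#' test suite: 64 x 64 scenes with a handful of seedlings and weeds.
#'
#' @param size `c(H, W)`, both divisible by 8.
#' @param n_seedlings,n_weeds shape counts (non-negative).
#' @param seedling_radius_range leaf semi-major-axis range in pixels.
#' @param weed_thickness_range weed stroke thickness range in pixels.
#' @param illumination_gradient relative strength of a linear illumination
#'   ramp across the scene (0 = flat lighting).
#' @param noise_sd standard deviation of per-pixel intensity noise (on the
#'   `[0, 1]` scale).
#' @param seed integer; a spec renders to a bit-identical scene every time.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(size = c(64L, 64L), n_seedlings = 3L, n_weeds = 4L,
                       seedling_radius_range = c(6, 14),
                       weed_thickness_range = c(2, 4),
                       illumination_gradient = 0.25, noise_sd = 0.03,
                       seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 2 || any(size %% 8L != 0L))
    stop("size must be c(H, W) with both divisible by 8")
  if (n_seedlings < 0 || n_weeds < 0) stop("shape counts must be >= 0")
  if (max(seedling_radius_range) > min(size))
    stop("seedling radius ", max(seedling_radius_range),
         " exceeds the canvas size ", min(size))
  structure(list(size = size, n_seedlings = as.integer(n_seedlings),
                 n_weeds = as.integer(n_weeds),
                 seedling_radius_range = seedling_radius_range,
                 weed_thickness_range = weed_thickness_range,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

# 0-based pixel-centre coordinate grids.
pixel_grid <- function(H, W) {
  list(r = matrix(0:(H - 1), H, W), c = matrix(0:(W - 1), H, W, byrow = TRUE))
}

ellipse_inside <- function(g, cy, cx, a, b, phi) {
  u <- cos(phi) * (g$c - cx) + sin(phi) * (g$r - cy)
  v <- -sin(phi) * (g$c - cx) + cos(phi) * (g$r - cy)
  (u / a)^2 + (v / b)^2 <= 1
}

disc_inside <- function(g, cy, cx, rad) {
  (g$r - cy)^2 + (g$c - cx)^2 <= rad^2
}

#' Render a scene specification into an image/mask pair
#'
#' Seedlings are drawn first, weeds afterwards; later shapes occlude
#' earlier ones. The drawn shape list is attached as attribute `"shapes"`
#' (type, geometry, class) so an independent membership test can re-derive
#' the mask.
#'
#' @param spec a [scene_spec()].
#' @return a `sample_pair` (image `[H, W, 3]` in `[0, 1]`, integer mask,
#'   id `scene_<seed>`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    H <- spec$size[1]; W <- spec$size[2]
    g <- pixel_grid(H, W)
    # soil background: brownish base + smooth mottling
    img <- array(0, dim = c(H, W, 3))
    base <- c(0.45, 0.33, 0.22)
    mottle <- blur_gaussian(array(stats::runif(H * W), dim = c(H, W, 1)), 2)
    mottle <- 0.12 * (mottle[, , 1] - mean(mottle)) / (stats::sd(mottle) + 1e-9)
    for (ch in 1:3) img[, , ch] <- base[ch] * (1 + mottle)
    mask <- matrix(0L, H, W)
    shapes <- list()

    paint <- function(inside, col) {
      jig <- 1 + 0.08 * (matrix(stats::runif(H * W), H, W) - 0.5)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[inside] <- (col[ch] * jig)[inside]
        img[, , ch] <<- pl
      }
    }

    # bean seedlings: 3-5 overlapping elliptical leaves around a centre
    for (s in seq_len(spec$n_seedlings)) {
      cy <- stats::runif(1, 0.15 * H, 0.85 * H)
      cx <- stats::runif(1, 0.15 * W, 0.85 * W)
      n_leaves <- sample(3:5, 1)
      col <- c(0.22, 0.55, 0.20) * stats::runif(1, 0.85, 1.15)
      for (l in seq_len(n_leaves)) {
        a <- stats::runif(1, spec$seedling_radius_range[1],
                          spec$seedling_radius_range[2])
        b <- a * stats::runif(1, 0.35, 0.55)
        phi <- stats::runif(1, 0, pi)
        ly <- cy + stats::rnorm(1, 0, a / 3)
        lx <- cx + stats::rnorm(1, 0, a / 3)
        inside <- ellipse_inside(g, ly, lx, a, b, phi)
        paint(inside, col)
        mask[inside] <- 1L
        shapes[[length(shapes) + 1L]] <-
          list(type = "ellipse", cy = ly, cx = lx, a = a, b = b, phi = phi,
               class = 1L)
      }
    }

    # weeds: thin random-walk polylines (stamped discs) or ragged blobs
    for (wd in seq_len(spec$n_weeds)) {
      thick <- stats::runif(1, spec$weed_thickness_range[1],
                            spec$weed_thickness_range[2])
      rad <- thick / 2
      col <- c(0.55, 0.62, 0.18) * stats::runif(1, 0.85, 1.15)
      if (stats::runif(1) < 0.75) {            # polyline
        py <- stats::runif(1, 0.1 * H, 0.9 * H)
        px <- stats::runif(1, 0.1 * W, 0.9 * W)
        th <- stats::runif(1, 0, 2 * pi)
        nstep <- sample(8:16, 1)
        inside <- matrix(FALSE, H, W)
        pts <- list()
        for (st in seq_len(nstep)) {
          inside <- inside | disc_inside(g, py, px, rad)
          pts[[st]] <- c(py, px)
          th <- th + stats::rnorm(1, 0, 0.5)
          py <- min(max(py + 1.5 * sin(th), 0), H - 1)
          px <- min(max(px + 1.5 * cos(th), 0), W - 1)
        }
        paint(inside, col)
        mask[inside] <- 2L
        shapes[[length(shapes) + 1L]] <-
          list(type = "polyline", points = do.call(rbind, pts), rad = rad,
               class = 2L)
      } else {                                  # ragged blob: disc cluster
        cy <- stats::runif(1, 0.1 * H, 0.9 * H)
        cx <- stats::runif(1, 0.1 * W, 0.9 * W)
        inside <- matrix(FALSE, H, W)
        centres <- list()
        for (bl in seq_len(sample(3:6, 1))) {
          by <- cy + stats::rnorm(1, 0, 1.5)
          bx <- cx + stats::rnorm(1, 0, 1.5)
          br <- rad * stats::runif(1, 0.8, 1.6)
          inside <- inside | disc_inside(g, by, bx, br)
          centres[[bl]] <- c(by, bx, br)
        }
        paint(inside, col)
        mask[inside] <- 2L
        shapes[[length(shapes) + 1L]] <-
          list(type = "blob", discs = do.call(rbind, centres), class = 2L)
      }
    }

    # uneven illumination + pixel noise (photometric only; mask untouched)
    dirn <- stats::runif(1, 0, 2 * pi)
    ramp <- (g$r / max(H - 1, 1) - 0.5) * sin(dirn) +
      (g$c / max(W - 1, 1) - 0.5) * cos(dirn)
    light <- 1 + spec$illumination_gradient * ramp
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * light +
        stats::rnorm(H * W, 0, spec$noise_sd)
    img <- pmin(pmax(img, 0), 1)

    pair <- new_sample_pair(img, mask, paste0("scene_", spec$seed))
    attr(pair, "shapes") <- shapes
    pair
  })
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes `n` folders (`scene_001`, ...) each holding `false.png` and
#' `gt.png`, mimicking the public dataset layout, plus a `manifest.csv`.
#' Scene i uses seed `template$seed + i - 1`.
#'
#' @param n number of scenes (>= 1).
#' @param template a [scene_spec()] providing all other parameters.
#' @param out output directory.
#' @param force overwrite a non-empty existing directory.
#' @return invisibly, the manifest data frame.
#' @export
make_synthetic_dataset <- function(n, template = scene_spec(), out,
                                   force = FALSE) {
  stopifnot(n >= 1)
  if (dir.exists(out) && length(list.files(out)) && !force)
    stop("output directory ", out, " is not empty; use force = TRUE")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("scene_%03d", seq_len(n))
  for (i in seq_len(n)) {
    sp <- template
    sp$seed <- template$seed + i - 1L
    pair <- render_scene(sp)
    write_sample_pair(pair, file.path(out, ids[i]))
  }
  manifest <- data.frame(id = ids, seed = template$seed + seq_len(n) - 1L)
  utils::write.csv(manifest, file.path(out, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Render a list of scenes in memory
#'
#' @param n number of scenes.
#' @param template a [scene_spec()]; scene i uses `template$seed + i - 1`.
#' @return list of `sample_pair`s.
#' @export
render_scenes <- function(n, template = scene_spec()) {
  lapply(seq_len(n), function(i) {
    sp <- template
    sp$seed <- template$seed + i - 1L
    render_scene(sp)
  })
}
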