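# Paired image/mask dataset handling. The on-disk layout mirrors the public
# bean-seedling/weed repository: one folder per sample holding the RGB
# image `false.png` and the color-coded label `gt.png`. Mask colors are
# mapped to class indices through a palette; the split is 7:2:1
# train/test/val.

#' Default mask palette
#'
#' @return 3 x 3 matrix (rows = classes background / bean_seedling / weed)
#'   of RGB values in `[0, 1]`: black, green, red.
#' @export
default_palette <- function() {
  p <- rbind(background = c(0, 0, 0),
             bean_seedling = c(0, 1, 0),
             weed = c(1, 0, 0))
  colnames(p) <- c("r", "g", "b")
  p
}

#' Map an RGB mask image to 0-based class indices
#'
#' @param rgb array `[H, W, 3]` in `[0, 1]` (e.g. from [png::readPNG()]).
#' @param palette class-by-RGB matrix; see [default_palette()].
#' @return integer matrix `[H, W]` of class indices; colors not in the
#'   palette raise an error naming the offending values.
#' @export
mask_from_rgb <- function(rgb, palette = default_palette()) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] >= 3)
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  key <- paste(round(rgb[, , 1] * 255), round(rgb[, , 2] * 255),
               round(rgb[, , 3] * 255))
  pk <- paste(round(palette[, 1] * 255), round(palette[, 2] * 255),
              round(palette[, 3] * 255))
  idx <- match(key, pk)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("mask contains colors not in the palette (R G B, 0-255): ",
         paste(utils::head(bad, 5), collapse = "; "),
         if (length(bad) > 5) " ..." else "")
  }
  matrix(idx - 1L, H, W)
}

#' Render a class mask back to RGB
#'
#' @param mask integer matrix `[H, W]` of 0-based class indices.
#' @param palette class-by-RGB matrix.
#' @return array `[H, W, 3]` in `[0, 1]`; `mask_from_rgb()` of the result
#'   recovers `mask` exactly.
#' @export
rgb_from_mask <- function(mask, palette = default_palette()) {
  if (any(mask < 0 | mask >= nrow(palette)))
    stop("mask values out of palette range")
  H <- nrow(mask); W <- ncol(mask)
  out <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) out[, , ch] <- matrix(palette[mask + 1L, ch], H, W)
  out
}

new_sample_pair <- function(image, mask, id) {
  if (!identical(dim(image)[1:2], dim(mask)[1:2]))
    stop("image and mask sizes differ for sample ", id)
  structure(list(image = image, mask = mask, id = id),
            class = "sample_pair")
}

#' Load a paired image/mask dataset
#'
#' Expects per-sample folders under `root`, each containing `false.png`
#' (RGB image) and `gt.png` (color-coded mask). Pairs are returned sorted
#' by folder name.
#'
#' @param root dataset directory.
#' @param palette mask palette; see [default_palette()].
#' @param image_name,mask_name file names inside each folder.
#' @return list of `sample_pair` objects (fields `image` `[H,W,3]` in
#'   `[0,1]`, `mask` `[H,W]` 0-based integer, `id`).
#' @export
load_dataset <- function(root, palette = default_palette(),
                         image_name = "false.png", mask_name = "gt.png") {
  if (!dir.exists(root)) stop("dataset root not found: ", root)
  dirs <- sort(list.dirs(root, recursive = FALSE))
  if (!length(dirs)) stop("no sample folders under ", root)
  lapply(dirs, function(d) {
    ip <- file.path(d, image_name); mp <- file.path(d, mask_name)
    if (!file.exists(ip)) stop("missing ", image_name, " in ", basename(d))
    if (!file.exists(mp)) stop("missing ", mask_name, " in ", basename(d))
    img <- png::readPNG(ip)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
    img <- img[, , 1:3, drop = FALSE]
    msk <- png::readPNG(mp)
    mask <- if (length(dim(msk)) == 3) mask_from_rgb(msk[, , 1:3], palette)
            else matrix(as.integer(round(msk * 255)), nrow(msk), ncol(msk))
    new_sample_pair(img, mask, basename(d))
  })
}

#' Write a sample pair to a dataset folder
#' @param pair a `sample_pair`.
#' @param dir destination folder (created if needed).
#' @param palette mask palette.
#' @export
write_sample_pair <- function(pair, dir, palette = default_palette()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png::writePNG(pair$image, file.path(dir, "false.png"))
  png::writePNG(rgb_from_mask(pair$mask, palette), file.path(dir, "gt.png"))
  invisible(dir)
}

# Run expr with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic 7:2:1 dataset split
#'
#' Shuffles the pairs with the given seed and partitions them into
#' disjoint, exhaustive train/test/val subsets. Subset sizes are the
#' rounded ratios with any remainder assigned to train (300 pairs at
#' 0.7/0.2/0.1 gives 210/60/30).
#'
#' @param pairs list of samples (any list).
#' @param ratios train/test/val fractions summing to 1.
#' @param seed integer; the same seed always yields the same partition.
#' @return list with `train`, `test`, `val`.
#' @export
split_dataset <- function(pairs, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  n <- length(pairs)
  n_test <- round(ratios[2] * n)
  n_val <- round(ratios[3] * n)
  n_train <- n - n_test - n_val
  if (n_train < 1 || n_test < 0 || n_val < 0 || n < 3)
    stop("too few pairs (", n, ") for a 3-way split")
  perm <- with_seed(seed, sample.int(n))
  list(train = pairs[perm[seq_len(n_train)]],
       test = pairs[perm[n_train + seq_len(n_test)]],
       val = pairs[perm[n_train + n_test + seq_len(n_val)]])
}

#' Stack sample pairs into network input arrays
#'
#' @param pairs list of `sample_pair` objects of equal size.
#' @return list with `x` `[H, W, 3, N]` and `y` `[H, W, N]`.
#' @export
pairs_to_batch <- function(pairs) {
  d <- dim(pairs[[1]]$image)
  N <- length(pairs)
  x <- array(0, dim = c(d[1], d[2], 3, N))
  y <- array(0L, dim = c(d[1], d[2], N))
  for (n in seq_len(N)) {
    x[, , , n] <- pairs[[n]]$image
    y[, , n] <- pairs[[n]]$mask
  }
  list(x = x, y = y)
}

#' Write a dataset manifest
#' @param pairs list of `sample_pair`s.
#' @param path CSV path.
#' @param split optional split label per pair (recycled).
#' @param origin optional originating id per pair (for augmented copies).
#' @export
write_manifest <- function(pairs, path, split = "train", origin = NA) {
  df <- data.frame(id = vapply(pairs, `[[`, character(1), "id"),
                   split = split, origin = origin)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
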