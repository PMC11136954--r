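# Dataset I/O: palette mapping round-trips, folder loading with clear
# errors, deterministic 7:2:1 split, augmentation contracts.

test_that("palette mapping is a bijection on valid masks and rejects unknown colors", {
  set.seed(1)
  mask <- matrix(sample(0:2, 48, TRUE), 6, 8)
  rgb <- rgb_from_mask(mask)
  expect_equal(mask_from_rgb(rgb), mask)
  bad <- rgb; bad[1, 1, ] <- c(0.5, 0.5, 0.5)
  expect_error(mask_from_rgb(bad), "128 128 128")
  expect_error(rgb_from_mask(matrix(7L, 2, 2)), "out of palette")
})

test_that("datasets load from folder trees, sorted, with named errors for defects", {
  root <- tempfile("ds")
  pairs <- tiny_scenes(3)
  for (p in pairs) write_sample_pair(p, file.path(root, p$id))
  got <- load_dataset(root)
  expect_length(got, 3)
  expect_equal(vapply(got, `[[`, character(1), "id"),
               sort(vapply(pairs, `[[`, character(1), "id")))
  expect_equal(dim(got[[1]]$image), c(16, 16, 3))
  # masks survive the PNG round trip exactly
  orig <- pairs[order(vapply(pairs, `[[`, character(1), "id"))]
  for (k in 1:3) expect_equal(got[[k]]$mask, orig[[k]]$mask)
  # a folder missing its mask is named in the error
  dir.create(file.path(root, "zz_broken"))
  png::writePNG(array(0.5, dim = c(8, 8, 3)),
                file.path(root, "zz_broken", "false.png"))
  expect_error(load_dataset(root), "zz_broken")
  unlink(root, recursive = TRUE)
})

test_that("7:2:1 split is sized, disjoint, exhaustive and seed-deterministic", {
  pairs <- as.list(seq_len(300))
  sp <- split_dataset(pairs, seed = 5)
  expect_equal(lengths(sp), c(train = 210L, test = 60L, val = 30L))
  expect_equal(sort(unname(unlist(sp))), 1:300)
  sp2 <- split_dataset(pairs, seed = 5)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(pairs, seed = 6)))
  sp10 <- split_dataset(as.list(1:10), seed = 1)
  expect_equal(lengths(sp10), c(train = 7L, test = 2L, val = 1L))
  expect_error(split_dataset(as.list(1:2)), "too few")
})

test_that("flips are involutions and photometric ops leave the mask untouched", {
  pair <- tiny_scenes(1)[[1]]
  for (op in c("horizontal_flip", "vertical_flip")) {
    once <- augment_pair(pair, augmentation_spec(op))
    twice <- augment_pair(once, augmentation_spec(op))
    expect_equal(twice$image, pair$image)
    expect_equal(twice$mask, pair$mask)
    expect_false(identical(once$mask, pair$mask) &&
                   identical(once$image, pair$image))
  }
  for (op in c("gaussian_blur", "sharpen", "brightness")) {
    out <- augment_pair(pair, augmentation_spec(op, seed = 3))
    expect_identical(out$mask, pair$mask)
    expect_false(identical(out$image, pair$image))
    expect_true(all(out$image >= 0 & out$image <= 1))
  }
})

test_that("rotation moves a delta pixel to the transposed location", {
  # a single labelled pixel off-centre, rotated 90 degrees CCW about the
  # image centre: (r, c) -> (cy + (c - cx), cx - (r - cy))
  H <- 9; W <- 9
  mask <- matrix(0L, H, W); mask[3, 7] <- 1L
  img <- array(0.5, dim = c(H, W, 3))
  pair <- epanet:::new_sample_pair(img, mask, "delta")
  out <- augment_pair(pair, augmentation_spec("rotate",
                                              params = list(angle = 90)))
  # centre is (4, 4) 0-based; source (2, 6) 0-based maps to (2, 6) rotated:
  # dst with inverse rotation by -90: expected at row cy+(c-cx)=6, col
  # cx-(r-cy)=6 (0-based), i.e. [7, 7] 1-based
  expect_equal(which(out$mask == 1L, arr.ind = TRUE)[1, ],
               c(row = 7L, col = 7L))
})

test_that("geometric ops keep size, stay in range, and are seed-deterministic", {
  pair <- tiny_scenes(1, seed = 21)[[1]]
  for (op in c("rotate", "translate", "crop_and_pad", "rotate_and_crop")) {
    a <- augment_pair(pair, augmentation_spec(op, seed = 5))
    b <- augment_pair(pair, augmentation_spec(op, seed = 5))
    expect_identical(a$image, b$image)
    expect_identical(a$mask, b$mask)
    expect_equal(dim(a$image), dim(pair$image))
    expect_true(all(a$mask %in% 0:2))
  }
  expect_error(augment_pair(pair, augmentation_spec("rotate",
                                                    params = list(angle = 90),
                                                    seed = 1)), NA)
  expect_error(augment_pair(pair,
                            augmentation_spec("brightness",
                                              params = list(delta = 0.9))),
               "outside the allowed range")
})

test_that("offline expansion yields originals plus one copy per spec, train-only by construction", {
  pairs <- tiny_scenes(3)
  out <- expand_offline(pairs, seed = 2)
  expect_length(out, 30)                     # 3 x (1 + 9)
  ids <- vapply(out, `[[`, character(1), "id")
  expect_equal(ids[1:3], vapply(pairs, `[[`, character(1), "id"))
  # every augmented id maps back to exactly one original
  orig_ids <- ids[1:3]
  for (id in ids[-(1:3)])
    expect_equal(sum(startsWith(id, orig_ids)), 1)
  out2 <- expand_offline(pairs, seed = 2)
  expect_identical(lapply(out, `[[`, "mask"), lapply(out2, `[[`, "mask"))
  # three pairs with two specs -> 9
  expect_length(expand_offline(pairs, default_augmentations()[1:2]), 9)
})

test_that("mask indicator planes transform consistently with the mask (geometric consistency)", {
  set.seed(9)
  pair <- tiny_scenes(1, seed = 30)[[1]]
  spec <- augmentation_spec("rotate", params = list(angle = 17))
  out <- augment_pair(pair, spec)
  # transform each class-indicator plane as an image and re-argmax
  planes <- array(0, dim = c(16, 16, 3))
  for (k in 0:2) planes[, , k + 1] <- (pair$mask == k) * 1
  ppair <- epanet:::new_sample_pair(planes, pair$mask, "planes")
  pout <- augment_pair(ppair, spec)
  # nearest-neighbour mask must agree with argmax of the warped indicators
  # wherever the indicators are unambiguous (interior pixels)
  amax <- apply(pout$image, c(1, 2), which.max) - 1L
  strong <- apply(pout$image, c(1, 2), max) > 0.75
  expect_gt(mean((amax == out$mask)[strong]), 0.97)
})
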