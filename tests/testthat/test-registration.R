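test_that("stitching reproduces trivial and round-trip layouts", {
  t1 <- matrix(runif(64 * 64), 64, 64)
  one <- stitch_tiles(list(t1), stitch_layout(c(1, 1), c(64, 64), 0.1))
  expect_equal(one, t1)
  const <- lapply(1:4, function(i) matrix(7, 64, 64))
  comp <- stitch_tiles(const, stitch_layout(c(2, 2), c(64, 64), 0.1))
  step <- round(64 * 0.9)
  expect_equal(dim(comp), c(64 + step, 64 + step))
  expect_true(all(abs(comp - 7) < 1e-12))
  expect_error(stitch_tiles(list(t1, matrix(0, 32, 32), t1, t1),
                            stitch_layout(c(2, 2), c(64, 64), 0.1)), "tile sizes")
})

test_that("cutting an image into overlapping tiles and stitching recovers it", {
  set.seed(31)
  h <- 64; step <- round(h * 0.9)
  n <- h + step
  img <- collalign:::gauss_smooth(matrix(runif(n * n, 0, 255), n, n), 2)
  tiles <- list(img[1:h, 1:h], img[1:h, step + 1:h],
                img[step + 1:h, 1:h], img[step + 1:h, step + 1:h])
  comp <- stitch_tiles(tiles, stitch_layout(c(2, 2), c(h, h), 0.1))
  expect_lt(mean(abs(comp - img)), 1)
})

test_that("decorrelation stretch whitens channel correlation", {
  set.seed(32)
  n <- 64
  base <- matrix(runif(n * n, 50, 200), n, n)
  rgb <- array(0, c(n, n, 3))
  for (ch in 1:3) rgb[, , ch] <- base + matrix(rnorm(n * n, 0, 10), n, n)
  out <- decorrelation_stretch(rgb, clip = FALSE)
  cc <- cor(matrix(out, ncol = 3))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
  # constant image: unchanged, flagged
  const <- array(128, c(8, 8, 3))
  expect_warning(res <- decorrelation_stretch(const), "degenerate")
  expect_true(attr(res, "degenerate"))
  expect_equal(as.numeric(res), as.numeric(const))
})

test_that("stretch acts as a per-channel rescale on already-white input", {
  set.seed(33)
  n <- 48
  rgb <- array(rnorm(n * n * 3, 100, 20), c(n, n, 3))  # independent channels
  out <- decorrelation_stretch(rgb, clip = FALSE)
  for (ch in 1:3)
    expect_gt(cor(as.vector(rgb[, , ch]), as.vector(out[, , ch])), 0.99)
})

test_that("k-means colour clustering isolates eosin-stained blobs", {
  set.seed(34)
  n <- 96
  conc <- array(0, c(n, n, 3))
  blob <- matrix(0, n, n)
  for (i in 1:6) blob <- collalign:::draw_segment(blob, runif(1, 10, n - 10),
                                                  runif(1, 10, n - 10),
                                                  runif(1, 10, n - 10),
                                                  runif(1, 10, n - 10), 4, 1)
  conc[, , 2] <- blob * 0.9
  rgb <- stain_compose(conc, stain_model_he())
  mask <- extract_collagen_mask(rgb, k = 2, seed = 1)
  truth <- blob > 0.5
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gte(dice, 0.95)
  expect_identical(mask, extract_collagen_mask(rgb, k = 2, seed = 1))
  expect_error(extract_collagen_mask(rgb, k = 1), "k must be")
})

test_that("mutual information matches its definition and symmetry", {
  set.seed(35)
  x <- matrix(runif(64 * 64), 64, 64)
  y <- matrix(runif(64 * 64), 64, 64)
  expect_equal(mutual_information(x, y), oracle_mi(x, y, 32), tolerance = 1e-12)
  expect_equal(mutual_information(x, y), mutual_information(y, x), tolerance = 1e-12)
  # MI(x, x) = entropy of x under the same binning
  h <- -sum((p <- tabulate(collalign:::bin_index(x, range(x), 32), 32) / length(x))[p > 0] *
              log2(p[p > 0]))
  expect_equal(mutual_information(x, x), h, tolerance = 1e-12)
  # independent images at large n: only the histogram bias remains
  big_x <- matrix(runif(160 * 160), 160, 160)
  big_y <- matrix(runif(160 * 160), 160, 160)
  expect_lt(mutual_information(big_x, big_y), 0.05)
  expect_error(mutual_information(x, matrix(0, 2, 2)), "dimensions")
})

make_reg_fixture <- function(seed, size = 160) {
  make_fiber_image(fiber_field_spec(n_fibers = 220, mean_angle = 40, kappa = 2,
                                    image_size_px = c(size, size), seed = seed))
}

test_that("registering an image to itself stays at the identity", {
  f <- make_reg_fixture(41)
  tf <- register_affine(f$image, f$image, seed = 1)
  expect_lt(max(abs(tf$m[, 3])), 0.25)
  expect_lt(max(abs(tf$m[, 1:2] - diag(2))), 0.005)
})

test_that("registration recovers known translation and rotation", {
  f <- make_reg_fixture(42)
  mov <- warp_affine(f$image, affine_invert(affine_translation(10, 5)))
  tf <- register_affine(f$image, mov, seed = 2)
  expect_lt(max(abs(tf$m[, 3] - c(10, 5))), 0.5)
  ctr <- c((ncol(f$image) - 1) / 2, (nrow(f$image) - 1) / 2)
  mov2 <- warp_affine(f$image, affine_invert(affine_rotation(5, ctr)))
  tf2 <- register_affine(f$image, mov2, seed = 2)
  ang <- atan2(tf2$m[2, 1], tf2$m[1, 1]) * 180 / pi
  expect_lt(abs(ang - 5), 0.5)
})

test_that("accepted mutual information is monotone within each level", {
  f <- make_reg_fixture(43)
  mov <- warp_affine(f$image, affine_invert(affine_translation(8, -6)))
  tf <- register_affine(f$image, mov, seed = 3)
  for (tr in attr(tf, "mi_trace")) expect_true(all(diff(tr) >= 0))
  expect_gte(attr(tf, "mi"), 0)
})

test_that("registration is deterministic under a fixed seed", {
  f <- make_reg_fixture(44)
  he <- make_he_pair(f$image, f$fibers, affine_translation(6, 9), seed = 5)
  a <- register_he_to_shg(he$rgb, f$image, seed = 6)
  b <- register_he_to_shg(he$rgb, f$image, seed = 6)
  expect_identical(a$m, b$m)
})

test_that("end-to-end H&E to SHG registration recovers the stored transform", {
  f <- make_reg_fixture(45)
  he <- make_he_pair(f$image, f$fibers, affine_translation(10, 5), seed = 7)
  tf <- register_he_to_shg(he$rgb, f$image, seed = 8)
  pts <- rbind(c(20, 20), c(140, 20), c(20, 140), c(140, 140))
  expect_lt(transform_point_error(tf, he$transform, pts), 1)
})

test_that("transform composition is approximately transitive", {
  f <- make_reg_fixture(46)
  ab <- affine_translation(7, -4)
  bc <- affine_rotation(3, c(79.5, 79.5))
  imgB <- warp_affine(f$image, affine_invert(ab))
  imgC <- warp_affine(f$image, affine_invert(affine_compose(bc, ab)))
  t_ab <- register_affine(f$image, imgB, seed = 9)
  t_bc <- register_affine(imgB, imgC, seed = 9)
  t_ac <- register_affine(f$image, imgC, seed = 9)
  pts <- rbind(c(30, 30), c(130, 30), c(30, 130), c(130, 130))
  expect_lt(transform_point_error(affine_compose(t_ab, t_bc), t_ac, pts), 2)
})

test_that("ROI transfer maps corners through the transform", {
  rs <- list(roi(10, 20, 40, region = "core", id = "r1"))
  same <- transfer_rois(rs, affine_identity())[[1]]
  expect_equal(c(same$x, same$y, same$side_px), c(10, 20, 40))
  shifted <- transfer_rois(rs, affine_translation(10, 5))[[1]]
  expect_equal(c(shifted$x, shifted$y, shifted$side_px), c(20, 25, 40))
  # 90 degree rotation about the origin: (x, y) -> (-y, x)
  rot <- transfer_rois(rs, affine_rotation(90))[[1]]
  expect_equal(rot$side_px, 40)
  expect_equal(c(rot$x, rot$y), c(-60, 10))
  clipped <- transfer_rois(rs, affine_translation(-20, 0), image_dim = c(64, 64))[[1]]
  expect_true(clipped$clipped)
  expect_gte(clipped$x, 0)
})
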