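test_that("alignment statistic matches closed forms on axial data", {
  expect_identical(alignment_score(rep(30, 100)), 1)
  expect_identical(alignment_score(rep(137.2, 7)), 1)
  expect_lt(abs(alignment_score(c(0, 90))), 1e-12)
  expect_lt(abs(alignment_score(c(0, 30)) - sqrt(0.75)), 1e-12)
  # equal-spaced orientations cancel
  expect_lt(alignment_score(c(0, 60, 120)), 1e-12)
  expect_true(is.na(alignment_score(numeric(0))))
})

test_that("alignment statistic equals the brute-force vector sum", {
  set.seed(42)
  for (i in 1:250) {
    th <- runif(sample(2:200, 1), 0, 180)
    expect_lt(abs(alignment_score(th) - oracle_resultant(th)), 1e-12)
  }
})

test_that("alignment is rotation-equivariant and axial", {
  set.seed(7)
  th <- runif(50, 0, 180)
  for (shift in c(10, 45, 90, 173.5)) {
    expect_equal(alignment_score((th + shift) %% 180), alignment_score(th),
                 tolerance = 1e-12)
  }
  expect_equal(alignment_score(th + 180), alignment_score(th), tolerance = 1e-12)
  # undoubled variant differs for axial data but agrees with its own oracle
  expect_lt(abs(alignment_score(th, axial = FALSE) -
                  oracle_resultant(th, axial = FALSE)), 1e-12)
})

test_that("length weighting is a weighted resultant", {
  th <- c(0, 90); w <- c(3, 1)
  z <- (3 * exp(0i) + 1 * exp(1i * pi)) / 4
  expect_equal(alignment_score(th, weights = w), Mod(z), tolerance = 1e-12)
})

test_that("a single bright bar yields one fiber at its orientation", {
  img <- matrix(0, 128, 128)
  img[64:66, 10:110] <- 1
  fs <- extract_fibers(img)
  expect_equal(nrow(fs), 1)
  d <- min(fs$theta_deg, 180 - fs$theta_deg)
  expect_lt(d, 2)
  expect_gt(fs$length_px, 80)
})

test_that("crossing bars yield segments peaking at both orientations", {
  img <- matrix(0, 160, 160)
  img[79:81, 10:150] <- 1           # horizontal, theta = 0
  img[10:150, 79:81] <- 1           # vertical, theta = 90
  fs <- extract_fibers(img, min_length_px = 20)
  expect_gte(nrow(fs), 2)
  # length-weighted orientation mass near 0 and near 90
  fold <- pmin(fs$theta_deg %% 180, 180 - fs$theta_deg %% 180)
  w_h <- sum(fs$length_px[fold < 3])
  w_v <- sum(fs$length_px[abs(fs$theta_deg - 90) < 3])
  expect_gt(w_h, 0.3 * sum(fs$length_px))
  expect_gt(w_v, 0.3 * sum(fs$length_px))
})

test_that("blank and constant images give an empty fiber set", {
  expect_equal(nrow(extract_fibers(matrix(0, 64, 64))), 0)
  expect_equal(nrow(extract_fibers(matrix(3.2, 64, 64))), 0)
})

test_that("extracted alignment increases with orientation concentration", {
  mean_r <- vapply(c(0, 1, 2, 4, 8), function(kap) {
    rs <- vapply(1:5, function(s) {
      f <- make_fiber_image(fiber_field_spec(n_fibers = 60, mean_angle = 45,
                                             kappa = kap, fiber_length_px = 40,
                                             image_size_px = c(128, 128),
                                             seed = 100 * kap + s))
      fs <- extract_fibers(f$image, min_length_px = 15)
      alignment_score(fs$theta_deg)
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("ROI alignment handles blank, aligned and out-of-bounds cases", {
  f <- make_fiber_image(fiber_field_spec(n_fibers = 60, mean_angle = 30,
                                         kappa = Inf, fiber_length_px = 60,
                                         image_size_px = c(128, 128),
                                         seed = 5))
  r <- roi_alignment(f$image, roi(16, 16, 96, id = "a"), min_length_px = 20)
  expect_false(r$undefined)
  expect_gt(r$R, 0.95)
  blank <- roi_alignment(matrix(0, 128, 128), roi(0, 0, 64, id = "b"))
  expect_true(blank$undefined)
  expect_true(is.na(blank$R))
  expect_error(roi_alignment(f$image, roi(100, 100, 64)), "outside")
})

test_that("disjoint ROIs over a stationary field agree in R", {
  f <- make_fiber_image(fiber_field_spec(n_fibers = 700, mean_angle = 60,
                                         kappa = 3, fiber_length_px = 30,
                                         fiber_length_sd = 5, fiber_width_px = 1,
                                         image_size_px = c(192, 400),
                                         seed = 9))
  r1 <- roi_alignment(f$image, roi(0, 0, 180, id = "left"), min_length_px = 8)
  r2 <- roi_alignment(f$image, roi(210, 0, 180, id = "right"), min_length_px = 8)
  expect_gte(r1$n_fibers, 100)
  expect_gte(r2$n_fibers, 100)
  expect_lt(abs(r1$R - r2$R), 0.1)
})

test_that("skeleton thinning reduces a thick bar to a one-pixel path", {
  bw <- matrix(0L, 40, 40)
  bw[18:22, 5:35] <- 1L
  sk <- thin_binary(bw)
  expect_true(all(sk[bw == 0L] == 0L))
  expect_lte(max(colSums(sk[, 7:33])), 1)
})
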