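#' Tile stitching layout
#'
#' @param grid_dim `c(rows, cols)` of the tile grid.
#' @param tile_size `c(H, W)` of each tile, pixels.
#' @param overlap fractional overlap between neighbouring tiles, in
#'   `[0, 0.5)` (acquisition default 10%).
#' @export
stitch_layout <- function(grid_dim, tile_size, overlap = 0.10) {
  if (overlap < 0 || overlap >= 0.5) stop("overlap must lie in [0, 0.5)")
  structure(list(grid_dim = as.integer(grid_dim),
                 tile_size = as.integer(tile_size), overlap = overlap),
            class = "stitch_layout")
}

#' Stitch a grid of image tiles into a composite
#'
#' Tiles are placed at the offsets implied by the layout (step =
#' `round(size * (1 - overlap))`) and blended in overlap zones by linear
#' feathering: each tile carries a weight ramp rising over the overlap
#' width, and the composite is the weight-normalised sum.
#'
#' @param tiles list of numeric matrices in row-major order
#'   (`tiles[[(i-1)*cols + j]]` is grid row i, column j).
#' @param layout a [stitch_layout()].
#' @return composite matrix.
#' @export
stitch_tiles <- function(tiles, layout) {
  stopifnot(inherits(layout, "stitch_layout"))
  nr <- layout$grid_dim[1]; nc <- layout$grid_dim[2]
  if (length(tiles) != nr * nc) stop("tile count does not match grid")
  h <- layout$tile_size[1]; w <- layout$tile_size[2]
  for (t in tiles) if (!all(dim(t) == c(h, w))) stop("inconsistent tile sizes")
  step_y <- round(h * (1 - layout$overlap)); step_x <- round(w * (1 - layout$overlap))
  ov_y <- h - step_y; ov_x <- w - step_x
  H <- h + (nr - 1) * step_y; W <- w + (nc - 1) * step_x
  ramp <- function(n, ov) {
    if (ov <= 0) return(rep(1, n))
    pmin(1, (seq_len(n)) / (ov + 1), (n + 1 - seq_len(n)) / (ov + 1))
  }
  wy <- ramp(h, ov_y); wx <- ramp(w, ov_x)
  wt <- outer(wy, wx)
  acc <- matrix(0, H, W); wsum <- matrix(0, H, W)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    t <- tiles[[(i - 1) * nc + j]]
    ys <- (i - 1) * step_y + seq_len(h); xs <- (j - 1) * step_x + seq_len(w)
    acc[ys, xs] <- acc[ys, xs] + t * wt
    wsum[ys, xs] <- wsum[ys, xs] + wt
  }
  acc / wsum
}

#' Decorrelation stretch of an RGB image
#'
#' Rotates the channels to the principal axes of the channel covariance,
#' equalises the variances to a common target sigma, rotates back and adds
#' the channel means; the result is clipped to `[0, 255]`. A constant image
#' (zero covariance) is returned unchanged with attribute
#' `degenerate = TRUE`.
#'
#' @param rgb H x W x 3 array.
#' @param target_sd common output channel sigma; default the mean of the
#'   input channel sigmas.
#' @param clip clip the result to `[0, 255]` (default TRUE).
#' @export
decorrelation_stretch <- function(rgb, target_sd = NULL, clip = TRUE) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  d <- dim(rgb)
  X <- matrix(rgb, ncol = 3)
  mu <- colMeans(X)
  C <- cov(X)
  ev <- eigen(C, symmetric = TRUE)
  if (any(ev$values <= 1e-10)) {
    attr(rgb, "degenerate") <- TRUE
    warning("degenerate channel covariance; image returned unchanged")
    return(rgb)
  }
  if (is.null(target_sd)) target_sd <- mean(sqrt(diag(C)))
  Z <- sweep(X, 2, mu) %*% ev$vectors %*% diag(1 / sqrt(ev$values))
  out <- sweep(Z %*% (target_sd * t(ev$vectors)), 2, mu, "+")
  if (clip) out <- pmin(pmax(out, 0), 255)
  array(out, d)
}

#' Extract a collagen mask from a brightfield image by colour clustering
#'
#' Applies [decorrelation_stretch()], clusters the stretched pixel colours
#' with k-means (fixed seed, multiple restarts), and returns the cluster
#' whose mean original colour, converted to optical density, is closest in
#' cosine distance to `reference_od` (default the eosin vector of the H&E
#' stain model, since collagen takes up eosin). If the reference equals the
#' background colour the background cluster is returned: the caller chooses
#' the reference.
#'
#' @param rgb H x W x 3 array.
#' @param k number of colour clusters, >= 2 (default 4).
#' @param reference_od length-3 OD direction of the target stain.
#' @param seed integer seed for the k-means initialisation.
#' @return logical matrix mask.
#' @export
extract_collagen_mask <- function(rgb, k = 4, reference_od = NULL, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (is.null(reference_od)) reference_od <- stain_model_he()$m[2, ]
  ds <- decorrelation_stretch(rgb)
  X <- matrix(ds, ncol = 3)
  set.seed(seed)
  km <- kmeans(X, centers = k, nstart = 5, iter.max = 100)
  orig <- matrix(rgb, ncol = 3)
  ref <- reference_od / sqrt(sum(reference_od^2))
  cosdist <- vapply(seq_len(k), function(cl) {
    m <- colMeans(orig[km$cluster == cl, , drop = FALSE])
    od <- -log10(pmax(m, 1) / 255)
    n <- sqrt(sum(od^2))
    if (n < 1e-3) return(2)           # near-white cluster: no stain
    1 - sum(od * ref) / n
  }, numeric(1))
  matrix(km$cluster == which.min(cosdist), nrow(rgb[, , 1]), ncol(rgb[, , 1]))
}

# equal-width bin index in 1..bins over a fixed range
bin_index <- function(v, rng, bins) {
  if (diff(rng) == 0) return(rep(1L, length(v)))
  pmin(pmax(floor((v - rng[1]) / diff(rng) * bins) + 1L, 1L), bins)
}

mi_from_bins <- function(ia, ib, bins) {
  joint <- tabulate(ia + bins * (ib - 1L), bins * bins)
  p <- joint / sum(joint)
  px <- rowSums(matrix(p, bins, bins)); py <- colSums(matrix(p, bins, bins))
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / (px[(seq_along(p) - 1) %% bins + 1][nz] *
                              py[(seq_along(p) - 1) %/% bins + 1][nz])))
}

#' Mutual information between two images
#'
#' MI (bits) of the joint histogram of a sampling of co-located pixel
#' pairs: the certainty with which intensities of one image map to similar
#' intensities in the other. Symmetric in its arguments;
#' `mutual_information(x, x)` equals the histogram entropy of `x`.
#'
#' @param a,b numeric matrices of identical size.
#' @param bins histogram bins per image (default 32).
#' @param sample_fraction fraction of pixels used (default 1 = all).
#' @param seed seed for the pixel sampling.
#' @export
mutual_information <- function(a, b, bins = 32, sample_fraction = 1, seed = 1) {
  if (!all(dim(a) == dim(b))) stop("images must have identical dimensions")
  idx <- seq_along(a)
  if (sample_fraction < 1) {
    set.seed(seed)
    idx <- sample(idx, max(ceiling(sample_fraction * length(a)), 2))
  }
  ia <- bin_index(a[idx], range(a), bins)
  ib <- bin_index(b[idx], range(b), bins)
  mi_from_bins(ia, ib, bins)
}

gauss_downsample <- function(img, factor) {
  if (factor == 1) return(img)
  sm <- gauss_smooth(img, sigma = factor / 2)
  as.matrix(EBImage::resize(EBImage::Image(sm), w = ncol(img) %/% factor,
                            h = nrow(img) %/% factor))
}

#' Multiresolution affine registration by mutual-information ascent
#'
#' Coarse-to-fine Gaussian pyramid (factor 2 per level). At each level the
#' six pose parameters (translation, rotation, log-scales, shear, acting
#' about the fixed-image centre, always in finest-resolution pixel units)
#' are refined by gradient ascent on the mutual information between the
#' fixed image and the resampled moving image, with a numerically
#' estimated gradient and step halving on non-improvement. Iteration stops
#' after `max_iter` steps per level or when the MI gain drops below `tol`.
#' If the final MI does not exceed the MI of the identity transform, the
#' identity is returned with attribute `warning = "no_improvement"`.
#'
#' @param fixed,moving numeric matrices (need not be the same size); the
#'   returned transform maps moving to fixed coordinates.
#' @param levels pyramid levels (default 3).
#' @param bins,sample_fraction,seed mutual-information settings
#'   (defaults 32 bins, 20% sampling).
#' @param max_iter maximum accepted/attempted steps per level (default 200).
#' @param tol minimum MI improvement to continue (default 1e-5).
#' @param init optional initial `affine_transform`.
#' @param init_search_px half-width (finest-resolution px) of the exhaustive
#'   translation sweep run at the coarsest level before gradient ascent
#'   (default 24; 0 disables).
#' @return `affine_transform` with attributes `mi` (final MI), `mi_trace`
#'   (accepted-MI sequence per level) and possibly `warning`.
#' @export
register_affine <- function(fixed, moving, levels = 3, bins = 32,
                            sample_fraction = 0.2, seed = 1, max_iter = 200,
                            tol = 1e-5, init = NULL, init_search_px = 24) {
  if (diff(range(fixed)) == 0 || diff(range(moving)) == 0)
    stop("both images must be non-constant")
  center <- c((ncol(fixed) - 1) / 2, (nrow(fixed) - 1) / 2)
  pose <- c(0, 0, 0, 0, 0, 0)
  if (!is.null(init)) {
    # express init as a pose about the centre (exact for rigid+scale+shear)
    A <- init$m[, 1:2]
    th <- atan2(A[2, 1], A[1, 1])
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    S <- solve(R) %*% A
    t0 <- init$m[, 3] - (center - A %*% center)
    pose <- c(t0[1], t0[2], th * 180 / pi, log(S[1, 1]), log(S[2, 2]), S[1, 2])
  }
  set.seed(seed)
  trace_all <- list()
  for (lev in seq(levels - 1, 0)) {
    f <- 2^lev
    fx <- gauss_downsample(fixed, f)
    mv <- gauss_downsample(moving, f)
    rng_f <- range(fx); rng_m <- range(mv)
    npx <- length(fx)
    nsamp <- max(ceiling(ifelse(lev == 0, sample_fraction, 1) * npx), 64)
    idx <- if (nsamp >= npx) seq_len(npx) else sample.int(npx, nsamp)
    ylv <- (idx - 1) %% nrow(fx); xlv <- (idx - 1) %/% nrow(fx)
    # finest-frame coordinates of the sampled fixed pixels
    xs <- f * xlv + (f - 1) / 2; ys <- f * ylv + (f - 1) / 2
    fbin <- bin_index(fx[idx], rng_f, bins)
    mi_of <- function(p) {
      tf <- affine_from_pose(p, center)
      src <- affine_apply(affine_invert(tf), cbind(xs, ys))
      mx <- (src[, 1] - (f - 1) / 2) / f
      my <- (src[, 2] - (f - 1) / 2) / f
      ok <- mx >= 0 & my >= 0 & mx <= ncol(mv) - 1 & my <= nrow(mv) - 1
      if (sum(ok) < 32) return(-Inf)
      v <- interp_bilinear(mv, mx[ok], my[ok])
      mi_from_bins(fbin[ok], bin_index(v, rng_m, bins), bins)
    }
    delta <- c(0.5 * f, 0.5 * f, 0.2, 0.004, 0.004, 0.004)
    cur <- mi_of(pose)
    if (lev == levels - 1 && init_search_px > 0) {
      # joint translation x rotation sweep at the coarsest level to find the
      # right basin of attraction before local ascent
      sweep_grid <- expand.grid(tx = seq(-init_search_px, init_search_px, by = 4),
                                ty = seq(-init_search_px, init_search_px, by = 4),
                                th = seq(-12, 12, by = 3))
      best_sweep <- pose
      for (si in seq_len(nrow(sweep_grid))) {
        cand <- pose + c(sweep_grid$tx[si], sweep_grid$ty[si],
                         sweep_grid$th[si], 0, 0, 0)
        val <- mi_of(cand)
        if (val > cur) { cur <- val; best_sweep <- cand }
      }
      pose <- best_sweep
    }
    step <- 2
    trace <- cur
    for (it in seq_len(max_iter)) {
      g <- vapply(1:6, function(j) {
        e <- rep(0, 6); e[j] <- delta[j]
        (mi_of(pose + e) - mi_of(pose - e)) / 2
      }, numeric(1))
      gn <- sqrt(sum(g^2))
      if (gn < 1e-12) break
      dirn <- g / gn * delta
      # backtracking line search along the (parameter-scaled) gradient
      gain <- 0; accepted <- FALSE
      while (step >= 0.05) {
        val <- mi_of(pose + step * dirn)
        if (val > cur + 1e-12) {
          pose <- pose + step * dirn
          gain <- val - cur
          cur <- val
          trace <- c(trace, cur)
          step <- min(step * 1.6, 16)
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) break
      if (gain < tol) break
    }
    trace_all[[as.character(f)]] <- trace
  }
  final <- affine_from_pose(pose, center)
  # guard: accept only if MI beats the identity at the finest level
  mi_final <- mutual_information(fixed, warp_affine(moving, final,
                                                    output_dim = dim(fixed)),
                                 bins = bins)
  mi_ident <- mutual_information(fixed, warp_affine(moving, affine_identity(),
                                                    output_dim = dim(fixed)),
                                 bins = bins)
  if (mi_final < mi_ident) {
    out <- affine_identity()
    attr(out, "mi") <- mi_ident
    attr(out, "mi_trace") <- trace_all
    attr(out, "warning") <- "no_improvement"
    return(out)
  }
  attr(final, "mi") <- mi_final
  attr(final, "mi_trace") <- trace_all
  final
}

#' Register a brightfield H&E image to an SHG image
#'
#' The two-step scheme: (1) extract collagenous stroma from the H&E image
#' (decorrelation stretch, then k-means colour clustering picking the
#' eosin-like cluster), (2) intensity-based multiresolution affine
#' registration of the (lightly smoothed) collagen mask to the SHG image by
#' mutual-information ascent. The same routine registers serial-section
#' pairs when run on tissue masks.
#'
#' @param he H x W x 3 brightfield array.
#' @param shg fixed SHG intensity matrix.
#' @param k,reference_od collagen-extraction settings (see
#'   [extract_collagen_mask()]).
#' @param mask_smooth_sigma Gaussian sigma applied to the binary mask
#'   before registration (default 2).
#' @param ... passed to [register_affine()].
#' @return `affine_transform` mapping H&E to SHG coordinates, with the
#'   attributes of [register_affine()] plus `collagen_mask`.
#' @export
register_he_to_shg <- function(he, shg, k = 4, reference_od = NULL,
                               mask_smooth_sigma = 2, ...) {
  mask <- extract_collagen_mask(he, k = k, reference_od = reference_od)
  mv <- gauss_smooth(mask * 1, mask_smooth_sigma)
  out <- register_affine(shg, mv, ...)
  attr(out, "collagen_mask") <- mask
  out
}

#' Transfer ROIs through an affine transform
#'
#' Maps the four corners of each ROI, re-imposes an axis-aligned square
#' (side = mean of the bounding-box extents, rounded), and clips to the
#' target image when `image_dim` is given; clipped ROIs are flagged.
#'
#' @param rois list of [roi()] objects.
#' @param tform `affine_transform` from the ROIs' frame to the target
#'   frame.
#' @param image_dim optional `c(H, W)` of the target image for clipping.
#' @return list of transferred ROIs.
#' @export
transfer_rois <- function(rois, tform, image_dim = NULL) {
  lapply(rois, function(r) {
    s <- r$side_px
    corners <- cbind(c(r$x, r$x + s, r$x, r$x + s),
                     c(r$y, r$y, r$y + s, r$y + s))
    mapped <- affine_apply(tform, corners)
    bx <- range(mapped[, 1]); by <- range(mapped[, 2])
    side <- round((diff(bx) + diff(by)) / 2)
    out <- roi(round(bx[1]), round(by[1]), side_px = side,
               region = r$region, id = r$id)
    if (!is.null(image_dim)) {
      H <- image_dim[1]; W <- image_dim[2]
      nx <- max(out$x, 0); ny <- max(out$y, 0)
      nside <- min(out$side_px, W - nx, H - ny)
      if (nx != out$x || ny != out$y || nside != out$side_px) {
        if (nside < 1) stop("ROI ", r$id, " falls entirely outside the target image")
        out$x <- nx; out$y <- ny; out$side_px <- as.integer(nside)
        out$clipped <- TRUE
      }
    }
    out
  })
}
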