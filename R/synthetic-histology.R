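#' Synthetic H&E brightfield image paired to an SHG fiber image
#'
#' Renders a brightfield image in the SHG frame — collagen structures as
#' eosin optical density at the fiber locations, nuclei as hematoxylin
#' disks — composes RGB through the Beer-Lambert forward model, then
#' resamples it so that the affine map taking the returned (moving) H&E
#' image back onto the (fixed) SHG image equals `transform`. The true
#' transform is returned for registration-recovery tests.
#'
#' @param shg intensity matrix from [make_fiber_image()].
#' @param fibers `fiber_set` of the drawn fibers (unused beyond sanity
#'   checks; the rendered collagen follows the SHG intensities).
#' @param transform `affine_transform`, moving (H&E) to fixed (SHG).
#' @param stains `stain_model`, default H&E.
#' @param seed integer seed for nuclei placement.
#' @param n_nuclei number of hematoxylin nuclei.
#' @param eosin_od peak eosin OD of the collagen structures.
#' @return list: `rgb` (H x W x 3, 8-bit), `transform` (true map),
#'   `stains`, `collagen_od` (eosin concentration in the fixed frame).
#' @export
make_he_pair <- function(shg, fibers = NULL, transform = affine_identity(),
                         stains = stain_model_he(), seed = 1,
                         n_nuclei = 150, eosin_od = 0.9) {
  stopifnot(inherits(transform, "affine_transform"))
  set.seed(seed)
  H <- nrow(shg); W <- ncol(shg)
  top <- max(shg)
  if (top <= 0) stop("SHG image has no structure to render")
  eos <- pmin(pmax(shg, 0) / top, 1) * eosin_od
  eos[eos < 0.1 * eosin_od] <- 0     # suppress background noise in the render
  hem <- matrix(0, H, W)
  nx <- runif(n_nuclei, 0, W - 1); ny <- runif(n_nuclei, 0, H - 1)
  nr <- runif(n_nuclei, 1.5, 3.5)
  for (i in seq_len(n_nuclei))
    hem <- draw_segment(hem, nx[i], ny[i], nx[i], ny[i], nr[i], 1)
  hem <- hem * 0.8
  conc <- array(0, c(H, W, 3))
  conc[, , 1] <- hem; conc[, , 2] <- eos
  rgb_fixed <- stain_compose(conc, stains)
  # moving image M(x_m) = fixed-frame render at transform(x_m)
  rgb <- warp_affine(rgb_fixed, affine_invert(transform), background = 255)
  list(rgb = rgb, transform = transform, stains = stains, collagen_od = eos)
}

#' Synthetic DAB/hematoxylin IHC image with known positivity
#'
#' Builds an organic tissue mask from thresholded smoothed noise, assigns
#' each tissue pixel to DAB with probability `target_positive_fraction`
#' (hematoxylin otherwise) with stain concentrations well above the
#' positivity threshold, and composes RGB through the stain forward model.
#' The realized positive fraction (DAB / (DAB + hematoxylin) by pixel
#' count) is recorded exactly from the assignment.
#'
#' @param target_positive_fraction in `[0, 1]`.
#' @param stains `stain_model`, default hematoxylin + DAB.
#' @param seed integer seed.
#' @param image_size `c(H, W)`.
#' @param tissue_fraction approximate fraction of the image covered by
#'   stained tissue.
#' @return list: `rgb`, `true_fraction`, `n_dab`, `n_hematoxylin`,
#'   `tissue_mask`, `stains`.
#' @export
make_ihc_image <- function(target_positive_fraction, stains = stain_model_hdab(),
                           seed = 1, image_size = c(128, 128),
                           tissue_fraction = 0.6) {
  if (target_positive_fraction < 0 || target_positive_fraction > 1)
    stop("target_positive_fraction must lie in [0, 1]")
  set.seed(seed)
  H <- image_size[1]; W <- image_size[2]
  field <- gauss_smooth(matrix(runif(H * W), H, W), 4)
  mask <- field > quantile(field, 1 - tissue_fraction)
  n_tissue <- sum(mask)
  if (n_tissue == 0) stop("empty tissue mask")
  is_dab <- rep(FALSE, n_tissue)
  if (target_positive_fraction > 0)
    is_dab <- runif(n_tissue) < target_positive_fraction
  if (target_positive_fraction == 1) is_dab[] <- TRUE
  conc <- array(0, c(H, W, 3))
  hem <- matrix(0, H, W); dab <- matrix(0, H, W)
  lvl <- runif(n_tissue, 0.5, 1.0)
  hv <- numeric(n_tissue); dv <- numeric(n_tissue)
  hv[!is_dab] <- lvl[!is_dab]
  dv[is_dab] <- lvl[is_dab]
  hem[mask] <- hv
  dab[mask] <- dv
  conc[, , 1] <- hem; conc[, , 2] <- dab
  rgb <- stain_compose(conc, stains)
  n_dab <- sum(is_dab); n_hem <- n_tissue - n_dab
  list(rgb = rgb, true_fraction = n_dab / n_tissue,
       n_dab = n_dab, n_hematoxylin = n_hem,
       tissue_mask = mask, stains = stains)
}

#' Synthetic per-cell marker table for EMT scoring
#'
#' Builds a cell table with an exact number of double-positive epithelial
#' cells: `round(frac_double * n_epithelial)` cells get both markers above
#' the thresholds, the rest have at least one marker below.
#'
#' @param n_cells total cells.
#' @param frac_double target double-positive fraction among epithelial
#'   cells.
#' @param frac_epithelial fraction of cells flagged epithelial.
#' @param thr1,thr2 thresholds the table is constructed against.
#' @param seed integer seed.
#' @return list: `cells` data.frame (`cell_id`, `marker1`, `marker2`,
#'   `epithelial`), `true_fraction`.
#' @export
make_cell_table <- function(n_cells = 100, frac_double = 0.2,
                            frac_epithelial = 1, thr1 = 0.5, thr2 = 0.5,
                            seed = 1) {
  set.seed(seed)
  epi <- rep(FALSE, n_cells)
  n_epi <- max(round(frac_epithelial * n_cells), 1)
  epi[sample.int(n_cells, n_epi)] <- TRUE
  n_dp <- round(frac_double * n_epi)
  dp <- rep(FALSE, n_cells)
  dp[sample(which(epi), n_dp)] <- TRUE
  m1 <- runif(n_cells, 0, thr1 * 0.9)
  m2 <- runif(n_cells, 0, thr2 * 0.9)
  # single positives among the non-double cells keep one marker high
  single <- !dp & runif(n_cells) < 0.4
  flip <- runif(n_cells) < 0.5
  m1[single & flip] <- runif(sum(single & flip), thr1, 1)
  m2[single & !flip] <- runif(sum(single & !flip), thr2, 1)
  m1[dp] <- runif(n_dp, thr1, 1)
  m2[dp] <- runif(n_dp, thr2, 1)
  list(cells = data.frame(cell_id = seq_len(n_cells), marker1 = m1,
                          marker2 = m2, epithelial = epi),
       true_fraction = n_dp / n_epi)
}
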