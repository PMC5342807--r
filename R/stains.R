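#' Stain model for colour deconvolution
#'
#' Rows of `m` are unit optical-density (OD) vectors for each stain in RGB
#' OD space; a 3-stain model must be invertible so a pixel OD vector can be
#' decomposed into per-stain concentrations. Rows are re-normalised to unit
#' length. If the third row is all zero it is replaced by a unit vector
#' orthogonal to the first two (the usual "residual" channel construction).
#'
#' @param m numeric 3 x 3 matrix, rows = stain OD vectors.
#' @param names character length 3 stain names.
#' @return object of class `stain_model`.
#' @examples
#' stain_model_hdab()
#' @export
stain_model <- function(m, names = c("stain1", "stain2", "stain3")) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L))) stop("stain matrix must be 3 x 3")
  if (all(m[3, ] == 0)) {
    r <- pracma_cross(m[1, ], m[2, ])
    if (sum(r^2) < 1e-12) stop("first two stain vectors are collinear")
    m[3, ] <- r
  }
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-12)) stop("stain vectors must be non-zero")
  m <- m / nrm
  if (abs(det(m)) < 1e-8) stop("stain matrix is singular")
  structure(list(m = m, names = names), class = "stain_model")
}

# cross product, avoids pulling in pracma for one line
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' @export
print.stain_model <- function(x, ...) {
  cat("stain model (rows = unit OD vectors):\n")
  m <- x$m; rownames(m) <- x$names; colnames(m) <- c("R", "G", "B")
  print(round(m, 4))
  invisible(x)
}

#' Standard stain models
#'
#' OD vectors from the widely used colour-deconvolution reference set:
#' hematoxylin (0.650, 0.704, 0.286), eosin (0.072, 0.990, 0.105),
#' DAB (0.268, 0.570, 0.776); the residual channel is orthogonal to the
#' first two stains.
#'
#' @export
stain_model_hdab <- function() {
  stain_model(rbind(c(0.650, 0.704, 0.286),
                    c(0.268, 0.570, 0.776),
                    c(0, 0, 0)),
              names = c("hematoxylin", "dab", "residual"))
}

#' @rdname stain_model_hdab
#' @export
stain_model_he <- function() {
  stain_model(rbind(c(0.650, 0.704, 0.286),
                    c(0.072, 0.990, 0.105),
                    c(0, 0, 0)),
              names = c("hematoxylin", "eosin", "residual"))
}

#' Convert 8-bit RGB intensities to optical density
#'
#' Beer-Lambert: `OD = -log10(I / I0)` per channel. Intensities are clamped
#' below at 1 so a zero pixel maps to a finite OD.
#'
#' @param rgb H x W x 3 array in `[0, 255]`.
#' @param I0 incident (background) intensity, scalar or length 3, > 0.
#' @return H x W x 3 array of optical densities (>= 0 where I <= I0).
#' @export
rgb_to_od <- function(rgb, I0 = 255) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (any(I0 <= 0)) stop("I0 must be > 0")
  I0 <- rep(I0, length.out = 3)
  od <- rgb
  for (ch in 1:3) od[, , ch] <- -log10(pmax(rgb[, , ch], 1) / I0[ch])
  od
}

#' Inverse of [rgb_to_od()]: compose per-stain concentrations into RGB
#'
#' Forward Beer-Lambert model used by the synthetic generators:
#' `I = I0 * 10^(-(C %*% M))` where rows of `M` are the stain OD vectors.
#'
#' @param concentrations H x W x 3 array (one slice per stain) or H x W
#'   matrix for a single stain.
#' @param stains `stain_model`.
#' @param I0 incident intensity.
#' @param quantize round to whole 8-bit values (default TRUE).
#' @return H x W x 3 RGB array in `[0, 255]`.
#' @export
stain_compose <- function(concentrations, stains, I0 = 255, quantize = TRUE) {
  if (length(dim(concentrations)) == 2L) {
    tmp <- array(0, c(dim(concentrations), 3))
    tmp[, , 1] <- concentrations
    concentrations <- tmp
  }
  d <- dim(concentrations)
  cmat <- matrix(concentrations, ncol = 3)
  od <- cmat %*% stains$m
  I0 <- rep(I0, length.out = 3)
  rgb <- sweep(10^(-od), 2, I0, "*")
  rgb <- pmin(pmax(rgb, 0), rep(I0, each = nrow(rgb)))
  if (quantize) rgb <- round(rgb)
  array(rgb, c(d[1], d[2], 3))
}

#' Colour deconvolution
#'
#' Decomposes a per-pixel OD vector into stain concentrations by inverting
#' the stain matrix. Negative concentrations (OD outside the stain simplex)
#' are clipped to zero and counted.
#'
#' @param od H x W x 3 OD array from [rgb_to_od()].
#' @param stains `stain_model`.
#' @return list with `concentrations` (H x W x 3, one slice per stain,
#'   ordered as the model rows), `n_clipped_negative`.
#' @export
color_deconvolve <- function(od, stains) {
  stopifnot(length(dim(od)) == 3L, dim(od)[3] == 3L)
  d <- dim(od)
  odm <- matrix(od, ncol = 3)
  conc <- odm %*% solve(stains$m)
  n_neg <- sum(conc < -1e-12)
  conc[conc < 0] <- 0
  list(concentrations = array(conc, d), n_clipped_negative = n_neg)
}

#' DAB positivity fraction
#'
#' Pixel classification rule: DAB-positive if `dab >= od_threshold` and
#' `dab > hematoxylin`; hematoxylin if `hematoxylin >= od_threshold` and
#' `hematoxylin >= dab`; otherwise background (excluded). The positivity
#' fraction is DAB pixels / (DAB + hematoxylin pixels).
#'
#' @param dab,hematoxylin concentration matrices of equal size.
#' @param od_threshold concentration threshold for a pixel to count as
#'   stained (default 0.15).
#' @return list of class `positivity_result`: `fraction` (NA and
#'   `undefined = TRUE` when no pixel is stained), pixel counts and the
#'   threshold used.
#' @export
positivity_fraction <- function(dab, hematoxylin, od_threshold = 0.15) {
  if (!all(dim(dab) == dim(hematoxylin)))
    stop("dab and hematoxylin grids must have identical dimensions")
  is_dab <- dab >= od_threshold & dab > hematoxylin
  is_hem <- hematoxylin >= od_threshold & hematoxylin >= dab & !is_dab
  n_dab <- sum(is_dab); n_hem <- sum(is_hem)
  n_bg <- length(dab) - n_dab - n_hem
  structure(list(
    fraction = if (n_dab + n_hem == 0) NA_real_ else n_dab / (n_dab + n_hem),
    undefined = n_dab + n_hem == 0,
    n_dab = n_dab, n_hematoxylin = n_hem, n_background = n_bg,
    od_threshold = od_threshold), class = "positivity_result")
}

#' Ordinal stromal score from a positivity fraction
#'
#' Three-level scale used for stromal syndecan-1: 1 = negative/low (< 10%),
#' 2 = moderate (10-50%, both boundaries included), 3 = high (> 50%).
#'
#' @param fraction numeric vector in `[0, 1]`.
#' @return integer vector of scores in `{1, 2, 3}`.
#' @export
stromal_score <- function(fraction) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE))
    stop("fraction must lie in [0, 1]")
  ifelse(fraction < 0.10, 1L, ifelse(fraction <= 0.50, 2L, 3L))
}

#' @rdname stromal_score
#' @param scores numeric vector of reviewer scores to average.
#' @export
average_scores <- function(scores) mean(as.numeric(scores))

#' EMT double-positivity fraction
#'
#' Fraction of epithelial cells co-expressing both markers (E-cadherin and
#' vimentin intensities at or above their thresholds), the operational
#' definition of the epithelial-to-mesenchymal phenotype used here.
#'
#' @param cells data.frame with columns `marker1`, `marker2` (nonnegative
#'   intensities) and logical `epithelial`.
#' @param thr1,thr2 positivity thresholds for the two markers.
#' @export
emt_double_positive_fraction <- function(cells, thr1, thr2) {
  stopifnot(all(c("marker1", "marker2", "epithelial") %in% names(cells)))
  if (any(cells$marker1 < 0) || any(cells$marker2 < 0))
    stop("marker intensities must be nonnegative")
  epi <- cells[cells$epithelial, , drop = FALSE]
  if (nrow(epi) == 0) stop("no epithelial cells in table")
  mean(epi$marker1 >= thr1 & epi$marker2 >= thr2)
}
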