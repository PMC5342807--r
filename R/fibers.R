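#' Collagen alignment: mean resultant vector length of axial orientations
#'
#' The alignment statistic R is the circular-statistics mean resultant
#' length computed on doubled angles, the standard treatment for axial
#' (orientation, mod-180) data:
#' `R = sqrt(mean(cos 2theta)^2 + mean(sin 2theta)^2)`.
#' R spans 0 (uniformly distributed orientations) to 1 (all fibers in the
#' same direction). Each fiber contributes one angle; optional length
#' weighting and an undoubled variant are exposed for sensitivity analysis.
#'
#' @param angles_deg fiber orientations, degrees (interpreted mod 180 when
#'   `axial = TRUE`).
#' @param axial double the angles before averaging (default TRUE).
#' @param weights optional nonnegative fiber weights (e.g. lengths).
#' @return R in `[0, 1]`; `NA` for an empty input (undefined).
#' @examples
#' alignment_score(rep(30, 100))   # 1
#' alignment_score(c(0, 90))       # 0
#' @export
alignment_score <- function(angles_deg, axial = TRUE, weights = NULL) {
  if (length(angles_deg) == 0) return(NA_real_)
  if (anyNA(angles_deg)) stop("angles must not contain NA")
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  if (length(weights) != length(angles_deg) || any(weights < 0))
    stop("weights must be nonnegative and match angles in length")
  mult <- if (axial) 2 else 1
  # rotate by the first angle: R is rotation-invariant, and this makes the
  # degenerate all-identical case evaluate to exactly 1
  th <- mult * (angles_deg - angles_deg[1]) * pi / 180
  w <- weights / sum(weights)
  min(sqrt(sum(w * cos(th))^2 + sum(w * sin(th))^2), 1)
}

#' Extract fiber segments from an SHG-style intensity image
#'
#' Simplified fiber segmenter: Gaussian smoothing, foreground thresholding
#' (Otsu on the normalised image by default, or a fixed intensity), binary
#' skeletonization (Zhang-Suen thinning), removal of skeleton branch points
#' to split the skeleton into simple paths, and one orientation per path
#' from the principal axis of its pixel coordinates. Path length is the
#' extent of the pixel cloud along the principal axis; segments shorter than
#' `min_length_px` are discarded.
#'
#' @param image 2-D numeric matrix.
#' @param min_length_px minimum retained segment length (default 30).
#' @param smoothing_scale Gaussian sigma in pixels (default 1.5).
#' @param threshold_method "otsu" or "fixed".
#' @param threshold intensity threshold when `threshold_method = "fixed"`.
#' @param pixel_size_um recorded on the returned set.
#' @return a [fiber_set()]; empty (0 fibers) for a blank image.
#' @export
extract_fibers <- function(image, min_length_px = 30, smoothing_scale = 1.5,
                           threshold_method = c("otsu", "fixed"),
                           threshold = NULL, pixel_size_um = 1) {
  if (length(dim(image)) != 2L) stop("image must be a 2-D single-channel matrix")
  threshold_method <- match.arg(threshold_method)
  empty <- fiber_set(data.frame(x = numeric(0), y = numeric(0),
                                theta_deg = numeric(0), length_px = numeric(0)),
                     pixel_size_um = pixel_size_um)
  rng <- range(image)
  if (diff(rng) == 0) return(empty)
  sm <- if (smoothing_scale > 0) gauss_smooth(image, smoothing_scale) else image
  if (threshold_method == "otsu") {
    nrm <- (sm - min(sm)) / diff(range(sm))
    th <- EBImage::otsu(EBImage::Image(nrm))
    bw <- nrm > th
  } else {
    if (is.null(threshold)) stop("fixed threshold requested but none given")
    bw <- sm > threshold
  }
  if (!any(bw)) return(empty)
  skel <- thin_binary(bw * 1L)
  # branch points are pixels whose 8-neighbourhood crossing number is >= 3
  # (simple-path pixels, including staircase corners, have 2 transitions);
  # the 3x3 neighbourhood of each branch point is cleared so junction zones
  # disconnect cleanly into simple arms
  branch <- matrix(as.integer(skel == 1L & crossing_number(skel) >= 3L),
                   nrow(skel), ncol(skel))
  paths <- skel
  paths[neighbor_count(branch) + branch > 0L] <- 0L
  idx <- which(paths == 1L)
  if (length(idx) == 0) return(empty)
  lab <- label_components8(paths)
  comp <- split(idx, lab[idx])
  H <- nrow(image)
  rows <- lapply(comp, function(ii) {
    y <- (ii - 1) %% H          # 0-based
    x <- (ii - 1) %/% H
    n <- length(ii)
    if (n < 3) return(NULL)
    xy <- cbind(x, y)
    cv <- cov(xy)
    ev <- eigen(cv, symmetric = TRUE)
    v <- ev$vectors[, 1]
    proj <- xy %*% v
    len <- diff(range(proj)) + 1
    data.frame(x = mean(x), y = mean(y),
               theta_deg = (atan2(v[2], v[1]) * 180 / pi) %% 180,
               length_px = len, n_px = n)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || nrow(rows) == 0) return(empty)
  rows <- rows[rows$length_px >= min_length_px, , drop = FALSE]
  if (nrow(rows) == 0) return(empty)
  rownames(rows) <- NULL
  fiber_set(rows, pixel_size_um = pixel_size_um)
}

gauss_smooth <- function(img, sigma) {
  size <- 2 * ceiling(3 * sigma) + 1
  br <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(img, br, boundary = "replicate"))
}

# shift matrix contents: out[y, x] = m[y + dy, x + dx], zero padded
shift_mat <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys - dy, xs - dx] <- m[ys, xs]
  out
}

neighbor_count <- function(bw) {
  s <- matrix(0L, nrow(bw), ncol(bw))
  for (dy in -1:1) for (dx in -1:1) if (dy || dx) s <- s + shift_mat(bw, dy, dx)
  s
}

# number of 0 -> 1 transitions around the 8-neighbourhood (circular order)
crossing_number <- function(bw) {
  p2 <- shift_mat(bw, -1, 0); p3 <- shift_mat(bw, -1, 1)
  p4 <- shift_mat(bw, 0, 1);  p5 <- shift_mat(bw, 1, 1)
  p6 <- shift_mat(bw, 1, 0);  p7 <- shift_mat(bw, 1, -1)
  p8 <- shift_mat(bw, 0, -1); p9 <- shift_mat(bw, -1, -1)
  (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) + (p4 == 0L & p5 == 1L) +
    (p5 == 0L & p6 == 1L) + (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
    (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
}

#' Morphological skeletonization by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels while preserving 8-connectivity until
#' a one-pixel-wide skeleton remains.
#'
#' @param bw binary integer matrix (0/1).
#' @return binary integer matrix of the same size.
#' @export
thin_binary <- function(bw) {
  bw <- matrix(as.integer(bw != 0), nrow(bw), ncol(bw))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours in Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
      p2 <- shift_mat(bw, -1, 0); p3 <- shift_mat(bw, -1, 1)
      p4 <- shift_mat(bw, 0, 1);  p5 <- shift_mat(bw, 1, 1)
      p6 <- shift_mat(bw, 1, 0);  p7 <- shift_mat(bw, 1, -1)
      p8 <- shift_mat(bw, 0, -1); p9 <- shift_mat(bw, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
        (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
        (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (step == 1) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      kill <- bw == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(kill)) {
        bw[kill] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  bw
}

# 8-connected component labels for a binary matrix; 0 elsewhere
label_components8 <- function(bw) {
  idx <- which(bw == 1L)
  lab <- matrix(0L, nrow(bw), ncol(bw))
  if (length(idx) == 0) return(lab)
  H <- nrow(bw)
  pos <- integer(length(bw)); pos[idx] <- seq_along(idx)
  edges <- NULL
  for (off in c(-1L, H - 1L, H, H + 1L)) {  # half the 8-neighbourhood
    j <- idx + off
    # guard against wrapping across matrix columns
    y <- (idx - 1L) %% H
    ok <- j >= 1L & j <= length(bw) & bw[pmax(pmin(j, length(bw)), 1L)] == 1L
    if (off == -1L) ok <- ok & y > 0L
    if (off == H - 1L) ok <- ok & y > 0L
    if (off == H + 1L) ok <- ok & y < H - 1L
    if (any(ok)) edges <- rbind(edges, cbind(pos[idx[ok]], pos[j[ok]]))
  }
  g <- igraph::graph_from_edgelist(
    rbind(matrix(rep(seq_along(idx), 2), ncol = 2), edges), directed = FALSE)
  lab[idx] <- igraph::components(g)$membership[seq_along(idx)]
  lab
}

#' Region of interest (ROI)
#'
#' A square ROI of physical size 400 x 400 um by default, half-open in
#' pixel coordinates: `[x, x + side) x [y, y + side)`, 0-based.
#'
#' @param x,y 0-based origin, pixels.
#' @param side_px side length, pixels; defaults to `round(side_um /
#'   pixel_size_um)`.
#' @param region region label, one of normal, low_grade, high_grade, core,
#'   edge.
#' @param id ROI identifier.
#' @param pixel_size_um,side_um used when `side_px` is missing.
#' @export
roi <- function(x, y, side_px = NULL, region = "core", id = NA_character_,
                pixel_size_um = 1, side_um = 400) {
  region <- match.arg(region, c("normal", "low_grade", "high_grade", "core", "edge"))
  if (is.null(side_px)) side_px <- round(side_um / pixel_size_um)
  if (side_px < 1) stop("ROI side must be >= 1 px")
  structure(list(x = x, y = y, side_px = as.integer(round(side_px)),
                 region = region, id = id, clipped = FALSE),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI %s [%s]: origin (%g, %g), side %d px%s\n",
              x$id, x$region, x$x, x$y, x$side_px,
              if (isTRUE(x$clipped)) " (clipped)" else ""))
  invisible(x)
}

#' Alignment of the fibers inside one ROI
#'
#' Crops the ROI, extracts fibers ([extract_fibers()]) and scores alignment.
#' Fibers belong to the ROI by centroid membership (always true for fibers
#' extracted from the crop). The result records `n_fibers` for quality
#' control; an ROI with no fibers yields a flagged-undefined R.
#'
#' @param image intensity matrix.
#' @param roi a [roi()]; must lie fully inside the image.
#' @param ... passed to [extract_fibers()].
#' @return list of class `alignment_result`: `R`, `n_fibers`, `roi_id`,
#'   `region`, `undefined`.
#' @export
roi_alignment <- function(image, roi, ...) {
  stopifnot(inherits(roi, "roi"))
  H <- nrow(image); W <- ncol(image)
  if (roi$x < 0 || roi$y < 0 || roi$x + roi$side_px > W || roi$y + roi$side_px > H)
    stop("ROI extends outside the image")
  crop <- image[(roi$y + 1):(roi$y + roi$side_px),
                (roi$x + 1):(roi$x + roi$side_px), drop = FALSE]
  fs <- extract_fibers(crop, ...)
  structure(list(R = alignment_score(fs$theta_deg),
                 n_fibers = nrow(fs), roi_id = roi$id, region = roi$region,
                 undefined = nrow(fs) == 0),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("ROI %s [%s]: R = %s (n_fibers = %d)\n", x$roi_id, x$region,
              if (x$undefined) "undefined" else sprintf("%.3f", x$R), x$n_fibers))
  invisible(x)
}
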