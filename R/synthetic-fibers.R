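#' Specification of a synthetic fiber field
#'
#' Describes a field of straight collagen-like fibers with orientations drawn
#' from an axial von Mises distribution: `2*theta ~ vonMises(2*mean_angle,
#' kappa)`, the standard construction for axial (mod-180) data.
#' `kappa = 0` gives uniform orientations; `kappa = Inf` (or
#' `degenerate = TRUE`) makes every fiber identical to `mean_angle`.
#'
#' @param n_fibers number of fibers (>= 0).
#' @param mean_angle mean orientation, degrees in `[0, 180)`.
#' @param kappa axial von Mises concentration, >= 0; may be `Inf`.
#' @param fiber_length_px mean fiber length, pixels.
#' @param fiber_length_sd sd of fiber length, pixels.
#' @param fiber_width_px fiber width, integer >= 1.
#' @param image_size_px `c(H, W)`, both >= 64.
#' @param pixel_size_um physical pixel size, microns.
#' @param seed integer seed; all randomness in [make_fiber_image()] flows
#'   from it.
#' @return object of class `fiber_field_spec`.
#' @export
fiber_field_spec <- function(n_fibers = 300, mean_angle = 90, kappa = 2,
                             fiber_length_px = 60, fiber_length_sd = 15,
                             fiber_width_px = 2, image_size_px = c(256, 256),
                             pixel_size_um = 1, seed = 1) {
  stopifnot(n_fibers >= 0, kappa >= 0, fiber_length_px > 0,
            fiber_width_px >= 1, length(image_size_px) == 2)
  if (any(image_size_px < 64)) stop("image dimensions must be >= 64")
  if (prod(image_size_px) == 0) stop("zero-area image")
  mean_angle <- mean_angle %% 180
  structure(list(n_fibers = as.integer(n_fibers), mean_angle = mean_angle,
                 kappa = kappa, fiber_length_px = fiber_length_px,
                 fiber_length_sd = fiber_length_sd,
                 fiber_width_px = as.integer(fiber_width_px),
                 image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "fiber_field_spec")
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. Used internally for axial orientations;
#' exported because tests and power studies need raw circular samples.
#'
#' @param n sample size.
#' @param mu mean direction, radians.
#' @param kappa concentration >= 0 (0 = circular uniform).
#' @return radians in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nacc <- sum(ok)
    if (nacc > 0) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1):(got + nacc)] <- (th + mu) %% (2 * pi)
      got <- got + nacc
    }
  }
  out
}

# axial orientations in degrees [0, 180): sample 2*theta, halve
sample_axial_angles <- function(n, mean_angle, kappa) {
  if (is.infinite(kappa)) return(rep(mean_angle %% 180, n))
  (rvonmises(n, mu = 2 * mean_angle * pi / 180, kappa = kappa) * 180 / pi / 2) %% 180
}

#' Render a synthetic SHG-like fiber image
#'
#' Draws anti-aliased straight segments on a dark background and returns the
#' image together with the ground-truth fiber table, so downstream fiber
#' extraction and alignment scoring can be checked against known truth.
#' Fiber centres are uniform over the image; intensity per fiber is ~1 with
#' small variation; optional Gaussian read noise and Poisson shot noise.
#'
#' @param spec a [fiber_field_spec()].
#' @param noise_sd sd of additive Gaussian background noise (image scale,
#'   foreground ~ 1).
#' @param poisson_scale if > 0, photon-count scale for Poisson noise
#'   (intensity -> rpois(intensity * scale) / scale).
#' @return list with `image` (H x W matrix), `fibers` (a `fiber_set`), and
#'   `spec`.
#' @examples
#' f <- make_fiber_image(fiber_field_spec(n_fibers = 50, seed = 2))
#' true_alignment(f$fibers)
#' @export
make_fiber_image <- function(spec, noise_sd = 0.02, poisson_scale = 0) {
  stopifnot(inherits(spec, "fiber_field_spec"))
  set.seed(spec$seed)
  H <- spec$image_size_px[1]; W <- spec$image_size_px[2]
  n <- spec$n_fibers
  theta <- sample_axial_angles(n, spec$mean_angle, spec$kappa)
  len <- pmax(abs(rnorm(n, spec$fiber_length_px, spec$fiber_length_sd)), 4)
  cx <- runif(n, 0, W - 1); cy <- runif(n, 0, H - 1)
  th <- theta * pi / 180
  dx <- cos(th) * len / 2; dy <- sin(th) * len / 2
  x1 <- cx - dx; y1 <- cy - dy; x2 <- cx + dx; y2 <- cy + dy
  amp <- runif(n, 0.8, 1.2)
  img <- matrix(0, H, W)
  half_w <- spec$fiber_width_px / 2
  for (i in seq_len(n)) {
    img <- draw_segment(img, x1[i], y1[i], x2[i], y2[i], half_w, amp[i])
  }
  if (poisson_scale > 0) img <- rpois(length(img), pmax(img, 0) * poisson_scale) / poisson_scale
  if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
  img <- matrix(pmax(img, 0), H, W)
  fibers <- fiber_set(data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                                 x = cx, y = cy,
                                 theta_deg = theta, length_px = len),
                      pixel_size_um = spec$pixel_size_um)
  list(image = img, fibers = fibers, spec = spec)
}

# additive anti-aliased capsule (segment with rounded caps) of half-width hw
draw_segment <- function(img, x1, y1, x2, y2, hw, amp = 1) {
  H <- nrow(img); W <- ncol(img)
  pad <- ceiling(hw) + 1
  xmin <- max(floor(min(x1, x2)) - pad, 0); xmax <- min(ceiling(max(x1, x2)) + pad, W - 1)
  ymin <- max(floor(min(y1, y2)) - pad, 0); ymax <- min(ceiling(max(y1, y2)) + pad, H - 1)
  if (xmin > xmax || ymin > ymax) return(img)
  xs <- xmin:xmax; ys <- ymin:ymax
  px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  t <- if (L2 == 0) rep(0, length(px)) else pmin(pmax(((px - x1) * vx + (py - y1) * vy) / L2, 0), 1)
  d <- sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
  val <- pmin(pmax(hw + 0.5 - d, 0), 1) * amp
  sub <- img[ys + 1, xs + 1, drop = FALSE]
  img[ys + 1, xs + 1] <- pmax(sub, matrix(val, length(ys), length(xs)))
  img
}

#' Fiber set container
#'
#' A data.frame of fiber segments with axial orientations. Required columns:
#' `x`, `y` (centroid, 0-based px), `theta_deg` in `[0, 180)`,
#' `length_px` > 0. Generator output also carries endpoints `x1,y1,x2,y2`.
#'
#' @param fibers data.frame as above.
#' @param pixel_size_um physical pixel size.
#' @param image_id optional source image identifier.
#' @export
fiber_set <- function(fibers, pixel_size_um = 1, image_id = NA_character_) {
  stopifnot(is.data.frame(fibers),
            all(c("x", "y", "theta_deg", "length_px") %in% names(fibers)))
  if (nrow(fibers) > 0) {
    fibers$theta_deg <- fibers$theta_deg %% 180
    if (any(fibers$length_px <= 0)) stop("fiber lengths must be > 0")
  }
  structure(fibers, class = c("fiber_set", "data.frame"),
            pixel_size_um = pixel_size_um, image_id = image_id)
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("fiber set: %d fibers (pixel size %.3g um)\n",
              nrow(x), attr(x, "pixel_size_um")))
  if (nrow(x)) print(head(as.data.frame(x), 5))
  invisible(x)
}

#' Ground-truth alignment of a fiber set
#'
#' Mean resultant vector length of the stored axial orientations (angle
#' doubling); deterministic given the table.
#'
#' @param fibers `fiber_set`.
#' @export
true_alignment <- function(fibers) alignment_score(fibers$theta_deg)

#' Write / read a fiber table as CSV
#'
#' Columns `x1,y1,x2,y2,theta_deg,length_px` (endpoints omitted when absent).
#'
#' @param fibers `fiber_set`; `path` file path.
#' @param path file path.
#' @export
write_fiber_csv <- function(fibers, path) {
  cols <- intersect(c("x1", "y1", "x2", "y2", "x", "y", "theta_deg", "length_px"),
                    names(fibers))
  write.csv(as.data.frame(fibers)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fiber_csv
#' @param pixel_size_um pixel size recorded on the returned set.
#' @export
read_fiber_csv <- function(path, pixel_size_um = 1) {
  df <- read.csv(path)
  if (!"x" %in% names(df) && all(c("x1", "x2") %in% names(df))) {
    df$x <- (df$x1 + df$x2) / 2; df$y <- (df$y1 + df$y2) / 2
  }
  fiber_set(df, pixel_size_um = pixel_size_um)
}
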