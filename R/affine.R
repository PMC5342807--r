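#' Planar affine transforms
#'
#' An affine transform is stored as a 2 x 3 matrix `[A | t]` taking
#' moving-image pixel coordinates to fixed-image coordinates:
#' `(x', y')^T = A %*% (x, y)^T + t`. The linear part must be invertible.
#'
#' @param m numeric 2 x 3 matrix.
#' @return An object of class `affine_transform`.
#' @examples
#' t1 <- affine_translation(10, 5)
#' affine_apply(t1, cbind(0, 0))
#' @export
affine_transform <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || !all(dim(m) == c(2L, 3L)))
    stop("affine transform must be a numeric 2 x 3 matrix")
  if (abs(det(m[, 1:2])) <= 1e-8)
    stop("affine linear part is singular (|det| <= 1e-8)")
  structure(list(m = m), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("affine transform (moving -> fixed, px):\n")
  print(x$m)
  invisible(x)
}

#' @rdname affine_transform
#' @export
affine_identity <- function() affine_transform(cbind(diag(2), c(0, 0)))

#' @rdname affine_transform
#' @param tx,ty translation in pixels.
#' @export
affine_translation <- function(tx, ty) affine_transform(cbind(diag(2), c(tx, ty)))

#' Rotation / scaling about a centre point
#'
#' @param degrees rotation angle, degrees, positive from +x towards +y.
#' @param sx,sy scale factors.
#' @param center length-2 centre of rotation/scaling `(x, y)` in pixels.
#' @return `affine_transform`.
#' @export
affine_rotation <- function(degrees, center = c(0, 0)) {
  th <- degrees * pi / 180
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t <- center - A %*% center
  affine_transform(cbind(A, t))
}

#' @rdname affine_rotation
#' @export
affine_scaling <- function(sx, sy = sx, center = c(0, 0)) {
  A <- diag(c(sx, sy))
  t <- center - A %*% center
  affine_transform(cbind(A, t))
}

#' Compose, invert and apply affine transforms
#'
#' `affine_compose(a, b)` returns the transform applying `b` first, then `a`.
#'
#' @param a,b `affine_transform` objects.
#' @export
affine_compose <- function(a, b) {
  A <- a$m[, 1:2] %*% b$m[, 1:2]
  t <- a$m[, 1:2] %*% b$m[, 3] + a$m[, 3]
  affine_transform(cbind(A, t))
}

#' @rdname affine_compose
#' @export
affine_invert <- function(a) {
  Ai <- solve(a$m[, 1:2])
  affine_transform(cbind(Ai, -Ai %*% a$m[, 3]))
}

#' @rdname affine_compose
#' @param xy n x 2 matrix of `(x, y)` coordinates.
#' @export
affine_apply <- function(a, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  t(a$m[, 1:2] %*% t(xy) + a$m[, 3])
}

#' Build a transform from pose parameters
#'
#' Parameters act about `center`: rotation `theta_deg`, log-scales, shear,
#' then translation. This is the parameterisation used by the registration
#' optimizer; it is equivalent to a general 6-parameter affine map.
#'
#' @param p numeric length 6: `(tx, ty, theta_deg, log_sx, log_sy, shear)`.
#' @param center length-2 centre `(x, y)`.
#' @export
affine_from_pose <- function(p, center = c(0, 0)) {
  th <- p[3] * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(exp(p[4]), 0, p[6], exp(p[5])), 2, 2)
  A <- R %*% S
  t <- c(p[1], p[2]) + center - A %*% center
  affine_transform(cbind(A, t))
}

#' Resample an image through an affine map
#'
#' Returns the moving image expressed in the fixed frame:
#' `out(x_f) = img(tform^{-1}(x_f))`, bilinear interpolation, out-of-bounds
#' pixels set to `background`.
#'
#' @param img numeric matrix (grayscale) or H x W x 3 array.
#' @param tform `affine_transform` mapping image (moving) to output (fixed)
#'   coordinates.
#' @param output_dim `c(H, W)` of the result; defaults to the input size.
#' @param background fill value for unmapped pixels.
#' @export
warp_affine <- function(img, tform, output_dim = NULL, background = 0) {
  if (length(dim(img)) == 3L) {
    out <- vapply(seq_len(dim(img)[3]), function(ch)
      warp_affine(img[, , ch], tform, output_dim, background),
      matrix(0, if (is.null(output_dim)) nrow(img) else output_dim[1],
             if (is.null(output_dim)) ncol(img) else output_dim[2]))
    return(out)
  }
  if (is.null(output_dim)) output_dim <- dim(img)
  H <- output_dim[1]; W <- output_dim[2]
  inv <- affine_invert(tform)
  g <- expand.grid(y = seq_len(H) - 1, x = seq_len(W) - 1)  # y fastest: column-major
  src <- affine_apply(inv, cbind(g$x, g$y))
  v <- interp_bilinear(img, src[, 1], src[, 2], background)
  matrix(v, H, W, byrow = FALSE)[]
}

# Bilinear interpolation at 0-based (x, y); out-of-bounds -> background.
interp_bilinear <- function(img, x, y, background = 0) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= W - 1 & y0 <= H - 1
  # clamp the +1 neighbour at the border so edge pixels interpolate to themselves
  x0c <- pmin(pmax(x0, 0), W - 1); y0c <- pmin(pmax(y0, 0), H - 1)
  x1c <- pmin(x0c + 1, W - 1);     y1c <- pmin(y0c + 1, H - 1)
  i00 <- y0c + 1 + H * x0c; i10 <- y0c + 1 + H * x1c
  i01 <- y1c + 1 + H * x0c; i11 <- y1c + 1 + H * x1c
  v <- (1 - fx) * (1 - fy) * img[i00] + fx * (1 - fy) * img[i10] +
    (1 - fx) * fy * img[i01] + fx * fy * img[i11]
  v[!ok] <- background
  v
}

#' Serialize / deserialize an affine transform as JSON
#'
#' @param tform `affine_transform`.
#' @param path file path.
#' @param metadata optional named list stored alongside the parameters.
#' @export
write_transform_json <- function(tform, path, metadata = list()) {
  obj <- c(list(matrix_row_major = as.numeric(t(tform$m)),
                convention = "2x3 [A|t], moving (x,y) -> fixed (x,y), 0-based pixels"),
           metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(matrix(obj$matrix_row_major, 2, 3, byrow = TRUE))
}
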