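#' Bilinear sampling of an image at fractional coordinates
#'
#' Samples `img` at positions (X, Y) with bilinear interpolation and
#' nearest-edge boundary extension: coordinates outside the grid are clamped
#' to the border before interpolation, so out-of-domain samples repeat the
#' edge value.
#'
#' @param img numeric matrix.
#' @param X,Y fractional column / row coordinates (1-based), any shape.
#' @param deriv if `TRUE`, also return the partial derivatives of the
#'   interpolant with respect to X and Y (zero where the coordinate was
#'   clamped, since the extended image is constant there).
#' @return numeric object shaped like `X` (values), or if `deriv` a list
#'   `list(value, dX, dY)`.
#' @keywords internal
bilinear_sample <- function(img, X, Y, deriv = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  dm <- dim(X)
  Xc <- pmin(pmax(as.numeric(X), 1), nc)
  Yc <- pmin(pmax(as.numeric(Y), 1), nr)
  x0 <- pmin(floor(Xc), nc - 1)
  y0 <- pmin(floor(Yc), nr - 1)
  tx <- Xc - x0
  ty <- Yc - y0
  base <- (x0 - 1) * nr + y0          # linear index of (y0, x0)
  v00 <- img[base]
  v10 <- img[base + nr]
  v01 <- img[base + 1]
  v11 <- img[base + nr + 1]
  top <- (1 - tx) * v00 + tx * v10
  bot <- (1 - tx) * v01 + tx * v11
  val <- (1 - ty) * top + ty * bot
  if (!deriv) {
    dim(val) <- dm
    return(val)
  }
  dX <- (1 - ty) * (v10 - v00) + ty * (v11 - v01)
  dY <- (1 - tx) * (v01 - v00) + tx * (v11 - v10)
  clampedX <- as.numeric(X) < 1 | as.numeric(X) > nc
  clampedY <- as.numeric(Y) < 1 | as.numeric(Y) > nr
  dX[clampedX] <- 0
  dY[clampedY] <- 0
  dim(val) <- dm; dim(dX) <- dm; dim(dY) <- dm
  list(value = val, dX = dX, dY = dY)
}

#' Catmull-Rom bicubic sampling with analytic derivatives
#'
#' C1 interpolation of `img` at fractional coordinates with replicate
#' (nearest-edge) boundary extension. Unlike bilinear interpolation the
#' derivative of the interpolant is continuous across pixel boundaries,
#' which the similarity force relies on (the sampled gradient-field
#' functional stays differentiable at integer displacements).
#'
#' @inheritParams bilinear_sample
#' @keywords internal
cubic_sample <- function(img, X, Y, deriv = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  dm <- dim(X)
  Xv <- as.numeric(X); Yv <- as.numeric(Y)
  Xc <- pmin(pmax(Xv, 1), nc)
  Yc <- pmin(pmax(Yv, 1), nr)
  x1 <- pmin(floor(Xc), nc - 1)
  y1 <- pmin(floor(Yc), nr - 1)
  tx <- Xc - x1
  ty <- Yc - y1
  # Catmull-Rom basis
  wgt <- function(t) list(0.5 * (-t + 2 * t^2 - t^3),
                          0.5 * (2 - 5 * t^2 + 3 * t^3),
                          0.5 * (t + 4 * t^2 - 3 * t^3),
                          0.5 * (-t^2 + t^3))
  dwgt <- function(t) list(0.5 * (-1 + 4 * t - 3 * t^2),
                           0.5 * (-10 * t + 9 * t^2),
                           0.5 * (1 + 8 * t - 9 * t^2),
                           0.5 * (-2 * t + 3 * t^2))
  wx <- wgt(tx); wy <- wgt(ty)
  cols <- lapply(-1:2, function(o) pmin(pmax(x1 + o, 1), nc))
  rows <- lapply(-1:2, function(o) pmin(pmax(y1 + o, 1), nr))
  val <- 0
  if (deriv) { dX <- 0; dY <- 0; dwx <- dwgt(tx); dwy <- dwgt(ty) }
  for (j in 1:4) {
    colbase <- (cols[[j]] - 1) * nr
    for (i in 1:4) {
      p <- img[colbase + rows[[i]]]
      val <- val + wy[[i]] * wx[[j]] * p
      if (deriv) {
        dX <- dX + wy[[i]] * dwx[[j]] * p
        dY <- dY + dwy[[i]] * wx[[j]] * p
      }
    }
  }
  if (!deriv) {
    dim(val) <- dm
    return(val)
  }
  dX[Xv < 1 | Xv > nc] <- 0
  dY[Yv < 1 | Yv > nr] <- 0
  dim(val) <- dm; dim(dX) <- dm; dim(dY) <- dm
  list(value = val, dX = dX, dY = dY)
}

#' Nearest-neighbour sampling with clamped coordinates
#' @keywords internal
nearest_sample <- function(img, X, Y) {
  nr <- nrow(img); nc <- ncol(img)
  dm <- dim(X)
  xi <- pmin(pmax(round(as.numeric(X)), 1), nc)
  yi <- pmin(pmax(round(as.numeric(Y)), 1), nr)
  val <- img[(xi - 1) * nr + yi]
  dim(val) <- dm
  val
}

# 1-D finite-difference stencil matrix: central differences in the interior,
# one-sided at the two borders. Applied along rows (premultiplied) or along
# columns (postmultiplied by its transpose). These stencils are shared by the
# image gradients, the elastic potential and the elastic operator so that the
# discrete bilinear-form identities hold exactly.
diff_matrix <- function(n, h = 1) {
  stopifnot(n >= 2, h > 0)
  C <- matrix(0, n, n)
  C[1, 1] <- -1 / h; C[1, 2] <- 1 / h
  C[n, n - 1] <- -1 / h; C[n, n] <- 1 / h
  if (n > 2) {
    for (j in 2:(n - 1)) {
      C[j, j - 1] <- -1 / (2 * h)
      C[j, j + 1] <- 1 / (2 * h)
    }
  }
  C
}

#' Discrete spatial gradient of an image
#'
#' Central differences in the interior, one-sided differences at the borders,
#' scaled by the pixel spacing.
#'
#' @param img numeric matrix.
#' @param spacing length-2 numeric `(dx, dy)`.
#' @return list with matrices `gx` (d/dx, along columns) and `gy` (d/dy).
#' @export
image_gradient <- function(img, spacing = c(1, 1)) {
  Cx <- diff_matrix(ncol(img), spacing[1])
  Cy <- diff_matrix(nrow(img), spacing[2])
  list(gx = img %*% t(Cx), gy = Cy %*% img)
}

#' Meshgrid of pixel-centre coordinates
#' @keywords internal
coord_grid <- function(nr, nc) {
  list(X = matrix(rep(seq_len(nc), each = nr), nr, nc),
       Y = matrix(rep(seq_len(nr), nc), nr, nc))
}

#' Gaussian smoothing (separable, replicate boundary)
#' @keywords internal
gaussian_smooth <- function(img, sigma = 1) {
  if (sigma <= 0) return(img)
  EBImage::gblur(img, sigma = sigma, boundary = "replicate")
}

#' Zero displacement field for a grid
#' @param dims integer `(nrow, ncol)`.
#' @export
zero_field <- function(dims) array(0, dim = c(dims[1], dims[2], 2))

check_field <- function(u, dims = NULL) {
  stopifnot(is.array(u), length(dim(u)) == 3, dim(u)[3] == 2, all(is.finite(u)))
  if (!is.null(dims)) stopifnot(all(dim(u)[1:2] == dims))
  invisible(u)
}

#' Binary erosion of a logical mask (diamond structuring element)
#' @keywords internal
erode_mask <- function(mask, px = 2) {
  if (px <= 0) return(mask)
  m <- EBImage::erode(mask * 1, EBImage::makeBrush(2 * px + 1, shape = "diamond"))
  m > 0.5
}
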