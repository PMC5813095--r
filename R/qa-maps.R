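#' Local deformation field (checkerboard) map
#'
#' Visualizes a deformation by sampling a checkerboard `C` through
#' `phi(x) = x + u(x)`: `LDF(x) = C(phi(x))`. The checkerboard is evaluated
#' analytically at the (continuous) deformed positions, so a pure translation
#' shifts the board without bending any line, while local deformation bows
#' and squeezes the grid cells.
#'
#' @param u displacement field.
#' @param checker_period checker square edge in pixels (>= 2).
#' @return numeric matrix of 0/1 checker values.
#' @export
ldf_map <- function(u, checker_period = 8) {
  check_field(u)
  stopifnot(checker_period >= 2)
  g <- coord_grid(dim(u)[1], dim(u)[2])
  px <- g$X + u[, , 1]
  py <- g$Y + u[, , 2]
  (floor((px - 1) / checker_period) + floor((py - 1) / checker_period)) %% 2
}

#' Local volume change map
#'
#' `LVC(x) = det(grad phi(x)) - 1` with `phi = id + u`; the Jacobian is
#' evaluated per pixel from the 3x3 neighbourhood by central differences.
#' Zero means local volume (area) preservation; positive values mark
#' expansion and negative values compression. Border pixels, where the 3x3
#' stencil is undefined, use one-sided differences and are flagged in the
#' `"border"` attribute.
#'
#' @param u displacement field (at least 3x3).
#' @return matrix of LVC values with logical attribute `"border"`.
#' @export
lvc_map <- function(u) {
  check_field(u)
  nr <- dim(u)[1]; nc <- dim(u)[2]
  stopifnot(nr >= 3, nc >= 3)
  gx <- image_gradient(u[, , 1], c(1, 1))   # d(ux)/dx, d(ux)/dy
  gy <- image_gradient(u[, , 2], c(1, 1))
  j11 <- 1 + gx$gx
  j12 <- gx$gy
  j21 <- gy$gx
  j22 <- 1 + gy$gy
  out <- j11 * j22 - j12 * j21 - 1
  border <- matrix(FALSE, nr, nc)
  border[c(1, nr), ] <- TRUE
  border[, c(1, nc)] <- TRUE
  attr(out, "border") <- border
  out
}

# map a scalar image to [0,1] with a fixed window (level +- width/2);
# NA-safe (NA -> 0)
window_normalize <- function(img, window = NULL) {
  if (is.null(window)) {
    fin <- img[is.finite(img)]
    window <- if (length(fin)) range(fin) else c(0, 1)
  }
  if (window[2] <= window[1]) window[2] <- window[1] + 1
  out <- (img - window[1]) / (window[2] - window[1])
  out[!is.finite(out)] <- 0
  pmin(pmax(out, 0), 1)
}

#' Isocontour overlay
#'
#' Draws the isocontour of a reference map at a given level on top of a
#' grayscale rendering of `map_image` (deterministic for a fixed window).
#' Contour polylines are extracted with [grDevices::contourLines()] and
#' rasterized onto the image.
#'
#' @param map_image scalar map to display.
#' @param reference_map reference image supplying the contour (same grid).
#' @param level contour level in the units of `reference_map`.
#' @param window display window `c(low, high)` for `map_image`
#'   (default: its finite range).
#' @param color RGB triple in `[0,1]` used for the contour.
#' @return an `c(nrow, ncol, 3)` RGB array with attribute `"contours"`
#'   holding the contour polylines (list of `x`/`y` pixel coordinates).
#' @export
isocontour_overlay <- function(map_image, reference_map, level,
                               window = NULL, color = c(1, 1, 1)) {
  stopifnot(all(dim(map_image) == dim(reference_map)))
  nr <- nrow(map_image); nc <- ncol(map_image)
  base <- window_normalize(map_image, window)
  rgb <- array(rep(base, 3), dim = c(nr, nc, 3))
  ref <- reference_map
  ref[!is.finite(ref)] <- min(ref[is.finite(ref)], level - 1)
  # contourLines indexes z[i, j] by x[i], y[j]: x = row coord, y = col coord;
  # a constant reference has no level set to draw
  cl <- if (diff(range(ref)) == 0) list()
        else grDevices::contourLines(x = seq_len(nr), y = seq_len(nc),
                                     z = ref, levels = level)
  contours <- list()
  for (cont in cl) {
    ry <- cont$x   # row coordinates
    cx <- cont$y   # column coordinates
    contours[[length(contours) + 1]] <- list(x = cx, y = ry)
    if (length(ry) < 2) next
    # subdivide segments so the rasterized line is connected
    for (s in seq_len(length(ry) - 1)) {
      npt <- max(2, ceiling(2 * max(abs(ry[s + 1] - ry[s]),
                                    abs(cx[s + 1] - cx[s]))) + 1)
      rr <- round(seq(ry[s], ry[s + 1], length.out = npt))
      cc <- round(seq(cx[s], cx[s + 1], length.out = npt))
      keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      idx <- (cc[keep] - 1) * nr + rr[keep]
      for (ch in 1:3) rgb[idx + (ch - 1) * nr * nc] <- color[ch]
    }
  }
  attr(rgb, "contours") <- contours
  rgb
}
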