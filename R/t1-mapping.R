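#' MOLLI image series
#'
#' Container for an ordered MOLLI frame stack with per-frame inversion times.
#' Frames are stored as a 3-D array `c(nrow, ncol, nframes)` in acquisition
#' order; fitting routines sort by inversion time internally.
#'
#' @param frames 3-D numeric array, or a list of co-shaped matrices.
#' @param inversion_times per-frame inversion times in ms (strictly positive).
#' @param magnitude whether intensities are magnitude images (non-negative,
#'   polarity lost); if `TRUE` the sign of the recovery curve is restored
#'   before fitting.
#' @param scheme optional scheme label, e.g. `"5s(3s)3s"`.
#' @param heart_rate optional heart rate in bpm.
#' @param spacing pixel spacing `(dx, dy)` in mm.
#' @return object of class `"molli_series"`.
#' @export
molli_series <- function(frames, inversion_times, magnitude = TRUE,
                         scheme = NA_character_, heart_rate = NA_real_,
                         spacing = c(1, 1)) {
  if (is.list(frames)) {
    dims <- dim(frames[[1]])
    stopifnot(all(vapply(frames, function(f) identical(dim(f), dims), logical(1))))
    frames <- array(unlist(frames), dim = c(dims, length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  nf <- dim(frames)[3]
  if (nf < 4) stop("a MOLLI series needs at least 4 frames")
  if (length(inversion_times) != nf)
    stop("one inversion time per frame is required")
  stopifnot(all(is.finite(inversion_times)), all(inversion_times > 0),
            all(is.finite(frames)))
  structure(list(frames = frames, inversion_times = as.numeric(inversion_times),
                 magnitude = isTRUE(magnitude), scheme = scheme,
                 heart_rate = heart_rate, spacing = spacing),
            class = "molli_series")
}

#' @export
print.molli_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("MOLLI series: %d frames of %dx%d (%s)\n", d[3], d[1], d[2],
              if (x$magnitude) "magnitude" else "signed"))
  cat("  TI [ms]:", paste(round(x$inversion_times, 1), collapse = ", "), "\n")
  if (!is.na(x$scheme)) cat("  scheme:", x$scheme,
                            if (!is.na(x$heart_rate)) sprintf("@ %g bpm", x$heart_rate), "\n")
  invisible(x)
}

#' @export
dim.molli_series <- function(x) dim(x$frames)

ir_model <- function(par, t) par[1] - par[2] * exp(-t / par[3])

ir_jacobian <- function(par, t) {
  e <- exp(-t / par[3])
  cbind(1, -e, -par[2] * e * t / par[3]^2)
}

#' Three-parameter inversion-recovery fit
#'
#' Fits the Look-Locker signal model `S(t) = A - B * exp(-t / T1star)` to one
#' pixel's (signed) intensity samples by Levenberg-Marquardt minimization.
#' The parameter covariance is estimated from the analytic Jacobian as
#' `sigma2 * (J'J)^-1` with `sigma2 = SSR / (n - 3)`.
#'
#' @param signal signed intensities (>= 4 finite samples).
#' @param times inversion times in ms, same length.
#' @param init optional `c(A, B, T1star)` start; defaults to
#'   `A = max(signal)`, `B = A - min(signal)`, `T1star = 1000`.
#' @param t1star_limits apparent-T1 validity window in ms; a fit outside it
#'   is flagged invalid.
#' @return list with `A`, `B`, `t1star`, `ssr`, `covariance` (3x3 or NULL),
#'   `valid`, `fitted`.
#' @export
fit_ir_three_param <- function(signal, times, init = NULL,
                               t1star_limits = c(1, 5000)) {
  stopifnot(length(signal) == length(times))
  ok <- is.finite(signal) & is.finite(times)
  signal <- signal[ok]; times <- times[ok]
  if (length(signal) < 4)
    return(list(A = NA_real_, B = NA_real_, t1star = NA_real_, ssr = NA_real_,
                covariance = NULL, valid = FALSE, fitted = NULL))
  if (is.null(init)) {
    A0 <- max(signal)
    B0 <- A0 - min(signal)
    if (B0 <= 0) B0 <- max(abs(signal)) + 1e-6
    init <- c(A0, B0, 1000)
  }
  # iteration-cap chatter from degenerate pixels is handled via the validity
  # flag, not as a user-facing warning
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(par = init,
                       fn = function(p) signal - ir_model(p, times),
                       jac = function(p) -ir_jacobian(p, times),
                       lower = c(-Inf, -Inf, 1), upper = c(Inf, Inf, 10000),
                       control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(A = NA_real_, B = NA_real_, t1star = NA_real_, ssr = NA_real_,
                covariance = NULL, valid = FALSE, fitted = NULL))
  p <- fit$par
  ssr <- sum(fit$fvec^2)
  n <- length(signal)
  J <- ir_jacobian(p, times)
  covariance <- tryCatch({
    sigma2 <- ssr / max(n - 3, 1)
    sigma2 * solve(crossprod(J))
  }, error = function(e) NULL)
  # B ~ 0 leaves T1* unidentifiable (flat signal): degenerate
  identifiable <- is.finite(p[2]) && abs(p[2]) > 1e-6 * max(abs(p[1]), 1e-12)
  valid <- identifiable && is.finite(p[3]) &&
    p[3] > t1star_limits[1] && p[3] < t1star_limits[2]
  list(A = p[1], B = p[2], t1star = p[3], ssr = ssr,
       covariance = covariance, valid = valid, fitted = ir_model(p, times))
}

#' Look-Locker correction of the apparent T1
#'
#' `T1 = (B/A - 1) * T1star`, correcting the apparent relaxation time of the
#' continuously-read-out inversion recovery for signal saturation.
#'
#' @param A,B,t1star fitted model parameters (vectorized).
#' @return corrected T1 in ms; `NA` where `A == 0`.
#' @export
look_locker_correct <- function(A, B, t1star) {
  out <- (B / A - 1) * t1star
  out[A == 0] <- NA_real_
  out
}

#' Restore the polarity of a magnitude inversion-recovery curve
#'
#' SSFP MOLLI magnitude data loses the sign of the recovery curve. Each
#' candidate sign-change index k (negating the first k samples in ascending
#' inversion-time order) is fitted with the three-parameter model and the
#' polarity with minimal residual is kept; ties resolve to the smallest k,
#' so an all-positive curve with no zero crossing keeps index 0.
#'
#' @param signal magnitude intensities.
#' @param times inversion times in ms (need not be sorted; candidates are
#'   formed in ascending-time order).
#' @param candidates optional integer vector of candidate indices to try
#'   (default: exhaustive, `0:(n-1)`).
#' @return list with `signal` (signed, original order), `index` (chosen k),
#'   and `fit` (the winning [fit_ir_three_param()] result).
#' @export
restore_polarity <- function(signal, times, candidates = NULL) {
  n <- length(signal)
  if (n < 4) return(list(signal = signal, index = 0L, fit = NULL))
  ord <- order(times)
  s_sorted <- signal[ord]
  t_sorted <- times[ord]
  if (is.null(candidates)) candidates <- 0:(n - 1)
  best <- NULL; best_k <- 0L
  for (k in candidates) {
    s_try <- s_sorted
    if (k > 0) s_try[seq_len(k)] <- -s_try[seq_len(k)]
    fit <- fit_ir_three_param(s_try, t_sorted)
    if (!is.null(fit$fitted) &&
        (is.null(best) || fit$ssr < best$ssr * (1 - 1e-9))) {
      best <- fit; best_k <- as.integer(k)
    }
  }
  s_signed <- s_sorted
  if (best_k > 0) s_signed[seq_len(best_k)] <- -s_signed[seq_len(best_k)]
  out <- numeric(n)
  out[ord] <- s_signed
  list(signal = out, index = best_k, fit = best)
}

# Candidate sign-change indices worth trying for a magnitude IR curve: the
# zero crossing sits at or just after the signal minimum (in ascending TI
# order), so only indices up to argmin+1 can win. k = 0 is always included.
polarity_candidates <- function(signal_sorted) {
  kmin <- which.min(signal_sorted)
  0:min(kmin + 1, length(signal_sorted) - 1)
}

#' Pixel-wise T1 mapping of a MOLLI series
#'
#' Runs per-pixel polarity restoration (magnitude data), the three-parameter
#' Levenberg-Marquardt fit, and the Look-Locker correction, and propagates
#' the fit covariance through the correction to a per-pixel SD fitting-error
#' map in ms (delta method on `T1 = (B/A - 1) * T1star`).
#'
#' @param series a [molli_series()].
#' @param mask optional logical matrix restricting the fit.
#' @param t1_limits corrected-T1 validity window in ms; values outside are
#'   masked out of `fit_mask`.
#' @return object of class `"t1_fit"`: matrices `A`, `B`, `t1star`, `t1`,
#'   `sd_error` (ms), `ssr`, logical `fit_mask`, and `polarity_index`.
#' @export
fit_t1_map <- function(series, mask = NULL, t1_limits = c(1, 5000)) {
  stopifnot(inherits(series, "molli_series"))
  d <- dim(series$frames)
  nr <- d[1]; nc <- d[2]; nf <- d[3]
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  stopifnot(identical(dim(mask), c(nr, nc)))
  ti <- series$inversion_times
  ord <- order(ti)
  t_sorted <- ti[ord]
  empty <- matrix(NA_real_, nr, nc)
  res <- list(A = empty, B = empty, t1star = empty, t1 = empty,
              sd_error = empty, ssr = empty,
              fit_mask = matrix(FALSE, nr, nc),
              polarity_index = matrix(NA_integer_, nr, nc),
              inversion_times = ti)
  frames_mat <- matrix(series$frames, nr * nc, nf)[, ord, drop = FALSE]
  for (idx in which(mask)) {
    s <- frames_mat[idx, ]
    if (series$magnitude) {
      pol <- restore_polarity(s, t_sorted, candidates = polarity_candidates(s))
      fit <- pol$fit
      res$polarity_index[idx] <- pol$index
    } else {
      fit <- fit_ir_three_param(s, t_sorted)
      res$polarity_index[idx] <- 0L
    }
    if (is.null(fit) || !fit$valid) next
    t1 <- look_locker_correct(fit$A, fit$B, fit$t1star)
    if (!is.finite(t1) || t1 <= t1_limits[1] || t1 >= t1_limits[2]) next
    res$A[idx] <- fit$A
    res$B[idx] <- fit$B
    res$t1star[idx] <- fit$t1star
    res$t1[idx] <- t1
    res$ssr[idx] <- fit$ssr
    res$fit_mask[idx] <- TRUE
    if (!is.null(fit$covariance)) {
      g <- c(-fit$B * fit$t1star / fit$A^2,
             fit$t1star / fit$A,
             fit$B / fit$A - 1)
      v <- drop(t(g) %*% fit$covariance %*% g)
      res$sd_error[idx] <- if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
    }
  }
  class(res) <- "t1_fit"
  res
}

#' @export
print.t1_fit <- function(x, ...) {
  cat(sprintf("T1 fit: %d/%d pixels valid; T1 median %.0f ms; SD error median %.2f ms\n",
              sum(x$fit_mask), length(x$fit_mask),
              median(x$t1[x$fit_mask]),
              median(x$sd_error[x$fit_mask], na.rm = TRUE)))
  invisible(x)
}
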