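#' Registration parameters
#'
#' Collects the tunable parameters of the elastic NGF registration. Defaults
#' follow the package's standard configuration; the Lame parameters and the
#' global regularization weight are intensity-scale dependent and exposed for
#' tuning (stiff material: large effective Young's modulus, Poisson ratio 0
#' with the default `lam = 0`).
#'
#' @param mu Lame shear parameter (> 0).
#' @param lam Lame volumetric parameter (>= 0).
#' @param alpha global weight multiplying the elastic potential in the joint
#'   objective `D[u] + alpha * S[u]`.
#' @param epsilon_fraction fraction of the mean edge mass used for the NGF
#'   noise threshold epsilon (see [estimate_epsilon()]).
#' @param n_levels multiresolution pyramid depth (>= 1); reduced with a
#'   warning when the image is too small.
#' @param max_outer_iter per-level cap on outer (Gauss-Newton) iterations.
#' @param update_tolerance convergence threshold on `max |delta u|` in pixels.
#' @param tau Tikhonov damping added to the elastic operator in the linear
#'   solve; handles the translational null space of the Neumann-discretized
#'   operator and acts as step damping.
#' @param cg_tolerance relative residual tolerance of the conjugate-gradient
#'   inner solver.
#' @param cg_max_iter iteration cap of the inner solver.
#' @param step_max trust-region cap on `max |delta u|` per outer iteration
#'   (pixels).
#' @param interpolation `"linear"` or `"nearest"`, used by [warp()].
#' @param spacing pixel spacing `(dx, dy)` in mm.
#' @param min_coarse_dim smallest allowed image dimension at the coarsest
#'   pyramid level.
#' @param verbose print per-iteration diagnostics.
#' @return a list of class `"registration_params"`.
#' @export
registration_params <- function(mu = 1, lam = 0, alpha = 1,
                                epsilon_fraction = 0.1,
                                n_levels = 3, max_outer_iter = 50,
                                update_tolerance = 0.05,
                                tau = 0.05, cg_tolerance = 1e-3,
                                cg_max_iter = 200, step_max = 1,
                                interpolation = c("linear", "nearest"),
                                spacing = c(1, 1), min_coarse_dim = 16,
                                verbose = FALSE) {
  stopifnot(mu > 0, lam >= 0, alpha > 0, epsilon_fraction > 0, n_levels >= 1,
            update_tolerance > 0, tau > 0, cg_tolerance > 0, step_max > 0,
            all(spacing > 0))
  p <- list(mu = mu, lam = lam, alpha = alpha,
            epsilon_fraction = epsilon_fraction,
            n_levels = as.integer(n_levels),
            max_outer_iter = as.integer(max_outer_iter),
            update_tolerance = update_tolerance, tau = tau,
            cg_tolerance = cg_tolerance, cg_max_iter = as.integer(cg_max_iter),
            step_max = step_max,
            interpolation = match.arg(interpolation),
            spacing = spacing, min_coarse_dim = min_coarse_dim,
            verbose = isTRUE(verbose))
  class(p) <- "registration_params"
  p
}

#' Edge-mass estimate of the NGF threshold epsilon
#'
#' The NGF noise threshold is chosen in relation to the total mass of edges
#' in the image: the spatial gradient modulus is integrated over the domain
#' and normalized by the domain measure, then scaled by `epsilon_fraction`.
#' A positive floor (1e-8 times the intensity range, or 1e-8 absolute for a
#' constant image) keeps epsilon strictly positive.
#'
#' Epsilon scales linearly with a global rescaling of the image intensities,
#' as the gradient modulus does.
#'
#' @param image numeric matrix.
#' @param epsilon_fraction positive scalar (default 0.1).
#' @param spacing pixel spacing.
#' @return positive scalar epsilon.
#' @export
estimate_epsilon <- function(image, epsilon_fraction = 0.1, spacing = c(1, 1)) {
  stopifnot(all(is.finite(image)), epsilon_fraction > 0)
  g <- image_gradient(image, spacing)
  edge_mass <- mean(sqrt(g$gx^2 + g$gy^2))   # (1/|Omega|) * integral |grad I|
  floorv <- 1e-8 * diff(range(image))
  eps <- max(epsilon_fraction * edge_mass, floorv)
  if (eps <= 0) eps <- 1e-8
  eps
}

#' Normalized gradient field of an image
#'
#' Computes `n(I, x) = grad I(x) / ||grad I(x)||_eps` with the regularized
#' norm `||v||_eps = sqrt(v1^2 + v2^2 + eps^2)`. Every vector has norm < 1;
#' flat regions (gradient below eps) give vectors near zero.
#'
#' @param image numeric matrix.
#' @param epsilon positive scalar, see [estimate_epsilon()].
#' @param spacing pixel spacing.
#' @return array `c(nrow, ncol, 2)`; `[,,1]` x component, `[,,2]` y component.
#' @export
normalized_gradient <- function(image, epsilon, spacing = c(1, 1)) {
  stopifnot(epsilon > 0)
  g <- image_gradient(image, spacing)
  den <- sqrt(g$gx^2 + g$gy^2 + epsilon^2)
  out <- array(0, dim = c(nrow(image), ncol(image), 2))
  out[, , 1] <- g$gx / den
  out[, , 2] <- g$gy / den
  out
}

# Core NGF evaluation: the polarity-symmetric regularized alignment term
#
#   ip(x) = (|<grad R(x), grad T(x+u)>| + eps_R * eps_T)
#           / (||grad R(x)||_eps_R * ||grad T(x+u)||_eps_T)
#
# with ||v||_eps = sqrt(v1^2 + v2^2 + eps^2). The epsilon product in the
# numerator treats the regularization as a shared latent gradient
# component, which makes ip = 1 exactly for perfectly aligned identical
# structure (and for two flat regions): the similarity is stationary at the
# identity, so registering an image to itself leaves the field at zero. The
# absolute value keeps the measure exactly invariant to intensity polarity
# and scale, the property that lets one reference frame serve the whole
# inversion-recovery series. Cauchy-Schwarz on the epsilon-augmented
# 3-vectors bounds ip in [0, 1].
#
# The template gradient is interpolated with Catmull-Rom (C1) sampling and
# normalized after sampling; `deriv = TRUE` also returns the analytic
# partials of ip needed for the force.
ngf_eval <- function(gR, eps_ref, gT, eps_tmpl, u, deriv = FALSE) {
  nr <- nrow(gR$gx); nc <- ncol(gR$gx)
  g <- coord_grid(nr, nc)
  X <- g$X + u[, , 1]
  Y <- g$Y + u[, , 2]
  nrmR <- sqrt(gR$gx^2 + gR$gy^2 + eps_ref^2)
  sx <- cubic_sample(gT$gx, X, Y, deriv = deriv)
  sy <- cubic_sample(gT$gy, X, Y, deriv = deriv)
  if (!deriv) {
    denT <- sqrt(sx^2 + sy^2 + eps_tmpl^2)
    S <- gR$gx * sx + gR$gy * sy
    return(list(ip = (abs(S) + eps_ref * eps_tmpl) / (nrmR * denT)))
  }
  vx <- sx$value; vy <- sy$value
  denT <- sqrt(vx^2 + vy^2 + eps_tmpl^2)
  S <- gR$gx * vx + gR$gy * vy
  q <- abs(S) + eps_ref * eps_tmpl
  ip <- q / (nrmR * denT)
  sg <- sign(S)
  dip <- function(dvx, dvy) {
    dS <- gR$gx * dvx + gR$gy * dvy
    dden <- (vx * dvx + vy * dvy) / denT
    sg * dS / (nrmR * denT) - q * dden / (nrmR * denT^2)
  }
  list(ip = ip, dip_dX = dip(sx$dX, sy$dX), dip_dY = dip(sx$dY, sy$dY))
}

resolve_epsilon_pair <- function(ref, tmpl, epsilon_pair, epsilon_fraction, spacing) {
  if (is.null(epsilon_pair)) {
    c(estimate_epsilon(ref, epsilon_fraction, spacing),
      estimate_epsilon(tmpl, epsilon_fraction, spacing))
  } else {
    stopifnot(length(epsilon_pair) == 2, all(epsilon_pair > 0))
    epsilon_pair
  }
}

#' Normalized-gradient-field distance between two images
#'
#' The NGF similarity `D = 1/2 * integral( 1 - ip(x)^2 ) dx`, discretized as
#' a pixel sum weighted by the pixel area, where `ip` is the regularized
#' alignment of the two normalized image gradients,
#' `ip = (|<grad R, grad T(x+u)>| + eps_R eps_T) / (||grad R||_eps ||grad
#' T(x+u)||_eps)` with `||v||_eps = sqrt(v1^2 + v2^2 + eps^2)`. Including
#' the epsilon product in the numerator (the epsilon-augmented form of the
#' normalized gradient inner product) makes perfectly aligned structure --
#' and mutually flat regions -- score as perfect agreement (`ip = 1`), so an
#' image registered to itself is already at the global minimum `D = 0`. The
#' absolute value makes D exactly invariant to multiplying either image by
#' any nonzero constant, including intensity inversion: only edge
#' *orientation* matters, not polarity or strength.
#'
#' D lies in `[0, |Omega|/2]`; the upper bound corresponds to everywhere
#' orthogonal strong gradients.
#'
#' @param ref,tmpl reference and template images (same dimensions).
#' @param u displacement field (defaults to zero).
#' @param epsilon_pair optional `(eps_ref, eps_tmpl)`; estimated from the
#'   images when `NULL`.
#' @param epsilon_fraction used when estimating epsilon.
#' @param spacing pixel spacing; the domain measure is
#'   `npixels * dx * dy`.
#' @return scalar distance.
#' @export
ngf_distance <- function(ref, tmpl, u = NULL, epsilon_pair = NULL,
                         epsilon_fraction = 0.1, spacing = c(1, 1)) {
  if (!all(dim(ref) == dim(tmpl))) stop("ref and tmpl must have the same dimensions")
  if (is.null(u)) u <- zero_field(dim(ref))
  check_field(u, dim(ref))
  eps <- resolve_epsilon_pair(ref, tmpl, epsilon_pair, epsilon_fraction, spacing)
  e <- ngf_eval(image_gradient(ref, spacing), eps[1],
                image_gradient(tmpl, spacing), eps[2], u)
  dA <- spacing[1] * spacing[2]
  0.5 * sum(1 - e$ip^2) * dA
}

#' Force vector of the NGF similarity
#'
#' The discrete Gateaux derivative of [ngf_distance()] with respect to the
#' displacement field, computed in closed form (the derivative of the
#' bilinear interpolant of the transported gradient field). Agrees with a
#' finite-difference perturbation of `ngf_distance` at interpolation-smooth
#' displacement values.
#'
#' @inheritParams ngf_distance
#' @return array `c(nrow, ncol, 2)`: the gradient of D with respect to u.
#' @export
similarity_force <- function(ref, tmpl, u, epsilon_pair = NULL,
                             epsilon_fraction = 0.1, spacing = c(1, 1)) {
  if (!all(dim(ref) == dim(tmpl))) stop("ref and tmpl must have the same dimensions")
  check_field(u, dim(ref))
  eps <- resolve_epsilon_pair(ref, tmpl, epsilon_pair, epsilon_fraction, spacing)
  e <- ngf_eval(image_gradient(ref, spacing), eps[1],
                image_gradient(tmpl, spacing), eps[2], u, deriv = TRUE)
  dA <- spacing[1] * spacing[2]
  f <- array(0, dim = dim(u))
  f[, , 1] <- -e$ip * e$dip_dX * dA
  f[, , 2] <- -e$ip * e$dip_dY * dA
  f
}

#' Linear elastic potential of a displacement field
#'
#' `S[u] = integral( mu/4 * sum_kl (d_k u_l + d_l u_k)^2
#'                   + lam/2 * (div u)^2 ) dx`,
#' discretized with the same finite-difference stencils used by the elastic
#' operator and solver (central interior, one-sided borders). S is zero
#' exactly for constant (rigid-translation) fields and positive otherwise
#' when `mu > 0`.
#'
#' @param u displacement field.
#' @param mu,lam Lame parameters.
#' @param spacing pixel spacing.
#' @return scalar `S[u] >= 0`.
#' @export
elastic_potential <- function(u, mu = 1, lam = 0, spacing = c(1, 1)) {
  check_field(u)
  stopifnot(mu > 0, lam >= 0)
  Cx <- diff_matrix(dim(u)[2], spacing[1])
  Cy <- diff_matrix(dim(u)[1], spacing[2])
  ux <- u[, , 1]; uy <- u[, , 2]
  dx_ux <- ux %*% t(Cx); dy_ux <- Cy %*% ux
  dx_uy <- uy %*% t(Cx); dy_uy <- Cy %*% uy
  e11 <- 2 * dx_ux
  e12 <- dy_ux + dx_uy
  e22 <- 2 * dy_uy
  divu <- dx_ux + dy_uy
  dA <- spacing[1] * spacing[2]
  sum(mu / 4 * (e11^2 + 2 * e12^2 + e22^2) + lam / 2 * divu^2) * dA
}

#' Discrete elastic (Navier-Lame) operator
#'
#' Returns a matrix-free symmetric linear operator `L` built from the same
#' stencils as [elastic_potential()], with Neumann-type boundary handling:
#' `L` is the gradient of S, so `<u, L u> = 2 * S[u]` exactly, `L` is
#' symmetric, and constant (translation) fields lie in its null space.
#'
#' @param dims grid dimensions `(nrow, ncol)`.
#' @param spacing pixel spacing.
#' @param mu,lam Lame parameters.
#' @return function taking and returning a displacement-field array.
#' @export
assemble_elastic_operator <- function(dims, spacing = c(1, 1), mu = 1, lam = 0) {
  stopifnot(all(dims >= 2), mu > 0, lam >= 0)
  Cx <- diff_matrix(dims[2], spacing[1])
  Cy <- diff_matrix(dims[1], spacing[2])
  tCx <- t(Cx); tCy <- t(Cy)
  dA <- spacing[1] * spacing[2]
  function(u) {
    ux <- u[, , 1]; uy <- u[, , 2]
    dx_ux <- ux %*% tCx; dy_ux <- Cy %*% ux
    dx_uy <- uy %*% tCx; dy_uy <- Cy %*% uy
    e11 <- 2 * dx_ux
    e12 <- dy_ux + dx_uy
    e22 <- 2 * dy_uy
    divu <- dx_ux + dy_uy
    out <- array(0, dim = dim(u))
    # grad_m S = dA * ( mu * sum_k D_k^T e_{km} + lam * D_m^T div )
    out[, , 1] <- dA * (mu * (e11 %*% Cx + tCy %*% e12) + lam * (divu %*% Cx))
    out[, , 2] <- dA * (mu * (e12 %*% Cx + tCy %*% e22) + lam * (tCy %*% divu))
    out
  }
}

# Conjugate gradients for the SPD system (alpha*L + tau*I) d = rhs,
# matrix-free on displacement-field arrays. Returns the best iterate and a
# convergence flag.
cg_solve <- function(apply_A, rhs, tol = 1e-3, max_iter = 200) {
  d <- array(0, dim = dim(rhs))
  r <- rhs
  p <- r
  rs <- sum(r * r)
  rs0 <- rs
  if (rs0 == 0) return(list(x = d, converged = TRUE, iter = 0L))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Ap <- apply_A(p)
    alpha <- rs / sum(p * Ap)
    if (!is.finite(alpha)) break
    d <- d + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    if (sqrt(rs_new / rs0) < tol) { converged <- TRUE; break }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  list(x = d, converged = converged, iter = it)
}

#' Single-level elastic NGF registration
#'
#' Minimizes the joint objective `D[u] + alpha * S[u]` on one resolution
#' level. Each outer iteration freezes the NGF force at the current field,
#' solves the damped Gauss-Newton system
#' `(alpha*L + tau*I) delta = -(force + alpha*L u)` by conjugate gradients,
#' caps the step at `step_max` pixels and backtracks (halving) until the
#' objective does not increase, so the objective is non-increasing over
#' accepted iterations. Iteration stops when `max |delta u|` falls below
#' `update_tolerance`.
#'
#' @param ref,tmpl images (same dimensions).
#' @param u_init initial displacement field.
#' @param params [registration_params()].
#' @return displacement field with attributes `objective` (per-iteration
#'   values of the joint objective, including the initial one) and
#'   `n_iter`.
#' @export
solve_level <- function(ref, tmpl, u_init = NULL, params = registration_params()) {
  if (!all(dim(ref) == dim(tmpl))) stop("ref and tmpl must have the same dimensions")
  if (is.null(u_init)) u_init <- zero_field(dim(ref))
  check_field(u_init, dim(ref))
  sp <- params$spacing
  eps <- resolve_epsilon_pair(ref, tmpl, NULL, params$epsilon_fraction, sp)
  gR <- image_gradient(ref, sp)
  gT <- image_gradient(tmpl, sp)
  dA <- sp[1] * sp[2]
  L <- assemble_elastic_operator(dim(ref), sp, params$mu, params$lam)
  apply_A <- function(v) params$alpha * L(v) + params$tau * v

  objective <- function(u) {
    e <- ngf_eval(gR, eps[1], gT, eps[2], u)
    0.5 * sum(1 - e$ip^2) * dA +
      params$alpha * elastic_potential(u, params$mu, params$lam, sp)
  }
  force <- function(u) {
    e <- ngf_eval(gR, eps[1], gT, eps[2], u, deriv = TRUE)
    f <- array(0, dim = dim(u))
    f[, , 1] <- -e$ip * e$dip_dX * dA
    f[, , 2] <- -e$ip * e$dip_dY * dA
    f
  }

  u <- u_init
  obj <- objective(u)
  obj_trace <- obj
  cg_warned <- FALSE
  n_done <- 0L
  for (it in seq_len(params$max_outer_iter)) {
    g <- force(u) + params$alpha * L(u)
    sol <- cg_solve(apply_A, -g, tol = params$cg_tolerance,
                    max_iter = params$cg_max_iter)
    if (!sol$converged && !cg_warned) {
      warning("conjugate-gradient inner solve did not reach tolerance; ",
              "using best iterate")
      cg_warned <- TRUE
    }
    d <- sol$x
    dmax <- max(abs(d))
    if (!is.finite(dmax) || dmax == 0) break
    scale <- min(1, params$step_max / dmax)
    step <- scale
    accepted <- FALSE
    for (bt in 1:12) {
      u_new <- u + step * d
      obj_new <- objective(u_new)
      if (obj_new <= obj) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    delta_max <- step * dmax
    u <- u_new
    obj <- obj_new
    obj_trace <- c(obj_trace, obj)
    n_done <- it
    if (params$verbose)
      message(sprintf("  iter %2d: obj=%.6g  max|du|=%.4f", it, obj, delta_max))
    if (delta_max < params$update_tolerance) break
    n_obj <- length(obj_trace)
    rel_dec <- (obj_trace[n_obj - 1] - obj) / max(abs(obj_trace[n_obj - 1]), 1e-12)
    if (rel_dec < 1e-7) break   # flat objective: stationary for practical purposes
  }
  attr(u, "objective") <- obj_trace
  attr(u, "n_iter") <- n_done
  u
}

#' Multiresolution image pyramid
#'
#' Gaussian smoothing (sigma = 1 px) followed by factor-2 decimation,
#' repeated `n_levels - 1` times. Returned coarsest first; the finest level
#' is the source image itself.
#'
#' @param img numeric matrix.
#' @param n_levels pyramid depth.
#' @return list of matrices, coarsest to finest.
#' @export
image_pyramid <- function(img, n_levels) {
  levels <- list(img)
  for (l in seq_len(n_levels - 1)) {
    prev <- levels[[1]]
    sm <- gaussian_smooth(prev, 1)
    levels <- c(list(sm[seq(1, nrow(sm), by = 2), seq(1, ncol(sm), by = 2)]),
                levels)
  }
  levels
}

# Up-sample a displacement field to a finer grid: bilinear resampling of each
# component at the coarse coordinates of the fine pixels, and doubling of the
# displacement values (a k-pixel coarse shift is a 2k-pixel fine shift).
upsample_field <- function(u, fine_dims) {
  g <- coord_grid(fine_dims[1], fine_dims[2])
  Xc <- (g$X + 1) / 2      # fine index i maps to coarse position (i+1)/2
  Yc <- (g$Y + 1) / 2
  out <- array(0, dim = c(fine_dims[1], fine_dims[2], 2))
  out[, , 1] <- 2 * bilinear_sample(u[, , 1], Xc, Yc)
  out[, , 2] <- 2 * bilinear_sample(u[, , 2], Xc, Yc)
  out
}

#' Multiresolution elastic NGF registration
#'
#' Registers the template to the reference coarse-to-fine: pyramids are built
#' for both images, [solve_level()] runs at the coarsest level from a zero
#' field, and the converged field is up-sampled (displacements doubled) to
#' initialize the next finer level. The pyramid depth is reduced with a
#' warning when the coarsest level would fall below `min_coarse_dim` pixels.
#'
#' @param ref,tmpl images (same dimensions).
#' @param params [registration_params()].
#' @return displacement field on the finest grid, with attribute
#'   `objective_by_level` (list of per-level objective traces).
#' @export
register <- function(ref, tmpl, params = registration_params()) {
  if (!all(dim(ref) == dim(tmpl))) stop("ref and tmpl must have the same dimensions")
  max_levels <- max(1L, floor(log2(min(dim(ref)) / params$min_coarse_dim)) + 1L)
  n_levels <- params$n_levels
  if (n_levels > max_levels) {
    warning(sprintf("pyramid depth reduced from %d to %d for a %dx%d image",
                    n_levels, max_levels, nrow(ref), ncol(ref)))
    n_levels <- max_levels
  }
  pyr_ref <- image_pyramid(ref, n_levels)
  pyr_tmpl <- image_pyramid(tmpl, n_levels)
  u <- NULL
  traces <- vector("list", n_levels)
  for (l in seq_len(n_levels)) {
    r <- pyr_ref[[l]]; t <- pyr_tmpl[[l]]
    # all levels solved in pixel units: the force/regularizer balance is then
    # resolution-independent, and displacements up-sample by a factor of 2
    level_params <- params
    if (is.null(u)) u <- zero_field(dim(r))
    else u <- upsample_field(u, dim(r))
    u <- solve_level(r, t, u, level_params)
    traces[[l]] <- attr(u, "objective")
  }
  attr(u, "objective") <- NULL
  attr(u, "n_iter") <- NULL
  attr(u, "objective_by_level") <- traces
  u
}

#' Warp an image by a displacement field
#'
#' Samples `T(x + u(x))` (pull-back) with the configured interpolation and
#' nearest-edge boundary extension.
#'
#' @param image numeric matrix.
#' @param u displacement field of matching dimensions.
#' @param interpolation `"linear"` (bilinear) or `"nearest"`.
#' @return warped image, same dimensions.
#' @export
warp <- function(image, u, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  check_field(u, dim(image))
  g <- coord_grid(nrow(image), ncol(image))
  X <- g$X + u[, , 1]
  Y <- g$Y + u[, , 2]
  if (interpolation == "linear") bilinear_sample(image, X, Y)
  else nearest_sample(image, X, Y)
}
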