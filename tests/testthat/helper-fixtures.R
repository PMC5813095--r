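# Shared fixture builders and independent oracles for the test suite.
# Oracles are deliberately written as naive per-pixel loops, independent of
# the vectorized implementations they check.

blur_fit <- function(m, sigma) {
  # Gaussian blur with a kernel radius that fits small test images
  radius <- min(2 * ceiling(3 * sigma) + 1,
                2 * floor((min(dim(m)) - 1) / 2) + 1)
  EBImage::gblur(m, sigma = sigma, radius = radius, boundary = "replicate")
}

smooth_random_image <- function(nr, nc, sigma = 1, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc), nr, nc)
  if (sigma > 0) m <- blur_fit(m, sigma)
  m
}

smooth_random_field <- function(nr, nc, amp = 0.5, seed = 1) {
  set.seed(seed)
  u <- array(0, dim = c(nr, nc, 2))
  for (k in 1:2)
    u[, , k] <- amp * blur_fit(matrix(rnorm(nr * nc), nr, nc), 2)
  u
}

constant_field <- function(dims, cx, cy) {
  u <- array(0, dim = c(dims[1], dims[2], 2))
  u[, , 1] <- cx
  u[, , 2] <- cy
  u
}

# one-sided/central stencil derivative of a 1-D sequence, loop version
oracle_deriv_1d <- function(v, h = 1) {
  n <- length(v)
  out <- numeric(n)
  out[1] <- (v[2] - v[1]) / h
  out[n] <- (v[n] - v[n - 1]) / h
  if (n > 2) for (j in 2:(n - 1)) out[j] <- (v[j + 1] - v[j - 1]) / (2 * h)
  out
}

# per-pixel |grad| sum oracle for the epsilon edge-mass rule
oracle_gradient <- function(img, spacing = c(1, 1)) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  for (r in seq_len(nr)) gx[r, ] <- oracle_deriv_1d(img[r, ], spacing[1])
  for (cc in seq_len(nc)) gy[, cc] <- oracle_deriv_1d(img[, cc], spacing[2])
  list(gx = gx, gy = gy)
}

# loop-based NGF distance at u = 0 (grid-aligned, no interpolation
# involved): per-pixel evaluation of the polarity-symmetric
# epsilon-augmented alignment via explicit 3-vectors
oracle_ngf_distance_u0 <- function(ref, tmpl, eps_ref, eps_tmpl, spacing = c(1, 1)) {
  gR <- oracle_gradient(ref, spacing)
  gT <- oracle_gradient(tmpl, spacing)
  acc <- 0
  for (r in seq_len(nrow(ref))) for (cc in seq_len(ncol(ref))) {
    vR <- c(gR$gx[r, cc], gR$gy[r, cc], eps_ref)
    vT <- c(gT$gx[r, cc], gT$gy[r, cc], eps_tmpl)
    ip <- (abs(sum(vR[1:2] * vT[1:2])) + vR[3] * vT[3]) /
      (sqrt(sum(vR^2)) * sqrt(sum(vT^2)))
    acc <- acc + 1 - ip^2
  }
  0.5 * acc * spacing[1] * spacing[2]
}

# loop-based elastic potential (direct summation of the strain-energy terms)
oracle_elastic_potential <- function(u, mu, lam, spacing = c(1, 1)) {
  g1 <- oracle_gradient(u[, , 1], spacing)   # d(ux)/dx, d(ux)/dy
  g2 <- oracle_gradient(u[, , 2], spacing)
  acc <- 0
  for (r in seq_len(dim(u)[1])) for (cc in seq_len(dim(u)[2])) {
    d <- matrix(c(g1$gx[r, cc], g1$gy[r, cc],
                  g2$gx[r, cc], g2$gy[r, cc]), 2, 2, byrow = TRUE)
    # d[l, k] = d_{x_k} u_l
    s <- 0
    for (k in 1:2) for (l in 1:2) s <- s + (d[l, k] + d[k, l])^2
    acc <- acc + mu / 4 * s + lam / 2 * (d[1, 1] + d[2, 2])^2
  }
  acc * spacing[1] * spacing[2]
}

# naive loop-based bilinear interpolation with edge clamping
oracle_bilinear_warp <- function(img, u) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    x <- min(max(cc + u[r, cc, 1], 1), nc)
    y <- min(max(r + u[r, cc, 2], 1), nr)
    x0 <- min(floor(x), nc - 1); y0 <- min(floor(y), nr - 1)
    tx <- x - x0; ty <- y - y0
    out[r, cc] <- (1 - ty) * ((1 - tx) * img[y0, x0] + tx * img[y0, x0 + 1]) +
      ty * ((1 - tx) * img[y0 + 1, x0] + tx * img[y0 + 1, x0 + 1])
  }
  out
}

# central finite-difference gradient of ngf_distance with respect to u
fd_similarity_gradient <- function(ref, tmpl, u, eps, h = 1e-6) {
  out <- array(0, dim = dim(u))
  for (k in seq_along(u)) {
    up <- u; up[k] <- up[k] + h
    um <- u; um[k] <- um[k] - h
    out[k] <- (ngf_distance(ref, tmpl, up, eps) -
               ngf_distance(ref, tmpl, um, eps)) / (2 * h)
  }
  out
}

# small motion-free noiseless study fixture reused across pipeline tests
small_phantom_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ph <- make_cardiac_phantom(cardiac_phantom_spec(n = 48, seed = 7))
    tn <- simulate_scheme_timing(scheme_spec("5s(3s)3s", heart_rate = 60))
    tp <- simulate_scheme_timing(scheme_spec("4s(1s)3s(1s)2s", heart_rate = 60))
    simN <- simulate_molli_series(ph, tn, "native", translation_sd = 0, seed = 1)
    simP <- simulate_molli_series(ph, tp, "post", translation_sd = 0, seed = 2)
    cache <<- list(phantom = ph, native = simN, post = simP)
    cache
  }
})
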