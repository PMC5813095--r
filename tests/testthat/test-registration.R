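test_that("epsilon follows the edge-mass rule and its floor", {
  # constant image: zero edge mass, positive floor
  eps0 <- estimate_epsilon(matrix(5, 8, 8))
  expect_gt(eps0, 0)
  expect_lt(eps0, 1e-6)

  img <- smooth_random_image(10, 12, seed = 3)
  expect_equal(estimate_epsilon(2 * img), 2 * estimate_epsilon(img),
               tolerance = 1e-12)

  # unit step edge: epsilon = fraction * mean gradient modulus, against a
  # per-pixel summation oracle
  step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  g <- oracle_gradient(step)
  expect_equal(estimate_epsilon(step, 0.1),
               0.1 * mean(sqrt(g$gx^2 + g$gy^2)), tolerance = 1e-12)
})

test_that("normalized gradients are bounded and correctly scaled", {
  expect_true(all(normalized_gradient(matrix(3, 6, 6), 0.5) == 0))

  # ramp I = x: gradient (1, 0) everywhere with these stencils
  ramp <- matrix(rep(1:9, each = 7), 7, 9)
  n_small_eps <- normalized_gradient(ramp, 1e-9)
  expect_equal(max(abs(n_small_eps[, , 1] - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(n_small_eps[, , 2])), 0)

  # epsilon equal to the gradient magnitude: norm 1/sqrt(2)
  n_eq <- normalized_gradient(ramp, 1)
  expect_equal(n_eq[, , 1], matrix(1 / sqrt(2), 7, 9), tolerance = 1e-12)

  # strict norm bound on random images
  for (s in 1:3) {
    nf <- normalized_gradient(smooth_random_image(9, 9, seed = s), 0.3)
    expect_true(all(sqrt(nf[, , 1]^2 + nf[, , 2]^2) < 1))
  }
})

test_that("NGF distance matches the direct summation oracle and its bounds", {
  ref <- smooth_random_image(9, 11, seed = 4)
  tmpl <- smooth_random_image(9, 11, seed = 5)
  eps <- c(estimate_epsilon(ref), estimate_epsilon(tmpl))
  expect_equal(ngf_distance(ref, tmpl, epsilon_pair = eps),
               oracle_ngf_distance_u0(ref, tmpl, eps[1], eps[2]),
               tolerance = 1e-10)

  # two constant images: both gradients vanish and the epsilon slots agree
  # perfectly, so flat-vs-flat is perfect agreement (D = 0); this is what
  # makes the identity a global minimum of the functional
  expect_equal(ngf_distance(matrix(2, 6, 8), matrix(7, 6, 8)), 0)
  # an image registered against itself is already optimal
  expect_equal(ngf_distance(ref, ref), 0, tolerance = 1e-12)

  # bounds under random fields
  for (s in 1:4) {
    u <- smooth_random_field(9, 11, amp = 1, seed = s)
    D <- ngf_distance(ref, tmpl, u, eps)
    expect_gte(D, 0)
    expect_lte(D, 9 * 11 / 2)
  }
})

test_that("NGF distance ignores intensity polarity and scale", {
  ref <- smooth_random_image(10, 10, seed = 6)
  tmpl <- smooth_random_image(10, 10, seed = 7)
  eps <- c(0.2, 0.2)
  D <- ngf_distance(ref, tmpl, epsilon_pair = eps)
  # inversion / rescaling of either image: epsilon must co-scale with the
  # image (the estimator does this automatically)
  expect_equal(ngf_distance(ref, -tmpl, epsilon_pair = eps), D, tolerance = 1e-12)
  expect_equal(ngf_distance(-3 * ref, tmpl, epsilon_pair = c(3 * 0.2, 0.2)), D,
               tolerance = 1e-12)
  expect_equal(ngf_distance(ref, 5 * tmpl, epsilon_pair = c(0.2, 5 * 0.2)), D,
               tolerance = 1e-12)

  # aligned sharp image scores strictly better than a shifted copy
  disc <- make_two_circle_pair(48, radii_reference = c(8, 8),
                               radii_target = c(8, 8))$ref
  shifted <- warp(disc, constant_field(c(48, 48), -2, 0))
  epsd <- rep(estimate_epsilon(disc), 2)
  expect_lt(ngf_distance(disc, disc, epsilon_pair = epsd),
            ngf_distance(disc, shifted, epsilon_pair = epsd))

  expect_error(ngf_distance(matrix(0, 4, 4), matrix(0, 5, 5)), "dimensions")
})

test_that("elastic potential matches direct strain-energy summation", {
  dims <- c(6, 7)
  expect_equal(elastic_potential(zero_field(dims)), 0)
  expect_equal(elastic_potential(constant_field(dims, 3.2, -1.7)), 0)

  # linear shear u = (a*x, 0): S = (mu + lam/2) * a^2 * |Omega| with these
  # stencils (exact derivative of a linear field everywhere)
  a <- 0.3
  g <- mollimap:::coord_grid(dims[1], dims[2])
  u_lin <- zero_field(dims)
  u_lin[, , 1] <- a * g$X
  expect_equal(elastic_potential(u_lin, mu = 1.3, lam = 0.8),
               (1.3 + 0.8 / 2) * a^2 * prod(dims), tolerance = 1e-12)

  for (s in 1:3) {
    u <- smooth_random_field(6, 7, amp = 1, seed = s)
    expect_equal(elastic_potential(u, mu = 1.1, lam = 0.4),
                 oracle_elastic_potential(u, 1.1, 0.4), tolerance = 1e-10)
    expect_gt(elastic_potential(u, mu = 1.1, lam = 0), 0)
  }
})

test_that("elastic operator reproduces the potential's bilinear form", {
  dims <- c(6, 6)
  L <- assemble_elastic_operator(dims, mu = 0.9, lam = 0.5)
  expect_equal(max(abs(L(constant_field(dims, 4, -2)))), 0)
  for (s in 1:3) {
    v <- smooth_random_field(6, 6, amp = 1, seed = 10 + s)
    w <- smooth_random_field(6, 6, amp = 1, seed = 20 + s)
    expect_equal(sum(v * L(w)), sum(w * L(v)), tolerance = 1e-10)
    expect_equal(sum(v * L(v)), 2 * elastic_potential(v, 0.9, 0.5),
                 tolerance = 1e-10)
  }
})

test_that("similarity force is the gradient of the NGF distance", {
  ref <- smooth_random_image(8, 8, seed = 8)
  tmpl <- smooth_random_image(8, 8, seed = 9)
  eps <- c(estimate_epsilon(ref), estimate_epsilon(tmpl))

  # generic (interpolation-smooth) displacement: all components match
  u <- smooth_random_field(8, 8, amp = 0.4, seed = 2)
  f <- similarity_force(ref, tmpl, u, eps)
  fd <- fd_similarity_gradient(ref, tmpl, u, eps)
  expect_lt(max(abs(f - fd) / pmax(abs(fd), 1e-6)), 1e-4)

  # at u = 0 the interior matches too (the boundary clamp kinks the
  # functional only at the domain border)
  u0 <- zero_field(c(8, 8))
  f0 <- similarity_force(ref, tmpl, u0, eps)
  fd0 <- fd_similarity_gradient(ref, tmpl, u0, eps)
  interior <- array(FALSE, dim = c(8, 8, 2))
  interior[2:7, 2:7, ] <- TRUE
  expect_lt(max(abs(f0 - fd0)[interior] / pmax(abs(fd0), 1e-6)[interior]), 1e-4)
})

test_that("force is a descent direction toward a known misalignment", {
  disc <- make_two_circle_pair(48, radii_reference = c(8, 8),
                               radii_target = c(8, 8))$ref
  u_true <- constant_field(c(48, 48), 2, -1.5)
  tmpl <- warp(disc, -u_true)       # features displaced by +u_true
  eps <- c(estimate_epsilon(disc), estimate_epsilon(tmpl))
  f <- similarity_force(disc, tmpl, zero_field(c(48, 48)), eps)
  # moving toward the truth must decrease D: <grad D, u_true> < 0
  expect_lt(sum(f * u_true), 0)

  # perfectly aligned pair: the identity is a stationary point of the
  # functional, so the force vanishes
  f_aligned <- similarity_force(disc, disc, zero_field(c(48, 48)),
                                rep(estimate_epsilon(disc), 2))
  expect_lt(max(abs(f_aligned)), 1e-10)
})

test_that("warp reproduces exact shifts and the bilinear oracle", {
  img <- smooth_random_image(16, 16, seed = 11)
  expect_identical(warp(img, zero_field(c(16, 16))), img)

  # integer translation: exact pixel shift with edge replication
  u_int <- constant_field(c(16, 16), 3, 0)
  w <- warp(img, u_int)
  expect_equal(w[, 1:13], img[, 4:16], tolerance = 1e-14)
  expect_equal(w[, 14:16], img[, c(16, 16, 16)], tolerance = 1e-14)
  expect_equal(warp(img, u_int, "nearest")[, 1:13], img[, 4:16])

  u <- smooth_random_field(16, 16, amp = 2, seed = 12)
  expect_equal(warp(img, u), oracle_bilinear_warp(img, u), tolerance = 1e-10)
})

test_that("single-level solve is monotone and recovers a small shift", {
  img <- make_cardiac_phantom(cardiac_phantom_spec(n = 48, seed = 3))$A
  p <- registration_params()

  # already aligned: converges immediately to a negligible field
  u_id <- solve_level(img, img, params = p)
  expect_lt(max(abs(u_id)), p$update_tolerance)
  expect_true(all(diff(attr(u_id, "objective")) <= 1e-9))

  # smooth blob: wide gradient support keeps a 3 px shift inside the
  # single-level capture range
  g <- mollimap:::coord_grid(48, 48)
  blob_img <- exp(-((g$X - 24)^2 + (g$Y - 24)^2) / (2 * 8^2))
  tmpl <- warp(blob_img, constant_field(c(48, 48), -3, 0))
  u <- solve_level(blob_img, tmpl,
                   params = registration_params(max_outer_iter = 100))
  expect_true(all(diff(attr(u, "objective")) <= 1e-9))
  blob <- blob_img > 0.1
  err <- sqrt((u[, , 1] - 3)^2 + u[, , 2]^2)
  expect_lt(mean(err[blob]), 1)
})

test_that("pyramid structure and displacement up-sampling are consistent", {
  img <- smooth_random_image(40, 52, seed = 13)
  pyr <- image_pyramid(img, 3)
  expect_identical(pyr[[3]], img)
  sizes <- vapply(pyr, function(m) prod(dim(m)), numeric(1))
  expect_true(all(diff(sizes) > 0))

  # a k-pixel coarse shift becomes a 2k-pixel fine shift
  up <- mollimap:::upsample_field(constant_field(c(10, 13), 1.5, -2), c(20, 26))
  expect_equal(unique(as.numeric(up[, , 1])), 3)
  expect_equal(unique(as.numeric(up[, , 2])), -4)
})

test_that("multiresolution registration handles identity and small images", {
  img <- make_cardiac_phantom(cardiac_phantom_spec(n = 64, seed = 5))$A
  u <- register(img, img)
  expect_lt(max(abs(u)), 0.1)

  expect_warning(register(img[1:20, 1:20], img[1:20, 1:20],
                          registration_params(n_levels = 3)),
                 "depth reduced")
  expect_error(register(img, img[1:32, 1:32]), "dimensions")
})

test_that("two-circle growth and shrinkage are recovered with compliant elasticity", {
  # strong local deformation: a more compliant regularization than the
  # stiff pipeline default lets the recovered field express the full
  # compression/expansion
  p <- registration_params(alpha = 0.15, update_tolerance = 0.01,
                           tau = 0.02, step_max = 2, max_outer_iter = 100)
  tc <- make_two_circle_pair(96)
  u <- register(tc$ref, tc$target, p)

  # warped template disc areas (intensity integrals) within 10% of the
  # reference areas
  w <- warp(tc$target, u)
  g <- mollimap:::coord_grid(96, 96)
  near1 <- sqrt((g$X - 0.3 * 96)^2 + (g$Y - 0.5 * 96)^2) < 22
  near2 <- sqrt((g$X - 0.7 * 96)^2 + (g$Y - 0.5 * 96)^2) < 22
  expect_lt(abs(sum(w[near1]) / sum(tc$ref[near1]) - 1), 0.10)
  expect_lt(abs(sum(w[near2]) / sum(tc$ref[near2]) - 1), 0.10)

  # mean LVC over each disc matches the analytic area ratio (r_t/r_r)^2 - 1
  # in sign and within a factor of two in magnitude
  lvc <- lvc_map(u)
  grown <- mean(lvc[tc$sign_mask > 0])
  shrunk <- mean(lvc[tc$sign_mask < 0])
  expect_gt(grown, ((15 / 12)^2 - 1) / 2)
  expect_lt(grown, ((15 / 12)^2 - 1) * 2)
  expect_lt(shrunk, ((9 / 12)^2 - 1) / 2)
  expect_gt(shrunk, ((9 / 12)^2 - 1) * 2)
})
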