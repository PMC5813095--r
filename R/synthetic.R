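#' MOLLI scheme specification
#'
#' A second-based MOLLI acquisition scheme: minimum durations of the
#' Look-Locker (LL) readout periods and of the recovery intervals between
#' them, plus the heart rate at which the scheme is executed. The common
#' shorthand (e.g. `"5s(3s)3s"` or `"4s(1s)3s(1s)2s"`, LL durations outside
#' parentheses, recovery minimums inside) is parsed directly.
#'
#' @param scheme scheme string, or `NULL` when durations are given directly.
#' @param ll_durations LL period minimum durations in s.
#' @param recovery_min recovery interval minimum durations in s (one fewer
#'   than LL periods).
#' @param heart_rate heart rate in bpm, in (20, 250).
#' @param ti_min minimal inversion-time delay in ms.
#' @param ti_stagger per-LL-period stagger added to the initial TI in ms
#'   (diversifies relaxation-curve sampling across periods).
#' @return list of class `"scheme_spec"`.
#' @export
scheme_spec <- function(scheme = NULL, ll_durations = NULL, recovery_min = NULL,
                        heart_rate = 60, ti_min = 87.7, ti_stagger = 100) {
  if (!is.null(scheme)) {
    parsed <- parse_scheme(scheme)
    ll_durations <- parsed$ll
    recovery_min <- parsed$recovery
  } else {
    scheme <- paste0(ll_durations[1], "s",
                     paste0(vapply(seq_along(recovery_min), function(i)
                       sprintf("(%gs)%gs", recovery_min[i], ll_durations[i + 1]),
                       character(1)), collapse = ""))
  }
  stopifnot(length(ll_durations) >= 1, all(ll_durations > 0),
            length(recovery_min) == length(ll_durations) - 1,
            all(recovery_min > 0) || length(recovery_min) == 0,
            heart_rate > 20, heart_rate < 250, ti_min > 0)
  structure(list(scheme = scheme, ll_durations = ll_durations,
                 recovery_min = recovery_min, heart_rate = heart_rate,
                 ti_min = ti_min, ti_stagger = ti_stagger),
            class = "scheme_spec")
}

parse_scheme <- function(scheme) {
  toks <- regmatches(scheme, gregexpr("\\(?[0-9.]+s\\)?", scheme))[[1]]
  if (!length(toks)) stop("cannot parse scheme string: ", scheme)
  is_rec <- grepl("^\\(", toks)
  # tokens must strictly alternate LL period, (recovery), LL period, ...
  if (is_rec[1] || is_rec[length(toks)] || any(diff(is_rec) == 0))
    stop("scheme must alternate LL periods and recovery intervals: ", scheme)
  vals <- as.numeric(sub("s", "", gsub("[()]", "", toks), fixed = TRUE))
  list(ll = vals[!is_rec], recovery = vals[is_rec])
}

#' Second-based MOLLI scheme timing
#'
#' Beat-counting rules for a second-defined MOLLI scheme at a given heart
#' rate: the number of single-shot acquisitions in each LL period is the
#' minimum duration divided by the R-R interval, rounded up to the next
#' integer; each recovery interval takes the fewest whole beats whose
#' duration covers the stated minimum; the breath-hold is the total beat
#' count times the R-R interval. Inversion times start at the minimal TI
#' delay (staggered per LL period) and advance by one R-R per acquired
#' image.
#'
#' @param spec a [scheme_spec()] (or a scheme string, converted with the
#'   default parameters).
#' @param heart_rate optional override of the spec's heart rate, bpm.
#' @return list with `images_per_period`, `recovery_beats`, `total_beats`,
#'   `scan_seconds`, `rr_seconds`, `inversion_times` (ms, acquisition
#'   order) and `period_index` per image.
#' @export
simulate_scheme_timing <- function(spec, heart_rate = NULL) {
  if (is.character(spec)) spec <- scheme_spec(spec)
  stopifnot(inherits(spec, "scheme_spec"))
  hr <- if (is.null(heart_rate)) spec$heart_rate else heart_rate
  stopifnot(hr > 20, hr < 250)
  rr <- 60 / hr
  eps <- 1e-9   # guard ceil() against floating division of exact multiples
  images <- as.integer(ceiling(spec$ll_durations / rr - eps))
  recovery <- if (length(spec$recovery_min))
    as.integer(ceiling(spec$recovery_min / rr - eps)) else integer(0)
  total_beats <- sum(images) + sum(recovery)
  ti <- numeric(0); block <- integer(0)
  for (b in seq_along(images)) {
    ti_b <- spec$ti_min + (b - 1) * spec$ti_stagger +
      (seq_len(images[b]) - 1) * rr * 1000
    ti <- c(ti, ti_b)
    block <- c(block, rep(b, images[b]))
  }
  list(images_per_period = images, recovery_beats = recovery,
       total_beats = total_beats, scan_seconds = total_beats * rr,
       rr_seconds = rr, inversion_times = ti, period_index = block,
       scheme = spec$scheme, heart_rate = hr)
}

#' Cardiac short-axis phantom specification
#'
#' A concentric-geometry left-ventricular phantom: circular blood pool
#' (cavity) inside a myocardial annulus on a tissue background, with an
#' optional focal lesion in the annulus. Native T1 values default to typical
#' 3T myocardium/blood; post-contrast myocardial T1 is derived from a target
#' ECV by inverting the ECV relation, so that the noiseless pipeline
#' round-trips the target exactly.
#'
#' @param n grid size in pixels (square grid).
#' @param r_epi,r_endo epicardial / endocardial radii in pixels.
#' @param t1_native named native T1 (ms) for `background`, `myocardium`,
#'   `blood` (blood must lie in the 1600-2200 ms pre-contrast range).
#' @param blood_t1_post post-contrast blood T1 (ms).
#' @param target_ecv target myocardial ECV in percent.
#' @param hematocrit hematocrit fraction in (0, 1).
#' @param A named equilibrium signal amplitudes per tissue class.
#' @param lesion `NULL`, or `list(center = c(x, y), radius, t1_native,
#'   ecv)` for a focal lesion inside the annulus.
#' @param edge_width smooth transition width of the tissue interfaces in
#'   pixels (partial-volume-like edges; 0 gives crisp discs).
#' @param texture_sd relative amplitude of a smooth multiplicative signal
#'   texture on A (0 disables).
#' @param texture_scale correlation length of the texture in pixels.
#' @param seed RNG seed for the texture.
#' @return list of class `"phantom_spec"`.
#' @export
cardiac_phantom_spec <- function(n = 128, r_epi = 0.30 * n, r_endo = 0.19 * n,
                                 t1_native = c(background = 450,
                                               myocardium = 1280,
                                               blood = 1900),
                                 blood_t1_post = 400,
                                 target_ecv = 26.3, hematocrit = 0.42,
                                 A = c(background = 400, myocardium = 1000,
                                       blood = 1300),
                                 lesion = NULL, edge_width = 1.5,
                                 texture_sd = 0.15, texture_scale = 3,
                                 seed = 1L) {
  stopifnot(n >= 32, r_epi > r_endo, r_endo > 2, r_epi < n / 2,
            all(t1_native > 0), blood_t1_post > 0,
            hematocrit > 0, hematocrit < 1,
            target_ecv > 0, target_ecv < 100)
  if (t1_native[["blood"]] < 1600 || t1_native[["blood"]] > 2200)
    stop("native blood T1 must lie in the 1600-2200 ms pre-contrast range")
  structure(list(n = as.integer(n), r_epi = r_epi, r_endo = r_endo,
                 t1_native = t1_native, blood_t1_post = blood_t1_post,
                 target_ecv = target_ecv, hematocrit = hematocrit,
                 A = A, lesion = lesion, edge_width = edge_width,
                 texture_sd = texture_sd, texture_scale = texture_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth radial indicator: 1 inside radius R, 0 outside, linear ramp of
# width w across the interface
disc_profile <- function(rad, R, w) {
  if (w <= 0) return(as.numeric(rad <= R))
  pmin(pmax((R + w / 2 - rad) / w, 0), 1)
}

# invert ECV = dR1_myo / dR1_blood * (1 - hct) for the post-contrast T1 of a
# tissue with given native T1 and target ECV
post_t1_from_ecv <- function(t1_native, ecv_percent, hct, blood_pre, blood_post) {
  dr1_blood <- 1 / blood_post - 1 / blood_pre
  dr1 <- (ecv_percent / 100) / (1 - hct) * dr1_blood
  1 / (1 / t1_native + dr1)
}

#' Build the cardiac phantom
#'
#' Renders the phantom geometry of a [cardiac_phantom_spec()] into a label
#' image, native and post-contrast ground-truth T1 maps, an equilibrium
#' signal map, and circular epicardial/endocardial contours.
#'
#' @param spec a [cardiac_phantom_spec()].
#' @return list of class `"cardiac_phantom"` with `labels` (0 background,
#'   1 myocardium, 2 blood, 3 lesion), `t1_native`, `t1_post`, `A`,
#'   `contours` (a [contour_set()]), `spec`.
#' @export
make_cardiac_phantom <- function(spec = cardiac_phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n
  g <- coord_grid(n, n)
  cx <- (n + 1) / 2
  rad <- sqrt((g$X - cx)^2 + (g$Y - cx)^2)
  s_epi <- disc_profile(rad, spec$r_epi, spec$edge_width)
  s_endo <- disc_profile(rad, spec$r_endo, spec$edge_width)
  labels <- matrix(0L, n, n)
  labels[rad <= spec$r_epi] <- 1L
  labels[rad <= spec$r_endo] <- 2L
  if (sum(labels == 1L) == 0) stop("phantom geometry leaves an empty annulus")

  tn <- spec$t1_native
  tp <- c(background = post_t1_from_ecv(tn[["background"]], 15, spec$hematocrit,
                                        tn[["blood"]], spec$blood_t1_post),
          myocardium = post_t1_from_ecv(tn[["myocardium"]], spec$target_ecv,
                                        spec$hematocrit, tn[["blood"]],
                                        spec$blood_t1_post),
          blood = spec$blood_t1_post)
  compose <- function(vals) {
    vals[["background"]] * (1 - s_epi) +
      vals[["myocardium"]] * (s_epi - s_endo) +
      vals[["blood"]] * s_endo
  }
  t1_native <- compose(as.list(tn))
  t1_post <- compose(as.list(tp))
  Amap <- compose(as.list(spec$A))

  if (!is.null(spec$lesion)) {
    les <- spec$lesion
    lrad <- sqrt((g$X - les$center[1])^2 + (g$Y - les$center[2])^2)
    s_les <- disc_profile(lrad, les$radius, spec$edge_width) * (s_epi - s_endo)
    labels[lrad <= les$radius & labels == 1L] <- 3L
    t1_les_post <- post_t1_from_ecv(les$t1_native, les$ecv, spec$hematocrit,
                                    tn[["blood"]], spec$blood_t1_post)
    t1_native <- t1_native + (les$t1_native - tn[["myocardium"]]) * s_les
    t1_post <- t1_post + (t1_les_post - tp[["myocardium"]]) * s_les
  }

  if (spec$texture_sd > 0) {
    set.seed(spec$seed)
    tex <- gaussian_smooth(matrix(rnorm(n * n), n, n), spec$texture_scale)
    tex <- tex / stats::sd(tex)
    Amap <- Amap * (1 + spec$texture_sd * tex)
  }

  theta <- seq(0, 2 * pi, length.out = 73)[-73]
  contours <- contour_set(
    epicardial = cbind(x = cx + spec$r_epi * cos(theta),
                       y = cx + spec$r_epi * sin(theta)),
    endocardial = cbind(x = cx + spec$r_endo * cos(theta),
                        y = cx + spec$r_endo * sin(theta)))

  structure(list(labels = labels, t1_native = t1_native, t1_post = t1_post,
                 A = Amap, contours = contours, spec = spec),
            class = "cardiac_phantom")
}

# smooth per-frame motion fields: global translation plus an optional
# low-order sinusoidal elastic component; the reference frame gets zero
make_motion_fields <- function(dims, n_frames, reference_index,
                               translation_sd = 2, elastic_amp = 0) {
  g <- coord_grid(dims[1], dims[2])
  lapply(seq_len(n_frames), function(i) {
    u <- zero_field(dims)
    if (i == reference_index) return(u)
    shift <- rnorm(2, 0, translation_sd)
    u[, , 1] <- shift[1]
    u[, , 2] <- shift[2]
    if (elastic_amp > 0) {
      amp <- stats::runif(2, 0, elastic_amp)
      ph <- stats::runif(2, 0, 2 * pi)
      u[, , 1] <- u[, , 1] + amp[1] * sin(2 * pi * g$Y / dims[1] + ph[1])
      u[, , 2] <- u[, , 2] + amp[2] * sin(2 * pi * g$X / dims[2] + ph[2])
    }
    u
  })
}

#' Simulate a MOLLI image series from a phantom
#'
#' Generates per-frame inversion-recovery signal
#' `S(TI) = A - B * exp(-TI / T1star)` with `B = f * A` and
#' `T1star = T1 / (f - 1)`, so the Look-Locker correction maps the fitted
#' parameters back to the phantom's ground-truth T1 exactly (inversion
#' factor `f` models imperfect inversion). Optional frame-to-frame smooth
#' displacements (breathing drift), Gaussian noise, and the magnitude
#' operation emulate the acquisition. All randomness is seeded.
#'
#' @param phantom a [make_cardiac_phantom()] result.
#' @param timing a [simulate_scheme_timing()] result (or a [scheme_spec()] /
#'   scheme string).
#' @param contrast `"native"` or `"post"`: which ground-truth T1 map drives
#'   the signal.
#' @param translation_sd per-frame translation SD in pixels.
#' @param elastic_amp amplitude bound of the smooth elastic motion component
#'   in pixels.
#' @param noise_sd Gaussian noise SD as a fraction of the maximum
#'   equilibrium signal.
#' @param magnitude apply the magnitude operation.
#' @param inversion_factor `f` above (2 = perfect inversion).
#' @param seed RNG seed.
#' @return list with `series` (a [molli_series()]), `true_fields` (list of
#'   per-frame displacement fields applied), `reference_index`, `clean_frames`
#'   (3-D array before motion/noise), and `timing`.
#' @export
simulate_molli_series <- function(phantom, timing = "5s(3s)3s",
                                  contrast = c("native", "post"),
                                  translation_sd = 2, elastic_amp = 0,
                                  noise_sd = 0, magnitude = TRUE,
                                  inversion_factor = 1.95, seed = 1L) {
  stopifnot(inherits(phantom, "cardiac_phantom"), inversion_factor > 1)
  contrast <- match.arg(contrast)
  if (is.character(timing) || inherits(timing, "scheme_spec"))
    timing <- simulate_scheme_timing(timing)
  ti <- timing$inversion_times
  nf <- length(ti)
  t1 <- if (contrast == "native") phantom$t1_native else phantom$t1_post
  Amap <- phantom$A
  Bmap <- inversion_factor * Amap
  t1star <- t1 / (inversion_factor - 1)
  dims <- dim(t1)
  set.seed(seed)
  reference_index <- max(which(ti == max(ti)))
  fields <- make_motion_fields(dims, nf, reference_index,
                               translation_sd, elastic_amp)
  clean <- array(0, dim = c(dims, nf))
  frames <- array(0, dim = c(dims, nf))
  sd_abs <- noise_sd * max(Amap)
  for (i in seq_len(nf)) {
    f <- Amap - Bmap * exp(-ti[i] / t1star)
    clean[, , i] <- f
    moved <- if (max(abs(fields[[i]])) > 0) warp(f, fields[[i]]) else f
    if (sd_abs > 0) moved <- moved + matrix(rnorm(prod(dims), 0, sd_abs), dims[1])
    if (magnitude) moved <- abs(moved)
    frames[, , i] <- moved
  }
  series <- molli_series(frames, ti, magnitude = magnitude,
                         scheme = if (!is.null(timing$scheme)) timing$scheme else NA_character_)
  list(series = series, true_fields = fields,
       reference_index = reference_index, clean_frames = clean,
       timing = timing)
}

#' Two-circle registration test pair
#'
#' The classic compression/expansion simulation: a reference image with two
#' equal discs and a target image in which one disc grew and the other
#' shrank. After registering the target to the reference, the local volume
#' change map should be positive (expansion) over the grown disc and
#' negative (compression) over the shrunk one.
#'
#' @param n grid size.
#' @param centers 2x2 matrix of disc centers (rows: disc; cols: x, y).
#'   Defaults to horizontally separated discs.
#' @param radii_reference,radii_target per-disc radii in pixels.
#' @param edge_width smooth edge width in pixels.
#' @return list with `ref`, `target` (matrices), `sign_mask` (+1 over the
#'   grown disc interior, -1 over the shrunk one, 0 elsewhere).
#' @export
make_two_circle_pair <- function(n = 96, centers = NULL,
                                 radii_reference = c(12, 12),
                                 radii_target = c(15, 9),
                                 edge_width = 2) {
  if (is.null(centers))
    centers <- rbind(c(0.3 * n, 0.5 * n), c(0.7 * n, 0.5 * n))
  stopifnot(nrow(centers) == 2, length(radii_reference) == 2,
            length(radii_target) == 2)
  sep <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  rmax <- pmax(radii_reference, radii_target)
  if (sep <= sum(rmax)) stop("circles overlap")
  if (any(centers - rmax < 1) || any(centers + rmax > n))
    stop("circles extend outside the grid")
  g <- coord_grid(n, n)
  render <- function(radii) {
    img <- matrix(0, n, n)
    for (k in 1:2) {
      rad <- sqrt((g$X - centers[k, 1])^2 + (g$Y - centers[k, 2])^2)
      img <- img + disc_profile(rad, radii[k], edge_width)
    }
    img
  }
  sign_mask <- matrix(0, n, n)
  for (k in 1:2) {
    rad <- sqrt((g$X - centers[k, 1])^2 + (g$Y - centers[k, 2])^2)
    s <- sign(radii_target[k] - radii_reference[k])
    sign_mask[rad <= 0.8 * min(radii_reference[k], radii_target[k])] <- s
  }
  list(ref = render(radii_reference), target = render(radii_target),
       sign_mask = sign_mask)
}
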