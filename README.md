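# mollimap

Motion correction and co-registration for cardiac MR T1 and extracellular
volume (ECV) mapping.

MOLLI T1 mapping acquires 8–14 single-shot images along the
inversion-recovery curve within one breath-hold; ECV mapping divides
relaxation-rate changes between a native and a post-contrast T1 map acquired
minutes apart. Both are exquisitely sensitive to in-plane motion: imperfect
breath-holding corrupts the pixel-wise curve fit, and native/post
misalignment corrupts the pixel-wise ECV ratio. `mollimap` addresses both
with a nonrigid, nonparametric elastic registration engine and the complete
workflow around it, for methods developers and image-analysis researchers
working on quantitative cardiac MR.

## The method

Registration finds the displacement field `u` minimizing the joint
functional

    T[u] = D[u; R, T] + alpha * S[u]

* `D` is a **normalized gradient field (NGF)** similarity,
  `D = 1/2 ∫ 1 − ip(x)² dx` with
  `ip = (|⟨∇R, ∇T(x+u)⟩| + εR·εT) / (‖∇R‖_εR · ‖∇T(x+u)‖_εT)` and
  `‖v‖_ε = (v1² + v2² + ε²)^½`. It compares edge *orientation* only: the
  measure is exactly invariant to intensity scale and polarity, which is
  what lets one reference frame serve a series whose contrast inverts
  through the signal null, and lets a native T1 map be the reference for a
  contrast-flipped post-contrast map. `ε` is set from the image's mean edge
  mass (`0.1 × mean |∇I|`).
* `S` is the **linear elastic potential** with Lamé parameters `(mu, lam)`,
  discretized with the same finite-difference stencils as the solver; the
  resulting Navier–Lamé operator is symmetric, annihilates translations,
  and satisfies `⟨u, Lu⟩ = 2 S[u]` exactly.
* The Euler–Lagrange system is linearized (damped Gauss–Newton), solved by
  **conjugate gradients**, and embedded in a coarse-to-fine **multiresolution
  pyramid**; iterations stop when the update drops below a tolerance
  (default 0.05 px).

On top of the engine: pixel-wise three-parameter inversion-recovery fitting
`S(t) = A − B·exp(−t/T1*)` (Levenberg–Marquardt) with polarity restoration
for magnitude data, Look-Locker correction `T1 = (B/A − 1)·T1*`, an SD
fitting-error map in ms, blood-pool segmentation on the native map
(T1 > 1400 ms inside the endocardial contour), pixel-wise
`ECV = ΔR1_myo/ΔR1_blood · (1 − hct)` with median blood T1, checkerboard
(LDF) and Jacobian-determinant (LVC) deformation-QA maps, second-based MOLLI
scheme timing, and a seeded synthetic phantom generator.

## Worked example

A complete phantom study: simulate native and post-contrast MOLLI series
with breathing motion and noise, then run motion correction, T1 fitting,
co-registration, and ECV mapping.

```r
library(mollimap)

timing <- simulate_scheme_timing(scheme_spec("5s(3s)3s", heart_rate = 50))
timing$images_per_period   # 5 3
timing$scan_seconds        # 13.2  (breath-hold over 11 beats)

phantom <- make_cardiac_phantom(cardiac_phantom_spec(n = 96, seed = 1))
native <- simulate_molli_series(phantom, "5s(3s)3s", contrast = "native",
                                translation_sd = 1.5, noise_sd = 0.01, seed = 11)
post <- simulate_molli_series(
  phantom, simulate_scheme_timing(scheme_spec("4s(1s)3s(1s)2s", heart_rate = 60)),
  contrast = "post", translation_sd = 1.5, noise_sd = 0.01, seed = 12)

native$series
#> MOLLI series: 8 frames of 96x96 (magnitude)
#>   TI [ms]: 87.7, 1087.7, 2087.7, 3087.7, 4087.7, 187.7, 1187.7, 2187.7
#>   scheme: 5s(3s)3s

study <- run_pipeline(native$series, post$series, phantom$contours,
                      hematocrit = 0.42)
study$ecv
#> ECV map: mean 26.5% (median 26.5%) over 1028 ROI pixels; hct 0.42
#>   median blood T1: 1895 ms native, 401 ms post
```

The phantom was built by inverting the ECV relation from a target of 26.3%
at hematocrit 0.42, so the recovered mean of 26.5% is within the expected
noise-level deviation; the median myocardial T1 comes back at 1280 ms (the
generator's ground truth) with a median SD fitting error of ~11 ms at 1%
noise, and the myocardial local volume change stays near zero
(median −0.007), i.e. the co-registration is close to volume preserving.
`study$ecv_uncoregistered` holds the comparison map computed without
co-registration, and `study$qa$lvc` / `study$qa$ldf` the deformation-QA
maps.

A command-line wrapper with subcommands `simulate`, `moco`, `t1fit`,
`coreg`, `ecv`, `qa` is installed at `inst/cli/mollimap`; see
`cli_dispatch()`.

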