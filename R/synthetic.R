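#' Specification for a synthetic principal-axis profile
#'
#' Describes a Monte-Carlo-like relative dose profile: a flat-top field of
#' width `fwhm` (the 50% isodose diameter) with error-function penumbrae of
#' 80-20 distance `penumbra_80_20`, optional penumbra asymmetry between the
#' positive and negative sides (z axis only on the real device), optional
#' Gaussian noise, sampled on `n_points` positions over \[-span, span\].
#'
#' When `fwhm`/`penumbra_80_20` are not given they default to field-realistic
#' values for the requested collimator and axis: the 50% diameter sits at the
#' nominal collimator size on x/y and is smaller on z (the z profile of this
#' device is the narrowest), penumbra widths scale down with field size, and
#' the z asymmetry shrinks from the 16 mm to the 4 mm field. These defaults
#' are approximations adopted for fixture realism, not vendor data.
#'
#' @param field_size_mm nominal collimator size: 16, 8 or 4.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param fwhm 50% isodose diameter, mm.
#' @param penumbra_80_20 80-20 penumbra distance, mm.
#' @param asymmetry penumbra skew: the positive-side penumbra width is
#'   scaled by (1 + asymmetry), the negative side by (1 - asymmetry).
#' @param noise_sd Gaussian noise standard deviation, percent.
#' @param n_points number of samples (>= 20).
#' @param span half-range of positions, mm.
#' @param seed integer seed for the noise.
#' @return an object of class `profile_spec`.
#' @export
profile_spec <- function(field_size_mm = c(16, 8, 4), axis = c("x", "y", "z"),
                         fwhm = NULL, penumbra_80_20 = NULL,
                         asymmetry = NULL, noise_sd = 0,
                         n_points = 201, span = NULL, seed = 1) {
  axis <- match.arg(axis)
  fs <- as.numeric(match.arg(as.character(field_size_mm[1]), c("16", "8", "4")))
  pre <- .field_presets(fs, axis)
  if (is.null(fwhm)) fwhm <- pre$fwhm
  if (is.null(penumbra_80_20)) penumbra_80_20 <- pre$pen
  if (is.null(asymmetry)) asymmetry <- if (axis == "z") pre$skew else 0
  if (fwhm <= 0 || penumbra_80_20 <= 0) stop("fwhm and penumbra must be positive")
  if (n_points < 20) stop("n_points must be at least 20")
  if (is.null(span)) span <- fwhm * 2.5
  structure(list(field_size_mm = fs, axis = axis, fwhm = fwhm,
                 penumbra_80_20 = penumbra_80_20, asymmetry = asymmetry,
                 noise_sd = noise_sd, n_points = as.integer(n_points),
                 span = span, seed = as.integer(seed)),
            class = "profile_spec")
}

# Fixture field scales per collimator and axis (mm); approximations chosen
# so the 50% isodose diameters sit at the nominal collimator sizes, with a
# narrower z profile and z asymmetry decreasing with field size.
.field_presets <- function(fs, axis) {
  row <- switch(as.character(fs),
    "16" = list(fwhm_xy = 16, fwhm_z = 12,  pen_xy = 3.5, pen_z = 2.6, skew = 0.10),
    "8"  = list(fwhm_xy = 8,  fwhm_z = 6,   pen_xy = 2.5, pen_z = 1.8, skew = 0.06),
    "4"  = list(fwhm_xy = 4,  fwhm_z = 3,   pen_xy = 1.6, pen_z = 1.2, skew = 0.02))
  if (axis == "z")
    list(fwhm = row$fwhm_z, pen = row$pen_z, skew = row$skew)
  else
    list(fwhm = row$fwhm_xy, pen = row$pen_xy, skew = 0)
}

# Noiseless two-edge flat-top profile value, percent of plateau. Edge
# centres are calibrated so that the 50% crossings of the *normalized*
# curve (max = 100%) sit exactly fwhm apart: when the penumbrae overlap
# the flat top, the raw maximum falls short of the asymptotic plateau and
# naive edge placement would push the crossings outward.
.flat_top <- function(k, fwhm, pen, asymmetry) {
  b <- pen / (2 * erfinv(0.6))        # erf edge with the requested 80-20 width
  b_pos <- b * (1 + asymmetry)
  b_neg <- b * (1 - asymmetry)
  c_neg <- -fwhm / 2
  c_pos <- fwhm / 2
  raw <- function(kk, cn, cp)
    50 * (erf((kk - cn) / b_neg) - erf((kk - cp) / b_pos))
  for (it in 1:8) {
    peak <- stats::optimize(function(kk) raw(kk, c_neg, c_pos),
                            c(c_neg, c_pos), maximum = TRUE)$objective
    half <- peak / 2
    k_neg <- stats::uniroot(function(kk) raw(kk, c_neg, c_pos) - half,
                            c(c_neg - 5 * b, 0), tol = 1e-12)$root
    k_pos <- stats::uniroot(function(kk) raw(kk, c_neg, c_pos) - half,
                            c(0, c_pos + 5 * b), tol = 1e-12)$root
    shift_n <- -fwhm / 2 - k_neg
    shift_p <- fwhm / 2 - k_pos
    c_neg <- c_neg + shift_n
    c_pos <- c_pos + shift_p
    if (max(abs(shift_n), abs(shift_p)) < 1e-10) break
  }
  raw(k, c_neg, c_pos)
}

#' Generate a synthetic dose profile
#'
#' Builds the profile described by a [profile_spec()]: a rising and a falling
#' error-function penumbra around a flat top, rescaled so the maximum sampled
#' dose is 100%, with optional per-point Gaussian noise. Identical seeds give
#' identical curves.
#'
#' @param spec a [profile_spec()].
#' @return a [profile_curve()].
#' @examples
#' cv <- synth_profile(profile_spec(4, "z"))
#' head(cv)
#' @export
synth_profile <- function(spec) {
  stopifnot(inherits(spec, "profile_spec"))
  k <- seq(-spec$span, spec$span, length.out = spec$n_points)
  d <- .flat_top(k, spec$fwhm, spec$penumbra_80_20, spec$asymmetry)
  d <- d / max(d) * 100
  if (spec$noise_sd > 0) {
    rng <- .seeded_rng(spec$seed)
    u1 <- vapply(seq_along(d), function(i) rng(), 0)
    u2 <- vapply(seq_along(d), function(i) rng(), 0)
    noise <- sqrt(-2 * log(pmax(u1, 1e-12))) * cos(2 * pi * u2)  # Box-Muller
    d <- d + spec$noise_sd * noise
  }
  d <- pmin(pmax(d, 0), 110)
  profile_curve(k, d, axis = spec$axis, field_size_mm = spec$field_size_mm)
}

#' Build a synthetic dose field for one collimator
#'
#' Generates the three principal-axis fixture profiles for a collimator,
#' fits each with the standard term counts, and composes the fits into a
#' [dose_field()]. With `scale` != 1 all fixture lengths (FWHM and penumbra)
#' are scaled proportionally, which is the construction used for field-size
#' ordering checks.
#'
#' @param field_size_mm 16, 8 or 4.
#' @param noise_sd profile noise, percent.
#' @param seed integer seed.
#' @param scale proportional scale factor on all profile lengths.
#' @return a `dose_field`.
#' @export
synth_field <- function(field_size_mm = c(16, 8, 4), noise_sd = 0, seed = 1,
                        scale = 1) {
  fs <- as.numeric(match.arg(as.character(field_size_mm[1]), c("16", "8", "4")))
  fit_axis <- function(axis) {
    pre <- .field_presets(fs, axis)
    sp <- profile_spec(fs, axis, fwhm = pre$fwhm * scale,
                       penumbra_80_20 = pre$pen * scale,
                       noise_sd = noise_sd, seed = seed)
    fit_profile(synth_profile(sp), seed = seed)
  }
  dose_field(fit_axis("x"), fit_axis("y"), fit_axis("z"), field_size_mm = fs)
}

#' Generate a synthetic reference point set
#'
#' Emulates a treatment-planning-system export: points rejection-sampled
#' uniformly in space where the model dose falls inside `dose_range`
#' (percent), with z snapped to a 1 mm grid, and reference doses equal to
#' the model dose at the stored location, optionally perturbed by a
#' multiplicative bias to emulate model/TPS disagreement.
#'
#' @param field a [dose_field()].
#' @param n number of points. The device-realistic defaults elsewhere in the
#'   package are 1700, 783 and 378 points for the 16, 8 and 4 mm fields.
#' @param dose_range inclusive (low, high) reference dose window, percent.
#' @param seed integer seed.
#' @param bias multiplicative dose perturbation (1 = none).
#' @param z_resolution z-grid spacing, mm.
#' @return a [reference_points()] set.
#' @export
generate_reference_points <- function(field, n, dose_range = c(19, 99),
                                      seed = 1, bias = 1, z_resolution = 1) {
  stopifnot(inherits(field, "dose_field"))
  if (n <= 0) stop("n must be positive")
  lo <- dose_range[1] / 100; hi <- dose_range[2] / 100
  span <- field$field_size_mm * 2.5
  rng <- .seeded_rng(seed)
  pts <- matrix(NA_real_, 0, 3)
  dos <- numeric(0)
  tries <- 0
  while (length(dos) < n) {
    m <- max(2 * (n - length(dos)), 1000)
    cand <- cbind((2 * vapply(1:m, function(i) rng(), 0) - 1) * span,
                  (2 * vapply(1:m, function(i) rng(), 0) - 1) * span,
                  round((2 * vapply(1:m, function(i) rng(), 0) - 1) * span /
                          z_resolution) * z_resolution)
    d <- evaluate_dose(field, cand)
    keep <- d >= lo & d <= hi
    pts <- rbind(pts, cand[keep, , drop = FALSE])
    dos <- c(dos, d[keep])
    tries <- tries + 1
    if (tries > 200 && length(dos) == 0)
      stop("dose range appears infeasible for this field")
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  dos <- dos[seq_len(n)] * 100 * bias
  reference_points(pts[, 1], pts[, 2], pts[, 3], dos,
                   field_size_mm = field$field_size_mm)
}
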