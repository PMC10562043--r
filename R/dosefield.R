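#' Elliptical 3D dose field from three principal-axis profiles
#'
#' Combines fitted x, y and z profile models into an analytical 3D relative
#' dose distribution. At a point \eqn{\vec r} at offset \eqn{\Delta\vec r}
#' from the field centre, with \eqn{\rho = |\Delta\vec r|},
#' \deqn{D(\vec r) = \sum_{k \in \{x,y,z\}} D_k(s_k\,\rho)\,
#'   \left(\frac{\Delta k}{\rho}\right)^2,}
#' i.e. each principal-axis profile is evaluated at the radial distance and
#' weighted by the squared direction cosine. The weights sum to one, so the
#' model reduces exactly to each 1D profile on its axis, gives circular
#' isodose cross-sections in the XY plane when the x and y profiles agree,
#' and elliptical cross-sections in planes containing z. The z profile is
#' evaluated at the signed distance `sign(dz) * rho` so any asymmetry of the
#' z profile about the XY plane carries over to the two hemispheres;
#' symmetric x/y models are insensitive to sign. All three profiles are
#' normalized internally so that the field centre evaluates to exactly 1.
#'
#' @param model_x,model_y,model_z [erf_sum()] models (or `erf_fit` objects)
#'   for the three principal axes.
#' @param field_size_mm nominal collimator size: 16, 8 or 4.
#' @param center field centre, mm (default the origin; dose distributions are
#'   shifted so the shot centre is at (0,0,0)).
#' @return an object of class `dose_field`.
#' @seealso [evaluate_dose()], [isodose_points()], [kvol()]
#' @export
dose_field <- function(model_x, model_y, model_z,
                       field_size_mm = c(16, 8, 4), center = c(0, 0, 0)) {
  as_model <- function(m) if (inherits(m, "erf_fit")) m$model else m
  model_x <- as_model(model_x); model_y <- as_model(model_y)
  model_z <- as_model(model_z)
  for (m in list(model_x, model_y, model_z))
    stopifnot(inherits(m, "erf_sum"))
  field_size_mm <- as.numeric(match.arg(as.character(field_size_mm[1]),
                                        c("16", "8", "4")))
  d0 <- c(evaluate_profile(model_x, 0), evaluate_profile(model_y, 0),
          evaluate_profile(model_z, 0))
  if (any(d0 <= 0))
    stop("profile models must be positive at the field centre")
  xy_same <- isTRUE(all.equal(unclass(model_x), unclass(model_y),
                              tolerance = 0))
  structure(list(field_size_mm = field_size_mm,
                 model_x = model_x, model_y = model_y, model_z = model_z,
                 center = as.numeric(center), d0 = d0, xy_same = xy_same),
            class = "dose_field")
}

#' Uniform dose field
#'
#' A degenerate field whose normalized dose is exactly 1 everywhere; useful
#' as the identity fixture for volume-averaging checks.
#'
#' @param field_size_mm nominal size label.
#' @return a `dose_field`.
#' @export
uniform_dose_field <- function(field_size_mm = 16) {
  flat <- erf_sum(A = 0, a = 0, b = 1, C0 = 100, symmetric = TRUE)
  dose_field(flat, flat, flat, field_size_mm = field_size_mm)
}

#' Evaluate the normalized 3D dose
#'
#' @param field a [dose_field()], or a plain function `f(x, y, z)` returning
#'   normalized dose (accepted anywhere a dose model is consumed).
#' @param points numeric 3-vector or an n-by-3 matrix of points, mm.
#' @return normalized dose (1 at the field centre), one value per point.
#' @export
evaluate_dose <- function(field, points) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  if (ncol(pts) != 3) stop("points must be a 3-vector or n-by-3 matrix")
  if (is.function(field)) return(field(pts[, 1], pts[, 2], pts[, 3]))
  stopifnot(inherits(field, "dose_field"))
  dx <- pts[, 1] - field$center[1]
  dy <- pts[, 2] - field$center[2]
  dz <- pts[, 3] - field$center[3]
  rho2 <- dx^2 + dy^2 + dz^2
  rho <- sqrt(rho2)
  out <- rep(1, nrow(pts))          # exactly 1 at the centre by definition
  nz <- rho2 > 0
  if (any(nz)) {
    r <- rho[nz]
    sz <- sign(dz[nz])
    sz[sz == 0] <- 1
    px <- evaluate_profile(field$model_x, r) / field$d0[1]
    py <- if (isTRUE(field$xy_same)) px else
      evaluate_profile(field$model_y, r) / field$d0[2]
    pz <- evaluate_profile(field$model_z, sz * r) / field$d0[3]
    out[nz] <- (px * dx[nz]^2 + py * dy[nz]^2 + pz * dz[nz]^2) / rho2[nz]
  }
  out
}

#' @export
predict.dose_field <- function(object, newdata, ...) {
  evaluate_dose(object, newdata)
}

#' @export
print.dose_field <- function(x, ...) {
  cat(sprintf("elliptical dose field, %g mm collimator\n", x$field_size_mm))
  cat(sprintf("  terms: x %d, y %d, z %d%s\n", x$model_x$n, x$model_y$n,
              x$model_z$n,
              if (x$model_z$symmetric) "" else " (z asymmetric)"))
  cat(sprintf("  centre at (%g, %g, %g) mm\n",
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' @export
plot.dose_field <- function(x, plane = c("xz", "xy"), span = NULL, n = 121,
                            levels = c(0.9, 0.8, 0.5, 0.2), ...) {
  plane <- match.arg(plane)
  if (is.null(span)) span <- x$field_size_mm * 1.2
  g <- seq(-span, span, length.out = n)
  gr <- expand.grid(u = g, v = g)
  pts <- if (plane == "xz") cbind(gr$u, 0, gr$v) else cbind(gr$u, gr$v, 0)
  z <- matrix(evaluate_dose(x, pts), n, n)
  graphics::contour(g, g, z, levels = levels,
                    xlab = if (plane == "xz") "x (mm)" else "x (mm)",
                    ylab = if (plane == "xz") "z (mm)" else "y (mm)", ...)
  invisible(x)
}

#' Points on an isodose surface
#'
#' Samples points on the surface where the normalized dose equals `level`,
#' by bisection along random directions from the field centre.
#'
#' @param field a [dose_field()].
#' @param level isodose level as a fraction of the central dose, in (0, 1).
#' @param n_samples number of surface points to return.
#' @param seed integer seed for the random directions.
#' @param r_max outer search radius, mm (default 4 times the field size).
#' @return an `n_samples`-by-3 matrix of points, each with
#'   `|evaluate_dose - level| < 1e-6`.
#' @export
isodose_points <- function(field, level, n_samples = 100, seed = 1,
                           r_max = NULL) {
  stopifnot(inherits(field, "dose_field"))
  if (!(level > 0 && level < 1))
    stop("level must lie strictly between 0 and 1")
  if (is.null(r_max)) r_max <- 4 * field$field_size_mm
  rng <- .seeded_rng(seed)
  out <- matrix(NA_real_, n_samples, 3)
  for (i in seq_len(n_samples)) {
    # uniform direction on the sphere
    repeat {
      u <- c(2 * rng() - 1, 2 * rng() - 1, 2 * rng() - 1)
      nu <- sqrt(sum(u^2))
      if (nu > 1e-6 && nu <= 1) break
    }
    u <- u / nu
    f <- function(r) evaluate_dose(field, r * u) - level
    lo <- 0; hi <- r_max
    if (f(hi) > 0)
      stop(sprintf("dose at radius %g exceeds level %g: level outside range",
                   r_max, level))
    for (it in 1:200) {       # bisection to well below the 1e-6 dose tolerance
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-12) break
    }
    out[i, ] <- u * (lo + hi) / 2
  }
  colnames(out) <- c("x", "y", "z")
  out
}
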