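#' Parametric detector active-volume geometry
#'
#' Describes the sensitive volume of a dosimetry detector in detector-local
#' coordinates: the long axis is the z-axis and the origin is the centroid of
#' the active volume (the placement convention puts that centroid at the
#' field centre). Three shapes are supported:
#'
#' * `"chamber"` — thimble ionization chamber: a cylindrical gas cavity of
#'   radius `cavity_radius` and length `cavity_length`, optionally closed on
#'   top by a hemispherical cap of the same radius, minus a coaxial
#'   cylindrical central electrode (radius `electrode_radius`, length
#'   `electrode_length`) rising from the cavity base.
#' * `"disk"` — a flat cylinder (silicon diode, diamond or scintillating
#'   fibre) of radius `radius` and thickness `thickness`, axis along z.
#' * `"box"` — a rectangular block with edge lengths `dx`, `dy`, `dz`.
#'
#' All dimensions are in mm.
#'
#' @param name detector label.
#' @param shape one of `"chamber"`, `"disk"`, `"box"`.
#' @param ... shape dimensions (see Details); also `type` (free-text detector
#'   class), `nominal_volume_mm3` (manufacturer-quoted volume) and
#'   `approximate` (logical: dimensions reconstructed from published
#'   constraints rather than taken from a data sheet).
#' @return an object of class `detector_geometry`.
#' @seealso [volume()], [contains()], [load_detector_library()]
#' @export
detector_geometry <- function(name, shape = c("chamber", "disk", "box"), ...) {
  shape <- match.arg(shape)
  g <- list(name = name, shape = shape, ...)
  defaults <- list(type = NA_character_, nominal_volume_mm3 = NA_real_,
                   approximate = NA)
  for (f in names(defaults)) if (is.null(g[[f]])) g[[f]] <- defaults[[f]]
  if (shape == "chamber") {
    req <- c("cavity_radius", "cavity_length")
    if (!all(req %in% names(g)))
      stop("chamber requires cavity_radius and cavity_length: ", name)
    if (is.null(g$cap)) g$cap <- FALSE
    if (is.null(g$electrode_radius)) g$electrode_radius <- 0
    if (is.null(g$electrode_length)) g$electrode_length <- 0
    if (g$cavity_radius <= 0 || g$cavity_length <= 0)
      stop("chamber cavity dimensions must be positive: ", name)
    if (g$electrode_radius >= g$cavity_radius)
      stop("electrode_radius must be smaller than cavity_radius: ", name)
    if (g$electrode_length > g$cavity_length +
        (if (isTRUE(g$cap)) g$cavity_radius else 0))
      stop("electrode longer than the cavity: ", name)
  } else if (shape == "disk") {
    if (!all(c("radius", "thickness") %in% names(g)))
      stop("disk requires radius and thickness: ", name)
    if (g$radius <= 0 || g$thickness <= 0)
      stop("disk dimensions must be positive: ", name)
  } else {
    if (!all(c("dx", "dy", "dz") %in% names(g)))
      stop("box requires dx, dy, dz: ", name)
    if (g$dx <= 0 || g$dy <= 0 || g$dz <= 0)
      stop("box dimensions must be positive: ", name)
  }
  class(g) <- "detector_geometry"
  v <- volume(g)
  if (v <= 0) stop("computed active volume is non-positive: ", name)
  if (is.finite(g$nominal_volume_mm3) &&
      abs(v - g$nominal_volume_mm3) > 0.10 * g$nominal_volume_mm3)
    warning(sprintf("%s: computed volume %.4g mm^3 deviates >10%% from nominal %.4g",
                    name, v, g$nominal_volume_mm3))
  g
}

#' Exact active volume of a detector
#'
#' Closed forms: disk \eqn{\pi r^2 t}; box \eqn{d_x d_y d_z}; chamber
#' \eqn{\pi r^2 L + \frac{2}{3}\pi r^3 \textrm{(if capped)} -
#' \pi r_e^2 L_e}.
#'
#' @param geometry a [detector_geometry()].
#' @return volume in mm^3.
#' @export
volume <- function(geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  switch(geometry$shape,
    disk = pi * geometry$radius^2 * geometry$thickness,
    box = geometry$dx * geometry$dy * geometry$dz,
    chamber = {
      v <- pi * geometry$cavity_radius^2 * geometry$cavity_length
      if (isTRUE(geometry$cap)) v <- v + 2 / 3 * pi * geometry$cavity_radius^3
      v - pi * geometry$electrode_radius^2 * geometry$electrode_length
    })
}

# z-extent of the active volume in construction coordinates, where the
# cavity/disk/box is centred at z = 0 and a cap (if any) sits on top.
.z_extent <- function(g) {
  switch(g$shape,
    disk = c(-g$thickness / 2, g$thickness / 2),
    box = c(-g$dz / 2, g$dz / 2),
    chamber = c(-g$cavity_length / 2,
                g$cavity_length / 2 +
                  (if (isTRUE(g$cap)) g$cavity_radius else 0)))
}

# Centroid z of the active volume in construction coordinates; the placement
# convention shifts the geometry so this point sits at the field centre.
.centroid_z <- function(g) {
  if (g$shape != "chamber") return(0)
  r <- g$cavity_radius; L <- g$cavity_length
  v_cyl <- pi * r^2 * L
  parts_v <- v_cyl
  parts_m <- 0                                     # cylinder centred at 0
  if (isTRUE(g$cap)) {
    v_cap <- 2 / 3 * pi * r^3
    z_cap <- L / 2 + 3 * r / 8                     # hemisphere centroid
    parts_v <- parts_v + v_cap
    parts_m <- parts_m + v_cap * z_cap
  }
  if (g$electrode_radius > 0 && g$electrode_length > 0) {
    v_e <- pi * g$electrode_radius^2 * g$electrode_length
    z_e <- -L / 2 + g$electrode_length / 2         # rises from the base
    parts_v <- parts_v - v_e
    parts_m <- parts_m - v_e * z_e
  }
  parts_m / parts_v
}

#' Point-inclusion test for a detector active volume
#'
#' Tests whether points (detector-local coordinates: active-volume centroid
#' at the origin, long axis along z) lie inside the active volume. For
#' chambers this is (cavity union cap) minus the electrode. Boundary points
#' count as inside.
#'
#' @param geometry a [detector_geometry()].
#' @param points 3-vector or n-by-3 matrix, mm.
#' @return logical vector.
#' @export
contains <- function(geometry, points) {
  stopifnot(inherits(geometry, "detector_geometry"))
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  x <- pts[, 1]; y <- pts[, 2]
  z <- pts[, 3] + .centroid_z(geometry)  # back to construction coordinates
  r2 <- x^2 + y^2
  switch(geometry$shape,
    disk = r2 <= geometry$radius^2 & abs(z) <= geometry$thickness / 2,
    box = abs(x) <= geometry$dx / 2 & abs(y) <= geometry$dy / 2 &
      abs(z) <= geometry$dz / 2,
    chamber = {
      R <- geometry$cavity_radius; L <- geometry$cavity_length
      in_body <- r2 <= R^2 & abs(z) <= L / 2
      in_cap <- if (isTRUE(geometry$cap))
        z > L / 2 & r2 + (z - L / 2)^2 <= R^2 else FALSE
      in_elec <- geometry$electrode_radius > 0 &
        r2 < geometry$electrode_radius^2 &
        z > -L / 2 & z < -L / 2 + geometry$electrode_length
      (in_body | in_cap) & !in_elec
    })
}

#' Monte Carlo estimate of the active volume
#'
#' Uniform sampling in the bounding box times the inclusion fraction;
#' serves as the independent check on the closed-form [volume()].
#'
#' @param geometry a [detector_geometry()].
#' @param n number of sample points.
#' @param seed integer seed.
#' @return a list with `volume` (mm^3), `se` (standard error) and `n`.
#' @export
mc_volume <- function(geometry, n = 1e6, seed = 1) {
  bb <- .bounding_box(geometry)
  set.seed(seed)
  pts <- cbind(stats::runif(n, bb[1, 1], bb[1, 2]),
               stats::runif(n, bb[2, 1], bb[2, 2]),
               stats::runif(n, bb[3, 1], bb[3, 2]))
  vbox <- prod(bb[, 2] - bb[, 1])
  inside <- contains(geometry, pts)
  p <- mean(inside)
  list(volume = vbox * p, se = vbox * sqrt(p * (1 - p) / n), n = n)
}

# Axis-aligned bounding box in detector-local (centroid-origin) coordinates.
.bounding_box <- function(g) {
  zc <- .centroid_z(g)
  ze <- .z_extent(g) - zc
  r <- switch(g$shape, disk = g$radius, chamber = g$cavity_radius, box = NA)
  if (g$shape == "box")
    rbind(c(-g$dx / 2, g$dx / 2), c(-g$dy / 2, g$dy / 2), ze)
  else
    rbind(c(-r, r), c(-r, r), ze)
}

#' @export
print.detector_geometry <- function(x, ...) {
  dims <- switch(x$shape,
    disk = sprintf("r = %g mm, t = %g mm", x$radius, x$thickness),
    box = sprintf("%g x %g x %g mm", x$dx, x$dy, x$dz),
    chamber = sprintf("cavity r = %g mm, L = %g mm%s%s", x$cavity_radius,
                      x$cavity_length,
                      if (isTRUE(x$cap)) " + hemispherical cap" else "",
                      if (x$electrode_radius > 0)
                        sprintf(", electrode r = %g, L = %g mm",
                                x$electrode_radius, x$electrode_length)
                      else ""))
  cat(sprintf("%s (%s): %s; V = %.4g mm^3%s\n", x$name, x$shape, dims,
              volume(x),
              if (isTRUE(x$approximate)) " [dimensions approximate]" else ""))
  invisible(x)
}

#' Load a detector-geometry library from YAML
#'
#' Each entry of the YAML list must carry `name`, a known `shape` keyword
#' and the dimensions that shape requires; optional fields are `type`,
#' `nominal_volume_mm3` and `approximate`. See the shipped library at
#' `system.file("extdata", "detectors.yaml", package = "gkvol")`.
#'
#' @param path YAML file path; defaults to the shipped 14-detector library.
#' @return a named list of [detector_geometry()] objects.
#' @export
load_detector_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "detectors.yaml", package = "gkvol")
  entries <- yaml::read_yaml(path)
  if (length(entries) == 0)
    stop("detector library is empty: ", path)
  out <- lapply(entries, function(e) {
    if (is.null(e$name)) stop("detector library entry without a name")
    if (is.null(e$shape) || !e$shape %in% c("chamber", "disk", "box"))
      stop(sprintf("unknown shape %s for detector '%s'",
                   deparse(e$shape), e$name))
    do.call(detector_geometry, e)
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}
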