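#' Reference dose-point set
#'
#' A set of spatial points with reference relative doses (percent), in the
#' format a treatment planning system export provides: one point per row
#' with its coordinates in mm and the reference dose at that point. Used to
#' check the analytical dose model's absorbed-dose sums over isodose-bounded
#' volumes.
#'
#' @param x,y,z coordinates, mm.
#' @param doses reference relative dose, percent.
#' @param field_size_mm nominal collimator size.
#' @return an object of class `reference_points` (a data frame with columns
#'   `x_mm`, `y_mm`, `z_mm`, `dose_percent`).
#' @export
reference_points <- function(x, y, z, doses, field_size_mm = c(16, 8, 4)) {
  fs <- as.numeric(match.arg(as.character(field_size_mm[1]), c("16", "8", "4")))
  n <- length(x)
  if (n == 0) stop("a reference point set cannot be empty")
  if (length(y) != n || length(z) != n || length(doses) != n)
    stop("x, y, z and doses must have equal length")
  if (any(!is.finite(doses)) || any(doses < 0) || any(doses > 110))
    stop("reference doses must be finite percentages in [0, 110]")
  out <- data.frame(x_mm = as.numeric(x), y_mm = as.numeric(y),
                    z_mm = as.numeric(z), dose_percent = as.numeric(doses))
  attr(out, "field_size_mm") <- fs
  class(out) <- c("reference_points", "data.frame")
  out
}

#' Read reference points from CSV
#'
#' Expects columns `x_mm, y_mm, z_mm, dose_percent`.
#'
#' @param path file path.
#' @inheritParams reference_points
#' @return a [reference_points()] set.
#' @export
read_reference_points <- function(path, field_size_mm = c(16, 8, 4)) {
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("x_mm", "y_mm", "z_mm", "dose_percent")
  if (!all(need %in% names(d)))
    stop("reference point file must have columns ", paste(need, collapse = ", "))
  reference_points(d$x_mm, d$y_mm, d$z_mm, d$dose_percent,
                   field_size_mm = field_size_mm)
}

#' Absorbed-dose sum over an isodose-bounded volume
#'
#' Approximates the dose integral from the field centre out to a given
#' isodose surface by summing the dose values of all points inside that
#' volume. Membership is decided on the reference dose: a point belongs to
#' the volume when its reference dose is at least `level_low` (as a fraction
#' of the central dose).
#'
#' @param doses dose values to sum, percent (reference or model doses).
#' @param ref_doses reference doses, percent, deciding membership; defaults
#'   to `doses`.
#' @param level_low lower isodose bound as a fraction in (0, 1).
#' @return the summed dose over the selected points (percent units).
#' @export
dose_sum <- function(doses, level_low, ref_doses = doses) {
  if (!(level_low > 0 && level_low < 1))
    stop("level_low must lie strictly between 0 and 1")
  inside <- ref_doses >= level_low * 100
  if (!any(inside))
    stop("no points inside the requested isodose volume")
  sum(doses[inside])
}

#' Relative model error over an isodose-bounded volume
#'
#' Compares the analytical model's absorbed-dose sum with a reference point
#' set over the volume bounded below by `level_low`:
#' \deqn{R_v = \frac{D_{ref} - D_{model}}{D_{ref}} \times 100\%,}
#' with both sums taken over the same point subset (membership decided on
#' the reference doses). The result is signed: positive when the model
#' underestimates the reference.
#'
#' @param ref a [reference_points()] set.
#' @param field a [dose_field()] (or dose function).
#' @param level_low lower isodose bound, fraction in (0, 1).
#' @return R_v in percent.
#' @examples
#' fld <- synth_field(4)
#' rp <- generate_reference_points(fld, 200, seed = 2)
#' model_error(rp, fld, 0.5)   # 0: the reference was generated by the model
#' @export
model_error <- function(ref, field, level_low) {
  stopifnot(inherits(ref, "reference_points"))
  model_d <- evaluate_dose(field, as.matrix(ref[, c("x_mm", "y_mm", "z_mm")])) * 100
  d_ref <- dose_sum(ref$dose_percent, level_low)
  d_model <- dose_sum(model_d, level_low, ref_doses = ref$dose_percent)
  if (d_ref == 0) stop("reference dose sum is zero")
  (d_ref - d_model) / d_ref * 100
}

#' Model-error curve across isodose volumes
#'
#' Evaluates [model_error()] for a sequence of lower isodose bounds
#' (volumes from the 100% point out to each level), the standard accuracy
#' summary for the elliptical dose model.
#'
#' @inheritParams model_error
#' @param levels lower bounds, fractions in (0, 1).
#' @return a data frame with columns `level` and `rv_percent`.
#' @export
model_error_curve <- function(ref, field,
                              levels = seq(0.9, 0.2, by = -0.1)) {
  data.frame(level = levels,
             rv_percent = vapply(levels, function(l)
               model_error(ref, field, l), 0))
}
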