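#' Axial scaling model for imaging through a refractive index mismatch
#'
#' When a dry objective (refractive index `n1`, typically vacuum or air)
#' focuses into vitreous ice (`n2` ~ 1.28 at cryogenic temperature), the
#' microscope's axial coordinate is compressed: a fluorescent emitter at
#' actual depth `z_actual` below the interface appears at nominal depth
#' `z_nominal = z_actual / S`, with scaling factor `S >= n2/n1`. Within the
#' linear regime (depths up to `linear_limit_um`) the compression is
#' depth-independent, so a single scalar `S` corrects all targeting depths.
#'
#' @param na Numerical aperture of the (dry) objective, `0 < na < n1`.
#' @param n1 Refractive index on the objective side (default 1.0, vacuum).
#' @param n2 Refractive index of the specimen (default 1.28, vitreous ice
#'   at 109 K).
#' @param linear_limit_um Depth in micrometres below which the linear
#'   scaling approximation is valid (default 9).
#'
#' @return An object of class `axial_scaling_model`.
#' @seealso [scaling_factor()], [focal_shift()], [place_asymmetric_pattern()]
#' @export
#' @examples
#' m <- axial_scaling_model(na = 0.85)
#' scaling_factor(m)
axial_scaling_model <- function(na, n1 = 1.0, n2 = 1.28, linear_limit_um = 9) {
  stopifnot(is.numeric(na), length(na) == 1L, is.finite(na))
  if (na <= 0) stop("numerical aperture must be positive", call. = FALSE)
  if (na >= n1) {
    stop("invalid aperture: na must be smaller than n1 for a dry objective",
         call. = FALSE)
  }
  if (n1 > n2) {
    stop("compressive mismatch requires n1 <= n2", call. = FALSE)
  }
  if (linear_limit_um <= 0) stop("linear_limit_um must be positive", call. = FALSE)
  structure(
    list(na = na, n1 = n1, n2 = n2, linear_limit_um = linear_limit_um),
    class = "axial_scaling_model"
  )
}

#' @export
print.axial_scaling_model <- function(x, ...) {
  cat(sprintf(
    "Axial scaling model: NA %.2f, n1 %.3f -> n2 %.3f (linear to %.1f um)\n",
    x$na, x$n1, x$n2, x$linear_limit_um))
  cat(sprintf("  scaling factor S = %.4f (paraxial bound %.4f)\n",
              scaling_factor(x), x$n2 / x$n1))
  invisible(x)
}

#' Axial scaling factor S = z_actual / z_nominal
#'
#' The high-NA scaling factor is obtained by averaging the ray ratio
#' `tan(theta1)/tan(theta2)` uniformly over the aperture,
#' `sin(theta1) in (0, NA/n1]`, with Snell refraction
#' `n1 sin(theta1) = n2 sin(theta2)`. This lies between the paraxial bound
#' `n2/n1` and the marginal-ray ratio; the averaging scheme is selectable.
#'
#' @param model An [axial_scaling_model()].
#' @param scheme Averaging scheme: `"aperture_mean"` (default; uniform
#'   average of the ray ratio over sin(theta1)), `"paraxial"` (`n2/n1`), or
#'   `"marginal"` (marginal ray only).
#' @return Dimensionless scalar `S >= n2/n1`.
#' @export
scaling_factor <- function(model,
                           scheme = c("aperture_mean", "paraxial", "marginal")) {
  stopifnot(inherits(model, "axial_scaling_model"))
  scheme <- match.arg(scheme)
  n1 <- model$n1; n2 <- model$n2
  if (n1 == n2) return(1)
  ratio <- function(u) {
    # u = sin(theta1); v = sin(theta2)
    v <- u * n1 / n2
    (n2 / n1) * sqrt(1 - v^2) / sqrt(1 - u^2)
  }
  u_max <- model$na / n1
  switch(scheme,
    paraxial = n2 / n1,
    marginal = ratio(u_max),
    aperture_mean = stats::integrate(ratio, 0, u_max,
                                     rel.tol = 1e-10)$value / u_max
  )
}

#' Focal shift of an emitter under refractive index mismatch
#'
#' Difference between actual and nominal emitter position,
#' `shift = z_actual - z_nominal`. With the linear model,
#' `shift = depth * (1 - 1/S)` per actual depth, or `depth * (S - 1)` per
#' nominal depth. Depths beyond the linear limit are still evaluated but
#' flagged via the `"beyond_linear_limit"` attribute.
#'
#' @param model An [axial_scaling_model()].
#' @param depth_um Emitter depth(s) in micrometres, non-negative.
#' @param convention Whether `depth_um` is the actual (`"actual"`, default)
#'   or the microscope-measured nominal (`"nominal"`) depth.
#' @inheritParams scaling_factor
#' @return Numeric vector of shifts (um), with logical attribute
#'   `beyond_linear_limit` marking depths outside the linear regime.
#' @export
focal_shift <- function(model, depth_um, convention = c("actual", "nominal"),
                        scheme = "aperture_mean") {
  stopifnot(inherits(model, "axial_scaling_model"), all(depth_um >= 0))
  convention <- match.arg(convention)
  S <- scaling_factor(model, scheme)
  shift <- switch(convention,
                  actual = depth_um * (1 - 1 / S),
                  nominal = depth_um * (S - 1))
  actual <- if (convention == "actual") depth_um else depth_um * S
  beyond <- actual > model$linear_limit_um + 1e-12
  if (any(beyond)) {
    warning("depth beyond linear regime (", model$linear_limit_um,
            " um); linear scaling model invalid there", call. = FALSE)
  }
  attr(shift, "beyond_linear_limit") <- beyond
  shift
}

#' Convert a nominal (microscope) depth to the actual depth
#'
#' @inheritParams focal_shift
#' @param nominal_um Nominal depth(s) in micrometres.
#' @return Actual depth(s), `nominal_um * S`.
#' @export
actual_depth <- function(model, nominal_um, scheme = "aperture_mean") {
  stopifnot(inherits(model, "axial_scaling_model"))
  nominal_um * scaling_factor(model, scheme)
}

#' Convert an actual depth to the nominal (microscope) depth
#'
#' @inheritParams focal_shift
#' @param actual_um Actual depth(s) in micrometres.
#' @return Nominal depth(s), `actual_um / S`.
#' @export
nominal_depth <- function(model, actual_um, scheme = "aperture_mean") {
  stopifnot(inherits(model, "axial_scaling_model"))
  actual_um / scaling_factor(model, scheme)
}

#' Place the asymmetric rough-milling pattern around a fluorescent target
#'
#' Because the axial coordinate is compressed, the emitter always sits
#' farther from the objective than its measured position: the bottom
#' pattern can be placed only a small margin below the coincident point,
#' while the top pattern must clear the worst-case focal shift of an
#' emitter whose nominal position coincides with the coincident point.
#'
#' @param model An [axial_scaling_model()].
#' @param max_nominal_depth_um Largest nominal target depth to guard
#'   against. Defaults to the nominal depth whose actual depth equals the
#'   model's linear limit.
#' @param bottom_margin_um Safety margin for the bottom pattern
#'   (default 0.3 um, "a few hundred nanometres").
#' @inheritParams scaling_factor
#' @return A list of class `pattern_placement` with `bottom_offset_um` and
#'   `top_offset_um` (both measured from the coincident point).
#' @export
place_asymmetric_pattern <- function(model,
                                     max_nominal_depth_um = NULL,
                                     bottom_margin_um = 0.3,
                                     scheme = "aperture_mean") {
  stopifnot(inherits(model, "axial_scaling_model"), bottom_margin_um > 0)
  S <- scaling_factor(model, scheme)
  if (is.null(max_nominal_depth_um)) {
    max_nominal_depth_um <- model$linear_limit_um / S
  }
  if (max_nominal_depth_um <= 0) {
    stop("max_nominal_depth_um must be positive", call. = FALSE)
  }
  worst_shift <- max_nominal_depth_um * (S - 1)
  placement <- list(
    bottom_offset_um = bottom_margin_um,
    top_offset_um = bottom_margin_um + worst_shift,
    scaling_factor = S,
    max_nominal_depth_um = max_nominal_depth_um
  )
  class(placement) <- "pattern_placement"
  placement
}

#' @export
print.pattern_placement <- function(x, ...) {
  cat(sprintf(
    "Milling pattern placement: bottom %.2f um below, top %.2f um above coincident point (S = %.3f)\n",
    x$bottom_offset_um, x$top_offset_um, x$scaling_factor))
  invisible(x)
}

#' Tabulate focal shift versus depth
#'
#' Convenience helper behind the `rim-shift` command line tool.
#'
#' @inheritParams focal_shift
#' @param depths_um Depths at which to evaluate the shift.
#' @return A data.frame with `depth_um`, `shift_um`, `nominal_um` and
#'   `beyond_linear_limit` columns.
#' @export
rim_shift_table <- function(model, depths_um, convention = "actual") {
  sh <- suppressWarnings(focal_shift(model, depths_um, convention))
  actual <- if (convention == "actual") depths_um else depths_um + sh
  data.frame(
    depth_um = depths_um,
    shift_um = as.numeric(sh),
    nominal_um = actual - as.numeric(sh),
    beyond_linear_limit = attr(sh, "beyond_linear_limit")
  )
}
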