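#' Scintillator detector geometry for transmission scattering patterns
#'
#' @param pixel_size_um Image pixel size at the scintillator plane (um/px).
#' @param center_px Beam center as `c(row, col)` in pixel coordinates
#'   (pixel centers at integer coordinates, origin top-left).
#' @param specimen_to_scintillator_um Camera length D (default 300 um).
#' @param max_angle_mrad Angular acceptance of the detector
#'   (default 218 mrad).
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(pixel_size_um, center_px,
                              specimen_to_scintillator_um = 300,
                              max_angle_mrad = 218) {
  stopifnot(pixel_size_um > 0, length(center_px) == 2L,
            specimen_to_scintillator_um > 0, max_angle_mrad > 0)
  structure(list(pixel_size_um = pixel_size_um,
                 center_px = center_px,
                 specimen_to_scintillator_um = specimen_to_scintillator_um,
                 max_angle_mrad = max_angle_mrad),
            class = "detector_geometry")
}

#' Convert a radial distance on the scintillator to a scattering angle
#'
#' `angle = arctan(r / D)`, with D the specimen-to-scintillator distance.
#'
#' @param r_um Radial distance(s) from the beam center (um), non-negative.
#' @param geometry A [detector_geometry()].
#' @return Scattering angle(s) in mrad.
#' @export
#' @examples
#' g <- detector_geometry(1, c(1, 1))
#' pixel_to_angle(33, g)  # ~109.6 mrad
pixel_to_angle <- function(r_um, geometry) {
  stopifnot(inherits(geometry, "detector_geometry"), all(r_um >= 0))
  atan(r_um / geometry$specimen_to_scintillator_um) * 1000
}

#' A single transmitted-electron scattering pattern
#'
#' @param image Numeric matrix of non-negative intensities.
#' @param geometry A [detector_geometry()]; its `center_px` must lie
#'   inside the image.
#' @param beam_energy_keV Primary beam energy (default 30).
#' @param probe_position Optional `(x, y)` probe position on the lamella.
#' @return An object of class `scatter_pattern`.
#' @export
scatter_pattern <- function(image, geometry, beam_energy_keV = 30,
                            probe_position = NULL) {
  stopifnot(is.matrix(image), inherits(geometry, "detector_geometry"))
  if (any(image < 0)) stop("intensities must be non-negative", call. = FALSE)
  ctr <- geometry$center_px
  if (ctr[1L] < 1 || ctr[1L] > nrow(image) ||
      ctr[2L] < 1 || ctr[2L] > ncol(image)) {
    stop("beam center outside image bounds", call. = FALSE)
  }
  structure(list(image = image, geometry = geometry,
                 beam_energy_keV = beam_energy_keV,
                 probe_position = probe_position),
            class = "scatter_pattern")
}

#' Radially integrated intensity profile of a scattering pattern
#'
#' Sums intensities into equal-angle annular bins about the calibrated
#' beam center, up to the detector's angular acceptance. Total counts are
#' conserved: the profile sums to the masked image sum.
#'
#' @param pattern A [scatter_pattern()].
#' @param n_bins Number of angular bins (default 64).
#' @param bf_cutoff_mrad Bright-field disc semi-angle to record on the
#'   profile (default 60 mrad; see [bf_cutoff_from_vacuum()]).
#' @return An object of class `radial_profile` with `angle_mrad` (bin
#'   centers), `intensity`, `bf_cutoff_mrad` and `bin_width_mrad`.
#' @export
radial_profile <- function(pattern, n_bins = 64, bf_cutoff_mrad = 60) {
  stopifnot(inherits(pattern, "scatter_pattern"), n_bins >= 1L)
  g <- pattern$geometry
  img <- pattern$image
  rows <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  cols <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  r_um <- sqrt((rows - g$center_px[1L])^2 + (cols - g$center_px[2L])^2) *
    g$pixel_size_um
  ang <- pixel_to_angle(r_um, g)
  keep <- ang <= g$max_angle_mrad
  width <- g$max_angle_mrad / n_bins
  bin <- pmin(floor(ang[keep] / width) + 1L, n_bins)
  intensity <- as.numeric(
    tapply(img[keep], factor(bin, levels = seq_len(n_bins)), sum))
  intensity[is.na(intensity)] <- 0
  structure(list(angle_mrad = (seq_len(n_bins) - 0.5) * width,
                 intensity = intensity,
                 bf_cutoff_mrad = bf_cutoff_mrad,
                 bin_width_mrad = width),
            class = "radial_profile")
}

#' Bright-field disc semi-angle from a vacuum beam exposure
#'
#' The bright-field cutoff is fine-tuned on an exposure through an empty
#' foil hole: the smallest angle containing a given fraction of the
#' unscattered beam intensity (default 99%).
#'
#' @param profile A [radial_profile()] of a vacuum exposure.
#' @param containment Intensity fraction to enclose (default 0.99).
#' @return Cutoff angle in mrad.
#' @export
bf_cutoff_from_vacuum <- function(profile, containment = 0.99) {
  stopifnot(inherits(profile, "radial_profile"))
  cs <- cumsum(profile$intensity) / sum(profile$intensity)
  idx <- which(cs >= containment)[1L]
  profile$angle_mrad[idx] + profile$bin_width_mrad / 2
}

#' Integrated dark-field over bright-field intensity ratio
#'
#' `ratio = sum(I(angle > cutoff)) / sum(I(angle <= cutoff))`. The ratio
#' increases monotonically with thickness over the working range and is
#' invariant to global intensity scaling.
#'
#' @param profile A [radial_profile()].
#' @param bf_cutoff_mrad Override for the cutoff stored on the profile.
#' @return Dimensionless ratio.
#' @export
df_bf_ratio <- function(profile, bf_cutoff_mrad = NULL) {
  stopifnot(inherits(profile, "radial_profile"))
  cutoff <- if (is.null(bf_cutoff_mrad)) profile$bf_cutoff_mrad else
    bf_cutoff_mrad
  bf <- sum(profile$intensity[profile$angle_mrad <= cutoff])
  df <- sum(profile$intensity[profile$angle_mrad > cutoff])
  if (bf <= 0) {
    stop("infinite ratio: no bright-field intensity (beam not captured)",
         call. = FALSE)
  }
  df / bf
}

#' Most common scattering angle of a radial profile
#'
#' Peak angle of the per-solid-angle-corrected radial distribution
#' (intensity per annulus divided by the annulus solid angle), refined to
#' sub-bin precision with a parabolic fit. Ties are broken toward the
#' lower angle and flagged.
#'
#' @param profile A [radial_profile()].
#' @return Angle in mrad, with attributes `ambiguous` (equal-peak tie)
#'   and `undefined` (flat profile; NA returned).
#' @export
most_common_angle <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  th <- profile$angle_mrad / 1000
  half <- profile$bin_width_mrad / 2000
  omega <- 2 * pi * (cos(pmax(th - half, 0)) - cos(th + half))
  dens <- profile$intensity / omega
  if (max(dens) - min(dens) <= .Machine$double.eps * max(1, max(dens))) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    attr(out, "ambiguous") <- FALSE
    return(out)
  }
  peak <- max(dens)
  at_peak <- which(abs(dens - peak) <= 1e-12 * max(1, peak))
  i0 <- at_peak[1L]
  ang <- profile$angle_mrad[i0]
  if (i0 > 1L && i0 < length(dens)) {
    ym <- dens[i0 - 1L]; y0 <- dens[i0]; yp <- dens[i0 + 1L]
    den <- ym - 2 * y0 + yp
    if (den < 0) {
      ang <- ang + 0.5 * (ym - yp) / den * profile$bin_width_mrad
    }
  }
  attr(ang, "undefined") <- FALSE
  attr(ang, "ambiguous") <- length(at_peak) > 1L
  ang
}
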