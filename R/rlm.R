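#' Instrument geometry for milling and transmission imaging
#'
#' @param fib_incidence_deg Angle between the ion beam and the sample plane
#'   (the milling angle theta, default 10 degrees).
#' @param sem_incidence_deg Electron-beam angle of incidence from the
#'   lamella normal, used for the q4STEM path-length correction
#'   (default 52 degrees).
#' @param mill_rate_nm_s Effective thinning rate along the ion-beam y axis
#'   in nm/s (default 2.4).
#' @return An object of class `instrument_geometry`.
#' @export
instrument_geometry <- function(fib_incidence_deg = 10,
                                sem_incidence_deg = 52,
                                mill_rate_nm_s = 2.4) {
  if (fib_incidence_deg <= 0 || fib_incidence_deg >= 90) {
    stop("fib_incidence_deg must lie in (0, 90)", call. = FALSE)
  }
  if (mill_rate_nm_s <= 0) stop("mill_rate_nm_s must be positive", call. = FALSE)
  structure(list(fib_incidence_deg = fib_incidence_deg,
                 sem_incidence_deg = sem_incidence_deg,
                 mill_rate_nm_s = mill_rate_nm_s),
            class = "instrument_geometry")
}

#' Lamella thickness from the wedge width
#'
#' The shallow milling angle leaves a tapered wedge at the foil side of
#' the lamella. Its footprint width `w` measured along the lamella axis in
#' a reflected-light image relates to the plateau thickness by
#' `d = w * sin(theta)`.
#'
#' @param w_um Wedge width in micrometres (non-negative; vectorised).
#' @param theta_deg Milling angle in degrees, in (0, 90).
#' @return Thickness in nanometres.
#' @export
#' @examples
#' thickness_from_wedge(15.3, 10)  # ~2657 nm
#' thickness_from_wedge(2.5, 10)   # ~434 nm
thickness_from_wedge <- function(w_um, theta_deg) {
  if (any(w_um < 0)) stop("w_um must be non-negative", call. = FALSE)
  if (theta_deg <= 0 || theta_deg >= 90) {
    stop("theta_deg must lie in (0, 90)", call. = FALSE)
  }
  1000 * w_um * sin(theta_deg * pi / 180)
}

#' Milling angle from defocus across the lamella length
#'
#' Focusing on the two ends of the lamella in reflected light gives the
#' height difference (defocus) over the lamella length, from which the
#' realised milling angle follows as `theta = arcsin(defocus / length)`.
#'
#' @param defocus_um Focus difference between the two lamella ends (um).
#' @param lamella_length_um Lamella length (um), positive.
#' @return Milling angle in degrees.
#' @export
#' @examples
#' milling_angle_from_defocus(4, 22.4)  # 10.2 degrees
milling_angle_from_defocus <- function(defocus_um, lamella_length_um) {
  if (lamella_length_um <= 0) stop("lamella_length_um must be positive", call. = FALSE)
  if (any(defocus_um < 0) || any(defocus_um > lamella_length_um)) {
    stop("defocus_um must lie in [0, lamella_length_um]", call. = FALSE)
  }
  asin(defocus_um / lamella_length_um) * 180 / pi
}

#' Validity range of the geometric thickness estimate
#'
#' The wedge-width method produces reliable estimates roughly between
#' 2000 and 400 nm; outside that window results are flagged, not dropped.
#'
#' @param d_nm Thickness estimates (nm).
#' @param lower_nm,upper_nm Validity window bounds (nm).
#' @return Character vector: `"ok"`, `"below_validity"` or `"above_validity"`.
#' @export
geometric_validity_flag <- function(d_nm, lower_nm = 400, upper_nm = 2000) {
  out <- rep("ok", length(d_nm))
  out[d_nm < lower_nm] <- "below_validity"
  out[d_nm > upper_nm] <- "above_validity"
  out
}

# Contiguous runs of TRUE in a logical vector -> two-column matrix (start, end)
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Measure the foil-side wedge width from a reflected-light frame
#'
#' Computes the mean intensity profile across the lamella width and
#' locates the bright foil-side band along the lamella length; its width
#' at the half-maximum-above-background crossings (sub-pixel, linear
#' interpolation) is the wedge width `w`.
#'
#' @param frame Numeric matrix of reflected intensities (rows = lamella
#'   length axis by default).
#' @param pixel_size_um Physical pixel size (um/px).
#' @param axis Axis along which the profile runs: `"y"` (profile over
#'   rows, averaging columns; default, matching the usual orientation with
#'   the lamella length vertical) or `"x"`.
#' @param foil_side Which end of the profile holds the foil-side band:
#'   `"low"` (small indices, default) or `"high"`.
#' @param k_sigma Detection threshold in robust standard deviations above
#'   background (default 3).
#' @param threshold_frac Fraction of the peak height above background at
#'   which the width is read off (default 0.5 = FWHM-style).
#' @return A list with `w_um`, `w_px`, `peak_index`, `peak_value`,
#'   `background`, `crossings_px` and the extracted `profile`.
#' @export
extract_wedge_width <- function(frame, pixel_size_um,
                                axis = c("y", "x"),
                                foil_side = c("low", "high"),
                                k_sigma = 3,
                                threshold_frac = 0.5) {
  stopifnot(is.matrix(frame), is.numeric(frame), pixel_size_um > 0)
  axis <- match.arg(axis)
  foil_side <- match.arg(foil_side)
  profile <- if (axis == "y") rowMeans(frame) else colMeans(frame)
  n <- length(profile)

  if (max(profile) - min(profile) <= 0) {
    stop("no wedge detected: flat intensity profile", call. = FALSE)
  }
  bg <- stats::median(profile)
  # noise scale from first differences: immune to the multi-level
  # structure (background / plateau / bright band) of a lamella profile
  sigma <- stats::mad(diff(profile)) / sqrt(2)
  if (sigma == 0) sigma <- 1e-3 * (max(profile) - min(profile))
  above <- profile > bg + k_sigma * sigma
  if (!any(above)) {
    stop("no wedge detected: no intensity peak above background (lamella ",
         "may be thinner than the geometric method resolves)", call. = FALSE)
  }
  peaks <- runs_of(above)
  # drop minor runs (noise excursions), then take the band closest to
  # the foil-side end of the profile
  heights <- apply(peaks, 1L, function(r)
    max(profile[r[1L]:r[2L]]) - bg)
  peaks <- peaks[heights >= 0.5 * max(heights), , drop = FALSE]
  pick <- if (foil_side == "low") which.min(peaks[, "start"]) else
    which.max(peaks[, "end"])
  run <- peaks[pick, ]
  # background for the width criterion: profile outside all bands
  outside <- rep(TRUE, n)
  for (r in seq_len(nrow(peaks))) outside[peaks[r, 1L]:peaks[r, 2L]] <- FALSE
  if (any(outside)) bg <- stats::median(profile[outside])
  seg <- profile[run["start"]:run["end"]]
  ipk <- unname(run["start"]) + which.max(seg) - 1L
  peak_val <- profile[ipk]
  level <- bg + threshold_frac * (peak_val - bg)

  # sub-pixel linear interpolation at the half-level crossings; a band
  # touching the frame edge is closed off half a pixel outside it
  left <- {
    i <- ipk
    while (i > 1L && profile[i - 1L] >= level) i <- i - 1L
    if (i == 1L) 0.5 else (i - 1) + (level - profile[i - 1L]) /
        (profile[i] - profile[i - 1L])
  }
  right <- {
    i <- ipk
    while (i < n && profile[i + 1L] >= level) i <- i + 1L
    if (i == n) n + 0.5 else i + (profile[i] - level) /
        (profile[i] - profile[i + 1L])
  }
  w_px <- right - left
  list(
    w_um = w_px * pixel_size_um,
    w_px = w_px,
    peak_index = as.integer(ipk),
    peak_value = peak_val,
    background = bg,
    crossings_px = c(left = left, right = right),
    profile = profile
  )
}

#' Reflected-light image series
#'
#' @param frames List of numeric matrices (all the same shape).
#' @param timestamps_s Strictly increasing acquisition times (s).
#' @param pixel_size_um Pixel size (um/px).
#' @param wavelength_nm Illumination wavelength (nm), optional.
#' @return An object of class `rlm_series`.
#' @export
rlm_series <- function(frames, timestamps_s, pixel_size_um,
                       wavelength_nm = NA_real_) {
  stopifnot(is.list(frames), length(frames) == length(timestamps_s),
            pixel_size_um > 0)
  if (length(frames) == 0L) stop("empty series", call. = FALSE)
  if (any(diff(timestamps_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  shp <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1L)))) {
    stop("all frames must share the same shape", call. = FALSE)
  }
  structure(list(frames = frames, timestamps_s = timestamps_s,
                 pixel_size_um = pixel_size_um,
                 wavelength_nm = wavelength_nm),
            class = "rlm_series")
}

#' Thickness-versus-time series from a milling image sequence
#'
#' Runs [extract_wedge_width()] on every frame and converts the widths to
#' thickness via [thickness_from_wedge()]. Frames without a detectable
#' wedge are flagged (`"no_wedge"`), never silently dropped; estimates
#' outside the geometric validity window keep their own flags.
#'
#' @param series An [rlm_series()].
#' @param theta_deg Milling angle in degrees.
#' @param ... Passed on to [extract_wedge_width()].
#' @return A data.frame `(t_s, w_um, d_nm, flag)` with attribute
#'   `monotone_nonincreasing` (logical; over the successfully measured
#'   frames).
#' @export
thickness_time_series <- function(series, theta_deg, ...) {
  stopifnot(inherits(series, "rlm_series"))
  n <- length(series$frames)
  w <- rep(NA_real_, n); flag <- character(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      extract_wedge_width(series$frames[[i]], series$pixel_size_um, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      flag[i] <- "no_wedge"
    } else {
      w[i] <- res$w_um
      flag[i] <- "ok"
    }
  }
  d <- rep(NA_real_, n)
  d[!is.na(w)] <- thickness_from_wedge(w[!is.na(w)], theta_deg)
  ok <- flag == "ok"
  flag[ok] <- geometric_validity_flag(d[ok])
  out <- data.frame(t_s = series$timestamps_s, w_um = w, d_nm = d, flag = flag)
  dd <- d[!is.na(d)]
  attr(out, "monotone_nonincreasing") <-
    length(dd) < 2L || all(diff(dd) <= 0)
  out
}
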