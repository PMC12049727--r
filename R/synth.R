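# Synthetic-data generators: every measurement modality is emulated from
# a known ground-truth thickness field, so all analysis pipelines can be
# exercised (and their recovery error quantified) without instrument
# data. Phantoms are 2.5D: a thickness field, not a volume.

#' Ground-truth lamella phantom
#'
#' Builds a thickness field with linear wedge tapers at both ends
#' (footprint width `w = d / sin(theta)`, the same relation the geometric
#' estimator inverts), a flat central plateau with an optional linear
#' leading-to-trailing ramp, and an optional band of platinum-rich
#' protective coating near the top end. Rows run along the lamella
#' length (y), columns across its width (x); pixels outside the lamella
#' footprint have zero thickness.
#'
#' @param length_um,width_um Lamella dimensions (um).
#' @param center_thickness_nm Plateau thickness (nm).
#' @param theta_deg Milling angle (default 10).
#' @param ramp_nm Total linear thickness reduction from the leading
#'   (Pt-coated) to the trailing end of the plateau (default 0).
#' @param pixel_size_um Pixel size (default 0.1 um).
#' @param pt_band_um Width of the platinum-rich band at the top end, 0 to
#'   disable (default 0).
#' @param border_um Vacuum margin rendered around the lamella on all
#'   sides (default 2 um); provides the zero-thickness background and
#'   the EFTEM baseline region.
#' @return An object of class `lamella_phantom`: `thickness_nm` matrix,
#'   `footprint`, `pt_mask`, `plateau_mask` (logical matrices),
#'   `pixel_size_um`, `theta_deg`, `foil_wedge_w_um`.
#' @export
make_phantom <- function(length_um, width_um, center_thickness_nm,
                         theta_deg = 10, ramp_nm = 0, pixel_size_um = 0.1,
                         pt_band_um = 0, border_um = 2) {
  stopifnot(length_um > 0, width_um > 0, center_thickness_nm > 0,
            pixel_size_um > 0, border_um >= 0)
  if (center_thickness_nm - abs(ramp_nm) < 0) {
    stop("ramp exceeds the center thickness", call. = FALSE)
  }
  ny <- round((length_um + 2 * border_um) / pixel_size_um)
  nx <- round((width_um + 2 * border_um) / pixel_size_um)
  y_um <- (seq_len(ny) - 0.5) * pixel_size_um - border_um
  sin_t <- sin(theta_deg * pi / 180)
  w_um <- center_thickness_nm / 1000 / sin_t  # wedge footprint, both ends
  if (2 * w_um >= length_um) {
    stop("lamella too short for its wedges at this thickness/angle",
         call. = FALSE)
  }
  # thickness profile along y; plateau between the wedges, ramped from
  # trailing (low y) to leading (high y) end by ramp_nm
  d_lead <- center_thickness_nm
  d_trail <- center_thickness_nm - ramp_nm
  y0 <- 0; y1 <- w_um; y2 <- length_um - w_um; y3 <- length_um
  prof <- numeric(ny)
  foil <- y_um >= y0 & y_um < y1
  plateau <- y_um >= y1 & y_um <= y2
  top <- y_um > y2 & y_um <= y3
  prof[foil] <- d_trail * (y_um[foil] - y0) / w_um
  prof[plateau] <- d_trail + (d_lead - d_trail) *
    (y_um[plateau] - y1) / max(y2 - y1, pixel_size_um)
  prof[top] <- d_lead * (y3 - y_um[top]) / w_um
  thickness <- matrix(prof, ny, nx)
  x_um <- (seq_len(nx) - 0.5) * pixel_size_um - border_um
  in_x <- x_um >= 0 & x_um <= width_um
  thickness[, !in_x] <- 0

  footprint <- thickness > 0
  pt_mask <- matrix(FALSE, ny, nx)
  if (pt_band_um > 0) {
    pt_mask[y_um > length_um - pt_band_um & y_um <= length_um, in_x] <- TRUE
  }
  plateau_mask <- matrix(plateau, ny, nx)
  plateau_mask[, !in_x] <- FALSE
  structure(list(thickness_nm = thickness, footprint = footprint,
                 pt_mask = pt_mask, plateau_mask = plateau_mask,
                 pixel_size_um = pixel_size_um, theta_deg = theta_deg,
                 foil_wedge_w_um = w_um, length_um = length_um,
                 width_um = width_um),
            class = "lamella_phantom")
}

#' Milling simulation over a phantom
#'
#' Uniform material removal at a constant rate: frame k has thickness
#' `max(truth - rate * t_k, 0)` everywhere, so the wedge footprints
#' shrink self-consistently as the lamella thins.
#'
#' @param phantom A [make_phantom()] object.
#' @param mill_rate_nm_s Thinning rate (default 2.4 nm/s).
#' @param frame_interval_s Time between frames (s).
#' @param n_frames Number of frames.
#' @param noise_sd Additive Gaussian noise, as a fraction of the rendered
#'   dynamic range (default 0.02).
#' @param seed RNG seed.
#' @return An object of class `mill_simulation`.
#' @export
mill_simulation <- function(phantom, mill_rate_nm_s = 2.4,
                            frame_interval_s = 30, n_frames = 10,
                            noise_sd = 0.02, seed = 1) {
  stopifnot(inherits(phantom, "lamella_phantom"), mill_rate_nm_s > 0,
            frame_interval_s > 0, n_frames >= 1, noise_sd >= 0)
  structure(list(phantom = phantom, mill_rate_nm_s = mill_rate_nm_s,
                 frame_interval_s = frame_interval_s, n_frames = n_frames,
                 noise_sd = noise_sd, seed = seed),
            class = "mill_simulation")
}

#' Render a reflected-light milling series from a simulation
#'
#' Per frame, the ground-truth thickness is decremented by
#' `rate * t` (floored at zero) and rendered to reflected intensity:
#' interference reflectivity of the local thickness on the lamella,
#' a bright constant on the foil-side wedge (the band whose width the
#' geometric method measures), a high constant on the Pt mask, a low
#' constant background, plus additive Gaussian noise.
#'
#' @param sim A [mill_simulation()].
#' @param params A [tfi_params()] for the rendering wavelength.
#' @param foil_level,pt_level,background_level Rendered intensity levels
#'   (defaults 3, 4 and 0.05 in units of `r_mea`).
#' @return A list with `series` (an [rlm_series()]) and `truth`
#'   (list of per-frame ground-truth thickness matrices).
#' @export
render_rlm_series <- function(sim, params,
                              foil_level = 3, pt_level = 4,
                              background_level = 0.05) {
  stopifnot(inherits(sim, "mill_simulation"), inherits(params, "tfi_params"))
  set.seed(sim$seed)
  ph <- sim$phantom
  t_s <- (seq_len(sim$n_frames) - 1L) * sim$frame_interval_s
  frames <- truth <- vector("list", sim$n_frames)
  for (k in seq_len(sim$n_frames)) {
    d <- pmax(ph$thickness_nm - sim$mill_rate_nm_s * t_s[k], 0)
    img <- matrix(background_level, nrow(d), ncol(d))
    on_lamella <- d > 0
    img[on_lamella] <- reflectivity(d[on_lamella], params)
    # the foil-side wedge reflects brightly against the grid foil
    wedge <- on_lamella & !ph$plateau_mask & !ph$pt_mask &
      row(d) <= nrow(d) / 2
    img[wedge] <- foil_level * params$r_mea
    img[ph$pt_mask & on_lamella] <- pt_level * params$r_mea
    if (sim$noise_sd > 0) {
      img <- img + stats::rnorm(length(img),
                                sd = sim$noise_sd * diff(range(img)))
    }
    frames[[k]] <- img
    truth[[k]] <- d
  }
  list(series = rlm_series(frames, t_s, ph$pixel_size_um,
                           params$wavelength_nm),
       truth = truth)
}

#' Render transmission scattering patterns over a phantom
#'
#' For each probe position, `dose` electron exit angles are drawn from a
#' Monte-Carlo run at the local ground-truth thickness, given uniform
#' azimuths, projected to the scintillator plane (`r = D tan(angle)`)
#' and binned into a detector image; counting statistics arise from the
#' sampling itself.
#'
#' @param phantom A [make_phantom()] object.
#' @param probe_positions Two-column matrix of (row, col) pixel positions
#'   on the phantom.
#' @param geometry A [detector_geometry()] describing the detector image.
#' @param image_px Detector image size in pixels (square, default 128).
#' @param dose Electrons per probe (default 4000).
#' @param seed Base seed; probe i uses `seed + i`.
#' @param beam_energy_keV Primary energy (default 30).
#' @return A list with `patterns` (list of [scatter_pattern()]) and
#'   `truth_nm` (local ground-truth thickness per probe).
#' @export
render_scatter_patterns <- function(phantom, probe_positions, geometry,
                                    image_px = 128, dose = 4000, seed = 1,
                                    beam_energy_keV = 30) {
  stopifnot(inherits(phantom, "lamella_phantom"),
            is.matrix(probe_positions), ncol(probe_positions) == 2L,
            inherits(geometry, "detector_geometry"))
  n <- nrow(probe_positions)
  patterns <- vector("list", n)
  truth <- numeric(n)
  for (i in seq_len(n)) {
    rc <- probe_positions[i, ]
    if (rc[1L] < 1 || rc[1L] > nrow(phantom$thickness_nm) ||
        rc[2L] < 1 || rc[2L] > ncol(phantom$thickness_nm)) {
      stop("probe position outside phantom", call. = FALSE)
    }
    truth[i] <- phantom$thickness_nm[rc[1L], rc[2L]]
    mc <- mc_simulate(truth[i], beam_energy_keV, n_electrons = dose,
                      seed = seed + i)
    ang <- mc$exit_angle_mrad[mc$fate == "transmitted"]
    ang <- ang[ang <= geometry$max_angle_mrad]
    set.seed(seed + i + 524287L)  # distinct stream from the transport run
    phi <- stats::runif(length(ang)) * 2 * pi
    r_um <- geometry$specimen_to_scintillator_um * tan(ang / 1000)
    px_r <- geometry$center_px[1L] + r_um * sin(phi) / geometry$pixel_size_um
    px_c <- geometry$center_px[2L] + r_um * cos(phi) / geometry$pixel_size_um
    ir <- round(px_r); ic <- round(px_c)
    keep <- ir >= 1 & ir <= image_px & ic >= 1 & ic <= image_px
    img <- matrix(0, image_px, image_px)
    if (any(keep)) {
      tab <- table(factor(ir[keep] + (ic[keep] - 1) * image_px,
                          levels = seq_len(image_px^2)))
      img[] <- as.numeric(tab)
    }
    patterns[[i]] <- scatter_pattern(img, geometry, beam_energy_keV,
                                     probe_position = rc)
  }
  list(patterns = patterns, truth_nm = truth)
}

#' Render an EFTEM unfiltered / zero-loss pair from a phantom
#'
#' `I0` is uniform illumination; `I = I0 * exp(-t / lambda_inel)` with
#' the ground-truth thickness `t` (zero in vacuum, which provides the
#' baseline region). Optional multiplicative Gaussian noise on both.
#'
#' @param phantom A [make_phantom()] object (vacuum = outside footprint).
#' @param lambda_inel_nm Inelastic mean free path (default 320).
#' @param i0_level Illumination level (default 1000 counts).
#' @param noise_frac Multiplicative noise fraction (default 0.01; 0 for
#'   an exact forward model).
#' @param seed RNG seed.
#' @param pre_tilt_deg Pre-tilt recorded in the parameters (default 0 so
#'   the rendered pair round-trips the truth directly).
#' @return A list with `pair` (an [eftem_pair()]) and `truth_nm`.
#' @export
render_eftem_pair <- function(phantom, lambda_inel_nm = 320,
                              i0_level = 1000, noise_frac = 0.01, seed = 1,
                              pre_tilt_deg = 0) {
  stopifnot(inherits(phantom, "lamella_phantom"), i0_level > 0,
            noise_frac >= 0)
  set.seed(seed)
  t <- phantom$thickness_nm
  I0 <- matrix(i0_level, nrow(t), ncol(t))
  I <- i0_level * exp(-t / lambda_inel_nm)
  if (noise_frac > 0) {
    I0 <- I0 * (1 + stats::rnorm(length(I0), sd = noise_frac))
    I <- I * (1 + stats::rnorm(length(I), sd = noise_frac))
  }
  params <- eftem_params(lambda_inel_nm,
                         pixel_size_nm = phantom$pixel_size_um * 1000,
                         pre_tilt_deg = pre_tilt_deg)
  pair <- eftem_pair(I0, I, params, vacuum_roi = !phantom$footprint)
  list(pair = pair, truth_nm = t)
}
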