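# Shared fixtures, all generated in code.

# default interference parameters at the blue channel
default_tfi <- function(...) tfi_params(wavelength_nm = 463, ...)

# a frame whose mean-y profile is a rectangular band of `width_px` rows
# at `level`, starting at `start_px`, over a flat background
band_frame <- function(n_rows = 120, n_cols = 20, start_px = 40,
                       width_px = 25, level = 1, background = 0.05) {
  f <- matrix(background, n_rows, n_cols)
  f[start_px:(start_px + width_px - 1L), ] <- level
  f
}

# detector geometry used across q4STEM tests: 1 um pixels, 129x129 image
# centered on an integer pixel so constructed radii are exact
test_geometry <- function(pixel_size_um = 1, n_px = 129)
  detector_geometry(pixel_size_um = pixel_size_um,
                    center_px = c((n_px + 1) / 2, (n_px + 1) / 2))

# image with all intensity on pixels at an exact radius (in px) from the
# center; returns the image and the pixel count used
ring_image <- function(n_px = 129, radius_px = 30, value = 2) {
  ctr <- (n_px + 1) / 2
  img <- matrix(0, n_px, n_px)
  img[ctr + radius_px, ctr] <- value
  img[ctr - radius_px, ctr] <- value
  img[ctr, ctr + radius_px] <- value
  img[ctr, ctr - radius_px] <- value
  img
}

# hand-built monotone lookup table for inversion arithmetic tests
toy_table <- function() {
  structure(list(thickness_nm = c(300, 325, 350),
                 df_bf_ratio = c(1.5, 2, 2.5),
                 ratio_se = c(0.05, 0.05, 0.05),
                 most_common_angle_mrad = c(40, 45, 50),
                 beam_energy_keV = 30,
                 material = "amorphous H2O, 0.94 g/cm^3",
                 density_g_cm3 = 0.94,
                 bf_cutoff_mrad = 60,
                 max_angle_mrad = 218,
                 n_electrons = 1000,
                 seed = 1),
            class = "mc_table")
}
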