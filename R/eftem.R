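#' Energy-filtered TEM acquisition parameters
#'
#' @param lambda_inel_nm Inelastic mean free path (default 320 nm for
#'   300 keV electrons in vitreous ice).
#' @param pixel_size_nm Image pixel size (nm/px).
#' @param pre_tilt_deg Lamella pre-tilt relative to the beam
#'   (default 10 degrees).
#' @return An object of class `eftem_params`.
#' @export
eftem_params <- function(lambda_inel_nm = 320, pixel_size_nm = NA_real_,
                         pre_tilt_deg = 10) {
  stopifnot(lambda_inel_nm > 0)
  structure(list(lambda_inel_nm = lambda_inel_nm,
                 pixel_size_nm = pixel_size_nm,
                 pre_tilt_deg = pre_tilt_deg),
            class = "eftem_params")
}

#' Paired unfiltered / zero-loss EFTEM images
#'
#' @param unfiltered Unfiltered image I0 (matrix).
#' @param zero_loss Zero-loss filtered image I (same shape).
#' @param params An [eftem_params()].
#' @param vacuum_roi Logical matrix marking pixels known to be vacuum
#'   (hole), used for the baseline correction; must be non-empty.
#' @return An object of class `eftem_pair`.
#' @export
eftem_pair <- function(unfiltered, zero_loss, params, vacuum_roi) {
  stopifnot(is.matrix(unfiltered), identical(dim(unfiltered), dim(zero_loss)),
            inherits(params, "eftem_params"),
            is.logical(vacuum_roi), identical(dim(vacuum_roi), dim(zero_loss)))
  if (!any(vacuum_roi)) stop("vacuum_roi is empty", call. = FALSE)
  structure(list(unfiltered = unfiltered, zero_loss = zero_loss,
                 params = params, vacuum_roi = vacuum_roi),
            class = "eftem_pair")
}

#' Zero-loss log-ratio thickness map
#'
#' Computes `t = lambda_inel * ln(I0 / I)` per pixel, subtracts the mean
#' over the vacuum region (baseline correction, so vacuum reads zero) and
#' divides by `cos(pre_tilt)` to convert the beam path length to the
#' lamella-normal thickness. Non-positive pixels are flagged `NA` and
#' excluded from the mask rather than propagated.
#'
#' @param pair An [eftem_pair()].
#' @param tilt_correct Apply the pre-tilt path-length correction
#'   (default `TRUE`).
#' @return A [thickness_map()] (method `"eftem"`). Baseline-corrected
#'   values on the vacuum region average zero; slightly negative
#'   noise-driven vacuum pixels are kept (masked valid) to preserve the
#'   zero mean, with the raw map in `metadata$baseline_nm`.
#' @export
eftem_thickness_map <- function(pair, tilt_correct = TRUE) {
  stopifnot(inherits(pair, "eftem_pair"))
  I0 <- pair$unfiltered
  I <- pair$zero_loss
  ok <- is.finite(I0) & is.finite(I) & I0 > 0 & I > 0
  t <- matrix(NA_real_, nrow(I0), ncol(I0))
  t[ok] <- pair$params$lambda_inel_nm * log(I0[ok] / I[ok])
  vac <- pair$vacuum_roi & ok
  if (!any(vac)) stop("no usable vacuum pixels for baseline", call. = FALSE)
  baseline <- mean(t[vac])
  t <- t - baseline
  if (tilt_correct) t <- t / cos(pair$params$pre_tilt_deg * pi / 180)
  map <- structure(list(
    values_nm = t,
    pixel_size_um = pair$params$pixel_size_nm / 1000,
    mask = ok,
    method = "eftem",
    metadata = list(lambda_inel_nm = pair$params$lambda_inel_nm,
                    pre_tilt_deg = pair$params$pre_tilt_deg,
                    tilt_corrected = tilt_correct,
                    baseline_nm = baseline)),
    class = "thickness_map")
  map
}

# Block-average a matrix by an integer factor (trailing partial blocks
# are dropped); thickness is a local mean quantity, so block means are
# the appropriate down-sampling for cross-method comparison.
block_mean <- function(m, factor) {
  stopifnot(factor >= 1L)
  if (factor == 1L) return(m)
  nr <- floor(nrow(m) / factor) * factor
  nc <- floor(ncol(m) / factor) * factor
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  rowgrp <- (seq_len(nr) - 1L) %/% factor
  colgrp <- (seq_len(nc) - 1L) %/% factor
  out <- rowsum(m, rowgrp, reorder = TRUE)
  out <- t(rowsum(t(out), colgrp, reorder = TRUE))
  out / factor^2
}

#' Quantitative comparison of two registered thickness maps
#'
#' Resamples the finer map to the coarser grid by block averaging, then
#' reports difference statistics over a region of interest plus the mean
#' line profiles of both maps along each axis. The maps must already be
#' registered onto a common physical origin.
#'
#' @param map_a,map_b [thickness_map()] objects (or plain matrices with
#'   equal pixel size).
#' @param roi Optional logical matrix on the coarser grid; defaults to
#'   pixels valid in both maps.
#' @return A list with `mean_diff_nm`, `sd_diff_nm`, `n`, and
#'   `profile_x` / `profile_y` data.frames of per-axis mean thickness for
#'   both maps. Differences are `a - b`.
#' @export
compare_maps <- function(map_a, map_b, roi = NULL) {
  va <- if (inherits(map_a, "thickness_map")) map_a$values_nm else map_a
  vb <- if (inherits(map_b, "thickness_map")) map_b$values_nm else map_b
  pa <- if (inherits(map_a, "thickness_map")) map_a$pixel_size_um else NA_real_
  pb <- if (inherits(map_b, "thickness_map")) map_b$pixel_size_um else NA_real_

  if (is.finite(pa) && is.finite(pb) && pa != pb) {
    if (pa < pb) {
      f <- pb / pa
      if (abs(f - round(f)) > 1e-6) {
        stop("pixel sizes are not integer multiples; resample externally",
             call. = FALSE)
      }
      va <- block_mean(va, as.integer(round(f)))
    } else {
      f <- pa / pb
      if (abs(f - round(f)) > 1e-6) {
        stop("pixel sizes are not integer multiples; resample externally",
             call. = FALSE)
      }
      vb <- block_mean(vb, as.integer(round(f)))
    }
  }
  nr <- min(nrow(va), nrow(vb)); nc <- min(ncol(va), ncol(vb))
  va <- va[seq_len(nr), seq_len(nc), drop = FALSE]
  vb <- vb[seq_len(nr), seq_len(nc), drop = FALSE]
  if (is.null(roi)) roi <- is.finite(va) & is.finite(vb)
  else roi <- roi[seq_len(nr), seq_len(nc), drop = FALSE] &
      is.finite(va) & is.finite(vb)
  if (!any(roi)) stop("empty region of interest", call. = FALSE)

  d <- (va - vb)[roi]
  va_roi <- va; va_roi[!roi] <- NA
  vb_roi <- vb; vb_roi[!roi] <- NA
  list(
    mean_diff_nm = mean(d),
    sd_diff_nm = stats::sd(d),
    n = sum(roi),
    profile_y = data.frame(index = seq_len(nr),
                           a = rowMeans(va_roi, na.rm = TRUE),
                           b = rowMeans(vb_roi, na.rm = TRUE)),
    profile_x = data.frame(index = seq_len(nc),
                           a = colMeans(va_roi, na.rm = TRUE),
                           b = colMeans(vb_roi, na.rm = TRUE))
  )
}
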