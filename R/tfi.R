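#' Refractive index of amorphous (vitreous) ice
#'
#' Bilinear interpolation of the packaged dispersion table of `n2`
#' versus wavelength and temperature for amorphous solid water. The
#' packaged table (`inst/extdata/asw_refractive_index_synthetic.csv`) is a
#' synthetic Cauchy-model stand-in, `n = A(T) + B/lambda^2`, anchored at
#' the measured value n2 = 1.28 at 109 K in the mid-visible; supply your
#' own table for quantitative dispersion work.
#'
#' @param wavelength_nm Wavelength(s) in nm (tabulated 400-700).
#' @param temperature_K Temperature in K (tabulated 100-140; default 109).
#' @param table Optional replacement table: a data.frame with columns
#'   `wavelength_nm`, `temperature_K`, `n2` on a full rectangular grid.
#' @return Numeric vector of refractive indices. Queries outside the
#'   tabulated range are clamped to the nearest edge and flagged via the
#'   logical attribute `extrapolated` (with a warning).
#' @export
#' @examples
#' refractive_index_ice(550, 109)  # 1.28
refractive_index_ice <- function(wavelength_nm, temperature_K = 109,
                                 table = NULL) {
  if (is.null(table)) table <- asw_dispersion_table()
  lam <- sort(unique(table$wavelength_nm))
  tk <- sort(unique(table$temperature_K))
  nmat <- matrix(NA_real_, length(lam), length(tk))
  nmat[cbind(match(table$wavelength_nm, lam),
             match(table$temperature_K, tk))] <- table$n2
  if (anyNA(nmat)) stop("dispersion table is not a full grid", call. = FALSE)

  k <- max(length(wavelength_nm), length(temperature_K))
  wl <- rep_len(wavelength_nm, k)
  tq <- rep_len(temperature_K, k)
  extrap <- wl < min(lam) | wl > max(lam) | tq < min(tk) | tq > max(tk)
  if (any(extrap)) {
    warning("query outside tabulated dispersion range; clamped to edge",
            call. = FALSE)
  }
  wl <- pmin(pmax(wl, min(lam)), max(lam))
  tq <- pmin(pmax(tq, min(tk)), max(tk))

  il <- pmax(1L, pmin(findInterval(wl, lam), length(lam) - 1L))
  it <- pmax(1L, pmin(findInterval(tq, tk), length(tk) - 1L))
  fx <- (wl - lam[il]) / (lam[il + 1L] - lam[il])
  fy <- (tq - tk[it]) / (tk[it + 1L] - tk[it])
  n <- (1 - fx) * (1 - fy) * nmat[cbind(il, it)] +
    fx * (1 - fy) * nmat[cbind(il + 1L, it)] +
    (1 - fx) * fy * nmat[cbind(il, it + 1L)] +
    fx * fy * nmat[cbind(il + 1L, it + 1L)]
  attr(n, "extrapolated") <- extrap
  n
}

asw_dispersion_table <- function() {
  path <- system.file("extdata", "asw_refractive_index_synthetic.csv",
                      package = "lamellometer", mustWork = TRUE)
  utils::read.csv(path)
}

#' Thin-film interference reflectivity model parameters
#'
#' The reflected intensity of a thin lamella of thickness `d` oscillates
#' with the interference phase `4 pi d n2 / lambda + pi` (the pi offset
#' encodes the phase jump at the vacuum-ice interface) under a decaying
#' envelope with length scale `L_nm` accounting for scattering and
#' coherence loss:
#' \deqn{r(d) = r_{mea} + r_A \, e(d/L) \cos(4\pi d n_2/\lambda + \pi)}
#' with envelope `e(x) = exp(-x)` (default) or `exp(-x^2)`.
#'
#' @param r_mea Mean reflectivity constant (intensity units, default 1).
#' @param r_A Oscillation amplitude constant (default 0.5, non-negative).
#' @param L_nm Coherence/scattering decay length in nm (default 500).
#' @param wavelength_nm Illumination wavelength (default 463).
#' @param temperature_K Specimen temperature (default 109 K).
#' @param n2 Refractive index of the film; looked up from the dispersion
#'   table when `NULL`.
#' @param envelope `"exponential"` (default) or `"gaussian"`.
#' @return An object of class `tfi_params`.
#' @export
tfi_params <- function(r_mea = 1, r_A = 0.5, L_nm = 500,
                       wavelength_nm = 463, temperature_K = 109,
                       n2 = NULL,
                       envelope = c("exponential", "gaussian")) {
  envelope <- match.arg(envelope)
  stopifnot(L_nm > 0, r_A >= 0)
  if (is.null(n2)) {
    n2 <- as.numeric(refractive_index_ice(wavelength_nm, temperature_K))
  }
  if (n2 <= 1) stop("n2 must exceed 1", call. = FALSE)
  structure(list(r_mea = r_mea, r_A = r_A, L_nm = L_nm,
                 wavelength_nm = wavelength_nm, temperature_K = temperature_K,
                 n2 = n2, envelope = envelope),
            class = "tfi_params")
}

#' Interference oscillation period in thickness
#'
#' Successive reflectivity extrema are spaced `lambda / (2 n2)` apart.
#'
#' @param params A [tfi_params()] object.
#' @return Period in nm.
#' @export
tfi_period <- function(params) {
  stopifnot(inherits(params, "tfi_params"))
  params$wavelength_nm / (2 * params$n2)
}

#' Model reflectivity of a thin film
#'
#' @param d_nm Film thickness(es) in nm, non-negative.
#' @param params A [tfi_params()] object.
#' @return Reflected intensity (same units as `r_mea`, `r_A`).
#' @export
#' @examples
#' p <- tfi_params()
#' reflectivity(0, p)  # r_mea - r_A
reflectivity <- function(d_nm, params) {
  stopifnot(inherits(params, "tfi_params"))
  if (any(d_nm < 0)) stop("d_nm must be non-negative", call. = FALSE)
  x <- d_nm / params$L_nm
  env <- switch(params$envelope,
                exponential = exp(-x),
                gaussian = exp(-x^2))
  params$r_mea + params$r_A * env *
    cos(4 * pi * d_nm * params$n2 / params$wavelength_nm + pi)
}

minmax_norm <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Fit the thickness offset of a constant-rate thinning intensity trace
#'
#' During even thinning at a known rate, timestamps map to thickness
#' decrements; only the global thickness offset (the final thickness at
#' the last frame) is unknown. It is found by minimising the squared
#' error between the min-max-normalised intensity trace and the equally
#' normalised reflectivity model. Normalisation makes the fit invariant
#' to affine intensity transforms, so `r_mea` and `r_A` need not be known.
#'
#' With the exponential envelope the normalised model is almost exactly
#' self-similar under offset shifts of one oscillation period
#' `P = lambda/(2 n2)`: only the truncated part-periods at the trace ends
#' distinguish branches, so with noisy data the global minimum can land
#' an integer number of periods off. Restrict `d_offset_search_nm` to a
#' window narrower than `P` around the geometric thickness estimate (the
#' workflow's branch anchor) for reliable absolute offsets; the Gaussian
#' envelope decays non-uniformly and resolves the branch globally.
#'
#' @param intensity Reflected intensity trace (one value per frame).
#' @param timestamps_s Acquisition times (s), strictly increasing.
#' @param mill_rate_nm_s Thinning rate (nm/s), positive.
#' @param params A [tfi_params()] object.
#' @param d_offset_search_nm Two-element search interval for the offset
#'   (nm), default `c(0, 2000)`.
#' @param grid_nm Offset grid step for the global pre-scan (default 1 nm),
#'   followed by local refinement.
#' @return List with `offset_nm`, `d_nm` (per-frame thickness), `residual`
#'   (sum of squared normalised errors) and `converged`.
#' @export
fit_trace <- function(intensity, timestamps_s, mill_rate_nm_s, params,
                      d_offset_search_nm = c(0, 2000), grid_nm = 1) {
  stopifnot(length(intensity) == length(timestamps_s),
            mill_rate_nm_s > 0, length(d_offset_search_nm) == 2L)
  if (any(diff(timestamps_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  span_nm <- mill_rate_nm_s * (max(timestamps_s) - min(timestamps_s))
  if (span_nm < tfi_period(params)) {
    stop("ambiguous offset: trace covers less than one oscillation period (",
         round(span_nm, 1), " nm < ", round(tfi_period(params), 1), " nm)",
         call. = FALSE)
  }
  if (stats::sd(intensity) == 0) {
    stop("ambiguous offset: constant intensity trace", call. = FALSE)
  }
  v <- minmax_norm(intensity)
  decrement <- mill_rate_nm_s * (max(timestamps_s) - timestamps_s)
  sse <- function(offset) {
    m <- reflectivity(offset + decrement, params)
    sum((v - minmax_norm(m))^2)
  }
  offs <- seq(d_offset_search_nm[1L], d_offset_search_nm[2L], by = grid_nm)
  vals <- vapply(offs, sse, numeric(1L))
  i0 <- which.min(vals)
  lo <- offs[max(1L, i0 - 1L)]; hi <- offs[min(length(offs), i0 + 1L)]
  opt <- if (hi > lo) stats::optimize(sse, c(lo, hi)) else
    list(minimum = offs[i0], objective = vals[i0])
  list(offset_nm = opt$minimum,
       d_nm = opt$minimum + decrement,
       residual = opt$objective,
       converged = TRUE)
}

#' Per-pixel normalisation state from an observed milling series
#'
#' The per-pixel minimum and maximum intensity over the frames of a
#' milling series estimate the local oscillation envelope, which is the
#' normalisation [fit_thickness_map()] expects.
#'
#' @param frames List of intensity matrices (or an [rlm_series()]).
#' @return List with matrices `lo` and `hi`.
#' @export
series_norm_range <- function(frames) {
  if (inherits(frames, "rlm_series")) frames <- frames$frames
  stopifnot(is.list(frames), length(frames) >= 2L)
  lo <- hi <- frames[[1L]]
  for (f in frames[-1L]) {
    lo <- pmin(lo, f); hi <- pmax(hi, f)
  }
  list(lo = lo, hi = hi)
}

# Row-wise range over the columns of a matrix, as a two-column matrix.
row_range <- function(m) {
  lo <- m[, 1L]; hi <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) {
    lo <- pmin(lo, m[, j]); hi <- pmax(hi, m[, j])
  }
  cbind(lo, hi)
}

#' Refine a thickness map by per-pixel interference fitting
#'
#' For every masked pixel, the squared error between the normalised
#' intensity and the normalised reflectivity model is minimised over one
#' interference branch, `d` in `[init - P/2, init + P/2]` with
#' `P = lambda/(2 n2)`, using the geometric estimate as the branch
#' anchor. The model is min-max normalised over the searched interval, so
#' the fit is insensitive to `r_mea`, `r_A` and to affine transforms of
#' the data. An initial estimate one full period off yields a result one
#' period off: branch selection is the geometric estimate's job.
#'
#' @param frame Numeric matrix of reflected intensities.
#' @param init_map Initial thickness estimate (nm): matrix or
#'   [thickness_map()], typically from the geometric method.
#' @param params A [tfi_params()] object.
#' @param mask Logical matrix of pixels to fit (default: all pixels with
#'   a finite initial estimate).
#' @param norm_lo,norm_hi Per-pixel intensity bounds (matrices) from the
#'   observed milling series, mapping `frame` to [0, 1]. If omitted,
#'   `frame` is assumed already normalised to [0, 1].
#' @param step_nm Grid step of the per-branch pre-scan (default 0.5 nm),
#'   followed by parabolic sub-grid refinement.
#' @param max_fit_nm Interference fitting is only attempted where the
#'   initial estimate is below this thickness (default 1500 nm, where a
#'   region of constant thickness shows clean interference); thicker
#'   pixels keep their initial value and are flagged.
#' @return A [thickness_map()] (method `"tfi"`) whose metadata carries the
#'   per-pixel `residual` matrix, a `flag` matrix (`"ok"`, `"no_init"`,
#'   `"above_validity"`, `"unmasked"`) and the fit parameters.
#' @export
fit_thickness_map <- function(frame, init_map, params, mask = NULL,
                              norm_lo = NULL, norm_hi = NULL,
                              step_nm = 0.5, max_fit_nm = 1500) {
  stopifnot(is.matrix(frame), inherits(params, "tfi_params"))
  init <- if (inherits(init_map, "thickness_map")) init_map$values_nm else init_map
  stopifnot(is.matrix(init), identical(dim(init), dim(frame)))
  if (is.null(mask)) mask <- is.finite(init)
  stopifnot(identical(dim(mask), dim(frame)))

  v <- frame
  if (!is.null(norm_lo)) {
    stopifnot(!is.null(norm_hi), identical(dim(norm_lo), dim(frame)),
              identical(dim(norm_hi), dim(frame)))
    v <- (frame - norm_lo) / (norm_hi - norm_lo)
  }

  flag <- matrix("unmasked", nrow(frame), ncol(frame))
  flag[mask] <- "ok"
  flag[mask & !is.finite(init)] <- "no_init"
  flag[mask & is.finite(init) & init > max_fit_nm] <- "above_validity"
  fit_px <- which(flag == "ok")

  out <- matrix(NA_real_, nrow(frame), ncol(frame))
  out[mask & is.finite(init)] <- init[mask & is.finite(init)]
  resid <- matrix(NA_real_, nrow(frame), ncol(frame))

  if (length(fit_px)) {
    P <- tfi_period(params)
    offs <- seq(-P / 2, P / 2, by = step_nm)
    D <- outer(init[fit_px], offs, "+")
    D[D < 0] <- 0
    R <- reflectivity(D, params)
    rr <- row_range(R)
    span <- pmax(rr[, 2L] - rr[, 1L], .Machine$double.eps)
    M <- (R - rr[, 1L]) / span
    obj <- (M - v[fit_px])^2
    # Within one branch the cosine is two-to-one: most intensities are
    # matched on two flanks, giving two near-degenerate minima. Among
    # candidates within `flank_tol` of the best objective, take the one
    # closest to the initial estimate (offset 0) rather than the
    # marginally lowest: the geometric init owns flank selection just as
    # it owns branch selection.
    flank_tol <- 1e-2
    mid <- which.min(abs(offs))
    nb <- length(offs)
    i0 <- vapply(seq_along(fit_px), function(i) {
      o <- obj[i, ]
      is_lmin <- c(o[1L] <= o[2L],
                   o[2:(nb - 1L)] <= o[1:(nb - 2L)] &
                     o[2:(nb - 1L)] <= o[3:nb],
                   o[nb] <= o[nb - 1L])
      cand <- which(is_lmin & o <= min(o) + flank_tol)
      if (!length(cand)) cand <- which.min(o)
      cand[which.min(abs(cand - mid))]
    }, integer(1L))
    d_hat <- D[cbind(seq_along(fit_px), i0)]
    # parabolic refinement where the minimum is interior
    interior <- i0 > 1L & i0 < length(offs)
    if (any(interior)) {
      ii <- which(interior)
      ym <- obj[cbind(ii, i0[ii] - 1L)]
      y0 <- obj[cbind(ii, i0[ii])]
      yp <- obj[cbind(ii, i0[ii] + 1L)]
      den <- ym - 2 * y0 + yp
      shift <- ifelse(den > 0, 0.5 * (ym - yp) / den, 0)
      d_hat[ii] <- d_hat[ii] + pmin(pmax(shift, -1), 1) * step_nm
    }
    d_hat[d_hat < 0] <- 0
    out[fit_px] <- d_hat
    resid[fit_px] <- obj[cbind(seq_along(fit_px), i0)]
  }

  tm <- thickness_map(out,
                      pixel_size_um = if (inherits(init_map, "thickness_map"))
                        init_map$pixel_size_um else NA_real_,
                      mask = mask & is.finite(out),
                      method = "tfi",
                      metadata = list(
                        wavelength_nm = params$wavelength_nm,
                        n2 = params$n2,
                        L_nm = params$L_nm,
                        envelope = params$envelope,
                        step_nm = step_nm,
                        max_fit_nm = max_fit_nm))
  tm$residual <- resid
  tm$flag <- flag
  tm$uniformity_sigma_nm <- uniformity_sigma(tm)
  tm
}

#' Fit a time series of thickness maps with optional monotonicity
#'
#' Applies [fit_thickness_map()] to each frame; with
#' `enforce_monotone = TRUE`, each fitted map is clipped from above by the
#' previous one (milling only removes material).
#'
#' @param frames List of intensity matrices, in acquisition order.
#' @param init_maps List of initial estimates (recycled if length one).
#' @param params A [tfi_params()] object.
#' @param enforce_monotone Clip per-pixel thickness to be non-increasing
#'   across frames (default `TRUE`).
#' @param ... Passed on to [fit_thickness_map()].
#' @return List of [thickness_map()] objects.
#' @export
fit_map_series <- function(frames, init_maps, params,
                           enforce_monotone = TRUE, ...) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  if (!is.list(init_maps)) init_maps <- list(init_maps)
  init_maps <- rep_len(init_maps, length(frames))
  maps <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    maps[[i]] <- fit_thickness_map(frames[[i]], init_maps[[i]], params, ...)
    if (enforce_monotone && i > 1L) {
      prev <- maps[[i - 1L]]$values_nm
      cur <- maps[[i]]$values_nm
      both <- is.finite(prev) & is.finite(cur)
      cur[both] <- pmin(cur[both], prev[both])
      maps[[i]]$values_nm <- cur
    }
  }
  maps
}

#' Thickness uniformity (one standard deviation)
#'
#' Population standard deviation of the thickness over a region of
#' interest, the quantity quoted as lamella uniformity.
#'
#' @param map A [thickness_map()] or numeric matrix (nm).
#' @param roi Optional logical matrix selecting the region; defaults to
#'   the map's validity mask (or all finite pixels).
#' @return Standard deviation in nm.
#' @export
uniformity_sigma <- function(map, roi = NULL) {
  vals <- if (inherits(map, "thickness_map")) map$values_nm else map
  if (is.null(roi)) {
    roi <- if (inherits(map, "thickness_map") && !is.null(map$mask))
      map$mask else is.finite(vals)
  }
  x <- vals[roi]
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("empty region of interest", call. = FALSE)
  sqrt(mean((x - mean(x))^2))
}
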