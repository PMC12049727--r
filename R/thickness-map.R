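#' 2D lamella thickness map
#'
#' Common container returned by all four measurement methods.
#'
#' @param values_nm Numeric matrix of thickness values (nm).
#' @param pixel_size_um Physical pixel size (um/px).
#' @param mask Logical validity matrix (default: finite values).
#' @param method One of `"geometric"`, `"tfi"`, `"q4stem"`, `"eftem"`,
#'   `"synthetic"`.
#' @param metadata Named list of parameter provenance.
#' @return An object of class `thickness_map`.
#' @export
thickness_map <- function(values_nm, pixel_size_um, mask = NULL,
                          method = c("geometric", "tfi", "q4stem", "eftem",
                                     "synthetic"),
                          metadata = list()) {
  stopifnot(is.matrix(values_nm), is.numeric(values_nm))
  method <- match.arg(method)
  if (is.null(mask)) mask <- is.finite(values_nm)
  stopifnot(is.logical(mask), identical(dim(mask), dim(values_nm)))
  if (any(values_nm[mask] < 0, na.rm = TRUE)) {
    stop("thickness must be non-negative where the mask is valid",
         call. = FALSE)
  }
  if (!is.na(pixel_size_um) && pixel_size_um <= 0) {
    stop("pixel_size_um must be positive", call. = FALSE)
  }
  structure(list(values_nm = values_nm, pixel_size_um = pixel_size_um,
                 mask = mask, method = method, metadata = metadata),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- x$values_nm[x$mask]
  cat(sprintf("Thickness map (%s): %d x %d px @ %s um/px\n",
              x$method, nrow(x$values_nm), ncol(x$values_nm),
              format(x$pixel_size_um)))
  if (length(v)) {
    cat(sprintf("  valid px: %d  mean %.1f nm  sd %.2f nm  range [%.1f, %.1f]\n",
                length(v), mean(v), stats::sd(v), min(v), max(v)))
  }
  invisible(x)
}

#' Write a thickness map as float TIFF plus JSON sidecar
#'
#' Values are stored as 32-bit float TIFF (scaled to [0, 1] by the
#' maximum, which the sidecar records) with the validity mask as a second
#' page; pixel size, method and metadata go into `<path>.json`.
#'
#' @param map A [thickness_map()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_thickness_map <- function(map, path) {
  stopifnot(inherits(map, "thickness_map"))
  vals <- map$values_nm
  vals[!is.finite(vals)] <- 0
  offset <- min(vals, 0)
  scale <- max(max(vals) - offset, 1e-12)
  tiff::writeTIFF(list((vals - offset) / scale,
                       matrix(as.numeric(map$mask), nrow(vals), ncol(vals))),
                  path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(
    format = "lamellometer.thickness_map",
    scale_nm = scale,
    offset_nm = offset,
    pixel_size_um = map$pixel_size_um,
    method = map$method,
    metadata = map$metadata
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a thickness map written by [write_thickness_map()]
#'
#' A missing or corrupted sidecar degrades gracefully: the values still
#' load (unscaled) with a provenance warning.
#'
#' @param path TIFF path.
#' @return A [thickness_map()].
#' @export
read_thickness_map <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  vals <- pages[[1L]]
  mask <- if (length(pages) >= 2L) pages[[2L]] > 0.5 else NULL
  sidecar <- if (file.exists(paste0(path, ".json"))) {
    tryCatch(jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE),
             error = function(e) NULL)
  }
  if (is.null(sidecar) ||
      !identical(sidecar$format, "lamellometer.thickness_map")) {
    warning("missing or corrupted sidecar for ", path,
            ": provenance unavailable, values loaded unscaled",
            call. = FALSE)
    sidecar <- list(scale_nm = 1, offset_nm = 0, pixel_size_um = NA_real_,
                    method = "synthetic", metadata = list())
  }
  off <- if (is.numeric(sidecar$offset_nm)) sidecar$offset_nm else 0
  vals <- vals * sidecar$scale_nm + off
  if (is.null(mask)) mask <- is.finite(vals)
  vals[!mask] <- NA_real_
  md <- sidecar$metadata
  if (is.null(md)) md <- list()
  # construct directly: stored maps may legitimately carry slightly
  # negative baseline-corrected values (e.g. EFTEM vacuum noise)
  structure(list(values_nm = vals,
                 pixel_size_um = sidecar$pixel_size_um,
                 mask = mask,
                 method = sidecar$method,
                 metadata = as.list(md)),
            class = "thickness_map")
}
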