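#' Read a TIFF / OME-TIFF image stack with metadata
#'
#' Frames are returned as numeric matrices. Pixel size and timestamps are
#' taken, in order of precedence, from the function arguments, from a
#' `<path>.json` sidecar written by [write_stack()], or from an OME-XML
#' `PhysicalSizeX` attribute in the TIFF ImageDescription. A stack with no
#' resolvable pixel size is an error: thickness estimation is meaningless
#' without it.
#'
#' @param path TIFF file path.
#' @param pixel_size_um Optional override for the pixel size (um/px).
#' @param timestamps_s Optional override for per-frame acquisition times.
#' @return A list with `frames` (list of matrices), `pixel_size_um` and
#'   `timestamps_s` (NULL when unknown).
#' @export
read_stack <- function(path, pixel_size_um = NULL, timestamps_s = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop("unreadable TIFF stack: ", conditionMessage(e),
                           call. = FALSE))
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first channel of RGB(A)
    attributes(p) <- list(dim = dim(p))       # drop TIFF tag attributes
    p
  })
  shp <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1L)))) {
    stop("mixed-shape TIFF stack", call. = FALSE)
  }

  sidecar <- if (file.exists(paste0(path, ".json"))) {
    tryCatch(jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE),
             error = function(e) NULL)
  }
  if (identical(sidecar$format, "lamellometer.stack") &&
      is.numeric(sidecar$scale)) {
    off <- if (is.numeric(sidecar$offset)) sidecar$offset else 0
    frames <- lapply(frames, function(f) f * sidecar$scale + off)
  }
  if (is.null(pixel_size_um)) pixel_size_um <- sidecar$pixel_size_um
  if (is.null(timestamps_s)) timestamps_s <- sidecar$timestamps_s
  if (is.null(pixel_size_um)) {
    desc <- attr(pages[[1L]], "description")
    if (!is.null(desc)) {
      m <- regmatches(desc, regexec('PhysicalSizeX="([0-9.eE+-]+)"', desc))[[1L]]
      if (length(m) == 2L) pixel_size_um <- as.numeric(m[2L])
    }
  }
  if (is.null(pixel_size_um) || is.na(pixel_size_um)) {
    stop("pixel size not found in metadata; pass pixel_size_um explicitly",
         call. = FALSE)
  }
  list(frames = frames, pixel_size_um = pixel_size_um,
       timestamps_s = timestamps_s)
}

#' Write an image stack with a JSON metadata sidecar
#'
#' Intensities are stored as 32-bit float TIFF scaled by the stack
#' maximum (recorded in the sidecar along with pixel size and
#' timestamps), so [read_stack()] round-trips physical values.
#'
#' @param frames List of numeric matrices (or a single matrix).
#' @param path Output TIFF path.
#' @param pixel_size_um Pixel size (um/px).
#' @param timestamps_s Optional per-frame times (s).
#' @param extra Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path, pixel_size_um, timestamps_s = NULL,
                        extra = list()) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1L, pixel_size_um > 0)
  offset <- min(vapply(frames, min, numeric(1L)), 0)
  scale <- max(max(vapply(frames, max, numeric(1L))) - offset, 1e-12)
  tiff::writeTIFF(lapply(frames, function(f) (f - offset) / scale), path,
                  bits.per.sample = 32L, reduce = FALSE)
  sidecar <- c(list(format = "lamellometer.stack",
                    scale = scale,
                    offset = offset,
                    pixel_size_um = pixel_size_um,
                    timestamps_s = timestamps_s),
               extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a run configuration from a YAML file
#'
#' Known top-level groups are `optics`, `rlm`, `tfi`, `q4stem`, `eftem`,
#' `synth`, `io` plus scalar `seed`; unknown keys are rejected to catch
#' typos early.
#'
#' @param path YAML file path.
#' @return Named list of configuration groups.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("optics", "rlm", "tfi", "q4stem", "eftem", "synth", "io", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg
}
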