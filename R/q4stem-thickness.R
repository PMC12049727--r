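#' Lamella thickness from a scattering pattern via table lookup
#'
#' Computes the radial profile and DF/BF ratio of the pattern, inverts
#' the Monte-Carlo table by monotone interpolation (ratio to beam path
#' length), and projects the path length onto the lamella normal with the
#' cosine of the beam's angle of incidence.
#'
#' @param pattern A [scatter_pattern()].
#' @param table An `mc_table` from [build_table()].
#' @param incidence_deg Beam incidence from the lamella normal
#'   (default 52 degrees); 0 means the path length is the thickness.
#' @param n_bins Radial bins for the profile (default 64).
#' @return A list with `d_nm`, `path_nm`, `df_bf_ratio`,
#'   `most_common_angle_mrad` (measured) and
#'   `table_most_common_angle_mrad` (interpolated from the table at the
#'   recovered path length, as a consistency check).
#' @export
thickness_from_pattern <- function(pattern, table, incidence_deg = 52,
                                   n_bins = 64) {
  stopifnot(inherits(pattern, "scatter_pattern"), inherits(table, "mc_table"))
  prof <- radial_profile(pattern, n_bins = n_bins,
                         bf_cutoff_mrad = table$bf_cutoff_mrad)
  ratio <- df_bf_ratio(prof)
  ratio_to_thickness(ratio, table, incidence_deg,
                     most_common_angle_mrad =
                       suppressWarnings(as.numeric(most_common_angle(prof))))
}

# Shared inversion: DF/BF ratio -> path length -> tilt-corrected thickness.
ratio_to_thickness <- function(ratio, table, incidence_deg,
                               most_common_angle_mrad = NA_real_) {
  rng <- range(table$df_bf_ratio)
  if (ratio < rng[1L] || ratio > rng[2L]) {
    stop(sprintf(
      "DF/BF ratio %.3g outside table range [%.3g, %.3g]: lamella too %s for this table",
      ratio, rng[1L], rng[2L], if (ratio > rng[2L]) "thick" else "thin"),
      call. = FALSE)
  }
  path <- stats::approx(table$df_bf_ratio, table$thickness_nm,
                        xout = ratio, ties = "ordered")$y
  mca_tab <- stats::approx(table$thickness_nm, table$most_common_angle_mrad,
                           xout = path, ties = "ordered")$y
  list(d_nm = path * cos(incidence_deg * pi / 180),
       path_nm = path,
       df_bf_ratio = ratio,
       incidence_deg = incidence_deg,
       most_common_angle_mrad = most_common_angle_mrad,
       table_most_common_angle_mrad = mca_tab)
}

#' Thickness along a scan of scattering patterns
#'
#' Applies [thickness_from_pattern()] to an ordered list of patterns
#' (a line scan or an unrolled map). Per-pattern failures (ratio outside
#' the table range, beam not captured) become flags, not dropped rows.
#'
#' @param patterns Non-empty list of [scatter_pattern()] objects sharing
#'   the detector geometry.
#' @param table An `mc_table`.
#' @param incidence_deg Beam incidence from the lamella normal (default 52).
#' @param ... Passed on to [thickness_from_pattern()].
#' @return A data.frame with one row per pattern: `position`, `d_nm`,
#'   `path_nm`, `df_bf_ratio`, `flag`.
#' @export
thickness_line_scan <- function(patterns, table, incidence_deg = 52, ...) {
  if (!is.list(patterns) || length(patterns) == 0L) {
    stop("empty pattern list", call. = FALSE)
  }
  n <- length(patterns)
  d <- path <- ratio <- rep(NA_real_, n)
  flag <- character(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      thickness_from_pattern(patterns[[i]], table, incidence_deg, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      flag[i] <- conditionMessage(res)
    } else {
      d[i] <- res$d_nm; path[i] <- res$path_nm; ratio[i] <- res$df_bf_ratio
      flag[i] <- "ok"
    }
  }
  data.frame(position = seq_len(n), d_nm = d, path_nm = path,
             df_bf_ratio = ratio, flag = flag)
}
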