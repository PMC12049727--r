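# Monte-Carlo transport of keV electrons through an amorphous-H2O slab.
#
# Physics model (CASINO-like, desk scale):
#  * elastic scattering: screened Rutherford cross-section per atom with
#    the conventional screening parameter alpha = 3.4e-3 Z^0.67 / E(keV)
#    and the relativistic correction ((E+511)/(E+1024))^2;
#  * free paths sampled from the exponential distribution of the total
#    elastic cross-section of H2O at the current energy;
#  * continuous slowing-down energy loss between collisions using the
#    Joy-Luo modified Bethe stopping power (valid down to low keV);
#  * no secondary-electron transport, no energy-loss straggling.

ATOMIC <- list(
  Z = c(H = 1, O = 8),
  A = c(H = 1.008, O = 15.999),
  # Berger-Seltzer mean ionisation energies, keV
  J = c(H = 0.0192, O = 0.095)
)
H2O_MOLAR_MASS <- 18.015
AVOGADRO <- 6.02214076e23

#' Screened Rutherford elastic cross-section per atom
#'
#' @param Z Atomic number.
#' @param E_keV Electron energy in keV.
#' @return Cross-section in cm^2.
#' @export
screened_rutherford_sigma <- function(Z, E_keV) {
  a <- screening_parameter(Z, E_keV)
  5.21e-21 * Z^2 / E_keV^2 * 4 * pi / (a * (1 + a)) *
    ((E_keV + 511) / (E_keV + 1024))^2
}

# conventional screening parameter
screening_parameter <- function(Z, E_keV) {
  3.4e-3 * Z^0.67 / E_keV
}

#' Elastic mean free path of electrons in amorphous ice
#'
#' @param E_keV Electron energy (keV).
#' @param density_g_cm3 Mass density of the amorphous ice
#'   (default 0.94 g/cm^3).
#' @return Mean free path in nm.
#' @export
elastic_mfp_nm <- function(E_keV, density_g_cm3 = 0.94) {
  n_mol <- density_g_cm3 / H2O_MOLAR_MASS * AVOGADRO  # molecules / cm^3
  sigma <- screened_rutherford_sigma(8, E_keV) +
    2 * screened_rutherford_sigma(1, E_keV)
  1e7 / (n_mol * sigma)
}

#' Electron stopping power in amorphous ice (Joy-Luo modified Bethe)
#'
#' @inheritParams elastic_mfp_nm
#' @return Stopping power in keV/nm.
#' @export
stopping_power_keV_nm <- function(E_keV, density_g_cm3 = 0.94) {
  Z <- ATOMIC$Z; A <- ATOMIC$A; J <- ATOMIC$J
  Cw <- c(H = 2 * A[["H"]] / H2O_MOLAR_MASS,
          O = A[["O"]] / H2O_MOLAR_MASS)
  k <- 0.731 + 0.0688 * log10(Z)
  s <- 0
  for (el in names(Z)) {
    s <- s + Cw[[el]] * Z[[el]] / A[[el]] *
      log(1.166 * (E_keV + k[[el]] * J[[el]]) / J[[el]])
  }
  78500 * density_g_cm3 / E_keV * s * 1e-7
}

# Sample a screened-Rutherford polar scattering cosine for screening
# parameter a (vectorised over a and the uniform deviate u).
sample_sr_cosine <- function(a, u) {
  1 - 2 * a * u / (1 + a - u)
}

# Rotate unit direction (u,v,w) by polar angle (ct, st) and azimuth phi.
rotate_direction <- function(u, v, w, ct, st, phi) {
  cphi <- cos(phi); sphi <- sin(phi)
  den <- sqrt(pmax(0, 1 - w^2))
  near_axis <- den < 1e-10
  den[near_axis] <- 1
  un <- u * ct + st * (u * w * cphi - v * sphi) / den
  vn <- v * ct + st * (v * w * cphi + u * sphi) / den
  wn <- w * ct - st * cphi * den
  if (any(near_axis)) {
    un[near_axis] <- st[near_axis] * cphi[near_axis]
    vn[near_axis] <- st[near_axis] * sphi[near_axis]
    wn[near_axis] <- sign(w[near_axis]) * ct[near_axis]
  }
  nrm <- sqrt(un^2 + vn^2 + wn^2)
  cbind(un / nrm, vn / nrm, wn / nrm)
}

#' Monte-Carlo electron transport through an amorphous-ice slab
#'
#' Simulates `n_electrons` electrons normally incident on a slab of
#' amorphous H2O, with single elastic scattering events (screened
#' Rutherford) separated by exponentially sampled free paths and
#' continuous slowing-down energy loss deposited along each segment (at
#' the segment midpoint radius). Electrons are followed until they exit
#' the slab (transmitted or backscattered) or fall below `cutoff_keV`
#' (absorbed; the residual energy is deposited locally). Energy is
#' conserved exactly: incident = transmitted + backscattered + deposited.
#'
#' @param thickness_nm Slab thickness (nm), non-negative.
#' @param beam_energy_keV Primary energy (default 30).
#' @param n_electrons Number of electrons (default 10000).
#' @param seed RNG seed; every stochastic operation takes one explicitly.
#' @param density_g_cm3 Ice density (default 0.94).
#' @param cutoff_keV Tracking cutoff (default 0.5 keV).
#' @return A list of class `mc_result`:
#'   `exit_angle_mrad`, `exit_energy_keV` and `fate`
#'   (`"transmitted"`, `"backscattered"`, `"absorbed"`) per electron;
#'   `n_collisions` per electron; `deposit` as a data.frame
#'   `(r_nm, energy_keV)` of deposition events (radius about the incident
#'   axis); plus the run parameters.
#' @export
mc_simulate <- function(thickness_nm, beam_energy_keV = 30,
                        n_electrons = 10000, seed = 1,
                        density_g_cm3 = 0.94, cutoff_keV = 0.5) {
  stopifnot(thickness_nm >= 0, n_electrons >= 1, beam_energy_keV > cutoff_keV)
  n <- as.integer(n_electrons)
  if (thickness_nm == 0) {
    return(structure(list(
      exit_angle_mrad = rep(0, n),
      exit_energy_keV = rep(beam_energy_keV, n),
      fate = rep("transmitted", n),
      n_collisions = rep(0L, n),
      deposit = data.frame(r_nm = numeric(0), energy_keV = numeric(0)),
      thickness_nm = 0, beam_energy_keV = beam_energy_keV,
      n_electrons = n, seed = seed, density_g_cm3 = density_g_cm3,
      cutoff_keV = cutoff_keV), class = "mc_result"))
  }
  set.seed(seed)

  # element selection probabilities from partial cross-sections; energy
  # dependence of the O:H ratio is negligible over a single run, so the
  # fractions are evaluated at the current mean energy each sweep.
  pos <- matrix(0, n, 3L)
  dir <- cbind(rep(0, n), rep(0, n), rep(1, n))
  E <- rep(beam_energy_keV, n)
  alive <- rep(TRUE, n)
  exit_angle <- rep(NA_real_, n)
  exit_energy <- rep(NA_real_, n)
  fate <- rep(NA_character_, n)
  ncol_ <- rep(0L, n)
  dep_r <- vector("list", 1000L)
  dep_e <- vector("list", 1000L)
  it <- 0L

  while (any(alive)) {
    it <- it + 1L
    if (it > 100000L) stop("transport failed to terminate", call. = FALSE)
    idx <- which(alive)
    m <- length(idx)
    mfp <- elastic_mfp_nm(E[idx], density_g_cm3)
    s <- -mfp * log(stats::runif(m))
    uz <- dir[idx, 3L]
    z_end <- pos[idx, 3L] + s * uz
    frac <- rep(1, m)
    tr <- z_end > thickness_nm
    bs <- z_end < 0
    frac[tr] <- (thickness_nm - pos[idx, 3L][tr]) / (s[tr] * uz[tr])
    frac[bs] <- (0 - pos[idx, 3L][bs]) / (s[bs] * uz[bs])
    path <- s * frac

    dE <- pmin(stopping_power_keV_nm(E[idx], density_g_cm3) * path,
               E[idx])
    mid <- pos[idx, 1:2, drop = FALSE] +
      dir[idx, 1:2, drop = FALSE] * (path / 2)
    dep_r[[it]] <- sqrt(mid[, 1L]^2 + mid[, 2L]^2)
    dep_e[[it]] <- dE
    E[idx] <- E[idx] - dE
    pos[idx, ] <- pos[idx, ] + dir[idx, ] * path

    out <- tr | bs
    oi <- idx[out]
    if (length(oi)) {
      exit_angle[oi] <- acos(pmin(1, pmax(-1, dir[oi, 3L]))) * 1000
      exit_energy[oi] <- E[oi]
      fate[oi] <- ifelse(tr[out], "transmitted", "backscattered")
      alive[oi] <- FALSE
    }
    inside <- idx[!out]
    low <- inside[E[inside] <= cutoff_keV]
    if (length(low)) {
      dep_r[[it]] <- c(dep_r[[it]],
                       sqrt(pos[low, 1L]^2 + pos[low, 2L]^2))
      dep_e[[it]] <- c(dep_e[[it]], E[low])
      E[low] <- 0
      fate[low] <- "absorbed"
      alive[low] <- FALSE
    }

    sv <- inside[alive[inside]]
    if (length(sv)) {
      m2 <- length(sv)
      sig_o <- screened_rutherford_sigma(8, E[sv])
      sig_h <- screened_rutherford_sigma(1, E[sv])
      p_oxygen <- sig_o / (sig_o + 2 * sig_h)
      Zel <- ifelse(stats::runif(m2) < p_oxygen, 8, 1)
      a <- screening_parameter(Zel, E[sv])
      ct <- sample_sr_cosine(a, stats::runif(m2))
      st <- sqrt(pmax(0, 1 - ct^2))
      phi <- stats::runif(m2) * 2 * pi
      dir[sv, ] <- rotate_direction(dir[sv, 1L], dir[sv, 2L], dir[sv, 3L],
                                    ct, st, phi)
      ncol_[sv] <- ncol_[sv] + 1L
    }
    if (it %% 1000L == 0L) {  # keep the deposit accumulators bounded
      dep_r <- c(list(unlist(dep_r)), vector("list", 1000L))
      dep_e <- c(list(unlist(dep_e)), vector("list", 1000L))
      it <- 1L
    }
  }

  structure(list(
    exit_angle_mrad = exit_angle,
    exit_energy_keV = exit_energy,
    fate = fate,
    n_collisions = ncol_,
    deposit = data.frame(r_nm = unlist(dep_r), energy_keV = unlist(dep_e)),
    thickness_nm = thickness_nm, beam_energy_keV = beam_energy_keV,
    n_electrons = n, seed = seed, density_g_cm3 = density_g_cm3,
    cutoff_keV = cutoff_keV), class = "mc_result")
}

#' Radius enclosing a given fraction of the deposited energy
#'
#' @param mc An `mc_result` from [mc_simulate()].
#' @param fraction Energy fraction to enclose (default 0.95).
#' @return Radius in nm about the incident beam axis.
#' @export
energy_containment_radius <- function(mc, fraction = 0.95) {
  stopifnot(inherits(mc, "mc_result"), fraction > 0, fraction <= 1)
  if (nrow(mc$deposit) == 0L) return(0)
  o <- order(mc$deposit$r_nm)
  cs <- cumsum(mc$deposit$energy_keV[o]) / sum(mc$deposit$energy_keV)
  mc$deposit$r_nm[o][which(cs >= fraction)[1L]]
}

#' Energy bookkeeping of a Monte-Carlo run
#'
#' @param mc An `mc_result`.
#' @return Named list with incident, transmitted, backscattered and
#'   deposited energy (keV) and the relative closure error.
#' @export
mc_energy_budget <- function(mc) {
  stopifnot(inherits(mc, "mc_result"))
  incident <- mc$n_electrons * mc$beam_energy_keV
  transmitted <- sum(mc$exit_energy_keV[mc$fate == "transmitted"], na.rm = TRUE)
  backscattered <- sum(mc$exit_energy_keV[mc$fate == "backscattered"],
                       na.rm = TRUE)
  deposited <- sum(mc$deposit$energy_keV)
  list(incident_keV = incident, transmitted_keV = transmitted,
       backscattered_keV = backscattered, deposited_keV = deposited,
       closure_rel = (transmitted + backscattered + deposited - incident) /
         incident)
}

# DF/BF ratio and most common exit angle from simulated exit angles,
# restricted to the detector acceptance.
mc_observables <- function(mc, bf_cutoff_mrad, max_angle_mrad = 218,
                           n_bins = 64) {
  ang <- mc$exit_angle_mrad[mc$fate == "transmitted"]
  ang <- ang[ang <= max_angle_mrad]
  n_bf <- sum(ang <= bf_cutoff_mrad)
  n_df <- sum(ang > bf_cutoff_mrad)
  ratio <- if (n_bf > 0) n_df / n_bf else Inf
  se <- if (n_bf > 0 && n_df > 0) ratio * sqrt(1 / n_df + 1 / n_bf) else NA_real_
  # most common angle via the same solid-angle-corrected histogram used
  # for measured profiles
  width <- max_angle_mrad / n_bins
  bin <- pmin(floor(ang / width) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  prof <- structure(list(angle_mrad = (seq_len(n_bins) - 0.5) * width,
                         intensity = as.numeric(counts),
                         bf_cutoff_mrad = bf_cutoff_mrad,
                         bin_width_mrad = width),
                    class = "radial_profile")
  mca <- if (sum(counts) > 0) most_common_angle(prof) else NA_real_
  list(df_bf_ratio = ratio, ratio_se = se,
       most_common_angle_mrad = as.numeric(mca),
       n_transmitted = length(ang))
}

#' Build a thickness lookup table from Monte-Carlo simulations
#'
#' Simulates each grid thickness and records the DF/BF ratio (within the
#' detector acceptance) and the most common scattering angle. A table
#' whose ratio is not strictly increasing with thickness is rejected:
#' that indicates Monte-Carlo noise too large for lookup inversion.
#'
#' @param thickness_grid_nm Thickness grid (nm), e.g. `seq(50, 1000, 50)`.
#' @param beam_energy_keV Primary energy (default 30).
#' @param n_electrons Electrons per grid point (default 10000).
#' @param seed Base seed; grid point i uses `seed + i`.
#' @param bf_cutoff_mrad Bright-field cutoff (default 60 mrad).
#' @param max_angle_mrad Detector acceptance (default 218 mrad).
#' @param density_g_cm3 Ice density (default 0.94).
#' @return An object of class `mc_table`: data.frame-like list with the
#'   grid, ratios, standard errors and most common angles, plus
#'   provenance (energy, material, n_electrons, seed).
#' @export
build_table <- function(thickness_grid_nm, beam_energy_keV = 30,
                        n_electrons = 10000, seed = 1,
                        bf_cutoff_mrad = 60, max_angle_mrad = 218,
                        density_g_cm3 = 0.94) {
  stopifnot(length(thickness_grid_nm) >= 2L, all(thickness_grid_nm >= 0),
            !is.unsorted(thickness_grid_nm, strictly = TRUE))
  k <- length(thickness_grid_nm)
  ratio <- se <- mca <- numeric(k)
  for (i in seq_len(k)) {
    mc <- mc_simulate(thickness_grid_nm[i], beam_energy_keV, n_electrons,
                      seed = seed + i, density_g_cm3 = density_g_cm3)
    obs <- mc_observables(mc, bf_cutoff_mrad, max_angle_mrad)
    ratio[i] <- obs$df_bf_ratio
    se[i] <- obs$ratio_se
    mca[i] <- obs$most_common_angle_mrad
  }
  if (any(diff(ratio) <= 0)) {
    stop("table rejected: DF/BF ratio not strictly increasing with ",
         "thickness; increase n_electrons or coarsen the grid",
         call. = FALSE)
  }
  structure(list(thickness_nm = thickness_grid_nm,
                 df_bf_ratio = ratio,
                 ratio_se = se,
                 most_common_angle_mrad = mca,
                 beam_energy_keV = beam_energy_keV,
                 material = sprintf("amorphous H2O, %.2f g/cm^3",
                                    density_g_cm3),
                 density_g_cm3 = density_g_cm3,
                 bf_cutoff_mrad = bf_cutoff_mrad,
                 max_angle_mrad = max_angle_mrad,
                 n_electrons = n_electrons,
                 seed = seed),
            class = "mc_table")
}

#' @export
print.mc_table <- function(x, ...) {
  cat(sprintf(
    "MC lookup table: %d thicknesses %g-%g nm, %g keV, %s\n",
    length(x$thickness_nm), min(x$thickness_nm), max(x$thickness_nm),
    x$beam_energy_keV, x$material))
  cat(sprintf("  BF cutoff %g mrad, acceptance %g mrad, %d e-/point, seed %d\n",
              x$bf_cutoff_mrad, x$max_angle_mrad, x$n_electrons, x$seed))
  print(utils::head(data.frame(thickness_nm = x$thickness_nm,
                               df_bf_ratio = x$df_bf_ratio,
                               se = x$ratio_se), 10L))
  invisible(x)
}

#' Write / read a Monte-Carlo lookup table as CSV with metadata header
#'
#' @param table An `mc_table`.
#' @param path CSV path; metadata is stored in `# key: value` header lines.
#' @return `path` (write) or an `mc_table` (read).
#' @export
write_mc_table <- function(table, path) {
  stopifnot(inherits(table, "mc_table"))
  meta <- c(beam_energy_keV = table$beam_energy_keV,
            density_g_cm3 = table$density_g_cm3,
            bf_cutoff_mrad = table$bf_cutoff_mrad,
            max_angle_mrad = table$max_angle_mrad,
            n_electrons = table$n_electrons,
            seed = table$seed)
  hdr <- sprintf("# %s: %s", names(meta), format(meta, scientific = FALSE))
  body <- utils::capture.output(utils::write.csv(
    data.frame(thickness_nm = table$thickness_nm,
               df_bf_ratio = table$df_bf_ratio,
               ratio_se = table$ratio_se,
               most_common_angle_mrad = table$most_common_angle_mrad),
    row.names = FALSE))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_mc_table
#' @param path CSV path.
#' @export
read_mc_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- as.numeric(trimws(sub("^[^:]*:", "", kv)))
  }
  df <- utils::read.csv(text = paste(grep("^#", lines, value = TRUE,
                                          invert = TRUE), collapse = "\n"))
  structure(c(as.list(df),
              list(beam_energy_keV = meta$beam_energy_keV,
                   material = sprintf("amorphous H2O, %.2f g/cm^3",
                                      meta$density_g_cm3),
                   density_g_cm3 = meta$density_g_cm3,
                   bf_cutoff_mrad = meta$bf_cutoff_mrad,
                   max_angle_mrad = meta$max_angle_mrad,
                   n_electrons = as.integer(meta$n_electrons),
                   seed = as.integer(meta$seed))),
            class = "mc_table")
}
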