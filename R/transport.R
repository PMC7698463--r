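#' Simulation configuration
#'
#' @param n_photons number of photons to launch
#' @param weight_threshold Russian-roulette trigger, as a fraction of each
#'   photon's initial weight (default 1e-4)
#' @param roulette_m roulette survival factor m: a sub-threshold photon
#'   survives with probability 1/m at m-fold weight (default 10)
#' @param max_events safety cap on events per photon; photons hitting the
#'   cap are retired into the roulette-killed ledger with a warning counter
#' @param seed integer seed for the run's random-number stream
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_photons = 1e5, weight_threshold = 1e-4,
                       roulette_m = 10L, max_events = 1e6, seed = 1L) {
  if (!(n_photons >= 1)) stop("n_photons must be >= 1")
  if (!(weight_threshold > 0 && weight_threshold < 1))
    stop("weight_threshold must be in (0, 1)")
  if (roulette_m < 2) stop("roulette_m must be >= 2")
  structure(list(n_photons = as.integer(n_photons),
                 weight_threshold = weight_threshold,
                 roulette_m = as.integer(roulette_m),
                 max_events = max_events, seed = as.integer(seed)),
            class = "sim_config")
}

#' Illumination source configuration
#'
#' A collimated beam at normal incidence on the anterior (z = 0) surface.
#' The default is a uniform disk of radius 1 cm centered over the anchor
#' (nipple apex) delivering 50 mW/cm^2, the irradiance customary in tissue
#' spectroscopy; a pencil beam is available for validation work.
#'
#' @param type `"disk"` or `"pencil"`
#' @param center (x, y) beam center in cm on the surface; `NULL` centers the
#'   beam on the volume anchor
#' @param radius disk radius in cm (ignored for pencil beams)
#' @param irradiance source irradiance in W/cm^2 (default 0.05)
#' @return list of class `source_config`
#' @export
source_config <- function(type = c("disk", "pencil"), center = NULL,
                          radius = 1.0, irradiance = 0.05) {
  type <- match.arg(type)
  if (!(irradiance > 0)) stop("irradiance must be positive")
  if (type == "disk" && !(radius > 0)) stop("disk radius must be positive")
  structure(list(type = type, center = center, radius = radius,
                 irradiance = irradiance),
            class = "source_config")
}

#' Sample a dimensionless free path as a physical step length
#'
#' `s = -ln(xi) / mu_t`, the exponential free path between interaction
#' sites in a medium of total attenuation `mu_t = mu_a + mu_s`.
#'
#' @param xi uniform deviates in (0, 1]
#' @param mu_t total attenuation coefficient, cm^-1 (must be positive;
#'   non-attenuating ambient voxels are handled by the traversal, not here)
#' @return step lengths in cm
#' @export
sample_step <- function(xi, mu_t) {
  if (any(mu_t <= 0)) stop("mu_t must be positive")
  if (any(xi <= 0 | xi > 1)) stop("xi must be in (0, 1]")
  -log(xi) / mu_t
}

#' Deposit the absorbed fraction of a photon's weight
#'
#' At an interaction site the photon sheds `mu_a / mu_t` of its current
#' weight into the local voxel.
#'
#' @param weight current photon weight(s)
#' @param mu_a,mu_s absorption and scattering coefficients, cm^-1
#' @return list with `dw` (deposited weight) and `weight` (remaining)
#' @export
deposit_weight <- function(weight, mu_a, mu_s) {
  if (any(mu_a < 0) || any(mu_s < 0)) stop("coefficients must be non-negative")
  mu_t <- mu_a + mu_s
  dw <- ifelse(mu_t > 0, weight * mu_a / mu_t, 0)
  list(dw = dw, weight = weight - dw)
}

#' Russian roulette for sub-threshold photons
#'
#' An unbiased termination rule: a photon below the weight threshold
#' survives with probability `1/m`, its weight multiplied by `m`; otherwise
#' it dies and its residual weight is retired to the roulette ledger.
#'
#' @param weight current photon weight
#' @param m survival factor (integer >= 2)
#' @param xi one uniform deviate in \[0, 1)
#' @return list with `weight` (0 if killed), `alive`, and `killed` (the
#'   weight retired to the ledger, 0 on survival)
#' @export
roulette <- function(weight, m, xi) {
  if (m < 2) stop("m must be >= 2")
  if (xi < 1 / m) list(weight = weight * m, alive = TRUE, killed = 0)
  else list(weight = 0, alive = FALSE, killed = weight)
}

# Launch positions/directions for a surface illumination run.
# Returns pos (N x 3), dir (N x 3), w0 (N), and the beam aperture area (cm^2).
.surface_launch <- function(vol, source, n, seed) {
  d <- dim(vol$labels); h <- vol$voxel_size
  ctr <- if (is.null(source$center)) vol$origin[1:2] else source$center
  .with_seed(seed, {
    if (source$type == "pencil") {
      x <- rep(ctr[1], n); y <- rep(ctr[2], n)
      area <- 1  # by convention, a pencil beam normalizes to 1 cm^2
    } else {
      rr <- source$radius * sqrt(runif(n))
      ph <- runif(n, 0, 2 * pi)
      x <- ctr[1] + rr * cos(ph)
      y <- ctr[2] + rr * sin(ph)
      area <- pi * source$radius^2
    }
    eps <- 1e-9
    x <- pmin(pmax(x, eps), d[1] * h - eps)
    y <- pmin(pmax(y, eps), d[2] * h - eps)
    list(pos = cbind(x, y, rep(0, n)),
         dir = cbind(rep(0, n), rep(0, n), rep(1, n)),
         w0 = rep(1, n), area = area)
  })
}

#' Run excitation transport and score fluence
#'
#' Launches `n_photons` unit-weight photons from the source onto the
#' anterior surface, tracks them through the voxelized medium at the band's
#' excitation (or emission) wavelength, and scores absorbed weight per
#' voxel, which is converted to fluence by [score_fluence()]. Specular
#' reflection at the first air/tissue entry is deducted deterministically
#' from the initial weight; all later index-mismatch crossings are decided
#' stochastically from the unpolarized Fresnel reflectance.
#'
#' @param vol a `label_volume`
#' @param band `"VIS"`, `"NIR"` or `"SWIR"`
#' @param source a [source_config()]
#' @param sim a [sim_config()]
#' @param role wavelength role, normally `"excitation"`
#' @param optics_table optional substitute optical table
#' @return object of class `fluence_volume`: list with `fluence` (W/cm^2 at
#'   the configured source irradiance), `absorbed` (summed deposited
#'   weight), `surface` (a `surface_map` of escaping weight binned on the
#'   anterior projection), `ledger`, and `meta`
#' @export
run_excitation <- function(vol, band, source = source_config(),
                           sim = sim_config(), role = "excitation",
                           optics_table = NULL) {
  validate_label_volume(vol)
  band <- .match_band(band); role <- .match_role(role)
  props <- .optics_matrix(band, role, table = optics_table)
  lau <- .surface_launch(vol, source, sim$n_photons, sim$seed)
  res <- mc_transport(vol$labels, props, vol$voxel_size,
                      lau$pos, lau$dir, lau$w0,
                      specular_launch = TRUE,
                      weight_threshold = sim$weight_threshold,
                      roulette_m = sim$roulette_m,
                      max_events = sim$max_events, seed = sim$seed)
  power_per_weight <- lau$area * source$irradiance / sim$n_photons
  meta <- list(band = band, role = role,
               wavelength_nm = band_wavelength(band, role),
               source = source, sim = sim, beam_area_cm2 = lau$area,
               power_per_weight = power_per_weight,
               voxel_size = vol$voxel_size)
  out <- score_fluence(res$absorbed, vol, band, role,
                       power_per_weight = power_per_weight,
                       optics_table = optics_table)
  out$surface <- .surface_map(res$surface, power_per_weight, vol$voxel_size, meta)
  out$ledger <- res$ledger
  out$meta <- meta
  out
}

#' Convert an absorbed-weight grid to fluence
#'
#' The collision estimator: `fluence[v] = absorbed[v] * P1 / (mu_a[v] *
#' V_voxel)` where `P1` is the source power carried per unit photon weight
#' (`beam_area * irradiance / n_photons` for surface illumination). The
#' result is the fluence rate in W/cm^2 for the configured source. Voxels of
#' a tissue with `mu_a = 0` have no collision estimate; they trigger an
#' error unless they received no absorbed weight (ambient voxels never do).
#'
#' @param absorbed 3D array of summed deposited weight
#' @param vol the `label_volume` the run used
#' @param band,role wavelength selection
#' @param power_per_weight watts represented by one unit of photon weight
#' @param optics_table optional substitute optical table
#' @return list of class `fluence_volume` with `fluence` and `absorbed`
#' @export
score_fluence <- function(absorbed, vol, band, role, power_per_weight = 1,
                          optics_table = NULL) {
  if (!identical(dim(absorbed), dim(vol$labels)))
    stop("absorbed grid does not match the volume")
  props <- .optics_matrix(band, role, table = optics_table)
  mu_a <- props[vol$labels + 1L, "mu_a"]
  dim(mu_a) <- dim(absorbed)
  Vvox <- vol$voxel_size^3
  bad <- mu_a == 0 & absorbed > 0
  if (any(bad))
    stop("fluence undefined: ", sum(bad),
         " voxels with mu_a = 0 received absorbed weight")
  fl <- array(0, dim = dim(absorbed))
  pos <- mu_a > 0
  fl[pos] <- absorbed[pos] * power_per_weight / (mu_a[pos] * Vvox)
  structure(list(fluence = fl, absorbed = absorbed,
                 ledger = NULL, surface = NULL, meta = NULL),
            class = "fluence_volume")
}

#' @export
print.fluence_volume <- function(x, ...) {
  cat("<fluence_volume>")
  if (!is.null(x$meta))
    cat(sprintf(" %s %s (%d nm)", x$meta$band, x$meta$role, x$meta$wavelength_nm))
  cat(sprintf("\n  peak fluence %.3g W/cm2, total absorbed weight %.4g\n",
              max(x$fluence), sum(x$absorbed)))
  if (!is.null(x$ledger))
    cat(sprintf("  ledger: launched %.6g = absorbed %.6g + escaped %.6g + killed %.6g\n",
                x$ledger$launched, x$ledger$absorbed, x$ledger$escaped,
                x$ledger$roulette_killed))
  invisible(x)
}

# internal constructor for surface maps (escaped weight -> irradiance)
.surface_map <- function(raw, power_per_weight, bin_cm, meta = NULL) {
  irr <- raw * power_per_weight / bin_cm^2
  structure(list(irradiance = irr, bin_cm = bin_cm,
                 power_per_weight = power_per_weight, meta = meta),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("<surface_map %d x %d bins of %g cm, peak %.3g W/cm2>\n",
              nrow(x$irradiance), ncol(x$irradiance), x$bin_cm,
              max(x$irradiance)))
  invisible(x)
}
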