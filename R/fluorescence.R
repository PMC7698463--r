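# Excitation -> emission coupling. The probe converts locally absorbed
# excitation into an isotropic emission source confined to the cancer:
# emitted power density = QY * epsC * Phi_ex (W/cm^3). The probe is a
# perturbation on top of the tabulated cancer absorption — epsC is not added
# to mu_a during excitation transport, and emitted photons are not
# reabsorbed by the probe (single-generation model).

.emission_seed <- function(seed) {
  as.integer((as.numeric(seed) + 1000003) %% 2147483647)
}

#' Initial emission weights at positions inside the cancer
#'
#' With the excitation gradient, a photon launched at position p carries a
#' weight proportional to the excitation fluence of its voxel; without the
#' gradient, every photon carries the fluence at the cancer center voxel
#' (the uniform-excitation approximation of layered models). In both modes
#' the scale is `QY * epsC * V_cancer / n_photons`, so the launched total
#' approximates the emitted power `QY * epsC * integral of Phi_ex over the
#' cancer` ([launch_emission()] renormalizes the with-gradient total to
#' that integral exactly).
#'
#' @param positions n x 3 matrix of points (cm) inside the cancer
#' @param vol the `label_volume` with an embedded cancer
#' @param fluence_ex excitation `fluence_volume`
#' @param fluorophore a `fluorophore_spec`
#' @param mode `"with_gradient"` or `"without_gradient"`
#' @param n_photons the number of photons the weights are spread over
#' @return numeric weights in watts
#' @export
emission_weight <- function(positions, vol, fluence_ex, fluorophore,
                            mode = c("with_gradient", "without_gradient"),
                            n_photons) {
  mode <- match.arg(mode)
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  h <- vol$voxel_size
  d <- dim(vol$labels)
  idx <- floor(sweep(positions, 2L, h, "/")) + 1L
  if (any(idx < 1L) || any(sweep(idx, 2L, d, ">")))
    stop("position outside the grid")
  lin <- idx[, 1] + d[1] * ((idx[, 2] - 1L) + d[2] * (idx[, 3] - 1L))
  if (any(vol$labels[lin] != tissue_labels()[["cancer"]]))
    stop("position outside the cancer")
  n_cvox <- sum(vol$labels == tissue_labels()[["cancer"]])
  V_cancer <- n_cvox * h^3
  scale <- fluorophore$quantum_yield * fluorophore$epsC * V_cancer / n_photons
  if (mode == "with_gradient") {
    phi <- fluence_ex$fluence[lin]
  } else {
    phi <- rep(.center_fluence(vol, fluence_ex), nrow(positions))
  }
  scale * phi
}

# excitation fluence at the voxel holding the cancer center (placement
# attribute if present, cancer-voxel centroid otherwise)
.center_fluence <- function(vol, fluence_ex) {
  h <- vol$voxel_size
  info <- attr(vol, "cancer")
  if (!is.null(info)) {
    ctr <- info$center
  } else {
    ci <- which(vol$labels == tissue_labels()[["cancer"]], arr.ind = TRUE)
    if (!nrow(ci)) stop("volume contains no cancer voxels")
    ctr <- (colMeans(ci) - 0.5) * h
  }
  idx <- pmin(pmax(floor(ctr / h) + 1L, 1L), dim(vol$labels))
  fluence_ex$fluence[idx[1], idx[2], idx[3]]
}

#' Build the emission photon ensemble
#'
#' Positions are uniform over the union of cancer voxels (voxel-list
#' sampling, then uniform within the voxel), directions isotropic on the
#' sphere, and weights follow the coupling mode. With the gradient, the
#' per-photon weights are proportional to the launch voxel's excitation
#' fluence and normalized so the launched total equals
#' `QY * epsC * sum(Phi_ex[v] * V_voxel)` over cancer voxels exactly;
#' without the gradient, every weight is
#' `QY * epsC * Phi_ex(center) * V_cancer / n`.
#'
#' @param vol `label_volume` with embedded cancer
#' @param fluence_ex excitation `fluence_volume`
#' @param fluorophore a `fluorophore_spec`
#' @param n_photons number of emission photons
#' @param mode `"with_gradient"` or `"without_gradient"`
#' @param seed integer seed
#' @return list with `pos`, `dir`, `w0` (watts), `total_power` and `mode`
#' @export
launch_emission <- function(vol, fluence_ex, fluorophore, n_photons,
                            mode = c("with_gradient", "without_gradient"),
                            seed = 1L) {
  mode <- match.arg(mode)
  h <- vol$voxel_size
  d <- dim(vol$labels)
  clin <- which(vol$labels == tissue_labels()[["cancer"]])
  if (!length(clin)) stop("volume contains no cancer voxels")
  n <- as.integer(n_photons)
  qy <- fluorophore$quantum_yield; epsC <- fluorophore$epsC
  .with_seed(seed, {
    pick <- clin[sample.int(length(clin), n, replace = TRUE)]
    k0 <- pick - 1L
    ix <- k0 %% d[1]
    iy <- (k0 %/% d[1]) %% d[2]
    iz <- k0 %/% (d[1] * d[2])
    pos <- cbind((ix + runif(n)) * h, (iy + runif(n)) * h, (iz + runif(n)) * h)
    uz <- 2 * runif(n) - 1
    phi <- runif(n, 0, 2 * pi)
    st <- sqrt(pmax(0, 1 - uz^2))
    dir <- cbind(st * cos(phi), st * sin(phi), uz)
    if (mode == "with_gradient") {
      total <- qy * epsC * sum(fluence_ex$fluence[clin]) * h^3
      raw <- fluence_ex$fluence[pick]
      s <- sum(raw)
      w0 <- if (s > 0) raw * (total / s) else rep(0, n)
    } else {
      phi_c <- .center_fluence(vol, fluence_ex)
      total <- qy * epsC * phi_c * length(clin) * h^3
      w0 <- rep(total / n, n)
    }
    list(pos = pos, dir = dir, w0 = w0, total_power = sum(w0), mode = mode)
  })
}

#' Run a two-stage fluorescence simulation
#'
#' Excitation transport at the band's excitation wavelength, construction of
#' the emission source inside the cancer (with or without the excitation
#' gradient), then emission transport at the emission wavelength with
#' escaping weight scored on the anterior surface.
#'
#' @param vol `label_volume` with embedded cancer (see [embed_cancer()])
#' @param band `"VIS"`, `"NIR"` or `"SWIR"`; the band also selects the
#'   fluorophore (fluorescein / ICG / PbS quantum dots)
#' @param source a [source_config()] for the excitation beam
#' @param sim a [sim_config()]; `n_photons` applies to each stage, and the
#'   emission stage uses a seed derived from `sim$seed`
#' @param mode `"with_gradient"` (emission weight follows the local
#'   excitation fluence) or `"without_gradient"` (spatially constant weight
#'   from the center-voxel fluence)
#' @param optics_table,fluorophore_table optional substitute tables
#' @return list of class `fluorescence_run` with elements `excitation` and
#'   `emission` (`fluence_volume`s), `surface` (the emission `surface_map`,
#'   W/cm^2), `launch` (the emission ensemble summary), `fluorophore`,
#'   `band` and `mode`
#' @export
run_fluorescence <- function(vol, band, source = source_config(),
                             sim = sim_config(),
                             mode = c("with_gradient", "without_gradient"),
                             optics_table = NULL, fluorophore_table = NULL) {
  mode <- match.arg(mode)
  band <- .match_band(band)
  fluo <- get_fluorophore(band, table = fluorophore_table)

  exc <- run_excitation(vol, band, source = source, sim = sim,
                        role = "excitation", optics_table = optics_table)

  em_seed <- .emission_seed(sim$seed)
  lau <- launch_emission(vol, exc, fluo, sim$n_photons, mode = mode,
                         seed = em_seed)

  props <- .optics_matrix(band, "emission", table = optics_table)
  res <- mc_transport(vol$labels, props, vol$voxel_size,
                      lau$pos, lau$dir, lau$w0,
                      specular_launch = FALSE,
                      weight_threshold = sim$weight_threshold,
                      roulette_m = sim$roulette_m,
                      max_events = sim$max_events, seed = em_seed)

  meta_em <- list(band = band, role = "emission",
                  wavelength_nm = band_wavelength(band, "emission"),
                  source = source, sim = sim, mode = mode,
                  power_per_weight = 1, voxel_size = vol$voxel_size)
  em <- score_fluence(res$absorbed, vol, band, "emission",
                      power_per_weight = 1, optics_table = optics_table)
  em$ledger <- res$ledger
  em$meta <- meta_em
  surf <- .surface_map(res$surface, 1, vol$voxel_size, meta_em)

  w <- lau$w0
  centroid_z <- if (sum(w) > 0) sum(lau$pos[, 3] * w) / sum(w) else NA_real_
  launch_summary <- list(total_power = lau$total_power, mode = mode,
                         n_photons = sim$n_photons,
                         weighted_centroid_z = centroid_z)

  structure(list(excitation = exc, emission = em, surface = surf,
                 launch = launch_summary, fluorophore = fluo,
                 band = band, mode = mode),
            class = "fluorescence_run")
}

#' @export
print.fluorescence_run <- function(x, ...) {
  cat(sprintf("<fluorescence_run %s, %s>\n", x$band, x$mode))
  cat(sprintf("  launched emission power %.4g W over %d photons\n",
              x$launch$total_power, x$launch$n_photons))
  cat(sprintf("  peak surface irradiance %.4g W/cm2\n", max(x$surface$irradiance)))
  invisible(x)
}
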