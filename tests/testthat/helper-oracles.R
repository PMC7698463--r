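# Shared fixtures and independent oracles used across the suite.

# Optical table where one tissue is replaced by custom coefficients, used to
# build matched-index / pure-absorber validation media.
custom_optics <- function(tissue = "fat", band = "NIR", role = "excitation",
                          mu_a = 1, mu_s = 10, g = 0, n = 1.0) {
  tab <- load_optics_table()
  sel <- tab$tissue == tissue & tab$band == band & tab$role == role
  tab[sel, c("mu_a", "mu_s", "g", "n")] <- list(mu_a, mu_s, g, n)
  tab
}

# Independent brute-force Monte Carlo for total diffuse reflectance of a
# semi-infinite homogeneous isotropically scattering medium (g = 0) with a
# matched boundary. No voxel traversal: for g = 0 only depth z and direction
# cosine uz matter. Photons start at z = 0 heading straight down; roulette as
# in the engine. Returns the reflectance estimate and its standard error.
oracle_semiinf_reflectance <- function(mu_a, mu_s, n_photons,
                                       wth = 1e-4, m = 10) {
  mut <- mu_a + mu_s
  z <- rep(0, n_photons); uz <- rep(1, n_photons)
  w <- rep(1, n_photons); alive <- rep(TRUE, n_photons)
  refl <- rep(0, n_photons)
  while (any(alive)) {
    i <- which(alive)
    s <- -log(runif(length(i))) / mut
    z2 <- z[i] + uz[i] * s
    esc <- z2 < 0
    refl[i[esc]] <- w[i[esc]]
    alive[i[esc]] <- FALSE
    j <- i[!esc]
    if (!length(j)) break
    z[j] <- z2[!esc]
    dw <- w[j] * mu_a / mut
    w[j] <- w[j] - dw
    uz[j] <- 2 * runif(length(j)) - 1
    low <- which(w[j] < wth)
    if (length(low)) {
      k <- j[low]
      surv <- runif(length(k)) < 1 / m
      w[k[surv]] <- w[k[surv]] * m
      alive[k[!surv]] <- FALSE
      w[k[!surv]] <- 0
    }
  }
  list(R = sum(refl) / n_photons, se = stats::sd(refl) / sqrt(n_photons))
}

# assert that the run's weight ledger closes exactly
expect_ledger_closes <- function(ledger, tol = 1e-9) {
  gap <- abs(ledger$launched -
             (ledger$absorbed + ledger$escaped + ledger$roulette_killed))
  expect_lt(gap / max(ledger$launched, 1e-300), tol)
}

# a small flat fat slab with an embedded cancer, reused by several tests
small_cancer_slab <- function(diameter = 0.3, depth = 0.3,
                              grid = c(50L, 50L, 60L)) {
  vol <- generate_slab_phantom(1.9, "fat", grid = grid, voxel_size = 0.033)
  embed_cancer(vol, diameter, depth)
}

# artificial excitation field that is uniform over the cancer voxels
uniform_fluence <- function(vol, value = 1) {
  fl <- array(0, dim = dim(vol$labels))
  fl[vol$labels == tissue_labels()[["cancer"]]] <- value
  structure(list(fluence = fl, absorbed = array(0, dim = dim(vol$labels)),
                 ledger = NULL, surface = NULL, meta = NULL),
            class = "fluence_volume")
}
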