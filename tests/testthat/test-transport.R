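# Transport physics: step sampling, weight deposition, scattering, boundary
# reflection, roulette, traversal against closed forms, and the run ledger.

test_that("free-path sampling follows -ln(xi)/mu_t", {
  expect_equal(sample_step(exp(-1), 1), 1)
  expect_equal(sample_step(exp(-2), 4), 0.5)
  expect_equal(sample_step(1, 10), 0)
  expect_error(sample_step(0.5, 0), "positive")
  expect_error(sample_step(0, 1), "xi")
  # ensemble mean = 1/mu_t within 3 standard errors
  set.seed(31)
  s <- sample_step(runif(1e6), 10)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 0.1), 3 * se)
})

test_that("deposition sheds mu_a/mu_t of the current weight", {
  d <- deposit_weight(1, 1, 3)
  expect_equal(d$dw, 0.25)
  expect_equal(d$weight, 0.75)
  # VIS skin coefficients
  d <- deposit_weight(0.5, 6.0, 625)
  expect_equal(d$dw, 0.5 * 6.0 / 631)
  d <- deposit_weight(0.8, 0, 100)
  expect_equal(d$dw, 0)
  expect_equal(d$weight, 0.8)
})

test_that("Henyey-Greenstein sampling reproduces the anisotropy", {
  # isotropic: mean cosine 0 by symmetry
  ct0 <- sample_hg_costheta(1e6, 0, seed = 5)
  expect_lt(abs(mean(ct0)), 3 * sd(ct0) / sqrt(length(ct0)))
  # forward-peaked: E[cos theta] = g, checked against numerical integration
  g <- 0.9
  dens <- function(ct) 0.5 * (1 - g^2) / (1 + g^2 - 2 * g * ct)^1.5
  m_num <- integrate(function(ct) ct * dens(ct), -1, 1)$value
  expect_equal(m_num, g, tolerance = 1e-6)
  ct <- sample_hg_costheta(1e6, g, seed = 6)
  expect_lt(abs(mean(ct) - m_num), 3 * sd(ct) / sqrt(length(ct)))
  expect_true(all(ct >= -1 & ct <= 1))
})

test_that("the spin update preserves unit norm in every regime", {
  set.seed(9)
  for (i in 1:200) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- spin_direction(u, 0.9, runif(1), runif(1))
    expect_lt(abs(sqrt(sum(v^2)) - 1), 1e-9)
  }
  # the |uz| ~ 1 special case
  v <- spin_direction(c(0, 0, 1), 0.9, 0.3, 0.7)
  expect_lt(abs(sqrt(sum(v^2)) - 1), 1e-9)
  v <- spin_direction(c(0, 0, -1), 0, 0.2, 0.1)
  expect_lt(abs(sqrt(sum(v^2)) - 1), 1e-9)
})

test_that("Fresnel reflectance covers matched, mismatched and total internal reflection", {
  expect_equal(fresnel_reflectance(1.37, 1.37, 0.7)$R, 0)
  # air -> skin at normal incidence: ((n-1)/(n+1))^2
  r <- fresnel_reflectance(1.0, 1.37, 1.0)
  expect_equal(r$R, ((1.37 - 1) / (1.37 + 1))^2, tolerance = 1e-12)
  expect_equal(r$cos_t, 1.0)
  # beyond the critical angle from the dense side
  crit <- sqrt(1 - (1.0 / 1.45)^2)  # cos of the critical angle
  r <- fresnel_reflectance(1.45, 1.0, crit * 0.5)
  expect_equal(r$R, 1)
  expect_error(fresnel_reflectance(1.0, 1.37, 0), "cos_i")
})

test_that("roulette is a fair game: unbiased and correctly bookkept", {
  r <- roulette(1e-5, 10, 0.05)
  expect_true(r$alive)
  expect_equal(r$weight, 1e-4)
  r <- roulette(1e-5, 10, 0.5)
  expect_false(r$alive)
  expect_equal(r$killed, 1e-5)
  # expectation preserved
  set.seed(21)
  xi <- runif(2e5)
  out <- vapply(xi, function(x) roulette(1e-5, 10, x)$weight, numeric(1))
  se <- sd(out) / sqrt(length(out))
  expect_lt(abs(mean(out) - 1e-5), 3 * se)
})

test_that("a pure absorber obeys Beer-Lambert through the voxel grid", {
  mu_a <- 2
  tab <- custom_optics(mu_a = mu_a, mu_s = 0, g = 0, n = 1.0)
  vol <- generate_slab_phantom(3.2, "fat", grid = c(40L, 40L, 100L))
  run <- run_excitation(vol, "NIR", source = source_config("pencil"),
                        sim = sim_config(n_photons = 1e5, seed = 7),
                        optics_table = tab)
  led <- run$ledger
  expect_ledger_closes(led)
  # fraction of launched weight crossing depth L: photons are fully absorbed
  # at their first interaction, so crossing = absorbed beyond L + transmitted
  h <- vol$voxel_size
  for (k in c(10L, 15L, 30L)) {
    L <- k * h
    crossed <- (sum(run$absorbed[, , (k + 1):100]) + led$escaped) /
      led$n_photons
    p <- exp(-mu_a * L)
    se <- sqrt(p * (1 - p) / led$n_photons)
    expect_lt(abs(crossed - p), 3 * se)
  }
})

test_that("a single-voxel absorber captures 1 - exp(-mu_a h) of the beam", {
  mu_a <- 8
  tab <- custom_optics(mu_a = mu_a, mu_s = 0, g = 0, n = 1.0)
  h <- 0.033
  vol <- generate_slab_phantom(h, "fat", grid = c(21L, 21L, 4L), voxel_size = h)
  run <- run_excitation(vol, "NIR", source = source_config("pencil"),
                        sim = sim_config(n_photons = 1e5, seed = 3),
                        optics_table = tab)
  p <- 1 - exp(-mu_a * h)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(run$ledger$absorbed / 1e5 - p), 3 * se)
})

test_that("specular reflection at the air/skin interface is deducted exactly", {
  vol <- generate_slab_phantom(3.0, "skin", grid = c(30L, 30L, 95L))
  run <- run_excitation(vol, "VIS", source = source_config("pencil"),
                        sim = sim_config(n_photons = 1000, seed = 2))
  R <- ((1.37 - 1) / (1.37 + 1))^2
  expect_equal(run$ledger$specular / run$ledger$launched, R, tolerance = 1e-12)
  expect_ledger_closes(run$ledger)
})

test_that("every run's weight ledger closes, including scattering media", {
  vol <- generate_slab_phantom(2.5, "fat", grid = c(40L, 40L, 80L),
                               skin_cap = TRUE)
  for (band in c("VIS", "NIR", "SWIR")) {
    run <- run_excitation(vol, band, sim = sim_config(n_photons = 5000,
                                                      seed = 11))
    expect_ledger_closes(run$ledger)
    expect_equal(run$ledger$launched, 5000)
  }
})

test_that("runs are bitwise deterministic for a fixed seed", {
  vol <- small_cancer_slab()
  a <- run_excitation(vol, "SWIR", sim = sim_config(n_photons = 3000, seed = 5))
  b <- run_excitation(vol, "SWIR", sim = sim_config(n_photons = 3000, seed = 5))
  expect_identical(a$absorbed, b$absorbed)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$surface$irradiance, b$surface$irradiance)
  c <- run_excitation(vol, "SWIR", sim = sim_config(n_photons = 3000, seed = 6))
  expect_false(identical(a$absorbed, c$absorbed))
})

test_that("total absorbed and escaped fractions are voxel-size invariant", {
  tab <- custom_optics(mu_a = 1, mu_s = 10, g = 0.9, n = 1.0)
  frac <- function(h, nvox, seed) {
    vol <- generate_slab_phantom(2.1, "fat", grid = rep(nvox, 3L),
                                 voxel_size = h)
    run <- run_excitation(vol, "NIR", source = source_config("pencil"),
                          sim = sim_config(n_photons = 3e4, seed = seed),
                          optics_table = tab)
    run$ledger$absorbed / run$ledger$launched
  }
  coarse <- frac(0.066, 32L, 13)  # same 2.11 cm cube, half the resolution
  fine <- frac(0.033, 64L, 14)
  # conservative 3-sigma bound on a binomial-like fraction at 3e4 photons
  expect_lt(abs(coarse - fine), 3 * sqrt(0.5 * 0.5 / 3e4) * 2)
})

test_that("fluence scoring is linear in irradiance and zero without absorption", {
  vol <- small_cancer_slab()
  sim <- sim_config(n_photons = 2000, seed = 4)
  a <- run_excitation(vol, "SWIR", source = source_config(irradiance = 0.05),
                      sim = sim)
  b <- run_excitation(vol, "SWIR", source = source_config(irradiance = 0.10),
                      sim = sim)
  expect_equal(b$fluence, 2 * a$fluence)
  zero <- score_fluence(array(0, dim = dim(vol$labels)), vol, "SWIR",
                        "excitation")
  expect_true(all(zero$fluence == 0))
})
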