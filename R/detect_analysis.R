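#' Bin escape events onto the anterior surface
#'
#' General-purpose event binning: weights of escape events are accumulated
#' by (x, y) bin on the anterior projection and converted to irradiance
#' (W/cm^2) by the per-weight power and the bin area. The transport engine
#' performs the same binning internally at voxel resolution; this function
#' exists for custom detector geometries and for verifying the accounting
#' identity between the escape ledger and the map integral.
#'
#' @param x,y event coordinates in cm
#' @param weight event weights
#' @param bin_cm bin edge length in cm
#' @param extent_cm (x, y) extent of the binned surface in cm
#' @param power_per_weight watts represented by one unit of weight
#' @return a `surface_map`
#' @export
score_surface <- function(x, y, weight, bin_cm, extent_cm,
                          power_per_weight = 1) {
  if (!(bin_cm > 0)) stop("bin_cm must be positive")
  nb <- pmax(1L, ceiling(extent_cm / bin_cm))
  ix <- pmin(pmax(floor(x / bin_cm) + 1L, 1L), nb[1])
  iy <- pmin(pmax(floor(y / bin_cm) + 1L, 1L), nb[2])
  raw <- matrix(0, nb[1], nb[2])
  if (length(weight)) {
    acc <- tapply(weight, list(factor(ix, levels = seq_len(nb[1])),
                               factor(iy, levels = seq_len(nb[2]))), sum)
    acc[is.na(acc)] <- 0
    raw <- matrix(acc, nb[1], nb[2])
  }
  .surface_map(raw, power_per_weight, bin_cm)
}

#' Judge detectability of a surface emission map
#'
#' A signal is detectable when it exceeds the sensor irradiance floor,
#' 10 nW/cm^2 by default (strictly "more than": a peak exactly at the
#' threshold is not detectable). The statistic is the peak bin by default;
#' `stat = "mean"` averages over a circular aperture centered on the peak.
#'
#' @param map a `surface_map`
#' @param threshold sensor floor in W/cm^2 (default 1e-8)
#' @param stat `"peak"` or `"mean"`
#' @param aperture_cm radius of the averaging aperture for `stat = "mean"`
#' @return list of class `detection_result`: `intensity` (W/cm^2),
#'   `detectable`, `threshold`, `stat`
#' @export
assess_detectability <- function(map, threshold = 1e-8,
                                 stat = c("peak", "mean"),
                                 aperture_cm = 0.5) {
  stat <- match.arg(stat)
  if (!inherits(map, "surface_map")) stop("map must be a surface_map")
  if (!(threshold >= 0)) stop("threshold must be non-negative")
  irr <- map$irradiance
  if (!length(irr) || all(irr == 0)) {
    intensity <- 0
  } else if (stat == "peak") {
    intensity <- max(irr)
  } else {
    pk <- which(irr == max(irr), arr.ind = TRUE)[1, ]
    h <- map$bin_cm
    nx <- nrow(irr); ny <- ncol(irr)
    cx <- (seq_len(nx) - pk[1]) * h
    cy <- (seq_len(ny) - pk[2]) * h
    sel <- outer(cx^2, cy^2, "+") <= aperture_cm^2
    intensity <- mean(irr[sel])
  }
  structure(list(intensity = intensity, detectable = intensity > threshold,
                 threshold = threshold, stat = stat),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %s %.4g W/cm2 vs floor %.3g: %s\n",
              x$stat, x$intensity, x$threshold,
              if (x$detectable) "DETECTABLE" else "not detectable"))
  invisible(x)
}

#' Size/depth/band detectability sweep
#'
#' Runs the two-stage fluorescence simulation for every combination of band,
#' cancer diameter and depth on copies of one base phantom, reusing the same
#' seed for every row (common random numbers, so band comparisons are not
#' confounded by geometry noise). Placement failures are recorded per row,
#' not fatal.
#'
#' @param vol base `label_volume` (no cancer embedded)
#' @param bands character vector of bands
#' @param diameters_cm,depths_cm sweep grids in cm
#' @param source a [source_config()]
#' @param sim a [sim_config()]
#' @param mode coupling mode, default `"with_gradient"`
#' @param threshold sensor floor in W/cm^2
#' @param optics_table,fluorophore_table optional substitute tables
#' @return data.frame with one row per (band, diameter, depth): peak
#'   surface intensity, detectability, emitted power, ledger totals, seed,
#'   and an `error` column (NA on success)
#' @export
sweep_detectability <- function(vol, bands, diameters_cm, depths_cm,
                                source = source_config(), sim = sim_config(),
                                mode = "with_gradient", threshold = 1e-8,
                                optics_table = NULL, fluorophore_table = NULL) {
  grid <- expand.grid(band = bands, diameter_cm = diameters_cm,
                      depth_cm = depths_cm, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    out <- data.frame(band = g$band, diameter_cm = g$diameter_cm,
                      depth_cm = g$depth_cm, peak_Wcm2 = NA_real_,
                      detectable = NA, emitted_W = NA_real_,
                      escaped_W = NA_real_, n_photons = sim$n_photons,
                      seed = sim$seed, error = NA_character_)
    res <- tryCatch({
      v <- embed_cancer(vol, g$diameter_cm, g$depth_cm)
      run_fluorescence(v, g$band, source = source, sim = sim, mode = mode,
                       optics_table = optics_table,
                       fluorophore_table = fluorophore_table)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
    } else {
      det <- assess_detectability(res$surface, threshold = threshold)
      out$peak_Wcm2 <- det$intensity
      out$detectable <- det$detectable
      out$emitted_W <- res$launch$total_power
      out$escaped_W <- res$emission$ledger$escaped
    }
    out
  })
  do.call(rbind, rows)
}

#' Render a log-scale cross-section of a fluence volume
#'
#' Extracts one plane of the fluence grid and draws it as a log10
#' pseudocolour image, optionally overlaying tissue contours from a label
#' volume. Returns the extracted slice invisibly so the numbers remain
#' accessible.
#'
#' @param fl a `fluence_volume`
#' @param plane axis normal to the section: `"x"`, `"y"` (default) or `"z"`
#' @param index 1-based slice index along that axis
#' @param log draw log10 of the fluence (values <= 0 shown at the floor)
#' @param floor smallest decade shown on the log scale, relative to the peak
#' @param vol optional `label_volume` for tissue/cancer contour overlay
#' @param file optional PNG output path; when `NULL`, draws on the active
#'   device
#' @return the 2D fluence slice, invisibly
#' @export
render_fluence_section <- function(fl, plane = c("y", "x", "z"), index,
                                   log = TRUE, floor = 1e-8, vol = NULL,
                                   file = NULL) {
  plane <- match.arg(plane)
  ax <- match(plane, c("x", "y", "z"))
  d <- dim(fl$fluence)
  if (length(index) != 1L || is.na(index) || index < 1 || index > d[ax])
    stop("plane index out of range")
  sl <- switch(plane,
               x = fl$fluence[index, , ],
               y = fl$fluence[, index, ],
               z = fl$fluence[, , index])
  z <- sl
  if (log) {
    top <- max(z)
    lo <- if (top > 0) log10(top * floor) else 0
    z <- log10(pmax(z, if (top > 0) top * floor else 1))
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 800)
    on.exit(grDevices::dev.off())
  }
  cols <- grDevices::hcl.colors(64, "Inferno")
  graphics::image(z[, rev(seq_len(ncol(z)))], col = cols, axes = FALSE,
                  main = sprintf("fluence section (%s = %d)%s", plane, index,
                                 if (log) ", log10 W/cm2" else ""))
  if (!is.null(vol)) {
    lsl <- switch(plane,
                  x = vol$labels[index, , ],
                  y = vol$labels[, index, ],
                  z = vol$labels[, , index])
    lsl <- lsl[, rev(seq_len(ncol(lsl)))]
    graphics::contour(seq(0, 1, length.out = nrow(lsl)),
                      seq(0, 1, length.out = ncol(lsl)),
                      lsl > 0, levels = 0.5, add = TRUE, drawlabels = FALSE,
                      col = "white")
    if (any(lsl == 4L))
      graphics::contour(seq(0, 1, length.out = nrow(lsl)),
                        seq(0, 1, length.out = ncol(lsl)),
                        lsl == 4L, levels = 0.5, add = TRUE,
                        drawlabels = FALSE, col = "cyan", lty = 2)
  }
  invisible(sl)
}
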