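# Synthetic anatomy: a semi-ellipsoidal breast with a 2-voxel skin shell and
# a branching duct tree converging on the nipple apex, plus flat slab
# phantoms for engine validation. Structural stand-ins, not anatomically
# validated geometry.

#' Parameters of the synthetic breast phantom
#'
#' @param grid integer length-3 voxel counts (x, y, z). The default
#'   (140, 100, 110) at 0.033 cm spans 4.6 x 3.3 x 3.6 cm, enough to hold a
#'   1 cm cancer at 2 cm depth, or a 1 mm cancer at 3 cm depth, inside the
#'   contour. The full-anatomy scale (500, 250, 220) is available by
#'   argument.
#' @param voxel_size isotropic voxel edge, cm
#' @param semi_axes ellipsoid semi-axes (ax, ay, az) in cm; the breast is the
#'   ellipsoid centered az below the apex, so its most anterior point (the
#'   nipple) touches z = 0. Default: 95% of the half-extents of the grid in
#'   x and y, and half the z extent.
#' @param n_ducts number of primary duct trunks radiating from the apex
#' @param branch_depth generations of binary branching per trunk
#' @param branch_length range (cm) of segment lengths, drawn uniformly
#' @param duct_radius duct lumen radius in cm at the trunk; tapers with
#'   generation
#' @param seed integer seed; the generator is deterministic for a fixed seed
#' @return list of class `phantom_params`
#' @export
phantom_params <- function(grid = c(140L, 100L, 110L), voxel_size = 0.033,
                           semi_axes = NULL, n_ducts = 8L, branch_depth = 4L,
                           branch_length = c(0.3, 0.8), duct_radius = 0.07,
                           seed = 1L) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 8L)) stop("grid must be 3 counts >= 8")
  if (!(voxel_size > 0)) stop("voxel_size must be positive")
  ext <- grid * voxel_size
  if (is.null(semi_axes))
    semi_axes <- c(0.475 * ext[1], 0.475 * ext[2], 0.5 * ext[3])
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("semi_axes must be 3 positive lengths (cm)")
  if (semi_axes[1] > ext[1] / 2 || semi_axes[2] > ext[2] / 2 ||
      2 * semi_axes[3] > ext[3] + voxel_size)
    stop("breast profile does not fit the grid")
  if (n_ducts < 0L) stop("n_ducts must be >= 0")
  structure(list(grid = grid, voxel_size = voxel_size, semi_axes = semi_axes,
                 n_ducts = as.integer(n_ducts),
                 branch_depth = as.integer(branch_depth),
                 branch_length = branch_length, duct_radius = duct_radius,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# run expr with a private RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# mark voxels whose centers lie within `radius` of segment p1--p2 and whose
# current label is `from`, with label `to`
.rasterize_capsule <- function(lab, h, p1, p2, radius, from, to) {
  d <- dim(lab)
  lo <- pmax(1L, floor((pmin(p1, p2) - radius) / h) + 1L)
  hi <- pmin(d, ceiling((pmax(p1, p2) + radius) / h))
  if (any(lo > hi)) return(lab)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  cx <- (ix - 0.5) * h; cy <- (iy - 0.5) * h; cz <- (iz - 0.5) * h
  v <- p2 - p1
  vv <- sum(v * v)
  px <- rep(cx, times = length(iy) * length(iz))
  py <- rep(rep(cy, each = length(ix)), times = length(iz))
  pz <- rep(cz, each = length(ix) * length(iy))
  if (vv == 0) {
    t <- 0
  } else {
    t <- ((px - p1[1]) * v[1] + (py - p1[2]) * v[2] + (pz - p1[3]) * v[3]) / vv
    t <- pmin(1, pmax(0, t))
  }
  dx <- px - (p1[1] + t * v[1])
  dy <- py - (p1[2] + t * v[2])
  dz <- pz - (p1[3] + t * v[3])
  hit <- dx * dx + dy * dy + dz * dz <= radius^2
  sub <- lab[ix, iy, iz, drop = FALSE]
  sel <- hit & (sub == from)
  sub[sel] <- to
  lab[ix, iy, iz] <- sub
  lab
}

#' Generate the synthetic breast phantom
#'
#' Builds a label volume with the structure of a voxelized breast model: an
#' ellipsoidal outer contour whose apex (nipple) touches the z = 0 plane, a
#' skin shell exactly 2 voxels thick derived per slice by 2D erosion of the
#' tissue mask, a fat interior, and a branching duct tree grown from the
#' apex by a depth-biased random binary branching process rasterized as
#' capsules. Deterministic for a fixed seed.
#'
#' @param params a [phantom_params()] list
#' @return a `label_volume` with the anchor at the nipple apex
#' @export
generate_breast_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  h <- params$voxel_size
  d <- params$grid
  ax <- params$semi_axes
  ctr <- c(d[1] / 2 * h, d[2] / 2 * h, ax[3])

  cx <- ((seq_len(d[1]) - 0.5) * h - ctr[1]) / ax[1]
  cy <- ((seq_len(d[2]) - 0.5) * h - ctr[2]) / ax[2]
  cz <- ((seq_len(d[3]) - 0.5) * h - ctr[3]) / ax[3]
  tissue <- outer(outer(cx^2, cy^2, "+"), cz^2, "+") <= 1

  lab <- array(0L, dim = d)
  fat <- tissue_labels()[["fat"]]; skin <- tissue_labels()[["skin"]]
  duct <- tissue_labels()[["duct"]]
  for (j in seq_len(d[2])) {
    m <- tissue[, j, ]
    if (!any(m)) next
    core <- erode_mask(m, 2L)
    sl <- matrix(0L, d[1], d[3])
    sl[m & !core] <- skin
    sl[core] <- fat
    lab[, j, ] <- sl
  }
  if (!any(lab == fat))
    stop("phantom parameters leave no fat interior")

  apex <- c(ctr[1], ctr[2], 0)

  if (params$n_ducts > 0L) {
    lab <- .with_seed(params$seed, {
      root <- apex + c(0, 0, 4 * h)  # just below the skin shell
      gen_radius <- function(g) params$duct_radius * 0.85^g
      segs <- list()
      grow <- function(p, dir, gen) {
        if (gen > params$branch_depth) return(invisible(NULL))
        len <- runif(1, params$branch_length[1], params$branch_length[2])
        q <- p + dir * len
        segs[[length(segs) + 1L]] <<- list(p1 = p, p2 = q, r = gen_radius(gen))
        for (k in 1:2) {
          nd <- dir + c(runif(1, -0.5, 0.5), runif(1, -0.5, 0.5),
                        runif(1, 0, 0.6))  # bias deeper, toward the chest
          nd <- nd / sqrt(sum(nd^2))
          grow(q, nd, gen + 1L)
        }
      }
      for (t in seq_len(params$n_ducts)) {
        phi <- runif(1, 0, 2 * pi)
        tilt <- runif(1, 0.2, 0.9)  # polar angle from +z
        dir <- c(sin(tilt) * cos(phi), sin(tilt) * sin(phi), cos(tilt))
        grow(root, dir, 0L)
      }
      for (s in segs)
        lab <- .rasterize_capsule(lab, h, s$p1, s$p2, s$r, fat, duct)
      lab
    })
  }

  vol <- label_volume(lab, voxel_size = h, origin = apex)
  validate_label_volume(vol)
  vol
}

#' Generate a homogeneous slab phantom
#'
#' A flat slab of one tissue filling the grid laterally, with its air
#' interface at z = 0 — the layered geometry used to validate the engine
#' against closed forms and the single-medium oracle (a spherical cancer in
#' a fat layer below a flat skin surface).
#'
#' @param thickness slab thickness in cm (rounded to whole voxels)
#' @param tissue slab tissue name (default `"fat"`)
#' @param grid integer length-3 voxel counts
#' @param voxel_size voxel edge in cm
#' @param skin_cap if `TRUE`, the top 2 voxel layers are skin
#' @return a `label_volume` with the anchor at the slab surface center
#' @export
generate_slab_phantom <- function(thickness, tissue = "fat",
                                  grid = c(90L, 90L, 100L),
                                  voxel_size = 0.033, skin_cap = FALSE) {
  tl <- tissue_labels()
  tissue <- tolower(tissue)
  if (!tissue %in% names(tl)[-1]) stop("unknown tissue '", tissue, "'")
  grid <- as.integer(grid)
  h <- voxel_size
  nlay <- min(grid[3], max(1L, round(thickness / h)))
  lab <- array(0L, dim = grid)
  lab[, , seq_len(nlay)] <- tl[[tissue]]
  if (skin_cap && nlay >= 2L) lab[, , 1:2] <- tl[["skin"]]
  label_volume(lab, voxel_size = h,
               origin = c(grid[1] / 2 * h, grid[2] / 2 * h, 0))
}

#' Render a label volume to a grayscale slice stack
#'
#' Inverse of the segmentation rule, for round-trip testing: fat and skin
#' render as 200, duct as 100, outside as 0 (skin is re-derived from the
#' border rule on re-segmentation, so it renders at the fat value). Cancer
#' voxels also render as 200: the segmentation classes cover only
#' skin/fat/duct.
#'
#' @param vol a `label_volume`
#' @return list of integer (x, z) matrices, one per y slice
#' @export
render_to_grayscale <- function(vol) {
  validate_label_volume(vol)
  tl <- tissue_labels()
  lut <- integer(5)
  lut[tl[["outside"]] + 1L] <- 0L
  lut[tl[["skin"]] + 1L] <- 200L
  lut[tl[["fat"]] + 1L] <- 200L
  lut[tl[["duct"]] + 1L] <- 100L
  lut[tl[["cancer"]] + 1L] <- 200L
  d <- dim(vol$labels)
  lapply(seq_len(d[2]), function(j)
    matrix(lut[vol$labels[, j, ] + 1L], d[1], d[3]))
}
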