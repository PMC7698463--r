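#' Construct a labeled voxel volume
#'
#' The medium for the transport engine: a 3D integer array of tissue labels
#' (see [tissue_labels()]) on an isotropic grid. Axis convention: x is
#' medio-lateral (first array dimension), y is the slice/stacking axis
#' (second), z is depth from the anterior surface (third; z grows into the
#' tissue). Voxel `(i, j, k)` (1-based) spans the half-open box
#' `[(i-1)h, ih) x [(j-1)h, jh) x [(k-1)h, kh)` in cm.
#'
#' @param labels 3D integer array with values in 0..4
#' @param voxel_size isotropic voxel edge in cm (default 0.033)
#' @param origin length-3 numeric, the grid coordinates (cm) of the
#'   anatomical anchor: the (x = 0, z = 0) point at the nipple apex from
#'   which cancer depth is measured. Defaults to the lateral grid center at
#'   z = 0.
#' @return object of class `label_volume`
#' @export
label_volume <- function(labels, voxel_size = 0.033, origin = NULL) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (!(voxel_size > 0)) stop("voxel_size must be positive")
  d <- dim(labels)
  if (is.null(origin))
    origin <- c(d[1] / 2 * voxel_size, d[2] / 2 * voxel_size, 0)
  if (length(origin) != 3L || !is.numeric(origin))
    stop("origin must be a numeric length-3 vector (cm)")
  vol <- structure(list(labels = labels, voxel_size = voxel_size,
                        origin = as.numeric(origin)),
                   class = "label_volume")
  validate_label_volume(vol)
  vol
}

#' Validate label-volume invariants
#'
#' Checks that labels are in 0..4, the voxel size is positive, and that no
#' cancer voxel touches ambient air (every cancer voxel must lie strictly
#' inside the tissue).
#'
#' @param vol a `label_volume`
#' @return `vol` invisibly; errors on violation
#' @export
validate_label_volume <- function(vol) {
  if (!inherits(vol, "label_volume")) stop("not a label_volume")
  lab <- vol$labels
  if (length(dim(lab)) != 3L) stop("labels must be a 3D array")
  if (!(vol$voxel_size > 0)) stop("voxel_size must be positive")
  rng <- range(lab)
  if (rng[1] < 0L || rng[2] > 4L) stop("labels must be in 0..4")
  ci <- which(lab == 4L, arr.ind = TRUE)
  if (nrow(ci)) {
    d <- dim(lab)
    if (any(ci[, 1] == 1L | ci[, 1] == d[1] | ci[, 2] == 1L | ci[, 2] == d[2] |
            ci[, 3] == 1L | ci[, 3] == d[3]))
      stop("cancer voxels must lie strictly inside the grid")
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      nb <- sweep(ci, 2L, off, "+")
      if (any(lab[nb] == 0L))
        stop("cancer voxels must not touch ambient air")
    }
  }
  invisible(vol)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  counts <- tabulate(x$labels + 1L, nbins = 5L)
  names(counts) <- names(tissue_labels())
  cat(sprintf("<label_volume %d x %d x %d, voxel %g cm>\n", d[1], d[2], d[3],
              x$voxel_size))
  cat("  anchor (cm):", paste(signif(x$origin, 4), collapse = ", "), "\n")
  cat("  voxels:", paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Convert a 24-bit RGB image to 8-bit grayscale
#'
#' ITU-R 601 luma weighting (0.299 R + 0.587 G + 0.114 B), rounded to the
#' nearest integer in 0..255. Accepts either 0..255 integers or the 0..1
#' doubles produced by [png::readPNG()]-style readers.
#'
#' @param image array of dimension (rows, cols, 3)
#' @return integer matrix in 0..255
#' @export
rgb_to_gray <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] < 3L)
    stop("image must be an array with 3 colour channels")
  img <- image[, , 1:3, drop = FALSE]
  if (max(img) <= 1 && is.double(image)) img <- img * 255
  if (min(img) < 0 || max(img) > 255) stop("channel values must be in [0, 255]")
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(as.integer(round(g)), nrow = d[1], ncol = d[2])
}

#' Segment a grayscale cross-section into tissue labels
#'
#' Thresholding rule for 8-bit cryosection-style slices: nonzero pixels form
#' the tissue region (value 0 is background air); within the tissue, the
#' 2-pixel border against the outside is skin, interior values above 180 are
#' fat, values in 80..120 are duct, and all remaining interior values fall
#' back to fat (fat is the bulk matrix of the breast and only three tissue
#' classes are defined).
#'
#' @param image integer matrix with values in 0..255 (a 0..1 double matrix is
#'   rescaled)
#' @return integer label matrix (see [tissue_labels()])
#' @export
segment_slice <- function(image) {
  if (!is.matrix(image)) stop("image must be a 2D matrix")
  img <- image
  if (is.double(img) && max(img) <= 1 && min(img) >= 0) img <- img * 255
  if (min(img) < 0 || max(img) > 255) stop("pixel values must be in [0, 255]")
  img <- round(img)
  tissue <- img > 0
  lab <- matrix(0L, nrow(img), ncol(img))
  if (!any(tissue)) return(lab)
  interior <- erode_mask(tissue, 2L)
  lab[tissue & !interior] <- tissue_labels()[["skin"]]
  lab[interior] <- tissue_labels()[["fat"]]
  lab[interior & img >= 80 & img <= 120] <- tissue_labels()[["duct"]]
  lab
}

#' Stack segmented slices into a label volume
#'
#' Slices are (x, z) label images (x medio-lateral, z depth) stacked along
#' the y axis in list order. The anatomical anchor is placed at the
#' shallowest tissue voxel of the middle slice (the nipple apex): its x
#' center and the z coordinate of its upper face.
#'
#' @param slices list of equally sized integer label matrices
#' @param voxel_size isotropic voxel edge in cm
#' @return a `label_volume` of shape (nx, n_slices, nz)
#' @export
stack_to_volume <- function(slices, voxel_size = 0.033) {
  if (!length(slices)) stop("empty slice list")
  d1 <- dim(slices[[1]])
  if (is.null(d1)) stop("slices must be matrices")
  for (s in slices)
    if (!identical(dim(s), d1)) stop("ragged stack: slices differ in size")
  nx <- d1[1]; nz <- d1[2]; ny <- length(slices)
  lab <- array(0L, dim = c(nx, ny, nz))
  for (j in seq_len(ny)) lab[, j, ] <- as.integer(slices[[j]])
  h <- voxel_size
  mid <- (ny + 1L) %/% 2L
  sl <- lab[, mid, , drop = TRUE]
  if (ny == 1L) sl <- matrix(sl, nx, nz)
  origin <- NULL
  ti <- which(sl > 0L, arr.ind = TRUE)
  if (nrow(ti)) {
    zmin <- min(ti[, 2])
    xs <- ti[ti[, 2] == zmin, 1]
    origin <- c((mean(xs) - 0.5) * h, (mid - 0.5) * h, (zmin - 1) * h)
  }
  label_volume(lab, voxel_size = h, origin = origin)
}

#' Embed a spherical fluorescence-labeled cancer
#'
#' Places a sphere of the given diameter with its upper surface `depth` cm
#' below the z = 0 anchor plane, laterally offset by (`x`, `y`) cm from the
#' anchor (the anatomy uses x = 0). Every voxel whose center lies inside the
#' sphere is relabeled cancer; the previous labels are retained so
#' [erase_cancer()] can restore the volume exactly.
#'
#' @param vol a `label_volume`
#' @param diameter sphere diameter in cm (0.1..1.0 supported continuously)
#' @param depth distance in cm from z = 0 to the upper surface of the sphere
#' @param x,y lateral offsets in cm from the anchor
#' @return the modified volume; attribute `"cancer"` carries the placement
#'   (diameter, depth, center, relabeled voxel indices and their previous
#'   labels, and `n_voxels`, the count of relabeled voxels)
#' @export
embed_cancer <- function(vol, diameter, depth, x = 0, y = 0) {
  validate_label_volume(vol)
  if (!(diameter > 0)) stop("diameter must be positive")
  if (depth < 0) stop("depth must be >= 0")
  h <- vol$voxel_size
  r <- diameter / 2
  ctr <- c(vol$origin[1] + x, vol$origin[2] + y, vol$origin[3] + depth + r)
  d <- dim(vol$labels)
  ir <- lapply(1:3, function(k) {
    lo <- max(1L, floor((ctr[k] - r) / h) + 1L)
    hi <- min(d[k], ceiling((ctr[k] + r) / h))
    if (lo > hi) integer(0) else lo:hi
  })
  if (!all(lengths(ir) > 0)) stop("cancer sphere lies outside the grid")
  cx <- (ir[[1]] - 0.5) * h - ctr[1]
  cy <- (ir[[2]] - 0.5) * h - ctr[2]
  cz <- (ir[[3]] - 0.5) * h - ctr[3]
  inside <- outer(outer(cx^2, cy^2, "+"), cz^2, "+") <= r^2
  sub <- which(inside, arr.ind = TRUE)
  if (!nrow(sub)) stop("sphere contains no voxel centers")
  idx <- cbind(ir[[1]][sub[, 1]], ir[[2]][sub[, 2]], ir[[3]][sub[, 3]])
  lin <- idx[, 1] + d[1] * ((idx[, 2] - 1L) + d[2] * (idx[, 3] - 1L))
  prev <- vol$labels[lin]
  if (any(prev == 0L))
    stop("placement error: cancer sphere extends outside the tissue")
  if (ctr[3] - r < vol$origin[3] - 1e-12)
    stop("placement error: cancer sphere extends above the surface")
  vol$labels[lin] <- tissue_labels()[["cancer"]]
  attr(vol, "cancer") <- list(diameter = diameter, depth = depth,
                              center = ctr, index = lin, previous = prev,
                              n_voxels = length(lin))
  validate_label_volume(vol)
  vol
}

#' Remove an embedded cancer, restoring the original labels
#'
#' @param vol a `label_volume` previously returned by [embed_cancer()]
#' @return the volume with the pre-embedding labels restored
#' @export
erase_cancer <- function(vol) {
  info <- attr(vol, "cancer")
  if (is.null(info)) stop("volume carries no cancer placement to erase")
  vol$labels[info$index] <- info$previous
  attr(vol, "cancer") <- NULL
  vol
}

#' Write a label volume to NIfTI with a JSON sidecar
#'
#' The labels go into an integer NIfTI file (voxel size in the header); the
#' sidecar `<path>.json` records the label map, voxel size and anchor so the
#' depth convention survives the round trip.
#'
#' @param vol a `label_volume`
#' @param path output path ending in `.nii` or `.nii.gz`
#' @return `path`, invisibly
#' @export
write_label_volume <- function(vol, path) {
  validate_label_volume(vol)
  img <- RNifti::asNifti(vol$labels,
                         pixdim = rep(vol$voxel_size * 10, 3))  # NIfTI is mm
  RNifti::writeNifti(img, path, datatype = "int16")
  side <- paste0(path, ".json")
  jsonlite::write_json(
    list(label_map = as.list(tissue_labels()),
         voxel_size_cm = vol$voxel_size,
         origin_cm = vol$origin,
         axes = c("x medio-lateral", "y slice", "z depth")),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a label volume written by [write_label_volume()]
#'
#' @param path NIfTI path (the `<path>.json` sidecar must be present)
#' @return a `label_volume`
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  lab <- array(as.integer(img), dim = dim(img))
  label_volume(lab, voxel_size = meta$voxel_size_cm, origin = meta$origin_cm)
}
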