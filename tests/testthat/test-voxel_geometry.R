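disk_image <- function(n = 60, r = 22, value = 200, blob_value = NULL,
                       blob_r = 6) {
  img <- matrix(0L, n, n)
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  img[d2 <= r^2] <- as.integer(value)
  if (!is.null(blob_value)) img[d2 <= blob_r^2] <- as.integer(blob_value)
  img
}

test_that("thresholds segment fat, duct, a 2-pixel skin ring, and background", {
  img <- disk_image(value = 200, blob_value = 100)
  lab <- segment_slice(img)
  tl <- tissue_labels()
  expect_setequal(unique(as.vector(lab)),
                  tl[c("outside", "skin", "fat", "duct")])
  expect_true(all(lab[img == 0] == tl[["outside"]]))
  # duct blob: interior value-100 pixels
  expect_true(all(lab[img == 100] == tl[["duct"]]))
  # the skin ring is tissue at distance <= 2 (Chebyshev) from the background
  tissue <- img > 0
  ring <- tissue & !erode_mask(tissue, 2L)
  expect_true(all(lab[ring] == tl[["skin"]]))
  expect_true(all(lab[tissue & !ring & img == 200] == tl[["fat"]]))
  # ring is exactly 2 pixels wide along a horizontal ray
  row <- which(tissue[, 30])
  expect_equal(sum(lab[row, 30] == tl[["skin"]]), 4L)  # 2 on each side
})

test_that("uniform zero image segments to all outside", {
  lab <- segment_slice(matrix(0L, 20, 20))
  expect_true(all(lab == 0L))
})

test_that("interior values outside both threshold windows fall back to fat", {
  img <- disk_image(value = 150)
  lab <- segment_slice(img)
  tl <- tissue_labels()
  tissue <- img > 0
  interior <- erode_mask(tissue, 2L)
  expect_true(all(lab[interior] == tl[["fat"]]))
  expect_true(all(lab[tissue & !interior] == tl[["skin"]]))
  expect_equal(sum(lab == tl[["duct"]]), 0L)
})

test_that("segmentation is idempotent on a consistent rendering", {
  img <- disk_image(value = 200, blob_value = 100)
  lab1 <- segment_slice(img)
  vol <- stack_to_volume(list(lab1, lab1, lab1))
  re <- render_to_grayscale(vol)
  lab2 <- segment_slice(re[[2]])
  expect_identical(lab2, lab1)
})

test_that("RGB conversion uses ITU-R 601 luma", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(rgb_to_gray(px(255, 255, 255))[1, 1], 255L)
  expect_equal(rgb_to_gray(px(0, 0, 0))[1, 1], 0L)
  expect_equal(rgb_to_gray(px(255, 0, 0))[1, 1], 76L)   # round(0.299 * 255)
  expect_equal(rgb_to_gray(px(0, 255, 0))[1, 1], 150L)  # round(0.587 * 255)
  # 0..1 doubles (image-reader convention) are accepted
  expect_equal(rgb_to_gray(array(c(1, 0, 0), dim = c(1, 1, 3)))[1, 1], 76L)
  expect_error(rgb_to_gray(matrix(0, 3, 3)), "3 colour channels")
})

test_that("slice stacks assemble into the documented (x, y, z) volume shape", {
  sl <- matrix(0L, 500, 220)
  sl[200:300, 5:100] <- tissue_labels()[["fat"]]
  vol <- stack_to_volume(rep(list(sl), 250))
  expect_equal(dim(vol$labels), c(500L, 250L, 220L))
  expect_true(all(vol$labels[, 17, ] == sl))
  # anchor sits on the shallowest tissue of the mid slice
  expect_equal(vol$origin[3], (5 - 1) * 0.033)

  one <- stack_to_volume(list(sl))
  expect_equal(dim(one$labels), c(500L, 1L, 220L))

  expect_error(stack_to_volume(list()), "empty")
  expect_error(stack_to_volume(list(sl, matrix(0L, 10, 10))), "ragged")
})

test_that("embedded sphere voxel count matches analytic volume and brute force", {
  h <- 0.033
  vol <- generate_slab_phantom(3.2, "fat", grid = c(80L, 80L, 100L))
  v <- embed_cancer(vol, diameter = 1.0, depth = 1.0)
  n <- attr(v, "cancer")$n_voxels
  expect_equal(n, sum(v$labels == 4L))
  analytic <- (pi / 6) * 1.0^3 / h^3
  expect_lt(abs(n - analytic) / analytic, 0.01)
  # brute-force enumeration oracle over the whole grid
  ctr <- attr(v, "cancer")$center
  d <- dim(vol$labels)
  cx <- (seq_len(d[1]) - 0.5) * h; cy <- (seq_len(d[2]) - 0.5) * h
  cz <- (seq_len(d[3]) - 0.5) * h
  inside <- outer(outer((cx - ctr[1])^2, (cy - ctr[2])^2, "+"),
                  (cz - ctr[3])^2, "+") <= 0.5^2
  expect_equal(n, sum(inside))
  expect_identical(which(v$labels == 4L), which(inside))
})

test_that("a one-voxel sphere centered on a voxel center labels exactly one voxel", {
  h <- 0.033
  vol <- generate_slab_phantom(2.0, "fat", grid = c(40L, 40L, 60L))
  r <- h / 2
  depth <- (20 - 0.5) * h - r  # center lands on a voxel center in z
  v <- embed_cancer(vol, diameter = h, depth = depth, x = h / 2, y = h / 2)
  expect_equal(attr(v, "cancer")$n_voxels, 1L)
})

test_that("the depth convention anchors the sphere's upper surface", {
  h <- 0.033
  vol <- generate_slab_phantom(2.0, "fat", grid = c(50L, 50L, 60L))
  v <- embed_cancer(vol, diameter = 0.4, depth = 1.0)
  ci <- which(v$labels == 4L, arr.ind = TRUE)
  top <- (min(ci[, 3]) - 0.5) * h  # shallowest cancer voxel center
  expect_lt(abs(top - 1.0), h / 2 + 1e-12)
})

test_that("embedding then erasing restores the volume exactly", {
  vol <- generate_slab_phantom(2.0, "fat", grid = c(40L, 40L, 60L))
  v <- embed_cancer(vol, 0.3, 0.5)
  expect_gt(attr(v, "cancer")$n_voxels, 0)
  back <- erase_cancer(v)
  expect_identical(back$labels, vol$labels)
  expect_error(erase_cancer(back), "no cancer placement")
})

test_that("impossible placements raise placement errors", {
  vol <- generate_slab_phantom(1.0, "fat", grid = c(40L, 40L, 60L))
  # sphere reaching below the slab into air
  expect_error(embed_cancer(vol, 0.6, 0.8), "outside the tissue")
  # sphere hanging above the surface
  expect_error(embed_cancer(vol, 0.6, -0.2), "depth")
  # laterally off the grid
  expect_error(embed_cancer(vol, 0.4, 0.2, x = 10), "outside")
})

test_that("cancer voxels touching air violate volume validation", {
  lab <- array(0L, dim = c(8, 8, 8))
  lab[3:6, 3:6, 3:6] <- 2L
  lab[3, 4, 4] <- 4L  # cancer voxel on the tissue/air boundary
  expect_error(label_volume(lab), "touch ambient")
})

test_that("label volumes round-trip through NIfTI plus sidecar bit-exactly", {
  vol <- small_cancer_slab()
  path <- file.path(withr::local_tempdir(), "vol.nii.gz")
  write_label_volume(vol, path)
  back <- read_label_volume(path)
  expect_identical(back$labels, vol$labels)
  expect_equal(back$voxel_size, vol$voxel_size)
  expect_equal(back$origin, vol$origin)
})
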