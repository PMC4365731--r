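# 2 mm isotropic test grid, world-symmetric about x = 0 so mirrored
# sphere ROIs have mirrored voxel counts.
sym_grid <- function() {
  affine <- rbind(cbind(diag(3) * 2, c(-19, -19, -19)), c(0, 0, 0, 1))
  voxel_grid(c(20L, 20L, 20L), affine)
}

test_that("NIfTI masks round-trip through write and read", {
  g <- sym_grid()
  set.seed(61)
  vox <- unique(cbind(sample(3:18, 7, TRUE), sample(3:18, 7, TRUE),
                      sample(3:18, 7, TRUE)))
  m <- rsagram:::new_roi_mask(g, vox, "toy", "L")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m, path)
  m2 <- read_mask(path, roi_id = "toy", hemisphere = "L")
  expect_equal(nrow(m2$voxels), nrow(vox))
  expect_setequal(apply(m2$voxels, 1, paste, collapse = ","),
                  apply(vox, 1, paste, collapse = ","))
  expect_true(rsagram:::grids_equal(m2$grid, g))
  # an all-zero mask is rejected
  zero <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(rsagram:::as_nifti_image(array(0, g$shape), g), zero)
  expect_error(read_mask(zero), "empty")
})

test_that("sphere ROIs match a brute-force voxel-center scan", {
  g <- sym_grid()
  # radius 0 at an exact voxel center selects exactly that voxel
  center <- as.numeric(rsagram:::voxel_world(g, matrix(c(5L, 7L, 9L), 1)))
  m0 <- make_sphere_roi(center, 0, g)
  expect_equal(nrow(m0$voxels), 1)
  expect_equal(as.integer(m0$voxels), c(5L, 7L, 9L))
  # 10 mm sphere vs an independent exhaustive scan
  ctr <- c(-8, 4, -2)
  m <- make_sphere_roi(ctr, 10, g)
  count <- 0L
  for (i in 1:20) for (j in 1:20) for (k in 1:20) {
    w <- g$affine %*% c(i - 1, j - 1, k - 1, 1)
    if (sum((w[1:3] - ctr)^2) <= 100 + 1e-9) count <- count + 1L
  }
  expect_equal(nrow(m$voxels), count)
  expect_error(make_sphere_roi(c(500, 0, 0), 5, g), "no voxel")
})

test_that("mirrored sphere centers give mirrored voxel counts", {
  g <- sym_grid()
  lh <- make_sphere_roi(c(-9, 4, -2), 10, g)
  rh <- make_sphere_roi(c(9, 4, -2), 10, g)
  expect_equal(nrow(lh$voxels), nrow(rh$voxels))
  expect_setequal(-(rsagram:::voxel_world(g, lh$voxels)[, 1]),
                  rsagram:::voxel_world(g, rh$voxels)[, 1])
})

test_that("sphere membership is invariant to whole-voxel translation", {
  g <- sym_grid()
  m1 <- make_sphere_roi(c(-5, 1, 3), 7, g)
  m2 <- make_sphere_roi(c(-5 + 2, 1 + 4, 3 - 2), 7, g)  # +1, +2, -1 voxels
  shifted <- sweep(m1$voxels, 2, c(1L, 2L, -1L), `+`)
  expect_setequal(apply(shifted, 1, paste, collapse = ","),
                  apply(m2$voxels, 1, paste, collapse = ","))
})

test_that("anterior/posterior split partitions the mask", {
  g <- sym_grid()
  m <- make_sphere_roi(c(0, 0, 0), 12, g, roi_id = "STG", hemisphere = "L")
  halves <- split_anterior_posterior(m)
  keys <- function(v) apply(v, 1, paste, collapse = ",")
  expect_equal(halves$anterior$roi_id, "aSTG")
  expect_equal(halves$posterior$roi_id, "pSTG")
  expect_length(intersect(keys(halves$anterior$voxels),
                          keys(halves$posterior$voxels)), 0)
  expect_setequal(c(keys(halves$anterior$voxels),
                    keys(halves$posterior$voxels)), keys(m$voxels))
  ya <- rsagram:::voxel_world(g, halves$anterior$voxels)[, 2]
  yp <- rsagram:::voxel_world(g, halves$posterior$voxels)[, 2]
  expect_gt(min(ya), max(yp) - 1e-9)
  # boundary below every voxel leaves the posterior half empty
  expect_error(split_anterior_posterior(m, boundary_y_mm = -100), "empty")
  halves2 <- suppressWarnings(
    split_anterior_posterior(m, boundary_y_mm = -100, require_both = FALSE))
  expect_null(halves2$posterior)
  expect_equal(nrow(halves2$anterior$voxels), nrow(m$voxels))
})

test_that("pattern extraction recovers planted voxel values from NIfTI", {
  g <- sym_grid()
  labels <- condition_labels(build_condition_set())
  m <- make_sphere_roi(c(0, 0, 0), 9, g, roi_id = "blob")
  n_vox <- nrow(m$voxels)
  expect_gte(n_vox, 50)
  set.seed(62)
  truth <- matrix(rnorm(n_vox * 12), n_vox, 12)
  dir <- withr::local_tempdir()
  paths <- character(0)
  for (ci in seq_along(labels)) {
    arr <- array(0, g$shape)
    arr[m$voxels] <- truth[, ci]
    p <- file.path(dir, paste0("cond-", labels[ci], ".nii.gz"))
    RNifti::writeNifti(rsagram:::as_nifti_image(arr, g), p)
    paths[labels[ci]] <- p
  }
  pm <- extract_patterns(paths, m, subject_id = "S01")
  expect_equal(dim(pm$values), c(n_vox, 12L))
  expect_equal(unname(pm$values), truth, tolerance = 1e-12)
  # three hand-picked voxels cross-checked through an independent reader
  pick <- c(1, 7, 33)
  img <- RNifti::readNifti(paths[labels[4]])
  for (v in pick) {
    expect_equal(unname(pm$values[v, 4]),
                 as.numeric(img[matrix(m$voxels[v, ], 1)]))
  }
  expect_error(extract_patterns(paths[-3], m), "missing condition")
  # grid mismatch is caught
  g2 <- voxel_grid(g$shape, rbind(cbind(diag(3) * 3, c(-19, -19, -19)),
                                  c(0, 0, 0, 1)))
  m2 <- make_sphere_roi(c(0, 0, 0), 9, g2, roi_id = "blob")
  expect_error(extract_patterns(paths, m2), "grid mismatch")
})

test_that("non-finite voxels are dropped with a message", {
  g <- sym_grid()
  labels <- condition_labels(build_condition_set())
  m <- make_sphere_roi(c(0, 0, 0), 6, g, roi_id = "blob")
  set.seed(63)
  dir <- withr::local_tempdir()
  paths <- character(0)
  for (ci in seq_along(labels)) {
    arr <- array(rnorm(prod(g$shape)), g$shape)
    if (ci == 2) arr[matrix(m$voxels[3, ], 1)] <- NaN
    p <- file.path(dir, paste0("cond-", labels[ci], ".nii.gz"))
    RNifti::writeNifti(rsagram:::as_nifti_image(arr, g), p)
    paths[labels[ci]] <- p
  }
  expect_message(pm <- extract_patterns(paths, m), "dropping 1")
  expect_equal(nrow(pm$values), nrow(m$voxels) - 1)
})

test_that("ROI catalogues mix mask files and sphere specs", {
  g <- rsagram::default_grid()
  dir <- withr::local_tempdir()
  m <- make_sphere_roi(c(-36, 20, -3), 10, g, roi_id = "L_FOP",
                       hemisphere = "L")
  write_mask(m, file.path(dir, "lfop.nii.gz"))
  cat_tab <- data.frame(
    roi_id = c("L_FOP", "R_FOP"),
    hemisphere = c("L", "R"),
    source = c("lfop.nii.gz", "sphere:36,20,-3,10"),
    stringsAsFactors = FALSE)
  write.table(cat_tab, file.path(dir, "catalogue.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  rois <- read_roi_catalogue(file.path(dir, "catalogue.tsv"), grid = g)
  expect_setequal(names(rois), c("L_FOP", "R_FOP"))
  expect_equal(nrow(rois$L_FOP$voxels), nrow(m$voxels))
  expect_gt(nrow(rois$R_FOP$voxels), 0)
})
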