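# Volumetric ROI handling: NIfTI masks, sphere ROIs around MNI
# coordinates, anterior/posterior splits, and voxel-pattern extraction.
#
# Conventions: voxel indices are 1-based R array indices; the NIfTI affine
# maps the 0-based index (i-1, j-1, k-1) to world (MNI mm) coordinates, so
# world = affine %*% c(idx - 1, 1). Sphere membership uses voxel centers.

#' Voxel grid: shape plus voxel-to-world affine
#'
#' @param shape Integer 3-vector of grid dimensions.
#' @param affine 4 x 4 voxel-to-world (mm) transform, applied to 0-based
#'   voxel indices per the NIfTI convention.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) {
    stop("shape must be 3 positive integers", call. = FALSE)
  }
  affine <- unname(as.matrix(affine))
  if (!identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine)) < .Machine$double.eps) {
    stop("affine must be an invertible 4 x 4 matrix", call. = FALSE)
  }
  structure(list(shape = shape, affine = affine), class = "voxel_grid")
}

#' Default synthetic analysis grid
#'
#' A 3 mm isotropic grid of 40 x 48 x 40 voxels whose origin places world
#' (0, 0, 0) near the grid center, covering roughly MNI
#' x in -60..57, y in -84..57, z in -48..69 mm.
#'
#' @return A [voxel_grid()].
#' @export
default_grid <- function() {
  affine <- rbind(cbind(diag(3) * 3, c(-60, -84, -48)), c(0, 0, 0, 1))
  voxel_grid(c(40L, 48L, 40L), affine)
}

grids_equal <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) < tol
}

voxel_world <- function(grid, voxels) {
  # voxels: n x 3 matrix of 1-based indices -> n x 3 world mm
  h <- cbind(voxels - 1, 1)
  t(grid$affine %*% t(h))[, 1:3, drop = FALSE]
}

new_roi_mask <- function(grid, voxels, roi_id, hemisphere = NA_character_) {
  voxels <- matrix(as.integer(voxels), ncol = 3)
  if (nrow(voxels) == 0) {
    stop("empty ROI mask: ", roi_id, call. = FALSE)
  }
  if (any(voxels < 1) || any(sweep(voxels, 2, grid$shape, `>`))) {
    stop("ROI voxel indices outside grid for ", roi_id, call. = FALSE)
  }
  structure(list(grid = grid, voxels = voxels, roi_id = roi_id,
                 hemisphere = hemisphere),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("ROI mask `", x$roi_id, "`: ", nrow(x$voxels), " voxels on a ",
      paste(x$grid$shape, collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

nifti_grid <- function(img) {
  voxel_grid(dim(img)[1:3], structure(RNifti::xform(img), code = NULL))
}

as_nifti_image <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  pd <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- pd
  aff <- grid$affine
  attr(aff, "code") <- 2L
  RNifti::qform(img) <- aff
  img
}

#' Read a binary ROI mask from NIfTI
#'
#' Voxels with value > 0.5 are in the mask; the voxel grid (shape and
#' affine) is captured from the header.
#'
#' @param path Path to a 3-D NIfTI file.
#' @param roi_id,hemisphere Labels for the resulting mask (default: file
#'   stem, unknown hemisphere).
#' @return An `roi_mask`.
#' @export
read_mask <- function(path, roi_id = NULL, hemisphere = NA_character_) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) {
    stop("mask is not a 3-D image: ", path, call. = FALSE)
  }
  if (is.null(roi_id)) roi_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  vox <- which(img > 0.5, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("empty ROI mask: ", path, call. = FALSE)
  new_roi_mask(nifti_grid(img), vox, roi_id, hemisphere)
}

#' Write an ROI mask to NIfTI
#'
#' @param mask An `roi_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  arr <- array(0, mask$grid$shape)
  arr[mask$voxels] <- 1
  RNifti::writeNifti(as_nifti_image(arr, mask$grid), path)
  invisible(path)
}

#' Sphere ROI around a world-space coordinate
#'
#' Selects the voxels whose centers lie within a Euclidean `radius_mm` of
#' `center_mm` (MNI mm). This is how the frontal operculum ROI is defined:
#' a 10 mm sphere centered on MNI (-36, 20, -3), mirrored to (36, 20, -3)
#' for the right hemisphere.
#'
#' @param center_mm World-space center, length-3 numeric (mm).
#' @param radius_mm Sphere radius (mm, >= 0).
#' @param grid A [voxel_grid()].
#' @param roi_id,hemisphere Labels.
#' @return An `roi_mask`.
#' @export
make_sphere_roi <- function(center_mm, radius_mm, grid,
                            roi_id = "sphere", hemisphere = NA_character_) {
  if (radius_mm < 0) stop("radius must be >= 0", call. = FALSE)
  all_vox <- as.matrix(expand.grid(seq_len(grid$shape[1]),
                                   seq_len(grid$shape[2]),
                                   seq_len(grid$shape[3])))
  w <- voxel_world(grid, all_vox)
  d2 <- (w[, 1] - center_mm[1])^2 + (w[, 2] - center_mm[2])^2 +
    (w[, 3] - center_mm[3])^2
  inside <- d2 <= radius_mm^2 + 1e-9
  if (!any(inside)) {
    stop("sphere ROI `", roi_id, "` contains no voxel centers ",
         "(outside the grid?)", call. = FALSE)
  }
  new_roi_mask(grid, all_vox[inside, , drop = FALSE], roi_id, hemisphere)
}

#' Split an ROI into anterior and posterior parts
#'
#' Partitions the mask at a world-space y coordinate: anterior voxels have
#' y > `boundary_y_mm`, posterior voxels the rest. By default the boundary
#' is the mask's own median y, so the halves are balanced per region. The
#' outputs carry `a`/`p` prefixes on the ROI id.
#'
#' @param mask An `roi_mask`.
#' @param boundary_y_mm Boundary (mm); default the median voxel-center y.
#' @param require_both Error if either half is empty (default `TRUE`);
#'   otherwise empty halves are returned as `NULL` with a warning.
#' @return A list with elements `anterior` and `posterior`.
#' @export
split_anterior_posterior <- function(mask, boundary_y_mm = NULL,
                                     require_both = TRUE) {
  y <- voxel_world(mask$grid, mask$voxels)[, 2]
  if (is.null(boundary_y_mm)) boundary_y_mm <- stats::median(y)
  ant <- y > boundary_y_mm
  halves <- list(anterior = NULL, posterior = NULL)
  make_half <- function(sel, prefix) {
    if (!any(sel)) {
      msg <- paste0("anterior/posterior split of `", mask$roi_id,
                    "` at y = ", boundary_y_mm, " leaves the ",
                    prefix, " half empty")
      if (require_both) stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      return(NULL)
    }
    new_roi_mask(mask$grid, mask$voxels[sel, , drop = FALSE],
                 paste0(substr(prefix, 1, 1), mask$roi_id),
                 mask$hemisphere)
  }
  halves$anterior <- make_half(ant, "anterior")
  halves$posterior <- make_half(!ant, "posterior")
  halves
}

#' Extract a pattern matrix from per-condition images
#'
#' Reads the per-condition volumetric parameter-estimate images, samples
#' them at the mask's voxels, and assembles the voxel x condition matrix in
#' the design's fixed condition order. All images must share the mask's
#' grid. Voxels with any non-finite value across conditions are dropped
#' with a message.
#'
#' @param condition_images Named character vector or list mapping condition
#'   label to NIfTI path; must cover all conditions in `conditions`.
#' @param mask An `roi_mask`.
#' @param subject_id Label.
#' @param conditions Condition order (default the canonical 12).
#' @return A [pattern_matrix()].
#' @export
extract_patterns <- function(condition_images, mask, subject_id = "sub",
                             conditions = condition_labels(build_condition_set())) {
  condition_images <- unlist(condition_images)
  missing <- setdiff(conditions, names(condition_images))
  if (length(missing) > 0) {
    stop("missing condition image(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- sapply(conditions, function(cond) {
    img <- RNifti::readNifti(condition_images[[cond]])
    if (!grids_equal(nifti_grid(img), mask$grid)) {
      stop("grid mismatch between mask `", mask$roi_id,
           "` and condition image for ", cond, call. = FALSE)
    }
    img[mask$voxels]
  })
  bad <- rowSums(!is.finite(vals)) > 0
  if (any(bad)) {
    message("extract_patterns: dropping ", sum(bad),
            " voxel(s) with non-finite values in ROI ", mask$roi_id)
    vals <- vals[!bad, , drop = FALSE]
  }
  pattern_matrix(vals, roi_id = mask$roi_id, subject_id = subject_id,
                 conditions = conditions)
}

#' Read an ROI catalogue
#'
#' A TSV with columns `roi_id`, `hemisphere`, `source`: `source` is either
#' a mask path (relative to the catalogue) or a sphere spec
#' `sphere:x,y,z,r` in mm.
#'
#' @param path Catalogue TSV path.
#' @param grid Grid used for sphere ROIs.
#' @return Named list of `roi_mask` objects.
#' @export
read_roi_catalogue <- function(path, grid = default_grid()) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  base <- dirname(path)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    src <- tab$source[i]
    if (startsWith(src, "sphere:")) {
      nums <- as.numeric(strsplit(sub("^sphere:", "", src), ",")[[1]])
      m <- make_sphere_roi(nums[1:3], nums[4], grid,
                           roi_id = tab$roi_id[i],
                           hemisphere = tab$hemisphere[i])
    } else {
      m <- read_mask(file.path(base, src), roi_id = tab$roi_id[i],
                     hemisphere = tab$hemisphere[i])
    }
    out[[tab$roi_id[i]]] <- m
  }
  out
}
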