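# Synthetic multi-subject study generator: voxel patterns with planted
# representational geometry, so the full pipeline can be exercised and
# verified without external imaging data.

#' Condition covariance implied by a model RDM
#'
#' Bridges a hypothesis model RDM to a generative condition covariance:
#' similarity `S = 1 - dissim` on constrained cells,
#' `unconstrained_similarity` on unconstrained cells, 1 on the diagonal;
#' then `Sigma = alpha S + (1 - alpha) I`, projected to the nearest
#' positive semidefinite matrix by clipping negative eigenvalues at zero
#' and re-symmetrizing.
#'
#' The default `unconstrained_similarity = 0` makes condition pairs the
#' model is agnostic about generate mutually independent patterns -- the
#' faithful generative reading of "agnostic" for detector models. Planting
#' an intermediate similarity (e.g. 0.5) instead induces graded structure
#' among non-target conditions that fully constrained categorical models
#' partially predict, which blurs the identity of the planted model.
#'
#' @param model A `model_rdm`.
#' @param alpha Mixing weight in `[0, 1]`: 0 gives the identity (no
#'   planted geometry), 1 the raw similarity matrix.
#' @param unconstrained_similarity Similarity planted on cells the model
#'   leaves unconstrained (default 0).
#' @return A positive semidefinite condition x condition matrix.
#' @export
similarity_covariance <- function(model, alpha = 0.5,
                                  unconstrained_similarity = 0) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  s <- 1 - model$dissim
  s[is.na(s)] <- unconstrained_similarity
  diag(s) <- 1
  sigma <- alpha * s + (1 - alpha) * diag(nrow(s))
  e <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  sigma <- e$vectors %*% (vals * t(e$vectors))
  dimnames(sigma) <- dimnames(model$dissim)
  (sigma + t(sigma)) / 2
}

#' Simulate voxel patterns for one ROI
#'
#' Per subject, generates a voxel x condition matrix as
#' `signal + noise`: each voxel's signal row is drawn i.i.d. from a
#' zero-mean Gaussian with the model-implied condition covariance
#' ([similarity_covariance()]), rescaled so the ratio of mean signal
#' variance to (unit) noise variance equals `snr`; noise is i.i.d.
#' standard normal. `model = "noise"` forces `snr = 0` (pure noise).
#'
#' @param model A `model_rdm`, or the string `"noise"`.
#' @param n_voxels Number of voxels (>= 10).
#' @param n_subjects Number of subjects (>= 1).
#' @param snr Signal-to-noise variance ratio (>= 0).
#' @param alpha Geometry mixing for [similarity_covariance()].
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream (used when a study-level seed governs generation).
#' @param conditions Condition labels.
#' @param roi_id Label stamped on the pattern matrices.
#' @return A list of [pattern_matrix()] objects, one per subject.
#' @export
simulate_roi_patterns <- function(model, n_voxels, n_subjects = 18L,
                                  snr = 5, alpha = 0.5, seed = NULL,
                                  conditions = condition_labels(build_condition_set()),
                                  roi_id = "roi") {
  if (n_voxels < 10) stop("n_voxels must be >= 10", call. = FALSE)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (snr < 0) stop("snr must be >= 0", call. = FALSE)
  is_noise <- identical(model, "noise")
  if (is_noise) snr <- 0
  n_c <- length(conditions)
  if (!is.null(seed)) set.seed(seed)
  if (snr > 0) {
    sigma <- similarity_covariance(model, alpha)
    e <- eigen(sigma, symmetric = TRUE)
    sq <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    scale <- sqrt(snr / mean(diag(sigma)))
  }
  lapply(seq_len(n_subjects), function(s) {
    noise <- matrix(stats::rnorm(n_voxels * n_c), n_voxels, n_c)
    if (snr > 0) {
      z <- matrix(stats::rnorm(n_voxels * n_c), n_voxels, n_c)
      vals <- scale * (z %*% sq) + noise
    } else {
      vals <- noise
    }
    pattern_matrix(vals, roi_id = roi_id,
                   subject_id = sprintf("S%02d", s),
                   conditions = conditions)
  })
}

#' Default ROI roster of the bilateral language network
#'
#' The 22 regions of interest: Brodmann areas 44, 45 and 47, the frontal
#' operculum (FOP), anterior and posterior superior / middle / inferior
#' temporal gyri, and the temporal pole, each in the left and right
#' hemisphere.
#'
#' @return A data frame with columns `roi_id`, `region`, `hemisphere`.
#' @export
default_roi_roster <- function() {
  regions <- c("BA44", "BA45", "BA47", "FOP", "aSTG", "pSTG",
               "aMTG", "pMTG", "aITG", "pITG", "TP")
  hemis <- c("L", "R")
  grid <- expand.grid(region = regions, hemisphere = hemis,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$roi_id <- paste(grid$hemisphere, grid$region, sep = "_")
  grid[, c("roi_id", "region", "hemisphere")]
}

#' Default planted scenario
#'
#' Which hypothesis geometry each ROI carries in the default synthetic
#' study: the inflection detector in L BA44, L pSTG and L aITG; the phrase
#' detector in bilateral aSTG and aMTG and in L pMTG (the left-lateralized
#' inflectional vs bilateral phrasal topography the detector analysis is
#' designed to resolve). All other ROIs are pure noise.
#'
#' @return Named character vector: roi_id -> model name or `"noise"`.
#' @export
default_planted_scenario <- function() {
  roster <- default_roi_roster()
  truth <- stats::setNames(rep("noise", nrow(roster)), roster$roi_id)
  truth[c("L_BA44", "L_pSTG", "L_aITG")] <- "detector_inflected"
  truth[c("L_aSTG", "R_aSTG", "L_aMTG", "R_aMTG", "L_pMTG")] <-
    "detector_phrase"
  truth
}

#' Simulate a full multi-subject study
#'
#' Generates voxel x condition pattern matrices for every subject and ROI,
#' with per-ROI planted model geometry given by a scenario, and records
#' the ground truth. Per-ROI voxel counts are drawn log-uniformly from
#' `voxel_range`, fixed by the seed. Identical seeds give bit-identical
#' studies.
#'
#' @param n_subjects Number of subjects (default 18).
#' @param scenario Named character vector roi_id -> model name or
#'   `"noise"` (default [default_planted_scenario()]).
#' @param snr Signal-to-noise variance ratio for planted ROIs (default 5).
#' @param alpha Geometry mixing (default 0.5).
#' @param voxel_range Length-2 range for log-uniform per-ROI voxel counts
#'   (default `c(50, 500)`).
#' @param seed Integer seed (required).
#' @param cs Condition set.
#' @return An object of class `synthetic_study`: list with `patterns`
#'   (`[[roi_id]][[subject_id]]`), `truth`, `roster`, `n_voxels`,
#'   `n_subjects`, `snr`, `alpha`, `seed`, `conditions`.
#' @export
simulate_study <- function(n_subjects = 18L,
                           scenario = default_planted_scenario(),
                           snr = 5, alpha = 0.5,
                           voxel_range = c(50L, 500L),
                           seed, cs = build_condition_set()) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for a reproducible study", call. = FALSE)
  }
  stopifnot_condition_set(cs)
  roi_ids <- names(scenario)
  if (is.null(roi_ids) || length(roi_ids) == 0) {
    stop("invalid scenario: must be a named roi_id -> model vector",
         call. = FALSE)
  }
  models <- standard_models(cs)
  bad <- setdiff(unique(scenario), c(names(models), "noise",
                                     paste0("dominance_detector_",
                                            SEQUENCE_TYPES)))
  if (length(bad) > 0) {
    stop("unknown planted model(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in setdiff(unique(scenario), c(names(models), "noise"))) {
    models[[nm]] <- dominance_modulated_detector(
      cs, sub("^dominance_detector_", "", nm))
  }
  set.seed(seed)
  n_vox <- round(exp(stats::runif(length(roi_ids),
                                  log(voxel_range[1]),
                                  log(voxel_range[2]))))
  names(n_vox) <- roi_ids
  patterns <- list()
  for (roi in roi_ids) {
    planted <- scenario[[roi]]
    mdl <- if (planted == "noise") "noise" else models[[planted]]
    subj <- simulate_roi_patterns(mdl, n_voxels = n_vox[[roi]],
                                  n_subjects = n_subjects, snr = snr,
                                  alpha = alpha, seed = NULL,
                                  conditions = condition_labels(cs),
                                  roi_id = roi)
    names(subj) <- vapply(subj, `[[`, character(1), "subject_id")
    patterns[[roi]] <- subj
  }
  roster <- default_roi_roster()
  roster <- roster[match(roi_ids, roster$roi_id), ]
  roster$roi_id <- roi_ids  # keep custom ids even off-roster
  roster$hemisphere[is.na(roster$hemisphere)] <-
    substr(roi_ids[is.na(roster$hemisphere)], 1, 1)
  structure(list(patterns = patterns, truth = scenario, roster = roster,
                 n_voxels = n_vox, n_subjects = as.integer(n_subjects),
                 snr = snr, alpha = alpha, seed = seed,
                 conditions = condition_labels(cs)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", x$n_subjects, "subjects x",
      length(x$patterns), "ROIs,", "snr =", x$snr,
      ", seed =", x$seed, "\n")
  planted <- x$truth[x$truth != "noise"]
  cat("Planted:", if (length(planted) == 0) "none" else
    paste(names(planted), planted, sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' Export a synthetic study as NIfTI volumes plus masks
#'
#' Writes one 3-D image per subject and condition
#' (`sub-<id>/cond-<label>.nii.gz`), one mask per ROI
#' (`masks/<roi_id>.nii.gz`), an ROI catalogue TSV and a truth manifest
#' JSON. ROIs are placed in disjoint blocks of a shared grid; condition
#' images carry each ROI's pattern values at its voxels (zero elsewhere),
#' so [extract_patterns()] on the export recovers the generator's
#' matrices.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory.
#' @param grid Target grid (default [default_grid()]).
#' @return Invisibly, a list with `masks` (roi_id -> mask path),
#'   `images` (`[[subject_id]]`: condition -> path), `catalogue`, `truth`.
#' @export
export_study_nifti <- function(study, dir, grid = default_grid()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  roi_ids <- names(study$patterns)
  # disjoint blocks: 10 x 10 x 6 = 600 voxels per block, filled in order
  block <- c(10L, 10L, 6L)
  per_axis <- grid$shape %/% block
  if (prod(per_axis) < length(roi_ids)) {
    stop("grid too small to place ", length(roi_ids), " ROIs", call. = FALSE)
  }
  if (max(study$n_voxels) > prod(block)) {
    stop("an ROI exceeds the block capacity of ", prod(block), " voxels",
         call. = FALSE)
  }
  masks <- list(); mask_paths <- character(0)
  for (k in seq_along(roi_ids)) {
    b <- k - 1L
    bx <- b %% per_axis[1]
    by <- (b %/% per_axis[1]) %% per_axis[2]
    bz <- b %/% (per_axis[1] * per_axis[2])
    offs <- c(bx, by, bz) * block
    nv <- study$n_voxels[[roi_ids[k]]]
    local_idx <- arrayInd(seq_len(nv), block)
    vox <- sweep(local_idx, 2, offs, `+`)
    m <- new_roi_mask(grid, vox, roi_ids[k],
                      study$roster$hemisphere[k])
    masks[[roi_ids[k]]] <- m
    p <- file.path(dir, "masks", paste0(roi_ids[k], ".nii.gz"))
    write_mask(m, p)
    mask_paths[roi_ids[k]] <- p
  }
  subjects <- names(study$patterns[[1]])
  images <- list()
  for (sub in subjects) {
    sdir <- file.path(dir, paste0("sub-", sub))
    dir.create(sdir, showWarnings = FALSE)
    paths <- character(0)
    for (ci in seq_along(study$conditions)) {
      cond <- study$conditions[ci]
      arr <- array(0, grid$shape)
      for (roi in roi_ids) {
        arr[masks[[roi]]$voxels] <- study$patterns[[roi]][[sub]]$values[, ci]
      }
      p <- file.path(sdir, paste0("cond-", cond, ".nii.gz"))
      img <- as_nifti_image(arr, grid)
      RNifti::writeNifti(img, p, datatype = "float")
      paths[cond] <- p
    }
    images[[sub]] <- paths
  }
  catalogue <- data.frame(
    roi_id = roi_ids,
    hemisphere = study$roster$hemisphere,
    source = file.path("masks", paste0(roi_ids, ".nii.gz")),
    stringsAsFactors = FALSE)
  cat_path <- file.path(dir, "roi_catalogue.tsv")
  utils::write.table(catalogue, cat_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(as.list(study$truth), truth_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(masks = mask_paths, images = images,
                 catalogue = cat_path, truth = truth_path))
}
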