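# End-to-end orchestration: patterns -> per-subject RDMs -> group RDMs ->
# model fits with permutation inference and FDR -> model comparisons ->
# MDS table, all written as tidy TSVs plus a JSON run manifest.

#' Fit hypothesis models across regions
#'
#' For each region: averages the per-subject activation RDMs, tests each
#' model with [permutation_test()], then computes FDR across regions
#' within each model family (mirroring correction for the number of
#' regions tested in each model).
#'
#' @param patterns Nested list `[[roi_id]][[subject_id]]` of
#'   [pattern_matrix()] objects.
#' @param models Named list of `model_rdm` objects.
#' @param method Correlation method.
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @param fdr `"storey"` (default) or `"bh"`.
#' @param drop_degenerate Drop subject/ROI pattern matrices that raise
#'   degenerate-pattern errors, with a warning (default `TRUE`).
#' @return A list with `fits` (data frame: region, hemisphere, model,
#'   statistic, p_value, q_value, n_perm, seed), `region_rdms` (group
#'   averages), `subject_rdms` (per region), and `dropped` (character).
#' @export
fit_models <- function(patterns, models,
                       method = c("spearman", "kendall_tau_a", "pearson"),
                       n_perm = 10000L, seed, fdr = c("storey", "bh"),
                       drop_degenerate = TRUE) {
  method <- match.arg(method)
  fdr <- match.arg(fdr)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required", call. = FALSE)
  }
  region_rdms <- list(); subject_rdms <- list(); dropped <- character(0)
  for (roi in names(patterns)) {
    rdms <- list()
    for (sub in names(patterns[[roi]])) {
      r <- tryCatch(activation_rdm(patterns[[roi]][[sub]]),
                    error = function(e) e)
      if (inherits(r, "error")) {
        if (!drop_degenerate) stop(r)
        warning("dropping subject ", sub, " in ROI ", roi, ": ",
                conditionMessage(r), call. = FALSE)
        dropped <- c(dropped, paste0(roi, "/", sub))
      } else {
        rdms[[sub]] <- r
      }
    }
    if (length(rdms) == 0) {
      warning("dropping ROI ", roi, ": no usable subjects", call. = FALSE)
      dropped <- c(dropped, roi)
      next
    }
    subject_rdms[[roi]] <- rdms
    region_rdms[[roi]] <- average_rdms(rdms)
  }
  rows <- list()
  set.seed(seed)
  test_seeds <- matrix(
    sample.int(.Machine$integer.max,
               length(region_rdms) * length(models)),
    nrow = length(region_rdms),
    dimnames = list(names(region_rdms), names(models)))
  for (roi in names(region_rdms)) {
    hemi <- sub("_.*$", "", roi)
    for (mn in names(models)) {
      pt <- permutation_test(region_rdms[[roi]], models[[mn]],
                             method = method, n_perm = n_perm,
                             seed = test_seeds[roi, mn])
      rows[[length(rows) + 1L]] <- data.frame(
        region = roi, hemisphere = hemi, model = mn,
        statistic = pt$statistic, p_value = pt$p_value,
        q_value = NA_real_, n_perm = pt$n_perm, seed = seed,
        stringsAsFactors = FALSE)
    }
  }
  fits <- do.call(rbind, rows)
  for (mn in unique(fits$model)) {
    sel <- fits$model == mn
    fits$q_value[sel] <- if (fdr == "storey") {
      storey_qvalues(fits$p_value[sel])$qvalues
    } else {
      stats::p.adjust(fits$p_value[sel], method = "BH")
    }
  }
  list(fits = fits, region_rdms = region_rdms,
       subject_rdms = subject_rdms, dropped = dropped)
}

#' Run the full RSA pipeline
#'
#' Orchestrates the whole analysis from a configuration: obtains patterns
#' (from a synthetic-study spec, a pattern manifest, or a NIfTI tree plus
#' ROI catalogue), computes per-subject and group activation RDMs, fits
#' the requested hypothesis models with permutation inference and FDR,
#' runs the requested model-vs-model comparisons, builds the region-model
#' MDS table, and (optionally) writes the results bundle.
#'
#' @param config A named list (or path to a YAML file) with fields:
#'   `seed` (required); `input` -- either
#'   `list(type = "synthetic", n_subjects =, snr =, alpha =, scenario =)`,
#'   `list(type = "manifest", path =)`, or
#'   `list(type = "nifti", images =, catalogue =)` where `images` is
#'   `[[subject_id]]` condition -> path;
#'   `models` (character, default all five standard models);
#'   `method` (default `"spearman"`); `n_perm` (default 10000);
#'   `fdr` (`"storey"`/`"bh"`); `comparisons` (list of model-name pairs);
#'   `output_dir` (optional; results written there if given).
#' @return An object of class `rsa_results`: list with `fits`,
#'   `comparisons`, `mds`, `region_rdms`, `subject_rdms`, `truth` (if
#'   synthetic), `config`, `manifest`.
#' @export
run_rsa <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  seed <- as.integer(config$seed)
  method <- if (is.null(config$method)) "spearman" else config$method
  n_perm <- if (is.null(config$n_perm)) 10000L else as.integer(config$n_perm)
  fdr <- if (is.null(config$fdr)) "storey" else config$fdr
  cs <- build_condition_set()
  model_names <- if (is.null(config$models)) {
    c("general_complexity", "complexity_type", "detector_stem",
      "detector_inflected", "detector_phrase")
  } else unlist(config$models)
  models <- standard_models(cs, names = model_names)

  input <- config$input
  if (is.null(input)) input <- list(type = "synthetic")
  truth <- NULL
  if (identical(input$type, "manifest")) {
    patterns <- read_pattern_manifest(input$path)
  } else if (identical(input$type, "nifti")) {
    rois <- read_roi_catalogue(input$catalogue)
    patterns <- list()
    for (roi in names(rois)) {
      for (sub in names(input$images)) {
        patterns[[roi]][[sub]] <- extract_patterns(
          input$images[[sub]], rois[[roi]], subject_id = sub,
          conditions = condition_labels(cs))
      }
    }
  } else if (is.null(input$type) || identical(input$type, "synthetic")) {
    scen <- if (is.null(input$scenario)) default_planted_scenario()
            else unlist(input$scenario)
    study <- simulate_study(
      n_subjects = if (is.null(input$n_subjects)) 18L
                   else as.integer(input$n_subjects),
      scenario = scen,
      snr = if (is.null(input$snr)) 5 else input$snr,
      alpha = if (is.null(input$alpha)) 0.5 else input$alpha,
      voxel_range = if (is.null(input$voxel_range)) c(50L, 500L)
                    else unlist(input$voxel_range),
      seed = seed, cs = cs)
    patterns <- study$patterns
    truth <- study$truth
  } else {
    stop("unknown input type: ", input$type, call. = FALSE)
  }

  fit <- fit_models(patterns, models, method = method, n_perm = n_perm,
                    seed = seed, fdr = fdr)

  comparisons <- NULL
  pairs <- config$comparisons
  if (is.null(pairs) && length(models) > 1) {
    pairs <- list()
    if (all(c("complexity_type", "general_complexity") %in% names(models))) {
      pairs <- c(pairs, list(c("complexity_type", "general_complexity")))
    }
    if (all(c("detector_phrase", "detector_inflected") %in% names(models))) {
      pairs <- c(pairs, list(c("detector_phrase", "detector_inflected")))
    }
  }
  if (length(pairs) > 0) {
    rows <- list()
    for (pr in pairs) {
      for (roi in names(fit$subject_rdms)) {
        cmp <- compare_models(fit$subject_rdms[[roi]],
                              models[[pr[1]]], models[[pr[2]]],
                              method = method, n_perm = n_perm,
                              seed = seed)
        rows[[length(rows) + 1L]] <- data.frame(
          region = roi, model_a = pr[1], model_b = pr[2],
          mean_difference = cmp$mean_difference, p_value = cmp$p_value,
          exhaustive = cmp$exhaustive, stringsAsFactors = FALSE)
      }
    }
    comparisons <- do.call(rbind, rows)
  }

  mds <- NULL
  if (length(fit$region_rdms) + length(models) >= 3) {
    dt <- model_region_distances(fit$region_rdms, models, method = method,
                                 model_pairs = "neutral")
    mds <- classical_mds(dt, dims = 2L)
  }

  manifest <- list(
    package = "rsagram",
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, method = method, n_perm = n_perm, fdr = fdr,
    models = names(models),
    n_regions = length(fit$region_rdms),
    dropped = fit$dropped,
    input_type = if (is.null(input$type)) "synthetic" else input$type)

  res <- structure(list(fits = fit$fits, comparisons = comparisons,
                        mds = mds, region_rdms = fit$region_rdms,
                        subject_rdms = fit$subject_rdms, truth = truth,
                        config = config, manifest = manifest),
                   class = "rsa_results")
  if (!is.null(config$output_dir)) {
    write_results(res, config$output_dir)
  }
  res
}

#' @export
print.rsa_results <- function(x, ...) {
  cat("RSA results:", length(x$region_rdms), "regions x",
      length(unique(x$fits$model)), "models; seed", x$manifest$seed, "\n")
  sig <- x$fits[x$fits$q_value < 0.05, ]
  cat(nrow(sig), "region-model fits significant at q < 0.05\n")
  invisible(x)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an RSA results bundle
#'
#' Writes `fits.tsv`, `comparisons.tsv` (if any), `mds_coordinates.tsv`
#' and `mds_residuals.tsv` (if computed), one group RDM TSV per region
#' under `rdms/`, and `manifest.json`. All outputs are plain text and
#' byte-stable for a fixed config and seed.
#'
#' @param res An `rsa_results` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$fits, file.path(dir, "fits.tsv"))
  if (!is.null(res$comparisons)) {
    write_tsv(res$comparisons, file.path(dir, "comparisons.tsv"))
  }
  if (!is.null(res$mds)) {
    coords <- data.frame(entity = rownames(res$mds$coordinates),
                         res$mds$coordinates, stringsAsFactors = FALSE)
    colnames(coords) <- c("entity",
                          paste0("dim", seq_len(ncol(coords) - 1)))
    write_tsv(coords, file.path(dir, "mds_coordinates.tsv"))
    write_tsv(res$mds$residuals, file.path(dir, "mds_residuals.tsv"))
  }
  dir.create(file.path(dir, "rdms"), showWarnings = FALSE)
  for (roi in names(res$region_rdms)) {
    write_rdm(res$region_rdms[[roi]],
              file.path(dir, "rdms", paste0(roi, ".tsv")))
  }
  manifest <- res$manifest
  if (!is.null(res$truth)) manifest$truth <- as.list(res$truth)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
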