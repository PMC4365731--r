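# First-order RDMs: correlation distances between condition patterns.

#' Pattern matrix for one subject in one ROI
#'
#' Wraps a voxel x condition matrix of per-condition activity estimates
#' (GLM betas, arbitrary units) with its provenance labels. Columns must
#' follow the condition order of the design's [build_condition_set()].
#'
#' @param values Numeric matrix, voxels in rows, conditions in columns.
#' @param roi_id,subject_id Character labels.
#' @param conditions Character vector of condition labels (defaults to the
#'   canonical 12-condition order); length must equal `ncol(values)`.
#' @return An object of class `pattern_matrix`.
#' @export
pattern_matrix <- function(values, roi_id = "roi", subject_id = "sub",
                           conditions = condition_labels(build_condition_set())) {
  values <- as.matrix(values)
  if (nrow(values) < 2) {
    stop("pattern matrix needs at least 2 voxels", call. = FALSE)
  }
  if (ncol(values) != length(conditions)) {
    stop("pattern matrix has ", ncol(values), " columns but ",
         length(conditions), " condition labels", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("pattern matrix contains non-finite values (subject ", subject_id,
         ", ROI ", roi_id, ")", call. = FALSE)
  }
  colnames(values) <- conditions
  structure(list(values = values, roi_id = roi_id, subject_id = subject_id,
                 conditions = conditions),
            class = "pattern_matrix")
}

#' @export
print.pattern_matrix <- function(x, ...) {
  cat("Pattern matrix: subject", x$subject_id, "ROI", x$roi_id, "--",
      nrow(x$values), "voxels x", ncol(x$values), "conditions\n")
  invisible(x)
}

#' Correlation distance between two voxel patterns
#'
#' The dissimilarity between two activation patterns is `1 - r`, where `r`
#' is the Pearson correlation across voxels; values lie in `[0, 2]`.
#' A pattern with zero variance across voxels has no defined correlation
#' and raises an error rather than propagating `NaN`.
#'
#' @param x,y Numeric vectors of equal length (>= 2 voxels).
#' @return A scalar distance in `[0, 2]`.
#' @examples
#' correlation_distance(c(1, 2, 3), c(2, 4, 6))  # 0
#' correlation_distance(c(1, 2, 3), c(3, 2, 1))  # 2
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("patterns must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate pattern: zero variance across voxels", call. = FALSE)
  }
  1 - stats::cor(x, y)
}

new_rdm <- function(dissim, conditions = colnames(dissim), n_subjects = 1L) {
  dimnames(dissim) <- list(conditions, conditions)
  structure(list(dissim = dissim, conditions = conditions,
                 n_subjects = as.integer(n_subjects)),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat("RDM:", nrow(x$dissim), "x", ncol(x$dissim), "correlation distances",
      sprintf("(n_subjects = %d)\n", x$n_subjects))
  invisible(x)
}

#' Activation RDM from a pattern matrix
#'
#' Computes the full condition x condition matrix of correlation distances
#' (`1 - r`, Pearson across voxels) between all pairs of condition
#' patterns. The result is symmetric with a zero diagonal. A condition
#' whose pattern is constant across voxels is degenerate and raises an
#' error naming the condition.
#'
#' @param p A [pattern_matrix()].
#' @return An object of class `rdm` with `n_subjects = 1`.
#' @export
activation_rdm <- function(p) {
  if (!inherits(p, "pattern_matrix")) {
    stop("expected a `pattern_matrix`", call. = FALSE)
  }
  v <- p$values
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- p$conditions[sds == 0]
    stop("degenerate pattern (zero variance across voxels) for condition(s) ",
         paste(bad, collapse = ", "), " in subject ", p$subject_id,
         ", ROI ", p$roi_id, call. = FALSE)
  }
  d <- 1 - stats::cor(v)
  diag(d) <- 0
  d <- (d + t(d)) / 2  # remove floating asymmetry
  new_rdm(d, p$conditions, n_subjects = 1L)
}

#' Average RDMs across subjects
#'
#' Cell-wise arithmetic mean of a list of same-shape RDMs; the result's
#' `n_subjects` is the sum of the inputs' counts. This is the group-level
#' RDM compared against hypothesis models.
#'
#' @param rdms Non-empty list of `rdm` objects with identical dimensions.
#' @return An `rdm`.
#' @export
average_rdms <- function(rdms) {
  if (length(rdms) == 0) stop("need at least one RDM", call. = FALSE)
  if (!all(vapply(rdms, inherits, logical(1), "rdm"))) {
    stop("all elements must be `rdm` objects", call. = FALSE)
  }
  dims <- vapply(rdms, function(r) nrow(r$dissim), integer(1))
  if (length(unique(dims)) != 1) {
    stop("RDM shape mismatch: ", paste(unique(dims), collapse = " vs "),
         call. = FALSE)
  }
  mean_d <- Reduce(`+`, lapply(rdms, `[[`, "dissim")) / length(rdms)
  new_rdm(mean_d, rdms[[1]]$conditions,
          n_subjects = sum(vapply(rdms, `[[`, integer(1), "n_subjects")))
}

#' Write / read an RDM as TSV
#'
#' Tab-separated square matrix with condition labels as header row and
#' first column; numbers are written with 17 significant digits so the
#' round trip is exact.
#'
#' @param r An `rdm`.
#' @param path File path.
#' @return `write_rdm` returns `path` invisibly; `read_rdm` returns an
#'   `rdm` (with `n_subjects` recovered from the header comment).
#' @export
write_rdm <- function(r, path) {
  labels <- r$conditions
  header <- paste0("# rdm n_subjects=", r$n_subjects)
  body <- c(paste(c("condition", labels), collapse = "\t"),
            vapply(seq_along(labels), function(i) {
              paste(c(labels[i], sprintf("%.17g", r$dissim[i, ])),
                    collapse = "\t")
            }, character(1)))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  lines <- readLines(path)
  n_subjects <- 1L
  if (startsWith(lines[1], "#")) {
    n_subjects <- as.integer(sub("^.*n_subjects=(\\d+).*$", "\\1", lines[1]))
    lines <- lines[-1]
  }
  tab <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                           row.names = 1, check.names = FALSE)
  new_rdm(unname(as.matrix(tab)), colnames(tab), n_subjects = n_subjects)
}

#' Read pattern matrices from a manifest
#'
#' Loads a study laid out as per-subject/ROI TSV pattern files listed in a
#' manifest with columns `subject_id`, `roi_id`, `path` (paths relative to
#' the manifest's directory). Each pattern file is a voxel x condition TSV
#' with a condition-label header row.
#'
#' @param manifest_path Path to the manifest TSV.
#' @return A nested list: `patterns[[roi_id]][[subject_id]]` of
#'   [pattern_matrix()] objects.
#' @export
read_pattern_manifest <- function(manifest_path) {
  man <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "roi_id", "path")
  if (!all(need %in% colnames(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  out <- list()
  for (i in seq_len(nrow(man))) {
    tab <- utils::read.table(file.path(base, man$path[i]), sep = "\t",
                             header = TRUE, check.names = FALSE)
    pm <- pattern_matrix(as.matrix(tab), roi_id = man$roi_id[i],
                         subject_id = man$subject_id[i],
                         conditions = colnames(tab))
    out[[man$roi_id[i]]][[man$subject_id[i]]] <- pm
  }
  out
}

#' @rdname read_pattern_manifest
#' @param patterns Nested list `[[roi_id]][[subject_id]]` of pattern
#'   matrices.
#' @param dir Output directory (created if absent).
#' @export
write_pattern_manifest <- function(patterns, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (roi in names(patterns)) {
    for (sub in names(patterns[[roi]])) {
      p <- patterns[[roi]][[sub]]
      rel <- file.path(paste0("sub-", sub),
                       paste0("roi-", roi, "_patterns.tsv"))
      dir.create(file.path(dir, dirname(rel)), recursive = TRUE,
                 showWarnings = FALSE)
      utils::write.table(
        as.data.frame(p$values), file.path(dir, rel), sep = "\t",
        row.names = FALSE, quote = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sub, roi_id = roi, path = rel,
        stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, rows)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}
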