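# Hypothesis model RDMs. Each model is a 12 x 12 matrix of predicted
# dissimilarities in [0, 1]; cells the hypothesis is agnostic about
# (including the diagonal) are NA and are excluded from all second-order
# correlations downstream.

new_model_rdm <- function(name, dissim, labels) {
  dimnames(dissim) <- list(labels, labels)
  diag(dissim) <- NA_real_
  obj <- structure(list(name = name, dissim = dissim), class = "model_rdm")
  validate_model_rdm(obj)
  obj
}

validate_model_rdm <- function(m) {
  d <- m$dissim
  if (!isTRUE(all.equal(d, t(d)))) {
    stop("model RDM `", m$name, "` is not symmetric", call. = FALSE)
  }
  vals <- d[upper.tri(d)]
  vals <- vals[!is.na(vals)]
  if (any(vals < 0 | vals > 1)) {
    stop("model RDM `", m$name, "` has constrained values outside [0, 1]",
         call. = FALSE)
  }
  if (length(unique(vals)) < 2) {
    stop("model RDM `", m$name,
         "` has fewer than 2 distinct constrained values; ",
         "rank correlation would be undefined", call. = FALSE)
  }
  invisible(m)
}

#' @export
print.model_rdm <- function(x, ...) {
  n_con <- sum(!is.na(x$dissim[upper.tri(x$dissim)]))
  cat("Model RDM `", x$name, "`: ", nrow(x$dissim), " x ", ncol(x$dissim),
      ", ", n_con, " constrained upper-triangle cells\n", sep = "")
  invisible(x)
}

model_mask <- function(m) !is.na(m$dissim)

#' General complexity model RDM
#'
#' Two-class categorical hypothesis: any grammatically complex sequence
#' (inflected form or phrase) evokes a pattern similar to every other
#' complex sequence and dissimilar to the pattern evoked by a bare stem.
#' Within-class cells (complex--complex and stem--stem) are 0, cross-class
#' cells are 1; all off-diagonal cells are constrained.
#'
#' Stem--stem cells default to 0 (the standard two-class convention for a
#' "category present" rank-correlation test); set
#' `constrain_stem_pairs = FALSE` to leave them unconstrained instead.
#'
#' @param cs A [build_condition_set()] object.
#' @param constrain_stem_pairs Logical; constrain stem--stem cells to 0
#'   (default `TRUE`) or mark them unconstrained.
#' @return A `model_rdm`.
#' @export
general_complexity_model <- function(cs = build_condition_set(),
                                     constrain_stem_pairs = TRUE) {
  stopifnot_condition_set(cs)
  complex <- cs$conditions$sequence_type != "stem"
  d <- outer(complex, complex, FUN = function(a, b) as.numeric(a != b))
  if (!constrain_stem_pairs) {
    d[outer(!complex, !complex, `&`)] <- NA_real_
  }
  new_model_rdm("general_complexity", d, condition_labels(cs))
}

#' Complexity-type model RDM
#'
#' Three-class categorical hypothesis: activation patterns are similar
#' within each sequence type (stem, inflected, phrase) and distinct between
#' types. Within-type cells are 0, between-type cells are 1; all
#' off-diagonal cells are constrained.
#'
#' @inheritParams general_complexity_model
#' @return A `model_rdm`.
#' @export
complexity_type_model <- function(cs = build_condition_set()) {
  stopifnot_condition_set(cs)
  ty <- cs$conditions$sequence_type
  d <- outer(ty, ty, FUN = function(a, b) as.numeric(a != b))
  new_model_rdm("complexity_type", d, condition_labels(cs))
}

#' Detector model RDM for one sequence type
#'
#' A detector selects regions where processing of a single sequence type
#' statistically dominates: the four conditions of the target type are
#' mutually similar (0) and dissimilar (1) to every non-target condition,
#' with equal weight to all four dominance categories. Cells among
#' non-target conditions are unconstrained by default, so the model is
#' agnostic to any structure there; `nontarget_value` can set them to a
#' fixed dissimilarity (e.g. 0.5) for a fully constrained variant.
#'
#' @inheritParams general_complexity_model
#' @param target One of `"stem"`, `"inflected"`, `"phrase"`.
#' @param nontarget_value `NA` (default, unconstrained) or a value in
#'   `[0, 1]` for non-target/non-target cells.
#' @return A `model_rdm`.
#' @export
detector_model <- function(cs = build_condition_set(),
                           target = c("stem", "inflected", "phrase"),
                           nontarget_value = NA_real_) {
  stopifnot_condition_set(cs)
  target <- match.arg(target)
  tg <- cs$conditions$sequence_type == target
  d <- outer(tg, tg, FUN = function(a, b) as.numeric(a != b))
  d[outer(!tg, !tg, `&`)] <- nontarget_value
  new_model_rdm(paste0("detector_", target), d, condition_labels(cs))
}

#' Dominance-modulated detector model RDM
#'
#' Weights a [detector_model()] by the stems' verb/noun dominance: within
#' the target type, the predicted dissimilarity between two conditions is
#' the absolute difference of their category dominance weights, grouping
#' the verb-unique and verb-dominant sets (weights 1.0 and 0.84) apart from
#' the noun-dominant and noun-unique sets (0.06 and 0.0). Target vs
#' non-target cells remain 1 and non-target cells unconstrained (or
#' `nontarget_value`).
#'
#' @inheritParams detector_model
#' @return A `model_rdm`.
#' @export
dominance_modulated_detector <- function(cs = build_condition_set(),
                                         target = c("stem", "inflected",
                                                    "phrase"),
                                         nontarget_value = NA_real_) {
  stopifnot_condition_set(cs)
  target <- match.arg(target)
  tg <- cs$conditions$sequence_type == target
  w <- unname(cs$weights[cs$conditions$category])
  d <- outer(tg, tg, FUN = function(a, b) as.numeric(a != b))
  within <- outer(tg, tg, `&`)
  d[within] <- abs(outer(w, w, `-`))[within]
  d[outer(!tg, !tg, `&`)] <- nontarget_value
  new_model_rdm(paste0("dominance_detector_", target), d,
                condition_labels(cs))
}

#' The five standard hypothesis models
#'
#' Convenience constructor for the full model family fit by the pipeline:
#' general complexity, complexity type, and the inflection and phrase
#' detectors in plain and dominance-modulated form.
#'
#' @inheritParams general_complexity_model
#' @param names Optional character subset of model names to build.
#' @return A named list of `model_rdm` objects.
#' @export
standard_models <- function(cs = build_condition_set(), names = NULL) {
  all <- list(
    general_complexity = general_complexity_model(cs),
    complexity_type = complexity_type_model(cs),
    detector_inflected = detector_model(cs, "inflected"),
    detector_phrase = detector_model(cs, "phrase"),
    detector_stem = detector_model(cs, "stem"))
  if (!is.null(names)) {
    unknown <- setdiff(names, c(names(all),
                                paste0("dominance_detector_",
                                       SEQUENCE_TYPES)))
    if (length(unknown) > 0) {
      stop("unknown model name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    extra <- intersect(names, paste0("dominance_detector_", SEQUENCE_TYPES))
    for (nm in extra) {
      tgt <- sub("^dominance_detector_", "", nm)
      all[[nm]] <- dominance_modulated_detector(cs, tgt)
    }
    all <- all[names]
  }
  all
}

#' Write / read a model RDM as TSV
#'
#' Plain-text exchange format: a single `#`-prefixed header line naming the
#' model and the condition order, then a 12 x 12 tab-separated matrix with
#' `NA` for unconstrained cells.
#'
#' @param m A `model_rdm`.
#' @param path Output file path.
#' @return `write_model_rdm` returns `path` invisibly; `read_model_rdm`
#'   returns a `model_rdm`.
#' @export
write_model_rdm <- function(m, path) {
  labels <- colnames(m$dissim)
  header <- paste0("# model=", m$name, " conditions=",
                   paste(labels, collapse = ","))
  lines <- apply(m$dissim, 1, function(row) {
    paste(ifelse(is.na(row), "NA", sprintf("%.17g", row)), collapse = "\t")
  })
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_model_rdm
#' @export
read_model_rdm <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "#")) {
    stop("not a model RDM TSV (missing header line): ", path, call. = FALSE)
  }
  name <- sub("^#\\s*model=(\\S+).*$", "\\1", lines[1])
  labels <- strsplit(sub("^.*conditions=(\\S+).*$", "\\1", lines[1]),
                     ",")[[1]]
  d <- as.matrix(utils::read.table(text = lines[-1], sep = "\t",
                                   na.strings = "NA"))
  if (nrow(d) != length(labels) || ncol(d) != length(labels)) {
    stop("model RDM dimensions do not match header condition list",
         call. = FALSE)
  }
  new_model_rdm(name, unname(d), labels)
}
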