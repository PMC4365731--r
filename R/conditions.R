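#' Sequence types and dominance categories of the grammatical design
#'
#' The design crosses three types of spoken sequence -- a bare stem
#' (e.g. *sing*, *rug*), its inflected form (*sings*, *rugs*) and a minimal
#' phrase (*I sing*, *a rug*) -- with four verb/noun dominance categories of
#' the underlying stem set: verb-unique, verb-dominant, noun-dominant and
#' noun-unique. Each category carries a dominance weight, the mean
#' verb/(verb+noun) usage ratio of its stems on a 0--1 scale.
#'
#' @name design-constants
#' @keywords internal
NULL

SEQUENCE_TYPES <- c("stem", "inflected", "phrase")

DOMINANCE_CATEGORIES <- c("verb_unique", "verb_dominant",
                          "noun_dominant", "noun_unique")

DEFAULT_DOMINANCE_WEIGHTS <- c(verb_unique   = 1.0,
                               verb_dominant = 0.84,
                               noun_dominant = 0.06,
                               noun_unique   = 0.0)

#' Build the canonical 12-condition set
#'
#' Constructs the ordered set of 12 experimental conditions: the cross of the
#' three sequence types (`stem`, `inflected`, `phrase`) with the four
#' dominance categories (`verb_unique`, `verb_dominant`, `noun_dominant`,
#' `noun_unique`). The ordering is fixed -- sequence types major, categories
#' in the order above -- so that RDM cell indices are reproducible across
#' runs, fixtures and exported matrices.
#'
#' @param weights Optional named numeric vector mapping the four dominance
#'   categories to weights in `[0, 1]`. Defaults to the design's mean
#'   dominance values: verb_unique 1.0, verb_dominant 0.84, noun_dominant
#'   0.06, noun_unique 0.0.
#' @return An object of class `condition_set`: a list with `conditions`
#'   (a data frame with columns `label`, `sequence_type`, `category`),
#'   `weights`, and `n` (always 12 for the full design).
#' @examples
#' cs <- build_condition_set()
#' cs$n
#' cs$weights[["verb_dominant"]]
#' @export
build_condition_set <- function(weights = NULL) {
  if (is.null(weights)) {
    weights <- DEFAULT_DOMINANCE_WEIGHTS
  } else {
    if (!is.numeric(weights) || is.null(names(weights))) {
      stop("`weights` must be a named numeric vector", call. = FALSE)
    }
    missing <- setdiff(DOMINANCE_CATEGORIES, names(weights))
    if (length(missing) > 0) {
      stop("`weights` must name all four dominance categories; missing: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    weights <- weights[DOMINANCE_CATEGORIES]
    if (any(!is.finite(weights)) || any(weights < 0) || any(weights > 1)) {
      stop("dominance weights must lie in [0, 1]", call. = FALSE)
    }
  }
  grid <- expand.grid(category = DOMINANCE_CATEGORIES,
                      sequence_type = SEQUENCE_TYPES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("sequence_type", "category")]
  grid$label <- paste(grid$sequence_type, grid$category, sep = ".")
  structure(
    list(conditions = grid[, c("label", "sequence_type", "category")],
         weights = weights,
         n = nrow(grid)),
    class = "condition_set")
}

#' @export
print.condition_set <- function(x, ...) {
  cat("Condition set:", x$n, "conditions",
      "(", length(unique(x$conditions$sequence_type)), "sequence types x",
      length(unique(x$conditions$category)), "dominance categories )\n")
  cat("Order:", paste(x$conditions$label, collapse = ", "), "\n")
  cat("Weights:",
      paste(names(x$weights), format(x$weights), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

condition_labels <- function(cs) cs$conditions$label

stopifnot_condition_set <- function(cs) {
  if (!inherits(cs, "condition_set")) {
    stop("expected a `condition_set` (see build_condition_set())",
         call. = FALSE)
  }
  invisible(cs)
}

#' Summary counts of the stimulus design
#'
#' Returns the bookkeeping totals of the auditory stimulus design: 160
#' matched stems (40 in each of the four dominance categories), each
#' presented once as a bare stem, once inflected and once in a minimal
#' phrase (480 test items), mixed with 240 acoustic-baseline and 240 silence
#' trials.
#'
#' @param stems_per_category Number of stems per dominance category
#'   (default 40).
#' @param n_baseline Number of acoustic baseline trials (default 240).
#' @param n_silence Number of silence trials (default 240).
#' @return A named list of integer counts: `n_conditions`, `n_categories`,
#'   `n_sequence_types`, `stems_per_category`, `n_stems`,
#'   `presentations_per_stem`, `n_test_items`, `items_per_condition`,
#'   `n_baseline`, `n_silence`, `n_trials_total`.
#' @export
stimulus_design <- function(stems_per_category = 40L,
                            n_baseline = 240L, n_silence = 240L) {
  n_cat <- length(DOMINANCE_CATEGORIES)
  n_typ <- length(SEQUENCE_TYPES)
  n_stems <- stems_per_category * n_cat
  n_test <- n_stems * n_typ
  list(n_conditions = n_cat * n_typ,
       n_categories = n_cat,
       n_sequence_types = n_typ,
       stems_per_category = as.integer(stems_per_category),
       n_stems = as.integer(n_stems),
       presentations_per_stem = n_typ,
       n_test_items = as.integer(n_test),
       items_per_condition = as.integer(n_test / (n_cat * n_typ)),
       n_baseline = as.integer(n_baseline),
       n_silence = as.integer(n_silence),
       n_trials_total = as.integer(n_test + n_baseline + n_silence))
}
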