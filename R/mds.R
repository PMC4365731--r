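# Second-order geometry: distances between regions and hypothesis models,
# embedded in low dimension with classical (Torgerson) MDS.

#' Distance table between regions and models
#'
#' Builds the symmetric matrix of second-order correlation distances
#' (`1 - correlation`) among a set of regions (their group-averaged
#' activation RDMs) and hypothesis models. Region-model cells use the
#' model's constrained cells; model-model cells use the cells constrained
#' in both models; region-region cells correlate full upper triangles.
#'
#' Two detector models constrain only their mutual cross-class cells,
#' where both predict a constant 1, so their joint correlation is
#' undefined; with `model_pairs = "error"` (default) such pairs raise an
#' error naming them, while `model_pairs = "neutral"` fills unconstrained
#' cells of both models with a neutral 0.5 for model-model cells only
#' (region-model cells always use the model's own constrained cells,
#' matching the fitted statistic).
#'
#' @param region_rdms Named list of `rdm` objects (group averages).
#' @param models Named list of `model_rdm` objects.
#' @param method Correlation method, as in [rdm_correlation()].
#' @param model_pairs `"error"` or `"neutral"`; see Details.
#' @return An object of class `distance_table`: list with `entities`,
#'   `kind` (`"region"`/`"model"`), and `dist` (symmetric matrix, zero
#'   diagonal).
#' @export
model_region_distances <- function(region_rdms, models,
                                   method = c("spearman", "kendall_tau_a",
                                              "pearson"),
                                   model_pairs = c("error", "neutral")) {
  method <- match.arg(method)
  model_pairs <- match.arg(model_pairs)
  n_r <- length(region_rdms); n_m <- length(models)
  if (n_r + n_m < 2) stop("need at least 2 entities", call. = FALSE)
  entities <- c(names(region_rdms), names(models))
  kind <- c(rep("region", n_r), rep("model", n_m))
  n <- n_r + n_m
  d <- matrix(0, n, n, dimnames = list(entities, entities))
  ut_of <- function(m) m[upper.tri(m)]
  pair_cor <- function(a, b) {
    if (length(unique(a)) < 2 || length(unique(b)) < 2 || length(a) < 3) {
      stop("insufficient usable cells for a second-order correlation",
           call. = FALSE)
    }
    second_order_cor(a, b, method)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- tryCatch({
        if (kind[i] == "region" && kind[j] == "region") {
          pair_cor(ut_of(region_rdms[[i]]$dissim),
                   ut_of(region_rdms[[j]]$dissim))
        } else if (kind[i] == "region" && kind[j] == "model") {
          rdm_correlation(region_rdms[[i]], models[[j - n_r]], method)
        } else {
          ma <- models[[i - n_r]]$dissim; mb <- models[[j - n_r]]$dissim
          if (model_pairs == "neutral") {
            ma[is.na(ma)] <- 0.5; mb[is.na(mb)] <- 0.5
          }
          keep <- upper.tri(ma) & !is.na(ma) & !is.na(mb)
          pair_cor(ma[keep], mb[keep])
        }
      }, error = function(e) {
        stop("cannot compute second-order distance between `", entities[i],
             "` and `", entities[j], "`: ", conditionMessage(e),
             call. = FALSE)
      })
      d[i, j] <- d[j, i] <- 1 - r
    }
  }
  structure(list(entities = entities, kind = kind, dist = d),
            class = "distance_table")
}

#' @export
print.distance_table <- function(x, ...) {
  cat("Distance table:", sum(x$kind == "region"), "regions,",
      sum(x$kind == "model"), "models\n")
  invisible(x)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a distance table in `dims` dimensions via the double-centering
#' eigendecomposition ([stats::cmdscale()]), with a canonical orientation:
#' axes are ordered by eigenvalue, and each axis's sign is fixed so that
#' the entity with the largest absolute loading on it (lexicographically
#' first label on ties) loads positively. Per-pair residuals between
#' embedded and input distances are reported so projection distortion is
#' explicit rather than hidden.
#'
#' @param d A [model_region_distances()] table, or a symmetric distance
#'   matrix with dimnames.
#' @param dims Embedding dimension (default 2), `>= 1` and smaller than the
#'   number of entities.
#' @return A list with `coordinates` (entity x dims matrix), `eigenvalues`,
#'   `residuals` (data frame: entity_a, entity_b, input_distance,
#'   embedded_distance, residual), and `stress` (root-mean-square
#'   residual).
#' @export
classical_mds <- function(d, dims = 2L) {
  dm <- if (inherits(d, "distance_table")) d$dist else as.matrix(d)
  n <- nrow(dm)
  if (dims < 1 || dims >= n) {
    stop("dims must be >= 1 and < number of entities", call. = FALSE)
  }
  off <- dm[upper.tri(dm)]
  if (length(unique(round(off, 12))) == 1) {
    warning("all pairwise distances are equal; embedding is degenerate",
            call. = FALSE)
  }
  fit <- stats::cmdscale(stats::as.dist(dm), k = dims, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < dims) {  # cmdscale drops axes with ~zero eigenvalue
    coords <- cbind(coords,
                    matrix(0, n, dims - ncol(coords)))
  }
  rownames(coords) <- rownames(dm)
  # canonical sign per axis: largest |loading| (lexicographic tie-break)
  labels <- rownames(coords)
  ord <- order(labels)
  for (k in seq_len(dims)) {
    v <- coords[ord, k]
    if (all(abs(v) < 1e-12)) next
    lead <- which(abs(v) >= max(abs(v)) - 1e-12)[1]
    if (v[lead] < 0) coords[, k] <- -coords[, k]
  }
  emb <- as.matrix(stats::dist(coords))
  ut <- which(upper.tri(dm), arr.ind = TRUE)
  residuals <- data.frame(
    entity_a = rownames(dm)[ut[, 1]],
    entity_b = rownames(dm)[ut[, 2]],
    input_distance = dm[ut],
    embedded_distance = emb[ut],
    stringsAsFactors = FALSE)
  residuals$residual <- residuals$embedded_distance -
    residuals$input_distance
  list(coordinates = coords,
       eigenvalues = fit$eig,
       residuals = residuals,
       stress = sqrt(mean(residuals$residual^2)))
}
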