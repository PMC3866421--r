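#' Cortical hidden representation of a stimulus
#'
#' The developing cortical representation of an object is the settled
#' activation pattern of the cortical hidden layer. Purely a readout: no
#' weights change.
#'
#' @inheritParams forward_settle
#' @return Numeric vector of length `n_hidden_cor` (default 15).
#' @export
extract_cortical_hidden <- function(model, features) {
  forward_settle(model, features)$h_cor
}

#' Cortical hidden representations of all category prototypes
#'
#' @param model A `dual_memory_model`.
#' @param set A `stimulus_set`; its prototype vectors are run through the
#'   model.
#' @return Matrix with one row per basic-level category (rownames are
#'   category names) and one column per cortical hidden unit.
#' @export
prototype_representations <- function(model, set) {
  proto <- set$prototypes
  reps <- t(apply(proto, 1, function(x) extract_cortical_hidden(model, x)))
  colnames(reps) <- paste0("h", seq_len(ncol(reps)))
  reps
}

#' Project representation vectors onto their first principal components
#'
#' Mean-centered PCA (no scaling) of the rows of `vectors`. Components are
#' ordered by decreasing explained variance, and the sign of each component
#' is fixed so that its largest-magnitude loading is positive, making the
#' projection reproducible across platforms.
#'
#' @param vectors Numeric matrix, one representation per row (at least 2).
#' @param n_components Number of components to keep (default 2).
#' @return A list with `scores` (n x `n_components`), `loadings` (one column
#'   per component), `explained_variance` (proportion per kept component),
#'   and `center`.
#' @export
pca_project <- function(vectors, n_components = 2) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2L) stop_config("need at least 2 vectors for PCA")
  n_components <- check_count(n_components, "n_components")
  if (n_components > ncol(vectors))
    stop_config("n_components exceeds the representation dimension")
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  load <- pc$rotation[, k, drop = FALSE]
  flip <- vapply(k, function(j) {
    v <- load[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  load <- sweep(load, 2, flip, `*`)
  scores <- pc$x[, k, drop = FALSE]
  scores <- sweep(scores, 2, flip, `*`)
  colnames(scores) <- colnames(load) <- paste0("pc", k)
  ev <- pc$sdev^2
  list(scores = scores, loadings = load,
       explained_variance = (ev / sum(ev))[k], center = pc$center)
}

#' Cluster-separation metrics for grouped representations
#'
#' Quantifies how clearly representations separate by group, replacing
#' visual inspection of a 2-D projection: the mean silhouette coefficient
#' (Euclidean distance, computed in the full representation space) and the
#' ratio of the mean inter-group centroid distance to the mean within-group
#' dispersion (mean distance of members to their group centroid). Singleton
#' groups contribute silhouette width 0 and dispersion 0.
#'
#' @param vectors Numeric matrix, one representation per row.
#' @param group_labels Group membership, one per row; at least 2 distinct
#'   groups.
#' @return A list with `silhouette`, `between_within_ratio`, and `degenerate`
#'   (`TRUE` when all points coincide, in which case the silhouette is 0 and
#'   the ratio `NA`).
#' @export
cluster_separation <- function(vectors, group_labels) {
  vectors <- as.matrix(vectors)
  g <- factor(group_labels)
  if (nrow(vectors) != length(g))
    stop_config("group_labels length must match the number of rows")
  if (nlevels(g) < 2L) stop_config("need at least 2 groups")

  d <- stats::dist(vectors)
  if (all(d < .Machine$double.eps)) {
    return(list(silhouette = 0, between_within_ratio = NA_real_,
                degenerate = TRUE))
  }
  sil <- cluster::silhouette(as.integer(g), d)
  sil_mean <- mean(sil[, "sil_width"])

  centroids <- rowsum(vectors, g) / as.vector(table(g))
  cd <- stats::dist(centroids)
  between <- mean(cd)
  within <- mean(vapply(levels(g), function(lev) {
    m <- vectors[g == lev, , drop = FALSE]
    if (nrow(m) == 1L) return(0)
    mu <- centroids[lev, ]
    mean(sqrt(rowSums(sweep(m, 2, mu)^2)))
  }, numeric(1)))
  ratio <- if (within > 0) between / within else Inf
  list(silhouette = sil_mean, between_within_ratio = ratio, degenerate = FALSE)
}
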