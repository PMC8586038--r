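# Functional typing of units: SVD-based PCA of the units x phases
# z-score table, complete-linkage hierarchical clustering on the first
# three components, and mapping of the clusters to the seven canonical
# archetypes by their mean phase profiles.

#' PCA of a phase z-score table
#'
#' Column-centers the units x phases table and decomposes it by singular
#' value decomposition; scores are the centered data projected on the
#' (orthonormal) loadings. Centering is the default: without it the first
#' component is dominated by the mean profile.
#'
#' @param table numeric matrix, units x phases (e.g. the `zscores`
#'   element of [phase_responses()]), >= 2 rows, finite entries.
#' @param center column-center before decomposition (default TRUE).
#' @return object of class `pca_result`: `scores` (units x k),
#'   `loadings` (phases x k, orthonormal columns), `explained_variance`
#'   (proportion per component), `center`.
#' @export
pca_zscores <- function(table, center = TRUE) {
  X <- unclass(as.matrix(table))
  if (nrow(X) < 2L) stop("pca_zscores: need >= 2 units")
  if (any(!is.finite(X))) stop("pca_zscores: non-finite entries")
  mu <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  rownames(scores) <- rownames(X)
  rownames(sv$v) <- colnames(X)
  var_prop <- if (sum(sv$d^2) > 0) sv$d^2 / sum(sv$d^2)
  else rep(0, length(sv$d))
  structure(list(scores = scores, loadings = sv$v,
                 explained_variance = var_prop, center = mu),
            class = "pca_result")
}

#' Cluster units on the leading principal components
#'
#' Complete-linkage agglomerative clustering (Euclidean metric) on the
#' first `n_pcs` score columns, with the dendrogram cut to exactly `k`
#' clusters.
#'
#' @param pca a [pca_zscores()] result.
#' @param n_pcs number of leading components to use (default 3).
#' @param k number of clusters (default 7; must not exceed the number of
#'   units).
#' @return object of class `type_assignment`: `cluster` (named integer
#'   vector per unit), `hclust` (the merge tree), `k`, `n_pcs`.
#' @export
cluster_types <- function(pca, n_pcs = 3, k = 7) {
  stopifnot(inherits(pca, "pca_result"))
  S <- pca$scores
  if (k > nrow(S)) stop("cluster_types: k exceeds the number of units")
  n_pcs <- min(n_pcs, ncol(S))
  hc <- stats::hclust(stats::dist(S[, seq_len(n_pcs), drop = FALSE],
                                  method = "euclidean"),
                      method = "complete")
  cl <- stats::cutree(hc, k = k)
  names(cl) <- rownames(S)
  structure(list(cluster = cl, hclust = hc, k = k, n_pcs = n_pcs),
            class = "type_assignment")
}

# Sign templates over (introduction, chase, attack, eating)
# operationalizing the archetype descriptions: I responds throughout
# introduction/chase/attack and drops during eating; II/III are the
# strong attack- and chase-dominant sustained responders; IV fires only
# at introduction; V/VI are the weaker attack- and chase-preferring
# cells; VII is flat.
archetype_templates <- function() {
  rbind(I   = c(1, 1, 1, -1),
        II  = c(0, 1, 2, -1),
        III = c(0, 2, 1, -1),
        IV  = c(1, 0, 0, 0),
        V   = c(0, 1, 1, 0),
        VI  = c(0, 1, 0, 0),
        VII = c(0, 0, 0, 0))
}

#' Label clusters with canonical archetypes
#'
#' Maps each cluster to the archetype whose sign template over
#' (introduction, chase, attack, eating) best matches the cluster's mean
#' z-profile, by cosine similarity with unique (assignment-cost
#' minimizing) matching. A cluster whose mean profile is near zero maps
#' to the nonresponsive archetype VII, whose score is `1 / (1 + |profile|)`
#' so that flat clusters prefer it over any direction template.
#'
#' @param assignment a [cluster_types()] result.
#' @param table the z-score table that was clustered (units x phases,
#'   with the four hunting-phase columns present).
#' @return the assignment with `type_label` (named character vector per
#'   unit), `cluster_profiles` (clusters x phases mean z) and
#'   `cluster_type` (type per cluster id) added.
#' @export
label_types <- function(assignment, table) {
  stopifnot(inherits(assignment, "type_assignment"))
  X <- unclass(as.matrix(table))
  cl <- assignment$cluster
  stopifnot(nrow(X) == length(cl))
  tmpl <- archetype_templates()
  phases <- colnames(tmpl) <- c("introduction", "chase", "attack",
                                "eating")
  if (!all(phases %in% colnames(X)))
    stop("label_types: table lacks hunting-phase columns")
  ks <- sort(unique(cl))
  prof <- t(vapply(ks, function(k)
    colMeans(X[cl == k, phases, drop = FALSE]), numeric(4)))
  rownames(prof) <- ks; colnames(prof) <- phases

  score <- matrix(0, nrow(prof), nrow(tmpl),
                  dimnames = list(ks, rownames(tmpl)))
  for (i in seq_len(nrow(prof))) for (j in seq_len(nrow(tmpl))) {
    p <- prof[i, ]; tm <- tmpl[j, ]
    score[i, j] <- if (all(tm == 0)) 1 / (1 + sqrt(sum(p^2)))
    else if (sqrt(sum(p^2)) < 1e-12) 0
    else sum(p * tm) / (sqrt(sum(p^2)) * sqrt(sum(tm^2)))
  }
  pick <- assign_unique(score)
  cluster_type <- stats::setNames(rownames(tmpl)[pick], ks)
  assignment$type_label <- stats::setNames(cluster_type[as.character(cl)],
                                           names(cl))
  assignment$cluster_profiles <- prof
  assignment$cluster_type <- cluster_type
  assignment
}

#' @export
print.type_assignment <- function(x, ...) {
  cat(sprintf("<type_assignment> %d units in %d clusters (%d PCs)\n",
              length(x$cluster), x$k, x$n_pcs))
  if (!is.null(x$type_label)) print(table(x$type_label))
  invisible(x)
}
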