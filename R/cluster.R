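#' Hierarchical clustering of standardized site profiles
#'
#' Agglomerative clustering of matrix rows with the configured distance
#' metric and linkage (defaults: Euclidean, average), the combination used
#' for the site overview heatmap.
#'
#' @param x Standardized numeric matrix (sites x tissue.sex), no missing
#'   values.
#' @param cfg An [atlas_config()].
#' @return An `hclust` object with leaves labelled by row name.
#' @export
cluster_rows <- function(x, cfg = atlas_config()) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 2) stop("clustering requires at least 2 rows")
  if (anyNA(x)) stop("clustering input must have no missing values")
  hclust(dist(x, method = cfg$cluster_metric), method = cfg$cluster_linkage)
}

#' Cut a dendrogram into k groups
#'
#' @param hc An `hclust` object from [cluster_rows()].
#' @param k Number of groups (1..n leaves).
#' @return Named integer vector, group id per leaf.
#' @export
cut_groups <- function(hc, k) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$order)
  if (k < 1 || k > n) stop("k must be between 1 and the number of leaves")
  cutree(hc, k = k)
}

#' Per-group over-representation analysis
#'
#' For every dendrogram group and every ontology term, tests whether the
#' group's members are annotated with the term more often than the members
#' of all other groups, with a Fisher exact test (one-sided over-
#' representation by default). Membership is counted at the site level: a
#' site carries a term when its protein's (closed) annotation set does.
#'
#' @param groups Named integer vector from [cut_groups()]; names are site
#'   keys.
#' @param site_protein Named character vector mapping site key to protein id.
#' @param annotations Named list: protein id -> character vector of term ids
#'   (normally the ancestor-closed map).
#' @param cfg An [atlas_config()].
#' @return Data frame with group, term, the 2x2 counts (`in_ann`, `in_not`,
#'   `out_ann`, `out_not`), `p` and `significant`.
#' @export
group_ora <- function(groups, site_protein, annotations, cfg = atlas_config()) {
  stopifnot(!is.null(names(groups)))
  prot <- site_protein[names(groups)]
  if (anyNA(prot)) stop("every site in `groups` needs a protein mapping")
  terms <- sort(unique(unlist(annotations[unique(prot)], use.names = FALSE)))
  if (!length(terms))
    return(data.frame(group = integer(), term = character(),
                      in_ann = integer(), in_not = integer(),
                      out_ann = integer(), out_not = integer(),
                      p = numeric(), significant = logical()))
  ann_mat <- vapply(terms, function(t)
    vapply(annotations[prot], function(s) t %in% s, logical(1)),
    logical(length(prot)))
  if (is.null(dim(ann_mat))) ann_mat <- matrix(ann_mat, nrow = length(prot))
  gids <- sort(unique(groups))
  N <- length(groups)
  K <- colSums(ann_mat)                       # annotated sites overall
  res <- vector("list", length(gids))
  for (gi in seq_along(gids)) {
    in_g <- groups == gids[gi]
    n <- sum(in_g)
    k <- colSums(ann_mat[in_g, , drop = FALSE])
    p <- fisher_exact_2x2_vec(k, n - k, K - k, (N - n) - (K - k),
                              alternative = cfg$ora_alternative)
    res[[gi]] <- data.frame(group = gids[gi], term = terms,
                            in_ann = as.integer(k), in_not = as.integer(n - k),
                            out_ann = as.integer(K - k),
                            out_not = as.integer((N - n) - (K - k)),
                            p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$significant <- out$p < cfg$ora_alpha
  out
}

#' Principal component analysis of site profiles
#'
#' PCA with samples (tissue-sex columns) as observations and sites as
#' features, on a feature-wise standardized matrix. Component signs are fixed
#' deterministically: the largest-magnitude loading of each component is made
#' positive.
#'
#' @param x Standardized numeric matrix, sites x samples.
#' @return An `atlas_pca` object: `scores` (samples x components), `loadings`
#'   (sites x components, orthonormal columns), `var_explained` (fractions,
#'   non-increasing).
#' @export
pca_sites <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2) stop("PCA requires at least 2 samples")
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = load,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2)),
            class = "atlas_pca")
}

#' @export
print.atlas_pca <- function(x, ...) {
  cat(sprintf("atlas_pca: %d samples, %d features; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), nrow(x$loadings),
              100 * x$var_explained[1],
              if (length(x$var_explained) > 1) 100 * x$var_explained[2] else NA))
  invisible(x)
}

#' Top-loading features of a principal component
#'
#' @param pca An `atlas_pca` object.
#' @param component Component index (default 1).
#' @param n Number of features to return.
#' @return Data frame of feature, loading, ranked by absolute loading.
#' @export
top_loadings <- function(pca, component = 1L, n = 10L) {
  stopifnot(inherits(pca, "atlas_pca"))
  l <- pca$loadings[, component]
  ord <- order(abs(l), decreasing = TRUE)[seq_len(min(n, length(l)))]
  data.frame(feature = rownames(pca$loadings)[ord], loading = l[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
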