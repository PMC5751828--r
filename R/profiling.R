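#' PAM (k-medoids) clustering of a dissimilarity matrix
#'
#' Partitioning around medoids via `cluster::pam` (BUILD initialization
#' followed by SWAP passes until no single medoid exchange lowers the
#' objective; deterministic given the matrix). The objective reported is the
#' total dissimilarity of every sample to its medoid.
#'
#' @param d symmetric dissimilarity matrix (or `distance_matrix`).
#' @param k number of clusters, `1 <= k <= n`.
#' @return List of class `clustering_result`: `k`, `labels` (named integer
#'   vector), `medoids` (sample ids), `objective`, `avg_silhouette` (`NA`
#'   when `k` is 1 or n), and optionally `profile_names` once assigned.
#' @export
pam_fit <- function(d, k) {
  dm <- check_distance_matrix(d)
  n <- nrow(dm)
  if (k < 1 || k > n) stop_np("k must be between 1 and n = %d", n)
  ids <- rownames(dm) %||% as.character(seq_len(n))
  if (k == n) {
    labels <- setNames(seq_len(n), ids)
    res <- list(k = k, labels = labels, medoids = ids, objective = 0,
                avg_silhouette = NA_real_)
  } else {
    dd <- as.dist(dm)
    objective_of <- function(fit) {
      med_idx <- match(fit$medoids, ids)
      sum(dm[cbind(seq_len(n), med_idx[as.integer(fit$clustering)])])
    }
    # BUILD + SWAP, then a few deterministic restarts from spread-out
    # initial medoids: SWAP is a local search and can stall on tiny
    # pathological instances, so small problems get extra starts
    fit <- cluster::pam(dd, k = k, diss = TRUE)
    best_obj <- objective_of(fit)
    if (n <= 60 && k > 1) {
      for (r in seq_len(min(8, n - k))) {
        init <- withr::with_seed(r, sort(sample.int(n, k)))
        alt <- cluster::pam(dd, k = k, diss = TRUE, medoids = init)
        alt_obj <- objective_of(alt)
        if (alt_obj < best_obj - 1e-12) { fit <- alt; best_obj <- alt_obj }
      }
    }
    med_idx <- match(fit$medoids, ids)
    labels <- setNames(as.integer(fit$clustering), ids)
    objective <- best_obj
    sil <- if (k >= 2) avg_silhouette(dm, labels) else NA_real_
    res <- list(k = k, labels = labels, medoids = ids[med_idx],
                objective = objective, avg_silhouette = sil)
  }
  structure(res, class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> k=%d, objective=%.4g, avg silhouette=%s\n",
              x$k, x$objective,
              if (is.na(x$avg_silhouette)) "NA" else
                sprintf("%.3f", x$avg_silhouette)))
  if (!is.null(x$profile_names))
    cat("  profiles:", paste(x$profile_names, collapse = ", "), "\n")
  invisible(x)
}

#' Average silhouette width of a clustering
#'
#' Mean over samples of `(b - a) / max(a, b)`, with `a` the mean
#' within-cluster dissimilarity (excluding self) and `b` the smallest mean
#' dissimilarity to another cluster; samples in singleton clusters
#' contribute 0 (the `cluster::silhouette` convention).
#'
#' @param d symmetric dissimilarity matrix.
#' @param labels integer cluster assignment (>= 2 nonempty clusters).
#' @return Scalar in `[-1, 1]`.
#' @export
avg_silhouette <- function(d, labels) {
  dm <- check_distance_matrix(d)
  if (length(unique(labels)) < 2)
    stop_np("average silhouette needs at least 2 clusters")
  sil <- cluster::silhouette(as.integer(labels), dmatrix = dm)
  mean(sil[, "sil_width"])
}

#' Gap statistic over a range of cluster counts
#'
#' Tibshirani-style gap curve adapted to dissimilarity input: samples are
#' embedded by classical multidimensional scaling, `n_ref` reference data
#' sets are drawn uniformly in the embedding's bounding box, and
#' `gap(k) = mean(log W_ref(k)) - log W_obs(k)` where `W` is the PAM
#' objective (computed on the original dissimilarities for the observed
#' data, and on Euclidean distances for the references). The selected `k`
#' is the smallest with `gap(k) >= gap(k+1) - se(k+1)`. Zero-dispersion
#' solutions are handled through `log(W + eps)`.
#'
#' @param d symmetric dissimilarity matrix from point-embeddable data.
#' @param k_range strictly increasing integer vector of candidate k.
#' @param n_ref number of reference data sets.
#' @param seed integer seed.
#' @param eps offset inside the logarithm (default 1e-10).
#' @return List with `curve` (data.frame `k`, `logW`, `E_logW`, `gap`, `se`)
#'   and `k_selected`.
#' @export
gap_statistic <- function(d, k_range = 1:8, n_ref = 50, seed = NULL,
                          eps = 1e-10) {
  dm <- check_distance_matrix(d)
  if (any(diff(k_range) <= 0)) stop_np("k_range must be strictly increasing")
  n <- nrow(dm)
  # cmdscale warns when nearly all eigenvalues vanish (identical points);
  # that degenerate case is handled below, so the warning is noise here
  emb <- suppressWarnings(cmdscale(as.dist(dm), k = min(n - 1, 10),
                                   eig = TRUE))
  pts <- emb$points
  if (is.null(dim(pts)) || ncol(pts) == 0)
    pts <- matrix(0, nrow = n, ncol = 1)  # all points coincide
  rownames(pts) <- rownames(dm)
  obj_of <- function(mat_d, k) pam_fit(mat_d, k)$objective
  logW <- vapply(k_range, function(k) log(obj_of(dm, k) + eps), numeric(1))
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  ref_logW <- with_seed_or_not(seed, {
    vapply(seq_len(n_ref), function(r) {
      ref <- vapply(seq_along(lo), function(j) runif(n, lo[j], hi[j]),
                    numeric(n))
      rd <- as.matrix(dist(ref))
      rownames(rd) <- colnames(rd) <- rownames(dm)
      vapply(k_range, function(k) log(obj_of(rd, k) + eps), numeric(1))
    }, numeric(length(k_range)))
  })
  ref_logW <- matrix(ref_logW, nrow = length(k_range))
  E_logW <- rowMeans(ref_logW)
  se <- apply(ref_logW, 1, sd) * sqrt(1 + 1 / n_ref)
  gap <- E_logW - logW
  k_selected <- k_range[length(k_range)]
  for (i in seq_len(length(k_range) - 1)) {
    if (gap[i] >= gap[i + 1] - se[i + 1]) { k_selected <- k_range[i]; break }
  }
  list(curve = data.frame(k = k_range, logW = logW, E_logW = E_logW,
                          gap = gap, se = se),
       k_selected = k_selected)
}

#' Composite NS + NPA abundance vectors
#'
#' Adjoins, per subject, the NS relative abundances of the top genera and
#' the NPA relative abundances of the same genera in the same order
#' (length `2 * length(genera)`); each half sums to at most 1 because
#' subjects may carry mass outside the top genera.
#'
#' @param cohort a [paired_cohort()].
#' @param genera the top-genera panel.
#' @return Numeric matrix, one row per subject, columns `NS:<genus>` then
#'   `NPA:<genus>`.
#' @export
composite_profiles <- function(cohort, genera) {
  ns <- as_proportions(cohort$ns)$mat[, genera, drop = FALSE]
  npa <- as_proportions(cohort$npa)$mat[, genera, drop = FALSE]
  out <- cbind(ns, npa)
  colnames(out) <- c(paste0("NS:", genera), paste0("NPA:", genera))
  out
}

# silhouette-based automatic k (the primary model-selection criterion)
select_k_silhouette <- function(dm, k_range) {
  k_range <- k_range[k_range >= 2 & k_range < nrow(dm)]
  sil <- vapply(k_range, function(k) pam_fit(dm, k)$avg_silhouette,
                numeric(1))
  k_range[which.max(sil)]
}

#' Cluster subjects on composite NS + NPA profiles
#'
#' Bray-Curtis dissimilarities between the adjoined top-genera vectors of
#' [composite_profiles()], clustered by PAM. The study's composite figure
#' uses `k = 10`; `k = "auto"` selects k over 2..15 by average silhouette
#' width.
#'
#' @param cohort a [paired_cohort()].
#' @param genera top-genera panel.
#' @param k integer, or `"auto"`.
#' @return A `clustering_result` with an extra `cluster_means` matrix
#'   (per-cluster mean abundance of each composite column, the heat-map
#'   summary) and the composite matrix as attribute `"composite"`.
#' @export
cluster_composite <- function(cohort, genera, k = 10) {
  comp <- composite_profiles(cohort, genera)
  dm <- as.matrix(vegan::vegdist(comp, method = "bray"))
  dimnames(dm) <- list(rownames(comp), rownames(comp))
  if (identical(k, "auto")) k <- select_k_silhouette(dm, 2:15)
  res <- pam_fit(dm, k)
  res$cluster_means <- t(vapply(sort(unique(res$labels)), function(cl)
    colMeans(comp[res$labels == cl, , drop = FALSE]),
    numeric(ncol(comp))))
  rownames(res$cluster_means) <- paste0("cluster", sort(unique(res$labels)))
  attr(res, "composite") <- comp
  res
}

#' Cluster one site's samples into dominance profiles
#'
#' Weighted UniFrac distances between the site's genus compositions,
#' PAM clustering (the replication analysis fixes `k = 6` for the NS site),
#' and dominance-profile naming via [name_profiles()]. When every pairwise
#' distance is zero (identical samples) the single-cluster solution is
#' returned directly.
#'
#' @param table proportions-mode `abundance_table`.
#' @param tree rooted `phylo` covering the table's taxa.
#' @param k integer, or `"auto"` (silhouette-selected over 2..8).
#' @param threshold dominance threshold passed to [name_profiles()].
#' @return A `clustering_result` with `profile_names` (per cluster) and
#'   `profiles` (per sample).
#' @export
cluster_site_profiles <- function(table, tree, k = 6, threshold = 0.40) {
  dm <- distance_matrix(table, "wunifrac", tree = tree)
  if (max(dm) == 0) {
    labels <- setNames(rep(1L, nrow(dm)), rownames(dm))
    res <- structure(list(k = 1L, labels = labels,
                          medoids = rownames(dm)[1], objective = 0,
                          avg_silhouette = NA_real_),
                     class = "clustering_result")
  } else {
    if (identical(k, "auto")) k <- select_k_silhouette(unclass(dm), 2:8)
    res <- pam_fit(dm, k)
  }
  res$profile_names <- name_profiles(res, table, threshold = threshold)
  res$profiles <- setNames(res$profile_names[res$labels],
                           names(res$labels))
  res
}

#' Name clusters by dominant genus
#'
#' A cluster is named `"<Genus>-dominant"` when the within-cluster mean
#' relative abundance of its top genus reaches `threshold`, and `"Mixed"`
#' otherwise. Ties on the mean are broken by higher prevalence (fraction of
#' the cluster's samples carrying the genus), then lexicographically, so
#' naming is deterministic.
#'
#' @param result a `clustering_result`.
#' @param table proportions-mode `abundance_table` the clustering was
#'   computed from.
#' @param threshold dominance threshold on the mean relative abundance.
#' @return Character vector of names, one per cluster index.
#' @export
name_profiles <- function(result, table, threshold = 0.40) {
  p <- as_proportions(table)$mat
  clusters <- sort(unique(result$labels))
  vapply(clusters, function(cl) {
    rows <- p[result$labels == cl, , drop = FALSE]
    mu <- colMeans(rows)
    prev <- colMeans(rows > 0)
    best <- order(-mu, -prev, colnames(rows))[1]
    if (mu[best] >= threshold)
      paste0(colnames(rows)[best], "-dominant") else "Mixed"
  }, character(1))
}
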