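#' Shannon diversity index (nats)
#'
#' `-sum(p * log(p))` with the convention `0 * log(0) = 0`. Natural-log
#' scale, so the maximum for a k-taxon community is `log(k)`.
#'
#' @param p proportion vector on the simplex (sums to 1 within 1e-6).
#' @return Nonnegative scalar.
#' @export
shannon_index <- function(p) {
  if (any(p < 0)) stop_np("proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-6)
    stop_np("proportions must sum to 1 (got %.8g)", sum(p))
  q <- p[p > 0]
  -sum(q * log(q))
}

#' Per-sample richness and Shannon diversity
#'
#' Richness counts taxa with nonzero abundance. By study convention alpha
#' diversity is computed on the rarefied table; pass an un-rarefied table to
#' opt out.
#'
#' @param x an `abundance_table` (counts are normalized internally).
#' @return data.frame with columns `sample`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(x) {
  p <- as_proportions(x)
  data.frame(
    sample = sample_ids(p),
    richness = as.integer(rowSums(p$mat > 0)),
    shannon = apply(p$mat, 1, shannon_index),
    row.names = NULL
  )
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)` over a shared taxon ordering. 0 for identical
#' vectors, 1 for disjoint supports.
#'
#' @param x,y nonnegative numeric vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop_np("abundances must be nonnegative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop_np("Bray-Curtis undefined: both vectors are all-zero")
  sum(abs(x - y)) / tot
}

# samples-by-branches weight matrix: entry (s, e) = total proportion of the
# taxa descending from edge e in sample s; also returns edge lengths
branch_weights <- function(mat, tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (anyDuplicated(tips)) stop_np("tree has duplicate leaf labels")
  miss <- setdiff(colnames(mat), tips)
  if (length(miss))
    stop_np("taxon missing from tree: %s", paste(miss, collapse = ", "))
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  # per-sample proportion carried by each node's subtree, accumulated bottom-up
  w <- matrix(0, nrow = nrow(mat), ncol = nnode)
  idx <- match(colnames(mat), tips)
  w[, idx] <- mat
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    w[, parent] <- w[, parent] + w[, child]
  }
  list(weights = w[, po$edge[, 2], drop = FALSE],  # one column per edge
       lengths = po$edge.length)
}

#' Weighted UniFrac distance between two communities
#'
#' Phylogeny-aware dissimilarity: for every branch of the rooted tree, the
#' absolute difference in the total relative abundance of the taxa descending
#' from that branch is weighted by the branch length. The raw variant is
#' `sum(b * |A_b - B_b|)`; the normalized variant (default) divides by
#' `sum(b * (A_b + B_b))` so values are comparable across communities and
#' bounded in `[0, 1]`.
#'
#' @param x,y named proportion vectors; names must be leaves of `tree`.
#' @param tree rooted `ape::phylo` tree with branch lengths.
#' @param normalized divide by the abundance-weighted total branch length?
#' @return Nonnegative scalar (in `[0, 1]` when normalized).
#' @export
weighted_unifrac <- function(x, y, tree, normalized = TRUE) {
  stopifnot(!is.null(names(x)), identical(names(x), names(y)))
  bw <- branch_weights(rbind(x, y), tree)
  raw <- sum(bw$lengths * abs(bw$weights[1, ] - bw$weights[2, ]))
  if (!normalized) return(raw)
  denom <- sum(bw$lengths * (bw$weights[1, ] + bw$weights[2, ]))
  if (denom == 0) return(0)
  raw / denom
}

#' All-pairs beta-diversity matrix
#'
#' Bray-Curtis dissimilarities are delegated to `vegan::vegdist`; weighted
#' UniFrac uses a vectorized branch-incidence computation equivalent to
#' calling [weighted_unifrac()] on every pair.
#'
#' @param x an `abundance_table` in proportions mode.
#' @param metric `"braycurtis"` or `"wunifrac"`.
#' @param tree rooted `phylo`, required for `"wunifrac"`.
#' @param normalized normalized weighted UniFrac? (ignored for Bray-Curtis).
#' @return A symmetric matrix of class `distance_matrix` with sample-id
#'   dimnames and a `"metric"` attribute.
#' @export
distance_matrix <- function(x, metric = c("braycurtis", "wunifrac"),
                            tree = NULL, normalized = TRUE) {
  metric <- match.arg(metric)
  stopifnot(inherits(x, "abundance_table"))
  if (x$mode != "proportions")
    stop_np("distance_matrix expects a proportions-mode table")
  m <- x$mat
  if (metric == "braycurtis") {
    d <- as.matrix(vegan::vegdist(m, method = "bray"))
  } else {
    if (is.null(tree)) stop_np("weighted UniFrac requires a tree")
    bw <- branch_weights(m, tree)
    scaled <- sweep(bw$weights, 2, bw$lengths, `*`)
    raw <- as.matrix(dist(scaled, method = "manhattan"))
    if (normalized) {
      s <- rowSums(scaled)
      denom <- outer(s, s, `+`)
      d <- ifelse(denom > 0, raw / denom, 0)
    } else {
      d <- raw
    }
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  diag(d) <- 0
  structure(d, metric = if (metric == "wunifrac" && !normalized)
    "wunifrac_raw" else metric, class = c("distance_matrix", "matrix"))
}

#' Write / read a distance matrix as square TSV
#'
#' @param d `distance_matrix` (or plain symmetric matrix).
#' @param path file path.
#' @return `path` invisibly (writer); a `distance_matrix` (reader).
#' @export
write_distance_matrix <- function(d, path) {
  out <- cbind(sample_id = rownames(d),
               as.data.frame(matrix(sprintf("%.17g", d), nrow = nrow(d))))
  colnames(out) <- c("sample_id", colnames(d))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(m, class = c("distance_matrix", "matrix"))
}

# shared validation for clustering inputs
check_distance_matrix <- function(d) {
  d <- unclass(as.matrix(d))
  if (nrow(d) != ncol(d)) stop_np("distance matrix must be square")
  if (any(d < 0)) stop_np("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-8) stop_np("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop_np("distance matrix diagonal must be 0")
  d
}
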