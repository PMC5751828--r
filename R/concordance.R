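#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks). Returns `NA` when either vector is constant, so callers can
#' decide how to treat undefined correlations.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Scalar in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop_np("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

# per-subject standardized rank matrix for fast mean within-pair Spearman:
# rows z-scored so that sum(zx * zy) is the Pearson correlation of ranks.
# Constant rows (undefined correlation) are flagged.
rank_z_rows <- function(mat) {
  r <- t(apply(mat, 1, rank))
  ctr <- r - rowMeans(r)
  ss <- sqrt(rowSums(ctr^2))
  valid <- ss > 0
  z <- ctr / ifelse(ss > 0, ss, 1)
  z[!valid, ] <- 0
  list(z = z, valid = valid)
}

#' Cross-site Spearman correlation matrix
#'
#' Entry (i, j) is the Spearman correlation across subjects between the NS
#' relative abundance of genus i and the NPA relative abundance of genus j.
#' The matrix is not symmetric: it compares two different sample types.
#' Genera constant across a site's samples yield undefined correlations,
#' which are reported as `NA` and flagged, never silently zeroed.
#'
#' @param cohort a [paired_cohort()].
#' @param genera genus panel (typically [top_genera_union()]).
#' @return List with `genera`, `rho` (matrix, NS rows x NPA columns) and
#'   `undefined` (logical matrix marking flagged entries).
#' @export
cross_site_correlation <- function(cohort, genera) {
  ns <- as_proportions(cohort$ns)$mat
  npa <- as_proportions(cohort$npa)$mat
  miss <- setdiff(genera, intersect(colnames(ns), colnames(npa)))
  if (length(miss)) stop_np("genera absent from a site table: %s",
                            paste(miss, collapse = ", "))
  if (nrow(ns) < 3) stop_np("need at least 3 complete pairs")
  rank_cols <- function(m) apply(m[, genera, drop = FALSE], 2, rank)
  rns <- rank_cols(ns); rnpa <- rank_cols(npa)
  const_ns <- apply(rns, 2, sd) == 0
  const_npa <- apply(rnpa, 2, sd) == 0
  rho <- suppressWarnings(cor(rns, rnpa))
  undefined <- outer(const_ns, const_npa, `|`)
  rho[undefined] <- NA_real_
  dimnames(rho) <- dimnames(undefined) <- list(genera, genera)
  list(genera = genera, rho = rho, undefined = undefined)
}

#' Permutation test of intra-individual cross-site concordance
#'
#' The observed statistic is the mean over subjects of the Spearman
#' correlation between a subject's NS and NPA abundance vectors over
#' `genera`. The null regenerates the statistic after uniformly shuffling
#' the NPA-to-subject assignment (fixed points allowed), emulating randomly
#' paired samples. Subjects whose NS or NPA vector is constant have an
#' undefined within-pair correlation and are dropped from the mean, with the
#' dropped count recorded. The one-sided p-value uses the add-one rule
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`, so it is never exactly 0.
#'
#' @param cohort a [paired_cohort()] with >= 10 subjects.
#' @param genera genus panel the within-pair vectors are restricted to.
#' @param n_perm number of permutations (study default 10000).
#' @param seed integer seed.
#' @return List of class `pairing_permutation_test`: `observed`, `null_mean`,
#'   `null_sd`, `null` (vector), `p_value`, `n_perm`, `n_dropped`, `seed`.
#' @export
pairing_permutation_test <- function(cohort, genera, n_perm = 10000,
                                     seed = NULL) {
  if (n_perm < 1) stop_np("n_perm must be at least 1")
  n <- length(cohort$subjects)
  if (n < 10) stop_np("need at least 10 paired subjects")
  ns <- as_proportions(cohort$ns)$mat[, genera, drop = FALSE]
  npa <- as_proportions(cohort$npa)$mat[, genera, drop = FALSE]
  zn <- rank_z_rows(ns); zp <- rank_z_rows(npa)
  pair_stat <- function(perm) {
    valid <- zn$valid & zp$valid[perm]
    if (!any(valid)) return(NA_real_)
    sum(rowSums(zn$z * zp$z[perm, , drop = FALSE])[valid]) / sum(valid)
  }
  observed <- pair_stat(seq_len(n))
  null <- with_seed_or_not(seed, vapply(seq_len(n_perm),
                                        function(b) pair_stat(sample(n)),
                                        numeric(1)))
  p <- (1 + sum(null >= observed, na.rm = TRUE)) / (1 + n_perm)
  structure(list(observed = observed, null_mean = mean(null, na.rm = TRUE),
                 null_sd = sd(null), null = null, p_value = p,
                 n_perm = n_perm,
                 n_dropped = sum(!(zn$valid & zp$valid)), seed = seed),
            class = "pairing_permutation_test")
}

#' @export
print.pairing_permutation_test <- function(x, ...) {
  cat(sprintf(paste0("Pairing permutation test: observed mean rho = %.3f, ",
                     "null %.3f (SD %.4f), p = %.4g (%d permutations, ",
                     "%d pairs dropped)\n"),
              x$observed, x$null_mean, x$null_sd, x$p_value, x$n_perm,
              x$n_dropped))
  invisible(x)
}
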