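# shared fixtures: everything is generated in code, no data files

random_counts_table <- function(n = 10, k = 6, site = "NS", seed = 1,
                                lambda = 50) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * k, lambda), nrow = n,
                dimnames = list(sprintf("s%02d", seq_len(n)),
                                sprintf("g%02d", seq_len(k))))
    m[m == 0] <- 1  # keep rows strictly positive for normalization tests
    abundance_table(m, site = site, mode = "counts")
  })
}

random_proportions_table <- function(n = 10, k = 6, site = "NS", seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rgamma(n * k, shape = 0.8), nrow = n,
                dimnames = list(sprintf("s%02d", seq_len(n)),
                                sprintf("g%02d", seq_len(k))))
    abundance_table(m / rowSums(m), site = site, mode = "proportions")
  })
}

# paired cohort built directly from matrices (deterministic edge cases)
cohort_from_mats <- function(ns_mat, npa_mat, site_id = "site01",
                             icu = NULL, los = NULL) {
  n <- nrow(ns_mat)
  md <- data.frame(subject = rownames(ns_mat),
                   site_id = rep_len(site_id, n),
                   icu_use = icu %||% rep(FALSE, n),
                   los_days = los %||% rep(2L, n))
  paired_cohort(abundance_table(ns_mat, "NS", "proportions"),
                abundance_table(npa_mat, "NPA", "proportions"), md)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small fast cohort spec for simulation-based tests
small_spec <- function(n = 120, seed = 1, ...) {
  cohort_spec(n_subjects = n, depth_mean = 3000, depth_min = 500,
              n_sites = 5, seed = seed, ...)
}

uniform_coupling <- function() {
  cp <- default_coupling()
  cp[] <- 1 / ncol(cp)
  cp
}

# independent oracle: average ranks by explicit counting, then the textbook
# Pearson formula — no calls into the package's rank/cor path
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# independent weighted-UniFrac oracle: enumerate every branch and look up
# its descendant tips via phangorn, accumulating b * |A_b - B_b|
oracle_wunifrac <- function(x, y, tree, normalized = TRUE) {
  raw <- 0; denom <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- tree$tip.label[phangorn::Descendants(tree, child, "tips")[[1]]]
    a <- sum(x[tips]); b <- sum(y[tips])
    raw <- raw + tree$edge.length[e] * abs(a - b)
    denom <- denom + tree$edge.length[e] * (a + b)
  }
  if (normalized) raw / denom else raw
}

# exhaustive k-medoids oracle: global optimum over all medoid subsets
oracle_pam_objective <- function(dm, k) {
  n <- nrow(dm)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    obj <- sum(apply(dm[, med, drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
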