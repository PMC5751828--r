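#' Prevalence filter for network genera
#'
#' Keeps genera with nonzero abundance in at least
#' `ceiling(min_frac * n_samples)` samples of the table (boundary
#' inclusive), the standard 10%-of-samples rule for co-occurrence analysis.
#'
#' @param x an `abundance_table` (counts or proportions).
#' @param min_frac minimum prevalence fraction in `(0, 1]`.
#' @return Character vector of retained genus names.
#' @export
prevalence_filter <- function(x, min_frac = 0.10) {
  stopifnot(inherits(x, "abundance_table"))
  if (min_frac <= 0 || min_frac > 1) stop_np("min_frac must be in (0, 1]")
  need <- ceiling(min_frac * nrow(x$mat))
  keep <- colSums(x$mat > 0) >= need
  colnames(x$mat)[keep]
}

# pseudocount-normalized distribution over subjects (for KLD)
kld_normalize <- function(v, pseudocount) {
  w <- v + pseudocount
  w / sum(w)
}

# the four ensemble metrics of a genus pair, vectorized over the columns of
# X against one vector y; returns a 4 x ncol(X) matrix
metric_block <- function(X, RX, Xt, LXt, xtlxt, y, pseudocount) {
  ry <- rank(y)
  sp <- if (sd(ry) == 0) rep(NA_real_, ncol(X)) else
    suppressWarnings(as.vector(cor(RX, ry)))
  pe <- if (sd(y) == 0) rep(NA_real_, ncol(X)) else
    suppressWarnings(as.vector(cor(X, y)))
  tot <- colSums(X) + sum(y)
  bc <- ifelse(tot > 0, colSums(abs(X - y)) / tot, NA_real_)
  yt <- kld_normalize(y, pseudocount)
  lyt <- log(yt)
  kl <- 0.5 * (xtlxt - as.vector(crossprod(Xt, lyt)) +
                 sum(yt * lyt) - as.vector(crossprod(LXt, yt)))
  rbind(spearman = sp, pearson = pe, braycurtis = bc, kld = kl)
}

# precomputations shared across null iterations for a fixed X
metric_context <- function(X, pseudocount) {
  RX <- apply(X, 2, rank)
  Xt <- apply(X, 2, kld_normalize, pseudocount = pseudocount)
  LXt <- log(Xt)
  list(X = X, RX = RX, Xt = Xt, LXt = LXt, xtlxt = colSums(Xt * LXt))
}

#' Association scores of one genus pair across subjects
#'
#' Computes the four ensemble metrics between two subject-indexed abundance
#' profiles: Spearman and Pearson correlation, Bray-Curtis dissimilarity, and
#' symmetrized Kullback-Leibler divergence
#' `0.5 * (KL(x~ || y~) + KL(y~ || x~))`, where `x~`, `y~` are the vectors
#' pseudocounted and renormalized to distributions over subjects.
#' Correlations of a constant vector are undefined and reported as `NA`.
#'
#' @param x,y nonnegative abundance vectors over the same subjects.
#' @param pseudocount added before KLD renormalization (default 1e-6).
#' @return Named numeric vector `spearman`, `pearson`, `braycurtis`, `kld`.
#' @export
cooccurrence_metrics <- function(x, y, pseudocount = 1e-6) {
  stopifnot(length(x) == length(y))
  ctx <- metric_context(matrix(x, ncol = 1), pseudocount)
  drop(metric_block(ctx$X, ctx$RX, ctx$Xt, ctx$LXt, ctx$xtlxt, y,
                    pseudocount))
}

# ReBoot-style null draw: permute the focal genus across subjects, then
# renormalize each subject's composition with the permuted value swapped in.
# y is the focal genus's relative abundance within the full composition, so
# the remaining mass of subject s is (1 - y_s).
renormalized_permutation <- function(y, perm) {
  yp <- y[perm]
  denom <- 1 - y + yp
  ifelse(denom > 0, yp / denom, 0)
}

#' Permutation significance of one cross-site genus pair
#'
#' For each of the four ensemble metrics, the target genus's abundance is
#' permuted across subjects `n_null` times and the metric recomputed,
#' giving an exchangeable null for the subject pairing. The two-sided
#' p-value is
#' `(1 + #(|null - mean(null)| >= |obs - mean(null)|)) / (1 + n_null)`.
#' Correlations vote co-occurrence when positive; dissimilarities
#' (Bray-Curtis, KLD) vote co-occurrence when the observed value falls below
#' the null median and co-exclusion when above.
#'
#' With `renormalize = TRUE` each permuted value is shuffled back into the
#' subject's composition and the composition renormalized (a ReBoot-style
#' correction for the spurious associations that closure induces among
#' genera of the same sample). Renormalization shifts the null's location
#' and spread relative to the observed pairing, so its p-values are not
#' calibrated under genuine independence; it is kept as an option for
#' within-composition screening, while the calibrated plain permutation is
#' the default used for cross-site edges (which closure does not couple).
#'
#' @param x source-genus abundance vector (relative abundances).
#' @param y target-genus relative abundance within its full composition.
#' @param n_null number of null permutations (values below 100 give unstable
#'   p-values and raise a warning).
#' @param seed integer seed.
#' @param pseudocount KLD pseudocount.
#' @param renormalize use the ReBoot-style renormalized null instead of the
#'   plain permutation null.
#' @return List with `scores`, `p_values`, `signs` (each named by metric).
#' @export
edge_significance <- function(x, y, n_null = 1000, seed = NULL,
                              pseudocount = 1e-6, renormalize = FALSE) {
  if (n_null < 1) stop_np("n_null must be at least 1")
  if (n_null < 100) warn_np("n_null = %d gives unstable p-values", n_null)
  ctx <- metric_context(matrix(x, ncol = 1), pseudocount)
  obs <- metric_block(ctx$X, ctx$RX, ctx$Xt, ctx$LXt, ctx$xtlxt, y,
                      pseudocount)
  n <- length(y)
  null <- with_seed_or_not(seed, vapply(seq_len(n_null), function(b) {
    perm <- sample(n)
    yb <- if (renormalize) renormalized_permutation(y, perm) else y[perm]
    metric_block(ctx$X, ctx$RX, ctx$Xt, ctx$LXt, ctx$xtlxt, yb,
                 pseudocount)[, 1]
  }, numeric(4)))
  summarize_edge(obs[, 1], null, n_null)
}

# obs: length-4 named vector; null: 4 x n_null matrix
summarize_edge <- function(obs, null, n_null) {
  ctr <- rowMeans(null, na.rm = TRUE)
  p <- vapply(seq_along(obs), function(m) {
    if (is.na(obs[m])) return(NA_real_)
    (1 + sum(abs(null[m, ] - ctr[m]) >= abs(obs[m] - ctr[m]), na.rm = TRUE)) /
      (1 + n_null)
  }, numeric(1))
  med <- apply(null, 1, median, na.rm = TRUE)
  sign_of <- function(m) {
    if (is.na(obs[m])) return(NA_character_)
    if (m %in% c("spearman", "pearson"))
      return(if (obs[m] > 0) "co-occurrence" else "co-exclusion")
    if (obs[m] < med[m]) "co-occurrence"
    else if (obs[m] > med[m]) "co-exclusion"
    else NA_character_
  }
  mn <- names(obs)
  list(scores = obs, p_values = setNames(p, mn),
       signs = setNames(vapply(mn, sign_of, character(1)), mn))
}

#' Ensemble consensus co-occurrence network between NS and NPA genera
#'
#' Evaluates every cross-site genus pair (NS source, NPA target) passing the
#' per-site prevalence filter, scoring each pair with the four ensemble
#' metrics and the renormalized permutation null of [edge_significance()].
#' An edge is retained when at least `min_support` metrics are significant at
#' `alpha` AND all significant metrics agree on the sign; pairs whose
#' significant metrics disagree are dropped and counted in the audit record.
#' Edge weight is the observed Spearman correlation.
#'
#' @param cohort a [paired_cohort()].
#' @param genera genus panel to test (default: the top-genera union).
#' @param alpha per-metric significance threshold.
#' @param min_support minimum number of concordant significant metrics.
#' @param n_null permutations per metric.
#' @param seed integer seed.
#' @param min_frac prevalence filter fraction.
#' @param pseudocount KLD pseudocount.
#' @param renormalize passed to the per-pair null (see
#'   [edge_significance()]); the cross-site default is the calibrated plain
#'   permutation.
#' @param adjust `"none"` (the replication default) or `"BH"` for a
#'   Benjamini-Hochberg correction of each metric's p-values across pairs.
#' @return Object of class `consensus_network`: `nodes` (site, genus),
#'   `edges` (data.frame with sign, Spearman weight, support count and
#'   per-metric p-values), `audit`, and the call parameters.
#' @export
build_consensus_network <- function(cohort, genera = NULL, alpha = 0.05,
                                    min_support = 2, n_null = 1000,
                                    seed = NULL, min_frac = 0.10,
                                    pseudocount = 1e-6, renormalize = FALSE,
                                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ns <- as_proportions(cohort$ns)
  npa <- as_proportions(cohort$npa)
  if (is.null(genera)) genera <- top_genera_union(ns, npa)
  ns_gen <- intersect(genera, prevalence_filter(ns, min_frac))
  npa_gen <- intersect(genera, prevalence_filter(npa, min_frac))
  empty <- data.frame(source_genus = character(), target_genus = character(),
                      sign = character(), weight = numeric(),
                      n_supporting = integer(), p_spearman = numeric(),
                      p_pearson = numeric(), p_braycurtis = numeric(),
                      p_kld = numeric(), stringsAsFactors = FALSE)
  if (!length(ns_gen) || !length(npa_gen)) {
    warn_np("prevalence filter left no genera to test")
    return(structure(list(nodes = empty[0, 1:2], edges = empty,
                          audit = list(dropped_conflicts = 0L,
                                       undefined_metrics = 0L),
                          alpha = alpha, min_support = min_support,
                          n_null = n_null, seed = seed),
                     class = "consensus_network"))
  }
  X <- ns$mat[, ns_gen, drop = FALSE]
  Y <- npa$mat[, npa_gen, drop = FALSE]
  ctx <- metric_context(X, pseudocount)
  metrics <- c("spearman", "pearson", "braycurtis", "kld")
  n <- nrow(X)
  results <- vector("list", length(npa_gen))
  seeds <- if (is.null(seed)) rep(list(NULL), length(npa_gen)) else
    lapply(seq_along(npa_gen), function(j) stage_seed(seed, npa_gen[j]))
  for (j in seq_along(npa_gen)) {
    y <- Y[, j]
    obs <- metric_block(ctx$X, ctx$RX, ctx$Xt, ctx$LXt, ctx$xtlxt, y,
                        pseudocount)
    null <- with_seed_or_not(seeds[[j]], {
      arr <- array(NA_real_, dim = c(4, ncol(X), n_null))
      for (b in seq_len(n_null)) {
        perm <- sample(n)
        yb <- if (renormalize) renormalized_permutation(y, perm) else
          y[perm]
        arr[, , b] <- metric_block(ctx$X, ctx$RX, ctx$Xt, ctx$LXt,
                                   ctx$xtlxt, yb, pseudocount)
      }
      arr
    })
    results[[j]] <- lapply(seq_along(ns_gen), function(i) {
      summarize_edge(setNames(obs[, i], metrics),
                     matrix(null[, i, ], nrow = 4,
                            dimnames = list(metrics, NULL)), n_null)
    })
  }
  # optional BH correction per metric across all pairs
  if (adjust == "BH") {
    for (m in metrics) {
      pv <- unlist(lapply(results, function(col)
        vapply(col, function(e) e$p_values[[m]], numeric(1))))
      pv <- p.adjust(pv, "BH")
      idx <- 1L
      for (j in seq_along(results)) for (i in seq_along(results[[j]])) {
        results[[j]][[i]]$p_values[[m]] <- pv[idx]; idx <- idx + 1L
      }
    }
  }
  rows <- list(); conflicts <- 0L; undefined <- 0L
  for (j in seq_along(npa_gen)) for (i in seq_along(ns_gen)) {
    e <- results[[j]][[i]]
    undefined <- undefined + sum(is.na(e$p_values))
    sig <- metrics[!is.na(e$p_values) & e$p_values < alpha &
                     !is.na(e$signs)]
    if (length(sig) < min_support) next
    sg <- unique(e$signs[sig])
    if (length(sg) > 1) { conflicts <- conflicts + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      source_genus = ns_gen[i], target_genus = npa_gen[j], sign = sg,
      weight = unname(e$scores["spearman"]),
      n_supporting = length(sig),
      p_spearman = unname(e$p_values["spearman"]),
      p_pearson = unname(e$p_values["pearson"]),
      p_braycurtis = unname(e$p_values["braycurtis"]),
      p_kld = unname(e$p_values["kld"]), stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else empty
  nodes <- rbind(data.frame(site = "NS", genus = ns_gen),
                 data.frame(site = "NPA", genus = npa_gen))
  structure(list(nodes = nodes, edges = edges,
                 audit = list(dropped_conflicts = conflicts,
                              undefined_metrics = undefined),
                 alpha = alpha, min_support = min_support, n_null = n_null,
                 seed = seed),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("<consensus_network> %d nodes, %d edges (alpha=%g, support>=%d, %d nulls); %d sign conflicts dropped\n",
              nrow(x$nodes), nrow(x$edges), x$alpha, x$min_support, x$n_null,
              x$audit$dropped_conflicts))
  invisible(x)
}

#' Write a consensus network edge list as TSV
#'
#' @param net a `consensus_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  df <- net$edges
  df <- cbind(source_site = rep("NS", nrow(df)),
              df[, "source_genus", drop = FALSE],
              target_site = rep("NPA", nrow(df)),
              df[, setdiff(names(df), "source_genus")])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
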