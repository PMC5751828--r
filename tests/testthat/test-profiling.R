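# small Euclidean distance matrix from random planar points
planar_dist <- function(n, seed, blobs = 1, sep = 8) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(blobs * 2, sd = sep), blobs, 2)
    pts <- centers[rep_len(seq_len(blobs), n), ] + matrix(rnorm(n * 2), n, 2)
    dm <- as.matrix(dist(pts))
    dimnames(dm) <- list(paste0("p", 1:n), paste0("p", 1:n))
    list(d = dm, blob = rep_len(seq_len(blobs), n))
  })
}

test_that("PAM matches closed forms and the exhaustive-medoid oracle", {
  pd <- planar_dist(9, seed = 1)
  r1 <- pam_fit(pd$d, 1)
  expect_identical(r1$medoids, rownames(pd$d)[which.min(rowSums(pd$d))])
  expect_equal(r1$objective, min(rowSums(pd$d)))

  rn <- pam_fit(pd$d, 9)
  expect_equal(rn$objective, 0)
  expect_equal(unname(rn$labels), 1:9)

  for (seed in 1:8) {
    pd <- planar_dist(8, seed = seed, blobs = 2, sep = 3)
    for (k in 2:3) {
      fit <- pam_fit(pd$d, k)
      expect_equal(fit$objective, oracle_pam_objective(pd$d, k),
                   tolerance = 1e-12)
      # every sample sits with its nearest medoid
      med_idx <- match(fit$medoids, rownames(pd$d))
      nearest <- apply(pd$d[, med_idx, drop = FALSE], 1, which.min)
      expect_equal(pd$d[cbind(seq_len(8), med_idx[fit$labels])],
                   pd$d[cbind(seq_len(8), med_idx[nearest])])
    }
  }

  bad <- pd$d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(pam_fit(bad, 2), "symmetric")
  neg <- pd$d; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(pam_fit(neg, 2), "negative")
  expect_error(pam_fit(pd$d, 0), "between")
})

test_that("average silhouette matches the per-sample formula", {
  # two blobs of duplicated points: perfect separation
  m <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  dm <- as.matrix(dist(m)); dimnames(dm) <- list(paste0("p", 1:6),
                                                 paste0("p", 1:6))
  expect_equal(avg_silhouette(dm, rep(1:2, each = 3)), 1)

  # worked 6-point instance against an explicit per-sample computation
  pd <- planar_dist(6, seed = 3, blobs = 2, sep = 2)
  labels <- pd$blob
  got <- avg_silhouette(pd$d, labels)
  sil_i <- vapply(1:6, function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- mean(pd$d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(pd$d[i, labels == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(got, mean(sil_i), tolerance = 1e-12)

  # random labels on a single blob cannot look well-separated
  for (seed in 1:20) {
    pd1 <- planar_dist(20, seed = 100 + seed)
    lab <- withr::with_seed(seed, sample(1:2, 20, replace = TRUE))
    if (length(unique(lab)) < 2) next
    expect_lte(avg_silhouette(pd1$d, lab), 0.25)
  }

  expect_error(avg_silhouette(pd$d, rep(1, 6)), "2 clusters")
})

test_that("gap statistic recovers planted cluster counts", {
  hits <- 0
  for (seed in 1:5) {
    pd <- planar_dist(90, seed = 200 + seed, blobs = 3, sep = 10)
    gs <- gap_statistic(pd$d, k_range = 1:6, n_ref = 30, seed = seed)
    if (gs$k_selected == 3) hits <- hits + 1
  }
  expect_gte(hits, 4)

  pd1 <- planar_dist(60, seed = 300)
  gs1 <- gap_statistic(pd1$d, k_range = 1:5, n_ref = 30, seed = 1)
  expect_equal(gs1$k_selected, 1)

  # duplicated identical points: zero-dispersion handled via log(W + eps)
  m <- matrix(1, 12, 2)
  dm <- as.matrix(dist(m)); dimnames(dm) <- list(paste0("p", 1:12),
                                                 paste0("p", 1:12))
  expect_no_error(gap_statistic(dm, k_range = 1:3, n_ref = 5, seed = 1))

  expect_error(gap_statistic(pd1$d, k_range = c(3, 2)), "increasing")
})

test_that("composite profiles adjoin the two sites in fixed genus order", {
  sim <- generate_cohort(small_spec(n = 50, seed = 31))
  g <- default_genera()[1:8]
  comp <- composite_profiles(sim$cohort, g)
  expect_equal(ncol(comp), 16)
  expect_identical(colnames(comp)[1:8], paste0("NS:", g))
  expect_true(all(rowSums(comp[, 1:8]) <= 1 + 1e-9))
  expect_true(all(rowSums(comp[, 9:16]) <= 1 + 1e-9))
  nsp <- to_relative_abundance(sim$cohort$ns)$mat
  expect_equal(unname(comp[, "NS:Moraxella"]), unname(nsp[, "Moraxella"]))
})

test_that("composite clustering recovers identity-coupled site patterns", {
  genera <- default_genera()
  profs <- default_ns_profiles(genera)
  nm <- vapply(profs, `[[`, character(1), "name")
  cp <- diag(length(profs)); dimnames(cp) <- list(nm, nm)
  sim <- generate_cohort(cohort_spec(n_subjects = 400, ns_profiles = profs,
                                     npa_profiles = profs, coupling = cp,
                                     depth_mean = 3000, depth_min = 500,
                                     seed = 32))
  g <- top_genera_union(to_relative_abundance(sim$cohort$ns),
                        to_relative_abundance(sim$cohort$npa))
  res <- cluster_composite(sim$cohort, g, k = 6)
  # within each cluster the dominant NS genus equals the dominant NPA genus
  half <- length(g)
  agree <- vapply(seq_len(res$k), function(cl) {
    mu <- res$cluster_means[cl, ]
    ns_top <- sub("^NS:", "", names(which.max(mu[1:half])))
    npa_top <- sub("^NPA:", "", names(which.max(mu[(half + 1):(2 * half)])))
    ns_top == npa_top
  }, logical(1))
  sizes <- table(res$labels)
  expect_gte(sum(sizes[agree]) / sum(sizes), 0.9)

  r1 <- cluster_composite(sim$cohort, g, k = 1)
  expect_equal(unique(unname(r1$labels)), 1L)

  perm <- withr::with_seed(33, sample(400))
  co2 <- paired_cohort(sim$cohort$ns, sim$cohort$npa,
                       sim$cohort$metadata[perm, ])
  res2 <- cluster_composite(co2, g, k = 6)
  common <- intersect(names(res$labels), names(res2$labels))
  expect_equal(adjusted_rand(res$labels[common], res2$labels[common]), 1)
})

test_that("site-profile clustering handles degenerate and duplicated input", {
  sim <- generate_cohort(small_spec(n = 60, seed = 41))
  nsp <- to_relative_abundance(sim$cohort$ns)
  tree <- generate_random_tree(default_genera(), seed = 42)

  mm <- nsp$mat[rep(1, 8), ]
  rownames(mm) <- paste0("r", 1:8)
  same <- abundance_table(mm, "NS", "proportions")
  res0 <- cluster_site_profiles(same, tree, k = 4)
  expect_equal(res0$k, 1L)

  res <- cluster_site_profiles(nsp, tree, k = 4)
  doubled <- abundance_table(rbind(nsp$mat,
                                   `rownames<-`(nsp$mat,
                                                paste0("dup_",
                                                       rownames(nsp$mat)))),
                             "NS", "proportions")
  res2 <- cluster_site_profiles(doubled, tree, k = 4)
  med1 <- nsp$mat[res$medoids, , drop = FALSE]
  med2 <- doubled$mat[res2$medoids, , drop = FALSE]
  ord <- function(m) m[order(apply(m, 1, paste, collapse = ",")), ]
  expect_equal(unname(ord(med1)), unname(ord(med2)), tolerance = 1e-12)
})

test_that("profile naming applies threshold, tie-break, and label invariance", {
  m <- rbind(c(0.78, 0.12, 0.10), c(0.80, 0.10, 0.10),
             c(0.29, 0.28, 0.43) / 1, c(0.25, 0.26, 0.49) / 1)
  m <- m / rowSums(m)
  dimnames(m) <- list(paste0("s", 1:4),
                      c("Staphylococcus", "Moraxella", "Zeta"))
  tab <- abundance_table(m, "NS", "proportions")
  res <- structure(list(labels = setNames(c(1L, 1L, 2L, 2L), paste0("s", 1:4))),
                   class = "clustering_result")
  nm <- name_profiles(res, tab, threshold = 0.40)
  expect_identical(nm[1], "Staphylococcus-dominant")
  expect_identical(nm[2], "Zeta-dominant")

  low <- abundance_table(m[3:4, ] / rowSums(m[3:4, ]), "NS", "proportions")
  res_low <- structure(list(labels = setNames(c(1L, 1L), paste0("s", 3:4))),
                       class = "clustering_result")
  expect_identical(name_profiles(res_low, low, threshold = 0.60), "Mixed")

  # exact tie with equal prevalence: lexicographically first genus wins
  tie <- matrix(c(0.45, 0.45, 0.10), 2, 3, byrow = TRUE,
                dimnames = list(c("a", "b"), c("Beta", "Alpha", "Rest")))
  ttab <- abundance_table(tie / rowSums(tie), "NS", "proportions")
  res_t <- structure(list(labels = setNames(c(1L, 1L), c("a", "b"))),
                     class = "clustering_result")
  expect_identical(name_profiles(res_t, ttab), "Alpha-dominant")

  # invariance to cluster index permutation
  res_p <- structure(list(labels = setNames(c(2L, 2L, 1L, 1L),
                                            paste0("s", 1:4))),
                     class = "clustering_result")
  expect_identical(name_profiles(res_p, tab)[c(2, 1)], nm)
})
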