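test_that("TSV round trips are exact and malformed input is rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgA\tgB", "s1\t5\t5", "s2\t0\t10"), path)
  tab <- read_abundance_table(path, site = "NS", mode = "counts")
  expect_equal(unname(rowSums(tab$mat)), c(10, 10))
  expect_identical(tab$mat, read_abundance_table(path, "NS", "counts")$mat)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, out)
  expect_identical(read_abundance_table(out, "NS", "counts")$mat, tab$mat)

  # proportions with non-terminating decimals survive a round trip exactly
  prop <- to_relative_abundance(random_counts_table(6, 5, seed = 3))
  write_abundance_table(prop, out)
  expect_identical(read_abundance_table(out, "NS", "proportions")$mat,
                   prop$mat)

  writeLines(c("sample_id\tgA\tgB", "s1\t-3\t5", "s2\t1\t1"), path)
  expect_error(read_abundance_table(path, "NS", "counts"), "negative|egative")
  writeLines(c("sample_id\tgA\tgB", "s1\t1\t2", "s1\t3\t4"), path)
  expect_error(read_abundance_table(path, "NS", "counts"), "duplicate")
  writeLines(c("sample_id\tgA\tgB", "s1\t1\t2", "s2\t3"), path)
  expect_error(read_abundance_table(path, "NS", "counts"))
  writeLines(c("sample_id\tgA\tgB", "s1\t1\ttwo", "s2\t3\t4"), path)
  expect_error(read_abundance_table(path, "NS", "counts"), "non-numeric")
})

test_that("genus collapse sums OTU columns and preserves row sums", {
  m <- matrix(c(3, 4, 5, 1, 0, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
  tab <- abundance_table(m, "NS", "counts")
  map <- c(o1 = "Staphylococcus", o2 = "Staphylococcus", o3 = "Moraxella")
  coll <- collapse_to_genus(tab, map)
  expect_equal(coll$mat["s1", "Staphylococcus"], 7)
  expect_equal(coll$mat["s1", "Moraxella"], 5)
  expect_equal(rowSums(coll$mat), rowSums(tab$mat))

  idmap <- setNames(colnames(m), colnames(m))
  expect_equal(unname(collapse_to_genus(tab, idmap)$mat), unname(m))

  # random table against an independent accumulation oracle
  big <- random_counts_table(10, 20, seed = 7)
  genera <- sprintf("G%d", 1:6)
  rmap <- withr::with_seed(8, setNames(sample(genera, 20, TRUE),
                                       taxon_ids(big)))
  coll2 <- collapse_to_genus(big, rmap)
  for (g in unique(rmap)) {
    expect_equal(unname(coll2$mat[, g]),
                 unname(rowSums(big$mat[, names(rmap)[rmap == g],
                                        drop = FALSE])))
  }

  # unmapped OTUs: bucket when enabled, error when not
  part <- rmap[-1]
  expect_error(collapse_to_genus(big, part, unclassified = NULL), "missing")
  bucketed <- collapse_to_genus(big, part)
  expect_true("Unclassified" %in% taxon_ids(bucketed))
  expect_equal(rowSums(bucketed$mat), rowSums(big$mat))
})

test_that("relative abundance normalizes rows and commutes with collapse", {
  m <- matrix(c(2, 2, 4), nrow = 1, dimnames = list("s1", c("a", "b", "c")))
  p <- to_relative_abundance(abundance_table(m, "NS", "counts"))
  expect_equal(unname(p$mat[1, ]), c(0.25, 0.25, 0.5))
  one <- matrix(7, 1, 1, dimnames = list("s1", "a"))
  expect_equal(unname(to_relative_abundance(
    abundance_table(one, "NS", "counts"))$mat[1, 1]), 1)

  for (seed in 1:5) {
    tab <- random_counts_table(8, 7, seed = seed)
    expect_true(all(abs(rowSums(to_relative_abundance(tab)$mat) - 1) < 1e-12))
  }

  zero <- matrix(c(1, 0), 2, 1, dimnames = list(c("s1", "szero"), "a"))
  expect_error(to_relative_abundance(abundance_table(zero, "NS", "counts")),
               "szero")

  # collapse-then-normalize == normalize-then-collapse, exactly per row
  tab <- random_counts_table(6, 12, seed = 11)
  map <- withr::with_seed(2, setNames(sample(sprintf("G%d", 1:4), 12, TRUE),
                                      taxon_ids(tab)))
  a <- to_relative_abundance(collapse_to_genus(tab, map))
  b <- collapse_to_genus(to_relative_abundance(tab), map)
  expect_equal(a$mat, b$mat)
})

test_that("top-genera union matches the brute-force ranking oracle", {
  tab <- random_proportions_table(12, 14, seed = 4)
  same <- top_genera_union(tab, abundance_table(tab$mat, "NPA",
                                                "proportions"), n_top = 5)
  expect_length(same, 5)

  # disjoint top sets by construction
  k <- 8
  m1 <- matrix(0.5 / (k - 1), 4, 2 * k)
  m1[, 1:k] <- m1[, 1:k] + 10
  m1 <- m1 / rowSums(m1)
  dimnames(m1) <- list(paste0("s", 1:4), sprintf("g%02d", 1:(2 * k)))
  m2 <- m1  # same values, but the abundant columns carry the other names
  colnames(m2) <- colnames(m1)[c((k + 1):(2 * k), 1:k)]
  m2 <- m2[, order(colnames(m2))]
  u <- top_genera_union(abundance_table(m1, "NS", "proportions"),
                        abundance_table(m2, "NPA", "proportions"),
                        n_top = k)
  expect_length(u, 2 * k)

  # random pair vs exhaustive sort-and-union oracle
  ns <- random_proportions_table(15, 20, "NS", seed = 5)
  npa <- random_proportions_table(15, 20, "NPA", seed = 6)
  got <- top_genera_union(ns, npa, n_top = 6)
  oracle_top <- function(m, n_top) {
    ab <- colSums(m)
    names(sort(ab, decreasing = TRUE))[1:n_top]
  }
  exp_set <- union(oracle_top(ns$mat, 6), oracle_top(npa$mat, 6))
  expect_setequal(got, exp_set)
  comb <- colSums(ns$mat)[exp_set] + colSums(npa$mat)[exp_set]
  expect_identical(as.character(got), names(sort(comb, decreasing = TRUE)))

  # invariant to sample order and taxon column order
  perm_r <- withr::with_seed(9, sample(nrow(ns$mat)))
  perm_c <- withr::with_seed(10, sample(ncol(ns$mat)))
  ns2 <- abundance_table(ns$mat[perm_r, perm_c], "NS", "proportions")
  expect_identical(as.character(top_genera_union(ns2, npa, n_top = 6)),
                   as.character(got))

  w <- testthat::capture_warnings(top_genera_union(ns, npa, n_top = 25))
  expect_true(length(w) >= 1 && all(grepl("only", w)))
})

test_that("rarefaction is exact-depth, seeded, and hypergeometric in mean", {
  tab <- random_counts_table(6, 5, seed = 12, lambda = 200)
  depth <- min(rowSums(tab$mat))
  r1 <- rarefy_table(tab, depth, seed = 99)
  expect_true(all(rowSums(r1$mat) == depth))
  expect_identical(r1$mat, rarefy_table(tab, depth, seed = 99)$mat)

  # a sample at exactly the target depth is returned unchanged
  i <- which.min(rowSums(tab$mat))
  expect_equal(r1$mat[i, ], tab$mat[i, ])

  m <- matrix(c(1000, 0), 1, 2, dimnames = list("s1", c("a", "b")))
  r2 <- rarefy_table(abundance_table(m, "NS", "counts"), 100, seed = 1)
  expect_equal(unname(r2$mat[1, ]), c(100, 0))

  # shallow samples are dropped and reported
  shallow <- tab
  shallow$mat[2, ] <- c(1, 0, 0, 0, 0)
  r3 <- rarefy_table(abundance_table(shallow$mat, "NS", "counts"), depth,
                     seed = 1)
  expect_identical(attr(r3, "dropped"), rownames(tab$mat)[2])

  expect_error(rarefy_table(tab, 0), "positive")
  expect_error(rarefy_table(to_relative_abundance(tab), 10), "counts")

  # multivariate hypergeometric mean: E[count_1] = depth * K1 / N
  m <- matrix(c(30, 70), 1, 2, dimnames = list("s1", c("a", "b")))
  htab <- abundance_table(m, "NS", "counts")
  draws <- vapply(1:400, function(s) rarefy_table(htab, 20, seed = s)$mat[1, 1],
                  numeric(1))
  expect_equal(mean(draws), 20 * 0.3, tolerance = 0.4 / 6)
})

test_that("paired cohorts align by subject id and reject inconsistency", {
  ns <- random_proportions_table(5, 4, "NS", seed = 1)
  npa <- random_proportions_table(5, 4, "NPA", seed = 2)
  md <- data.frame(subject = rev(rownames(ns$mat)), site_id = "h1")
  co <- paired_cohort(ns, npa, md)
  expect_identical(rownames(co$ns$mat), md$subject)  # joined by id, not row
  expect_equal(co$ns$mat["s03", ], ns$mat["s03", ])

  md_bad <- data.frame(subject = c(md$subject[-1], "ghost"), site_id = "h1")
  expect_error(paired_cohort(ns, npa, md_bad), "missing subjects")
  md_neg <- transform(md, los_days = -1)
  expect_error(paired_cohort(ns, npa, md_neg), "nonnegative")
})
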