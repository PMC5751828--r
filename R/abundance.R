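#' Construct a genus/OTU abundance table
#'
#' The basic container of the package: a samples-by-taxa matrix tagged with
#' the anatomic site it was collected from (`"NS"` anterior-nares swab,
#' `"NPA"` nasopharyngeal aspirate, or any other label) and the measurement
#' mode. In `"counts"` mode entries are nonnegative read counts; in
#' `"proportions"` mode every row is a relative-abundance vector summing to 1.
#'
#' @param mat numeric matrix, rows = samples, columns = taxa; must carry
#'   unique rownames (sample ids) and colnames (taxon ids).
#' @param site site label, e.g. `"NS"` or `"NPA"`.
#' @param mode `"counts"` or `"proportions"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(mat, site, mode = c("counts", "proportions")) {
  mode <- match.arg(mode)
  if (!is.matrix(mat) || !is.numeric(mat))
    stop_np("abundance table must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop_np("abundance table needs sample rownames and taxon colnames")
  x <- structure(list(mat = mat, site = as.character(site)[1], mode = mode),
                 class = "abundance_table")
  validate_abundance_table(x)
  x
}

#' Validate an abundance table's invariants
#'
#' Checks nonnegativity, finiteness, unique sample/taxon ids, and (in
#' proportions mode) unit row sums. Called by all constructors; exposed for
#' defensive use after manual manipulation.
#'
#' @param x an `abundance_table`.
#' @return `x`, invisibly; errors describe the violated invariant.
#' @export
validate_abundance_table <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  m <- x$mat
  if (anyDuplicated(rownames(m)))
    stop_np("duplicate sample ids: %s",
            paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop_np("duplicate taxon ids: %s",
            paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (any(!is.finite(m))) stop_np("non-finite abundance values")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop_np("negative abundance for sample '%s', taxon '%s'",
            rownames(m)[bad[1]], colnames(m)[bad[2]])
  }
  if (x$mode == "proportions") {
    rs <- rowSums(m)
    off <- which(abs(rs - 1) > 1e-9)
    if (length(off))
      stop_np("proportion rows must sum to 1 (sample '%s' sums to %.12g)",
              rownames(m)[off[1]], rs[off[1]])
  }
  invisible(x)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> site=%s mode=%s: %d samples x %d taxa\n",
              x$site, x$mode, nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' @rdname abundance_table
#' @export
sample_ids <- function(x) rownames(x$mat)

#' @rdname abundance_table
#' @export
taxon_ids <- function(x) colnames(x$mat)

#' Read an abundance table from TSV
#'
#' Expects a UTF-8 tab-separated file whose header row holds taxon ids and
#' whose first column holds sample ids. Numeric parsing is locale-independent
#' (C-locale decimal point).
#'
#' @param path file path.
#' @inheritParams abundance_table
#' @return An `abundance_table`.
#' @export
read_abundance_table <- function(path, site, mode = c("counts", "proportions")) {
  mode <- match.arg(mode)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "", comment.char = "",
                   fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop_np("'%s': expected sample-id column plus taxa", path)
  ids <- df[[1]]
  num <- vapply(df[-1], function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) stop_np("'%s': non-numeric abundance value '%s'",
                          path, col[which(is.na(v))[1]])
    v
  }, numeric(nrow(df)))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(ids, colnames(df)[-1]))
  abundance_table(num, site = site, mode = mode)
}

#' Write an abundance table to TSV
#'
#' Mirrors [read_abundance_table()] bit-exactly: counts are written as
#' integers and proportions with full double precision, so a write/read
#' round trip reproduces the table exactly.
#'
#' @param x an `abundance_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  validate_abundance_table(x)
  m <- x$mat
  chr <- if (x$mode == "counts" && all(m == round(m))) {
    matrix(sprintf("%d", as.integer(m)), nrow = nrow(m))
  } else {
    matrix(sprintf("%.17g", m), nrow = nrow(m))
  }
  out <- cbind(sample_id = rownames(m), as.data.frame(chr))
  colnames(out) <- c("sample_id", colnames(m))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a two-column OTU-to-genus taxonomy map
#'
#' @param path TSV with columns `otu_id` and `genus` (header required).
#' @return Named character vector mapping OTU id to genus name.
#' @export
read_taxonomy_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 2) stop_np("taxonomy map needs two columns (otu_id, genus)")
  setNames(df[[2]], df[[1]])
}

#' Collapse OTU columns to genus level
#'
#' Sums the columns of an OTU table within each genus of the taxonomy map.
#' Row sums are preserved exactly, so collapsing commutes with
#' [to_relative_abundance()]. OTUs missing from the map are routed to the
#' `unclassified` bucket genus (which then competes in top-genera rankings
#' like any other genus), or raise an error when `unclassified = NULL`.
#'
#' @param x an `abundance_table` whose columns are OTU ids.
#' @param taxmap named character vector, OTU id -> genus name.
#' @param unclassified name of the catch-all genus, or `NULL` to forbid
#'   unmapped OTUs.
#' @return An `abundance_table` with one column per genus.
#' @export
collapse_to_genus <- function(x, taxmap, unclassified = "Unclassified") {
  stopifnot(inherits(x, "abundance_table"))
  otus <- taxon_ids(x)
  genus <- unname(taxmap[otus])
  if (anyNA(genus)) {
    missing <- otus[is.na(genus)]
    if (is.null(unclassified))
      stop_np("OTUs missing from taxonomy map: %s",
              paste(head(missing, 5), collapse = ", "))
    genus[is.na(genus)] <- unclassified
  }
  collapsed <- t(rowsum(t(x$mat), group = genus))
  collapsed <- collapsed[, order(colnames(collapsed)), drop = FALSE]
  abundance_table(collapsed, site = x$site, mode = x$mode)
}

#' Convert counts to relative abundances
#'
#' @param x an `abundance_table` in counts mode; every sample must have at
#'   least one read.
#' @return The table in proportions mode (each row divided by its sum).
#' @export
to_relative_abundance <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$mode != "counts") stop_np("table is already in proportions mode")
  rs <- rowSums(x$mat)
  if (any(rs == 0))
    stop_np("sample '%s' has zero total abundance; cannot normalize",
            rownames(x$mat)[which(rs == 0)[1]])
  abundance_table(x$mat / rs, site = x$site, mode = "proportions")
}

# proportions table whatever the input mode
as_proportions <- function(x) {
  if (x$mode == "proportions") x else to_relative_abundance(x)
}

#' Union of the most abundant genera from two sites
#'
#' Per-site overall abundance of a genus is the sum of its relative
#' abundances over all samples of that site. The `n_top` highest-ranking
#' genera of each site are pooled; the union is returned ordered by combined
#' (NS + NPA) overall abundance, ties broken lexicographically. With the
#' study defaults (`n_top = 10`) the two top-10 lists overlap in 5 genera,
#' giving the 15 comparative genera.
#'
#' @param ns,npa `abundance_table`s in proportions mode for the two sites.
#' @param n_top number of top genera per site.
#' @return Character vector of genus names; attribute `"short"` is `TRUE`
#'   (with a warning) when a site has fewer than `n_top` genera.
#' @export
top_genera_union <- function(ns, npa, n_top = 10) {
  stopifnot(inherits(ns, "abundance_table"), inherits(npa, "abundance_table"))
  if (ns$mode != "proportions" || npa$mode != "proportions")
    stop_np("top_genera_union expects proportions-mode tables")
  short <- FALSE
  site_top <- function(x) {
    ab <- colSums(x$mat)
    if (length(ab) < n_top) {
      warn_np("site '%s' has only %d genera (< n_top = %d); using all",
              x$site, length(ab), n_top)
      short <<- TRUE
    }
    names(ab)[order(-ab, names(ab))][seq_len(min(n_top, length(ab)))]
  }
  union_set <- union(site_top(ns), site_top(npa))
  combined <- setNames(numeric(length(union_set)), union_set)
  for (x in list(ns, npa)) {
    ab <- colSums(x$mat)
    hit <- intersect(union_set, names(ab))
    combined[hit] <- combined[hit] + ab[hit]
  }
  out <- names(combined)[order(-combined, names(combined))]
  attr(out, "short") <- short
  out
}

#' Rarefy a count table to even depth
#'
#' Each retained sample is subsampled uniformly without replacement to
#' exactly `depth` reads; samples with fewer than `depth` reads are dropped
#' and reported via the `"dropped"` attribute. Reproducible given `seed`.
#'
#' @param x an `abundance_table` in counts mode with integer entries.
#' @param depth target reads per sample; defaults to the minimum row sum
#'   among samples with at least `floor` reads.
#' @param seed integer seed (optional; `NULL` uses the current RNG stream).
#' @param floor minimum acceptable sequencing depth when `depth` is derived
#'   from the data (default 1000 reads).
#' @return A counts-mode `abundance_table` with all row sums equal `depth`.
#' @export
rarefy_table <- function(x, depth = NULL, seed = NULL, floor = 1000) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$mode != "counts") stop_np("rarefaction needs a counts table")
  if (any(x$mat != round(x$mat))) stop_np("rarefaction needs integer counts")
  rs <- rowSums(x$mat)
  if (is.null(depth)) {
    eligible <- rs[rs >= floor]
    if (!length(eligible))
      stop_np("no sample reaches the depth floor of %d reads", floor)
    depth <- min(eligible)
  }
  depth <- as.integer(depth)
  if (depth <= 0) stop_np("rarefaction depth must be a positive integer")
  keep <- rs >= depth
  dropped <- rownames(x$mat)[!keep]
  m <- x$mat[keep, , drop = FALSE]
  k <- ncol(m)
  out <- with_seed_or_not(seed, t(apply(m, 1, function(row) {
    if (sum(row) == depth) return(as.numeric(row))
    picks <- sample(rep.int(seq_len(k), row), depth)
    tabulate(picks, nbins = k)
  })))
  dimnames(out) <- list(rownames(m), colnames(m))
  res <- abundance_table(out, site = x$site, mode = "counts")
  attr(res, "dropped") <- dropped
  attr(res, "depth") <- depth
  res
}

#' Assemble a paired two-site cohort
#'
#' Aligns one NS and one NPA sample per subject with a per-subject metadata
#' table. All joins are by subject id, never by row position. Metadata must
#' contain a `subject` column and a `site_id` column (collection hospital);
#' the clinical covariate dictionary used by the severity models is
#' documented in [fit_profile_logistic()].
#'
#' @param ns,npa `abundance_table`s whose sample ids are subject ids.
#' @param metadata data.frame with one row per subject.
#' @return An object of class `paired_cohort` with elements `subjects`,
#'   `ns`, `npa`, `metadata`.
#' @export
paired_cohort <- function(ns, npa, metadata) {
  stopifnot(inherits(ns, "abundance_table"), inherits(npa, "abundance_table"),
            is.data.frame(metadata), "subject" %in% names(metadata))
  subjects <- as.character(metadata$subject)
  if (anyDuplicated(subjects)) stop_np("duplicate subject ids in metadata")
  for (tab in list(ns, npa)) {
    miss <- setdiff(subjects, sample_ids(tab))
    if (length(miss))
      stop_np("site '%s' table is missing subjects: %s", tab$site,
              paste(head(miss, 5), collapse = ", "))
  }
  ns$mat <- ns$mat[subjects, , drop = FALSE]
  npa$mat <- npa$mat[subjects, , drop = FALSE]
  if (!is.null(metadata$los_days) && any(!is.na(metadata$los_days) &
                                         metadata$los_days < 0))
    stop_np("los_days must be nonnegative")
  structure(list(subjects = subjects, ns = ns, npa = npa,
                 metadata = metadata),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort> %d subjects; NS %d taxa, NPA %d taxa; %d metadata columns\n",
              length(x$subjects), ncol(x$ns$mat), ncol(x$npa$mat),
              ncol(x$metadata)))
  invisible(x)
}
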