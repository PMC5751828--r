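#' Default genus panel for simulated cohorts
#'
#' The 15 comparative genera of the paired upper-airway design, ordered from
#' most to least abundant overall.
#'
#' @return Character vector of 15 genus names.
#' @export
default_genera <- function() {
  c("Staphylococcus", "Moraxella", "Streptococcus", "Haemophilus",
    "Corynebacterium", "Dolosigranulum", "Enterobacter", "Neisseria",
    "Enterococcus", "Bacillus", "Acinetobacter", "Prevotella",
    "Alloprevotella", "Veillonella", "Gemella")
}

# a profile = name + mixing weight + Dirichlet concentration vector over genera
make_profile <- function(name, weight, alpha) {
  stopifnot(all(alpha > 0))
  list(name = name, weight = weight, alpha = alpha)
}

# site-level background abundance ordering (most-to-least common), used to
# spread the non-dominant mass of a profile realistically: rare genera stay
# rare in every profile, which also gives paired samples a shared
# within-subject rank structure across sites
ns_background <- function(genera = default_genera()) {
  bg <- setNames(rep(0.004, length(genera)), genera)
  bg[c("Staphylococcus", "Corynebacterium", "Moraxella", "Haemophilus",
       "Dolosigranulum", "Streptococcus", "Enterobacter", "Enterococcus",
       "Bacillus", "Acinetobacter")] <-
    c(0.41, 0.10, 0.09, 0.07, 0.05, 0.05, 0.05, 0.02, 0.02, 0.02)
  bg
}

npa_background <- function(genera = default_genera()) {
  bg <- setNames(rep(0.004, length(genera)), genera)
  bg[c("Moraxella", "Streptococcus", "Haemophilus", "Staphylococcus",
       "Neisseria", "Prevotella", "Corynebacterium", "Dolosigranulum",
       "Alloprevotella", "Veillonella", "Gemella")] <-
    c(0.31, 0.30, 0.20, 0.02, 0.02, 0.02, 0.01, 0.01, 0.01, 0.01, 0.01)
  bg
}

# dominant-genus profile: Dirichlet mean `mean_dom` on the dominant genus,
# optional named secondary means, remainder spread over the other genera in
# proportion to the site background; the total concentration controls
# within-profile variability (chosen so planted profiles are separated
# enough to be recoverable by distance-based clustering)
dominant_profile <- function(name, weight, genera, dominant, mean_dom,
                             secondary = NULL, concentration = 12,
                             background = ns_background(genera)) {
  means <- setNames(numeric(length(genera)), genera)
  means[dominant] <- mean_dom
  if (!is.null(secondary)) means[names(secondary)] <- secondary
  rest <- setdiff(genera, c(dominant, names(secondary)))
  means[rest] <- (1 - sum(means)) * background[rest] / sum(background[rest])
  make_profile(name, weight, concentration * means)
}

default_ns_profiles <- function(genera = default_genera()) {
  bg <- ns_background(genera)
  mixed_means <- setNames(numeric(length(genera)), genera)
  mixed_means[c("Staphylococcus", "Streptococcus", "Moraxella",
                "Corynebacterium", "Dolosigranulum", "Haemophilus",
                "Enterobacter")] <- c(0.29, 0.14, 0.13, 0.07, 0.07, 0.06, 0.03)
  rest <- names(mixed_means)[mixed_means == 0]
  mixed_means[rest] <- 0.21 * bg[rest] / sum(bg[rest])
  list(
    dominant_profile("Staphylococcus-dominant", 0.445, genera,
                     "Staphylococcus", 0.78),
    dominant_profile("Corynebacterium-dominant", 0.134, genera,
                     "Corynebacterium", 0.62,
                     secondary = c(Dolosigranulum = 0.10)),
    dominant_profile("Moraxella-dominant", 0.130, genera,
                     "Moraxella", 0.60, secondary = c(Acinetobacter = 0.08)),
    make_profile("Mixed", 0.144, 6 * mixed_means),
    dominant_profile("Enterobacter-dominant", 0.075, genera,
                     "Enterobacter", 0.60),
    dominant_profile("Haemophilus-dominant", 0.072, genera,
                     "Haemophilus", 0.74)
  )
}

default_npa_profiles <- function(genera = default_genera()) {
  bg <- npa_background(genera)
  mixed_means <- setNames(numeric(length(genera)), genera)
  mixed_means[c("Moraxella", "Streptococcus", "Haemophilus",
                "Neisseria", "Prevotella")] <- c(0.24, 0.28, 0.14, 0.07, 0.05)
  rest <- names(mixed_means)[mixed_means == 0]
  mixed_means[rest] <- (1 - sum(mixed_means)) * bg[rest] / sum(bg[rest])
  list(
    dominant_profile("Moraxella-dominant", NA, genera, "Moraxella", 0.66,
                     background = bg),
    dominant_profile("Streptococcus-dominant", NA, genera,
                     "Streptococcus", 0.63, background = bg),
    dominant_profile("Haemophilus-dominant", NA, genera, "Haemophilus",
                     0.70, background = bg),
    make_profile("Mixed", NA, 6 * mixed_means)
  )
}

# P(NPA profile | NS profile); rows = NS profiles, columns = NPA profiles.
# Concentrated on the same-genus profile for Haemophilus and Moraxella,
# diffuse from the Staphylococcus profile (whose NPA counterpart can be any
# of the four groups).
default_coupling <- function() {
  m <- rbind(
    "Staphylococcus-dominant"  = c(0.31, 0.31, 0.19, 0.19),
    "Corynebacterium-dominant" = c(0.30, 0.30, 0.12, 0.28),
    "Moraxella-dominant"       = c(0.75, 0.08, 0.04, 0.13),
    "Mixed"                    = c(0.25, 0.30, 0.15, 0.30),
    "Enterobacter-dominant"    = c(0.28, 0.34, 0.14, 0.24),
    "Haemophilus-dominant"     = c(0.05, 0.08, 0.75, 0.12)
  )
  colnames(m) <- c("Moraxella-dominant", "Streptococcus-dominant",
                   "Haemophilus-dominant", "Mixed")
  m
}

#' Specification of a simulated paired two-site cohort
#'
#' Bundles every tunable of the generator. The defaults emulate the study
#' conditions: 815 subjects at 17 collection sites, 15 focal genera, six
#' anterior-nares (NS) dominance profiles and four nasopharyngeal (NPA)
#' profiles, cross-site profile coupling concentrated for Haemophilus and
#' Moraxella, negative-binomial sequencing depth, a site random intercept of
#' SD 0.5 on the log-odds scale, and an intensive-care outcome whose odds
#' ratios versus the Moraxella-dominant reference profile are planted at the
#' study's unadjusted values (Haemophilus 6.2 in particular).
#'
#' @param n_subjects number of subjects.
#' @param genera ordered genus panel.
#' @param ns_profiles,npa_profiles lists of profiles (`name`, `weight`,
#'   Dirichlet `alpha`); NPA weights are implied by `coupling`.
#' @param coupling row-stochastic matrix `P(NPA profile | NS profile)`.
#' @param depth_mean,depth_size negative-binomial read-depth model; draws are
#'   truncated below at `depth_min` so every sample clears rarefaction.
#' @param depth_min minimum per-sample depth.
#' @param n_sites number of collection hospitals; relative site sizes are
#'   drawn once from a Gamma(5) weight vector.
#' @param site_sd SD of the site random intercept (log-odds).
#' @param outcome list: `intercept` (log-odds of intensive care in the
#'   reference profile at covariate means), named `profile_log_or` offsets,
#'   and named `covariate_coefs`.
#' @param los list: negative-binomial `mu` and `size` for hospital length of
#'   stay plus named per-profile `log_mult` mean multipliers.
#' @param seed integer master seed for the generator.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 815,
                        genera = default_genera(),
                        ns_profiles = default_ns_profiles(genera),
                        npa_profiles = default_npa_profiles(genera),
                        coupling = default_coupling(),
                        depth_mean = 20000, depth_size = 5, depth_min = 2000,
                        n_sites = 17, site_sd = 0.5,
                        outcome = list(
                          intercept = -2.58,
                          profile_log_or = c(
                            "Moraxella-dominant"       = 0,
                            "Haemophilus-dominant"     = log(6.2),
                            "Staphylococcus-dominant"  = log(2.5),
                            "Corynebacterium-dominant" = log(3.75),
                            "Enterobacter-dominant"    = log(4.51),
                            "Mixed"                    = log(3.86)),
                          covariate_coefs = c(age_months = -0.08,
                                              abx_prehosp = 0.45)),
                        los = list(mu = 2.2, size = 1.5,
                                   log_mult = c("Haemophilus-dominant" =
                                                  log(1.8))),
                        seed = 20180103) {
  spec <- list(n_subjects = n_subjects, genera = genera,
               ns_profiles = ns_profiles, npa_profiles = npa_profiles,
               coupling = coupling, depth_mean = depth_mean,
               depth_size = depth_size, depth_min = depth_min,
               n_sites = n_sites, site_sd = site_sd, outcome = outcome,
               los = los, seed = seed)
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_subjects < 1) stop_np("n_subjects must be positive")
  if (!length(spec$ns_profiles) || !length(spec$npa_profiles))
    stop_np("profile lists must be nonempty")
  w <- vapply(spec$ns_profiles, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) stop_np("NS profile weights must sum to 1")
  for (p in c(spec$ns_profiles, spec$npa_profiles)) {
    if (length(p$alpha) != length(spec$genera) || any(p$alpha <= 0))
      stop_np("profile '%s': Dirichlet concentrations must be positive and match the genus panel", p$name)
  }
  ns_names <- vapply(spec$ns_profiles, `[[`, character(1), "name")
  npa_names <- vapply(spec$npa_profiles, `[[`, character(1), "name")
  if (!identical(rownames(spec$coupling), ns_names) ||
      !identical(colnames(spec$coupling), npa_names))
    stop_np("coupling dimnames must match the NS / NPA profile names")
  if (any(abs(rowSums(spec$coupling) - 1) > 1e-9))
    stop_np("coupling rows must sum to 1")
  if (spec$site_sd < 0) stop_np("site_sd must be nonnegative")
  invisible(spec)
}

# one Dirichlet draw per row of subjects sharing the same alpha
rdirichlet_block <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# covariate marginals are independent and deliberately simple; rates follow
# the cohort's published characteristics table
draw_covariates <- function(n) {
  data.frame(
    age_months = pmin(11L, as.integer(rgamma(n, shape = 2.2, scale = 2))),
    male = rbinom(n, 1, 0.59),
    race_ethnicity = factor(sample(c("nh_white", "nh_black", "hispanic",
                                     "other"), n, replace = TRUE,
                                   prob = c(0.44, 0.23, 0.29, 0.04)),
                            levels = c("nh_white", "nh_black", "hispanic",
                                       "other")),
    gest_age_weeks = sample(32:41, n, replace = TRUE,
                            prob = c(0.03, 0.03, 0.03, 0.03, 0.03,
                                     0.10, 0.15, 0.25, 0.25, 0.10)),
    prev_breathing = rbinom(n, 1, 0.21),
    daycare = rbinom(n, 1, 0.23),
    other_children = rbinom(n, 1, 0.79),
    hx_antibiotics = rbinom(n, 1, 0.31),
    hx_corticosteroids = rbinom(n, 1, 0.15),
    abx_prehosp = rbinom(n, 1, 0.33),
    virus_pcr = factor(sample(c("RSV_only", "rhinovirus_only",
                                "RSV_rhinovirus", "other"), n, replace = TRUE,
                              prob = c(0.58, 0.05, 0.12, 0.25)),
                       levels = c("RSV_only", "rhinovirus_only",
                                  "RSV_rhinovirus", "other"))
  )
}

#' Generate a paired two-site cohort with known ground truth
#'
#' For each subject: an NS profile is drawn from the profile weights, the NPA
#' profile from the corresponding coupling row, the two compositions from the
#' profiles' Dirichlet distributions, read depths from a truncated negative
#' binomial, and counts from a multinomial. Eleven clinical covariates are
#' drawn from independent documented marginals; intensive-care use follows a
#' logistic model with per-NS-profile log-odds offsets, covariate terms and a
#' Gaussian site random intercept; length of stay follows a profile-shifted
#' negative binomial. Fully reproducible under `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return List with elements `cohort` (a [paired_cohort()] with counts-mode
#'   tables) and `truth` (per-subject data.frame of true NS/NPA profile,
#'   site, linear predictor and outcome probability; never consumed by the
#'   analysis functions).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  g <- spec$genera
  n <- spec$n_subjects
  ns_names <- vapply(spec$ns_profiles, `[[`, character(1), "name")
  npa_names <- vapply(spec$npa_profiles, `[[`, character(1), "name")
  with_seed_or_not(spec$seed, {
    subj <- sprintf("S%04d", seq_len(n))
    w <- vapply(spec$ns_profiles, `[[`, numeric(1), "weight")
    ns_prof <- sample(seq_along(ns_names), n, replace = TRUE, prob = w)
    npa_prof <- integer(n)
    for (i in seq_along(ns_names)) {
      sel <- ns_prof == i
      if (any(sel))
        npa_prof[sel] <- sample(seq_along(npa_names), sum(sel),
                                replace = TRUE, prob = spec$coupling[i, ])
    }
    draw_site <- function(profiles, prof_idx) {
      comp <- matrix(0, n, length(g), dimnames = list(subj, g))
      for (i in seq_along(profiles)) {
        sel <- prof_idx == i
        if (any(sel)) comp[sel, ] <- rdirichlet_block(sum(sel),
                                                      profiles[[i]]$alpha)
      }
      comp
    }
    ns_comp <- draw_site(spec$ns_profiles, ns_prof)
    npa_comp <- draw_site(spec$npa_profiles, npa_prof)
    depths <- function() pmax(rnbinom(n, mu = spec$depth_mean,
                                      size = spec$depth_size), spec$depth_min)
    ns_depth <- depths(); npa_depth <- depths()
    draw_counts <- function(comp, depth) {
      out <- vapply(seq_len(n),
                    function(i) rmultinom(1, depth[i], comp[i, ])[, 1],
                    numeric(length(g)))
      t(out)
    }
    ns_counts <- draw_counts(ns_comp, ns_depth)
    npa_counts <- draw_counts(npa_comp, npa_depth)
    dimnames(ns_counts) <- dimnames(npa_counts) <- list(subj, g)

    site_w <- rgamma(spec$n_sites, shape = 5)
    site <- sample(seq_len(spec$n_sites), n, replace = TRUE,
                   prob = site_w / sum(site_w))
    site_id <- sprintf("site%02d", site)
    site_int <- rnorm(spec$n_sites, 0, spec$site_sd)

    cov <- draw_covariates(n)
    oc <- spec$outcome
    lp <- oc$intercept + unname(oc$profile_log_or[ns_names[ns_prof]]) +
      site_int[site]
    for (v in names(oc$covariate_coefs)) {
      col <- cov[[v]]
      lp <- lp + oc$covariate_coefs[[v]] * as.numeric(col)
    }
    p_icu <- plogis(lp)
    icu <- rbinom(n, 1, p_icu)
    los_mult <- exp(ifelse(ns_names[ns_prof] %in% names(spec$los$log_mult),
                           spec$los$log_mult[ns_names[ns_prof]], 0))
    los <- rnbinom(n, mu = spec$los$mu * los_mult, size = spec$los$size)

    metadata <- cbind(data.frame(subject = subj, site_id = site_id),
                      cov,
                      data.frame(icu_use = icu == 1, los_days = as.integer(los)))
    cohort <- paired_cohort(
      abundance_table(ns_counts, site = "NS", mode = "counts"),
      abundance_table(npa_counts, site = "NPA", mode = "counts"),
      metadata)
    truth <- data.frame(subject = subj,
                        ns_profile = ns_names[ns_prof],
                        npa_profile = npa_names[npa_prof],
                        site_id = site_id,
                        linear_predictor = lp,
                        p_icu = p_icu)
    list(cohort = cohort, truth = truth)
  })
}

#' Random ultrametric genus tree
#'
#' Draws a random rooted bifurcating topology over the genus panel and
#' assigns ultrametric Grafen-style branch lengths with a small height
#' exponent (`rho = 0.15`), placing most divergences deep in the tree. This
#' emulates a genus-level 16S phylogeny, where the focal genera span several
#' phyla and even the closest pair is separated by long terminal branches —
#' unlike a coalescent tree, whose near-zero tip branches would make
#' adjacent genera phylogenetically indistinguishable.
#'
#' @param genera unique genus names (>= 2).
#' @param seed integer seed.
#' @param rho Grafen height exponent; smaller values push divergences
#'   toward the root.
#' @return A rooted ultrametric `phylo` object with positive branch lengths.
#' @export
generate_random_tree <- function(genera, seed = NULL, rho = 0.15) {
  if (length(genera) < 2) stop_np("need at least 2 genera for a tree")
  if (anyDuplicated(genera)) stop_np("duplicate genus names")
  topo <- with_seed_or_not(seed, {
    if (length(genera) == 2)
      ape::read.tree(text = sprintf("(%s,%s);", genera[1], genera[2]))
    else
      ape::rtopology(length(genera), rooted = TRUE, tip.label = genera)
  })
  ape::compute.brlen(topo, method = "Grafen", power = rho)
}

#' Write the simulator's outputs as pipeline input files
#'
#' Serializes the cohort as the plain-text formats the readers consume:
#' `ns_counts.tsv`, `npa_counts.tsv`, `metadata.csv`, `tree.nwk`, plus
#' `ground_truth.csv` for evaluation.
#'
#' @param sim result of [generate_cohort()].
#' @param tree optional `phylo` to write alongside.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_inputs <- function(sim, dir, tree = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(sim$cohort$ns, file.path(dir, "ns_counts.tsv"))
  write_abundance_table(sim$cohort$npa, file.path(dir, "npa_counts.tsv"))
  write.csv(sim$cohort$metadata, file.path(dir, "metadata.csv"),
            row.names = FALSE)
  write.csv(sim$truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  if (!is.null(tree)) ape::write.tree(tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}
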