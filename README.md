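# nichepair

Paired anterior-nares and nasopharyngeal microbiota analysis for infant
bronchiolitis cohorts.

## The problem

Nasal swabs (NS) of the anterior nares are far easier to collect — even by
parents at home — than nasopharyngeal aspirates (NPA), but the two sites
host different microbial communities. For microbiome–severity studies of
infant bronchiolitis the question is whether the NS community is concordant
enough with the NPA community to (a) track the same genera within an
individual and (b) reproduce the established associations between
nasopharyngeal dominance profiles (e.g. *Haemophilus*-dominant vs
*Moraxella*-dominant) and severity outcomes such as intensive-care use and
hospital length of stay.

`nichepair` implements that analysis as a tested, reusable pipeline for
genus-level 16S abundance tables from a paired two-site, multicenter
design:

* **Data model & I/O** — samples x taxa tables (TSV), OTU→genus collapse,
  relative abundance, seeded rarefaction, strict subject-id pairing.
* **Diversity** — richness, Shannon index *H = −Σ pᵢ ln pᵢ*; Bray-Curtis
  *d(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)*; weighted UniFrac
  *dᵂ(x,y) = Σ_b l_b |A_b − B_b|* over tree branches (normalized by
  *Σ_b l_b (A_b + B_b)* by default).
* **Concordance** — the cross-site Spearman matrix and a permutation test
  of the mean within-pair Spearman correlation against randomly re-paired
  samples, with the add-one rule *p = (1 + #{null ≥ obs})/(1 + B)*.
* **Ensemble network** — CoNet-style consensus of Spearman, Pearson,
  Bray-Curtis and symmetrized Kullback-Leibler scores for every NS x NPA
  genus pair at ≥10% prevalence; edges need ≥2 significant (p < 0.05),
  sign-unanimous metrics and are weighted by the observed Spearman value.
* **Profiling** — PAM (k-medoids) on Bray-Curtis of composite NS+NPA
  vectors (k = 10) and on weighted UniFrac of NS compositions (k = 6),
  with silhouette and gap-statistic model selection and dominance naming
  (≥0.40 mean share → "Genus-dominant", else "Mixed").
* **Severity** — crude odds ratios *OR = ad/bc* with Woolf intervals,
  fixed-effects logistic models, and mixed-effects logistic models with a
  collection-site random intercept, adjusted for 11 patient-level
  covariates.
* **Synthetic cohorts** — a seeded generator that emulates the study
  structure (815 subjects, 17 sites, 6 NS / 4 NPA dominance profiles,
  cross-site profile coupling, planted outcome odds ratios) so the whole
  pipeline is testable end-to-end without the unreleased cohort data.

## Worked example

```r
library(nichepair)

spec   <- cohort_spec(n_subjects = 300, seed = 2026)  # emulated paired cohort
sim    <- generate_cohort(spec)
cohort <- sim$cohort
ns     <- to_relative_abundance(cohort$ns)
npa    <- to_relative_abundance(cohort$npa)

genera <- top_genera_union(ns, npa)       # union of each site's top 10
head(genera, 5)
#> [1] "Staphylococcus"  "Moraxella"       "Streptococcus"   "Haemophilus"
#> [5] "Corynebacterium"

pairing_permutation_test(cohort, genera, n_perm = 1000, seed = 1)
#> Pairing permutation test: observed mean rho = 0.215, null 0.206 (SD 0.0062),
#>   p = 0.05894 (1000 permutations, 0 pairs dropped)

tree <- generate_random_tree(spec$genera, seed = 3)
prof <- cluster_site_profiles(ns, tree, k = 6)        # weighted UniFrac + PAM
table(prof$profiles)
#> Corynebacterium-dominant    Enterobacter-dominant     Haemophilus-dominant
#>                       51                       28                       20
#>       Moraxella-dominant  Staphylococcus-dominant
#>                       46                      155
```

The observed mean within-pair correlation (0.215) barely exceeds its
re-pairing null (0.206) because the generator couples the two sites only
through profile membership; the profile table shows the planted dominance
structure recovered from the NS site alone.

Crude odds-ratio arithmetic on the published profile-level outcome counts
bundled with the package (`published_profile_outcomes()`):

```r
pub      <- published_profile_outcomes()
profiles <- rep(pub$profile, pub$n)
icu      <- unlist(lapply(seq_len(nrow(pub)), function(i)
  c(rep(TRUE, pub$icu[i]), rep(FALSE, pub$n[i] - pub$icu[i]))))
tabs <- profile_outcome_tables(profiles, icu, reference = "Moraxella-dominant")
crude_or(tabs$tables[["Haemophilus-dominant"]])
#> OR 6.20 (95% CI 2.27-16.93), p = 0.000368 [crude]
```

An infant in the *Haemophilus*-dominant NS profile had 6.2 times the odds
of intensive-care use of an infant in the *Moraxella*-dominant profile.
`run_pipeline(pipeline_config(...))` chains every stage (simulate/ingest →
diversity → concordance → network → profiling → severity) and writes all
intermediate artifacts plus a machine-readable `summary.json`.

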