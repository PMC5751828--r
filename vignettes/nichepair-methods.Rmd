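---
title: "Methods: paired upper-airway microbiota profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired upper-airway microbiota profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`nichepair` analyses paired upper-airway microbiota samples: for every
subject one anterior-nares nasal swab (NS) and one nasopharyngeal aspirate
(NPA), with genus-level 16S abundance tables, subject metadata from a
multicenter design, and a rooted genus phylogeny. The pipeline answers two
questions. First, how concordant are the two sampling sites within an
individual — overall (a permutation test on the mean within-pair Spearman
correlation), per genus pair (a cross-site correlation matrix and an
ensemble co-occurrence network), and structurally (clustering of composite
NS + NPA profiles)? Second, do microbiota dominance profiles derived from
the easier-to-collect NS samples carry the same associations with
bronchiolitis severity (intensive-care use, hospital length of stay) that
were previously established for NPA profiles?

Because the original cohort's sequence data are not deposited, every stage
is exercised on synthetic cohorts from a seeded generator that emulates the
study's structure. The generator is first-class, tested code: its ground
truth drives the package's parameter-recovery checks.

# Data model

Abundance tables are samples-by-taxa matrices tagged with a site label and
a mode (`counts` or `proportions`; proportion rows must sum to 1 within
1e-9). OTU-level tables are collapsed to genus by exact column summation,
which commutes with row normalization. Paired cohorts join one NS and one
NPA sample per subject strictly by subject id — never by row position — so
tables can be stored and shuffled freely without silent misalignment.
Unclassified OTUs are routed to a reserved `"Unclassified"` genus
(configurable) that competes in abundance rankings like any other genus,
preserving mass.

The comparative genus panel is the union of each site's `n_top = 10` most
abundant genera, where a genus's overall abundance at a site is the sum of
its relative abundances over all subjects; the union is ordered by combined
abundance with lexicographic tie-breaks so the panel is deterministic.

Rarefaction subsamples each retained sample's reads uniformly without
replacement to a common depth (default: the minimum row sum among samples
with at least 1000 reads, a conventional floor; samples below the depth are
dropped and reported). Alpha diversity (genus richness and the Shannon
index) is computed on the rarefied table by default, with the un-rarefied
option exposed; the Shannon index uses natural logarithms, consistent with
the magnitude of reported airway diversity values at these richness levels.

# Synthetic cohort generator

A cohort specification fixes, in one serializable object: 815 subjects, 15
focal genera, 17 collection hospitals with Gamma-weighted uneven sizes, six
NS dominance profiles with mixing weights (Staphylococcus 0.445,
Corynebacterium 0.134, Moraxella 0.130, Mixed 0.144, Enterobacter 0.075,
Haemophilus 0.072), four NPA profiles (Moraxella, Streptococcus,
Haemophilus, Mixed), and a row-stochastic coupling matrix
P(NPA profile | NS profile). The coupling concentrates 0.75 on the
same-genus NPA profile for Haemophilus-dominant and Moraxella-dominant NS
subjects and is diffuse from the Staphylococcus-dominant NS profile, whose
subjects map to all four NPA groups — the qualitative cross-site mapping
the analysis is designed to detect.

Per subject, compositions are drawn from profile-specific Dirichlet
distributions. A dominant profile's Dirichlet mean places 0.60–0.78 on its
dominant genus (total concentration 12); the non-dominant mass is spread
proportionally to a site-level background ordering so that rare genera stay
rare in every profile, as in real communities. Mixed profiles use a lower
concentration (6) around a background-weighted mean. The dominance means
sit in the upper range of the reported per-profile cluster means; together
with the concentration they are chosen so the planted six-profile structure
is separated enough to be recoverable by distance-based clustering — the
regime the replication analysis assumes. Read depths are negative binomial
(mean 20000, size 5, truncated below at 2000 so every sample clears
rarefaction and pairing stays intact), and counts are multinomial.

Eleven clinical covariates are drawn from independent, documented marginals
calibrated to the cohort's characteristics table (age in months from a
discretized gamma; binary covariates Bernoulli; race/ethnicity and viral
PCR categorical). No attempt is made to copy the real joint covariate
structure. Intensive-care use follows a logistic model: intercept −2.58
(reference-profile risk near 6% at covariate means), per-NS-profile
log-odds offsets planted at the reported unadjusted odds ratios (in
particular log 6.2 for Haemophilus-dominant and 0 for the
Moraxella-dominant reference), coefficients −0.08 per month of age and 0.45
for pre-hospitalization antibiotics, and a Gaussian site random intercept
with SD 0.5. Length of stay is negative binomial with a Haemophilus-profile
mean multiplier of 1.8. The generator records per-subject ground truth
(profiles, site, linear predictor, outcome probability), which analysis
functions never read.

The genus tree for weighted UniFrac is a random rooted bifurcating topology
with ultrametric Grafen-style branch lengths using a small height exponent
(0.15). This places most divergences deep in the tree, which is the
realistic geometry for 15 genera spanning several bacterial phyla; a
coalescent tree's near-zero terminal branches would make neighboring genera
phylogenetically indistinguishable and is not a plausible model of a
genus-level 16S phylogeny.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: subject-level composition coupling beyond
profile membership (within a profile, NS and NPA draws are independent, so
the mean within-pair correlation exceeds its permutation null only
modestly, unlike the strong intra-individual correlation reported for the
real cohort); joint covariate structure and covariate–profile confounding;
sequencing artifacts, contamination, and species-level variation.

# Concordance

The observed statistic is the mean over subjects of the Spearman
correlation between the subject's NS and NPA abundance vectors restricted
to the top-genera panel (a flag admits all shared genera). The null
shuffles the NPA-to-subject assignment uniformly — fixed points allowed,
matching "randomly paired" — and recomputes the statistic; with B
permutations the one-sided p-value is `(1 + #(null >= obs)) / (1 + B)`, so
p is never exactly zero and a saturated result reports `p < 1/(B+1)`.
Subjects whose NS or NPA vector is constant have an undefined within-pair
correlation; they are dropped from the mean and counted in the output
rather than silently zeroed. The implementation standardizes per-subject
rank vectors once, making each permutation a single elementwise product —
10000 permutations on 815 subjects take seconds.

# Ensemble co-occurrence network

Cross-site genus pairs (NS source, NPA target) passing a 10%-of-samples
prevalence filter in their own site are scored with four association
metrics: Spearman and Pearson correlation across subjects, Bray-Curtis
dissimilarity between the two subject-indexed profiles, and symmetrized
Kullback-Leibler divergence after adding a pseudocount (1e-6, configurable)
and renormalizing each profile to a distribution over subjects. An edge is
kept when at least two metrics are significant at p < 0.05 and all
significant metrics agree on the direction (correlations: co-occurrence
iff positive; dissimilarities: co-occurrence iff the observed value falls
below the null median). Pairs whose significant metrics disagree are
dropped and counted in an audit record. Edge weight is the observed
Spearman correlation. No multiple-testing correction is applied in
replication mode; a Benjamini-Hochberg switch exists.

Per-metric significance uses a permutation null for the target genus with
the two-sided rule
`p = (1 + #(|null − mean(null)| >= |obs − mean(null)|)) / (1 + B)`.
Two null constructions are provided. The default permutes the target
vector across subjects unchanged; it is exchangeable with the observed
pairing, and its rejection rate under genuine independence is nominal for
all four metrics (the package's calibration tests verify this at
alpha = 0.05). The alternative (`renormalize = TRUE`) is the ReBoot-style
compositional correction: the permuted value is shuffled back into the
subject's composition and the focal share renormalized,
`y'_s = y_perm(s) / (1 − y_s + y_perm(s))`. That correction is designed for
within-composition screening, where closure induces spurious negative
associations; applied to a cross-site pair it couples each null draw to the
original subject's share, shifting the null's location and spread so that
its p-values are conservative for correlations and anticonservative for
divergence metrics. Since the network here is bipartite across two
different compositions — closure does not link an NS share to an NPA
share — the calibrated plain permutation is the scientifically appropriate
default, and the renormalized variant remains available for within-site
use.

# Dominance profiling

Clustering is k-medoids (PAM: greedy BUILD initialization, then SWAP passes
until no single exchange lowers the total dissimilarity to medoids),
computed by `cluster::pam` behind a thin wrapper that reports the exact
objective, medoid ids, and the average silhouette width. For small
problems (n <= 60) the wrapper adds a few deterministic random-restart
initializations and keeps the best solution, because a single BUILD+SWAP
run is a local search and can stall on small pathological instances; on
tiny problems the result then matches exhaustive enumeration over all
medoid subsets, which the tests verify.

Two clusterings mirror the study. The composite clustering adjoins each
subject's NS and NPA top-genera proportions (each half summing to at most
1), computes Bray-Curtis dissimilarities on the adjoined vectors, and runs
PAM with k = 10 in replication mode. The site clustering runs PAM on
normalized weighted UniFrac distances of one site's full compositions with
k = 6 for NS replication. Weighted UniFrac is implemented over a
branch-incidence matrix: raw distance `sum_b l_b |A_b − B_b|` over branches
b with length `l_b` and subtree abundance sums `A_b`, `B_b`; the normalized
variant divides by `sum_b l_b (A_b + B_b)` and is the default so values are
comparable across communities (the raw variant is exposed).

Model selection reports both criteria the study used: the average
silhouette width (the primary criterion, used for automatic k) and the gap
statistic. Because the data enter as dissimilarities, the gap statistic's
reference sets are drawn uniformly in the bounding box of a classical
multidimensional-scaling embedding — an approximation of the original
feature-space procedure, documented as such. Dispersion enters as
`log(W + eps)` with eps = 1e-10 so zero-dispersion solutions (duplicated
points) are handled; the selected k is the smallest with
`gap(k) >= gap(k+1) − se(k+1)`.

Clusters are named by dominance: `"<Genus>-dominant"` when the
within-cluster mean relative abundance of the top genus reaches 0.40, else
`"Mixed"`. The threshold sits between the reported dominant-profile means
(0.48–0.78) and the reported mixed-profile maximum (0.29). Ties break by
higher within-cluster prevalence, then lexicographically, so naming is
deterministic and invariant to cluster relabeling.

# Severity models

Outcomes are intensive-care use and length of stay dichotomized at >= 5
days (the primary threshold; >= 3 is available as an option for comparison
with the antecedent NPA analysis; event counts are monotone in the
threshold). Three estimators are provided, all complete-case with a
reported drop count:

* **Crude odds ratios** from 2x2 tables, `OR = ad/bc`, with Woolf
  (log-scale Wald) confidence intervals; a zero cell raises an error
  directing to the Haldane-Anscombe +0.5 correction. The per-profile 2x2
  builder produces profile-versus-reference tables and
  one-versus-all-others tables.
* **Fixed-effects logistic regression** (`stats::glm`), exposure either
  the full profile factor against a reference profile or one profile
  versus all others, optionally adjusted for the 11 patient-level
  covariates (age, sex, race/ethnicity, gestational age, previous
  breathing problems, daycare, other children at home, history of
  antibiotic use, history of corticosteroid use, antibiotics at the
  pre-hospitalization visit, respiratory viruses by PCR; categorical
  covariates reference-coded). Quasi-separation is flagged when fitted
  probabilities pin to 0/1 with a diverging coefficient.
* **Mixed-effects logistic regression** (`lme4::glmer`) adding a Gaussian
  random intercept for collection site, fitted by the Laplace
  approximation (the approximation used is recorded; adaptive quadrature
  available via `nAGQ`). A single-site cohort raises an error directing to
  the fixed-effects model.

For an unadjusted one-versus-reference exposure the logistic fit is
saturated, so its exponentiated coefficient equals the crude odds ratio
exactly — a cross-check the tests enforce to 1e-6. Crude 2x2 arithmetic on
the published profile-level outcome counts bundled with the package
reproduces the reported unadjusted intensive-care odds ratios for
Haemophilus (6.20), Corynebacterium (3.75) and Enterobacter (4.51) versus
the Moraxella reference, and Moraxella versus all others (0.30); the other
published unadjusted values do not arise from 2x2 arithmetic (they are
model-based), so both computations are provided and labelled.

# Determinism and problem sizes

Every stochastic stage takes a seed; the pipeline derives per-stage
substreams from one master seed and the stage name, so re-running a single
stage never perturbs another, and a repeated run is byte-identical. The
package's simulation-based checks use cohorts of 815 subjects and 17 sites
for parameter recovery (100 replicates for the planted odds ratio and site
SD, 20 for profile recovery, 10 for network edge recovery), 200 replicates
of small independent cohorts for null calibration, and exhaustive oracles
at n <= 10; these sizes keep the full suite to a few minutes while leaving
Monte-Carlo margins comfortably inside the asserted bounds.

# Known limitations

* Profile-level coupling is the only cross-site dependence, so the
  generator's within-pair concordance signal is weak relative to the real
  cohort's; power properties of the pairing test on real data are not
  established by these simulations.
* Weighted-UniFrac profile recovery varies substantially with the random
  tree's geometry (adjusted Rand index roughly 0.55–0.9 across seeds at
  the default settings); the median, not every draw, clears 0.8.
* The gap statistic's MDS-box reference is an approximation; for strongly
  non-Euclidean dissimilarities its calibration is heuristic, which is one
  reason silhouette is the primary selection criterion.
* Site random-intercept SD estimates from 17 sites are noisy; single-cohort
  estimates scatter widely around the planted 0.5.
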