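---
title: "Methods: two-phase clustering and knowledge-informed cluster selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-phase clustering and knowledge-informed cluster selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`foresite` implements an unsupervised pipeline for discovering recurring
functional sites in protein structures. Its inputs are (a) a table of
microenvironment vectors — per site, physicochemical property counts
over concentric radial shells around a central atom — and (b) a
knowledge corpus linking the proteins behind those sites to documents
(titles and abstracts) and to categorical annotations. Its output is a
disjoint set of site clusters, each scored for internal geometric
coherence and external literature coherence, annotated with enriched
terms, and rendered as static HTML.

This vignette records the model assumptions, the defaults and why they
hold, the numerical conventions, and the places where the design was
genuinely open and a choice had to be made.

# The vector model and its geometry

A microenvironment vector counts properties in radial shells; its entries
are non-negative counts or signed charge sums on very different scales.
Two normalizations are applied in sequence:

* **Per-feature standardization** divides each feature by its population
  (divisor *n*) standard deviation over the entire set, so no property
  dominates by scale. Constant features are left unchanged (divisor 1):
  dividing a zero-variance column by zero would propagate NaN through
  every downstream stage for no informational gain. No centering happens
  at this stage; centering is folded into the PCA.
* **Cosine geometry at clustering time.** All clustering stages
  (spherical k-means, hierarchical trees, node correlation, silhouettes)
  unit-normalize rows and use `1 - cosine` as the distance. The direction
  of a microenvironment profile — the *mix* of properties — matters more
  than its magnitude, which mostly tracks local atom density.

PCA (`fit_pca`) runs on the standardized, not unit-normalized, vectors:
reduction and sphere geometry are deliberately decoupled, with the cosine
step entering only after reduction. Components are computed by
`stats::prcomp` with centering; a deterministic sign convention (the
largest-magnitude loading of each component is made positive) removes the
sign ambiguity of eigenvectors so runs are reproducible across BLAS
builds. Explained variances use the sample (divisor *n − 1*) convention
of `prcomp`, and `transform`ed scores reproduce them exactly.

# Coarse partitioning: spherical k-means

`kmeans_cosine` alternates cosine assignment and centroid update, where a
centroid is the normalized mean of its members — the direction that
maximizes the mean cosine to them — so the objective
(sum of `1 - cosine` to assigned centers) is non-increasing; this is
asserted at every iteration. Details the method leaves open were fixed
as follows:

* **Initialization**: k-means++-style seeding adapted to cosine distance,
  with a caller-supplied seed. Default `n_restarts = 10`, best objective
  wins, ties to the lowest seed.
* **Convergence**: assignment fixed point, or objective improvement below
  `tol = 1e-6`, or `max_iter = 300`.
* **Empty clusters** are repaired by reseeding with the point farthest
  (in cosine) from its current centroid; repair never increases the
  objective.
* Assignment ties go to the lowest centroid index; all-zero rows are
  rejected (they have no direction).

Default `k = 40` and `n_pc = 80` are the configuration the method
was developed with; both are plain arguments, and `parameter_sweep` reruns the
reduce/coarse stages over a grid, reporting per-class best-cluster
hypergeometric enrichment, mean cosine silhouette and purity.

# Trees, node correlation, and selection

Within each coarse cluster (never globally — the two-phase design is the
point: the coarse pass makes the refinement tractable and local),
`hac_cosine` builds the exact single-linkage tree. Equal-distance merges
are broken deterministically: each active cluster is represented by its
smallest leaf index and the lexicographically smallest representative
pair merges first. Complete and average linkage exist behind an argument
for the evaluation sweeps only.

**Node correlation** `C` is realized as the cosine similarity between
the unit-normalized branch mean vectors of a node's two children,
clamped to `[0, 1]`. The quantity the original tooling reported at a
node is not recoverable in detail; branch-centroid cosine is the natural
realization consistent with the pipeline's metric, and the clamp keeps it in the stated `[0, 1]` range. Larger nodes average member noise away, so in
planted data the root of a genuine cluster has *higher* `C` than its
fragments — this is what lets selection prefer whole clusters without
external knowledge.

**The combined score.** The selection statistic takes into account node
correlation `C`, functional coherence `F` and size `N`, weighting the
two coherence measures approximately equally; its literal algebraic form
is not recoverable. The package's default is

    S = N^e · (w_C · C + w_F · min(F, F_cap) / F_cap),
    w_C = w_F = 0.5,  F_cap = 10,  e = 1,

chosen to honor the two defining constraints: `C` is bounded in
`[0, 1]` while `F` is unbounded above, so equal weighting requires
mapping `F` onto a comparable scale — a hard cap at `F_cap = 10`, well above
the 3.0 coherence filter, then normalizing to `[0, 1]`, so saturation
only affects strongly coherent clusters.
All four constants are configurable via `score_weights()`. The default
is validated only by its qualitative properties (linearity in `N`,
strict monotonicity in `C` and in `F` below the cap, `S = 0` at zero
coherence), never by matching any reference cluster list.

**Selection** is a bottom-up dynamic pass: a node is selected when its
score strictly exceeds the summed best of its branches; on ties the
descendant selection is kept (strict `>`).
The result is the maximum-total antichain, verified in the tests against
exhaustive enumeration. Leaves score 0 unless explicitly scored.
Filtering keeps `N ≥ 5` and `F > 3.0` (both strict thresholds
configurable); the complementary high-`C`/low-`F` list is also
available, since such clusters (disulfides, surface artifacts) are
informative negatives.

A node whose proteins have no documents gets `F = 0` with a warning
rather than an error, so one literature-poor subtree cannot abort a
whole coarse cluster.

# Functional coherence (NDPG)

The statistic follows the neighbor-divergence-per-gene construction as
far as it is documented: documents are weighted word vectors compared by
cosine; the 20 most similar documents are a document's semantic
neighbors; a document's score with respect to a cluster is the sum of
its neighbors' fractional references (the in-cluster share of a
neighbor's mapped proteins); per protein, the observed score
distribution is compared to a Poisson reference by KL divergence; `F`
averages that divergence over cluster proteins. Three details are not
specified anywhere and are fixed here as defaults:

* **Word-vector weighting**: `log(1 + tf) · idf` with
  `idf = ln(n_docs / df)`, unit-normalized; the same tokenizer as the
  annotation stage (lowercase, stop-worded, hyphen-preserving).
* **Binning**: document scores are floored to integer bins; the observed
  distribution is the relative frequency over occupied bins.
* **Poisson rate**: the protein's mean observed score, floored at
  `1e-6`. With this restriction-to-occupied-bins convention the KL sum
  is provably non-negative (the Poisson mass over a bin subset is ≤ 1),
  so `F ≥ 0` always; a protein whose scores are all zero contributes
  `KL ≈ 0`.

Neighbor lists are not symmetrized; ties in neighbor similarity break by
ascending document id; `m` is capped at `n_docs − 1` for tiny corpora.
Documents flagged as large-scale studies are removed at corpus
construction (they reference so many proteins that their fractional
references are noise), and the number removed is recorded. Proteins with
no surviving documents are excluded from the mean — scoring them 0 would
deflate `F` wherever the corpus is merely sparse — and reported in an
exclusion tally.

# Annotation scoring

Terms come from categorical per-protein tables (keywords, GO-like terms,
HETATM ligand codes, MeSH-like headings) and from literature unigrams
and bigrams. The counting entity is always the protein; for literature
terms a protein counts once per term if any of its documents contains
it, so one heavily published protein cannot inflate a count. Enrichment
is the upper tail of the hypergeometric distribution (enrichment only —
depletion has no use in discovery), via `stats::phyper`. The Bonferroni
factor is the number of distinct terms observed in the cluster for that
category — the hypotheses actually tested — rather than the universe
size; corrected p-values are capped at 1 and thresholded strictly at
0.01.

The entropy score for a literature term is the Shannon entropy of the
distribution `D_tp` (the share of the cluster's term-containing
documents belonging to protein `p`), normalized by the maximum entropy
over the cluster's terms *before* idf weighting, then multiplied by
`idf_t = ln(n_docs / df_t)` over the whole corpus. A term confined to
one protein scores exactly 0; the pre-idf maximum is attained by the
term most evenly spread across proteins. The significance cutoff defaults to 2.7.

# Synthetic study conditions

The generators define the conditions every test runs under; they are
pure functions of their arguments and a seed.

* **Vectors** (`gen_vectors`): planted unit centers with pairwise
  angular separation at least 60° by default; members are
  `center + noise · z/√dim`, renormalized, so `noise` is the expected
  perturbation norm and the expected cosine of a member to its center is
  `≈ 1/√(1 + noise²)` (0.995 at the default `noise = 0.1`). Background
  points are uniform on the sphere, labeled −1. Default dimension 264
  (44 properties × 6 shells).
* **Corpora** (`gen_corpus`): each topic owns a 50-word vocabulary, 5%
  of it shared across topics; a topic document draws 80% of its 50
  tokens from the topic vocabulary and the rest from a 3000-word
  background vocabulary; each protein has exactly 5 documents, one of
  which (`offtopic_fraction = 0.2`) is entirely background. The
  off-topic share reflects that only part of a real protein's
  literature concerns the function it shares with a cluster, and it is
  what gives per-protein score distributions the bimodal shape (some
  documents score high, some near zero) that the KL-vs-Poisson
  construction detects; with perfectly homogeneous literatures the
  statistic would be near-blind by design.
* **Reference conditions** used by the acceptance checks: 200 proteins
  (20 topics of 10, or topic/background mixes), within-topic word
  overlap 0.8 and cross-topic 0.05, 5 documents per protein; vector
  studies of 3 × 50 sites in dimension 264 at 60° separation and noise
  0.1. Oracle comparisons run at enumeration-friendly sizes
  (hypergeometric universes up to 25, trees up to 10 leaves, antichain
  enumeration up to 8 leaves), and multi-seed properties use 10–20
  seeds — sizes chosen so the whole suite stays in the minutes range
  while every claim is still computed, not assumed.

What the generators do **not** emulate: real abstract language (Zipfian
frequencies, named entities, negation), many-to-many protein–document
mappings (each synthetic document maps to one protein, so fractional
references are 0/1 at the document level), correlated features within
shells, and any correspondence between the surrogate PDB-derived
property set and the original 44-property representation. Passing tests
therefore demonstrate the pipeline's mechanics, determinism and
discriminative behavior under controlled signal, not performance on real
corpora.

# Degenerate inputs and edge conventions

* Single-site sets cannot be standardized (population sd undefined).
* All-zero vectors are rejected by every cosine-based stage.
* Shell binning in the structure reader is half-open `[inner, outer)`
  with the outermost shell closed; a central residue lacking an SG atom
  falls back to CB then CA with a warning. The disulfide filter uses a
  2.5 Å SG–SG threshold — comfortably above the ~2.05 Å covalent bond
  and below nonbonded contact distances.
* Dilution series at fraction 1.0 return the base cluster unchanged;
  fixed mode preserves size, additive mode grows it to
  `⌈base/fraction⌉`.
* Silhouettes assign width 0 to singleton clusters; clusters of one
  coarse member are skipped by the tree stage (never selectable).
* HTML rendering contains no timestamps or absolute paths, so reruns are
  byte-identical; the run manifest (config, seed, input MD5 hashes,
  package version) carries the reproducibility burden instead.

# Known limitations

The surrogate property extractor is explicitly not the original
44-property microenvironment representation (those definitions live in
prior work and are out of scope); pipeline correctness is therefore
established on synthetic vectors. The coherence statistic's absolute
scale depends on corpus density — cutoffs tuned on one corpus (the 3.0
coherence filter, the 2.7 entropy cutoff) are defaults to be recalibrated
on a new corpus, not universal constants. Selection is hard
(non-overlapping); soft or overlapping motif assignment is out of scope.
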