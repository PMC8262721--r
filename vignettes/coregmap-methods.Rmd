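---
title: "coregmap: models, parameters and design choices"
author: "coregmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coregmap: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coregmap)
```

# Scope and data model

`coregmap` analyses population-scale quantitative omics: an expression
matrix (proteins or transcripts in rows, samples in columns), an e/pQTL
table linking variants (rsIDs) to genes, a trait-association table linking
variants to molecular or clinical phenotypes, and local reference extracts
(protein complexes, scored interactions, subcellular localisations, drug
interactions, variant consequences). The pipeline connects these layers:
co-regulation (which features covary), genetics (which variants drive
which features), and co-mapping (which variants tie features to
phenotypes), and summarises the result as a typed multi-omic network.

Expression data travel as a `SummarizedExperiment`; pair-level statistics,
references, genome layouts and networks are S4 objects
(`CorrelationSet`, `ReferenceSet`, `GenomeLayout`, `MultiOmicGraph`) with
validity checks; QTL, trait and LD-block records stay validated
data.frames.

# Missing values

Proteomics matrices are rarely complete. Two complementary mechanisms are
offered:

* **Filtering** (`filterMissing`): a feature is removed iff its missing
  fraction *strictly exceeds* the cutoff, so a feature exactly at the
  cutoff stays. The default pipeline cutoff is 0.5.
* **Imputation** (`imputeMissing`): `downshift_normal` draws replacements
  per feature from Normal(mean − 1.8·sd, (0.3·sd)²) of the observed
  values — the standard left-shifted-distribution model for intensities
  missing because they fall below detection. The shift (1.8 sd) and width
  (0.3 sd) follow the convention popularised by proteomics processing
  suites; both the draws and the whole pipeline are reproducible from a
  single integer seed. `feature_min` substitutes the observed minimum;
  `none` leaves gaps and correlation proceeds on pairwise-complete
  observations, with `n_obs` recorded per pair.

# Correlation model

All `choose(F, 2)` unordered pairs are scored with one of:

* **Pearson**, the parametric default;
* **Spearman**, Pearson on average ranks (ties averaged);
* **biweight midcorrelation (bicor)**, the robust estimator of Langfelder
  & Horvath: with `u = (x − median(x)) / (9·mad(x))` (unscaled MAD) and
  Tukey weights `w = (1 − u²)²·1[|u| < 1]`, each vector is weighted,
  centred on its median and normalised to unit length; the correlation is
  the inner product. We apply no outlier-proportion capping
  (`maxPOutliers`-style); implementations that cap can differ in the
  extreme tails, a divergence we accept and document rather than hide. If
  a vector's MAD is zero the biweight is undefined and that vector falls
  back to mean/SD standardisation with a warning; if its variance is also
  zero the correlation is an error.

Significance is the two-sided Student-t test of zero correlation,
`t = r·sqrt((n−2)/(1−r²))` on `n − 2` df, with `|r| = 1` mapped to p = 0.
The test is exact under bivariate normality and is used for all three
estimators; for Spearman and bicor it is an approximation, adequate at the
sample sizes (tens of samples) the tool targets. q-values use
Benjamini–Hochberg (default) or Bonferroni via `p.adjust`. The
multiple-testing family is deliberately *all* emitted pairs — no
thresholding happens before adjustment, so q-values do not depend on
display cutoffs. Pairs with fewer than `minObs` (default 3)
pairwise-complete observations are omitted and counted, preserving
`emitted + skipped = choose(F, 2)`.

# Reference annotation and enrichment

Pairs are flagged against any number of references: pairwise catalogues
(STRING/BioPlex-style extracts, optionally scored) and complex catalogues
(CORUM-style member lists, where a complex of size k contributes all
C(k, 2) pairs). Scored catalogues can be restricted to their top score
decile with `filterTopPercentile` — retaining `ceil(N·p/100)` pairs under
a stable sort, so ties at the boundary keep earlier-listed pairs; on a
118,162-pair catalogue the 10th percentile keeps exactly 11,817.

Enrichment of reference membership among correlated pairs uses the
Pearson chi-squared test of independence on the 2×2 table
(correlated × in-reference), 1 df, *without* Yates continuity
correction — the pair families here are large (thousands of pairs), where
the correction only biases; a warning fires when any expected count drops
below 5. `sensitivityGrid` evaluates the test and the overlap fraction
over a default 9 × 8 grid (r cutoffs 0.1–0.9 step 0.1; q cutoffs 1e−4,
1e−3, 0.01, 0.05, 0.1, 0.2, 0.25, 1 — 72 combinations) so users can see
how conclusions move with the thresholds before fixing them; degenerate
cells are flagged rather than fatal.

Subcellular localisations are propagated through an acyclic parent
ontology: each feature's compartment set is replaced by its
transitive-ancestor closure (a protein annotated to a nuclear speck also
counts as nucleoplasmic and nuclear). Propagation is idempotent and
cycles are an error. Features with no annotation count as "different
compartment", not unknown — a conservative choice that never manufactures
co-localisation.

# QTL handling

Significance filtering respects the measure's direction (p-values keep
`≤ cut`, LOD scores keep `≥ cut`) and accepts per-proxy cutoffs (e.g.
stricter thresholds for trans than cis) with a global fallback.
`classifyCisTrans` calls a record cis iff the SNP lies on the gene's
chromosome within the closed window `[gene_start − w, gene_end + w]`; the
default `w` = 1 Mb is the common systems-genetics convention, and because
published datasets draw this line differently the user's own proxy column
is preserved untouched next to the computed one. Consequence terms from a
local rsID lookup are mapped to HIGH/MODERATE/LOW/MODIFIER impact ratings
by a shipped, editable table aligned with variant-annotation tools;
unknown terms become MODIFIER with a warning. Manhattan coordinates come
from a prefix-sum genome layout (chromosomes ordered numerically, then X,
Y, MT, then lexicographically); p = 0 is clamped to 1e−300 before −log10
so plot values stay finite.

# Co-mapping and networks

`comap` is an exact inner join on rsID: every (QTL row, trait row)
combination sharing a variant becomes a co-mapping, so cardinality is
`Σ_rsid |QTL_rsid|·|Trait_rsid|` by construction. The multi-omic graph
types its nodes (snp, feature, trait, ld_block, chromosome) and edges
(coregulation, qtl, trait_assoc), each edge carrying its layer's
annotations. SNP nodes can be collapsed into LD-block nodes (closed
interval membership; boundary SNPs belong to the block; SNPs outside all
blocks stay individual) or chromosome nodes; parallel edges of the same
type merge with multiplicities summed — total multiplicity is conserved —
while edges of different types never merge. Bait views extract induced
subgraphs: a gene with its direct neighbours; a complex with its members,
their SNP/trait neighbours, and the traits reached through those SNPs
(the two-hop trait reach is our choice, documented here, so that a
complex view still shows the phenotypes its variants tie to); a trait
with its SNPs and those SNPs' features. Graph filters (reference flag,
compartment, minimum impact, proxy) prune failing edges or nodes and then
drop isolated nodes, keeping a designated bait even when isolated.

# Synthetic studies

`generateStudy` produces every pipeline input with planted, recoverable
structure. Co-regulated complexes use a single latent factor per complex,
`x = sqrt(ρ)·f + sqrt(1−ρ)·ε`, giving exact expected pairwise correlation
ρ — chosen precisely because it has a closed-form target the tests can
check. Defaults (60 samples, 200 features, 5 complexes of 8 at ρ = 0.8,
5% values missing completely at random, 30 cis + 20 trans QTLs, 10
traits, 5 co-mapped SNPs) describe a compact inbred-panel-style proteomics
study; the synthetic genome is 20 chromosomes (1–19, X) of 150 Mb and
expression sits on a log2-intensity-like scale (baselines ~N(25, 2)).
Cis SNPs are placed inside their gene body and trans SNPs on another
chromosome, so class recovery is exact even at window 0; decoy trait SNPs
use a disjoint rsID range, so co-mapping recovery has no false positives
by construction; scored decoy interactions outnumber planted pairs more
than 9:1 with strictly lower scores, so planted pairs survive the
top-decile filter by construction.

What the generator does *not* emulate — realistic LD structure,
non-random missingness, heavy-tailed effect sizes, shared factors across
complexes, batch structure — bounds what green tests mean: they certify
the statistics, joins and graph algebra, not performance on any
particular real cohort.

# Numerical and policy choices

* Duplicate feature ids at ingest: keep the row with fewest missing
  values, first occurrence on ties, with a warning.
* Missing-value tokens: empty cell, `NA`, `NaN`, `nan` (case-insensitive).
* Columns bind by configurable header names, not position, so real
  exports with extra columns load.
* Chromosome labels are opaque strings with any `chr` prefix stripped;
  positions are 1-based, unit-agnostic numbers (bp or cM).
* Trait tables deduplicate (rsid, trait) keeping the most significant
  record; QTL rows with `gene_start > gene_end` are dropped with a
  warning.
* LD blocks must be non-overlapping per chromosome (error otherwise):
  block membership must be unambiguous for multiplicity conservation.
* All exports are plain CSV/GraphML/SVG/PDF; identical inputs, config and
  seed give byte-identical CSVs.

Test problem sizes (tens of features, dozens of samples, 50-fixture
oracle sweeps, a 10,000-draw imputation check) were chosen to exercise
every code path while keeping the whole suite fast to run routinely.

# Limitations

Exact numeric parity with other bicor implementations is not guaranteed
where they apply outlier capping. The t-based p-value is approximate for
the rank and robust estimators. Identifier mapping relies on a
user-supplied table rather than a live annotation service, and the
consequence lookup is a local extract, so coverage equals the extract's
coverage. The sensitivity grid's default composition is one reasonable
choice among many; it is fully overridable.
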