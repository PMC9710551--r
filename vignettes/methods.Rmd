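---
title: "Methods: embedding-based SAV pathogenicity annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: embedding-based SAV pathogenicity annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`savanno` treats missense-variant pathogenicity as binary classification
over a fixed-length encoding of one single amino acid variant (SAV):

* **Positional block (4608 features by default).** Two per-residue
  embedding backends embed the wild-type sequence and the sequence with the
  single substitution applied. For a variant at position *i*, the rows at
  *i* of the four matrices (variant and wild-type, per backend) are
  concatenated in a fixed order. The defaults mirror the production
  dimensions of the ESM-1v-class (D = 1280, input capped at 1024 residues)
  and ProtT5-class (D = 1024, unbounded) protein language models:
  2·1280 + 2·1024 = 4608.
* **Function block (600 features).** The host protein's GO annotation is
  reduced to *leaf terms* — every term that is a proper ancestor
  (`is_a`/`part_of` transitive closure, within its namespace) of another
  annotated term is dropped — then the precomputed 200-dimensional vectors
  of the surviving terms are averaged separately per sub-ontology and
  concatenated in (MF, CC, BP) order. Annotation is protein-level: every
  variant of a protein shares its function block.
* **Predictor.** The 5208-vector is standardised (train-set mean/sd),
  projected by PCA fitted on training rows only, and scored by an
  RBF-kernel C-SVM solved by sequential minimal optimisation. The decision
  rule is P/LP iff score ≥ 0. An isotonic regression fitted on pooled
  out-of-fold decision scores maps scores to calibrated probabilities, and
  RI = round(20·|p − 0.5|) compresses the probability into an integer
  confidence in 0..10.

The assumptions worth stating: (i) a single embedding row carries enough
local context to characterise the substitution — true for transformer
embeddings, where every row conditions on the whole (windowed) sequence;
(ii) protein-level function is informative about variant-level effect only
in aggregate, which is why the function block helps but cannot separate
two variants of the same protein; (iii) PCA truncation does not destroy
class signal — true only when the signal contributes enough variance,
see "Numerical choices".

# Homology-aware evaluation

Naive random splits leak information between homologous proteins. The
package clusters proteins by connected components of a similarity graph
(edges require identity ≥ 0.25 **and** coverage ≥ 0.40) and assigns whole
clusters to a blind set (target 10 % of variants; 20 % is a supported
alternative) and k = 10 cross-validation folds. Assignment is greedy
least-loaded-first over clusters sorted by decreasing variant count with
seeded tie shuffling; a label term steers near-ties toward folds whose
P/LP share tracks the global fraction. Clusters are never split: a giant
cluster produces visible imbalance rather than hidden leakage, and
`audit_leakage()` verifies that no retained edge crosses a bin boundary.

The internal aligner (Smith–Waterman, BLOSUM62, gap open 11 / extend 1 —
the standard protein-BLAST penalties) exists for test- and toy-scale sets.
Identity is matches over aligned columns (gaps included); coverage is the
aligned span of the shorter sequence over that sequence's length, a
documented choice since the reference point of coverage is genuinely open.
At production scale a precomputed edge file from a dedicated clustering
tool is the intended input (`read_edge_file()`); the toy aligner has no
E-value model, so *short* random sequences (≲100 residues) can link
spuriously — a known limitation, not a target of the tests, which use
100-mers and longer.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pca_components` | 2400 | projected dimension; capped at training rank |
| `svm_C` | 1 | SVM cost (box constraint), unitless |
| `svm_gamma` | `"scale"` = 1/(d·Var(X)) | RBF width, inverse squared feature units |
| `decision_threshold` | 0 | raw-score threshold for the P/LP label |
| grid | pca ∈ {1200, 2400}, C ∈ {1, 10, 100}, γ ∈ {scale, 1e-3, 1e-4} | `grid_search_cv()` candidates |
| `blind_fraction` / `k` | 0.10 / 10 | held-out share and CV fold count |
| `min_identity` / `min_coverage` | 0.25 / 0.40 | similarity-edge thresholds |
| window | 201 | residues fed to a backend when its length cap is exceeded |

The hyperparameter grid is a design default (the original optimisation
grid is not public); model selection maximises mean validation MCC with
ties broken toward fewer PCA components, then smaller C — prefer the
simpler model when performance is indistinguishable.

# The synthetic world

`make_fixture()` states a small world in which every stage is testable
offline:

* random sequences over the 20 canonical residues (length ~ N(mean, mean/6),
  floor 30), exact-count labels (`round(plp_fraction · n_variants)` P/LP);
* variants placed at distinct valid positions, wild-type read off the
  sequence, hosts label-grouped so proteins are (mostly) class-pure —
  mirroring the fact that disease proteins are a minority subset;
* two mock backends producing bounded pseudo-random matrices that are pure
  functions of (salt, sequence content): equal sequences embed equally,
  while changing any single residue changes every row, mimicking a
  language model's context sensitivity;
* class signal: for P/LP variants only, the mutated sequence's embedding
  row at the variant position is shifted by a vector lying in a random
  `latent_dim` = 10-dimensional orthonormal subspace rotated into the full
  embedding dimension. `embedding_separation` is the **per-latent-dimension**
  shift in pooled-SD units, so the total mean separation is
  `separation·√10` pooled SDs. This reading (rather than total distance)
  is deliberate: with total distance 3σ the Bayes-optimal MCC is ≈ 0.87,
  which would contradict the package's own recovery requirement of
  MCC > 0.9 at "3σ"; per-dimension shifts also match how the latent
  subspace is constructed. Rotation into the full space before PCA mirrors
  the pipeline's assumption that PCA retains signal;
* GO signal: a 33-node toy DAG (three namespaces; root, two mid terms, one
  reached by `part_of`, eight leaves each). Leaf pools are label-biased
  (disease-pool term vectors offset +0.5 per coordinate, benign −0.5); with
  probability `go_signal` a protein samples its two leaves per namespace
  from the pool matching its variants' majority label, otherwise from all
  leaves. A redundant ancestor is annotated 30 % of the time, exercising
  leaf filtering.

What a green test establishes: the pipeline recovers a planted
class-conditional mean shift through encoding, standardisation, PCA, the
SVM and calibration, at the stated signal strengths, and gains from GO
signal monotonically. What it does not establish: behaviour on real
language-model geometry (anisotropic, heavy-tailed, position-correlated),
real GO DAG topology and annotation depth bias, dataset shift between
catalogues, or per-protein correlation structure beyond the simple
class-purity device.

# Numerical choices

* **Standardise-then-PCA** (default on): the production feature blocks
  have very different scales, so standardisation is the safe default; the
  paper-scale architecture is silent on it and the flag is exposed. The
  cost is that standardisation whitens per-feature variance, so PCA keeps
  a planted signal only through its *between-class* variance contribution;
  signals confined to one coordinate can be diluted by heavy truncation.
  Tests that assert recovery therefore spread signal over several
  coordinates (as the latent-subspace fixture does) or use full rank.
* **SMO tolerance** 1e-3 (KKT gap), dense kernel, maximal-violating-pair
  selection; the intercept averages −y·∇f over free support vectors with a
  midpoint fallback. Agreement with an independent reference
  implementation is ~1e-6 at tolerance 1e-6.
* **Isotonic calibration**: weighted pool-adjacent-violators with tie
  pooling, linear interpolation between knots (the convention of the most
  widely used implementation), clamped outside the fitted score range.
  Pooled out-of-fold fitting gives one deployable calibrator; per-fold
  averaging was rejected as it yields no single monotone map.
* **Reliability index rounding** is half-away-from-zero with a 1e-9 guard
  so RI(p) = RI(1−p) holds exactly under floating point.
* **Undefined ratios** (zero denominators in precision/recall/MCC, AUC on
  single-class folds) surface as `NA` and are excluded from per-fold means
  with a warning — never silently zeroed.
* **Degenerate inputs**: empty annotation ⇒ zero function block; constant
  features ⇒ unscaled; windows near termini are shifted, not truncated, so
  the backend always sees the full window length when the sequence allows.

# Design choices where the design was open

* "Contrasting annotation" conflicts are evaluated per unique
  (accession, position, wt, mut) key across all sources **after** somatic
  and uncertain records are removed: a somatic B/LB report does not veto a
  germline P/LP assertion. Disease-id filtering of P/LP happens after
  conflict removal, so a disease-id-less P/LP record still vetoes a B/LB
  one.
* Records whose accession has no sequence are excluded with reason
  `no_sequence` rather than raised — catalogue merges routinely contain
  orphans; the CLI's strict mode (`encode`) raises instead.
* The 201-residue window applies per backend and only when that backend's
  cap is exceeded; an unbounded backend sees the full sequence.
* Leaf determination uses `is_a` **and** `part_of` by default (standard GO
  ancestor practice); a flag restricts to `is_a`.
* Model persistence is an RDS archive embedding a format version and a
  feature-layout checksum verified on load.

# Known limitations

* The toy aligner has no E-value statistics (see above); real-scale edge
  generation is delegated to external tools by design.
* The dense-kernel SMO is intended for ≤ a few thousand training rows —
  adequate for the package's evaluation machinery; production-scale
  training (10^5 rows) would need kernel caching and shrinking.
* Real-backend adapters are out of scope here; the backend contract
  (`embedding_backend()`) and the precomputed-matrix route
  (`precomputed_backend()`) are the integration points.
* Calibration quality is reported as a decile reliability gap; with very
  strong signal most mass sits in the extreme deciles and the middle
  deciles are sparse, so the gap is a coarse diagnostic there.
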