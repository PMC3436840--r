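---
title: "Predicting drug-target interactions from adverse-event profiles: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-target interactions from adverse-event profiles: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmpkr)
```

## The problem

Most drugs bind proteins besides their intended therapeutic target. These
off-targets drive side effects, and occasionally new indications, but for
thousands of compounds the full target profile is unknown. The premise of
this package is that a drug's *phenotypic* footprint — the side effects
reported for it in a spontaneous adverse-event reporting system such as the
FDA's AERS/FAERS — carries a signal about its protein targets: drugs that
bind the same proteins tend to provoke overlapping adverse-event profiles,
even when their chemical structures are unrelated. The package turns raw
quarterly report files into side-effect profiles, converts profiles into a
drug-drug similarity (a kernel), pairs it with a protein-protein sequence
kernel, and scores every drug-target pair with a closed-form pairwise
kernel regression.

## Side-effect profiles

Quarterly report files come as two `$`-delimited tables joined on the
report identifier (ISR): a DRUG table listing each mentioned drug with a
role code, and a REAC table listing reaction keywords. Only drugs flagged
primary or secondary suspect (PS/SS) are attributed the report's reactions;
concomitant and interacting entries (C/I) are discarded, because a
co-medication listed for completeness should not inherit the event.

Keywords are filtered on their report frequency $d_k$ (number of reports
containing keyword $k$ divided by all reports):

* too-frequent keywords ($d_k >$ `max_freq`) are removed — ubiquitous
  complaints like nausea carry little information about any one drug;
* too-rare keywords (fewer than `min_reports` reports) are removed as
  unreliable.

The package defaults, `max_freq = 0.001` and `min_reports = 5`, are scaled
to a multi-million-report corpus; they are only jointly satisfiable when
the corpus holds at least `min_reports / max_freq` = 5000 reports. For
smaller corpora the upper cutoff must be raised in proportion; the
synthetic-world analyses in the tests and the acceptance script use
`max_freq = 0.05` on a 2000-report corpus, which keeps the same intent
(drop the ubiquitous head and the unreliable tail of the keyword
distribution).

Two profile codings are available: **bit** (`1` if the drug ever co-occurs
with the keyword) and **freq**. The source material does not pin down the
freq denominator, so the package codes the *drug-conditional* frequency —
reports containing both drug and keyword over reports containing the drug —
which makes profiles comparable between heavily- and rarely-reported drugs;
the global-denominator variant is available via `denominator = "global"`.

## Weighted-cosine pharmacological similarity

Profiles are compared by a weighted cosine

$$ s(\mathbf{x}, \mathbf{x}') =
   \frac{\sum_k w_k x_k x'_k}
        {\sqrt{\sum_k w_k x_k^2}\sqrt{\sum_k w_k x'^2_k}}, \qquad
   w_k = \exp\!\left(-\frac{d_k^2}{(h\sigma)^2}\right), $$

where $\sigma$ is the mean of the retained $d_k$ and $h$ (default 1) sets
the bandwidth. The weight down-ranks common keywords and emphasizes rare,
phenotypically specific ones (agnosia says more about a drug than
dizziness). Any positive, strictly decreasing function of $d_k$ preserves
the intent; the chosen Gaussian-in-$d_k$ form is the package's own and is
pluggable through `keyword_weights(fun = ...)`. A profile with zero
weighted norm — a drug with no retained keyword — gets similarity 0 to
everything, itself included; this matches the treatment of entities with
missing data throughout (their kernel rows are zero, so their predictions
are zero rather than undefined).

Chemical and genomic similarities are deliberately simple surrogates
behind the same matrix contract, so precomputed matrices from heavier
tools can be dropped in: Tanimoto coefficients on binary fingerprints
(`chem_similarity()`), and Smith–Waterman local-alignment scores
normalized as $SW(a,b)/\sqrt{SW(a,a)\,SW(b,b)}$
(`seq_similarity()`, BLOSUM62, gap open 10 / extend 0.5 by default, with
the scoring scheme recorded in the result's attributes). Integrated
kernels (e.g. a pharmacological sum plus the chemical matrix) are
entrywise sums after aligning every input to the entity union, absent
entities contributing zero rows (`integrate_similarity()`).

## Pairwise kernel regression

Given $n_x$ drugs with kernel $K_x$, $n_y$ targets with kernel $K_y$, and
a 0/1 interaction label matrix $Z$, the model scores a pair
$(\mathbf{x}, \mathbf{y})$ as

$$ f(\mathbf{x}, \mathbf{y}) = \sum_{i,j} \beta_{ij}\,
   k_x(\mathbf{x}, \mathbf{x}_i)\, k_y(\mathbf{y}, \mathbf{y}_j)
   = \mathbf{k}_x^\top B\, \mathbf{k}_y, $$

the tensor-product factorization of a pairwise kernel machine. Minimizing
$\|Z - K_x B K_y\|_F^2$ gives the closed form $B = K_x^{-1} Z K_y^{-1}$,
computed as two symmetric positive-definite solves (Cholesky), never an
explicit inverse. The factorization means the $n_x n_y \times n_x n_y$
pairwise kernel is never formed; the package's tests verify agreement with
an explicitly assembled pairwise-space model to $10^{-8}$ on small
instances, which is the central correctness oracle.

Two regularizations are available and composable:

* **Low-rank labels** — replace $Z$ by its best rank-$q$ SVD truncation
  before solving (`q` argument). `q = min(n_x, n_y)` (the default) is the
  exact solution.
* **Ridge** — similarity matrices are conditioned as $S + \lambda I$
  (`condition_kernel()`, with an optional spectral shift when a matrix is
  indefinite) before inversion.

One consequence shaped the cross-validation design and deserves spelling
out. If pairs involving training entities are scored with rows of the
*conditioned* kernel, the ridge cancels exactly:
$f = (S+\lambda I)(S+\lambda I)^{-1} Z_q (S+\lambda I)^{-1}(S+\lambda I)
= Z_q$, so held-out labels (zeroed in $Z$) are predicted as zero no matter
the kernels — the model degenerates to low-rank label completion.
`run_cv()` therefore solves on the conditioned matrices but scores with
the raw similarity rows, i.e. with the kernel *function*. Under this view
$\lambda$ is the model's genuine regularization strength: as
$\lambda \to 0$ the fit interpolates the training labels, and as
$\lambda \to \infty$ predictions are fully smoothed onto kernel
neighborhoods. The default $\lambda = 1$ sits between the two; cross-
validated AUC on the reference synthetic world is flat between
$\lambda = 0.5$ and $10$, so the choice is not delicate.

## Evaluation: two cross-validation schemes

Both schemes are 3-fold with 5 re-randomized repetitions by default, and
both report AUC (rank-based, ties at 1/2) and AUPR (non-interpolated step
curve; the conservative convention, since interpolation inflates small-
positive-set areas). Per-fold metrics are averaged within a repeat and
summarized as mean ± SD over repeats; pooling scores across folds first is
available as an option.

* **Pair-wise CV** splits the full drug × target grid by pair and zeroes
  the test pairs' labels during training. It answers: given a drug with
  some known targets, can we find its missing ones? The model can exploit
  the drug's own remaining labels through target-kernel smoothing.
* **Block-wise CV** splits *drugs*; a fold's test set is all pairs of its
  drugs, which contribute no training rows at all. It answers the harder
  question: can we predict targets for a drug with no known interactions,
  from kernel neighbors alone? Block-wise AUC is systematically below
  pair-wise AUC — on the reference synthetic world by about 0.05–0.08 —
  mirroring the gap between finding extra off-targets of characterized
  drugs and profiling uncharacterized ones.

Negatives are all non-gold pairs in the scored region, consistent with
treating the gold standard as the complete positive set. As a permutation
null, `shuffle_edges()` rewires the gold standard by degree-preserving
double-edge swaps; because single draws have appreciable variance
(SD ≈ 0.02 in mean AUC), null levels are estimated as means over ~20
draws. The null sits slightly *below* 0.5 (≈ 0.46–0.49 on the reference
world): rewired held-out edges are excluded, by construction, from the
cells where a drug's training edges concentrate the model's scores — a
mild exclusion bias inherent to degree-preserving nulls on dense graphs,
not a defect of the scorer.

## Representative-drug selection

Drug collections are full of near-duplicates optimized from a common
lead; leaving them in makes any CV optimistic. `single_linkage_clusters()`
cuts the single-linkage dendrogram of the chemical similarity at a
threshold — implemented exactly as connected components of the graph with
edges where similarity is *strictly* greater than the threshold (ties at
the threshold do not merge) — and `select_representatives()` keeps one
random member per cluster (seeded; the draw depends only on sorted cluster
membership, not input order). `representative_sweep()` runs thresholds
0.1–1.0 in 0.1 steps; counts are non-decreasing in the threshold because
single-linkage components nest.

## The synthetic world

`generate_world()` builds a fully seeded testbed emulating every input
format: quarterly report files, fingerprints, protein FASTA, and a gold
standard. Its structural assumptions are exactly the ones the predictor
relies on, so recovery is informative:

* **Drug classes** (default 5 × 8 drugs) share side-effect signatures: 30
  signature keywords per class, a configurable fraction (default 0.1)
  drawn from a pool shared across classes. Each report names one PS drug,
  sometimes an SS class-mate (15%) or an unrelated co-medication with role
  C/I (30%), and draws 4 signature keywords plus 2 background keywords
  from a power-law popularity over the 2000-keyword universe (exponent
  1.5). The power-law head is frequent enough to trip the upper vocabulary
  filter and its tail rare enough to trip the lower one, so both removal
  paths are exercised on realistically shaped data.
* **Target families** (default 4 × 5 targets) are point-mutated copies of
  a family ancestor (200 aa, 5% per-site substitution), giving normalized
  Smith–Waterman similarity ≈ 0.87 within and ≈ 0.04 between families.
* **Gold standard.** Each drug has a primary family. The first four
  classes map whole-class to the four families; the fifth class's members
  are assigned families round-robin — a pharmacologically coherent class
  whose members diverge in their targets. This choice keeps expected
  target degrees balanced (an unbalanced assignment lets a degree-
  preserving null retain exploitable signal) and creates drugs whose own
  labels carry information their class-mates lack, which is precisely
  what separates the two CV schemes. A drug keeps each of its family's
  targets with probability `class_target_fidelity` (default 0.95); the
  escaped mass redistributes uniformly over off-family targets, so the
  per-drug interaction budget is conserved and fidelity 1 yields an
  exactly block-structured matrix.
* **Fingerprints** are built from disjoint global/class/private bit groups
  sized so within- and between-class Tanimoto hit the requested bands
  (defaults 0.6 / 0.1) exactly, which makes threshold behavior of the
  clustering sharply testable.

What the generator does **not** emulate: duplicate and follow-up reports,
MedDRA vocabulary structure, reporting biases correlated with drug age or
market size, indication-driven confounding (sick patients report events
caused by the disease), or heavy-tailed target degree distributions of
real interactomes. Passing recovery tests on this world demonstrates that
the pipeline's statistics and linear algebra do what they claim under the
model's own assumptions — not that the method will attain similar AUC on
real pharmacovigilance data.

## Numerical and degenerate-input conventions

* Kernels are symmetrized ($\,(S + S^\top)/2$) and conditioned before any
  solve; a non-positive-definite kernel after conditioning is a hard
  error suggesting a larger jitter, not a silent pseudo-inverse.
* Zero-norm profiles, empty fingerprints and all-zero kernel rows score 0
  against everything; reports emptied by the role filter are dropped;
  an empty vocabulary after filtering is a hard error naming the
  thresholds.
* AUC requires both classes and AUPR at least one positive; single-class
  inputs are hard errors rather than NaN.
* Prediction ties in `rank_predictions()` break lexicographically by
  (drug, target), making ranked output reproducible.
* All randomness (fold assignment, representative draws, world
  generation, rewiring) flows from explicit integer seeds; per-repeat CV
  substreams are derived from the plan seed.

## Problem sizes

The bundled analyses run at desk scale by design: the reference world has
40 drugs × 20 targets (800 pairs, ~200 edges, 2000 reports), factorization
oracles use instances with $n_x n_y \le 100$, and the clustering oracle
uses 100 random matrices up to $n = 30$. The closed-form solve is
$O(n_x^3 + n_y^3 + n_x n_y (n_x + n_y))$ and handles thousands of drugs
on a workstation; the quadratic-memory pairwise-space construction exists
only inside tests, as the oracle the factorization is checked against.

## Known limitations

* The freq-profile denominator and the label scale of $Z$ are
  conventions, not recoverable facts; both are configurable and the
  defaults are stated above.
* Report-frequency profiles conflate reporting rate with true
  event rate; no disproportionality correction (PRR/ROR) is applied.
* The surrogate chemical/sequence kernels are not the marginalized graph
  kernel or the local-alignment kernel; results with the surrogates
  quantify the pipeline, not those specific kernels.
* Scores are uncalibrated regression outputs; `rank_predictions()`
  thresholds by value or score quantile, and any probabilistic reading is
  unsupported.
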