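# pharmpkr

Drug–target interaction prediction from adverse-event side-effect
profiles, for computational pharmacologists and cheminformaticians who
want to find off-targets of marketed drugs — including drugs whose
chemical structure is uninformative or unavailable (biologics, extracts).

## What it does

Spontaneous adverse-event reports (FDA AERS/FAERS-style quarterly files)
are a phenotypic readout of a drug's protein interactions: drugs hitting
the same targets provoke overlapping side effects. `pharmpkr` implements
the full pipeline:

1. **Profiles** — parse `$`-delimited DRUG/REAC quarter files, keep
   suspect drugs (roles PS/SS), filter keywords by report frequency
   (`d_k ≤ max_freq`, count ≥ `min_reports`), and code each drug as a
   vector over retained keywords (binary or frequency-valued).
2. **Similarity** — weighted cosine between profiles,

   `s(x, x') = Σₖ wₖ xₖ x'ₖ / (√Σₖ wₖ xₖ² · √Σₖ wₖ x'ₖ²)`,
   `wₖ = exp(−dₖ² / (hσ)²)`,

   which emphasizes rare, informative keywords (σ is the mean keyword
   frequency, h a bandwidth). Surrogate chemical (Tanimoto fingerprint)
   and genomic (normalized Smith–Waterman) kernels, plus entrywise kernel
   integration, share the same matrix contract.
3. **Prediction** — pairwise kernel regression: with drug kernel `K_x`,
   target kernel `K_y` and label matrix `Z`, the weight matrix has the
   closed form `B = K_x⁻¹ Z K_y⁻¹` (two Cholesky solves; optional rank-q
   SVD truncation of `Z` and ridge conditioning), and a pair scores
   `f(x, y) = k_xᵀ B k_y` — the tensor-product factorization avoids ever
   forming the n_x·n_y pairwise kernel.
4. **Evaluation** — pair-wise (split pairs) and block-wise (split drugs)
   3-fold cross-validation with AUC/AUPR over repeated randomizations,
   degree-preserving permutation nulls, and single-linkage
   representative-drug selection to de-duplicate chemical series.
5. **Synthetic data** — a seeded generator emitting every input format
   (report quarters, fingerprints, FASTA, gold standard) with known
   ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(pharmpkr)

# a fully seeded synthetic world: 40 drugs in 5 classes, 20 targets in
# 4 families, 2000 adverse-event reports, gold-standard edge list
tw <- generate_world(world_spec(seed = 42), dir = "fixtures")

reports  <- aers_filter_suspect(
  aers_parse_quarter("fixtures/DRUG25Q1.TXT", "fixtures/REAC25Q1.TXT"))
reports
#> report_set: 2000 reports, 40 distinct drugs, 393 distinct keywords

vocab    <- aers_vocabulary(reports, max_freq = 0.05, min_reports = 5)
vocab
#> keyword_vocabulary: 178 keywords from 2000 reports; sigma = 0.02158 h = 1
profiles <- aers_profiles(reports, vocab, mode = "bit")

S_drug <- pharm_similarity(profiles, vocab)         # weighted cosine
S_prot <- seq_similarity("fixtures/proteins.fasta") # normalized SW
gold   <- read_interactions("fixtures/interactions.tsv")

run_cv(S_drug, S_prot, gold, cv_plan("pairwise", n_folds = 3, n_repeats = 5, seed = 1))
#> cv_result (pairwise, 3 folds x 5 repeats):
#>   AUC  = 0.9327 (SD 0.0060)
#>   AUPR = 0.8923 (SD 0.0112)
run_cv(S_drug, S_prot, gold, cv_plan("blockwise", n_folds = 3, n_repeats = 5, seed = 1))
#> cv_result (blockwise, 3 folds x 5 repeats):
#>   AUC  = 0.8485 (SD 0.0204)
#>   AUPR = 0.8011 (SD 0.0238)
```

Pair-wise CV (held-out *pairs*: find missing targets of known drugs)
recovers the interaction network with AUC 0.93; block-wise CV (held-out
*drugs*: profile a drug with no known targets) is distinctly harder, AUC
0.85 — the gap between completing a partially known drug and predicting
for an uncharacterized one.

Training on everything and ranking novel candidates:

```r
Kx <- condition_kernel(S_drug, jitter = 1)
Ky <- condition_kernel(S_prot, jitter = 1)
model <- pkr_fit(Kx, Ky, dti_label_matrix(gold, rownames(S_drug), rownames(S_prot)))
head(rank_predictions(pkr_predict(model, S_drug, S_prot), known = gold,
                      quantile = 0.99), 5)
#>   drug_id target_id     score
#> 1    D011      T009 0.6316321
#> 2    D032      T017 0.6071964
#> 3    D023      T012 0.5567973
#> 4    D025      T018 0.5452001
#> 5    D019      T015 0.5237185
```

The scores are uncalibrated regression outputs; high-scoring non-gold
pairs are the candidate off-targets.

A thin command-line wrapper with subcommands `simulate`, `build-profiles`,
`similarity`, `cluster`, `cv`, `train`, `predict` is installed at
`inst/cli/pharmpkr.R`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pharmpkr.R", package="pharmpkr"))')" \
  cv --method AERS-bit --drug-files fixtures/DRUG25Q1.TXT \
  --reac-files fixtures/REAC25Q1.TXT --fasta fixtures/proteins.fasta \
  --interactions fixtures/interactions.tsv --max-freq 0.05 --min-reports 5 \
  --scheme pairwise --seed 1 --out out/
```

See `vignettes/pharmpkr-methods.Rmd` for the model, its assumptions, the
synthetic world's design, and the numerical conventions.

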