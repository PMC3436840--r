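#' Specification of a synthetic drug-target world
#'
#' The generator emulates the statistical structure the prediction method
#' relies on: drugs fall into pharmacological classes whose members share
#' both side-effect signatures and target proteins ("similar ligands
#' interact with similar proteins"), targets fall into sequence families,
#' and adverse-event reports carry a heavy-tailed background of unrelated
#' keywords on top of the class signal.
#'
#' @param n_drug_classes Number of drug classes (default 5).
#' @param drugs_per_class Drugs per class (default 8).
#' @param n_target_families Number of protein families (default 4).
#' @param targets_per_family Targets per family (default 5).
#' @param n_keywords Size of the side-effect keyword universe (default
#'   2000).
#' @param reports_per_drug Adverse-event reports filed per drug (default
#'   50).
#' @param keyword_frequency_tail Power-law exponent of the background
#'   keyword popularity (default 1.5); the most popular background
#'   keywords are frequent enough to trip the vocabulary's upper frequency
#'   filter, the tail rare enough to trip the report-count filter.
#' @param signature_size Signature keywords per class (default 30).
#' @param class_keyword_overlap Fraction of each class signature drawn
#'   from a pool shared by all classes, in \[0, 1\] (default 0.1).
#' @param keywords_per_report Signature keyword draws per report
#'   (default 4).
#' @param background_per_report Background keyword draws per report
#'   (default 2); 0 gives noise-free reports.
#' @param class_target_fidelity Probability that a drug interacts with
#'   each target of its class's assigned family; off-family interactions
#'   occur with probability `1 - class_target_fidelity` (default 0.95).
#' @param chem_within_class,chem_between_class Exact Tanimoto similarity
#'   between fingerprints within and between classes (defaults 0.6 / 0.1).
#' @param seq_length Ancestor protein length (default 200).
#' @param seq_mutation_rate Per-site substitution probability from the
#'   family ancestor (default 0.05).
#' @param report_coverage Fraction of drugs that appear in the report
#'   roster (default 1); withheld drugs exercise the zero-kernel-row
#'   missing-data convention.
#' @param p_comed Probability a report lists an extra concomitant or
#'   interacting co-medication (default 0.3).
#' @param p_ss Probability a report lists a secondary-suspect class-mate
#'   (default 0.15).
#' @param seed RNG seed; the world is fully determined by it.
#' @return A `world_spec` list.
#' @export
world_spec <- function(n_drug_classes = 5, drugs_per_class = 8,
                       n_target_families = 4, targets_per_family = 5,
                       n_keywords = 2000, reports_per_drug = 50,
                       keyword_frequency_tail = 1.5, signature_size = 30,
                       class_keyword_overlap = 0.1, keywords_per_report = 4,
                       background_per_report = 2,
                       class_target_fidelity = 0.95,
                       chem_within_class = 0.6, chem_between_class = 0.1,
                       seq_length = 200, seq_mutation_rate = 0.05,
                       report_coverage = 1, p_comed = 0.3, p_ss = 0.15,
                       seed = 42) {
  spec <- as.list(environment())
  stopifnot(n_drug_classes >= 1, drugs_per_class >= 1,
            n_target_families >= 1, targets_per_family >= 1,
            n_keywords > 0, reports_per_drug > 0, signature_size > 0,
            class_keyword_overlap >= 0, class_keyword_overlap <= 1,
            class_target_fidelity >= 0, class_target_fidelity <= 1,
            report_coverage > 0, report_coverage <= 1,
            seq_mutation_rate >= 0, seq_mutation_rate <= 1)
  if (chem_between_class >= chem_within_class)
    stop("infeasible chemical bands: between-class similarity (",
         chem_between_class, ") must be below within-class (",
         chem_within_class, ")")
  structure(spec, class = "world_spec")
}

#' Generate a synthetic world and its fixture files
#'
#' Emits every file format the pipeline consumes, alongside the ground
#' truth used by tests:
#' * `DRUG25Q1.TXT` / `REAC25Q1.TXT` — one quarter of `$`-delimited
#'   adverse-event reports; each report names one primary-suspect drug,
#'   sometimes a secondary suspect from the same class and/or an unrelated
#'   co-medication (roles C/I), and keywords drawn from the class
#'   signature plus power-law background noise.
#' * `fingerprints.tsv` — bit fingerprints built from disjoint global,
#'   class-core and private bit groups sized so that within- and
#'   between-class Tanimoto equal the requested bands exactly.
#' * `proteins.fasta` — family members as point-mutated copies of a random
#'   family ancestor.
#' * `interactions.tsv` — gold-standard edges: each drug interacts with
#'   each target of its primary family with probability
#'   `class_target_fidelity`, and with each off-family target with
#'   probability `1 - class_target_fidelity`. Classes beyond the number of
#'   families distribute their members' primary families round-robin, so
#'   expected target degrees stay balanced.
#' * `truth.json` — class and family assignments, signatures, the edge
#'   list and the full report roster.
#'
#' @param spec A [world_spec()].
#' @param dir Output directory (created); `NULL` generates in memory only.
#' @return Invisibly, a `world_truth` list: `spec`, `drug_class`,
#'   `target_family`, `signatures`, `interactions`, `reports` (a
#'   `report_set`), `fingerprints`, `sequences`, and `files` (paths, when
#'   `dir` is given).
#' @export
generate_world <- function(spec = world_spec(), dir = NULL) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(spec$seed)
  n_drugs <- spec$n_drug_classes * spec$drugs_per_class
  n_targets <- spec$n_target_families * spec$targets_per_family
  drug_ids <- sprintf("D%03d", seq_len(n_drugs))
  target_ids <- sprintf("T%03d", seq_len(n_targets))
  drug_class <- rep(seq_len(spec$n_drug_classes), each = spec$drugs_per_class)
  names(drug_class) <- drug_ids
  target_family <- rep(seq_len(spec$n_target_families),
                       each = spec$targets_per_family)
  names(target_family) <- target_ids

  ## --- keyword universe: background popularity ~ rank^(-tail);
  ##     class signatures sit outside the popular head so the background
  ##     does not swamp them
  kw_ids <- sprintf("k%04d", seq_len(spec$n_keywords))
  bg_prob <- seq_len(spec$n_keywords)^(-spec$keyword_frequency_tail)
  bg_prob <- bg_prob / sum(bg_prob)
  n_shared <- round(spec$class_keyword_overlap * spec$signature_size)
  head_skip <- min(200L, spec$n_keywords %/% 4L)
  sig_pool_start <- head_skip + 1L
  need <- n_shared + spec$n_drug_classes * (spec$signature_size - n_shared)
  if (sig_pool_start + need - 1L > spec$n_keywords)
    stop("keyword universe too small for the requested signatures")
  shared_sig <- kw_ids[seq(sig_pool_start, length.out = n_shared)]
  excl_start <- sig_pool_start + n_shared
  signatures <- lapply(seq_len(spec$n_drug_classes), function(c) {
    n_excl <- spec$signature_size - n_shared
    excl <- kw_ids[seq(excl_start + (c - 1L) * n_excl, length.out = n_excl)]
    c(shared_sig, excl)
  })

  ## --- report roster
  reported_drugs <- drug_ids[seq_len(max(1L, round(spec$report_coverage * n_drugs)))]
  isr <- character(0); drugs <- list(); keywords <- list()
  rid <- 0L
  for (d in reported_drugs) {
    cls <- drug_class[[d]]
    for (r in seq_len(spec$reports_per_drug)) {
      rid <- rid + 1L
      entries <- data.frame(drug_id = d, role = "PS",
                            stringsAsFactors = FALSE)
      if (spec$drugs_per_class > 1 && stats::runif(1) < spec$p_ss) {
        mates <- setdiff(drug_ids[drug_class == cls], d)
        entries <- rbind(entries, data.frame(
          drug_id = sample(mates, 1), role = "SS"))
      }
      if (stats::runif(1) < spec$p_comed) {
        entries <- rbind(entries, data.frame(
          drug_id = sample(drug_ids, 1), role = sample(c("C", "I"), 1)))
      }
      kws <- unique(c(
        sample(signatures[[cls]], spec$keywords_per_report, replace = TRUE),
        if (spec$background_per_report > 0)
          sample(kw_ids, spec$background_per_report, replace = TRUE,
                 prob = bg_prob)))
      isr[rid] <- sprintf("ISR%06d", rid)
      drugs[[rid]] <- entries
      keywords[[rid]] <- sort(kws)
    }
  }
  reports <- new_report_set(isr, drugs, keywords)

  ## --- fingerprints: disjoint bit groups give exact Tanimoto bands.
  ##     sizes (g, c, u) solve (g+c)/(g+c+2u) = within and
  ##     g/(g+2c+2u) = between, up to integer rounding
  u <- 50L
  gc_sum <- round(2 * u * spec$chem_within_class / (1 - spec$chem_within_class))
  cc <- round((gc_sum - spec$chem_between_class * (gc_sum + 2 * u)) /
                (1 + spec$chem_between_class))
  g <- gc_sum - cc
  if (g < 0 || cc <= 0)
    stop("infeasible chemical bands: cannot realize within = ",
         spec$chem_within_class, ", between = ", spec$chem_between_class)
  nbits <- g + spec$n_drug_classes * cc + n_drugs * u
  fp <- matrix(0, n_drugs, nbits,
               dimnames = list(drug_ids, paste0("b", seq_len(nbits))))
  if (g > 0) fp[, seq_len(g)] <- 1
  for (i in seq_len(n_drugs)) {
    cls <- drug_class[i]
    fp[i, g + (cls - 1L) * cc + seq_len(cc)] <- 1
    fp[i, g + spec$n_drug_classes * cc + (i - 1L) * u + seq_len(u)] <- 1
  }

  ## --- protein family sequences
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  ancestors <- replicate(spec$n_target_families,
                         sample(aa, spec$seq_length, replace = TRUE),
                         simplify = FALSE)
  sequences <- vapply(seq_len(n_targets), function(i) {
    s <- ancestors[[target_family[i]]]
    mut <- stats::runif(spec$seq_length) < spec$seq_mutation_rate
    s[mut] <- vapply(s[mut], function(res) sample(setdiff(aa, res), 1), "")
    paste(s, collapse = "")
  }, character(1))
  names(sequences) <- target_ids

  ## --- gold-standard interactions.
  ## Each drug has a primary target family: the first n_target_families
  ## classes map whole-class to a family; members of surplus classes are
  ## assigned families round-robin (a pharmacologically coherent class
  ## whose members diverge in their primary targets), keeping expected
  ## target degrees balanced across families.
  drug_family <- integer(n_drugs)
  for (c in seq_len(spec$n_drug_classes)) {
    members <- which(drug_class == c)
    drug_family[members] <- if (c <= spec$n_target_families) c else
      ((seq_along(members) - 1L) %% spec$n_target_families) + 1L
  }
  names(drug_family) <- drug_ids
  in_block <- outer(drug_family, target_family, `==`)
  ## a drug keeps each family interaction with prob fidelity; the escaped
  ## (1 - fidelity) mass redistributes uniformly over off-family targets,
  ## so per-drug edge budgets are conserved and fidelity = 1 gives exact
  ## block structure
  n_off <- n_targets - spec$targets_per_family
  p_off <- if (n_off > 0) (1 - spec$class_target_fidelity) *
    spec$targets_per_family / n_off else 0
  p_edge <- ifelse(in_block, spec$class_target_fidelity, p_off)
  edge <- matrix(stats::runif(n_drugs * n_targets), n_drugs) < p_edge
  idx <- which(edge, arr.ind = TRUE)
  interactions <- data.frame(drug_id = drug_ids[idx[, 1]],
                             target_id = target_ids[idx[, 2]],
                             stringsAsFactors = FALSE)
  interactions <- interactions[order(interactions$drug_id,
                                     interactions$target_id), ]
  rownames(interactions) <- NULL

  truth <- structure(list(
    spec = spec, drug_class = drug_class, target_family = target_family,
    drug_family = drug_family,
    signatures = signatures, interactions = interactions,
    reports = reports, fingerprints = fp, sequences = sequences,
    files = NULL), class = "world_truth")

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      drug = file.path(dir, "DRUG25Q1.TXT"),
      reac = file.path(dir, "REAC25Q1.TXT"),
      fingerprints = file.path(dir, "fingerprints.tsv"),
      fasta = file.path(dir, "proteins.fasta"),
      interactions = file.path(dir, "interactions.tsv"),
      truth = file.path(dir, "truth.json"))
    write_aers_quarter(reports, files$drug, files$reac)
    write_fingerprints(fp, files$fingerprints)
    Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences),
                                files$fasta)
    write_interactions(interactions, files$interactions)
    jsonlite::write_json(list(
      seed = spec$seed,
      drug_class = as.list(drug_class),
      target_family = as.list(target_family),
      drug_family = as.list(drug_family),
      signatures = signatures,
      interactions = interactions,
      reports = lapply(seq_along(reports$isr), function(r) list(
        isr = reports$isr[r], drugs = reports$drugs[[r]],
        keywords = reports$keywords[[r]]))),
      files$truth, auto_unbox = TRUE, digits = NA)
    truth$files <- files
  }
  invisible(truth)
}

#' Serialize a report set to AERS-dialect files
#'
#' @param reports A `report_set`.
#' @param drug_file,reac_file Output paths.
#' @param sep Field delimiter (default `"$"`).
#' @export
write_aers_quarter <- function(reports, drug_file, reac_file, sep = "$") {
  stopifnot(inherits(reports, "report_set"))
  drug_lines <- unlist(lapply(seq_along(reports$isr), function(r) {
    d <- reports$drugs[[r]]
    paste(reports$isr[r], seq_len(nrow(d)), d$role, d$drug_id, sep = sep)
  }))
  reac_lines <- unlist(lapply(seq_along(reports$isr), function(r)
    paste(reports$isr[r], reports$keywords[[r]], sep = sep)))
  writeLines(c(paste("ISR", "DRUG_SEQ", "ROLE_COD", "DRUGNAME", sep = sep),
               drug_lines), drug_file)
  writeLines(c(paste("ISR", "PT", sep = sep), reac_lines), reac_file)
  invisible(c(drug_file, reac_file))
}

#' Degree-preserving shuffle of an interaction edge list
#'
#' Randomizes a bipartite edge list while preserving every drug's and
#' target's degree, via repeated double-edge swaps. Used as the
#' permutation null: a predictor run on rewired gold standards should
#' score at chance level.
#'
#' @param edges Data frame with `drug_id`, `target_id`.
#' @param seed RNG seed.
#' @param n_swaps Attempted swaps (default `10 * nrow(edges)`).
#' @return Rewired edge data frame with the same degree sequences.
#' @export
shuffle_edges <- function(edges, seed = 1, n_swaps = 10 * nrow(edges)) {
  m <- nrow(edges)
  if (m < 2) return(edges)
  set.seed(seed)
  d <- edges$drug_id; t_ <- edges$target_id
  key <- function(a, b) paste(a, b, sep = "\r")
  present <- new.env(hash = TRUE)
  for (i in seq_len(m)) assign(key(d[i], t_[i]), TRUE, envir = present)
  for (s in seq_len(n_swaps)) {
    ij <- sample.int(m, 2)
    i <- ij[1]; j <- ij[2]
    if (d[i] == d[j] || t_[i] == t_[j]) next
    if (exists(key(d[i], t_[j]), envir = present, inherits = FALSE) ||
        exists(key(d[j], t_[i]), envir = present, inherits = FALSE)) next
    rm(list = c(key(d[i], t_[i]), key(d[j], t_[j])), envir = present)
    tmp <- t_[i]; t_[i] <- t_[j]; t_[j] <- tmp
    assign(key(d[i], t_[i]), TRUE, envir = present)
    assign(key(d[j], t_[j]), TRUE, envir = present)
  }
  out <- data.frame(drug_id = d, target_id = t_, stringsAsFactors = FALSE)
  out[order(out$drug_id, out$target_id), , drop = FALSE]
}
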