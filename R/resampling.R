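# The sequence-assignment permutation null and bootstrap stability
# selection. The permutation shuffles which peptide sequence belongs to
# which classical allele within each gene, preserving every allele-disease
# relationship (allele dosages are untouched) while breaking the
# residue-allele linkage: deviance explained by the best few residues under
# this null measures what chance tagging of classical alleles can achieve.

#' Permute allele-to-sequence assignments
#'
#' Within each gene independently, the mapping allele -> full peptide
#' sequence is permuted uniformly at random; the per-gene multiset of
#' sequences is preserved and allele frequencies (hence allele-disease
#' relationships) are untouched. Genes with a single allele are left
#' unpermuted.
#'
#' @param alignment Peptide alignment tibble.
#' @param seed Integer seed.
#' @param genes Optional subset of genes to permute (default all).
#' @return A permuted alignment tibble of the same shape.
#' @export
permute_sequence_assignment <- function(alignment, seed = 1L, genes = NULL) {
  genes <- genes %||% unique(alignment$gene)
  set.seed(derive_seed(seed, "permute_alignment"))
  out <- alignment
  for (g in genes) {
    rows <- out$gene == g
    alleles <- unique(out$allele[rows])
    if (length(alleles) < 2L) next
    new_owner <- setNames(sample(alleles), alleles)
    out$allele[rows] <- unname(new_owner[out$allele[rows]])
  }
  out
}

# Greedy deviance-maximising forward selection of exactly k predictors
# (no significance threshold): at each step the candidate that most reduces
# the residual deviance enters (ties lexicographic; rank-deficient
# candidates skipped). Returns the selected set and the deviance explained
# relative to the covariates-only model.
greedy_topk <- function(M, y, Z, k) {
  X0 <- intercept_design(length(y), Z)
  f0 <- glm_dev(X0, y)
  null_dev <- f0$deviance
  cur_rank <- f0$rank
  cur_dev <- null_dev
  selected <- character(0)
  cands <- sort(colnames(M)[apply(M, 2L, var) > 0])
  for (step in seq_len(k)) {
    best <- NULL
    best_dev <- Inf
    for (nm in setdiff(cands, selected)) {
      f1 <- glm_dev(cbind(X0, M[, nm]), y)
      if (f1$rank <= cur_rank) next
      if (f1$deviance < best_dev) {
        best <- nm
        best_dev <- f1$deviance
      }
    }
    if (is.null(best)) break
    selected <- c(selected, best)
    X0 <- cbind(X0, M[, best])
    colnames(X0)[ncol(X0)] <- best
    cur_rank <- cur_rank + 1L
    cur_dev <- best_dev
  }
  list(selected = selected, deviance_explained = null_dev - cur_dev,
       n_selected = length(selected))
}

#' Sequence-assignment permutation null for top-k residue deviance
#'
#' Computes the deviance explained (null deviance minus residual deviance,
#' covariate-adjusted when covariates are supplied) by the best k residues
#' in the observed data, then repeats the computation on `B` permuted
#' alignments: each permutation reassigns sequences to alleles within genes
#' ([permute_sequence_assignment()]), residue dosages are re-derived from
#' the untouched allele dosages, and the top k residues are re-selected by
#' deviance-maximising forward search (`fixed_residues = TRUE` instead
#' keeps the observed residues' identities). The empirical p uses the
#' add-one convention (1 + #\{D_perm >= D_obs\}) / (B + 1).
#'
#' @param allele_dosages Output of [allele_dosage()] (invariant under the
#'   permutation).
#' @param alignment Observed peptide alignment.
#' @param phenotype Binary 0/1 vector.
#' @param k Number of top residues (>= 1).
#' @param covariates Optional covariate data frame.
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed; the whole `D_perm` vector is reproducible from
#'   (`seed`, `B`).
#' @param fixed_residues Keep the observed top-k residue identities instead
#'   of re-selecting per permutation.
#' @param max_retries Retries per replicate when a permutation leaves fewer
#'   than `k` polymorphic residues.
#' @return An object of class `hla_permnull`: list with `k`, `d_obs`,
#'   `d_perm` (length `B`), `p`, `observed_residues`, `B`, `seed`, `scope`.
#' @export
permutation_null <- function(allele_dosages, alignment, phenotype, k,
                             covariates = NULL, B = 100L, seed = 1L,
                             fixed_residues = FALSE, max_retries = 20L) {
  k <- check_count(k, "k")
  B <- check_count(B, "B")
  y <- check_phenotype(phenotype, nrow(allele_dosages))
  Z <- covariate_matrix(covariates, nrow(allele_dosages))

  obs_pool <- polymorphic_pool(residue_dosage(allele_dosages, alignment))
  obs <- greedy_topk(dosage_matrix(obs_pool), y, Z, k)
  if (obs$n_selected < k) {
    abort(paste0("only ", obs$n_selected,
                 " independent polymorphic residues available for k = ", k))
  }

  d_perm <- numeric(B)
  for (b in seq_len(B)) {
    got <- NA_real_
    for (attempt in seq_len(max_retries)) {
      perm_aln <- permute_sequence_assignment(
        alignment, seed = derive_seed(seed, paste0("perm", b, ".", attempt)))
      pool <- polymorphic_pool(residue_dosage(allele_dosages, perm_aln))
      M <- dosage_matrix(pool)
      if (fixed_residues) {
        keys <- intersect(obs$selected, colnames(M))
        X0 <- intercept_design(length(y), Z)
        f0 <- glm_dev(X0, y)
        f1 <- glm_dev(cbind(X0, M[, keys, drop = FALSE]), y)
        got <- f0$deviance - f1$deviance
        break
      }
      res <- greedy_topk(M, y, Z, k)
      if (res$n_selected == k) {
        got <- res$deviance_explained
        break
      }
    }
    if (is.na(got)) {
      abort(paste0("replicate ", b, ": fewer than k polymorphic residues in ",
                   max_retries, " permutation attempts"))
    }
    d_perm[b] <- got
  }
  structure(
    list(k = k, d_obs = obs$deviance_explained, d_perm = d_perm,
         p = (1 + sum(d_perm >= obs$deviance_explained)) / (B + 1),
         observed_residues = obs$selected, B = B, seed = seed,
         scope = "within-gene, all genes jointly"),
    class = "hla_permnull"
  )
}

#' @export
print.hla_permnull <- function(x, ...) {
  cat("<hla_permnull> k = ", x$k, ", B = ", x$B,
      "; deviance explained = ", format(x$d_obs, digits = 5),
      ", empirical p = ", format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Bootstrap stability of stepwise selection
#'
#' Repeats forward stepwise selection on subsamples: each replicate draws
#' `floor(fraction * n_cases)` cases and `floor(fraction * n_controls)`
#' controls without replacement and selects up to `top_k` predictors,
#' recording the order of entry. The summary tabulates, for each predictor
#' and entry rank, the fraction of replicates in which it entered at that
#' rank. Predictors left constant by a subsample simply cannot enter in
#' that replicate.
#'
#' @param pool Dosage tibble of candidate predictors.
#' @param phenotype Binary 0/1 vector.
#' @param covariates Optional covariate data frame.
#' @param B Replicates (the reference analysis uses 1000).
#' @param fraction Subsampling fraction in (0, 1), conventionally 2/3.
#' @param top_k Predictors selected per replicate (conventionally 20).
#' @param p_enter Optional entry threshold; by default entry is
#'   unthresholded (the best `top_k` always enter, as a rank-stability
#'   analysis requires).
#' @param seed Integer seed.
#' @return An object of class `hla_stability`: list with `replicates`
#'   (tibble `replicate`, `step`, `predictor`), `rank_freq` (tibble
#'   `predictor`, `rank`, `frequency`), `B`, `fraction`.
#' @export
bootstrap_stability <- function(pool, phenotype, covariates = NULL,
                                B = 100L, fraction = 2 / 3, top_k = 20L,
                                p_enter = NULL, seed = 1L) {
  B <- check_count(B, "B")
  fraction <- check_prob(fraction, "fraction", lo = 0, hi = 1, lo_open = TRUE)
  top_k <- check_count(top_k, "top_k")
  y <- check_phenotype(phenotype, nrow(pool))
  if (is.null(p_enter)) p_enter <- 1 - 1e-12
  cases <- which(y == 1)
  controls <- which(y == 0)
  n_case_take <- if (fraction == 1) length(cases) else
    floor(fraction * length(cases))
  n_ctrl_take <- if (fraction == 1) length(controls) else
    floor(fraction * length(controls))

  reps <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, paste0("boot", b)))
    idx <- c(sample(cases, n_case_take), sample(controls, n_ctrl_take))
    cov_b <- if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE]
    tr <- forward_stepwise(pool[idx, ], y[idx], cov_b,
                           p_enter = p_enter, max_steps = top_k)
    reps[[b]] <- if (nrow(tr) > 0L) {
      tibble(replicate = b, step = tr$step, predictor = tr$predictor)
    } else {
      tibble(replicate = integer(), step = integer(), predictor = character())
    }
  }
  replicates <- bind_rows(reps)
  rank_freq <- replicates |>
    dplyr::count(.data$predictor, rank = .data$step) |>
    mutate(frequency = .data$n / B) |>
    select("predictor", "rank", "frequency") |>
    arrange(.data$rank, desc(.data$frequency))
  structure(list(replicates = replicates, rank_freq = rank_freq,
                 B = B, fraction = fraction, top_k = top_k, seed = seed),
            class = "hla_stability")
}

#' @export
print.hla_stability <- function(x, ...) {
  cat("<hla_stability> B = ", x$B, ", fraction = ",
      format(x$fraction, digits = 4), ", top_k = ", x$top_k, "\n", sep = "")
  top <- x$rank_freq[x$rank_freq$rank == 1L, ]
  if (nrow(top) > 0L) {
    cat("rank-1 entries:\n")
    print(head(top, 5L))
  }
  invisible(x)
}
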