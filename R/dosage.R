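# From genotype posteriors + peptide alignment to expected-copy (dosage)
# matrices. Dosage of a predictor is the posterior-weighted expected number
# of copies (0-2) an individual carries; per gene the allele dosages sum to
# 2 and per aligned position the residue dosages (gap included) sum to 2.

#' Expected classical-allele copy counts from genotype posteriors
#'
#' For each individual and allele, the dosage is the posterior-weighted count
#' of copies over all candidate genotypes (averaging over the possible
#' genotype combinations).
#'
#' @param posteriors Genotype posterior table: tibble with columns
#'   `individual_id`, `gene`, `allele1`, `allele2`, `posterior`; per
#'   individual-gene the posteriors must sum to 1 (within 1e-6).
#' @param gene Optional single gene; default uses every gene in the table
#'   (individuals missing a gene get `NA` dosages for that gene's alleles).
#' @return A dosage tibble: `individual_id` plus one numeric column per
#'   allele, named `gene*allele` (e.g. `"HLA-DQA1*04:01"`).
#' @export
allele_dosage <- function(posteriors, gene = NULL) {
  genes <- if (is.null(gene)) unique(posteriors$gene) else gene
  if (!all(genes %in% posteriors$gene)) {
    abort(paste0("gene not present in posterior table: ",
                 paste(setdiff(genes, posteriors$gene), collapse = ", ")))
  }
  per_gene <- lapply(genes, function(g) {
    pg <- posteriors[posteriors$gene == g, ]
    tot <- tapply(pg$posterior, pg$individual_id, sum)
    zero <- names(tot)[tot <= 0]
    if (length(zero) > 0L) {
      abort(paste0("zero total posterior for gene ", g, ", individual(s): ",
                   paste(zero, collapse = ", ")))
    }
    off <- names(tot)[abs(tot - 1) > 1e-6]
    if (length(off) > 0L) {
      abort(paste0("posteriors for gene ", g, " do not sum to 1 for: ",
                   paste(head(off, 5L), collapse = ", ")))
    }
    alleles <- sort(unique(c(pg$allele1, pg$allele2)))
    ids <- sort(unique(pg$individual_id))
    M <- matrix(0, length(ids), length(alleles),
                dimnames = list(ids, allele_key(g, alleles)))
    i <- match(pg$individual_id, ids)
    j1 <- match(allele_key(g, pg$allele1), colnames(M))
    j2 <- match(allele_key(g, pg$allele2), colnames(M))
    cell <- c((j1 - 1L) * length(ids) + i, (j2 - 1L) * length(ids) + i)
    acc <- rowsum(rep(pg$posterior, 2L), group = cell)
    M[as.integer(rownames(acc))] <- acc[, 1L]
    as_dosage_tibble(M, ids)
  })
  out <- Reduce(function(a, b) dplyr::full_join(a, b, by = "individual_id"),
                per_gene)
  arrange(out, .data$individual_id)
}

#' Expected residue copy counts at aligned peptide positions
#'
#' Converts allele dosages into residue dosages: the dosage of residue `r` at
#' position `p` of a gene is the sum of that gene's allele dosages over
#' alleles carrying `r` at `p`. The gap symbol `"_"` is a first-class residue
#' level, so per position the residue dosages (gap included) sum to 2.
#' Positions carrying a single residue level are kept but flagged in the
#' `"monomorphic"` attribute (and excluded by [polymorphic_pool()]).
#'
#' @param allele_dosages Output of [allele_dosage()].
#' @param alignment Peptide alignment tibble (`gene`, `allele`, `position`,
#'   `residue`); every allele column must be resolvable in it.
#' @return A dosage tibble: `individual_id` plus one column per residue,
#'   named `gene@position:residue` (e.g. `"HLA-DPB1@11:L"`), with attribute
#'   `monomorphic` (character vector of single-residue position keys).
#' @export
residue_dosage <- function(allele_dosages, alignment) {
  info <- parse_allele_key(dosage_cols(allele_dosages))
  aln_id <- paste(alignment$gene, alignment$allele)
  missing <- info$key[!paste(info$gene, info$allele) %in% aln_id]
  if (length(missing) > 0L) {
    abort(paste0("allele(s) absent from alignment: ",
                 paste(missing, collapse = ", ")))
  }
  A <- dosage_matrix(allele_dosages)
  blocks <- list()
  mono <- character(0)
  for (g in unique(info$gene)) {
    g_alleles <- info$allele[info$gene == g]
    aln_g <- alignment[alignment$gene == g & alignment$allele %in% g_alleles, ]
    for (p in sort(unique(aln_g$position))) {
      ap <- aln_g[aln_g$position == p, ]
      res_levels <- sort(unique(ap$residue))
      keys <- residue_key(g, p, res_levels)
      B <- vapply(res_levels, function(r) {
        cols <- allele_key(g, ap$allele[ap$residue == r])
        rowSums(A[, cols, drop = FALSE])
      }, numeric(nrow(A)))
      colnames(B) <- keys
      blocks[[length(blocks) + 1L]] <- B
      if (length(res_levels) == 1L) mono <- c(mono, keys)
    }
  }
  out <- as_dosage_tibble(do.call(cbind, blocks), allele_dosages$individual_id)
  attr(out, "monomorphic") <- mono
  out
}

#' Drop monomorphic and constant predictors from a dosage pool
#'
#' Association pools exclude positions that carry a single residue (or any
#' predictor with zero variance in the sample at hand); the alignment itself
#' keeps them.
#'
#' @param dosages A dosage tibble.
#' @return The dosage tibble without flagged-monomorphic or constant columns.
#' @export
polymorphic_pool <- function(dosages) {
  mono <- attr(dosages, "monomorphic") %||% character(0)
  keep <- setdiff(dosage_cols(dosages), mono)
  M <- dosage_matrix(dosages[c("individual_id", keep)])
  keep <- keep[apply(M, 2L, function(x) var(x, na.rm = TRUE) > 0)]
  out <- dosages[c("individual_id", keep)]
  attr(out, "monomorphic") <- character(0)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Best-guess genotype filter
#'
#' Keeps, per individual-gene, only the highest-posterior genotype as a point
#' mass provided its posterior exceeds `threshold`; otherwise the
#' individual-gene is treated as missing (its rows are dropped, and
#' downstream analyses drop such individuals predictor-wise).
#'
#' @param posteriors Genotype posterior table.
#' @param threshold Acceptance cutoff in (0, 1\]; the conventional choice for
#'   imputed HLA genotypes is 0.8.
#' @return A filtered posterior table of point masses (`posterior = 1`).
#' @export
best_guess_filter <- function(posteriors, threshold = 0.8) {
  threshold <- check_prob(threshold, "threshold", lo = 0, hi = 1, lo_open = TRUE)
  posteriors |>
    group_by(.data$individual_id, .data$gene) |>
    filter(row_number() == which.max(.data$posterior)) |>
    ungroup() |>
    filter(.data$posterior > threshold) |>
    mutate(posterior = 1)
}

#' Imputed predictor frequencies
#'
#' The imputed frequency of an allele or residue is its mean dosage divided
#' by 2 (the case/control columns of a marginal association table).
#'
#' @param dosages A dosage tibble.
#' @param subset Optional individual ids (or logical vector) to restrict to,
#'   e.g. cases only.
#' @return A tibble with columns `predictor` and `frequency`.
#' @export
residue_frequency <- function(dosages, subset = NULL) {
  d <- dosages
  if (!is.null(subset)) {
    d <- if (is.logical(subset)) d[subset, ] else
      d[d$individual_id %in% subset, ]
  }
  if (nrow(d) == 0L) abort("empty individual subset")
  M <- dosage_matrix(d)
  tibble(predictor = colnames(M),
         frequency = unname(colMeans(M, na.rm = TRUE)) / 2)
}

#' Pairwise squared correlation of dosage predictors
#'
#' Squared Pearson correlation between dosage columns, the LD measure used
#' for alternative-explanation screening and predictor pruning. Constant
#' columns get `NA` rows/columns and are listed in the `"constant"`
#' attribute.
#'
#' @param dosages A dosage tibble.
#' @return A symmetric r-squared matrix of class `hla_r2` (diagonal 1 for
#'   non-constant predictors).
#' @export
correlation_r2 <- function(dosages) {
  M <- dosage_matrix(dosages)
  if (nrow(M) < 2L) abort("at least 2 individuals required")
  const <- colnames(M)[apply(M, 2L, function(x) var(x, na.rm = TRUE) == 0)]
  suppressWarnings(r2 <- cor(M, use = "pairwise.complete.obs")^2)
  r2[const, ] <- NA_real_
  r2[, const] <- NA_real_
  diag(r2)[!colnames(M) %in% const] <- 1
  structure(r2, constant = const, class = c("hla_r2", class(r2)))
}

#' Greedy low-correlation index set
#'
#' A single greedy pass in the given predictor order keeps a predictor iff
#' its r-squared with every already-kept predictor is below `r2_max` — the
#' filtering used to thin near-duplicate residues before model search.
#'
#' @param corr An [correlation_r2()] matrix.
#' @param r2_max Exclusion threshold in (0, 1\].
#' @param order Optional predictor ranking (character vector); defaults to
#'   column order.
#' @return Character vector of retained predictor ids (constant predictors
#'   are never retained).
#' @export
prune_index_set <- function(corr, r2_max, order = NULL) {
  r2_max <- check_prob(r2_max, "r2_max", lo = 0, hi = 1, lo_open = TRUE)
  order <- order %||% colnames(corr)
  order <- setdiff(order, attr(corr, "constant"))
  kept <- character(0)
  for (p in order) {
    if (length(kept) == 0L || all(corr[p, kept] < r2_max, na.rm = TRUE)) {
      kept <- c(kept, p)
    }
  }
  kept
}

#' Single-linkage LD tag groups
#'
#' Partitions predictors into LD groups by single-linkage clustering at
#' r-squared >= `tag_r2` (so a chain a~b~c groups together even if a~c is
#' weaker). Constant (monomorphic) predictors are discarded before grouping.
#' The conventional threshold is 0.9604 = 0.98^2.
#'
#' @param corr An [correlation_r2()] matrix.
#' @param tag_r2 Grouping threshold in (0, 1\].
#' @return A tibble with columns `predictor` and `group` (integer labels).
#' @export
tag_groups <- function(corr, tag_r2 = 0.9604) {
  tag_r2 <- check_prob(tag_r2, "tag_r2", lo = 0, hi = 1, lo_open = TRUE)
  keep <- setdiff(colnames(corr), attr(corr, "constant"))
  if (length(keep) == 0L) return(tibble(predictor = character(), group = integer()))
  if (length(keep) == 1L) return(tibble(predictor = keep, group = 1L))
  d <- as.dist(1 - unclass(corr)[keep, keep])
  grp <- cutree(hclust(d, method = "single"), h = 1 - tag_r2)
  tibble(predictor = keep, group = as.integer(grp)) |>
    arrange(.data$group, .data$predictor)
}
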