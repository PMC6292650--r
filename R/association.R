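# Logistic-regression engine for dosage predictors: single-predictor tests,
# multi-df omnibus tests per position or gene, non-multiplicative genetic
# models, pairwise interaction scans and principal-component covariates.
#
# Conventions (held throughout the package): the Wald p is the headline;
# the likelihood-ratio p is always computed alongside and substituted,
# flagged, when the fit does not converge or shows separation (|beta| > 15),
# which extreme odds ratios in imputed HLA data do produce. AIC = residual
# deviance + 2 * number of fitted parameters, exactly.

MAX_ABS_BETA <- 15

# Maximum-likelihood logistic fit via base R's IRLS. X must include the
# intercept column. Returns enough to build Wald and LRT statistics.
glm_dev <- function(X, y) {
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = stats::glm.control(epsilon = 1e-8, maxit = 50L))
  )
  p <- fit$rank
  se <- rep(NA_real_, ncol(X))
  names(se) <- colnames(X)
  if (p > 0L) {
    Rm <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    Rm[lower.tri(Rm)] <- 0
    covm <- chol2inv(Rm)
    piv <- fit$qr$pivot[seq_len(p)]
    se[piv] <- sqrt(diag(covm))
  }
  list(
    coef = fit$coefficients,
    se = se,
    deviance = fit$deviance,
    rank = p,
    aic = fit$deviance + 2 * p,
    converged = fit$converged
  )
}

freq_by_status <- function(x, y) {
  c(cases = mean(x[y == 1]) / 2, controls = mean(x[y == 0]) / 2)
}

# Single-predictor fit against the covariates-only reduced model.
fit_one <- function(x, y, Z, predictor) {
  ok <- !is.na(x)
  x <- x[ok]; y1 <- y[ok]
  Z1 <- if (is.null(Z)) NULL else Z[ok, , drop = FALSE]
  if (length(unique(y1)) < 2L) abort("phenotype single-class after dropping missing dosages")
  X0 <- intercept_design(length(y1), Z1)
  X1 <- cbind(X0, x)
  colnames(X1)[ncol(X1)] <- predictor
  f1 <- glm_dev(X1, y1)
  f0 <- glm_dev(X0, y1)
  beta <- unname(f1$coef[predictor])
  se <- unname(f1$se[predictor])
  p_wald <- if (is.na(beta) || is.na(se)) NA_real_ else
    2 * stats::pnorm(-abs(beta / se))
  p_lrt <- pchisq(max(f0$deviance - f1$deviance, 0), df = 1L,
                  lower.tail = FALSE)
  separated <- !f1$converged || (!is.na(beta) && abs(beta) > MAX_ABS_BETA)
  fr <- freq_by_status(x, y1)
  tibble(
    predictor = predictor,
    n = length(y1),
    freq_cases = fr[["cases"]],
    freq_controls = fr[["controls"]],
    beta = beta,
    or = exp(beta),
    se = se,
    p_wald = p_wald,
    p_lrt = p_lrt,
    p = if (separated || is.na(p_wald)) p_lrt else p_wald,
    df = 1L,
    deviance = f1$deviance,
    null_deviance = f0$deviance,
    aic = f1$aic,
    converged = f1$converged && !separated
  )
}

#' Marginal dosage logistic regression
#'
#' Fits each dosage predictor, one at a time, in a maximum-likelihood
#' logistic regression of case/control status with optional fixed
#' covariates, the per-residue (or per-allele, per-SNP) marginal association
#' test. Individuals with a missing dosage are dropped predictor-wise.
#'
#' @param dosages Dosage tibble (`individual_id` + predictor columns), rows
#'   aligned with `phenotype`.
#' @param phenotype Binary 0/1 vector (1 = case), one entry per row of
#'   `dosages`.
#' @param covariates Optional data frame of covariates (e.g. principal
#'   component scores, gender), same row order.
#' @return A tibble of class `hla_assoc`, one row per predictor: `beta` (log
#'   odds per dosage unit), `or`, `se`, `p_wald`, `p_lrt`, headline `p`
#'   (Wald, or LRT when flagged non-converged/separated), imputed
#'   case/control frequencies, deviances and AIC.
#' @export
#' @examples
#' fx <- default_fixture(seed = 2, n_genes = 2, n_positions = 6)
#' mod <- disease_model(-1, NULL)
#' coh <- simulate_cohort(fx$pool, fx$haplotype_model, fx$alignment, mod,
#'                        n_cases = 60, n_controls = 60, seed = 2)
#' dos <- polymorphic_pool(residue_dosage(allele_dosage(coh$posteriors),
#'                                        fx$alignment))
#' fit_logistic(dos, coh$phenotypes$status)
fit_logistic <- function(dosages, phenotype, covariates = NULL) {
  y <- check_phenotype(phenotype, nrow(dosages))
  Z <- covariate_matrix(covariates, nrow(dosages))
  cols <- dosage_cols(dosages)
  const <- cols[vapply(dosages[cols],
                       function(x) var(x, na.rm = TRUE) == 0, TRUE)]
  if (length(const) == length(cols)) {
    abort(paste0("degenerate (constant) predictor(s): ",
                 paste(const, collapse = ", ")))
  }
  if (length(const) > 0L) {
    warn(paste0("skipping constant predictor(s): ",
                paste(const, collapse = ", ")))
    cols <- setdiff(cols, const)
  }
  out <- map_dfr(cols, function(nm) fit_one(dosages[[nm]], y, Z, nm))
  class(out) <- c("hla_assoc", class(out))
  out
}

# Joint model of a predictor block against the covariates-only reduced
# model: the multi-df likelihood-ratio machinery shared by omnibus tests.
fit_block <- function(M, y, Z) {
  ok <- stats::complete.cases(M)
  M <- M[ok, , drop = FALSE]; y1 <- y[ok]
  Z1 <- if (is.null(Z)) NULL else Z[ok, , drop = FALSE]
  X0 <- intercept_design(length(y1), Z1)
  f1 <- glm_dev(cbind(X0, M), y1)
  f0 <- glm_dev(X0, y1)
  df <- f1$rank - f0$rank
  tibble(
    n = length(y1),
    df = df,
    deviance = f1$deviance,
    null_deviance = f0$deviance,
    aic = f1$aic,
    p = if (df < 1L) NA_real_ else
      pchisq(max(f0$deviance - f1$deviance, 0), df = df, lower.tail = FALSE),
    converged = f1$converged
  )
}

# Non-rare columns of a block, reference (most frequent) dropped. Returns
# NULL when fewer than 2 columns survive the frequency filter.
ref_dropped_block <- function(M, min_freq) {
  fr <- colMeans(M, na.rm = TRUE) / 2
  M <- M[, fr > min_freq, drop = FALSE]
  if (ncol(M) < 2L) return(NULL)
  fr <- fr[fr > min_freq]
  M[, -which.max(fr), drop = FALSE]
}

#' Omnibus multi-df test per amino-acid position
#'
#' Tests all non-rare residues at a position simultaneously: a
#' likelihood-ratio test of the model holding every retained residue dosage
#' (the most frequent residue dropped as reference, since per-position
#' dosages sum to 2) against the covariates-only model, with df = retained
#' residues - 1. Positions with fewer than 2 retained residues are returned
#' flagged not-testable.
#'
#' @param residue_dosages Output of [residue_dosage()].
#' @param phenotype Binary 0/1 vector.
#' @param covariates Optional covariate data frame.
#' @param min_freq Residues at imputed frequency <= `min_freq` (default
#'   0.5%) are excluded before testing.
#' @return A tibble of class `hla_omnibus`: one row per position with `df`,
#'   LRT `p`, deviances, `aic` and a `testable` flag.
#' @export
omnibus_position_test <- function(residue_dosages, phenotype,
                                  covariates = NULL, min_freq = 0.005) {
  y <- check_phenotype(phenotype, nrow(residue_dosages))
  Z <- covariate_matrix(covariates, nrow(residue_dosages))
  info <- parse_residue_key(dosage_cols(residue_dosages))
  M <- dosage_matrix(residue_dosages)
  groups <- split(info$key, paste(info$gene, info$position, sep = "@"))
  out <- map_dfr(names(groups), function(gp) {
    keys <- groups[[gp]]
    block <- ref_dropped_block(M[, keys, drop = FALSE], min_freq)
    meta <- tibble(gene = sub("@.*$", "", gp),
                   position = as.integer(sub("^.*@", "", gp)))
    if (is.null(block)) {
      return(dplyr::bind_cols(meta, tibble(
        n = NA_integer_, df = NA_integer_, deviance = NA_real_,
        null_deviance = NA_real_, aic = NA_real_, p = NA_real_,
        converged = NA, testable = FALSE)))
    }
    dplyr::bind_cols(meta, fit_block(block, y, Z), tibble(testable = TRUE))
  })
  out <- arrange(out, .data$p)
  class(out) <- c("hla_omnibus", class(out))
  out
}

#' Omnibus multi-df test per gene
#'
#' As [omnibus_position_test()], over a gene's classical-allele dosages (all
#' non-rare alleles simultaneously, one dropped as reference). With
#' `conditional = TRUE` each gene is additionally adjusted for all non-rare
#' alleles at every other gene, the conditional variant that separates a
#' gene's own signal from cross-gene LD.
#'
#' @param allele_dosages Output of [allele_dosage()].
#' @param phenotype Binary 0/1 vector.
#' @param covariates Optional covariate data frame.
#' @param min_freq Frequency cutoff, default 0.5%.
#' @param conditional Adjust each gene for all other genes' non-rare alleles.
#' @return A tibble of class `hla_omnibus`, one row per gene.
#' @export
omnibus_gene_test <- function(allele_dosages, phenotype, covariates = NULL,
                              min_freq = 0.005, conditional = FALSE) {
  y <- check_phenotype(phenotype, nrow(allele_dosages))
  Z <- covariate_matrix(covariates, nrow(allele_dosages))
  info <- parse_allele_key(dosage_cols(allele_dosages))
  M <- dosage_matrix(allele_dosages)
  genes <- unique(info$gene)
  blocks <- lapply(genes, function(g) {
    ref_dropped_block(M[, info$key[info$gene == g], drop = FALSE], min_freq)
  })
  names(blocks) <- genes
  out <- map_dfr(genes, function(g) {
    block <- blocks[[g]]
    meta <- tibble(gene = g)
    if (is.null(block)) {
      return(dplyr::bind_cols(meta, tibble(
        n = NA_integer_, df = NA_integer_, deviance = NA_real_,
        null_deviance = NA_real_, aic = NA_real_, p = NA_real_,
        converged = NA, testable = FALSE)))
    }
    Zg <- Z
    if (conditional) {
      others <- do.call(cbind, blocks[setdiff(genes, g)])
      if (!is.null(others)) Zg <- cbind(Z, others)
    }
    dplyr::bind_cols(meta, fit_block(block, y, Zg), tibble(testable = TRUE))
  })
  out <- arrange(out, .data$p)
  class(out) <- c("hla_omnibus", class(out))
  out
}

#' Genotype copy-count probabilities for one predictor
#'
#' From the genotype posterior table, the per-individual probabilities of
#' carrying 0, 1 or 2 copies of a classical allele (key `gene*allele`) or of
#' a residue (key `gene@position:residue`, resolved through the alignment) —
#' the expectations non-multiplicative genetic codings are built from.
#'
#' @param posteriors Genotype posterior table.
#' @param key Predictor key.
#' @param alignment Peptide alignment (required for residue keys).
#' @return A tibble `individual_id`, `p0`, `p1`, `p2`.
#' @export
genotype_prob <- function(posteriors, key, alignment = NULL) {
  if (grepl("@", key, fixed = TRUE)) {
    k <- parse_residue_key(key)
    if (is.null(alignment)) abort("residue keys require `alignment`")
    carrier_set <- carriers(alignment, k$gene, k$position, k$residue)
    g <- k$gene
  } else {
    k <- parse_allele_key(key)
    carrier_set <- k$allele
    g <- k$gene
  }
  pg <- posteriors[posteriors$gene == g, ]
  if (nrow(pg) == 0L) abort(paste0("gene not in posterior table: ", g))
  copies <- (pg$allele1 %in% carrier_set) + (pg$allele2 %in% carrier_set)
  pg |>
    mutate(copies = copies) |>
    group_by(.data$individual_id) |>
    summarise(p0 = sum(.data$posterior[.data$copies == 0L]),
              p1 = sum(.data$posterior[.data$copies == 1L]),
              p2 = sum(.data$posterior[.data$copies == 2L]),
              .groups = "drop")
}

#' Compare allelic, dominant, recessive and genotypic models
#'
#' Fits the four genetic codings of one predictor on the genotype-posterior
#' expectations — allelic (multiplicative, per-copy) = P(1 copy) + 2 P(2
#' copies); dominant = P(>= 1 copy); recessive = P(2 copies); genotypic = the
#' two indicator expectations (2 df) — and ranks them by AIC. The preferred
#' model is the one with the lowest AIC.
#'
#' @param posteriors Genotype posterior table.
#' @param phenotype Binary 0/1 vector aligned with the sorted unique
#'   individuals of the posterior table.
#' @param key Predictor key (`gene*allele` or `gene@position:residue`).
#' @param alignment Peptide alignment (for residue keys).
#' @param covariates Optional covariate data frame.
#' @return A tibble of class `hla_models`, one row per coding, ranked by
#'   AIC, with a `preferred` flag.
#' @export
genetic_model_compare <- function(posteriors, phenotype, key,
                                  alignment = NULL, covariates = NULL) {
  gp <- genotype_prob(posteriors, key, alignment) |>
    arrange(.data$individual_id)
  y <- check_phenotype(phenotype, nrow(gp))
  Z <- covariate_matrix(covariates, nrow(gp))
  codings <- list(
    allelic = cbind(dose = gp$p1 + 2 * gp$p2),
    dominant = cbind(dom = gp$p1 + gp$p2),
    recessive = cbind(rec = gp$p2),
    genotypic = cbind(het = gp$p1, hom = gp$p2)
  )
  out <- map_dfr(names(codings), function(m) {
    res <- fit_block(codings[[m]], y, Z)
    dplyr::bind_cols(tibble(predictor = key, model = m), res)
  })
  out <- arrange(out, .data$aic) |>
    mutate(preferred = .data$aic == min(.data$aic))
  class(out) <- c("hla_models", class(out))
  out
}

#' Pairwise interaction scan
#'
#' For every pair of dosage predictors, adds the dosage product term to the
#' two-main-effects logistic model and tests it with a 1-df likelihood-ratio
#' test (departure from joint multiplicativity). Collinear pairs
#' (r-squared > 0.99) are skipped and flagged. The Bonferroni threshold
#' 0.05 / (number of pairs tested) is attached as the `bonferroni`
#' attribute and as a per-row significance flag.
#'
#' @param dosages Dosage tibble with at least 2 predictors.
#' @param phenotype Binary 0/1 vector.
#' @param covariates Optional covariate data frame.
#' @return A tibble of class `hla_interactions`: `predictor1`, `predictor2`,
#'   interaction `beta`, `p` (LRT), `skipped`, `significant`.
#' @export
interaction_scan <- function(dosages, phenotype, covariates = NULL) {
  y <- check_phenotype(phenotype, nrow(dosages))
  Z <- covariate_matrix(covariates, nrow(dosages))
  cols <- dosage_cols(dosages)
  if (length(cols) < 2L) abort("at least 2 predictors required")
  M <- dosage_matrix(dosages)
  pairs <- combn(cols, 2L)
  n_pairs <- ncol(pairs)
  out <- map_dfr(seq_len(n_pairs), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    r2 <- suppressWarnings(cor(M[, a], M[, b], use = "complete.obs")^2)
    base <- tibble(predictor1 = a, predictor2 = b)
    if (!is.na(r2) && r2 > 0.99) {
      return(dplyr::bind_cols(base, tibble(beta = NA_real_, p = NA_real_,
                                           df = NA_integer_, skipped = TRUE)))
    }
    main <- cbind(M[, a], M[, b])
    colnames(main) <- c(a, b)
    prod_col <- cbind(interaction = M[, a] * M[, b])
    res <- fit_block(prod_col, y, cbind(Z, main))
    ok <- stats::complete.cases(main)
    Zok <- if (is.null(Z)) NULL else Z[ok, , drop = FALSE]
    Xfull <- cbind(intercept_design(sum(ok), Zok),
                   main[ok, , drop = FALSE], prod_col[ok, , drop = FALSE])
    beta <- unname(glm_dev(Xfull, y[ok])$coef["interaction"])
    dplyr::bind_cols(base, tibble(beta = beta, p = res$p, df = res$df,
                                  skipped = FALSE))
  })
  bonf <- 0.05 / sum(!out$skipped)
  out$significant <- !out$skipped & out$p < bonf
  attr(out, "bonferroni") <- bonf
  class(out) <- c("hla_interactions", class(out))
  out
}

#' Principal-component covariates from SNP dosages
#'
#' Standard stratification covariates: SNPs inside the exclusion region (by
#' default the extended MHC, chr6:25,650,000-33,426,000) and constant SNPs
#' are removed, a greedy r-squared pruning pass thins LD, columns are
#' standardized and the top `n_pcs` principal-component score vectors are
#' returned with a deterministic sign convention (the largest-magnitude
#' loading of each component is positive).
#'
#' @param snp_dosages SNP dosage tibble (`individual_id` + SNP columns).
#' @param snp_info Tibble `snp`, `chrom`, `pos` giving SNP coordinates.
#' @param exclude_region List or vector `(chrom, start, end)`.
#' @param n_pcs Number of score vectors.
#' @param prune_r2 Greedy pruning threshold on pairwise r-squared.
#' @return A covariate tibble: `individual_id`, `PC1` ... `PCn`.
#' @export
compute_pcs <- function(snp_dosages, snp_info,
                        exclude_region = list("6", 25650000, 33426000),
                        n_pcs = 10L, prune_r2 = 0.2) {
  n_pcs <- check_count(n_pcs, "n_pcs")
  M <- dosage_matrix(snp_dosages)
  inside <- snp_info$snp[snp_info$chrom == exclude_region[[1]] &
                           snp_info$pos >= exclude_region[[2]] &
                           snp_info$pos <= exclude_region[[3]]]
  keep <- setdiff(colnames(M), inside)
  keep <- keep[apply(M[, keep, drop = FALSE], 2L, var) > 0]
  if (length(keep) == 0L) abort("no SNPs left after region/constant filtering")
  M <- M[, keep, drop = FALSE]
  r2 <- suppressWarnings(cor(M)^2)
  kept <- prune_index_set(structure(r2, constant = character(0),
                                    class = c("hla_r2", "matrix")),
                          r2_max = prune_r2)
  if (length(kept) < n_pcs) {
    abort(paste0("fewer SNPs (", length(kept), ") than requested PCs (",
                 n_pcs, ") after filtering"))
  }
  S <- scale(M[, kept, drop = FALSE])
  pc <- prcomp(S, center = FALSE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(tibble(individual_id = snp_dosages$individual_id),
                   as_tibble(scores))
}
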