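# Synthetic case/control cohorts with the statistical structure the
# fine-mapping analysis assumes: per-gene classical-allele pools, cross-gene
# haplotype LD, allele->peptide maps, planted causal residues under a
# multiplicative (per-copy) logistic disease model, and imputation-style
# posterior uncertainty.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a classical-allele pool for one gene
#'
#' Draws a population frequency spectrum for `n_alleles` named alleles from a
#' symmetric Dirichlet distribution and returns them sorted by decreasing
#' frequency. `concentration = Inf` gives the symmetric (equal-frequency)
#' limit.
#'
#' @param gene Gene identifier, e.g. `"HLA-DPB1"`.
#' @param n_alleles Number of alleles (at least 2).
#' @param concentration Positive Dirichlet concentration; small values give
#'   skewed, realistic spectra (one or two common alleles, many rare ones).
#' @param seed Integer seed; the draw is deterministic in (`gene`, `seed`).
#' @return A tibble with columns `gene`, `allele` (two-field names such as
#'   `"03:01"`) and `frequency` (sums to 1).
#' @export
#' @examples
#' build_allele_pool("HLA-DPB1", n_alleles = 5, concentration = 1, seed = 7)
build_allele_pool <- function(gene, n_alleles, concentration = 1, seed = 1L) {
  n_alleles <- check_count(n_alleles, "n_alleles", min = 2L)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration <= 0) {
    abort("`concentration` must be a positive number (Inf allowed)")
  }
  set.seed(derive_seed(seed, paste0("pool:", gene)))
  if (is.infinite(concentration)) {
    freq <- rep(1 / n_alleles, n_alleles)
  } else {
    w <- rgamma(n_alleles, shape = concentration)
    if (sum(w) == 0) w <- rep(1, n_alleles)
    freq <- w / sum(w)
  }
  tibble(
    gene = gene,
    allele = sprintf("%02d:01", seq_len(n_alleles)),
    frequency = sort(freq, decreasing = TRUE)
  )
}

#' Build a cross-gene haplotype LD model
#'
#' Founder haplotypes spanning every gene in the pool are drawn allele-wise
#' from the pool frequencies and given Dirichlet frequencies. At simulation
#' time each gamete is, with probability `lambda`, drawn independently per
#' gene (no LD) and otherwise copied from a founder haplotype, so `lambda = 1`
#' yields gene independence and `lambda = 0` pure haplotype LD.
#'
#' @param pool Allele pool tibble (`gene`, `allele`, `frequency`), one or
#'   more genes (rows of [build_allele_pool()] outputs).
#' @param n_haplotypes Number of founder haplotypes.
#' @param lambda Recombination mixing weight in \[0, 1\].
#' @param concentration Dirichlet concentration for haplotype frequencies.
#' @param seed Integer seed.
#' @return An object of class `haplotype_model`: a list with `genes`,
#'   `haplotypes` (tibble with one column per gene plus `frequency`) and
#'   `lambda`.
#' @export
build_haplotype_model <- function(pool, n_haplotypes = 30L, lambda = 0.5,
                                  concentration = 1, seed = 1L) {
  n_haplotypes <- check_count(n_haplotypes, "n_haplotypes")
  lambda <- check_prob(lambda, "lambda")
  genes <- unique(pool$gene)
  set.seed(derive_seed(seed, "haplotype_model"))
  haps <- lapply(genes, function(g) {
    pg <- pool[pool$gene == g, ]
    sample(pg$allele, n_haplotypes, replace = TRUE, prob = pg$frequency)
  })
  names(haps) <- genes
  w <- rgamma(n_haplotypes, shape = concentration)
  haps <- as_tibble(haps)
  haps$frequency <- w / sum(w)
  structure(list(genes = genes, haplotypes = haps, lambda = lambda),
            class = "haplotype_model")
}

#' Simulate an allele-to-peptide alignment
#'
#' Generates a peptide alignment for every gene in the pool: a shared set of
#' aligned positions per gene (integers, never 0; a fraction negative,
#' denoting leader-peptide numbering) and, for each allele, one residue per
#' position. Positions carry between 1 and `max_residues` distinct residues;
#' the gap symbol `"_"` (absent residue) may appear as a residue level.
#'
#' @param pool Allele pool tibble.
#' @param n_positions Aligned positions per gene.
#' @param max_residues Maximum distinct residues at a position.
#' @param neg_frac Fraction of positions given negative (leader) numbering.
#' @param gap_prob Probability that a position's alphabet includes the gap.
#' @param seed Integer seed.
#' @return A tibble with columns `gene`, `allele`, `position`, `residue`.
#' @export
simulate_alignment <- function(pool, n_positions = 15L, max_residues = 4L,
                               neg_frac = 0.15, gap_prob = 0.05, seed = 1L) {
  n_positions <- check_count(n_positions, "n_positions")
  set.seed(derive_seed(seed, "alignment"))
  out <- lapply(unique(pool$gene), function(g) {
    alleles <- pool$allele[pool$gene == g]
    n_neg <- round(neg_frac * n_positions)
    positions <- c(
      if (n_neg > 0) sort(-sample(1:25, n_neg)),
      sort(sample(1:230, n_positions - n_neg))
    )
    per_pos <- lapply(positions, function(p) {
      k <- sample(seq_len(max_residues), 1L,
                  prob = c(2, 5, 2, 1)[seq_len(max_residues)])
      alphabet <- sample(AA_LETTERS, k)
      if (k > 1L && runif(1) < gap_prob) alphabet[k] <- "_"
      w <- rgamma(k, shape = 1.5)
      res <- sample(alphabet, length(alleles), replace = TRUE, prob = w / sum(w))
      tibble(gene = g, allele = alleles, position = p, residue = res)
    })
    bind_rows(per_pos)
  })
  bind_rows(out)
}

#' Specify a logistic disease model with planted causal residues
#'
#' @param intercept Baseline log-odds of disease.
#' @param effects Tibble with columns `gene`, `position`, `residue`, `beta`
#'   (per-copy log odds ratio), or `NULL` for a null model.
#' @param covariate_effects Optional named numeric vector of log-odds effects
#'   for standard-normal covariates generated alongside the cohort.
#' @return An object of class `disease_model`.
#' @export
#' @examples
#' disease_model(-1.5, tibble::tibble(
#'   gene = "HLA-DPB1", position = 11L, residue = "L", beta = log(3)
#' ))
disease_model <- function(intercept = -1, effects = NULL,
                          covariate_effects = NULL) {
  if (is.null(effects)) {
    effects <- tibble(gene = character(), position = integer(),
                      residue = character(), beta = numeric())
  }
  effects <- as_tibble(effects)
  stopifnot(all(c("gene", "position", "residue", "beta") %in% names(effects)))
  if (!all(is.finite(intercept)) || !all(is.finite(effects$beta))) {
    abort("disease-model coefficients must be finite")
  }
  if (!is.null(covariate_effects) &&
      (is.null(names(covariate_effects)) || anyNA(covariate_effects))) {
    abort("`covariate_effects` must be a named finite numeric vector")
  }
  structure(list(intercept = intercept, effects = effects,
                 covariate_effects = covariate_effects),
            class = "disease_model")
}

# Alleles of `gene` carrying `residue` at `position` in the alignment.
carriers <- function(alignment, gene, position, residue) {
  alignment$allele[alignment$gene == gene &
                     alignment$position == position &
                     alignment$residue == residue]
}

# One gamete per row: matrix of allele names, one column per gene.
draw_gametes <- function(n, pool, model) {
  genes <- model$genes
  G <- matrix("", n, length(genes), dimnames = list(NULL, genes))
  indep <- runif(n) < model$lambda
  n_hap <- sum(!indep)
  if (n_hap > 0L) {
    idx <- sample.int(nrow(model$haplotypes), n_hap, replace = TRUE,
                      prob = model$haplotypes$frequency)
    for (g in genes) G[!indep, g] <- model$haplotypes[[g]][idx]
  }
  if (any(indep)) {
    for (g in genes) {
      pg <- pool[pool$gene == g, ]
      G[indep, g] <- sample(pg$allele, sum(indep), replace = TRUE,
                            prob = pg$frequency)
    }
  }
  G
}

#' Simulate a case/control cohort
#'
#' Draws diplotypes as two independent gametes from the haplotype model,
#' assigns disease status by the logistic model on true causal-residue copy
#' counts, and oversamples until the exact case and control quotas are filled
#' (the retrospective sampling a case/control logistic analysis assumes).
#' Genotype posteriors are point masses on the true genotype; apply
#' [blur_posteriors()] to emulate imputation uncertainty.
#'
#' @param pool Allele pool tibble covering every gene of the model.
#' @param haplotype_model A [build_haplotype_model()] object.
#' @param alignment Peptide alignment tibble; every causal residue of
#'   `model` must be resolvable in it.
#' @param model A [disease_model()].
#' @param n_cases,n_controls Exact cohort composition.
#' @param seed Integer seed.
#' @param max_batches Bound on quota-filling attempts (each batch draws
#'   `2 * (n_cases + n_controls)` individuals) before a simulation-failure
#'   error.
#' @return An object of class `hla_cohort`: list with `phenotypes`
#'   (`individual_id`, `status`), `diplotypes` (`individual_id`, `gene`,
#'   `allele1`, `allele2`), `posteriors` (point-mass genotype posterior
#'   table), optional `covariates`, and a `config` echo.
#' @export
simulate_cohort <- function(pool, haplotype_model, alignment, model,
                            n_cases, n_controls, seed = 1L,
                            max_batches = 200L) {
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  eff <- model$effects
  if (nrow(eff) > 0L) {
    carrier_sets <- lapply(seq_len(nrow(eff)), function(i) {
      cs <- carriers(alignment, eff$gene[i], eff$position[i], eff$residue[i])
      if (length(cs) == 0L) {
        abort(paste0("causal residue not in alignment: ",
                     residue_key(eff$gene[i], eff$position[i], eff$residue[i])))
      }
      cs
    })
  } else {
    carrier_sets <- list()
  }
  n_cov <- length(model$covariate_effects)

  set.seed(derive_seed(seed, "cohort"))
  genes <- haplotype_model$genes
  batch <- 2L * (n_cases + n_controls)
  acc_g1 <- acc_g2 <- NULL
  acc_y <- numeric(0)
  acc_z <- NULL
  need_cases <- n_cases
  need_controls <- n_controls
  for (b in seq_len(max_batches)) {
    G1 <- draw_gametes(batch, pool, haplotype_model)
    G2 <- draw_gametes(batch, pool, haplotype_model)
    eta <- rep(model$intercept, batch)
    for (i in seq_along(carrier_sets)) {
      cnt <- (G1[, eff$gene[i]] %in% carrier_sets[[i]]) +
        (G2[, eff$gene[i]] %in% carrier_sets[[i]])
      eta <- eta + eff$beta[i] * cnt
    }
    Z <- NULL
    if (n_cov > 0L) {
      Z <- matrix(rnorm(batch * n_cov), batch, n_cov,
                  dimnames = list(NULL, names(model$covariate_effects)))
      eta <- eta + drop(Z %*% model$covariate_effects)
    }
    y <- rbinom(batch, 1L, plogis(eta))
    take <- c(head(which(y == 1L), need_cases),
              head(which(y == 0L), need_controls))
    if (length(take) > 0L) {
      acc_g1 <- rbind(acc_g1, G1[take, , drop = FALSE])
      acc_g2 <- rbind(acc_g2, G2[take, , drop = FALSE])
      acc_y <- c(acc_y, y[take])
      if (n_cov > 0L) acc_z <- rbind(acc_z, Z[take, , drop = FALSE])
      need_cases <- n_cases - sum(acc_y == 1L)
      need_controls <- n_controls - sum(acc_y == 0L)
    }
    if (need_cases == 0L && need_controls == 0L) break
  }
  if (need_cases > 0L || need_controls > 0L) {
    abort(paste0("simulation failure: case/control quotas unreachable after ",
                 max_batches, " batches (check the disease model's intercept)"))
  }

  n <- length(acc_y)
  ids <- sprintf("ind%05d", seq_len(n))
  diplotypes <- bind_rows(lapply(genes, function(g) {
    tibble(individual_id = ids, gene = g,
           allele1 = pmin(acc_g1[, g], acc_g2[, g]),
           allele2 = pmax(acc_g1[, g], acc_g2[, g]))
  })) |> arrange(.data$individual_id, .data$gene)
  posteriors <- diplotypes
  posteriors$posterior <- 1
  covariates <- if (n_cov > 0L) {
    dplyr::bind_cols(tibble(individual_id = ids), as_tibble(acc_z))
  } else {
    NULL
  }
  structure(
    list(
      phenotypes = tibble(individual_id = ids, status = as.integer(acc_y)),
      diplotypes = diplotypes,
      posteriors = posteriors,
      covariates = covariates,
      config = list(seed = seed, n_cases = n_cases, n_controls = n_controls,
                    lambda = haplotype_model$lambda,
                    intercept = model$intercept, effects = eff)
    ),
    class = "hla_cohort"
  )
}

#' @export
print.hla_cohort <- function(x, ...) {
  cat("<hla_cohort> ", sum(x$phenotypes$status == 1L), " cases / ",
      sum(x$phenotypes$status == 0L), " controls; ",
      length(unique(x$diplotypes$gene)), " genes; seed ", x$config$seed,
      "\n", sep = "")
  invisible(x)
}

#' Add imputation-uncertainty noise to genotype posteriors
#'
#' Redistributes each individual-gene's posterior mass from the true genotype
#' over a sparse candidate set (the true genotype plus genotypes sharing at
#' least one allele with it, as real imputer output looks) via a Dirichlet
#' perturbation centred on the truth. `temperature = 0` returns the cohort
#' unchanged; larger temperatures spread more mass away from the truth.
#'
#' @param cohort An `hla_cohort`.
#' @param temperature Non-negative noise level; the true genotype's Dirichlet
#'   concentration is `1 + 1/temperature` against 1 for each alternative.
#' @param pool Allele pool tibble (source of alternative alleles).
#' @param n_alternatives Alternative genotypes per individual-gene.
#' @param seed Integer seed.
#' @return The cohort with a blurred `posteriors` table (per individual-gene
#'   posteriors still sum to 1).
#' @export
blur_posteriors <- function(cohort, temperature, pool, n_alternatives = 3L,
                            seed = 1L) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature < 0) {
    abort("`temperature` must be a single non-negative number")
  }
  if (temperature == 0) return(cohort)
  n_alternatives <- check_count(n_alternatives, "n_alternatives")
  set.seed(derive_seed(seed, "blur"))
  dip <- cohort$diplotypes
  out <- vector("list", nrow(dip))
  allele_by_gene <- split(pool$allele, pool$gene)
  alpha_true <- 1 + 1 / temperature
  for (i in seq_len(nrow(dip))) {
    g <- dip$gene[i]
    a1 <- dip$allele1[i]
    a2 <- dip$allele2[i]
    others <- setdiff(allele_by_gene[[g]], c(a1, a2))
    k <- min(n_alternatives, length(others))
    if (k == 0L) {
      out[[i]] <- tibble(individual_id = dip$individual_id[i], gene = g,
                         allele1 = a1, allele2 = a2, posterior = 1)
      next
    }
    partner <- sample(c(a1, a2), k, replace = TRUE)
    alt <- sample(others, k)
    w <- rgamma(k + 1L, shape = c(alpha_true, rep(1, k)))
    w <- w / sum(w)
    out[[i]] <- tibble(
      individual_id = dip$individual_id[i], gene = g,
      allele1 = c(a1, pmin(partner, alt)),
      allele2 = c(a2, pmax(partner, alt)),
      posterior = w
    )
  }
  cohort$posteriors <- bind_rows(out)
  cohort
}

#' Simulate a SNP dosage matrix
#'
#' Light-weight SNP dosages (copies of the alternate allele, 0/1/2) for
#' covariate construction and mixed-pool selection: binomial draws at random
#' allele frequencies, with optional population substructure (allele-frequency
#' divergence between two subpopulations) and optional tagging of a given
#' numeric column (a residue dosage) to emulate LD between a SNP and a causal
#' residue.
#'
#' @param n Individuals.
#' @param n_snps SNPs.
#' @param seed Integer seed.
#' @param maf_range Minor-allele-frequency range for the base frequencies.
#' @param subpop Optional 0/1 vector of subpopulation labels (length `n`).
#' @param fst Allele-frequency divergence scale used when `subpop` is given.
#' @param tag Optional numeric vector (length `n`, values in \[0, 2\]) that the
#'   first `n_tag` SNPs copy with noise (`tag_noise` flip probability).
#' @param n_tag,tag_noise Tagging controls.
#' @return A list with `dosages` (tibble, `individual_id` + one column per
#'   SNP) and `info` (tibble `snp`, `chrom`, `pos`).
#' @export
simulate_snp_dosages <- function(n, n_snps, seed = 1L, maf_range = c(0.05, 0.5),
                                 subpop = NULL, fst = 0.05,
                                 tag = NULL, n_tag = 1L, tag_noise = 0.05) {
  n <- check_count(n, "n")
  n_snps <- check_count(n_snps, "n_snps")
  set.seed(derive_seed(seed, "snps"))
  p <- runif(n_snps, maf_range[1], maf_range[2])
  D <- matrix(0, n, n_snps)
  for (j in seq_len(n_snps)) {
    pj <- rep(p[j], n)
    if (!is.null(subpop)) {
      shift <- rnorm(1, 0, sqrt(fst * p[j] * (1 - p[j])))
      pj <- pmin(pmax(p[j] + shift * (2 * subpop - 1), 0.01), 0.99)
    }
    D[, j] <- rbinom(n, 2L, pj)
  }
  if (!is.null(tag)) {
    for (j in seq_len(min(n_tag, n_snps))) {
      flip <- runif(n) < tag_noise
      D[, j] <- ifelse(flip, rbinom(n, 2L, mean(tag) / 2), round(tag))
    }
  }
  snps <- sprintf("rs%06d", seq_len(n_snps))
  colnames(D) <- snps
  list(
    dosages = as_dosage_tibble(D, sprintf("ind%05d", seq_len(n))),
    info = tibble(snp = snps, chrom = "6",
                  pos = sort(sample.int(5e7, n_snps)))
  )
}

#' Default synthetic study fixture
#'
#' An eight-gene fixture mirroring the gene content of a UK-scale HLA
#' fine-mapping study: classical class I and class II loci with 10-25 alleles
#' each, skewed frequency spectra, cross-gene haplotype LD and a shared
#' peptide alignment — the dimensionality downstream residue pools need
#' (hundreds of residue predictors).
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (up to 8), smallest fixture first.
#' @param n_positions Aligned positions per gene.
#' @param lambda Haplotype-LD mixing weight.
#' @return A list with `pool`, `haplotype_model`, `alignment`.
#' @export
default_fixture <- function(seed = 1L, n_genes = 8L, n_positions = 15L,
                            lambda = 0.5) {
  genes <- c("HLA-DPB1", "HLA-DRB1", "HLA-DQB1", "HLA-C",
             "HLA-DQA1", "HLA-B", "HLA-A", "HLA-DPA1")[seq_len(n_genes)]
  set.seed(derive_seed(seed, "fixture_sizes"))
  sizes <- sample(10:25, length(genes), replace = TRUE)
  pool <- bind_rows(lapply(seq_along(genes), function(i) {
    build_allele_pool(genes[i], sizes[i], concentration = 0.5, seed = seed)
  }))
  list(
    pool = pool,
    haplotype_model = build_haplotype_model(pool, n_haplotypes = 30L,
                                            lambda = lambda, seed = seed),
    alignment = simulate_alignment(pool, n_positions = n_positions, seed = seed)
  )
}
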