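# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately avoid the package's fitting path (and glm.fit):
# plain Newton-Raphson on the logistic log-likelihood, and brute-force
# enumeration over posterior-weighted genotypes.

# Newton-Raphson logistic MLE. X includes the intercept column.
irls_oracle <- function(X, y, max_iter = 100L, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * W, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Brute-force residue dosages: enumerate every candidate genotype of every
# individual-gene and accumulate posterior-weighted residue copy counts.
brute_force_residue_dosage <- function(posteriors, alignment) {
  res_levels <- unique(alignment[c("gene", "position", "residue")])
  keys <- paste0(res_levels$gene, "@", res_levels$position, ":",
                 res_levels$residue)
  ids <- sort(unique(posteriors$individual_id))
  M <- matrix(0, length(ids), length(keys), dimnames = list(ids, keys))
  res_of <- function(g, a) {
    sub <- alignment[alignment$gene == g & alignment$allele == a, ]
    paste0(g, "@", sub$position, ":", sub$residue)
  }
  for (r in seq_len(nrow(posteriors))) {
    id <- posteriors$individual_id[r]
    g <- posteriors$gene[r]
    w <- posteriors$posterior[r]
    for (a in c(posteriors$allele1[r], posteriors$allele2[r])) {
      for (k in res_of(g, a)) M[id, k] <- M[id, k] + w
    }
  }
  M
}

# A small hand-buildable posterior table (2 genes, uncertain genotypes).
toy_posteriors <- function() {
  tibble::tribble(
    ~individual_id, ~gene, ~allele1, ~allele2, ~posterior,
    "i1", "G1", "01:01", "01:01", 1.0,
    "i2", "G1", "01:01", "02:01", 0.6,
    "i2", "G1", "01:01", "03:01", 0.4,
    "i3", "G1", "02:01", "03:01", 1.0,
    "i1", "G2", "01:01", "02:01", 1.0,
    "i2", "G2", "01:01", "01:01", 1.0,
    "i3", "G2", "02:01", "02:01", 1.0
  )
}

toy_alignment <- function() {
  tibble::tribble(
    ~gene, ~allele, ~position, ~residue,
    "G1", "01:01", 11L, "L",
    "G1", "02:01", 11L, "G",
    "G1", "03:01", 11L, "G",
    "G1", "01:01", 57L, "D",
    "G1", "02:01", 57L, "D",
    "G1", "03:01", 57L, "A",
    "G1", "01:01", -13L, "_",
    "G1", "02:01", -13L, "A",
    "G1", "03:01", -13L, "A",
    "G2", "01:01", 9L, "H",
    "G2", "02:01", 9L, "Y"
  )
}

# Residue keys with intermediate population frequency: usable plant targets.
candidate_residues <- function(fx, fmin = 0.2, fmax = 0.8) {
  frq <- dplyr::inner_join(fx$alignment, fx$pool, by = c("gene", "allele")) |>
    dplyr::group_by(gene, position, residue) |>
    dplyr::summarise(f = sum(frequency), .groups = "drop") |>
    dplyr::filter(f > fmin, f < fmax, residue != "_")
  frq
}

# One candidate per gene (the commonest intermediate-frequency residue).
# Widens the frequency window if the fixture offers too few candidates.
pick_causals <- function(fx, n, fmin = 0.2, fmax = 0.8) {
  repeat {
    frq <- candidate_residues(fx, fmin, fmax)
    frq <- frq[!duplicated(frq$gene), ]
    if (nrow(frq) >= n || (fmin < 0.02)) break
    fmin <- fmin / 2
    fmax <- 1 - (1 - fmax) / 2
  }
  head(frq, n)
}

# Random uncertain posterior table for oracle-equivalence fixtures.
random_posteriors <- function(n_ind, pool, seed) {
  set.seed(seed)
  rows <- list()
  for (g in unique(pool$gene)) {
    alleles <- pool$allele[pool$gene == g]
    for (i in seq_len(n_ind)) {
      k <- sample(1:3, 1)
      a1 <- sample(alleles, k, replace = TRUE)
      a2 <- sample(alleles, k, replace = TRUE)
      w <- rgamma(k, 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        individual_id = sprintf("i%03d", i), gene = g,
        allele1 = pmin(a1, a2), allele2 = pmax(a1, a2),
        posterior = w / sum(w))
    }
  }
  out <- dplyr::bind_rows(rows)
  # merge duplicate genotypes so pairs stay unordered-unique
  out |>
    dplyr::group_by(individual_id, gene, allele1, allele2) |>
    dplyr::summarise(posterior = sum(posterior), .groups = "drop")
}

# Cohort with planted per-copy effects at given residue rows (gene,
# position, residue, beta); returns cohort plus derived pools.
planted_cohort <- function(fx, effects, n_cases, n_controls, seed,
                           intercept = -1.5) {
  mod <- disease_model(intercept, effects)
  coh <- simulate_cohort(fx$pool, fx$haplotype_model, fx$alignment, mod,
                         n_cases, n_controls, seed = seed)
  ad <- allele_dosage(coh$posteriors)
  ad <- ad[match(coh$phenotypes$individual_id, ad$individual_id), ]
  rd <- residue_dosage(ad, fx$alignment)
  list(cohort = coh, allele_dosages = ad, residue_dosages = rd,
       pool = polymorphic_pool(rd), y = coh$phenotypes$status)
}
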