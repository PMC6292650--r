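# Study-condition experiments shared by the acceptance test suite and
# scripts/acceptance.R (which sources this file from the repository root).
# Each experiment recomputes its quantity from scratch by running the
# package; only the master seed varies.

# --- analytic / combinatorial constants ----------------------------------

exp_search_space <- function() {
  list(
    residue_pairs = count_combinations(1028, 2),
    residue_triples = count_combinations(1028, 3),
    position_pairs = count_combinations(368, 2)
  )
}

exp_thresholds <- function() {
  list(
    bonferroni_residues = signif(0.05 / 1028, 3),
    bonferroni_positions = signif(0.05 / 368, 3),
    tag_r2 = 0.98^2
  )
}

# --- oracle equivalence ---------------------------------------------------

# Max |beta difference| between fit_logistic and the Newton-Raphson oracle
# over 20 random small case/control fixtures.
exp_irls_agreement <- function(seed) {
  worst <- 0
  for (s in 1:20) {
    set.seed(derive_seed_local(seed, paste0("irls", s)))
    n <- 150 + 10 * s
    x <- rbinom(n, 2, runif(1, 0.2, 0.6)) + runif(n, 0, 0.1)
    z <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + 0.6 * x + 0.3 * z))
    if (length(unique(y)) < 2) next
    d <- tibble::tibble(individual_id = as.character(1:n), x = x)
    fit <- fit_logistic(d, y, covariates = data.frame(z = z))
    oracle <- irls_oracle(cbind(1, z, x), y)
    worst <- max(worst, abs(fit$beta - oracle[3]))
  }
  worst
}

# Max |dosage difference| between residue_dosage and brute-force genotype
# enumeration over random 50-individual posterior fixtures.
exp_dosage_agreement <- function(seed) {
  fx <- default_fixture(seed = derive_seed_local(seed, "dosfix"),
                        n_genes = 2, n_positions = 6)
  worst <- 0
  for (s in 1:3) {
    post <- random_posteriors(50, fx$pool,
                              seed = derive_seed_local(seed, paste0("dos", s)))
    rd <- residue_dosage(allele_dosage(post), fx$alignment)
    oracle <- brute_force_residue_dosage(post, fx$alignment)
    M <- as.matrix(rd[setdiff(names(rd), "individual_id")])
    rownames(M) <- rd$individual_id
    worst <- max(worst, max(abs(M[rownames(oracle), colnames(oracle)] -
                                  oracle)))
  }
  worst
}

# Max deviation of the conservation sums (gene allele dosages and
# per-position residue dosages, both = 2 per individual) on a full
# eight-gene fixture.
exp_conservation <- function(seed) {
  fx <- default_fixture(seed = derive_seed_local(seed, "consfix"),
                        n_genes = 8, n_positions = 10)
  coh <- simulate_cohort(fx$pool, fx$haplotype_model, fx$alignment,
                         disease_model(0), 200, 200,
                         seed = derive_seed_local(seed, "conscoh"))
  coh <- blur_posteriors(coh, 0.3, fx$pool,
                         seed = derive_seed_local(seed, "consblur"))
  ad <- allele_dosage(coh$posteriors)
  rd <- residue_dosage(ad, fx$alignment)
  worst <- 0
  a_info <- parse_allele_key(setdiff(names(ad), "individual_id"))
  for (g in unique(a_info$gene)) {
    s <- rowSums(ad[a_info$key[a_info$gene == g]])
    worst <- max(worst, max(abs(s - 2)))
  }
  r_info <- parse_residue_key(setdiff(names(rd), "individual_id"))
  for (gp in unique(paste(r_info$gene, r_info$position))) {
    s <- rowSums(rd[r_info$key[paste(r_info$gene, r_info$position) == gp]])
    worst <- max(worst, max(abs(s - 2)))
  }
  worst
}

# --- calibration ----------------------------------------------------------

# Type-I error of the 1-df dosage test at alpha = 0.05: 500 null
# simulations of n = 1000.
exp_type1_error <- function(seed, n_sims = 500L, n = 1000L) {
  set.seed(derive_seed_local(seed, "type1"))
  reject <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    x <- rbinom(n, 2, runif(1, 0.1, 0.5))
    y <- rbinom(n, 1, 0.5)
    d <- tibble::tibble(individual_id = as.character(1:n), x = x)
    reject[i] <- fit_logistic(d, y)$p_wald < 0.05
  }
  mean(reject)
}

# One allele-level-effect dataset: disease driven directly by a classical
# allele, so residue structure carries no information beyond alleles.
allele_effect_dataset <- function(seed, n_cases = 250L, n_controls = 250L,
                                  n_alleles = 12L, n_positions = 6L) {
  pool <- build_allele_pool("HLA-DRB1", n_alleles, concentration = 0.8,
                            seed = seed)
  aln <- simulate_alignment(pool, n_positions = n_positions, seed = seed)
  hm <- build_haplotype_model(pool, 20, lambda = 0.5, seed = seed)
  coh <- simulate_cohort(pool, hm, aln, disease_model(0),
                         n_cases, n_controls, seed = seed)
  target <- pool$allele[1]
  dip <- coh$diplotypes
  copies <- (dip$allele1 == target) + (dip$allele2 == target)
  copies <- copies[match(coh$phenotypes$individual_id, dip$individual_id)]
  set.seed(derive_seed_local(seed, "y"))
  y <- rbinom(length(copies), 1, plogis(-0.5 + log(2.5) * copies))
  ad <- allele_dosage(coh$posteriors)
  ad <- ad[match(coh$phenotypes$individual_id, ad$individual_id), ]
  list(allele_dosages = ad, alignment = aln, y = y)
}

# Empirical permutation p over independent allele-level-effect datasets
# (alignment re-drawn per dataset, so the observed assignment is one
# uniform draw from its orbit): approximately Uniform(0,1).
exp_perm_uniformity <- function(seed, n_datasets = 100L, B = 99L) {
  ps <- numeric(0)
  for (d in seq_len(n_datasets)) {
    ds <- allele_effect_dataset(derive_seed_local(seed, paste0("unif", d)))
    if (length(unique(ds$y)) < 2) next
    pn <- permutation_null(ds$allele_dosages, ds$alignment, ds$y, k = 1,
                           B = B,
                           seed = derive_seed_local(seed, paste0("upn", d)))
    ps <- c(ps, pn$p)
  }
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  list(p_values = ps, ks_p = unname(ks$p.value))
}

# --- parameter recovery ---------------------------------------------------

# Marginal recovery of a planted per-copy OR 3.0 residue at n = 5000+5000:
# mean OR estimate and 95% CI coverage over 50 replicates.
exp_or_recovery <- function(seed, reps = 50L) {
  fx <- default_fixture(seed = derive_seed_local(seed, "orfix"),
                        n_genes = 1, n_positions = 6)
  cz <- pick_causals(fx, 1, fmin = 0.25, fmax = 0.75)
  key <- paste0(cz$gene, "@", cz$position, ":", cz$residue)
  eff <- tibble::tibble(gene = cz$gene, position = cz$position,
                        residue = cz$residue, beta = log(3))
  ors <- covered <- numeric(reps)
  for (r in seq_len(reps)) {
    pc <- planted_cohort(fx, eff, 5000, 5000,
                         seed = derive_seed_local(seed, paste0("or", r)),
                         intercept = -2)
    fit <- fit_logistic(pc$pool[c("individual_id", key)], pc$y)
    ors[r] <- fit$or
    covered[r] <- abs(fit$beta - log(3)) < qnorm(0.975) * fit$se
  }
  list(mean_or = mean(ors), coverage = mean(covered))
}

# Forward stepwise recovery of 5 planted residues (per-copy ORs 3 .. 1.5,
# one per gene) from a five-gene pool at n = 5000+5000, threshold 4.87e-5.
# A planted residue counts as recovered when the selected set contains it
# or a near-perfect correlate (r^2 > 0.95, e.g. its mirror at a biallelic
# position); at most one unrelated extra is allowed.
exp_stepwise_recovery <- function(seed, reps = 25L) {
  fx <- default_fixture(seed = derive_seed_local(seed, "swfix"),
                        n_genes = 5, n_positions = 8)
  cz <- pick_causals(fx, 5)
  cz$beta <- log(c(3, 2.5, 2, 1.7, 1.5))[seq_len(nrow(cz))]
  keys <- paste0(cz$gene, "@", cz$position, ":", cz$residue)
  wins <- 0L
  for (r in seq_len(reps)) {
    pc <- planted_cohort(fx, cz[c("gene", "position", "residue", "beta")],
                         5000, 5000,
                         seed = derive_seed_local(seed, paste0("sw", r)),
                         intercept = -2)
    tr <- forward_stepwise(pc$pool, pc$y, p_enter = 4.87e-5)
    M <- as.matrix(pc$pool[setdiff(names(pc$pool), "individual_id")])
    alias <- lapply(keys, function(k) colnames(M)[cor(M[, k], M)^2 > 0.95])
    hit <- vapply(alias, function(s) any(tr$predictor %in% s), TRUE)
    extras <- sum(!tr$predictor %in% unlist(alias))
    if (all(hit) && extras <= 1L) wins <- wins + 1L
  }
  wins / reps
}

# Bootstrap stability under one overwhelming planted signal (per-copy OR 3,
# n = 5000+5000): combined rank-1 entry frequency of the causal residue and
# its perfect mirrors over B replicates of 2/3 subsampling.
exp_stability_rank1 <- function(seed, B = 100L) {
  fx <- default_fixture(seed = derive_seed_local(seed, "stfix"),
                        n_genes = 2, n_positions = 6)
  cz <- pick_causals(fx, 1, fmin = 0.25, fmax = 0.75)
  key <- paste0(cz$gene, "@", cz$position, ":", cz$residue)
  pc <- planted_cohort(fx, tibble::tibble(gene = cz$gene,
                                          position = cz$position,
                                          residue = cz$residue,
                                          beta = log(3)),
                       5000, 5000,
                       seed = derive_seed_local(seed, "stcoh"),
                       intercept = -2)
  st <- bootstrap_stability(pc$pool, pc$y, B = B, fraction = 2 / 3,
                            top_k = 3, seed = derive_seed_local(seed, "stb"))
  M <- as.matrix(pc$pool[setdiff(names(pc$pool), "individual_id")])
  aliases <- colnames(M)[cor(M[, key], M)^2 > 0.95]
  r1 <- st$rank_freq[st$rank_freq$rank == 1L &
                       st$rank_freq$predictor %in% aliases, ]
  sum(r1$frequency)
}

# --- permutation power and null behaviour ---------------------------------

# Residue-concentrated signal: a causal residue shared by several alleles
# of one gene (per-copy OR 2.5, n = 400+400). Returns the empirical p of
# the k = 1 permutation test per run.
exp_perm_power <- function(seed, runs = 20L, B = 200L) {
  ps <- numeric(runs)
  for (r in seq_len(runs)) {
    s <- derive_seed_local(seed, paste0("pow", r))
    pool <- build_allele_pool("HLA-DRB1", 16, concentration = 0.8, seed = s)
    aln <- simulate_alignment(pool, n_positions = 8, seed = s)
    hm <- build_haplotype_model(pool, 20, lambda = 0.5, seed = s)
    frq_all <- dplyr::inner_join(aln, pool, by = c("gene", "allele")) |>
      dplyr::group_by(position, residue) |>
      dplyr::summarise(f = sum(frequency), n_all = dplyr::n(),
                       .groups = "drop") |>
      dplyr::filter(residue != "_")
    frq <- dplyr::filter(frq_all, f > 0.2, f < 0.6, n_all >= 4)
    if (nrow(frq) == 0L) {
      frq <- dplyr::filter(frq_all, f > 0.15, f < 0.7, n_all >= 3)
    }
    if (nrow(frq) == 0L) frq <- dplyr::filter(frq_all, f > 0.1, f < 0.9)
    cz <- frq[1, ]
    mod <- disease_model(-1, tibble::tibble(
      gene = "HLA-DRB1", position = cz$position, residue = cz$residue,
      beta = log(2.5)))
    coh <- simulate_cohort(pool, hm, aln, mod, 400, 400, seed = s)
    ad <- allele_dosage(coh$posteriors)
    ad <- ad[match(coh$phenotypes$individual_id, ad$individual_id), ]
    pn <- permutation_null(ad, aln, coh$phenotypes$status, k = 1, B = B,
                           seed = derive_seed_local(seed, paste0("ppn", r)))
    ps[r] <- pn$p
  }
  ps
}

# Allele-level signal (not concentrated in residues): empirical p per run.
exp_perm_null_behaviour <- function(seed, runs = 20L, B = 200L) {
  ps <- numeric(0)
  for (r in seq_len(runs)) {
    ds <- allele_effect_dataset(derive_seed_local(seed, paste0("nul", r)),
                                n_cases = 300L, n_controls = 300L,
                                n_alleles = 16L, n_positions = 8L)
    if (length(unique(ds$y)) < 2) next
    pn <- permutation_null(ds$allele_dosages, ds$alignment, ds$y, k = 1,
                           B = B,
                           seed = derive_seed_local(seed, paste0("npn", r)))
    ps <- c(ps, pn$p)
  }
  ps
}

# --- exhaustive search ----------------------------------------------------

# Does the pair search reproduce an independent glm enumeration on a pool
# of <= 10 predictors (ranking over full-rank pairs, AIC ties broken
# identically)? Returns 1 (agree) / 0.
exp_search_oracle_agreement <- function(seed) {
  fx <- default_fixture(seed = derive_seed_local(seed, "sofix"),
                        n_genes = 2, n_positions = 6)
  cz <- pick_causals(fx, 1)
  pc <- planted_cohort(fx, tibble::tibble(gene = cz$gene,
                                          position = cz$position,
                                          residue = cz$residue,
                                          beta = log(2)),
                       250, 250, seed = derive_seed_local(seed, "socoh"))
  pool <- pc$pool[, 1:9]
  sr <- exhaustive_residue_search(pool, pc$y, k = 2)
  cols <- setdiff(names(pool), "individual_id")
  oracle <- do.call(rbind, lapply(
    utils::combn(sort(cols), 2, simplify = FALSE), function(nms) {
      df <- data.frame(y = pc$y, a = pool[[nms[1]]], b = pool[[nms[2]]])
      m <- stats::glm(y ~ a + b, data = df, family = stats::binomial())
      data.frame(combination = paste(nms, collapse = " + "),
                 aic = stats::AIC(m))
    }))
  oracle <- oracle[oracle$combination %in% sr$combination[!sr$collinear], ]
  oracle <- oracle[order(round(oracle$aic, 6), oracle$combination), ]
  mine <- sr[!sr$collinear, ]
  mine <- mine[order(round(mine$aic, 6), mine$combination), ]
  agree <- identical(mine$combination, oracle$combination) &&
    max(abs(mine$aic - oracle$aic)) < 1e-8
  as.numeric(agree)
}

# Best-pair recovery: two planted independent residues (per-copy ORs 2.5
# and 2) among decoys at n = 5000+5000; success when the AIC-best pair is
# the planted pair (up to r^2 > 0.95 aliases).
exp_best_pair_recovery <- function(seed, reps = 25L) {
  fx <- default_fixture(seed = derive_seed_local(seed, "bpfix"),
                        n_genes = 2, n_positions = 8)
  cz <- pick_causals(fx, 2)
  cz$beta <- log(c(2.5, 2))[seq_len(nrow(cz))]
  keys <- paste0(cz$gene, "@", cz$position, ":", cz$residue)
  wins <- 0L
  for (r in seq_len(reps)) {
    pc <- planted_cohort(fx, cz[c("gene", "position", "residue", "beta")],
                         5000, 5000,
                         seed = derive_seed_local(seed, paste0("bp", r)),
                         intercept = -2)
    sr <- exhaustive_residue_search(pc$pool, pc$y, k = 2, max_models = 1e4)
    best <- strsplit(sr$combination[1], " + ", fixed = TRUE)[[1]]
    M <- as.matrix(pc$pool[setdiff(names(pc$pool), "individual_id")])
    alias <- lapply(keys, function(k) colnames(M)[cor(M[, k], M)^2 > 0.95])
    ok <- any(best %in% alias[[1]]) && any(best %in% alias[[2]]) &&
      !any(best %in% intersect(alias[[1]], alias[[2]]))
    if (ok) wins <- wins + 1L
  }
  wins / reps
}

# Local stable seed derivation mirroring the package's stage hashing.
derive_seed_local <- function(master, stage) {
  codes <- utf8ToInt(as.character(stage))
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 + h) %% 2147483647)
}
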