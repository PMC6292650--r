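# Regression engine: closed-form and IRLS oracles, AIC identity, omnibus
# reparametrization, genetic-model codings, interactions, PCs.

test_that("single binary predictor reproduces the 2x2 odds ratio", {
  # cases: 30 exposed / 70 unexposed; controls: 10 / 90
  d <- tibble::tibble(
    individual_id = as.character(1:200),
    x = c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  )
  y <- c(rep(1, 100), rep(0, 100))
  fit <- fit_logistic(d, y)
  expect_equal(fit$or, (30 * 90) / (70 * 10), tolerance = 1e-6)
  expect_equal(fit$beta, log(27 / 7), tolerance = 1e-6)
})

test_that("logistic fits match an independent Newton-Raphson oracle", {
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- 150 + 10 * s
    x <- rbinom(n, 2, runif(1, 0.2, 0.6)) + runif(n, 0, 0.1)
    z <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + 0.6 * x + 0.3 * z))
    if (length(unique(y)) < 2) next
    d <- tibble::tibble(individual_id = as.character(1:n), x = x)
    fit <- fit_logistic(d, y, covariates = data.frame(z = z))
    oracle <- irls_oracle(cbind(1, z, x), y)
    expect_lt(abs(fit$beta - oracle[3]), 1e-6)
  }
})

test_that("duplicating every row keeps the OR and shrinks SE by sqrt(2)", {
  set.seed(3)
  n <- 400
  x <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * x))
  d1 <- tibble::tibble(individual_id = as.character(1:n), x = x)
  d2 <- tibble::tibble(individual_id = as.character(1:(2 * n)),
                       x = rep(x, 2))
  f1 <- fit_logistic(d1, y)
  f2 <- fit_logistic(d2, rep(y, 2))
  expect_equal(f1$or, f2$or, tolerance = 1e-6)
  expect_equal(f1$se / sqrt(2), f2$se, tolerance = 1e-6)
})

test_that("the AIC identity holds exactly on every fit", {
  fx <- default_fixture(seed = 13, n_genes = 2, n_positions = 6)
  pc <- planted_cohort(fx, NULL, 150, 150, seed = 5)
  fit <- fit_logistic(pc$pool, pc$y)
  # one predictor + intercept = 2 parameters
  expect_equal(fit$aic, fit$deviance + 2 * 2)
  om <- omnibus_position_test(pc$residue_dosages, pc$y)
  om <- om[om$testable, ]
  expect_equal(om$aic, om$deviance + 2 * (om$df + 1))
})

test_that("degenerate inputs are rejected", {
  d <- tibble::tibble(individual_id = as.character(1:10), x = rep(1, 10))
  expect_error(fit_logistic(d, rep(0:1, 5)), "constant")
  d$x <- rnorm(10)
  expect_error(fit_logistic(d, rep(1, 10)), "both cases and controls")
})

test_that("null simulations give nominal type-I error", {
  set.seed(42)
  reject <- vapply(1:200, function(i) {
    n <- 300
    x <- rbinom(n, 2, 0.4)
    y <- rbinom(n, 1, 0.5)
    d <- tibble::tibble(individual_id = as.character(1:n), x = x)
    fit_logistic(d, y)$p_wald < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.09)
})

test_that("biallelic omnibus equals the single-residue LRT and mirrors invert", {
  rd <- residue_dosage(allele_dosage(toy_posteriors()), toy_alignment())
  fx <- default_fixture(seed = 17, n_genes = 2, n_positions = 6)
  pc <- planted_cohort(fx, pick_causals(fx, 1) |>
                         dplyr::mutate(beta = log(2)) |>
                         dplyr::select(gene, position, residue, beta),
                       300, 300, seed = 6)
  info <- parse_residue_key(setdiff(names(pc$pool), "individual_id"))
  counts <- table(paste(info$gene, info$position))
  bi <- names(counts)[counts == 2][1]
  keys <- info$key[paste(info$gene, info$position) == bi]
  single <- fit_logistic(pc$pool[c("individual_id", keys[1])], pc$y)
  mirror <- fit_logistic(pc$pool[c("individual_id", keys[2])], pc$y)
  om <- omnibus_position_test(pc$residue_dosages[c("individual_id", keys)],
                              pc$y)
  expect_equal(om$df[om$testable], 1L)
  expect_equal(om$p[om$testable], single$p_lrt, tolerance = 1e-10)
  # OR(L) = 1/OR(G), p equal
  expect_equal(single$or, 1 / mirror$or, tolerance = 1e-6)
  expect_equal(single$p, mirror$p, tolerance = 1e-10)
})

test_that("conditional gene omnibus removes a purely LD-driven signal", {
  fx <- default_fixture(seed = 21, n_genes = 2, n_positions = 6, lambda = 0)
  cz <- pick_causals(fx, 1)
  pc <- planted_cohort(fx, tibble::tibble(gene = cz$gene,
                                          position = cz$position,
                                          residue = cz$residue,
                                          beta = log(2.5)),
                       700, 700, seed = 8)
  marg <- omnibus_gene_test(pc$allele_dosages, pc$y)
  cond <- omnibus_gene_test(pc$allele_dosages, pc$y, conditional = TRUE)
  other <- setdiff(marg$gene, cz$gene)
  # under pure haplotype LD the non-causal gene shows marginal signal ...
  expect_lt(marg$p[marg$gene == other], 0.05)
  # ... which conditioning on the causal gene's alleles attenuates
  expect_gt(cond$p[cond$gene == other] / marg$p[marg$gene == other], 10)
})

test_that("genetic-model codings reduce to genotype indicators at point masses", {
  gp <- genotype_prob(toy_posteriors(), "G1*01:01")
  # i1 homozygous 01:01, i3 carries none
  expect_equal(gp$p2[gp$individual_id == "i1"], 1)
  expect_equal(gp$p0[gp$individual_id == "i3"], 1)
  gp2 <- genotype_prob(toy_posteriors(), "G1@11:G", toy_alignment())
  expect_equal(gp2$p1[gp2$individual_id == "i2"], 1)

  fx <- default_fixture(seed = 23, n_genes = 1, n_positions = 6)
  cz <- pick_causals(fx, 1)
  pc <- planted_cohort(fx, tibble::tibble(gene = cz$gene,
                                          position = cz$position,
                                          residue = cz$residue,
                                          beta = log(2)),
                       400, 400, seed = 3)
  key <- paste0(cz$gene, "@", cz$position, ":", cz$residue)
  gm <- genetic_model_compare(pc$cohort$posteriors, pc$y, key, fx$alignment)
  expect_setequal(gm$model, c("allelic", "dominant", "recessive", "genotypic"))
  expect_equal(gm$df[gm$model == "genotypic"], 2L)
  expect_equal(sum(gm$preferred), 1L)
  expect_equal(gm$aic, sort(gm$aic))
})

test_that("dominant truth out-ranks the misspecified codings by AIC", {
  # under true dominance the dominant coding must beat the allelic and
  # recessive codings; the genotypic coding nests the truth and is allowed
  # to win its 2-AIC handicap occasionally
  set.seed(99)
  wins <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    n <- 4000
    g <- rbinom(n, 2, 0.35)
    y <- rbinom(n, 1, plogis(-1 + log(2.5) * (g >= 1)))
    post <- tibble::tibble(
      individual_id = sprintf("i%05d", 1:n), gene = "G",
      allele1 = ifelse(g >= 1, "01:01", "02:01"),
      allele2 = ifelse(g == 2, "01:01", "02:01"),
      posterior = 1)
    gm <- genetic_model_compare(post, y, "G*01:01")
    aic <- setNames(gm$aic, gm$model)
    if (aic["dominant"] < aic["allelic"] &&
        aic["dominant"] < aic["recessive"]) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("under multiplicative truth with few homozygotes the dominant fit is close", {
  set.seed(101)
  n <- 4000
  g <- rbinom(n, 2, 0.03)  # a handful of homozygotes: no information on g=2
  y <- rbinom(n, 1, plogis(-1 + log(2) * g))
  post <- tibble::tibble(
    individual_id = sprintf("i%05d", 1:n), gene = "G",
    allele1 = ifelse(g >= 1, "01:01", "02:01"),
    allele2 = ifelse(g == 2, "01:01", "02:01"),
    posterior = 1)
  gm <- genetic_model_compare(post, y, "G*01:01")
  aic <- setNames(gm$aic, gm$model)
  expect_lt(abs(aic["allelic"] - aic["dominant"]), 2)
})

test_that("interaction scan skips collinear pairs and finds planted products", {
  set.seed(7)
  n <- 2500
  a <- rbinom(n, 2, 0.4); b <- rbinom(n, 2, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 0.2 * a + 0.2 * b + log(2) * a * b))
  d <- tibble::tibble(individual_id = as.character(1:n),
                      a = a, b = b, a2 = 2 - a)
  sc <- interaction_scan(d, y)
  expect_true(sc$skipped[sc$predictor1 == "a" & sc$predictor2 == "a2"])
  ab <- sc[sc$predictor1 == "a" & sc$predictor2 == "b", ]
  expect_lt(ab$p, attr(sc, "bonferroni"))
  expect_gt(ab$beta, 0)
})

test_that("main-effects-only data gives calibrated interaction p-values", {
  set.seed(11)
  ps <- vapply(1:100, function(i) {
    n <- 400
    a <- rbinom(n, 2, 0.4); b <- rbinom(n, 2, 0.4)
    y <- rbinom(n, 1, plogis(-0.5 + 0.3 * a + 0.3 * b))
    d <- tibble::tibble(individual_id = as.character(1:n), a = a, b = b)
    interaction_scan(d, y)$p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("principal components are orthogonal, sign-fixed and track structure", {
  set.seed(19)
  n <- 200
  subpop <- rep(0:1, each = n / 2)
  snps <- simulate_snp_dosages(n, 80, seed = 3, subpop = subpop, fst = 0.3)
  pcs <- compute_pcs(snps$dosages, snps$info,
                     exclude_region = list("6", 0, 1), n_pcs = 4,
                     prune_r2 = 0.9)
  S <- as.matrix(pcs[paste0("PC", 1:4)])
  G <- crossprod(S)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_gt(abs(cor(S[, 1], subpop)), 0.9)
  # all SNPs excluded -> error
  expect_error(
    compute_pcs(snps$dosages, snps$info,
                exclude_region = list("6", 0, 6e7), n_pcs = 2),
    "no SNPs left")
  # deterministic
  pcs2 <- compute_pcs(snps$dosages, snps$info,
                      exclude_region = list("6", 0, 1), n_pcs = 4,
                      prune_r2 = 0.9)
  expect_identical(pcs, pcs2)
})

test_that("independent noise covariates barely move the estimate", {
  fx <- default_fixture(seed = 29, n_genes = 1, n_positions = 6)
  cz <- pick_causals(fx, 1)
  pc <- planted_cohort(fx, tibble::tibble(gene = cz$gene,
                                          position = cz$position,
                                          residue = cz$residue,
                                          beta = log(2)),
                       800, 800, seed = 4)
  key <- paste0(cz$gene, "@", cz$position, ":", cz$residue)
  d <- pc$pool[c("individual_id", key)]
  f0 <- fit_logistic(d, pc$y)
  set.seed(31)
  noise <- as.data.frame(matrix(rnorm(1600 * 10), 1600, 10))
  f1 <- fit_logistic(d, pc$y, covariates = noise)
  expect_lt(abs(f1$beta - f0$beta), 3 * f0$se)
})
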