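# Dosage construction: posterior-weighted copy counts, conservation,
# best-guess filtering, frequencies, correlation and pruning machinery.

test_that("allele dosages are posterior-weighted copy counts", {
  ad <- allele_dosage(toy_posteriors(), gene = "G1")
  # homozygous point mass
  expect_equal(ad[["G1*01:01"]][ad$individual_id == "i1"], 2)
  expect_equal(ad[["G1*02:01"]][ad$individual_id == "i1"], 0)
  # linearity of expectation: 0.6 (01:01,02:01) + 0.4 (01:01,03:01)
  i2 <- ad$individual_id == "i2"
  expect_equal(ad[["G1*01:01"]][i2], 1.0)
  expect_equal(ad[["G1*02:01"]][i2], 0.6)
  expect_equal(ad[["G1*03:01"]][i2], 0.4)
  # conservation
  sums <- rowSums(ad[setdiff(names(ad), "individual_id")])
  expect_true(all(abs(sums - 2) < 1e-6))
  expect_error(allele_dosage(toy_posteriors(), gene = "G9"), "not present")
})

test_that("residue dosages sum alleles carrying the residue, gap included", {
  ad <- allele_dosage(toy_posteriors())
  rd <- residue_dosage(ad, toy_alignment())
  i2 <- rd$individual_id == "i2"
  # 01:01 carries L at G1 pos 11 (dosage 1.0); 02:01 and 03:01 carry G
  expect_equal(rd[["G1@11:L"]][i2], 1.0)
  expect_equal(rd[["G1@11:G"]][i2], 1.0)
  # gap is a residue level and participates in conservation
  expect_equal(rd[["G1@-13:_"]][i2], 1.0)
  expect_equal(rd[["G1@-13:A"]][i2], 1.0)
  for (pos_cols in list(c("G1@11:L", "G1@11:G"),
                        c("G1@57:D", "G1@57:A"),
                        c("G1@-13:_", "G1@-13:A"),
                        c("G2@9:H", "G2@9:Y"))) {
    expect_true(all(abs(rowSums(rd[pos_cols]) - 2) < 1e-6))
  }
  expect_error(
    residue_dosage(ad, toy_alignment()[toy_alignment()$allele != "03:01", ]),
    "absent from alignment")
})

test_that("residue dosages match the brute-force genotype enumeration", {
  fx <- default_fixture(seed = 11, n_genes = 2, n_positions = 6)
  for (s in 1:3) {
    post <- random_posteriors(50, fx$pool, seed = 40 + s)
    ad <- allele_dosage(post)
    rd <- residue_dosage(ad, fx$alignment)
    oracle <- brute_force_residue_dosage(post, fx$alignment)
    M <- as.matrix(rd[setdiff(names(rd), "individual_id")])
    rownames(M) <- rd$individual_id
    common <- intersect(colnames(M), colnames(oracle))
    expect_setequal(colnames(M), colnames(oracle))
    expect_lt(max(abs(M[rownames(oracle), common] - oracle[, common])), 1e-10)
  }
})

test_that("monomorphic positions are flagged and excluded from pools", {
  aln <- toy_alignment()
  aln$residue[aln$gene == "G1" & aln$position == 11L] <- "L"
  rd <- residue_dosage(allele_dosage(toy_posteriors()), aln)
  expect_true("G1@11:L" %in% attr(rd, "monomorphic"))
  expect_true(all(rd[["G1@11:L"]] == 2))
  pool <- polymorphic_pool(rd)
  expect_false("G1@11:L" %in% names(pool))
})

test_that("best-guess filtering keeps confident point masses only", {
  post <- toy_posteriors()
  bg <- best_guess_filter(post, threshold = 0.8)
  # i2/G1 max posterior 0.6 -> missing
  expect_false(any(bg$individual_id == "i2" & bg$gene == "G1"))
  expect_true(all(bg$posterior == 1))
  bg2 <- best_guess_filter(post, threshold = 0.5)
  kept <- bg2[bg2$individual_id == "i2" & bg2$gene == "G1", ]
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$allele2, "02:01")
  expect_error(best_guess_filter(post, 0), "threshold")
  # filtered dosages are integers
  ad <- allele_dosage(bg, gene = "G1")
  vals <- unlist(ad[setdiff(names(ad), "individual_id")])
  expect_true(all(vals %in% c(0, 1, 2)))
})

test_that("frequencies are mean dosage over 2 and complements sum to 1", {
  d <- tibble::tibble(individual_id = c("a", "b", "c"),
                      x = c(0, 1, 2), y = c(2, 1, 0))
  fr <- residue_frequency(d)
  expect_equal(fr$frequency, c(0.5, 0.5))
  expect_equal(sum(fr$frequency), 1)
  expect_equal(residue_frequency(d, subset = c("a"))$frequency, c(0, 1))
  expect_error(residue_frequency(d, subset = character(0)), "empty")
})

test_that("r-squared machinery: mirrors, self, constants, independence", {
  rd <- residue_dosage(allele_dosage(toy_posteriors()), toy_alignment())
  r2 <- correlation_r2(rd)
  expect_equal(unclass(r2)["G1@11:L", "G1@11:G"], 1)
  expect_equal(diag(unclass(r2))[["G1@57:D"]], 1)
  set.seed(1)
  big <- tibble::tibble(individual_id = sprintf("i%05d", 1:10000),
                        u = rbinom(10000, 2, 0.3),
                        v = rbinom(10000, 2, 0.4),
                        w = rep(2, 10000))
  r2b <- correlation_r2(big)
  expect_lt(unclass(r2b)["u", "v"], 0.01)
  expect_true("w" %in% attr(r2b, "constant"))
  expect_true(is.na(unclass(r2b)["w", "u"]))
})

test_that("greedy pruning keeps one representative per correlated block", {
  set.seed(2)
  n <- 500
  a <- rbinom(n, 2, 0.5); b <- rbinom(n, 2, 0.3)
  jitter2 <- function(x) pmin(pmax(x + rbinom(n, 1, 0.04) -
                                     rbinom(n, 1, 0.04), 0), 2)
  d <- tibble::tibble(individual_id = as.character(1:n),
                      a1 = a, a2 = jitter2(a), a3 = 2 - a,
                      b1 = b, b2 = jitter2(b))
  r2 <- correlation_r2(d)
  kept <- prune_index_set(r2, r2_max = 0.8)
  expect_length(kept, 2L)
  expect_setequal(substr(kept, 1, 1), c("a", "b"))
  # r2_max = 1 keeps everything except perfect duplicates
  expect_setequal(prune_index_set(r2, 1), c("a1", "a2", "b1", "b2"))
})

test_that("tag groups use single-linkage transitivity", {
  # chain a~b (0.97), b~c (0.97), a~c (0.90): one group at 0.96
  r2 <- matrix(c(1, 0.97, 0.90,
                 0.97, 1, 0.97,
                 0.90, 0.97, 1), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  r2 <- structure(r2, constant = character(0), class = c("hla_r2", "matrix"))
  tg <- tag_groups(r2, tag_r2 = 0.96)
  expect_equal(length(unique(tg$group)), 1L)
  # independent columns give singletons
  r2i <- structure(diag(3), constant = character(0),
                   class = c("hla_r2", "matrix"))
  dimnames(r2i) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(length(unique(tag_groups(r2i, 0.9604)$group)), 3L)
})
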