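# Stepwise selection: determinism, threshold monotonicity, conditional
# scans, backward elimination, mixed pools, haplogroups.

make_selection_fixture <- function(seed = 33) {
  fx <- default_fixture(seed = seed, n_genes = 3, n_positions = 8)
  cz <- pick_causals(fx, 2)
  pc <- planted_cohort(
    fx,
    tibble::tibble(gene = cz$gene, position = cz$position,
                   residue = cz$residue, beta = c(log(2.5), log(1.8))),
    800, 800, seed = seed)
  pc$causal_keys <- paste0(cz$gene, "@", cz$position, ":", cz$residue)
  pc$fx <- fx
  pc
}

test_that("forward selection is deterministic and respects its threshold", {
  pc <- make_selection_fixture()
  tr1 <- forward_stepwise(pc$pool, pc$y, p_enter = 1e-4)
  tr2 <- forward_stepwise(pc$pool, pc$y, p_enter = 1e-4)
  expect_identical(tr1, tr2)
  expect_true(all(tr1$p_enter < 1e-4))
  expect_equal(tr1$step, seq_len(nrow(tr1)))
  # default threshold is Bonferroni over the realized pool
  tr3 <- forward_stepwise(pc$pool, pc$y)
  expect_equal(attr(tr3, "p_enter"),
               0.05 / (length(names(pc$pool)) - 1L))
})

test_that("a stricter threshold selects a subset", {
  pc <- make_selection_fixture(seed = 35)
  loose <- forward_stepwise(pc$pool, pc$y, p_enter = 1e-3)
  strict <- forward_stepwise(pc$pool, pc$y, p_enter = 1e-8)
  expect_lte(nrow(strict), nrow(loose))
  expect_true(all(strict$predictor %in% loose$predictor))
})

test_that("planted residues enter the model first", {
  pc <- make_selection_fixture(seed = 37)
  tr <- forward_stepwise(pc$pool, pc$y, p_enter = 1e-4)
  expect_gte(nrow(tr), 1L)
  M <- as.matrix(pc$pool[setdiff(names(pc$pool), "individual_id")])
  r2_first <- max(cor(M[, tr$predictor[1]], M[, pc$causal_keys])^2)
  expect_gt(r2_first, 0.95)
})

test_that("backward elimination drops redundant near-duplicates only", {
  pc <- make_selection_fixture(seed = 39)
  expect_identical(
    backward_check(character(0), pc$pool, pc$y, p_stay = 1e-4), character(0))
  tr <- forward_stepwise(pc$pool, pc$y, p_enter = 1e-4)
  kept <- backward_check(tr, pc$pool, pc$y)
  expect_setequal(kept, tr$predictor)
  # force-enter a near-duplicate of the top predictor: one of the two goes
  key <- tr$predictor[1]
  twin <- pc$pool
  twin$twin_col <- pmin(pmax(twin[[key]] +
                               ifelse(seq_len(nrow(twin)) %% 50 == 0, 1, 0),
                             0), 2)
  forced <- c(key, "twin_col")
  kept2 <- backward_check(forced, twin, pc$y, p_stay = 1e-4)
  expect_lt(length(kept2), 2L)
})

test_that("conditional scans reduce to marginals and absorb their own set", {
  pc <- make_selection_fixture(seed = 41)
  small <- pc$pool[, 1:10]
  marg <- fit_logistic(small, pc$y)
  sc0 <- conditional_scan(small, NULL, pc$y)
  m <- marg[match(sc0$predictor, marg$predictor), ]
  expect_equal(sc0$p, m$p, tolerance = 1e-10)

  tr <- forward_stepwise(pc$pool, pc$y, p_enter = 1e-4)
  cond <- pc$pool[c("individual_id", tr$predictor)]
  sc <- conditional_scan(cond, cond, pc$y)
  expect_true(all(sc$skipped))
})

test_that("conditioning on the causal residue removes an LD-only signal", {
  fx <- default_fixture(seed = 43, n_genes = 2, n_positions = 6, lambda = 0)
  cz <- pick_causals(fx, 1)
  pc <- planted_cohort(fx, tibble::tibble(gene = cz$gene,
                                          position = cz$position,
                                          residue = cz$residue,
                                          beta = log(2.5)),
                       800, 800, seed = 10)
  key <- paste0(cz$gene, "@", cz$position, ":", cz$residue)
  info <- parse_residue_key(setdiff(names(pc$pool), "individual_id"))
  other_gene <- setdiff(unique(info$gene), cz$gene)
  targets <- pc$pool[c("individual_id", info$key[info$gene == other_gene])]
  marg <- conditional_scan(targets, NULL, pc$y)
  tagged <- marg$predictor[which.min(marg$p)]
  # the strongest LD-borne signal at the other gene ...
  expect_lt(min(marg$p, na.rm = TRUE), 1e-3)
  cond <- conditional_scan(targets, pc$pool[c("individual_id", key)], pc$y)
  expect_gt(cond$p[cond$predictor == tagged], 0.01)
})

test_that("mixed pools reduce correctly and record entry types", {
  pc <- make_selection_fixture(seed = 45)
  tr_plain <- forward_stepwise(pc$pool, pc$y, p_enter = 1e-4)
  tr_mixed <- mixed_pool_stepwise(list(residue = pc$pool), pc$y,
                                  p_enter = 1e-4)
  expect_equal(tr_mixed$predictor, tr_plain$predictor)
  expect_true(all(tr_mixed$type == "residue"))

  # duplicated predictor across two pools enters once, from the first pool
  dup <- pc$pool[c("individual_id", pc$causal_keys[1])]
  tr_dup <- mixed_pool_stepwise(list(residue = pc$pool, snp = dup), pc$y,
                                p_enter = 1e-4)
  expect_false(any(duplicated(tr_dup$predictor)))
  expect_equal(tr_dup$type[tr_dup$predictor == pc$causal_keys[1]], "residue")
})

test_that("a shared residue is preferred over either carrier allele", {
  # causal residue carried by 2 alleles: the residue aggregates both
  # carrier alleles' signal, so it out-competes each individual allele
  fx <- default_fixture(seed = 47, n_genes = 1, n_positions = 6)
  frq <- candidate_residues(fx, 0.2, 0.7)
  aln <- fx$alignment
  counts <- vapply(seq_len(nrow(frq)), function(i) {
    length(unique(aln$allele[aln$gene == frq$gene[i] &
                               aln$position == frq$position[i] &
                               aln$residue == frq$residue[i]]))
  }, integer(1))
  cz <- frq[counts >= 2, ][1, ]
  wins <- 0L
  for (r in 1:5) {
    pc <- planted_cohort(fx, tibble::tibble(gene = cz$gene,
                                            position = cz$position,
                                            residue = cz$residue,
                                            beta = log(2.5)),
                         700, 700, seed = 200 + r)
    tr <- mixed_pool_stepwise(
      list(residue = pc$pool, allele = pc$allele_dosages), pc$y,
      p_enter = 1e-4, max_steps = 1L)
    if (nrow(tr) == 1L && tr$type[1] == "residue") wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("haplogroup assignment separates independent signals", {
  # two planted signals on unlinked genes -> two groups
  fx <- default_fixture(seed = 49, n_genes = 2, n_positions = 6, lambda = 1)
  cz <- pick_causals(fx, 2)
  expect_equal(length(unique(cz$gene)), 2L)
  pc <- planted_cohort(
    fx, tibble::tibble(gene = cz$gene, position = cz$position,
                       residue = cz$residue, beta = c(log(2.5), log(2.5))),
    900, 900, seed = 12)
  keys <- paste0(cz$gene, "@", cz$position, ":", cz$residue)
  marg <- fit_logistic(pc$pool, pc$y)
  sig <- marg$predictor[marg$p < 1e-6]
  expect_true(all(keys %in% sig))
  hg <- assign_haplogroups(pc$pool[c("individual_id", sig)], pc$y)
  expect_equal(hg$group[hg$predictor == keys[1]] !=
                 hg$group[hg$predictor == keys[2]], TRUE)
  # perfectly correlated predictors share a group
  mirror_pool <- pc$pool[c("individual_id", keys[1])]
  mirror_pool$mirror <- 2 - mirror_pool[[keys[1]]]
  hg2 <- assign_haplogroups(mirror_pool, pc$y)
  expect_equal(length(unique(hg2$group)), 1L)
  # single predictor: one group, itself lead
  hg3 <- assign_haplogroups(pc$pool[c("individual_id", keys[1])], pc$y)
  expect_equal(nrow(hg3), 1L)
  expect_true(hg3$lead)
})
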