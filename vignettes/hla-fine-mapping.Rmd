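---
title: "Fine-mapping HLA association signal to amino acid residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping HLA association signal to amino acid residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlafinemap)
library(dplyr)
```

## The problem

Case/control association in the MHC is the strongest genetic signal in many
autoimmune diseases, but it arrives entangled: classical HLA alleles are
long haplotypes of amino acid substitutions, genes across the region sit in
extensive linkage disequilibrium (LD), and imputation from SNP data returns
genotype *posteriors*, not hard calls. The question this package addresses
is whether the allele- and SNP-level association can be explained more
parsimoniously by a handful of specific amino acid residues — and whether
such an explanation could have arisen by chance tagging of the classical
alleles themselves.

The analysis chain is:

1. **Dosages.** For each individual, the expected number of copies (0–2)
   of each classical allele is the posterior-weighted count over candidate
   genotypes; residue dosages then sum the allele dosages of the alleles
   carrying that residue at that aligned position. Per gene the allele
   dosages sum to 2, and per position the residue dosages (the gap `_`
   counts as a residue level) sum to 2 — conservation identities the
   package enforces and tests.
2. **Association.** Every predictor is tested by maximum-likelihood
   logistic regression on the dosage scale, the standard additive
   ("allelic", per-copy) coding. Multi-df omnibus tests take all non-rare
   residues at a position (or alleles at a gene) jointly, dropping the
   most frequent level as reference because of the sum-to-2 constraint.
3. **Stepwise selection.** Forward conditional selection with a
   Bonferroni entry threshold of 0.05 over the realized pool size (a pool
   of 1028 residues gives the conventional 4.87×10⁻⁵; a stricter 10⁻⁸
   variant is a config switch), followed by a backward elimination check.
   Conditional scans then ask how much SNP/allele signal remains given the
   selected residues.
4. **Permutation null.** Within each gene the allele→sequence assignment
   is permuted, preserving every allele–disease relationship while
   breaking the residue–allele linkage; the deviance explained by the best
   k residues in the observed data is compared with its distribution over
   B permutations.
5. **Stability and search.** Bootstrap stability selection (2/3 of cases
   and 2/3 of controls per replicate, entry ranks tabulated) and an
   exhaustive AIC-ranked search over all residue (or position) pairs and
   triples.

## Model and assumptions

The disease model throughout is prospective logistic,

$$\operatorname{logit}\, P(Y_i = 1) = \beta_0 + \sum_j \beta_j d_{ij} + \gamma' z_i,$$

with $d_{ij}$ the expected copy count (dosage) of predictor $j$ in
individual $i$ and $z_i$ optional covariates. Using dosages in place of
genotypes is the usual first-order treatment of imputation uncertainty; it
is unbiased under accurate posteriors but mildly conservative when
uncertainty is large. Case/control (retrospective) sampling biases only
the intercept, so the odds ratios and their tests are valid.

Fitting uses base R's iteratively reweighted least squares
(`stats::glm.fit`). The headline p-value is Wald; the likelihood-ratio p
is always computed alongside and substituted (with a flag) when the fit
fails to converge or shows separation (|β| > 15 on the log-odds scale) —
imputed HLA data genuinely produce near-separated predictors at rare
alleles. The AIC identity `AIC = residual deviance + 2 × parameters` holds
exactly for every fit, and the test suite checks the fitter against an
independent Newton–Raphson oracle to |Δβ| < 10⁻⁶.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `p_enter` | 0.05 / pool size | forward-entry threshold (4.87×10⁻⁵ at 1028 residues) |
| `p_strict` | 10⁻⁸ | stricter stopping variant |
| `p_sep` | 10⁻⁴ | haplogroup separation threshold (pairwise conditioning) |
| `min_freq` | 0.005 | rare-predictor exclusion (imputed frequency = mean dosage / 2) |
| `best_guess` | 0.8 | posterior cutoff for best-guess genotype mode |
| `tag_r2` | 0.9604 | single-linkage LD-group threshold (= 0.98²) |
| `fraction`, `top_k` | 2/3, 20 | bootstrap subsample fraction and selected set size |
| `B` | analysis-dependent | permutations / bootstrap replicates |

Dosage mode (full posterior) is the default; best-guess mode
(`best_guess_filter()`) is opt-in per analysis, and individuals whose
best-guess genotype falls below the cutoff are dropped predictor-wise
(complete-case), a choice the package documents rather than inherits —
missing-data handling in this setting has no single convention.

Two further documented choices: the omnibus parametrization drops the
most frequent level as reference (stabilises the design matrix under the
sum-to-2 constraint), and the correlation screens are exposed as both an
r²-style exclusion (`prune_index_set()`) and a single-linkage grouping
(`tag_groups()`), because "correlation below 0.98" filters are used in
the field sometimes on r and sometimes on r²; both thresholds are plain
arguments.

## The synthetic cohort generator

No individual-level HLA genotype data can ship with a package like this,
so the generator is first-class, tested code rather than a fixture. It
emulates:

- per-gene classical-allele pools with Dirichlet frequency spectra
  (concentration 0.5 by default: one or two common alleles, a tail of
  rare ones, as real HLA loci show);
- cross-gene LD through founder haplotypes spanning all genes, blended
  with independent per-gene draws by a single mixing weight λ (λ = 1 no
  LD, λ = 0 pure haplotype structure). The default λ = 0.5 produces the
  cross-gene confounding that conditional analyses must untangle; real
  MHC LD is not summarised by any single number, and no published
  cohort's LD surface is being estimated here;
- planted causal residues under the per-copy logistic model, with exact
  case/control quotas filled by oversampling (the retrospective design);
- imputation uncertainty via Dirichlet blurring of the genotype
  posteriors over a sparse candidate set (the true genotype plus
  genotypes sharing an allele), mimicking the sparsity of real imputer
  output.

The default eight-gene fixture (`default_fixture()`) mirrors the classical
class I and II loci (HLA-A, -B, -C, -DRB1, -DQA1, -DQB1, -DPA1, -DPB1)
with 10–25 alleles per gene, giving residue pools in the hundreds — the
dimensionality the downstream machinery is exercised at.

What the generator does *not* emulate: genuine recombination maps and
haplotype blocks, population stratification beyond optional covariates,
genotyping error, and the particular allele frequencies of any real
cohort. Passing tests therefore demonstrate that the machinery is correct
and calibrated under the assumed data-generating process, not that any
specific biological finding would replicate.

## Numerical choices

- IRLS: at most 50 iterations, deviance tolerance 10⁻⁸; separation
  heuristic |β| > 15.
- Stepwise ties (identical p-to-enter) break by larger |β|, then
  lexicographic predictor id, making every trace deterministic; duplicate
  predictors offered by two pools enter once, keeping the earliest pool's
  copy.
- The permutation null re-selects the top k residues per permutation by
  deviance-maximising forward search — the null must be allowed the same
  opportunism as the observed analysis; fixing the observed residue
  identities instead is exposed as `fixed_residues = TRUE`. The empirical
  p uses the add-one convention (1 + #{D ≥ D_obs})/(B + 1). Permutation
  scope is within-gene (position sets differ between genes), all genes
  jointly per replicate.
- Collinear subsets in the exhaustive search are flagged with infinite
  AIC rather than silently re-ranked; mirror residues at a biallelic
  position sum to 2 and are the canonical example.
- Exact integer combinatorics (`count_combinations()`) use iterated
  multiply-then-divide and refuse results beyond 2⁵³ rather than return
  floating-point approximations.
- All randomness derives from a master seed by stable string hashing of
  stage names, so toggling one pipeline stage never shifts another
  stage's stream and results are independent of evaluation order.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the generator at sizes
chosen to make each property measurable with comfortable margins on a
single CPU: type-I error over 500 null fits of n = 1000; permutation-p
uniformity over 100 independent datasets at B = 99; odds-ratio recovery
(per-copy OR 3.0) over 50 cohorts of 5000 cases + 5000 controls;
five-residue stepwise recovery over 25 such cohorts from a five-gene,
~70-residue pool; bootstrap stability at B = 100; permutation power and
null behaviour over 20 runs each at B = 200; and exhaustive-search
exactness against a full glm enumeration on pools of ≤ 10 predictors. The
reference analyses these mirror used larger B (10⁴ permutations, 10³
bootstrap replicates) at a single cohort; the properties checked are
invariant to that scaling, which only narrows Monte-Carlo error.

## Worked example

```{r example}
fx <- default_fixture(seed = 42, n_genes = 3, n_positions = 8)
frq <- fx$alignment |>
  inner_join(fx$pool, by = c("gene", "allele")) |>
  group_by(gene, position, residue) |>
  summarise(f = sum(frequency), .groups = "drop") |>
  filter(f > 0.25, f < 0.75, residue != "_")
causal <- frq[1, ]
mod <- disease_model(-1.5, tibble::tibble(
  gene = causal$gene, position = causal$position,
  residue = causal$residue, beta = log(2.5)))

cohort <- simulate_cohort(fx$pool, fx$haplotype_model, fx$alignment, mod,
                          n_cases = 1000, n_controls = 1000, seed = 42)
alleles <- allele_dosage(cohort$posteriors)
alleles <- alleles[match(cohort$phenotypes$individual_id,
                         alleles$individual_id), ]
residues <- residue_dosage(alleles, fx$alignment)
pool <- polymorphic_pool(residues)
y <- cohort$phenotypes$status

fit_logistic(pool, y) |> arrange(p) |> head(3)

trace <- forward_stepwise(pool, y)
trace

perm <- permutation_null(alleles, fx$alignment, y, k = 1, B = 100, seed = 42)
perm
```

## Known limitations

- Dosage-scale interaction terms are products of expectations, not
  expectations of products; with high imputation certainty the difference
  is negligible, with poor imputation it attenuates interaction tests.
- The stepwise path is greedy; the exhaustive pair/triple search covers
  the combinations a greedy path can miss, but orders above 3 are out of
  scope (stochastic model search belongs to dedicated tools).
- Haplogroup assignment conditions pairwise on group leads only, exactly
  as the convention it implements states; it is a reporting device, not a
  joint model.
- p-values for predictors selected by the same data are not adjusted for
  selection; the bootstrap stability module is the honest summary of
  selection reliability.
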