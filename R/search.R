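# Exhaustive best-pair and best-triple model searches over residues and
# over multi-df positions, ranked by AIC, plus the exact combinatorial
# bookkeeping: a greedy stepwise path need not find the best *combination*,
# so pools of modest size are enumerated in full.

#' Exact binomial coefficient
#'
#' Number of k-subsets of n items, computed by exact integer arithmetic
#' (iterated multiply-then-divide, each intermediate an exact integer), so
#' search-space sizes like choose(1028, 3) = 180,534,276 are reported
#' without floating-point slop.
#'
#' @param n Pool size (non-negative integer).
#' @param k Combination order, `0 <= k <= n`.
#' @return The exact count as a double (errors beyond 2^53).
#' @export
#' @examples
#' count_combinations(1028, 2) # 527878
count_combinations <- function(n, k) {
  n <- check_count(n, "n", min = 0L)
  k <- check_count(k, "k", min = 0L)
  if (k > n) abort("`k` must not exceed `n`")
  k <- min(k, n - k)
  res <- 1
  for (i in seq_len(k)) {
    res <- res * (n - k + i)
    res <- res / i  # exact: product of i consecutive integers is divisible by i!
    if (res > 2^53) abort("combination count exceeds exact integer range")
  }
  round(res)
}

search_result <- function(rows, space, level, k) {
  rows <- arrange(rows, .data$aic, .data$df, .data$combination) |>
    mutate(rank = row_number()) |>
    select("rank", dplyr::everything())
  attr(rows, "search_space") <- space
  attr(rows, "level") <- level
  attr(rows, "k") <- k
  class(rows) <- c("hla_search", class(rows))
  rows
}

#' Exhaustive search over residue combinations
#'
#' Fits every k-subset (k = 2 or 3) of the pool's predictors jointly (k df)
#' and ranks the models by AIC; unlike the greedy stepwise path, the winner
#' is the best *combination*. Collinear subsets get infinite AIC and a
#' flag. Near-ties in AIC are visible in the ranking. Higher-order searches
#' are combinatorially prohibitive and out of scope.
#'
#' @param pool Dosage tibble with at least k non-constant predictors.
#' @param phenotype Binary 0/1 vector.
#' @param covariates Optional covariate data frame.
#' @param k Combination order, 2 or 3.
#' @param max_models Refuse searches whose model count exceeds this budget
#'   unless `force = TRUE`.
#' @param force Override the budget guard.
#' @return A tibble of class `hla_search`: `rank`, `combination` (ids joined
#'   by `" + "`), `aic`, `deviance`, `df`, `collinear`; attribute
#'   `search_space` holds the exact model count.
#' @export
exhaustive_residue_search <- function(pool, phenotype, covariates = NULL,
                                      k = 2L, max_models = 1e6,
                                      force = FALSE) {
  k <- check_count(k, "k", min = 2L)
  if (!k %in% c(2L, 3L)) abort("`k` must be 2 or 3")
  y <- check_phenotype(phenotype, nrow(pool))
  Z <- covariate_matrix(covariates, nrow(pool))
  M <- dosage_matrix(pool)
  M <- M[, apply(M, 2L, var) > 0, drop = FALSE]
  if (ncol(M) < k) abort("pool has fewer than k non-constant predictors")
  space <- count_combinations(ncol(M), k)
  if (space > max_models && !force) {
    abort(paste0("search space (", space, " models) exceeds the budget (",
                 max_models, "); use force = TRUE to override"))
  }
  X_base <- intercept_design(length(y), Z)
  f0 <- glm_dev(X_base, y)
  combos <- combn(sort(colnames(M)), k)
  rows <- map_dfr(seq_len(ncol(combos)), function(i) {
    nms <- combos[, i]
    f1 <- glm_dev(cbind(X_base, M[, nms, drop = FALSE]), y)
    collinear <- f1$rank < f0$rank + k
    tibble(
      combination = paste(nms, collapse = " + "),
      aic = if (collinear) Inf else f1$aic,
      deviance = f1$deviance,
      df = f1$rank - f0$rank,
      collinear = collinear
    )
  })
  search_result(rows, space, "residue", k)
}

#' Exhaustive search over amino-acid position combinations
#'
#' As [exhaustive_residue_search()], but each candidate model includes all
#' retained (non-rare, reference-dropped) residues at every position of the
#' combination — multi-df models of position pairs or triples.
#'
#' @param residue_dosages Output of [residue_dosage()].
#' @param phenotype Binary 0/1 vector.
#' @param covariates Optional covariate data frame.
#' @param k Combination order, 2 or 3.
#' @param min_freq Residue frequency cutoff (default 0.5%).
#' @param max_models,force Search budget guard.
#' @return A tibble of class `hla_search` with positions labelled
#'   `gene@position`.
#' @export
exhaustive_position_search <- function(residue_dosages, phenotype,
                                       covariates = NULL, k = 2L,
                                       min_freq = 0.005, max_models = 1e6,
                                       force = FALSE) {
  k <- check_count(k, "k", min = 2L)
  if (!k %in% c(2L, 3L)) abort("`k` must be 2 or 3")
  y <- check_phenotype(phenotype, nrow(residue_dosages))
  Z <- covariate_matrix(covariates, nrow(residue_dosages))
  info <- parse_residue_key(dosage_cols(residue_dosages))
  M <- dosage_matrix(residue_dosages)
  pos_keys <- split(info$key, paste0(info$gene, "@", info$position))
  blocks <- lapply(pos_keys, function(keys) {
    ref_dropped_block(M[, keys, drop = FALSE], min_freq)
  })
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  if (length(blocks) < k) abort("fewer than k polymorphic positions")
  space <- count_combinations(length(blocks), k)
  if (space > max_models && !force) {
    abort(paste0("search space (", space, " models) exceeds the budget (",
                 max_models, "); use force = TRUE to override"))
  }
  X_base <- intercept_design(length(y), Z)
  f0 <- glm_dev(X_base, y)
  combos <- combn(sort(names(blocks)), k)
  rows <- map_dfr(seq_len(ncol(combos)), function(i) {
    nms <- combos[, i]
    B <- do.call(cbind, blocks[nms])
    full_df <- ncol(B)
    f1 <- glm_dev(cbind(X_base, B), y)
    collinear <- f1$rank < f0$rank + full_df
    tibble(
      combination = paste(nms, collapse = " + "),
      aic = if (collinear) Inf else f1$aic,
      deviance = f1$deviance,
      df = f1$rank - f0$rank,
      collinear = collinear
    )
  })
  search_result(rows, space, "position", k)
}
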