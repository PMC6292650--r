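# Forward/backward stepwise conditional selection over amino-acid residues,
# classical alleles and SNPs; conditional scans given a selected set; and
# the pairwise haplogroup-assignment rule for marginally associated
# predictors.

# Conditional single-predictor statistics for every candidate column of M
# given the design X0 (intercept + covariates + entered predictors).
# Headline p is Wald, LRT substituted on non-convergence/separation, the
# same statistic fit_logistic() reports.
cond_stats <- function(M, y, X0, candidates) {
  if (length(candidates) == 0L) {
    return(tibble(predictor = character(), beta = numeric(),
                  p = numeric(), deviance = numeric()))
  }
  f0 <- glm_dev(X0, y)
  map_dfr(candidates, function(nm) {
    x <- M[, nm]
    if (var(x) == 0) {
      return(tibble(predictor = nm, beta = NA_real_, p = NA_real_,
                    deviance = NA_real_))
    }
    X1 <- cbind(X0, x)
    colnames(X1)[ncol(X1)] <- nm
    f1 <- glm_dev(X1, y)
    beta <- unname(f1$coef[nm])
    se <- unname(f1$se[nm])
    if (f1$rank <= f0$rank || is.na(beta)) {
      return(tibble(predictor = nm, beta = NA_real_, p = NA_real_,
                    deviance = f1$deviance))
    }
    p_wald <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
    p_lrt <- pchisq(max(f0$deviance - f1$deviance, 0), 1L, lower.tail = FALSE)
    separated <- !f1$converged || abs(beta) > MAX_ABS_BETA
    tibble(predictor = nm, beta = beta,
           p = if (separated || is.na(p_wald)) p_lrt else p_wald,
           deviance = f1$deviance)
  })
}

# Total tie-break ordering: smallest p, then larger |beta|, then
# lexicographic predictor id.
pick_best <- function(stats) {
  stats <- stats[!is.na(stats$p), ]
  if (nrow(stats) == 0L) return(NULL)
  ord <- order(stats$p, -abs(stats$beta), stats$predictor)
  stats[ord[1L], ]
}

new_trace <- function(entries, p_enter, pool_size) {
  out <- entries
  attr(out, "p_enter") <- p_enter
  attr(out, "pool_size") <- pool_size
  class(out) <- c("hla_trace", class(out))
  out
}

#' Forward stepwise conditional selection
#'
#' Repeatedly fits every remaining pool predictor conditional on those
#' already entered (plus covariates) and enters the most significant one
#' while its p-to-enter stays below `p_enter`; stops otherwise or at
#' `max_steps`. Ties are broken by larger absolute effect, then
#' lexicographic predictor id, so the trace is deterministic.
#'
#' The default `p_enter` is the Bonferroni-corrected 0.05 over the realized
#' pool size (number of polymorphic predictors offered); a pool of 1028
#' residues gives the conventional 4.87e-5.
#'
#' @param pool Dosage tibble of candidate predictors.
#' @param phenotype Binary 0/1 vector.
#' @param covariates Optional covariate data frame.
#' @param p_enter Entry threshold in (0, 1); default `0.05 / pool size`.
#' @param max_steps Maximum entries (default 20).
#' @param types Optional named character vector predictor -> pool type,
#'   recorded per entry.
#' @return A tibble of class `hla_trace`: `step`, `predictor`, `type`,
#'   `p_enter` (p at entry), `beta` (at entry), `deviance` (residual, after
#'   entry), with attributes `p_enter` (threshold) and `pool_size`. An empty
#'   trace is valid.
#' @export
forward_stepwise <- function(pool, phenotype, covariates = NULL,
                             p_enter = NULL, max_steps = 20L, types = NULL) {
  y <- check_phenotype(phenotype, nrow(pool))
  Z <- covariate_matrix(covariates, nrow(pool))
  M <- dosage_matrix(pool)
  poly <- colnames(M)[apply(M, 2L, var) > 0]
  M <- M[, poly, drop = FALSE]
  if (is.null(p_enter)) p_enter <- 0.05 / max(ncol(M), 1L)
  p_enter <- check_prob(p_enter, "p_enter", lo = 0, hi = 1,
                        lo_open = TRUE, hi_open = TRUE)
  max_steps <- check_count(max_steps, "max_steps")

  entered <- character(0)
  rows <- list()
  X0 <- intercept_design(length(y), Z)
  while (length(entered) < max_steps) {
    candidates <- setdiff(colnames(M), entered)
    if (length(candidates) == 0L) break
    best <- pick_best(cond_stats(M, y, X0, candidates))
    if (is.null(best) || best$p >= p_enter) break
    entered <- c(entered, best$predictor)
    X0 <- cbind(X0, M[, best$predictor])
    colnames(X0)[ncol(X0)] <- best$predictor
    rows[[length(rows) + 1L]] <- tibble(
      step = length(entered),
      predictor = best$predictor,
      type = if (is.null(types)) NA_character_ else
        unname(types[best$predictor]),
      p_enter = best$p,
      beta = best$beta,
      deviance = best$deviance
    )
  }
  entries <- if (length(rows) > 0L) bind_rows(rows) else
    tibble(step = integer(), predictor = character(), type = character(),
           p_enter = numeric(), beta = numeric(), deviance = numeric())
  new_trace(entries, p_enter, ncol(M))
}

#' Backward elimination check of a selected set
#'
#' Refits each selected predictor conditional on all the others (plus
#' covariates) and drops any whose conditional p is >= `p_stay`, iterating
#' to a fixed point (worst predictor removed first).
#'
#' @param trace An [forward_stepwise()] trace (or character vector of
#'   predictor ids).
#' @param pool Dosage tibble containing the selected predictors.
#' @param phenotype Binary 0/1 vector.
#' @param covariates Optional covariate data frame.
#' @param p_stay Retention threshold; defaults to the trace's entry
#'   threshold.
#' @return Character vector of retained predictor ids.
#' @export
backward_check <- function(trace, pool, phenotype, covariates = NULL,
                           p_stay = NULL) {
  selected <- if (is.character(trace)) trace else trace$predictor
  if (is.null(p_stay)) p_stay <- attr(trace, "p_enter") %||% 0.05
  if (length(selected) == 0L) return(character(0))
  y <- check_phenotype(phenotype, nrow(pool))
  Z <- covariate_matrix(covariates, nrow(pool))
  M <- dosage_matrix(pool)[, selected, drop = FALSE]
  repeat {
    if (length(selected) == 0L) break
    stats <- map_dfr(selected, function(nm) {
      X0 <- cbind(intercept_design(length(y), Z),
                  M[, setdiff(selected, nm), drop = FALSE])
      cond_stats(M, y, X0, nm)
    })
    worst <- order(-stats$p, stats$predictor)[1L]
    if (is.na(stats$p[worst]) || stats$p[worst] >= p_stay) {
      selected <- setdiff(selected, stats$predictor[worst])
    } else {
      break
    }
  }
  selected
}

#' Conditional association scan
#'
#' Fits each target predictor with a fixed conditioning set (e.g. the top
#' stepwise residues) as covariates — the scan that asks how much SNP,
#' classical-allele or residue association remains once the selected
#' residues are accounted for. Targets that are themselves in the
#' conditioning set are skipped. Conditioning on nothing reproduces the
#' marginal scan.
#'
#' @param targets Dosage tibble of target predictors.
#' @param conditioning Dosage tibble of conditioning predictors (or `NULL`).
#' @param phenotype Binary 0/1 vector.
#' @param covariates Optional covariate data frame.
#' @return A tibble of class `hla_scan`: per-target conditional `beta`, `p`,
#'   `skipped` flag; attribute `min_p` holds the scan's minimum p over
#'   non-skipped targets.
#' @export
conditional_scan <- function(targets, conditioning, phenotype,
                             covariates = NULL) {
  y <- check_phenotype(phenotype, nrow(targets))
  Z <- covariate_matrix(covariates, nrow(targets))
  M <- dosage_matrix(targets)
  cond_names <- character(0)
  X0 <- intercept_design(length(y), Z)
  if (!is.null(conditioning) && length(dosage_cols(conditioning)) > 0L) {
    C <- dosage_matrix(conditioning)
    if (nrow(C) != nrow(M)) abort("conditioning rows do not match targets")
    cond_names <- colnames(C)
    X0 <- cbind(X0, C)
  }
  scan_cols <- setdiff(colnames(M), cond_names)
  skipped <- setdiff(colnames(M), scan_cols)
  stats <- cond_stats(M, y, X0, scan_cols)
  out <- bind_rows(
    stats |> mutate(skipped = is.na(.data$p)),
    tibble(predictor = skipped, beta = NA_real_, p = NA_real_,
           deviance = NA_real_, skipped = TRUE)
  )
  attr(out, "min_p") <- if (any(!out$skipped)) min(out$p[!out$skipped]) else NA_real_
  class(out) <- c("hla_scan", class(out))
  out
}

#' Forward stepwise over mixed predictor pools
#'
#' Concatenates residue, classical-allele and SNP pools and runs
#' [forward_stepwise()], recording which pool each entry came from.
#' Duplicated predictors (identical dosage columns offered by two pools)
#' are offered once, keeping the copy from the earliest pool in the list
#' order (the documented tie rule).
#'
#' @param pools Named list of dosage tibbles, e.g.
#'   `list(residue = ..., allele = ..., snp = ...)`; rows aligned.
#' @param phenotype Binary 0/1 vector.
#' @param covariates Optional covariate data frame.
#' @param p_enter Entry threshold; default Bonferroni over the combined
#'   deduplicated pool.
#' @param max_steps Maximum entries.
#' @return An `hla_trace` whose `type` column names the source pool.
#' @export
mixed_pool_stepwise <- function(pools, phenotype, covariates = NULL,
                                p_enter = NULL, max_steps = 20L) {
  pools <- pools[!vapply(pools, is.null, TRUE)]
  if (length(pools) == 0L) abort("no non-empty pools supplied")
  ids <- pools[[1L]]$individual_id
  cols <- list()
  types <- character(0)
  for (nm in names(pools)) {
    p <- pools[[nm]]
    if (!identical(p$individual_id, ids)) {
      abort("all pools must share the same individuals in the same order")
    }
    for (cn in dosage_cols(p)) {
      if (!cn %in% names(types)) {
        cols[[cn]] <- p[[cn]]
        types[cn] <- nm
      }
    }
  }
  combined <- dplyr::bind_cols(tibble(individual_id = ids), as_tibble(cols))
  M <- dosage_matrix(combined)
  dup <- duplicated(M, MARGIN = 2L)
  combined <- combined[c("individual_id", colnames(M)[!dup])]
  forward_stepwise(combined, phenotype, covariates, p_enter = p_enter,
                   max_steps = max_steps, types = types)
}

#' Assign marginally significant predictors to haplogroups
#'
#' Greedy pairwise-conditioning rule: the most significant unassigned
#' predictor seeds a new group (its lead); every remaining unassigned
#' predictor joins that group iff its p conditional on the lead alone (a
#' two-predictor model) is >= `p_sep` — i.e. its signal is absorbed by the
#' lead. Predictors still significant against every existing lead seed new
#' (independent) groups.
#'
#' @param pool Dosage tibble of the marginally significant predictors.
#' @param phenotype Binary 0/1 vector.
#' @param covariates Optional covariate data frame.
#' @param p_sep Separation threshold (default 1e-4).
#' @return A tibble of class `hla_haplogroups`: `predictor`, `group`,
#'   `lead` (logical), `p_marginal`, `p_conditional_on_lead`.
#' @export
assign_haplogroups <- function(pool, phenotype, covariates = NULL,
                               p_sep = 1e-4) {
  p_sep <- check_prob(p_sep, "p_sep", lo = 0, hi = 1, lo_open = TRUE,
                      hi_open = TRUE)
  y <- check_phenotype(phenotype, nrow(pool))
  Z <- covariate_matrix(covariates, nrow(pool))
  M <- dosage_matrix(pool)
  X_base <- intercept_design(length(y), Z)
  marg <- cond_stats(M, y, X_base, colnames(M)) |>
    arrange(.data$p, .data$predictor)
  unassigned <- marg$predictor[!is.na(marg$p)]
  rows <- list()
  group <- 0L
  while (length(unassigned) > 0L) {
    group <- group + 1L
    lead_id <- unassigned[1L]
    unassigned <- unassigned[-1L]
    rows[[length(rows) + 1L]] <- tibble(
      predictor = lead_id, group = group, lead = TRUE,
      p_marginal = marg$p[marg$predictor == lead_id],
      p_conditional_on_lead = NA_real_
    )
    if (length(unassigned) == 0L) break
    X0 <- cbind(X_base, M[, lead_id])
    colnames(X0)[ncol(X0)] <- lead_id
    cond <- cond_stats(M, y, X0, unassigned)
    absorbed <- cond$predictor[is.na(cond$p) | cond$p >= p_sep]
    for (pr in absorbed) {
      p_m <- marg$p[marg$predictor == pr]
      p_c <- cond$p[cond$predictor == pr]
      rows[[length(rows) + 1L]] <- tibble(
        predictor = pr, group = group, lead = FALSE,
        p_marginal = p_m, p_conditional_on_lead = p_c
      )
    }
    unassigned <- setdiff(unassigned, absorbed)
  }
  out <- bind_rows(rows)
  class(out) <- c("hla_haplogroups", class(out))
  out
}
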