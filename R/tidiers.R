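# broom-style tidiers for the package's result objects.

#' Tidy an association scan
#'
#' @param x An `hla_assoc` tibble from [fit_logistic()].
#' @param ... Unused.
#' @return A tibble with broom-conventional columns `term`, `estimate`
#'   (log odds), `std.error`, `statistic`, `p.value`.
#' @export
tidy.hla_assoc <- function(x, ...) {
  tibble(term = x$predictor, estimate = x$beta, std.error = x$se,
         statistic = x$beta / x$se, p.value = x$p)
}

#' @rdname tidy.hla_assoc
#' @export
glance.hla_assoc <- function(x, ...) {
  tibble(n_predictors = nrow(x), n = max(x$n),
         min_p = min(x$p, na.rm = TRUE),
         n_converged = sum(x$converged, na.rm = TRUE))
}

#' Tidy a stepwise trace
#'
#' @param x An `hla_trace` from [forward_stepwise()].
#' @param ... Unused.
#' @return Entry-ordered tibble `step`, `term`, `estimate`, `p.value`,
#'   `deviance`.
#' @export
tidy.hla_trace <- function(x, ...) {
  tibble(step = x$step, term = x$predictor, estimate = x$beta,
         p.value = x$p_enter, deviance = x$deviance)
}

#' @rdname tidy.hla_trace
#' @export
glance.hla_trace <- function(x, ...) {
  tibble(n_selected = nrow(x), p_enter = attr(x, "p_enter"),
         pool_size = attr(x, "pool_size"))
}

#' Tidy a permutation-null result
#'
#' @param x An `hla_permnull` from [permutation_null()].
#' @param ... Unused.
#' @return One row per permutation: `replicate`, `deviance_explained`.
#' @export
tidy.hla_permnull <- function(x, ...) {
  tibble(replicate = seq_len(x$B), deviance_explained = x$d_perm)
}

#' @rdname tidy.hla_permnull
#' @export
glance.hla_permnull <- function(x, ...) {
  tibble(k = x$k, d_obs = x$d_obs, p = x$p, B = x$B)
}

#' Tidy a stability-selection result
#'
#' @param x An `hla_stability` from [bootstrap_stability()].
#' @param ... Unused.
#' @return The predictor-by-rank selection-frequency table.
#' @export
tidy.hla_stability <- function(x, ...) x$rank_freq

#' @rdname tidy.hla_stability
#' @export
glance.hla_stability <- function(x, ...) {
  r1 <- x$rank_freq[x$rank_freq$rank == 1L, ]
  tibble(B = x$B, fraction = x$fraction, top_k = x$top_k,
         rank1_predictor = if (nrow(r1)) r1$predictor[which.max(r1$frequency)]
         else NA_character_,
         rank1_frequency = if (nrow(r1)) max(r1$frequency) else NA_real_)
}

#' Tidy an exhaustive-search ranking
#'
#' @param x An `hla_search`.
#' @param ... Unused.
#' @return The ranked model table as a plain tibble.
#' @export
tidy.hla_search <- function(x, ...) as_tibble(x)

#' @rdname tidy.hla_search
#' @export
glance.hla_search <- function(x, ...) {
  tibble(level = attr(x, "level"), k = attr(x, "k"),
         search_space = attr(x, "search_space"),
         best_combination = x$combination[1L], best_aic = x$aic[1L])
}
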