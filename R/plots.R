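# ggplot2 autoplot() methods for the main result types.

#' Plot a marginal or conditional association scan
#'
#' A Manhattan-style view: -log10(p) per predictor, grouped by gene and
#' ordered by aligned position when the predictors are residue keys.
#'
#' @param object An `hla_assoc` from [fit_logistic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hla_assoc <- function(object, ...) {
  d <- as_tibble(object)
  is_residue <- all(grepl("@", d$predictor, fixed = TRUE))
  if (is_residue) {
    d <- dplyr::bind_cols(d["p"], parse_residue_key(d$predictor))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$position,
                                    y = -log10(.data$p),
                                    colour = .data$gene)) +
      ggplot2::geom_point() +
      ggplot2::facet_wrap(~gene, scales = "free_x") +
      ggplot2::labs(x = "aligned peptide position",
                    y = expression(-log[10](p)), colour = NULL) +
      ggplot2::theme_bw() +
      ggplot2::theme(legend.position = "none")
  } else {
    d$idx <- seq_len(nrow(d))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$idx, y = -log10(.data$p))) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "predictor", y = expression(-log[10](p))) +
      ggplot2::theme_bw()
  }
}

#' Plot the sequence-assignment permutation null
#'
#' Histogram of the permuted deviances explained with the observed value
#' marked — the tail position of the observed line is the empirical
#' evidence that the residues out-explain chance tagging of classical
#' alleles.
#'
#' @param object An `hla_permnull` from [permutation_null()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hla_permnull <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$deviance_explained)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$d_obs, colour = "red") +
    ggplot2::labs(
      x = paste0("deviance explained by top ", object$k, " residue(s)"),
      y = "permutations",
      subtitle = paste0("empirical p = ", format(object$p, digits = 4),
                        " (B = ", object$B, ")")) +
    ggplot2::theme_bw()
}

#' Plot bootstrap selection stability
#'
#' Predictor-by-entry-rank tile map of selection frequencies over the
#' bootstrap replicates.
#'
#' @param object An `hla_stability` from [bootstrap_stability()].
#' @param max_rank Show entry ranks up to this value.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hla_stability <- function(object, max_rank = 5L, ...) {
  d <- object$rank_freq |> filter(.data$rank <= max_rank)
  keep <- d |>
    group_by(.data$predictor) |>
    summarise(m = max(.data$frequency), .groups = "drop") |>
    arrange(desc(.data$m)) |>
    head(15L)
  d <- d[d$predictor %in% keep$predictor, ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$rank),
                                  y = .data$predictor,
                                  fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "entry rank", y = NULL, fill = "frequency") +
    ggplot2::theme_bw()
}

#' Plot a stepwise trace
#'
#' Significance at entry per step of the forward selection.
#'
#' @param object An `hla_trace` from [forward_stepwise()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hla_trace <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step,
                                  y = -log10(.data$p_enter))) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$predictor),
                       hjust = -0.1, vjust = 0.5, size = 3) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "p_enter")),
                        linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = d$step,
                                limits = c(min(d$step), max(d$step) + 0.5)) +
    ggplot2::labs(x = "step", y = expression(-log[10](p[enter]))) +
    ggplot2::theme_bw()
}
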