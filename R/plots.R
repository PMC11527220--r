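# ggplot2 views of the main result types.

#' Rank plot of ensemble gene scores
#'
#' Genes ordered by ensemble Z with benchmark genes (if given) highlighted,
#' and the risk-gene cutoff drawn as a horizontal reference.
#'
#' @param scores A `gene_score_table`.
#' @param bench Optional character vector of benchmark genes to highlight.
#' @param z_cutoff Cutoff line (default 1.645).
#' @return A ggplot object.
#' @export
plot_gene_scores <- function(scores, bench = NULL, z_cutoff = 1.645) {
  df <- scores |>
    mutate(benchmark = if (is.null(bench)) {
      FALSE
    } else {
      .data$gene %in% normalize_symbols(bench)
    })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$z)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$benchmark), size = 1) +
    ggplot2::geom_hline(yintercept = z_cutoff, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
      guide = if (is.null(bench)) "none" else "legend"
    ) +
    ggplot2::labs(
      x = "gene rank", y = "ensemble Z score", colour = "benchmark"
    ) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of a proximity screen
#'
#' Proximity Z against observed distance, candidate region (Z below the
#' screening cutoff) shaded.
#'
#' @param object A `proximity_screen` tibble.
#' @param z_max Screening cutoff drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot proximity_screen
#' @export
autoplot.proximity_screen <- function(object, z_max = -3, ...) {
  ggplot2::ggplot(
    object |> filter(!is.na(.data$z)),
    ggplot2::aes(x = .data$distance, y = .data$z)
  ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$z < z_max), size = 2) +
    ggplot2::geom_hline(yintercept = z_max, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
      guide = "none"
    ) +
    ggplot2::labs(x = "closest network distance d(S,T)",
      y = "proximity Z score") +
    ggplot2::theme_minimal()
}

#' Covariate balance (love) plot of a matched trial
#'
#' Absolute standardized mean differences per covariate on the matched
#' sample with the balance limit drawn as a reference.
#'
#' @param object A `matched_trial`.
#' @param smd_cutoff Balance limit (default 0.2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot matched_trial
#' @export
autoplot.matched_trial <- function(object, smd_cutoff = 0.2, ...) {
  df <- object$smd |>
    mutate(covariate = stats::reorder(.data$covariate, .data$smd))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$smd, y = .data$covariate)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = smd_cutoff, linetype = "dashed") +
    ggplot2::labs(x = "absolute standardized mean difference",
      y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of per-trial hazard ratios
#'
#' Hazard ratios of all balanced emulated trials with bootstrap CIs and the
#' drug-level median HR as a reference line.
#'
#' @param object An `emulation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot emulation_result
#' @export
autoplot.emulation_result <- function(object, ...) {
  ok <- object$trials |> filter(.data$balanced, .data$estimable)
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$hr, y = factor(.data$trial))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_vline(
      xintercept = object$summary$median_hr, colour = "firebrick"
    ) +
    ggplot2::labs(x = "hazard ratio", y = "emulated trial") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
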