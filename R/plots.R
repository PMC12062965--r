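# ggplot2 views of the main result types; all return ggplot objects and
# never write files.

#' Plot the taxonomic spread of co-occurrence groups
#'
#' @param spread Long tibble from [summarize_taxonomic_spread()].
#' @return A ggplot bar chart, faceted by domain pair.
#' @export
plot_taxonomic_spread <- function(spread) {
  spread |>
    mutate(pair = paste(.data$multicopy_accession, .data$te_accession,
                        sep = " / ")) |>
    ggplot2::ggplot(ggplot2::aes(
      x = stats::reorder(.data$clade_name, -.data$n), y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$pair), scales = "free") +
    ggplot2::labs(x = NULL, y = "proteins") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot relative domain positions from a positional-bias analysis
#'
#' Each point is one protein; points below the diagonal have the TE/viral
#' domain N-terminal of the multicopy domain.
#'
#' @param bias A `positional_bias` object.
#' @return A ggplot scatter plot.
#' @export
plot_positional_bias <- function(bias) {
  tidy(bias) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$multicopy_midpoint_rel,
                                 y = .data$te_midpoint_rel)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "multicopy domain midpoint (relative)",
                  y = "TE/viral domain midpoint (relative)") +
    ggplot2::theme_minimal()
}

#' Plot TE-proximity enrichment scores
#'
#' Signed -log10(q) per PFAM family (positive = enriched above the
#' bootstrap null), one panel per stratum.
#'
#' @param results Tibble from [run_te_enrichment()].
#' @param alpha Significance line drawn at `-log10(alpha)` (default 0.05).
#' @return A ggplot.
#' @export
plot_enrichment <- function(results, alpha = 0.05) {
  results |>
    ggplot2::ggplot(ggplot2::aes(
      x = stats::reorder(.data$pfam_id, .data$score), y = .data$score)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1, 1) * -log10(alpha), linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$stratum)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(signed ~ -log[10](q))) +
    ggplot2::theme_minimal()
}

#' @rdname roc_analysis
#' @param object A `roc_result`.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- object$points |> arrange(.data$fpr, .data$tpr)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%s: AUC = %.3f", object$metric, object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a per-residue minimum-distance profile
#'
#' @param profile Tibble from [min_distance_profile()] (one or several
#'   bait/prey pairs). Residues with no contact partner are omitted.
#' @param domain_map Optional domain map to shade bait domains.
#' @return A ggplot line plot.
#' @export
plot_distance_profile <- function(profile, domain_map = NULL) {
  p <- ggplot2::ggplot(
    filter(profile, !is.na(.data$min_dist)),
    ggplot2::aes(x = .data$residue_index, y = .data$min_dist,
                 colour = .data$prey_id))
  if (!is.null(domain_map)) {
    p <- p + ggplot2::geom_rect(
      data = domain_map,
      ggplot2::aes(xmin = .data$start_res, xmax = .data$end_res,
                   ymin = -Inf, ymax = Inf, fill = .data$domain_label),
      inherit.aes = FALSE, alpha = 0.15)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "bait residue", y = "min distance to prey (Å)") +
    ggplot2::theme_minimal()
}
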