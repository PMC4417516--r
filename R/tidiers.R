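#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mediation result into one row per path
#'
#' @param x A `mediation_result` from [bootstrap_mediation()].
#' @param ... Unused.
#' @return Tibble with `term` (a, b, direct, indirect, total) and
#'   `estimate`; the indirect row carries `std.error` and `p.value`.
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "direct", "indirect", "total"),
    estimate = c(x$a, x$b, x$direct, x$indirect, x$total),
    std.error = c(NA, NA, NA, x$boot_se, NA),
    p.value = c(NA, NA, NA, x$p_indirect, NA)
  )
}

#' @param x A `mediation_result`.
#' @param ... Unused.
#' @rdname tidy.mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_boot = x$n_boot, n_skipped = x$n_skipped,
                 seed = x$seed)
}

#' Tidy a stability report into per-replicate Jaccard rows
#'
#' @param x A `stability_report`.
#' @param ... Unused.
#' @return Tibble: `replicate`, `jaccard`, `sub_seed`.
#' @export
tidy.stability_report <- function(x, ...) x$replicate_jaccard

#' @rdname tidy.stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(
    reps = x$config$reps,
    fraction = x$config$fraction,
    threshold = x$config$threshold,
    mean_jaccard = x$mean_jaccard,
    consensus_edges = length(x$consensus$edges),
    consensus_modules = max(x$consensus_partition$module),
    consensus_pairwise_jaccard = if (is.null(x$consensus_pairwise_jaccard))
      NA_real_ else mean(x$consensus_pairwise_jaccard$jaccard)
  )
}

#' Volcano-style plot of an association scan
#'
#' Effect estimates against `-log10(q)`, with the significance threshold
#' drawn as a horizontal line.
#'
#' @param object An `association_scan` tibble.
#' @param fdr Significance threshold to draw (default 0.001).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.association_scan <- function(object, fdr = 0.001, ...) {
  df <- object[!is.na(object$q.value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = -log10(pmax(.data$q.value, 1e-300)))) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(fdr), linetype = "dashed") +
    ggplot2::labs(x = "estimate (per year)", y = "-log10 q-value") +
    ggplot2::theme_minimal()
}

#' Plot the replicate-vs-consensus stability contrast
#'
#' Histogram of per-replicate Jaccard indices against the full-data
#' network, with the mean replicate Jaccard and (when available) the mean
#' consensus-vs-consensus Jaccard marked as vertical lines.
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_report <- function(object, ...) {
  df <- object$replicate_jaccard
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$jaccard)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean_jaccard, colour = "steelblue") +
    ggplot2::labs(x = "replicate vs full-data Jaccard", y = "replicates") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(object$consensus_pairwise_jaccard)) {
    p <- p + ggplot2::geom_vline(
      xintercept = mean(object$consensus_pairwise_jaccard$jaccard),
      colour = "firebrick", linetype = "dashed")
  }
  p
}

#' Bar plot of module eigengene-age partial correlations
#'
#' @param report Result of [eigengene_age_report()].
#' @return A ggplot object.
#' @export
plot_eigengene_age <- function(report) {
  df <- report$table
  df$module <- factor(df$module)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$partial_r,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "module", y = "partial correlation with age") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
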