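#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the expected RG count model
#'
#' @param x an `rb_expected_model`.
#' @param ... unused.
#' @return one row per polynomial term: term, estimate.
#' @export
tidy.rb_expected_model <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' One-row summary of the expected RG count model
#'
#' @param x an `rb_expected_model`.
#' @param ... unused.
#' @return tibble: n_genes, n, sum_observed, sum_expected, n_floored,
#'   r_squared.
#' @export
glance.rb_expected_model <- function(x, ...) {
  f <- x$fitted
  ss_res <- sum((f$observed - f$expected)^2)
  ss_tot <- sum((f$observed - mean(f$observed))^2)
  tibble(
    n_genes = nrow(f), n = x$n,
    sum_observed = sum(f$observed), sum_expected = sum(f$expected),
    n_floored = sum(f$floored),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  )
}

#' Tidy a contribution estimate
#'
#' @param x an `rb_contribution`.
#' @param ... unused.
#' @return the one-row estimate table (contribution-table shaped).
#' @export
tidy.rb_contribution <- function(x, ...) x$estimate

#' One-row summary of a contribution fit
#'
#' @param x an `rb_contribution`.
#' @param ... unused.
#' @return tibble: class, n_trios, n_genes_q, bootstrap_B, bootstrap_se.
#' @export
glance.rb_contribution <- function(x, ...) {
  tibble(
    class = x$class,
    n_trios = nrow(x$per_trio),
    n_genes_q = nrow(x$q_gene),
    bootstrap_B = x$B,
    bootstrap_se = if (length(x$boot) > 0) sd(x$boot, na.rm = TRUE) else NA_real_
  )
}

#' Quantile-quantile plot of gene burden p-values
#'
#' Observed versus expected -log10 p under the global null, the standard
#' diagnostic for the genome-wide binomial burden scan.
#'
#' @param object an `rb_enrichment` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rb_enrichment <- function(object, ...) {
  n <- nrow(object)
  dat <- tibble(
    observed = -log10(sort(object$p_value)),
    expected = -log10(stats::ppoints(n))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  title = "Gene burden Q-Q plot") +
    ggplot2::theme_minimal()
}

#' Contribution estimates with bootstrap intervals
#'
#' @param object an `rb_contribution_table` (or the `estimate` of a single
#'   fit).
#' @param ... unused.
#' @return a ggplot object showing the attributable fraction per variant
#'   class with its percentile CI.
#' @export
autoplot.rb_contribution_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$class, y = 100 * .data$fraction)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = 100 * .data$ci_low,
                                          ymax = 100 * .data$ci_high)) +
    ggplot2::labs(x = NULL, y = "Attributable fraction (%)",
                  title = "Recessive contribution by variant class") +
    ggplot2::theme_minimal()
}

#' Empirical distribution of inbreeding coefficients
#'
#' @param f_table an `rb_consanguinity` tibble (or any tibble with `f`),
#'   optionally with a `group` column for overlaying cohorts.
#' @return a ggplot object (log10 x scale, F = 0 shown at the axis floor).
#' @export
plot_f_distribution <- function(f_table) {
  dat <- as_tibble(f_table)
  dat$f_plot <- pmax(dat$f, 1e-5)
  aes <- if ("group" %in% names(dat)) {
    ggplot2::aes(x = .data$f_plot, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$f_plot)
  }
  ggplot2::ggplot(dat, aes) +
    ggplot2::stat_ecdf() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = 0.0009, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "Inbreeding coefficient F (log scale)",
                  y = "Cumulative fraction of probands") +
    ggplot2::theme_minimal()
}

#' Heatmap of ratio-of-max expression in dendrogram order
#'
#' @param normalized ratio-of-max expression tibble.
#' @param clustering optional `rb_upgma` result ordering the genes.
#' @return a ggplot tile heatmap.
#' @export
plot_expression_specificity <- function(normalized, clustering = NULL) {
  long <- pivot_longer(normalized, -"gene", names_to = "cell_type",
                       values_to = "ratio")
  if (!is.null(clustering)) {
    long$gene <- factor(long$gene, levels = clustering$order)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_type, y = .data$gene,
                                     fill = .data$ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "ratio of max") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
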