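#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a differential-methylation fit
#'
#' One row per tested locus, sorted by absolute methylation change.
#'
#' @param x A `retro_dm` object from [differential_methylation()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy retro_dm
#' @export
tidy.retro_dm <- function(x, ...) {
  x$results
}

#' One-row summary of a differential-methylation fit
#'
#' @param x A `retro_dm` object.
#' @param ... Unused.
#' @return A one-row tibble: populations, alpha, loci tested and
#'   significant, and the median methylation change among significant loci.
#' @method glance retro_dm
#' @export
glance.retro_dm <- function(x, ...) {
  sig <- x$results[x$results$significant, , drop = FALSE]
  tibble(pop_a = x$pop_a, pop_b = x$pop_b, alpha = x$alpha,
         n_tested = x$n_tested, n_significant = nrow(sig),
         median_delta_significant = if (nrow(sig)) stats::median(sig$delta)
                                    else NA_real_)
}

#' @export
print.retro_dm <- function(x, ...) {
  cat(sprintf("<retro_dm> %s vs %s: %d loci tested, %d significant (alpha = %g)\n",
              x$pop_a, x$pop_b, x$n_tested, sum(x$results$significant), x$alpha))
  print(utils::head(x$results, 5))
  invisible(x)
}

#' Volcano-style plot of per-locus differential methylation
#'
#' Methylation change (`delta`, population B minus A) against the
#' Bonferroni-corrected p-value on a -log10 scale; significant loci
#' highlighted.
#'
#' @param object A `retro_dm` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot retro_dm
#' @export
autoplot.retro_dm <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                   y = -log10(pmax(.data$p_adj, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = sprintf("methylation change (%s - %s)",
                              object$pop_b, object$pop_a),
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = sprintf("corrected p < %g", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Composite methylation profile plot
#'
#' @param object A `retro_composite` tibble from [composite_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot retro_composite
#' @export
autoplot.retro_composite <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rel_pos, y = .data$mean_meth)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.6, colour = "darkgreen") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "bp from element 5' terminus", y = "mean methylation") +
    ggplot2::theme_minimal()
}

#' Locus methylation profile plot (genome space and CpG space)
#'
#' @param object A `retro_locus_profile` tibble from [locus_profile()].
#' @param ... Unused.
#' @return A ggplot, faceted by coordinate space.
#' @method autoplot retro_locus_profile
#' @export
autoplot.retro_locus_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble(x = df$pos, y = df$smoothed, space = "genome space"),
    tibble(x = df$cpg_index, y = df$fraction, space = "CpG space"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "grey40") +
    ggplot2::geom_point(size = 0.5, na.rm = TRUE) +
    ggplot2::facet_wrap(~space, scales = "free_x") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "methylation fraction") +
    ggplot2::theme_minimal()
}

#' Lollipop-style plot of bisulfite amplicon reads
#'
#' One row per read, one column per reference CpG; filled points are
#' methylated CpGs, open points unmethylated, missing calls omitted.
#'
#' @param reads Called amplicon tibble from [call_amplicon()].
#' @param max_reads Cap on displayed reads (default 100).
#' @return A ggplot.
#' @export
plot_amplicon <- function(reads, max_reads = 100L) {
  reads <- utils::head(reads, max_reads)
  m <- amplicon_matrix(reads)
  df <- tibble(read = rep(seq_len(nrow(m)), ncol(m)),
               cpg = rep(seq_len(ncol(m)), each = nrow(m)),
               state = as.vector(m))
  df <- df[df$state != ".", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cpg, y = .data$read,
                                   fill = .data$state == "M")) +
    ggplot2::geom_point(shape = 21, size = 1.6) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white"),
                               labels = c(`TRUE` = "methylated",
                                          `FALSE` = "unmethylated")) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "CpG site", y = "read", fill = NULL) +
    ggplot2::theme_minimal()
}
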