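# ggplot2 visualisations for the main result types.

#' Plot a per-column alignment profile
#'
#' Diversity track along the alignment with gap-masked (not retained)
#' columns marked; conserved candidate regions appear as low flat
#' stretches.
#'
#' @param profile An [build_profile()] result.
#' @param regions Optional [find_conserved_regions()] tibble to shade.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, regions = NULL) {
  stopifnot(is.data.frame(profile))
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$column, y = .data$diversity)) +
    ggplot2::geom_line(colour = "grey30", na.rm = TRUE) +
    ggplot2::geom_point(
      data = dplyr::filter(profile, !.data$retained),
      colour = "firebrick", size = 0.6, na.rm = TRUE
    ) +
    ggplot2::labs(
      x = "alignment column (0-based)",
      y = "diversity (1 - sum p^2)",
      title = "Per-column nucleotide diversity",
      subtitle = "red points: columns masked by the gap filter"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start_column, xmax = .data$end_column,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15
    )
  }
  p
}

#' Plot per-level assay coverage
#'
#' Bar chart of percent coverage per taxonomic level; accepts a
#' [numerical_coverage()] tibble (optionally with an `assay` column, e.g.
#' the `$coverage` element of [compare_assays()]).
#'
#' @param coverage Coverage tibble with `level` and `percent` columns.
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage) {
  stopifnot(is.data.frame(coverage))
  aes <- if ("assay" %in% names(coverage)) {
    ggplot2::aes(x = .data$level, y = .data$percent, fill = .data$assay)
  } else {
    ggplot2::aes(x = .data$level, y = .data$percent)
  }
  ggplot2::ggplot(coverage, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "coverage (%)",
                  title = "In silico assay coverage by taxonomic level") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_quantbac
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$log10_copies, y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10(copies per reaction)", y = "Ct",
      title = sprintf("Standard curve: slope %.3f, efficiency %.1f%%, r^2 %.4f",
                      object$slope, 100 * object$efficiency, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot methods for quantbac result objects
#'
#' `autoplot()` on a `standard_curve` draws the dilution series with the
#' fitted line; on a `cov_report` it draws inter- and intra-run CoV
#' against concentration for Ct and copy number.
#'
#' @param object A `standard_curve` or `cov_report` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot_quantbac
NULL

#' @rdname autoplot_quantbac
#' @method autoplot cov_report
#' @export
autoplot.cov_report <- function(object, ...) {
  long <- object$by_concentration |>
    tidyr::pivot_longer(
      c("inter_run_cov_pct", "intra_run_mean_cov_pct"),
      names_to = "type", values_to = "cov_pct"
    ) |>
    dplyr::mutate(type = dplyr::recode(.data$type,
      inter_run_cov_pct = "inter-run",
      intra_run_mean_cov_pct = "intra-run (mean)"
    ))
  ggplot2::ggplot(long, ggplot2::aes(
    x = log10(.data$known_copies), y = .data$cov_pct,
    colour = .data$quantity, linetype = .data$type
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log10(copies per reaction)", y = "CoV (%)",
                  title = "Inter- and intra-run coefficients of variation") +
    ggplot2::theme_minimal()
}
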