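# qPCR quantification arithmetic: plasmid-standard normalization,
# standard-curve fitting (slope, r-squared, efficiency), replicate outlier
# exclusion, inter/intra-run coefficients of variation, and
# bacteria-to-human ribosomal-copy / genome-equivalent ratios.

#' Constants for bacteria-to-human ratio arithmetic
#'
#' Defaults: 3.94 16S rRNA gene copies per average bacterial genome
#' (rrnDB estimate), 400 18S rRNA gene copies per human genome, and a
#' diploid human genome of 5,758 Mb, i.e. 5758/978 ~ 5.887 pg. The printed
#' three-decimal mass 5.887 pg is used verbatim (not the higher-precision
#' quotient) so that downstream integer ratios reproduce the published
#' convention; every constant is overridable.
#'
#' @param bact_16s_copies_per_genome 16S copies per bacterial genome.
#' @param human_18s_copies_per_genome 18S copies per human genome.
#' @param diploid_genome_mb Diploid human genome size in Mb.
#' @param mb_per_pg Megabases per picogram of DNA (978).
#' @param human_diploid_genome_pg Mass of the diploid human genome in pg.
#' @return A list of class `quant_constants`.
#' @export
quant_constants <- function(bact_16s_copies_per_genome = 3.94,
                            human_18s_copies_per_genome = 400,
                            diploid_genome_mb = 5758,
                            mb_per_pg = 978,
                            human_diploid_genome_pg = 5.887) {
  structure(
    list(
      bact_16s_copies_per_genome = bact_16s_copies_per_genome,
      human_18s_copies_per_genome = human_18s_copies_per_genome,
      diploid_genome_mb = diploid_genome_mb,
      mb_per_pg = mb_per_pg,
      human_diploid_genome_pg = human_diploid_genome_pg
    ),
    class = "quant_constants"
  )
}

#' Plasmid-standard normalization factor from a measured crossing point
#'
#' qPCR-based normalization of cloned plasmid standards: a stock measured
#' at crossing point `cp` is scaled onto the target crossing point scale
#' with the dilution factor `2^(target_cp - cp)`, exploiting the per-cycle
#' doubling of PCR (one cycle = twofold).
#'
#' @param cp Measured Cp/Ct value of the non-normalized stock (> 0).
#' @param target_cp Target Cp value defining the normalized scale
#'   (default 10).
#' @return The dilution factor `2^(target_cp - cp)`.
#' @examples
#' normalization_factor(11) # 0.5
#' @export
normalization_factor <- function(cp, target_cp = 10) {
  if (any(cp <= 0)) rlang::abort("`cp` must be positive")
  2^(target_cp - cp)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(known copies) across a dilution
#' series, with reaction efficiency derived from the slope as
#' `10^(-1/slope) - 1` (a slope of -3.3219 = -1/log10(2) is perfect
#' doubling, 100%).
#'
#' @param points Tibble of wells with columns `known_copies` and `ct`
#'   (optionally `run_id`, `curve_id`); `NA` Ct values (non-detects) are
#'   dropped.
#' @param use_means Fit on per-concentration mean Ct (default) or on
#'   individual wells (`FALSE`).
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `efficiency` (fraction), `n_points`,
#'   `n_concentrations`, `positive_slope` (warning flag) and the
#'   underlying `lm` fit. Supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @export
fit_standard_curve <- function(points, use_means = TRUE) {
  stopifnot(is.data.frame(points))
  if (!all(c("known_copies", "ct") %in% names(points))) {
    rlang::abort("`points` needs columns `known_copies` and `ct`")
  }
  pts <- points |>
    dplyr::filter(!is.na(.data$ct))
  if (any(pts$known_copies <= 0)) {
    rlang::abort("`known_copies` must be positive")
  }
  if (length(unique(pts$known_copies)) < 3) {
    rlang::abort("need at least 3 distinct concentrations to fit a curve")
  }
  fit_data <- if (use_means) {
    pts |>
      dplyr::group_by(.data$known_copies) |>
      dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  } else {
    pts[, c("known_copies", "ct")]
  }
  fit_data <- dplyr::mutate(fit_data, log10_copies = log10(.data$known_copies))
  model <- stats::lm(ct ~ log10_copies, data = fit_data)
  slope <- unname(stats::coef(model)[["log10_copies"]])
  intercept <- unname(stats::coef(model)[["(Intercept)"]])
  structure(
    list(
      slope = slope,
      intercept = intercept,
      # suppress summary.lm's "essentially perfect fit" warning: noiseless
      # dilution series are a legitimate closed-form check
      r_squared = suppressWarnings(summary(model)$r.squared),
      efficiency = 10^(-1 / slope) - 1,
      n_points = nrow(fit_data),
      n_concentrations = length(unique(fit_data$known_copies)),
      positive_slope = slope >= 0,
      model = model,
      data = fit_data
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    paste0("<standard_curve> slope %.4f, intercept %.3f, r^2 %.5f, ",
           "efficiency %.1f%% (%d concentrations)\n"),
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency,
    x$n_concentrations
  ))
  if (x$positive_slope) cat("warning: non-negative slope\n")
  invisible(x)
}

#' Tidiers for quantbac fitted objects
#'
#' `tidy()` returns per-term coefficient estimates of a standard-curve
#' fit; `glance()` returns a one-row model summary (slope, intercept,
#' r-squared, efficiency); `tidy()` on an assay definition returns its
#' component oligos as a tibble.
#'
#' @param x A `standard_curve` or `assay_definition` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_quantbac
NULL

#' @rdname tidy_quantbac
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  s <- suppressWarnings(summary(x$model)$coefficients)
  tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname tidy_quantbac
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    r_squared = x$r_squared,
    efficiency = x$efficiency,
    efficiency_pct = 100 * x$efficiency,
    n_points = x$n_points,
    n_concentrations = x$n_concentrations,
    positive_slope = x$positive_slope
  )
}

#' Back-calculate copies per reaction from Ct via a fitted curve
#'
#' @param fit A [fit_standard_curve()] result.
#' @param ct Numeric Ct value(s).
#' @return Copies per reaction, `10^((ct - intercept) / slope)`.
#' @export
copies_from_ct <- function(fit, ct) {
  stopifnot(inherits(fit, "standard_curve"))
  10^((ct - fit$intercept) / fit$slope)
}

#' Triplicate outlier exclusion rule
#'
#' For a triplicate with Ct standard deviation above 0.3, a single clear
#' outlier (differing by more than 0.3 cycles from *both* other
#' replicates, while those two agree within 0.3) is excluded; otherwise
#' all replicates are retained, with a `dispersed` flag when the SD
#' criterion fired but no single clear outlier exists.
#'
#' @param ct_triplicate Numeric vector of exactly 3 Ct values.
#' @param sd_threshold SD trigger (default 0.3 cycles).
#' @param delta_threshold Outlier distance (default 0.3 cycles).
#' @return A list: `retained` (values kept), `excluded` (value removed, or
#'   empty), `excluded_index`, `dispersed` (logical).
#' @export
exclude_outlier <- function(ct_triplicate, sd_threshold = 0.3,
                            delta_threshold = 0.3) {
  if (length(ct_triplicate) != 3 || anyNA(ct_triplicate)) {
    rlang::abort("`ct_triplicate` must be 3 non-missing Ct values")
  }
  x <- ct_triplicate
  if (stats::sd(x) <= sd_threshold) {
    return(list(retained = x, excluded = numeric(0),
                excluded_index = integer(0), dispersed = FALSE))
  }
  is_outlier <- vapply(1:3, function(i) {
    others <- x[-i]
    all(abs(x[i] - others) > delta_threshold) &&
      abs(diff(others)) <= delta_threshold
  }, logical(1))
  if (sum(is_outlier) == 1) {
    i <- which(is_outlier)
    list(retained = x[-i], excluded = x[i], excluded_index = i,
         dispersed = FALSE)
  } else {
    list(retained = x, excluded = numeric(0), excluded_index = integer(0),
         dispersed = TRUE)
  }
}

#' Apply the triplicate outlier rule across a plate
#'
#' Groups wells by run, curve and concentration and applies
#' [exclude_outlier()] to each complete triplicate; groups of other sizes
#' are left untouched.
#'
#' @param plate Tibble with columns `run_id`, `curve_id`, `known_copies`,
#'   `ct` (and optionally `well`).
#' @inheritParams exclude_outlier
#' @return `plate` with logical columns `excluded` and `dispersed` added.
#' @export
apply_outlier_rule <- function(plate, sd_threshold = 0.3,
                               delta_threshold = 0.3) {
  stopifnot(is.data.frame(plate))
  plate |>
    dplyr::group_by(.data$run_id, .data$curve_id, .data$known_copies) |>
    dplyr::group_modify(function(df, key) {
      df$excluded <- FALSE
      df$dispersed <- FALSE
      ok <- !is.na(df$ct)
      if (sum(ok) == 3) {
        res <- exclude_outlier(df$ct[ok], sd_threshold, delta_threshold)
        if (length(res$excluded_index) == 1) {
          df$excluded[which(ok)[res$excluded_index]] <- TRUE
        }
        df$dispersed <- res$dispersed
      }
      df
    }) |>
    dplyr::ungroup()
}

.cov_pct <- function(x) 100 * stats::sd(x) / mean(x)

#' Inter- and intra-run coefficients of variation of a validation plate
#'
#' Computes, per plasmid-standard concentration and for both Ct value and
#' back-calculated copy number: the inter-run CoV (SD/mean across all
#' retained wells of all standard curves over all runs, as percent) and
#' the intra-run CoV (one CoV per in-run standard curve across its
#' replicate wells, then mean and SD over those curve-level CoVs). Copy
#' numbers are back-calculated per well from that well's own in-run fitted
#' curve (or from `fit` if supplied). Non-detects (`NA` Ct) are dropped
#' and the triplicate outlier rule is applied first.
#'
#' @param plate Tibble with columns `run_id`, `curve_id`, `known_copies`,
#'   `ct`.
#' @param fit Optional single [fit_standard_curve()] used to back-calculate
#'   copies for all wells; by default each run-curve is fitted separately.
#' @param exclude_outliers Apply [exclude_outlier()] per triplicate
#'   first (default `TRUE`).
#' @return A list of class `cov_report`: `$by_concentration`, a tibble
#'   with `known_copies`, `quantity` (`"ct"` or `"copies"`),
#'   `inter_run_cov_pct`, `intra_run_mean_cov_pct`,
#'   `intra_run_sd_cov_pct`, `n_curves`; and `$curve_fits`, the per-curve
#'   [glance()] summaries.
#' @export
cov_report <- function(plate, fit = NULL, exclude_outliers = TRUE) {
  stopifnot(is.data.frame(plate))
  needed <- c("run_id", "curve_id", "known_copies", "ct")
  if (!all(needed %in% names(plate))) {
    rlang::abort(paste0("`plate` needs columns: ",
                        paste(needed, collapse = ", ")))
  }
  wells <- dplyr::filter(plate, !is.na(.data$ct))
  if (length(unique(wells$run_id)) < 2) {
    rlang::abort("inter-run CoV needs at least 2 runs")
  }
  if (exclude_outliers) {
    wells <- apply_outlier_rule(wells) |>
      dplyr::filter(!.data$excluded)
  }
  curves <- wells |>
    dplyr::group_by(.data$run_id, .data$curve_id) |>
    dplyr::group_modify(function(df, key) {
      cf <- if (is.null(fit)) fit_standard_curve(df) else fit
      dplyr::mutate(df, copies = copies_from_ct(cf, .data$ct))
    }) |>
    dplyr::ungroup()
  if (nrow(dplyr::distinct(curves, .data$run_id, .data$curve_id)) < 2) {
    rlang::abort("intra-run CoV needs at least 2 standard curves")
  }

  long <- curves |>
    tidyr::pivot_longer(c("ct", "copies"), names_to = "quantity",
                        values_to = "value")
  inter <- long |>
    dplyr::group_by(.data$known_copies, .data$quantity) |>
    dplyr::summarise(inter_run_cov_pct = .cov_pct(.data$value),
                     .groups = "drop")
  intra <- long |>
    dplyr::group_by(.data$known_copies, .data$quantity, .data$run_id,
                    .data$curve_id) |>
    dplyr::summarise(curve_cov = .cov_pct(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$known_copies, .data$quantity) |>
    dplyr::summarise(
      intra_run_mean_cov_pct = mean(.data$curve_cov),
      intra_run_sd_cov_pct = stats::sd(.data$curve_cov),
      n_curves = dplyr::n(),
      .groups = "drop"
    )
  fits <- wells |>
    dplyr::group_by(.data$run_id, .data$curve_id) |>
    dplyr::group_modify(function(df, key) {
      glance.standard_curve(if (is.null(fit)) fit_standard_curve(df) else fit)
    }) |>
    dplyr::ungroup()
  structure(
    list(
      by_concentration = dplyr::left_join(
        inter, intra, by = c("known_copies", "quantity")
      ) |>
        dplyr::arrange(.data$quantity, .data$known_copies),
      curve_fits = fits
    ),
    class = "cov_report"
  )
}

#' @export
print.cov_report <- function(x, ...) {
  cat("<cov_report>\n")
  print(x$by_concentration)
  invisible(x)
}

#' Human 18S rRNA gene copies in a mass of human genomic DNA
#'
#' `copies = mass_ng * 1000 / human_diploid_genome_pg *
#' human_18s_copies_per_genome`, rounded half-up to the nearest integer
#' (5 ng of human gDNA carries 339,732 18S copies under the default
#' constants).
#'
#' @param mass_ng Human genomic DNA mass in nanograms (>= 0).
#' @param constants A [quant_constants()] list.
#' @return Integer-valued copy count.
#' @export
human_ribosomal_copies <- function(mass_ng, constants = quant_constants()) {
  if (any(mass_ng < 0)) rlang::abort("`mass_ng` must be non-negative")
  round_half_up(
    mass_ng * 1000 / constants$human_diploid_genome_pg *
      constants$human_18s_copies_per_genome
  )
}

#' Genome-equivalent counts of a bacteria/human template mixture
#'
#' Converts a bacterial 16S copy count and a human gDNA mass into genome
#' equivalents: bacterial genomes = copies / 3.94 (average 16S copies per
#' genome), human genomes = mass in pg / 5.887 pg per diploid genome; both
#' rounded half-up. A detection limit of 500 16S copies against 5 ng of
#' human DNA corresponds to 127 bacterial genomes among 849 human genomes.
#'
#' @param bacterial_copies Bacterial 16S rRNA gene copies (>= 0).
#' @param human_mass_ng Human genomic DNA mass in ng (>= 0).
#' @param constants A [quant_constants()] list.
#' @return A one-row tibble: `bacterial_genomes`, `human_genomes`.
#' @export
genome_equivalents <- function(bacterial_copies, human_mass_ng,
                               constants = quant_constants()) {
  if (any(bacterial_copies < 0) || any(human_mass_ng < 0)) {
    rlang::abort("inputs must be non-negative")
  }
  tibble::tibble(
    bacterial_genomes = round_half_up(
      bacterial_copies / constants$bact_16s_copies_per_genome
    ),
    human_genomes = round_half_up(
      human_mass_ng * 1000 / constants$human_diploid_genome_pg
    )
  )
}

#' Bacteria-to-human ribosomal gene copy ratio at a detection limit
#'
#' Expresses a limit of detection as a simplified 1:n bacteria-to-human
#' ribosomal gene copy ratio: n is the number of human 18S copies (from
#' [human_ribosomal_copies()]) per bacterial 16S copy, rounded half-up.
#'
#' @param bacterial_copies Bacterial 16S copies at the detection limit
#'   (> 0).
#' @param human_mass_ng Human genomic DNA mass in ng.
#' @param constants A [quant_constants()] list.
#' @return A one-row tibble: `bacterial_copies`, `human_mass_ng`,
#'   `human_copies`, `ratio_bacteria` (always 1), `ratio_human`.
#' @export
lod_ratio <- function(bacterial_copies, human_mass_ng,
                      constants = quant_constants()) {
  if (any(bacterial_copies <= 0)) {
    rlang::abort("`bacterial_copies` must be positive")
  }
  human_copies <- human_ribosomal_copies(human_mass_ng, constants)
  tibble::tibble(
    bacterial_copies = bacterial_copies,
    human_mass_ng = human_mass_ng,
    human_copies = human_copies,
    ratio_bacteria = 1,
    ratio_human = round_half_up(human_copies / bacterial_copies)
  )
}
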