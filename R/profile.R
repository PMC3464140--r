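# Per-column nucleotide distribution profiling of 16S rRNA gene multiple
# sequence alignments: the design-side summary used to locate conserved
# primer/probe sites.

#' Simpson-based diversity score of a set of allele frequencies
#'
#' Computes `1 - sum(p_i^2)` over the A/C/G/T frequencies (the complement
#' form of Simpson's index), so a fully conserved position scores 0 and
#' maximal four-allele variation scores 0.75. Set `complement = FALSE` to
#' obtain the raw `sum(p_i^2)` instead.
#'
#' @param allele_freqs Named numeric vector of allele frequencies (names in
#'   A/C/G/T); must sum to 1 within `1e-9`.
#' @param complement If `TRUE` (default) return `1 - sum(p^2)`, else
#'   `sum(p^2)`.
#' @return A number in `[0, 1]`.
#' @examples
#' simpson_diversity(c(A = 0.6, C = 0.4)) # 0.48
#' @export
simpson_diversity <- function(allele_freqs, complement = TRUE) {
  if (!is.numeric(allele_freqs) || length(allele_freqs) == 0) {
    rlang::abort("`allele_freqs` must be a non-empty numeric vector")
  }
  if (abs(sum(allele_freqs) - 1) > 1e-9) {
    rlang::abort("`allele_freqs` must sum to 1 (tolerance 1e-9)")
  }
  s <- sum(allele_freqs^2)
  if (complement) 1 - s else s
}

.as_aligned_matrix <- function(alignment) {
  if (inherits(alignment, "XStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  if (!is.character(alignment)) {
    rlang::abort("`alignment` must be a named character vector or an XStringSet")
  }
  if (length(alignment) < 2) {
    rlang::abort("`alignment` needs at least 2 sequences")
  }
  if (length(unique(nchar(alignment))) != 1) {
    rlang::abort("aligned sequences must all have equal length")
  }
  if (is.null(names(alignment)) || anyNA(names(alignment)) ||
        any(names(alignment) == "")) {
    rlang::abort("`alignment` sequences must all be named")
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  rownames(mat) <- names(alignment)
  mat
}

#' Build a per-column nucleotide distribution profile of an alignment
#'
#' Classifies every alignment column into A/C/G/T, gap (`-` or `.`) and
#' "other" counts (IUPAC ambiguity characters in target rows count as
#' "other" and are excluded from allele frequencies), computes the gap
#' fraction, the Simpson-complement diversity of the non-gap A/C/G/T
#' frequencies, a degenerate consensus base, and a map from alignment
#' columns to 1-based positions on a named reference sequence.
#'
#' @param alignment Named character vector of equal-length gapped
#'   sequences, a `Biostrings::XStringSet`, or a path to an aligned FASTA
#'   file.
#' @param reference_id Name of the reference sequence in the alignment
#'   whose ungapped coordinates define `ref_pos`.
#' @param gap_threshold Columns with gap fraction above this are flagged
#'   not `retained` (the design-side gap filter; default 0.03).
#' @param include_threshold Minimum allele frequency for an allele to be
#'   covered by the degenerate consensus `majority_base` (default 0.05).
#' @return A tibble of class `alignment_profile`, one row per column, with
#'   columns `column` (0-based index), `ref_pos` (1-based reference
#'   position, `NA` where the reference is gapped), counts `A`, `C`, `G`,
#'   `T`, `other`, `gap`, then `gap_fraction`, `diversity` (`NA` when a
#'   column has no plain base), `majority_base` and `retained`. Attributes
#'   `n_sequences`, `reference_id` and `gap_threshold` record the context.
#' @export
build_profile <- function(alignment, reference_id,
                          gap_threshold = 0.03,
                          include_threshold = 0.05) {
  if (is.character(alignment) && length(alignment) == 1 &&
        file.exists(alignment)) {
    alignment <- read_alignment(alignment)
  }
  mat <- .as_aligned_matrix(alignment)
  if (!reference_id %in% rownames(mat)) {
    rlang::abort(sprintf("reference `%s` not found in the alignment", reference_id))
  }
  n <- nrow(mat)
  n_col <- ncol(mat)

  is_gap <- mat == "-" | mat == "."
  counts <- sapply(c("A", "C", "G", "T"), function(b) colSums(mat == b))
  counts <- matrix(counts, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  gap <- colSums(is_gap)
  other <- n - rowSums(counts) - gap

  n_allele <- rowSums(counts)
  freqs <- counts / ifelse(n_allele == 0, NA_real_, n_allele)
  diversity <- 1 - rowSums(freqs^2)

  majority_base <- vapply(seq_len(n_col), function(j) {
    if (n_allele[j] == 0) {
      return(NA_character_)
    }
    keep <- freqs[j, ] >= include_threshold
    if (!any(keep)) keep <- freqs[j, ] == max(freqs[j, ])
    iupac_code_for(colnames(freqs)[keep])
  }, character(1))

  ref_chars <- mat[reference_id, ]
  ref_gap <- ref_chars == "-" | ref_chars == "."
  ref_pos <- cumsum(!ref_gap)
  ref_pos[ref_gap] <- NA_integer_

  gap_fraction <- gap / n
  profile <- tibble::tibble(
    column = seq_len(n_col) - 1L,
    ref_pos = as.integer(ref_pos),
    A = as.integer(counts[, "A"]),
    C = as.integer(counts[, "C"]),
    G = as.integer(counts[, "G"]),
    T = as.integer(counts[, "T"]),
    other = as.integer(other),
    gap = as.integer(gap),
    gap_fraction = gap_fraction,
    diversity = diversity,
    majority_base = majority_base,
    retained = gap_fraction <= gap_threshold
  )
  class(profile) <- c("alignment_profile", class(profile))
  attr(profile, "n_sequences") <- n
  attr(profile, "reference_id") <- reference_id
  attr(profile, "gap_threshold") <- gap_threshold
  profile
}

#' Gap-filter an alignment profile
#'
#' Returns the 0-based indices of columns whose gap fraction does not
#' exceed the threshold. The design convention is a 3% gap filter: columns
#' gappier than that are masked from design consideration (they stay in
#' the profile, flagged).
#'
#' @param profile An [build_profile()] result.
#' @param threshold Gap fraction ceiling in `[0, 1]` (default 0.03).
#' @return Sorted integer vector of retained 0-based column indices.
#' @export
gap_filter <- function(profile, threshold = 0.03) {
  stopifnot(is.data.frame(profile))
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    rlang::abort("`threshold` must be in [0, 1]")
  }
  sort(profile$column[profile$gap_fraction <= threshold])
}

#' Identify conserved regions of an alignment profile
#'
#' Finds maximal runs of consecutive columns that pass the gap filter and
#' whose diversity does not exceed a ceiling, keeping runs whose ungapped
#' (reference-mapped) length reaches the requested window. These are the
#' candidate regions for primer/probe placement.
#'
#' @param profile An [build_profile()] result.
#' @param window_ungapped_length Minimum number of reference-mapped
#'   columns a region must span (e.g. 500 for a 500 bp design region).
#' @param diversity_ceiling Maximum per-column diversity allowed inside a
#'   region (default 0.1).
#' @param gap_threshold Gap-fraction ceiling per column (default 0.03).
#' @return A tibble with one row per region: `start_column`, `end_column`
#'   (0-based inclusive), `length_ungapped`, `max_diversity`,
#'   `mean_gap_fraction`, `ref_start`, `ref_end`; sorted by
#'   `start_column`.
#' @export
find_conserved_regions <- function(profile, window_ungapped_length,
                                   diversity_ceiling = 0.1,
                                   gap_threshold = 0.03) {
  stopifnot(is.data.frame(profile))
  if (window_ungapped_length < 1) {
    rlang::abort("`window_ungapped_length` must be >= 1")
  }
  pass <- profile$gap_fraction <= gap_threshold &
    !is.na(profile$diversity) &
    profile$diversity <= diversity_ceiling

  runs <- rle(pass)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)

  regions <- purrr::map_dfr(keep, function(k) {
    idx <- starts[k]:ends[k]
    ref <- profile$ref_pos[idx]
    tibble::tibble(
      start_column = profile$column[idx[1]],
      end_column = profile$column[idx[length(idx)]],
      length_ungapped = sum(!is.na(ref)),
      max_diversity = max(profile$diversity[idx]),
      mean_gap_fraction = mean(profile$gap_fraction[idx]),
      ref_start = if (any(!is.na(ref))) min(ref, na.rm = TRUE) else NA_integer_,
      ref_end = if (any(!is.na(ref))) max(ref, na.rm = TRUE) else NA_integer_
    )
  })
  if (nrow(regions) == 0) {
    return(tibble::tibble(
      start_column = integer(), end_column = integer(),
      length_ungapped = integer(), max_diversity = numeric(),
      mean_gap_fraction = numeric(), ref_start = integer(),
      ref_end = integer()
    ))
  }
  regions |>
    dplyr::filter(.data$length_ungapped >= window_ungapped_length) |>
    dplyr::arrange(.data$start_column)
}

#' Map an alignment-column span to reference coordinates
#'
#' Translates a 0-based alignment column span into 1-based positions on
#' the profile's reference sequence, using the nearest mapped (reference
#' non-gap) columns inside the span.
#'
#' @param profile An [build_profile()] result.
#' @param start_col,end_col 0-based inclusive alignment columns.
#' @return Named integer vector `c(ref_start, ref_end)`.
#' @export
map_to_reference <- function(profile, start_col, end_col) {
  stopifnot(is.data.frame(profile))
  if (start_col > end_col) {
    rlang::abort("`start_col` must be <= `end_col`")
  }
  span <- profile |>
    dplyr::filter(.data$column >= start_col, .data$column <= end_col,
                  !is.na(.data$ref_pos))
  if (nrow(span) == 0) {
    rlang::abort("span contains no reference-mapped column")
  }
  c(ref_start = min(span$ref_pos), ref_end = max(span$ref_pos))
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (gap `-` or `.`).
#' @return Named character vector of aligned sequences (uppercased).
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write aligned (or unaligned) sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}

#' Write a per-column profile to TSV
#'
#' Mirrors the base-distribution output used in primer/probe design: one
#' row per alignment column with counts, gap fraction, diversity and the
#' retained flag.
#'
#' @param profile An [build_profile()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(as.data.frame(profile), path)
  invisible(path)
}
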