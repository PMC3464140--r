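# In silico coverage pipeline: eligibility filtering of taxonomy-annotated
# 16S records, IUPAC-aware perfect-match testing of the three assay
# components under stringent and relaxed criteria, stepwise numerical and
# taxonomic coverage with phylum/genus/species dereplication, and two-assay
# comparison.

.coverage_levels <- c("all_sequences", "species", "genus", "phylum")
.excluded_phyla <- c("bacteria insertia sedis", "unclassified bacteria")

.check_records <- function(records) {
  needed <- c("seq_id", "phylum", "genus", "species", "sequence",
              "ref_start", "ref_end")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    rlang::abort(paste0("`records` is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  records
}

#' Filter records eligible for coverage analysis of an assay
#'
#' A record is eligible when its reference span fully contains the assay
#' amplicon (both primer sites and the probe site lie inside the record),
#' so every assay component has the data needed for match testing. Records
#' with missing span metadata are excluded and counted in the
#' `n_missing_span` attribute. Set `partial = TRUE` to instead require only
#' overlap with the amplicon.
#'
#' @param records Tibble with columns `seq_id`, `phylum`, `genus`,
#'   `species`, `sequence`, `ref_start`, `ref_end`.
#' @param assay An [assay_definition()] with primer coordinates.
#' @param partial If `TRUE`, require only overlap with the amplicon
#'   instead of full containment (default `FALSE`).
#' @return The eligible subset of `records`, with attributes `n_input`,
#'   `n_missing_span` and `n_eligible`.
#' @export
filter_eligible <- function(records, assay, partial = FALSE) {
  .check_records(records)
  span <- amplicon_span(assay)
  has_span <- !is.na(records$ref_start) & !is.na(records$ref_end)
  ok <- if (partial) {
    has_span & records$ref_start <= span$ref_end &
      records$ref_end >= span$ref_start
  } else {
    has_span & records$ref_start <= span$ref_start &
      records$ref_end >= span$ref_end
  }
  out <- records[ok, , drop = FALSE]
  attr(out, "n_input") <- nrow(records)
  attr(out, "n_missing_span") <- sum(!has_span)
  attr(out, "n_eligible") <- nrow(out)
  out
}

# The effective search pattern of one assay component under a criterion:
# full-length oligo under the stringent criterion; under the relaxed
# criterion the 3'-terminal 8 nt of each primer (probe always full).
# Reverse primers are searched as their reverse complement, since records
# are in the standard 16S sense orientation.
.component_pattern <- function(oligo, criterion) {
  criterion <- match.arg(criterion, c("stringent", "relaxed"))
  s <- oligo$sequence
  if (criterion == "relaxed" && oligo$role != "probe") {
    if (nchar(s) < 8) {
      rlang::abort("relaxed criterion needs primers of at least 8 nt")
    }
    s <- stringr::str_sub(s, -8)
  }
  if (oligo$role == "reverse_primer") s <- revcomp_iupac(s)
  s
}

#' Test one assay component against record sequences
#'
#' Scans each whole record sequence for an IUPAC perfect match of the
#' component pattern ([iupac_match()] semantics: target-side ambiguity
#' characters never match). The stringent criterion uses the full-length
#' oligo; the relaxed criterion uses the 3'-terminal 8 nt of a primer and
#' the full-length probe. The reverse primer is matched as its reverse
#' complement.
#'
#' @param sequences Character vector of plain/IUPAC record sequences (or a
#'   records tibble, in which case its `sequence` column is used).
#' @param oligo An [oligo()].
#' @param criterion `"stringent"` or `"relaxed"`.
#' @return Logical vector: does each sequence contain a perfect match?
#' @export
component_hit <- function(sequences, oligo, criterion = "stringent") {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  pattern <- .component_pattern(oligo, criterion)
  stringr::str_detect(toupper(sequences), iupac_to_regex(pattern))
}

#' Match all three assay components against records
#'
#' @param records Eligible records tibble (see [filter_eligible()]).
#' @param assay An [assay_definition()].
#' @param criterion `"stringent"` or `"relaxed"`.
#' @return A tibble: `seq_id`, `forward_hit`, `reverse_hit`, `probe_hit`,
#'   `assay_match` (the conjunction: a record matches the assay only when
#'   all three components match).
#' @export
assay_match <- function(records, assay, criterion = "stringent") {
  .check_records(records)
  tibble::tibble(
    seq_id = records$seq_id,
    forward_hit = component_hit(records$sequence, assay$forward, criterion),
    reverse_hit = component_hit(records$sequence, assay$reverse, criterion),
    probe_hit = component_hit(records$sequence, assay$probe, criterion)
  ) |>
    dplyr::mutate(assay_match = .data$forward_hit & .data$reverse_hit &
                    .data$probe_hit)
}

# per-record OTU labels at each analysis level
.otu_labels <- function(records, level, delim = "|") {
  switch(level,
    all_sequences = records$seq_id,
    species = paste(records$phylum, records$genus, records$species,
                    sep = delim),
    genus = paste(records$phylum, records$genus, sep = delim),
    phylum = records$phylum,
    rlang::abort(sprintf("unknown level `%s`", level))
  )
}

.level_otu_table <- function(records, matched_ids, level, delim) {
  otu <- .otu_labels(records, level, delim)
  keep <- rep(TRUE, nrow(records))
  if (level == "phylum") {
    keep <- !tolower(trimws(records$phylum)) %in% .excluded_phyla
  }
  tibble::tibble(otu = otu[keep],
                 matched = records$seq_id[keep] %in% matched_ids) |>
    dplyr::group_by(.data$otu) |>
    dplyr::summarise(covered = any(.data$matched), .groups = "drop") |>
    dplyr::arrange(.data$otu)
}

#' Stepwise numerical coverage of an assay
#'
#' Implements the stepwise coverage calculation: first over all eligible
#' sequences (numerator = assay-matched sequence IDs), then dereplicated at
#' the species (Phylum|Genus|species), genus (Phylum|Genus) and phylum
#' levels. An OTU is covered when at least one of its sequences matches all
#' three assay components. At the phylum level the ambiguous phyla
#' "Bacteria Insertia Sedis" and "Unclassified Bacteria" are excluded from
#' numerator and denominator; taxa whose genus/species labels contain
#' "unclassified" are retained.
#'
#' @param records Eligible records (already passed through
#'   [filter_eligible()]).
#' @param assay An [assay_definition()].
#' @param criterion `"stringent"` or `"relaxed"`.
#' @param delim Delimiter for concatenated taxonomic identifications
#'   (default `"|"`).
#' @return A tibble with one row per level (`all_sequences`, `species`,
#'   `genus`, `phylum`): `level`, `numerator`, `denominator`, `percent`.
#' @export
numerical_coverage <- function(records, assay, criterion = "stringent",
                               delim = "|") {
  .check_records(records)
  if (nrow(records) == 0) {
    rlang::abort("no eligible records: cannot compute coverage")
  }
  matches <- assay_match(records, assay, criterion)
  matched_ids <- matches$seq_id[matches$assay_match]
  purrr::map_dfr(.coverage_levels, function(level) {
    tab <- .level_otu_table(records, matched_ids, level, delim)
    tibble::tibble(
      level = level,
      numerator = sum(tab$covered),
      denominator = nrow(tab),
      percent = 100 * sum(tab$covered) / nrow(tab)
    )
  }) |>
    dplyr::mutate(level = factor(.data$level, levels = .coverage_levels))
}

#' Covered and uncovered OTU listings per taxonomic level
#'
#' For each analysis level, dereplicates the eligible records into OTUs and
#' labels each as covered (at least one assay-matched sequence) or
#' uncovered; the two sets partition the OTUs at every level.
#'
#' @inheritParams numerical_coverage
#' @return A tibble: `level`, `otu`, `covered` (logical), sorted by level
#'   and OTU.
#' @export
taxonomic_coverage <- function(records, assay, criterion = "stringent",
                               delim = "|") {
  .check_records(records)
  if (nrow(records) == 0) {
    rlang::abort("no eligible records: cannot compute coverage")
  }
  matches <- assay_match(records, assay, criterion)
  matched_ids <- matches$seq_id[matches$assay_match]
  purrr::map_dfr(.coverage_levels, function(level) {
    .level_otu_table(records, matched_ids, level, delim) |>
      dplyr::mutate(level = level, .before = 1)
  }) |>
    dplyr::mutate(level = factor(.data$level, levels = .coverage_levels)) |>
    dplyr::arrange(.data$level, .data$otu)
}

# per-phylum genus coverage with "not covered" / "poorly covered" flags
.phylum_annotations <- function(records, assay, criterion, delim) {
  matches <- assay_match(records, assay, criterion)
  matched_ids <- matches$seq_id[matches$assay_match]
  keep <- !tolower(trimws(records$phylum)) %in% .excluded_phyla
  recs <- records[keep, , drop = FALSE]
  tibble::tibble(
    phylum = recs$phylum,
    genus_otu = paste(recs$phylum, recs$genus, sep = delim),
    matched = recs$seq_id %in% matched_ids
  ) |>
    dplyr::group_by(.data$phylum, .data$genus_otu) |>
    dplyr::summarise(genus_covered = any(.data$matched), .groups = "drop") |>
    dplyr::group_by(.data$phylum) |>
    dplyr::summarise(
      phylum_covered = any(.data$genus_covered),
      genera_covered = sum(.data$genus_covered),
      genera_total = dplyr::n(),
      genus_percent = 100 * sum(.data$genus_covered) / dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      not_covered = !.data$phylum_covered,
      poorly_covered = .data$phylum_covered &
        (.data$genera_total - .data$genera_covered) / .data$genera_total > 0.5
    ) |>
    dplyr::arrange(.data$phylum)
}

#' Compare the coverage of two assays
#'
#' Runs eligibility filtering (independently per assay, so denominators may
#' differ) and numerical coverage for both assays, reports per-level
#' improvement of assay A over assay B, and annotates each phylum under
#' each assay as "not covered" (no matched sequence) or "poorly covered"
#' (more than 50% of its genera uncovered).
#'
#' @param records Full records tibble (eligibility is computed here).
#' @param assay_a,assay_b [assay_definition()] objects.
#' @param criterion `"stringent"` or `"relaxed"`.
#' @param delim Taxonomy concatenation delimiter (default `"|"`).
#' @return A list of class `assay_comparison`: `$coverage` (per assay and
#'   level), `$improvement` (per level, `percent_a - percent_b`), and
#'   `$phylum_annotations` (per assay and phylum).
#' @export
compare_assays <- function(records, assay_a, assay_b,
                           criterion = "stringent", delim = "|") {
  .check_records(records)
  elig_a <- filter_eligible(records, assay_a)
  elig_b <- filter_eligible(records, assay_b)
  cov_a <- numerical_coverage(elig_a, assay_a, criterion, delim) |>
    dplyr::mutate(assay = assay_a$assay_name, .before = 1)
  cov_b <- numerical_coverage(elig_b, assay_b, criterion, delim) |>
    dplyr::mutate(assay = assay_b$assay_name, .before = 1)
  improvement <- dplyr::left_join(
    cov_a, cov_b,
    by = "level", suffix = c("_a", "_b")
  ) |>
    dplyr::transmute(
      level = .data$level,
      percent_a = .data$percent_a,
      percent_b = .data$percent_b,
      improvement = .data$percent_a - .data$percent_b
    )
  ann <- dplyr::bind_rows(
    .phylum_annotations(elig_a, assay_a, criterion, delim) |>
      dplyr::mutate(assay = assay_a$assay_name, .before = 1),
    .phylum_annotations(elig_b, assay_b, criterion, delim) |>
      dplyr::mutate(assay = assay_b$assay_name, .before = 1)
  )
  structure(
    list(
      coverage = dplyr::bind_rows(cov_a, cov_b),
      improvement = improvement,
      phylum_annotations = ann,
      criterion = criterion
    ),
    class = "assay_comparison"
  )
}

#' @export
print.assay_comparison <- function(x, ...) {
  cat(sprintf("<assay_comparison> criterion: %s\n", x$criterion))
  print(x$coverage)
  cat("improvement (assay A - assay B):\n")
  print(x$improvement)
  invisible(x)
}

#' Read an unaligned 16S collection (FASTA + taxonomy TSV)
#'
#' The taxonomy table must carry the columns `seq_id`, `phylum`, `genus`,
#' `species`, `ref_start`, `ref_end` (the reference span emulating
#' database position metadata); sequences are joined on their FASTA IDs.
#'
#' @param fasta_path Path to an unaligned FASTA file.
#' @param taxonomy_path Path to the taxonomy/coordinate TSV.
#' @return A records tibble usable by [filter_eligible()].
#' @export
read_collection <- function(fasta_path, taxonomy_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  tax <- readr::read_tsv(taxonomy_path, show_col_types = FALSE)
  .check_records(dplyr::mutate(
    tax,
    sequence = unname(toupper(as.character(seqs)[tax$seq_id])),
    .after = "species"
  ))
}

#' Write a 16S collection to FASTA + taxonomy TSV
#'
#' @param records Records tibble.
#' @param fasta_path,taxonomy_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_collection <- function(records, fasta_path, taxonomy_path) {
  .check_records(records)
  write_fasta(stats::setNames(records$sequence, records$seq_id), fasta_path)
  readr::write_tsv(
    records[, c("seq_id", "phylum", "genus", "species",
                "ref_start", "ref_end")],
    taxonomy_path
  )
  invisible(list(fasta = fasta_path, taxonomy = taxonomy_path))
}
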