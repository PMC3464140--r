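# Assay representation and design rules: degenerate oligos with reference
# coordinates, degeneracy limits, salt-adjusted melting temperatures and
# amplicon geometry.

# round half up (R's round() is half-to-even; printed assay tables and
# ratio arithmetic use conventional half-up rounding)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Construct an oligonucleotide
#'
#' @param name Oligo name.
#' @param sequence IUPAC DNA string, written 5'->3'.
#' @param role One of `"forward_primer"`, `"reverse_primer"`, `"probe"`.
#' @param ref_start,ref_end Optional 1-based inclusive reference positions
#'   (e.g. *E. coli* 16S numbering) of the site the oligo targets. When
#'   both are given the span length must equal the oligo length.
#' @return An object of class `oligo`.
#' @export
oligo <- function(name, sequence, role,
                  ref_start = NA_integer_, ref_end = NA_integer_) {
  role <- match.arg(role, c("forward_primer", "reverse_primer", "probe"))
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) rlang::abort("`sequence` must be non-empty")
  .check_iupac(sequence)
  if (!is.na(ref_start) && !is.na(ref_end) &&
        (ref_end - ref_start + 1L) != nchar(sequence)) {
    rlang::abort(sprintf(
      "oligo `%s`: coordinate span (%d-%d) does not equal sequence length %d",
      name, ref_start, ref_end, nchar(sequence)
    ))
  }
  structure(
    list(
      name = name, sequence = sequence, role = role,
      ref_start = as.integer(ref_start), ref_end = as.integer(ref_end)
    ),
    class = "oligo"
  )
}

#' @export
print.oligo <- function(x, ...) {
  cat(sprintf(
    "<oligo> %s (%s) 5'-%s-3' [%s-%s], %d degeneracies\n",
    x$name, x$role, x$sequence,
    ifelse(is.na(x$ref_start), "?", x$ref_start),
    ifelse(is.na(x$ref_end), "?", x$ref_end),
    count_degeneracies(x$sequence)
  ))
  invisible(x)
}

#' Construct an assay definition (forward primer, reverse primer, probe)
#'
#' @param assay_name Assay name.
#' @param forward,reverse,probe [oligo()] objects with the matching roles.
#' @return An object of class `assay_definition`.
#' @export
assay_definition <- function(assay_name, forward, reverse, probe) {
  stopifnot(inherits(forward, "oligo"), inherits(reverse, "oligo"),
            inherits(probe, "oligo"))
  if (forward$role != "forward_primer" || reverse$role != "reverse_primer" ||
        probe$role != "probe") {
    rlang::abort("oligo roles must be forward_primer / reverse_primer / probe")
  }
  coords <- c(forward$ref_start, probe$ref_start, reverse$ref_end)
  if (!anyNA(coords) &&
        !(forward$ref_start < probe$ref_start && probe$ref_start < reverse$ref_end)) {
    rlang::abort("coordinates must satisfy forward start < probe start < reverse end")
  }
  structure(
    list(assay_name = assay_name, forward = forward, reverse = reverse,
         probe = probe),
    class = "assay_definition"
  )
}

#' @export
print.assay_definition <- function(x, ...) {
  cat(sprintf("<assay_definition> %s\n", x$assay_name))
  print(x$forward)
  print(x$reverse)
  print(x$probe)
  invisible(x)
}

#' @rdname tidy_quantbac
#' @method tidy assay_definition
#' @export
tidy.assay_definition <- function(x, ...) {
  purrr::map_dfr(list(x$forward, x$reverse, x$probe), function(o) {
    tibble::tibble(
      assay_name = x$assay_name, name = o$name, role = o$role,
      sequence = o$sequence, ref_start = o$ref_start, ref_end = o$ref_end,
      n_degeneracies = count_degeneracies(o$sequence),
      n_variants = n_variants(o$sequence)
    )
  })
}

#' The broad-coverage pan-bacterial V3-V4 TaqMan assay
#'
#' The packaged broad-coverage 16S rRNA gene qPCR assay targeting a 466 bp
#' amplicon bracketing V3-V4 (*E. coli* positions 341-806): a degenerate
#' forward primer (positions 341-356), a degenerate reverse primer
#' (786-806) and a non-degenerate hydrolysis probe (519-532).
#'
#' @return An [assay_definition()].
#' @export
pan_bacterial_assay <- function() {
  assay_definition(
    "panbact_v34",
    forward = oligo("panbact_F", "CCTACGGGDGGCWGCA", "forward_primer", 341L, 356L),
    reverse = oligo("panbact_R", "GGACTACHVGGGTMTCTAATC", "reverse_primer", 786L, 806L),
    probe = oligo("panbact_P", "CAGCAGCCGCGGTA", "probe", 519L, 532L)
  )
}

#' A synthetic narrow-coverage comparison assay
#'
#' A deliberately non-degenerate variant of the same V3-V4 sites, shipped
#' as a synthetic stand-in for a narrower published assay so the two-assay
#' comparison pipeline can be exercised without external sequences. Because
#' it carries no degeneracies it matches only the subset of targets whose
#' sites happen to carry these exact alleles.
#'
#' @return An [assay_definition()].
#' @export
example_comparison_assay <- function() {
  assay_definition(
    "narrow_v34_synthetic",
    forward = oligo("narrow_F", "CCTACGGGAGGCAGCA", "forward_primer", 341L, 356L),
    reverse = oligo("narrow_R", "GGACTACCAGGGTATCTAATC", "reverse_primer", 786L, 806L),
    probe = oligo("narrow_P", "CAGCAGCCGCGGTA", "probe", 519L, 532L)
  )
}

#' Validate an assay against the degeneracy design rules
#'
#' Rule 1: a primer may carry at most `max_primer_degeneracies` (default 3)
#' degenerate bases. Rule 2: the probe may carry none (degenerate probes
#' compromise hydrolysis-probe quantification).
#'
#' @param assay An [assay_definition()].
#' @param max_primer_degeneracies Primer degeneracy ceiling (default 3).
#' @return A tibble with one row per component: `component`, `rule`,
#'   `n_degeneracies`, `limit`, `pass`.
#' @export
validate_assay <- function(assay, max_primer_degeneracies = 3L) {
  stopifnot(inherits(assay, "assay_definition"))
  d <- c(
    forward = count_degeneracies(assay$forward$sequence),
    reverse = count_degeneracies(assay$reverse$sequence),
    probe = count_degeneracies(assay$probe$sequence)
  )
  tibble::tibble(
    component = c("forward_primer", "reverse_primer", "probe"),
    rule = c("primer_max_degeneracies", "primer_max_degeneracies",
             "probe_no_degeneracies"),
    n_degeneracies = as.integer(d),
    limit = c(max_primer_degeneracies, max_primer_degeneracies, 0L),
    pass = as.integer(d) <= c(max_primer_degeneracies,
                              max_primer_degeneracies, 0L)
  )
}

#' Does an assay pass all design rules?
#'
#' @inheritParams validate_assay
#' @return `TRUE` or `FALSE`.
#' @export
assay_valid <- function(assay, max_primer_degeneracies = 3L) {
  all(validate_assay(assay, max_primer_degeneracies)$pass)
}

#' Salt-adjusted melting temperature of a plain DNA sequence
#'
#' The classic salt-adjusted Tm with the two length regimes used by common
#' online oligo calculators: for sequences of at least 14 nt,
#' `Tm = 100.5 + 41 (nG+nC)/N - 820/N + 16.6 log10([Na+])`; for shorter
#' sequences the Wallace-style form
#' `Tm = 2 (nA+nT) + 4 (nG+nC) - 16.6 log10(0.050) + 16.6 log10([Na+])`.
#'
#' @param sequence Plain ACGT string(s), length >= 8 (vectorized).
#' @param sodium_molar Monovalent cation concentration in mol/L
#'   (default 0.05).
#' @return Numeric Tm in degrees Celsius (unrounded).
#' @export
salt_adjusted_tm <- function(sequence, sodium_molar = 0.05) {
  sequence <- toupper(sequence)
  if (any(stringr::str_detect(sequence, "[^ACGT]"))) {
    rlang::abort("`sequence` must be plain ACGT; use tm_range() for degenerate oligos")
  }
  n <- nchar(sequence)
  if (any(n < 8)) rlang::abort("`sequence` must be at least 8 nt")
  gc <- stringr::str_count(sequence, "[GC]")
  at <- n - gc
  salt <- 16.6 * log10(sodium_molar)
  ifelse(
    n >= 14,
    100.5 + 41 * gc / n - 820 / n + salt,
    2 * at + 4 * gc - 16.6 * log10(0.050) + salt
  )
}

#' Melting-temperature range of a degenerate oligo
#'
#' Expands the oligo into all plain variants, computes the salt-adjusted
#' Tm of each, and reports the minimum and maximum rounded half-up to one
#' decimal (the presentation convention of assay tables).
#'
#' @param x An [oligo()] or IUPAC DNA string.
#' @param sodium_molar Monovalent cation concentration in mol/L
#'   (default 0.05).
#' @return A one-row tibble: `tm_min`, `tm_max`, `n_variants`.
#' @export
tm_range <- function(x, sodium_molar = 0.05) {
  seqs <- expand_degenerate(x)
  tms <- salt_adjusted_tm(seqs, sodium_molar)
  tibble::tibble(
    tm_min = round_half_up(min(tms), 1),
    tm_max = round_half_up(max(tms), 1),
    n_variants = length(seqs)
  )
}

#' Amplicon span and length of an assay
#'
#' @param assay An [assay_definition()] with coordinates on both primers.
#' @return A one-row tibble: `ref_start`, `ref_end`, `length` (1-based
#'   inclusive).
#' @export
amplicon_span <- function(assay) {
  stopifnot(inherits(assay, "assay_definition"))
  start <- assay$forward$ref_start
  end <- assay$reverse$ref_end
  if (is.na(start) || is.na(end)) {
    rlang::abort("both primers need reference coordinates")
  }
  if (end <= start) rlang::abort("amplicon end must exceed its start")
  tibble::tibble(ref_start = start, ref_end = end,
                 length = end - start + 1L)
}

#' Read / write assay definitions as TSV
#'
#' The on-disk form is a three-row table with columns `assay_name`,
#' `name`, `role`, `sequence`, `ref_start`, `ref_end`.
#'
#' @param assay An [assay_definition()].
#' @param path File path.
#' @return `write_assay_tsv()` returns `path` invisibly;
#'   `read_assay_tsv()` returns an [assay_definition()].
#' @export
write_assay_tsv <- function(assay, path) {
  readr::write_tsv(
    tidy.assay_definition(assay)[, c("assay_name", "name", "role",
                                     "sequence", "ref_start", "ref_end")],
    path
  )
  invisible(path)
}

#' @rdname write_assay_tsv
#' @export
read_assay_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  get_oligo <- function(role) {
    row <- tab[tab$role == role, ]
    if (nrow(row) != 1) {
      rlang::abort(sprintf("assay table must contain exactly one `%s` row", role))
    }
    oligo(row$name, row$sequence, role, row$ref_start, row$ref_end)
  }
  assay_definition(
    tab$assay_name[1],
    forward = get_oligo("forward_primer"),
    reverse = get_oligo("reverse_primer"),
    probe = get_oligo("probe")
  )
}
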