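# Synthetic-data generators with exact ground truth: alignments with
# planted conserved/variable/gappy columns, taxonomy-annotated 16S
# collections with planted per-level coverage and mismatch positions, and
# simulated qPCR plates with known efficiency and noise. Every generator
# is deterministic under its seed and emits a truth table the analysis
# modules can be checked against exactly.

.with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# ---------------------------------------------------------------- alignment

#' Specification of a synthetic alignment
#'
#' Blocks are laid out left to right. Kinds: `conserved` (one base, all
#' rows identical), `biallelic` (two alleles; exactly `round(p * n)` rows
#' carry the major allele, so the per-column diversity is known exactly),
#' `random` (each row uniform over ACGT) and `gappy` (a conserved base
#' with exactly `round(rate * (n - 1))` of the non-reference rows gapped).
#' The reference row (row 1) is never gapped, so reference coordinates are
#' contiguous.
#'
#' @param n_sequences Number of aligned sequences (>= 2).
#' @param blocks Tibble (or data frame) with columns `length`, `kind`
#'   (`conserved` / `biallelic` / `random` / `gappy`) and `param` (major
#'   allele frequency for `biallelic`, gap rate for `gappy`, `NA`
#'   otherwise).
#' @param seed Integer RNG seed (`NULL` = use the current RNG state).
#' @return A list of class `alignment_spec`.
#' @export
alignment_spec <- function(n_sequences, blocks, seed = NULL) {
  blocks <- tibble::as_tibble(blocks)
  stopifnot(all(c("length", "kind") %in% names(blocks)))
  if (!"param" %in% names(blocks)) blocks$param <- NA_real_
  if (any(blocks$length < 1)) rlang::abort("block lengths must be >= 1")
  bad <- setdiff(blocks$kind, c("conserved", "biallelic", "random", "gappy"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown block kind(s): ", paste(bad, collapse = ", ")))
  }
  needs_param <- blocks$kind %in% c("biallelic", "gappy")
  if (any(needs_param & (is.na(blocks$param) | blocks$param < 0 |
                           blocks$param > 1))) {
    rlang::abort("biallelic/gappy blocks need `param` in [0, 1]")
  }
  if (n_sequences < 2) rlang::abort("`n_sequences` must be >= 2")
  structure(
    list(n_sequences = as.integer(n_sequences), blocks = blocks, seed = seed),
    class = "alignment_spec"
  )
}

#' Generate a synthetic alignment with per-column ground truth
#'
#' Emulates the structure of a pre-aligned 16S core-set alignment:
#' stretches of conserved columns interrupted by variable and gap-rich
#' blocks. Allele and gap counts are planted exactly (not sampled), so the
#' truth table's expected gap fraction and diversity are exact for every
#' non-`random` column.
#'
#' @param spec An [alignment_spec()].
#' @param reference_id Name given to the (ungapped) reference row
#'   (default `"reference"`).
#' @return A list: `alignment` (named character vector, reference first)
#'   and `truth` (tibble with `column` (0-based), `kind`,
#'   `expected_gap_fraction`, `expected_diversity`; `NA` diversity for
#'   `random` columns).
#' @export
make_alignment <- function(spec, reference_id = "reference") {
  stopifnot(inherits(spec, "alignment_spec"))
  n <- spec$n_sequences
  bases <- c("A", "C", "G", "T")
  .with_seed(spec$seed, {
    cols <- list()
    truth <- list()
    for (b in seq_len(nrow(spec$blocks))) {
      len <- spec$blocks$length[b]
      kind <- spec$blocks$kind[b]
      param <- spec$blocks$param[b]
      for (j in seq_len(len)) {
        col <- switch(kind,
          conserved = rep(sample(bases, 1), n),
          biallelic = {
            ab <- sample(bases, 2)
            k <- round_half_up(param * n)
            col <- rep(ab[2], n)
            col[sample.int(n, k)] <- ab[1]
            col
          },
          random = sample(bases, n, replace = TRUE),
          gappy = {
            g <- round_half_up(param * (n - 1))
            col <- rep(sample(bases, 1), n)
            # reference row (1) stays ungapped
            col[1 + sample.int(n - 1, g)] <- "-"
            col
          }
        )
        exp_gap <- if (kind == "gappy") {
          round_half_up(param * (n - 1)) / n
        } else {
          0
        }
        exp_div <- switch(kind,
          conserved = 0,
          biallelic = {
            k <- round_half_up(param * n)
            1 - ((k / n)^2 + ((n - k) / n)^2)
          },
          random = NA_real_,
          gappy = 0
        )
        cols[[length(cols) + 1L]] <- col
        truth[[length(truth) + 1L]] <- tibble::tibble(
          kind = kind, expected_gap_fraction = exp_gap,
          expected_diversity = exp_div
        )
      }
    }
    mat <- do.call(cbind, cols)
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- c(reference_id,
                     sprintf("seq_%04d", seq_len(n - 1)))
    truth <- dplyr::bind_rows(truth) |>
      dplyr::mutate(column = dplyr::row_number() - 1L, .before = 1)
    list(alignment = seqs, truth = truth)
  })
}

# --------------------------------------------------------------- collection

#' Specification of a synthetic taxonomy-annotated 16S collection
#'
#' Describes a balanced taxonomy tree (phyla / genera per phylum / species
#' per genus / sequences per species) of target records built around an
#' amplicon template carrying the assay's primer and probe sites, plus a
#' list of planted mismatches that break chosen components in chosen taxa.
#'
#' @param n_phyla,genera_per_phylum,species_per_genus,seqs_per_species
#'   Taxonomy tree sizes.
#' @param template_length Reference template length in bp (must contain
#'   the assay amplicon; default 900).
#' @param planted_miss Tibble with columns `otu` (a phylum `"P04"`, genus
#'   `"P02|G02"` or species `"P01|G01|s01"` selector; every sequence in
#'   the OTU receives the mismatch), `component` (`"forward"`,
#'   `"reverse"`, `"probe"`) and `offset3` (0-based offset of the
#'   substituted base from the oligo 3' end; offsets of 8 or more on a
#'   primer lie outside the relaxed 3'-8-mer). `NULL` for none.
#' @param span_coverage_fraction Fraction of records whose reference span
#'   contains the full amplicon (the rest start inside it and are
#'   ineligible; default 1).
#' @param seed Integer RNG seed (`NULL` = use the current RNG state).
#' @return A list of class `collection_spec`.
#' @export
collection_spec <- function(n_phyla = 34, genera_per_phylum = 2,
                            species_per_genus = 2, seqs_per_species = 2,
                            template_length = 900,
                            planted_miss = NULL,
                            span_coverage_fraction = 1,
                            seed = NULL) {
  if (!is.null(planted_miss)) {
    planted_miss <- tibble::as_tibble(planted_miss)
    stopifnot(all(c("otu", "component", "offset3") %in% names(planted_miss)))
    bad <- setdiff(planted_miss$component, c("forward", "reverse", "probe"))
    if (length(bad) > 0) {
      rlang::abort(paste0("unknown component(s) in planted_miss: ",
                          paste(bad, collapse = ", ")))
    }
  }
  if (span_coverage_fraction < 0 || span_coverage_fraction > 1) {
    rlang::abort("`span_coverage_fraction` must be in [0, 1]")
  }
  structure(
    list(
      n_phyla = n_phyla, genera_per_phylum = genera_per_phylum,
      species_per_genus = species_per_genus,
      seqs_per_species = seqs_per_species,
      template_length = template_length,
      planted_miss = planted_miss,
      span_coverage_fraction = span_coverage_fraction,
      seed = seed
    ),
    class = "collection_spec"
  )
}

#' Default planted mismatches echoing published coverage structure
#'
#' Three whole phyla carry a probe-center mismatch (uncovered under both
#' criteria, so the phylum report reads 31/34 covered on the default
#' 34-phylum tree), one species carries a forward-primer 5'-end mismatch
#' (outside the 3' 8-mer: uncovered under the stringent criterion only)
#' and one genus carries a reverse-primer 5'-end mismatch (likewise
#' stringent-only), plus one species with a mismatch inside the reverse
#' 3' 8-mer (uncovered under both).
#'
#' @return A `planted_miss` tibble for [collection_spec()].
#' @export
default_planted_miss <- function() {
  tibble::tibble(
    otu = c("P04", "P11", "P23", "P01|G01|s01", "P02|G02", "P03|G01|s02"),
    component = c("probe", "probe", "probe", "forward", "reverse", "reverse"),
    offset3 = c(7L, 7L, 7L, 12L, 15L, 3L)
  )
}

# brute-force degenerate-match scanner (expansion + fixed substring),
# independent of the coverage module's regex matcher; used by the repair
# pass and available to tests as an oracle
brute_force_sites <- function(sequence, pattern) {
  hits <- lapply(expand_degenerate(pattern), function(v) {
    stringr::str_locate_all(sequence, stringr::fixed(v))[[1]][, 1]
  })
  sort(unique(unlist(hits)))
}

# patterns whose occurrences must be confined to the planted sites
.site_patterns <- function(assay) {
  fwd <- assay$forward$sequence
  rev <- assay$reverse$sequence
  prb <- assay$probe$sequence
  fstart <- assay$forward$ref_start
  rstart <- assay$reverse$ref_start
  pstart <- assay$probe$ref_start
  list(
    list(pattern = fwd, allowed = fstart),
    list(pattern = revcomp_iupac(rev), allowed = rstart),
    list(pattern = prb, allowed = pstart),
    # relaxed 3'-8-mers: forward tail sits at the site 3' end; the reverse
    # tail reverse-complements onto the start of the embedded rc site
    list(pattern = stringr::str_sub(fwd, -8),
         allowed = fstart + nchar(fwd) - 8L),
    list(pattern = revcomp_iupac(stringr::str_sub(rev, -8)),
         allowed = rstart)
  )
}

# mutate accidental matches away so the planted sites are the only ones;
# `footprints` are template positions that must not be touched
.repair_sequence <- function(chars, patterns, footprints, offset = 0L) {
  bases <- c("A", "C", "G", "T")
  for (iter in 1:100) {
    dirty <- FALSE
    for (p in patterns) {
      plen <- nchar(p$pattern)
      hits <- brute_force_sites(paste(chars, collapse = ""), p$pattern)
      extra <- setdiff(hits + offset, p$allowed)
      for (h in extra - offset) {
        window <- h:(h + plen - 1L)
        mutable <- window[!(window + offset) %in% footprints]
        if (length(mutable) == 0) {
          rlang::abort("cannot repair accidental site match without touching a planted site")
        }
        pos <- mutable[1]
        cls <- strsplit(iupac_codes[[substr(p$pattern, pos - h + 1L,
                                            pos - h + 1L)]], "")[[1]]
        choices <- setdiff(bases, c(cls, chars[pos]))
        if (length(choices) == 0) choices <- setdiff(bases, cls)
        chars[pos] <- sample(choices, 1)
        dirty <- TRUE
      }
    }
    if (!dirty) {
      return(chars)
    }
  }
  rlang::abort("site repair did not converge")
}

#' Generate a synthetic 16S collection with exact coverage ground truth
#'
#' Builds a balanced taxonomy of target records around a random reference
#' template that carries exact (per-record randomly chosen) expansions of
#' the assay's forward primer, probe and reverse-complemented reverse
#' primer sites, then introduces the planted mismatches: each substitution
#' is drawn from the bases *outside* the pattern's IUPAC class at that
#' position, so it is guaranteed to break matching. A repair pass removes
#' any accidental match of a full site or relaxed 3'-8-mer elsewhere in a
#' record (verified with a brute-force expansion scanner), so the planted
#' sites are provably the only matches and the truth tables are exact.
#'
#' @param spec A [collection_spec()].
#' @param assay An [assay_definition()] whose amplicon fits inside
#'   `spec$template_length`.
#' @return A list: `records` (tibble: `seq_id`, `phylum`, `genus`,
#'   `species`, `sequence`, `ref_start`, `ref_end`), `truth_per_record`
#'   (per eligible record: `seq_id`, `eligible`, `stringent`, `relaxed`)
#'   and `truth_coverage` (tibble: `criterion`, `level`, `numerator`,
#'   `denominator`, `percent` over eligible records).
#' @export
make_collection <- function(spec, assay = pan_bacterial_assay()) {
  stopifnot(inherits(spec, "collection_spec"),
            inherits(assay, "assay_definition"))
  span <- amplicon_span(assay)
  if (span$ref_end > spec$template_length) {
    rlang::abort("`template_length` must contain the assay amplicon")
  }
  bases <- c("A", "C", "G", "T")
  fwd <- assay$forward
  rev <- assay$reverse
  prb <- assay$probe
  rc_rev <- revcomp_iupac(rev$sequence)
  patterns <- .site_patterns(assay)
  footprints <- c(
    fwd$ref_start:fwd$ref_end,
    prb$ref_start:prb$ref_end,
    rev$ref_start:rev$ref_end
  )

  # planted misses indexed by component with template position + class
  miss_tab <- spec$planted_miss
  if (!is.null(miss_tab) && nrow(miss_tab) > 0) {
    miss_tab <- miss_tab |>
      dplyr::mutate(
        oligo_len = dplyr::case_when(
          .data$component == "forward" ~ nchar(fwd$sequence),
          .data$component == "reverse" ~ nchar(rev$sequence),
          TRUE ~ nchar(prb$sequence)
        )
      )
    if (any(miss_tab$offset3 < 0 | miss_tab$offset3 >= miss_tab$oligo_len)) {
      rlang::abort("planted `offset3` must lie inside the oligo")
    }
    miss_tab <- miss_tab |>
      dplyr::mutate(
        # template position of the substituted base; for the reverse
        # primer the 3' end maps onto the *start* of the embedded rc site
        template_pos = dplyr::case_when(
          .data$component == "forward" ~ fwd$ref_end - .data$offset3,
          .data$component == "reverse" ~ rev$ref_start + .data$offset3,
          TRUE ~ prb$ref_end - .data$offset3
        ),
        # IUPAC class of the embedded (sense-strand) pattern at that spot
        class = dplyr::case_when(
          .data$component == "forward" ~
            substr(fwd$sequence, nchar(fwd$sequence) - .data$offset3,
                   nchar(fwd$sequence) - .data$offset3),
          .data$component == "reverse" ~
            substr(rc_rev, .data$offset3 + 1L, .data$offset3 + 1L),
          TRUE ~ substr(prb$sequence, nchar(prb$sequence) - .data$offset3,
                        nchar(prb$sequence) - .data$offset3)
        ),
        # a primer mismatch at 3' offset >= 8 spares the relaxed 8-mer
        breaks_relaxed = .data$component == "probe" | .data$offset3 < 8L
      )
  }

  .with_seed(spec$seed, {
    taxa <- tidyr::expand_grid(
      phylum = sprintf("P%02d", seq_len(spec$n_phyla)),
      genus = sprintf("G%02d", seq_len(spec$genera_per_phylum)),
      species = sprintf("s%02d", seq_len(spec$species_per_genus)),
      rep = seq_len(spec$seqs_per_species)
    )
    n_rec <- nrow(taxa)
    taxa$seq_id <- sprintf("SEQ%05d", seq_len(n_rec))

    # which records are eligible (span contains the amplicon)
    n_elig <- round_half_up(spec$span_coverage_fraction * n_rec)
    eligible <- rep(FALSE, n_rec)
    if (n_elig > 0) eligible[sample.int(n_rec, n_elig)] <- TRUE

    template <- sample(bases, spec$template_length, replace = TRUE)

    build_one <- function(i) {
      chars <- template
      # fresh random expansion of each site per record
      plant <- function(site_seq, start) {
        v <- strsplit(sample(expand_degenerate(site_seq), 1), "")[[1]]
        chars[start:(start + length(v) - 1L)] <<- v
      }
      plant(fwd$sequence, fwd$ref_start)
      plant(prb$sequence, prb$ref_start)
      plant(rc_rev, rev$ref_start)

      # planted mismatches for this record's taxa
      rec_otus <- c(
        taxa$phylum[i],
        paste(taxa$phylum[i], taxa$genus[i], sep = "|"),
        paste(taxa$phylum[i], taxa$genus[i], taxa$species[i], sep = "|")
      )
      hit_strict <- TRUE
      hit_relax <- TRUE
      if (!is.null(miss_tab) && nrow(miss_tab) > 0) {
        mine <- miss_tab[miss_tab$otu %in% rec_otus, , drop = FALSE]
        for (m in seq_len(nrow(mine))) {
          cls <- strsplit(iupac_codes[[mine$class[m]]], "")[[1]]
          choices <- setdiff(bases, cls)
          chars[mine$template_pos[m]] <- sample(choices, 1)
          hit_strict <- FALSE
          if (mine$breaks_relaxed[m]) hit_relax <- FALSE
        }
      }

      if (eligible[i]) {
        ref_start <- 1L
        ref_end <- spec$template_length
      } else {
        # start inside the amplicon so containment fails
        ref_start <- span$ref_start +
          sample.int(span$ref_end - span$ref_start - 1L, 1)
        ref_end <- spec$template_length
        chars <- chars[ref_start:ref_end]
      }
      chars <- .repair_sequence(chars, patterns, footprints,
                                offset = ref_start - 1L)
      list(
        sequence = paste(chars, collapse = ""),
        ref_start = ref_start, ref_end = ref_end,
        stringent = hit_strict, relaxed = hit_relax
      )
    }

    built <- purrr::map(seq_len(n_rec), build_one)
    records <- taxa |>
      dplyr::transmute(
        seq_id = .data$seq_id, phylum = .data$phylum, genus = .data$genus,
        species = .data$species,
        sequence = purrr::map_chr(built, "sequence"),
        ref_start = purrr::map_int(built, ~ as.integer(.x$ref_start)),
        ref_end = purrr::map_int(built, ~ as.integer(.x$ref_end))
      ) |>
      dplyr::arrange(.data$seq_id)

    truth_per_record <- taxa |>
      dplyr::transmute(
        seq_id = .data$seq_id,
        eligible = eligible,
        stringent = purrr::map_lgl(built, "stringent"),
        relaxed = purrr::map_lgl(built, "relaxed")
      ) |>
      dplyr::arrange(.data$seq_id)

    # truth coverage computed with its own (simple) dereplication, kept
    # independent of the coverage module's implementation
    elig_taxa <- taxa[truth_per_record$eligible[match(taxa$seq_id,
                                                      truth_per_record$seq_id)], ]
    truth_coverage <- purrr::map_dfr(c("stringent", "relaxed"), function(cr) {
      matched <- truth_per_record$seq_id[truth_per_record$eligible &
                                           truth_per_record[[cr]]]
      purrr::map_dfr(.coverage_levels, function(level) {
        labels <- switch(level,
          all_sequences = elig_taxa$seq_id,
          species = paste(elig_taxa$phylum, elig_taxa$genus,
                          elig_taxa$species, sep = "|"),
          genus = paste(elig_taxa$phylum, elig_taxa$genus, sep = "|"),
          phylum = elig_taxa$phylum
        )
        covered_otus <- unique(labels[elig_taxa$seq_id %in% matched])
        all_otus <- unique(labels)
        tibble::tibble(
          criterion = cr, level = level,
          numerator = length(covered_otus), denominator = length(all_otus),
          percent = 100 * length(covered_otus) / length(all_otus)
        )
      })
    }) |>
      dplyr::mutate(level = factor(.data$level, levels = .coverage_levels))

    list(records = records, truth_per_record = truth_per_record,
         truth_coverage = truth_coverage)
  })
}

# -------------------------------------------------------------------- plate

#' Specification of a simulated qPCR validation plate
#'
#' Emulates the multi-run validation design: `n_runs` independent runs,
#' each with `curves_per_run` in-run standard curves, each curve a
#' dilution series over `decades` measured in `replicates` wells. Ct
#' values follow `intercept + slope * log10(copies) + N(0, ct_noise_sd)`
#' with `slope = -1 / log10(1 + true_efficiency)`.
#'
#' @param true_efficiency Reaction efficiency as a fraction (1 = perfect
#'   doubling; default 0.95).
#' @param intercept Ct at 1 copy per reaction (default 38).
#' @param decades Known copies per reaction of the dilution series
#'   (default `10^(2:8)`).
#' @param n_runs,curves_per_run,replicates Plate design (defaults 3, 3, 3).
#' @param ct_noise_sd SD of Gaussian Ct noise in cycles (default 0.1).
#' @param seed Integer RNG seed (`NULL` = use the current RNG state).
#' @return A list of class `plate_spec`.
#' @export
plate_spec <- function(true_efficiency = 0.95, intercept = 38,
                       decades = 10^(2:8), n_runs = 3, curves_per_run = 3,
                       replicates = 3, ct_noise_sd = 0.1, seed = NULL) {
  if (any(decades <= 0)) rlang::abort("`decades` must be positive")
  if (ct_noise_sd < 0) rlang::abort("`ct_noise_sd` must be >= 0")
  if (true_efficiency <= 0) rlang::abort("`true_efficiency` must be > 0")
  structure(
    list(
      true_efficiency = true_efficiency, intercept = intercept,
      decades = decades, n_runs = n_runs, curves_per_run = curves_per_run,
      replicates = replicates, ct_noise_sd = ct_noise_sd, seed = seed
    ),
    class = "plate_spec"
  )
}

#' Simulate a qPCR validation plate with known truth
#'
#' @param spec A [plate_spec()].
#' @return A list: `plate` (tibble: `run_id`, `curve_id`, `well`,
#'   `known_copies`, `ct`) and `truth` (list with the generating `slope`,
#'   `intercept`, `efficiency`, `ct_noise_sd`).
#' @export
make_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  slope <- -1 / log10(1 + spec$true_efficiency)
  .with_seed(spec$seed, {
    plate <- tidyr::expand_grid(
      run_id = sprintf("run%d", seq_len(spec$n_runs)),
      curve_id = sprintf("curve%d", seq_len(spec$curves_per_run)),
      known_copies = spec$decades,
      replicate = seq_len(spec$replicates)
    ) |>
      dplyr::mutate(
        well = sprintf("%s_%s_c%g_r%d", .data$run_id, .data$curve_id,
                       log10(.data$known_copies), .data$replicate),
        ct = spec$intercept + slope * log10(.data$known_copies) +
          stats::rnorm(dplyr::n(), 0, spec$ct_noise_sd)
      ) |>
      dplyr::select("run_id", "curve_id", "well", "known_copies", "ct")
    list(
      plate = plate,
      truth = list(slope = slope, intercept = spec$intercept,
                   efficiency = spec$true_efficiency,
                   ct_noise_sd = spec$ct_noise_sd)
    )
  })
}
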