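# Per-column alignment profiling: counting, diversity, gap filtering,
# conserved-region calling and reference coordinate mapping.

test_that("column counting classifies bases, gaps and ambiguity characters", {
  aln <- c(r = "AAC-", s1 = "AAC-", s2 = "ACN-", s3 = "A--T")
  prof <- build_profile(aln, reference_id = "r")

  expect_equal(nrow(prof), 4L)
  expect_equal(attr(prof, "n_sequences"), 4L)
  # every column's counts sum to the number of sequences
  expect_true(all(prof$A + prof$C + prof$G + prof$T +
                    prof$other + prof$gap == 4L))

  # col 0: all A
  expect_equal(prof$A[1], 4L)
  expect_equal(prof$diversity[1], 0)
  expect_equal(prof$majority_base[1], "A")

  # col 1: {A, A, C, -} -> gap 0.25, freqs A 2/3, C 1/3
  expect_equal(prof$gap_fraction[2], 0.25)
  expect_equal(prof$diversity[2], 1 - ((2 / 3)^2 + (1 / 3)^2))

  # col 2: N is "other", excluded from allele frequencies
  expect_equal(prof$other[3], 1L)
  expect_equal(prof$diversity[3], 0) # remaining alleles all C

  # col 3: one T among gaps -> diversity 0; all-gap handling via ref map
  expect_equal(prof$gap[4], 3L)
})

test_that("parsing is case-insensitive and '.' is a gap", {
  aln <- c(r = "acg.", s = "ACG-")
  prof <- build_profile(aln, reference_id = "r")
  expect_equal(prof$A[1], 2L)
  expect_equal(prof$gap[4], 2L)
  expect_true(is.na(prof$diversity[4]))
})

test_that("build_profile rejects ragged alignments and unknown references", {
  expect_error(build_profile(c(a = "AC", b = "ACG"), "a"), "equal length")
  expect_error(build_profile(c(a = "AC", b = "AC"), "zz"), "not found")
})

test_that("simpson_diversity matches hand-computed values and validates input", {
  expect_equal(simpson_diversity(c(A = 1)), 0)
  expect_equal(simpson_diversity(c(A = .25, C = .25, G = .25, T = .25)), 0.75)
  expect_equal(simpson_diversity(c(A = 0.6, C = 0.4)), 0.48)
  expect_equal(simpson_diversity(c(A = 0.6, C = 0.4), complement = FALSE), 0.52)
  expect_error(simpson_diversity(c(A = 0.6, C = 0.5)), "sum to 1")
})

test_that("planted biallelic and gappy columns reproduce exact truth", {
  spec <- alignment_spec(
    n_sequences = 10,
    blocks = tibble::tibble(
      length = c(20, 1, 5, 10),
      kind = c("conserved", "biallelic", "gappy", "random"),
      param = c(NA, 0.6, 0.25, NA)
    ),
    seed = 42
  )
  al <- make_alignment(spec)
  prof <- build_profile(al$alignment, "reference")

  # planted 60/40 column scores exactly 1 - (0.36 + 0.16)
  expect_equal(prof$diversity[21], 0.48)
  expect_equal(al$truth$expected_diversity[21], 0.48)
  # exact-count planting: profile reproduces the whole truth table
  nonrandom <- al$truth$kind != "random"
  expect_equal(prof$diversity[nonrandom],
               al$truth$expected_diversity[nonrandom])
  expect_equal(prof$gap_fraction, al$truth$expected_gap_fraction)
})

test_that("gap filter retains exactly the columns at or below threshold", {
  spec <- alignment_spec(
    n_sequences = 50,
    blocks = tibble::tibble(
      length = c(95, 5),
      kind = c("random", "gappy"),
      param = c(NA, 0.5)
    ),
    seed = 7
  )
  al <- make_alignment(spec)
  prof <- build_profile(al$alignment, "reference")

  retained <- gap_filter(prof, 0.03)
  expect_identical(retained, 0:94) # the 5 gappy columns are removed
  # monotone: raising the threshold never drops a retained column
  for (thr in c(0.05, 0.2, 0.6, 1)) {
    expect_true(all(retained %in% gap_filter(prof, thr)))
  }
  expect_identical(gap_filter(prof, 1), 0:99)
  expect_error(gap_filter(prof, 1.5), "\\[0, 1\\]")
})

test_that("conserved-region calling recovers a planted conserved block", {
  spec <- alignment_spec(
    n_sequences = 20,
    blocks = tibble::tibble(
      length = c(40, 500, 40),
      kind = c("random", "conserved", "random"),
      param = NA
    ),
    seed = 3
  )
  al <- make_alignment(spec)
  prof <- build_profile(al$alignment, "reference")
  regions <- find_conserved_regions(prof, window_ungapped_length = 500,
                                    diversity_ceiling = 0.1)
  expect_equal(nrow(regions), 1L)
  expect_equal(regions$start_column, 40L)
  expect_equal(regions$end_column, 539L)
  expect_equal(regions$length_ungapped, 500L)
  expect_lte(regions$max_diversity, 0.1)

  # every reported region passes all three criteria on re-check
  cols <- regions$start_column:regions$end_column
  sub <- prof[prof$column %in% cols, ]
  expect_true(all(sub$gap_fraction <= 0.03))
  expect_true(all(sub$diversity <= 0.1))

  # a fully conserved gap-free alignment yields one region spanning it all
  spec2 <- alignment_spec(5, tibble::tibble(length = 600, kind = "conserved",
                                            param = NA), seed = 1)
  prof2 <- build_profile(make_alignment(spec2)$alignment, "reference")
  r2 <- find_conserved_regions(prof2, 500)
  expect_equal(c(r2$start_column, r2$end_column), c(0L, 599L))

  # alternating conserved/variable columns with a zero ceiling: no region
  alt <- c(r = paste(rep("AC", 10), collapse = ""),
           s = paste(rep("AG", 10), collapse = ""),
           t = paste(rep("AT", 10), collapse = ""))
  prof3 <- build_profile(alt, "r")
  expect_equal(nrow(find_conserved_regions(prof3, 2, diversity_ceiling = 0)), 0L)
})

test_that("alignment columns map to reference coordinates through gaps", {
  # reference has a gap at column 5 (0-based): columns after it shift back
  aln <- c(ref = "ACGTA-CGTACGT", s1 = "ACGTAACGTACGT")
  prof <- build_profile(aln, "ref")
  expect_equal(unname(map_to_reference(prof, 10, 12)), c(10L, 12L))
  expect_equal(unname(map_to_reference(prof, 6, 6)), c(6L, 6L))
  # 0-based to 1-based shift on a gapless reference
  aln2 <- c(ref = "ACGTACGTACGTACGTACGTACGTA", s1 = "ACGTACGTACGTACGTACGTACGTA")
  prof2 <- build_profile(aln2, "ref")
  expect_equal(unname(map_to_reference(prof2, 10, 20)), c(11L, 21L))
  # span with no mapped column errors
  expect_error(map_to_reference(prof, 5, 5), "no reference-mapped")
  # mapped length equals the ungapped reference length
  full <- map_to_reference(prof, 0, nrow(prof) - 1)
  expect_equal(unname(full["ref_end"]), 12L)
})

test_that("map_to_reference round-trips a conserved region", {
  spec <- alignment_spec(
    n_sequences = 12,
    blocks = tibble::tibble(length = c(30, 100, 30),
                            kind = c("random", "conserved", "random"),
                            param = NA),
    seed = 11
  )
  prof <- build_profile(make_alignment(spec)$alignment, "reference")
  reg <- find_conserved_regions(prof, 100)
  coords <- map_to_reference(prof, reg$start_column, reg$end_column)
  # locate the mapped span back in the alignment: it must contain the
  # original mapped columns
  back <- prof[!is.na(prof$ref_pos) &
                 prof$ref_pos >= coords["ref_start"] &
                 prof$ref_pos <= coords["ref_end"], ]
  expect_true(min(back$column) >= reg$start_column)
  expect_true(max(back$column) <= reg$end_column)
  expect_equal(nrow(back), reg$length_ungapped)
})

test_that("profile TSV and FASTA round-trip through files", {
  spec <- alignment_spec(5, tibble::tibble(length = 30, kind = "random",
                                           param = NA), seed = 2)
  al <- make_alignment(spec)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(al$alignment, fa)
  expect_identical(read_alignment(fa), al$alignment)

  prof <- build_profile(al$alignment, "reference")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$gap_fraction, prof$gap_fraction)
  expect_equal(back$diversity, prof$diversity)
})
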