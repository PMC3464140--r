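# In silico coverage pipeline: eligibility, IUPAC perfect-match testing
# under both criteria, stepwise dereplicated coverage and assay comparison.

test_that("eligibility requires full amplicon containment", {
  assay <- pan_bacterial_assay()
  records <- tibble::tibble(
    seq_id = c("a", "b", "c", "d"),
    phylum = "P", genus = "G", species = "s",
    sequence = strrep("A", 20),
    ref_start = c(1L, 500L, 341L, NA),
    ref_end = c(1500L, 1500L, 806L, 1500L)
  )
  elig <- filter_eligible(records, assay)
  expect_identical(elig$seq_id, c("a", "c")) # exact span boundary included
  expect_equal(attr(elig, "n_missing_span"), 1L)

  # partial-overlap mode keeps the record starting inside the amplicon
  part <- filter_eligible(records, assay, partial = TRUE)
  expect_identical(part$seq_id, c("a", "b", "c"))
})

test_that("iupac_match applies the perfect-match rule position-wise", {
  expect_true(iupac_match("CAGCAGCCGCGGTA", "CAGCAGCCGCGGTA"))
  # D = A/G/T, not C
  expect_false(iupac_match("D", "C"))
  expect_true(all(vapply(c("A", "G", "T"), iupac_match,
                         pattern = "D", logical(1))))
  # ambiguity in the target is never a match, even N vs N
  expect_false(iupac_match("ACGT", "ACGN"))
  expect_false(iupac_match("ACGN", "ACGN"))
  expect_error(iupac_match("ACG", "AC"), "equal length")
})

test_that("component hits honour criterion, orientation and mismatch position", {
  assay <- pan_bacterial_assay()
  fwd <- assay$forward
  rev <- assay$reverse
  flank <- function(core) paste0(strrep("T", 30), core, strrep("T", 30))

  # exact forward expansion: hit under both criteria
  hit <- flank("CCTACGGGAGGCAGCA")
  expect_true(component_hit(hit, fwd, "stringent"))
  expect_true(component_hit(hit, fwd, "relaxed"))

  # mismatch at the primer 5' end (outside the 3' 8-mer):
  # stringent fails, relaxed still matches
  five_prime_miss <- flank("GCTACGGGAGGCAGCA")
  expect_false(component_hit(five_prime_miss, fwd, "stringent"))
  expect_true(component_hit(five_prime_miss, fwd, "relaxed"))

  # mismatch inside the 3' 8-mer: both fail
  three_prime_miss <- flank("CCTACGGGAGGCAGGA")
  expect_false(component_hit(three_prime_miss, fwd, "stringent"))
  expect_false(component_hit(three_prime_miss, fwd, "relaxed"))

  # reverse primer is found as its reverse complement on the sense strand
  rc_site <- flank(revcomp_iupac("GGACTACCAGGGTATCTAATC"))
  expect_true(component_hit(rc_site, rev, "stringent"))
  expect_false(component_hit(flank("GGACTACCAGGGTATCTAATC"), rev, "stringent"))

  # an N inside the target site defeats matching
  n_site <- flank("CCTACGGGAGGCNGCA")
  expect_false(component_hit(n_site, fwd, "stringent"))

  expect_error(
    component_hit("ACGTACGT", oligo("short", "ACGTACG", "forward_primer"),
                  "relaxed"),
    "at least 8"
  )
})

test_that("assay_match is the conjunction of the three component hits", {
  assay <- pan_bacterial_assay()
  coll <- make_collection(
    collection_spec(n_phyla = 2, genera_per_phylum = 1, species_per_genus = 1,
                    seqs_per_species = 1,
                    planted_miss = tibble::tibble(
                      otu = "P02", component = "probe", offset3 = 5L
                    ),
                    seed = 5),
    assay
  )
  m <- assay_match(coll$records, assay, "stringent")
  expect_identical(m$assay_match, m$forward_hit & m$reverse_hit & m$probe_hit)
  rec1 <- m[m$seq_id == coll$records$seq_id[1], ]
  expect_true(rec1$assay_match)
  rec2 <- m[m$seq_id == coll$records$seq_id[2], ]
  expect_true(rec2$forward_hit && rec2$reverse_hit)
  expect_false(rec2$probe_hit)
  expect_false(rec2$assay_match)
})

test_that("matching agrees with the brute-force expansion oracle", {
  withr::with_seed(2024, {
    bases <- c("A", "C", "G", "T")
    codes <- names(quantbac::iupac_codes)
    for (i in 1:300) {
      plen <- sample(4:10, 1)
      # mostly plain bases with a couple of degeneracies
      pat <- paste(
        ifelse(stats::runif(plen) < 0.25, sample(codes, plen, replace = TRUE),
               sample(bases, plen, replace = TRUE)),
        collapse = ""
      )
      win <- paste(
        ifelse(stats::runif(plen) < 0.05, "N",
               sample(bases, plen, replace = TRUE)),
        collapse = ""
      )
      expect_identical(iupac_match(pat, win), oracle_window_match(pat, win),
                       info = paste(pat, win))
    }

    # scanning oracle: any expansion as exact substring
    oli <- oligo("probe-like", "CAGCWGCCGYGGTA", "probe")
    for (i in 1:200) {
      target <- random_acgt(60)
      expect_identical(
        unname(component_hit(target, oli, "stringent")),
        oracle_contains(target, oli$sequence),
        info = target
      )
    }
  })
})

test_that("stepwise numerical coverage dereplicates and counts per level", {
  assay <- pan_bacterial_assay()
  # 3 species across 2 genera / 1 phylum; sequences of 2 species match
  coll <- make_collection(
    collection_spec(
      n_phyla = 1, genera_per_phylum = 1, species_per_genus = 3,
      seqs_per_species = 2,
      planted_miss = tibble::tibble(
        otu = "P01|G01|s03", component = "probe", offset3 = 6L
      ),
      seed = 9
    ),
    assay
  )
  cov <- numerical_coverage(coll$records, assay, "stringent")
  sp <- cov[cov$level == "species", ]
  expect_equal(sp$numerator, 2L)
  expect_equal(sp$denominator, 3L)
  expect_equal(sp$percent, 100 * 2 / 3)
  # at-least-one rule: the genus is still covered
  gen <- cov[cov$level == "genus", ]
  expect_equal(gen$numerator, 1L)
  expect_equal(gen$denominator, 1L)
  expect_equal(cov$numerator[cov$level == "all_sequences"], 4L)
})

test_that("phylum level excludes ambiguous phyla but keeps unclassified genera", {
  assay <- pan_bacterial_assay()
  coll <- make_collection(
    collection_spec(n_phyla = 3, genera_per_phylum = 1, species_per_genus = 1,
                    seqs_per_species = 1, seed = 13),
    assay
  )
  records <- coll$records
  records$phylum[2] <- "Bacteria Insertia Sedis"
  records$phylum[3] <- "unclassified bacteria" # case-insensitive
  records$genus[1] <- "unclassified_Genus"

  cov <- numerical_coverage(records, assay, "stringent")
  ph <- cov[cov$level == "phylum", ]
  expect_equal(ph$denominator, 1L) # only P01 remains
  expect_equal(ph$numerator, 1L)
  # genus level keeps everything, including "unclassified" labels
  expect_equal(cov$denominator[cov$level == "genus"], 3L)

  tax <- taxonomic_coverage(records, assay, "stringent")
  expect_true("P01|unclassified_Genus" %in% tax$otu[tax$level == "genus"])
  expect_false(any(grepl("Insertia", tax$otu[tax$level == "phylum"])))
})

test_that("covered and uncovered OTUs partition every level", {
  assay <- pan_bacterial_assay()
  coll <- make_collection(
    collection_spec(n_phyla = 4, planted_miss = tibble::tibble(
      otu = c("P02", "P03|G01"), component = c("probe", "forward"),
      offset3 = c(7L, 3L)
    ), seed = 21),
    assay
  )
  elig <- filter_eligible(coll$records, assay)
  tax <- taxonomic_coverage(elig, assay, "stringent")
  cov <- numerical_coverage(elig, assay, "stringent")
  for (lv in levels(cov$level)) {
    sub <- tax[tax$level == lv, ]
    expect_equal(nrow(sub), cov$denominator[cov$level == lv])
    expect_equal(sum(sub$covered), cov$numerator[cov$level == lv])
    expect_false(any(duplicated(sub$otu)))
  }
  # the planted uncovered genus appears exactly once in the uncovered list
  unc_gen <- tax$otu[tax$level == "genus" & !tax$covered]
  expect_equal(sum(unc_gen == "P03|G01"), 1L)
})

test_that("hierarchy is consistent: covered species imply covered genus and phylum", {
  assay <- pan_bacterial_assay()
  coll <- make_collection(
    collection_spec(n_phyla = 5, planted_miss = default_planted_miss()[4:6, ],
                    seed = 31),
    assay
  )
  elig <- filter_eligible(coll$records, assay)
  tax <- taxonomic_coverage(elig, assay, "stringent")
  sp <- tax[tax$level == "species" & tax$covered, ]
  gen_cov <- tax$otu[tax$level == "genus" & tax$covered]
  ph_cov <- tax$otu[tax$level == "phylum" & tax$covered]
  sp_parts <- strsplit(sp$otu, "|", fixed = TRUE)
  expect_true(all(vapply(sp_parts, function(p) {
    paste(p[1], p[2], sep = "|") %in% gen_cov && p[1] %in% ph_cov
  }, logical(1))))
})

test_that("reports are deterministic under input reordering", {
  assay <- pan_bacterial_assay()
  coll <- make_collection(collection_spec(n_phyla = 3, seed = 17), assay)
  elig <- filter_eligible(coll$records, assay)
  shuffled <- elig[rev(seq_len(nrow(elig))), ]
  expect_equal(numerical_coverage(elig, assay, "relaxed"),
               numerical_coverage(shuffled, assay, "relaxed"))
  expect_equal(taxonomic_coverage(elig, assay, "relaxed"),
               taxonomic_coverage(shuffled, assay, "relaxed"))
})

test_that("assay comparison reports per-level improvement and phylum flags", {
  assay <- pan_bacterial_assay()
  coll <- make_collection(collection_spec(n_phyla = 3, seed = 23), assay)

  # identical assays: improvement 0 everywhere
  cmp_same <- compare_assays(coll$records, assay, assay, "stringent")
  expect_true(all(cmp_same$improvement$improvement == 0))

  # assay B = assay A with a probe that mismatches every record
  bad_probe <- assay_definition(
    "bad_probe",
    forward = assay$forward, reverse = assay$reverse,
    probe = oligo("p", revcomp_iupac("CAGCAGCCGCGGTA"), "probe", 519L, 532L)
  )
  cmp <- compare_assays(coll$records, assay, bad_probe, "stringent")
  expect_true(all(cmp$improvement$improvement >= 0))
  annB <- cmp$phylum_annotations[
    cmp$phylum_annotations$assay == "bad_probe", ]
  expect_true(all(annB$not_covered))
  annA <- cmp$phylum_annotations[
    cmp$phylum_annotations$assay == assay$assay_name, ]
  expect_false(any(annA$not_covered))
})

test_that("poorly covered phyla (>50% genera uncovered) are flagged", {
  assay <- pan_bacterial_assay()
  # P01 has 3 genera; break 2 of them -> 2/3 > 50% uncovered
  coll <- make_collection(
    collection_spec(
      n_phyla = 2, genera_per_phylum = 3, species_per_genus = 1,
      seqs_per_species = 1,
      planted_miss = tibble::tibble(
        otu = c("P01|G01", "P01|G02"), component = "probe",
        offset3 = c(7L, 7L)
      ),
      seed = 29
    ),
    assay
  )
  cmp <- compare_assays(coll$records, assay, example_comparison_assay(),
                        "stringent")
  ann <- cmp$phylum_annotations[cmp$phylum_annotations$assay ==
                                  assay$assay_name, ]
  expect_true(ann$poorly_covered[ann$phylum == "P01"])
  expect_false(ann$not_covered[ann$phylum == "P01"]) # still covered
  expect_false(ann$poorly_covered[ann$phylum == "P02"])
})

test_that("collections round-trip through FASTA + taxonomy TSV", {
  coll <- make_collection(collection_spec(n_phyla = 2, seed = 37))
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_collection(coll$records, fa, tsv)
  back <- read_collection(fa, tsv)
  expect_equal(as.data.frame(back), as.data.frame(coll$records))
})
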