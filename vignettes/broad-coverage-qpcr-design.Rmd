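---
title: "Designing and validating broad-coverage 16S rRNA gene qPCR assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating broad-coverage 16S rRNA gene qPCR assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantbac)
library(dplyr)
```

`quantbac` covers the computational side of building a pan-bacterial 16S
rRNA gene TaqMan qPCR assay: finding conserved primer/probe sites in a
large alignment, enforcing degeneracy rules and computing melting
temperatures, estimating taxonomic coverage in silico, and the arithmetic
of quantitative validation. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices we made where
the methodology left them open.

## 1. Profiling an alignment for conserved sites

A universal assay is designed from a multiple sequence alignment of
diverse 16S genes. `build_profile()` reduces the alignment to one row per
column:

* **counts** of A, C, G, T, gap (`-` or `.`) and "other" — any IUPAC
  ambiguity character in a target row. Ambiguity characters are *not*
  credited to an allele: downstream, coverage analysis treats target-side
  ambiguity as unmatchable, so design statistics should not pretend an N
  supports any particular base.
* **allele frequencies** over the plain A/C/G/T calls only. Gaps are not
  in the denominator: a column that is half gaps but all-A in the
  remaining rows is perfectly conserved *where sequence exists*, and the
  gap filter (below) separately decides whether it is usable at all.
* **diversity**: the Simpson complement `1 − Σ pᵢ²` of those frequencies.
  0 means one allele; 0.75 is the four-allele uniform maximum. The raw
  `Σ pᵢ²` form is available via `simpson_diversity(..., complement =
  FALSE)` for readers who prefer a "dominance" orientation.
* a **degenerate consensus** (`majority_base`): the IUPAC code covering
  every allele with frequency at least `include_threshold` (default 5%).
  This mirrors how degenerate bases are incorporated in practice: common
  variants earn a degenerate position, rare ones do not.

The **gap filter** (default threshold 3%) masks columns whose gap fraction
exceeds the threshold from design consideration. Masked columns stay in
the profile with `retained = FALSE`; they are simply ineligible as
primer/probe real estate, because a column that is an indel in a
non-trivial fraction of taxa cannot anchor a universal oligo.

`find_conserved_regions()` then reports maximal runs of consecutive
columns that pass the gap filter and a diversity ceiling (default 0.1),
keeping runs whose *reference-mapped* length reaches the requested window
(e.g. 500 bp). Lengths are counted in reference positions rather than
alignment columns because alignments of large collections are gap-rich;
a 500-column run full of reference gaps is not a 500 bp region.
`map_to_reference()` converts any column span to 1-based coordinates of a
chosen reference row (conventionally *E. coli* numbering), using the
nearest mapped columns inside the span.

Open parameters, and why these defaults: the gap threshold (0.03) is the
standard design-tool setting; the diversity ceiling (0.1) admits columns
with a minor allele up to ~5%, which is the same populations the 5%
consensus threshold would fold into a degenerate base. Both are arguments,
not constants.

## 2. Assay representation and design rules

An assay is three oligos — forward primer, reverse primer, probe — each an
IUPAC string with optional 1-based inclusive reference coordinates. Two
rules gate a design (`validate_assay()`): each primer may carry at most
three degenerate bases, and the hydrolysis probe none. Degenerate probes
degrade the quantitative signal (each probe variant has its own
hybridization efficiency), which is why the probe site must be chosen from
the most conserved stretch available.

`tm_range()` reports the melting temperature of a degenerate oligo as the
min–max over its full expansion (`expand_degenerate()`), using the
salt-adjusted formula with two length regimes:

* N ≥ 14 nt: `Tm = 100.5 + 41·(nG+nC)/N − 820/N + 16.6·log10([Na+])`
* N < 14 nt: `Tm = 2·(nA+nT) + 4·(nG+nC) − 16.6·log10(0.050) +
  16.6·log10([Na+])`

with `[Na+] = 0.05` M by default (the convention of common online
calculators; exposed as `sodium_molar`). No frequency weighting is applied
across variants — a range is the honest summary when one primer is many
molecules. Results are rounded half-up to one decimal, the presentation
convention of assay tables; note that published tables produced by online
calculators can differ from the exact formula by up to ~0.1 °C, which is
why our own checks use a ±0.1 °C band. MGB-probe melting temperatures come
from proprietary vendor models and are deliberately out of scope: the
probe's Tm is user metadata, never computed.

The packaged `pan_bacterial_assay()` targets a 466 bp amplicon
(reference positions 341–806) bracketing V3–V4, with a degenerate forward
primer (341–356, 2 degeneracies, 6 variants), a degenerate reverse primer
(786–806, 3 degeneracies, 18 variants) and a 14 nt non-degenerate probe
(519–532). `example_comparison_assay()` is a *synthetic* non-degenerate
variant of the same sites, shipped only so the comparison pipeline has a
second, deliberately narrower assay to run against.

## 3. In silico coverage

Coverage asks: of the sequences in a large taxonomy-annotated 16S
collection, how many — and how many species, genera, phyla — contain a
perfect match for *all three* assay components?

**Eligibility.** Only sequences whose annotated reference span fully
contains the amplicon are analysed (`filter_eligible()`); a sequence that
stops inside the amplicon can never match the missing component, and
counting it would conflate database truncation with assay failure. A
partial-overlap mode exists behind a flag for exploratory use. Because
eligibility depends on the assay's coordinates, two assays being compared
have independently computed denominators.

**Perfect-match testing.** A component hits a record when some window of
the record equals the oligo under IUPAC semantics: the window character
must be a plain A/C/G/T inside the pattern's class. Ambiguity characters
in the *target* never match — a conservative rule that slightly
understates coverage rather than crediting unknown bases. Records are
assumed in the standard sense orientation (as database exports are), so
the forward primer and probe are matched as written and the reverse primer
as its reverse complement; matching scans the entire record rather than
only the annotated coordinate window, since position metadata is
approximate. Two criteria are supported: **stringent** (full-length
oligos) and **relaxed** (3′-terminal 8 nt of each primer, full-length
probe always) — the relaxed criterion reflects the biochemistry that
3′-end mismatches abort extension while 5′ mismatches often still amplify.
Stringent matches are provably a subset of relaxed matches.

**Union vs conjunction.** Descriptions of this style of analysis sometimes
write the three component conditions with a union symbol while the
surrounding text demands a match "for all three components". We implement
the conjunction — forward ∧ reverse ∧ probe — which is the only reading
under which a single molecule is actually detectable, and we do not offer
a disjunction flag.

**Stepwise dereplication.** Numerical coverage is computed first over all
eligible sequences (numerator = matched sequence IDs), then at the
species, genus and phylum levels after dereplicating on concatenated
taxonomic identifications (`Phylum|Genus|species`, `Phylum|Genus`,
`Phylum`; delimiter configurable). An OTU is covered when it contains at
least one matched sequence. At the phylum level the two ambiguous bins
("Bacteria Insertia Sedis", "Unclassified Bacteria", matched
case-insensitively) are removed from numerator and denominator; genus- and
species-level names containing "unclassified" are retained because they
are too abundant to discard. `taxonomic_coverage()` returns the
covered/uncovered OTU listings whose disjoint union is exactly the
dereplicated OTU set. `compare_assays()` adds per-level improvement deltas
and per-phylum annotations: *not covered* (no matched sequence in the
phylum) and *poorly covered* (more than 50% of the phylum's genera
uncovered).

## 4. Quantification arithmetic

**Plasmid-standard normalization.** Standards quantified by qPCR rather
than by mass avoid the error-prone ng→copies conversion. A stock measured
at crossing point Cp is brought onto a target scale (default Cp 10) with
the dilution factor `2^(10 − Cp)` — one cycle is one doubling.

**Standard curves.** `fit_standard_curve()` regresses Ct on
log₁₀(copies/reaction) by OLS (per-concentration means by default,
per-well behind a flag) and derives `efficiency = 10^(−1/slope) − 1`;
slope −3.3219 = −1/log₁₀2 is perfect doubling. Dilution series need at
least three concentrations; a non-negative slope is flagged, not an error.
The fit is a `standard_curve` object with `tidy()`, `glance()` and
`autoplot()` methods.

**Outlier rule.** Triplicates with Ct SD > 0.3 are inspected: if exactly
one replicate is more than 0.3 cycles from *both* others while those two
agree within 0.3, it is excluded; otherwise all are kept with a
`dispersed` flag. Note a +0.5-cycle deviation on two identical siblings
has SD ≈ 0.29 and does not trigger the rule — the threshold is on the
spread, not the outlier distance alone.

**Coefficients of variation.** For a multi-run validation design (3 runs
× 3 in-run curves × triplicates by default), `cov_report()` computes per
concentration: the **inter-run** CoV (SD/mean × 100 across all retained
wells of all curves of all runs) and the **intra-run** CoV (one CoV per
in-run curve across its replicate wells, then mean ± SD over the nine
curve-level values). Both are computed for Ct and for copy number; copies
are back-calculated per well from that well's own in-run fitted curve
(back-calculation is the only choice that yields a nonzero copy-number CoV
when the nominal input per well is fixed), or from a single supplied fit.

**Detection-limit ratios.** With the default constants — 3.94 16S copies
per average bacterial genome, 400 18S copies per human genome, and a
5,758 Mb diploid human genome at 978 Mb/pg ⇒ 5.887 pg — 5 ng of human
gDNA carries `5 × 1000 / 5.887 × 400 = 339,732` 18S copies (rounded
half-up). A detection limit of 500 16S copies against 5 ng is then the
simplified ribosomal ratio 1:679 and the genome-equivalent ratio 127:849.
We use the printed three-decimal 5.887 pg verbatim rather than the
higher-precision quotient, because the conventional integer results above
only reproduce with the rounded constant; all constants are overridable
through `quant_constants()`. Integer rounding is half-up throughout
(`round()`'s half-to-even would give the same values here, but half-up is
the convention such tables use). The package does **not** estimate a limit
of detection from data — reagent-borne bacterial DNA contamination makes a
pure-standard LOD ill-defined — it only converts user-supplied
dynamic-range bounds into ratios.

## 5. What the synthetic generators emulate

All inputs can be generated with exact ground truth, which is how the
package tests itself.

* `make_alignment()` emulates the block structure of a curated core-set
  alignment: conserved stretches, biallelic columns, uniformly random
  columns, and gap-rich columns. Allele and gap counts are planted
  *exactly* (`k = round(p·n)` rows carry the major allele) rather than
  sampled, so the truth table's expected diversity and gap fraction are
  exact, not asymptotic. A planted 60/40 column scores exactly
  `1 − (0.6² + 0.4²) = 0.48`.
* `make_collection()` builds a balanced taxonomy (default 34 phyla × 2
  genera × 2 species × 2 sequences) of records around a random template
  carrying per-record random expansions of the assay sites (the reverse
  primer site embedded as its reverse complement). Planted mismatches
  substitute a site base with one drawn from *outside* the pattern's IUPAC
  class at that position — a substitution inside a degenerate class would
  silently still match. A repair pass then removes accidental matches of
  any full site or relaxed 3′-8-mer elsewhere in each record, verified
  with a brute-force expansion scanner that is independent of the coverage
  module's matcher; without it, random flanks would contain a spurious
  8-mer hit in a few percent of records and the truth tables would not be
  exact. The default planted-mismatch set (`default_planted_miss()`)
  breaks the probe in three phyla — so the phylum report reads 31/34 =
  91.2%, echoing the shape of a database-scale analysis at desk scale —
  plus primer mismatches at 5′ (stringent-only) and 3′ (both criteria)
  positions.
* `make_plate()` simulates the validation design: Ct = intercept +
  slope·log₁₀(copies) + N(0, σ), slope = −1/log₁₀(1 + E). Defaults (E =
  0.95, σ = 0.1, 10²–10⁸ copies, 3 runs × 3 curves × triplicates) mirror a
  plasmid-standard validation experiment.

What they do **not** emulate: phylogenetically realistic sequence
evolution (taxa are independent mutations of one template), chimeras,
sequencing error, database misannotation, real taxonomic imbalance, or
qPCR artefacts beyond Gaussian Ct noise (no inhibition, no plateau
effects, no reagent contamination). Passing tests on synthetic collections
therefore demonstrates that the *pipeline arithmetic* is exact and the
match semantics correct — not that any particular assay achieves a given
coverage of real databases, which requires running the same pipeline on a
real export (formats: FASTA plus a `seq_id/phylum/genus/species/
ref_start/ref_end` TSV, via `read_collection()`).

## 6. Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive on the reference; alignment columns
  0-based. `amplicon_span()` length is `end − start + 1`.
* Tm and ratio rounding is half-up (one decimal / nearest integer).
* Matching is case-insensitive; `.` is accepted as a gap alongside `-`.
* An all-gap alignment column has undefined allele frequencies: its
  diversity is `NA` and it can never join a conserved region.
* Empty eligible sets raise errors rather than returning 0/0 reports.
* Reports are sorted (levels in stepwise order, OTUs lexicographically),
  so identical inputs give byte-identical outputs regardless of row order.
* Generator seeds: every generator takes a `seed` and is deterministic
  under it; `NULL` uses the ambient RNG state.

Problem sizes used in the package's own test suite — collections of a few
hundred records, 100-collection randomized property sweeps at 16 records
each, 189-well plates — were chosen as the smallest sizes at which every
planted structure (34 phyla, three uncovered; criterion splits; CoV
regimes) is exactly representable.

## 7. Known limitations

* Alignment profiling loads the alignment as a dense character matrix:
  fine for core-set-scale alignments (thousands of rows), not for
  millions.
* Coverage matching is exact-match only — no mismatch-tolerant or
  thermodynamic scoring; that is the definition of the method, but it is
  known to be conservative relative to laboratory amplification, where
  5′-mismatched targets often amplify fine.
* Reference spans are trusted input metadata; the package does not align
  records to a reference to infer them.
* No primer search/optimization: conserved-region output informs a human
  designer, it does not propose oligos.
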