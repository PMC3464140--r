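# IUPAC nucleotide code tables and degenerate-sequence primitives.
#
# These primitives underpin both assay design (degeneracy counting, full
# expansion for Tm ranges) and in silico coverage analysis (perfect-match
# testing of degenerate oligos against plain-ACGT targets).

#' IUPAC nucleotide classes
#'
#' Named character vector mapping each IUPAC nucleotide code to the set of
#' plain bases it denotes (as a collapsed string, e.g. `D = "AGT"`).
#'
#' @format A named character vector of length 15.
#' @export
iupac_codes <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# reverse lookup: sorted allele string -> degenerate code
.code_for_alleles <- stats::setNames(names(iupac_codes), iupac_codes)

.iupac_chars <- function(sequence) {
  strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
}

.check_iupac <- function(sequence, arg = "sequence") {
  chars <- .iupac_chars(sequence)
  bad <- setdiff(unique(chars), names(iupac_codes))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "`%s` contains non-IUPAC character(s): %s", arg,
      paste(bad, collapse = ", ")
    ))
  }
  chars
}

#' Degenerate code for a set of alleles
#'
#' Returns the single IUPAC character covering exactly the given set of
#' plain bases (e.g. `c("A", "G")` gives `"R"`).
#'
#' @param alleles Character vector of plain bases (subset of A/C/G/T).
#' @return A single IUPAC character, or `NA` if `alleles` is empty.
#' @export
iupac_code_for <- function(alleles) {
  alleles <- sort(unique(toupper(alleles)))
  if (length(alleles) == 0) {
    return(NA_character_)
  }
  if (!all(alleles %in% c("A", "C", "G", "T"))) {
    rlang::abort("`alleles` must be plain bases A/C/G/T")
  }
  unname(.code_for_alleles[paste(alleles, collapse = "")])
}

#' Count degenerate positions in an IUPAC sequence
#'
#' A position is degenerate when its IUPAC class contains more than one
#' base. Assay-design rules limit primers to at most three degeneracies and
#' forbid any in the hydrolysis probe (see [validate_assay()]).
#'
#' @param sequence IUPAC DNA string (or an [oligo()]).
#' @return Integer count of degenerate positions.
#' @examples
#' count_degeneracies("CCTACGGGDGGCWGCA") # 2
#' @export
count_degeneracies <- function(sequence) {
  if (inherits(sequence, "oligo")) sequence <- sequence$sequence
  chars <- .check_iupac(sequence)
  sum(nchar(iupac_codes[chars]) > 1L)
}

#' Expand a degenerate sequence into all plain-ACGT variants
#'
#' Cartesian product of the per-position IUPAC classes; the number of
#' variants is the product of class sizes.
#'
#' @param sequence IUPAC DNA string (or an [oligo()]).
#' @return Character vector of plain ACGT sequences (deterministic order).
#' @examples
#' expand_degenerate("AR") # "AA" "AG"
#' @export
expand_degenerate <- function(sequence) {
  if (inherits(sequence, "oligo")) sequence <- sequence$sequence
  chars <- .check_iupac(sequence)
  sets <- strsplit(iupac_codes[chars], "", fixed = TRUE)
  Reduce(
    function(acc, set) as.vector(t(outer(acc, set, paste0))),
    sets,
    accumulate = FALSE,
    init = ""
  )
}

#' Number of plain variants encoded by a degenerate sequence
#'
#' @inheritParams expand_degenerate
#' @return Integer: the product of per-position IUPAC class sizes.
#' @export
n_variants <- function(sequence) {
  if (inherits(sequence, "oligo")) sequence <- sequence$sequence
  chars <- .check_iupac(sequence)
  prod(nchar(iupac_codes[chars]))
}

#' Reverse complement of an IUPAC sequence
#'
#' Complements degenerate codes class-wise (R <-> Y, B <-> V, ...).
#'
#' @param sequence IUPAC DNA string.
#' @return Reverse-complemented IUPAC string.
#' @export
revcomp_iupac <- function(sequence) {
  .check_iupac(sequence)
  comp <- chartr(
    "ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
    toupper(sequence)
  )
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Position-wise IUPAC perfect match
#'
#' Tests whether a plain-sequence window perfectly matches a (possibly
#' degenerate) pattern of the same length. At every position the window
#' character must be a plain A/C/G/T contained in the pattern's IUPAC
#' class; any ambiguity character in the *window* (e.g. N) is unmatchable,
#' so target-side ambiguity never counts as a hit. This is the
#' perfect-match rule of the in silico coverage analysis.
#'
#' @param pattern IUPAC DNA string.
#' @param window Plain DNA string of the same length.
#' @return `TRUE` or `FALSE`.
#' @examples
#' iupac_match("AD", "AG") # TRUE: D covers A/G/T
#' iupac_match("AD", "AC") # FALSE
#' iupac_match("AN", "AN") # FALSE: N in the target is unmatchable
#' @export
iupac_match <- function(pattern, window) {
  pchars <- .check_iupac(pattern, "pattern")
  wchars <- .iupac_chars(window)
  if (length(pchars) != length(wchars)) {
    rlang::abort("`pattern` and `window` must have equal length")
  }
  classes <- iupac_codes[pchars]
  all(stringr::str_detect(classes, stringr::fixed(wchars)) &
        wchars %in% c("A", "C", "G", "T"))
}

# Regex character-class translation of an IUPAC pattern. The classes only
# ever contain ACGT, so ambiguity characters in the scanned target can
# never match -- the same semantics as iupac_match().
iupac_to_regex <- function(sequence) {
  chars <- .check_iupac(sequence)
  classes <- iupac_codes[chars]
  paste0(
    ifelse(nchar(classes) == 1L, classes, paste0("[", classes, "]")),
    collapse = ""
  )
}
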