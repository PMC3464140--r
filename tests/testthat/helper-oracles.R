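# Brute-force oracles and small fixture builders shared across tests.

# independent matcher: expand the degenerate pattern and look for any
# variant as an exact substring (reverse primers must be pre-reverse-
# complemented by the caller)
oracle_contains <- function(sequence, pattern) {
  any(vapply(
    expand_degenerate(pattern),
    function(v) grepl(v, sequence, fixed = TRUE),
    logical(1)
  ))
}

# position-wise oracle for iupac_match: set membership per position
oracle_window_match <- function(pattern, window) {
  p <- strsplit(pattern, "")[[1]]
  w <- strsplit(window, "")[[1]]
  all(mapply(function(pc, wc) {
    wc %in% strsplit(quantbac::iupac_codes[[pc]], "")[[1]] &&
      wc %in% c("A", "C", "G", "T")
  }, p, w))
}

random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
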