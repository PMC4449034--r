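# Small sequence helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T, case preserved as
#'   upper case).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

# Extract a 1-based closed subsequence from a single reference chromosome.
ref_slice <- function(reference, chrom, start, end) {
  seq <- reference[[chrom]]
  if (is.null(seq)) {
    abort(sprintf("chromosome '%s' not present in the reference", chrom))
  }
  if (start < 1L || end > nchar(seq)) {
    abort(sprintf(
      "requested slice %s:%d-%d lies outside the chromosome (length %d)",
      chrom, start, end, nchar(seq)
    ))
  }
  substr(seq, start, end)
}

# Replace a single base at `pos` in a sequence string.
seq_substitute <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

is_base <- function(x) x %in% DNA_BASES
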