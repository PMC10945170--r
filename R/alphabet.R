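#' IUPAC nucleotide ambiguity codes
#'
#' Named character vector mapping each IUPAC DNA code to the
#' alphabetically sorted set of unambiguous bases it denotes.
#'
#' @format named character vector of length 15.
#' @export
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# reverse lookup: sorted base-set string -> code
.CODE_FOR_SET <- local({
  x <- names(IUPAC_CODES)
  names(x) <- unname(IUPAC_CODES)
  x
})

.LH_ALPHABET_RE <- "^[ACGTRYSWKMBDHVN-]*$"

#' Count unambiguous bases in DNA strings
#'
#' Counts characters in `{A, C, G, T}`.  Ambiguity codes, `N` and the
#' gap character never count.  This is the primary key of the
#' representative-sequence selection rule.
#'
#' @param x character vector of IUPAC DNA strings.
#' @return integer vector of counts.
#' @examples
#' unambiguous_count("ACGTNN-R")  # 4
#' @export
unambiguous_count <- function(x) {
  nchar(gsub("[^ACGT]", "", toupper(x)))
}

# TRUE for strings drawn only from the IUPAC DNA alphabet plus gap '-'
.valid_residues <- function(x) grepl(.LH_ALPHABET_RE, toupper(x))

#' Collapse sequence copies into an IUPAC consensus
#'
#' Per alignment column the minimal IUPAC code covering the union of
#' base sets observed across copies is emitted.  Gaps are ignored in
#' the union unless the column is all-gap, in which case the consensus
#' keeps the gap.  Union rather than majority consensus preserves
#' every observed state.
#'
#' @param copies character vector of equal-length IUPAC DNA strings
#'   (at least one).
#' @return single consensus string of the common length.
#' @examples
#' collapse_consensus(c("ACGT", "ACGA"))  # "ACGW"
#' @export
collapse_consensus <- function(copies) {
  copies <- toupper(copies)
  if (length(copies) < 1L) stop("collapse_consensus: need at least one copy")
  if (!all(.valid_residues(copies)))
    stop("collapse_consensus: residues outside the IUPAC DNA alphabet")
  w <- unique(nchar(copies))
  if (length(w) != 1L)
    stop("collapse_consensus: copies differ in length (",
         paste(w, collapse = ", "), ")")
  if (length(copies) == 1L) return(copies)
  m <- matrix(unlist(strsplit(copies, "", fixed = TRUE), use.names = FALSE),
              nrow = length(copies), byrow = TRUE)
  out <- vapply(seq_len(ncol(m)), function(j) {
    ch <- unique(m[, j])
    ch <- ch[ch != "-"]
    if (length(ch) == 0L) return("-")
    bases <- sort(unique(unlist(strsplit(IUPAC_CODES[ch], "", fixed = TRUE),
                                use.names = FALSE)))
    unname(.CODE_FOR_SET[paste(bases, collapse = "")])
  }, character(1))
  paste(out, collapse = "")
}

# reverse complement preserving ambiguity codes and gaps
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
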