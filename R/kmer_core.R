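#' Encode a nucleotide k-mer as a packed 64-bit value
#'
#' Packs an ACGT string 2 bits per base (A=00, C=01, G=10, T=11) with the
#' first base in the most significant bit pair.  The result is returned as
#' a 16-digit lowercase hexadecimal string; lexicographic order on these
#' strings equals numeric order on the packed values.
#'
#' @param seq character vector of nucleotide strings, each of length `k`.
#' @param k k-mer length in bases (1--32); databases use 32.
#' @return character vector of 16-hex-digit encodings; `NA` where the input
#'   contains a non-ACGT character (ambiguity codes are skipped by callers)
#'   or has the wrong length.
#' @examples
#' encode_kmer(strrep("A", 32))  # "0000000000000000"
#' decode_kmer(encode_kmer("ACGT", k = 4), k = 4)
#' @export
encode_kmer <- function(seq, k = 32L) {
  kt_encode(as.character(seq), as.integer(k))
}

#' Decode a packed k-mer back to its nucleotide string
#'
#' Inverse of [encode_kmer()].
#'
#' @param kmer character vector of 16-hex-digit packed k-mers.
#' @inheritParams encode_kmer
#' @return character vector of ACGT strings of length `k`.
#' @export
decode_kmer <- function(kmer, k = 32L) {
  kt_decode(as.character(kmer), as.integer(k))
}

#' Reverse complement of a packed k-mer
#'
#' An involution: applying it twice returns the input.
#'
#' @inheritParams decode_kmer
#' @return character vector of packed reverse-complement k-mers.
#' @export
reverse_complement_kmer <- function(kmer, k = 32L) {
  kt_revcomp(as.character(kmer), as.integer(k))
}

#' Canonical (strand-independent) form of a packed k-mer
#'
#' Returns whichever of the k-mer and its reverse complement has the lower
#' 64-bit value, making downstream matching independent of strand.
#'
#' @inheritParams decode_kmer
#' @return character vector of packed canonical k-mers.
#' @export
canonical_kmer <- function(kmer, k = 32L) {
  kt_canonical(as.character(kmer), as.integer(k))
}

#' 64-bit FNV-1 hash
#'
#' The Fowler–Noll–Vo FNV-1 variant (multiply by the 64-bit FNV prime, then
#' XOR with the next byte), used to rank candidate k-mers within a window.
#' A packed k-mer is hashed over its 8 bytes in little-endian order.
#'
#' @param x a raw vector of bytes, or a character vector of 16-hex-digit
#'   packed k-mers (each hashed over its 8 little-endian bytes).
#' @return character vector of 16-hex-digit hash values.
#' @examples
#' fnv1_64(raw(0))  # the FNV-1 offset basis
#' @export
fnv1_64 <- function(x) {
  if (is.raw(x)) kt_fnv1_raw(x) else kt_fnv1_kmer(as.character(x))
}

#' Select the minimum-hash representative k-mer of one window
#'
#' Among all k-mers starting inside the window segment (and fully contained
#' in the sequence -- the final window keeps its right "wing" of k-1 bases
#' where available, truncated at the sequence end), each candidate is
#' canonicalized and FNV-1-hashed; the candidate with the minimal hash is
#' returned.  Candidates containing non-ACGT bases are skipped.  Ties on
#' the hash break to the smaller canonical value, then the leftmost start.
#'
#' @param sequence a single nucleotide string.
#' @param start 0-based offset of the window segment.
#' @param window segment length W in bases (candidate start positions).
#' @param k k-mer length (default 32).
#' @return one packed canonical k-mer, or `NA` when no valid candidate
#'   exists in the window.
#' @export
select_window_kmer <- function(sequence, start, window, k = 32L) {
  kt_window_min(as.character(sequence)[1], as.numeric(start),
                as.integer(window), as.integer(k))
}

#' Minimize a sequence: one representative k-mer per window
#'
#' Tiles the sequence with non-overlapping windows at offsets 0, W, 2W, ...
#' and applies [select_window_kmer()] to each.  Windows with no valid
#' candidate are dropped; duplicate k-mers across windows are retained
#' (deduplication happens when a taxon set is built).
#'
#' With `window = 1` every position contributes its canonical k-mer, i.e.
#' the complete non-redundant k-mer set of the sequence once deduplicated.
#'
#' @inheritParams select_window_kmer
#' @return character vector of packed canonical k-mers, at most
#'   `ceiling(nchar(sequence) / window)` long; empty when the sequence is
#'   shorter than `k`.
#' @export
minimize_sequence <- function(sequence, window, k = 32L) {
  kt_minimize(as.character(sequence)[1], as.integer(window), as.integer(k))
}
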