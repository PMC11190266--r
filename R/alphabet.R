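#' @keywords internal
"_PACKAGE"

#' @useDynLib evhdesign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

#' Amino-acid alphabets
#'
#' `aa_alphabet()` returns the ordered symbol set used throughout the package:
#' the 20 standard amino acids in alphabetical one-letter order, optionally
#' followed by the gap symbol `"-"`. Models are fit over the 21-state alphabet
#' (gap included); design proposals and mutation scans are restricted to the
#' 20 amino acids.
#'
#' @param gap include the gap symbol as the final state?
#' @return character vector of single-letter symbols.
#' @export
#' @examples
#' aa_alphabet()          # 21 states, gap last
#' aa_alphabet(gap = FALSE)
aa_alphabet <- function(gap = TRUE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (gap) c(aa, "-") else aa
}

GAP <- "-"
# ambiguous/non-standard residues collapsed to gap so q stays fixed
UNKNOWN_RESIDUES <- c("X", "B", "Z", "U", "O", "J", ".", "*")

#' Encode and decode sequences
#'
#' Sequences are handled internally as integer vectors indexing into an
#' ordered alphabet. Unknown residues (X, B, Z, U, O, ...) are mapped to the
#' gap state so the number of states stays fixed.
#'
#' @param seq a character string, or an already-encoded integer vector
#'   (returned unchanged after range checks).
#' @param alphabet ordered symbol vector, typically [aa_alphabet()].
#' @return `encode_seq()`: integer vector of 1-based state indices;
#'   `decode_seq()`: a single character string.
#' @export
encode_seq <- function(seq, alphabet = aa_alphabet()) {
  if (is.numeric(seq)) {
    seq <- as.integer(seq)
    if (any(seq < 1L | seq > length(alphabet)))
      stop("encoded sequence contains states outside the alphabet", call. = FALSE)
    return(seq)
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- toupper(strsplit(seq, "", fixed = TRUE)[[1]])
  chars[chars %in% UNKNOWN_RESIDUES] <- GAP
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("sequence contains symbols outside the alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  idx
}

#' @rdname encode_seq
#' @export
decode_seq <- function(seq, alphabet = aa_alphabet()) {
  paste(alphabet[seq], collapse = "")
}

# encode every row of an alignment into an n x L integer matrix
encode_rows <- function(rows, alphabet = aa_alphabet()) {
  m <- t(vapply(rows, encode_seq, integer(nchar(rows[[1]])),
                alphabet = alphabet, USE.NAMES = FALSE))
  storage.mode(m) <- "integer"
  m
}
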