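# The 20 standard residues in one-letter alphabetical order. This order
# fixes the component layout of every gram vector and matrix in the package.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity/rare letters that may appear in real FASTA but are outside the
# standard alphabet every encoder is defined over.
AA_NONSTANDARD <- c("B", "Z", "X", "U", "O", "J")

#' Reduced six-letter amino-acid alphabet
#'
#' Partition of the 20 standard residues into six physicochemical groups:
#' group 1 = D,E,N,Q (acidic/amide); group 2 = H,R,K (basic); group 3 = C;
#' group 4 = S,T,P,A,G (small); group 5 = M,I,L,V (aliphatic hydrophobic);
#' group 6 = F,Y,W (aromatic). Used to build the 36 reduced-alphabet
#' dipeptide grams.
#'
#' @return Named integer vector mapping each one-letter residue to its group
#'   index in 1..6.
#' @examples
#' six_letter_alphabet()[c("D", "K", "C", "A", "L", "W")]
#' @export
six_letter_alphabet <- function() {
  c(D = 1L, E = 1L, N = 1L, Q = 1L,
    H = 2L, R = 2L, K = 2L,
    C = 3L,
    S = 4L, T = 4L, P = 4L, A = 4L, G = 4L,
    M = 5L, I = 5L, L = 5L, V = 5L,
    F = 6L, Y = 6L, W = 6L)
}

# Check a sequence against the standard alphabet; returns the offending
# letters (empty if clean).
nonstandard_letters <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unique(chars[!chars %in% AA20])
}

assert_standard_residue <- function(letter, what = "residue") {
  if (length(letter) != 1L || !letter %in% AA20) {
    stop_validation(sprintf("%s '%s' is not one of the 20 standard amino acids",
                            what, paste(letter, collapse = "")))
  }
  invisible(letter)
}
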