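#' BLOSUM62 substitution matrix (canonical 20-residue alphabet)
#'
#' The standard BLOSUM62 amino-acid substitution scores used for local
#' alignment of the CE1 epitope query against candidate mimic proteins and
#' for the conserved-substitution call: a non-identical aligned pair is
#' "conserved" when its BLOSUM62 score is greater than 0.
#'
#' Scores are the published integer half-bit values; only the 20 canonical
#' residues are included because the pipeline rejects ambiguity codes.
#'
#' @return An integer 20 x 20 symmetric matrix with dimnames
#'   `ARNDCQEGHILKMFPSTWYV`.
#' @examples
#' blosum62()["D", "E"] # 2, a conserved substitution
#' blosum62()["D", "W"] # -4, a mismatch
#' @export
blosum62 <- function() .blosum62

.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.blosum62 <- local({
  rows <- c(
    A = " 4 -1 -2 -2  0 -1 -1  0 -2 -1 -1 -1 -1 -2 -1  1  0 -3 -2  0",
    R = "-1  5  0 -2 -3  1  0 -2  0 -3 -2  2 -1 -3 -2 -1 -1 -3 -2 -3",
    N = "-2  0  6  1 -3  0  0  0  1 -3 -3  0 -2 -3 -2  1  0 -4 -2 -3",
    D = "-2 -2  1  6 -3  0  2 -1 -1 -3 -4 -1 -3 -3 -1  0 -1 -4 -3 -3",
    C = " 0 -3 -3 -3  9 -3 -4 -3 -3 -1 -1 -3 -1 -2 -3 -1 -1 -2 -2 -1",
    Q = "-1  1  0  0 -3  5  2 -2  0 -3 -2  1  0 -3 -1  0 -1 -2 -1 -2",
    E = "-1  0  0  2 -4  2  5 -2  0 -3 -3  1 -2 -3 -1  0 -1 -3 -2 -2",
    G = " 0 -2  0 -1 -3 -2 -2  6 -2 -4 -4 -2 -3 -3 -2  0 -2 -2 -3 -3",
    H = "-2  0  1 -1 -3  0  0 -2  8 -3 -3 -1 -2 -1 -2 -1 -2 -2  2 -3",
    I = "-1 -3 -3 -3 -1 -3 -3 -4 -3  4  2 -3  1  0 -3 -2 -1 -3 -1  3",
    L = "-1 -2 -3 -4 -1 -2 -3 -4 -3  2  4 -2  2  0 -3 -2 -1 -2 -1  1",
    K = "-1  2  0 -1 -3  1  1 -2 -1 -3 -2  5 -1 -3 -1  0 -1 -3 -2 -2",
    M = "-1 -1 -2 -3 -1  0 -2 -3 -2  1  2 -1  5  0 -2 -1 -1 -1 -1  1",
    F = "-2 -3 -3 -3 -2 -3 -3 -3 -1  0  0 -3  0  6 -4 -2 -2  1  3 -1",
    P = "-1 -2 -2 -1 -3 -1 -1 -2 -2 -3 -3 -1 -2 -4  7 -1 -1 -4 -3 -2",
    S = " 1 -1  1  0 -1  0  0  0 -1 -2 -2  0 -1 -2 -1  4  1 -3 -2 -2",
    T = " 0 -1  0 -1 -1 -1 -1 -2 -2 -1 -1 -1 -1 -2 -1  1  5 -2 -2  0",
    W = "-3 -3 -4 -4 -2 -2 -3 -2 -2 -3 -2 -3 -1  1 -4 -3 -2 11  2 -3",
    Y = "-2 -2 -2 -3 -2 -1 -2 -3  2 -1 -1 -2 -1  3 -3 -2 -2  2  7 -1",
    V = " 0 -3 -3 -3 -1 -2 -2 -3 -3  3  1 -2  1 -1 -2 -2  0 -3 -1  4"
  )
  m <- t(vapply(rows, function(r) as.integer(strsplit(trimws(r), "\\s+")[[1]]),
                integer(20)))
  dimnames(m) <- list(.aa_alphabet, .aa_alphabet)
  storage.mode(m) <- "integer"
  m
})

# Map an amino-acid string to 1-based indices into the BLOSUM62 alphabet,
# erroring with the offending position on any non-canonical residue.
.aa_index <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop(sprintf("%s must be a non-empty character scalar", what))
  }
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, .aa_alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("non-canonical residue '%s' at position %d of %s",
                 chars[bad], bad, what))
  }
  idx
}
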