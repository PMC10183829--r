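#' @useDynLib ufmevo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats as.dist cor cutree dist hclust optim quantile rbinom
#'   rexp rnorm rpois runif sd setNames
#' @importFrom utils combn head read.delim write.table
NULL

# Canonical residue order used throughout the package; X is position 21 and
# scores 0 against everything.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Encode a protein sequence as integer codes
#'
#' @param seq character scalar over the 20-residue alphabet; `X` is allowed
#'   and scores zero against every residue.
#' @return integer vector of 1-based codes into [AA_ALPHABET].
#' @keywords internal
encode_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  code <- match(ch, AA_ALPHABET)
  if (anyNA(code)) {
    bad <- unique(ch[is.na(code)])
    stop("invalid residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  code
}

decode_seq <- function(code) paste(AA_ALPHABET[code], collapse = "")

#' BLOSUM62 substitution scores on the package alphabet
#'
#' Returns the standard 20x20 integer BLOSUM62 table (taken from the copy
#' shipped with Biostrings) extended with an `X` row/column scored 0, in the
#' package residue order.
#'
#' @return 21x21 numeric matrix with dimnames [AA_ALPHABET].
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  aa20 <- AA_ALPHABET[1:20]
  S <- matrix(0, 21, 21, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  S[aa20, aa20] <- B[aa20, aa20]
  S
}

#' Background amino-acid frequencies
#'
#' Robinson & Robinson frequencies, the standard BLAST background model,
#' normalised to sum to 1 over the 20 canonical residues.
#'
#' @return named numeric vector of length 20.
#' @export
aa_background <- function() {
  f <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  f <- f[AA_ALPHABET[1:20]]
  f / sum(f)
}

#' Construct a scoring scheme for pairwise and profile alignment
#'
#' @param matrix 21x21 substitution matrix over [AA_ALPHABET] (default
#'   [blosum62()]); a 20x20 matrix over the canonical residues is accepted
#'   and extended with a zero `X` row/column.
#' @param gap_open positive gap-opening penalty; a gap of length L costs
#'   `gap_open + (L - 1) * gap_extend`.
#' @param gap_extend positive gap-extension penalty, at most `gap_open`.
#' @return object of class `scoring_matrix`.
#' @export
scoring_matrix <- function(matrix = blosum62(), gap_open = 11, gap_extend = 1) {
  if (nrow(matrix) == 20L && ncol(matrix) == 20L) {
    m21 <- base::matrix(0, 21, 21, dimnames = list(AA_ALPHABET, AA_ALPHABET))
    m21[rownames(matrix), colnames(matrix)] <- matrix
    matrix <- m21
  }
  stopifnot(is.matrix(matrix), nrow(matrix) == 21L, ncol(matrix) == 21L)
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric", call. = FALSE)
  if (gap_open <= 0 || gap_extend <= 0 || gap_extend > gap_open)
    stop("require 0 < gap_extend <= gap_open", call. = FALSE)
  structure(list(S = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_matrix")
}

#' Read a whitespace-delimited substitution matrix (e.g. an LG-derived
#' log-odds table) from a text file
#'
#' The file must have residue one-letter codes as header and row names.
#'
#' @param path file path.
#' @return 21x21 numeric matrix usable with [scoring_matrix()].
#' @export
read_substitution_matrix <- function(path) {
  tab <- as.matrix(read.delim(path, sep = "", check.names = FALSE))
  aa <- intersect(AA_ALPHABET[1:20], rownames(tab))
  if (length(aa) < 20L) stop("matrix file must cover the 20 canonical residues")
  S <- matrix(0, 21, 21, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  S[aa, aa] <- tab[aa, aa]
  S
}
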