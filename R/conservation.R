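# Column conservation scoring: single-group expected pair score with 1-9
# binning (a declared simplified stand-in for phylogenetic rate models),
# two-group signature scoring, and weighted-count logo statistics.

# Per-group, gap-excluded, Henikoff-weighted residue frequencies.
# Returns list(freqs = L x 20 matrix, occupancy = weighted non-gap fraction).
.weighted_freqs <- function(aln, weights) {
  L <- ncol(aln)
  aa20 <- AA_ALPHABET[1:20]
  f <- matrix(0, L, 20, dimnames = list(NULL, aa20))
  occ <- numeric(L)
  wtot <- sum(weights)
  for (i in seq_len(nrow(aln))) {
    row <- aln[i, ]
    ok <- row %in% aa20
    if (any(ok)) {
      idx <- cbind(which(ok), match(row[ok], aa20))
      f[idx] <- f[idx] + weights[i]
      occ[ok] <- occ[ok] + weights[i]
    }
  }
  occ <- occ / wtot
  norm <- rowSums(f)
  nz <- norm > 0
  f[nz, ] <- f[nz, , drop = FALSE] / norm[nz]
  list(freqs = f, occupancy = occ)
}

#' Two-group (signature) conservation score per column
#'
#' For groups A and B with gap-excluded Henikoff-weighted residue
#' frequencies `f_A`, `f_B`, the column score is
#' `TC(c) = sum_a sum_b f_A(a) f_B(b) S(a, b)`. Negative values mark
#' columns where the two groups carry dissimilar residues (divergent
#' signature positions); columns where either group is entirely gapped are
#' flagged missing (`NA`).
#'
#' @param msa a [grouped_msa()] whose `groups` take exactly two values.
#' @param matrix a [scoring_matrix()] (substitution scores only; default
#'   BLOSUM62).
#' @return data.frame of class `column_score_track`: column, score, flag,
#'   plus the group sizes in attributes.
#' @export
twogroup_score <- function(msa, matrix = scoring_matrix()) {
  stopifnot(inherits(msa, "grouped_msa"), !is.null(msa$groups))
  gl <- sort(unique(msa$groups))
  if (length(gl) != 2L) stop("exactly two groups required", call. = FALSE)
  ia <- which(msa$groups == gl[1]); ib <- which(msa$groups == gl[2])
  if (!length(ia) || !length(ib)) stop("a group has zero rows", call. = FALSE)
  wa <- henikoff_weights(msa_subset_rows(msa, ia))$weights
  wb <- henikoff_weights(msa_subset_rows(msa, ib))$weights
  fa <- .weighted_freqs(msa$aln[ia, , drop = FALSE], wa)
  fb <- .weighted_freqs(msa$aln[ib, , drop = FALSE], wb)
  S <- matrix$S[1:20, 1:20]
  sc <- rowSums((fa$freqs %*% S) * fb$freqs)
  miss <- fa$occupancy == 0 | fb$occupancy == 0
  sc[miss] <- NA_real_
  out <- data.frame(column = seq_along(sc), score = sc,
                    flag = ifelse(miss, "missing", ""))
  attr(out, "group_sizes") <- setNames(c(length(ia), length(ib)), gl)
  class(out) <- c("column_score_track", "data.frame")
  out
}

#' Single-group column conservation with 1-9 bins
#'
#' Expected pair score `sum_a sum_b f(a) f(b) S(a, b)` per column with
#' Henikoff-weighted, gap-excluded frequencies; bins are a rank-based
#' equal-frequency partition of the scored columns into 9 classes (9 =
#' most conserved; ties share the minimum rank, so degenerate alignments
#' collapse into one class). A simplified proxy: no phylogenetic rate
#' estimation is performed.
#'
#' @param msa a [grouped_msa()] with >= 2 rows.
#' @param matrix a [scoring_matrix()].
#' @return data.frame `column_score_track`: column, score, bin, flag.
#' @export
column_conservation <- function(msa, matrix = scoring_matrix()) {
  stopifnot(inherits(msa, "grouped_msa"))
  if (nrow(msa$aln) < 2L) stop("need >= 2 rows", call. = FALSE)
  w <- henikoff_weights(msa)$weights
  fr <- .weighted_freqs(msa$aln, w)
  S <- matrix$S[1:20, 1:20]
  sc <- rowSums((fr$freqs %*% S) * fr$freqs)
  miss <- fr$occupancy == 0
  sc[miss] <- NA_real_
  bin <- rep(NA_integer_, length(sc))
  ok <- !miss
  if (any(ok)) {
    r <- rank(sc[ok], ties.method = "min")
    bin[ok] <- as.integer(ceiling(r * 9 / sum(ok)))
  }
  out <- data.frame(column = seq_along(sc), score = sc, bin = bin,
                    flag = ifelse(miss, "missing", ""))
  class(out) <- c("column_score_track", "data.frame")
  out
}

#' Weighted-count logo statistics
#'
#' Henikoff-weighted, gap-excluded residue frequencies per column and their
#' information content `IC(c) = log2(20) - H(c)`; gap content is reported
#' as (one minus) occupancy. All-gap columns have `NA` IC.
#'
#' @param msa a [grouped_msa()].
#' @return list with `freqs` (L x 20), `ic` (bits), `occupancy`.
#' @export
logo_counts <- function(msa) {
  stopifnot(inherits(msa, "grouped_msa"), nrow(msa$aln) >= 1L)
  w <- msa$weights
  if (is.null(w)) w <- henikoff_weights(msa)$weights
  fr <- .weighted_freqs(msa$aln, w)
  H <- apply(fr$freqs, 1, function(p) {
    p <- p[p > 0]
    if (!length(p)) return(NA_real_)
    -sum(p * log2(p))
  })
  ic <- log2(20) - H
  ic[fr$occupancy == 0] <- NA_real_
  list(freqs = fr$freqs, ic = ic, occupancy = fr$occupancy)
}
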