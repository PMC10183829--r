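# Multiple alignment construction (progressive, NJ guide tree) and the
# trimming / fragment-filtering rules applied before tree building and
# conservation analysis.

#' Grouped multiple sequence alignment
#'
#' @param seqs named character vector of equal-length aligned rows
#'   (gap character `-`).
#' @param groups optional character vector of per-row group labels (e.g.
#'   `"UFM1+"` / `"UFM1-"`), recycled names from `seqs` if unnamed.
#' @param weights optional positive per-row weights summing to 1.
#' @return object of class `grouped_msa` with fields `ids`, `aln`
#'   (rows x columns character matrix), `groups`, `weights`.
#' @export
grouped_msa <- function(seqs, groups = NULL, weights = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("aligned rows must have equal length", call. = FALSE)
  aln <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  if (is.null(dim(aln))) aln <- matrix(aln, nrow = 1L)
  rownames(aln) <- names(seqs)
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(seqs))
    groups <- setNames(as.character(groups), names(seqs))
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(seqs), all(weights > 0),
              abs(sum(weights) - 1) < 1e-9)
    weights <- setNames(weights, names(seqs))
  }
  structure(list(ids = names(seqs), aln = aln, groups = groups,
                 weights = weights), class = "grouped_msa")
}

#' @export
print.grouped_msa <- function(x, ...) {
  cat("grouped_msa:", nrow(x$aln), "rows x", ncol(x$aln), "columns",
      if (!is.null(x$groups)) paste0("(groups: ",
        paste(unique(x$groups), collapse = ", "), ")") else "", "\n")
  invisible(x)
}

#' Aligned rows as strings
#' @param msa a `grouped_msa`.
#' @return named character vector.
#' @export
msa_strings <- function(msa) {
  setNames(apply(msa$aln, 1, paste, collapse = ""), msa$ids)
}

msa_subset_rows <- function(msa, keep) {
  grouped_msa(msa_strings(msa)[keep],
              groups = if (!is.null(msa$groups)) msa$groups[keep])
}

# Residue frequency matrix (L x 21) of an alignment block; rows may sum to
# < 1 when columns contain gaps.
.block_freqs <- function(block) {
  L <- ncol(block)
  f <- matrix(0, L, 21)
  n <- nrow(block)
  for (i in seq_len(n)) {
    code <- match(block[i, ], AA_ALPHABET)
    ok <- !is.na(code)
    if (any(ok)) {
      idx <- cbind(which(ok), code[ok])
      f[idx] <- f[idx] + 1 / n
    }
  }
  f
}

#' Progressive multiple alignment
#'
#' Pairwise global alignments give identity distances, a neighbor-joining
#' guide tree (midpoint-rooted) orders profile-profile merges; fully
#' deterministic. Replaces an external aligner so the whole pipeline stays
#' self-contained and seedable.
#'
#' @param seqs named character vector of unaligned protein sequences.
#' @param scoring a [scoring_matrix()].
#' @return a [grouped_msa()].
#' @export
progressive_align <- function(seqs, scoring = scoring_matrix()) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  n <- length(seqs)
  if (n == 1L) return(grouped_msa(seqs))
  codes <- lapply(seqs, encode_seq)
  ids <- names(seqs)

  align_pair_blocks <- function(ba, bb) {
    fa <- .block_freqs(ba); fb <- .block_freqs(bb)
    cs <- fa %*% scoring$S %*% t(fb)
    p <- profile_nw_cpp(cs, scoring$gap_open, scoring$gap_extend)
    ncolm <- length(p$pa)
    outa <- matrix("-", nrow(ba), ncolm)
    outb <- matrix("-", nrow(bb), ncolm)
    ia <- p$pa > 0; ib <- p$pb > 0
    outa[, ia] <- ba[, p$pa[ia], drop = FALSE]
    outb[, ib] <- bb[, p$pb[ib], drop = FALSE]
    out <- rbind(outa, outb)
    rownames(out) <- c(rownames(ba), rownames(bb))
    out
  }

  blocks <- lapply(ids, function(id)
    matrix(strsplit(toupper(seqs[[id]]), "")[[1]], nrow = 1,
           dimnames = list(id, NULL)))
  names(blocks) <- ids

  if (n == 2L) {
    merged <- align_pair_blocks(blocks[[1]], blocks[[2]])
  } else {
    # identity distance from pairwise global alignments
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      r <- nw_affine_cpp(codes[[i]], codes[[j]], scoring$S,
                         scoring$gap_open, scoring$gap_extend)
      pair <- r$qaln > 0 & r$taln > 0
      idy <- if (any(pair)) mean(r$qaln[pair] == r$taln[pair]) else 0
      D[i, j] <- D[j, i] <- 1 - idy
    }
    guide <- if (n == 3L) {
      pr <- which(D == min(D[upper.tri(D)]), arr.ind = TRUE)[1, ]
      first <- sort(ids[pr]); rest <- setdiff(ids, first)
      list(list(first[1], first[2]), rest[1])
    } else {
      tr <- ape::nj(as.dist(D))
      tr$edge.length[tr$edge.length < 0] <- 0
      tr <- phangorn::midpoint(tr)
      .phylo_to_nested(tr)
    }
    merge_rec <- function(node) {
      if (is.character(node)) return(blocks[[node]])
      align_pair_blocks(merge_rec(node[[1]]), merge_rec(node[[2]]))
    }
    merged <- merge_rec(guide)
  }
  rows <- setNames(apply(merged, 1, paste, collapse = ""), rownames(merged))
  grouped_msa(rows[ids[ids %in% names(rows)]])
}

# Convert a rooted binary-ish phylo into nested lists of tip labels,
# resolving multifurcations left-to-right deterministically.
.phylo_to_nested <- function(tr) {
  ntip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  rec <- function(node) {
    if (node <= ntip) return(tr$tip.label[node])
    ch <- kids[[as.character(node)]]
    sub <- lapply(ch, rec)
    while (length(sub) > 2L) {
      sub <- c(list(list(sub[[1]], sub[[2]])), sub[-(1:2)])
    }
    list(sub[[1]], sub[[2]])
  }
  rec(ntip + 1L)
}

#' Trim alignment columns by gap content
#'
#' Retains exactly the columns whose non-gap fraction is at least
#' `gap_threshold` (the trimAl `-gt` convention: "gap threshold of 30%"
#' keeps columns with >= 30% residues).
#'
#' @param msa a [grouped_msa()].
#' @param gap_threshold in `[0, 1]`; default 0.3.
#' @return trimmed `grouped_msa`; retained column indices in
#'   `attr(, "kept_columns")`.
#' @export
trim_columns <- function(msa, gap_threshold = 0.3) {
  stopifnot(inherits(msa, "grouped_msa"),
            gap_threshold >= 0, gap_threshold <= 1)
  nongap <- colMeans(msa$aln != "-")
  keep <- which(nongap >= gap_threshold)
  aln <- msa$aln[, keep, drop = FALSE]
  rows <- setNames(apply(aln, 1, paste, collapse = ""), msa$ids)
  out <- grouped_msa(rows, groups = msa$groups)
  attr(out, "kept_columns") <- keep
  out
}

#' Drop fragmentary rows
#'
#' Removes rows whose non-gap fraction over the current columns is below
#' `min_data` (the "< 50% data" fragment rule).
#'
#' @param msa a [grouped_msa()].
#' @param min_data in `[0, 1]`; default 0.5.
#' @return filtered `grouped_msa` (possibly 0 rows, with a warning).
#' @export
filter_fragments <- function(msa, min_data = 0.5) {
  stopifnot(inherits(msa, "grouped_msa"), min_data >= 0, min_data <= 1)
  frac <- rowMeans(msa$aln != "-")
  keep <- frac >= min_data
  if (!any(keep)) {
    warning("all rows filtered as fragments", call. = FALSE)
    out <- msa
    out$ids <- character(0)
    out$aln <- msa$aln[0, , drop = FALSE]
    out$groups <- if (!is.null(msa$groups)) msa$groups[0]
    out$weights <- NULL
    return(out)
  }
  msa_subset_rows(msa, which(keep))
}

#' Henikoff position-based sequence weights
#'
#' Per column with `r` distinct residues, a row carrying a residue occurring
#' `s` times contributes `1/(r*s)`; gaps contribute nothing. Row sums are
#' normalised to total 1.
#'
#' @param msa a [grouped_msa()].
#' @return the alignment with `weights` filled in.
#' @export
henikoff_weights <- function(msa) {
  stopifnot(inherits(msa, "grouped_msa"), nrow(msa$aln) >= 1L)
  n <- nrow(msa$aln)
  raw <- numeric(n)
  for (c in seq_len(ncol(msa$aln))) {
    col <- msa$aln[, c]
    res <- col[col != "-"]
    if (!length(res)) next
    tab <- table(res)
    r <- length(tab)
    contrib <- 1 / (r * as.numeric(tab[col]))
    contrib[is.na(contrib)] <- 0
    raw <- raw + contrib
  }
  if (sum(raw) == 0) raw <- rep(1, n)
  msa$weights <- setNames(raw / sum(raw), msa$ids)
  msa
}

#' Realign a column range in place
#'
#' Curation utility: the rows of the given column window are de-gapped,
#' realigned with [progressive_align()] and spliced back.
#'
#' @param msa a [grouped_msa()].
#' @param from,to 1-based inclusive column range.
#' @param scoring a [scoring_matrix()].
#' @return a `grouped_msa`.
#' @export
realign_range <- function(msa, from, to, scoring = scoring_matrix()) {
  stopifnot(from >= 1, to <= ncol(msa$aln), from <= to)
  mid <- msa$aln[, from:to, drop = FALSE]
  degap <- apply(mid, 1, function(r) paste(r[r != "-"], collapse = ""))
  nonempty <- nchar(degap) > 0
  if (sum(nonempty) >= 2) {
    sub <- progressive_align(setNames(degap[nonempty], msa$ids[nonempty]),
                             scoring)
    W <- ncol(sub$aln)
    newmid <- matrix("-", nrow(msa$aln), W, dimnames = list(msa$ids, NULL))
    newmid[sub$ids, ] <- sub$aln
  } else newmid <- mid
  aln <- cbind(msa$aln[, seq_len(from - 1), drop = FALSE], newmid,
               msa$aln[, seq(to + 1, length.out = ncol(msa$aln) - to),
                       drop = FALSE])
  rows <- setNames(apply(aln, 1, paste, collapse = ""), msa$ids)
  grouped_msa(rows, groups = msa$groups)
}
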