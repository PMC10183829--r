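# Presence/absence matrix assembly, phi-coefficient co-evolution and
# Ward-D2 clustering.

#' Assemble the presence/absence matrix from staged search results
#'
#' An entry is 1 iff a candidate survived the E-value threshold and the
#' paralog screen in any stage; the earliest successful stage is recorded
#' as provenance (`round1 < profile < genome-rescue`).
#'
#' @param records data.frame with columns `taxon`, `family`, `stage`
#'   (one row per surviving candidate), `id` optional.
#' @param taxa,families row / column universes of the matrix.
#' @return binary matrix (taxa x families) with a character provenance
#'   matrix in `attr(, "provenance")` (`""` where absent).
#' @export
assemble_matrix <- function(records, taxa, families) {
  stages <- c("round1", "profile", "genome-rescue")
  stopifnot(all(c("taxon", "family", "stage") %in% names(records)))
  if (nrow(records)) {
    stopifnot(all(records$taxon %in% taxa), all(records$family %in% families),
              all(records$stage %in% stages))
    key <- paste(records$taxon, records$family, records$stage,
                 if ("id" %in% names(records)) records$id else "")
    if (anyDuplicated(key))
      stop("conflicting duplicate records", call. = FALSE)
  }
  M <- matrix(0L, length(taxa), length(families),
              dimnames = list(taxa, families))
  prov <- matrix("", length(taxa), length(families),
                 dimnames = list(taxa, families))
  if (nrow(records)) {
    records$rank <- match(records$stage, stages)
    ord <- records[order(records$rank), ]
    for (k in seq_len(nrow(ord))) {
      tx <- ord$taxon[k]; fam <- ord$family[k]
      if (M[tx, fam] == 0L) {
        M[tx, fam] <- 1L
        prov[tx, fam] <- ord$stage[k]
      }
    }
  }
  attr(M, "provenance") <- prov
  M
}

#' Phi coefficient of two binary vectors
#'
#' `phi = (n11*n00 - n10*n01) / sqrt(n1. * n0. * n.1 * n.0)`; equals the
#' Pearson correlation of the 0/1 vectors. Returns `NA` (undefined) when
#' any marginal is zero.
#'
#' @param x,y equal-length binary vectors (length >= 2).
#' @return numeric in `[-1, 1]`, or `NA` when undefined.
#' @export
phi <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  stopifnot(length(x) >= 2L, all(x %in% 0:1), all(y %in% 0:1))
  n11 <- sum(x == 1 & y == 1); n00 <- sum(x == 0 & y == 0)
  n10 <- sum(x == 1 & y == 0); n01 <- sum(x == 0 & y == 1)
  m <- c(n11 + n10, n01 + n00, n11 + n01, n10 + n00)
  if (any(m == 0)) return(NA_real_)
  (n11 * n00 - n10 * n01) / sqrt(prod(m))
}

#' Pairwise phi matrix of a presence/absence matrix
#'
#' @param pam binary matrix (taxa x families).
#' @param taxa optional taxon filter (row subset) applied before
#'   correlation.
#' @return symmetric matrix of phi coefficients with unit diagonal;
#'   undefined pairs are `NA` and flagged in `attr(, "undefined")`.
#' @export
phi_matrix <- function(pam, taxa = NULL) {
  if (!is.null(taxa)) pam <- pam[taxa, , drop = FALSE]
  fam <- colnames(pam)
  n <- length(fam)
  P <- matrix(1, n, n, dimnames = list(fam, fam))
  for (i in seq_len(n)) {
    if (length(unique(pam[, i])) == 1L) P[i, i] <- NA_real_
    if (i == n) break
    for (j in (i + 1):n) {
      P[i, j] <- P[j, i] <- phi(pam[, i], pam[, j])
    }
  }
  attr(P, "undefined") <- is.na(P)
  P
}

#' Ward-D2 clustering of the phi matrix
#'
#' Rows of the phi matrix (each family's profile of correlations) are
#' clustered with Euclidean distances under the Ward-D2 update. Undefined
#' entries are mean-imputed (with a warning) before clustering.
#'
#' @param phim output of [phi_matrix()].
#' @return `hclust` object; a newick rendering is available through
#'   [cluster_newick()].
#' @export
ward_cluster <- function(phim) {
  M <- unclass(phim)
  attr(M, "undefined") <- NULL
  if (nrow(M) == 1L) {
    return(structure(list(merge = matrix(integer(0), 0, 2), height = numeric(0),
                          order = 1L, labels = rownames(M),
                          method = "ward.D2", dist.method = "euclidean"),
                     class = "hclust"))
  }
  if (anyNA(M)) {
    warning("undefined phi entries mean-imputed before clustering",
            call. = FALSE)
    fill <- mean(M[upper.tri(M)], na.rm = TRUE)
    if (is.nan(fill)) fill <- 0
    M[is.na(M)] <- fill
  }
  ord <- order(rownames(M))
  M <- M[ord, ord, drop = FALSE]
  hclust(dist(M), method = "ward.D2")
}

#' Newick rendering of a dendrogram
#' @param hc an `hclust`.
#' @return newick string.
#' @export
cluster_newick <- function(hc) {
  if (!length(hc$height)) return(paste0("(", hc$labels, ");"))
  ape::write.tree(ape::as.phylo(hc))
}
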