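# Iterative homology search: pairwise Smith-Waterman round, PSSM profile
# re-search with calibrated E-values, and a six-frame genome rescue stage.

# Karlin-Altschul defaults for gapped BLOSUM62 (11/1); declared, overridable.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Optimal local alignment with affine gaps
#'
#' Smith-Waterman over the 20-residue alphabet (`X` allowed, scored 0) with
#' gap cost `gap_open + (L-1) * gap_extend` and deterministic traceback
#' (diagonal > up > left).
#'
#' @param query,target protein sequences (character scalars).
#' @param scoring a [scoring_matrix()].
#' @return list of class `alignment_hit`: `score` (raw), `bits`, spans
#'   (`qstart`..`tend`, 1-based inclusive; 0 when the best score is 0) and
#'   the aligned strings.
#' @export
smith_waterman <- function(query, target, scoring = scoring_matrix()) {
  q <- encode_seq(query)
  t <- encode_seq(target)
  r <- sw_affine_cpp(q, t, scoring$S, scoring$gap_open, scoring$gap_extend)
  qa <- ifelse(r$qaln == 0, "-", AA_ALPHABET[pmax(r$qaln, 1)])
  ta <- ifelse(r$taln == 0, "-", AA_ALPHABET[pmax(r$taln, 1)])
  structure(list(score = r$score,
                 bits = (KA_LAMBDA * r$score - log(KA_K)) / log(2),
                 qstart = r$qstart, qend = r$qend,
                 tstart = r$tstart, tend = r$tend,
                 qaln = paste(qa, collapse = ""),
                 taln = paste(ta, collapse = "")),
            class = "alignment_hit")
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for raw score `S` in a search space of
#' `m * n` residues.
#'
#' @param raw_score raw alignment score.
#' @param m,n query and database lengths (residues), both >= 1.
#' @param lambda_,K positive Karlin-Altschul constants; defaults are the
#'   standard gapped BLOSUM62(11/1) values.
#' @return expected number of chance hits (>= 0).
#' @export
evalue <- function(raw_score, m, n, lambda_ = KA_LAMBDA, K = KA_K) {
  if (lambda_ <= 0 || K <= 0) stop("lambda and K must be positive", call. = FALSE)
  if (m < 1 || n < 1) stop("m and n must be >= 1", call. = FALSE)
  K * m * n * exp(-lambda_ * raw_score)
}

#' First-iteration homology search against per-taxon proteomes
#'
#' Every query is aligned locally against every target; per target the best
#' query alignment is kept and thresholded on its Karlin-Altschul E-value
#' with `n` the total residue count of the searched proteome.
#'
#' @param queries named character vector of query proteins.
#' @param proteomes a [proteome_set()].
#' @param threshold E-value cutoff (default `1e-5`).
#' @param scoring a [scoring_matrix()].
#' @return data.frame with columns query, target, taxon, raw, bits, evalue,
#'   qstart, qend, tstart, tend.
#' @export
search_round1 <- function(queries, proteomes, threshold = 1e-5,
                          scoring = scoring_matrix()) {
  stopifnot(threshold > 0, inherits(proteomes, "proteome_set"))
  if (!length(proteomes$proteins) || !sum(lengths(proteomes$proteins)))
    stop("empty proteome set", call. = FALSE)
  qcodes <- lapply(queries, encode_seq)
  out <- list()
  for (tx in proteomes$taxa) {
    prot <- proteomes$proteins[[tx]]
    if (!length(prot)) next
    db_n <- sum(nchar(prot))
    for (tg in names(prot)) {
      tcode <- encode_seq(prot[[tg]])
      best <- NULL
      for (qn in names(queries)) {
        r <- sw_affine_cpp(qcodes[[qn]], tcode, scoring$S,
                           scoring$gap_open, scoring$gap_extend)
        if (is.null(best) || r$score > best$score) {
          best <- r; best$query <- qn
        }
      }
      ev <- evalue(best$score, m = nchar(queries[[best$query]]), n = db_n)
      if (ev < threshold) {
        out[[length(out) + 1L]] <- data.frame(
          query = best$query, target = tg, taxon = tx, raw = best$score,
          bits = (KA_LAMBDA * best$score - log(KA_K)) / log(2), evalue = ev,
          qstart = best$qstart, qend = best$qend,
          tstart = best$tstart, tend = best$tend,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(query = character(), target = character(),
                      taxon = character(), raw = numeric(), bits = numeric(),
                      evalue = numeric(), qstart = integer(), qend = integer(),
                      tstart = integer(), tend = integer()))
  do.call(rbind, out)
}

#' Build a position-specific log-odds profile from an alignment
#'
#' Henikoff-weighted residue counts per retained column are converted to
#' base-2 log-odds against the background:
#' `log2(((wc + pc * bg) / (total + pc)) / bg)`.
#'
#' @param msa a [grouped_msa()]; typically trimmed at gap threshold 0.1
#'   before profile construction.
#' @param pseudocount_weight non-negative pseudocount mass `pc`.
#' @param background background frequencies (default [aa_background()]).
#' @return object of class `profile_model` with fields `length`, `scores`
#'   (L x 21, X column 0), `background`, `counts`, `consensus`.
#' @export
build_profile <- function(msa, pseudocount_weight = 1,
                          background = aa_background()) {
  stopifnot(inherits(msa, "grouped_msa"))
  if (ncol(msa$aln) == 0L) stop("alignment has zero retained columns", call. = FALSE)
  w <- msa$weights
  if (is.null(w)) w <- henikoff_weights(msa)$weights
  L <- ncol(msa$aln)
  aa20 <- AA_ALPHABET[1:20]
  counts <- matrix(0, L, 20, dimnames = list(NULL, aa20))
  for (i in seq_len(nrow(msa$aln))) {
    row <- msa$aln[i, ]
    ok <- row %in% aa20
    if (any(ok)) {
      idx <- cbind(which(ok), match(row[ok], aa20))
      counts[idx] <- counts[idx] + w[i]
    }
  }
  pc <- pseudocount_weight
  total <- rowSums(counts)
  freq <- (counts + pc * matrix(background, L, 20, byrow = TRUE)) / (total + pc)
  scores <- log2(sweep(freq, 2, background, "/"))
  scores <- cbind(scores, X = 0)
  consensus <- paste(aa20[max.col(counts, ties.method = "first")], collapse = "")
  structure(list(length = L, scores = scores, background = background,
                 counts = counts, consensus = consensus,
                 lambda = NULL, K = NULL),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat("profile_model: length", x$length,
      if (!is.null(x$lambda)) sprintf("(calibrated, lambda=%.3f)", x$lambda)
      else "(uncalibrated)", "\n")
  invisible(x)
}

#' Calibrate profile score statistics on shuffled sequences
#'
#' Scores the profile against `n_shuffle` random sequences drawn from the
#' background composition and fits a Gumbel (extreme-value) distribution by
#' maximum likelihood; `lambda = 1/beta` and `K = exp(mu/beta) / (L * n0)`
#' convert null exceedance probabilities into Karlin-Altschul style E-values.
#'
#' @param profile a `profile_model`.
#' @param n_shuffle number of null sequences (default 200).
#' @param null_length their length (default `2 * L`, floor 100).
#' @param seed integer seed; calibration is deterministic given it.
#' @param scoring gap penalties for placement.
#' @return the profile with `lambda`, `K`, `null_scores` filled in.
#' @export
calibrate_profile <- function(profile, n_shuffle = 200, null_length = NULL,
                              seed = 1, scoring = scoring_matrix()) {
  L <- profile$length
  n0 <- if (is.null(null_length)) max(100L, 2L * L) else null_length
  bg <- profile$background
  scores <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffle), function(i) {
      s <- sample.int(20L, n0, replace = TRUE, prob = bg)
      pssm_local_cpp(profile$scores, s, scoring$gap_open, scoring$gap_extend)$score
    }, numeric(1))
  })
  # Gumbel MLE
  b0 <- stats::sd(scores) * sqrt(6) / pi
  if (b0 <= 0) b0 <- 1
  nll <- function(par) {
    mu <- par[1]; beta <- exp(par[2])
    z <- (scores - mu) / beta
    sum(log(beta) + z + exp(-z))
  }
  fit <- optim(c(mean(scores) - 0.5772 * b0, log(b0)), nll, method = "BFGS")
  mu <- fit$par[1]; beta <- exp(fit$par[2])
  profile$lambda <- 1 / beta
  profile$K <- exp(mu / beta) / (L * n0)
  profile$null_scores <- scores
  profile
}

#' Profile search against per-taxon proteomes
#'
#' Best local PSSM placement (affine gaps) per target, converted to an
#' E-value with the profile's calibrated extreme-value statistics and
#' thresholded.
#'
#' @param profile a calibrated `profile_model` (uncalibrated profiles are
#'   calibrated on the fly with `seed`).
#' @param proteomes a [proteome_set()].
#' @param threshold E-value cutoff.
#' @param scoring gap penalties.
#' @param seed seed used only if calibration is missing.
#' @return data.frame of hits (target, taxon, raw, evalue).
#' @export
profile_search <- function(profile, proteomes, threshold = 1e-5,
                           scoring = scoring_matrix(), seed = 1) {
  stopifnot(inherits(profile, "profile_model"), inherits(proteomes, "proteome_set"))
  if (is.null(profile$lambda))
    profile <- calibrate_profile(profile, seed = seed, scoring = scoring)
  out <- list()
  for (tx in proteomes$taxa) {
    prot <- proteomes$proteins[[tx]]
    if (!length(prot)) next
    db_n <- sum(nchar(prot))
    for (tg in names(prot)) {
      tcode <- encode_seq(prot[[tg]])
      r <- pssm_local_cpp(profile$scores, tcode, scoring$gap_open, scoring$gap_extend)
      ev <- profile$K * profile$length * db_n * exp(-profile$lambda * r$score)
      if (ev < threshold) {
        out[[length(out) + 1L]] <- data.frame(
          target = tg, taxon = tx, raw = r$score, evalue = ev,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(target = character(), taxon = character(),
                      raw = numeric(), evalue = numeric()))
  do.call(rbind, out)
}

#' Six-frame translation ORFs
#'
#' Translates all six frames with the standard genetic code, splits at stop
#' codons and reports ORFs of at least `min_orf` residues with 1-based
#' coordinates on the forward strand. ORFs consisting solely of `X`
#' (ambiguous codons) are dropped.
#'
#' @param genome nucleotide sequence over ACGTN.
#' @param min_orf minimum ORF length in residues (>= 10).
#' @return data.frame: orf, strand, frame, start, end, protein.
#' @export
six_frame_orfs <- function(genome, min_orf = 30) {
  stopifnot(is.character(genome), length(genome) == 1L, min_orf >= 10)
  gup <- toupper(genome)
  if (grepl("[^ACGTN]", gup)) stop("invalid nucleotide", call. = FALSE)
  dna <- Biostrings::DNAString(gup)
  len <- length(dna)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else Biostrings::reverseComplement(dna)
    for (frame in 1:3) {
      nlen <- len - frame + 1L
      ncod <- nlen %/% 3L
      if (ncod < 1L) next
      sub <- Biostrings::subseq(s, frame, frame + 3L * ncod - 1L)
      aa <- as.character(suppressWarnings(
        Biostrings::translate(sub, if.fuzzy.codon = "X")))
      # split at stops, track codon offsets
      parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
      pos <- 1L
      for (p in parts) {
        plen <- nchar(p)
        if (plen >= min_orf && grepl("[^X]", p)) {
          c1 <- pos; c2 <- pos + plen - 1L   # codon indices on this strand
          s1 <- frame + 3L * (c1 - 1L); s2 <- frame + 3L * c2 - 1L
          if (strand == "+") { st <- s1; en <- s2 }
          else { st <- len - s2 + 1L; en <- len - s1 + 1L }
          rows[[length(rows) + 1L]] <- data.frame(
            strand = strand, frame = frame, start = st, end = en,
            protein = p, stringsAsFactors = FALSE)
        }
        pos <- pos + plen + 1L
      }
    }
  }
  if (!length(rows))
    return(data.frame(orf = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      protein = character()))
  df <- do.call(rbind, rows)
  df <- cbind(orf = sprintf("orf%03d", seq_len(nrow(df))), df)
  df
}

#' Genome rescue by six-frame translation plus profile search
#'
#' The stand-in for translated (tBLASTn-style) searching of unannotated
#' genomes: ORFs from [six_frame_orfs()] are scored with the calibrated
#' profile and passing ORFs are reported as predicted proteins.
#'
#' @inheritParams profile_search
#' @param genome nucleotide sequence over ACGTN.
#' @param min_orf minimum ORF length (residues).
#' @return data.frame of predicted proteins with profile E-values and
#'   forward-strand coordinates; zero rows when nothing passes.
#' @export
six_frame_rescue <- function(profile, genome, min_orf = 30, threshold = 1e-5,
                             scoring = scoring_matrix(), seed = 1) {
  stopifnot(inherits(profile, "profile_model"))
  if (is.null(profile$lambda))
    profile <- calibrate_profile(profile, seed = seed, scoring = scoring)
  orfs <- six_frame_orfs(genome, min_orf = min_orf)
  if (!nrow(orfs)) return(cbind(orfs, raw = numeric(0), evalue = numeric(0)))
  db_n <- sum(nchar(orfs$protein))
  res <- lapply(seq_len(nrow(orfs)), function(i) {
    r <- pssm_local_cpp(profile$scores, encode_seq(orfs$protein[i]),
                        scoring$gap_open, scoring$gap_extend)
    ev <- profile$K * profile$length * db_n * exp(-profile$lambda * r$score)
    c(raw = r$score, evalue = ev)
  })
  res <- do.call(rbind, res)
  out <- cbind(orfs, res)
  out[out$evalue < threshold, , drop = FALSE]
}
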