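# AIM / sAIM motif grammar: scanning, mutation and sAIM -> cAIM conversion.
#
# cAIM (canonical ATG8-interacting motif / LIR): [WFY] x x [LIV]
# sAIM (shuffled AIM):                           I [DS] W [GD]

CAIM_PATTERN <- "[WFY]..[LIV]"
SAIM_PATTERN <- "I[DS]W[GD]"

.scan_motif <- function(seq, pattern, pattern_id, seq_id) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  m <- gregexpr(paste0("(?=(", pattern, "))"), s, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(pattern = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      match = character(), stringsAsFactors = FALSE))
  starts <- as.integer(m)
  data.frame(pattern = pattern_id, seq_id = seq_id, start = starts,
             end = starts + 3L,
             match = substring(s, starts, starts + 3L),
             stringsAsFactors = FALSE)
}

#' Scan for canonical ATG8-interacting motifs (cAIM / LIR)
#'
#' Reports every (possibly overlapping) 4-mer matching `[WFY]xx[LIV]`,
#' 1-based inclusive coordinates.
#'
#' @param seq protein sequence.
#' @param seq_id id recorded in the hit table.
#' @return data.frame: pattern, seq_id, start, end, match.
#' @export
scan_caim <- function(seq, seq_id = "seq") .scan_motif(seq, CAIM_PATTERN, "cAIM", seq_id)

#' Scan for shuffled AIMs (sAIM)
#'
#' Reports every 4-mer matching `I[DS]W[GD]` (IDWG/IDWD plus the
#' serine variant `ISW[GD]`).
#'
#' @inheritParams scan_caim
#' @return data.frame: pattern, seq_id, start, end, match.
#' @export
scan_saim <- function(seq, seq_id = "seq") .scan_motif(seq, SAIM_PATTERN, "sAIM", seq_id)

#' Convert a sAIM into a cAIM by residue reordering
#'
#' The 4-mer `x1 x2 x3 x4` at `site_start` (which must match the sAIM
#' grammar) is reordered to `x3 x2 x4 x1`: IDWD becomes WDDI and IDWG
#' becomes WDGI, a canonical `[WFY]xx[LIV]` motif. Sequence length is
#' preserved.
#'
#' @param seq protein sequence.
#' @param site_start 1-based start of the sAIM.
#' @return the converted sequence.
#' @export
saim_to_caim <- function(seq, site_start) {
  s <- toupper(seq)
  stopifnot(site_start >= 1, site_start + 3L <= nchar(s))
  four <- substring(s, site_start, site_start + 3L)
  if (!grepl(paste0("^", SAIM_PATTERN, "$"), four))
    stop("site does not match the sAIM pattern: ", four, call. = FALSE)
  x <- strsplit(four, "")[[1]]
  conv <- paste0(x[3], x[2], x[4], x[1])
  paste0(substring(s, 1, site_start - 1L), conv,
         substring(s, site_start + 4L, nchar(s)))
}

#' Point-mutate residues
#'
#' Single or combinatorial substitutions (e.g. the W-to-A sAIM
#' inactivation constructs).
#'
#' @param seq protein sequence.
#' @param position 1-based positions (vector allowed).
#' @param to replacement residues (recycled).
#' @return mutated sequence.
#' @export
mutate_motif <- function(seq, position, to) {
  s <- strsplit(toupper(seq), "")[[1]]
  if (any(position < 1 | position > length(s)))
    stop("position out of range", call. = FALSE)
  to <- rep_len(toupper(to), length(position))
  stopifnot(all(to %in% AA_ALPHABET))
  s[position] <- to
  paste(s, collapse = "")
}

#' Motif hits in BED-like coordinates
#'
#' Converts the 1-based inclusive hit table to 0-based half-open intervals
#' (seq id, start-1, end, pattern id).
#'
#' @param hits output of [scan_caim()] / [scan_saim()].
#' @return data.frame: seq_id, start0, end, pattern.
#' @export
motif_hits_bed <- function(hits) {
  data.frame(seq_id = hits$seq_id, start0 = hits$start - 1L, end = hits$end,
             pattern = hits$pattern, stringsAsFactors = FALSE)
}
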