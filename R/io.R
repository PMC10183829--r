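#' Proteome set container
#'
#' Bundles per-taxon protein collections with optional per-taxon nucleotide
#' genomes, the inputs of the homology-search stages.
#'
#' @param proteins named list (one element per taxon) of named character
#'   vectors of protein sequences.
#' @param genomes optional named list of single nucleotide sequences
#'   (characters over ACGTN), names a subset of the taxa.
#' @return object of class `proteome_set`.
#' @export
proteome_set <- function(proteins, genomes = NULL) {
  stopifnot(is.list(proteins), length(proteins) >= 1L,
            !is.null(names(proteins)), !anyDuplicated(names(proteins)))
  for (tx in names(proteins)) {
    p <- proteins[[tx]]
    if (length(p) && (is.null(names(p)) || anyDuplicated(names(p))))
      stop("proteins of taxon ", tx, " must have unique names", call. = FALSE)
  }
  if (!is.null(genomes)) {
    stopifnot(is.list(genomes), !is.null(names(genomes)))
    if (!all(names(genomes) %in% names(proteins)))
      stop("genome taxa must be a subset of proteome taxa", call. = FALSE)
  }
  structure(list(proteins = proteins, genomes = genomes,
                 taxa = names(proteins)), class = "proteome_set")
}

#' @export
print.proteome_set <- function(x, ...) {
  cat("proteome_set:", length(x$taxa), "taxa,",
      sum(vapply(x$proteins, length, 1L)), "proteins,",
      length(x$genomes), "genomes\n")
  invisible(x)
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings keeping sequences as named character
#' vectors, the package's working representation.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Serialize a profile model to a documented text format
#'
#' Header lines (`#key value`) carry length, background frequencies and the
#' calibration constants; then one row of 20 log-odds scores per column.
#'
#' @param profile a `profile_model`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("#alphabet", paste(AA_ALPHABET[1:20], collapse = " ")),
    paste("#length", profile$length),
    paste("#background", paste(formatC(profile$background, digits = 8,
                                       format = "f"), collapse = " ")),
    paste("#lambda", ifelse(is.null(profile$lambda), NA, profile$lambda)),
    paste("#K", ifelse(is.null(profile$K), NA, profile$K)),
    paste("#consensus", profile$consensus)), con)
  write.table(round(profile$scores[, 1:20, drop = FALSE], 6), con,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @return `read_profile` returns a `profile_model`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) sub(paste0("^#", key, " "), "",
                            grep(paste0("^#", key, " "), hdr, value = TRUE)[1])
  L <- as.integer(getv("length"))
  bg <- as.numeric(strsplit(getv("background"), " ")[[1]])
  names(bg) <- AA_ALPHABET[1:20]
  lam <- suppressWarnings(as.numeric(getv("lambda")))
  K <- suppressWarnings(as.numeric(getv("K")))
  body <- lines[!grepl("^#", lines)]
  sc <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  stopifnot(nrow(sc) == L, ncol(sc) == 20L)
  scores <- cbind(sc, 0)
  colnames(scores) <- AA_ALPHABET
  structure(list(length = L, scores = scores, background = bg,
                 counts = NULL, consensus = getv("consensus"),
                 lambda = if (is.na(lam)) NULL else lam,
                 K = if (is.na(K)) NULL else K),
            class = "profile_model")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) read.delim(path, sep = "\t", stringsAsFactors = FALSE)
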