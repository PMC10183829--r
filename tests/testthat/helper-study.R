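# Shared fixtures: the default synthetic study and its pipeline run are
# expensive, so they are built once per test session and cached.

.cache <- new.env(parent = emptyenv())

get_study <- function(seed = 1) {
  key <- paste0("study", seed)
  if (is.null(.cache[[key]])) .cache[[key]] <- simulate_study(seed)
  .cache[[key]]
}

get_run <- function(seed = 1) {
  key <- paste0("run", seed)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- suppressMessages(suppressWarnings(
      run_study(pipeline_config(seed = seed))))
  .cache[[key]]
}

# Alignment columns (in the trimmed C53 alignment) of the planted motifs.
planted_motif_columns <- function(res, pattern = "sAIM") {
  mt <- res$study$truth$motifs
  mt <- mt[mt$pattern == pattern & mt$seq_id %in% res$c53$msa_full$ids, ]
  cols <- unique(unlist(lapply(seq_len(nrow(mt)), function(k)
    seq_to_msa_columns(res$c53$msa_full, mt$seq_id[k],
                       mt$start[k]:mt$end[k]))))
  match(cols, res$c53$kept_columns)
}

# Columns of the conserved N-terminal helix block (positions 1..80 of every
# C53), in trimmed-alignment coordinates.
helix_columns <- function(res) {
  ids <- res$c53$msa_full$ids
  cols <- unique(unlist(lapply(ids, function(id)
    seq_to_msa_columns(res$c53$msa_full, id, 1:80))))
  tc <- match(cols, res$c53$kept_columns)
  tc[!is.na(tc)]
}

random_protein <- function(n, alphabet = c("A", "C", "D", "E", "F", "G",
                                           "H", "I", "K", "L", "M", "N",
                                           "P", "Q", "R", "S", "T", "V",
                                           "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
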