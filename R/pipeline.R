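# End-to-end orchestration of the synthetic comparative study.

#' Pipeline configuration
#'
#' @param seed integer seed controlling generation, calibration and every
#'   other stochastic step.
#' @param n_taxa number of taxa for the synthetic study.
#' @param evalue_threshold E-value cutoff for both search iterations.
#' @param gap_trim gap threshold for alignment trimming (default 0.3).
#' @param gap_trim_profile gap threshold before profile building (0.1).
#' @param min_data fragment filter threshold (default 0.5).
#' @param min_orf minimum ORF length for genome rescue.
#' @param out_dir optional output directory; `NULL` keeps results in
#'   memory only.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_taxa = 12, evalue_threshold = 1e-5,
                            gap_trim = 0.3, gap_trim_profile = 0.1,
                            min_data = 0.5, min_orf = 30, out_dir = NULL) {
  stopifnot(evalue_threshold > 0, gap_trim >= 0, gap_trim <= 1,
            min_data >= 0, min_data <= 1, min_orf >= 10)
  structure(list(seed = as.integer(seed), n_taxa = n_taxa,
                 evalue_threshold = evalue_threshold, gap_trim = gap_trim,
                 gap_trim_profile = gap_trim_profile, min_data = min_data,
                 min_orf = min_orf, out_dir = out_dir),
            class = "pipeline_config")
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste(..., collapse = " ")))
}

# Search + screen one family; returns candidate records and intermediates.
.analyze_family <- function(fam, query, proteomes, cfg, scoring) {
  qid <- paste0("REF_", fam)
  r1 <- search_round1(setNames(query, qid), proteomes,
                      threshold = cfg$evalue_threshold, scoring = scoring)
  cand1 <- unique(r1$target)

  seq_of <- function(ids) {
    out <- character(0)
    for (tx in proteomes$taxa) {
      hit <- intersect(ids, names(proteomes$proteins[[tx]]))
      out[hit] <- proteomes$proteins[[tx]][hit]
    }
    out
  }

  # references anchoring the ortholog clade: the query plus the best
  # round-1 hit of each taxon (the iteration-1 ortholog set)
  anchors <- qid
  if (nrow(r1)) {
    byt <- split(r1, r1$taxon)
    anchors <- c(qid, vapply(byt, function(d) d$target[which.max(d$raw)], ""))
  }

  screen <- function(ids) {
    if (length(ids) < 2L) return(ids)
    seqs <- c(setNames(query, qid), seq_of(ids))
    msa <- progressive_align(seqs, scoring)
    msa <- trim_columns(msa, cfg$gap_trim)
    msa <- filter_fragments(msa, cfg$min_data)
    kept <- setdiff(msa$ids, qid)
    if (length(kept) < 2L || !(qid %in% msa$ids)) return(kept)
    D <- pairwise_distance(msa)
    if (anyNA(D) || nrow(D) < 3L) return(kept)
    gt <- neighbor_joining(D)
    refs <- setdiff(intersect(anchors, gt$tip.label), qid)
    if (!length(refs)) return(kept)
    og <- if (qid %in% gt$tip.label) qid
    setdiff(screen_paralogs(gt, refs, outgroup = og), qid)
  }

  orth1 <- screen(cand1)

  profile <- NULL
  cand2 <- orth1
  if (length(orth1) >= 2L) {
    pm <- progressive_align(c(setNames(query, qid), seq_of(orth1)), scoring)
    pm <- trim_columns(pm, cfg$gap_trim_profile)
    profile <- build_profile(henikoff_weights(pm))
    profile <- calibrate_profile(profile, seed = cfg$seed + 101L,
                                 scoring = scoring)
    hits2 <- profile_search(profile, proteomes,
                            threshold = cfg$evalue_threshold,
                            scoring = scoring)
    cand2 <- union(orth1, unique(hits2$target))
  }
  orth2 <- screen(cand2)

  records <- data.frame(taxon = character(), family = character(),
                        stage = character(), id = character(),
                        stringsAsFactors = FALSE)
  for (id in orth2) {
    tx <- sub("\\|.*$", "", id)
    stage <- if (id %in% cand1) "round1" else "profile"
    records <- rbind(records, data.frame(taxon = tx, family = fam,
                                         stage = stage, id = id))
  }

  # genome rescue for taxa without a surviving ortholog
  rescued <- list()
  if (!is.null(profile)) {
    missing_tx <- setdiff(proteomes$taxa, unique(records$taxon))
    for (tx in missing_tx) {
      g <- proteomes$genomes[[tx]]
      if (is.null(g)) next
      rh <- six_frame_rescue(profile, g, min_orf = cfg$min_orf,
                             threshold = cfg$evalue_threshold,
                             scoring = scoring, seed = cfg$seed + 101L)
      if (nrow(rh)) {
        best <- rh[which.min(rh$evalue), ]
        id <- paste0(tx, "|", fam, "_rescued")
        records <- rbind(records, data.frame(taxon = tx, family = fam,
                                             stage = "genome-rescue", id = id))
        rescued[[id]] <- best
      }
    }
  }
  list(records = records, round1 = r1, orthologs = orth2,
       profile = profile, rescued = rescued)
}

#' Run the end-to-end synthetic study
#'
#' Simulation, two-iteration homology search with paralog screening,
#' genome rescue, presence/absence assembly, Dollo loss mapping, phi
#' co-evolution with Ward-D2 clustering, and the grouped C53 conservation
#' and motif analysis. Deterministic given the config.
#'
#' @param config a [pipeline_config()].
#' @param study optionally a pre-built [simulate_study()] result (must
#'   match the config seed); default generates one.
#' @return list of class `study_result` with the study, the assembled
#'   matrix (`presence`), per-family `loss_maps`, `phi`, `dendrogram`,
#'   `c53` (grouped MSA, score tracks, motif hits) and `records`.
#' @export
run_study <- function(config = pipeline_config(), study = NULL) {
  cfg <- config
  scoring <- scoring_matrix()
  if (is.null(study)) {
    .stage_log("simulate", "seed", cfg$seed, "n_taxa", cfg$n_taxa)
    study <- simulate_study(cfg$seed, n_taxa = cfg$n_taxa)
  }
  taxa <- sort(rownames(study$truth$presence))
  proteomes <- proteome_set(study$proteomes, study$genomes)

  records <- list(); fam_out <- list()
  for (fam in study$families) {
    res <- .analyze_family(fam, study$queries[[paste0("REF_", fam)]],
                           proteomes, cfg, scoring)
    .stage_log("search", fam, ":", nrow(res$round1), "round1 hits,",
               length(res$orthologs), "orthologs,",
               length(res$rescued), "rescued")
    records[[fam]] <- res$records
    fam_out[[fam]] <- res
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL

  presence <- assemble_matrix(records, taxa, study$families)
  .stage_log("matrix", sum(presence), "present entries of", length(presence))

  loss_maps <- list()
  for (fam in study$families) {
    p <- presence[, fam]
    if (any(p == 1))
      loss_maps[[fam]] <- dollo_losses(study$tree, p)
  }

  phim <- phi_matrix(presence)
  dend <- ward_cluster(phim)
  .stage_log("coevolve", "phi computed for", ncol(presence), "families")

  # grouped C53 conservation: groups from the assembled UFM1 column
  c53_ids <- records$id[records$family == "c53"]
  c53_seqs <- character(0)
  for (tx in taxa) {
    hit <- intersect(c53_ids, names(study$proteomes[[tx]]))
    c53_seqs[hit] <- study$proteomes[[tx]][hit]
  }
  c53_full <- progressive_align(c53_seqs, scoring)
  c53_msa <- trim_columns(c53_full, cfg$gap_trim)
  c53_kept <- attr(c53_msa, "kept_columns")
  c53_msa <- filter_fragments(c53_msa, cfg$min_data)
  grp <- ifelse(presence[sub("\\|.*$", "", c53_msa$ids), "ufm1"] == 1,
                "UFM1+", "UFM1-")
  c53_msa$groups <- setNames(grp, c53_msa$ids)
  tg <- twogroup_score(c53_msa, scoring)
  cons <- column_conservation(c53_msa, scoring)
  motif_hits <- do.call(rbind, lapply(names(c53_seqs), function(id)
    rbind(scan_saim(c53_seqs[[id]], id), scan_caim(c53_seqs[[id]], id))))
  .stage_log("conserve", ncol(c53_msa$aln), "columns scored;",
             nrow(motif_hits), "motif hits")

  out <- structure(list(study = study, config = cfg, records = records,
                        presence = presence, loss_maps = loss_maps,
                        phi = phim, dendrogram = dend,
                        c53 = list(msa = c53_msa, msa_full = c53_full,
                                   kept_columns = c53_kept, twogroup = tg,
                                   conservation = cons, motifs = motif_hits),
                        family_results = fam_out),
                   class = "study_result")
  if (!is.null(cfg$out_dir)) write_study_outputs(out, cfg$out_dir)
  out
}

#' Write the analytic outputs of a study run
#'
#' Presence/absence and provenance TSVs, loss map TSV, phi TSV, dendrogram
#' newick, conservation tracks, motif hits (1-based table and BED-like
#' 0-based half-open), and a JSON run manifest with config, seed and
#' package version.
#'
#' @param result a [run_study()] result.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_study_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pres <- result$presence
  write_tsv(data.frame(taxon = rownames(pres), as.data.frame(unclass(pres))),
            file.path(out_dir, "presence.tsv"))
  prov <- attr(pres, "provenance")
  write_tsv(data.frame(taxon = rownames(prov), as.data.frame(prov)),
            file.path(out_dir, "provenance.tsv"))
  ldf <- do.call(rbind, lapply(names(result$loss_maps), function(f) {
    lm <- result$loss_maps[[f]]
    if (lm$n_losses)
      data.frame(family = f, branch = lm$loss_branches, n_losses = lm$n_losses)
  }))
  if (is.null(ldf)) ldf <- data.frame(family = character(),
                                      branch = character(),
                                      n_losses = integer())
  write_tsv(ldf, file.path(out_dir, "losses.tsv"))
  write_tsv(data.frame(family = rownames(result$phi),
                       as.data.frame(unclass(result$phi))),
            file.path(out_dir, "phi.tsv"))
  writeLines(cluster_newick(result$dendrogram),
             file.path(out_dir, "dendrogram.nwk"))
  write_tsv(result$c53$twogroup, file.path(out_dir, "twogroup.tsv"))
  write_tsv(result$c53$conservation, file.path(out_dir, "conservation.tsv"))
  write_tsv(result$c53$motifs, file.path(out_dir, "motifs.tsv"))
  write_tsv(motif_hits_bed(result$c53$motifs), file.path(out_dir, "motifs.bed"))
  manifest <- list(config = unclass(result$config),
                   seed = result$config$seed,
                   package = "ufmevo",
                   version = as.character(utils::packageVersion("ufmevo")),
                   n_taxa = nrow(pres), families = colnames(pres))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Map sequence positions to alignment columns
#'
#' @param msa a [grouped_msa()].
#' @param id row id.
#' @param positions 1-based residue positions in the de-gapped row.
#' @return alignment column indices (`NA` for positions trimmed away).
#' @export
seq_to_msa_columns <- function(msa, id, positions) {
  row <- msa$aln[match(id, msa$ids), ]
  resno <- cumsum(row != "-")
  resno[row == "-"] <- NA
  match(positions, resno)
}
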