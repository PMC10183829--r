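# Synthetic study generator: species tree, gene families with correlated
# presence/absence (single gain at the root, sampled branch losses),
# diverged paralogs, composition-matched decoys, fragmentary orthologs,
# C53-like sequences whose IDRs carry sAIMs only in UFM1-retaining taxa,
# and one unannotated ortholog hidden in a nucleotide genome.

#' Simulate a rooted binary species tree
#'
#' Random topology with exponential branch lengths (mean `mean_branch`,
#' units: expected substitutions per site); pure function of
#' `(n_taxa, seed, mean_branch)`.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param seed integer seed.
#' @param mean_branch mean branch length (default 0.12).
#' @return rooted binary `phylo` with leaves `t01, t02, ...` and internal
#'   labels `n1, n2, ...`.
#' @export
simulate_tree <- function(n_taxa, seed, mean_branch = 0.12) {
  if (n_taxa < 3) stop("n_taxa must be >= 3", call. = FALSE)
  tr <- withr::with_seed(seed, {
    t0 <- ape::rtree(n_taxa, rooted = TRUE,
                     tip.label = sprintf("t%02d", seq_len(n_taxa)))
    t0$edge.length <- rexp(nrow(t0$edge), rate = 1 / mean_branch)
    t0
  })
  tr$node.label <- paste0("n", seq_len(tr$Nnode))
  tr
}

.sub_probs <- function(S, tau = 0.5) {
  P <- exp(S[1:20, 1:20] * tau)
  diag(P) <- 0
  P / rowSums(P)
}

# Evolve integer-coded sequence along one branch: substitution count
# ~ Poisson(branch_length * length); replacement residue drawn proportional
# to the exponentiated BLOSUM62 row of the current residue.
.evolve_codes <- function(codes, bl, P) {
  n <- length(codes)
  k <- rpois(1, bl * n)
  if (k > 0) {
    pos <- sample.int(n, k, replace = TRUE)
    for (p in pos) {
      a <- codes[p]
      if (a <= 20) codes[p] <- sample.int(20L, 1L, prob = P[a, ])
    }
  }
  codes
}

.random_protein_codes <- function(len, prob = aa_background()) {
  sample.int(20L, len, replace = TRUE, prob = prob)
}

#' Family specification for the generator
#'
#' @param family family id.
#' @param root_seq root amino-acid sequence (length >= 30).
#' @param loss_prob per-branch loss probability in `[0, 1]`.
#' @param partner_losses optional loss-branch labels copied from a
#'   correlation partner (overrides sampling).
#' @param paralog_count,decoy_count extra diverged copies / unrelated
#'   composition-matched decoys per taxon.
#' @param paralog_rate branch-rate inflation for paralogs (default 3).
#' @return list of class `family_spec`.
#' @export
family_spec <- function(family, root_seq, loss_prob = 0.1,
                        partner_losses = NULL, paralog_count = 0,
                        decoy_count = 0, paralog_rate = 3) {
  stopifnot(nchar(root_seq) >= 30, loss_prob >= 0, loss_prob <= 1)
  structure(list(family = family, root_seq = root_seq, loss_prob = loss_prob,
                 partner_losses = partner_losses,
                 paralog_count = paralog_count, decoy_count = decoy_count,
                 paralog_rate = paralog_rate),
            class = "family_spec")
}

# Sample canonical loss branches for a tree: edges are visited in preorder
# (parents before children, ape's cladewise order); each branch still
# carrying the family loses it with probability p, and branches below a
# loss are skipped. Returns canonical (maximal absent subtree) labels.
.sample_losses <- function(tree, p, min_present = 1, max_absent = NULL) {
  ntip <- length(tree$tip.label)
  labels <- c(tree$tip.label, tree$node.label)
  repeat {
    lost_below <- logical(ntip + tree$Nnode)
    lost <- character(0)
    for (k in seq_len(nrow(tree$edge))) {
      a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
      if (lost_below[a]) { lost_below[b] <- TRUE; next }
      if (runif(1) < p) { lost_below[b] <- TRUE; lost <- c(lost, labels[b]) }
    }
    pres <- dollo_presence(tree, lost)
    nab <- sum(pres == 0)
    if (sum(pres == 1) >= min_present &&
        (is.null(max_absent) || nab <= max_absent)) {
      if (length(lost)) {
        lm <- dollo_losses(tree, pres)
        return(list(loss_branches = lm$loss_branches, presence = pres))
      }
      return(list(loss_branches = character(0), presence = pres))
    }
  }
}

#' Evolve one gene family over the species tree
#'
#' Single gain at the root; losses sampled per branch (or copied from a
#' correlation partner); surviving lineages accumulate per-site
#' substitutions (count ~ Poisson(branch length x length), replacements
#' drawn from exponentiated BLOSUM62 rows). Paralogs are extra copies
#' evolved at `paralog_rate` times the branch lengths; decoys are random
#' sequences matching the root's residue composition.
#'
#' @param spec a [family_spec()].
#' @param tree a rooted `phylo` from [simulate_tree()].
#' @param seed integer seed.
#' @return list: `seqs` (per-taxon named character vectors), `presence`
#'   (named 0/1), `loss_branches` (canonical labels), `family`.
#' @export
evolve_family <- function(spec, tree, seed) {
  stopifnot(inherits(spec, "family_spec"), inherits(tree, "phylo"))
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  P <- .sub_probs(blosum62())
  withr::with_seed(seed, {
    if (!is.null(spec$partner_losses)) {
      loss <- spec$partner_losses
      pres <- dollo_presence(tree, loss)
    } else if (spec$loss_prob == 0) {
      loss <- character(0)
      pres <- setNames(rep(1L, length(tree$tip.label)), tree$tip.label)
    } else {
      sl <- .sample_losses(tree, spec$loss_prob)
      loss <- sl$loss_branches; pres <- sl$presence
    }
    root <- encode_seq(spec$root_seq)
    evolve_down <- function(rate_mult, start = root) {
      ntip <- length(tree$tip.label)
      seqs_at <- vector("list", ntip + tree$Nnode)
      seqs_at[[ntip + 1L]] <- start
      for (k in seq_len(nrow(tree$edge))) {   # cladewise: parents first
        a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
        seqs_at[[b]] <- .evolve_codes(seqs_at[[a]],
                                      tree$edge.length[k] * rate_mult, P)
      }
      stats::setNames(lapply(seq_len(ntip), function(i)
        decode_seq(seqs_at[[i]])), tree$tip.label)
    }
    # the ortholog crown radiation sits on a short stem below the family
    # root (where the reference query lives), and paralogs duplicate off
    # the root on their own longer stem before evolving at an inflated
    # rate: both clades are then separable in gene trees
    orth <- evolve_down(1, start = .evolve_codes(root, 0.1, P))
    pars <- lapply(seq_len(spec$paralog_count), function(k)
      evolve_down(spec$paralog_rate, start = .evolve_codes(root, 0.5, P)))
    comp <- tabulate(root, 20)
    seqs <- list()
    for (tx in tree$tip.label) {
      v <- character(0)
      if (pres[tx] == 1) {
        v[paste0(tx, "|", spec$family)] <- orth[[tx]]
        for (k in seq_along(pars))
          v[paste0(tx, "|", spec$family, "_par", k)] <- pars[[k]][[tx]]
      }
      for (k in seq_len(spec$decoy_count))
        v[paste0(tx, "|decoy_", spec$family, k)] <-
          decode_seq(.random_protein_codes(length(root), prob = comp))
      seqs[[tx]] <- v
    }
    list(seqs = seqs, presence = pres, loss_branches = loss,
         family = spec$family)
  })
}

# ---- C53-like sequences ---------------------------------------------------

.C53_LAYOUT <- list(
  helix = 80L, idr = 140L,
  saim = c(sAIM1 = 31L, sAIM2 = 42L, sAIM3 = 96L),
  caim = 66L, caim_seq = "WEIV",
  # conserved anchor blocks flanking every motif (locally constrained
  # motif context, shared by all taxa); drawn from an alphabet without
  # I/W/D/S so no anchor can take part in a sAIM match
  anchors = list(c(24L, 30L), c(35L, 41L), c(46L, 52L), c(59L, 65L),
                 c(70L, 76L), c(89L, 95L), c(100L, 106L)),
  del = c(110L, 139L))   # tail segment removed in UFM1- taxa

.ANCHOR_ALPHABET <- c("Q", "N", "E", "T", "P", "A", "G", "K", "R", "H")

# Replacement pools guaranteed dissimilar (negative BLOSUM62 score) to the
# consensus sAIM residues I, D, W, D and unable to recreate the grammar.
.ABLATE_POOLS <- list(c("S", "T", "N", "Q", "E", "K", "R", "G", "P"),
                      c("A", "L", "V", "M", "F", "C"),
                      c("A", "G", "S", "T", "P", "D", "E", "K", "N", "Q"),
                      c("A", "L", "V", "M", "F", "C"))

.scrub_saims <- function(seq) {
  repeat {
    h <- scan_saim(seq)
    if (!nrow(h)) return(seq)
    seq <- mutate_motif(seq, h$start[1] + 2L, "A")  # kill the W
  }
}

#' Build C53-like sequences with UFM1-dependent sAIM content
#'
#' All taxa share conserved alpha-helical flanks (slow substitution rate)
#' around an intrinsically disordered region (fast rate). The motifs sit
#' between short conserved anchor blocks shared by every taxon, which keeps
#' them aligned column-to-column across groups. UFM1-retaining taxa carry
#' three sAIMs (`IDWD`, under purifying selection) plus one cAIM;
#' UFM1-lacking taxa have the sAIM sites ablated with biochemically
#' dissimilar residues (negative BLOSUM62 scores against the consensus), a
#' shortened IDR (tail deletion) and retain the cAIM; any accidental sAIM
#' in a UFM1-lacking sequence is scrubbed.
#'
#' @param presence_of_ufm1 named 0/1 vector over taxa.
#' @param seed integer seed.
#' @param helix_rate,idr_rate expected substitutions/site applied to the
#'   flanks and the (unconstrained) IDR respectively.
#' @return list: `seqs` (named character, one per taxon, ids
#'   `<taxon>|c53`), `motifs` (truth table: taxon, seq_id, pattern, start,
#'   end), `template` (the reference C53 used as homology query).
#' @export
build_c53_sequences <- function(presence_of_ufm1, seed,
                                helix_rate = 0.05, idr_rate = 0.3) {
  if (!length(presence_of_ufm1)) stop("empty presence map", call. = FALSE)
  lay <- .C53_LAYOUT
  P <- .sub_probs(blosum62())
  put <- function(s, at, piece)
    paste0(substring(s, 1, at - 1L), piece,
           substring(s, at + nchar(piece), nchar(s)))
  withr::with_seed(seed, {
    hN <- .random_protein_codes(lay$helix)
    hC <- .random_protein_codes(lay$helix)
    idr_str <- decode_seq(.random_protein_codes(lay$idr))
    for (a in lay$anchors)
      idr_str <- put(idr_str, a[1],
                     paste(sample(.ANCHOR_ALPHABET, a[2] - a[1] + 1L,
                                  replace = TRUE), collapse = ""))
    for (nm in names(lay$saim))
      idr_str <- put(idr_str, lay$saim[[nm]], "IDWD")
    idr_str <- put(idr_str, lay$caim, lay$caim_seq)
    idr <- encode_seq(idr_str)
    template <- paste0(decode_seq(hN), idr_str, decode_seq(hC))
    # positions kept invariant in every taxon: anchors (motif positions are
    # restored per group below)
    anchor_pos <- unlist(lapply(lay$anchors, function(a) a[1]:a[2]))

    seqs <- character(0)
    motifs <- list()
    for (tx in names(presence_of_ufm1)) {
      hn <- decode_seq(.evolve_codes(hN, helix_rate, P))
      hc <- decode_seq(.evolve_codes(hC, helix_rate, P))
      mut <- .evolve_codes(idr, idr_rate, P)
      mut[anchor_pos] <- idr[anchor_pos]
      ids <- decode_seq(mut)
      if (presence_of_ufm1[tx] == 1) {
        for (nm in names(lay$saim)) ids <- put(ids, lay$saim[[nm]], "IDWD")
        ids <- put(ids, lay$caim, lay$caim_seq)
        seq <- paste0(hn, ids, hc)
        for (nm in names(lay$saim)) {
          st <- lay$helix + lay$saim[[nm]]
          motifs[[length(motifs) + 1L]] <- data.frame(
            taxon = tx, seq_id = paste0(tx, "|c53"), pattern = "sAIM",
            start = st, end = st + 3L, stringsAsFactors = FALSE)
        }
        st <- lay$helix + lay$caim
        motifs[[length(motifs) + 1L]] <- data.frame(
          taxon = tx, seq_id = paste0(tx, "|c53"), pattern = "cAIM",
          start = st, end = st + 3L, stringsAsFactors = FALSE)
      } else {
        for (nm in names(lay$saim)) {
          abl <- paste(vapply(.ABLATE_POOLS, function(p) sample(p, 1), ""),
                       collapse = "")
          ids <- put(ids, lay$saim[[nm]], abl)
        }
        ids <- put(ids, lay$caim, lay$caim_seq)
        ids <- paste0(substring(ids, 1, lay$del[1] - 1L),
                      substring(ids, lay$del[2] + 1L, lay$idr))
        seq <- .scrub_saims(paste0(hn, ids, hc))
        st <- lay$helix + lay$caim
        motifs[[length(motifs) + 1L]] <- data.frame(
          taxon = tx, seq_id = paste0(tx, "|c53"), pattern = "cAIM",
          start = st, end = st + 3L, stringsAsFactors = FALSE)
      }
      seqs[paste0(tx, "|c53")] <- seq
    }
    list(seqs = seqs, motifs = do.call(rbind, motifs), template = template)
  })
}

# ---- full study -----------------------------------------------------------

.CODON_TABLE <- NULL

.reverse_translate <- function(protein) {
  aa <- Biostrings::GENETIC_CODE
  by_aa <- split(names(aa), unname(aa))
  ch <- strsplit(protein, "")[[1]]
  cods <- vapply(ch, function(a) sample(by_aa[[a]], 1), "")
  paste0(paste(cods, collapse = ""), "TAA")
}

.random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                          replace = TRUE), collapse = "")

.revcomp <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Simulate a complete synthetic study
#'
#' Generates the default stated world: a seeded species tree, seven gene
#' families emulating the UFMylation pathway plus C53 (with DDRGK1 as the
#' planted correlation partner of UFM1, its losses copied), paralogs for
#' two families, composition-matched decoys, two planted fragmentary
#' orthologs (truncated below 50%), and one ortholog omitted from its
#' proteome but encoded on the reverse strand of that taxon's genome.
#'
#' @param seed integer seed; the whole study is a pure function of the
#'   arguments.
#' @param n_taxa number of taxa (default 12).
#' @param mean_branch mean branch length (default 0.12).
#' @return list of class `synthetic_study`: `tree`, `families`,
#'   `proteomes` (per-taxon named vectors), `genomes`, `queries`,
#'   `truth` (presence matrix, losses, motifs, fragments, hidden),
#'   `groups` (UFM1 labels), `seed`.
#' @export
simulate_study <- function(seed, n_taxa = 12, mean_branch = 0.12) {
  tree <- simulate_tree(n_taxa, seed = seed, mean_branch = mean_branch)
  taxa <- sort(tree$tip.label)
  # paralogs only in families without a planted fragment or hidden
  # ortholog, so those perturbations stay visible in the assembled matrix
  fam_cfg <- list(
    list(family = "ufm1",   len = 210, loss = 0.12, paralogs = 1, decoys = 1),
    list(family = "uba5",   len = 260, loss = 0.05, paralogs = 0, decoys = 0),
    list(family = "ufc1",   len = 200, loss = 0.05, paralogs = 0, decoys = 0),
    list(family = "ufl1",   len = 280, loss = 0.05, paralogs = 1, decoys = 1),
    list(family = "ufsp2",  len = 240, loss = 0.08, paralogs = 0, decoys = 0),
    list(family = "ddrgk1", len = 230, loss = NA,   paralogs = 0, decoys = 0))

  sub_seed <- function(i) (seed %% 100000L) * 1000L + i

  # UFM1 first: its presence pattern must be informative (both states).
  ufm1_root <- withr::with_seed(sub_seed(1),
                                decode_seq(.random_protein_codes(210)))
  i <- 0L
  repeat {
    ev_ufm1 <- evolve_family(
      family_spec("ufm1", ufm1_root, loss_prob = 0.12, paralog_count = 1,
                  decoy_count = 1),
      tree, seed = sub_seed(2) + i * 17L)
    nab <- sum(ev_ufm1$presence == 0)
    if (nab >= 2 && nab <= n_taxa - 3) break
    i <- i + 1L
  }

  fams <- list(ufm1 = ev_ufm1)
  roots <- c(ufm1 = ufm1_root)
  k <- 10L
  for (cfg in fam_cfg[-1]) {
    root <- withr::with_seed(sub_seed(k), decode_seq(.random_protein_codes(cfg$len)))
    spec <- family_spec(cfg$family, root,
                        loss_prob = ifelse(is.na(cfg$loss), 0, cfg$loss),
                        partner_losses = if (cfg$family == "ddrgk1")
                          ev_ufm1$loss_branches,
                        paralog_count = cfg$paralogs, decoy_count = cfg$decoys)
    fams[[cfg$family]] <- evolve_family(spec, tree, seed = sub_seed(k + 1))
    roots[cfg$family] <- root
    k <- k + 10L
  }

  c53 <- build_c53_sequences(fams$ufm1$presence, seed = sub_seed(90))
  fams$c53 <- list(seqs = lapply(setNames(taxa, taxa), function(tx)
                     c53$seqs[paste0(tx, "|c53")]),
                   presence = setNames(rep(1L, length(taxa)), taxa),
                   loss_branches = character(0), family = "c53")
  roots["c53"] <- c53$template
  families <- names(fams)

  proteomes <- lapply(setNames(taxa, taxa), function(tx)
    unlist(lapply(fams, function(f) f$seqs[[tx]])))
  # unlist() prefixes names with the list element name; restore ids
  proteomes <- lapply(proteomes, function(v) {
    names(v) <- sub("^[^.]*\\.", "", names(v))
    v
  })

  # planted fragments: truncate to 40% (below the 50%-data rule)
  frag <- list()
  for (ff in c("ufc1", "ufsp2")) {
    pres_tx <- taxa[fams[[ff]]$presence[taxa] == 1]
    if (length(pres_tx) >= 3) {
      tx <- pres_tx[ifelse(ff == "ufc1", 2L, 3L)]
      id <- paste0(tx, "|", ff)
      full <- proteomes[[tx]][[id]]
      proteomes[[tx]][[id]] <- substring(full, 1, floor(0.4 * nchar(full)))
      frag[[length(frag) + 1L]] <- data.frame(taxon = tx, family = ff, id = id,
                                              stringsAsFactors = FALSE)
    }
  }
  fragments <- if (length(frag)) do.call(rbind, frag) else
    data.frame(taxon = character(), family = character(), id = character())

  # hidden genome ortholog: last present taxon of uba5 (not fragmentary)
  pres_tx <- taxa[fams$uba5$presence[taxa] == 1]
  hidden_tx <- pres_tx[length(pres_tx)]
  hidden_id <- paste0(hidden_tx, "|uba5")
  hidden_prot <- proteomes[[hidden_tx]][[hidden_id]]
  proteomes[[hidden_tx]] <-
    proteomes[[hidden_tx]][names(proteomes[[hidden_tx]]) != hidden_id]

  genomes <- withr::with_seed(sub_seed(95), {
    g <- lapply(setNames(taxa, taxa), function(tx) .random_dna(3000))
    cds <- .reverse_translate(hidden_prot)
    flank <- .random_dna(2000)
    g[[hidden_tx]] <- paste0(flank, .revcomp(cds), .random_dna(2000))
    g
  })
  hidden <- data.frame(taxon = hidden_tx, family = "uba5", id = hidden_id,
                       strand = "-", start = 2001L,
                       end = 2000L + nchar(hidden_prot) * 3L + 3L,
                       protein = hidden_prot, stringsAsFactors = FALSE)

  presence <- do.call(cbind, lapply(fams, function(f) f$presence[taxa]))
  colnames(presence) <- families
  losses <- lapply(fams, `[[`, "loss_branches")

  structure(list(
    tree = tree, families = families,
    proteomes = proteomes, genomes = genomes,
    queries = setNames(as.character(roots[families]),
                       paste0("REF_", families)),
    truth = list(presence = presence, losses = losses,
                 motifs = c53$motifs, fragments = fragments, hidden = hidden),
    groups = setNames(ifelse(fams$ufm1$presence[taxa] == 1, "UFM1+", "UFM1-"),
                      taxa),
    seed = seed), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", length(x$truth$presence[, 1]), "taxa,",
      length(x$families), "families, seed", x$seed, "\n")
  invisible(x)
}

#' Write a study to a file tree
#'
#' FASTA proteome and genome per taxon, newick species tree, group-label
#' TSV, reference query FASTA, and ground-truth TSVs. One declared
#' taxon/family ortholog is absent from the proteome FASTA but encoded in
#' that taxon's genome (see `truth/hidden.tsv`).
#'
#' @param study a [simulate_study()] result.
#' @param out_dir output directory (created).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(study, out_dir) {
  for (d in c("", "proteomes", "genomes", "truth"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  taxa <- rownames(study$truth$presence)
  for (tx in taxa) {
    write_fasta(study$proteomes[[tx]],
                file.path(out_dir, "proteomes", paste0(tx, ".faa")))
    write_fasta(setNames(study$genomes[[tx]], tx),
                file.path(out_dir, "genomes", paste0(tx, ".fna")))
  }
  ape::write.tree(study$tree, file.path(out_dir, "species_tree.nwk"))
  write_fasta(study$queries, file.path(out_dir, "queries.faa"))
  write_tsv(data.frame(taxon = taxa, group = study$groups[taxa]),
            file.path(out_dir, "groups.tsv"))
  pres <- study$truth$presence
  long <- data.frame(taxon = rep(rownames(pres), ncol(pres)),
                     family = rep(colnames(pres), each = nrow(pres)),
                     present = as.integer(pres))
  write_tsv(long, file.path(out_dir, "truth", "presence.tsv"))
  lt <- study$truth$losses
  ldf <- do.call(rbind, lapply(names(lt), function(f)
    if (length(lt[[f]])) data.frame(family = f, branch = lt[[f]],
                                    n_losses = length(lt[[f]]))))
  if (is.null(ldf)) ldf <- data.frame(family = character(),
                                      branch = character(),
                                      n_losses = integer())
  write_tsv(ldf, file.path(out_dir, "truth", "losses.tsv"))
  write_tsv(study$truth$motifs, file.path(out_dir, "truth", "motifs.tsv"))
  write_tsv(study$truth$fragments, file.path(out_dir, "truth", "fragments.tsv"))
  write_tsv(study$truth$hidden, file.path(out_dir, "truth", "hidden.tsv"))
  invisible(out_dir)
}

#' Read back a fixture written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `proteomes`, `genomes`, `tree`, `queries`, `groups`,
#'   `truth`.
#' @export
read_fixture <- function(dir) {
  pf <- list.files(file.path(dir, "proteomes"), full.names = TRUE)
  taxa <- sub("\\.faa$", "", basename(pf))
  proteomes <- setNames(lapply(pf, read_fasta), taxa)
  gf <- list.files(file.path(dir, "genomes"), full.names = TRUE)
  genomes <- setNames(lapply(gf, function(p) unname(read_fasta(p))[1]),
                      sub("\\.fna$", "", basename(gf)))
  groups_df <- read_tsv(file.path(dir, "groups.tsv"))
  list(proteomes = proteomes, genomes = genomes,
       tree = ape::read.tree(file.path(dir, "species_tree.nwk")),
       queries = read_fasta(file.path(dir, "queries.faa")),
       groups = setNames(groups_df$group, groups_df$taxon),
       truth = list(
         presence = read_tsv(file.path(dir, "truth", "presence.tsv")),
         losses = read_tsv(file.path(dir, "truth", "losses.tsv")),
         motifs = read_tsv(file.path(dir, "truth", "motifs.tsv")),
         fragments = read_tsv(file.path(dir, "truth", "fragments.tsv")),
         hidden = read_tsv(file.path(dir, "truth", "hidden.tsv"))))
}
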