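# The synthetic-data generator: trees, family evolution, C53 construction,
# fixture round trips.

test_that("simulate_tree is deterministic and shaped correctly", {
  tr <- simulate_tree(3, seed = 1)
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(nrow(tr$edge), 4L)  # rooted binary: 2n - 2 edges
  expect_true(all(tr$edge.length >= 0))
  expect_identical(ape::write.tree(simulate_tree(8, seed = 7)),
                   ape::write.tree(simulate_tree(8, seed = 7)))
  expect_false(identical(ape::write.tree(simulate_tree(8, seed = 7)),
                         ape::write.tree(simulate_tree(8, seed = 8))))
  expect_error(simulate_tree(2, seed = 1), "n_taxa")
})

test_that("evolve_family honours loss structure and rates", {
  tr <- simulate_tree(6, seed = 3)
  root <- strrep("ACDEFGHIKLMNPQRSTVWY", 3)
  ev0 <- evolve_family(family_spec("f", root, loss_prob = 0), tr, seed = 5)
  expect_true(all(ev0$presence == 1))
  expect_equal(ev0$loss_branches, character(0))
  # correlation partner: identical loss branch sets by construction
  ev1 <- evolve_family(family_spec("g", root, loss_prob = 0.25), tr, seed = 6)
  ev2 <- evolve_family(family_spec("h", root,
                                   partner_losses = ev1$loss_branches),
                       tr, seed = 7)
  expect_identical(ev2$loss_branches, ev1$loss_branches)
  expect_equal(ev2$presence, ev1$presence)
  # zero branch lengths: no substitutions inside the tree, so every
  # ortholog equals the (stem-evolved) crown ancestor exactly
  tr0 <- tr; tr0$edge.length[] <- 0
  ev3 <- evolve_family(family_spec("z", root, loss_prob = 0), tr0, seed = 8)
  seqs <- unlist(lapply(ev3$seqs, function(v) v[grepl("\\|z$", names(v))]))
  expect_equal(length(unique(unname(seqs))), 1L)  # all leaves identical
  # determinism
  ev4 <- evolve_family(family_spec("f", root, loss_prob = 0), tr, seed = 5)
  expect_identical(ev4$seqs, ev0$seqs)
})

test_that("decoys match ortholog residue composition", {
  tr <- simulate_tree(8, seed = 9)
  root <- withr::with_seed(2, random_protein(250))
  ev <- evolve_family(family_spec("f", root, loss_prob = 0, decoy_count = 2),
                      tr, seed = 10)
  comp <- function(s) {
    t <- table(factor(strsplit(s, "")[[1]], levels = LETTERS))
    as.numeric(t / sum(t))
  }
  root_comp <- comp(root)
  for (tx in names(ev$seqs)) {
    for (id in grep("decoy", names(ev$seqs[[tx]]), value = TRUE)) {
      expect_lt(max(abs(comp(ev$seqs[[tx]][[id]]) - root_comp)), 0.08)
    }
  }
})

test_that("build_c53_sequences plants the UFM1-conditional motif pattern", {
  pres <- setNames(c(1, 1, 1, 0, 0), paste0("t", 1:5))
  out <- build_c53_sequences(pres, seed = 4)
  for (tx in names(pres)) {
    s <- out$seqs[[paste0(tx, "|c53")]]
    if (pres[tx] == 1) {
      expect_gte(nrow(scan_saim(s)), 2L)
    } else {
      expect_equal(nrow(scan_saim(s)), 0L)
      expect_gte(nrow(scan_caim(s)), 1L)
    }
  }
  # UFM1-lacking IDRs are consistently shorter
  lens <- nchar(out$seqs)
  expect_lt(max(lens[paste0(c("t4", "t5"), "|c53")]),
            min(lens[paste0(c("t1", "t2", "t3"), "|c53")]))
  # truth coordinates point at real motif instances
  for (k in seq_len(nrow(out$motifs))) {
    m <- out$motifs[k, ]
    sub <- substr(out$seqs[[m$seq_id]], m$start, m$end)
    pat <- if (m$pattern == "sAIM") "^I[DS]W[GD]$" else "^[WFY]..[LIV]$"
    expect_match(sub, pat)
  }
  # determinism / seed sensitivity
  expect_identical(build_c53_sequences(pres, seed = 4)$seqs, out$seqs)
  expect_false(identical(build_c53_sequences(pres, seed = 5)$seqs, out$seqs))
  expect_error(build_c53_sequences(setNames(numeric(0), character(0)), 1),
               "empty")
})

test_that("the default study satisfies its own ground-truth invariants", {
  st <- get_study()
  pres <- st$truth$presence
  expect_equal(dim(pres), c(12L, 7L))
  # Dollo consistency: presence is reproducible from the loss lists
  taxa <- rownames(pres)
  for (fam in st$families) {
    expect_equal(dollo_presence(st$tree, st$truth$losses[[fam]])[taxa],
                 setNames(pres[, fam], taxa), info = fam)
  }
  # the hidden ortholog is absent from its proteome but in the genome
  hid <- st$truth$hidden
  expect_false(hid$id %in% names(st$proteomes[[hid$taxon]]))
  expect_equal(pres[hid$taxon, hid$family], 1L)
  expect_match(st$genomes[[hid$taxon]], "", fixed = TRUE)
  # fragments are below half length of their family root
  for (k in seq_len(nrow(st$truth$fragments))) {
    fr <- st$truth$fragments[k, ]
    len <- nchar(st$proteomes[[fr$taxon]][[fr$id]])
    qlen <- nchar(st$queries[[paste0("REF_", fr$family)]])
    expect_lt(len / qlen, 0.5)
  }
  # generation is a pure function of the seed
  expect_identical(simulate_study(1)$proteomes, st$proteomes)
})

test_that("write_fixture round-trips through the io module", {
  st <- get_study()
  dir <- withr::local_tempdir()
  write_fixture(st, dir)
  back <- read_fixture(dir)
  taxa <- rownames(st$truth$presence)
  for (tx in taxa) {
    expect_equal(back$proteomes[[tx]], st$proteomes[[tx]], info = tx)
    expect_equal(unname(back$genomes[[tx]]), st$genomes[[tx]])
  }
  expect_equal(back$queries, st$queries)
  expect_equal(sort(back$tree$tip.label), sort(st$tree$tip.label))
  expect_equal(nrow(back$truth$presence),
               nrow(st$truth$presence) * ncol(st$truth$presence))
  hid <- st$truth$hidden
  expect_false(hid$id %in% names(back$proteomes[[hid$taxon]]))
})
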