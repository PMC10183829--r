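# Pairwise search, E-values, profiles and the six-frame rescue stage.

test_that("smith_waterman scores and spans behave on constructed cases", {
  h <- smith_waterman("WWWWW", "WWWWW")
  expect_equal(h$score, 55)  # 5 x BLOSUM62 W/W = 5 x 11
  expect_equal(c(h$qstart, h$qend, h$tstart, h$tend), c(1, 5, 1, 5))

  # no positive-scoring pair: local alignment floor is 0 with empty span
  h0 <- smith_waterman("WWW", "PPP")
  expect_equal(h0$score, 0)
  expect_equal(c(h0$qstart, h0$qend), c(0, 0))
  expect_equal(h0$qaln, "")

  expect_error(smith_waterman("", "WW"), "empty|invalid")
  expect_error(smith_waterman("W*W", "WW"), "invalid residue")

  # X is scored zero against everything
  hx <- smith_waterman("WXW", "WXW")
  expect_equal(hx$score, 22)
})

test_that("smith_waterman equals exhaustive local-alignment enumeration", {
  sm <- scoring_matrix()
  withr::with_seed(11, {
    for (i in 1:60) {
      q <- random_protein(sample(2:8, 1))
      t <- random_protein(sample(2:8, 1))
      got <- smith_waterman(q, t, sm)$score
      oracle <- ufmevo:::sw_enumerate_cpp(ufmevo:::encode_seq(q),
                                          ufmevo:::encode_seq(t), sm$S,
                                          sm$gap_open, sm$gap_extend)
      expect_equal(got, oracle, info = paste(q, t))
    }
  })
})

test_that("evalue implements Karlin-Altschul statistics", {
  expect_equal(evalue(0, 100, 100), 410)  # K*m*n*e^0 with K = 0.041
  expect_equal(evalue(50, 100, 100), 0.041 * 1e4 * exp(-0.267 * 50),
               tolerance = 1e-12)
  expect_equal(evalue(50, 100, 100), 6.5e-4, tolerance = 0.01)
  # linear in n; strictly decreasing in raw score
  expect_equal(evalue(30, 100, 200), 2 * evalue(30, 100, 100))
  s <- vapply(0:20 * 5, evalue, numeric(1), m = 100, n = 100)
  expect_true(all(diff(s) < 0))
  expect_error(evalue(10, 100, 100, lambda_ = 0), "positive")
  expect_error(evalue(10, 100, 100, K = -1), "positive")
  expect_error(evalue(10, 0, 100), ">= 1")
})

test_that("search_round1 finds planted orthologs and rejects decoys", {
  st <- get_study()
  prot <- proteome_set(st$proteomes)
  q <- st$queries["REF_ufm1"]
  hits <- search_round1(q, prot)
  truth <- st$truth$presence[, "ufm1"]
  orth_ids <- paste0(names(truth)[truth == 1], "|ufm1")
  expect_true(all(orth_ids %in% hits$target))
  expect_false(any(grepl("decoy", hits$target)))
  # threshold = Inf reports every target
  all_hits <- search_round1(q, prot, threshold = Inf)
  expect_equal(nrow(all_hits), sum(lengths(st$proteomes)))
  expect_error(search_round1(q, proteome_set(list(t01 = character(0)))),
               "empty")
})

test_that("build_profile produces sign-correct log-odds", {
  msa <- grouped_msa(c(a = "WAC", b = "WAC", c = "WAC"))
  prof <- build_profile(msa)
  expect_equal(prof$length, 3L)
  expect_gt(prof$scores[1, "W"], 0)
  expect_lt(prof$scores[1, "P"], 0)
  # single-sequence profile: searching the sequence itself scores exactly
  # the sum of its own column log-odds (full ungapped placement)
  one <- build_profile(grouped_msa(c(x = "WACDEFGHIKLMNPQRSTVWYACDEFWWKL")))
  self <- sum(one$scores[cbind(seq_len(one$length),
                               ufmevo:::encode_seq("WACDEFGHIKLMNPQRSTVWYACDEFWWKL"))])
  hit <- ufmevo:::pssm_local_cpp(one$scores,
                                 ufmevo:::encode_seq("WACDEFGHIKLMNPQRSTVWYACDEFWWKL"),
                                 11, 1)
  expect_equal(hit$score, self, tolerance = 1e-9)
  # pseudocount weight -> infinity flattens all log-odds to 0
  flat <- build_profile(msa, pseudocount_weight = 1e9)
  expect_lt(max(abs(flat$scores[, 1:20])), 1e-6)
  empty <- trim_columns(grouped_msa(c(a = "-", b = "-")), 0.3)
  expect_error(build_profile(empty), "zero retained")
})

test_that("profile round-trips through the text serialization", {
  st <- get_study()
  msa <- progressive_align(c(REF = substr(st$queries[["REF_ufm1"]], 1, 60),
                             A = substr(st$proteomes$t01[["t01|ufm1"]], 1, 60)))
  prof <- calibrate_profile(build_profile(msa), n_shuffle = 50, seed = 3)
  path <- withr::local_tempfile(fileext = ".pssm")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$length, prof$length)
  expect_equal(back$scores[, 1:20], unname(prof$scores[, 1:20]),
               ignore_attr = TRUE, tolerance = 1e-5)
  expect_equal(back$lambda, prof$lambda, tolerance = 1e-6)
})

test_that("profile_search is self-consistent and beats shuffled input", {
  withr::with_seed(5, {
    seqs <- setNames(as.list(replicate(6, random_protein(80))), letters[1:6])
  })
  # sequences share a planted conserved core
  core <- "DEWLKNFPQRGHSTVMAYCW"
  seqs <- lapply(seqs, function(s) paste0(substr(s, 1, 30), core,
                                          substr(s, 51, 80)))
  msa <- progressive_align(unlist(seqs))
  prof <- calibrate_profile(build_profile(henikoff_weights(msa)), seed = 9)
  cons <- prof$consensus
  shuf <- withr::with_seed(4,
    paste(sample(strsplit(cons, "")[[1]]), collapse = ""))
  pr <- proteome_set(list(tx = c(cons = cons, shuf = shuf)))
  hits <- profile_search(prof, pr, threshold = Inf)
  expect_equal(hits$target[which.max(hits$raw)], "cons")
  expect_gt(hits$raw[hits$target == "cons"], hits$raw[hits$target == "shuf"])
})

test_that("profile search rescues a divergent ortholog round 1 misses", {
  # family whose conserved positions admit conservative substitutions
  # (residue groups) rather than identities: a single query carries one
  # residue per column, the profile carries the column preference
  groups <- list(c("I", "L", "V", "M"), c("F", "Y", "W"),
                 c("D", "E", "N", "Q"), c("K", "R", "H"),
                 c("S", "T", "A", "G"))
  withr::with_seed(21, {
    L <- 220
    cons_pos <- sort(sample(L, 60))
    cons_grp <- sample(seq_along(groups), 60, replace = TRUE)
    make <- function() {
      s <- strsplit(random_protein(L), "")[[1]]
      s[cons_pos] <- vapply(cons_grp, function(g) sample(groups[[g]], 1), "")
      paste(s, collapse = "")
    }
    train <- setNames(vapply(1:8, function(i) make(), ""), paste0("m", 1:8))
    distant <- make()
  })
  query <- train[[1]]
  prot <- proteome_set(list(tx = c(far = distant)))
  r1 <- search_round1(c(q = query), prot, threshold = 1e-5)
  expect_equal(nrow(r1), 0L)  # pairwise search misses it
  msa <- grouped_msa(train)   # equal-length rows are already aligned
  prof <- calibrate_profile(build_profile(henikoff_weights(msa)), seed = 2)
  h2 <- profile_search(prof, prot, threshold = 1e-5)
  expect_true("far" %in% h2$target)  # profile recovers it
  # sensitivity ordering at equal threshold
  expect_gte(as.integer(nrow(h2) > 0), as.integer(nrow(r1) > 0))
})

test_that("six-frame translation and rescue honour the genetic code", {
  orfs <- six_frame_orfs(paste0("ATG", strrep("GCC", 15), "TAA"), min_orf = 10)
  fwd <- orfs[orfs$strand == "+" & orfs$frame == 1, ]
  expect_equal(fwd$protein, paste0("M", strrep("A", 15)))
  expect_equal(c(fwd$start, fwd$end), c(1, 48))

  expect_equal(nrow(six_frame_orfs(strrep("N", 300), min_orf = 10)), 0L)
  expect_error(six_frame_orfs("ACGU"), "invalid nucleotide")

  # round trip: reported coordinates re-translate to the reported peptide
  st <- get_study()
  hid <- st$truth$hidden
  g <- st$genomes[[hid$taxon]]
  orfs <- six_frame_orfs(g, min_orf = 30)
  hit <- orfs[orfs$strand == "-" & grepl(hid$protein, orfs$protein, fixed = TRUE), ]
  expect_gte(nrow(hit), 1L)
  seg <- substr(g, hit$start[1], hit$end[1])
  retrans <- as.character(Biostrings::translate(Biostrings::reverseComplement(
    Biostrings::DNAString(seg))))
  expect_equal(retrans, hit$protein[1])
})
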