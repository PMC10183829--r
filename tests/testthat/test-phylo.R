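# Distances, neighbor joining, paralog screening, Dollo loss mapping.

test_that("pairwise_distance is a Poisson-corrected p-distance", {
  msa <- grouped_msa(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL"))
  expect_equal(unname(pairwise_distance(msa)["a", "b"]), 0)
  # p = 0.1 -> -ln(0.9)
  msa2 <- grouped_msa(c(a = "ACDEFGHIKL", b = "WCDEFGHIKL"))
  expect_equal(unname(pairwise_distance(msa2)["a", "b"]), -log(0.9),
               tolerance = 1e-12)
  # symmetric; zero-shared-column pairs are NA with a warning
  D <- pairwise_distance(msa2)
  expect_equal(D, t(D))
  expect_warning(D3 <- pairwise_distance(
    grouped_msa(c(a = "AC--", b = "--DE", c = "ACDE"))), "undefined")
  expect_true(is.na(D3["a", "b"]))
})

test_that("neighbor_joining recovers additive trees", {
  # ((A:1,B:2),(C:3,D:4)) with internal edge 1
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  # the AB|CD split is recovered: unrooted distance to the generating tree 0
  true <- ape::read.tree(text = "((A:1,B:2):0.5,(C:3,D:4):0.5);")
  expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  # recovered patristic distances match the additive input
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(D), rownames(D)],
               D, tolerance = 1e-8)
  # 3 taxa: closed-form three-point branch lengths
  D3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(D3)
  cps <- as.matrix(ape::cophenetic.phylo(t3))[rownames(D3), rownames(D3)]
  expect_equal(cps, D3, tolerance = 1e-8)
  # input order invariance (no ties)
  perm <- c(3, 1, 4, 2)
  tr2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0, 0, 1, 1, 1, 0), 3, 3,
                                       dimnames = list(letters[1:3],
                                                       letters[1:3]))),
               "symmetric")
})

test_that("neighbor_joining recovers 100 seeded random additive topologies", {
  withr::with_seed(31, {
    for (i in 1:100) {
      n <- sample(4:6, 1)
      true <- ape::rtree(n, rooted = FALSE)
      true$edge.length <- true$edge.length + 0.1  # keep edges positive
      D <- as.matrix(ape::cophenetic.phylo(true))
      got <- neighbor_joining(D)
      expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(got)), 0,
                   ignore_attr = TRUE, info = paste("case", i))
    }
  })
})

test_that("screen_paralogs keeps the reference clade", {
  gt <- ape::read.tree(text = paste0(
    "((r1:0.1,(r2:0.1,r3:0.15):0.05):0.3,",
    "(p1:0.9,(p2:0.8,p3:1.1):0.4):0.3);"))
  kept <- screen_paralogs(gt, c("r1", "r2", "r3"))
  expect_setequal(kept, c("r1", "r2", "r3"))
  # reference set = all leaves retains everything
  expect_setequal(screen_paralogs(gt, gt$tip.label), gt$tip.label)
  # monotone: adding a reference never shrinks the returned set
  k1 <- screen_paralogs(gt, "r2")
  k2 <- screen_paralogs(gt, c("r2", "p1"))
  expect_true(all(k1 %in% k2))
  expect_error(screen_paralogs(gt, "nope"), "missing")
})

test_that("the pipeline's paralog screen removes rate-inflated paralogs", {
  res <- get_run()
  ids <- res$records$id
  expect_equal(sum(grepl("_par", ids)), 0L)
  expect_equal(sum(grepl("decoy", ids)), 0L)
  # and keeps the true orthologs: recall over non-fragment families
  st <- res$study
  for (fam in c("ufm1", "ddrgk1")) {
    truth <- st$truth$presence[, fam]
    want <- paste0(names(truth)[truth == 1], "|", fam)
    expect_true(all(want %in% ids))
  }
})

test_that("dollo_losses maps losses as maximal absent subtrees", {
  tr <- ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;")
  lm <- dollo_losses(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(lm$n_losses, 1L)
  expect_equal(lm$loss_branches, "cd")
  expect_equal(dollo_losses(tr, c(A = 1, B = 1, C = 1, D = 1))$n_losses, 0L)
  lm2 <- dollo_losses(tr, c(A = 1, B = 0, C = 1, D = 0))
  expect_equal(lm2$n_losses, 2L)
  expect_setequal(lm2$loss_branches, c("B", "D"))
  expect_error(dollo_losses(tr, c(A = 0, B = 0, C = 0, D = 0)),
               "all-absent")
  # mrca mode confines the gain to the present clade
  lm3 <- dollo_losses(tr, c(A = 1, B = 1, C = 0, D = 0), gain = "mrca")
  expect_equal(lm3$gain_node, "ab")
  expect_equal(lm3$n_losses, 0L)
})

test_that("dollo forward simulation reproduces presence exactly", {
  withr::with_seed(17, {
    for (i in 1:25) {
      n <- sample(4:10, 1)
      tr <- ape::rtree(n)
      tr$node.label <- paste0("n", seq_len(tr$Nnode))
      pres <- setNames(rbinom(n, 1, 0.7), tr$tip.label)
      if (all(pres == 0)) pres[1] <- 1
      lm <- dollo_losses(tr, pres)
      expect_equal(dollo_presence(tr, lm$loss_branches), pres,
                   ignore_attr = TRUE)
    }
  })
})

test_that("dollo loss counts are minimal versus brute-force enumeration", {
  withr::with_seed(23, {
    for (n in 4:8) {
      tr <- ape::rtree(n)
      tr$node.label <- paste0("n", seq_len(tr$Nnode))
      labels <- c(tr$tip.label, tr$node.label)
      branch_ids <- labels[tr$edge[, 2]]
      # leaf sets below every branch, computed once
      below <- lapply(tr$edge[, 2], function(v)
        if (v <= n) tr$tip.label[v] else ape::extract.clade(tr, v)$tip.label)
      names(below) <- branch_ids
      for (code in 1:(2^n - 2)) {   # skip all-absent and include mixed
        pres <- setNames(as.integer(intToBits(code)[1:n]), tr$tip.label)
        lm <- dollo_losses(tr, pres)
        # no strictly smaller branch set explains the absences
        if (lm$n_losses > 0) {
          for (k in 0:(lm$n_losses - 1)) {
            combos <- if (k == 0) list(character(0)) else
              asplit(combn(branch_ids, k), 2)
            ok <- vapply(combos, function(cb) {
              p <- setNames(rep(1L, n), tr$tip.label)
              for (b in cb) p[below[[b]]] <- 0L
              identical(unname(p), unname(pres))
            }, logical(1))
            expect_false(any(ok),
                         info = sprintf("n=%d code=%d k=%d", n, code, k))
          }
        }
        # and its own set does explain them
        expect_equal(dollo_presence(tr, lm$loss_branches), pres,
                     ignore_attr = TRUE)
      }
    }
  })
})
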