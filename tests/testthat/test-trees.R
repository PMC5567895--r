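test_that("NJ reconstructs additive distance matrices exactly", {
  # the worked 4-taxon case: ((A:1,B:2):1,(C:3,D:4))
  tr0 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  coph <- cophenetic(tr0)
  dm <- make_dm(coph[LETTERS[1:4], LETTERS[1:4]],
                rep("Sp_x", 4), LETTERS[1:4])
  tr <- nj_tree(dm)
  expect_equal(unname(cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]]),
               unname(coph[LETTERS[1:4], LETTERS[1:4]]),
               tolerance = 1e-10)
  expect_true(oracle_has_split(tr, c("A", "B")))

  set.seed(31)
  for (n in 5:8) {
    tr0 <- ape::rtree(n)
    tr0$edge.length <- runif(nrow(tr0$edge), 0.05, 1)
    coph <- cophenetic(tr0)
    ids <- tr0$tip.label
    dm <- make_dm(coph[ids, ids], rep("Sp_x", n), ids)
    tr <- nj_tree(dm)
    expect_equal(phangorn::RF.dist(ape::unroot(tr0), tr), 0)
    expect_equal(unname(cophenetic(tr)[ids, ids]),
                 unname(coph[ids, ids]), tolerance = 1e-8)
  }
})

test_that("three taxa obey the three-point branch length formulas", {
  d <- matrix(c(0, 0.3, 0.4, 0.3, 0, 0.5, 0.4, 0.5, 0), 3, 3)
  dm <- make_dm(d, rep("Sp_x", 3), c("a", "b", "c"))
  tr <- nj_tree(dm)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(unname(len["a"]), (0.3 + 0.4 - 0.5) / 2)
  expect_equal(unname(len["b"]), (0.3 + 0.5 - 0.4) / 2)
  expect_equal(unname(len["c"]), (0.4 + 0.5 - 0.3) / 2)
})

test_that("NJ refuses undefined pairs and clamps negative branches", {
  v <- matrix(0.1, 4, 4); diag(v) <- 0
  v[1, 2] <- v[2, 1] <- NA
  dm <- make_dm(v, rep("Sp_x", 4))
  dm$defined[1, 2] <- dm$defined[2, 1] <- FALSE
  expect_error(nj_tree(dm), "matrix error.*t01 / t02")

  set.seed(32)
  for (rep in 1:5) {
    dm2 <- random_dm(n_species = 2, per = 3)
    expect_true(all(nj_tree(dm2)$edge.length >= 0))
  }

  two <- make_dm(matrix(c(0, 1, 1, 0), 2), rep("Sp_x", 2))
  expect_error(nj_tree(two), "at least 3")
})

test_that("bootstrap consensus is deterministic and sane at the edges", {
  aln <- worked_fixture()
  t1 <- bootstrap_consensus(aln, replicates = 30, seed = 42)
  t2 <- bootstrap_consensus(aln, replicates = 30, seed = 42)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_identical(attr(t1, "split_support"), attr(t2, "split_support"))

  sup <- attr(t1, "split_support")$support
  expect_true(all(sup >= 0 & sup <= 100))

  # a single replicate is its own consensus, all supports 100
  t3 <- bootstrap_consensus(aln, replicates = 1, seed = 5)
  expect_true(all(attr(t3, "split_support")$support == 100))
  expect_equal(attr(t3, "n_used"), 1L)
})

test_that("clearly separated species attain full bootstrap support", {
  set.seed(33)
  sim <- simulate_barcodes(sim_spec(
    n_species = 2, individuals = 3,
    loci = data.frame(name = "l", length = 600L, rate = 1,
                      indels = FALSE),
    inter_scale = 0.2, intra_scale = 0.002, seed = 77))
  tr <- bootstrap_consensus(sim$l, replicates = 100, seed = 8)
  res <- resolution_score(tr)
  expect_equal(res$per_species$support, c(100, 100))
  expect_equal(res$n_resolved, 2L)
})

test_that("resolution applies a strict support cutoff on bipartitions", {
  # hand-built supported tree: Sp_a clade at 55%, Sp_b clade at 80%
  tr <- ape::read.tree(text =
    "((a1:1,a2:1)55:1,(b1:1,b2:1)80:1,c1:1);")
  sp <- setNames(c("Sp_a", "Sp_a", "Sp_b", "Sp_b", "Sp_c"),
                 c("a1", "a2", "b1", "b2", "c1"))
  res <- resolution_score(tr, species = sp, cutoff = 60)
  per <- res$per_species
  expect_false(per$resolved[per$species == "Sp_a"])
  expect_true(per$resolved[per$species == "Sp_b"])
  expect_equal(res$excluded, "Sp_c")
  expect_equal(res$n_species_scored, 2L)
  expect_equal(res$n_individuals_resolved, 2L)

  # cutoff is strict: exactly 60 does not resolve
  res60 <- resolution_score(tr, species = sp, cutoff = 55)
  expect_false(res60$per_species$resolved[per$species == "Sp_a"])
})

test_that("resolution equals an exhaustive bipartition membership check", {
  set.seed(34)
  for (rep in 1:5) {
    sim <- simulate_barcodes(sim_spec(
      n_species = 5, individuals = 3,
      loci = data.frame(name = "l", length = 400L, rate = 1,
                        indels = FALSE),
      inter_scale = 0.1, intra_scale = 0.004, seed = 500 + rep))
    tr <- bootstrap_consensus(sim$l, replicates = 40, seed = rep)
    res <- resolution_score(tr)
    sp <- attr(tr, "species")
    for (i in seq_len(nrow(res$per_species))) {
      row <- res$per_species[i, ]
      members <- names(sp)[sp == row$species]
      present <- oracle_has_split(tr, members)
      if (row$support > 50) expect_true(present)
      if (!present) expect_lte(row$support, 50)
    }
  }
})

test_that("Fitch length matches hand evaluation and exhaustive enumeration", {
  # invariant alignment: zero length, undefined indices
  m <- matrix("A", 4, 10)
  aln <- labelled_alignment(m, letters[1:4], rep(c("G_s1", "G_s2"), 2))
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  fs <- fitch_score(tr, aln)
  expect_equal(fs$tree_length, 0L)
  expect_false(fs$defined)

  # one A,A,G,G column on the matching topology: a single step, CI 1
  m2 <- m
  m2[, 5] <- c("A", "A", "G", "G")
  aln2 <- labelled_alignment(m2, letters[1:4], rep(c("G_s1", "G_s2"), 2))
  fs2 <- fitch_score(tr, aln2)
  expect_equal(fs2$tree_length, 1L)
  expect_equal(fs2$ci, 1)
  expect_equal(fs2$rc, fs2$ci * fs2$ri, tolerance = 1e-12)

  # random gap-free 6-taxon alignments vs brute-force enumeration
  set.seed(35)
  for (rep in 1:6) {
    mat <- random_alignment(6, 15, gap_prob = 0, amb_prob = 0)
    rownames(mat) <- paste0("t", 1:6)
    aln3 <- labelled_alignment(mat, paste0("t", 1:6),
                               rep(c("G_s1", "G_s2", "G_s3"), 2))
    topo <- ape::rtree(6, tip.label = paste0("t", 1:6))
    expect_equal(fitch_score(topo, aln3)$tree_length,
                 oracle_fitch(topo, mat))
  }
})

test_that("Fitch length is invariant to leaf permutation and re-rooting", {
  set.seed(36)
  mat <- random_alignment(6, 20, gap_prob = 0.05, amb_prob = 0.02)
  rownames(mat) <- paste0("t", 1:6)
  aln <- labelled_alignment(mat, paste0("t", 1:6), paste0("G_s", 1:6))
  topo <- ape::rtree(6, tip.label = paste0("t", 1:6))
  base <- fitch_score(topo, aln)$tree_length
  perm <- sample(6)
  aln2 <- labelled_alignment(mat[perm, ], paste0("t", 1:6)[perm],
                             aln$species[perm])
  expect_equal(fitch_score(topo, aln2)$tree_length, base)
  rerooted <- ape::root(topo, outgroup = "t3", resolve.root = TRUE)
  expect_equal(fitch_score(rerooted, aln)$tree_length, base)
})

test_that("MP search finds the exhaustive optimum on 5 taxa", {
  set.seed(37)
  for (rep in 1:4) {
    mat <- random_alignment(5, 20, gap_prob = 0, amb_prob = 0)
    rownames(mat) <- paste0("t", 1:5)
    aln <- labelled_alignment(mat, paste0("t", 1:5),
                              c("G_s1", "G_s1", "G_s2", "G_s2", "G_s3"))
    all_topos <- phangorn::allTrees(5, tip.label = paste0("t", 1:5))
    best_exhaustive <- min(vapply(all_topos, oracle_fitch, 0, mat))
    mp <- mp_search(aln, n_starts = 5, seed = rep)
    expect_equal(mp$score$tree_length, best_exhaustive)
  }
})

test_that("MP search is deterministic and respects a single informative split", {
  m <- matrix("C", 5, 12)
  m[, 3] <- c("A", "A", "G", "G", "G")
  aln <- labelled_alignment(m, paste0("t", 1:5),
                            c("G_s1", "G_s1", "G_s2", "G_s2", "G_s3"))
  mp1 <- mp_search(aln, n_starts = 3, seed = 9)
  mp2 <- mp_search(aln, n_starts = 3, seed = 9)
  expect_equal(mp1$score$tree_length, mp2$score$tree_length)
  expect_equal(ape::write.tree(mp1$tree), ape::write.tree(mp2$tree))
  # any topology containing the split {t1,t2} attains length 1
  expect_equal(mp1$score$tree_length, 1L)
  expect_true(oracle_has_split(mp1$tree, c("t1", "t2")))
})
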