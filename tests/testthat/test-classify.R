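test_that("best match verdicts follow the conspecificity of tied best hits", {
  v <- matrix(0.2, 5, 5); diag(v) <- 0
  v[1, 2] <- v[2, 1] <- 0.01          # unique conspecific best hit
  dm <- make_dm(v, c("Sp_a", "Sp_a", "Sp_b", "Sp_b", "Sp_c"))
  expect_equal(best_match(dm, "t01")$verdict, "correct")

  # tie between a conspecific and a heterospecific
  v2 <- v
  v2[1, 3] <- v2[3, 1] <- 0.01
  dm2 <- make_dm(v2, c("Sp_a", "Sp_a", "Sp_b", "Sp_b", "Sp_c"))
  r <- best_match(dm2, "t01")
  expect_equal(r$verdict, "ambiguous")
  expect_setequal(r$best_ids, c("t02", "t03"))

  # all best hits heterospecific
  expect_equal(best_match(dm, "t05")$verdict, "incorrect")
})

test_that("a singleton species query can never be correct", {
  set.seed(21)
  for (rep in 1:20) {
    dm <- random_dm(n_species = 3, per = 3)
    dm$species[5] <- "Sp_lonely"
    for (m in list(function() best_match(dm, 5),
                   function() best_close_match(dm, 5, 0.05),
                   function() all_species_barcodes(dm, 5, 0.05))) {
      expect_false(m()$verdict == "correct")
    }
  }
})

test_that("best close match respects the threshold and degrades to no_match", {
  v <- matrix(0.2, 4, 4); diag(v) <- 0
  v[1, 2] <- v[2, 1] <- 0.05
  dm <- make_dm(v, c("Sp_a", "Sp_a", "Sp_b", "Sp_b"))
  expect_equal(best_close_match(dm, "t01", threshold = 0.03)$verdict,
               "no_match")
  expect_equal(best_close_match(dm, "t01", threshold = 0.05)$verdict,
               "correct")
})

test_that("BCM at infinite threshold reproduces BM verdict for verdict", {
  set.seed(22)
  for (rep in 1:20) {
    dm <- random_dm(n_species = 4, per = sample(2:3, 1))
    for (q in seq_along(dm$ids)) {
      expect_equal(best_close_match(dm, q, threshold = Inf)$verdict,
                   best_match(dm, q)$verdict)
    }
  }
})

test_that("raising the BCM threshold never turns correct into no_match", {
  set.seed(23)
  for (rep in 1:10) {
    dm <- random_dm(n_species = 3, per = 3)
    for (q in seq_along(dm$ids)) {
      v1 <- best_close_match(dm, q, threshold = 0.02)$verdict
      v2 <- best_close_match(dm, q, threshold = 0.08)$verdict
      if (v1 == "correct") expect_equal(v2, "correct")
    }
  }
})

test_that("all species barcodes separates clean clusters and flags ties", {
  v <- matrix(0.2, 4, 4); diag(v) <- 0
  v[1, 2] <- v[2, 1] <- 0.01
  v[3, 4] <- v[4, 3] <- 0.01
  dm <- make_dm(v, c("Sp_a", "Sp_a", "Sp_b", "Sp_b"))
  for (q in 1:4)
    expect_equal(all_species_barcodes(dm, q, 0.5)$verdict, "correct")

  # heterospecific strictly closer than the farthest conspecific
  v2 <- v
  v2[1, 3] <- v2[3, 1] <- 0.005
  dm2 <- make_dm(v2, c("Sp_a", "Sp_a", "Sp_b", "Sp_b"))
  expect_equal(all_species_barcodes(dm2, 1, 0.5)$verdict, "incorrect")

  # exact tie between farthest conspecific and nearest heterospecific
  v3 <- v
  v3[1, 3] <- v3[3, 1] <- 0.01
  dm3 <- make_dm(v3, c("Sp_a", "Sp_a", "Sp_b", "Sp_b"))
  expect_equal(all_species_barcodes(dm3, 1, 0.5)$verdict, "ambiguous")
})

test_that("per-query verdicts equal the brute-force oracle on random matrices", {
  set.seed(24)
  for (rep in 1:60) {
    dm <- random_dm(n_species = sample(2:4, 1), per = sample(1:3, 1) + 1)
    thr <- sample(c(0.02, 0.05, Inf), 1)
    for (q in seq_along(dm$ids)) {
      expect_equal(best_match(dm, q)$verdict,
                   oracle_classify(dm, q, "BM"))
      expect_equal(best_close_match(dm, q, thr)$verdict,
                   oracle_classify(dm, q, "BCM", thr))
      expect_equal(all_species_barcodes(dm, q, thr)$verdict,
                   oracle_classify(dm, q, "ASB", thr))
    }
  }
})

test_that("percentile threshold is the interpolated order statistic", {
  s <- mk_summary_cl(c(0.00, 0.01, 0.02, 0.03, 0.10))
  t95 <- percentile_threshold(s, 95)
  expect_gt(t95, 0.03)
  expect_lt(t95, 0.10)
  expect_equal(t95, 0.03 + 0.8 * 0.07, tolerance = 1e-12)

  expect_equal(percentile_threshold(mk_summary_cl(rep(0.004, 7)), 95),
               0.004)
  expect_error(percentile_threshold(mk_summary_cl(numeric(0)), 95),
               "threshold error")

  set.seed(25)
  for (rep in 1:10) {
    x <- rexp(sample(5:50, 1), 100)
    cov <- sample(c(50, 90, 95, 99), 1)
    expect_equal(percentile_threshold(mk_summary_cl(x), cov),
                 oracle_percentile(x, cov), tolerance = 1e-12)
  }
})

test_that("dataset percentages aggregate per-query verdicts and sum to 100", {
  # two species x two identical specimens: everything correct
  aln <- labelled_alignment(
    c("AAAAAAAAAA", "AAAAAAAAAA", "GGGGGGGGGG", "GGGGGGGGGG"),
    sprintf("s%d", 1:4), rep(c("Sp_a", "Sp_b"), each = 2))
  dm <- distance_matrix(aln)
  for (m in c("BM", "BCM", "ASB")) {
    r <- classify_dataset(dm, m, threshold = 0.5)
    expect_equal(r$pct_correct, 100)
    expect_equal(r$n_queries, 4L)
  }

  set.seed(26)
  for (rep in 1:10) {
    dm <- random_dm(n_species = 3, per = 3)
    r <- classify_dataset(dm, "BCM", threshold = 0.04,
                          fold_no_match = FALSE)
    expect_equal(r$pct_correct + r$pct_ambiguous + r$pct_incorrect +
                   r$pct_no_match, 100, tolerance = 1e-9)
    orc <- sapply(seq_along(dm$ids), function(q)
      oracle_classify(dm, q, "BCM", 0.04))
    expect_equal(r$pct_correct, 100 * mean(orc == "correct"))
    # folding moves no_match into incorrect
    rf <- classify_dataset(dm, "BCM", threshold = 0.04,
                           fold_no_match = TRUE)
    expect_equal(rf$pct_incorrect,
                 r$pct_incorrect + r$pct_no_match)
    expect_equal(rf$pct_no_match, 0)
  }
})

test_that("dataset percentages are invariant to specimen ordering", {
  set.seed(27)
  dm <- random_dm(n_species = 4, per = 3)
  perm <- sample(length(dm$ids))
  dmp <- make_dm(dm$values[perm, perm], dm$species[perm],
                 dm$ids[perm])
  for (m in c("BM", "BCM", "ASB")) {
    a <- classify_dataset(dm, m, threshold = 0.05)
    b <- classify_dataset(dmp, m, threshold = 0.05)
    expect_equal(a$pct_correct, b$pct_correct)
    expect_equal(a$pct_ambiguous, b$pct_ambiguous)
    expect_equal(a$pct_incorrect, b$pct_incorrect)
  }
})

test_that("well-separated simulated species are always identified by BM", {
  set.seed(28)
  for (rep in 1:10) {
    sim <- simulate_barcodes(sim_spec(
      n_species = 6, individuals = 3,
      loci = data.frame(name = "l", length = 500L, rate = 1,
                        indels = FALSE),
      inter_scale = 0.08, intra_scale = 0.004, seed = 4000 + rep))
    r <- classify_dataset(distance_matrix(sim$l), "BM")
    expect_equal(r$pct_correct, 100)
  }
})
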