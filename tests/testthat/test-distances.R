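test_that("k2p matches closed-form evaluations", {
  a <- strrep("A", 100)
  expect_equal(k2p(a, a)$distance, 0)
  expect_equal(k2p(a, a)$n_compared, 100L)

  # 10 transitions out of 100: P = 0.1, Q = 0, d = -log(0.8)/2
  b <- paste0(strrep("G", 10), strrep("A", 90))
  r <- k2p(a, b)
  expect_equal(r$p_transition, 0.1)
  expect_equal(r$q_transversion, 0)
  expect_equal(r$distance, -0.5 * log(0.8), tolerance = 1e-12)

  # mixed: 5 ts + 8 tv out of 50
  x <- rep("A", 50)
  y <- x; y[1:5] <- "G"; y[6:13] <- "C"
  r2 <- k2p(x, y)
  expect_equal(r2$p_transition, 0.1)
  expect_equal(r2$q_transversion, 0.16)
  expect_equal(r2$distance,
               -0.5 * log(1 - 0.2 - 0.16) - 0.25 * log(1 - 0.32),
               tolerance = 1e-12)
  expect_gte(r2$distance, r2$p_transition + r2$q_transversion)
})

test_that("k2p flags saturation and missing overlap instead of erroring", {
  a <- rep("A", 10)
  b <- rep("G", 10)  # P = 1: log argument <= 0
  r <- k2p(a, b)
  expect_false(r$defined)
  expect_true(is.na(r$distance))

  r2 <- k2p(rep("-", 10), rep("A", 10))
  expect_false(r2$defined)
  expect_equal(r2$n_compared, 0L)

  expect_error(k2p(rep("A", 5), rep("A", 6)), "input error")
})

test_that("k2p collapses to Jukes-Cantor when transversions are twice transitions", {
  # with Q = 2P the K2P formula reduces to JC on p = P + Q
  for (k in c(1L, 3L, 7L)) {
    n <- 100L
    x <- rep("A", n)
    y <- x
    y[seq_len(k)] <- "G"                      # k transitions
    y[k + seq_len(2 * k)] <- "C"              # 2k transversions
    d <- k2p(x, y)$distance
    p <- 3 * k / n
    expect_equal(d, -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)
  }
})

test_that("distance_matrix equals the per-pair oracle and ape's K80", {
  set.seed(5)
  for (rep in 1:6) {
    aln <- random_labelled(n_species = 2, per = sample(2:3, 1),
                           L = sample(30:60, 1), gap_prob = 0.08,
                           amb_prob = 0.04)
    dm <- distance_matrix(aln)
    expect_true(isSymmetric(unname(dm$values)))
    expect_true(all(diag(dm$values) == 0))
    expect_true(isSymmetric(dm$defined))
    n <- nrow(aln$seqs)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        o <- oracle_k2p(aln$seqs[i, ], aln$seqs[j, ])
        expect_equal(dm$defined[i, j], o$defined)
        if (o$defined) {
          expect_equal(dm$values[i, j], o$d, tolerance = 1e-12)
          expect_equal(dm$p_transition[i, j], o$P, tolerance = 1e-12)
          expect_equal(dm$n_compared[i, j], o$n, ignore_attr = TRUE)
        }
      }
    }
    # cross-check against ape's K80 with pairwise deletion (ambiguity
    # codes removed first: ape treats them partially, we treat as missing)
    m2 <- aln$seqs
    m2[!(m2 %in% c("A", "C", "G", "T"))] <- "-"
    dd <- ape::dist.dna(ape::as.DNAbin(m2), model = "K80",
                        pairwise.deletion = TRUE)
    ours <- dm$values
    ref <- as.matrix(dd)
    ok <- dm$defined & is.finite(ref)
    expect_equal(ours[ok], ref[ok], tolerance = 1e-9)
  }
})

test_that("divergence summary matches hand enumeration", {
  # two species, two identical sequences each, inter distance constant
  v <- matrix(0.1, 4, 4)
  v[1, 2] <- v[2, 1] <- 0
  v[3, 4] <- v[4, 3] <- 0
  diag(v) <- 0
  dm <- make_dm(v, c("Sp_a", "Sp_a", "Sp_b", "Sp_b"))
  s <- summarize_divergence(dm)
  expect_equal(s$intra_all, c(0, 0))
  expect_equal(s$mean_intra, 0)
  expect_equal(s$mean_inter, 0.1)
  expect_equal(length(s$inter_all), 4L)
  expect_equal(unname(s$theta), c(0, 0))
  expect_equal(unname(s$coalescent_depth), c(0, 0))
  expect_equal(length(s$intra_all) + length(s$inter_all) +
                 s$n_undefined_pairs, 4 * 3 / 2)
})

test_that("theta never exceeds coalescent depth and SE is the SE of the mean", {
  set.seed(10)
  dm <- random_dm(n_species = 4, per = 4)
  s <- summarize_divergence(dm)
  expect_true(all(s$theta <= s$coalescent_depth + 1e-15))
  expect_equal(s$se_intra, sd(s$intra_all) / sqrt(length(s$intra_all)))
  expect_true(all(s$range_intra %in% s$intra_all))
  expect_true(all(s$range_inter %in% s$inter_all))
})

test_that("removing a singleton species leaves intra statistics unchanged", {
  set.seed(11)
  v <- random_dm(n_species = 3, per = 3)
  # append a singleton
  n <- 10
  vals <- matrix(0, n, n)
  vals[1:9, 1:9] <- v$values
  vals[10, 1:9] <- vals[1:9, 10] <- runif(9, 0.2, 0.3)
  dm_with <- make_dm(vals, c(v$species, "Sp_single"))
  s_with <- summarize_divergence(dm_with)
  s_without <- summarize_divergence(v)
  expect_equal(s_with$intra_all, s_without$intra_all)
  expect_equal(s_with$mean_intra, s_without$mean_intra)
  expect_equal(s_with$theta, s_without$theta)
  expect_equal(s_with$singletons, "Sp_single")
})

test_that("undefined pairs are excluded from summaries, not clamped", {
  v <- matrix(0.05, 4, 4); diag(v) <- 0
  v[1, 3] <- v[3, 1] <- NA
  dm <- make_dm(v, c("Sp_a", "Sp_a", "Sp_b", "Sp_b"))
  s <- summarize_divergence(dm)
  expect_equal(s$n_undefined_pairs, 1L)
  expect_equal(length(s$inter_all), 3L)
})

test_that("simulated data shows mean intra below mean inter", {
  set.seed(12)
  for (rep in 1:3) {
    sim <- simulate_barcodes(sim_spec(n_species = 5, individuals = 3,
                                      inter_scale = 0.06,
                                      intra_scale = 0.004,
                                      seed = 800 + rep))
    s <- summarize_divergence(distance_matrix(sim$plastid_fast))
    expect_lt(s$mean_intra, s$mean_inter)
  }
})
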