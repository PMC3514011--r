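test_that("diversity indices match direct pair enumeration", {
  x <- aligned_seq_set(c("AAAAAAAAAA", "AAAAAAAATT"))
  div <- diversity_indices(x)
  expect_equal(div$pi, 0.2)
  expect_equal(div$S, 2L)
  expect_equal(div$K, 2L)
  expect_equal(div$S_over_n, 1)
  expect_false(div$d_defined)

  same <- aligned_seq_set(rep("ACGTACGT", 6))
  ds <- diversity_indices(same)
  expect_equal(ds$S, 0L)
  expect_equal(ds$pi, 0)
  expect_equal(ds$K, 1L)
  expect_true(is.na(ds$D))

  expect_error(diversity_indices(aligned_seq_set("ACGT")), "sample-size")

  y <- random_seq_set(8, 60, seed = 13)
  dy <- diversity_indices(y)
  orc <- oracle_pair_stats(y$sequences)
  expect_equal(dy$pi, orc$mean_prop, tolerance = 1e-12)
  expect_equal(dy$S, oracle_segregating(y$sequences))
  expect_gte(dy$pi, 0)
  expect_lte(dy$K, 8L)
})

test_that("Tajima's D equals the textbook formula and is invariant to relabeling", {
  # 4 sequences, 1 singleton mutation
  x <- aligned_seq_set(c("AAAAAAAAAA", "AAAAAAAAAA", "AAAAAAAAAA",
                         "AAAAAAAAAT"))
  expect_equal(tajimas_d(x), oracle_tajima_d(x$sequences),
               tolerance = 1e-10)

  for (seed in 1:4) {
    y <- random_seq_set(sample(4:12, 1), 50, seed = 30 + seed)
    expect_equal(tajimas_d(y), oracle_tajima_d(y$sequences),
                 tolerance = 1e-10)
    # column shuffle leaves D unchanged
    set.seed(seed)
    cols <- sample(50)
    shuffled <- vapply(strsplit(y$sequences, ""),
                       function(s) paste(s[cols], collapse = ""), "")
    ys <- aligned_seq_set(shuffled)
    expect_equal(tajimas_d(ys), tajimas_d(y), tolerance = 1e-12)
    # row order / labels do not matter
    prm <- sample(length(y$labels))
    yp <- aligned_seq_set(y$sequences[prm])
    expect_equal(tajimas_d(yp), tajimas_d(y), tolerance = 1e-12)
  }

  expect_error(tajimas_d(aligned_seq_set(c("AA", "AT", "TA"))),
               "sample-size")
  expect_error(tajimas_d(aligned_seq_set(rep("ACGT", 5))), "undefined")
})

test_that("the simulated Tajima null is seeded, two-tailed and directionally correct", {
  cfg <- sim_config(n_clades = 1, n_per_clade = 10, niche_centers = 12)
  s <- simulate_sequences(cfg, seed = 41)$seqs
  r1 <- tajima_null_test(s, replicates = 300, seed = 7)
  r2 <- tajima_null_test(s, replicates = 300, seed = 7)
  expect_identical(r1$p_upper, r2$p_upper)
  expect_identical(r1$null_D, r2$null_D)
  expect_gte(r1$p_upper + r1$p_lower, 1)       # ties counted both sides
  expect_true(r1$p_upper > 0 && r1$p_upper <= 1)

  # a balanced mixture of two deep clades inflates D: upper tail small,
  # lower tail near 1
  cfg2 <- sim_config(n_clades = 2, n_per_clade = 6,
                     net_divergence_target = 0.15)
  mix <- simulate_sequences(cfg2, seed = 42)$seqs
  expect_gt(tajimas_d(mix), 1)
  rmix <- tajima_null_test(mix, replicates = 300, seed = 8)
  expect_lt(rmix$p_upper, 0.1)
  expect_gt(rmix$p_lower, 0.9)

  expect_error(tajima_null_test(s, replicates = 50), "configuration")
})

test_that("AMOVA matches the brute-force sum-of-squares partition", {
  set.seed(42)
  base <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
  mut <- function(pos, to) { s <- base; s[pos] <- to; paste(s, collapse = "") }
  seqs <- c(paste(base, collapse = ""), mut(1, "G"), mut(2, "T"),
            mut(5:7, c("T", "A", "C")), mut(c(5, 6, 8), c("T", "A", "A")),
            mut(c(5, 7, 9), c("T", "C", "T")))
  x <- aligned_seq_set(seqs, populations = rep(c("p1", "p2"), each = 3))
  d <- pairwise_k2p(x)
  res <- amova(d, x$populations, permutations = 0)
  orc <- oracle_amova_two_level(d, x$populations)
  expect_equal(res$phi_ST, orc$phi_ST, tolerance = 1e-12)
  expect_equal(unname(res$variance_components[2:3]),
               c(orc$sigma_b, orc$sigma_c), tolerance = 1e-12)
  # the SSD partition is exact
  expect_equal(unname(res$ssd["total"]),
               unname(res$ssd["among_pops"] + res$ssd["within_pops"]),
               tolerance = 1e-9)
  expect_equal(unname(res$ssd["total"]), orc$ssd_total, tolerance = 1e-12)
})

test_that("AMOVA handles fixed differences, permutation seeding and degenerate designs", {
  # two populations fixed for haplotypes 1 step apart: all variance between
  x <- aligned_seq_set(c(rep("AAAAAAAAAA", 4), rep("AAAAAAAAAG", 4)),
                       populations = rep(c("p1", "p2"), each = 4))
  d <- pairwise_k2p(x)
  res <- amova(d, x$populations, permutations = 99, seed = 1)
  expect_equal(res$phi_ST, 1)
  expect_true(res$p_ST >= 1 / 100 && res$p_ST <= 1)

  r2 <- amova(d, x$populations, permutations = 99, seed = 1)
  expect_identical(r2$p_ST, res$p_ST)

  expect_error(amova(d, rep("p1", 8)), "two populations")
  grp_one <- stats::setNames(c("g", "g"), c("p1", "p2"))
  expect_error(amova(d, x$populations, groups = grp_one), "degenerate")
  z <- dist_matrix(matrix(0, 4, 4), labels = paste0("s", 1:4))
  expect_error(amova(z, rep(c("a", "b"), 2)), "undefined Phi")
})

test_that("hierarchical AMOVA partitions variance across groups and permits negative components", {
  cfg <- sim_config(n_clades = 2, n_per_clade = 12)
  sim <- simulate_sequences(cfg, seed = 2)
  d <- pairwise_k2p(sim$seqs)
  # two populations per clade, clades as groups
  pops <- paste0(sim$clades, rep(c("_a", "_b"), length.out = 24))
  names(pops) <- sim$seqs$labels
  grps <- stats::setNames(sub("_.*", "", sort(unique(pops))),
                          sort(unique(pops)))
  h <- amova(d, pops, groups = grps, permutations = 99, seed = 3)
  expect_gt(h$phi_CT, 0.9)          # clades are deeply diverged
  expect_lte(h$phi_ST, 1)
  expect_equal(unname(h$ssd["total"]),
               sum(h$ssd[c("among_groups", "among_pops_within_groups",
                           "within_pops")]), tolerance = 1e-9)
  # within-clade split is arbitrary, so sigma_b can go (slightly) negative
  expect_true(is.finite(h$variance_components[["among_pops_within_groups"]]))
  expect_true(all(c(h$p_ST, h$p_SC, h$p_CT) >= 1 / 100))
})

test_that("pairwise Phi_ST agrees with two-population AMOVA runs", {
  cfg <- sim_config(n_clades = 3, n_per_clade = 6,
                    niche_centers = c(11, 16, 21))
  sim <- simulate_sequences(cfg, seed = 5)
  d <- pairwise_k2p(sim$seqs)
  pw <- pairwise_phi_st(d, sim$clades, permutations = 0)
  pops <- sort(unique(sim$clades))
  for (i in 1:2) {
    for (j in (i + 1):3) {
      idx <- which(sim$clades %in% pops[c(i, j)])
      sub <- dist_matrix(as.matrix(d)[idx, idx])
      ref <- amova(sub, sim$clades[idx], permutations = 0)
      expect_equal(pw$phi_ST[pops[i], pops[j]], ref$phi_ST,
                   tolerance = 1e-12)
    }
  }

  # a population split at random against itself: Phi_ST near zero
  one <- simulate_sequences(sim_config(n_clades = 1, n_per_clade = 16,
                                       niche_centers = 12), seed = 6)
  d1 <- pairwise_k2p(one$seqs)
  set.seed(7)
  halves <- sample(rep(c("h1", "h2"), 8))
  r0 <- amova(d1, stats::setNames(halves, one$seqs$labels),
              permutations = 0)
  expect_lt(abs(r0$phi_ST), 0.2)

  # two monomorphic, distinct populations: Phi_ST = 1
  mono <- aligned_seq_set(c(rep("AAAAAAAAAA", 3), rep("GAAAAAAAAA", 3)),
                          populations = rep(c("x", "y"), each = 3))
  pwm <- pairwise_phi_st(pairwise_k2p(mono), mono$populations,
                         permutations = 0)
  expect_equal(pwm$phi_ST["x", "y"], 1)
})
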