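test_that("the packaged occurrence table loads and validates", {
  tab <- fixture_table()
  expect_s3_class(tab, "sample_table")
  expect_equal(sum(tab$count[tab$phylogroup == "subovoidea"]), 23L)
  expect_equal(sum(tab$count), 457L)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("region,site,latitude,longitude,sst_c,phylogroup,count,source",
             empty)
  expect_error(load_sample_table(empty), "empty")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("region,site,latitude,longitude,sst_c,phylogroup,count,source",
               "x,y,10,10,15.0,A,0,z"), bad)
  expect_error(load_sample_table(bad), "row 1")
})

test_that("weighted median SST reproduces the clade thermal regimes", {
  tab <- fixture_table()
  expect_equal(weighted_median_sst(tab, "new_sp")$median_sst, 11.8)
  expect_equal(weighted_median_sst(tab, "new_sp")$n, 108L)
  expect_equal(weighted_median_sst(tab, "subovoidea")$median_sst, 26.0)
  expect_equal(weighted_median_sst(tab, "A")$median_sst, 15.1)

  one <- tab[tab$site == "Bremerton", , drop = FALSE]
  expect_equal(weighted_median_sst(one, "new_sp")$median_sst, 10.0)
  expect_error(weighted_median_sst(tab, "nonesuch"), "phylogroup")

  # splitting a row into two rows with the same total count changes nothing
  split <- tab
  r <- which(split$phylogroup == "new_sp" & split$count > 1)[1]
  extra <- split[r, ]
  extra$count <- 1L
  split$count[r] <- split$count[r] - 1L
  split <- rbind(split, extra)
  class(split) <- class(tab)
  expect_equal(weighted_median_sst(split, "new_sp")$median_sst,
               weighted_median_sst(tab, "new_sp")$median_sst)
})

test_that("the bootstrap CI of the median is seeded and attains only observable medians", {
  tab <- fixture_table()
  b1 <- bootstrap_median_ci(tab, "new_sp", seed = 5)
  b2 <- bootstrap_median_ci(tab, "new_sp", seed = 5)
  expect_identical(b1[c("ci_low", "ci_high")], b2[c("ci_low", "ci_high")])
  expect_lte(b1$ci_low, b1$ci_high)

  const <- tab[tab$phylogroup == "subovoidea" & tab$sst_c == 26, ]
  class(const) <- class(tab)
  bc <- bootstrap_median_ci(const, "subovoidea", seed = 1)
  expect_equal(bc$ci_low, 26)
  expect_equal(bc$ci_high, 26)

  # two-value multiset {10 x k, 12 x k}: endpoints must be in {10, 11, 12}
  two <- data.frame(region = "r", site = c("a", "b"), latitude = 0,
                    longitude = 0, sst_c = c(10, 12), phylogroup = "A",
                    count = 30L, source = "synthetic")
  class(two) <- c("sample_table", "data.frame")
  bt <- bootstrap_median_ci(two, "A", seed = 3)
  expect_true(all(c(bt$ci_low, bt$ci_high) %in% c(10, 11, 12)))
  # brute-force resampler agreement under the same seed
  set.seed(3)
  meds <- replicate(1000, median(sample(rep(c(10, 12), each = 30), 20,
                                        replace = TRUE)))
  expect_equal(bt$ci_low, unname(quantile(meds, 0.025, type = 1)))
  expect_equal(bt$ci_high, unname(quantile(meds, 0.975, type = 1)))

  expect_error(bootstrap_median_ci(tab, "A", replicates = 10),
               "configuration")
})

test_that("distance matrices over units have the advertised geometry", {
  tab <- data.frame(region = "r", site = c("a", "b", "c"),
                    latitude = c(0, 3, 10), longitude = c(0, 4, 0),
                    sst_c = c(11.8, 17.1, 11.8),
                    phylogroup = c("A", "B", "A"), count = 1L,
                    source = "synthetic")
  class(tab) <- c("sample_table", "data.frame")
  g <- geo_distance_matrix(tab)
  expect_equal(g[1, 2], 5)                      # 3-4-5 on raw degrees
  expect_equal(g[1, 1], 0)
  s <- sst_distance_matrix(tab)
  expect_equal(s[1, 2], 5.3)
  expect_equal(s[1, 3], 0)

  fx <- fixture_table()
  gf <- as.matrix(geo_distance_matrix(fx, unit = "site"))
  expect_equal(gf, t(gf))
  # triangle inequality on all site triples
  n <- nrow(gf)
  ok <- TRUE
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (gf[i, j] > gf[i, k] + gf[k, j] + 1e-9) ok <- FALSE
  }
  expect_true(ok)
  sf <- as.matrix(sst_distance_matrix(fx, unit = "site"))
  u <- coipop:::.mantel_units(fx, "site")
  expect_equal(sf, abs(outer(u$sst_c, u$sst_c, "-")),
               ignore_attr = TRUE)
})

test_that("clade indicator dissimilarity encodes presence/absence", {
  tab <- data.frame(region = "r", site = c("a", "b", "c"),
                    latitude = 1:3, longitude = 0, sst_c = c(10, 12, 14),
                    phylogroup = c("A", "A", "A"), count = 1L,
                    source = "synthetic")
  class(tab) <- c("sample_table", "data.frame")
  expect_true(all(as.matrix(clade_indicator_matrix(tab, "A")) == 0))

  tab$phylogroup <- c("B", "A", "A")
  ci <- as.matrix(clade_indicator_matrix(tab, "B"))
  expect_equal(sum(ci), 4)                      # 2 unit entries per side
  expect_equal(ci[1, 2], 1); expect_equal(ci[2, 3], 0)
  # complementing the indicator leaves the dissimilarity unchanged
  ca <- as.matrix(clade_indicator_matrix(tab, "A"))
  expect_equal(ca, ci, ignore_attr = TRUE)
})

test_that("the partial Mantel statistic matches direct computation", {
  A <- random_symmetric(12, 1); B <- random_symmetric(12, 2)
  C <- random_symmetric(12, 3)
  for (rk in c(TRUE, FALSE)) {
    pm <- partial_mantel(A, B, C, permutations = 0, ranked = rk)
    expect_equal(pm$r, oracle_partial_r(A, B, C, ranked = rk),
                 tolerance = 1e-12)
  }
  # external cross-check
  vg <- vegan::mantel.partial(stats::as.dist(unclass(A)),
                              stats::as.dist(unclass(B)),
                              stats::as.dist(unclass(C)),
                              method = "spearman", permutations = 0)
  expect_equal(partial_mantel(A, B, C, permutations = 0)$r,
               unname(vg$statistic), tolerance = 1e-12)

  # A = B gives r = 1 whatever the nuisance matrix
  expect_equal(partial_mantel(A, A, C, permutations = 0)$r, 1,
               tolerance = 1e-12)
  expect_equal(partial_mantel(A, A, C, permutations = 0, ranked = FALSE)$r,
               1, tolerance = 1e-12)

  # rank invariance under common monotone transforms of A and B
  sq <- function(M) dist_matrix(as.matrix(M)^2)
  expect_equal(partial_mantel(sq(A), sq(B), C, permutations = 0)$r,
               partial_mantel(A, B, C, permutations = 0)$r,
               tolerance = 1e-12)

  p1 <- partial_mantel(A, B, C, permutations = 199, seed = 4)
  p2 <- partial_mantel(A, B, C, permutations = 199, seed = 4)
  expect_identical(p1$p, p2$p)
  expect_true(p1$p >= 1 / 200 && p1$p <= 1)

  Z <- dist_matrix(matrix(1, 5, 5) - diag(5))
  expect_error(partial_mantel(Z, random_symmetric(5, 8),
                              random_symmetric(5, 9), permutations = 0),
               "degenerate matrix A")
  expect_error(partial_mantel(A, B, random_symmetric(6, 10)),
               "conformable")
})

test_that("clade-SST tests recover programmed thermal segregation and honour the null", {
  cfg <- sim_config(niche_centers = c(12, 20), niche_widths = 1.5,
                    colonies_per_site = 10)
  occ <- simulate_occurrence(cfg, seed = 11)
  res <- clade_sst_tests(occ, permutations = 499, seed = 12)
  pair <- res[res$test == "pairwise", ]
  expect_gt(pair$r, 0)
  expect_lt(pair$p, 0.05)
  expect_equal(res$permutations, rep(499L, nrow(res)))

  # shuffled labels kill the association on average
  set.seed(13)
  ps <- replicate(5, {
    u <- coipop:::.expand_colonies(occ)
    u$phylogroup <- sample(u$phylogroup)
    u$unit_id <- paste0("c", seq_len(nrow(u)))
    A <- coipop:::.clade_mismatch_matrix(u)
    B <- sst_distance_matrix(occ)
    C <- geo_distance_matrix(occ)
    partial_mantel(A, B, C, permutations = 99)$p
  })
  expect_gt(mean(ps), 0.2)

  expect_error(clade_sst_tests(occ, phylogroups = "clade1"), "two")
})
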