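# Shared fixture builders and independent brute-force oracles.
# Oracles deliberately avoid the package's own code paths.

random_seq_set <- function(n, L, seed, pops = "unassigned") {
  set.seed(seed)
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), L,
                                    replace = TRUE), collapse = ""))
  aligned_seq_set(seqs, populations = pops)
}

# a shallow family of related sequences (suitable for K2P: low divergence)
related_seq_set <- function(n, L, seed, max_mut = 3, pops = "unassigned") {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- replicate(n, {
    s <- base
    k <- sample(0:max_mut, 1)
    if (k > 0) {
      pos <- sample(L, k)
      s[pos] <- vapply(s[pos], function(x) {
        sample(setdiff(c("A", "C", "G", "T"), x), 1)
      }, "")
    }
    paste(s, collapse = "")
  })
  aligned_seq_set(seqs, populations = pops)
}

random_symmetric <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  dist_matrix(m + t(m))
}

# closed-form K2P from explicit transition/transversion fractions
oracle_k2p <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

# mean pairwise difference count and proportion by direct enumeration
oracle_pair_stats <- function(seq_strings) {
  mats <- strsplit(seq_strings, "")
  n <- length(mats)
  cnt <- c(); prop <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      nd <- sum(mats[[i]] != mats[[j]])
      cnt <- c(cnt, nd)
      prop <- c(prop, nd / length(mats[[i]]))
    }
  }
  list(mean_count = mean(cnt), mean_prop = mean(prop))
}

oracle_segregating <- function(seq_strings) {
  m <- do.call(rbind, strsplit(seq_strings, ""))
  sum(apply(m, 2, function(col) length(unique(col[col %in% c("A", "C", "G", "T")])) > 1))
}

# textbook Tajima's D, written out independently
oracle_tajima_d <- function(seq_strings) {
  n <- length(seq_strings)
  S <- oracle_segregating(seq_strings)
  pi_hat <- oracle_pair_stats(seq_strings)$mean_count
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# flat two-population AMOVA by direct evaluation of the SS partition
oracle_amova_two_level <- function(D, pops) {
  D2 <- as.matrix(D)^2
  N <- nrow(D2)
  labs <- sort(unique(pops))
  ss <- function(idx) if (length(idx) < 2) 0 else sum(D2[idx, idx]) / (2 * length(idx))
  ss_tot <- ss(seq_len(N))
  ss_wp <- sum(sapply(labs, function(p) ss(which(pops == p))))
  n_p <- sapply(labs, function(p) sum(pops == p))
  P <- length(labs)
  sig_c <- ss_wp / (N - P)
  n_prime <- (N - sum(n_p^2) / N) / (P - 1)
  sig_b <- ((ss_tot - ss_wp) / (P - 1) - sig_c) / n_prime
  list(sigma_b = sig_b, sigma_c = sig_c,
       phi_ST = sig_b / (sig_b + sig_c),
       ssd_total = ss_tot, ssd_within = ss_wp)
}

# direct partial correlation of lower triangles
oracle_partial_r <- function(A, B, C, ranked = FALSE) {
  v <- function(M) { M <- as.matrix(M); M[lower.tri(M)] }
  a <- v(A); b <- v(B); c_ <- v(C)
  if (ranked) { a <- rank(a); b <- rank(b); c_ <- rank(c_) }
  rab <- cor(a, b); rac <- cor(a, c_); rbc <- cor(b, c_)
  (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
}

# exhaustive Steiner point search: the sequence over {A,C,G,T}^L
# minimising the summed Hamming distance to the given sequences
oracle_steiner_cost <- function(seq_strings) {
  mats <- strsplit(seq_strings, "")
  L <- length(mats[[1]])
  states <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, c(rep(list(states), L),
                                 stringsAsFactors = FALSE))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    cand <- as.character(grid[r, ])
    cost <- sum(sapply(mats, function(s) sum(s != cand)))
    best <- min(best, cost)
  }
  best
}

# independent recomputation of the statistical-parsimony probability
oracle_parsimony_prob <- function(j, m) {
  lam <- j / m
  a <- 0.75 * (1 - exp(-4 * lam / 3))
  num <- j * (log(lam) - lam) - lam * (m - j)
  den <- j * log(a) + (m - j) * log(1 - a)
  min(exp(num - den), 1)
}

fixture_table <- function() {
  load_sample_table(system.file("extdata", "watersipora_table1.csv",
                                package = "coipop"))
}
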