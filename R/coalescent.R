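# Neutral coalescent machinery: genealogy simulation for the Tajima's D
# null distribution (fixed-S conditioning by default) and helpers shared
# with the sequence generator.

#' Evaluate code with a temporarily fixed RNG seed
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate one Kingman coalescent genealogy
#'
#' Time is in units of 2N generations. Returns, for every branch, its
#' length and the number of sampled leaves descending from it — all that is
#' needed to place mutations and count pairwise differences.
#'
#' @param n Sample size (>= 2).
#' @return Data frame with columns `length` and `leaves` (2n - 2 branches).
#' @keywords internal
sim_genealogy <- function(n) {
  leaves <- as.list(seq_len(n))          # active lineages: leaf sets
  counts <- rep(1L, n)
  lens <- rep(0, n)
  out_len <- numeric(0); out_cnt <- integer(0)
  k <- n
  while (k > 1L) {
    t <- stats::rexp(1L, rate = k * (k - 1) / 2)
    lens <- lens + t
    pair <- sample.int(k, 2L)
    i <- min(pair); j <- max(pair)
    out_len <- c(out_len, lens[i], lens[j])
    out_cnt <- c(out_cnt, counts[i], counts[j])
    counts[i] <- counts[i] + counts[j]
    lens[i] <- 0
    counts <- counts[-j]; lens <- lens[-j]
    k <- k - 1L
  }
  data.frame(length = out_len, leaves = out_cnt)
}

#' Tajima's D under a simulated neutral null
#'
#' Simulates `replicates` neutral coalescent genealogies at the observed
#' sample size and places exactly the observed number of segregating sites
#' `S` on each (fixed-S conditioning: mutations are distributed among
#' branches with probability proportional to branch length, infinite-sites).
#' With `theta` supplied, mutation numbers are instead Poisson with rate
#' `theta/2` per branch-length unit (fixed-theta mode). Each simulated
#' genealogy yields a D value; p-values use the add-one rule, counting ties
#' on both sides.
#'
#' @param x An [aligned_seq_set()] on which [tajimas_d()] is defined.
#' @param replicates Number of simulated genealogies (>= 100).
#' @param seed Optional integer seed for reproducibility.
#' @param theta If `NULL` (default) condition on the observed S; otherwise
#'   simulate with this population mutation rate (4 N mu for the locus).
#' @return List with `D` (observed), `p_upper` (`Pr(D_null >= D_obs)`),
#'   `p_lower`, `replicates`, and the vector of simulated values `null_D`.
#' @export
tajima_null_test <- function(x, replicates = 5000, seed = NULL,
                             theta = NULL) {
  stopifnot(inherits(x, "aligned_seq_set"))
  if (replicates < 100) {
    stop("configuration error: need >= 100 replicates for a stable p",
         call. = FALSE)
  }
  n <- length(x$labels)
  D_obs <- tajimas_d(x)
  S_obs <- .segregating_sites(as_seq_matrix(x))
  null_D <- with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      g <- sim_genealogy(n)
      if (is.null(theta)) {
        S <- S_obs
        hits <- stats::rmultinom(1L, S, prob = g$length)[, 1L]
      } else {
        hits <- stats::rpois(nrow(g), lambda = g$length * theta / 2)
        S <- sum(hits)
        if (S == 0L) return(0)   # D undefined; null contributes its centre
      }
      pi_count <- sum(hits * g$leaves * (n - g$leaves)) / choose(n, 2)
      .tajima_d_from_counts(pi_count, S, n)
    }, 0)
  })
  m <- replicates
  list(
    D = D_obs,
    p_upper = (1 + sum(null_D >= D_obs)) / (m + 1),
    p_lower = (1 + sum(null_D <= D_obs)) / (m + 1),
    replicates = m,
    null_D = null_D
  )
}
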