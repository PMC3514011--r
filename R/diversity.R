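# Diversity indices and Tajima's D.
#
# S counts alignment columns with >= 2 distinct unambiguous bases.
# pi (per site) is the mean over sequence pairs of the proportion of
# differing sites among pairwise-complete sites; Tajima's D uses the mean
# pairwise difference *count* on the same pairwise-deletion basis.

.pairwise_diff_stats <- function(m) {
  # m: character matrix; returns mean pairwise count and proportion
  n <- nrow(m)
  unamb <- matrix(m %in% .unambiguous, nrow = n)
  cnt <- 0; prop <- 0; npairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- unamb[i, ] & unamb[j, ]
      nd <- sum(m[i, ok] != m[j, ok])
      cnt <- cnt + nd
      prop <- prop + nd / sum(ok)
      npairs <- npairs + 1L
    }
  }
  list(mean_count = cnt / npairs, mean_prop = prop / npairs)
}

.segregating_sites <- function(m) {
  sum(apply(m, 2L, function(col) {
    length(unique(col[col %in% .unambiguous])) >= 2L
  }))
}

#' Tajima (1989) constants for sample size n
#' @noRd
.tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

.tajima_d_from_counts <- function(pi_count, S, n) {
  k <- .tajima_constants(n)
  (pi_count - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tajima's D for an alignment
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the Tajima (1989)
#' constants computed from the sample size; `pi` here is the mean pairwise
#' difference count (not per site).
#'
#' @param x An [aligned_seq_set()] with at least 4 sequences and at least
#'   one segregating site.
#' @return The D statistic (numeric scalar).
#' @export
tajimas_d <- function(x) {
  stopifnot(inherits(x, "aligned_seq_set"))
  n <- length(x$labels)
  if (n < 4L) stop("sample-size error: Tajima's D needs n >= 4",
                   call. = FALSE)
  m <- as_seq_matrix(x)
  S <- .segregating_sites(m)
  if (S == 0L) stop("undefined statistic: no segregating sites",
                    call. = FALSE)
  .tajima_d_from_counts(.pairwise_diff_stats(m)$mean_count, S, n)
}

#' Standard diversity indices for a population sample
#'
#' Returns the classic per-population summary: sample size `n`, haplotype
#' number `K`, segregating sites `S`, `S/n`, nucleotide diversity `pi` with
#' its standard deviation (Nei 1987, eq. 10.7), and Tajima's `D` (`NA` with
#' `d_defined = FALSE` when `S = 0` or `n < 4`).
#'
#' @param x An [aligned_seq_set()] with `n >= 2`.
#' @return A list with elements `n`, `K`, `S`, `S_over_n`, `pi`, `pi_sd`,
#'   `D`, `d_defined`.
#' @export
diversity_indices <- function(x) {
  stopifnot(inherits(x, "aligned_seq_set"))
  n <- length(x$labels)
  if (n < 2L) stop("sample-size error: need n >= 2", call. = FALSE)
  m <- as_seq_matrix(x)
  S <- .segregating_sites(m)
  ps <- .pairwise_diff_stats(m)
  K <- nrow(collapse_haplotypes(x))
  pi <- ps$mean_prop
  L <- x$length
  kc <- .tajima_constants(max(n, 2L))
  pi_var <- kc$b1 / L * pi + kc$b2 * pi^2
  d_def <- S >= 1L && n >= 4L
  list(
    n = n, K = K, S = S, S_over_n = S / n,
    pi = pi, pi_sd = sqrt(max(pi_var, 0)),
    D = if (d_def) .tajima_d_from_counts(ps$mean_count, S, n) else NA_real_,
    d_defined = d_def
  )
}
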