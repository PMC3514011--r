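# Analysis of molecular variance (Excoffier, Smouse & Quattro 1992).
# Sums of squared deviations come straight from the squared distance
# matrix: SSD over a set of N individuals = sum_{i<j} d_ij^2 / N. Variance
# components may be negative and are reported as-is.

.amova_ssd <- function(D2, idx) {
  n <- length(idx)
  if (n < 2L) return(0)
  sum(D2[idx, idx]) / (2 * n)
}

# core decomposition; pop = integer vector (population of each individual),
# grp = integer vector (group of each population) or NULL
.amova_components <- function(D2, pop, grp = NULL) {
  N <- length(pop)
  pops <- sort(unique(pop))
  P <- length(pops)
  n_p <- vapply(pops, function(p) sum(pop == p), 0L)
  ssd_tot <- .amova_ssd(D2, seq_len(N))
  ssd_wp <- sum(vapply(pops, function(p) .amova_ssd(D2, which(pop == p)), 0))
  if (is.null(grp)) {
    df_ap <- P - 1L; df_wp <- N - P
    ms_ap <- (ssd_tot - ssd_wp) / df_ap
    sigma_c <- ssd_wp / df_wp
    n1 <- (N - sum(n_p^2) / N) / df_ap
    sigma_b <- (ms_ap - sigma_c) / n1
    return(list(sigma_a = 0, sigma_b = sigma_b, sigma_c = sigma_c,
                ssd = c(total = ssd_tot, among_pops = ssd_tot - ssd_wp,
                        within_pops = ssd_wp),
                df = c(among_pops = df_ap, within_pops = df_wp)))
  }
  gs <- sort(unique(grp))
  G <- length(gs)
  grp_of_ind <- grp[match(pop, pops)]
  ssd_wg <- sum(vapply(gs, function(g) .amova_ssd(D2, which(grp_of_ind == g)), 0))
  ssd_ap_wg <- ssd_wg - ssd_wp
  ssd_ag <- ssd_tot - ssd_wg
  df_ag <- G - 1L; df_ap <- P - G; df_wp <- N - P
  N_g <- vapply(gs, function(g) sum(grp_of_ind == g), 0L)
  sum_np2_over_Ng <- sum(vapply(seq_along(gs), function(k) {
    sum(n_p[grp == gs[k]]^2) / N_g[k]
  }, 0))
  n1 <- (N - sum_np2_over_Ng) / df_ap
  n2 <- (sum_np2_over_Ng - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(N_g^2) / N) / df_ag
  sigma_c <- ssd_wp / df_wp
  sigma_b <- (ssd_ap_wg / df_ap - sigma_c) / n1
  sigma_a <- (ssd_ag / df_ag - sigma_c - n2 * sigma_b) / n3
  list(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       ssd = c(total = ssd_tot, among_groups = ssd_ag,
               among_pops_within_groups = ssd_ap_wg, within_pops = ssd_wp),
       df = c(among_groups = df_ag, among_pops_within_groups = df_ap,
              within_pops = df_wp))
}

.phi_from_components <- function(cmp, hierarchical) {
  tot <- cmp$sigma_a + cmp$sigma_b + cmp$sigma_c
  if (hierarchical) {
    list(phi_ST = (cmp$sigma_a + cmp$sigma_b) / tot,
         phi_SC = cmp$sigma_b / (cmp$sigma_b + cmp$sigma_c),
         phi_CT = cmp$sigma_a / tot)
  } else {
    list(phi_ST = cmp$sigma_b / tot, phi_SC = NA_real_, phi_CT = NA_real_)
  }
}

#' Analysis of molecular variance with permutation tests
#'
#' Partitions squared-distance variation among groups, among populations
#' within groups, and within populations, with Excoffier-style sums of
#' squares (`SSD = sum d^2 / (2N)` partitioning). Significance of each
#' Phi-statistic is assessed by permutation: individuals among all
#' populations for `phi_ST`, individuals among populations within groups
#' for `phi_SC`, and whole populations among groups for `phi_CT`; p-values
#' use the add-one rule `(1 + b) / (m + 1)`. Negative variance components
#' are retained, not truncated.
#'
#' @param dist A [dist_matrix()] of individual distances (K2P distances for
#'   nucleotide AMOVA, or 0/1 haplotype mismatches for a frequency-only
#'   analysis).
#' @param populations Named character vector (label -> population) or vector
#'   aligned with the matrix labels.
#' @param groups Optional named character vector (population -> group) for
#'   the hierarchical design; `NULL` for a flat two-level analysis.
#' @param permutations Number of permutations (default 5000).
#' @param seed Optional integer seed.
#' @return List with `phi_ST`, `phi_SC`, `phi_CT`, `variance_components`
#'   (`among_groups`, `among_pops_within_groups`, `within_pops`), `ssd`,
#'   `df`, `p_ST`, `p_SC`, `p_CT`, `permutations`.
#' @export
amova <- function(dist, populations, groups = NULL, permutations = 5000,
                  seed = NULL) {
  D2 <- as.matrix(dist)^2
  labs <- rownames(D2)
  if (!is.null(names(populations))) populations <- populations[labs]
  populations <- as.character(populations)
  if (length(populations) != nrow(D2) || anyNA(populations)) {
    stop("populations must cover every matrix label", call. = FALSE)
  }
  pops <- sort(unique(populations))
  if (length(pops) < 2L) stop("need at least two populations", call. = FALSE)
  pop <- match(populations, pops)
  hierarchical <- !is.null(groups)
  grp <- NULL
  if (hierarchical) {
    if (is.null(names(groups))) stop("groups must be a named vector (population -> group)",
                                     call. = FALSE)
    gvals <- as.character(groups[pops])
    if (anyNA(gvals)) stop("groups must cover every population", call. = FALSE)
    if (length(unique(gvals)) < 2L) {
      stop("degenerate design: a single group was supplied", call. = FALSE)
    }
    grp <- match(gvals, sort(unique(gvals)))
  }
  if (all(D2 == 0)) stop("undefined Phi: all distances are zero",
                         call. = FALSE)
  cmp <- .amova_components(D2, pop, grp)
  phi <- .phi_from_components(cmp, hierarchical)
  m <- as.integer(permutations)
  p_ST <- p_SC <- p_CT <- NA_real_
  if (m > 0L) {
    perm <- with_seed(seed, {
      st <- sc <- ct <- numeric(m)
      for (r in seq_len(m)) {
        # (i) individuals among all populations
        pop_i <- sample(pop)
        st[r] <- .phi_from_components(
          .amova_components(D2, pop_i, grp), hierarchical)$phi_ST
        if (hierarchical) {
          # (ii) individuals among populations within groups
          pop_ii <- pop
          for (g in unique(grp)) {
            idx <- which(grp[pop] == g)
            pop_ii[idx] <- sample(pop[idx])
          }
          sc[r] <- .phi_from_components(
            .amova_components(D2, pop_ii, grp), TRUE)$phi_SC
          # (iii) whole populations among groups
          ct[r] <- .phi_from_components(
            .amova_components(D2, pop, sample(grp)), TRUE)$phi_CT
        }
      }
      list(st = st, sc = sc, ct = ct)
    })
    p_ST <- (1 + sum(perm$st >= phi$phi_ST)) / (m + 1)
    if (hierarchical) {
      p_SC <- (1 + sum(perm$sc >= phi$phi_SC)) / (m + 1)
      p_CT <- (1 + sum(perm$ct >= phi$phi_CT)) / (m + 1)
    }
  }
  list(
    phi_ST = phi$phi_ST, phi_SC = phi$phi_SC, phi_CT = phi$phi_CT,
    variance_components = c(among_groups = cmp$sigma_a,
                            among_pops_within_groups = cmp$sigma_b,
                            within_pops = cmp$sigma_c),
    ssd = cmp$ssd, df = cmp$df,
    p_ST = p_ST, p_SC = p_SC, p_CT = p_CT,
    permutations = m
  )
}

#' Pairwise Phi_ST between populations
#'
#' Each population pair is analysed as a flat two-population AMOVA on the
#' corresponding sub-matrix.
#'
#' @inheritParams amova
#' @return List of two matrices, `phi_ST` and `p`, with population names as
#'   dimnames (`NA` on the diagonal).
#' @export
pairwise_phi_st <- function(dist, populations, permutations = 5000,
                            seed = NULL) {
  D <- as.matrix(dist)
  labs <- rownames(D)
  if (!is.null(names(populations))) populations <- populations[labs]
  populations <- as.character(populations)
  pops <- sort(unique(populations))
  k <- length(pops)
  if (k < 2L) stop("need at least two populations", call. = FALSE)
  phi <- p <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      idx <- which(populations %in% pops[c(i, j)])
      sub <- dist_matrix(D[idx, idx, drop = FALSE])
      res <- amova(sub, populations[idx], permutations = permutations,
                   seed = seed)
      phi[i, j] <- phi[j, i] <- res$phi_ST
      p[i, j] <- p[j, i] <- res$p_ST
    }
  }
  list(phi_ST = phi, p = p)
}
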