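#!/usr/bin/env Rscript
# Stage 3: diversity indices, Tajima's D with a simulated null, and
# hierarchical AMOVA.
#
# Per-clade diversity summaries (n, K, S, S/n, pi, D); the D null uses
# 5,000 fixed-S coalescent genealogies; the AMOVA splits each clade into
# two pseudo-populations nested in clade-level groups and tests the Phi
# statistics with 5,000 permutations.

suppressPackageStartupMessages(library(coipop))
seed <- 20260930

x <- read_fasta("results/synthetic_coi.fasta")
clades <- utils::read.csv("results/synthetic_clades.csv")
pops <- stats::setNames(clades$clade, clades$label)

rows <- list()
for (cl in sort(unique(pops))) {
  sub <- aligned_seq_set(x$sequences[pops[x$labels] == cl],
                         labels = x$labels[pops[x$labels] == cl])
  div <- diversity_indices(sub)
  tn <- if (div$d_defined) {
    tajima_null_test(sub, replicates = 5000, seed = seed)
  } else list(p_upper = NA_real_, p_lower = NA_real_)
  rows[[cl]] <- data.frame(
    population = cl, n = div$n, K = div$K, S = div$S,
    S_over_n = div$S_over_n, pi = div$pi, pi_sd = div$pi_sd,
    D = div$D, p_D_lower = tn$p_lower, p_D_upper = tn$p_upper)
  cat(sprintf("%s: n=%d K=%d S=%d pi=%.4f D=%s\n", cl, div$n, div$K,
              div$S, div$pi, format(round(div$D, 4))))
}
utils::write.csv(do.call(rbind, rows), "results/diversity_indices.csv",
                 row.names = FALSE)

d <- read_dist_matrix("results/k2p_distances.csv")
subpops <- paste0(pops[rownames(d)], rep(c("_a", "_b"),
                                         length.out = nrow(d)))
names(subpops) <- rownames(d)
grps <- stats::setNames(sub("_.*", "", sort(unique(subpops))),
                        sort(unique(subpops)))
res <- amova(d, subpops, groups = grps, permutations = 5000, seed = seed)
utils::write.csv(
  data.frame(statistic = c("phi_ST", "phi_SC", "phi_CT",
                           "sigma2_among_groups",
                           "sigma2_among_pops_within_groups",
                           "sigma2_within_pops",
                           "p_ST", "p_SC", "p_CT"),
             value = c(res$phi_ST, res$phi_SC, res$phi_CT,
                       unname(res$variance_components), res$p_ST,
                       res$p_SC, res$p_CT)),
  "results/amova.csv", row.names = FALSE)
cat(sprintf("AMOVA: Phi_CT=%.4f (p=%.4f), Phi_SC=%.4f, Phi_ST=%.4f (p=%.4f)\n",
            res$phi_CT, res$p_CT, res$phi_SC, res$phi_ST, res$p_ST))

pw <- pairwise_phi_st(d, subpops, permutations = 999, seed = seed + 1)
utils::write.csv(as.data.frame(pw$phi_ST), "results/pairwise_phi_st.csv")
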