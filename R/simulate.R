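# Synthetic-data generator: deeply diverged COI clades with shallow
# within-clade variation, sampling sites along an SST gradient with
# Gaussian thermal-niche occupancy, and zooid lengths declining with
# temperature. Defaults emulate the magnitudes seen in invasive bryozoan
# COI surveys: inter-clade K2P divergences of order 0.12-0.24, within-clade
# nucleotide diversity of order 0.01, site SSTs spanning roughly 10-26 C.

#' Simulation configuration
#'
#' All generators are pure functions of `(config, seed)`.
#'
#' @param n_clades Number of deeply diverged clades.
#' @param net_divergence_target Expected net K2P divergence (substitutions/
#'   site) between every clade pair; clade ancestors sit on a star with
#'   branch depth `target / 2`.
#' @param within_clade_theta Population mutation parameter (4 N mu per
#'   locus) of the neutral coalescent within each clade.
#' @param seq_length Alignment columns (>= 100).
#' @param ts_tv_ratio Transition / transversion *rate* ratio of the Kimura
#'   mutation kernel (a mutation is a transition with probability
#'   `k / (k + 2)`).
#' @param n_per_clade Sequences sampled per clade.
#' @param n_sites_geo Sampling sites along the latitudinal SST gradient.
#' @param sst_range Range of site mean SSTs (deg C), evenly spaced along
#'   the gradient.
#' @param niche_centers Thermal-niche centre per clade (deg C).
#' @param niche_widths Gaussian niche width per clade (deg C, > 0).
#' @param p_max Occupancy probability at the niche centre.
#' @param colonies_per_site Sampling effort: binomial trials per site and
#'   clade.
#' @param zooid_slope Change in zooid length per deg C (mm / deg C;
#'   negative for the cold-larger pattern).
#' @param zooid_intercept Zooid length at 0 deg C (mm).
#' @param zooid_sigma Additive noise SD of zooid length (mm).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_clades = 2,
                       net_divergence_target = 0.15,
                       within_clade_theta = 5,
                       seq_length = 500,
                       ts_tv_ratio = 4,
                       n_per_clade = 20,
                       n_sites_geo = 12,
                       sst_range = c(10, 26),
                       niche_centers = c(12, 18),
                       niche_widths = 2,
                       p_max = 0.9,
                       colonies_per_site = 20,
                       zooid_slope = -0.02,
                       zooid_intercept = 1.2,
                       zooid_sigma = 0.1) {
  cfg <- list(n_clades = n_clades,
              net_divergence_target = net_divergence_target,
              within_clade_theta = within_clade_theta,
              seq_length = seq_length, ts_tv_ratio = ts_tv_ratio,
              n_per_clade = n_per_clade, n_sites_geo = n_sites_geo,
              sst_range = sst_range,
              niche_centers = rep_len(niche_centers, n_clades),
              niche_widths = rep_len(niche_widths, n_clades),
              p_max = p_max, colonies_per_site = colonies_per_site,
              zooid_slope = zooid_slope,
              zooid_intercept = zooid_intercept,
              zooid_sigma = zooid_sigma)
  if (cfg$seq_length < 100) stop("seq_length must be >= 100", call. = FALSE)
  if (cfg$within_clade_theta <= 0 || any(cfg$niche_widths <= 0) ||
      cfg$ts_tv_ratio <= 0) {
    stop("rates and widths must be positive", call. = FALSE)
  }
  if (cfg$net_divergence_target < 0 || cfg$net_divergence_target > 0.7) {
    stop("configuration error: divergence target unreachable (saturation)",
         call. = FALSE)
  }
  if (cfg$p_max < 0 || cfg$p_max > 1) stop("p_max must lie in [0, 1]",
                                           call. = FALSE)
  min_len <- cfg$zooid_intercept + cfg$zooid_slope * max(cfg$sst_range)
  if (min_len <= 0) {
    stop("configuration error: zooid parameters imply non-positive lengths",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# COI-like base frequencies used for root sequences (AT-rich, as typical
# of invertebrate mitochondrial protein-coding genes)
.root_base_freqs <- c(A = 0.31, C = 0.19, G = 0.17, T = 0.33)

# apply n_mut Kimura-kernel mutations to a base vector at uniform sites
.mutate <- function(seq_vec, n_mut, ts_tv_ratio) {
  if (n_mut == 0L) return(seq_vec)
  ts_prob <- ts_tv_ratio / (ts_tv_ratio + 2)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  pos <- sample.int(length(seq_vec), n_mut, replace = TRUE)
  for (p in pos) {
    b <- seq_vec[p]
    seq_vec[p] <- if (stats::runif(1) < ts_prob) transition[[b]]
                  else sample(transversions[[b]], 1L)
  }
  seq_vec
}

# simulate sequences for the tips of a coalescent tree started at root_seq;
# mutation rate is per lineage per unit branch length, locus-wide
.evolve_tree <- function(tree, root_seq, locus_rate, ts_tv_ratio) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  seqs <- vector("list", n_node)
  root <- n_tip + 1L
  seqs[[root]] <- root_seq
  ord <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
  # preorder traversal: parents always precede children in rcoal edge
  # numbering only if we walk edges from the root outwards
  pending <- ord[ord[, 1L] == root, , drop = FALSE]
  while (nrow(pending) > 0L) {
    nxt <- NULL
    for (k in seq_len(nrow(pending))) {
      par <- pending[k, 1L]; child <- pending[k, 2L]
      len <- tree$edge.length[which(tree$edge[, 1L] == par &
                                      tree$edge[, 2L] == child)]
      n_mut <- stats::rpois(1L, len * locus_rate)
      seqs[[child]] <- .mutate(seqs[[par]], n_mut, ts_tv_ratio)
      kids <- ord[ord[, 1L] == child, , drop = FALSE]
      if (nrow(kids) > 0L) nxt <- rbind(nxt, kids)
    }
    pending <- if (is.null(nxt)) ord[0L, , drop = FALSE] else nxt
  }
  do.call(rbind, seqs[seq_len(n_tip)])
}

#' Simulate clade-structured COI-like sequences
#'
#' Each clade is a standard neutral coalescent sample (theta =
#' `within_clade_theta`) hanging off a star phylogeny of clade ancestors:
#' every ancestor branch receives an expected `target / 2` substitutions
#' per site, so the expected net K2P divergence between any two clades is
#' the configured target (within-clade diversity cancels in the net
#' divergence). Mutations follow a Kimura two-parameter kernel at the
#' configured transition/transversion rate ratio.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed (same seed, same FASTA bytes).
#' @return List with `seqs` (an [aligned_seq_set()], populations set to the
#'   clade label) and `clades` (named character vector of true labels).
#' @export
simulate_sequences <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    L <- cfg$seq_length
    root <- sample(names(.root_base_freqs), L, replace = TRUE,
                   prob = .root_base_freqs)
    half_depth_mut <- cfg$net_divergence_target / 2 * L
    seqs <- character(0); labs <- character(0); pops <- character(0)
    for (cl in seq_len(cfg$n_clades)) {
      anc <- .mutate(root, stats::rpois(1L, half_depth_mut),
                     cfg$ts_tv_ratio)
      n <- cfg$n_per_clade
      tip_mat <- if (n == 1L) {
        matrix(anc, nrow = 1L)
      } else {
        tree <- ape::rcoal(n)
        tm <- .evolve_tree(tree, anc, cfg$within_clade_theta / 2,
                           cfg$ts_tv_ratio)
        # tip numbering of the simulated genealogy is not exchangeable;
        # shuffle so sample labels carry no topological information
        tm[sample(n), , drop = FALSE]
      }
      clade_name <- paste0("clade", cl)
      seqs <- c(seqs, apply(tip_mat, 1L, paste, collapse = ""))
      labs <- c(labs, paste0(clade_name, "_", seq_len(n)))
      pops <- c(pops, rep(clade_name, n))
    }
    x <- aligned_seq_set(seqs, labels = labs, populations = pops)
    list(seqs = x, clades = stats::setNames(pops, labs))
  })
}

#' Simulate a sample-occurrence table along an SST gradient
#'
#' Sites are evenly spaced along a latitudinal gradient with SST spanning
#' `sst_range`; each clade's colony count at a site is binomial
#' (`colonies_per_site`, `p`) with
#' `p = p_max exp(-(sst - centre)^2 / (2 width^2))`. Rows with count 0 are
#' dropped.
#'
#' @inheritParams simulate_sequences
#' @return A `sample_table` (see [load_sample_table()]) with phylogroups
#'   `clade1`, `clade2`, ...
#' @export
simulate_occurrence <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    ns <- cfg$n_sites_geo
    sst <- seq(cfg$sst_range[1L], cfg$sst_range[2L], length.out = ns)
    lat <- seq(48, 32, length.out = ns)       # poleward-cold gradient
    lon <- -122 + stats::runif(ns, -0.5, 0.5)
    rows <- list(); k <- 0L
    for (s in seq_len(ns)) {
      for (cl in seq_len(cfg$n_clades)) {
        p <- cfg$p_max *
          exp(-(sst[s] - cfg$niche_centers[cl])^2 /
                (2 * cfg$niche_widths[cl]^2))
        cnt <- stats::rbinom(1L, cfg$colonies_per_site, p)
        if (cnt > 0L) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            region = "synthetic", site = paste0("site", s),
            latitude = lat[s], longitude = lon[s], sst_c = sst[s],
            phylogroup = paste0("clade", cl), count = cnt,
            source = "simulated", stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("sample_table", "data.frame")
    out
  })
}

#' Simulate zooid-morphometric records for an occurrence table
#'
#' One record per colony: `L_z = intercept + slope * sst + N(0, sigma)`,
#' with width and orifice dimensions scaled allometrically with
#' multiplicative log-normal noise.
#'
#' @inheritParams simulate_sequences
#' @param tab A `sample_table` (e.g. from [simulate_occurrence()]).
#' @return Data frame of zooid records (`colony_id`, `phylogroup`, `site`,
#'   `sst_c`, `L_z_mm`, `W_z_mm`, `L_or_mm`, `W_or_mm`).
#' @export
simulate_zooids <- function(cfg, tab, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    u <- .expand_colonies(tab)
    n <- nrow(u)
    L_z <- cfg$zooid_intercept + cfg$zooid_slope * u$sst_c +
      stats::rnorm(n, 0, cfg$zooid_sigma)
    L_z <- pmax(L_z, 0.05)       # floor: lengths are physical
    lnoise <- function(sd) exp(stats::rnorm(n, 0, sd))
    rec <- data.frame(
      colony_id = paste0("col", seq_len(n)),
      phylogroup = u$phylogroup, site = u$site, sst_c = u$sst_c,
      L_z_mm = L_z,
      W_z_mm = 0.55 * L_z * lnoise(0.08),
      L_or_mm = 0.28 * L_z * lnoise(0.08),
      W_or_mm = 0.33 * L_z * lnoise(0.08),
      stringsAsFactors = FALSE)
    rec
  })
}
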