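# Kimura 2-parameter distances and net between-clade divergence.
# Transitions are A<->G and C<->T; everything else among {A,C,G,T} is a
# transversion. Sites where either sequence carries an ambiguity code, N or
# a gap are excluded pair by pair (pairwise deletion).

.purines <- c("A", "G")

#' Kimura 2-parameter distance between two aligned sequences
#'
#' With `P` the transition and `Q` the transversion fraction over
#' pairwise-complete sites, the distance is
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` substitutions per site.
#'
#' @param a,b Nucleotide strings of equal length, or single-row character
#'   vectors of bases.
#' @return Distance in substitutions/site.
#' @export
k2p_distance <- function(a, b) {
  av <- if (length(a) == 1L) strsplit(toupper(a), "")[[1]] else toupper(a)
  bv <- if (length(b) == 1L) strsplit(toupper(b), "")[[1]] else toupper(b)
  if (length(av) != length(bv)) stop("sequences of unequal length",
                                     call. = FALSE)
  ok <- av %in% .unambiguous & bv %in% .unambiguous
  if (!any(ok)) stop("no comparable (pairwise unambiguous) sites",
                     call. = FALSE)
  .k2p_from_counts(sum(.is_transition(av[ok], bv[ok])),
                   sum(.is_transversion(av[ok], bv[ok])),
                   sum(ok))
}

.is_transition <- function(a, b) {
  a != b & ((a %in% .purines) == (b %in% .purines))
}

.is_transversion <- function(a, b) {
  a != b & ((a %in% .purines) != (b %in% .purines))
}

.k2p_from_counts <- function(ts, tv, n_sites) {
  P <- ts / n_sites
  Q <- tv / n_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("saturation: Kimura 2-parameter distance undefined (P = ",
         signif(P, 4), ", Q = ", signif(Q, 4), ")", call. = FALSE)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' All pairwise K2P distances for an alignment
#'
#' @param x An [aligned_seq_set()] or a `haplotype_table` (each haplotype
#'   once).
#' @return A [dist_matrix()] labelled by sequence labels (or haplotype ids).
#' @export
pairwise_k2p <- function(x) {
  if (inherits(x, "haplotype_table")) {
    m <- do.call(rbind, strsplit(x$sequence, ""))
    rownames(m) <- x$haplotype_id
  } else {
    stopifnot(inherits(x, "aligned_seq_set"))
    m <- as_seq_matrix(x)
  }
  n <- nrow(m)
  pur <- matrix(m %in% .purines, nrow = n)
  unamb <- matrix(m %in% .unambiguous, nrow = n)
  d <- matrix(0, n, n)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      ok <- unamb[i, ] & unamb[j, ]
      if (!any(ok)) stop("no comparable sites between ", rownames(m)[i],
                         " and ", rownames(m)[j], call. = FALSE)
      diffs <- m[i, ok] != m[j, ok]
      ts <- sum(diffs & (pur[i, ok] == pur[j, ok]))
      tv <- sum(diffs) - ts
      d[i, j] <- d[j, i] <- tryCatch(
        .k2p_from_counts(ts, tv, sum(ok)),
        error = function(e) stop("pair (", rownames(m)[i], ", ",
                                 rownames(m)[j], "): ",
                                 conditionMessage(e), call. = FALSE)
      )
    }
  }
  dist_matrix(d, labels = rownames(m))
}

#' Net K2P divergence between two sequence groups
#'
#' Within-group divergence is the mean over unordered within-group pairs
#' (0 for singleton groups); between-group divergence the mean over all
#' cross pairs; net divergence corrects the between-group mean for shared
#' ancestral polymorphism:
#' `d_net = d_between - (d_within_X + d_within_Y) / 2`.
#'
#' @param x An [aligned_seq_set()].
#' @param partition Named character vector (label -> group) or character
#'   vector aligned with `x$labels`, with exactly two group values.
#' @return List with `d_within_X`, `d_within_Y`, `d_between`, `d_net` and
#'   `groups` (the two group names, alphabetical).
#' @export
net_divergence <- function(x, partition) {
  stopifnot(inherits(x, "aligned_seq_set"))
  if (!is.null(names(partition))) {
    partition <- partition[x$labels]
  }
  partition <- as.character(partition)
  if (length(partition) != length(x$labels) || anyNA(partition)) {
    stop("partition must cover every sequence label", call. = FALSE)
  }
  gs <- sort(unique(partition))
  if (length(gs) != 2L) stop("partition error: need exactly two non-empty groups",
                             call. = FALSE)
  d <- pairwise_k2p(x)
  within_mean <- function(g) {
    idx <- which(partition == g)
    if (length(idx) < 2L) return(0)
    mean(lower_triangle(d[idx, idx, drop = FALSE]))
  }
  ix <- which(partition == gs[1L]); iy <- which(partition == gs[2L])
  dwx <- within_mean(gs[1L])
  dwy <- within_mean(gs[2L])
  dbt <- mean(d[ix, iy])
  list(d_within_X = dwx, d_within_Y = dwy, d_between = dbt,
       d_net = dbt - (dwx + dwy) / 2, groups = gs)
}
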