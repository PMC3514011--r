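# Median-joining haplotype networks (Bandelt, Forster & Roehl 1999) and a
# statistical-parsimony connection limit. Character states are restricted
# to A/C/G/T: ambiguous columns must be masked upstream (see
# collapse_haplotypes), which is also how the haplotype tables consumed
# here are produced.

.hamming_matrix <- function(seq_mat) {
  n <- nrow(seq_mat)
  d <- matrix(0L, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d[i, j] <- d[j, i] <- sum(seq_mat[i, ] != seq_mat[j, ])
      }
    }
  }
  d
}

# single-linkage merge level for every pair (the subdominant ultrametric:
# min over paths of the max step), via hclust on the observed distances
.merge_levels <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(matrix(0, n, n))
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  as.matrix(stats::cophenetic(hc))
}

# feasible links of the epsilon-relaxed minimum-spanning network:
# (u, v) is kept iff d(u, v) <= merge_level(u, v) + epsilon. With
# epsilon = 0 this is the union of all minimum spanning trees.
.feasible_links <- function(d, epsilon) {
  n <- nrow(d)
  if (n < 2L) return(cbind(from = integer(0), to = integer(0)))
  M <- .merge_levels(d)
  keep <- which(d <= M + epsilon & upper.tri(d), arr.ind = TRUE)
  keep <- keep[order(d[keep], keep[, 1L], keep[, 2L]), , drop = FALSE]
  cbind(from = keep[, 1L], to = keep[, 2L])
}

.majority_median <- function(a, b, c) {
  # columnwise majority consensus of three sequences; ties (all three
  # distinct) resolved in favour of the first sequence, which keeps the
  # median within one step of a on tied columns and makes output
  # deterministic
  out <- a
  bc <- b == c
  out[bc] <- b[bc]
  out
}

#' Median-joining haplotype network
#'
#' Builds the epsilon-relaxed minimum-spanning network on Hamming distances
#' between haplotype sequences, then iteratively inserts majority-consensus
#' median (Steiner) vectors of triplets connected in the current network
#' whenever they reduce connection cost, following Bandelt et al. (1999).
#' Per round, all candidate medians whose connection cost is within
#' `epsilon` of the round's minimum are added. After convergence, median
#' vectors with fewer than three links are deleted (repeatedly) and the
#' network is rebuilt. Tie-breaks are lexicographic by (steps, node id), so
#' the output is independent of input order.
#'
#' @param haps A `haplotype_table` from [collapse_haplotypes()] (sequences
#'   must be equal-length and unambiguous).
#' @param epsilon Non-negative integer relaxation parameter; 0 (default)
#'   gives the strict median-joining network.
#' @return A `haplo_network`: list with `nodes` (data frame: `id`,
#'   `sequence`, `frequency`, `median_vector`, plus per-population counts)
#'   and `edges` (data frame: `from`, `to`, `steps`, `confident`).
#' @export
median_joining <- function(haps, epsilon = 0L) {
  stopifnot(inherits(haps, "haplotype_table"))
  if (epsilon < 0) stop("epsilon must be non-negative", call. = FALSE)
  seqs <- haps$sequence
  if (length(unique(nchar(seqs))) != 1L) {
    stop("alignment error: haplotype sequences of unequal length",
         call. = FALSE)
  }
  bad <- !vapply(strsplit(seqs, ""), function(s) all(s %in% .unambiguous),
                 TRUE)
  if (any(bad)) {
    stop("ambiguous characters in haplotypes ",
         paste(haps$haplotype_id[bad], collapse = ", "),
         "; mask columns upstream", call. = FALSE)
  }
  node_seq <- seqs
  node_id <- haps$haplotype_id
  observed <- rep(TRUE, length(seqs))
  n_median <- 0L
  repeat {
    m <- do.call(rbind, strsplit(node_seq, ""))
    d <- .hamming_matrix(m)
    links <- .feasible_links(d, epsilon)
    # candidate triplets: u - v and v - w linked in the current network
    adj <- vector("list", nrow(m))
    for (k in seq_len(nrow(links))) {
      adj[[links[k, 1L]]] <- c(adj[[links[k, 1L]]], links[k, 2L])
      adj[[links[k, 2L]]] <- c(adj[[links[k, 2L]]], links[k, 1L])
    }
    cand_seq <- character(0); cand_cost <- integer(0)
    for (v in seq_len(nrow(m))) {
      nb <- sort(unique(adj[[v]]))
      if (length(nb) < 2L) next
      for (a_i in seq_len(length(nb) - 1L)) {
        for (b_i in seq.int(a_i + 1L, length(nb))) {
          u <- nb[a_i]; w <- nb[b_i]
          med <- .majority_median(m[v, ], m[u, ], m[w, ])
          ms <- paste(med, collapse = "")
          if (ms %in% node_seq || ms %in% cand_seq) next
          cost <- sum(med != m[u, ]) + sum(med != m[v, ]) +
            sum(med != m[w, ])
          cand_seq <- c(cand_seq, ms)
          cand_cost <- c(cand_cost, cost)
        }
      }
    }
    if (length(cand_seq) == 0L) break
    lambda <- min(cand_cost)
    add <- cand_seq[cand_cost <= lambda + epsilon]
    add <- sort(unique(add))     # deterministic insertion order
    n_new <- length(add)
    node_seq <- c(node_seq, add)
    node_id <- c(node_id, paste0("mv", n_median + seq_len(n_new)))
    observed <- c(observed, rep(FALSE, n_new))
    n_median <- n_median + n_new
  }
  # cleanup: drop median vectors with degree < 3, iterating to a fixed point
  repeat {
    m <- do.call(rbind, strsplit(node_seq, ""))
    d <- .hamming_matrix(m)
    links <- .feasible_links(d, epsilon)
    deg <- tabulate(c(links[, 1L], links[, 2L]), nbins = nrow(m))
    drop <- which(!observed & deg < 3L)
    if (length(drop) == 0L) break
    node_seq <- node_seq[-drop]
    node_id <- node_id[-drop]
    observed <- observed[-drop]
  }
  pop_cols <- setdiff(names(haps), c("haplotype_id", "sequence",
                                     "total_count"))
  nodes <- data.frame(
    id = node_id,
    sequence = node_seq,
    frequency = ifelse(observed,
                       haps$total_count[match(node_id, haps$haplotype_id)],
                       0L),
    median_vector = !observed,
    stringsAsFactors = FALSE
  )
  for (p in pop_cols) {
    v <- integer(nrow(nodes))
    v[observed] <- haps[[p]][match(node_id[observed], haps$haplotype_id)]
    nodes[[p]] <- v
  }
  edges <- data.frame(
    from = node_id[links[, 1L]],
    to = node_id[links[, 2L]],
    steps = d[links],
    confident = rep(NA, nrow(links)),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges), class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("Median-joining network: ", sum(!x$nodes$median_vector),
      " haplotypes + ", sum(x$nodes$median_vector),
      " median vectors, ", nrow(x$edges), " links\n", sep = "")
  invisible(x)
}

#' Statistical-parsimony connection limit
#'
#' Probability model: substitutions hit each of the `seq_length` sites as
#' independent Poisson processes under a Jukes-Cantor kernel, with the
#' per-site rate estimated by the plug-in `j / seq_length` for a pair of
#' haplotypes showing `j` differences. A `j`-step connection is
#' *parsimonious* when every observed difference reflects exactly one
#' substitution and no site carries hidden (superimposed or back-) changes,
#' so
#' `P(parsimony | j) = (lambda e^-lambda)^j e^(-lambda (m - j)) / (a^j (1 - a)^(m - j))`
#' with `a = 3/4 (1 - e^(-4 lambda / 3))` the per-site probability of an
#' observable difference. The connection limit is the largest `j` whose
#' parsimony probability exceeds `confidence`; 0 observed differences are
#' always confident.
#'
#' @param seq_length Number of analysed sites (e.g. 489 or 388 for the
#'   barcode windows used in the networks).
#' @param confidence Required parsimony probability, e.g. 0.95.
#' @return Integer: the maximum number of mutational steps regarded as a
#'   confident connection.
#' @export
parsimony_limit <- function(seq_length, confidence = 0.95) {
  if (seq_length < 1L) stop("seq_length must be >= 1", call. = FALSE)
  if (!(confidence > 0 && confidence < 1)) {
    stop("confidence must lie strictly between 0 and 1", call. = FALSE)
  }
  probs <- parsimony_probability(seq_len(seq_length), seq_length)
  below <- which(probs <= confidence)
  if (length(below) == 0L) return(as.integer(seq_length))
  as.integer(min(below) - 1L)
}

#' @rdname parsimony_limit
#' @param j Number of observed differences (vectorised).
#' @return For `parsimony_probability`: the parsimony probability for each
#'   `j`.
#' @export
parsimony_probability <- function(j, seq_length) {
  m <- seq_length
  lambda <- j / m
  a <- 0.75 * (1 - exp(-4 * lambda / 3))
  lp <- j * log(lambda * exp(-lambda)) - lambda * (m - j) -
    (j * log(a) + (m - j) * log1p(-a))
  out <- exp(lp)
  out[j == 0] <- 1
  pmin(out, 1)
}

#' Flag network edges by a connection limit
#'
#' Edges whose mutational step count is at most `limit` are marked
#' `confident = TRUE`, the rest `FALSE`; no edge is removed. Typically
#' `limit = parsimony_limit(window_length, 0.95)`.
#'
#' @param net A `haplo_network`.
#' @param limit Positive integer step limit.
#' @return The network with its `confident` edge column filled in.
#' @export
flag_edges <- function(net, limit) {
  stopifnot(inherits(net, "haplo_network"))
  if (limit < 1L) stop("limit must be >= 1", call. = FALSE)
  net$edges$confident <- net$edges$steps <= limit
  net
}

#' Export a haplotype network
#'
#' Writes the edge list (`source`, `target`, `steps`, `confident`) and the
#' node table (frequencies per population) as CSV, or the whole network as
#' GraphML.
#'
#' @param net A `haplo_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    transform(net$edges, confident = as.character(confident)),
    directed = FALSE,
    vertices = net$nodes[, c("id", "frequency", "median_vector")]
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edges <- function(net, path) {
  out <- net$edges
  names(out)[1:2] <- c("source", "target")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_nodes <- function(net, path) {
  utils::write.csv(net$nodes, path, row.names = FALSE)
  invisible(path)
}
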