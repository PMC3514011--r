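make_haps <- function(seqs) collapse_haplotypes(aligned_seq_set(seqs))

test_that("tree-like haplotype data needs no median vectors", {
  # chain A - B - C, one step each
  net <- median_joining(make_haps(c("AAAAAA", "AAAAAT", "AAAATT")))
  expect_equal(sum(net$nodes$median_vector), 0L)
  expect_equal(nrow(net$edges), 2L)
  expect_true(all(net$edges$steps == 1L))

  # single haplotype: one node, no edges
  single <- median_joining(make_haps("ACGTAC"))
  expect_equal(nrow(single$nodes), 1L)
  expect_equal(nrow(single$edges), 0L)
})

test_that("a star triplet gains exactly one median vector at the consensus", {
  net <- median_joining(make_haps(c("TAAAAA", "ATAAAA", "AATAAA")))
  mv <- net$nodes[net$nodes$median_vector, ]
  expect_equal(nrow(mv), 1L)
  expect_equal(mv$sequence, "AAAAAA")
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$steps == 1L))
  # every median vector keeps degree >= 3
  deg <- table(c(net$edges$from, net$edges$to))
  expect_gte(deg[[mv$id]], 3L)
})

test_that("median vectors match exhaustive Steiner enumeration on small toys", {
  toys <- list(
    c("TAAAA", "ATAAA", "AATAA"),
    c("ACGTA", "GCGTT", "ACATT"),
    c("AAAAAA", "TTAAAA", "ATTAAA")
  )
  for (seqs in toys) {
    net <- median_joining(make_haps(seqs))
    cost <- sum(net$edges$steps)
    expect_equal(cost, oracle_steiner_cost(seqs))
  }
})

test_that("with epsilon 0 the network of tree-like data is the minimum spanning tree", {
  # haplotypes generated along a random tree by single mutations at fresh
  # sites: distances are additive and the MST is the true tree
  set.seed(17)
  L <- 40
  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- list(root)
  parent <- c(NA)
  used <- integer(0)
  for (k in 2:8) {
    p <- sample(k - 1, 1)
    s <- seqs[[p]]
    site <- sample(setdiff(seq_len(L), used), 1)
    used <- c(used, site)
    s[site] <- sample(setdiff(c("A", "C", "G", "T"), s[site]), 1)
    seqs[[k]] <- s
    parent[k] <- p
  }
  strs <- vapply(seqs, paste, "", collapse = "")
  net <- median_joining(make_haps(strs))
  expect_equal(sum(net$nodes$median_vector), 0L)
  expect_equal(nrow(net$edges), 7L)            # a spanning tree
  expect_true(all(net$edges$steps == 1L))
  # cross-check against an independent MST of the Hamming distances
  m <- do.call(rbind, strsplit(strs, ""))
  h <- outer(seq_len(8), seq_len(8),
             Vectorize(function(i, j) sum(m[i, ] != m[j, ])))
  g <- igraph::graph_from_adjacency_matrix(h, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  expect_equal(sum(igraph::E(mst)$weight), sum(net$edges$steps))
})

test_that("network output does not depend on haplotype input order", {
  seqs <- c("ACGTAA", "ACGTAT", "ACGTTT", "GCGTAA", "ACATAA")
  net1 <- median_joining(make_haps(seqs))
  net2 <- median_joining(make_haps(rev(seqs)))
  edge_key <- function(net) {
    s <- net$nodes$sequence[match(net$edges$from, net$nodes$id)]
    t <- net$nodes$sequence[match(net$edges$to, net$nodes$id)]
    sort(paste(pmin(s, t), pmax(s, t), net$edges$steps))
  }
  expect_equal(edge_key(net1), edge_key(net2))
  expect_equal(sort(net1$nodes$sequence), sort(net2$nodes$sequence))
})

test_that("the parsimony limit follows the connection-probability model", {
  probs <- parsimony_probability(1:20, 489)
  orc <- vapply(1:20, oracle_parsimony_prob, 0, m = 489)
  expect_equal(probs, orc, tolerance = 1e-12)
  lim <- parsimony_limit(489, 0.95)
  expect_true(parsimony_probability(lim, 489) > 0.95)
  expect_true(parsimony_probability(lim + 1, 489) <= 0.95)
  expect_gt(parsimony_limit(489, 0.95), parsimony_limit(100, 0.95))

  # zero observed differences are always confident
  expect_equal(parsimony_probability(0, 489), 1)
  # vanishing confidence lets everything connect
  expect_equal(parsimony_limit(100, 1e-300), 100L)
  expect_error(parsimony_limit(0, 0.95), "seq_length")
  expect_error(parsimony_limit(100, 1), "confidence")
})

test_that("edge flagging by a step limit is total and idempotent", {
  net <- median_joining(make_haps(c("AAAAAAAAAAAA", "AAAAAAAAAAAT",
                                    "TTTTTTTTTTTT")))
  f9 <- flag_edges(net, 9)
  expect_true(all(f9$edges$confident[f9$edges$steps <= 9]))
  expect_false(any(f9$edges$confident[f9$edges$steps > 9]))
  expect_equal(nrow(f9$edges), nrow(net$edges))   # nothing removed
  expect_identical(flag_edges(f9, 9)$edges, f9$edges)
  expect_error(flag_edges(net, 0), "limit")
})

test_that("networks export to edge list, node table and GraphML", {
  net <- flag_edges(median_joining(make_haps(c("TAAAAA", "ATAAAA",
                                               "AATAAA"))), 9)
  e <- withr::local_tempfile(fileext = ".csv")
  n <- withr::local_tempfile(fileext = ".csv")
  g <- withr::local_tempfile(fileext = ".graphml")
  write_network_edges(net, e)
  write_network_nodes(net, n)
  write_network_graphml(net, g)
  edf <- read.csv(e)
  expect_equal(nrow(edf), 3L)
  expect_true(all(c("source", "target", "steps", "confident") %in%
                    names(edf)))
  ndf <- read.csv(n)
  expect_equal(nrow(ndf), 4L)
  gg <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(gg), 4)
  expect_equal(igraph::ecount(gg), 3)
})
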