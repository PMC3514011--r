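#!/usr/bin/env Rscript
# Stage 4: median-joining haplotype network with the statistical-parsimony
# connection limit. Edges longer than the 95% limit (computed from the
# analysed window length) are flagged as low-confidence, the convention
# used when drawing haplotype networks with dashed connectors.

suppressPackageStartupMessages(library(coipop))

haps <- read_haplotype_table("results/haplotypes.csv")
net <- median_joining(haps)
limit <- parsimony_limit(nchar(haps$sequence[1]), 0.95)
net <- flag_edges(net, limit)

write_network_edges(net, "results/network_edges.csv")
write_network_nodes(net, "results/network_nodes.csv")
write_network_graphml(net, "results/network.graphml")

cat("Median-joining network:", sum(!net$nodes$median_vector),
    "haplotypes,", sum(net$nodes$median_vector), "median vectors,",
    nrow(net$edges), "links.\n")
cat("95% connection limit at", nchar(haps$sequence[1]), "sites:", limit,
    "steps;", sum(!net$edges$confident),
    "link(s) exceed it (the deep between-clade connection).\n")
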