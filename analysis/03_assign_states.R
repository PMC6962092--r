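#!/usr/bin/env Rscript
# Stage 3: assign chromatin states to promoters and binding sites, and
# label the network.
#
# Each region's state is the one with the highest fold-enrichment score
# S = (r_s/n) / (c_s/t) against the genome-wide segmentation. Promoter
# states label the nodes; each edge takes the state of its representative
# binding site. Recovery is reported against the intended node states.

suppressPackageStartupMessages(library(chromotif))

seg <- read_segmentation("results/study/segmentation.bed")
tss <- read_tss("results/study/tss.tsv")
peaks <- read.delim("results/study/peaks.tsv")
truth <- jsonlite::read_json("results/study/ground_truth.json",
                             simplifyVector = TRUE)
net <- read_network("results/network_edges.tsv", "results/network_nodes.tsv")

promoters <- promoter_from_tss(tss)
prom_states <- assign_states(
  data.frame(chrom = promoters$chrom, start = promoters$start,
             end = promoters$end, name = promoters$name), seg)
tfbs_states <- assign_states(
  data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
             name = peaks$name), seg)

labeled <- label_network(net, prom_states, tfbs_states)
intended <- unlist(truth$intended_node_states)
cat("state recovery:",
    round(100 * mean(prom_states[names(intended)] == intended), 1), "%\n")

dist <- state_distribution(labeled)
cat("node state distribution (top 5):\n")
print(head(dist$nodes[order(-dist$nodes$frequency), ], 5), row.names = FALSE)
cat("edge state distribution (top 5):\n")
print(head(dist$edges[order(-dist$edges$frequency), ], 5), row.names = FALSE)

write_network(labeled, "results/labeled_edges.tsv", "results/labeled_nodes.tsv")
write.table(data.frame(region = names(prom_states), state = prom_states),
            "results/promoter_states.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/labeled_{edges,nodes}.tsv, results/promoter_states.tsv\n")
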