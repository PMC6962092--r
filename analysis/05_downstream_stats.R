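#!/usr/bin/env Rscript
# Stage 5: expression by chromatin-state composition and gene-set
# enrichment of FFL targets.
#
# Summarizes cell-line expression of FFL targets per colored class,
# compares the most- vs least-active compositions by Wilcoxon rank-sum,
# and runs a hypergeometric over-representation test of the FFL targets
# against a synthetic gene-set collection (one set per chromatin state of
# the generator's ground truth, plus random sets), BH-adjusted.

suppressPackageStartupMessages(library(chromotif))

inst <- read.delim("results/ffl_instances.tsv")
cell <- read.delim("results/study/expression_cellline.tsv")
expr <- stats::setNames(cell$fpkm, cell$gene)
nodes <- read.delim("results/labeled_nodes.tsv")

summ <- target_expression_by_composition(inst, expr)
summ <- summ[order(-summ$mean_expression), ]
cat("target expression by composition (top 5):\n")
print(head(summ[c("class", "n_targets", "mean_expression")], 5),
      row.names = FALSE)

# compare targets sitting in the most active vs least active node states
act <- chromatin_states()
st_of <- stats::setNames(nodes$state, nodes$gene)
tgt <- unique(inst$target)
hi <- tgt[st_of[tgt] %in% act$state[act$activity >= 4]]
lo <- tgt[st_of[tgt] %in% act$state[act$activity <= 2]]
if (length(hi) && length(lo)) {
  cmp <- compare_compositions(expr[hi], expr[lo])
  cat(sprintf("active vs repressed targets: n = %d vs %d, rank-sum p = %.4g (%s)\n",
              length(hi), length(lo), cmp$p_value, cmp$method))
} else {
  cat("too few targets in contrasting states for a rank-sum comparison\n")
}

# synthetic gene sets: genes grouped by their intended chromatin state
set.seed(5)
universe <- nodes$gene
sets <- split(universe, st_of[universe])
names(sets) <- sprintf("state_%s_genes", names(sets))
sets <- c(sets, lapply(stats::setNames(1:5, sprintf("random_%d", 1:5)),
                       function(i) sample(universe, 20)))
enr <- hypergeometric_enrichment(unique(inst$target), sets, universe)
cat("gene-set enrichment of FFL targets (top 5):\n")
print(head(enr[c("term", "overlap", "term_size", "p", "p_adj")], 5),
      row.names = FALSE)

write.table(summ[c("class", "n_targets", "mean_expression")],
            "results/composition_expression.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(enr, "results/target_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/composition_expression.tsv, results/target_enrichment.tsv\n")
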