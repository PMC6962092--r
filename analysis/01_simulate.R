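#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study fixture.
#
# Produces every input the downstream stages consume — a one-chromosome
# genome with 150 genes (25 TFs), its 15-state segmentation, TF binding
# sites and DHSs realizing a known edge set (plus 20 decoy sites without
# DHS support), a 16-tissue expression panel, a cell-line expression
# vector, and a 197-patient survival cohort whose prognostic signal is the
# first intended feedforward loop. Written to results/study/ in the
# pipeline's plain-text formats, with the ground truth as JSON.

suppressPackageStartupMessages(library(chromotif))

cfg <- synthetic_config(n_genes = 150, n_tfs = 30, edge_density = 0.06,
                        noise_sd = 0.1, seed = 1)
study <- simulate_study(cfg, n_decoys = 20)
write_study(study, "results/study")

cat("genes:           ", nrow(study$genome$genes), "\n")
cat("segmentation:    ", nrow(study$genome$seg), "intervals tiling",
    cfg$chrom_length, "bp\n")
cat("intended edges:  ", nrow(study$truth$intended_edges), "\n")
cat("binding sites:   ", nrow(study$peaks), "(",
    sum(startsWith(study$peaks$name, "decoy")), "decoys )\n")
cat("DHSs:            ", nrow(study$dhs), "\n")
cat("survival cohort: ", nrow(study$survival), "patients,",
    round(100 * mean(study$survival$event == 0), 1), "% censored\n")
cat("prognostic FFL:  ",
    paste(unlist(study$truth$prognostic_ffls), collapse = " -> "), "\n")
cat("wrote results/study/\n")
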