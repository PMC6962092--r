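test_that("config validation rejects out-of-range parameters", {
  expect_error(synthetic_config(edge_density = 0), "edge_density")
  expect_error(synthetic_config(hazard_ratio = 0), "hazard_ratio")
  expect_error(synthetic_config(censoring_fraction = 1), "censoring_fraction")
  expect_error(synthetic_config(n_tfs = 10, n_genes = 5))
})

test_that("genome generator tiles the chromosome and is deterministic", {
  cfg <- synthetic_config(n_genes = 10, n_tfs = 3, seed = 1)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genes, g2$genes)
  expect_identical(as.data.frame(g1$seg), as.data.frame(g2$seg))
  seg <- g1$seg
  expect_equal(seg$start[1], 0)
  expect_equal(seg$end[nrow(seg)], cfg$chrom_length)
  expect_true(all(seg$start[-1] == seg$end[-nrow(seg)])) # gap-free, disjoint
  expect_equal(sum(attr(seg, "totals")), cfg$chrom_length)
  # empty case: no genes, chromosome still tiled
  g0 <- generate_genome(synthetic_config(n_genes = 0, n_tfs = 0, chrom_length = 5000))
  expect_equal(nrow(g0$genes), 0L)
  expect_equal(g0$seg$end[nrow(g0$seg)], 5000)
  # infeasible packing is an explicit sizing error
  expect_error(generate_genome(synthetic_config(n_genes = 100, n_tfs = 5,
                                                chrom_length = 1e5)),
               "non-overlapping")
})

test_that("each promoter is dominated by the intended state (>= 80% of bases)", {
  cfg <- synthetic_config(n_genes = 40, n_tfs = 8, seed = 6)
  genome <- generate_genome(cfg)
  g <- genome$genes
  seg <- as.data.frame(genome$seg)
  for (i in seq_len(nrow(g))) {
    idx <- seg$start >= g$promoter_start[i] & seg$end <= g$promoter_end[i]
    dom <- sum(seg$end[idx & seg$state == g$intended_state[i]] -
                 seg$start[idx & seg$state == g$intended_state[i]])
    expect_gte(dom / 3000, 0.8)
  }
})

test_that("peaks realize intended edges exactly; decoys without DHS never become edges", {
  cfg <- synthetic_config(n_genes = 40, n_tfs = 10, edge_density = 0.08, seed = 2)
  genome <- generate_genome(cfg)
  truth <- ground_truth_edges(genome)
  pk <- generate_peaks_dhs(genome, truth, n_decoys = 15)
  pr <- promoter_from_tss(genome$genes)
  net <- call_tfbs_targets(pk$peaks, pr, pk$dhs)
  expect_setequal(paste(net$edges$tf, net$edges$target),
                  paste(truth$intended_edges$tf, truth$intended_edges$target))
  # brute-force interval check agrees
  expect_identical(sort(paste(net$edges$tf, net$edges$target)),
                   oracle_edge_set(pk$peaks, pr, pk$dhs))
  # all TFBS are 41 bp
  expect_true(all(pk$peaks$end - pk$peaks$start == 41))
  # zero intended edges -> no peaks
  t0 <- truth; t0$intended_edges <- truth$intended_edges[0, ]
  pk0 <- generate_peaks_dhs(genome, t0)
  expect_equal(nrow(pk0$peaks), 0L)
})

test_that("single intended edge is recovered; removing its DHS removes it", {
  cfg <- synthetic_config(n_genes = 5, n_tfs = 1, seed = 9)
  genome <- generate_genome(cfg)
  truth <- structure(list(
    intended_edges = data.frame(tf = "TF001", target = "G0002", sign = 1L),
    intended_node_states = stats::setNames(genome$genes$intended_state,
                                           genome$genes$gene)),
    class = "ground_truth")
  pk <- generate_peaks_dhs(genome, truth)
  pr <- promoter_from_tss(genome$genes)
  net <- call_tfbs_targets(pk$peaks, pr, pk$dhs)
  expect_equal(paste(net$edges$tf, net$edges$target), "TF001 G0002")
  # same peak without any DHS: no edge (the DHS filter is doing the work)
  net0 <- call_tfbs_targets(pk$peaks, pr, pk$dhs[0, ])
  expect_equal(nrow(net0$edges), 0L)
})

test_that("expression generator recovers intended edge signs", {
  # noise-free: single-regulator targets correlate exactly +-1
  cfg0 <- synthetic_config(n_genes = 30, n_tfs = 6, edge_density = 0.05,
                           noise_sd = 0, seed = 4)
  genome0 <- generate_genome(cfg0)
  truth0 <- ground_truth_edges(genome0)
  ex0 <- generate_expression(genome0, truth0)
  tab <- table(truth0$intended_edges$target)
  singles <- names(tab)[tab == 1]
  e1 <- truth0$intended_edges[truth0$intended_edges$target %in% singles, ]
  for (i in seq_len(nrow(e1))) {
    r <- cor(ex0$tissue[e1$tf[i], ], ex0$tissue[e1$target[i], ])
    expect_equal(r, e1$sign[i], tolerance = 1e-12)
  }
  # default noise, ~200 edges: sign recovery >= 99%
  cfg <- synthetic_config(n_genes = 420, n_tfs = 20, edge_density = 0.025,
                          seed = 7)
  genome <- generate_genome(cfg)
  truth <- ground_truth_edges(genome)
  expect_gt(nrow(truth$intended_edges), 150)
  ex <- generate_expression(genome, truth)
  r <- vapply(seq_len(nrow(truth$intended_edges)), function(i)
    cor(ex$tissue[truth$intended_edges$tf[i], ],
        ex$tissue[truth$intended_edges$target[i], ]), numeric(1))
  expect_gte(mean(sign(r) == truth$intended_edges$sign), 0.99)
})

test_that("cell-line expression means are monotone in state activity", {
  cfg <- synthetic_config(n_genes = 400, n_tfs = 40, seed = 12)
  genome <- generate_genome(cfg)
  truth <- ground_truth_edges(genome)
  ex <- generate_expression(genome, truth)
  st <- genome$genes$intended_state
  mean_of <- function(s) mean(log2(ex$cell_line[st == s]))
  # active promoter (1) > weak transcribed (11) > heterochromatin (13)
  expect_gt(mean_of(1), mean_of(11))
  expect_gt(mean_of(11), mean_of(13))
})

test_that("survival generator honors censoring and plants proportional hazards", {
  ex <- generate_cohort_expression(c("a", "b", "c"), 200, seed = 1)
  ffl <- data.frame(top = "a", inter = "b", target = "c")
  # zero censoring: all events observed
  s0 <- generate_survival(ex, ffl, hazard_ratio = 2, censoring_fraction = 0,
                          seed = 2)
  expect_true(all(s0$event == 1L))
  expect_true(all(s0$time > 0))
  # requested censoring achieved within tolerance
  s3 <- generate_survival(ex, ffl, hazard_ratio = 1.5,
                          censoring_fraction = 0.3, seed = 3)
  expect_lt(abs(mean(s3$event == 0) - 0.3), 0.05)
  # determinism
  s3b <- generate_survival(ex, ffl, hazard_ratio = 1.5,
                           censoring_fraction = 0.3, seed = 3)
  expect_identical(s3, s3b)
  expect_error(generate_survival(ex, ffl, hazard_ratio = -1), "hazard_ratio")
  expect_error(generate_survival(ex, ffl, censoring_fraction = 1),
               "censoring_fraction")
})

test_that("null survival cohorts give uniform log-rank p-values", {
  # hazard_ratio = 1: median-split log-rank should reject at the nominal
  # rate; 400 replicates keeps the check fast, the acceptance suite runs
  # the full calibration
  p <- vapply(1:400, function(i) {
    ex <- generate_cohort_expression(c("a", "b", "c"), 100, seed = 10000 + i)
    sv <- generate_survival(ex, data.frame(top = "a", inter = "b", target = "c"),
                            hazard_ratio = 1, censoring_fraction = 0,
                            seed = 20000 + i)
    sc <- risk_score(c("a", "b", "c"), ex)
    logrank_test(median_split(sc), sv$time, sv$event)$p_value
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("the study writer emits files the readers round-trip", {
  cfg <- synthetic_config(n_genes = 15, n_tfs = 4, edge_density = 0.1, seed = 13)
  st <- simulate_study(cfg)
  dir <- tempfile()
  write_study(st, dir)
  seg <- read_segmentation(file.path(dir, "segmentation.bed"))
  expect_equal(as.data.frame(seg), as.data.frame(st$genome$seg))
  expr <- read_expression(file.path(dir, "expression_tissues.tsv"))
  expect_equal(expr, st$expression$tissue, tolerance = 1e-12)
  sv <- read_survival(file.path(dir, "survival.tsv"))
  expect_equal(sv$time, st$survival$time, tolerance = 1e-12)
  expect_identical(sv$event, st$survival$event)
  tss <- read_tss(file.path(dir, "tss.tsv"))
  expect_identical(tss$gene, st$genome$genes$gene)
})
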