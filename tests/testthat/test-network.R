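test_that("promoter windows follow the strand-aware 2.5 kb / 0.5 kb rule", {
  g <- data.frame(gene = c("a", "b", "c"), chrom = "c",
                  strand = c("+", "-", "+"), tss = c(10000, 10000, 100))
  pr <- promoter_from_tss(g)
  expect_equal(pr$start, c(7500, 9500, 0))
  expect_equal(pr$end, c(10500, 12500, 600))
  expect_true(all(pr$end - pr$start <= 3000))
  expect_error(promoter_from_tss(transform(g, strand = ".")), "strand")
})

test_that("edge calling follows the >=1 bp TFBS/promoter/DHS overlap rule", {
  promoters <- data.frame(chrom = "c", start = 0, end = 3000,
                          strand = "+", name = "gene1")
  peaks <- data.frame(chrom = "c", start = 100, end = 141, tf = "TF1",
                      name = "s1")
  # DHS overlapping the TFBS by exactly 1 bp
  net <- call_tfbs_targets(peaks, promoters,
                           data.frame(chrom = "c", start = 140, end = 200))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$tf, "TF1")
  expect_equal(net$edges$target, "gene1")
  # no DHS anywhere -> no edge
  net0 <- call_tfbs_targets(peaks, promoters,
                            data.frame(chrom = character(0), start = numeric(0),
                                       end = numeric(0)))
  expect_equal(nrow(net0$edges), 0L)
  # DHS adjacent but not overlapping (half-open) -> no edge
  net1 <- call_tfbs_targets(peaks, promoters,
                            data.frame(chrom = "c", start = 141, end = 200))
  expect_equal(nrow(net1$edges), 0L)
  # empty promoter map warns and returns an empty network
  expect_warning(
    net2 <- call_tfbs_targets(peaks, promoters[0, ],
                              data.frame(chrom = "c", start = 140, end = 200)),
    "empty promoter")
  expect_equal(nrow(net2$edges), 0L)
})

test_that("edge calling equals the all-pairs brute-force oracle and is order-independent", {
  set.seed(42)
  for (rep in 1:5) {
    promoters <- data.frame(chrom = "c", start = (0:19) * 500,
                            end = (0:19) * 500 + 400, strand = "+",
                            name = sprintf("g%02d", 1:20))
    peaks <- data.frame(chrom = "c",
                        start = sample(0:10200, 60, replace = TRUE),
                        tf = sample(sprintf("tf%d", 1:3), 60, replace = TRUE))
    peaks$end <- peaks$start + 41
    peaks$name <- sprintf("s%02d", seq_len(nrow(peaks)))
    dhs <- data.frame(chrom = "c", start = sample(0:10200, 15, replace = TRUE))
    dhs$end <- dhs$start + sample(30:200, 15, replace = TRUE)
    net <- call_tfbs_targets(peaks, promoters, dhs)
    got <- sort(paste(net$edges$tf, net$edges$target))
    expect_identical(got, oracle_edge_set(peaks, promoters, dhs))
    # permuting the inputs leaves the edge set unchanged
    net_p <- call_tfbs_targets(peaks[sample(nrow(peaks)), ],
                               promoters[sample(nrow(promoters)), ],
                               dhs[sample(nrow(dhs)), ])
    expect_setequal(paste(net_p$edges$tf, net_p$edges$target), got)
  }
})

test_that("representative TFBS is the largest-overlap site with leftmost tie-break", {
  promoters <- data.frame(chrom = "c", start = 0, end = 3000, strand = "+",
                          name = "g1")
  # site A overlaps the promoter by 10 bp, site B fully inside
  peaks <- data.frame(chrom = "c", start = c(2990, 100), end = c(3031, 141),
                      tf = "tf1", name = c("A", "B"))
  dhs <- data.frame(chrom = "c", start = 0, end = 4000)
  net <- call_tfbs_targets(peaks, promoters, dhs)
  expect_equal(net$edges$rep_tfbs, "B")
  # exact tie: two fully contained sites -> leftmost start wins
  peaks2 <- data.frame(chrom = "c", start = c(500, 100), end = c(541, 141),
                       tf = "tf1", name = c("right", "left"))
  net2 <- call_tfbs_targets(peaks2, promoters, dhs)
  expect_equal(net2$edges$rep_tfbs, "left")
})

test_that("edge signs follow correlation sign; degenerate edges are dropped and counted", {
  net <- regnet(data.frame(gene = c("tf", "up", "down", "flat"),
                           is_tf = c(TRUE, FALSE, FALSE, FALSE)),
                data.frame(tf = "tf", target = c("up", "down", "flat")))
  x <- c(1, 3, 2, 5, 4, 6)
  expr <- rbind(tf = x, up = 2 * x, down = -x, flat = rep(1, 6))
  signed <- sign_edges(net, expr, "pearson")
  expect_equal(nrow(signed$edges), 2L)
  expect_equal(signed$edges$rho[signed$edges$target == "up"], 1)
  expect_equal(signed$edges$sign[signed$edges$target == "up"], 1L)
  expect_equal(signed$edges$rho[signed$edges$target == "down"], -1)
  expect_equal(signed$edges$sign[signed$edges$target == "down"], -1L)
  expect_equal(unname(attr(signed, "dropped")["degenerate"]), 1L)
  # missing gene drops the edge with a count
  expr2 <- expr[c("tf", "up", "down"), ]
  signed2 <- sign_edges(net, expr2, "pearson")
  expect_equal(unname(attr(signed2, "dropped")["missing"]), 1L)
})

test_that("signing is invariant under affine (Pearson) and monotone (Spearman) transforms", {
  set.seed(8)
  net <- synthetic_base_network(30, 8, 0.1, seed = 8)
  expr <- matrix(2^rnorm(30 * 16), nrow = 30,
                 dimnames = list(net$nodes$gene, NULL))
  p0 <- sign_edges(net, expr, "pearson")
  s0 <- sign_edges(net, expr, "spearman")
  expr_aff <- expr * 3.7 + 11       # positive affine on every row
  expect_equal(sign_edges(net, expr_aff, "pearson")$edges$rho, p0$edges$rho)
  expr_mono <- expr^3               # strictly monotone
  expect_equal(sign_edges(net, expr_mono, "spearman")$edges$rho, s0$edges$rho)
})

test_that("sign concordance is 1 on identical maps, 0 on flipped, exact on mixtures", {
  net <- regnet(data.frame(gene = c("t", "a", "b"), is_tf = c(TRUE, FALSE, FALSE)),
                data.frame(tf = "t", target = c("a", "b"), sign = c(1L, -1L)))
  net_flip <- net
  net_flip$edges$sign <- -net$edges$sign
  expect_equal(sign_concordance(net, net), 1)
  expect_equal(sign_concordance(net, net_flip), 0)
  net_half <- net
  net_half$edges$sign <- c(1L, 1L)
  expect_equal(sign_concordance(net, net_half), 0.5)
  empty <- regnet(data.frame(gene = "t", is_tf = TRUE),
                  data.frame(tf = character(0), target = character(0),
                             sign = integer(0)))
  expect_error(sign_concordance(net, empty), "undefined")
})

test_that("noise-free synthetic expression gives perfect Pearson/Spearman agreement", {
  cfg <- synthetic_config(n_genes = 80, n_tfs = 16, edge_density = 0.05,
                          noise_sd = 0, seed = 7)
  st <- simulate_study(cfg)
  pr <- promoter_from_tss(st$genome$genes)
  net <- call_tfbs_targets(st$peaks, pr, st$dhs)
  sp <- sign_edges(net, st$expression$tissue, "pearson")
  ss <- sign_edges(net, st$expression$tissue, "spearman")
  # single-regulator targets respond monotonically to their TF, so the two
  # coefficients must agree in sign there; and those signs are the truth
  indeg <- table(st$truth$intended_edges$target)
  mono <- function(nn) {
    nn$edges <- nn$edges[nn$edges$target %in% names(indeg)[indeg == 1], ]
    nn
  }
  expect_equal(sign_concordance(mono(sp), mono(ss)), 1)
  m <- merge(mono(sp)$edges, st$truth$intended_edges, by = c("tf", "target"))
  expect_gt(nrow(m), 0)
  expect_true(all(m$sign.x == m$sign.y))
})
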