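test_that("single-motif networks are classified correctly", {
  ffl <- regnet(data.frame(gene = c("A", "B", "C"), is_tf = c(TRUE, TRUE, FALSE),
                           state = c(1L, 2L, 3L)),
                data.frame(tf = c("A", "A", "B"), target = c("B", "C", "C")))
  cen <- enumerate_triads(ffl)
  expect_equal(unname(cen$counts["030T"]), 1L)
  expect_equal(sum(cen$counts), 1L)

  fanout <- regnet(data.frame(gene = c("A", "B", "C"), is_tf = c(TRUE, FALSE, FALSE),
                              state = 1L),
                   data.frame(tf = c("A", "A"), target = c("B", "C")))
  expect_equal(unname(enumerate_triads(fanout)$counts["021D"]), 1L)

  cascade <- regnet(data.frame(gene = c("A", "B", "C"), is_tf = c(TRUE, TRUE, FALSE),
                               state = 1L),
                    data.frame(tf = c("A", "B"), target = c("B", "C")))
  expect_equal(unname(enumerate_triads(cascade)$counts["021C"]), 1L)

  empty <- regnet(data.frame(gene = c("A", "B"), is_tf = TRUE, state = 1L),
                  data.frame(tf = "A", target = "B"))
  expect_equal(sum(enumerate_triads(empty)$counts), 0L)
})

test_that("plain and colored censuses equal exhaustive brute force on random graphs", {
  for (seed in 1:20) {
    net <- random_regnet(n_nodes = sample(8:30, 1), edge_prob = 0.1,
                         seed = seed)
    cen <- enumerate_triads(net)
    plain <- cen$counts
    expect_census_equal(census_to_code_keys(plain),
                        oracle_triad_census(net, colored = FALSE))
    col <- colored_census(net)
    expect_census_equal(census_to_code_keys(col),
                        oracle_triad_census(net, colored = TRUE))
    # conservation: colored counts within a topology sum to the plain count
    lab <- sub("\\|.*$", "", names(col))
    sums <- tapply(as.integer(col), lab, sum)
    expect_equal(sums[names(sums)], plain[names(sums)],
                 ignore_attr = TRUE)
  }
})

test_that("colored keys are invariant under color-preserving relabeling", {
  # the same FFL entered with nodes in different input orders
  k <- lapply(list(c("A", "B", "C"), c("C", "A", "B"), c("B", "C", "A")),
              function(ord) {
    nodes <- data.frame(gene = ord, is_tf = TRUE,
                        state = c(A = 1L, B = 2L, C = 3L)[ord])
    net <- regnet(nodes, data.frame(tf = c("A", "A", "B"),
                                    target = c("B", "C", "C")))
    names(colored_census(net))
  })
  expect_length(unique(unlist(k)), 1L)
  # symmetric topology (fan-out): targets with swapped states share a key
  n1 <- regnet(data.frame(gene = c("A", "B", "C"), is_tf = TRUE,
                          state = c(5L, 1L, 2L)),
               data.frame(tf = c("A", "A"), target = c("B", "C")))
  n2 <- regnet(data.frame(gene = c("A", "B", "C"), is_tf = TRUE,
                          state = c(5L, 2L, 1L)),
               data.frame(tf = c("A", "A"), target = c("B", "C")))
  expect_identical(names(colored_census(n1)), names(colored_census(n2)))
})

test_that("FFL sign classification matches the coherence rule and fixed anchors", {
  expect_equal(classify_ffl(1, 1, 1), "C1")
  expect_equal(classify_ffl(1, -1, 1), "I1")
  # coherence rule: coherent iff sign(AC) == sign(AB) * sign(BC)
  grid <- expand.grid(ab = c(1, -1), bc = c(1, -1), ac = c(1, -1))
  type <- classify_ffl(grid$ab, grid$bc, grid$ac)
  coherent <- grid$ac == grid$ab * grid$bc
  expect_equal(startsWith(type, "C"), coherent)
  expect_length(unique(type), 8L)
  expect_error(classify_ffl(1, NA, 1), "missing")
})

test_that("FFL instances carry structural roles and match the census count", {
  net <- synthetic_base_network(60, 20, 0.06, seed = 4)
  inst <- extract_ffl_instances(net)
  expect_equal(nrow(inst), unname(enumerate_triads(net)$counts["030T"]))
  ek <- paste(net$edges$tf, net$edges$target)
  for (i in seq_len(min(nrow(inst), 10))) {
    expect_true(all(c(paste(inst$top[i], inst$inter[i]),
                      paste(inst$inter[i], inst$target[i]),
                      paste(inst$top[i], inst$target[i])) %in% ek))
  }
  # single C1-FFL: roles identified by degree
  one <- regnet(data.frame(gene = c("X", "Y", "Z"), is_tf = c(TRUE, TRUE, FALSE),
                           state = 1L),
                data.frame(tf = c("X", "X", "Y"), target = c("Y", "Z", "Z"),
                           sign = 1L))
  i1 <- extract_ffl_instances(one)
  expect_equal(i1[c("top", "inter", "target")],
               data.frame(top = "X", inter = "Y", target = "Z"))
  expect_equal(i1$ffl_type, "C1")
})

test_that("edge-swap randomization preserves degrees, mutual dyads and simplicity", {
  net <- synthetic_base_network(500, 100, 0.02, seed = 3)
  deg <- function(n) list(
    out = table(factor(n$edges$tf, levels = n$nodes$gene)),
    inn = table(factor(n$edges$target, levels = n$nodes$gene)))
  mutual <- function(n) {
    k <- paste(n$edges$tf, n$edges$target)
    sum(k %in% paste(n$edges$target, n$edges$tf)) / 2
  }
  r <- randomize_network(net, n_swaps = 1e4, seed = 11)
  expect_gte(attr(r, "accepted"), 1e4)
  expect_identical(deg(r), deg(net))
  expect_identical(mutual(r), mutual(net))
  expect_false(any(r$edges$tf == r$edges$target))
  expect_identical(anyDuplicated(r$edges[c("tf", "target")]), 0L)
  k0 <- paste(net$edges$tf, net$edges$target)
  k1 <- paste(r$edges$tf, r$edges$target)
  expect_lt(length(intersect(k0, k1)) / length(union(k0, k1)), 1)
  # zero swaps: identity; fixed seed: reproducible
  expect_identical(randomize_network(net, n_swaps = 0)$edges, net$edges)
  expect_identical(randomize_network(net, 1e3, seed = 5)$edges,
                   randomize_network(net, 1e3, seed = 5)$edges)
  # node labels stay attached to nodes
  expect_identical(r$nodes, net$nodes)
})

test_that("motif significance reproduces the add-one estimator and z arithmetic", {
  real <- c(ffl = 4L)
  ens <- list(c(ffl = 1L), c(ffl = 2L), c(ffl = 3L))
  st <- motif_significance(real, ens, min_count = 0)
  expect_equal(st$P, 1 / 4)
  expect_equal(st$z, (4 - 2) / 1)
  expect_equal(st$nz, 1)   # single class: unit-length projection
  st_plain <- motif_significance(real, ens, min_count = 0, plain_p = TRUE)
  expect_equal(st_plain$P, 0)
  # real equals every ensemble count: sd 0 -> z defined 0, P = 1
  st0 <- motif_significance(c(a = 2L), list(c(a = 2L), c(a = 2L)), min_count = 0)
  expect_equal(st0$z, 0)
  expect_equal(st0$P, 1)
  expect_false(st0$degenerate)
  # degenerate: sd 0 but real != mean
  std <- motif_significance(c(a = 5L, b = 3L),
                            list(c(a = 2L, b = 2L), c(a = 2L, b = 4L)),
                            min_count = 0)
  expect_true(std$degenerate[std$class == "a"])
  expect_gt(std$z[std$class == "a"], 1e5)
  expect_equal(std$nz[std$class == "a"], 1)
  expect_error(motif_significance(real, list()), "at least one")
})

test_that("normalized z-scores have unit Euclidean norm over non-degenerate classes", {
  set.seed(9)
  net <- synthetic_base_network(120, 30, 0.03, seed = 9)
  real <- colored_census(net)
  ens <- lapply(1:30, function(r) colored_census(randomize_network(net, seed = r)))
  st <- motif_significance(real, ens, min_count = 0)
  nz <- st$nz[!st$degenerate]
  if (any(st$z[!st$degenerate] != 0)) expect_equal(sqrt(sum(nz^2)), 1)
})

test_that("filter_significant applies the P / nz / count thresholds jointly", {
  stats <- data.frame(class = c("a", "b", "c", "d"),
                      N_real = c(600, 499, 600, 600),
                      rand_mean = 1, rand_sd = 1, z = 1,
                      nz = c(0.2, 0.2, -0.1, 0.2),
                      P = c(0.005, 0.005, 0.005, 0.02),
                      degenerate = FALSE, significant = NA)
  keep <- filter_significant(stats)
  expect_identical(keep$class, "a")
  stats0 <- transform(stats, z = 0, nz = 0)
  expect_equal(nrow(filter_significant(stats0)), 0L)
})

test_that("planting increases the class census by at least the requested copies", {
  base <- synthetic_base_network(300, 60, 0.01, seed = 21)
  spec <- list(list(topology = "030T", composition = c(1, 1, 1), copies = 50))
  net <- plant_colored_motifs(base, spec, seed = 22)
  key <- "030T|1.1.1"
  n0 <- colored_census(base)[key]; n0 <- if (is.na(n0)) 0L else n0
  n1 <- colored_census(net)[key]
  expect_gte(unname(n1 - n0), 50L)
  # deterministic under the seed; no-op on empty specs
  net2 <- plant_colored_motifs(base, spec, seed = 22)
  expect_identical(net$edges, net2$edges)
  expect_identical(plant_colored_motifs(base, list(), 1), base)
  expect_error(plant_colored_motifs(base, list(list(topology = "030T",
                                                    composition = c(0, 1, 99),
                                                    copies = 1))),
               "unknown state")
})
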