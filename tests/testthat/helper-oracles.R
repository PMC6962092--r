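# Independent brute-force oracles used to validate the package's optimized
# implementations. Everything here recomputes from first principles:
# exhaustive triple scans, per-base counting, full permutation enumeration.

# --- triad oracle ----------------------------------------------------------
# 6-bit code of an ordered node triple under the shared bit convention.
oracle_pair_bits <- matrix(0L, 3, 3)
oracle_pair_bits[1, 2] <- 1L; oracle_pair_bits[2, 1] <- 2L
oracle_pair_bits[1, 3] <- 4L; oracle_pair_bits[3, 1] <- 8L
oracle_pair_bits[2, 3] <- 16L; oracle_pair_bits[3, 2] <- 32L

oracle_perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

oracle_code <- function(adj, nodes) {
  code <- 0L
  for (i in 1:3) for (j in 1:3) {
    if (i != j && adj[nodes[i], nodes[j]]) {
      code <- bitwOr(code, oracle_pair_bits[i, j])
    }
  }
  code
}

oracle_recode <- function(code, perm) {
  out <- 0L
  for (i in 1:3) for (j in 1:3) {
    if (i != j && bitwAnd(code, oracle_pair_bits[perm[i], perm[j]]) != 0L)
      out <- bitwOr(out, oracle_pair_bits[i, j])
  }
  out
}

# exhaustive census over all C(n,3) triples: counts keyed by canonical code
# (minimum code over the 6 permutations); colored keys additionally carry
# the minimal state triple over minimizing permutations.
oracle_triad_census <- function(network, colored = FALSE) {
  genes <- network$nodes$gene
  n <- length(genes)
  adj <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  if (nrow(network$edges))
    adj[cbind(network$edges$tf, network$edges$target)] <- TRUE
  states <- network$nodes$state
  out <- list()
  if (n < 3) return(integer(0))
  for (trip in utils::combn(n, 3, simplify = FALSE)) {
    code <- oracle_code(adj, trip)
    # weak connectivity: at least two of the three unordered pairs linked
    ab <- bitwAnd(code, 3L) != 0L; ac <- bitwAnd(code, 12L) != 0L
    bc <- bitwAnd(code, 48L) != 0L
    if (sum(ab, ac, bc) < 2L) next
    codes <- vapply(oracle_perms, function(p) oracle_recode(code, p), integer(1))
    canon <- min(codes)
    if (colored) {
      best <- NULL
      for (k in which(codes == canon)) {
        p <- oracle_perms[[k]]
        s <- states[trip[p]]
        key <- sprintf("%02d.%02d.%02d", s[1], s[2], s[3])
        if (is.null(best) || key < best) best <- key
      }
      key <- paste0(canon, "|", best)
    } else {
      key <- as.character(canon)
    }
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  unlist(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# convert package census names (MAN label / label|s1.s2.s3) to the oracle's
# canonical-code keys, via the package's public topology table
census_to_code_keys <- function(counts) {
  tt <- triad_topologies()
  nm <- names(counts)
  lab <- sub("\\|.*$", "", nm)
  states <- ifelse(grepl("\\|", nm), sub("^.*\\|", "", nm), "")
  code <- tt$canonical_code[match(lab, tt$label)]
  newnm <- ifelse(states == "", as.character(code),
                  paste0(code, "|", vapply(strsplit(states, ".", fixed = TRUE),
                                           function(s) paste(sprintf("%02d", as.integer(s)), collapse = "."),
                                           character(1))))
  stats::setNames(as.integer(counts), newnm)
}

expect_census_equal <- function(a, b) {
  a <- a[a != 0]; b <- b[b != 0]
  expect_setequal(names(a), names(b))
  expect_identical(a[sort(names(a))], b[sort(names(b))])
}

# --- interval oracle -------------------------------------------------------
# all-pairs scan over every (peak, promoter, DHS) triple
oracle_edge_set <- function(peaks, promoters, dhs) {
  ov <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
  edges <- character(0)
  for (i in seq_len(nrow(peaks))) for (j in seq_len(nrow(promoters))) {
    if (peaks$chrom[i] != promoters$chrom[j]) next
    if (peaks$tf[i] == promoters$name[j]) next
    if (ov(peaks$start[i], peaks$end[i], promoters$start[j], promoters$end[j]) < 1) next
    hit_dhs <- FALSE
    for (k in seq_len(nrow(dhs))) {
      if (peaks$chrom[i] == dhs$chrom[k] &&
          ov(peaks$start[i], peaks$end[i], dhs$start[k], dhs$end[k]) >= 1) {
        hit_dhs <- TRUE; break
      }
    }
    if (hit_dhs) edges <- c(edges, paste(peaks$tf[i], promoters$name[j]))
  }
  sort(unique(edges))
}

# --- per-base state counting oracle ---------------------------------------
oracle_state_overlap <- function(region, seg, n_states) {
  counts <- numeric(n_states)
  for (b in seq(region$start, region$end - 1)) {
    hit <- which(seg$chrom == region$chrom & seg$start <= b & b < seg$end)
    if (length(hit)) counts[seg$state[hit[1]]] <- counts[seg$state[hit[1]]] + 1
  }
  counts
}

# --- exact rank-sum oracle -------------------------------------------------
# two-sided p by full enumeration of all C(n1+n2, n1) group assignments of
# the pooled values, using the rank-sum statistic of group 1
oracle_ranksum_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  ev <- n1 * (length(pooled) + 1) / 2
  stats_all <- utils::combn(length(pooled), n1, function(idx) sum(r[idx]))
  mean(abs(stats_all - ev) >= abs(obs - ev) - 1e-9)
}

# --- log-rank arithmetic oracle -------------------------------------------
# accumulate O - E and hypergeometric variance over distinct event times
oracle_logrank <- function(groups, times, events) {
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  o_minus_e <- 0; v <- 0; obs <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == gl[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == gl[1])
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- o_minus_e^2 / v
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# --- small fixture builders ------------------------------------------------
random_regnet <- function(n_nodes, edge_prob, seed, n_states = 4) {
  set.seed(seed)
  genes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- expand.grid(tf = genes, target = genes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$tf != pairs$target, ]
  e <- pairs[stats::runif(nrow(pairs)) < edge_prob, ]
  rownames(e) <- NULL
  regnet(data.frame(gene = genes, is_tf = rep(TRUE, n_nodes),
                    state = sample.int(n_states, n_nodes, replace = TRUE)),
         e)
}
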