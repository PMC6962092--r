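# Colored triad census and motif significance.
#
# A triple of nodes (x1, x2, x3) is encoded by a 6-bit adjacency code:
#   bit 1: x1->x2   bit 2: x2->x1
#   bit 4: x1->x3   bit 8: x3->x1
#   bit16: x2->x3   bit32: x3->x2
# The canonical code of an isomorphism class is the minimum code over the 6
# node permutations; 13 weakly connected classes exist without self-loops.
# Colored (chromatin-state) classes canonicalize the node-state triple by
# minimizing over the permutations that realize the canonical code, so two
# colored subgraphs share a key iff related by a color-preserving
# isomorphism.

PERMS3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

pair_bit <- local({
  m <- matrix(0L, 3, 3)
  m[1, 2] <- 1L; m[2, 1] <- 2L; m[1, 3] <- 4L
  m[3, 1] <- 8L; m[2, 3] <- 16L; m[3, 2] <- 32L
  m
})

recode_triad <- function(code, perm) {
  out <- 0L
  for (i in 1:3) for (j in 1:3) {
    if (i != j && bitwAnd(code, pair_bit[perm[i], perm[j]]) != 0L)
      out <- bitwOr(out, pair_bit[i, j])
  }
  out
}

triad_is_connected <- function(code) {
  ab <- bitwAnd(code, 3L) != 0L
  ac <- bitwAnd(code, 12L) != 0L
  bc <- bitwAnd(code, 48L) != 0L
  sum(ab, ac, bc) >= 2L
}

triad_label <- function(code) {
  # Davis-Leinhardt style MAN labels for the 13 connected classes
  has <- function(i, j) bitwAnd(code, pair_bit[i, j]) != 0L
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  M <- A <- 0L
  for (p in pairs) {
    f <- has(p[1], p[2]); r <- has(p[2], p[1])
    if (f && r) M <- M + 1L else if (f || r) A <- A + 1L
  }
  N <- 3L - M - A
  base <- paste0(M, A, N)
  outd <- vapply(1:3, function(i) sum(vapply(1:3, function(j) i != j && has(i, j), logical(1))), integer(1))
  ind <- vapply(1:3, function(i) sum(vapply(1:3, function(j) i != j && has(j, i), logical(1))), integer(1))
  suffix <- ""
  if (base == "021") {
    suffix <- if (any(outd == 2L)) "D" else if (any(ind == 2L)) "U" else "C"
  } else if (base == "111") {
    # the asymmetric edge points into (D) or out of (U) the mutual dyad
    mut <- which(vapply(1:3, function(i) any(vapply(1:3, function(j) i != j && has(i, j) && has(j, i), logical(1))), logical(1)))
    third <- setdiff(1:3, mut)
    suffix <- if (any(vapply(mut, function(m) has(third, m), logical(1)))) "D" else "U"
  } else if (base == "030") {
    suffix <- if (all(outd == 1L) && all(ind == 1L)) "C" else "T"
  } else if (base == "120") {
    mutpair <- NULL
    for (p in pairs) if (has(p[1], p[2]) && has(p[2], p[1])) mutpair <- p
    third <- setdiff(1:3, mutpair)
    into <- vapply(mutpair, function(m) has(third, m), logical(1))
    outof <- vapply(mutpair, function(m) has(m, third), logical(1))
    suffix <- if (all(into)) "D" else if (all(outof)) "U" else "C"
  }
  paste0(base, suffix)
}

triad_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    canon <- integer(64)
    perm_sets <- vector("list", 64)
    for (code in 0:63) {
      codes <- vapply(seq_len(nrow(PERMS3)), function(k) recode_triad(code, PERMS3[k, ]), integer(1))
      canon[code + 1L] <- min(codes)
      perm_sets[[code + 1L]] <- PERMS3[codes == min(codes), , drop = FALSE]
    }
    connected <- vapply(0:63, triad_is_connected, logical(1))
    classes <- sort(unique(canon[connected]))
    topo_of_code <- rep(NA_integer_, 64)
    topo_of_code[connected] <- match(canon[connected], classes)
    labels <- vapply(classes, triad_label, character(1))
    cache <<- list(canon = canon, perm_sets = perm_sets,
                   topo_of_code = topo_of_code, classes = classes,
                   labels = labels)
    cache
  }
})

#' The 13 connected directed triad isomorphism classes
#'
#' @return data.frame with `topology` (integer id used throughout the
#'   package), `canonical_code` (6-bit adjacency code of the canonical
#'   representative) and `label` (Davis-Leinhardt MAN label; the
#'   feedforward loop is `030T`, the single-input / fan-out module `021D`).
#' @export
triad_topologies <- function() {
  tt <- triad_tables()
  data.frame(topology = seq_along(tt$classes),
             canonical_code = tt$classes, label = tt$labels,
             stringsAsFactors = FALSE)
}

#' Topology id of the feedforward loop
#' @return integer id of the FFL (`030T`) class in [triad_topologies()].
#' @export
ffl_topology_id <- function() {
  tt <- triad_topologies()
  tt$topology[tt$label == "030T"]
}

net_edge_index <- function(network) {
  genes <- network$nodes$gene
  list(genes = genes,
       from = match(network$edges$tf, genes),
       to = match(network$edges$target, genes))
}

#' Census of connected three-node subgraphs
#'
#' Enumerates every weakly connected induced three-node subgraph of a simple
#' directed network and classifies it into one of the 13 triad isomorphism
#' classes. Induced counting (the FANMOD convention): the full adjacency
#' pattern among the three nodes defines the class.
#'
#' @param network a [regnet()].
#' @return list of class `triad_census`: `counts` (named integer vector over
#'   topology labels, zeros included), and `triples` (integer matrix with
#'   columns `n1, n2, n3` — node indices into `network$nodes`, ascending —
#'   `code` and `topology`).
#' @export
enumerate_triads <- function(network) {
  stopifnot(inherits(network, "regnet"))
  tt <- triad_tables()
  idx <- net_edge_index(network)
  tr <- cpp_connected_triads(length(idx$genes), idx$from, idx$to)
  topo <- tt$topo_of_code[tr[, 4] + 1L]
  counts <- integer(length(tt$classes))
  if (length(topo)) {
    tb <- tabulate(topo, nbins = length(tt$classes))
    counts <- tb
  }
  names(counts) <- tt$labels
  list(counts = counts,
       triples = cbind(tr, topology = topo)) |>
    structure(class = "triad_census")
}

state_triple_code <- function(s1, s2, s3) (s1 * 16L + s2) * 16L + s3

decode_state_triple <- function(enc) {
  s3 <- enc %% 16L; enc <- enc %/% 16L
  s2 <- enc %% 16L
  cbind(enc %/% 16L, s2, s3)
}

#' Census of chromatin-state-colored triads
#'
#' Counts connected three-node subgraphs jointly by topology and the
#' canonical (automorphism-minimal) chromatin-state assignment of their
#' nodes. Edge states are carried by the network but do not define classes.
#'
#' @param network a labeled [regnet()] (every node must have a state).
#' @return named integer vector of counts; names are class keys of the form
#'   `"<label>|s1.s2.s3"` with states in canonical node order. Attribute
#'   `triples` holds the per-triple matrix (`n1,n2,n3,code,topology,class`)
#'   with `class` an index into the names.
#' @export
colored_census <- function(network) {
  stopifnot(inherits(network, "regnet"))
  if (anyNA(network$nodes$state))
    stop("colored_census requires every node to carry a chromatin state")
  tt <- triad_tables()
  cen <- enumerate_triads(network)
  tr <- cen$triples
  if (!nrow(tr)) {
    out <- integer(0)
    attr(out, "triples") <- tr
    return(out)
  }
  st <- matrix(network$nodes$state[tr[, 1:3]], ncol = 3)
  enc <- rep(NA_integer_, nrow(tr))
  for (code in unique(tr[, 4])) {
    rows <- which(tr[, 4] == code)
    perms <- tt$perm_sets[[code + 1L]]
    best <- NULL
    for (k in seq_len(nrow(perms))) {
      p <- perms[k, ]
      cand <- state_triple_code(st[rows, p[1]], st[rows, p[2]], st[rows, p[3]])
      best <- if (is.null(best)) cand else pmin(best, cand)
    }
    enc[rows] <- best
  }
  topo <- tr[, 5]
  key_num <- topo * 4096L * 16L + enc
  uk <- sort(unique(key_num))
  dec <- decode_state_triple(uk %% (4096L * 16L))
  keys <- sprintf("%s|%d.%d.%d", tt$labels[uk %/% (4096L * 16L)],
                  dec[, 1], dec[, 2], dec[, 3])
  cls <- match(key_num, uk)
  counts <- tabulate(cls, nbins = length(uk))
  names(counts) <- keys
  attr(counts, "triples") <- cbind(cen$triples, class = cls)
  counts
}

#' Classify a feedforward loop by its edge signs
#'
#' With top TF A, intermediate TF B and target C, the FFL is coherent when
#' the direct sign equals the product of the indirect signs:
#' `sign(A->C) = sign(A->B) * sign(B->C)`. Types follow the standard
#' Mangan-Alon enumeration; C1 = (+,+,+), I1 = (+,-,+).
#'
#' @param sign_ab,sign_bc,sign_ac numeric vectors of +1/-1 (recycled).
#' @return character vector in `C1..C4, I1..I4`.
#' @export
classify_ffl <- function(sign_ab, sign_bc, sign_ac) {
  n <- max(length(sign_ab), length(sign_bc), length(sign_ac))
  sign_ab <- rep_len(sign_ab, n); sign_bc <- rep_len(sign_bc, n)
  sign_ac <- rep_len(sign_ac, n)
  if (anyNA(c(sign_ab, sign_bc, sign_ac)))
    stop("classification refused: missing edge sign")
  if (!all(c(sign_ab, sign_bc, sign_ac) %in% c(-1, 1)))
    stop("signs must be +1 or -1")
  key <- paste(sign_ab, sign_bc, sign_ac)
  map <- c("1 1 1" = "C1", "-1 -1 1" = "C2", "1 -1 -1" = "C3",
           "-1 1 -1" = "C4", "1 -1 1" = "I1", "-1 -1 -1" = "I2",
           "1 1 -1" = "I3", "-1 1 1" = "I4")
  unname(map[key])
}

#' Degree-preserving randomization by edge swapping
#'
#' Produces a null-model network by repeatedly swapping the endpoints of
#' random edge pairs. Every node's in- and out-degree is preserved exactly,
#' and mutual (reciprocal) dyads are swapped only with other mutual dyads so
#' the count of every two-node subgraph type is conserved — proposals that
#' would create a self-loop, a duplicate edge, or convert between single and
#' mutual dyads are rejected and retried. Node labels stay attached to
#' nodes; edge attributes travel with edges.
#'
#' @param network a [regnet()].
#' @param n_swaps number of *accepted* swaps to perform. Default
#'   `min(1e6, 10 * nrow(network$edges))`.
#' @param seed optional integer seed (caller RNG state is preserved).
#' @param max_attempts cap on attempted swaps (default `100 * n_swaps`).
#' @return the randomized network; attributes `accepted` and `attempts`
#'   record the swap counts.
#' @export
randomize_network <- function(network, n_swaps = NULL, seed = NULL,
                              max_attempts = NULL) {
  stopifnot(inherits(network, "regnet"))
  e <- network$edges
  if (is.null(n_swaps)) n_swaps <- min(1e6, 10 * nrow(e))
  if (n_swaps < 0) stop("n_swaps must be >= 0")
  if (is.null(max_attempts)) max_attempts <- max(100 * n_swaps, 1000)
  if (n_swaps == 0 || nrow(e) < 2) {
    attr(network, "accepted") <- 0L
    attr(network, "attempts") <- 0L
    return(network)
  }
  idx <- net_edge_index(network)
  run <- function() cpp_swap_edges(length(idx$genes), idx$from, idx$to,
                                   as.integer(n_swaps), as.double(max_attempts))
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  e$tf <- idx$genes[res$from]
  e$target <- idx$genes[res$to]
  rownames(e) <- NULL
  network$edges <- e
  attr(network, "accepted") <- res$accepted
  attr(network, "attempts") <- res$attempts
  network
}

#' Significance of colored motif classes against a randomized ensemble
#'
#' For each colored class observed in the real network or in any randomized
#' network, computes the empirical P-value, the z-score and the normalized
#' z-score (significance-profile style: the z-vector over all classes in the
#' run scaled to unit Euclidean length).
#'
#' The empirical P-value uses the add-one estimator
#' `P = (#\{rand >= real\} + 1) / (R + 1)` by default so that P is never 0
#' with a finite ensemble; `plain_p = TRUE` gives the plain fraction.
#' Classes with zero ensemble standard deviation get `z = 0` when the real
#' count equals the ensemble mean and otherwise a large sentinel z of the
#' correct sign with `degenerate = TRUE`; the normalizing norm is computed
#' over non-degenerate classes only.
#'
#' @param real named integer vector from [colored_census()] (or any census).
#' @param ensemble list of R such vectors from randomized networks.
#' @param p_threshold,nz_threshold,min_count significance filters:
#'   `P < p_threshold`, `nz > nz_threshold`, `N_real >= min_count`.
#' @param plain_p use the plain fraction estimator instead of add-one.
#' @return data.frame (class, N_real, rand_mean, rand_sd, z, nz, P,
#'   degenerate, significant), sorted by P then class key.
#' @export
motif_significance <- function(real, ensemble, p_threshold = 0.01,
                               nz_threshold = 0, min_count = 500,
                               plain_p = FALSE) {
  R <- length(ensemble)
  if (R < 1) stop("ensemble must contain at least one randomized census")
  keys <- sort(unique(c(names(real), unlist(lapply(ensemble, names)))))
  get <- function(v) {
    out <- stats::setNames(numeric(length(keys)), keys)
    if (length(v)) out[names(v)] <- v
    out
  }
  x <- get(real)
  M <- vapply(ensemble, get, numeric(length(keys)))
  if (is.null(dim(M))) M <- matrix(M, nrow = length(keys))
  rmean <- rowMeans(M)
  rsd <- apply(M, 1, stats::sd)
  if (R == 1) rsd[] <- 0
  ge <- rowSums(M >= matrix(x, nrow = length(keys), ncol = R))
  P <- if (plain_p) ge / R else (ge + 1) / (R + 1)
  degenerate <- rsd == 0 & x != rmean
  z <- numeric(length(keys))
  ok <- rsd > 0
  z[ok] <- (x[ok] - rmean[ok]) / rsd[ok]
  z[degenerate] <- sign(x[degenerate] - rmean[degenerate]) * 1e6
  nrm <- sqrt(sum(z[!degenerate]^2))
  nz <- numeric(length(keys))
  if (nrm > 0) nz[!degenerate] <- z[!degenerate] / nrm
  nz[degenerate] <- sign(z[degenerate])
  out <- data.frame(class = keys, N_real = unname(x), rand_mean = rmean,
                    rand_sd = rsd, z = z, nz = nz, P = P,
                    degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$P < p_threshold & out$nz > nz_threshold &
    out$N_real >= min_count
  out[order(out$P, out$class), , drop = FALSE]
}

#' Filter motif classes passing all significance criteria
#'
#' Retains classes with empirical `P < p_threshold`, normalized z-score
#' above `nz_threshold`, and a real-network count of at least `min_count`
#' (defaults 0.01, 0 and 500).
#'
#' @param stats data.frame from [motif_significance()].
#' @inheritParams motif_significance
#' @return the subset of rows passing all three criteria.
#' @export
filter_significant <- function(stats, p_threshold = 0.01, nz_threshold = 0,
                               min_count = 500) {
  stats[stats$P < p_threshold & stats$nz > nz_threshold &
          stats$N_real >= min_count, , drop = FALSE]
}

#' Extract feedforward-loop instances from a labeled, signed network
#'
#' Every induced FFL triple is returned with its structural roles (the node
#' with out-degree 2 in the triad is the top TF, in-degree 2 the target),
#' edge signs, coherent/incoherent type and chromatin-state composition.
#'
#' @param network a signed, labeled [regnet()].
#' @param classes optional character vector of colored class keys (as in
#'   [colored_census()] names); instances of other classes are dropped.
#' @return data.frame (top, inter, target, sign_ab, sign_bc, sign_ac,
#'   ffl_type, state_top, state_inter, state_target, class).
#' @export
extract_ffl_instances <- function(network, classes = NULL) {
  cen <- colored_census(network)
  tr <- attr(cen, "triples")
  empty <- data.frame(top = character(0), inter = character(0),
                      target = character(0), sign_ab = numeric(0),
                      sign_bc = numeric(0), sign_ac = numeric(0),
                      ffl_type = character(0), state_top = integer(0),
                      state_inter = integer(0), state_target = integer(0),
                      class = character(0), stringsAsFactors = FALSE)
  if (!nrow(tr)) return(empty)
  tr <- tr[tr[, "topology"] == ffl_topology_id(), , drop = FALSE]
  if (!nrow(tr)) return(empty)
  genes <- network$nodes$gene
  states <- network$nodes$state
  e <- network$edges
  ekey <- paste(e$tf, e$target, sep = "\r")
  has_edge <- function(u, v) match(paste(genes[u], genes[v], sep = "\r"), ekey)
  res <- lapply(seq_len(nrow(tr)), function(i) {
    nd <- tr[i, 1:3]
    adj <- outer(nd, nd, function(u, v) !is.na(has_edge(u, v)))
    diag(adj) <- FALSE
    top <- nd[rowSums(adj) == 2]
    target <- nd[colSums(adj) == 2]
    inter <- setdiff(nd, c(top, target))
    i_ab <- has_edge(top, inter); i_bc <- has_edge(inter, target)
    i_ac <- has_edge(top, target)
    s <- if ("sign" %in% names(e)) c(e$sign[i_ab], e$sign[i_bc], e$sign[i_ac]) else rep(NA_real_, 3)
    data.frame(top = genes[top], inter = genes[inter], target = genes[target],
               sign_ab = s[1], sign_bc = s[2], sign_ac = s[3],
               ffl_type = if (anyNA(s)) NA_character_ else classify_ffl(s[1], s[2], s[3]),
               state_top = states[top], state_inter = states[inter],
               state_target = states[target],
               class = names(cen)[tr[i, "class"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(classes)) out <- out[out$class %in% classes, , drop = FALSE]
  out <- out[!duplicated(out[c("top", "inter", "target")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
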