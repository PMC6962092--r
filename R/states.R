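#' The 15-class chromatin-state vocabulary
#'
#' Chromatin states learned from combinatorial histone-mark patterns
#' (multivariate HMM segmentations of the Ernst et al. type). State ids are
#' 1-15; any segmentation whose labels map onto this table is accepted.
#'
#' @return A data.frame with columns `state` (integer 1-15), `name`, and
#'   `activity`, a rough transcriptional-activity rank used only by the
#'   synthetic-data generator (higher = more active).
#' @export
chromatin_states <- function() {
  data.frame(
    state = 1:15,
    name = c(
      "Active Promoter", "Weak Promoter", "Poised Promoter",
      "Strong Enhancer", "Strong Enhancer (2)",
      "Weak Enhancer", "Weak Enhancer (2)",
      "Insulator", "Txn Transition", "Txn Elongation", "Weak Txn",
      "Polycomb Repressed", "Heterochromatin/Low",
      "Repetitive/CNV", "Repetitive/CNV (2)"
    ),
    # log-scale expression activity used by the simulator; chosen so that
    # active promoter > weak transcribed > heterochromatin
    activity = c(5.0, 3.5, 1.5, 4.0, 4.0, 3.0, 3.0, 2.5,
                 4.2, 4.2, 2.8, 1.0, 0.5, 1.2, 1.2),
    stringsAsFactors = FALSE
  )
}

#' Construct a chromatin-state segmentation
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `state` (integer in `1:n_states`).
#' @param n_states number of states in the vocabulary (default 15).
#' @return An object of class `segmentation`: the interval table (sorted)
#'   with attributes `n_states`, `totals` (genome-wide bases per state,
#'   `c_s`) and `grand_total` (`t`).
#' @export
segmentation <- function(intervals, n_states = 15L) {
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(intervals)))
  intervals$state <- as.integer(intervals$state)
  if (nrow(intervals)) {
    if (any(intervals$start < 0) || any(intervals$end <= intervals$start))
      stop("segmentation intervals must satisfy 0 <= start < end")
    if (any(intervals$state < 1L | intervals$state > n_states))
      stop("segmentation states must lie in 1..", n_states)
  }
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  # overlap check within chromosome
  for (ch in unique(intervals$chrom)) {
    x <- intervals[intervals$chrom == ch, ]
    if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)]))
      stop("segmentation intervals overlap on ", ch)
  }
  totals <- vapply(seq_len(n_states), function(s) {
    idx <- intervals$state == s
    sum(as.numeric(intervals$end[idx] - intervals$start[idx]))
  }, numeric(1))
  structure(intervals,
            class = c("segmentation", "data.frame"),
            n_states = as.integer(n_states),
            totals = totals,
            grand_total = sum(totals))
}

seg_totals <- function(seg) attr(seg, "totals")
seg_n_states <- function(seg) attr(seg, "n_states")

#' Per-state base overlap between regions and a segmentation
#'
#' Workhorse used by [state_enrichment_score()] and [assign_states()]: for
#' each query region, the number of bases overlapping each chromatin state.
#' Intersection is done with IRanges.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param seg a [segmentation()].
#' @return numeric matrix, `nrow(regions)` x `n_states`, of overlap bases.
#' @keywords internal
state_overlap_matrix <- function(regions, seg) {
  n_states <- seg_n_states(seg)
  out <- matrix(0, nrow = nrow(regions), ncol = n_states)
  if (!nrow(regions) || !nrow(seg)) return(out)
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    si <- which(seg$chrom == ch)
    if (!length(si)) next
    qr <- IRanges::IRanges(start = regions$start[ri] + 1L, end = regions$end[ri])
    sr <- IRanges::IRanges(start = seg$start[si] + 1L, end = seg$end[si])
    hits <- IRanges::findOverlaps(qr, sr)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(IRanges::end(qr)[qh], IRanges::end(sr)[sh]) -
      pmax(IRanges::start(qr)[qh], IRanges::start(sr)[sh]) + 1
    st <- seg$state[si][sh]
    acc <- rowsum(as.numeric(ov), group = (qh - 1L) * n_states + st)
    key <- as.integer(rownames(acc))
    out[cbind(ri[(key - 1L) %/% n_states + 1L], (key - 1L) %% n_states + 1L)] <-
      out[cbind(ri[(key - 1L) %/% n_states + 1L], (key - 1L) %% n_states + 1L)] + acc[, 1]
  }
  out
}

#' Fold-enrichment profile of chromatin states over a region
#'
#' For a region (promoter or TF binding site) and a genome segmentation,
#' computes the per-state enrichment score
#' \deqn{S_s = (r_s / n) / (c_s / t)}
#' where `r_s` is the number of region bases overlapping state `s`, `n` the
#' number of region bases covered by the segmentation, `c_s` the genome-wide
#' base total of state `s` and `t` the genome-wide total over all states.
#' `S_s` is defined 0 when `c_s = 0` and `r_s = 0`; `c_s = 0` with `r_s > 0`
#' is a data-integrity error.
#'
#' @param region one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param seg a [segmentation()].
#' @return An object of class `state_enrichment`: list with `r_s`, `n`,
#'   `c_s`, `t` and the score vector `S`.
#' @export
state_enrichment_score <- function(region, seg) {
  region <- as.data.frame(region[c("chrom", "start", "end")])
  if (region$end - region$start <= 0) stop("region length must be > 0")
  r_s <- drop(state_overlap_matrix(region, seg))
  n <- sum(r_s)
  if (n == 0) stop("region has zero bases covered by the segmentation; enrichment undefined")
  c_s <- seg_totals(seg)
  t <- attr(seg, "grand_total")
  if (any(c_s == 0 & r_s > 0))
    stop("inconsistent segmentation: state with genome total 0 overlaps the region")
  S <- ifelse(c_s == 0, 0, (r_s / n) / (c_s / t))
  structure(list(region = region, r_s = r_s, n = n, c_s = c_s, t = t, S = S),
            class = "state_enrichment")
}

#' Assign the chromatin state of a region
#'
#' The state with the highest fold-enrichment score is selected. Exact ties
#' on the score are broken toward the state with more observed bases `r_s`,
#' then toward the smaller state id.
#'
#' @inheritParams state_enrichment_score
#' @return integer state id.
#' @export
assign_state <- function(region, seg) {
  prof <- state_enrichment_score(region, seg)
  pick_state(prof$S, prof$r_s)
}

pick_state <- function(S, r_s) {
  best <- which(S == max(S))
  if (length(best) > 1L) best <- best[r_s[best] == max(r_s[best])]
  as.integer(min(best))
}

#' Assign chromatin states to many regions at once
#'
#' Vectorized form of [assign_state()].
#'
#' @param regions data.frame with `chrom`, `start`, `end` and a `name` column
#'   identifying each region.
#' @param seg a [segmentation()].
#' @return named integer vector of state ids (NA for regions with zero
#'   covered bases, reported with a warning).
#' @export
assign_states <- function(regions, seg) {
  if (!nrow(regions))
    return(stats::setNames(integer(0), character(0)))
  r <- state_overlap_matrix(regions, seg)
  c_s <- seg_totals(seg)
  t <- attr(seg, "grand_total")
  n <- rowSums(r)
  S <- sweep(r / pmax(n, 1), 2, ifelse(c_s == 0, NA, c_s / t), `/`)
  S[is.na(S)] <- 0
  res <- vapply(seq_len(nrow(regions)), function(i) {
    if (n[i] == 0) return(NA_integer_)
    pick_state(S[i, ], r[i, ])
  }, integer(1))
  if (anyNA(res))
    warning(sum(is.na(res)), " region(s) had no segmentation coverage; state NA")
  stats::setNames(res, regions$name)
}

#' Label network nodes and edges with chromatin states
#'
#' Node states come from promoter states; each edge takes the state of its
#' representative TF binding site. Nodes present in the network but absent
#' from the promoter-state map are a hard error (never silently defaulted).
#'
#' @param network a [regnet()].
#' @param promoter_states named integer vector: gene -> state.
#' @param tfbs_states named integer vector: TFBS id -> state; looked up via
#'   the `rep_tfbs` edge column. Optional if the network has no edges or no
#'   `rep_tfbs` column.
#' @return the network with `nodes$state` and `edges$state` filled in.
#' @export
label_network <- function(network, promoter_states, tfbs_states = NULL) {
  stopifnot(inherits(network, "regnet"))
  missing_nodes <- setdiff(network$nodes$gene, names(promoter_states))
  if (length(missing_nodes))
    stop("no promoter state for node(s): ", paste(missing_nodes, collapse = ", "))
  network$nodes$state <- as.integer(promoter_states[network$nodes$gene])
  if (nrow(network$edges)) {
    if (!is.null(tfbs_states) && "rep_tfbs" %in% names(network$edges)) {
      missing_e <- setdiff(network$edges$rep_tfbs, names(tfbs_states))
      if (length(missing_e))
        stop("no TFBS state for representative site(s): ",
             paste(utils::head(missing_e, 5), collapse = ", "))
      network$edges$state <- as.integer(tfbs_states[network$edges$rep_tfbs])
    } else if (!"state" %in% names(network$edges)) {
      network$edges$state <- NA_integer_
    }
  }
  network
}

#' Chromatin-state frequency distributions of a labeled network
#'
#' @param network a labeled [regnet()].
#' @return list with data.frames `nodes` and `edges`, each (state, count,
#'   frequency); frequencies sum to 1 per table (empty tables for empty
#'   networks).
#' @export
state_distribution <- function(network) {
  stopifnot(inherits(network, "regnet"))
  tab <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(state = integer(0), count = integer(0), frequency = numeric(0)))
    tt <- table(x)
    data.frame(state = as.integer(names(tt)), count = as.integer(tt),
               frequency = as.integer(tt) / length(x))
  }
  list(nodes = tab(network$nodes$state),
       edges = tab(if ("state" %in% names(network$edges)) network$edges$state else integer(0)))
}
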