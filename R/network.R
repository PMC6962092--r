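#' Construct a regulatory network object
#'
#' A simple directed TF->gene graph. Self-loops are dropped (they are not
#' part of three-node motif analysis) and duplicate (tf, target) pairs are
#' an error.
#'
#' @param nodes data.frame with `gene` (character) and `is_tf` (logical);
#'   an optional `state` column carries chromatin-state labels.
#' @param edges data.frame with `tf`, `target` and optional `sign` (+1/-1),
#'   `rho`, `state`, `rep_tfbs` columns.
#' @return object of class `regnet`.
#' @export
regnet <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  stopifnot(all(c("gene", "is_tf") %in% names(nodes)),
            all(c("tf", "target") %in% names(edges)))
  if (anyDuplicated(nodes$gene)) stop("duplicate node ids")
  edges <- edges[edges$tf != edges$target, , drop = FALSE]
  if (anyDuplicated(edges[c("tf", "target")]))
    stop("duplicate (tf, target) edges")
  if (nrow(edges)) {
    bad <- setdiff(c(edges$tf, edges$target), nodes$gene)
    if (length(bad)) stop("edge endpoint(s) not in node table: ",
                          paste(utils::head(bad, 5), collapse = ", "))
    not_tf <- unique(edges$tf[!edges$tf %in% nodes$gene[nodes$is_tf]])
    if (length(not_tf)) stop("edge source(s) not flagged is_tf: ",
                             paste(utils::head(not_tf, 5), collapse = ", "))
  }
  rownames(nodes) <- rownames(edges) <- NULL
  attr(nodes, "out.attrs") <- attr(edges, "out.attrs") <- NULL
  structure(list(nodes = nodes, edges = edges), class = "regnet")
}

#' @export
print.regnet <- function(x, ...) {
  cat("regulatory network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$is_tf), "TFs ),", nrow(x$edges), "edges\n")
  if ("sign" %in% names(x$edges) && nrow(x$edges))
    cat("  signed:", sum(x$edges$sign > 0), "+ /", sum(x$edges$sign < 0), "-\n")
  invisible(x)
}

#' Promoter intervals around transcription start sites
#'
#' 3 kb promoters: 2.5 kb upstream to 0.5 kb downstream of the TSS,
#' strand-aware, clamped at the chromosome start (coordinates are 0-based
#' half-open). Genes whose promoter would be empty after clamping are
#' skipped with a warning.
#'
#' @param genes data.frame with `gene`, `chrom`, `strand` ("+"/"-") and
#'   `tss` columns.
#' @param upstream,downstream window sizes in bases.
#' @return data.frame (chrom, start, end, strand, name) of promoters.
#' @export
promoter_from_tss <- function(genes, upstream = 2500L, downstream = 500L) {
  stopifnot(all(c("gene", "chrom", "strand", "tss") %in% names(genes)))
  if (!nrow(genes))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), name = character(0)))
  if (!all(genes$strand %in% c("+", "-")))
    stop("unknown strand value(s); must be '+' or '-'")
  if (any(genes$tss < 0)) stop("tss must be >= 0")
  start <- ifelse(genes$strand == "+", genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(genes$strand == "+", genes$tss + downstream, genes$tss + upstream)
  start <- pmax(start, 0)
  keep <- end > start
  if (!all(keep)) {
    warning(sum(!keep), " gene(s) with empty promoter after clamping were skipped")
  }
  data.frame(chrom = genes$chrom[keep], start = as.integer(start[keep]),
             end = as.integer(end[keep]), strand = genes$strand[keep],
             name = genes$gene[keep], stringsAsFactors = FALSE)
}

overlap_pairs <- function(a, b) {
  # indices of (i in a, j in b) with >= 1 bp overlap, same chrom
  if (!nrow(a) || !nrow(b))
    return(data.frame(a = integer(0), b = integer(0), bases = numeric(0)))
  res <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == ch); bi <- which(b$chrom == ch)
    qa <- IRanges::IRanges(a$start[ai] + 1L, a$end[ai])
    qb <- IRanges::IRanges(b$start[bi] + 1L, b$end[bi])
    h <- IRanges::findOverlaps(qa, qb)
    if (!length(h)) next
    i <- S4Vectors::queryHits(h); j <- S4Vectors::subjectHits(h)
    ov <- pmin(IRanges::end(qa)[i], IRanges::end(qb)[j]) -
      pmax(IRanges::start(qa)[i], IRanges::start(qb)[j]) + 1
    res[[ch]] <- data.frame(a = ai[i], b = bi[j], bases = as.numeric(ov))
  }
  if (!length(res))
    return(data.frame(a = integer(0), b = integer(0), bases = numeric(0)))
  do.call(rbind, unname(res))
}

#' Call TF->gene edges from binding sites, promoters and DHSs
#'
#' A gene is a target of a TF if at least one of the TF's binding sites
#' overlaps the gene's promoter by >= 1 bp and also overlaps a DNase
#' hypersensitive site by >= 1 bp. Multiple supporting sites collapse to one
#' edge; the site with the largest promoter overlap (ties: leftmost start)
#' is kept as the edge's representative TFBS for later state labeling.
#'
#' @param peaks data.frame of binding sites with `chrom`, `start`, `end`,
#'   `tf` and `name` (site id) columns.
#' @param promoters promoter table as returned by [promoter_from_tss()].
#' @param dhs data.frame of DHS intervals (`chrom`, `start`, `end`).
#' @return unsigned [regnet()]; edges carry `rep_tfbs` ids.
#' @export
call_tfbs_targets <- function(peaks, promoters, dhs) {
  if (!nrow(promoters)) {
    warning("empty promoter map; returning empty network")
    tfs <- unique(peaks$tf)
    return(regnet(data.frame(gene = tfs, is_tf = rep(TRUE, length(tfs))),
                  data.frame(tf = character(0), target = character(0),
                             rep_tfbs = character(0))))
  }
  pp <- overlap_pairs(peaks, promoters)       # peak x promoter
  pd <- overlap_pairs(peaks, dhs)             # peak x DHS
  open_peak <- unique(pd$a)
  pp <- pp[pp$a %in% open_peak, , drop = FALSE]
  edges <- data.frame(tf = character(0), target = character(0),
                      rep_tfbs = character(0), stringsAsFactors = FALSE)
  if (nrow(pp)) {
    cand <- data.frame(tf = peaks$tf[pp$a], target = promoters$name[pp$b],
                       tfbs = peaks$name[pp$a], bases = pp$bases,
                       start = peaks$start[pp$a], stringsAsFactors = FALSE)
    # drop self-edges (TF binding its own promoter) before deduplication
    cand <- cand[cand$tf != cand$target, , drop = FALSE]
    if (nrow(cand)) {
      ord <- order(cand$tf, cand$target, -cand$bases, cand$start)
      cand <- cand[ord, ]
      keep <- !duplicated(cand[c("tf", "target")])
      edges <- data.frame(tf = cand$tf[keep], target = cand$target[keep],
                          rep_tfbs = cand$tfbs[keep], stringsAsFactors = FALSE)
    }
  }
  tfs <- unique(peaks$tf)
  genes <- union(tfs, unique(c(promoters$name, edges$target)))
  regnet(data.frame(gene = genes, is_tf = genes %in% tfs, stringsAsFactors = FALSE),
         edges)
}

#' Sign network edges by cross-tissue expression correlation
#'
#' The correlation between the TF's and the target's expression across the
#' tissue panel determines the regulation sign: positive correlation ->
#' activation, negative -> repression. Edges whose genes are missing from
#' the matrix, or whose correlation is undefined (a constant expression
#' vector) or exactly zero, are dropped and counted.
#'
#' @param network a [regnet()].
#' @param expr numeric matrix, genes (rows, named) x tissues (columns).
#' @param method "pearson" or "spearman".
#' @return the network with `sign` (+1/-1), `rho` and `method` columns on
#'   edges; attribute `dropped` records the counts of excluded edges.
#' @export
sign_edges <- function(network, expr, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(network, "regnet"))
  e <- network$edges
  dropped <- c(missing = 0L, degenerate = 0L, zero = 0L)
  if (nrow(e)) {
    present <- e$tf %in% rownames(expr) & e$target %in% rownames(expr)
    dropped["missing"] <- sum(!present)
    e <- e[present, , drop = FALSE]
    if (nrow(e)) {
      rho <- vapply(seq_len(nrow(e)), function(i) {
        x <- expr[e$tf[i], ]; y <- expr[e$target[i], ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
        stats::cor(x, y, method = method)
      }, numeric(1))
      dropped["degenerate"] <- sum(is.na(rho))
      dropped["zero"] <- sum(!is.na(rho) & rho == 0)
      keep <- !is.na(rho) & rho != 0
      e <- e[keep, , drop = FALSE]
      e$rho <- rho[keep]
      e$sign <- ifelse(e$rho > 0, 1L, -1L)
      e$method <- method
    }
  }
  rownames(e) <- NULL
  network$edges <- e
  attr(network, "dropped") <- dropped
  network
}

#' Sign concordance between two signing methods
#'
#' Fraction of edges shared by the two signed networks (same unsigned edge
#' set; edges dropped by either method are excluded from the denominator)
#' that carry the same sign. Used to compare Pearson against Spearman
#' signing.
#'
#' @param net1,net2 signed [regnet()]s from the same unsigned edge set.
#' @return numeric fraction in \[0, 1\].
#' @export
sign_concordance <- function(net1, net2) {
  k1 <- paste(net1$edges$tf, net1$edges$target, sep = "\r")
  k2 <- paste(net2$edges$tf, net2$edges$target, sep = "\r")
  shared <- intersect(k1, k2)
  if (!length(shared)) stop("no shared signed edges; concordance undefined")
  s1 <- net1$edges$sign[match(shared, k1)]
  s2 <- net2$edges$sign[match(shared, k2)]
  mean(s1 == s2)
}
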