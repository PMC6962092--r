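#' Mean target expression per colored FFL class
#'
#' Summarizes cell-line expression of FFL target genes by chromatin-state
#' composition class. Targets are deduplicated within a class; targets
#' without an expression value are skipped and reported.
#'
#' @param instances data.frame from [extract_ffl_instances()].
#' @param expr named numeric vector of cell-line expression.
#' @return data.frame (class, n_targets, mean_expression) with a list
#'   column `targets`; attribute `skipped` counts targets lacking
#'   expression.
#' @export
target_expression_by_composition <- function(instances, expr) {
  if (!nrow(instances)) {
    out <- data.frame(class = character(0), n_targets = integer(0),
                      mean_expression = numeric(0), stringsAsFactors = FALSE)
    out$targets <- list()
    attr(out, "skipped") <- 0L
    return(out)
  }
  skipped <- 0L
  res <- lapply(split(instances, instances$class), function(d) {
    tg <- unique(d$target)
    hasx <- tg %in% names(expr)
    skipped <<- skipped + sum(!hasx)
    tg <- tg[hasx]
    data.frame(class = d$class[1], n_targets = length(tg),
               mean_expression = if (length(tg)) mean(expr[tg]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$targets <- lapply(split(instances, instances$class), function(d)
    intersect(unique(d$target), names(expr)))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Two-sided Wilcoxon rank-sum comparison of two expression groups
#'
#' Exact test when both groups have at most 25 observations and there are
#' no ties; otherwise the normal approximation with tie correction. The
#' method actually used is recorded.
#'
#' @param group1,group2 non-empty numeric vectors.
#' @return list (p_value, statistic, method) of class `ranksum_comparison`.
#' @export
compare_compositions <- function(group1, group2) {
  if (!length(group1) || !length(group2))
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group1, group2)) > 0
  exact <- length(group1) <= 25 && length(group2) <= 25 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group1, group2, alternative = "two.sided",
                       exact = exact, correct = !exact))
  structure(list(p_value = wt$p.value, statistic = unname(wt$statistic),
                 method = if (exact) "exact" else "normal approximation with tie correction"),
            class = "ranksum_comparison")
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: tab-separated lines `term<TAB>description<TAB>gene...`.
#' @return named list of character vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[`, character(1), 2), names(sets))
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional named descriptions (defaults to the term id).
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- stats::setNames(names(sets), names(sets))
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, description[[nm]], sets[[nm]]), collapse = "\t"), character(1)),
    path)
}

#' Hypergeometric gene-set over-representation test
#'
#' Upper-tail hypergeometric p-value per term (probability of an overlap at
#' least as large as observed, given the term size, query size and
#' universe), with Benjamini-Hochberg adjustment across all tested terms.
#' Gene sets are intersected with the universe; the query must be a subset
#' of the universe.
#'
#' @param query character vector of genes of interest.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe background gene vector.
#' @param alpha adjusted-p cutoff for the `significant` flag.
#' @return data.frame (term, overlap, term_size, query_size, universe_size,
#'   p, p_adj, significant), sorted by p.
#' @export
hypergeometric_enrichment <- function(query, gene_sets, universe,
                                      alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (length(setdiff(query, universe)))
    stop("query contains genes outside the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, overlap = k, term_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), overlap = integer(0),
                      term_size = integer(0), query_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  }
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out[order(out$p, out$term), , drop = FALSE]
}
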