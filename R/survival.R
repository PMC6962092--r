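#' Equally weighted expression risk score for an FFL's genes
#'
#' Per-patient linear combination of the expression of the FFL's three node
#' genes, weighted equally. In the default standardized mode every gene is
#' first standardized across the cohort (mean 0, sd 1) so genes on
#' different FPKM scales contribute equally; `standardize = FALSE` gives
#' the literal raw sum. Zero-variance genes are excluded with a warning
#' (standardized mode); if all genes are excluded the score is an error.
#'
#' @param genes character vector of the FFL's node genes.
#' @param expr genes x patients expression matrix.
#' @param standardize standardize each gene before summing (default TRUE).
#' @return named numeric vector of per-patient scores.
#' @export
risk_score <- function(genes, expr, standardize = TRUE) {
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  x <- expr[genes, , drop = FALSE]
  if (standardize) {
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) {
      warning("zero-variance gene(s) excluded from risk score: ",
              paste(genes[sds == 0], collapse = ", "))
      x <- x[sds > 0, , drop = FALSE]
      if (!nrow(x)) stop("all genes zero-variance; risk score undefined")
      sds <- sds[sds > 0]
    }
    x <- (x - rowMeans(x)) / sds
  }
  stats::setNames(colSums(x), colnames(expr))
}

#' Median split of risk scores into high- and low-risk groups
#'
#' Scores above the median are "high", scores below are "low"; scores equal
#' to the median go to the low-risk group (a deterministic tie rule that
#' keeps the high group strictly above the median). Refuses to split when
#' all scores are identical.
#'
#' @param scores numeric vector (>= 2 patients).
#' @return factor with levels `low`, `high`, named like `scores`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 patients to split")
  if (stats::sd(scores) == 0) stop("all risk scores identical; split refused")
  med <- stats::median(scores)
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

#' Two-group log-rank test
#'
#' Standard log-rank: observed minus expected events accumulated over the
#' distinct event times, variance-normalized, chi-square with 1 df.
#' Censored observations at an event time are considered at risk at that
#' time (censoring after events at ties). Both groups having zero events
#' gives p = 1 with a warning.
#'
#' @param groups two-level factor (or vector) of group labels.
#' @param times positive event/censoring times.
#' @param events 1 = event observed, 0 = censored.
#' @return list (statistic, p_value, observed, expected) of class
#'   `logrank_test`.
#' @export
logrank_test <- function(groups, times, events) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    stop("log-rank test requires exactly two non-empty groups")
  if (sum(events) == 0) {
    warning("no events in either group; log-rank p = 1")
    return(structure(list(statistic = 0, p_value = 1,
                          observed = c(0, 0), expected = c(0, 0)),
                     class = "logrank_test"))
  }
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  structure(list(statistic = unname(sd_fit$chisq),
                 p_value = stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE),
                 observed = sd_fit$obs, expected = sd_fit$exp),
            class = "logrank_test")
}

#' Kaplan-Meier survival curves per group
#'
#' @inheritParams logrank_test
#' @return data.frame (group, time, n_risk, n_event, survival): the KM step
#'   function evaluated at the observed times of each group, starting at
#'   survival 1 at time 0.
#' @export
km_curves <- function(groups, times, events) {
  groups <- factor(groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  strata <- if (is.null(fit$strata)) stats::setNames(length(fit$time), levels(groups)[1]) else fit$strata
  grp <- rep(sub("^groups=", "", names(strata)), strata)
  base <- do.call(rbind, lapply(unique(grp), function(g) {
    data.frame(group = g, time = 0, n_risk = max(fit$n.risk[grp == g]),
               n_event = 0, survival = 1, stringsAsFactors = FALSE)
  }))
  rbind(base,
        data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, survival = fit$surv,
                   stringsAsFactors = FALSE))
}

#' Screen FFLs as survival biomarkers
#'
#' For each FFL: equally weighted risk score, median split into high/low
#' groups, Kaplan-Meier comparison by log-rank test. Results are ranked by
#' p-value; the direction column reports which group has worse survival
#' (higher event rate relative to expectation). Raw p-values are reported
#' (matching the screen's original use) alongside Benjamini-Hochberg
#' adjusted ones. FFLs that cannot be tested (missing genes, degenerate
#' scores) are listed in attribute `untestable`.
#'
#' @param ffls data.frame with columns `top`, `inter`, `target`.
#' @param cohort data.frame (patient, time, event) with the expression
#'   matrix in attribute `expression`, as from [generate_survival()], or
#'   pass `expr` explicitly.
#' @param expr optional genes x patients expression matrix overriding the
#'   cohort attribute.
#' @param alpha significance level for the `significant` flag (raw p).
#' @param standardize passed to [risk_score()].
#' @return data.frame (top, inter, target, statistic, p, p_adj, direction,
#'   n_high, n_low, significant) sorted by p.
#' @export
screen_ffls <- function(ffls, cohort, expr = NULL, alpha = 0.05,
                        standardize = TRUE) {
  if (is.null(expr)) expr <- attr(cohort, "expression")
  if (is.null(expr)) stop("no expression matrix supplied")
  ffls <- as.data.frame(ffls)
  empty <- data.frame(top = character(0), inter = character(0),
                      target = character(0), statistic = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      direction = character(0), n_high = integer(0),
                      n_low = integer(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  if (!nrow(ffls)) {
    attr(empty, "untestable") <- empty[0, 1:3]
    return(empty)
  }
  expr <- expr[, cohort$patient, drop = FALSE]
  rows <- list(); untestable <- list()
  for (i in seq_len(nrow(ffls))) {
    gs <- unlist(ffls[i, c("top", "inter", "target")])
    res <- tryCatch({
      sc <- risk_score(gs, expr, standardize = standardize)
      grp <- median_split(sc)
      lr <- logrank_test(grp, cohort$time, cohort$event)
      hi <- which(levels(grp) == "high")
      direction <- if (lr$observed[hi] >= lr$expected[hi]) "high-risk worse" else "low-risk worse"
      data.frame(top = gs[1], inter = gs[2], target = gs[3],
                 statistic = lr$statistic, p = lr$p_value, p_adj = NA_real_,
                 direction = direction,
                 n_high = sum(grp == "high"), n_low = sum(grp == "low"),
                 significant = NA, stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error"))
      untestable[[length(untestable) + 1L]] <-
        data.frame(top = gs[1], inter = gs[2], target = gs[3],
                   reason = conditionMessage(res), stringsAsFactors = FALSE)
    else rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out)) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p < alpha
    out <- out[order(out$p), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "untestable") <- if (length(untestable)) do.call(rbind, untestable) else NULL
  out
}
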