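# Synthetic study generator: toy genome, 15-state segmentation, TF binding
# sites and DHSs realizing a known edge set, a 16-tissue expression panel
# with sign-consistent TF-target correlations, planted colored motifs, and
# survival cohorts with planted proportional-hazards effects. Every
# generator is deterministic under a fixed seed.

#' Configuration for the synthetic study
#'
#' @param n_genes,n_tfs number of genes and (a subset of them) TFs.
#' @param chrom_length length of the single synthetic chromosome; default
#'   places each gene in a 6 kb slot.
#' @param n_states chromatin-state vocabulary size (default 15).
#' @param n_tissues tissue-panel size for edge signing (default 16,
#'   mirroring a Human-Body-Map-like panel).
#' @param edge_density probability that a (TF, gene) pair is an intended
#'   regulatory edge.
#' @param noise_sd relative noise of target expression around its
#'   TF-driven mean (default 0.1; 0 gives exactly linear responses).
#' @param planted_motif_specs list of planting specs, see
#'   [plant_colored_motifs()].
#' @param hazard_ratio per-standard-deviation hazard ratio of the planted
#'   prognostic signal.
#' @param censoring_fraction requested fraction of censored patients.
#' @param n_patients survival cohort size (default 197, a TCGA-LAML-sized
#'   cohort).
#' @param seed integer seed; all generators derive their streams from it.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 200L, n_tfs = 30L, chrom_length = NULL,
                             n_states = 15L, n_tissues = 16L,
                             edge_density = 0.02, noise_sd = 0.1,
                             planted_motif_specs = list(),
                             hazard_ratio = 2, censoring_fraction = 0.3,
                             n_patients = 197L, seed = 1L) {
  if (is.null(chrom_length)) chrom_length <- max(n_genes, 1) * 6000 + 10000
  stopifnot(n_genes >= 0, n_tfs >= 0, n_tfs <= n_genes,
            n_states >= 1, n_tissues >= 2, n_patients >= 2)
  if (edge_density <= 0 || edge_density >= 1) stop("edge_density must be in (0,1)")
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    stop("censoring_fraction must be in [0,1)")
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 chrom_length = as.numeric(chrom_length),
                 n_states = as.integer(n_states),
                 n_tissues = as.integer(n_tissues),
                 edge_density = edge_density, noise_sd = noise_sd,
                 planted_motif_specs = planted_motif_specs,
                 hazard_ratio = hazard_ratio,
                 censoring_fraction = censoring_fraction,
                 n_patients = as.integer(n_patients),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate the toy genome: gene annotation plus chromatin segmentation
#'
#' Places `n_genes` non-overlapping 3 kb promoters on one chromosome, each
#' dominated (92% of bases) by the gene's intended chromatin state with an
#' 8% contamination block of a different state, and tiles the rest of the
#' chromosome with 500 bp blocks cycling through all states. The
#' segmentation tiles `[0, chrom_length)` with no gaps or overlaps.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_genome`: `genes` (gene, chrom, strand,
#'   tss, is_tf, intended_state, promoter_start, promoter_end), `seg`
#'   (a [segmentation()]), and the config.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_genes
  L <- config$chrom_length
  K <- config$n_states
  with_seed(config$seed, {
    if (n > 0) {
      slot <- floor(L / n)
      if (slot < 3200)
        stop("chrom_length too small to place ", n,
             " non-overlapping 3 kb promoters (need >= ", n * 3200, " bases)")
    }
    genes <- if (n == 0) {
      data.frame(gene = character(0), chrom = character(0), strand = character(0),
                 tss = numeric(0), is_tf = logical(0), intended_state = integer(0),
                 promoter_start = numeric(0), promoter_end = numeric(0),
                 stringsAsFactors = FALSE)
    } else {
      slot_start <- (seq_len(n) - 1) * slot
      jitter <- floor(stats::runif(n, 0, pmax(slot - 3100, 1)))
      p0 <- slot_start + 50 + jitter
      p0 <- pmin(p0, slot_start + slot - 3050)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      tss <- ifelse(strand == "+", p0 + 2500, p0 + 500)
      st <- sample.int(K, n, replace = TRUE)
      data.frame(
        gene = c(sprintf("TF%03d", seq_len(config$n_tfs)),
                 sprintf("G%04d", seq_len(n - config$n_tfs))),
        chrom = "chrS", strand = strand, tss = tss,
        is_tf = seq_len(n) <= config$n_tfs,
        intended_state = st, promoter_start = p0, promoter_end = p0 + 3000,
        stringsAsFactors = FALSE)
    }
    # segmentation: promoter blocks + round-robin filler
    iv <- list()
    rr <- sample.int(K, 1)  # round-robin cursor for filler blocks
    fill <- function(from, to) {
      if (to <= from) return(NULL)
      brk <- seq(from, to, by = 500)
      if (brk[length(brk)] < to) brk <- c(brk, to)
      st <- ((rr + seq_len(length(brk) - 1L) - 2L) %% K) + 1L
      rr <<- ((rr + length(brk) - 2L) %% K) + 1L
      data.frame(chrom = "chrS", start = brk[-length(brk)], end = brk[-1], state = st)
    }
    pos <- 0
    for (i in seq_len(nrow(genes))) {
      p0 <- genes$promoter_start[i]
      iv[[length(iv) + 1L]] <- fill(pos, p0)
      s <- genes$intended_state[i]
      contam <- (s %% K) + 1L
      iv[[length(iv) + 1L]] <- data.frame(
        chrom = "chrS", start = c(p0, p0 + 2760), end = c(p0 + 2760, p0 + 3000),
        state = c(s, contam))
      pos <- p0 + 3000
    }
    iv[[length(iv) + 1L]] <- fill(pos, L)
    seg <- segmentation(do.call(rbind, iv), n_states = K)
    structure(list(genes = genes, seg = seg, config = config),
              class = "synthetic_genome")
  })
}

#' Intended regulatory edges and node states (the ground truth)
#'
#' Draws the intended TF->gene edge set (each ordered (TF, gene) pair, no
#' self-loops, included with probability `edge_density`) with random signs.
#' Edges are restricted to run from lower to higher gene index (TFs come
#' first), making the intended network acyclic so that tissue expression
#' can be generated in topological order with exact sign control.
#'
#' @param genome a [generate_genome()] result.
#' @return list of class `ground_truth`: `intended_edges` (tf, target,
#'   sign) and `intended_node_states` (named integer vector).
#' @export
ground_truth_edges <- function(genome) {
  stopifnot(inherits(genome, "synthetic_genome"))
  cfg <- genome$config
  with_seed(cfg$seed + 1L, {
    g <- genome$genes
    tfs <- g$gene[g$is_tf]
    pairs <- expand.grid(tf = tfs, target = g$gene, stringsAsFactors = FALSE)
    pairs <- pairs[match(pairs$tf, g$gene) < match(pairs$target, g$gene), , drop = FALSE]
    keep <- stats::runif(nrow(pairs)) < cfg$edge_density
    e <- pairs[keep, , drop = FALSE]
    e$sign <- sample(c(1L, -1L), nrow(e), replace = TRUE)
    rownames(e) <- NULL
    structure(list(intended_edges = e,
                   intended_node_states = stats::setNames(g$intended_state, g$gene)),
              class = "ground_truth")
  })
}

#' Generate TF binding sites and DHSs realizing the intended edges
#'
#' For every intended edge, a 41 bp binding site (peak summit +/- 20 bp) is
#' placed in the target's promoter overlapping a DHS by >= 1 bp. Intended
#' non-edges get no such configuration. Optionally, decoy binding sites are
#' placed in promoters *without* DHS support: they must not become edges.
#'
#' @param genome a [generate_genome()] result.
#' @param truth a [ground_truth_edges()] result (or a compatible list with
#'   `intended_edges`).
#' @param n_decoys number of decoy (TF, gene) non-edge sites to place.
#' @return list with `peaks` (chrom, start, end, tf, name) and `dhs`
#'   (chrom, start, end, name) tables.
#' @export
generate_peaks_dhs <- function(genome, truth, n_decoys = 0L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  g <- genome$genes
  cfg <- genome$config
  e <- truth$intended_edges
  bad <- setdiff(unique(c(e$tf, e$target)), g$gene)
  if (length(bad)) stop("intended edges reference unknown gene(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  with_seed(cfg$seed + 2L, {
    peaks <- dhs <- NULL
    if (nrow(e)) {
      # slot index of each edge within its target promoter
      ord <- order(e$target, e$tf)
      e <- e[ord, , drop = FALSE]
      slot <- stats::ave(seq_len(nrow(e)), e$target, FUN = seq_along)
      # real sites occupy the left 2/3 of the promoter; decoys the right end
      if (any(50 + slot * 45 + 90 > 2000))
        stop("promoter too crowded to place distinct binding sites")
      p0 <- g$promoter_start[match(e$target, g$gene)]
      s <- p0 + 50 + (slot - 1) * 45
      peaks <- data.frame(chrom = "chrS", start = s, end = s + 41,
                          tf = e$tf, name = paste0("site_", e$tf, "_", e$target),
                          stringsAsFactors = FALSE)
      dhs <- data.frame(chrom = "chrS", start = s + 30, end = s + 90,
                        name = paste0("dhs_", e$tf, "_", e$target),
                        stringsAsFactors = FALSE)
    } else {
      peaks <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                          tf = character(0), name = character(0), stringsAsFactors = FALSE)
      dhs <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                        name = character(0), stringsAsFactors = FALSE)
    }
    if (n_decoys > 0 && nrow(g)) {
      tfs <- g$gene[g$is_tf]
      ek <- paste(e$tf, e$target)
      cand <- expand.grid(tf = tfs, target = g$gene, stringsAsFactors = FALSE)
      cand <- cand[cand$tf != cand$target & !(paste(cand$tf, cand$target) %in% ek), ]
      cand <- cand[sample.int(nrow(cand), min(n_decoys, nrow(cand))), , drop = FALSE]
      dslot <- stats::ave(seq_len(nrow(cand)), cand$target, FUN = seq_along)
      if (any(dslot * 45 > 800))
        stop("promoter too crowded to place decoy binding sites")
      p0 <- g$promoter_start[match(cand$target, g$gene)]
      s <- p0 + 3000 - 100 - dslot * 45
      peaks <- rbind(peaks, data.frame(
        chrom = "chrS", start = s, end = s + 41, tf = cand$tf,
        name = paste0("decoy_", cand$tf, "_", cand$target), stringsAsFactors = FALSE))
    }
    rownames(peaks) <- rownames(dhs) <- NULL
    list(peaks = peaks, dhs = dhs)
  })
}

#' Generate the tissue expression panel and a cell-line expression vector
#'
#' FPKM-like log-normal expression. Each TF gets an independent tissue
#' profile; each target's expression responds linearly to its regulators'
#' expression with the intended sign, plus relative Gaussian noise
#' (`config$noise_sd`), so intended edge signs are recovered by correlation
#' with high probability (exactly, at zero noise). Cell-line expression
#' means follow the chromatin-state activity ranking (active promoter >
#' weak transcribed > heterochromatin).
#'
#' @param genome a [generate_genome()] result.
#' @param truth a [ground_truth_edges()] result.
#' @param config optional config override (defaults to the genome's).
#' @return list with `tissue` (genes x tissues matrix) and `cell_line`
#'   (named vector).
#' @export
generate_expression <- function(genome, truth, config = genome$config) {
  stopifnot(inherits(genome, "synthetic_genome"))
  g <- genome$genes
  K <- config$n_tissues
  act <- chromatin_states()$activity
  if (config$n_states != 15L)
    act <- rep_len(act, config$n_states)
  mu <- 2^act[g$intended_state]        # FPKM-scale state-dependent mean
  names(mu) <- g$gene
  with_seed(config$seed + 3L, {
    expr <- matrix(NA_real_, nrow = nrow(g), ncol = K,
                   dimnames = list(g$gene, sprintf("tissue%02d", seq_len(K))))
    regs <- split(seq_len(nrow(truth$intended_edges)), truth$intended_edges$target)
    # the intended network is acyclic with edges running down the gene
    # order, so generating in table order visits regulators before targets
    for (i in seq_len(nrow(g))) {
      gene <- g$gene[i]
      idx <- regs[[gene]]
      if (is.null(idx)) {
        expr[i, ] <- mu[i] * 2^stats::rnorm(K, 0, 0.7)
      } else {
        tfs <- truth$intended_edges$tf[idx]
        sgn <- truth$intended_edges$sign[idx]
        # per-regulator contributions are summed on the 1/sqrt(k) scale so
        # each regulator keeps a detectable partial correlation, and
        # clamped to [-1, 1] (the clamp never triggers for k = 1, keeping
        # the single-regulator noise-free response exactly linear)
        contrib <- vapply(seq_along(tfs), function(k) {
          x <- expr[tfs[k], ]
          dev <- x - mean(x)
          md <- max(abs(dev))
          sgn[k] * (if (md > 0) dev / md else dev)
        }, numeric(K))
        combo <- rowSums(matrix(contrib, nrow = K)) / sqrt(length(tfs))
        combo <- pmin(pmax(combo, -1), 1)
        eps <- if (config$noise_sd > 0) stats::rnorm(K, 0, config$noise_sd) else 0
        expr[i, ] <- pmax(mu[i] * (1 + 0.8 * combo + eps), 1e-9)
      }
    }
    cell <- mu * 2^stats::rnorm(nrow(g), 0, 0.3)
    list(tissue = expr, cell_line = cell)
  })
}

#' A directly simulated labeled, signed regulatory network
#'
#' Convenience generator for the motif-discovery stage: random TF->gene
#' edges with random signs, skipping the genomic plumbing. Node chromatin
#' states are assigned in balanced proportions separately within TFs and
#' within non-TFs (then shuffled), so every state has both regulator and
#' target representatives and any composition can be planted.
#'
#' @param n_nodes,n_tfs,edge_density,n_states,seed as in
#'   [synthetic_config()].
#' @return a labeled signed [regnet()].
#' @export
synthetic_base_network <- function(n_nodes = 300L, n_tfs = 60L,
                                   edge_density = 0.01, n_states = 15L,
                                   seed = 1L) {
  with_seed(seed, {
    genes <- c(sprintf("TF%03d", seq_len(n_tfs)),
               sprintf("G%04d", seq_len(n_nodes - n_tfs)))
    nodes <- data.frame(gene = genes, is_tf = seq_len(n_nodes) <= n_tfs,
                        state = c(sample(rep_len(seq_len(n_states), n_tfs)),
                                  sample(rep_len(seq_len(n_states), n_nodes - n_tfs))),
                        stringsAsFactors = FALSE)
    pairs <- expand.grid(tf = genes[seq_len(n_tfs)], target = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$tf != pairs$target, , drop = FALSE]
    e <- pairs[stats::runif(nrow(pairs)) < edge_density, , drop = FALSE]
    e$sign <- sample(c(1L, -1L), nrow(e), replace = TRUE)
    rownames(e) <- NULL
    regnet(nodes, e)
  })
}

#' Plant extra copies of colored motif classes into a network
#'
#' Adds edges so that the census count of each requested colored class
#' increases by at least the requested number of copies. Each planted
#' feedforward loop uses nodes with the requested chromatin states (top and
#' intermediate must be TFs); candidate triples are accepted only when the
#' missing edges and their reversals are absent, which guarantees planted
#' instances are induced FFLs and that planting never destroys an earlier
#' planted instance. The degree sequence changes by construction and is
#' recorded for audit.
#'
#' @param network a labeled [regnet()].
#' @param specs list of specs: each a list with `topology` (currently only
#'   `"030T"`, the FFL), `composition` (states of top, intermediate,
#'   target), `copies`, and optional `signs` (defaults `c(1, 1, 1)`, a
#'   C1-FFL).
#' @param seed integer seed.
#' @return the augmented network, with attributes `planted` (data.frame of
#'   planted triples) and `degree_before` for audit.
#' @export
plant_colored_motifs <- function(network, specs, seed = 1L) {
  stopifnot(inherits(network, "regnet"))
  if (!length(specs)) return(network)
  nodes <- network$nodes
  n_states <- max(15L, nodes$state, na.rm = TRUE)
  for (sp in specs) {
    if (!identical(sp$topology, "030T"))
      stop("only FFL ('030T') planting is supported")
    if (any(sp$composition < 1 | sp$composition > n_states))
      stop("unknown state id in planting composition")
  }
  deg_before <- table(factor(c(network$edges$tf, network$edges$target),
                             levels = nodes$gene))
  ekey <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(network$edges)))
    assign(paste(network$edges$tf[i], network$edges$target[i], sep = "\r"),
           TRUE, envir = ekey)
  has <- function(u, v) exists(paste(u, v, sep = "\r"), envir = ekey)
  new_edges <- list()
  planted <- list()
  with_seed(seed, {
    for (sp in specs) {
      comp <- sp$composition
      sgn <- if (is.null(sp$signs)) c(1L, 1L, 1L) else as.integer(sp$signs)
      top_pool <- nodes$gene[nodes$is_tf & nodes$state == comp[1]]
      int_pool <- nodes$gene[nodes$is_tf & nodes$state == comp[2]]
      tgt_pool <- nodes$gene[nodes$state == comp[3]]
      if (!length(top_pool) || !length(int_pool) || !length(tgt_pool))
        stop("no nodes available for planting composition ",
             paste(comp, collapse = "."))
      # enumerate candidate triples once and walk them in random order,
      # preferring non-TF targets: those plantings never consume a
      # (top, inter) pair orientation through the reverse-edge guard
      cand <- expand.grid(a = top_pool, b = int_pool, cc = tgt_pool,
                          stringsAsFactors = FALSE)
      cand <- cand[cand$a != cand$b & cand$a != cand$cc & cand$b != cand$cc, ,
                   drop = FALSE]
      tgt_is_tf <- cand$cc %in% nodes$gene[nodes$is_tf]
      cand <- cand[order(tgt_is_tf, sample.int(nrow(cand))), , drop = FALSE]
      base_present <- vapply(seq_len(nrow(cand)), function(r)
        has(cand$a[r], cand$b[r]) && has(cand$b[r], cand$cc[r]) &&
          has(cand$a[r], cand$cc[r]), logical(1))
      done <- 0L; row <- 0L
      while (done < sp$copies) {
        row <- row + 1L
        if (row > nrow(cand))
          stop("unable to plant requested motif copies; network too constrained")
        a <- cand$a[row]; b <- cand$b[row]; cc <- cand$cc[row]
        req <- list(c(a, b), c(b, cc), c(a, cc))
        present <- vapply(req, function(p) has(p[1], p[2]), logical(1))
        rev_present <- any(vapply(req, function(p) has(p[2], p[1]), logical(1)))
        if (all(present)) {
          # a new induced instance assembled from edges of earlier
          # plantings counts as a copy; one already complete in the base
          # network does not
          if (!base_present[row] && !rev_present) {
            planted[[length(planted) + 1L]] <-
              data.frame(top = a, inter = b, target = cc,
                         composition = paste(comp, collapse = "."),
                         stringsAsFactors = FALSE)
            done <- done + 1L
          }
          next
        }
        if (rev_present) next
        for (k in which(!present)) {
          p <- req[[k]]
          assign(paste(p[1], p[2], sep = "\r"), TRUE, envir = ekey)
          new_edges[[length(new_edges) + 1L]] <-
            data.frame(tf = p[1], target = p[2], sign = sgn[k],
                       stringsAsFactors = FALSE)
        }
        planted[[length(planted) + 1L]] <-
          data.frame(top = a, inter = b, target = cc,
                     composition = paste(comp, collapse = "."),
                     stringsAsFactors = FALSE)
        done <- done + 1L
      }
    }
  })
  if (length(new_edges)) {
    add <- do.call(rbind, new_edges)
    for (col in setdiff(names(network$edges), names(add))) add[[col]] <- NA
    network$edges <- rbind(network$edges, add[names(network$edges)])
    rownames(network$edges) <- NULL
  }
  attr(network, "planted") <- do.call(rbind, planted)
  attr(network, "degree_before") <- deg_before
  network
}

#' Generate a patient expression cohort
#'
#' Independent log-normal expression per gene; used as the background on
#' which [generate_survival()] plants a prognostic signal.
#'
#' @param genes character vector of gene ids.
#' @param n_patients cohort size.
#' @param seed integer seed.
#' @return genes x patients matrix.
#' @export
generate_cohort_expression <- function(genes, n_patients = 197L, seed = 1L) {
  with_seed(seed, {
    m <- matrix(2^stats::rnorm(length(genes) * n_patients, 4, 1.2),
                nrow = length(genes),
                dimnames = list(genes, sprintf("P%04d", seq_len(n_patients))))
    m
  })
}

#' Generate survival outcomes with a planted proportional-hazards effect
#'
#' Event times are exponential with a per-patient hazard multiplier
#' `hazard_ratio^z`, where `z` is the patient's standardized risk score
#' (the equally weighted, per-gene standardized expression sum over the
#' prognostic FFL genes; `hazard_ratio = 1` gives a null cohort).
#' Independent uniform censoring on `[0, m]` with the horizon `m` tuned by
#' bisection so the expected censored fraction matches the request.
#'
#' @param expr genes x patients expression matrix.
#' @param prognostic_ffls data.frame with columns `top`, `inter`, `target`
#'   (may be empty / NULL for a pure null cohort).
#' @param hazard_ratio per-SD hazard ratio (> 0).
#' @param censoring_fraction requested censored fraction in `[0, 1)`.
#' @param seed integer seed.
#' @param baseline_rate exponential baseline hazard (per day).
#' @return data.frame of class `survival_cohort`: (patient, time, event)
#'   with the expression matrix in attribute `expression` and the true
#'   per-patient risk in attribute `true_risk`.
#' @export
generate_survival <- function(expr, prognostic_ffls = NULL, hazard_ratio = 2,
                              censoring_fraction = 0.3, seed = 1L,
                              baseline_rate = 1 / 500) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    stop("censoring_fraction must be in [0,1)")
  n <- ncol(expr)
  z <- rep(0, n)
  if (!is.null(prognostic_ffls) && nrow(as.data.frame(prognostic_ffls))) {
    pf <- as.data.frame(prognostic_ffls)
    sc <- vapply(seq_len(nrow(pf)), function(i) {
      risk_score(unlist(pf[i, c("top", "inter", "target")]), expr)
    }, numeric(n))
    z <- drop(scale(rowMeans(matrix(sc, nrow = n))))
  }
  with_seed(seed, {
    rate <- baseline_rate * hazard_ratio^z
    T_ev <- stats::rexp(n, rate = rate)
    if (censoring_fraction == 0) {
      time <- T_ev; event <- rep(1L, n)
    } else {
      f <- function(m) mean(pmin(T_ev / m, 1)) - censoring_fraction
      lo <- min(T_ev) / 2; hi <- max(T_ev) * 1000
      for (it in 1:200) {
        mid <- sqrt(lo * hi)
        if (f(mid) > 0) lo <- mid else hi <- mid
      }
      m <- sqrt(lo * hi)
      C <- stats::runif(n, 0, m)
      event <- as.integer(T_ev <= C)
      time <- pmin(T_ev, C)
    }
    out <- data.frame(patient = colnames(expr), time = pmax(time, 1e-9),
                      event = event, stringsAsFactors = FALSE)
    attr(out, "expression") <- expr
    attr(out, "true_risk") <- z
    class(out) <- c("survival_cohort", "data.frame")
    out
  })
}

#' Run the whole synthetic study generator
#'
#' Produces every input artifact the pipeline consumes, plus the ground
#' truth: genome and segmentation, binding sites and DHSs, tissue and
#' cell-line expression, the intended network (with planted motifs if
#' requested), and a survival cohort whose prognostic signal is the first
#' intended FFL (if any).
#'
#' @param config a [synthetic_config()].
#' @param n_decoys decoy binding sites without DHS support.
#' @return list with `genome`, `truth`, `peaks`, `dhs`, `expression`,
#'   `cohort_expression`, `survival`, and `config`.
#' @export
simulate_study <- function(config = synthetic_config(), n_decoys = 0L) {
  genome <- generate_genome(config)
  truth <- ground_truth_edges(genome)
  pk <- generate_peaks_dhs(genome, truth, n_decoys = n_decoys)
  ex <- generate_expression(genome, truth)
  # intended network, for ground-truth FFLs
  g <- genome$genes
  nodes <- data.frame(gene = g$gene, is_tf = g$is_tf,
                      state = g$intended_state, stringsAsFactors = FALSE)
  net <- regnet(nodes, truth$intended_edges)
  ffls <- extract_ffl_instances(net)
  truth$prognostic_ffls <- if (nrow(ffls)) ffls[1, c("top", "inter", "target")] else NULL
  cohort <- generate_cohort_expression(g$gene, config$n_patients,
                                       seed = config$seed + 4L)
  surv <- generate_survival(cohort, truth$prognostic_ffls,
                            hazard_ratio = config$hazard_ratio,
                            censoring_fraction = config$censoring_fraction,
                            seed = config$seed + 5L)
  list(genome = genome, truth = truth, peaks = pk$peaks, dhs = pk$dhs,
       expression = ex, cohort_expression = cohort, survival = surv,
       config = config)
}
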