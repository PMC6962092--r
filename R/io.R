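# Plain-text readers/writers for the formats the pipeline exchanges:
# BED (0-based half-open; column 4 is the state label or the feature name),
# TSV tables (TSS, expression, survival, edge lists) and JSON configs.

#' Read a BED-style interval file
#'
#' @param path BED file (>= 3 columns; no header). Column 4, when present,
#'   is returned as `name`.
#' @return data.frame (chrom, start, end\[, name\]), 0-based half-open.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  x[seq_len(min(ncol(x), 4))]
}

#' Write intervals as BED
#' @param x data.frame with `chrom`, `start`, `end` and optionally a fourth
#'   column to write as the BED name field.
#' @param path output file.
#' @param name_col which column to put in BED column 4 (default `name`,
#'   or `state` for segmentations).
#' @export
write_bed <- function(x, path, name_col = intersect(c("name", "state"), names(x))[1]) {
  cols <- x[c("chrom", "start", "end")]
  if (!is.na(name_col) && !is.null(name_col) && name_col %in% names(x))
    cols[[4]] <- x[[name_col]]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a ChromHMM-style segmentation BED
#'
#' State labels may be bare integers ("7") or prefixed ("state7", "7_Weak"
#' etc.); the leading integer is used.
#' @param path BED file with the state label in column 4.
#' @param n_states vocabulary size.
#' @return a [segmentation()].
#' @export
read_segmentation <- function(path, n_states = 15L) {
  x <- read_bed(path)
  if (ncol(x) < 4) stop("segmentation BED needs a state label in column 4")
  lab <- as.character(x$name)
  st <- suppressWarnings(as.integer(sub("^[^0-9]*([0-9]+).*$", "\\1", lab)))
  if (anyNA(st)) stop("unparseable state label(s): ",
                      paste(utils::head(unique(lab[is.na(st)]), 5), collapse = ", "))
  segmentation(data.frame(chrom = x$chrom, start = x$start, end = x$end,
                          state = st), n_states = n_states)
}

#' Write a segmentation as BED
#' @param seg a [segmentation()].
#' @param path output file.
#' @export
write_segmentation <- function(seg, path) write_bed(as.data.frame(seg), path, "state")

#' Read / write the TSS table (gene, chrom, strand, tss)
#' @param path TSV file with header.
#' @return data.frame.
#' @export
read_tss <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_tss
#' @param x data.frame to write.
#' @export
write_tss <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write an expression matrix (genes x samples TSV)
#' @param path TSV with header; first column gene ids.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  as.matrix(x)
}

#' @rdname read_expression
#' @param x matrix to write.
#' @export
write_expression <- function(x, path) {
  utils::write.table(data.frame(gene = rownames(x), x, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a survival table (patient, time, event TSV)
#' @param path TSV with header.
#' @return data.frame.
#' @export
read_survival <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("patient", "time", "event") %in% names(x)))
  x
}

#' @rdname read_survival
#' @param x data.frame to write.
#' @export
write_survival <- function(x, path) {
  utils::write.table(as.data.frame(x)[c("patient", "time", "event")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read a network edge list TSV
#'
#' Columns: tf, target and whatever attributes the edges carry (sign, rho,
#' state, rep_tfbs, ...). Node metadata (is_tf flag, node states) is stored
#' alongside in a second TSV so a labeled network round-trips unchanged.
#'
#' @param network a [regnet()].
#' @param edge_path,node_path output TSVs.
#' @export
write_network <- function(network, edge_path, node_path = NULL) {
  utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(node_path))
    utils::write.table(network$nodes, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(network)
}

#' @rdname write_network
#' @return `read_network`: a [regnet()].
#' @export
read_network <- function(edge_path, node_path) {
  edges <- utils::read.table(edge_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  nodes <- utils::read.table(node_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  regnet(nodes, edges)
}

#' Write a synthetic study to a directory in the pipeline's file formats
#'
#' Writes segmentation/peaks/DHS BEDs, TSS, tissue and cohort expression
#' TSVs, the survival TSV, and the ground truth + config as JSON.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_segmentation(study$genome$seg, p("segmentation.bed"))
  write_tss(study$genome$genes[c("gene", "chrom", "strand", "tss", "is_tf")],
            p("tss.tsv"))
  write_bed(study$peaks, p("peaks.bed"), "name")
  utils::write.table(study$peaks, p("peaks.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bed(study$dhs, p("dhs.bed"), "name")
  write_expression(study$expression$tissue, p("expression_tissues.tsv"))
  utils::write.table(
    data.frame(gene = names(study$expression$cell_line),
               fpkm = unname(study$expression$cell_line)),
    p("expression_cellline.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression(study$cohort_expression, p("cohort_expression.tsv"))
  write_survival(study$survival, p("survival.tsv"))
  truth <- study$truth
  jsonlite::write_json(
    list(intended_edges = truth$intended_edges,
         intended_node_states = as.list(truth$intended_node_states),
         prognostic_ffls = truth$prognostic_ffls),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(study$config), p("config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
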