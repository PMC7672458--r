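write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a fractionation experiment to TSV files
#'
#' Writes `counts.tsv` (gene_id plus one column per sample), `design.tsv`,
#' and when present `intronic.tsv` and `truth.tsv`, into `dir`.
#'
#' @param experiment a [fracseq_experiment()]
#' @param dir output directory (created if needed)
#' @return invisibly, the files written
#' @export
write_fracseq <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(experiment, "counts")
  files <- c(
    write_tsv(data.frame(gene_id = rownames(counts), counts,
                         check.names = FALSE), file.path(dir, "counts.tsv")),
    write_tsv(as.data.frame(SummarizedExperiment::colData(experiment)),
              file.path(dir, "design.tsv")))
  if ("intronic" %in% SummarizedExperiment::assayNames(experiment)) {
    intr <- SummarizedExperiment::assay(experiment, "intronic")
    files <- c(files, write_tsv(
      data.frame(gene_id = rownames(intr), intr, check.names = FALSE),
      file.path(dir, "intronic.tsv")))
  }
  truth <- S4Vectors::metadata(experiment)$truth
  if (!is.null(truth))
    files <- c(files, write_tsv(truth, file.path(dir, "truth.tsv")))
  invisible(files)
}

#' Read a fractionation experiment from TSV files
#'
#' Inverse of [write_fracseq()]: reads `counts.tsv` and `design.tsv` (and
#' `intronic.tsv` / `truth.tsv` when present) from `dir`.
#'
#' @param dir directory containing the TSV files
#' @return a [fracseq_experiment()]
#' @export
read_fracseq <- function(dir) {
  cdf <- read_tsv(file.path(dir, "counts.tsv"))
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$gene_id
  design <- read_tsv(file.path(dir, "design.tsv"))
  intronic <- NULL
  if (file.exists(file.path(dir, "intronic.tsv"))) {
    idf <- read_tsv(file.path(dir, "intronic.tsv"))
    intronic <- as.matrix(idf[, -1, drop = FALSE])
    rownames(intronic) <- idf$gene_id
  }
  truth <- if (file.exists(file.path(dir, "truth.tsv")))
    read_tsv(file.path(dir, "truth.tsv")) else NULL
  fracseq_experiment(counts, design, intronic = intronic, truth = truth)
}
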