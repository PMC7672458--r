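#' FPKM matrix
#'
#' `FPKM = count / ((exonic_length / 1e3) * (sample_total / 1e6))`. Used
#' here only for the expression filter (mean FPKM > 1), not for
#' between-sample statistics.
#'
#' @param counts gene x sample count matrix
#' @param exonic_lengths per-gene exonic (mature) lengths, nt; recycled by
#'   gene name when named
#' @param totals per-sample mapped totals; defaults to column sums
#' @return matrix of FPKM values, same dimensions as `counts`
#' @export
compute_fpkm <- function(counts, exonic_lengths, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (!is.null(names(exonic_lengths)) && !is.null(rownames(counts)))
    exonic_lengths <- exonic_lengths[rownames(counts)]
  if (length(exonic_lengths) != nrow(counts))
    stop("need one exonic length per gene", call. = FALSE)
  if (any(!is.finite(exonic_lengths) | exonic_lengths <= 0))
    stop("exonic lengths must be positive", call. = FALSE)
  if (any(!is.finite(totals) | totals <= 0))
    stop("per-sample totals must be positive", call. = FALSE)
  sweep(counts / (exonic_lengths / 1e3), 2, totals / 1e6, "/")
}

#' Expression and mitochondrial gene filter
#'
#' Keeps genes whose mean FPKM across *all* samples is strictly greater
#' than `fpkm_min` and whose chromosome is not the mitochondrial label.
#'
#' @param fpkm gene x sample FPKM matrix (see [compute_fpkm()])
#' @param gene_metrics [gene_metrics()] table (for the chromosome column)
#' @param fpkm_min mean-FPKM threshold (strict inequality)
#' @param mito_chrom mitochondrial chromosome label
#' @return character vector of retained gene ids
#' @export
filter_genes <- function(fpkm, gene_metrics, fpkm_min = 1, mito_chrom = "chrM") {
  mean_fpkm <- rowMeans(as.matrix(fpkm))
  keep <- names(mean_fpkm)[mean_fpkm > fpkm_min]
  mito <- gene_metrics$gene_id[gene_metrics$chromosome == mito_chrom]
  setdiff(keep, mito)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-nonzero genes of the ratio of its
#' count to the gene's geometric mean across samples. A sample scaled by a
#' constant c gets its factor scaled by c.
#'
#' @param counts gene x sample count matrix
#' @param pseudocount added to all counts before the computation; use a
#'   positive value when no gene is nonzero in every sample
#' @return named numeric vector of positive per-sample factors
#' @export
size_factors <- function(counts, pseudocount = 0) {
  counts <- as.matrix(counts) + pseudocount
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop("no gene has nonzero counts in every sample; ",
         "rerun with a positive 'pseudocount'", call. = FALSE)
  logg <- rowMeans(log(counts[ok, , drop = FALSE]))
  sf <- apply(counts[ok, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - logg)))
  sf
}

#' Size-factor-normalized counts
#'
#' @param counts gene x sample count matrix
#' @param sf per-sample size factors (see [size_factors()])
#' @return normalized matrix `counts[, s] / sf[s]`
#' @export
normalized_counts <- function(counts, sf = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (length(sf) != ncol(counts))
    stop("need one size factor per sample", call. = FALSE)
  if (!is.null(names(sf)) && !is.null(colnames(counts)))
    sf <- sf[colnames(counts)]
  sweep(counts, 2, sf, "/")
}

fraction_alias <- c(N = "nuclear", C = "cytoplasmic", T = "total",
                    nuclear = "nuclear", cytoplasmic = "cytoplasmic",
                    total = "total")

# mean, per-gene variance-of-the-mean and replicate count of normalized
# counts for one (fraction, condition) cell; with <= 2 replicates the
# per-gene relative variance is replaced by its pooled (mean over genes)
# value, as a constant-CV estimate
cell_moments <- function(norm, design, fraction, condition, prior_count) {
  sel <- design$fraction == fraction & design$condition == condition
  if (!any(sel))
    stop("design error: no samples with fraction '", fraction,
         "' and condition '", condition, "'", call. = FALSE)
  m <- norm[, sel, drop = FALSE]
  n <- ncol(m)
  mu <- rowMeans(m)
  v <- apply(m, 1, stats::var) / n
  if (n <= 2) {
    rel <- mean(v / (mu + prior_count)^2, na.rm = TRUE)
    v <- rel * (mu + prior_count)^2
  }
  list(mean = mu, var_mean = v, n = n)
}

#' Per-gene localization change between knockdown and control
#'
#' For contrast pair (A, B) (default nuclear vs cytoplasmic) and a
#' knockdown condition, computes per gene the log2 ratio-of-ratios
#' `delta_raw = log2((A_kd + p) / (B_kd + p)) - log2((A_ctrl + p) / (B_ctrl + p))`
#' on size-factor-normalized replicate means (p = `prior_count`), its
#' standard error by first-order (delta-method) propagation of the
#' replicate variance of each of the four means, and an empirical-Bayes
#' shrunken estimate `delta_shrunk = delta_raw * tau2 / (tau2 + se^2)`
#' where `tau2 = max(0, var(delta_raw) - mean(se^2))` is the
#' method-of-moments prior variance across genes. Shrinkage never changes
#' sign and never increases magnitude.
#'
#' @param experiment a [fracseq_experiment()] / `SummarizedExperiment`
#' @param contrast two fraction labels, e.g. `c("nuclear", "cytoplasmic")`
#'   (aliases "N", "C", "T" accepted)
#' @param kd knockdown condition label
#' @param control control condition label
#' @param prior_count pseudocount added to normalized means
#' @param genes optional gene ids to restrict to (e.g. [filter_genes()] output)
#' @param sf optional precomputed size factors over all samples
#' @return data.frame: gene_id, the four cell means, delta_raw, se,
#'   delta_shrunk; attributes `contrast`, `kd`, `control`, `tau2`
#' @export
delta_localization <- function(experiment,
                               contrast = c("nuclear", "cytoplasmic"),
                               kd = "KD_A", control = "control",
                               prior_count = 4, genes = NULL, sf = NULL) {
  counts <- SummarizedExperiment::assay(experiment, "counts")
  design <- as.data.frame(SummarizedExperiment::colData(experiment))
  contrast <- unname(fraction_alias[contrast])
  if (length(contrast) != 2 || anyNA(contrast))
    stop("contrast must be two of nuclear/cytoplasmic/total", call. = FALSE)
  for (cond in c(kd, control))
    if (!cond %in% design$condition)
      stop("design error: condition '", cond, "' absent from design",
           call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- normalized_counts(counts, sf)
  if (!is.null(genes)) norm <- norm[rownames(norm) %in% genes, , drop = FALSE]

  a_kd <- cell_moments(norm, design, contrast[1], kd, prior_count)
  b_kd <- cell_moments(norm, design, contrast[2], kd, prior_count)
  a_ct <- cell_moments(norm, design, contrast[1], control, prior_count)
  b_ct <- cell_moments(norm, design, contrast[2], control, prior_count)

  p <- prior_count
  delta_raw <- (log2(a_kd$mean + p) - log2(b_kd$mean + p)) -
    (log2(a_ct$mean + p) - log2(b_ct$mean + p))
  ln2sq <- log(2)^2
  var_log2 <- function(cm) cm$var_mean / ((cm$mean + p)^2 * ln2sq)
  se <- sqrt(var_log2(a_kd) + var_log2(b_kd) + var_log2(a_ct) + var_log2(b_ct))

  tau2 <- max(0, stats::var(delta_raw) - mean(se^2))
  shrink <- if (tau2 == 0) rep(0, length(delta_raw)) else tau2 / (tau2 + se^2)
  out <- data.frame(gene_id = rownames(norm),
                    mean_kd_a = a_kd$mean, mean_kd_b = b_kd$mean,
                    mean_ctrl_a = a_ct$mean, mean_ctrl_b = b_ct$mean,
                    delta_raw = delta_raw, se = se,
                    delta_shrunk = delta_raw * shrink,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- contrast
  attr(out, "kd") <- kd
  attr(out, "control") <- control
  attr(out, "tau2") <- tau2
  out
}

#' Intronic read fraction per sample
#'
#' `sum(intronic) / (sum(intronic) + sum(exonic))` over the genes of each
#' selected sample; requires the `intronic` assay.
#'
#' @param experiment a [fracseq_experiment()] with an `intronic` assay
#' @param fraction,condition optional filters on the design
#' @return data.frame: sample, fraction, condition, intronic_fraction
#' @export
intronic_read_fraction <- function(experiment, fraction = NULL, condition = NULL) {
  if (!"intronic" %in% SummarizedExperiment::assayNames(experiment))
    stop("experiment has no 'intronic' assay; intronic read fractions ",
         "are unavailable", call. = FALSE)
  design <- as.data.frame(SummarizedExperiment::colData(experiment))
  sel <- rep(TRUE, nrow(design))
  if (!is.null(fraction)) sel <- sel & design$fraction %in% unname(fraction_alias[fraction])
  if (!is.null(condition)) sel <- sel & design$condition %in% condition
  exonic <- colSums(SummarizedExperiment::assay(experiment, "counts")[, sel, drop = FALSE])
  intr <- colSums(SummarizedExperiment::assay(experiment, "intronic")[, sel, drop = FALSE])
  data.frame(sample = design$sample[sel], fraction = design$fraction[sel],
             condition = design$condition[sel],
             intronic_fraction = ifelse(exonic + intr == 0, 0,
                                        intr / (intr + exonic)),
             stringsAsFactors = FALSE, row.names = NULL)
}
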