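#' Per-transcript architecture metrics
#'
#' For every transcript in the annotation: pre-mRNA length (genomic span of
#' its exons, introns included), exonic length (sum of exon widths, the
#' mature "exons-only" transcript length), exon count, fraction intronic
#' `(pre_mrna_length - exonic_length) / pre_mrna_length`, exon density
#' `n_exons / exonic_length`, and 3'UTR length (exonic distance from the
#' 3'-most CDS coordinate to the transcript 3' end; `NA` when the
#' transcript carries no CDS records). All metrics are strand-invariant
#' except that the 3' end is taken in transcription orientation.
#'
#' @param annotation an [annotation_set()]
#' @return data.frame with one row per transcript: transcript_id, gene_id,
#'   pre_mrna_length, exonic_length, n_exons, fraction_intronic,
#'   exon_density, utr3_length
#' @export
transcript_metrics <- function(annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  ex <- ann_exons(annotation)
  if (!nrow(ex))
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      pre_mrna_length = integer(0), exonic_length = integer(0),
                      n_exons = integer(0), fraction_intronic = numeric(0),
                      exon_density = numeric(0), utr3_length = numeric(0)))
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]

  # overlapping exons within a transcript are a validation error
  same_tx <- c(FALSE, ex$transcript_id[-1] == ex$transcript_id[-nrow(ex)])
  overlap <- same_tx & ex$start <= c(0L, ex$end[-nrow(ex)])
  if (any(overlap))
    stop("overlapping exons in transcript(s): ",
         paste(unique(ex$transcript_id[overlap]), collapse = ", "),
         call. = FALSE)

  tx_id <- factor(ex$transcript_id, levels = unique(ex$transcript_id))
  width <- ex$end - ex$start + 1L
  exonic_length <- as.integer(rowsum(width, tx_id))
  n_exons <- as.integer(tabulate(tx_id))
  tx_start <- as.integer(tapply(ex$start, tx_id, min))
  tx_end <- as.integer(tapply(ex$end, tx_id, max))
  pre_mrna_length <- tx_end - tx_start + 1L
  strand <- vapply(split(ex$strand, tx_id), `[`, character(1), 1L)
  gene_id <- unname(vapply(split(ex$gene_id, tx_id), `[`, character(1), 1L))

  # 3'UTR: exonic bases strictly 3' of the CDS in transcription orientation
  cds <- annotation$records[annotation$records$type == "CDS", , drop = FALSE]
  utr3 <- rep(NA_real_, nlevels(tx_id))
  names(utr3) <- levels(tx_id)
  if (nrow(cds)) {
    cds_tx <- intersect(unique(cds$transcript_id), levels(tx_id))
    cds_end3 <- tapply(cds$end, cds$transcript_id, max)    # + strand boundary
    cds_start3 <- tapply(cds$start, cds$transcript_id, min) # - strand boundary
    for (t in cds_tx) {
      rows <- ex$transcript_id == t
      s <- ex$start[rows]; e <- ex$end[rows]
      if (strand[t] == "-") {
        b <- cds_start3[[t]]   # 3' UTR is genomically left of the CDS
        utr3[t] <- sum(pmax(0L, pmin(e, b - 1L) - s + 1L))
      } else {
        b <- cds_end3[[t]]
        utr3[t] <- sum(pmax(0L, e - pmax(s - 1L, b)))
      }
    }
  }

  data.frame(transcript_id = levels(tx_id), gene_id = gene_id,
             pre_mrna_length = pre_mrna_length, exonic_length = exonic_length,
             n_exons = n_exons,
             fraction_intronic = (pre_mrna_length - exonic_length) / pre_mrna_length,
             exon_density = n_exons / exonic_length,
             utr3_length = unname(utr3),
             stringsAsFactors = FALSE, row.names = NULL)
}

# median that skips NA and returns NA for empty input
median_na <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) NA_real_ else stats::median(x)
}

# round half away from zero (values here are positive exon-count medians)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Gene-level median architecture metrics
#'
#' Collapses [transcript_metrics()] to one row per gene by taking the
#' median of each metric across the gene's transcripts (the average of the
#' middle two for even transcript counts). Transcripts without a CDS are
#' skipped (not zeroed) in the 3'UTR median. Adds the gene span
#' (`gene_length`, minimum transcript start to maximum transcript end),
#' the exon class -- `"single"` iff the *unrounded* median exon count is
#' exactly 1, else `"multi"` -- and the median exon count rounded to the
#' nearest integer (halves away from zero).
#'
#' @param annotation an [annotation_set()]
#' @param tx_metrics optional precomputed [transcript_metrics()] table
#' @return data.frame keyed by gene_id
#' @export
gene_metrics <- function(annotation, tx_metrics = transcript_metrics(annotation)) {
  stopifnot(inherits(annotation, "annotation_set"))
  if (!nrow(tx_metrics))
    return(data.frame(gene_id = character(0), biotype = character(0),
                      chromosome = character(0), gene_class = character(0),
                      gene_length = integer(0), pre_mrna_length = numeric(0),
                      exonic_length = numeric(0), n_exons = numeric(0),
                      fraction_intronic = numeric(0), exon_density = numeric(0),
                      utr3_length = numeric(0), exon_class = character(0),
                      rounded_exon_count = integer(0)))
  gid <- factor(tx_metrics$gene_id, levels = unique(tx_metrics$gene_id))
  med <- function(col) as.numeric(tapply(tx_metrics[[col]], gid, median_na))
  g <- ann_genes(annotation)
  g <- g[match(levels(gid), g$gene_id), , drop = FALSE]

  tx <- ann_transcripts(annotation)
  tgid <- factor(tx$gene_id, levels = levels(gid))
  gene_length <- as.integer(tapply(tx$end, tgid, max) - tapply(tx$start, tgid, min) + 1L)

  med_exons <- med("n_exons")
  data.frame(gene_id = levels(gid),
             biotype = g$gene_type,
             chromosome = g$seqnames,
             gene_class = g$gene_class,
             gene_length = gene_length,
             pre_mrna_length = med("pre_mrna_length"),
             exonic_length = med("exonic_length"),
             n_exons = med_exons,
             fraction_intronic = med("fraction_intronic"),
             exon_density = med("exon_density"),
             utr3_length = med("utr3_length"),
             exon_class = ifelse(med_exons == 1, "single", "multi"),
             rounded_exon_count = as.integer(round_half_away(med_exons)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pre-mRNA length bins
#'
#' Assigns median pre-mRNA lengths to the six bins `<10`, `10-20`, `20-30`,
#' `30-40`, `40-50`, `>50` kb. Bins are left-closed, right-open on the kb
#' boundaries (exactly 10,000 nt falls in `10-20 kb`); the last bin is
#' closed at 50 kb on the left.
#'
#' @param length_nt numeric vector of median pre-mRNA lengths in nt
#' @return factor with the six bin labels as levels, in length order
#' @export
assign_length_bin <- function(length_nt) {
  if (any(!is.finite(length_nt) | length_nt <= 0))
    stop("pre-mRNA lengths must be positive and finite", call. = FALSE)
  labels <- c("<10 kb", "10-20 kb", "20-30 kb", "30-40 kb", "40-50 kb", ">50 kb")
  idx <- findInterval(length_nt, c(10, 20, 30, 40, 50) * 1000) + 1L
  factor(labels[idx], levels = labels)
}
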