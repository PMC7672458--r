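# Independent brute-force oracles used to validate the package's own
# implementations. These deliberately avoid the code paths they check.

# Mann-Whitney U by direct pair counting (no ranks)
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values into groups of size nx and ny
oracle_mww_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  u_obs <- oracle_u(x, y)
  u_all <- apply(idx, 2, function(i) oracle_u(pooled[i], pooled[-i]))
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

# per-base coverage oracle for transcript metrics: materializes every
# exonic genomic position
oracle_transcript_metrics <- function(starts, ends) {
  pos <- unlist(Map(seq.int, starts, ends))
  stopifnot(!anyDuplicated(pos))
  exonic <- length(pos)
  span <- max(pos) - min(pos) + 1L
  list(pre_mrna_length = span, exonic_length = exonic,
       n_exons = length(starts),
       fraction_intronic = (span - exonic) / span,
       exon_density = length(starts) / exonic)
}

# random toy transcript (exon starts/ends, sorted, non-overlapping,
# total span <= max_span)
random_toy_exons <- function(max_span = 10000L) {
  n <- sample(1:8, 1)
  span <- sample(seq(2L * n + 1L, max_span), 1)
  start0 <- sample(1:50000, 1)
  if (n == 1L) return(data.frame(start = start0, end = start0 + span - 1L))
  bounds <- sort(sample(seq_len(span - 1L), 2L * (n - 1L)))
  edges <- c(1L, bounds, span)
  starts <- start0 + edges[seq(1, 2 * n, by = 2)] - 1L
  ends <- start0 + edges[seq(2, 2 * n, by = 2)] - 1L
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

# wrap exon tables into a minimal annotation_set
toy_annotation <- function(exon_list, strand = "+", biotype = "protein_coding",
                           chrom = "chr1") {
  recs <- list()
  for (i in seq_along(exon_list)) {
    ex <- exon_list[[i]]
    gid <- sprintf("G%03d", i)
    tid <- paste0(gid, ".T1")
    st <- if (length(strand) > 1) strand[i] else strand
    recs[[length(recs) + 1L]] <- data.frame(
      seqnames = chrom, source = "test", type = "gene",
      start = min(ex$start), end = max(ex$end), strand = st, gene_id = gid,
      transcript_id = NA_character_, gene_type = biotype, gene_class = "toy",
      exon_number = NA_integer_)
    recs[[length(recs) + 1L]] <- data.frame(
      seqnames = chrom, source = "test", type = "transcript",
      start = min(ex$start), end = max(ex$end), strand = st, gene_id = gid,
      transcript_id = tid, gene_type = biotype, gene_class = "toy",
      exon_number = NA_integer_)
    recs[[length(recs) + 1L]] <- data.frame(
      seqnames = chrom, source = "test", type = "exon",
      start = ex$start, end = ex$end, strand = st, gene_id = gid,
      transcript_id = tid, gene_type = biotype, gene_class = "toy",
      exon_number = seq_len(nrow(ex)))
  }
  annotation_set(do.call(rbind, recs))
}

# small noise-free experiment with two fractions, two conditions and
# exactly the given per-cell counts (each replicated `reps` times)
toy_experiment <- function(n_kd, c_kd, n_ctrl, c_ctrl, reps = 2) {
  genes <- paste0("g", seq_along(n_kd))
  cells <- list(nuclear.KD = n_kd, cytoplasmic.KD = c_kd,
                nuclear.control = n_ctrl, cytoplasmic.control = c_ctrl)
  counts <- NULL; design <- NULL
  for (nm in names(cells)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    for (r in seq_len(reps)) {
      counts <- cbind(counts, cells[[nm]])
      design <- rbind(design, data.frame(
        sample = paste(parts[1], parts[2], r, sep = "_"),
        fraction = parts[1], condition = parts[2], replicate = r))
    }
  }
  rownames(counts) <- genes
  colnames(counts) <- design$sample
  fracseq_experiment(counts, design)
}

default_test_annotation <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_toy_annotation(default_templates(2000), seed = 11)
    cache
  }
})
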