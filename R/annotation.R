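#' AnnotationSet: a flat table of gene/transcript/exon/CDS records
#'
#' Internal representation mirrors GTF: one row per feature with 1-based
#' closed coordinates (lengths are `end - start + 1`). Rows of `type`
#' "gene" carry no transcript_id; "exon" and "CDS" rows are numbered in
#' transcription order via `exon_number`.
#'
#' @param records data.frame with columns seqnames, source, type, start,
#'   end, strand, gene_id, transcript_id, gene_type, gene_class, exon_number
#' @return object of class `annotation_set`
#' @export
annotation_set <- function(records = empty_annotation_records()) {
  req <- c("seqnames", "source", "type", "start", "end", "strand",
           "gene_id", "transcript_id", "gene_type", "gene_class", "exon_number")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("annotation records missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records <- as.data.frame(records)[req]
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  records$exon_number <- as.integer(records$exon_number)
  for (col in c("seqnames", "source", "type", "strand", "gene_id",
                "transcript_id", "gene_type", "gene_class"))
    records[[col]] <- as.character(records[[col]])
  rownames(records) <- NULL
  bad <- which(records$end < records$start)
  if (length(bad))
    stop("annotation records with end < start at rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  structure(list(records = records), class = "annotation_set")
}

empty_annotation_records <- function() {
  data.frame(seqnames = character(0), source = character(0),
             type = character(0), start = integer(0), end = integer(0),
             strand = character(0), gene_id = character(0),
             transcript_id = character(0), gene_type = character(0),
             gene_class = character(0), exon_number = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.annotation_set <- function(x, ...) {
  r <- x$records
  cat("annotation_set:", sum(r$type == "gene"), "genes,",
      sum(r$type == "transcript"), "transcripts,",
      sum(r$type == "exon"), "exons on",
      length(unique(r$seqnames)), "chromosome(s)\n")
  invisible(x)
}

#' @rdname annotation_set
#' @param x an `annotation_set`
#' @export
ann_genes <- function(x) x$records[x$records$type == "gene", , drop = FALSE]

#' @rdname annotation_set
#' @export
ann_transcripts <- function(x) x$records[x$records$type == "transcript", , drop = FALSE]

#' @rdname annotation_set
#' @export
ann_exons <- function(x) x$records[x$records$type == "exon", , drop = FALSE]

# split total into k parts, each >= 1 (uniform random composition)
random_composition <- function(total, k) {
  stopifnot(total >= k, k >= 1)
  if (k == 1L) return(total)
  cuts <- sort(sample.int(total - 1L, k - 1L))
  diff(c(0L, cuts, total))
}

# exon/intron layout for one transcript: returns data.frame(start, end)
# of exons in genomic order within [tx_start, tx_end]
layout_exons <- function(tx_start, tx_end, n_exons) {
  span <- tx_end - tx_start + 1L
  if (span < 2L * n_exons - 1L)            # not enough room for introns >= 1
    n_exons <- max(1L, (span + 1L) %/% 2L)
  if (n_exons == 1L)
    return(data.frame(start = tx_start, end = tx_end))
  lo <- n_exons
  hi <- span - (n_exons - 1L)
  exonic <- round(span * stats::rbeta(1, 2, 6))
  exonic <- as.integer(min(max(exonic, lo), hi))
  exon_len <- random_composition(exonic, n_exons)
  intron_len <- random_composition(span - exonic, n_exons - 1L)
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- tx_start
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    ends[i] <- pos + exon_len[i] - 1L
    pos <- ends[i] + 1L + if (i < n_exons) intron_len[i] else 0L
  }
  data.frame(start = starts, end = ends)
}

# map transcript-orientation exonic interval [t_from, t_to] (1-based,
# inclusive) to genomic intervals given exons in genomic order and strand
exonic_to_genomic <- function(exons, strand, t_from, t_to) {
  ord <- if (strand == "-") rev(seq_len(nrow(exons))) else seq_len(nrow(exons))
  lens <- exons$end - exons$start + 1L
  out <- list()
  cum <- 0L
  for (i in ord) {
    a <- cum + 1L; b <- cum + lens[i]   # transcript coords of this exon
    lo <- max(a, t_from); hi <- min(b, t_to)
    if (lo <= hi) {
      if (strand == "-") {
        g_end <- exons$end[i] - (lo - a)
        g_start <- exons$end[i] - (hi - a)
      } else {
        g_start <- exons$start[i] + (lo - a)
        g_end <- exons$start[i] + (hi - a)
      }
      out[[length(out) + 1L]] <- c(g_start, g_end)
    }
    cum <- cum + lens[i]
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, out)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

#' Generate a synthetic gene annotation
#'
#' Draws genes from a list of [gene_class_template()]s, places them
#' non-overlapping along their chromosomes with random intergenic gaps,
#' lays out ordered non-overlapping exons within each transcript span and
#' adds CDS records (with 5' and 3' UTRs) to sufficiently long
#' protein-coding transcripts. Fully deterministic for a fixed seed.
#'
#' @param templates list of [gene_class_template()]
#' @param seed integer seed controlling all randomness
#' @return an [annotation_set()]
#' @export
make_toy_annotation <- function(templates = default_templates(), seed = 1L) {
  if (inherits(templates, "gene_class_template")) templates <- list(templates)
  for (t in templates)
    if (!inherits(t, "gene_class_template"))
      stop("templates must be gene_class_template objects", call. = FALSE)
  set.seed(as.integer(seed))

  # draw per-gene skeletons first
  genes <- list()
  gi <- 0L
  for (tpl in templates) {
    if (tpl$n_genes == 0L) next
    chrom <- sample(tpl$chromosomes, tpl$n_genes, replace = TRUE)
    span <- pmax(200L, as.integer(round(stats::rlnorm(
      tpl$n_genes, tpl$span_log_mean, tpl$span_log_sd))))
    ntx <- draw_law(tpl$transcripts_per_gene_law, tpl$n_genes)
    for (i in seq_len(tpl$n_genes)) {
      gi <- gi + 1L
      genes[[gi]] <- list(gene_id = sprintf("G%05d", gi), class = tpl$name,
                          biotype = tpl$biotype, chrom = chrom[i],
                          span = span[i], ntx = ntx[i],
                          single_exon = tpl$single_exon, tpl = tpl)
    }
  }
  if (!length(genes)) return(annotation_set())

  # place genes sequentially per chromosome, non-overlapping
  chrom_pos <- new.env(parent = emptyenv())
  rec <- vector("list", length(genes) * 4L)
  ri <- 0L
  add <- function(row) { ri <<- ri + 1L; rec[[ri]] <<- row }
  for (g in genes) {
    offset <- if (is.null(chrom_pos[[g$chrom]])) 10000L else chrom_pos[[g$chrom]]
    gap <- as.integer(sample(5000:20000, 1L))
    g_start <- offset + gap
    g_end <- g_start + g$span - 1L
    chrom_pos[[g$chrom]] <- g_end
    strand <- sample(c("+", "-"), 1L)
    add(data.frame(seqnames = g$chrom, source = "fracseqtools", type = "gene",
                   start = g_start, end = g_end, strand = strand,
                   gene_id = g$gene_id, transcript_id = NA_character_,
                   gene_type = g$biotype, gene_class = g$class,
                   exon_number = NA_integer_))
    for (j in seq_len(g$ntx)) {
      if (j == 1L) {
        t_start <- g_start; t_end <- g_end
      } else {                              # alternative isoforms: sub-spans
        t_start <- g_start + as.integer(floor(stats::runif(1, 0, 0.25) * g$span))
        t_end <- g_end - as.integer(floor(stats::runif(1, 0, 0.25) * g$span))
      }
      tx_id <- sprintf("%s.T%d", g$gene_id, j)
      n_ex <- if (g$single_exon) 1L else max(1L, draw_law(g$tpl$exon_count_law, 1L))
      exons <- layout_exons(t_start, t_end, n_ex)
      add(data.frame(seqnames = g$chrom, source = "fracseqtools",
                     type = "transcript", start = t_start, end = t_end,
                     strand = strand, gene_id = g$gene_id, transcript_id = tx_id,
                     gene_type = g$biotype, gene_class = g$class,
                     exon_number = NA_integer_))
      n_ex <- nrow(exons)
      tx_order <- if (strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
      exon_no <- integer(n_ex); exon_no[tx_order] <- seq_len(n_ex)
      add(data.frame(seqnames = g$chrom, source = "fracseqtools", type = "exon",
                     start = exons$start, end = exons$end, strand = strand,
                     gene_id = g$gene_id, transcript_id = tx_id,
                     gene_type = g$biotype, gene_class = g$class,
                     exon_number = exon_no))
      exonic_len <- sum(exons$end - exons$start + 1L)
      if (g$biotype == "protein_coding" && exonic_len >= 300L) {
        utr5 <- max(3L, as.integer(round(0.10 * exonic_len)))
        utr3 <- max(30L, as.integer(round(0.25 * exonic_len)))
        if (exonic_len - utr5 - utr3 >= 60L) {
          cds <- exonic_to_genomic(exons, strand, utr5 + 1L, exonic_len - utr3)
          cds <- cds[order(cds$start), , drop = FALSE]
          hit <- vapply(seq_len(nrow(cds)), function(k)
            which(exons$start <= cds$start[k] & exons$end >= cds$end[k])[1],
            integer(1))
          add(data.frame(seqnames = g$chrom, source = "fracseqtools",
                         type = "CDS", start = cds$start, end = cds$end,
                         strand = strand, gene_id = g$gene_id,
                         transcript_id = tx_id, gene_type = g$biotype,
                         gene_class = g$class, exon_number = exon_no[hit]))
        }
      }
    }
  }
  annotation_set(do.call(rbind, rec[seq_len(ri)]))
}

gtf_attr_string <- function(r) {
  attrs <- sprintf('gene_id "%s";', r$gene_id)
  has_tx <- !is.na(r$transcript_id)
  attrs[has_tx] <- paste0(attrs[has_tx],
                          sprintf(' transcript_id "%s";', r$transcript_id[has_tx]))
  attrs <- paste0(attrs, sprintf(' gene_type "%s";', r$gene_type))
  attrs <- paste0(attrs, sprintf(' gene_class "%s";', r$gene_class))
  has_no <- !is.na(r$exon_number)
  attrs[has_no] <- paste0(attrs[has_no],
                          sprintf(' exon_number %d;', r$exon_number[has_no]))
  attrs
}

#' Write an annotation as GTF
#'
#' GENCODE attribute dialect (`gene_id`, `transcript_id`, `gene_type`),
#' 1-based closed coordinates, deterministic record order, so identical
#' annotation sets serialize to byte-identical files.
#'
#' @param annotation an [annotation_set()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_set"))
  r <- annotation$records
  header <- c("##description: synthetic annotation generated by fracseqtools",
              "##format: gtf")
  lines <- if (nrow(r)) {
    paste(r$seqnames, r$source, r$type, r$start, r$end, ".", r$strand, ".",
          gtf_attr_string(r), sep = "\t")
  } else character(0)
  writeLines(c(header, lines), path)
  invisible(path)
}
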