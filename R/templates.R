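#' Distribution laws for template fields
#'
#' Small serializable descriptions of discrete distributions used by gene
#' class templates (exon counts, transcripts per gene). Supported types:
#' `"fixed"` (always `value`), `"poisson1"` (1 + Poisson(lambda)), and
#' `"uniform"` (integer uniform on `min..max`).
#'
#' @param type one of "fixed", "poisson1", "uniform"
#' @param ... parameters of the law (`value`; `lambda`; `min`, `max`)
#' @return a list of class `count_law`
#' @export
count_law <- function(type = c("fixed", "poisson1", "uniform"), ...) {
  type <- match.arg(type)
  params <- list(...)
  law <- c(list(type = type), params)
  switch(type,
    fixed = {
      if (is.null(law$value) || law$value < 1)
        stop("count_law(fixed): 'value' must be >= 1", call. = FALSE)
    },
    poisson1 = {
      if (is.null(law$lambda) || !is.finite(law$lambda) || law$lambda < 0)
        stop("count_law(poisson1): 'lambda' must be finite and >= 0", call. = FALSE)
    },
    uniform = {
      if (is.null(law$min) || is.null(law$max) || law$min < 1 || law$max < law$min)
        stop("count_law(uniform): need 1 <= min <= max", call. = FALSE)
    })
  structure(law, class = "count_law")
}

draw_law <- function(law, n) {
  stopifnot(inherits(law, "count_law"))
  if (n == 0L) return(integer(0))
  switch(law$type,
    fixed    = rep.int(as.integer(law$value), n),
    poisson1 = 1L + stats::rpois(n, law$lambda),
    uniform  = as.integer(sample(seq.int(law$min, law$max), n, replace = TRUE)))
}

#' Gene class template
#'
#' Describes one class of synthetic genes: how long their genomic spans are
#' (lognormal), how many exons and transcripts they carry, their biotype and
#' which chromosomes they may be placed on. Classes with
#' `single_exon = TRUE` (e.g. histone-like genes or single-exon lncRNAs)
#' force every transcript to exactly one exon, hence zero intronic fraction.
#'
#' @param name label for the class (e.g. "histone_like")
#' @param n_genes number of genes to generate from this template
#' @param span_log_mean,span_log_sd lognormal parameters of the pre-mRNA
#'   genomic span, in nt
#' @param exon_count_law a [count_law()] for exons per transcript
#' @param transcripts_per_gene_law a [count_law()] for transcripts per gene
#' @param biotype "protein_coding" or "lncRNA"
#' @param chromosomes character vector of chromosome labels to place genes on
#' @param single_exon force one exon per transcript
#' @return a list of class `gene_class_template`
#' @export
gene_class_template <- function(name, n_genes,
                                span_log_mean, span_log_sd,
                                exon_count_law = count_law("poisson1", lambda = 5),
                                transcripts_per_gene_law = count_law("fixed", value = 1),
                                biotype = c("protein_coding", "lncRNA"),
                                chromosomes = paste0("chr", 1:5),
                                single_exon = FALSE) {
  biotype <- match.arg(biotype)
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 0)
    stop("invalid template '", name, "': n_genes must be a single number >= 0",
         call. = FALSE)
  if (!is.finite(span_log_mean))
    stop("invalid template '", name, "': span_log_mean must be finite", call. = FALSE)
  if (!is.finite(span_log_sd) || span_log_sd < 0)
    stop("invalid template '", name, "': span_log_sd must be finite and >= 0",
         call. = FALSE)
  if (!inherits(exon_count_law, "count_law"))
    stop("invalid template '", name, "': exon_count_law must be a count_law",
         call. = FALSE)
  if (!inherits(transcripts_per_gene_law, "count_law"))
    stop("invalid template '", name,
         "': transcripts_per_gene_law must be a count_law", call. = FALSE)
  if (length(chromosomes) < 1L)
    stop("invalid template '", name, "': chromosome pool empty", call. = FALSE)
  structure(list(name = name, n_genes = as.integer(n_genes),
                 span_log_mean = span_log_mean, span_log_sd = span_log_sd,
                 exon_count_law = exon_count_law,
                 transcripts_per_gene_law = transcripts_per_gene_law,
                 biotype = biotype, chromosomes = chromosomes,
                 single_exon = isTRUE(single_exon)),
            class = "gene_class_template")
}

#' Default gene class templates
#'
#' A human-genome-inspired mix: short intronless histone-like genes, compact
#' multi-exon ribosomal-like genes, a broad lognormal class of generic
#' multi-exon genes centred near the ~21 kb genome-wide median pre-mRNA
#' length, short multi-exon genes, single- and multi-exon lncRNAs, and a
#' handful of mitochondrially encoded genes on their own "chrM" label so the
#' mitochondrial exclusion filter is exercisable.
#'
#' @param n_genes total number of genes across the non-mitochondrial classes
#' @param n_mito number of mitochondrial genes (default 13, as on the human
#'   mitochondrial genome)
#' @return list of [gene_class_template()] objects
#' @export
default_templates <- function(n_genes = 2000, n_mito = 13) {
  frac <- c(histone_like = 0.05, ribosomal_like = 0.05, long_multiexon = 0.65,
            short_multiexon = 0.10, lncRNA_single = 0.05, lncRNA_multi = 0.10)
  n <- round(n_genes * frac)
  n["long_multiexon"] <- n_genes - sum(n[names(n) != "long_multiexon"])
  list(
    gene_class_template("histone_like", n[["histone_like"]],
                        span_log_mean = log(600), span_log_sd = 0.3,
                        exon_count_law = count_law("fixed", value = 1),
                        single_exon = TRUE),
    gene_class_template("ribosomal_like", n[["ribosomal_like"]],
                        span_log_mean = log(4000), span_log_sd = 0.4,
                        exon_count_law = count_law("uniform", min = 4, max = 6)),
    gene_class_template("long_multiexon", n[["long_multiexon"]],
                        span_log_mean = log(22000), span_log_sd = 1.0,
                        exon_count_law = count_law("poisson1", lambda = 8),
                        transcripts_per_gene_law = count_law("uniform", min = 1, max = 3)),
    gene_class_template("short_multiexon", n[["short_multiexon"]],
                        span_log_mean = log(6000), span_log_sd = 0.5,
                        exon_count_law = count_law("poisson1", lambda = 3)),
    gene_class_template("lncRNA_single", n[["lncRNA_single"]],
                        span_log_mean = log(3000), span_log_sd = 0.6,
                        exon_count_law = count_law("fixed", value = 1),
                        biotype = "lncRNA", single_exon = TRUE),
    gene_class_template("lncRNA_multi", n[["lncRNA_multi"]],
                        span_log_mean = log(15000), span_log_sd = 0.7,
                        exon_count_law = count_law("uniform", min = 2, max = 5),
                        biotype = "lncRNA"),
    gene_class_template("mito", n_mito,
                        span_log_mean = log(1000), span_log_sd = 0.3,
                        exon_count_law = count_law("fixed", value = 1),
                        chromosomes = "chrM", single_exon = TRUE)
  )
}
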