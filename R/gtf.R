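#' Read a GTF annotation
#'
#' Parses a GENCODE-dialect GTF via rtracklayer and returns an
#' [annotation_set()] restricted to genes whose `gene_type` is in
#' `biotypes`. Coordinates are kept 1-based closed as in the file.
#'
#' @param path GTF file path
#' @param biotypes gene_type labels to retain
#' @return an [annotation_set()]
#' @export
read_gtf <- function(path, biotypes = c("protein_coding", "lncRNA")) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  body <- !startsWith(raw, "#") & nzchar(raw)
  nfield <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    lineno <- which(body)[which(nfield != 9L)[1]]
    stop("malformed GTF line ", lineno, " in ", path,
         ": expected 9 tab-separated fields, got ", nfield[nfield != 9L][1],
         call. = FALSE)
  }
  if (!any(body)) return(annotation_set())

  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  get_attr <- function(name, default = NA_character_) {
    if (name %in% names(mc)) as.character(mc[[name]]) else
      rep(default, length(gr))
  }
  records <- data.frame(
    seqnames = as.character(GenomeInfoDb::seqnames(gr)),
    source = as.character(mc$source),
    type = as.character(mc$type),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    gene_id = get_attr("gene_id"),
    transcript_id = get_attr("transcript_id"),
    gene_type = get_attr("gene_type"),
    gene_class = get_attr("gene_class"),
    exon_number = suppressWarnings(as.integer(get_attr("exon_number"))),
    stringsAsFactors = FALSE)

  keep_genes <- unique(records$gene_id[records$gene_type %in% biotypes])
  records <- records[records$gene_id %in% keep_genes, , drop = FALSE]

  tx_with_exon <- unique(records$transcript_id[records$type == "exon"])
  tx_all <- unique(records$transcript_id[records$type == "transcript"])
  orphans <- setdiff(tx_all, tx_with_exon)
  if (length(orphans))
    stop("transcript(s) with no exon records: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  annotation_set(records)
}
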