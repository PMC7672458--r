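test_that("biotype filter retains only requested gene types", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttest\tgene\t100\t1099\t.\t+\t.\tgene_id "g1"; gene_type "protein_coding";',
    'chr1\ttest\ttranscript\t100\t1099\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; gene_type "protein_coding";',
    'chr1\ttest\texon\t100\t1099\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; gene_type "protein_coding";',
    'chr1\ttest\tgene\t5000\t5099\t.\t+\t.\tgene_id "g2"; gene_type "miRNA";',
    'chr1\ttest\ttranscript\t5000\t5099\t.\t+\t.\tgene_id "g2"; transcript_id "t2"; gene_type "miRNA";',
    'chr1\ttest\texon\t5000\t5099\t.\t+\t.\tgene_id "g2"; transcript_id "t2"; gene_type "miRNA";'),
    path)
  ann <- read_gtf(path, biotypes = c("protein_coding", "lncRNA"))
  expect_equal(unique(ann$records$gene_id), "g1")
})

test_that("malformed GTF lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("## header",
               'chr1\ttest\tgene\t1\t10\t.\t+\t.\tgene_id "g";',
               "chr1\tbroken line"), path)
  expect_error(read_gtf(path), "line 3")
})

test_that("transcripts without exon records are a validation error", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttest\tgene\t1\t100\t.\t+\t.\tgene_id "g1"; gene_type "protein_coding";',
    'chr1\ttest\ttranscript\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; gene_type "protein_coding";'),
    path)
  expect_error(read_gtf(path), "no exon")
})

test_that("single- and two-exon worked examples give the documented metrics", {
  ann <- toy_annotation(list(
    data.frame(start = 100L, end = 1099L),
    data.frame(start = c(101L, 301L), end = c(200L, 400L))))
  tm <- transcript_metrics(ann)
  one <- tm[tm$gene_id == "G001", ]
  expect_equal(one$pre_mrna_length, 1000)
  expect_equal(one$exonic_length, 1000)
  expect_equal(one$n_exons, 1)
  expect_equal(one$fraction_intronic, 0)
  expect_equal(one$exon_density, 0.001)
  two <- tm[tm$gene_id == "G002", ]
  expect_equal(two$pre_mrna_length, 300)
  expect_equal(two$exonic_length, 200)
  expect_equal(two$n_exons, 2)
  expect_equal(two$fraction_intronic, 1 / 3)
  expect_equal(two$exon_density, 0.01)
})

test_that("overlapping exons are rejected", {
  ann <- toy_annotation(list(data.frame(start = c(1L, 50L), end = c(100L, 120L))))
  expect_error(transcript_metrics(ann), "overlap")
})

test_that("length metrics are strand-invariant", {
  exons <- list(data.frame(start = c(101L, 301L, 601L),
                           end = c(200L, 400L, 900L)))
  plus <- transcript_metrics(toy_annotation(exons, strand = "+"))
  minus <- transcript_metrics(toy_annotation(exons, strand = "-"))
  for (col in c("pre_mrna_length", "exonic_length", "n_exons",
                "fraction_intronic", "exon_density"))
    expect_equal(plus[[col]], minus[[col]])
})

test_that("3'UTR length follows the CDS on either strand", {
  base <- toy_annotation(list(data.frame(start = c(101L, 301L),
                                         end = c(200L, 400L))))
  add_cds <- function(ann, strand) {
    r <- ann$records
    r$strand <- strand
    # CDS covers exonic positions 21..150 of the 200 nt mature transcript
    cds <- if (strand == "+") data.frame(start = c(121L, 301L), end = c(200L, 350L))
           else data.frame(start = c(151L, 301L), end = c(200L, 380L))
    r <- rbind(r, data.frame(
      seqnames = "chr1", source = "test", type = "CDS",
      start = cds$start, end = cds$end, strand = strand, gene_id = "G001",
      transcript_id = "G001.T1", gene_type = "protein_coding",
      gene_class = "toy", exon_number = c(1L, 2L)))
    annotation_set(r)
  }
  # + strand: exonic bases after CDS end 350 -> positions 351..400 = 50 nt
  expect_equal(transcript_metrics(add_cds(base, "+"))$utr3_length, 50)
  # - strand: exonic bases before CDS start 151 -> 101..150 = 50 nt
  expect_equal(transcript_metrics(add_cds(base, "-"))$utr3_length, 50)
  # no CDS -> undefined
  expect_true(is.na(transcript_metrics(base)$utr3_length))
})

test_that("gene medians, exon classes and rounding follow the definitions", {
  mk <- function(n_exon_counts) {
    exs <- lapply(n_exon_counts, function(k) {
      starts <- seq(1L, by = 200L, length.out = k)
      data.frame(start = starts, end = starts + 99L)
    })
    recs <- list()
    for (i in seq_along(exs)) {
      ex <- exs[[i]]
      tid <- sprintf("G001.T%d", i)
      recs[[length(recs) + 1L]] <- data.frame(
        seqnames = "chr1", source = "t", type = "transcript",
        start = min(ex$start), end = max(ex$end), strand = "+",
        gene_id = "G001", transcript_id = tid, gene_type = "protein_coding",
        gene_class = "toy", exon_number = NA_integer_)
      recs[[length(recs) + 1L]] <- data.frame(
        seqnames = "chr1", source = "t", type = "exon",
        start = ex$start, end = ex$end, strand = "+", gene_id = "G001",
        transcript_id = tid, gene_type = "protein_coding", gene_class = "toy",
        exon_number = seq_len(nrow(ex)))
    }
    gene <- data.frame(seqnames = "chr1", source = "t", type = "gene",
                       start = 1L, end = max(vapply(exs, function(e) max(e$end), 1L)),
                       strand = "+", gene_id = "G001",
                       transcript_id = NA_character_,
                       gene_type = "protein_coding", gene_class = "toy",
                       exon_number = NA_integer_)
    annotation_set(rbind(gene, do.call(rbind, recs)))
  }
  # single transcript: medians equal that transcript's metrics
  gm1 <- gene_metrics(mk(3))
  expect_equal(gm1$n_exons, 3)
  expect_equal(gm1$exon_class, "multi")
  # {1,2,4} -> median 2, multi
  gm2 <- gene_metrics(mk(c(1, 2, 4)))
  expect_equal(gm2$n_exons, 2)
  expect_equal(gm2$exon_class, "multi")
  # {1,1,3} -> median exactly 1 (unrounded), single
  gm3 <- gene_metrics(mk(c(1, 1, 3)))
  expect_equal(gm3$n_exons, 1)
  expect_equal(gm3$exon_class, "single")
  # {1,2} -> median 1.5: not single; rounds half away from zero to 2
  gm4 <- gene_metrics(mk(c(1, 2)))
  expect_equal(gm4$n_exons, 1.5)
  expect_equal(gm4$exon_class, "multi")
  expect_equal(gm4$rounded_exon_count, 2L)
})

test_that("length bins use left-closed kb boundaries with six intervals", {
  b <- assign_length_bin(c(21000, 5000, 10000, 9999, 50000, 123456))
  expect_equal(as.character(b),
               c("20-30 kb", "<10 kb", "10-20 kb", "<10 kb", ">50 kb", ">50 kb"))
  expect_equal(nlevels(b), 6)
  expect_error(assign_length_bin(c(100, -5)), "positive")
})

test_that("metrics agree with the per-base coverage oracle on random toy transcripts", {
  set.seed(101)
  exon_list <- replicate(50, random_toy_exons(), simplify = FALSE)
  tm <- transcript_metrics(toy_annotation(exon_list))
  for (i in seq_along(exon_list)) {
    o <- oracle_transcript_metrics(exon_list[[i]]$start, exon_list[[i]]$end)
    row <- tm[tm$gene_id == sprintf("G%03d", i), ]
    expect_equal(row$pre_mrna_length, o$pre_mrna_length)
    expect_equal(row$exonic_length, o$exonic_length)
    expect_equal(row$n_exons, o$n_exons)
    expect_equal(row$fraction_intronic, o$fraction_intronic)
    expect_equal(row$exon_density, o$exon_density)
  }
})
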