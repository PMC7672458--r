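test_that("FPKM follows the defining formula and its invariances", {
  counts <- matrix(c(0, 100, 100, 50), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  fpkm <- compute_fpkm(counts, c(g1 = 1000, g2 = 2000), totals = c(1e7, 1e7))
  expect_equal(fpkm["g1", "s1"], 0)
  expect_equal(fpkm["g2", "s1"], 5)   # 100 / (2 kb * 10 M)
  # scaling one sample's counts and its total by 10 leaves its column unchanged
  fpkm10 <- compute_fpkm(counts * c(1, 1, 10, 10), c(g1 = 1000, g2 = 2000),
                         totals = c(1e7, 1e8))
  expect_equal(fpkm10[, "s2"], fpkm[, "s2"])
  expect_error(compute_fpkm(counts, c(g1 = 1000, g2 = 2000), totals = c(0, 1)),
               "positive")
})

test_that("gene filter applies strict mean-FPKM cutoff and drops chrM", {
  fpkm <- matrix(c(0.5, 1.0, 1.01, 3, 10, 500), 6, 1,
                 dimnames = list(paste0("g", 1:6), "s1"))
  gm <- data.frame(gene_id = paste0("g", 1:6),
                   chromosome = c(rep("chr1", 5), "chrM"))
  keep <- filter_genes(fpkm, gm)
  expect_setequal(keep, c("g3", "g4", "g5"))   # strict > 1; chrM excluded
})

test_that("size factors match the closed-form doubled-library example", {
  counts <- matrix(c(10, 40, 90, 20, 80, 180), 3, 2,
                   dimnames = list(paste0("g", 1:3), c("A", "B")))
  sf <- size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  # identical samples -> unit factors
  expect_equal(unname(size_factors(cbind(counts[, 1], counts[, 1]))), c(1, 1))
  # scale equivariance: scaling sample B by c scales the factor ratio by c
  sf3 <- size_factors(sweep(counts, 2, c(1, 3), "*"))
  expect_equal(sf3[["B"]] / sf3[["A"]], 3 * sf[["B"]] / sf[["A"]])
  # no all-nonzero gene -> advisory error
  bad <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(size_factors(bad), "pseudocount")
  expect_silent(size_factors(bad, pseudocount = 0.5))
})

test_that("normalized counts divide columns by their factors", {
  counts <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(normalized_counts(counts, c(x = 1, y = 2)),
               counts / rep(c(1, 2), each = 2), ignore_attr = TRUE)
  expect_equal(normalized_counts(counts, c(x = 1, y = 1)), counts * 1)
})

test_that("delta is zero when knockdown equals control and matches the noise-free example", {
  se <- toy_experiment(n_kd = c(200, 30), c_kd = c(100, 60),
                       n_ctrl = c(200, 30), c_ctrl = c(100, 60))
  loc <- delta_localization(se, kd = "KD", control = "control",
                            sf = rep(1, 8))
  expect_equal(loc$delta_raw, c(0, 0))
  expect_equal(loc$delta_shrunk, c(0, 0))

  # control N/C = 2, KD N/C = 8, prior 0 -> delta_raw = 2
  se2 <- toy_experiment(n_kd = c(800, 100), c_kd = c(100, 100),
                        n_ctrl = c(200, 100), c_ctrl = c(100, 100))
  loc2 <- delta_localization(se2, kd = "KD", control = "control",
                             prior_count = 0, sf = rep(1, 8))
  expect_equal(loc2$delta_raw[1], 2)
})

test_that("shrinkage preserves sign and never inflates magnitude", {
  ann <- default_test_annotation()
  se <- simulate_fracseq_counts(ann, effect_model(), seed = 21)
  loc <- delta_localization(se, kd = "KD_A")
  expect_true(all(abs(loc$delta_shrunk) <= abs(loc$delta_raw) + 1e-12))
  expect_true(all(sign(loc$delta_shrunk) == sign(loc$delta_raw) |
                  loc$delta_shrunk == 0))
  expect_true(all(is.finite(loc$delta_raw)))
  expect_true(attr(loc, "tau2") >= 0)
})

test_that("swapping condition labels negates every delta exactly", {
  ann <- make_toy_annotation(default_templates(150), seed = 1)
  se <- simulate_fracseq_counts(ann, effect_model(), seed = 22)
  fwd <- delta_localization(se, kd = "KD_A", control = "control")
  rev <- delta_localization(se, kd = "control", control = "KD_A")
  expect_equal(rev$delta_raw, -fwd$delta_raw)
  expect_equal(rev$se, fwd$se)
})

test_that("permuting replicate labels within a condition leaves deltas unchanged", {
  ann <- make_toy_annotation(default_templates(150), seed = 1)
  se <- simulate_fracseq_counts(ann, effect_model(), seed = 23)
  counts <- SummarizedExperiment::assay(se, "counts")
  design <- as.data.frame(SummarizedExperiment::colData(se))
  base <- delta_localization(se, kd = "KD_A")
  swap <- design$fraction == "nuclear" & design$condition == "KD_A"
  idx <- which(swap)
  perm <- seq_len(ncol(counts))
  perm[idx] <- idx[c(2, 3, 1)]
  counts2 <- counts[, perm]
  colnames(counts2) <- colnames(counts)
  se2 <- fracseq_experiment(counts2, design)
  again <- delta_localization(se2, kd = "KD_A")
  expect_equal(again$delta_raw, base$delta_raw)
  expect_equal(again$se, base$se)
})

test_that("all three contrast pairs are computable and consistent", {
  ann <- make_toy_annotation(default_templates(150), seed = 1)
  se <- simulate_fracseq_counts(ann, effect_model(), seed = 24)
  nc <- delta_localization(se, c("N", "C"), kd = "KD_A")
  nt <- delta_localization(se, c("N", "T"), kd = "KD_A")
  ct <- delta_localization(se, c("C", "T"), kd = "KD_A")
  # log2(N/C) = log2(N/T) - log2(C/T) holds for the raw deltas at prior 0
  nc0 <- delta_localization(se, c("N", "C"), kd = "KD_A", prior_count = 0)
  nt0 <- delta_localization(se, c("N", "T"), kd = "KD_A", prior_count = 0)
  ct0 <- delta_localization(se, c("C", "T"), kd = "KD_A", prior_count = 0)
  expect_equal(nc0$delta_raw, nt0$delta_raw - ct0$delta_raw, tolerance = 1e-9)
  expect_error(delta_localization(se, kd = "KD_X"), "KD_X")
})

test_that("intronic read fractions follow their defining ratio", {
  ann <- make_toy_annotation(default_templates(100), seed = 1)
  se <- simulate_fracseq_counts(ann, effect_model(), seed = 25)
  irf <- intronic_read_fraction(se, fraction = "cytoplasmic")
  expect_true(all(irf$fraction == "cytoplasmic"))
  counts <- SummarizedExperiment::assay(se, "counts")
  intr <- SummarizedExperiment::assay(se, "intronic")
  s <- irf$sample[1]
  expect_equal(irf$intronic_fraction[1],
               sum(intr[, s]) / (sum(intr[, s]) + sum(counts[, s])))
  # zero intronic counts -> 0
  se0 <- fracseq_experiment(counts, as.data.frame(SummarizedExperiment::colData(se)),
                            intronic = intr * 0L)
  expect_true(all(intronic_read_fraction(se0)$intronic_fraction == 0))
  # missing intronic assay -> feature-unavailable error
  se1 <- fracseq_experiment(counts, as.data.frame(SummarizedExperiment::colData(se)))
  expect_error(intronic_read_fraction(se1), "intronic")
})
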