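flat_masks <- function(dim = c(100, 100)) {
  cell <- ellipse <- matrix(FALSE, dim[1], dim[2])
  r <- row(cell); c <- col(cell)
  cell <- ((r - 50)^2 / 45^2 + (c - 50)^2 / 40^2) <= 1
  nuc <- ((r - 50)^2 / 20^2 + (c - 50)^2 / 18^2) <= 1
  list(nucleus = nuc, cell = cell)
}

test_that("cytoplasmic/total ratio matches hand-computed partitions", {
  m <- flat_masks()
  rna <- matrix(0, 100, 100)
  rna[m$cell & !m$nucleus] <- 1
  expect_equal(cyto_total_ratio(rna, m$nucleus, m$cell, "none"), 1)
  rna2 <- matrix(0, 100, 100)
  rna2[m$nucleus] <- 1
  expect_equal(cyto_total_ratio(rna2, m$nucleus, m$cell, "none"), 0)
  # 30 units nuclear, 70 cytoplasmic
  rna3 <- matrix(0, 100, 100)
  rna3[m$nucleus] <- 30 / sum(m$nucleus)
  rna3[m$cell & !m$nucleus] <- 70 / sum(m$cell & !m$nucleus)
  expect_equal(cyto_total_ratio(rna3, m$nucleus, m$cell, "none"), 0.7)
  # uniform rescaling leaves the ratio unchanged; zero signal errors
  expect_equal(cyto_total_ratio(rna3 * 37, m$nucleus, m$cell, "none"), 0.7)
  expect_error(cyto_total_ratio(rna3 * 0, m$nucleus, m$cell), "zero total")
  # background subtraction removes a constant offset
  expect_equal(cyto_total_ratio(rna3 + 5, m$nucleus, m$cell, "outside_cell"),
               0.7, tolerance = 1e-10)
})

test_that("speckle segmentation hits the target area and recovers planted foci", {
  img <- simulate_cell_image(seed = 7)
  seg <- segment_speckles(img$sc35, img$nucleus_mask)
  expect_gte(seg$area_fraction, 0.095)
  expect_lte(seg$area_fraction, 0.105)
  expect_true(!any(seg$speckle_mask & !img$nucleus_mask))
  # planted foci recovered: Jaccard of mask vs equal-area truth disks > 0.8
  sc <- img$truth$speckle_centers
  truth_mask <- matrix(FALSE, nrow(img$sc35), ncol(img$sc35))
  r <- row(truth_mask); c <- col(truth_mask)
  rad2 <- 0.10 * sum(img$nucleus_mask) / (nrow(sc) * pi)
  for (i in seq_len(nrow(sc)))
    truth_mask <- truth_mask |
      ((r - sc$row[i])^2 + (c - sc$col[i])^2 <= rad2)
  truth_mask <- truth_mask & img$nucleus_mask
  jac <- sum(seg$speckle_mask & truth_mask) / sum(seg$speckle_mask | truth_mask)
  expect_gt(jac, 0.8)
  # every focus contributes selected pixels
  hit <- vapply(seq_len(nrow(sc)), function(i)
    any(seg$speckle_mask[(r - sc$row[i])^2 + (c - sc$col[i])^2 <= 4]),
    logical(1))
  expect_true(all(hit))
})

test_that("constant SC35 image is segmented deterministically with a tie warning", {
  m <- flat_masks()
  sc35 <- matrix(1, 100, 100)
  expect_warning(seg <- segment_speckles(sc35, m$nucleus), "tie")
  expect_gte(seg$area_fraction, 0.095)
  expect_lte(seg$area_fraction, 0.105)
  seg2 <- suppressWarnings(segment_speckles(sc35, m$nucleus))
  expect_identical(seg$speckle_mask, seg2$speckle_mask)
  expect_error(segment_speckles(sc35[1:40, 1:40], m$nucleus[1:40, 1:40]),
               "1000")
})

test_that("speckle enrichment matches closed-form uniform and degenerate cases", {
  m <- flat_masks()
  speckle <- m$nucleus & (row(m$nucleus) < 48)
  rna_uniform <- matrix(0, 100, 100); rna_uniform[m$nucleus] <- 3
  enr <- speckle_enrichment(rna_uniform, speckle, m$nucleus, m$cell)
  expect_equal(enr$spec_over_nuc, sum(speckle) / sum(m$nucleus))
  rna_all_spec <- matrix(0, 100, 100); rna_all_spec[speckle] <- 1
  enr2 <- speckle_enrichment(rna_all_spec, speckle, m$nucleus, m$cell)
  expect_equal(enr2$spec_over_nuc, 1)
  expect_equal(enr2$spec_over_total, 1)
  expect_error(speckle_enrichment(rna_uniform, m$cell, m$nucleus, m$cell),
               "inside")
})

test_that("brightest-speckle Pearson is exactly 1 for affine-related channels", {
  img <- simulate_cell_image(seed = 8)
  seg <- segment_speckles(img$sc35, img$nucleus_mask)
  same <- brightest_speckle_pearson(img$sc35, img$sc35, seg$speckle_mask)
  expect_equal(same$per_speckle$r, rep(1, nrow(same$per_speckle)),
               tolerance = 1e-12)
  affine <- brightest_speckle_pearson(3 * img$sc35 + 7, img$sc35,
                                      seg$speckle_mask)
  expect_equal(affine$per_speckle$r, rep(1, nrow(affine$per_speckle)),
               tolerance = 1e-12)
  expect_lte(nrow(same$per_speckle), 10)
  # k larger than the number of components: uses all, no error
  allk <- brightest_speckle_pearson(img$rna, img$sc35, seg$speckle_mask,
                                    k = 1000)
  expect_gte(nrow(allk$per_speckle), nrow(same$per_speckle))
})

test_that("brightest-speckle Pearson is centred on zero for independent noise", {
  set.seed(13)
  vals <- replicate(20, {
    img <- simulate_cell_image(seed = sample.int(1e6, 1))
    seg <- segment_speckles(img$sc35, img$nucleus_mask)
    noise <- matrix(runif(length(img$rna)), nrow(img$rna))
    suppressWarnings(
      brightest_speckle_pearson(noise, img$sc35, seg$speckle_mask)$mean_r)
  })
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("experiment-level Pearson averaging follows cells-then-experiments", {
  cells <- data.frame(experiment = rep(1:3, each = 4),
                      mean_r = c(rep(0.2, 4), rep(0.4, 4), rep(0.9, 4)))
  agg <- pearson_experiment_mean(cells)
  expect_equal(unname(agg$experiment_means), c(0.2, 0.4, 0.9))
  expect_equal(agg$mean, 0.5)
  expect_equal(agg$se, sd(c(0.2, 0.4, 0.9)) / sqrt(3))
})

test_that("spot detection is empty on blank images and invariant to brightness", {
  expect_equal(nrow(detect_spots(matrix(0, 80, 80))), 0)
  expect_equal(nrow(detect_spots(matrix(5, 80, 80))), 0)
  img <- simulate_cell_image(n_speckles = 0, w_spec = 0, w_nuc = 0, w_cyt = 0,
                             bg_offset = 50, n_spots_nuclear = 15,
                             n_spots_cytoplasmic = 15, seed = 14)
  s1 <- detect_spots(img$rna)
  s2 <- detect_spots(img$rna * 2)
  expect_identical(s1[c("row", "col")], s2[c("row", "col")])
  expect_gt(nrow(s1), 0)
})

test_that("planted spots are recovered and classified by compartment", {
  img <- simulate_cell_image(n_speckles = 0, w_spec = 0, w_nuc = 0, w_cyt = 0,
                             bg_offset = 50, n_spots_nuclear = 20,
                             n_spots_cytoplasmic = 30, seed = 15)
  spots <- detect_spots(img$rna)
  cls <- classify_spots(spots, img$nucleus_mask, img$cell_mask)
  expect_equal(cls$n_nuclear, 20)
  expect_equal(cls$n_cytoplasmic, 30)
  expect_equal(cls$nuclear_fraction, 0.4)
  # all spots inside nucleus -> fraction 1
  nuc_only <- img$truth$spots[img$truth$spots$compartment == "nuclear", ]
  cls2 <- classify_spots(nuc_only, img$nucleus_mask, img$cell_mask)
  expect_equal(cls2$nuclear_fraction, 1)
})

test_that("nuclear-fraction fold change is recovered from a 2.5x enrichment design", {
  set.seed(16)
  cells <- list()
  for (i in 1:8) {
    n_tot <- 50
    # control: 20% nuclear; knockdown: 50% nuclear (2.5x)
    for (cond in c("control", "KD")) {
      p <- if (cond == "KD") 0.5 else 0.2
      nn <- rbinom(1, n_tot, p)
      img <- simulate_cell_image(n_speckles = 0, w_spec = 0, w_nuc = 0,
                                 w_cyt = 0, bg_offset = 50,
                                 n_spots_nuclear = max(nn, 1),
                                 n_spots_cytoplasmic = max(n_tot - nn, 1),
                                 seed = 1600 + i * 10 + (cond == "KD"))
      cls <- classify_spots(detect_spots(img$rna), img$nucleus_mask,
                            img$cell_mask)
      cells[[length(cells) + 1L]] <- data.frame(
        condition = cond, n_nuclear = cls$n_nuclear,
        n_cytoplasmic = cls$n_cytoplasmic)
    }
  }
  fc <- nuclear_fraction_fold_change(do.call(rbind, cells), "KD", "control")
  expect_gte(fc$fold_change, 2)
  expect_lte(fc$fold_change, 3)
})

test_that("decay-ratio time course reproduces unit ratios and decay shapes", {
  cells <- expand.grid(condition = c("control", "KD"), timepoint = c(0, 1, 2),
                       cell = 1:6, stringsAsFactors = FALSE)
  cells$signal <- 100
  tc <- decay_ratio_timecourse(cells, "KD", "control")
  expect_equal(tc$ratio, rep(1, 3))
  # a fixed unstable fraction decaying in the first hour, then a plateau
  set.seed(17)
  decayed <- cells
  retain <- ifelse(decayed$timepoint == 0, 1,
                   ifelse(decayed$timepoint == 1, 0.6, 0.58))
  decayed$signal <- ifelse(decayed$condition == "KD",
                           100 * retain, 100) * rlnorm(nrow(decayed), 0, 0.05)
  tc2 <- decay_ratio_timecourse(decayed, "KD", "control")
  expect_lt(tc2$ratio[2], tc2$ratio[1])
  expect_lt(abs(tc2$ratio[3] - tc2$ratio[2]), 0.15)
  expect_true(all(is.finite(tc2$se)))
  # scale invariance
  scaled <- decayed; scaled$signal <- scaled$signal * 1000
  expect_equal(decay_ratio_timecourse(scaled, "KD", "control")$ratio, tc2$ratio)
})
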