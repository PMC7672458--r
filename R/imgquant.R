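subtract_background <- function(img, cell_mask,
                                background = c("outside_cell", "none")) {
  background <- match.arg(background)
  if (background == "none") return(img)
  outside <- !cell_mask
  bg <- if (any(outside)) stats::median(img[outside]) else 0
  pmax(img - bg, 0)
}

#' Cytoplasmic / total RNA intensity ratio
#'
#' Fraction of (background-subtracted) RNA signal in the cytoplasm:
#' `sum(rna over cell \ nucleus) / sum(rna over cell)`. Background default
#' is the median intensity outside the cell mask, clipped at zero.
#'
#' @param rna non-negative intensity matrix
#' @param nucleus_mask,cell_mask boolean matrices, nucleus inside cell
#' @param background "outside_cell" (default) or "none"
#' @return scalar in `[0, 1]`
#' @export
cyto_total_ratio <- function(rna, nucleus_mask, cell_mask,
                             background = c("outside_cell", "none")) {
  stopifnot(all(dim(rna) == dim(nucleus_mask)),
            all(dim(rna) == dim(cell_mask)))
  if (any(nucleus_mask & !cell_mask))
    stop("nucleus_mask must lie inside cell_mask", call. = FALSE)
  img <- subtract_background(rna, cell_mask, background)
  total <- sum(img[cell_mask])
  if (total <= 0) stop("undefined ratio: zero total signal in cell", call. = FALSE)
  sum(img[cell_mask & !nucleus_mask]) / total
}

#' Area-constrained nuclear speckle segmentation
#'
#' Selects the brightest SC35 pixels within the nucleus so that the
#' selected area is `target_fraction` of the nuclear area, within
#' `tolerance` (default 10% +/- 0.5% of nuclear pixels, the standard
#' speckle-thresholding constraint). The threshold is the
#' `(1 - target_fraction)` quantile of nuclear SC35 intensities; when ties
#' at the threshold would push the achieved area outside the tolerance,
#' tied pixels are included in deterministic pixel-index order and a
#' warning is emitted.
#'
#' @param sc35 SC35 channel intensity matrix
#' @param nucleus_mask boolean matrix with >= 1000 TRUE pixels
#' @param target_fraction target selected fraction of nuclear area
#' @param tolerance allowed deviation of the achieved fraction
#' @return list: `speckle_mask` (boolean matrix, subset of nucleus_mask),
#'   `area_fraction` achieved, `threshold` used
#' @export
segment_speckles <- function(sc35, nucleus_mask, target_fraction = 0.10,
                             tolerance = 0.005) {
  stopifnot(all(dim(sc35) == dim(nucleus_mask)))
  idx <- which(nucleus_mask)
  n <- length(idx)
  if (n < 1000)
    stop("nucleus_mask must contain at least 1000 pixels", call. = FALSE)
  v <- sc35[idx]
  k <- max(1L, round(target_fraction * n))
  vs <- sort(v, decreasing = TRUE)
  thr <- vs[k]
  n_above <- sum(v > thr)
  n_tie <- sum(v == thr)
  sel <- logical(n)
  sel[v > thr] <- TRUE
  need <- k - n_above
  if (need > 0) {
    tied <- which(v == thr)          # deterministic pixel-index tie-break
    sel[tied[seq_len(need)]] <- TRUE
    if ((n_above + n_tie) / n > target_fraction + tolerance &&
        n_above / n < target_fraction - tolerance)
      warning("intensity ties at the speckle threshold; broke ties by ",
              "pixel index to reach the target area", call. = FALSE)
  }
  mask <- matrix(FALSE, nrow(sc35), ncol(sc35))
  mask[idx[sel]] <- TRUE
  list(speckle_mask = mask, area_fraction = sum(sel) / n, threshold = thr)
}

#' Speckle enrichment of RNA signal
#'
#' RNA intensity in the speckle mask as a fraction of the total nuclear
#' ("spec/nuc") and total cellular ("spec/total") RNA intensity.
#'
#' @param rna RNA channel intensity matrix
#' @param speckle_mask,nucleus_mask,cell_mask nested boolean masks
#' @return list: `spec_over_nuc`, `spec_over_total`
#' @export
speckle_enrichment <- function(rna, speckle_mask, nucleus_mask, cell_mask) {
  if (any(speckle_mask & !nucleus_mask))
    stop("speckle_mask must lie inside nucleus_mask", call. = FALSE)
  if (any(nucleus_mask & !cell_mask))
    stop("nucleus_mask must lie inside cell_mask", call. = FALSE)
  nuc <- sum(rna[nucleus_mask])
  if (nuc <= 0) stop("undefined enrichment: zero nuclear signal", call. = FALSE)
  spec <- sum(rna[speckle_mask])
  list(spec_over_nuc = spec / nuc, spec_over_total = spec / sum(rna[cell_mask]))
}

#' Pearson colocalization over the brightest speckles
#'
#' Decomposes the speckle mask into connected components, ranks them by
#' peak SC35 intensity, and for each of the top `k` (or all, if fewer)
#' computes the Pearson correlation between the RNA and SC35 channels over
#' the component's pixels plus a 1-pixel dilation (to include speckle
#' borders). Components smaller than 4 pixels are skipped with a warning.
#'
#' @param rna,sc35 intensity matrices
#' @param speckle_mask boolean speckle mask (see [segment_speckles()])
#' @param k number of brightest speckles to analyze
#' @return list: `per_speckle` (data.frame component, peak, n_pixels, r),
#'   `mean_r` (per-cell mean over analyzed speckles)
#' @export
brightest_speckle_pearson <- function(rna, sc35, speckle_mask, k = 10) {
  labels <- EBImage::bwlabel(speckle_mask * 1)
  n_comp <- max(labels)
  if (n_comp == 0)
    return(list(per_speckle = data.frame(component = integer(0),
                                         peak = numeric(0),
                                         n_pixels = integer(0), r = numeric(0)),
                mean_r = NA_real_))
  peak <- vapply(seq_len(n_comp), function(i) max(sc35[labels == i]), numeric(1))
  size <- tabulate(labels[labels > 0], nbins = n_comp)
  usable <- which(size >= 4)
  if (length(usable) < n_comp)
    warning(n_comp - length(usable),
            " speckle component(s) smaller than 4 pixels skipped", call. = FALSE)
  top <- usable[order(peak[usable], decreasing = TRUE)]
  top <- top[seq_len(min(k, length(top)))]
  brush <- EBImage::makeBrush(3, shape = "box")
  rows <- lapply(top, function(i) {
    roi <- EBImage::dilate((labels == i) * 1, brush) > 0
    data.frame(component = i, peak = peak[i], n_pixels = sum(roi),
               r = stats::cor(rna[roi], sc35[roi]))
  })
  per <- do.call(rbind, rows)
  list(per_speckle = per, mean_r = mean(per$r))
}

#' Average per-cell Pearson values the way imaging experiments are reported
#'
#' Cells are averaged within each experiment and the experiment means are
#' averaged, with the standard error across experiments.
#'
#' @param cell_means data.frame with columns `experiment` and `mean_r`
#' @return list: `experiment_means`, `mean`, `se`
#' @export
pearson_experiment_mean <- function(cell_means) {
  stopifnot(all(c("experiment", "mean_r") %in% names(cell_means)))
  em <- vapply(split(cell_means$mean_r, cell_means$experiment), mean,
               numeric(1))
  list(experiment_means = em, mean = mean(em),
       se = if (length(em) > 1) stats::sd(em) / sqrt(length(em)) else NA_real_)
}

#' Detect diffraction-limited spots
#'
#' Band-pass filters the image (Gaussian smoothing at `smoothing_scale`
#' minus a 5x-wider Gaussian estimate of the local background), then
#' reports local maxima of the residual exceeding
#' `background median + threshold_sigmas * robust SD` (median absolute
#' deviation of the residual), with a minimum separation of one
#' `smoothing_scale` between detections (brightest kept). The threshold is
#' relative, so uniform rescaling of intensities leaves detections
#' unchanged.
#'
#' @param image non-negative intensity matrix
#' @param smoothing_scale Gaussian SD in pixels
#' @param threshold_sigmas detection threshold in robust SDs above background
#' @return data.frame: row, col, intensity (band-passed), one row per spot
#' @export
detect_spots <- function(image, smoothing_scale = 1.5, threshold_sigmas = 5) {
  stopifnot(all(image >= 0))
  sm <- as.matrix(EBImage::gblur(image, sigma = smoothing_scale)) -
    as.matrix(EBImage::gblur(image, sigma = 5 * smoothing_scale))
  bg <- stats::median(sm)
  rsd <- stats::mad(sm)
  if (rsd == 0) return(data.frame(row = integer(0), col = integer(0),
                                  intensity = numeric(0)))
  thr <- bg + threshold_sigmas * rsd
  sz <- 2L * ceiling(smoothing_scale) + 1L
  maxfilt <- as.matrix(EBImage::dilate(sm, EBImage::makeBrush(sz, "box")))
  cand <- which(sm >= maxfilt & sm > thr, arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(row = integer(0), col = integer(0), intensity = numeric(0)))
  vals <- sm[cand]
  o <- order(vals, decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]
  vals <- vals[o]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {        # greedy minimum-separation pass
    if (i == 1L) { keep[1L] <- TRUE; next }
    d2 <- (cand[seq_len(i - 1L), 1][keep[seq_len(i - 1L)]] - cand[i, 1])^2 +
      (cand[seq_len(i - 1L), 2][keep[seq_len(i - 1L)]] - cand[i, 2])^2
    keep[i] <- all(d2 >= smoothing_scale^2)
  }
  data.frame(row = cand[keep, 1], col = cand[keep, 2],
             intensity = vals[keep], row.names = NULL)
}

#' Classify spots as nuclear or cytoplasmic
#'
#' Membership by center-pixel mask lookup (no sub-pixel interpolation): a
#' spot whose center pixel is in the nucleus mask is nuclear; in the cell
#' mask but not the nucleus, cytoplasmic; outside the cell mask, discarded
#' and reported.
#'
#' @param spots data.frame with `row`, `col` (see [detect_spots()])
#' @param nucleus_mask,cell_mask boolean matrices
#' @return list: `n_nuclear`, `n_cytoplasmic`, `n_discarded`,
#'   `nuclear_fraction`
#' @export
classify_spots <- function(spots, nucleus_mask, cell_mask) {
  if (!nrow(spots))
    return(list(n_nuclear = 0L, n_cytoplasmic = 0L, n_discarded = 0L,
                nuclear_fraction = NA_real_))
  r <- pmin(pmax(round(spots$row), 1L), nrow(cell_mask))
  c <- pmin(pmax(round(spots$col), 1L), ncol(cell_mask))
  at <- cbind(r, c)
  in_cell <- cell_mask[at]
  in_nuc <- nucleus_mask[at] & in_cell
  n_nuc <- sum(in_nuc)
  n_cyt <- sum(in_cell & !in_nuc)
  list(n_nuclear = n_nuc, n_cytoplasmic = n_cyt,
       n_discarded = sum(!in_cell),
       nuclear_fraction = if (n_nuc + n_cyt > 0) n_nuc / (n_nuc + n_cyt)
       else NA_real_)
}

#' Fold change of the nuclear spot fraction between conditions
#'
#' Aggregates per-cell spot counts by condition and returns the ratio of
#' nuclear fractions (knockdown over control).
#'
#' @param spot_table data.frame with columns `condition`, `n_nuclear`,
#'   `n_cytoplasmic` (one row per cell)
#' @param kd,control condition labels
#' @return list: `nuclear_fraction_kd`, `nuclear_fraction_control`,
#'   `fold_change`
#' @export
nuclear_fraction_fold_change <- function(spot_table, kd, control) {
  frac <- function(cond) {
    rows <- spot_table$condition == cond
    if (!any(rows)) stop("condition '", cond, "' absent", call. = FALSE)
    nn <- sum(spot_table$n_nuclear[rows])
    nc <- sum(spot_table$n_cytoplasmic[rows])
    nn / (nn + nc)
  }
  fk <- frac(kd); fc <- frac(control)
  list(nuclear_fraction_kd = fk, nuclear_fraction_control = fc,
       fold_change = fk / fc)
}

#' Decay-ratio time course
#'
#' Per timepoint, the ratio of mean signal in the knockdown condition over
#' the control condition, with the standard error by first-order
#' propagation of the two means' standard errors. Timepoints where either
#' condition has a single cell get an `NA` standard error.
#'
#' @param signal_by_cell data.frame with columns `condition`, `timepoint`,
#'   `signal` (one row per cell)
#' @param kd,control condition labels
#' @return data.frame: timepoint, ratio, se, n_kd, n_control
#' @export
decay_ratio_timecourse <- function(signal_by_cell, kd = "KD",
                                   control = "control") {
  stopifnot(all(c("condition", "timepoint", "signal") %in% names(signal_by_cell)))
  tps <- sort(unique(signal_by_cell$timepoint))
  rows <- lapply(tps, function(tp) {
    at <- signal_by_cell$timepoint == tp
    xk <- signal_by_cell$signal[at & signal_by_cell$condition == kd]
    xc <- signal_by_cell$signal[at & signal_by_cell$condition == control]
    if (!length(xk) || !length(xc))
      stop("timepoint ", tp, " lacks condition '",
           if (!length(xk)) kd else control, "'", call. = FALSE)
    mk <- mean(xk); mc <- mean(xc)
    se <- if (length(xk) > 1 && length(xc) > 1) {
      sek <- stats::sd(xk) / sqrt(length(xk))
      sec <- stats::sd(xc) / sqrt(length(xc))
      (mk / mc) * sqrt((sek / mk)^2 + (sec / mc)^2)
    } else NA_real_
    data.frame(timepoint = tp, ratio = mk / mc, se = se,
               n_kd = length(xk), n_control = length(xc))
  })
  do.call(rbind, rows)
}
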