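ellipse_mask <- function(dim, center, radii) {
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  c <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  ((r - center[1]) / radii[1])^2 + ((c - center[2]) / radii[2])^2 <= 1
}

# add a peak-normalized Gaussian of amplitude `amp` at (row, col) in place
add_gaussian <- function(mat, row, col, sigma, amp) {
  w <- ceiling(4 * sigma)
  rr <- max(1, round(row) - w):min(nrow(mat), round(row) + w)
  cc <- max(1, round(col) - w):min(ncol(mat), round(col) + w)
  dr <- (rr - row)^2
  dc <- (cc - col)^2
  mat[rr, cc] <- mat[rr, cc] + amp * exp(-outer(dr, dc, "+") / (2 * sigma^2))
  mat
}

sample_in_mask <- function(mask, n, max_attempts = 200L, what = "point",
                           min_sep = 0, existing = NULL) {
  if (n == 0L) return(data.frame(row = numeric(0), col = numeric(0)))
  rows <- c(existing$row, numeric(n)); cols <- c(existing$col, numeric(n))
  n0 <- length(existing$row)
  for (i in n0 + seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      r <- stats::runif(1, 1, nrow(mask))
      c <- stats::runif(1, 1, ncol(mask))
      if (!mask[round(r), round(c)]) next
      if (i > 1 && min_sep > 0) {
        prev <- seq_len(i - 1L)
        if (min((rows[prev] - r)^2 + (cols[prev] - c)^2) < min_sep^2) next
      }
      rows[i] <- r; cols[i] <- c; ok <- TRUE; break
    }
    if (!ok)
      stop("failed to place ", what, " inside mask after ", max_attempts,
           " attempts", call. = FALSE)
  }
  data.frame(row = rows[n0 + seq_len(n)], col = cols[n0 + seq_len(n)])
}

#' Simulate a two-channel cell image with known ground truth
#'
#' Nucleus and cell are nested ellipses. The SC35 (speckle marker) channel
#' is a nucleoplasmic baseline plus `n_speckles` Gaussian foci placed
#' inside the nucleus. The RNA channel is a weighted mixture of the
#' speckle field (`w_spec`), a uniform nucleoplasmic component (`w_nuc`)
#' and a uniform cytoplasmic component (`w_cyt`), plus optional
#' diffraction-limited smFISH-like spots at recorded coordinates. Noise is
#' Poisson on photon counts scaled by `gain`, so intensities stay
#' non-negative. Spot amplitudes are set per compartment as
#' `spot_snr * sqrt(baseline / gain)` (peak over shot-noise SD).
#'
#' @param dim image dimensions (rows, cols), each >= 64
#' @param n_speckles number of SC35 foci (>= 0)
#' @param speckle_sigma focus Gaussian SD, pixels
#' @param sc35_nucleoplasm,sc35_speckle_amp SC35 baseline and focus peak
#' @param w_spec,w_nuc,w_cyt RNA mixture weights (intensity units)
#' @param n_spots_nuclear,n_spots_cytoplasmic planted spot counts
#' @param spot_sigma spot PSF SD, pixels
#' @param spot_snr spot peak amplitude in units of local shot-noise SD
#' @param spot_min_sep minimum center-to-center spot separation, pixels
#' @param bg_offset small constant added everywhere (camera offset)
#' @param gain photons per intensity unit for the Poisson noise model
#' @param noise disable to obtain the noise-free expectation
#' @param seed integer seed
#' @return object of class `cell_image`: list with `sc35`, `rna`,
#'   `nucleus_mask`, `cell_mask` and `truth` (speckle centers, spot
#'   coordinates with compartment labels, mixture weights)
#' @export
simulate_cell_image <- function(dim = c(192, 192), n_speckles = 12,
                                speckle_sigma = 2.5,
                                sc35_nucleoplasm = 30, sc35_speckle_amp = 300,
                                w_spec = 150, w_nuc = 50, w_cyt = 50,
                                n_spots_nuclear = 0, n_spots_cytoplasmic = 0,
                                spot_sigma = 1.2, spot_snr = 10,
                                spot_min_sep = 5,
                                bg_offset = 2, gain = 1, noise = TRUE,
                                seed = 1L) {
  if (any(dim < 64)) stop("image dimensions must be >= 64x64", call. = FALSE)
  if (n_speckles < 0) stop("speckle count must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  center <- (dim + 1) / 2
  cell_mask <- ellipse_mask(dim, center, dim * c(0.42, 0.38))
  nucleus_mask <- ellipse_mask(dim, center, dim * c(0.22, 0.19))
  cyto_mask <- cell_mask & !nucleus_mask

  # keep focus centers away from the nuclear rim so foci stay nuclear
  inner <- ellipse_mask(dim, center, dim * c(0.22, 0.19) - 2 * speckle_sigma)
  speckles <- sample_in_mask(inner, n_speckles, what = "speckle center")
  field <- matrix(0, dim[1], dim[2])
  for (i in seq_len(nrow(speckles)))
    field <- add_gaussian(field, speckles$row[i], speckles$col[i],
                          speckle_sigma, 1)

  sc35 <- bg_offset + sc35_nucleoplasm * nucleus_mask + sc35_speckle_amp * field
  rna <- bg_offset + w_spec * field + w_nuc * nucleus_mask + w_cyt * cyto_mask

  spots <- data.frame(row = numeric(0), col = numeric(0),
                      compartment = character(0))
  if (n_spots_nuclear > 0 || n_spots_cytoplasmic > 0) {
    nuc_spots <- sample_in_mask(nucleus_mask, n_spots_nuclear,
                                what = "nuclear spot", min_sep = spot_min_sep)
    cyt_spots <- sample_in_mask(cyto_mask, n_spots_cytoplasmic,
                                what = "cytoplasmic spot",
                                min_sep = spot_min_sep, existing = nuc_spots)
    amp_nuc <- spot_snr * sqrt((bg_offset + w_nuc + w_spec * 0) / gain)
    amp_cyt <- spot_snr * sqrt((bg_offset + w_cyt) / gain)
    for (i in seq_len(nrow(nuc_spots)))
      rna <- add_gaussian(rna, nuc_spots$row[i], nuc_spots$col[i],
                          spot_sigma, amp_nuc)
    for (i in seq_len(nrow(cyt_spots)))
      rna <- add_gaussian(rna, cyt_spots$row[i], cyt_spots$col[i],
                          spot_sigma, amp_cyt)
    spots <- rbind(
      if (nrow(nuc_spots)) cbind(nuc_spots, compartment = "nuclear"),
      if (nrow(cyt_spots)) cbind(cyt_spots, compartment = "cytoplasmic"))
  }

  if (noise) {
    sc35 <- matrix(stats::rpois(length(sc35), gain * sc35) / gain,
                   dim[1], dim[2])
    rna <- matrix(stats::rpois(length(rna), gain * rna) / gain,
                  dim[1], dim[2])
  }

  structure(list(sc35 = sc35, rna = rna, nucleus_mask = nucleus_mask,
                 cell_mask = cell_mask,
                 truth = list(speckle_centers = speckles, spots = spots,
                              weights = c(w_spec = w_spec, w_nuc = w_nuc,
                                          w_cyt = w_cyt),
                              bg_offset = bg_offset, seed = as.integer(seed))),
            class = "cell_image")
}

#' @export
print.cell_image <- function(x, ...) {
  cat("cell_image:", nrow(x$rna), "x", ncol(x$rna), "px;",
      nrow(x$truth$speckle_centers), "speckles,",
      nrow(x$truth$spots), "planted spots\n")
  invisible(x)
}

#' Write a cell image to 16-bit grayscale TIFFs
#'
#' Channels are written as 16-bit TIFF (intensities clipped to 0..65535),
#' masks as binary TIFFs, and the ground truth (if any) as TSV tables.
#'
#' @param image a `cell_image`
#' @param dir output directory
#' @param prefix file name prefix
#' @return invisibly, the vector of files written
#' @export
write_cell_image <- function(image, dir, prefix = "cell") {
  stopifnot(inherits(image, "cell_image"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(dir, paste0(prefix, "_", name))
  to16 <- function(m) pmin(pmax(m, 0), 65535) / 65535
  EBImage::writeImage(to16(image$sc35), f("sc35.tiff"), type = "tiff",
                      bits.per.sample = 16L)
  EBImage::writeImage(to16(image$rna), f("rna.tiff"), type = "tiff",
                      bits.per.sample = 16L)
  EBImage::writeImage(image$nucleus_mask * 1, f("nucleus_mask.tiff"),
                      type = "tiff", bits.per.sample = 8L)
  EBImage::writeImage(image$cell_mask * 1, f("cell_mask.tiff"),
                      type = "tiff", bits.per.sample = 8L)
  files <- c(f("sc35.tiff"), f("rna.tiff"), f("nucleus_mask.tiff"),
             f("cell_mask.tiff"))
  if (nrow(image$truth$spots)) {
    utils::write.table(image$truth$spots, f("spots_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f("spots_truth.tsv"))
  }
  invisible(files)
}
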