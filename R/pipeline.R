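#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end synthetic analysis: generator
#' size and effect model, replicate number, expression filter, the
#' contrasts to compute, and the imaging batch. All randomness derives
#' from the single `seed`.
#'
#' @param seed integer seed (mandatory for the stochastic stages)
#' @param n_genes number of non-mitochondrial genes to simulate
#' @param effect an [effect_model()]
#' @param replicates replicates per (fraction, condition)
#' @param fpkm_min mean-FPKM filter threshold (> 0)
#' @param contrasts list of 2-vectors of fraction labels
#' @param kd_conditions knockdown condition labels to contrast vs control
#' @param control control condition label
#' @param prior_count pseudocount for [delta_localization()]
#' @param n_cells number of synthetic cells for the imaging stage
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L, n_genes = 2000,
                            effect = effect_model(), replicates = 3L,
                            fpkm_min = 1,
                            contrasts = list(c("nuclear", "cytoplasmic"),
                                             c("nuclear", "total"),
                                             c("cytoplasmic", "total")),
                            kd_conditions = c("KD_A", "KD_D"),
                            control = "control",
                            prior_count = 4, n_cells = 5L) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("config error: 'seed' is mandatory", call. = FALSE)
  if (fpkm_min <= 0) stop("config error: fpkm_min must be positive", call. = FALSE)
  if (prior_count < 0) stop("config error: prior_count must be >= 0", call. = FALSE)
  if (!length(kd_conditions))
    stop("design error: no knockdown condition configured; need at least ",
         "one condition besides '", control, "'", call. = FALSE)
  stopifnot(inherits(effect, "effect_model"))
  for (ct in contrasts)
    if (length(ct) != 2 || anyNA(fraction_alias[ct]))
      stop("config error: contrast must be two of nuclear/cytoplasmic/total",
           call. = FALSE)
  structure(list(seed = as.integer(seed), n_genes = n_genes, effect = effect,
                 replicates = as.integer(replicates), fpkm_min = fpkm_min,
                 contrasts = contrasts, kd_conditions = kd_conditions,
                 control = control, prior_count = prior_count,
                 n_cells = as.integer(n_cells)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Flat YAML with top-level keys matching [pipeline_config()] arguments;
#' an `effect:` mapping is passed to [effect_model()].
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$effect)) raw$effect <- do.call(effect_model, raw$effect)
  if (!is.null(raw$contrasts)) raw$contrasts <- lapply(raw$contrasts, unlist)
  do.call(pipeline_config, raw)
}

#' Run the full synthetic analysis pipeline
#'
#' Stages: (1) simulate annotation and fractionation counts, (2) extract
#' gene-architecture metrics, (3) compute filtered localization tables for
#' every configured contrast and knockdown, (4) stratified reports
#' (feature correlations, gene-class contrasts, length bins,
#' length-controlled exon analysis), (5) imaging batch (speckle
#' segmentation, enrichment and brightest-speckle Pearson per synthetic
#' cell). Writes TSV outputs plus `manifest.tsv` (stage status, outputs,
#' package version, seed, parameter hash) and `log.txt` (timings). A rerun
#' with the same config writes byte-identical TSVs. Any stage failure
#' aborts with the stage named; outputs of completed stages are preserved.
#'
#' @param config a [pipeline_config()]
#' @param outdir run directory, created if needed
#' @return invisibly, the manifest data.frame
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "log.txt")
  cat("fracseqtools pipeline, seed ", config$seed, "\n", sep = "", file = log_path)
  logmsg <- function(...) cat(..., "\n", sep = "", file = log_path, append = TRUE)

  manifest <- data.frame(stage = character(0), status = character(0),
                         outputs = character(0), stringsAsFactors = FALSE)
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logmsg(sprintf("stage %-10s done in %.1fs", name,
                   proc.time()[["elapsed"]] - t0))
    manifest <<- rbind(manifest, data.frame(
      stage = name, status = "completed",
      outputs = paste(basename(files), collapse = ","),
      stringsAsFactors = FALSE))
  }

  run_stage("simdata", function() {
    state$annotation <- make_toy_annotation(
      default_templates(config$n_genes), seed = config$seed)
    gtf <- file.path(outdir, "annotation.gtf")
    write_gtf(state$annotation, gtf)
    state$experiment <- simulate_fracseq_counts(
      state$annotation, config$effect, replicates = config$replicates,
      seed = config$seed + 1L)
    c(gtf, write_fracseq(state$experiment, outdir))
  })

  run_stage("annofeat", function() {
    state$gm <- gene_metrics(state$annotation)
    write_tsv(state$gm, file.path(outdir, "gene_metrics.tsv"))
  })

  run_stage("locstats", function() {
    counts <- SummarizedExperiment::assay(state$experiment, "counts")
    fpkm <- compute_fpkm(counts, stats::setNames(state$gm$exonic_length,
                                                 state$gm$gene_id))
    state$keep <- filter_genes(fpkm, state$gm, fpkm_min = config$fpkm_min)
    sf <- size_factors(counts)
    files <- character(0)
    state$loc <- list()
    for (ct in config$contrasts) for (kd in config$kd_conditions) {
      loc <- delta_localization(state$experiment, contrast = ct, kd = kd,
                                control = config$control,
                                prior_count = config$prior_count,
                                genes = state$keep, sf = sf)
      key <- paste0(substr(ct[1], 1, 1), substr(ct[2], 1, 1), "_", kd)
      state$loc[[key]] <- loc
      files <- c(files, write_tsv(loc, file.path(
        outdir, paste0("localization_", key, ".tsv"))))
    }
    files
  })

  run_stage("strata", function() {
    loc <- state$loc[[paste0("nc_", config$kd_conditions[1])]]
    gm <- state$gm
    files <- c(
      write_tsv(feature_correlations(loc, gm),
                file.path(outdir, "feature_correlations.tsv")))
    classes <- stats::setNames(gm$gene_class, gm$gene_id)
    classes <- classes[classes %in% c("histone_like", "ribosomal_like",
                                      "lncRNA_single")]
    gc <- group_compare(loc, classes)
    lb <- length_bin_analysis(loc, gm)
    lc <- length_controlled_exon_analysis(loc, gm)
    files <- c(files,
               write_tsv(gc$tests, file.path(outdir, "class_tests.tsv")),
               write_tsv(lb$summary, file.path(outdir, "length_bins.tsv")),
               write_tsv(lb$tests, file.path(outdir, "length_bin_tests.tsv")),
               write_tsv(lc$within_tests,
                         file.path(outdir, "exon_within_window_tests.tsv")),
               write_tsv(lc$between_tests,
                         file.path(outdir, "exon_between_window_tests.tsv")))
    files
  })

  run_stage("imgquant", function() {
    rows <- lapply(seq_len(config$n_cells), function(i) {
      img <- simulate_cell_image(seed = config$seed + 1000L + i)
      seg <- segment_speckles(img$sc35, img$nucleus_mask)
      enr <- speckle_enrichment(img$rna, seg$speckle_mask, img$nucleus_mask,
                                img$cell_mask)
      bp <- brightest_speckle_pearson(img$rna, img$sc35, seg$speckle_mask)
      data.frame(cell = i, area_fraction = seg$area_fraction,
                 spec_over_nuc = enr$spec_over_nuc,
                 spec_over_total = enr$spec_over_total,
                 mean_pearson = bp$mean_r,
                 cyto_total = cyto_total_ratio(img$rna, img$nucleus_mask,
                                               img$cell_mask))
    })
    write_tsv(do.call(rbind, rows), file.path(outdir, "imaging.tsv"))
  })

  params_path <- file.path(outdir, "params.yaml")
  dump <- config
  dump$effect <- unclass(dump$effect)
  yaml::write_yaml(unclass(dump), params_path)
  info <- data.frame(
    stage = c("version", "seed", "param_hash"), status = "info",
    outputs = c(as.character(utils::packageVersion("fracseqtools")),
                as.character(config$seed),
                unname(tools::md5sum(params_path))),
    stringsAsFactors = FALSE)
  manifest <- rbind(manifest, info)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(manifest)
}
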