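delta_column <- function(loc, delta_col) {
  if (!delta_col %in% names(loc))
    stop("localization table has no column '", delta_col, "'", call. = FALSE)
  stats::setNames(loc[[delta_col]], loc$gene_id)
}

group_summary <- function(values, label) {
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  data.frame(group = label, n = length(values), median = q[2],
             q1 = q[1], q3 = q[3], stringsAsFactors = FALSE)
}

#' Correlations between localization change and gene architecture
#'
#' Spearman correlation (with p-value) of the per-gene localization delta
#' against each architecture metric, plus any extra per-gene covariates
#' (e.g. the total-level expression change, to relate level changes to
#' export changes). Computed over the intersection of gene ids, dropping
#' missing metric values per metric.
#'
#' @param loc a [delta_localization()] table
#' @param gm a [gene_metrics()] table
#' @param covariates optional named list of per-gene numeric vectors
#'   (named by gene_id)
#' @param delta_col which delta column to use
#' @param metrics metric columns of `gm` to correlate
#' @return data.frame: metric, n, rho, p
#' @export
feature_correlations <- function(loc, gm, covariates = NULL,
                                 delta_col = "delta_shrunk",
                                 metrics = c("gene_length", "pre_mrna_length",
                                             "exonic_length", "n_exons",
                                             "fraction_intronic",
                                             "exon_density", "utr3_length")) {
  delta <- delta_column(loc, delta_col)
  common <- intersect(names(delta), gm$gene_id)
  if (!length(common))
    stop("no genes shared between localization table and metrics", call. = FALSE)
  gm <- gm[match(common, gm$gene_id), , drop = FALSE]
  delta <- delta[common]
  one <- function(name, values) {
    ok <- is.finite(values) & is.finite(delta)
    ct <- spearman_cor(values[ok], delta[ok])
    data.frame(metric = name, n = ct$n, rho = ct$rho, p = ct$p,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(metrics, function(mcol) one(mcol, gm[[mcol]]))
  for (nm in names(covariates))
    rows[[length(rows) + 1L]] <- one(nm, covariates[[nm]][common])
  do.call(rbind, rows)
}

#' Gene-group contrasts of localization change
#'
#' Compares each gene group against the background (all other genes in the
#' localization table, excluding the group itself) with Mann-Whitney tests,
#' Benjamini-Hochberg-adjusted across the comparison family. Groups may be
#' given either as a named vector (gene_id -> label) or as a named list of
#' gene-id sets; both give identical results on the same partition.
#' Groups with fewer than 2 members are excluded with a warning.
#'
#' @param loc a [delta_localization()] table
#' @param groups named character vector (names = gene ids, values = labels)
#'   or named list of gene-id vectors
#' @param delta_col which delta column to use
#' @return list with `summary` (per-group n/median/quartiles) and `tests`
#'   (group, n_group, n_background, U, p, q, direction)
#' @export
group_compare <- function(loc, groups, delta_col = "delta_shrunk") {
  delta <- delta_column(loc, delta_col)
  if (is.list(groups)) {
    groups <- stats::setNames(
      rep(names(groups), lengths(groups)), unlist(groups, use.names = FALSE))
  }
  groups <- groups[names(groups) %in% names(delta)]
  labels <- sort(unique(groups))
  keep <- labels[vapply(labels, function(l) sum(groups == l) >= 2, logical(1))]
  dropped <- setdiff(labels, keep)
  if (length(dropped))
    warning("excluding group(s) with < 2 members: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (length(keep) < 1)
    stop("need at least one group with >= 2 members", call. = FALSE)

  summ <- do.call(rbind, c(
    lapply(keep, function(l) group_summary(delta[names(groups)[groups == l]], l)),
    list(group_summary(delta, "all"))))
  tests <- do.call(rbind, lapply(keep, function(l) {
    in_group <- names(delta) %in% names(groups)[groups == l]
    mw <- mann_whitney_u(delta[in_group], delta[!in_group])
    data.frame(group = l, n_group = sum(in_group),
               n_background = sum(!in_group), U = mw$U, p = mw$p,
               direction = ifelse(
                 stats::median(delta[in_group]) > stats::median(delta[!in_group]),
                 "higher", "lower"),
               stringsAsFactors = FALSE)
  }))
  tests$q <- bh_adjust(tests$p)
  list(summary = summ, tests = tests[, c("group", "n_group", "n_background",
                                         "U", "p", "q", "direction")])
}

#' Localization change across pre-mRNA length bins
#'
#' Distributions of the localization delta per [assign_length_bin()] bin,
#' with Mann-Whitney tests for adjacent bins and for each bin against all
#' other genes, Benjamini-Hochberg-adjusted across all tests of the
#' section. Empty bins are reported with n = 0 and excluded from testing.
#'
#' @param loc a [delta_localization()] table
#' @param gm a [gene_metrics()] table
#' @param delta_col which delta column to use
#' @return list with `summary` and `tests` data.frames
#' @export
length_bin_analysis <- function(loc, gm, delta_col = "delta_shrunk") {
  delta <- delta_column(loc, delta_col)
  common <- intersect(names(delta), gm$gene_id)
  gm <- gm[match(common, gm$gene_id), , drop = FALSE]
  delta <- delta[common]
  bin <- assign_length_bin(gm$pre_mrna_length)

  summ <- do.call(rbind, lapply(levels(bin), function(b)
    group_summary(delta[bin == b], b)))
  occupied <- levels(bin)[table(bin)[levels(bin)] >= 2]

  tests <- list()
  for (i in seq_len(length(occupied) - 1L)) {       # adjacent occupied bins
    a <- occupied[i]; b <- occupied[i + 1L]
    mw <- mann_whitney_u(delta[bin == a], delta[bin == b])
    tests[[length(tests) + 1L]] <- data.frame(
      comparison = paste(a, "vs", b), type = "adjacent",
      n_x = mw$n_x, n_y = mw$n_y, U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  }
  if (length(occupied) >= 2) {
    for (b in occupied) {                            # each vs all others
      mw <- mann_whitney_u(delta[bin == b], delta[bin != b])
      tests[[length(tests) + 1L]] <- data.frame(
        comparison = paste(b, "vs rest"), type = "vs_rest",
        n_x = mw$n_x, n_y = mw$n_y, U = mw$U, p = mw$p, stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(comparison = character(0), type = character(0),
               n_x = integer(0), n_y = integer(0), U = numeric(0),
               p = numeric(0))
  tests$q <- bh_adjust(tests$p)
  list(summary = summ, tests = tests)
}

#' Exon-count effects at matched pre-mRNA length
#'
#' Within narrow pre-mRNA length windows (defaults 5-6 kb and 20-25 kb),
#' stratifies genes by rounded median exon count and tests all pairwise
#' exon-count contrasts within each window; additionally tests matched
#' exon-count groups *between* windows. Separating the two axes this way
#' distinguishes a pure length effect (between-window differences, no
#' within-window structure) from an exon-count effect. Windows with fewer
#' than 2 occupied exon-count groups are summarized without tests.
#'
#' @param loc a [delta_localization()] table
#' @param gm a [gene_metrics()] table
#' @param windows list of `c(lo, hi)` length windows in nt (left-closed,
#'   right-open)
#' @param delta_col which delta column to use
#' @param min_group minimum genes per exon-count group
#' @return list with `summary`, `within_tests`, `between_tests`
#' @export
length_controlled_exon_analysis <- function(loc, gm,
                                            windows = list(c(5000, 6000),
                                                           c(20000, 25000)),
                                            delta_col = "delta_shrunk",
                                            min_group = 2L) {
  delta <- delta_column(loc, delta_col)
  common <- intersect(names(delta), gm$gene_id)
  gm <- gm[match(common, gm$gene_id), , drop = FALSE]
  delta <- delta[common]
  win_label <- function(w) sprintf("%g-%g kb", w[1] / 1000, w[2] / 1000)

  summ <- list(); within <- list(); groups_by_window <- list()
  for (w in windows) {
    lab <- win_label(w)
    in_w <- gm$pre_mrna_length >= w[1] & gm$pre_mrna_length < w[2]
    ex <- gm$rounded_exon_count[in_w]
    d <- delta[in_w]
    counts <- table(ex)
    occ <- as.integer(names(counts)[counts >= min_group])
    groups_by_window[[lab]] <- lapply(stats::setNames(occ, occ),
                                      function(k) d[ex == k])
    for (k in sort(unique(ex))) {
      s <- group_summary(d[ex == k], sprintf("%s exons=%d", lab, k))
      s$window <- lab; s$exon_count <- k
      summ[[length(summ) + 1L]] <- s
    }
    if (length(occ) >= 2) {
      pairs <- utils::combn(sort(occ), 2)
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1, j]; b <- pairs[2, j]
        mw <- mann_whitney_u(d[ex == a], d[ex == b])
        within[[length(within) + 1L]] <- data.frame(
          window = lab, comparison = sprintf("exons %d vs %d", a, b),
          n_x = mw$n_x, n_y = mw$n_y, U = mw$U, p = mw$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_tests <- data.frame(window = character(0), comparison = character(0),
                            n_x = integer(0), n_y = integer(0), U = numeric(0),
                            p = numeric(0))
  within <- if (length(within)) do.call(rbind, within) else empty_tests
  within$q <- bh_adjust(within$p)

  between <- list()
  if (length(groups_by_window) >= 2) {
    labs <- names(groups_by_window)
    for (j in seq_len(length(labs) - 1L)) for (k in seq.int(j + 1L, length(labs))) {
      shared <- intersect(names(groups_by_window[[j]]), names(groups_by_window[[k]]))
      for (g in shared) {
        mw <- mann_whitney_u(groups_by_window[[j]][[g]],
                             groups_by_window[[k]][[g]])
        between[[length(between) + 1L]] <- data.frame(
          window = paste(labs[j], "vs", labs[k]),
          comparison = sprintf("matched exons=%s", g),
          n_x = mw$n_x, n_y = mw$n_y, U = mw$U, p = mw$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  between <- if (length(between)) do.call(rbind, between) else empty_tests
  between$q <- bh_adjust(between$p)

  summ <- if (length(summ)) do.call(rbind, summ) else
    data.frame(group = character(0), n = integer(0), median = numeric(0),
               q1 = numeric(0), q3 = numeric(0), window = character(0),
               exon_count = integer(0))
  list(summary = summ, within_tests = within, between_tests = between)
}
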