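# all permutations of 1..n as an (n! x n) integer matrix; n <= 8 here
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# mid-ranks
midrank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with p-value
#'
#' rho is the Pearson correlation of mid-ranks. The p-value is exact (full
#' permutation enumeration, two-sided) for n <= 8, and otherwise uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return list with elements `rho`, `p`, `n`, `method`
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n)
    stop("spearman_cor needs equal-length vectors with n >= 3", call. = FALSE)
  rx <- midrank(x); ry <- midrank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: constant input vector", call. = FALSE)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

#' Mann-Whitney U test
#'
#' U counts, over all (x_i, y_j) pairs, the times x_i exceeds y_j (ties
#' count one half), computed via mid-ranks. The two-sided p-value is exact
#' by enumeration of all C(nx+ny, nx) group assignments when the combined
#' sample size is at most 12 and there are no ties
#' (`p = min(1, 2 * min(P(U <= u), P(U >= u)))`), and otherwise uses the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors, both non-empty
#' @return list with elements `U`, `p`, `n_x`, `n_y`, `method`
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0)
    stop("mann_whitney_u needs two non-empty samples", call. = FALSE)
  combined <- c(x, y)
  r <- midrank(combined)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  N <- nx + ny
  has_ties <- anyDuplicated(combined) > 0

  if (N <= 12 && !has_ties) {
    subsets <- utils::combn(N, nx)
    u_all <- colSums(matrix(r[subsets], nrow = nx)) - nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= U + 1e-9), mean(u_all >= U - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(combined)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal approximation"
  }
  list(U = U, p = p, n_x = nx, n_y = ny, method = method)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#' `NA` p-values propagate as `NA` and do not count toward m.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`
#' @return vector of q-values, same order as input
#' @export
bh_adjust <- function(pvals) {
  out <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0) return(out)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / seq.int(m, 1)))
  out[ok][o] <- q
  out
}
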