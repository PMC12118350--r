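#' Per-block f2 statistics
#'
#' Computes unbiased f2 estimates for every pair of the requested groups in
#' physical genome blocks (default 4 Mb per chromosome; a final partial
#' window is kept as a smaller block). With `maxmiss = 0` only sites with at
#' least one called chromosome in *every* group are used, so all pairs share
#' one block structure. The finite-sample heterozygosity correction uses
#' allele counts; when `adjust_pseudohaploid` is `TRUE`, groups without any
#' heterozygous genotype are treated as carrying one chromosome per
#' individual, which keeps f2 unbiased for pseudohaploid data.
#'
#' @param data A [snp_dataset()].
#' @param pops Groups to include (default: all groups in `data`).
#' @param blgsize Block size in bp (default 4e6).
#' @param maxmiss Maximum tolerated fraction of groups without data at a
#'   site; only 0 (complete group-level data) is supported.
#' @param adjust_pseudohaploid Adjust allele counts for pseudohaploid groups.
#' @return A `block_fstats` object: list with `pops`, `pairs` (tibble `p1`,
#'   `p2`), `f2` (matrix blocks x pairs of per-block mean f2), `weights`
#'   (per-block usable-site counts), `blocks` (tibble `chrom`, `start`).
#' @export
compute_f2_blocks <- function(data, pops = dataset_groups(data),
                              blgsize = 4e6, maxmiss = 0,
                              adjust_pseudohaploid = TRUE) {
  stopifnot(inherits(data, "snp_dataset"), maxmiss == 0)
  if (length(pops) < 2) stop("need at least two groups for f2")
  cnt <- .group_counts(data, pops, adjust_pseudohaploid)
  usable <- rowSums(cnt$n < 1) == 0
  if (!any(usable)) stop("no usable sites: every site lacks data in some group")

  block <- .block_index(data$snp[usable, ], blgsize)
  p <- cnt$a[usable, , drop = FALSE] / cnt$n[usable, , drop = FALSE]
  corr <- .het_correction(cnt$a[usable, , drop = FALSE],
                          cnt$n[usable, , drop = FALSE])

  pairs <- tibble::as_tibble(t(utils::combn(pops, 2)), .name_repair = ~ c("p1", "p2"))
  nb <- max(block$idx)
  f2 <- matrix(0, nb, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- match(pairs$p1[k], pops); j <- match(pairs$p2[k], pops)
    v <- (p[, i] - p[, j])^2 - corr[, i] - corr[, j]
    f2[, k] <- rowsum(v, block$idx)[, 1] / tabulate(block$idx, nb)
  }
  colnames(f2) <- paste(pairs$p1, pairs$p2, sep = "|")
  structure(
    list(pops = pops, pairs = pairs, f2 = f2,
         weights = tabulate(block$idx, nb), blocks = block$blocks,
         blgsize = blgsize),
    class = "block_fstats"
  )
}

#' @export
print.block_fstats <- function(x, ...) {
  cat(sprintf(
    "<block_fstats> %d groups, %d blocks (%d sites), block size %.3g bp\n",
    length(x$pops), length(x$weights), sum(x$weights), x$blgsize
  ))
  invisible(x)
}

# allele counts per site x group: `a` = alternative-allele count, `n` =
# called chromosomes; pseudohaploid groups (optionally) counted one
# chromosome per individual
.group_counts <- function(data, pops, adjust_pseudohaploid = TRUE) {
  a <- matrix(0, nrow(data$geno), length(pops))
  n <- matrix(0, nrow(data$geno), length(pops))
  for (k in seq_along(pops)) {
    sub <- data$geno[, data$ind$group == pops[k], drop = FALSE]
    if (ncol(sub) == 0) stop("group absent from dataset: ", pops[k])
    pseudo <- adjust_pseudohaploid && !any(sub == 1L, na.rm = TRUE)
    if (pseudo) {
      a[, k] <- rowSums(sub, na.rm = TRUE) / 2
      n[, k] <- rowSums(!is.na(sub))
    } else {
      a[, k] <- rowSums(sub, na.rm = TRUE)
      n[, k] <- 2 * rowSums(!is.na(sub))
    }
  }
  list(a = a, n = n)
}

# unbiased estimate of p(1-p)/n per site x group (0 when n < 2)
.het_correction <- function(a, n) {
  h <- a * (n - a) / pmax(n * (n - 1), 1)
  out <- h / pmax(n, 1)
  out[n < 2] <- 0
  out
}

# genome block index: consecutive blgsize windows within each chromosome
.block_index <- function(snp, blgsize) {
  key <- paste(snp$chrom, floor((snp$pos - 1) / blgsize), sep = ":")
  ord <- unique(key)
  idx <- match(key, ord)
  parts <- do.call(rbind, strsplit(ord, ":", fixed = TRUE))
  blocks <- tibble::tibble(
    chrom = parts[, 1],
    start = as.numeric(parts[, 2]) * blgsize + 1
  )
  list(idx = idx, blocks = blocks)
}

# per-block series of an f-statistic as a linear combination of f2 columns
.fstat_block_series <- function(blocks, type, pops) {
  col <- function(x, y) {
    if (x == y) return(rep(0, nrow(blocks$f2)))
    k <- which((blocks$pairs$p1 == x & blocks$pairs$p2 == y) |
                 (blocks$pairs$p1 == y & blocks$pairs$p2 == x))
    if (!length(k)) stop("group pair not present in f2 blocks: ", x, ", ", y)
    blocks$f2[, k]
  }
  switch(type,
    f2 = col(pops[1], pops[2]),
    f3 = (col(pops[1], pops[2]) + col(pops[1], pops[3]) -
            col(pops[2], pops[3])) / 2,
    f4 = (col(pops[1], pops[4]) + col(pops[2], pops[3]) -
            col(pops[1], pops[3]) - col(pops[2], pops[4])) / 2,
    stop("unknown statistic type: ", type)
  )
}

#' f2, f3 and f4 statistics with block-jackknife errors
#'
#' Evaluates an f-statistic as a linear combination of per-block f2 values
#' (f3(T;A,B) = (f2(T,A)+f2(T,B)-f2(A,B))/2; f4(A,B;C,D) =
#' (f2(A,D)+f2(B,C)-f2(A,C)-f2(B,D))/2) and returns the weighted
#' block-jackknife estimate and standard error.
#'
#' @param blocks A [compute_f2_blocks()] object.
#' @param type `"f2"`, `"f3"` or `"f4"`.
#' @param pops Group names: 2 for f2, 3 for f3 (target first), 4 for f4.
#' @return A one-row tibble: `statistic`, `estimate`, `se`, `z`, `n_blocks`,
#'   `n_snps`.
#' @export
f_stat <- function(blocks, type = c("f2", "f3", "f4"), pops) {
  stopifnot(inherits(blocks, "block_fstats"))
  type <- match.arg(type)
  arity <- c(f2 = 2, f3 = 3, f4 = 4)[[type]]
  if (length(pops) != arity) stop(type, " takes ", arity, " groups")
  series <- .fstat_block_series(blocks, type, pops)
  jk <- jackknife_estimate(series, blocks$weights)
  label <- switch(type,
    f2 = sprintf("f2(%s, %s)", pops[1], pops[2]),
    f3 = sprintf("f3(%s; %s, %s)", pops[1], pops[2], pops[3]),
    f4 = sprintf("f4(%s, %s; %s, %s)", pops[1], pops[2], pops[3], pops[4])
  )
  tibble::tibble(
    statistic = label, estimate = jk$estimate, se = jk$se,
    z = if (jk$se > 0) jk$estimate / jk$se else NA_real_,
    n_blocks = length(blocks$weights), n_snps = sum(blocks$weights)
  )
}

#' f4 computed directly off genotypes with per-quadruplet site selection
#'
#' In "allsnps" mode missing data are removed per population quadruplet: a
#' site is used iff all four groups have at least one called chromosome
#' there. The per-site statistic is the product of allele-frequency
#' differences, with heterozygosity corrections added for any repeated
#' group, and the block jackknife runs over those sites.
#'
#' @param data A [snp_dataset()].
#' @param quad Character vector of 4 group names (A, B; C, D).
#' @param blgsize Block size in bp.
#' @param adjust_pseudohaploid See [compute_f2_blocks()].
#' @return A one-row tibble as in [f_stat()].
#' @export
f4_allsnps <- function(data, quad, blgsize = 4e6, adjust_pseudohaploid = TRUE) {
  ser <- .f4_allsnps_series(data, quad, blgsize, adjust_pseudohaploid)
  jk <- jackknife_estimate(ser$series, ser$weights)
  tibble::tibble(
    statistic = sprintf("f4(%s, %s; %s, %s)", quad[1], quad[2], quad[3], quad[4]),
    estimate = jk$estimate, se = jk$se,
    z = if (jk$se > 0) jk$estimate / jk$se else NA_real_,
    n_blocks = length(ser$weights), n_snps = sum(ser$weights)
  )
}

.f4_allsnps_series <- function(data, quad, blgsize = 4e6,
                               adjust_pseudohaploid = TRUE) {
  stopifnot(inherits(data, "snp_dataset"), length(quad) == 4)
  pops <- unique(quad)
  cnt <- .group_counts(data, pops, adjust_pseudohaploid)
  usable <- rowSums(cnt$n < 1) == 0
  if (!any(usable)) {
    stop("no overlapping sites for quadruplet (", paste(quad, collapse = ", "), ")")
  }
  a <- cnt$a[usable, , drop = FALSE]; n <- cnt$n[usable, , drop = FALSE]
  p <- a / n
  corr <- .het_correction(a, n)
  i <- match(quad, pops)
  v <- (p[, i[1]] - p[, i[2]]) * (p[, i[3]] - p[, i[4]])
  # unbiasedness corrections for repeated groups
  if (quad[1] == quad[3]) v <- v - corr[, i[1]]
  if (quad[2] == quad[4]) v <- v - corr[, i[2]]
  if (quad[1] == quad[4]) v <- v + corr[, i[1]]
  if (quad[2] == quad[3]) v <- v + corr[, i[2]]
  block <- .block_index(data$snp[usable, ], blgsize)
  nb <- max(block$idx)
  list(
    series = rowsum(v, block$idx)[, 1] / tabulate(block$idx, nb),
    weights = tabulate(block$idx, nb)
  )
}

#' Weighted delete-one-block jackknife
#'
#' Given per-block values of a statistic and non-negative block weights
#' (usable-site counts), returns the weighted jackknife estimate and
#' standard error (Busing-style weighting: pseudovalues are formed with
#' per-block inverse leave-out fractions).
#'
#' @param block_values Numeric vector of per-block statistic values.
#' @param block_weights Non-negative weights, same length.
#' @return List with `estimate` and `se`.
#' @export
jackknife_estimate <- function(block_values, block_weights) {
  keep <- block_weights > 0
  v <- block_values[keep]; w <- block_weights[keep]
  g <- length(v)
  if (g < 2) stop("jackknife SE needs at least 2 non-empty blocks")
  W <- sum(w)
  theta <- sum(w * v) / W
  loo <- (W * theta - w * v) / (W - w)       # delete-one estimates
  h <- W / w
  theta_j <- g * theta - sum((1 - w / W) * loo)
  tau <- h * theta - (h - 1) * loo
  var_j <- mean((tau - theta_j)^2 / (h - 1))
  list(estimate = theta, se = sqrt(var_j))
}

# jackknife mean vector and covariance for a blocks x p matrix of per-block
# statistic values (same weighting as jackknife_estimate, element-wise)
.jackknife_cov <- function(V, weights) {
  keep <- weights > 0
  V <- V[keep, , drop = FALSE]; w <- weights[keep]
  g <- nrow(V)
  if (g < 2) stop("jackknife covariance needs at least 2 non-empty blocks")
  W <- sum(w)
  theta <- colSums(V * w) / W
  loo <- (matrix(theta, g, ncol(V), byrow = TRUE) * W - V * w) / (W - w)
  h <- W / w
  theta_j <- g * theta - colSums((1 - w / W) * loo)
  tau <- matrix(theta, g, ncol(V), byrow = TRUE) * h - loo * (h - 1)
  centred <- sweep(tau, 2, theta_j) / sqrt(h - 1)
  list(estimate = theta, cov = crossprod(centred) / g)
}

#' Pairwise Hudson FST matrix
#'
#' Hudson's FST estimator as a ratio of averages across sites: per site the
#' numerator is \eqn{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#' and the denominator \eqn{p_1(1-p_2) + p_2(1-p_1)}; both are summed over
#' sites before taking the ratio. Sites where a group has fewer than two
#' called chromosomes contribute nothing to that pair.
#'
#' @param data A [snp_dataset()].
#' @param slice Optional sampling date; keeps only individuals with that
#'   `date` in the individual table.
#' @param groups Optional explicit group subset (applied after `slice`).
#' @return Symmetric FST matrix with zero diagonal, dimnames = group labels.
#' @export
fst_matrix <- function(data, slice = NULL, groups = NULL) {
  stopifnot(inherits(data, "snp_dataset"))
  if (!is.null(slice)) {
    if (is.null(data$ind$date)) stop("dataset has no sampling dates")
    keep <- data$ind$date == slice
    data <- snp_dataset(data$geno[, keep, drop = FALSE], data$snp,
                        data$ind[keep, ], data$ploidy)
  }
  pops <- if (is.null(groups)) dataset_groups(data) else groups
  if (length(pops) < 2) stop("need at least two groups in the slice")
  cnt <- .group_counts(data, pops, adjust_pseudohaploid = TRUE)
  a <- cnt$a; n <- cnt$n
  ok <- n >= 2
  p <- ifelse(ok, a / pmax(n, 1), NA_real_)

  if (!anyNA(p)) {
    # complete data: all pair sums via cross-products
    ssum <- colSums(p)
    s2 <- crossprod(p)                       # sum p_i p_j
    hterm <- colSums(p * (1 - p) / (n - 1))
    num <- matrix(diag(s2), length(pops), length(pops)) +
      matrix(diag(s2), length(pops), length(pops), byrow = TRUE) -
      2 * s2 - outer(hterm, hterm, "+")
    den <- outer(ssum, ssum, "+") - 2 * s2
    fst <- num / den
  } else {
    fst <- matrix(NA_real_, length(pops), length(pops))
    for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
      m <- ok[, i] & ok[, j]
      pa <- a[m, i] / n[m, i]; pb <- a[m, j] / n[m, j]
      num <- sum((pa - pb)^2 - pa * (1 - pa) / (n[m, i] - 1) -
                   pb * (1 - pb) / (n[m, j] - 1))
      den <- sum(pa * (1 - pb) + pb * (1 - pa))
      fst[i, j] <- fst[j, i] <- if (den > 0) num / den else NA_real_
    }
  }
  diag(fst) <- 0
  dimnames(fst) <- list(pops, pops)
  fst
}
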