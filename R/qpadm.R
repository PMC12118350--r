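#' f4 matrix machinery shared by qpWave and qpAdm
#'
#' Builds the (L-1) x (R-1) matrix of f4(left1, left_i; right1, right_j)
#' statistics per genome block, either as linear combinations of
#' precomputed per-block f2 values ("from-f2" mode, a [compute_f2_blocks()]
#' object) or directly off genotypes with per-quadruplet site selection
#' ("allsnps" mode, a [snp_dataset()]). The basis choice (first left group,
#' first right group) is fixed; results are basis-invariant up to numerical
#' tolerance.
#'
#' @keywords internal
#' @noRd
.f4_matrix <- function(fsource, left, right, blgsize = 4e6,
                       adjust_pseudohaploid = TRUE) {
  a <- length(left) - 1; b <- length(right) - 1
  stopifnot(a >= 1, b >= 1)
  if (length(intersect(left, right))) stop("left and right sets must be disjoint")
  if (inherits(fsource, "block_fstats")) {
    nb <- length(fsource$weights)
    V <- matrix(0, nb, a * b)
    for (j in seq_len(b)) for (i in seq_len(a)) {
      V[, (j - 1) * a + i] <- .fstat_block_series(
        fsource, "f4", c(left[1], left[i + 1], right[1], right[j + 1])
      )
    }
    wts <- matrix(fsource$weights, nb, a * b)
  } else if (inherits(fsource, "snp_dataset")) {
    blocks_all <- .block_index(fsource$snp, blgsize)
    nb <- max(blocks_all$idx)
    V <- matrix(0, nb, a * b)
    wts <- matrix(0, nb, a * b)
    for (j in seq_len(b)) for (i in seq_len(a)) {
      quad <- c(left[1], left[i + 1], right[1], right[j + 1])
      cnt <- .group_counts(fsource, unique(quad), adjust_pseudohaploid)
      usable <- rowSums(cnt$n < 1) == 0
      if (!any(usable)) {
        stop("no overlapping sites for quadruplet (",
             paste(quad, collapse = ", "), ")")
      }
      p <- cnt$a[usable, , drop = FALSE] / cnt$n[usable, , drop = FALSE]
      ix <- match(quad, unique(quad))
      v <- (p[, ix[1]] - p[, ix[2]]) * (p[, ix[3]] - p[, ix[4]])
      bidx <- blocks_all$idx[usable]
      cnt <- tabulate(bidx, nb)
      sums <- rowsum(v, bidx)[, 1][match(seq_len(nb), sort(unique(bidx)))]
      sums[is.na(sums)] <- 0
      V[, (j - 1) * a + i] <- sums / pmax(cnt, 1)
      wts[, (j - 1) * a + i] <- cnt
    }
  } else {
    stop("fsource must be a block_fstats or snp_dataset object")
  }
  keep <- rowSums(wts) > 0
  list(V = V[keep, , drop = FALSE], wts = wts[keep, , drop = FALSE],
       dims = c(a, b))
}

# weighted estimates, common-weight jackknife covariance, and the delete-one
# leave-out matrix needed for weight SEs
.f4_moments <- function(fm, ridge = 1e-5, fudge_twice = FALSE) {
  w <- rowMeans(fm$wts)
  jk <- .jackknife_cov(fm$V, w)
  Q <- jk$cov
  lambda <- ridge * mean(diag(Q))
  Q <- Q + diag(lambda, nrow(Q))
  if (fudge_twice) Q <- Q + diag(lambda, nrow(Q))
  Qi <- tryCatch(solve(Q), error = function(e) {
    stop("covariance regularization failed: ", conditionMessage(e))
  })
  list(x = jk$estimate, Qi = Qi, w = w, V = fm$V, dims = fm$dims)
}

# alternating generalized least squares fit of the best rank-r matrix;
# returns the minimized quadratic form and the factor A (a x r)
.rank_fit <- function(x, Qi, dims, r, tol = 1e-10, max_iter = 200) {
  a <- dims[1]; b <- dims[2]
  if (r == 0) {
    return(list(stat = drop(t(x) %*% Qi %*% x), A = matrix(0, a, 0)))
  }
  X <- matrix(x, a, b)
  sv <- svd(X)
  A <- sv$u[, seq_len(r), drop = FALSE]
  B <- diag(sv$d[seq_len(r)], r) %*% t(sv$v[, seq_len(r), drop = FALSE])
  obj <- Inf
  for (it in seq_len(max_iter)) {
    # solve for B given A
    MB <- diag(b) %x% A
    B <- matrix(solve(t(MB) %*% Qi %*% MB, t(MB) %*% Qi %*% x), r, b)
    # solve for A given B
    MA <- t(B) %x% diag(a)
    A <- matrix(solve(t(MA) %*% Qi %*% MA, t(MA) %*% Qi %*% x), a, r)
    res <- x - as.vector(A %*% B)
    new_obj <- drop(t(res) %*% Qi %*% res)
    if (is.finite(obj) && abs(obj - new_obj) <= tol * max(1, abs(obj))) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  list(stat = obj, A = A)
}

#' qpWave rank test
#'
#' Tests whether the matrix of f4 statistics connecting the "left" and
#' "right" population sets is consistent with rank `rank`, i.e. with at most
#' `rank + 1` independent gene-flow streams. The best rank-`rank` matrix is
#' fitted by alternating generalized least squares under the block-jackknife
#' covariance of the f4 matrix; the minimized quadratic form is compared to
#' a chi-square distribution with (L-1-rank)(R-1-rank) degrees of freedom.
#'
#' @param left,right Disjoint character vectors of group labels (L >= 2,
#'   R >= 2).
#' @param rank Tested rank, 0 <= rank < min(L-1, R-1).
#' @param fsource A [compute_f2_blocks()] object, or a [snp_dataset()] for
#'   "allsnps" mode.
#' @param blgsize Block size (allsnps mode).
#' @param fudge_twice Apply the ridge regularization of the covariance twice
#'   (compatibility flag; default FALSE).
#' @return A `qpwave_result`: list with `left`, `right`, `rank`, `chisq`,
#'   `dof`, `p_value`, `n_snps`, `n_blocks`.
#' @export
qpwave_test <- function(left, right, rank = 0, fsource, blgsize = 4e6,
                        fudge_twice = FALSE) {
  L <- length(left); R <- length(right)
  stopifnot(L >= 2, R >= 2)
  if (rank < 0 || rank > min(L - 1, R - 1)) {
    stop("rank must satisfy 0 <= rank <= min(L-1, R-1)")
  }
  fm <- .f4_matrix(fsource, left, right, blgsize)
  mo <- .f4_moments(fm, fudge_twice = fudge_twice)
  fit <- .rank_fit(mo$x, mo$Qi, mo$dims, min(rank, mo$dims[1], mo$dims[2]))
  dof <- (L - 1 - rank) * (R - 1 - rank)
  structure(
    list(left = left, right = right, rank = rank,
         chisq = fit$stat, dof = dof,
         p_value = if (dof <= 0) 1 else
           stats::pchisq(fit$stat, dof, lower.tail = FALSE),
         n_snps = round(mean(colSums(fm$wts))), n_blocks = nrow(fm$V)),
    class = "qpwave_result"
  )
}

#' @export
print.qpwave_result <- function(x, ...) {
  cat(sprintf(
    "<qpwave_result> rank %d: chisq = %.3f, dof = %d, P = %.4g (%d blocks)\n",
    x$rank, x$chisq, x$dof, x$p_value, x$n_blocks
  ))
  invisible(x)
}

#' Fit a qpAdm admixture model
#'
#' Models the target as a mixture of `sources` against the `right` reference
#' set: the n x (R-1) matrix of f4(target, source_k; right_1, right_j)
#' statistics is fitted at rank n-1 under its block-jackknife covariance;
#' admixture weights are the left null vector of the fitted matrix,
#' normalized to sum to 1 (weights are *not* constrained to [0, 1]); the
#' model P-value is the qpWave rank test for left = target + sources at
#' rank n-1 (dof = R - n); weight standard errors come from delete-one-block
#' refits.
#'
#' @param target Target group label.
#' @param sources Character vector of proxy sources (n >= 1).
#' @param right Character vector of references (R >= n + 2 for a testable
#'   model).
#' @inheritParams qpwave_test
#' @return A `qpadm_result`: list with `target`, `sources`, `right`,
#'   `weights`, `se`, `p_value`, `chisq`, `dof`, `n_snps`, `n_blocks`,
#'   `maxdiff` (max |weight - 1/n|), `maxse`.
#' @export
fit_qpadm <- function(target, sources, right, fsource, blgsize = 4e6,
                      fudge_twice = FALSE) {
  n <- length(sources); R <- length(right)
  stopifnot(n >= 1)
  if (target %in% c(sources, right)) stop("target must not appear among sources or right groups")
  if (R < n + 2) stop("need at least n + 2 right groups for a testable model (dof = R - n)")
  fm <- .f4_matrix(fsource, c(target, sources), right, blgsize)
  mo <- .f4_moments(fm, fudge_twice = fudge_twice)
  r <- n - 1
  fit <- .rank_fit(mo$x, mo$Qi, mo$dims, r)
  dof <- R - n
  weights <- .null_weights(fit$A, mo$x, mo$dims)

  # delete-one-block refits for weight SEs; the jackknife covariance is
  # recomputed for each deletion (holding it fixed understates the weight
  # variance noticeably)
  W <- sum(mo$w)
  g <- length(mo$w)
  loo_w <- matrix(NA_real_, g, n)
  ridge <- 1e-5
  for (bl in seq_len(g)) {
    jk_b <- .jackknife_cov(mo$V[-bl, , drop = FALSE], mo$w[-bl])
    lambda <- ridge * mean(diag(jk_b$cov))
    Q_b <- jk_b$cov + diag(lambda * if (fudge_twice) 2 else 1, nrow(jk_b$cov))
    Qi_b <- solve(Q_b)
    x_b <- jk_b$estimate
    fit_b <- .rank_fit(x_b, Qi_b, mo$dims, r)
    loo_w[bl, ] <- .null_weights(fit_b$A, x_b, mo$dims)
  }
  h <- W / mo$w
  theta_j <- g * weights - colSums((1 - mo$w / W) * loo_w)
  tau <- matrix(weights, g, n, byrow = TRUE) * h - loo_w * (h - 1)
  se <- sqrt(colMeans(sweep(tau, 2, theta_j)^2 / (h - 1)))

  structure(
    list(target = target, sources = sources, right = right,
         weights = stats::setNames(weights, sources),
         se = stats::setNames(se, sources),
         chisq = fit$stat, dof = dof,
         p_value = stats::pchisq(fit$stat, dof, lower.tail = FALSE),
         n_snps = round(mean(colSums(fm$wts))), n_blocks = g,
         maxdiff = max(abs(weights - 1 / n)), maxse = max(se)),
    class = "qpadm_result"
  )
}

# admixture weights: the left null vector of the fitted rank-(n-1) matrix,
# normalized to sum to 1; for n = 1 the weight is 1 by construction
.null_weights <- function(A, x, dims) {
  n <- dims[1]
  if (n == 1) return(1)
  sv <- svd(A, nu = n)
  w <- sv$u[, n]
  if (ncol(A) >= n) stop("degenerate fit: fitted matrix has no left null vector")
  s <- sum(w)
  if (abs(s) < 1e-12) stop("degenerate fit: null vector weights sum to 0")
  w / s
}

#' @export
print.qpadm_result <- function(x, ...) {
  cat(sprintf(
    "<qpadm_result> %s = %s\n  P = %.4g (dof %d), weights: %s\n",
    x$target, paste(x$sources, collapse = " + "),
    x$p_value, x$dof,
    paste(sprintf("%s %.3f (SE %.3f)", x$sources, x$weights, x$se),
          collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.qpadm_result <- function(x, ...) {
  tibble::tibble(
    target = x$target, source = x$sources,
    estimate = unname(x$weights), std.error = unname(x$se)
  )
}

#' @export
glance.qpadm_result <- function(x, ...) {
  tibble::tibble(
    target = x$target, n_sources = length(x$sources),
    p.value = x$p_value, statistic = x$chisq, dof = x$dof,
    maxdiff = x$maxdiff, maxse = x$maxse,
    n_snps = x$n_snps, n_blocks = x$n_blocks
  )
}

#' @export
tidy.qpwave_result <- function(x, ...) {
  tibble::tibble(
    rank = x$rank, statistic = x$chisq, dof = x$dof, p.value = x$p_value,
    n_snps = x$n_snps, n_blocks = x$n_blocks
  )
}

#' Trailing (simpler) models of an n-way model
#'
#' All simpler models composed of the model's own target and/or proxy
#' sources: the target, or the first proxy source, modelled as a mixture of
#' 1 to n-1 of the remaining proxy sources. These are the models some
#' composite feasibility criteria require to be rejected.
#'
#' @param target Target group label.
#' @param sources Proxy sources of the n-way model (n >= 2 for a non-empty
#'   result; n = 1 returns an empty list).
#' @return Tibble with `target`, `sources` (list column), `n`.
#' @export
trailing_models <- function(target, sources) {
  n <- length(sources)
  out <- tibble::tibble(target = character(), sources = list(), n = integer())
  if (n < 2) return(out)
  specs <- list(list(head = target, rest = sources),
                list(head = sources[1], rest = sources[-1]))
  for (sp in specs) {
    for (k in seq_len(min(n - 1, length(sp$rest)))) {
      combos <- utils::combn(sp$rest, k, simplify = FALSE)
      out <- dplyr::bind_rows(out, tibble::tibble(
        target = sp$head, sources = combos, n = k
      ))
    }
  }
  out
}
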