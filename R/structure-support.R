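#' LD pruning by windowed r-squared
#'
#' Slides a window of `window` SNPs in steps of `step` SNPs along each
#' chromosome and greedily removes one SNP of every pair whose genotype
#' correlation satisfies r^2 > `r2` (the later SNP of the pair is dropped),
#' mirroring the common `--indep-pairwise` procedure.
#'
#' @param data A [snp_dataset()].
#' @param window Window size in SNPs (default 2000).
#' @param step Window step in SNPs (default 100).
#' @param r2 r-squared threshold (default 0.5).
#' @return Integer vector of retained site indices.
#' @export
ld_prune <- function(data, window = 2000, step = 100, r2 = 0.5) {
  stopifnot(inherits(data, "snp_dataset"))
  g <- data$geno
  keep <- rep(TRUE, nrow(g))
  for (ch in unique(data$snp$chrom)) {
    sites <- which(data$snp$chrom == ch)
    starts <- seq(1, max(1, length(sites) - 1), by = step)
    for (s in starts) {
      win <- sites[s:min(s + window - 1, length(sites))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      gw <- g[win, , drop = FALSE]
      gw <- t(gw)
      storage.mode(gw) <- "double"
      cc <- suppressWarnings(stats::cor(gw, use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      for (i in seq_len(ncol(cc) - 1)) {
        if (!keep[win[i]]) next
        hits <- which(cc[i, ] ^ 2 > r2)
        hits <- hits[hits > i & keep[win[hits]]]
        keep[win[hits]] <- FALSE
      }
      if (s + window - 1 >= length(sites)) break
    }
  }
  which(keep)
}

#' LD-pruned principal component analysis of genotypes
#'
#' Prunes sites with [ld_prune()], drops monomorphic sites, mean-centres
#' and variance-standardizes genotypes per site (missing genotypes imputed
#' at the site mean), and returns the leading principal components per
#' individual.
#'
#' @param data A [snp_dataset()].
#' @param n_pc Number of components (default 10).
#' @param window,step,r2 Pruning parameters (see [ld_prune()]).
#' @return Tibble with `id`, `group` and `PC1` ... `PCn`.
#' @export
ld_prune_and_pca <- function(data, n_pc = 10, window = 2000, step = 100,
                             r2 = 0.5) {
  sites <- ld_prune(data, window, step, r2)
  g <- data$geno[sites, , drop = FALSE]
  storage.mode(g) <- "double"
  mu <- rowMeans(g, na.rm = TRUE)
  miss <- is.na(g)
  if (any(miss)) g[miss] <- matrix(mu, nrow(g), ncol(g))[miss]
  v <- apply(g, 1, stats::var)
  poly <- v > 0
  g <- (g[poly, , drop = FALSE] - mu[poly]) / sqrt(v[poly])
  if (nrow(g) < n_pc) stop("fewer polymorphic pruned sites than components")
  pc <- stats::prcomp(t(g), center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  dplyr::bind_cols(
    tibble::tibble(id = data$ind$id, group = data$ind$group),
    tibble::as_tibble(scores)
  )
}

#' Does a 3D PC configuration support a 2-way admixture model?
#'
#' Supported when the target-group centroid projects onto the segment
#' connecting the two source-group centroids in PC1-3 space and lies within
#' `max_diameters` target-cluster diameters (maximal within-target pairwise
#' distance; 0 for a singleton target, which then must lie on the segment)
#' of that segment.
#'
#' @param pcs Tibble from [ld_prune_and_pca()] (needs `group` and PC1-3).
#' @param target,source1,source2 Group labels.
#' @param max_diameters Allowed distance in target-cluster diameters
#'   (default 3).
#' @return Logical.
#' @export
pca_support <- function(pcs, target, source1, source2, max_diameters = 3) {
  need <- c("PC1", "PC2", "PC3")
  stopifnot(all(need %in% names(pcs)))
  pts <- function(gr) as.matrix(pcs[pcs$group == gr, need])
  tg <- pts(target); s1 <- pts(source1); s2 <- pts(source2)
  if (!nrow(tg) || !nrow(s1) || !nrow(s2)) stop("group missing from PC table")
  ct <- colMeans(tg); c1 <- colMeans(s1); c2 <- colMeans(s2)
  diam <- if (nrow(tg) > 1) max(stats::dist(tg)) else 0
  seg <- c2 - c1
  seg_len2 <- sum(seg^2)
  if (seg_len2 == 0) return(FALSE)
  tproj <- sum((ct - c1) * seg) / seg_len2
  if (tproj < 0 || tproj > 1) return(FALSE)
  off <- sqrt(sum((ct - (c1 + tproj * seg))^2))
  off <= max_diameters * diam
}

#' Does an unsupervised clustering (ADMIXTURE-style) result support a 2-way
#' model?
#'
#' Decision rules applied per ancestry-component number K, any single K
#' sufficing:
#' \enumerate{
#'   \item at least 5 of the target individuals (or half, for smaller
#'     groups) are modelled as mixtures of >= 2 components with a minor
#'     component above 2\%;
#'   \item some component A is shared between the target and >= 5
#'     individuals of source 1 but not source 2, and some component B
#'     between the target and source 2 but not source 1 (or both components
#'     occur in both sources in clearly different proportions);
#'   \item a single component shared by the target with both sources is not
#'     evidence;
#'   \item components in the target absent from both sources are ignored;
#'   \item components in a source absent from the target are ignored.
#' }
#'
#' @param q_matrices Named list (per K) of numeric matrices: individuals x
#'   components, rows summing to 1, with rownames = individual ids.
#' @param groups Named character vector mapping individual id to group.
#' @param target,source1,source2 Group labels.
#' @param min_minor Minor-component threshold (default 0.02).
#' @return Logical.
#' @export
admixture_support <- function(q_matrices, groups, target, source1, source2,
                              min_minor = 0.02) {
  for (Q in q_matrices) {
    ids <- rownames(Q)
    if (is.null(ids)) stop("Q matrix needs individual ids as rownames")
    gr <- groups[ids]
    if (anyNA(gr)) stop("individuals missing from the group map")
    qt <- Q[gr == target, , drop = FALSE]
    q1 <- Q[gr == source1, , drop = FALSE]
    q2 <- Q[gr == source2, , drop = FALSE]
    if (!nrow(qt) || !nrow(q1) || !nrow(q2)) stop("group missing from Q matrix")

    ## rule 1: enough target individuals modelled as true mixtures
    mixed <- rowSums(qt > min_minor) >= 2
    if (sum(mixed) < min(5, ceiling(nrow(qt) / 2))) next

    ## components present in the target (rule 4: others ignored)
    present_t <- colSums(qt > min_minor) > 0
    share1 <- colSums(q1 > min_minor) >= min(5, ceiling(nrow(q1) / 2))
    share2 <- colSums(q2 > min_minor) >= min(5, ceiling(nrow(q2) / 2))
    ## rule 5: source components absent from the target are ignored
    cand <- which(present_t & (share1 | share2))
    a_ok <- any(share1[cand] & !share2[cand])
    b_ok <- any(share2[cand] & !share1[cand])
    if (a_ok && b_ok) return(TRUE)
    ## both components in both sources, but in clearly different proportions
    both <- cand[share1[cand] & share2[cand]]
    if (length(both) >= 2) {
      m1 <- colMeans(q1)[both]; m2 <- colMeans(q2)[both]
      ratio <- (m1 + 1e-6) / (m2 + 1e-6)
      if (max(ratio) > 2 && min(ratio) < 0.5) return(TRUE)
    }
    ## rule 3: a single shared component is not evidence
  }
  FALSE
}
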