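test_that("LD pruning removes correlated sites like the windowed oracle", {
  d <- toy_dataset(50, seed = 13)
  # duplicate site 10 at site 11: r^2 = 1, the later copy must go
  g <- d$geno
  g[11, ] <- g[10, ]
  dd <- snp_dataset(g, d$snp, d$ind, "diploid")
  kept <- ld_prune(dd, window = 50, step = 10, r2 = 0.5)
  expect_true(10 %in% kept)
  expect_false(11 %in% kept)
  # brute-force all-pairs-in-window oracle on the same data; the 0.45
  # threshold avoids genotype configurations whose r^2 sits exactly on the
  # cutoff, where the two correlation code paths may round differently
  kept45 <- ld_prune(dd, window = 50, step = 10, r2 = 0.45)
  oracle_keep <- rep(TRUE, 50)
  for (i in 1:49) {
    if (!oracle_keep[i]) next
    for (j in (i + 1):50) {
      if (!oracle_keep[j]) next
      r <- suppressWarnings(stats::cor(g[i, ], g[j, ]))
      if (!is.na(r) && r^2 > 0.45) oracle_keep[j] <- FALSE
    }
  }
  expect_equal(kept45, which(oracle_keep))
})

test_that("PCA separates diverged populations on PC1", {
  withr::with_seed(21, {
    p1 <- runif(300, 0.05, 0.95)
    shift <- pmin(pmax(p1 + rnorm(300, 0, 0.4), 0.02), 0.98)
    geno <- cbind(
      matrix(rbinom(300 * 8, 2, rep(p1, 8)), 300, 8),
      matrix(rbinom(300 * 8, 2, rep(shift, 8)), 300, 8)
    )
    d <- snp_dataset(
      geno,
      tibble::tibble(id = paste0("s", 1:300), chrom = "1", cm = 0,
                     pos = seq_len(300) * 1000L, ref = "A", alt = "C"),
      tibble::tibble(id = paste0("i", 1:16), sex = "U",
                     group = rep(c("P1", "P2"), each = 8)),
      "diploid"
    )
    pcs <- ld_prune_and_pca(d, n_pc = 5, window = 300, step = 50)
    gap <- abs(mean(pcs$PC1[pcs$group == "P1"]) -
                 mean(pcs$PC1[pcs$group == "P2"]))
    spread <- max(stats::sd(pcs$PC1[pcs$group == "P1"]),
                  stats::sd(pcs$PC1[pcs$group == "P2"]))
    expect_gt(gap, spread)
  })
})

test_that("PCA support rule uses the inter-source segment", {
  mkpcs <- function(tgt_centre, diam = 1) {
    pts <- rbind(
      cbind(rnorm(5, -10, 0.1), rnorm(5, 0, 0.1), rnorm(5, 0, 0.1)),
      cbind(rnorm(5, 10, 0.1), rnorm(5, 0, 0.1), rnorm(5, 0, 0.1)),
      cbind(tgt_centre[1] + c(-diam / 2, diam / 2, 0, 0, 0),
            tgt_centre[2] + c(0, 0, -diam / 2, diam / 2, 0),
            tgt_centre[3] + rep(0, 5))
    )
    tibble::tibble(
      id = paste0("i", 1:15), group = rep(c("S1", "S2", "T"), each = 5),
      PC1 = pts[, 1], PC2 = pts[, 2], PC3 = pts[, 3]
    )
  }
  withr::with_seed(3, {
    expect_true(pca_support(mkpcs(c(0, 0, 0)), "T", "S1", "S2"))
    expect_true(pca_support(mkpcs(c(0, 2.5, 0)), "T", "S1", "S2"))
    expect_false(pca_support(mkpcs(c(0, 5.5, 0)), "T", "S1", "S2"))
    # beyond the segment ends: unsupported
    expect_false(pca_support(mkpcs(c(14, 0, 0)), "T", "S1", "S2"))
  })
  # singleton target: zero diameter forces exact placement on the segment
  single <- tibble::tibble(
    id = paste0("i", 1:11), group = c(rep("S1", 5), rep("S2", 5), "T"),
    PC1 = c(rep(-1, 5), rep(1, 5), 0), PC2 = c(rep(0, 10), 0.2),
    PC3 = 0
  )
  expect_false(pca_support(single, "T", "S1", "S2"))
  single$PC2[11] <- 0
  expect_true(pca_support(single, "T", "S1", "S2"))
})

test_that("clustering support rules accept two-sided sharing only", {
  ids <- sprintf("i%02d", 1:30)
  groups <- stats::setNames(rep(c("T", "S1", "S2"), each = 10), ids)
  mkq <- function(t_mix, s1_comp, s2_comp) {
    Q <- matrix(0, 30, 2, dimnames = list(ids, NULL))
    Q[1:10, ] <- rep(t_mix, each = 10)
    Q[11:20, ] <- rep(s1_comp, each = 10)
    Q[21:30, ] <- rep(s2_comp, each = 10)
    Q
  }
  # component 1 private to S1, component 2 to S2, target mixed: supported
  q_good <- mkq(c(0.5, 0.5), c(0.98, 0.02), c(0.02, 0.98))
  expect_true(admixture_support(list(K2 = q_good), groups, "T", "S1", "S2"))
  # a single component shared with both sources: unsupported
  q_one <- mkq(c(1, 0), c(1, 0), c(1, 0))
  expect_false(admixture_support(list(K2 = q_one), groups, "T", "S1", "S2"))
  # target unmixed (no minor component above 2%): unsupported
  q_pure <- mkq(c(0.99, 0.01), c(0.98, 0.02), c(0.02, 0.98))
  expect_false(admixture_support(list(K2 = q_pure), groups, "T", "S1", "S2"))
  # one K value suffices
  expect_true(admixture_support(list(K2 = q_one, K3 = q_good), groups,
                                "T", "S1", "S2"))
  # a source-private component absent from the target is ignored
  Q3 <- cbind(q_good, 0)
  Q3[11:20, ] <- rep(c(0.68, 0.02, 0.30), each = 10)
  expect_true(admixture_support(list(K3 = Q3), groups, "T", "S1", "S2"))
})
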