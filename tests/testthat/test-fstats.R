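d <- toy_dataset(40, seed = 3)
blocks <- compute_f2_blocks(d, blgsize = 1e6)

test_that("per-block f2 matches a brute-force oracle with bias correction", {
  ia <- which(d$ind$group == "A"); ib <- which(d$ind$group == "B")
  # single-block comparison: all 40 sites fall into 4 blocks of 10 sites
  expect_equal(length(blocks$weights), 4)
  for (b in seq_len(4)) {
    sites <- ((b - 1) * 10 + 1):(b * 10)
    expect_equal(
      unname(blocks$f2[b, "A|B"]),
      oracle_f2(d$geno[sites, , drop = FALSE], ia, ib),
      tolerance = 1e-12
    )
  }
  expect_equal(f_stat(blocks, "f2", c("A", "A"))$estimate, 0)
})

test_that("f3 and f4 match direct allele-frequency oracles", {
  oracle_f4 <- function(geno, ia, ib, ic, id_) {
    mean(vapply(seq_len(nrow(geno)), function(s) {
      p <- function(ix) sum(geno[s, ix]) / (2 * length(ix))
      (p(ia) - p(ib)) * (p(ic) - p(id_))
    }, numeric(1)))
  }
  groups <- split(seq_len(nrow(d$ind)), d$ind$group)
  # f4 of four distinct groups: corrections cancel exactly
  f4_pkg <- mean(admixscreen:::.fstat_block_series(blocks, "f4",
                                                   c("A", "B", "C", "D")) *
                   blocks$weights) / mean(blocks$weights)
  expect_equal(f4_pkg, oracle_f4(d$geno, groups$A, groups$B, groups$C,
                                 groups$D), tolerance = 1e-12)
  # f3 with inner-group correction
  ocf3 <- oracle_f2(d$geno, groups$A, groups$B) / 2 +
    oracle_f2(d$geno, groups$A, groups$C) / 2 -
    oracle_f2(d$geno, groups$B, groups$C) / 2
  f3_pkg <- f_stat(blocks, "f3", c("A", "B", "C"))
  est_direct <- sum(admixscreen:::.fstat_block_series(blocks, "f3",
                                                      c("A", "B", "C")) *
                      blocks$weights) / sum(blocks$weights)
  expect_equal(est_direct, ocf3, tolerance = 1e-12)
  expect_true(is.finite(f3_pkg$se))
})

test_that("f4 algebraic identities hold", {
  f4 <- function(p) f_stat(blocks, "f4", p)$estimate
  expect_equal(f4(c("A", "B", "A", "B")),
               f_stat(blocks, "f2", c("A", "B"))$estimate, tolerance = 1e-12)
  expect_equal(f4(c("A", "B", "C", "D")), -f4(c("B", "A", "C", "D")),
               tolerance = 1e-12)
  expect_equal(f4(c("A", "B", "C", "D")), f4(c("C", "D", "A", "B")),
               tolerance = 1e-12)
})

test_that("allsnps f4 equals the from-f2 route on complete data and handles
           missingness per quadruplet", {
  full <- f4_allsnps(d, c("A", "B", "C", "D"), blgsize = 1e6)
  via_f2 <- f_stat(blocks, "f4", c("A", "B", "C", "D"))
  expect_equal(full$estimate, via_f2$estimate, tolerance = 1e-12)
  expect_equal(full$se, via_f2$se, tolerance = 1e-12)

  dm <- toy_dataset(60, seed = 8, missing = 0.3)
  got <- f4_allsnps(dm, c("A", "B", "C", "D"), blgsize = 1e6)
  # brute-force per-quadruplet oracle
  groups <- split(seq_len(nrow(dm$ind)), dm$ind$group)
  ok <- vapply(seq_len(nrow(dm$geno)), function(s) {
    all(vapply(groups[c("A", "B", "C", "D")], function(ix) {
      any(!is.na(dm$geno[s, ix]))
    }, logical(1)))
  }, logical(1))
  p_of <- function(s, ix) {
    g <- dm$geno[s, ix]; g <- g[!is.na(g)]
    sum(g) / (2 * length(g))
  }
  vals <- vapply(which(ok), function(s) {
    (p_of(s, groups$A) - p_of(s, groups$B)) *
      (p_of(s, groups$C) - p_of(s, groups$D))
  }, numeric(1))
  expect_equal(got$estimate, mean(vals), tolerance = 1e-12)
  expect_lt(got$n_snps, nrow(dm$geno))

  dm$geno[, dm$ind$group == "A"] <- NA_integer_
  dm2 <- snp_dataset(dm$geno, dm$snp, dm$ind, "diploid")
  expect_error(f4_allsnps(dm2, c("A", "B", "C", "D")), "no overlapping sites")
})

test_that("weighted jackknife reduces to closed forms", {
  expect_equal(jackknife_estimate(rep(2.5, 6), rep(10, 6))$se, 0)
  # equal weights: standard delete-one jackknife
  v <- c(1.2, 0.8, 1.5, 0.9, 1.1)
  jk <- jackknife_estimate(v, rep(7, 5))
  g <- length(v)
  loo <- vapply(seq_len(g), function(j) mean(v[-j]), numeric(1))
  expect_equal(jk$estimate, mean(v))
  expect_equal(jk$se, sqrt((g - 1) / g * sum((loo - mean(loo))^2)),
               tolerance = 1e-12)
  # unequal weights: hand-computed pseudovalue formula
  w <- c(4, 1, 3, 2, 5)
  jk2 <- jackknife_estimate(v, w)
  W <- sum(w)
  theta <- sum(w * v) / W
  loo <- vapply(seq_len(g), function(j) sum(w[-j] * v[-j]) / (W - w[j]),
                numeric(1))
  h <- W / w
  theta_j <- g * theta - sum((1 - w / W) * loo)
  tau <- h * theta - (h - 1) * loo
  expect_equal(jk2$estimate, theta, tolerance = 1e-12)
  expect_equal(jk2$se, sqrt(mean((tau - theta_j)^2 / (h - 1))),
               tolerance = 1e-12)
  expect_error(jackknife_estimate(1, 1), "at least 2")
})

test_that("jackknife SE scales like 1/sqrt(n_blocks) on iid blocks", {
  withr::with_seed(42, {
    se_at <- function(g) {
      mean(replicate(40, jackknife_estimate(rnorm(g), rep(1, g))$se))
    }
    ratio <- se_at(25) / se_at(100)
    expect_gt(ratio, 1.6)
    expect_lt(ratio, 2.6)
  })
})

test_that("block partitioning follows physical windows per chromosome", {
  snp <- tibble::tibble(
    id = paste0("s", 1:300),
    chrom = rep(c("1", "2", "3"), each = 100),
    cm = 0, pos = rep(seq(5e5, 995e5, length.out = 100), 3), ref = "A",
    alt = "C"
  )
  bl <- admixscreen:::.block_index(snp, 4e6)
  expect_equal(max(bl$idx), 75) # 25 four-Mb blocks per 100-Mb chromosome
})

test_that("Hudson FST matches hand oracles and boundary cases", {
  groups <- split(seq_len(nrow(d$ind)), d$ind$group)
  fst <- fst_matrix(d)
  expect_equal(fst["A", "B"], oracle_fst(d$geno, groups$A, groups$B),
               tolerance = 1e-12)
  expect_equal(fst, t(fst))
  expect_true(all(diag(fst) == 0))
  # missing-data path agrees with the oracle too
  dm <- toy_dataset(60, seed = 4, missing = 0.25)
  gm <- split(seq_len(nrow(dm$ind)), dm$ind$group)
  fstm <- fst_matrix(dm)
  expect_equal(fstm["A", "C"], oracle_fst(dm$geno, gm$A, gm$C),
               tolerance = 1e-12)
  # fixed difference: FST = 1
  g2 <- matrix(c(rep(0L, 4), rep(2L, 4)), 2, 4, byrow = FALSE)
  g2 <- rbind(c(0L, 0L, 2L, 2L), c(0L, 0L, 2L, 2L))
  dd <- snp_dataset(
    g2,
    tibble::tibble(id = c("s1", "s2"), chrom = "1", cm = 0, pos = c(100L, 200L),
                   ref = "A", alt = "C"),
    tibble::tibble(id = paste0("i", 1:4), sex = "U",
                   group = c("X", "X", "Y", "Y")),
    "pseudohaploid"
  )
  fst2 <- fst_matrix(dd)
  expect_equal(fst2["X", "Y"], 1)
})
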