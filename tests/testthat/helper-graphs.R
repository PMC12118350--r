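# Hand-built admixture graphs used across tests.

# deeply nested outgroups R1..R4, donor-side sister R3/S1, recipient-side
# sister S2; T = 0.3 * S1-lineage + 0.7 * S2-lineage, pulse at 100
alpha_graph <- function(alpha = 0.3) {
  nodes <- tibble::tibble(
    node = c("R1", "R2", "R3", "R4", "S1", "S2", "T",
             "x1", "x2", "x3", "y1", "y2", "z", "aT"),
    date = c(0, 0, 0, 0, 0, 0, 0, 3000, 2600, 2200, 1800, 1600, 1200, 100),
    type = c(rep("leaf", 7), "root", rep("divergence", 5), "admixture")
  )
  edges <- tibble::tibble(
    id = 1:13,
    from = c("x1", "x1", "x2", "x2", "x3", "x3", "y1", "y1", "y2", "y2",
             "z", "z", "aT"),
    to = c("R1", "x2", "R2", "x3", "y1", "y2", "R3", "S1", "R4", "z",
           "S2", "aT", "T"),
    ne = 3000
  )
  admixture_graph(nodes, edges,
                  tibble::tibble(node = "aT", donor_edge = 8L, prop = alpha))
}

# strictly cladal pair L1/L2 on a caterpillar of outgroups R1..R5
null_graph <- function() {
  nodes <- tibble::tibble(
    node = c("L1", "L2", "R1", "R2", "R3", "R4", "R5",
             "x1", "x2", "x3", "x4", "x5", "x6", "xL"),
    date = c(0, 0, 0, 0, 0, 0, 0, 2000, 1700, 1400, 1100, 800, 500, 30),
    type = c(rep("leaf", 7), "root", rep("divergence", 6))
  )
  edges <- tibble::tibble(
    id = 1:13,
    from = c("x1", "x1", "x2", "x2", "x3", "x3", "x4", "x4", "x5", "x5",
             "x6", "xL", "xL"),
    to = c("R1", "x2", "R2", "x3", "R3", "x4", "R4", "x5", "R5", "x6",
           "xL", "L1", "L2"),
    ne = 3000
  )
  admixture_graph(nodes, edges)
}

# a small synthetic genotype dataset built directly (no simulation)
toy_dataset <- function(n_sites = 40, groups = c(A = 3, B = 3, C = 2, D = 2),
                        seed = 1, missing = 0) {
  withr::with_seed(seed, {
    n_ind <- sum(groups)
    p <- runif(n_sites, 0.1, 0.9)
    geno <- matrix(rbinom(n_sites * n_ind, 2, rep(p, n_ind)),
                   n_sites, n_ind)
    if (missing > 0) geno[runif(length(geno)) < missing] <- NA_integer_
    snp <- tibble::tibble(
      id = paste0("s", seq_len(n_sites)), chrom = "1",
      cm = seq_len(n_sites) * 1e5 * 1e-8, pos = seq_len(n_sites) * 100000L,
      ref = "A", alt = "C"
    )
    ind <- tibble::tibble(
      id = paste0("i", seq_len(n_ind)), sex = "U",
      group = rep(names(groups), groups)
    )
    snp_dataset(geno, snp, ind, "diploid")
  })
}

# brute-force unbiased f2 between two groups, averaged over sites
oracle_f2 <- function(geno, ix_a, ix_b) {
  vals <- vapply(seq_len(nrow(geno)), function(s) {
    ga <- geno[s, ix_a]; gb <- geno[s, ix_b]
    ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
    na <- 2 * length(ga); nb <- 2 * length(gb)
    if (na < 1 || nb < 1) return(NA_real_)
    aa <- sum(ga); ab <- sum(gb)
    pa <- aa / na; pb <- ab / nb
    ha <- if (na >= 2) aa * (na - aa) / (na * (na - 1)) else 0
    hb <- if (nb >= 2) ab * (nb - ab) / (nb * (nb - 1)) else 0
    (pa - pb)^2 - ha / na - hb / nb
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# brute-force Hudson FST (ratio of averages)
oracle_fst <- function(geno, ix_a, ix_b) {
  num <- 0; den <- 0
  for (s in seq_len(nrow(geno))) {
    ga <- geno[s, ix_a]; gb <- geno[s, ix_b]
    ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
    na <- 2 * length(ga); nb <- 2 * length(gb)
    if (na < 2 || nb < 2) next
    pa <- sum(ga) / na; pb <- sum(gb) / nb
    num <- num + (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
    den <- den + pa * (1 - pb) + pb * (1 - pa)
  }
  num / den
}
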