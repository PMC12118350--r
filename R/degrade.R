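#' Degrade a diploid dataset to archaeogenetic quality
#'
#' Emulates typical ancient-DNA data: genotypes are made pseudohaploid by
#' sampling one random allele at every heterozygous site; each individual
#' independently loses sites at a missing rate drawn uniformly from 5-95%;
#' and each group is thinned to a uniformly drawn 1-10 individuals. The
#' whole procedure is repeated until more than `min_sites` sites remain
#' polymorphic across the retained groups (group-level allele frequencies
#' not all fixed), or the retry budget is exhausted.
#'
#' @param data A diploid [snp_dataset()].
#' @param min_sites Required number of polymorphic sites (20000 for 300-Mb
#'   genomes, 66000 for 1000- and 3000-Mb genomes in the screening study
#'   conditions).
#' @param seed Integer seed.
#' @param max_group_size Upper bound of the per-group size draw (default 10).
#' @param retries Retry budget (default 1000).
#' @return A pseudohaploid [snp_dataset()]; sites are a subset of the input
#'   sites (those polymorphic after degradation) and group labels are
#'   preserved.
#' @export
degrade_dataset <- function(data, min_sites, seed, max_group_size = 10,
                            retries = 1000) {
  stopifnot(inherits(data, "snp_dataset"))
  if (data$ploidy != "diploid") stop("degrade_dataset expects diploid input")
  groups <- dataset_groups(data)
  withr::with_seed(.child_rng(seed, "degrade"), {
    for (attempt in seq_len(retries)) {
      keep_ind <- unlist(lapply(groups, function(g) {
        ix <- which(data$ind$group == g)
        n <- sample.int(min(max_group_size, length(ix)), 1)
        sort(sample(ix, n))
      }))
      g <- data$geno[, keep_ind, drop = FALSE]
      # pseudohaploid: heterozygotes become 0 or 2 with equal probability
      het <- which(g == 1L)
      g[het] <- 2L * (stats::runif(length(het)) < 0.5)
      # per-individual missingness
      miss_rate <- stats::runif(ncol(g), 0.05, 0.95)
      for (j in seq_len(ncol(g))) {
        drop <- stats::runif(nrow(g)) < miss_rate[j]
        g[drop, j] <- NA_integer_
      }
      ind <- data$ind[keep_ind, ]
      poly <- .polymorphic_sites(g, ind$group)
      if (sum(poly) > min_sites) {
        out <- snp_dataset(g[poly, , drop = FALSE], data$snp[poly, ], ind,
                           ploidy = "pseudohaploid")
        attr(out, "missing_rates") <- miss_rate
        attr(out, "attempts") <- attempt
        return(out)
      }
    }
    stop("degradation retry budget (", retries, " attempts) exhausted: ",
         "input too small to retain > ", min_sites, " polymorphic sites")
  })
}

# sites where, pooling called alleles within each group, more than one allele
# is observed across the groups
.polymorphic_sites <- function(geno, group_of) {
  groups <- unique(group_of)
  alt <- matrix(0, nrow(geno), length(groups))
  tot <- matrix(0, nrow(geno), length(groups))
  for (k in seq_along(groups)) {
    sub <- geno[, group_of == groups[k], drop = FALSE]
    alt[, k] <- rowSums(sub, na.rm = TRUE)
    tot[, k] <- 2 * rowSums(!is.na(sub))
  }
  alt_all <- rowSums(alt)
  tot_all <- rowSums(tot)
  tot_all > 0 & alt_all > 0 & alt_all < tot_all
}
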