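#' SNP dataset container
#'
#' Genotypes with site and individual metadata, following EIGENSTRAT
#' semantics: the genotype matrix holds, per site and individual, the count
#' of the alternative allele (0, 1, 2) with `NA` for missing data (written
#' and read as `9`). Pseudohaploid data contain no heterozygous calls.
#'
#' @param geno Integer matrix, sites x individuals; values 0/1/2/`NA`.
#' @param snp Tibble with columns `id`, `chrom`, `cm` (genetic position,
#'   Morgans in this package), `pos` (physical position), `ref`, `alt`.
#' @param ind Tibble with columns `id`, `sex`, `group` and optionally `date`
#'   (sampling date in generations before present).
#' @param ploidy `"diploid"` or `"pseudohaploid"`.
#' @return An object of class `snp_dataset`.
#' @export
snp_dataset <- function(geno, snp, ind, ploidy = c("diploid", "pseudohaploid")) {
  ploidy <- match.arg(ploidy)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(
    nrow(geno) == nrow(snp), ncol(geno) == nrow(ind),
    all(c("id", "chrom", "pos") %in% names(snp)),
    all(c("id", "group") %in% names(ind))
  )
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype values must be 0, 1, 2 or missing")
  }
  if (ploidy == "pseudohaploid" && any(geno == 1L, na.rm = TRUE)) {
    stop("pseudohaploid data must not contain heterozygous genotypes")
  }
  for (ch in unique(snp$chrom)) {
    p <- snp$pos[snp$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions must be strictly increasing within a chromosome")
    }
  }
  if (!"sex" %in% names(ind)) ind$sex <- "U"
  if (!"cm" %in% names(snp)) snp$cm <- snp$pos * 1e-8
  structure(
    list(geno = geno, snp = tibble::as_tibble(snp),
         ind = tibble::as_tibble(ind), ploidy = ploidy),
    class = "snp_dataset"
  )
}

#' @export
print.snp_dataset <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf(
    "<snp_dataset> %d sites x %d individuals (%d groups), %s, %.1f%% missing\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$ind$group)), x$ploidy, 100 * miss
  ))
  invisible(x)
}

#' Group labels of a SNP dataset
#' @param data A [snp_dataset()].
#' @return Character vector of unique group labels in order of appearance.
#' @export
dataset_groups <- function(data) unique(data$ind$group)

#' Read and write EIGENSTRAT triples
#'
#' `write_eigenstrat()` writes `prefix.geno` (one character per genotype per
#' individual, `9` = missing), `prefix.snp` (id, chromosome, genetic
#' position, physical position, ref, alt) and `prefix.ind` (id, sex, group).
#' `read_eigenstrat()` reads them back; the round trip is lossless.
#'
#' @param data A [snp_dataset()].
#' @param prefix Path prefix for the three files.
#' @return `read_eigenstrat()` returns a [snp_dataset()];
#'   `write_eigenstrat()` returns `prefix` invisibly.
#' @export
write_eigenstrat <- function(data, prefix) {
  stopifnot(inherits(data, "snp_dataset"))
  g <- data$geno
  g[is.na(g)] <- 9L
  lines <- apply(g, 1, paste0, collapse = "")
  writeLines(lines, paste0(prefix, ".geno"))
  snp <- data$snp
  utils::write.table(
    data.frame(snp$id, snp$chrom, format(snp$cm, digits = 10), snp$pos,
               snp$ref, snp$alt),
    paste0(prefix, ".snp"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  ind <- data$ind
  utils::write.table(
    data.frame(ind$id, ind$sex, ind$group), paste0(prefix, ".ind"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  if ("date" %in% names(data$ind)) {
    utils::write.table(
      data.frame(ind$id, ind$date), paste0(prefix, ".dates"),
      quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
    )
  }
  invisible(prefix)
}

#' @rdname write_eigenstrat
#' @param ploidy Ploidy flag to attach on read; `"auto"` flags the dataset
#'   pseudohaploid when no heterozygous genotype is present.
#' @export
read_eigenstrat <- function(prefix, ploidy = c("auto", "diploid", "pseudohaploid")) {
  ploidy <- match.arg(ploidy)
  geno_file <- paste0(prefix, ".geno")
  for (f in paste0(prefix, c(".geno", ".snp", ".ind"))) {
    if (!file.exists(f)) stop("missing file: ", f)
  }
  snp <- utils::read.table(paste0(prefix, ".snp"),
    col.names = c("id", "chrom", "cm", "pos", "ref", "alt"),
    colClasses = c("character", "character", "numeric", "integer",
                   "character", "character")
  )
  ind <- utils::read.table(paste0(prefix, ".ind"),
    col.names = c("id", "sex", "group"), colClasses = "character"
  )
  n_ind <- nrow(ind)

  lines <- readLines(geno_file)
  if (length(lines) != nrow(snp)) {
    stop(sprintf(".geno has %d rows but .snp has %d", length(lines), nrow(snp)))
  }
  widths <- nchar(lines)
  if (any(widths != n_ind)) {
    stop(sprintf(
      ".geno row width mismatch at line %d: %d characters for %d individuals",
      which(widths != n_ind)[1], widths[widths != n_ind][1], n_ind
    ))
  }
  g <- matrix(
    utf8ToInt(paste0(lines, collapse = "")) - utf8ToInt("0"),
    nrow = length(lines), ncol = n_ind, byrow = TRUE
  )
  if (any(!g %in% c(0L, 1L, 2L, 9L))) {
    stop("invalid genotype value in .geno (allowed: 0, 1, 2, 9)")
  }
  g[g == 9L] <- NA_integer_
  dates_file <- paste0(prefix, ".dates")
  if (file.exists(dates_file)) {
    dates <- utils::read.table(dates_file, col.names = c("id", "date"))
    ind$date <- dates$date[match(ind$id, dates$id)]
  }
  if (ploidy == "auto") {
    ploidy <- if (any(g == 1L, na.rm = TRUE)) "diploid" else "pseudohaploid"
  }
  snp_dataset(g, tibble::as_tibble(snp), tibble::as_tibble(ind), ploidy)
}

#' Restrict a SNP dataset to a subset of groups
#' @param data A [snp_dataset()].
#' @param groups Character vector of group labels to keep.
#' @return A [snp_dataset()] with only the selected individuals.
#' @export
subset_groups <- function(data, groups) {
  stopifnot(inherits(data, "snp_dataset"))
  missing <- setdiff(groups, data$ind$group)
  if (length(missing)) stop("groups not present: ", paste(missing, collapse = ", "))
  keep <- data$ind$group %in% groups
  snp_dataset(data$geno[, keep, drop = FALSE], data$snp, data$ind[keep, ],
              data$ploidy)
}
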