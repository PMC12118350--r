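#' Simulate genotypes from an admixture graph
#'
#' Translates the graph into an msprime demography (one population per graph
#' edge; population splits at divergence nodes, pulse admixture events at
#' admixture nodes) and simulates `n_chrom` chromosomes of length
#' `chrom_len` with a flat recombination rate of 2e-8 per nt per generation
#' (chromosome boundaries carry rate log(2) so chromosomes are effectively
#' unlinked), a flat mutation rate of 1.25e-8 under a binary model, and the
#' discrete-time Wright-Fisher model for the 25 most recent generations. Ten
#' diploid individuals are sampled per leaf at its sampling date.
#'
#' @param graph An [random_admixture_graph()] object.
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param seed Integer seed.
#' @param n_per_leaf Diploid individuals sampled per leaf (default 10).
#' @param dir Scratch directory for the engine files (default a tempdir).
#' @return A diploid [snp_dataset()] with group labels = leaf names and
#'   per-individual sampling dates.
#' @export
simulate_ags_genotypes <- function(graph, n_chrom = 3, chrom_len = 1e8, seed,
                                   n_per_leaf = 10, dir = tempfile("ags")) {
  stopifnot(inherits(graph, "admixture_graph"), chrom_len > 0)
  dates <- stats::setNames(graph$nodes$date, graph$nodes$node)
  edges <- graph$edges
  pop <- function(id) paste0("e", id)
  root <- setdiff(edges$from, edges$to)[1]

  populations <- c(
    lapply(seq_len(nrow(edges)), function(i) {
      list(name = pop(edges$id[i]), size = edges$ne[i])
    }),
    list(list(name = "eroot",
              size = round(mean(edges$ne[edges$from == root]))))
  )
  admix_nodes <- graph$admix$node
  splits <- list()
  admixtures <- list()
  for (nd in unique(edges$from)) {
    child_edges <- edges$id[edges$from == nd]
    if (nd %in% admix_nodes) {
      a <- graph$admix[graph$admix$node == nd, ]
      parent_edge <- edges$id[edges$to == nd]
      admixtures[[length(admixtures) + 1]] <- list(
        time = dates[nd], derived = pop(child_edges),
        ancestral = I(c(pop(parent_edge), pop(a$donor_edge))),
        proportions = I(c(1 - a$prop, a$prop))
      )
    } else {
      parent_edge <- if (nd == root) "eroot" else pop(edges$id[edges$to == nd])
      splits[[length(splits) + 1]] <- list(
        time = dates[nd], derived = I(as.list(pop(child_edges))),
        ancestral = parent_edge
      )
    }
  }
  leaves <- graph_leaves(graph)
  samples <- lapply(seq_len(nrow(leaves)), function(i) {
    terminal <- edges$id[edges$to == leaves$node[i]]
    list(population = pop(terminal), group = leaves$node[i],
         n = n_per_leaf, time = leaves$date[i])
  })
  spec <- list(
    populations = populations, splits = splits, admixtures = admixtures,
    migrations = list(), samples = samples,
    chromosomes = as.list(rep(chrom_len, n_chrom)),
    recomb_rate = 2e-8, mut_rate = 1.25e-8, dtwf_generations = 25,
    seed = .child_rng(seed, "msprime")
  )
  .run_engine(spec, dir, context = function() {
    f <- tempfile("graph", fileext = ".tsv")
    write_graph_tsv(graph, f)
    f
  })
}

#' Simulate genotypes on a stepping-stone landscape
#'
#' Runs the coalescent on the landscape: demes of 1000 diploids arise by
#' multifurcation 2520 generations before present and then exchange migrants
#' according to the gene-flow schedule. By default 3 diploid individuals per
#' deme are sampled at 0, 100 and 300 generations before present (64 demes x
#' 3 slices x 3 individuals = 576 individuals), with group labels
#' `d<deme>_t<slice>`. Genome: single chromosome (500 Mb at full scale),
#' recombination 1e-8 and mutation 1.25e-8 per nt per generation.
#'
#' @param landscape A [build_hex_landscape()] object.
#' @param flows A [sample_gene_flows()] schedule.
#' @param genome_len Genome length in bp (default 5e8; scaled-down runs keep
#'   all rates and change only this length).
#' @param seed Integer seed.
#' @param slices Sampling times in generations before present.
#' @param n_per_deme Diploid individuals per deme per slice.
#' @param dir Scratch directory for the engine files.
#' @return A diploid [snp_dataset()].
#' @export
simulate_ssl <- function(landscape, flows, genome_len = 5e8, seed,
                         slices = c(0, 100, 300), n_per_deme = 3,
                         dir = tempfile("ssl")) {
  stopifnot(inherits(landscape, "hex_landscape"),
            inherits(flows, "gene_flow_schedule"), genome_len > 0)
  n <- nrow(landscape$demes)
  populations <- c(
    lapply(seq_len(n), function(k) {
      list(name = paste0("d", k), size = landscape$deme_size)
    }),
    list(list(name = "anc", size = landscape$deme_size))
  )
  splits <- list(list(
    time = .ssl_split_time(),
    derived = I(as.list(paste0("d", seq_len(n)))), ancestral = "anc"
  ))
  rates <- dplyr::left_join(flows$rates, flows$epochs, by = "epoch")
  migrations <- lapply(seq_len(nrow(rates)), function(i) {
    list(time = rates$start[i], source = paste0("d", rates$from[i]),
         dest = paste0("d", rates$to[i]), rate = rates$rate[i])
  })
  samples <- unlist(lapply(slices, function(tt) {
    lapply(seq_len(n), function(k) {
      list(population = paste0("d", k), group = paste0("d", k, "_t", tt),
           n = n_per_deme, time = tt)
    })
  }), recursive = FALSE)
  spec <- list(
    populations = populations, splits = splits, admixtures = list(),
    migrations = migrations, samples = samples,
    chromosomes = list(genome_len),
    recomb_rate = 1e-8, mut_rate = 1.25e-8, dtwf_generations = 0,
    seed = .child_rng(seed, "msprime")
  )
  .run_engine(spec, dir, context = function() {
    f <- tempfile("schedule", fileext = ".yaml")
    write_landscape_yaml(landscape, flows, f)
    f
  })
}

# run the bundled msprime helper on a JSON spec and read the result back;
# `context` writes a serialized description of the inputs next to the error
# message when the engine fails
.run_engine <- function(spec, dir, context = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec$out_prefix <- file.path(dir, "sim")
  spec_file <- file.path(dir, "spec.json")
  jsonlite::write_json(spec, spec_file, auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(system2(
    .python_bin(), c(.engine_script(), shQuote(spec_file)),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    extra <- if (!is.null(context)) {
      paste0("\ninputs serialized to: ", context())
    } else ""
    stop("coalescent engine failed:\n", paste(out, collapse = "\n"), extra)
  }
  read_eigenstrat(spec$out_prefix, ploidy = "diploid")
}

#' Serialize a landscape and gene-flow schedule to YAML
#'
#' @param landscape A [build_hex_landscape()] object.
#' @param flows A [sample_gene_flows()] schedule.
#' @param path Output file.
#' @return `read_landscape_yaml()` returns `list(landscape, flows)`.
#' @export
write_landscape_yaml <- function(landscape, flows, path) {
  obj <- list(
    deme_size = landscape$deme_size,
    demes = lapply(seq_len(nrow(landscape$demes)), function(i) {
      list(deme = landscape$demes$deme[i], x = landscape$demes$x[i],
           y = landscape$demes$y[i])
    }),
    adjacency = lapply(seq_len(nrow(landscape$edges)), function(i) {
      list(from = landscape$edges$from[i], to = landscape$edges$to[i])
    }),
    type = flows$type,
    epochs = lapply(seq_len(nrow(flows$epochs)), function(i) {
      as.list(flows$epochs[i, ])
    }),
    rates = lapply(seq_len(nrow(flows$rates)), function(i) {
      as.list(flows$rates[i, ])
    })
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_landscape_yaml
#' @export
read_landscape_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  demes <- dplyr::bind_rows(obj$demes)
  edges <- dplyr::bind_rows(obj$adjacency)
  landscape <- structure(
    list(demes = demes, edges = edges,
         hops = .hop_distances(nrow(demes), edges),
         deme_size = obj$deme_size),
    class = "hex_landscape"
  )
  flows <- structure(
    list(type = obj$type, epochs = dplyr::bind_rows(obj$epochs),
         rates = dplyr::bind_rows(obj$rates)),
    class = "gene_flow_schedule"
  )
  list(landscape = landscape, flows = flows)
}
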