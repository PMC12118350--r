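#' Configuration of a screening run grid
#'
#' Bundles the simulation, protocol and criterion grids of a screening run
#' so that every run is fully reconstructible from its persisted
#' configuration and seed.
#'
#' @param landscape_types Landscape types to simulate (see
#'   [landscape_types()]).
#' @param protocols,densities Protocol and density grids.
#' @param criteria Character vector of criterion labels (see
#'   [feasibility_criteria()]).
#' @param n_replicates Simulation replicates per landscape type.
#' @param n_experiments Experiments per replicate x protocol x density cell.
#' @param genome_len Genome length in bp.
#' @param blgsize f2 block size in bp.
#' @param max_complexity Highest model complexity fitted.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(landscape_types = "1e-3_1e-2",
                       protocols = c("distal_rotating", "distal_nonrotating"),
                       densities = 13,
                       criteria = "plain:0.01:none",
                       n_replicates = 1, n_experiments = 5,
                       genome_len = 25e6, blgsize = 1e6,
                       max_complexity = 2, seed = 1,
                       out_dir = tempfile("screen")) {
  cfg <- list(
    landscape_types = landscape_types, protocols = protocols,
    densities = densities, criteria = criteria,
    n_replicates = n_replicates, n_experiments = n_experiments,
    genome_len = genome_len, blgsize = blgsize,
    max_complexity = max_complexity, seed = seed, out_dir = out_dir
  )
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  class(cfg) <- "run_config"
  cfg
}

#' Run a screening grid
#'
#' Simulates each landscape replicate, draws the experiments of every
#' protocol x density cell, fits all models, applies the feasibility
#' criteria and writes one TSV of model-level results per cell. Completed
#' cells (matching config hash on disk) are skipped, so an interrupted run
#' resumes where it stopped.
#'
#' @param config A [run_config()].
#' @return Tibble manifest: one row per cell with the output path and
#'   counts.
#' @export
run_screen_grid <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))
  land <- build_hex_landscape()
  samples <- ssl_sample_table(land)
  manifest <- list()
  for (type in config$landscape_types) {
    for (rep_i in seq_len(config$n_replicates)) {
      rep_seed <- .child_rng(config$seed, paste("replicate", type, rep_i))
      data <- NULL
      for (protocol in config$protocols) for (dens in config$densities) {
        cell <- sprintf("%s_rep%d_%s_%d", type, rep_i, protocol, dens)
        out_file <- file.path(config$out_dir, paste0(cell, ".tsv"))
        stamp <- paste0(out_file, ".done")
        if (file.exists(stamp) &&
            identical(readLines(stamp, warn = FALSE)[1], config$hash)) {
          manifest[[cell]] <- tibble::tibble(
            cell = cell, path = out_file, n_models = NA_integer_,
            reused = TRUE
          )
          next
        }
        if (is.null(data)) {
          flows <- sample_gene_flows(land, type, seed = rep_seed)
          data <- simulate_ssl(land, flows, genome_len = config$genome_len,
                               seed = rep_seed)
        }
        blocks <- NULL # per-experiment group sets differ; compute per fit
        rows <- list()
        for (k in seq_len(config$n_experiments)) {
          ex <- draw_randomized_experiment(
            samples, protocol, dens,
            seed = .child_rng(rep_seed, paste("exp", protocol, dens, k))
          )
          f2 <- compute_f2_blocks(
            data, pops = unique(c(ex$target$group, ex$pool$group,
                                  ex$right$group)),
            blgsize = config$blgsize, adjust_pseudohaploid = FALSE
          )
          for (crit in config$criteria) {
            oc <- run_experiment(ex, crit, f2,
                                 max_complexity = config$max_complexity,
                                 blgsize = config$blgsize)
            md <- oc$models
            demes <- .model_demes(md, ex)
            opt <- dplyr::bind_rows(lapply(seq_len(nrow(md)), function(i) {
              model_optimality(land, demes$target_deme[i],
                               demes$source_demes[[i]])
            }))
            rows[[length(rows) + 1]] <- tibble::tibble(
              experiment = k, criterion = crit, level = md$level,
              target = md$target,
              sources = vapply(md$sources, paste, "", collapse = ","),
              p_value = md$p_value,
              weights = vapply(md$weights, function(w) {
                paste(signif(w, 8), collapse = ",")
              }, ""),
              feasible = md$feasible,
              max_st = opt$max_st, min_angle = opt$min_angle,
              dist_ideal = opt$dist_ideal
            )
          }
        }
        tab <- dplyr::bind_rows(rows)
        tab$config_hash <- config$hash
        tab$seed <- config$seed
        utils::write.table(tab, out_file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        writeLines(config$hash, stamp)
        manifest[[cell]] <- tibble::tibble(
          cell = cell, path = out_file, n_models = nrow(tab), reused = FALSE
        )
      }
    }
  }
  dplyr::bind_rows(manifest)
}
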