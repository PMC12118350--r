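#' Era structure of stepping-stone landscape histories
#'
#' Demes arise by multifurcation from a single ancestor and then exchange
#' migrants through three consecutive gene-flow eras whose durations emulate
#' a pre-LGM / LGM / post-LGM division of the late Pleistocene and Holocene:
#' 1400, 350 and 770 generations. All times are in generations; the present
#' is generation 0 and the multifurcation happens 2520 generations before
#' present (2220 generations before the oldest, 300-generations-old, sampling
#' point).
#'
#' @keywords internal
#' @name ssl_eras
NULL

.ssl_eras <- function() {
  tibble::tibble(
    era = c("post-LGM", "LGM", "pre-LGM"),
    start = c(0, 770, 1120),   # generations before present
    end = c(770, 1120, 2520)
  )
}

.ssl_split_time <- function() 2520

#' Known landscape types and their per-generation gene-flow intensity ranges
#'
#' @return Character vector of the four type labels.
#' @export
landscape_types <- function() {
  c("1e-5_1e-4", "1e-4_1e-3", "1e-3_1e-2", "1e-5_1e-2")
}

#' Draw an era-structured gene-flow schedule for a landscape
#'
#' Assigns a per-generation migration rate to every directed nearest-neighbour
#' edge of the landscape, independently in the two directions, for each
#' gene-flow epoch. A rate is the fraction of a deme's individuals that come
#' from the given neighbouring deme in one generation. Four landscape types
#' are supported:
#' \describe{
#'   \item{`"1e-5_1e-4"`, `"1e-4_1e-3"`, `"1e-3_1e-2"`}{rates drawn uniformly
#'     from the stated closed interval. Rates are redrawn at the start of each
#'     of the three eras, except for `"1e-3_1e-2"` where redrawing happens 5
#'     times per era at equal time intervals (15 epochs in total).}
#'   \item{`"1e-5_1e-2"`}{rates are absolute values of draws from a normal
#'     distribution centred at 0, truncated at 1e-2; the standard deviation
#'     (3.9e-3) puts ~99% of the absolute draws below 1e-2. Redrawn once per
#'     era.}
#' }
#'
#' @param landscape A [build_hex_landscape()] object.
#' @param type One of [landscape_types()].
#' @param seed Integer seed; every replicate should use a fresh seed.
#' @return A `gene_flow_schedule`: list with `type`, `epochs` (tibble with
#'   `epoch`, `era`, `start`, `end` in generations before present) and
#'   `rates` (tibble with `epoch`, `from`, `to`, `rate`).
#' @export
sample_gene_flows <- function(landscape, type = landscape_types(), seed) {
  stopifnot(inherits(landscape, "hex_landscape"))
  type <- match.arg(type)
  eras <- .ssl_eras()
  n_per_era <- if (type == "1e-3_1e-2") 5L else 1L
  epochs <- dplyr::bind_rows(lapply(seq_len(nrow(eras)), function(i) {
    bounds <- seq(eras$start[i], eras$end[i], length.out = n_per_era + 1)
    tibble::tibble(
      era = eras$era[i],
      start = bounds[-length(bounds)],
      end = bounds[-1]
    )
  }))
  epochs$epoch <- seq_len(nrow(epochs))

  n_edges <- nrow(landscape$edges)
  rng <- .child_rng(seed, "gene-flows")
  draw <- switch(type,
    "1e-5_1e-4" = function(n) stats::runif(n, 1e-5, 1e-4),
    "1e-4_1e-3" = function(n) stats::runif(n, 1e-4, 1e-3),
    "1e-3_1e-2" = function(n) stats::runif(n, 1e-3, 1e-2),
    "1e-5_1e-2" = function(n) pmin(abs(stats::rnorm(n, 0, 3.9e-3)), 1e-2)
  )
  rates <- withr::with_seed(rng, {
    dplyr::bind_rows(lapply(epochs$epoch, function(ep) {
      tibble::tibble(
        epoch = ep,
        from = landscape$edges$from,
        to = landscape$edges$to,
        rate = draw(n_edges)
      )
    }))
  })
  structure(
    list(type = type, epochs = epochs[, c("epoch", "era", "start", "end")],
         rates = rates),
    class = "gene_flow_schedule"
  )
}

#' @export
print.gene_flow_schedule <- function(x, ...) {
  cat(sprintf(
    "<gene_flow_schedule> type %s: %d epochs, %d directed edges, rates %.2g-%.2g\n",
    x$type, nrow(x$epochs), length(unique(paste(x$rates$from, x$rates$to))),
    min(x$rates$rate), max(x$rates$rate)
  ))
  invisible(x)
}
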