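#' Build a hexagonal-lattice stepping-stone landscape
#'
#' Constructs an approximately circular landscape of `n_demes` panmictic demes
#' placed on a unit triangular lattice (demes at the vertices of triangles
#' tiling the plane, so interior demes have six nearest neighbours at distance
#' 1). The layout takes the `n_demes` lattice points closest to the origin,
#' breaking distance ties by polar angle, and connects every pair of demes at
#' Euclidean distance 1 by a bidirectional gene-flow edge. The construction is
#' deterministic.
#'
#' Spatial model-optimality metrics on the landscape use the *lattice step
#' (hop) distance*: nearest neighbours are at distance 1, demes two steps
#' apart at distance 2, and so on. On the default 64-deme landscape the
#' maximal hop distance between demes is 9, which is used as the
#' normalisation constant for source-target-source angles (see
#' [model_optimality()]).
#'
#' @param n_demes Number of demes (default 64; other values are built on a
#'   best-effort basis but are not the layout the screening protocols assume).
#' @param deme_size Diploid effective size of every deme (default 1000).
#' @return An object of class `hex_landscape`: a list with
#'   \describe{
#'     \item{demes}{tibble with `deme` (integer id, 1-based), `x`, `y`
#'       coordinates in lattice units.}
#'     \item{edges}{tibble of directed nearest-neighbour edges `from`, `to`
#'       (both directions listed).}
#'     \item{hops}{integer matrix of pairwise lattice step distances.}
#'     \item{deme_size}{per-deme diploid effective size.}
#'   }
#' @examples
#' land <- build_hex_landscape()
#' range(table(land$edges$from)) # node degrees 3..6
#' max(land$hops)                # 9
#' @export
build_hex_landscape <- function(n_demes = 64, deme_size = 1000) {
  stopifnot(n_demes >= 7)
  span <- ceiling(sqrt(n_demes)) + 4
  grid <- expand.grid(i = -span:span, j = -span:span)
  x <- grid$i + grid$j / 2
  y <- grid$j * sqrt(3) / 2
  # centre the landscape on the midpoint of a lattice edge: the shells
  # around that point close at exactly 64 points, giving a deterministic,
  # approximately circular layout with node degrees 3-6 and lattice-step
  # diameter 9
  r <- round(sqrt((x - 0.5)^2 + y^2), 9)
  ord <- order(r, atan2(y, x - 0.5))
  keep <- ord[seq_len(n_demes)]
  demes <- tibble::tibble(deme = seq_len(n_demes), x = x[keep], y = y[keep])

  d2 <- outer(demes$x, demes$x, "-")^2 + outer(demes$y, demes$y, "-")^2
  adj <- abs(d2 - 1) < 1e-9
  idx <- which(adj, arr.ind = TRUE)
  edges <- tibble::tibble(from = idx[, 1], to = idx[, 2])

  hops <- .hop_distances(n_demes, edges)
  structure(
    list(demes = demes, edges = edges, hops = hops, deme_size = deme_size),
    class = "hex_landscape"
  )
}

# BFS hop distances over the nearest-neighbour graph
.hop_distances <- function(n, edges) {
  nbr <- split(edges$to, edges$from)
  hops <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(nbr[as.character(frontier)], use.names = FALSE))
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- dist[frontier[1]] + 1L
      frontier <- nxt
    }
    hops[s, ] <- dist
  }
  if (anyNA(hops)) stop("landscape adjacency graph is disconnected")
  hops
}

#' @export
print.hex_landscape <- function(x, ...) {
  deg <- table(factor(x$edges$from, levels = x$demes$deme))
  cat(sprintf(
    "<hex_landscape> %d demes (Ne = %d diploids each), node degree %d-%d, hop diameter %d\n",
    nrow(x$demes), x$deme_size, min(deg), max(deg), max(x$hops)
  ))
  invisible(x)
}

#' Source-target distance on a stepping-stone landscape
#'
#' Lattice step (hop) distance between a source deme and the target deme:
#' samples from the same deme (at any sampling time) are at distance 0,
#' nearest neighbours at distance 1, and so on.
#'
#' @param landscape A [build_hex_landscape()] object.
#' @param target,source Deme ids (vectors recycle; `source` may be a vector).
#' @return Numeric vector of distances.
#' @export
st_distance <- function(landscape, target, source) {
  stopifnot(inherits(landscape, "hex_landscape"))
  n <- nrow(landscape$demes)
  if (any(c(target, source) < 1 | c(target, source) > n)) {
    stop("unknown deme id")
  }
  as.numeric(landscape$hops[cbind(rep(target, length.out = length(source)), source)])
}

#' Minimal source-target-source angle
#'
#' The smallest planar angle (in degrees) subtended at the target deme by any
#' pair of source demes. If any source occupies the same deme as the target
#' the angle is undefined and `NA` is returned.
#'
#' @param landscape A [build_hex_landscape()] object.
#' @param target Target deme id.
#' @param sources Integer vector of at least two source deme ids.
#' @return Angle in degrees, or `NA_real_` when undefined.
#' @export
min_sts_angle <- function(landscape, target, sources) {
  stopifnot(inherits(landscape, "hex_landscape"), length(sources) >= 2)
  xy <- as.matrix(landscape$demes[, c("x", "y")])
  v <- sweep(xy[sources, , drop = FALSE], 2, xy[target, ])
  len <- sqrt(rowSums(v^2))
  if (any(len < 1e-12)) return(NA_real_)
  pairs <- utils::combn(length(sources), 2)
  cosang <- (v[pairs[1, ], 1] * v[pairs[2, ], 1] +
               v[pairs[1, ], 2] * v[pairs[2, ], 2]) /
    (len[pairs[1, ]] * len[pairs[2, ]])
  min(acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
}

#' @describeIn build_hex_landscape ggplot of the deme layout and gene-flow
#'   edges.
#' @param object,... `hex_landscape` object (and ignored extra arguments).
#' @export
autoplot.hex_landscape <- function(object, ...) {
  seg <- dplyr::mutate(object$edges,
    x = object$demes$x[.data$from], y = object$demes$y[.data$from],
    xend = object$demes$x[.data$to], yend = object$demes$y[.data$to]
  )
  ggplot2::ggplot(object$demes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(xend = .data$xend, yend = .data$yend),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$deme),
      nudge_y = 0.18, size = 2.6
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (lattice units)", y = "y (lattice units)") +
    ggplot2::theme_minimal()
}
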