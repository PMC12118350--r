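#' Random dated admixture graphs
#'
#' Generates a random admixture-graph-shaped history: a bifurcating scaffold
#' over `n_leaves` sampled populations onto which `n_admix` pulse admixture
#' events are grafted between time-compatible lineages. Demographic events
#' are not dated independently: every event sits on a ladder of "topological
#' depth" levels whose consecutive rungs are separated by gaps drawn
#' uniformly from 20-120 generations (scaled by `max_depth / 800`), so
#' events of the same depth are tied to the same date, and leaf sampling
#' dates are tied to the same ladder. Per-edge effective sizes are drawn
#' uniformly from 1000-10000 diploids and admixture proportions from
#' 10-50%.
#'
#' The generator uses independent child seeds per phase (topology, dates,
#' admixture placement, effective sizes, proportions), all derived from
#' `seed`.
#'
#' @param n_leaves Number of sampled populations (leaves), named A, B, C, ...
#' @param n_admix Number of pulse admixture events.
#' @param max_depth Upper bound on the graph depth in generations (800 and
#'   3000 are the two depths the screening study conditions use; date gaps
#'   scale with `max_depth / 800`).
#' @param seed Integer master seed.
#' @return An object of class `admixture_graph`: list with `nodes` (tibble:
#'   `node`, `date`, `type`), `edges` (tibble: `id`, `from`, `to`, `ne`),
#'   `admix` (tibble: `node`, `donor_edge`, `prop` - the proportion
#'   contributed by the donor lineage), and `max_depth`.
#' @examples
#' g <- random_admixture_graph(13, 10, 800, seed = 1)
#' nrow(g$admix)
#' @export
random_admixture_graph <- function(n_leaves = 13, n_admix = 10,
                                   max_depth = 800, seed) {
  stopifnot(n_leaves >= 2, n_admix >= 0, max_depth >= 200)
  scale <- max(1, max_depth / 800)
  leaves <- make.unique(rep(LETTERS, length.out = n_leaves), sep = "")
  if (n_leaves <= 26) leaves <- LETTERS[seq_len(n_leaves)]

  ## phase 1: random bifurcating scaffold -------------------------------
  topo <- withr::with_seed(.child_rng(seed, "topology"), {
    cluster <- as.list(leaves)
    names(cluster) <- leaves
    level <- stats::setNames(rep(0L, n_leaves), leaves)
    joins <- list()
    avail <- leaves
    for (k in seq_len(n_leaves - 1)) {
      pick <- sample(length(avail), 2)
      a <- avail[pick[1]]; b <- avail[pick[2]]
      node <- paste0("n", k)
      level[node] <- 1L + max(level[a], level[b])
      joins[[k]] <- list(node = node, children = c(a, b))
      avail <- c(avail[-pick], node)
    }
    list(joins = joins, level = level)
  })
  level <- topo$level
  root <- topo$joins[[n_leaves - 1]]$node
  max_level <- level[root]

  ## phase 2: event-date ladder -----------------------------------------
  # leaf sampling dates are tied to the ladder: a leaf sits at a level
  # strictly below its parent node
  leaf_levels <- withr::with_seed(.child_rng(seed, "leaf-dates"), {
    vapply(leaves, function(lf) {
      parent <- topo$joins[[which(vapply(topo$joins, function(j) {
        lf %in% j$children
      }, logical(1)))[1]]]$node
      sample.int(level[parent], 1) - 1L
    }, integer(1))
  })
  # admixture events occupy dedicated ladder rungs interleaved between tree
  # levels; a rung in slot s (between levels s and s+1) needs >= 2 tree
  # edges spanning it (a recipient and a donor)
  edge_tbl <- dplyr::bind_rows(lapply(topo$joins, function(j) {
    tibble::tibble(from = j$node, to = j$children)
  }))
  lv_of <- function(nd) {
    ifelse(nd %in% leaves, leaf_levels[nd], level[nd])
  }
  span_count <- vapply(0:(max_level - 1), function(s) {
    sum(lv_of(edge_tbl$to) <= s & lv_of(edge_tbl$from) >= s + 1)
  }, numeric(1))
  good_slots <- (0:(max_level - 1))[span_count >= 2]
  if (n_admix > 0 && !length(good_slots)) {
    stop("admixture graph construction failed: no time-compatible edge pair")
  }

  ## phases 2-3: dated ladder + grafted admixture events, retried as a
  ## unit; on repeated failure fewer dedicated admixture rungs are used
  graph <- NULL
  last_err <- NULL
  n_extra0 <- if (n_admix > 0) min(n_admix, length(good_slots)) else 0
  for (attempt in seq_len(60)) {
    n_extra <- if (n_admix > 0) max(1, n_extra0 - (attempt - 1) %/% 10) else 0
    res <- try(withr::with_seed(.child_rng(seed, paste("build", attempt)), {
      slot_of_rung <- if (n_extra > 0) {
        sort(sample(good_slots, n_extra,
                    replace = n_extra > length(good_slots)))
      } else integer(0)
      # ladder: one rung per tree level plus the admixture rungs,
      # consecutive rungs separated by 20-120 generations (scaled)
      n_rungs <- max_level + n_extra
      gaps <- stats::runif(n_rungs, 20, 120) * scale
      cd <- cumsum(gaps)
      if (cd[n_rungs] > max_depth) {
        stop("cannot fit ", n_rungs, " event levels within max_depth = ",
             max_depth)
      }
      rung_of_level <- vapply(seq_len(max_level), function(l) {
        l + sum(slot_of_rung < l)
      }, numeric(1))
      level_date <- function(l) {
        ifelse(l == 0, 0, cd[rung_of_level[pmax(l, 1)]])
      }
      admix_dates <- cd[vapply(seq_along(slot_of_rung), function(i) {
        slot_of_rung[i] + i
      }, numeric(1))]

      nodes <- tibble::tibble(
        node = c(leaves, paste0("n", seq_len(n_leaves - 1))),
        date = unname(c(level_date(leaf_levels),
                        level_date(level[paste0("n", seq_len(n_leaves - 1))]))),
        type = c(rep("leaf", n_leaves),
                 rep("divergence", n_leaves - 2), "root")
      )
      edges <- edge_tbl
      edges$id <- seq_len(nrow(edges))
      g <- list(
        nodes = nodes, edges = edges[, c("id", "from", "to")],
        admix = tibble::tibble(node = character(), donor_edge = integer(),
                               prop = numeric()),
        max_depth = max_depth
      )
      # every admixture rung receives at least one event (round robin), so
      # the event ladder keeps its 20-120 generation spacing
      rung_seq <- admix_dates[(seq_len(n_admix) - 1) %% max(1, n_extra) + 1]
      for (k in seq_len(n_admix)) {
        g <- .graft_admixture(g, paste0("adm", k), rung_seq[k])
      }
      g
    }), silent = TRUE)
    if (!inherits(res, "try-error")) { graph <- res; break }
    last_err <- attr(res, "condition")
  }
  if (is.null(graph)) {
    stop("admixture graph construction failed: ",
         conditionMessage(last_err))
  }

  ## phases 4-5: effective sizes and proportions ------------------------
  graph$edges$ne <- withr::with_seed(
    .child_rng(seed, "ne"),
    round(stats::runif(nrow(graph$edges), 1000, 10000))
  )
  graph$admix$prop <- withr::with_seed(
    .child_rng(seed, "props"),
    stats::runif(nrow(graph$admix), 0.10, 0.50)
  )
  graph$scale <- scale
  structure(graph, class = "admixture_graph")
}

# insert one pulse admixture event at ladder date `d`: pick a recipient
# edge whose span strictly contains d, split it there, and pick a donor
# edge also strictly spanning d
.graft_admixture <- function(graph, name, d) {
  dates <- stats::setNames(graph$nodes$date, graph$nodes$node)
  spans <- data.frame(
    id = graph$edges$id,
    top = dates[graph$edges$from],
    bot = dates[graph$edges$to]
  )
  ok <- spans$bot < d & d < spans$top
  # existing pulse attachment points must stay strictly inside their edges
  bad <- graph$admix$donor_edge[abs(dates[graph$admix$node] - d) < 1e-9]
  recip_ok <- ok & !(spans$id %in% bad)
  if (sum(ok) < 2 || !any(recip_ok)) {
    stop("admixture graph construction failed: no time-compatible edge pair")
  }
  for (try in seq_len(1000)) {
    ids <- spans$id[recip_ok]
    pick <- data.frame(edge = ids[sample.int(length(ids), 1)], date = d)
    donor_ok <- spans$id != pick$edge & spans$bot < pick$date & pick$date < spans$top
    if (!any(donor_ok)) next
    donor <- spans$id[donor_ok][sample.int(sum(donor_ok), 1)]
    e <- graph$edges[graph$edges$id == pick$edge, ]
    new_id <- max(graph$edges$id) + 1L
    graph$nodes <- dplyr::bind_rows(
      graph$nodes,
      tibble::tibble(node = name, date = pick$date, type = "admixture")
    )
    graph$edges <- dplyr::bind_rows(
      graph$edges[graph$edges$id != pick$edge, ],
      tibble::tibble(id = c(pick$edge, new_id),
                     from = c(e$from, name), to = c(name, e$to))
    )
    # upper segment keeps the old id so existing donor references pointing
    # at dates above the split stay valid; re-point references below it
    older <- graph$admix$donor_edge == pick$edge &
      dates[graph$admix$node] < pick$date
    graph$admix$donor_edge[older] <- new_id
    graph$admix <- dplyr::bind_rows(
      graph$admix,
      tibble::tibble(node = name, donor_edge = donor, prop = NA_real_)
    )
    return(graph)
  }
  stop("admixture graph construction failed: donor search budget exhausted")
}

#' Build an admixture graph from explicit tables
#'
#' Constructor for hand-specified histories (case studies, fixtures, unit
#' tests). No ladder-spacing constraints are imposed; structural invariants
#' (acyclicity, strict dating) still apply.
#'
#' @param nodes Tibble with `node`, `date`, `type`
#'   (leaf/divergence/admixture/root).
#' @param edges Tibble with `id`, `from`, `to`, `ne`.
#' @param admix Tibble with `node`, `donor_edge`, `prop` (may be empty).
#' @param max_depth Nominal depth bound (default: max node date).
#' @return An `admixture_graph`.
#' @export
admixture_graph <- function(nodes, edges,
                            admix = tibble::tibble(node = character(),
                                                   donor_edge = integer(),
                                                   prop = numeric()),
                            max_depth = max(nodes$date)) {
  g <- structure(
    list(nodes = tibble::as_tibble(nodes), edges = tibble::as_tibble(edges),
         admix = tibble::as_tibble(admix), max_depth = max_depth,
         scale = max(1, max_depth / 800)),
    class = "admixture_graph"
  )
  dates <- stats::setNames(g$nodes$date, g$nodes$node)
  if (any(dates[g$edges$to] >= dates[g$edges$from])) {
    stop("child node not strictly younger than parent")
  }
  g
}

#' @export
print.admixture_graph <- function(x, ...) {
  cat(sprintf(
    "<admixture_graph> %d leaves, %d admixture events, depth %.0f generations\n",
    sum(x$nodes$type == "leaf"), nrow(x$admix),
    max(x$nodes$date)
  ))
  invisible(x)
}

#' Leaves of an admixture graph with their sampling dates
#' @param graph An [random_admixture_graph()] object.
#' @return Tibble with `node` and `date`.
#' @export
graph_leaves <- function(graph) {
  dplyr::filter(graph$nodes, .data$type == "leaf")[, c("node", "date")]
}

#' Extend all terminal branches to the present
#'
#' Sets every leaf sampling date to 0, keeping topology, effective sizes and
#' admixture proportions unchanged; terminal branches accumulate more drift.
#'
#' @param graph An [random_admixture_graph()] object.
#' @return The modified `admixture_graph`.
#' @export
extend_to_present <- function(graph) {
  stopifnot(inherits(graph, "admixture_graph"))
  graph$nodes$date[graph$nodes$type == "leaf"] <- 0
  graph
}

#' Validate admixture-graph invariants
#'
#' Checks acyclicity, leaf/admixture-event counts, strict child-younger-than-
#' parent dating, the depth bound, the 20-120 generation spacing of the event
#' ladder (scaled by depth/800), effective-size and proportion ranges.
#'
#' @param graph An `admixture_graph`.
#' @param n_leaves,n_admix Expected counts (NULL to skip).
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_admixture_graph <- function(graph, n_leaves = NULL, n_admix = NULL) {
  stopifnot(inherits(graph, "admixture_graph"))
  nodes <- graph$nodes; edges <- graph$edges
  dates <- stats::setNames(nodes$date, nodes$node)
  if (!is.null(n_leaves) && sum(nodes$type == "leaf") != n_leaves) {
    stop("leaf count mismatch")
  }
  if (!is.null(n_admix) && nrow(graph$admix) != n_admix) {
    stop("admixture event count mismatch")
  }
  if (any(dates[edges$to] >= dates[edges$from])) {
    stop("child node not strictly younger than parent")
  }
  if (max(nodes$date) > graph$max_depth) stop("graph deeper than max_depth")
  # pulse attachment points must lie strictly inside their donor edge
  if (nrow(graph$admix)) {
    d <- dates[graph$admix$node]
    top <- dates[edges$from[match(graph$admix$donor_edge, edges$id)]]
    bot <- dates[edges$to[match(graph$admix$donor_edge, edges$id)]]
    if (any(d <= bot | d >= top)) stop("pulse date outside donor edge span")
    if (any(graph$admix$prop < 0.10 | graph$admix$prop > 0.50)) {
      stop("admixture proportion outside [0.10, 0.50]")
    }
  }
  if (!is.null(edges$ne) &&
      any(edges$ne < 1000 | edges$ne > 10000)) {
    stop("edge effective size outside [1000, 10000]")
  }
  scale <- if (!is.null(graph$scale)) graph$scale else max(1, graph$max_depth / 800)
  ev <- sort(unique(nodes$date[nodes$date > 0]))
  gaps <- diff(c(0, ev))
  if (any(gaps < 20 * scale - 1e-9 | gaps > 120 * scale + 1e-9)) {
    stop("event ladder spacing outside 20-120 generations (scaled)")
  }
  # acyclicity via topological elimination
  g <- edges
  repeat {
    sinks <- setdiff(g$to, g$from)
    if (!length(sinks)) break
    g <- g[!g$to %in% sinks, ]
    if (!nrow(g)) break
  }
  if (nrow(g)) stop("graph contains a cycle")
  invisible(TRUE)
}

#' Serialize an admixture graph to a TSV record and back
#'
#' One record per edge (`edge` rows: id, parent, child, dates, Ne) and per
#' admixture event (`admix` rows: node, donor edge, proportion). The round
#' trip is exact.
#'
#' @param graph An `admixture_graph`.
#' @param path Output file.
#' @return `read_graph_tsv()` returns the `admixture_graph`.
#' @export
write_graph_tsv <- function(graph, path) {
  dates <- stats::setNames(graph$nodes$date, graph$nodes$node)
  types <- stats::setNames(graph$nodes$type, graph$nodes$node)
  rec <- rbind(
    data.frame(
      record = "edge", id = graph$edges$id, a = graph$edges$from,
      b = graph$edges$to,
      x = format(dates[graph$edges$from], digits = 17),
      y = format(dates[graph$edges$to], digits = 17),
      z = as.character(graph$edges$ne), w = types[graph$edges$to],
      stringsAsFactors = FALSE
    ),
    data.frame(
      record = "admix", id = graph$admix$donor_edge, a = graph$admix$node,
      b = "", x = format(graph$admix$prop, digits = 17), y = "",
      z = "", w = "", stringsAsFactors = FALSE
    ),
    data.frame(
      record = "meta", id = 0L, a = "", b = "", x = "", y = "",
      z = format(graph$max_depth, digits = 17), w = "",
      stringsAsFactors = FALSE
    )
  )
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  rec <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  ed <- rec[rec$record == "edge", ]
  am <- rec[rec$record == "admix", ]
  edges <- tibble::tibble(
    id = as.integer(ed$id), from = ed$a, to = ed$b, ne = as.numeric(ed$z)
  )
  node_dates <- c(
    stats::setNames(as.numeric(ed$x), ed$a),
    stats::setNames(as.numeric(ed$y), ed$b)
  )
  node_dates <- node_dates[!duplicated(names(node_dates))]
  types <- stats::setNames(ed$w, ed$b)
  root <- setdiff(edges$from, edges$to)[1]
  nodes <- tibble::tibble(
    node = names(node_dates),
    date = unname(node_dates),
    type = dplyr::if_else(names(node_dates) == root, "root",
                          unname(types[names(node_dates)]))
  )
  admix <- tibble::tibble(
    node = am$a, donor_edge = as.integer(am$id), prop = as.numeric(am$x)
  )
  max_depth <- as.numeric(rec$z[rec$record == "meta"][1])
  structure(
    list(nodes = nodes, edges = edges, admix = admix, max_depth = max_depth,
         scale = max(1, max_depth / 800)),
    class = "admixture_graph"
  )
}
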