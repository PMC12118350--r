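#' Ancestry flow through an admixture graph
#'
#' Backwards-in-time propagation of ancestry mass from a sampled population
#' (or from an internal lineage point) up through the graph. Every edge is
#' split into segments at the dates where pulse admixture events attach to
#' it; the function returns, for each segment, the probability that a
#' lineage from the origin traverses it. These occupancies are the basis of
#' expected f-statistics, cladality and symmetry tests, and
#' ancestry-proportion propagation.
#'
#' @keywords internal
#' @noRd
.graph_segments <- function(graph) {
  dates <- stats::setNames(graph$nodes$date, graph$nodes$node)
  segs <- lapply(seq_len(nrow(graph$edges)), function(i) {
    e <- graph$edges[i, ]
    cuts <- sort(unique(dates[graph$admix$node[graph$admix$donor_edge == e$id]]))
    bounds <- c(dates[e$to], cuts, dates[e$from])
    tibble::tibble(
      edge = e$id, bot = bounds[-length(bounds)], top = bounds[-1],
      ne = e$ne
    )
  })
  dplyr::bind_rows(segs)
}

# occupancy of each segment by ancestry mass flowing up from `origin`
# (a leaf name, or a list(edge =, date =) lineage point)
.ancestry_flow <- function(graph, origin, segs = .graph_segments(graph)) {
  dates <- stats::setNames(graph$nodes$date, graph$nodes$node)
  edges <- graph$edges
  admix <- graph$admix
  prop <- stats::setNames(admix$prop, admix$node)
  donor <- stats::setNames(admix$donor_edge, admix$node)

  # per-edge list of (enter_date, mass)
  entry <- vector("list", max(edges$id))
  push <- function(edge_id, at, mass) {
    entry[[edge_id]] <<- rbind(entry[[edge_id]], c(at, mass))
  }
  if (is.character(origin)) {
    term <- edges$id[edges$to == origin]
    if (!length(term)) stop("unknown origin leaf: ", origin)
    push(term, dates[origin], 1)
  } else {
    push(origin$edge, origin$date, 1)
  }

  # process nodes in date order: mass arriving at an edge's top node moves
  # into the parent edge(s)
  ord <- graph$nodes[order(graph$nodes$date), ]
  for (i in seq_len(nrow(ord))) {
    nd <- ord$node[i]
    in_edges <- edges$id[edges$from == nd]
    mass <- 0
    for (e in in_edges) {
      if (!is.null(entry[[e]])) mass <- mass + sum(entry[[e]][, 2])
    }
    if (mass <= 0) next
    out_edge <- edges$id[edges$to == nd]
    if (nd %in% admix$node) {
      push(out_edge, dates[nd], mass * (1 - prop[nd]))
      push(donor[nd], dates[nd], mass * prop[nd])
    } else if (length(out_edge)) {
      push(out_edge, dates[nd], mass)
    } # root: mass leaves the graph
  }
  occ <- vapply(seq_len(nrow(segs)), function(i) {
    en <- entry[[segs$edge[i]]]
    if (is.null(en)) return(0)
    sum(en[en[, 1] <= segs$bot[i] + 1e-9, 2])
  }, numeric(1))
  occ
}

# covariance-with-root c(X, Y) = sum over segments of drift * occX * occY
# for a drift vector (per segment)
.flow_cov <- function(occ_x, occ_y, drift) sum(drift * occ_x * occ_y)

#' Expected f4 statistic of an admixture graph
#'
#' Computed analytically from the graph: drift per edge segment is
#' duration / (2 Ne) and the expectation follows from shared-path
#' covariances of ancestry flows.
#'
#' @param graph An [random_admixture_graph()] object.
#' @param pops Character vector of 4 leaf names (A, B; C, D).
#' @param drift Optional per-segment drift override (used for
#'   branch-length randomization).
#' @return Expected f4 value (drift units).
#' @export
expected_f4 <- function(graph, pops, drift = NULL) {
  segs <- .graph_segments(graph)
  if (is.null(drift)) drift <- (segs$top - segs$bot) / (2 * segs$ne)
  fl <- lapply(unique(pops), function(p) .ancestry_flow(graph, p, segs))
  names(fl) <- unique(pops)
  c_ <- function(x, y) .flow_cov(fl[[x]], fl[[y]], drift)
  c_(pops[1], pops[3]) - c_(pops[1], pops[4]) -
    c_(pops[2], pops[3]) + c_(pops[2], pops[4])
}

#' Classify a 2-way qpAdm model on an admixture graph as FP or TP
#'
#' Applies topological rules to the simulated history (its topology and
#' admixture proportions) to decide whether "target = source1 + source2" is
#' a false-positive model. The rules, checked in order:
#' \enumerate{
#'   \item the target is strictly cladal with a proxy source (expected f4 of
#'     target/proxy against all other leaf pairs is a structural zero, i.e.
#'     zero at the simulated branch lengths and at randomized redraws);
#'   \item a proxy source descends from a gene flow leaving the target's
#'     direct lineage after the target's last admixture event;
#'   \item a proxy source is symmetrically related to both true ancestry
#'     sources of the target (represents neither), or both proxies
#'     represent the same true source;
#'   \item a proxy source represents a true source but derives less than
#'     40\% of its ancestry from it;
#'   \item a true source of the target is a deep-branching lineage not
#'     represented by any sampled population and a proxy stands in for it.
#' }
#' The true sources are the two parent lineages of the last admixture event
#' on the target's unbroken lineage, each taken up to the point where it
#' merges with the other parent lineage. Rule 5 is evaluated before rules 3
#' and 4 (an unsamplable source makes every 2-way model for the target
#' false); the reported `rule` id always refers to the list above. Targets
#' without admixture get label `"no-admixture"` (their models count as
#' negatives).
#'
#' @param graph An [random_admixture_graph()] object.
#' @param target,sources Leaf names (2 sources).
#' @param n_redraws Branch-length randomization redraws for structural-zero
#'   tests (default 10).
#' @param seed Seed for the redraws.
#' @return One-row tibble: `target`, `source1`, `source2`, `label` (`"TP"`,
#'   `"FP"` or `"no-admixture"`), `rule` (first triggering FP rule id or
#'   `NA`), `aeh_diff` (admixture-event count of the target minus the
#'   average over sources).
#' @export
classify_ags_model <- function(graph, target, sources, n_redraws = 10,
                               seed = 1) {
  stopifnot(length(sources) == 2)
  leaves <- graph_leaves(graph)$node
  stopifnot(all(c(target, sources) %in% leaves))
  segs <- .graph_segments(graph)
  dates <- stats::setNames(graph$nodes$date, graph$nodes$node)
  edges <- graph$edges
  tol <- 1e-9

  drift0 <- (segs$top - segs$bot) / (2 * segs$ne)
  drifts <- withr::with_seed(.child_rng(seed, "drift-redraws"), {
    c(list(drift0), lapply(seq_len(n_redraws), function(k) {
      stats::runif(nrow(segs), 0.001, 0.2)
    }))
  })

  flows <- lapply(leaves, function(p) .ancestry_flow(graph, p, segs))
  names(flows) <- leaves

  # admixture events on a leaf's history; unbroken-lineage events have
  # occupancy 1 on the edge below the event
  child_edge <- stats::setNames(
    edges$id[match(graph$admix$node, edges$from)], graph$admix$node
  )
  aeh <- vapply(leaves, function(p) {
    if (!nrow(graph$admix)) return(0L)
    sum(vapply(graph$admix$node, function(a) {
      any(segs$edge == child_edge[a] & flows[[p]] > tol)
    }, logical(1)))
  }, integer(1))
  aeh_diff <- aeh[target] - mean(aeh[sources])

  out <- function(label, rule = NA_integer_) {
    tibble::tibble(target = target, source1 = sources[1],
                   source2 = sources[2], label = label, rule = rule,
                   aeh_diff = unname(aeh_diff))
  }

  # target's unbroken-lineage admixture events
  occ_t <- flows[[target]]
  top_seg <- function(edge_id) {
    ix <- which(segs$edge == edge_id)
    ix[which.max(segs$bot[ix])]
  }
  unbroken <- graph$admix$node[vapply(graph$admix$node, function(a) {
    abs(occ_t[top_seg(child_edge[a])] - 1) < tol
  }, logical(1))]
  if (!length(unbroken)) return(out("no-admixture"))
  a_star <- unbroken[which.min(dates[unbroken])]
  d_star <- dates[a_star]
  recip_edge <- edges$id[edges$to == a_star]
  donor_edge <- graph$admix$donor_edge[graph$admix$node == a_star]
  ts_points <- list(
    recipient = list(edge = recip_edge, date = d_star),
    donor = list(edge = donor_edge, date = d_star)
  )
  ts_flows <- lapply(ts_points, function(p) .ancestry_flow(graph, p, segs))

  others <- setdiff(leaves, c(target, sources))
  structural_zero <- function(value_fn) {
    all(vapply(drifts, function(d) abs(value_fn(d)) < tol, logical(1)))
  }
  cval <- function(fx, fy, d) .flow_cov(fx, fy, d)

  ## rule 1: strict cladality of target with a proxy source
  for (p in sources) {
    rest <- setdiff(leaves, c(target, p))
    if (length(rest) >= 2) {
      pairs <- utils::combn(rest, 2)
      cladal <- all(vapply(seq_len(ncol(pairs)), function(k) {
        structural_zero(function(d) {
          cval(flows[[target]], flows[[pairs[1, k]]], d) -
            cval(flows[[target]], flows[[pairs[2, k]]], d) -
            cval(flows[[p]], flows[[pairs[1, k]]], d) +
            cval(flows[[p]], flows[[pairs[2, k]]], d)
        })
      }, logical(1)))
      if (cladal) return(out("FP", 1L))
    }
  }

  ## rule 2: proxy descends from a gene flow off the target's post-A* lineage
  for (a in graph$admix$node) {
    if (dates[a] >= d_star - 1e-9) next
    de <- graph$admix$donor_edge[graph$admix$node == a]
    # the pulse leaves from (de, date_a): on the target's unbroken lineage
    # iff the target fully occupies the donor-edge segment above that date
    ix <- which(segs$edge == de & abs(segs$bot - dates[a]) < 1e-9)
    if (!length(ix) || occ_t[ix] < 1 - tol) next
    for (p in sources) {
      if (any(flows[[p]][segs$edge == child_edge[a]] > tol)) {
        return(out("FP", 2L))
      }
    }
  }

  ## a true source is the lineage from the event point up to where it
  ## merges with the other parent lineage; its exclusive segments (occupied
  ## by this parent's flow but not the other's) carry the source-specific
  ## drift
  excl <- list(
    recipient = ts_flows$recipient > tol & ts_flows$donor < tol,
    donor = ts_flows$donor > tol & ts_flows$recipient < tol
  )
  ## share of a true source's exclusive drift that population p also
  ## traverses (at any ancestry fraction)
  ts_share <- function(p, side) {
    ix <- which(excl[[side]])
    if (!length(ix)) return(0)
    d <- drift0[ix]
    sum(d[flows[[p]][ix] > tol]) / sum(d)
  }
  ## maximal ancestry fraction p derives through the source's exclusive
  ## lineage
  ts_frac <- function(p, side) {
    ix <- which(excl[[side]])
    if (!length(ix)) return(0)
    max(flows[[p]][ix])
  }

  ## rule 5: a true source is deep-branching and unrepresented - no sampled
  ## population shares a substantial part of its exclusive drift (checked
  ## before rules 3-4: with an unsamplable source every 2-way model for
  ## this target is false)
  for (side in c("recipient", "donor")) {
    shares <- vapply(setdiff(leaves, target), function(x) ts_share(x, side),
                     numeric(1))
    if (max(shares) < 0.2) return(out("FP", 5L))
  }

  ## representation of true sources by proxies (rules 3-4)
  rep_of <- vapply(sources, function(p) {
    if (structural_zero(function(d) {
      cval(flows[[p]], ts_flows$recipient, d) -
        cval(flows[[p]], ts_flows$donor, d)
    })) return(NA_character_)
    diff <- cval(flows[[p]], ts_flows$recipient, drift0) -
      cval(flows[[p]], ts_flows$donor, drift0)
    if (diff > 0) "recipient" else "donor"
  }, character(1))

  ## rule 3: a proxy represents no true source, or both represent the same
  if (any(is.na(rep_of))) return(out("FP", 3L))
  if (rep_of[1] == rep_of[2]) return(out("FP", 3L))

  ## rule 4: represented but with < 40% ancestry from the true source
  for (k in seq_along(sources)) {
    if (ts_frac(sources[k], rep_of[k]) < 0.4) return(out("FP", 4L))
  }
  out("TP")
}

#' Classify all 2-way models of an enumeration
#'
#' @param graph An [random_admixture_graph()] object.
#' @param models Tibble with `target` and `sources` (list column of pairs),
#'   as produced by [enumerate_ags_rotating()].
#' @inheritParams classify_ags_model
#' @return `models` with `label`, `rule`, `aeh_diff` columns appended.
#' @export
classify_ags_models <- function(graph, models, n_redraws = 10, seed = 1) {
  res <- lapply(seq_len(nrow(models)), function(i) {
    classify_ags_model(graph, models$target[i], models$sources[[i]],
                       n_redraws = n_redraws, seed = seed)
  })
  res <- dplyr::bind_rows(res)
  models$label <- res$label
  models$rule <- res$rule
  models$aeh_diff <- res$aeh_diff
  models
}
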