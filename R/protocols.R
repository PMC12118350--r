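#' Enumerate the rotating screen over a 13-group history
#'
#' Every group in turn is the target and every unordered pair of the
#' remaining groups the proxy sources, with the other 10 groups forming the
#' "right" set: 13 x choose(12, 2) = 858 two-way models for 13 groups.
#'
#' @param groups Character vector of group labels (exactly 13 for the
#'   standard screen; any length >= 4 is accepted).
#' @return Tibble with `target`, `sources` (list column of length-2
#'   vectors), `right` (list column), `n`.
#' @export
enumerate_ags_rotating <- function(groups) {
  if (length(groups) < 4) stop("rotating enumeration needs at least 4 groups")
  if (anyDuplicated(groups)) stop("group labels must be distinct")
  out <- lapply(groups, function(tg) {
    rest <- setdiff(groups, tg)
    pairs <- utils::combn(rest, 2, simplify = FALSE)
    tibble::tibble(
      target = tg, sources = pairs,
      right = lapply(pairs, function(p) setdiff(rest, p)), n = 2L
    )
  })
  dplyr::bind_rows(out)
}

#' Enumerate the nonrotating screen over an admixture graph
#'
#' The 6 oldest sampled groups (ties in sampling dates resolved in
#' alphabetical order) form a fixed "right" set; each of the remaining 7
#' groups is a target with every pair of the other 6 as proxy sources:
#' 7 x choose(6, 2) = 105 two-way models.
#'
#' @param graph An [random_admixture_graph()] object (13 leaves).
#' @param n_right Size of the fixed right set (default 6).
#' @return Tibble as in [enumerate_ags_rotating()], plus a `right_set`
#'   attribute.
#' @export
enumerate_ags_nonrotating <- function(graph, n_right = 6) {
  leaves <- graph_leaves(graph)
  leaves <- leaves[order(-leaves$date, leaves$node), ]
  right <- leaves$node[seq_len(n_right)]
  rest <- sort(setdiff(leaves$node, right))
  out <- lapply(rest, function(tg) {
    pairs <- utils::combn(setdiff(rest, tg), 2, simplify = FALSE)
    tibble::tibble(target = tg, sources = pairs,
                   right = list(right), n = 2L)
  })
  out <- dplyr::bind_rows(out)
  attr(out, "right_set") <- right
  out
}

#' Temporal stratification of models
#'
#' Keeps distal models only: models whose target sampling date is less than
#' or equal to the sampling dates of all proxy sources.
#'
#' @param models Tibble with `target` and `sources` (list column).
#' @param dates Named vector of sampling dates (generations before present).
#' @return The filtered tibble.
#' @export
filter_distal <- function(models, dates) {
  keep <- vapply(seq_len(nrow(models)), function(i) {
    all(dates[models$target[i]] <= dates[models$sources[[i]]])
  }, logical(1))
  models[keep, ]
}

#' Standard sample table of a stepping-stone simulation
#'
#' The deme x time-slice grid of sampled groups, with the group labels
#' [simulate_ssl()] assigns.
#'
#' @param landscape A [build_hex_landscape()] object.
#' @param slices Sampling times (generations before present).
#' @return Tibble with `group`, `deme`, `date`.
#' @export
ssl_sample_table <- function(landscape, slices = c(0, 100, 300)) {
  tidyr::crossing(date = slices, deme = landscape$demes$deme) |>
    dplyr::mutate(group = paste0("d", .data$deme, "_t", .data$date)) |>
    dplyr::select("group", "deme", "date")
}

#' Draw a randomized qpAdm experiment on a landscape
#'
#' Randomized landscape sampling for the four screening protocols. Densities
#' are quoted as the rotating-set size (13 or 18); nonrotating protocols use
#' 10 or 15 proxies and "right" demes.
#' \describe{
#'   \item{distal nonrotating}{target at present; 10/15 "right" demes from
#'     the 300-generation slice; 10/15 proxy demes from the 100-generation
#'     slice.}
#'   \item{proximal nonrotating}{10/15 "right" demes from the 300-generation
#'     slice; 10/15 proxies from the present and 100-generation slices
#'     pooled; the target from the 100- or 300-generation slice.}
#'   \item{distal rotating}{target at present; a rotating set of 13/18
#'     deme-slice draws from the 100- and 300-generation slices pooled.}
#'   \item{proximal rotating}{a set of 14/19 deme-slice draws from all three
#'     slices; one non-300-generation member becomes the target and the rest
#'     rotate.}
#' }
#'
#' @param samples A [ssl_sample_table()] tibble (all three slices present).
#' @param protocol One of `"distal_rotating"`, `"proximal_rotating"`,
#'   `"distal_nonrotating"`, `"proximal_nonrotating"`.
#' @param density 13 or 18 (rotating-set quotation).
#' @param seed Integer seed.
#' @return A `qpadm_experiment`: list with `protocol`, `density`, `target`
#'   (one-row tibble), `pool` (candidate proxy sources; the rotating set for
#'   rotating protocols), `right` (fixed right set or `NULL`), `rotating`.
#' @export
draw_randomized_experiment <- function(samples,
                                       protocol = c("distal_rotating",
                                                    "proximal_rotating",
                                                    "distal_nonrotating",
                                                    "proximal_nonrotating"),
                                       density = 13, seed = 1) {
  protocol <- match.arg(protocol)
  stopifnot(density %in% c(13, 18))
  slices <- sort(unique(samples$date))
  if (length(slices) < 3) stop("need all three time slices in the sample table")
  present <- slices[1]; mid <- slices[2]; old <- slices[3]
  n_nr <- if (density == 13) 10 else 15
  take <- function(df, n) {
    if (nrow(df) < n) stop("insufficient demes in slice for the requested density")
    df[sample.int(nrow(df), n), ]
  }
  withr::with_seed(.child_rng(seed, paste("experiment", protocol, density)), {
    out <- switch(protocol,
      distal_nonrotating = {
        target <- take(samples[samples$date == present, ], 1)
        right <- take(samples[samples$date == old, ], n_nr)
        pool <- take(samples[samples$date == mid, ], n_nr)
        list(target = target, pool = pool, right = right, rotating = FALSE)
      },
      proximal_nonrotating = {
        right <- take(samples[samples$date == old, ], n_nr)
        pool <- take(samples[samples$date %in% c(present, mid), ], n_nr)
        tcand <- samples[samples$date %in% c(mid, old), ]
        tcand <- dplyr::anti_join(tcand, dplyr::bind_rows(pool, right),
                                  by = "group")
        target <- take(tcand, 1)
        list(target = target, pool = pool, right = right, rotating = FALSE)
      },
      distal_rotating = {
        target <- take(samples[samples$date == present, ], 1)
        pool <- take(samples[samples$date %in% c(mid, old), ], density)
        list(target = target, pool = pool, right = NULL, rotating = TRUE)
      },
      proximal_rotating = {
        set <- take(samples, density + 1)
        tcand <- set[set$date != old, ]
        if (nrow(tcand) == 0) stop("no eligible target in the rotating draw")
        target <- tcand[sample.int(nrow(tcand), 1), ]
        list(target = target, pool = set[set$group != target$group, ],
             right = NULL, rotating = TRUE)
      }
    )
    structure(c(out, list(protocol = protocol, density = density)),
              class = "qpadm_experiment")
  })
}

#' Draw a systematic qpAdm experiment around a central target
#'
#' The rotating set (or proxy set) of 16 demes comes exclusively from the
#' 1st and 3rd circles of demes around the target: `k_first` nearest
#' neighbours (hop distance 1) plus `16 - k_first` demes of the 3rd circle
#' (hop distance 3), sampled at 100 generations before present. The
#' nonrotating variant uses the same proxies and a fixed right set of 16
#' demes of the 3rd circle sampled at 300 generations.
#'
#' @param landscape A [build_hex_landscape()] object.
#' @param target_deme Central target deme id (sampled at present).
#' @param k_first Number of 1st-circle demes included (0-6).
#' @param rotating Build the rotating (TRUE) or nonrotating variant.
#' @param n_set Size of the rotating/proxy set (default 16).
#' @param seed Seed for choosing which 3rd-circle demes fill the set.
#' @return A `qpadm_experiment` (see [draw_randomized_experiment()]).
#' @export
draw_systematic_experiment <- function(landscape, target_deme, k_first,
                                       rotating = TRUE, n_set = 16, seed = 1) {
  stopifnot(k_first >= 0, k_first <= 6)
  circle1 <- which(landscape$hops[target_deme, ] == 1)
  circle3 <- which(landscape$hops[target_deme, ] == 3)
  if (length(circle1) < 6 || length(circle3) < n_set - k_first) {
    missing <- max(0, 6 - length(circle1)) + max(0, n_set - k_first - length(circle3))
    stop("incomplete circles around deme ", target_deme, ": ", missing,
         " demes short (1st circle ", length(circle1), ", 3rd circle ",
         length(circle3), ")")
  }
  withr::with_seed(.child_rng(seed, paste("systematic", target_deme, k_first)), {
    first <- sort(sample(circle1, k_first))
    third <- sort(sample(circle3, n_set - k_first))
    pool <- tibble::tibble(
      deme = c(first, third), date = 100,
      group = paste0("d", c(first, third), "_t100")
    )
    target <- tibble::tibble(deme = target_deme, date = 0,
                             group = paste0("d", target_deme, "_t0"))
    right <- if (!rotating) {
      r3 <- sort(sample(circle3, min(n_set, length(circle3))))
      tibble::tibble(deme = r3, date = 300, group = paste0("d", r3, "_t300"))
    } else NULL
    structure(
      list(target = target, pool = pool, right = right, rotating = rotating,
           protocol = if (rotating) "distal_rotating" else "distal_nonrotating",
           density = n_set),
      class = "qpadm_experiment"
    )
  })
}

#' @export
print.qpadm_experiment <- function(x, ...) {
  cat(sprintf(
    "<qpadm_experiment> %s, target %s, %d candidate sources%s\n",
    x$protocol, x$target$group, nrow(x$pool),
    if (is.null(x$right)) " (rotating)" else sprintf(", %d right groups", nrow(x$right))
  ))
  invisible(x)
}

#' All models of one complexity level of an experiment
#'
#' For a rotating experiment the sources are every `complexity`-sized
#' combination of the rotating set and the remaining members form the
#' "right" set; for a nonrotating experiment the right set is fixed.
#'
#' @param experiment A `qpadm_experiment`.
#' @param complexity Number of proxy sources per model.
#' @return Tibble with `target`, `sources`, `right` (list columns), `n`,
#'   `source_demes` (list column of deme ids), `target_deme`.
#' @export
experiment_models <- function(experiment, complexity) {
  pool <- experiment$pool
  stopifnot(complexity >= 1, complexity <= nrow(pool))
  combos <- utils::combn(nrow(pool), complexity, simplify = FALSE)
  tibble::tibble(
    target = experiment$target$group,
    sources = lapply(combos, function(ix) pool$group[ix]),
    right = lapply(combos, function(ix) {
      if (experiment$rotating) pool$group[-ix] else experiment$right$group
    }),
    n = as.integer(complexity),
    source_demes = lapply(combos, function(ix) pool$deme[ix]),
    target_deme = experiment$target$deme
  )
}

#' The grid of 36 composite model-feasibility criteria
#'
#' Three conditions on admixture-fraction estimates (EAF), crossed with
#' conditions on the model P-value and on the P-values of "trailing"
#' simpler models:
#' \itemize{
#'   \item EAF condition: `strict` (every weight +/- 2 SE inside (0, 1)),
#'     `plain` (every weight inside (0, 1)), `loose` (inside (-0.3, 1.3));
#'   \item model P-value threshold: 0.001, 0.01, 0.05, 0.1 or 0.5 with
#'     trailing models rejected at the same threshold (`same`), or with
#'     trailing models not checked (`none`);
#'   \item or model P-value threshold 0.05 or 0.5 with trailing models
#'     rejected at the fixed 0.001 threshold (`fixed`).
#' }
#'
#' @return Tibble of 36 rows: `eaf_condition`, `p_main`, `trailing_rule`,
#'   `p_trailing`, `label`.
#' @export
feasibility_criteria <- function() {
  thresholds <- c(0.001, 0.01, 0.05, 0.1, 0.5)
  base <- dplyr::bind_rows(
    tibble::tibble(p_main = thresholds, trailing_rule = "same",
                   p_trailing = thresholds),
    tibble::tibble(p_main = thresholds, trailing_rule = "none",
                   p_trailing = NA_real_),
    tibble::tibble(p_main = c(0.05, 0.5), trailing_rule = "fixed",
                   p_trailing = 0.001)
  )
  out <- tidyr::crossing(eaf_condition = c("strict", "plain", "loose"), base)
  out$label <- sprintf("%s:%g:%s", out$eaf_condition, out$p_main,
                       out$trailing_rule)
  out[, c("eaf_condition", "p_main", "trailing_rule", "p_trailing", "label")]
}

#' Parse a criterion label
#' @param label String like `"strict:0.01:same"`.
#' @return One-row tibble as in [feasibility_criteria()].
#' @export
parse_criterion <- function(label) {
  grid <- feasibility_criteria()
  hit <- grid[grid$label == label, ]
  if (nrow(hit) != 1) stop("unknown criterion label: ", label)
  hit
}

#' Apply a composite feasibility criterion to a fitted model
#'
#' A model is feasible when (1) its weights satisfy the criterion's EAF
#' condition (all intervals open), (2) its P-value is at or above the main
#' threshold, and (3) when the criterion checks trailing models, every
#' trailing simpler model is rejected (P-value strictly below the trailing
#' threshold).
#'
#' @param result A [fit_qpadm()] result, or a list/one-row tibble with
#'   `weights`, `se`, `p_value`.
#' @param trailing Numeric vector of trailing-model P-values (required iff
#'   the criterion checks them).
#' @param criterion A row of [feasibility_criteria()] or a label string.
#' @return Logical.
#' @export
apply_feasibility <- function(result, trailing = NULL, criterion) {
  if (is.character(criterion)) criterion <- parse_criterion(criterion)
  w <- result$weights; se <- result$se; p <- result$p_value
  eaf_ok <- switch(criterion$eaf_condition,
    strict = all(w - 2 * se > 0 & w + 2 * se < 1),
    plain = all(w > 0 & w < 1),
    loose = all(w > -0.3 & w < 1.3),
    stop("unknown EAF condition")
  )
  p_ok <- p >= criterion$p_main
  trail_ok <- if (criterion$trailing_rule == "none") {
    TRUE
  } else {
    if (is.null(trailing)) stop("criterion requires trailing-model P-values")
    all(trailing < criterion$p_trailing)
  }
  eaf_ok && p_ok && trail_ok
}

#' Run a qpAdm experiment
#'
#' Fits all models of an experiment from complexity 1 up to
#' `max_complexity`, assesses feasibility under one criterion, and derives
#' the stop level: the first complexity level with at least one feasible
#' model. In exhaustive mode (the randomized-protocol convention) all levels
#' are fitted regardless and the stop level derived afterwards; otherwise
#' fitting stops at the stop level (the systematic-protocol convention).
#' Trailing-model P-values reuse the right set of the model under test;
#' models whose fit fails are recorded and counted as rejections.
#'
#' @param experiment A `qpadm_experiment`.
#' @param criterion Criterion row or label (see [feasibility_criteria()]).
#' @param fsource A [compute_f2_blocks()] object or [snp_dataset()].
#' @param max_complexity Highest model complexity (default 4).
#' @param exhaustive Fit all levels regardless of feasibility.
#' @param blgsize Block size for allsnps mode.
#' @return An `experiment_outcome`: list with `models` (tibble: one row per
#'   model with `level`, `p_value`, `weights`, `se`, `feasible`, `error`),
#'   `stop_level` (NA when nothing is feasible), `feasible_at_stop`,
#'   `criterion`, `experiment`.
#' @export
run_experiment <- function(experiment, criterion, fsource, max_complexity = 4,
                           exhaustive = TRUE, blgsize = 4e6) {
  if (is.character(criterion)) criterion <- parse_criterion(criterion)
  cache <- new.env(parent = emptyenv())
  p_of <- function(target, sources, right) {
    key <- paste(target, paste(sources, collapse = ","),
                 paste(sort(right), collapse = ","), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- tryCatch({
      if (length(sources) == 1) {
        qpwave_test(c(target, sources), right, rank = 0, fsource,
                    blgsize = blgsize)$p_value
      } else {
        fit_qpadm(target, sources, right, fsource, blgsize = blgsize)$p_value
      }
    }, error = function(e) NA_real_)
    cache[[key]] <- p
    p
  }
  rows <- list()
  stop_level <- NA_integer_
  for (lev in seq_len(max_complexity)) {
    models <- experiment_models(experiment, lev)
    for (i in seq_len(nrow(models))) {
      tg <- models$target[i]; src <- models$sources[[i]]
      rt <- models$right[[i]]
      fit <- tryCatch(
        if (lev == 1) {
          qw <- qpwave_test(c(tg, src), rt, rank = 0, fsource, blgsize = blgsize)
          list(weights = stats::setNames(1, src), se = stats::setNames(0, src),
               p_value = qw$p_value)
        } else {
          fit_qpadm(tg, src, rt, fsource, blgsize = blgsize)
        },
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          level = lev, target = tg, sources = list(src), right = list(rt),
          p_value = NA_real_, weights = list(NULL), se = list(NULL),
          feasible = FALSE, error = conditionMessage(fit)
        )
        next
      }
      trailing <- NULL
      if (criterion$trailing_rule != "none" && lev >= 1) {
        tm <- trailing_models(tg, src)
        trailing <- vapply(seq_len(nrow(tm)), function(j) {
          p_of(tm$target[j], tm$sources[[j]], rt)
        }, numeric(1))
        trailing[is.na(trailing)] <- 1  # failed trailing fit: not rejected
      }
      feas <- apply_feasibility(fit, trailing, criterion)
      rows[[length(rows) + 1]] <- tibble::tibble(
        level = lev, target = tg, sources = list(src), right = list(rt),
        p_value = fit$p_value, weights = list(fit$weights),
        se = list(fit$se), feasible = feas, error = NA_character_
      )
    }
    lev_rows <- dplyr::bind_rows(rows)
    if (is.na(stop_level) && any(lev_rows$feasible[lev_rows$level == lev])) {
      stop_level <- lev
      if (!exhaustive) break
    }
  }
  models <- dplyr::bind_rows(rows)
  structure(
    list(models = models, stop_level = stop_level,
         feasible_at_stop = if (!is.na(stop_level)) {
           models[models$level == stop_level & models$feasible, ]
         } else models[0, ],
         criterion = criterion, experiment = experiment),
    class = "experiment_outcome"
  )
}

#' @export
print.experiment_outcome <- function(x, ...) {
  cat(sprintf(
    "<experiment_outcome> %d models fitted, stop level %s, %d feasible at stop\n",
    nrow(x$models), ifelse(is.na(x$stop_level), "none", x$stop_level),
    nrow(x$feasible_at_stop)
  ))
  invisible(x)
}

#' Model competition among feasible models of one target
#'
#' Retests feasible models against enlarged "right" sets built from the
#' alternative proxy sources of the competing models. In `"pool-right"` mode
#' every model is retested once with all alternative sources (those not in
#' the model) added to its right set; in `"one-by-one"` mode a model is
#' retested once per alternative source and survives only if it is never
#' rejected. A single feasible model passes automatically.
#'
#' @param feasible Tibble of feasible models (`target`, `sources`, `right`
#'   list columns) for one target.
#' @param mode `"pool-right"` or `"one-by-one"`.
#' @param criterion Criterion row or label; trailing models are not
#'   re-examined at the competition step.
#' @param fsource f-statistic source passed to [fit_qpadm()].
#' @param blgsize Block size for allsnps mode.
#' @return The rows of `feasible` that survive competition, with a
#'   `competition_p` list column of the retest P-values.
#' @export
model_competition <- function(feasible, mode = c("pool-right", "one-by-one"),
                              criterion, fsource, blgsize = 4e6) {
  mode <- match.arg(mode)
  if (is.character(criterion)) criterion <- parse_criterion(criterion)
  if (nrow(feasible) == 0) return(feasible)
  stopifnot(length(unique(feasible$target)) == 1)
  if (nrow(feasible) == 1) {
    feasible$competition_p <- list(numeric(0))
    return(feasible)
  }
  all_sources <- unique(unlist(feasible$sources))
  keep <- logical(nrow(feasible))
  pvals <- vector("list", nrow(feasible))
  criterion_nt <- criterion
  criterion_nt$trailing_rule <- "none"
  for (i in seq_len(nrow(feasible))) {
    src <- feasible$sources[[i]]
    alts <- setdiff(all_sources, src)
    retests <- if (mode == "pool-right") {
      list(unique(c(feasible$right[[i]], alts)))
    } else {
      lapply(alts, function(a) unique(c(feasible$right[[i]], a)))
    }
    ok <- TRUE
    ps <- numeric(0)
    for (rt in retests) {
      fit <- tryCatch(
        fit_qpadm(feasible$target[i], src, rt, fsource, blgsize = blgsize),
        error = function(e) NULL
      )
      if (is.null(fit)) { ok <- FALSE; break }
      ps <- c(ps, fit$p_value)
      if (!apply_feasibility(fit, NULL, criterion_nt)) { ok <- FALSE; break }
    }
    keep[i] <- ok
    pvals[[i]] <- ps
  }
  out <- feasible[keep, ]
  out$competition_p <- pvals[keep]
  out
}
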