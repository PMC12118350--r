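#' Spatial optimality metrics of an admixture model on a landscape
#'
#' For a target deme and n source demes: the maximal and average
#' source-target (ST) hop distance; the minimal source-target-source (STS)
#' angle in degrees; the normalized angle (scaled so the maximal possible
#' angle of the complexity class - 180, 120 and 90 degrees for 2-, 3- and
#' 4-way models - equals 9, the maximal possible ST distance on the
#' standard landscape); and the Euclidean distance in the (ST distance,
#' normalized angle) plane to the ideal symmetric model at (1, 9). When a
#' source occupies the target deme the angle, normalized angle and distance
#' to ideal are undefined (`NA`).
#'
#' @param landscape A [build_hex_landscape()] object.
#' @param target_deme Target deme id.
#' @param source_demes Integer vector of source deme ids (n >= 1; angles
#'   need n >= 2).
#' @param variant Use the maximal (`"max"`) or average (`"avg"`) ST distance
#'   in the distance-to-ideal computation.
#' @return One-row tibble: `n`, `max_st`, `avg_st`, `min_angle`,
#'   `norm_angle`, `dist_ideal`.
#' @export
model_optimality <- function(landscape, target_deme, source_demes,
                             variant = c("max", "avg")) {
  variant <- match.arg(variant)
  n <- length(source_demes)
  d <- st_distance(landscape, target_deme, source_demes)
  max_st <- max(d); avg_st <- mean(d)
  angle <- if (n >= 2) min_sts_angle(landscape, target_deme, source_demes)
           else NA_real_
  norm <- angle * 9 / .max_angle(n)
  st <- if (variant == "max") max_st else avg_st
  dist_ideal <- if (n >= 2) sqrt((st - 1)^2 + (9 - norm)^2) else NA_real_
  tibble::tibble(
    n = n, max_st = max_st, avg_st = avg_st,
    min_angle = angle, norm_angle = norm, dist_ideal = dist_ideal
  )
}

# maximal possible minimal pairwise angle around the target
.max_angle <- function(n) {
  if (n < 2) return(NA_real_)
  c(180, 120, 90, 72, 60, 51.4285714285714)[n - 1]
}

#' Classify a model as optimal or nonoptimal
#'
#' Default rule: optimal iff the distance to the ideal symmetric model is at
#' most `threshold` (5: the median of the metric over the randomized screen
#' divided by 2 and rounded). Alternative rule `"nearest-neighbors"`:
#' optimal iff every source is at ST distance <= 1. Models with undefined
#' angle return `NA` under the distance rule.
#'
#' @param metrics Tibble from [model_optimality()] (vectorized over rows).
#' @param threshold Distance threshold (default 5).
#' @param rule `"distance"` or `"nearest-neighbors"`.
#' @return Logical vector.
#' @export
classify_optimal <- function(metrics, threshold = 5,
                             rule = c("distance", "nearest-neighbors")) {
  rule <- match.arg(rule)
  if (rule == "distance") {
    metrics$dist_ideal <= threshold
  } else {
    metrics$max_st <= 1
  }
}

#' Prestudy odds of the systematic screen by direct enumeration
#'
#' In the systematic setup the candidate source set holds `n_first` nearest
#' neighbours of the target and `n_third` demes of the third circle, and a
#' model is true when all its sources are nearest neighbours. The odds of an
#' n-way model being true are then purely combinatorial:
#' choose(n_first, n) / (choose(n_first + n_third, n) - choose(n_first, n)).
#'
#' @param complexity Model complexity n.
#' @param n_first Nearest-neighbour demes in the set (default 6).
#' @param n_third Third-circle demes in the set (default 10).
#' @return Prestudy odds (true / false model count).
#' @export
prestudy_odds_systematic <- function(complexity, n_first = 6, n_third = 10) {
  true <- choose(n_first, complexity)
  all <- choose(n_first + n_third, complexity)
  true / (all - true)
}

#' Prestudy odds of randomized screens from experiment geometry
#'
#' Draws randomized experiments for the four protocols and both sampling
#' densities, enumerates every model of the requested complexity, computes
#' optimality metrics, drops models with undefined angles, classifies with
#' [classify_optimal()] and pools the optimal / nonoptimal counts over all
#' draws.
#'
#' @param landscape A [build_hex_landscape()] object.
#' @param complexity Model complexity (2, 3 or 4).
#' @param n_per_cell Experiments per protocol x density cell.
#' @param seed Integer seed.
#' @param threshold Distance-to-ideal threshold.
#' @param protocols,densities Protocol and density grids to pool over.
#' @return List with `odds`, `n_optimal`, `n_nonoptimal`, `n_undefined`,
#'   `n_experiments`.
#' @export
prestudy_odds_randomized <- function(landscape, complexity, n_per_cell = 500,
                                     seed = 1, threshold = 5,
                                     protocols = c("distal_rotating",
                                                   "proximal_rotating",
                                                   "distal_nonrotating",
                                                   "proximal_nonrotating"),
                                     densities = c(13, 18)) {
  samples <- ssl_sample_table(landscape)
  xy <- as.matrix(landscape$demes[, c("x", "y")])
  hops <- landscape$hops
  pair_idx <- utils::combn(complexity, 2)
  max_ang <- .max_angle(complexity)
  n_opt <- 0; n_non <- 0; n_undef <- 0; n_exp <- 0
  for (protocol in protocols) {
    for (density in densities) {
      for (k in seq_len(n_per_cell)) {
        ex <- draw_randomized_experiment(
          samples, protocol, density,
          seed = .child_rng(seed, paste(protocol, density, k))
        )
        tgt <- ex$target$deme
        pool <- ex$pool$deme
        combos <- utils::combn(length(pool), complexity)
        src <- matrix(pool[combos], nrow = complexity)
        d <- matrix(hops[tgt, src], nrow = complexity)
        vx <- matrix(xy[src, 1] - xy[tgt, 1], nrow = complexity)
        vy <- matrix(xy[src, 2] - xy[tgt, 2], nrow = complexity)
        len <- sqrt(vx^2 + vy^2)
        undef <- colSums(d == 0) > 0
        ang <- rep(Inf, ncol(src))
        for (p in seq_len(ncol(pair_idx))) {
          i <- pair_idx[1, p]; j <- pair_idx[2, p]
          cosang <- (vx[i, ] * vx[j, ] + vy[i, ] * vy[j, ]) / (len[i, ] * len[j, ])
          ang <- pmin(ang, acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
        }
        max_st <- apply(d, 2, max)
        dist_ideal <- sqrt((max_st - 1)^2 + (9 - ang * 9 / max_ang)^2)
        opt <- dist_ideal <= threshold
        n_opt <- n_opt + sum(opt[!undef])
        n_non <- n_non + sum(!opt[!undef])
        n_undef <- n_undef + sum(undef)
        n_exp <- n_exp + 1
      }
    }
  }
  list(odds = n_opt / n_non, n_optimal = n_opt, n_nonoptimal = n_non,
       n_undefined = n_undef, n_experiments = n_exp)
}

#' Flag an experiment whose outcome would be misleading in practice
#'
#' At the stop level of the experiment, models are split into nonrejected
#' (feasible) and rejected; the experiment is misleading when the minimal
#' distance to the ideal symmetric model among nonrejected models exceeds
#' the minimum among rejected models by more than `margin` (default 8, the
#' diagonal of a right triangle with legs 2 in the optimality-metric
#' plane). When the stop level is 1 the optimality plane does not exist and
#' the rule compares minimal ST distances instead. Models with undefined
#' angle are excluded from the distance comparison; an experiment with no
#' rejected models at the stop level is not misleading.
#'
#' @param outcome An [run_experiment()] outcome.
#' @param landscape A [build_hex_landscape()] object.
#' @param margin Threshold on the distance difference (default 8).
#' @param variant ST-distance variant passed to [model_optimality()].
#' @return Logical (`NA` when the experiment has no stop level).
#' @export
classify_experiment_misleading <- function(outcome, landscape, margin = 8,
                                           variant = "max") {
  if (is.na(outcome$stop_level)) return(NA)
  lev <- outcome$stop_level
  models <- outcome$models[outcome$models$level == lev, ]
  demes <- .model_demes(models, outcome$experiment)
  if (lev == 1) {
    stat <- vapply(seq_len(nrow(models)), function(i) {
      st_distance(landscape, demes$target_deme[i], demes$source_demes[[i]])
    }, numeric(1))
  } else {
    stat <- vapply(seq_len(nrow(models)), function(i) {
      model_optimality(landscape, demes$target_deme[i],
                       demes$source_demes[[i]], variant)$dist_ideal
    }, numeric(1))
  }
  nonrej <- stat[models$feasible & !is.na(stat)]
  rej <- stat[!models$feasible & !is.na(stat)]
  if (!length(rej) || !length(nonrej)) return(FALSE)
  if (lev == 1) {
    min(nonrej) > min(rej)
  } else {
    (min(nonrej) - min(rej)) > margin
  }
}

# map group labels of an outcome's models back to deme ids
.model_demes <- function(models, experiment) {
  lookup <- dplyr::bind_rows(experiment$target, experiment$pool,
                             experiment$right)
  list(
    target_deme = lookup$deme[match(models$target, lookup$group)],
    source_demes = lapply(models$sources, function(s) {
      lookup$deme[match(s, lookup$group)]
    })
  )
}

#' Binned densities of all vs feasible models in optimality-metric space
#'
#' Bins models in the (ST distance, minimal STS angle) plane, counts all and
#' feasible models per bin, and reports Spearman's rank correlation between
#' the two counts over populated bins. Models with undefined angle are
#' excluded.
#'
#' @param metrics Tibble of per-model optimality metrics (from
#'   [model_optimality()], row-bound).
#' @param feasible Logical vector, one element per row of `metrics`.
#' @param st_breaks,angle_breaks Bin boundaries.
#' @param variant Bin on `max_st` (`"max"`) or `avg_st` (`"avg"`).
#' @return List with `bins` (tibble: bin mid-points, `n_all`, `n_feasible`)
#'   and `rho` (Spearman correlation; `NA` when undefined).
#' @export
summarize_metric_space <- function(metrics, feasible,
                                   st_breaks = seq(0, 10, 1),
                                   angle_breaks = seq(0, 180, 20),
                                   variant = c("max", "avg")) {
  variant <- match.arg(variant)
  st <- if (variant == "max") metrics$max_st else metrics$avg_st
  ok <- !is.na(metrics$min_angle)
  st <- st[ok]; ang <- metrics$min_angle[ok]; fe <- feasible[ok]
  bs <- cut(st, st_breaks, include.lowest = TRUE)
  ba <- cut(ang, angle_breaks, include.lowest = TRUE)
  key <- interaction(bs, ba, drop = TRUE)
  n_all <- tapply(fe, key, length)
  n_fea <- tapply(fe, key, sum)
  bins <- tibble::tibble(
    bin = names(n_all), n_all = as.integer(n_all), n_feasible = as.integer(n_fea)
  )
  rho <- if (nrow(bins) >= 3 && sum(bins$n_feasible) > 0 &&
             stats::sd(bins$n_feasible) > 0) {
    suppressWarnings(stats::cor(bins$n_all, bins$n_feasible, method = "spearman"))
  } else NA_real_
  list(bins = bins, rho = rho)
}

#' @describeIn summarize_metric_space ggplot of the binned densities.
#' @param object Result of `summarize_metric_space()`.
#' @param ... Ignored.
#' @export
plot_metric_space <- function(object, ...) {
  long <- tidyr::pivot_longer(object$bins, c("n_all", "n_feasible"),
                              names_to = "set", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$count,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6)) +
    ggplot2::labs(x = "(ST distance, min STS angle) bin", y = "models")
}
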