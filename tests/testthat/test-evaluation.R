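land <- build_hex_landscape()
centre <- which.min((land$demes$x - mean(land$demes$x))^2 +
                      (land$demes$y - mean(land$demes$y))^2)

test_that("optimality metrics follow the ideal-point geometry", {
  nbr <- land$edges$to[land$edges$from == centre]
  xy <- land$demes
  east <- nbr[which(abs(xy$x[nbr] - (xy$x[centre] + 1)) < 1e-9 &
                      abs(xy$y[nbr] - xy$y[centre]) < 1e-9)]
  west <- nbr[which(abs(xy$x[nbr] - (xy$x[centre] - 1)) < 1e-9 &
                      abs(xy$y[nbr] - xy$y[centre]) < 1e-9)]
  ideal <- model_optimality(land, centre, c(east, west))
  expect_equal(ideal$max_st, 1)
  expect_equal(ideal$min_angle, 180)
  expect_equal(ideal$norm_angle, 9)
  expect_equal(ideal$dist_ideal, 0)
  expect_true(classify_optimal(ideal))
  # forced arithmetic: maxST 3, angle 60 -> sqrt((3-1)^2 + (9-3)^2)
  two_e <- which(abs(xy$x - (xy$x[centre] + 3)) < 1e-9 &
                   abs(xy$y - xy$y[centre]) < 1e-9)
  ne3 <- which(abs(xy$x - (xy$x[centre] + 1.5)) < 1e-9 &
                 abs(xy$y - (xy$y[centre] + 3 * sqrt(3) / 2)) < 1e-9)
  m <- model_optimality(land, centre, c(two_e, ne3))
  expect_equal(m$max_st, 3)
  expect_equal(m$min_angle, 60, tolerance = 1e-9)
  expect_equal(m$dist_ideal, sqrt((3 - 1)^2 + (9 - 3)^2), tolerance = 1e-9)
  expect_false(classify_optimal(m))
  expect_gte(m$max_st, m$avg_st)
  # source on the target deme: undefined angle
  und <- model_optimality(land, centre, c(centre, east))
  expect_true(is.na(und$min_angle) && is.na(und$dist_ideal))
})

test_that("systematic prestudy odds match exhaustive enumeration", {
  # independent oracle: enumerate the 16-deme systematic set and classify
  # by the nearest-neighbours-only rule
  ex <- draw_systematic_experiment(land, centre, k_first = 6, seed = 1)
  combos <- utils::combn(nrow(ex$pool), 2)
  truth <- vapply(seq_len(ncol(combos)), function(k) {
    all(st_distance(land, centre, ex$pool$deme[combos[, k]]) <= 1)
  }, logical(1))
  expect_equal(sum(truth), 15)
  expect_equal(length(truth), 120)
  expect_equal(prestudy_odds_systematic(2), sum(truth) / sum(!truth))
  for (n in c(3, 6)) {
    combos <- utils::combn(nrow(ex$pool), n)
    truth <- vapply(seq_len(ncol(combos)), function(k) {
      all(st_distance(land, centre, ex$pool$deme[combos[, k]]) <= 1)
    }, logical(1))
    expect_equal(prestudy_odds_systematic(n), sum(truth) / sum(!truth))
  }
})

test_that("count-based and rate-based FDR agree on random confusion tables", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      n <- sample(50:500, 1)
      truth <- runif(n) < runif(1, 0.05, 0.5)
      pred <- ifelse(truth, runif(n) < 0.7, runif(n) < 0.2)
      cs <- confusion_summary(truth, pred)
      if (cs$tp + cs$fp == 0 || cs$fp + cs$tn == 0 || cs$tp + cs$fn == 0) next
      expect_equal(fdr_from_rates(cs$odds, cs$fpr, cs$fnr), cs$fdr,
                   tolerance = 1e-12)
      expect_equal(cs$ppv + cs$fdr, 1, tolerance = 1e-12)
    }
  })
  expect_equal(fdr_from_rates(0.5, 0, 0.3), 0)
  expect_equal(fdr_from_rates(2, 0.1, 1), 1)
  expect_error(fdr_from_rates(1, 0, 1), "undefined")
})

test_that("misleading-experiment rule compares distance extremes", {
  mk_outcome <- function(level, feas, target_deme, source_demes) {
    structure(list(
      models = tibble::tibble(
        level = level, target = "t",
        sources = lapply(seq_along(feas), function(i) {
          paste0("s", source_demes[[i]])
        }),
        right = list("r"), p_value = 0.5,
        weights = list(NULL), se = list(NULL),
        feasible = feas, error = NA_character_
      ),
      stop_level = level[1],
      experiment = structure(list(
        target = tibble::tibble(group = "t", deme = target_deme, date = 0),
        pool = tibble::tibble(
          group = paste0("s", unique(unlist(source_demes))),
          deme = unique(unlist(source_demes)), date = 100
        ),
        right = NULL, rotating = TRUE
      ), class = "qpadm_experiment")
    ), class = "experiment_outcome")
  }
  xy <- land$demes
  east <- which(abs(xy$x - (xy$x[centre] + 1)) < 1e-9 &
                  abs(xy$y - xy$y[centre]) < 1e-9)
  west <- which(abs(xy$x - (xy$x[centre] - 1)) < 1e-9 &
                  abs(xy$y - xy$y[centre]) < 1e-9)
  # two adjacent demes far from the target: large distance, tiny angle,
  # distance-to-ideal near its maximum
  far_a <- which(land$hops[centre, ] >= 4)[1]
  far_b <- intersect(land$edges$to[land$edges$from == far_a],
                     which(land$hops[centre, ] >= 4))[1]
  stopifnot(!is.na(far_b))
  bad <- model_optimality(land, centre, c(far_a, far_b))$dist_ideal
  expect_gt(bad - 0, 8) # the ideal pair scores 0, so the margin is exceeded
  # feasible model is the awful one, rejected model ideal: misleading
  oc <- mk_outcome(c(2L, 2L), c(TRUE, FALSE), centre,
                   list(c(far_a, far_b), c(east, west)))
  expect_true(classify_experiment_misleading(oc, land))
  # all models feasible: vacuous, not misleading
  oc2 <- mk_outcome(c(2L, 2L), c(TRUE, TRUE), centre,
                    list(c(far_a, far_b), c(east, west)))
  expect_false(classify_experiment_misleading(oc2, land))
  # 1-way rule compares minimal ST distances directly
  oc3 <- mk_outcome(c(1L, 1L), c(TRUE, FALSE), centre,
                    list(far_a, east))
  expect_true(classify_experiment_misleading(oc3, land))
  oc4 <- mk_outcome(c(1L, 1L), c(FALSE, TRUE), centre,
                    list(far_a, east))
  expect_false(classify_experiment_misleading(oc4, land))
})

test_that("metric-space summaries track feasibility structure", {
  withr::with_seed(5, {
    mets <- dplyr::bind_rows(lapply(1:300, function(i) {
      tgt <- sample(64, 1)
      src <- sample(setdiff(1:64, tgt), 2)
      model_optimality(land, tgt, src)
    }))
  })
  all_f <- summarize_metric_space(mets, rep(TRUE, nrow(mets)))
  expect_equal(all_f$rho, 1)
  none <- summarize_metric_space(mets, rep(FALSE, nrow(mets)))
  expect_true(is.na(none$rho))
  # feasibility concentrated at symmetric short models decorrelates counts
  sharp <- mets$dist_ideal <= 4 & !is.na(mets$dist_ideal)
  loose <- mets$dist_ideal <= 12 & !is.na(mets$dist_ideal)
  rho_sharp <- summarize_metric_space(mets, sharp)$rho
  rho_loose <- summarize_metric_space(mets, loose)$rho
  expect_lt(rho_sharp, rho_loose)
})

test_that("randomized prestudy odds fall steeply with model complexity", {
  o2 <- prestudy_odds_randomized(land, 2, n_per_cell = 20, seed = 17)
  o3 <- prestudy_odds_randomized(land, 3, n_per_cell = 10, seed = 17)
  expect_gt(o2$odds, 2.5 * o3$odds)
  expect_equal(o2$n_experiments, 160)
})
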