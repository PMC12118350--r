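land <- build_hex_landscape()
samples <- ssl_sample_table(land)

test_that("rotating enumeration yields all bisections", {
  models <- enumerate_ags_rotating(LETTERS[1:13])
  expect_equal(nrow(models), 858)
  expect_true(all(vapply(seq_len(nrow(models)), function(i) {
    length(models$sources[[i]]) == 2 &&
      length(models$right[[i]]) == 10 &&
      !models$target[i] %in% models$sources[[i]] &&
      !any(models$sources[[i]] %in% models$right[[i]]) &&
      !models$target[i] %in% models$right[[i]]
  }, logical(1))))
  expect_equal(nrow(enumerate_ags_rotating(LETTERS[1:4])), 12)
  expect_error(enumerate_ags_rotating(LETTERS[1:3]), "at least 4")
})

test_that("nonrotating enumeration fixes the six oldest groups as rights", {
  g <- random_admixture_graph(13, 10, 800, seed = 9)
  models <- enumerate_ags_nonrotating(g)
  expect_equal(nrow(models), 105)
  right <- attr(models, "right_set")
  dates <- stats::setNames(graph_leaves(g)$date, graph_leaves(g)$node)
  expect_true(min(dates[right]) >= max(dates[setdiff(LETTERS[1:13], right)]) ||
                all(sort(dates, decreasing = TRUE)[1:6] == sort(dates[right],
                                                                decreasing = TRUE)))
  # all-equal dates: alphabetical tie-break
  g2 <- extend_to_present(g)
  m2 <- enumerate_ags_nonrotating(g2)
  expect_equal(attr(m2, "right_set"), LETTERS[1:6])
  # distal filtering never keeps a model with a source younger than target
  distal <- filter_distal(models, dates)
  if (nrow(distal)) {
    expect_true(all(vapply(seq_len(nrow(distal)), function(i) {
      dates[distal$target[i]] <= min(dates[distal$sources[[i]]])
    }, logical(1))))
  }
})

test_that("randomized experiment draws respect protocol membership rules", {
  ex <- draw_randomized_experiment(samples, "distal_nonrotating", 13, seed = 5)
  expect_equal(ex$target$date, 0)
  expect_equal(nrow(ex$right), 10)
  expect_true(all(ex$right$date == 300))
  expect_equal(nrow(ex$pool), 10)
  expect_true(all(ex$pool$date == 100))

  ex18 <- draw_randomized_experiment(samples, "distal_nonrotating", 18, seed = 5)
  expect_equal(nrow(ex18$pool), 15)

  exp_pr <- draw_randomized_experiment(samples, "proximal_rotating", 13, seed = 6)
  expect_false(exp_pr$target$date == 300)
  expect_equal(nrow(exp_pr$pool), 13)

  exd <- draw_randomized_experiment(samples, "distal_rotating", 18, seed = 7)
  expect_equal(exd$target$date, 0)
  expect_equal(nrow(exd$pool), 18)
  expect_true(all(exd$pool$date %in% c(100, 300)))

  exn <- draw_randomized_experiment(samples, "proximal_nonrotating", 13, seed = 8)
  expect_true(exn$target$date %in% c(100, 300))
  expect_true(all(exn$pool$date %in% c(0, 100)))
  expect_true(all(exn$right$date == 300))
  expect_false(exn$target$group %in% c(exn$pool$group, exn$right$group))
})

test_that("proximal-rotating draws cover deme-slices near-uniformly", {
  counts <- table(factor(unlist(lapply(1:800, function(k) {
    ex <- draw_randomized_experiment(samples, "proximal_rotating", 13, seed = k)
    c(ex$target$group, ex$pool$group)
  })), levels = samples$group))
  chi <- stats::chisq.test(as.vector(counts))
  expect_gt(chi$p.value, 0.01)
})

test_that("systematic experiments compose first and third circles", {
  centre <- which.min((land$demes$x - mean(land$demes$x))^2 +
                        (land$demes$y - mean(land$demes$y))^2)
  ex6 <- draw_systematic_experiment(land, centre, k_first = 6, seed = 2)
  d6 <- st_distance(land, centre, ex6$pool$deme)
  expect_equal(sum(d6 == 1), 6)
  expect_equal(sum(d6 == 3), 10)
  ex0 <- draw_systematic_experiment(land, centre, k_first = 0, seed = 2)
  expect_true(all(st_distance(land, centre, ex0$pool$deme) == 3))
  exn <- draw_systematic_experiment(land, centre, k_first = 3,
                                    rotating = FALSE, seed = 2)
  expect_equal(nrow(exn$right), 16)
  expect_true(all(st_distance(land, centre, exn$right$deme) == 3))
  # boundary deme lacks a complete third circle
  corner <- which.max(land$demes$x^2 + land$demes$y^2)
  expect_error(draw_systematic_experiment(land, corner, 6), "incomplete")
})

test_that("the criterion grid holds exactly 36 distinct criteria", {
  grid <- feasibility_criteria()
  expect_equal(nrow(grid), 36)
  expect_equal(anyDuplicated(grid$label), 0)
  expect_equal(unname(table(grid$eaf_condition)), rep(12L, 3),
               ignore_attr = TRUE)
  expect_equal(sum(grid$trailing_rule == "fixed"), 6)
  expect_true(all(grid$p_trailing[grid$trailing_rule == "fixed"] == 0.001))
})

test_that("composite feasibility combines EAF, P-value and trailing rules", {
  res <- list(weights = c(0.6, 0.4), se = c(0.05, 0.05), p_value = 0.5)
  expect_true(apply_feasibility(res, trailing = c(1e-4, 1e-3, 5e-3),
                                "strict:0.01:same"))
  expect_false(apply_feasibility(res, trailing = c(1e-4, 0.5, 5e-3),
                                 "strict:0.01:same"))
  expect_error(apply_feasibility(res, NULL, "strict:0.01:same"), "trailing")
  bad <- list(weights = c(1.2, -0.2), se = c(0.01, 0.01), p_value = 0.9)
  expect_false(apply_feasibility(bad, NULL, "strict:0.5:none"))
  expect_false(apply_feasibility(bad, NULL, "plain:0.5:none"))
  expect_true(apply_feasibility(bad, NULL, "loose:0.5:none"))
  # monotone in the main threshold when trailing models are not checked
  for (eaf in c("strict", "plain", "loose")) {
    f <- vapply(c(0.001, 0.01, 0.05, 0.1, 0.5), function(p) {
      apply_feasibility(res, NULL, sprintf("%s:%g:none", eaf, p))
    }, logical(1))
    expect_true(all(diff(f) <= 0)) # raising the threshold never adds models
  }
})

test_that("experiments progress and stop at the first feasible level", {
  g <- alpha_graph()
  d <- simulate_ags_genotypes(g, n_chrom = 1, chrom_len = 1e7, seed = 31,
                              n_per_leaf = 6)
  f2 <- compute_f2_blocks(d, blgsize = 1e6)
  ex <- structure(
    list(
      target = tibble::tibble(group = "T", deme = 1, date = 0),
      pool = tibble::tibble(group = c("S1", "S2", "R4"), deme = 2:4,
                            date = 100),
      right = tibble::tibble(group = c("R1", "R2", "R3"), deme = 5:7,
                             date = 300),
      rotating = FALSE, protocol = "distal_nonrotating", density = 13
    ),
    class = "qpadm_experiment"
  )
  oc <- run_experiment(ex, "loose:0.01:none", f2, max_complexity = 2)
  expect_s3_class(oc$models, "tbl_df")
  expect_equal(nrow(oc$models), 3 + 3)
  if (!is.na(oc$stop_level) && oc$stop_level > 1) {
    expect_false(any(oc$models$feasible[oc$models$level < oc$stop_level]))
  }
  if (!is.na(oc$stop_level)) {
    expect_true(all(oc$feasible_at_stop$level == oc$stop_level))
    expect_gte(nrow(oc$feasible_at_stop), 1)
  }
  # level sizes for a rotating spec follow binomial counts
  exr <- draw_randomized_experiment(samples, "distal_rotating", 13, seed = 3)
  expect_equal(nrow(experiment_models(exr, 1)), 13)
  expect_equal(nrow(experiment_models(exr, 2)), 78)
  expect_equal(nrow(experiment_models(exr, 3)), 286)
  expect_equal(nrow(experiment_models(exr, 4)), 715)
})

test_that("model competition retests against alternative sources", {
  g <- alpha_graph()
  d <- simulate_ags_genotypes(g, n_chrom = 1, chrom_len = 1e7, seed = 32,
                              n_per_leaf = 6)
  f2 <- compute_f2_blocks(d, blgsize = 1e6)
  feas <- tibble::tibble(
    target = "T",
    sources = list(c("S1", "S2"), c("S1", "R4")),
    right = list(c("R1", "R2", "R3", "R4"), c("R1", "R2", "R3", "S2"))
  )
  # singleton passes untouched
  single <- model_competition(feas[1, ], "pool-right", "loose:0.01:none", f2)
  expect_equal(nrow(single), 1)
  expect_equal(length(single$competition_p[[1]]), 0)
  # one-by-one mode: k alternatives -> up to k retests per model
  res <- model_competition(feas, "one-by-one", "loose:0.5:none", f2)
  expect_true(all(vapply(res$competition_p, length, 1L) <= 1))
  resp <- model_competition(feas, "pool-right", "loose:0.5:none", f2)
  expect_true(all(vapply(resp$competition_p, length, 1L) <= 1))
})
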