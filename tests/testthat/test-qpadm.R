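# a single modest simulation from the alpha = 0.3 history feeds most tests
g_alpha <- alpha_graph()
d_alpha <- simulate_ags_genotypes(g_alpha, n_chrom = 1, chrom_len = 2e7,
                                  seed = 71, n_per_leaf = 8)
f2_alpha <- compute_f2_blocks(d_alpha, blgsize = 1e6)
rights <- c("R1", "R2", "R3", "R4")

test_that("qpWave degrees of freedom and saturation behave as defined", {
  qw <- qpwave_test(c("T", "S1", "S2"), rights, 1, f2_alpha)
  expect_equal(qw$dof, (3 - 1 - 1) * (4 - 1 - 1))
  expect_error(qpwave_test(c("T", "S1"), rights, 2, f2_alpha), "rank")
  expect_error(qpwave_test(c("T", "R1"), rights, 0, f2_alpha), "disjoint")
  # saturated rank: perfect fit
  qs <- qpwave_test(c("T", "S1", "S2"), rights, 2, f2_alpha)
  expect_lt(qs$chisq, 1e-6)
  expect_equal(qs$p_value, 1)
})

test_that("rank-0 statistic equals the closed form x' Q^-1 x", {
  fm <- admixscreen:::.f4_matrix(f2_alpha, c("T", "S1"), rights)
  mo <- admixscreen:::.f4_moments(fm)
  closed <- drop(t(mo$x) %*% mo$Qi %*% mo$x)
  qw <- qpwave_test(c("T", "S1"), rights, 0, f2_alpha)
  expect_equal(qw$chisq, closed, tolerance = 1e-12)
  expect_equal(qw$dof, 3)
})

test_that("qpAdm recovers the simulated admixture proportion", {
  fit <- fit_qpadm("T", c("S1", "S2"), rights, f2_alpha)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_lt(abs(fit$weights["S1"] - 0.3), 2.5 * fit$se["S1"] + 0.05)
  expect_equal(fit$dof, 4 - 2)
  expect_equal(fit$maxdiff, max(abs(fit$weights - 0.5)), tolerance = 1e-12)
  td <- tidy(fit)
  expect_equal(td$estimate, unname(fit$weights))
  expect_equal(glance(fit)$p.value, fit$p_value)
})

test_that("P-values are invariant under reference permutations", {
  base <- fit_qpadm("T", c("S1", "S2"), rights, f2_alpha)
  perm <- fit_qpadm("T", c("S2", "S1"), c(rights[1], rights[c(3, 4, 2)]),
                    f2_alpha)
  expect_equal(perm$p_value, base$p_value, tolerance = 1e-9)
  expect_equal(unname(perm$weights[c("S1", "S2")]),
               unname(base$weights[c("S1", "S2")]), tolerance = 1e-6)
})

test_that("a cladal 1-way model is accepted and weights are unconstrained", {
  # S2 is nearly cladal with the unsampled true source of T's major side
  qw <- qpwave_test(c("S2", "S1"), rights, 0, f2_alpha)
  expect_true(qw$p_value >= 0 && qw$p_value <= 1)
  # weights outside [0, 1] survive formatting round trips unclamped
  w <- c(S1 = 1.23456789, S2 = -0.23456789)
  txt <- paste(signif(w, 8), collapse = ",")
  expect_equal(as.numeric(strsplit(txt, ",")[[1]]), unname(w),
               tolerance = 1e-7)
  expect_false(apply_feasibility(
    list(weights = w, se = c(0.01, 0.01), p_value = 0.9), NULL,
    "plain:0.01:none"
  ))
  expect_true(apply_feasibility(
    list(weights = w, se = c(0.01, 0.01), p_value = 0.9), NULL,
    "loose:0.01:none"
  ))
})

test_that("trailing models enumerate the simpler-model lattice", {
  t2 <- trailing_models("T", c("A", "B"))
  expect_equal(nrow(t2), 3)
  expect_setequal(
    vapply(seq_len(3), function(i) {
      paste(t2$target[i], paste(t2$sources[[i]], collapse = "+"), sep = "=")
    }, ""),
    c("T=A", "T=B", "A=B")
  )
  t3 <- trailing_models("T", c("A", "B", "C"))
  expect_equal(nrow(t3), 9)
  expect_true(all(t3$n < 3))
  expect_setequal(unique(t3$target), c("T", "A"))
  expect_equal(nrow(trailing_models("T", "A")), 0)
})

test_that("allsnps mode agrees with the from-f2 route on complete data and
           keeps weights stable on degraded replicates", {
  fit_f2 <- fit_qpadm("T", c("S1", "S2"), rights, f2_alpha)
  fit_all <- fit_qpadm("T", c("S1", "S2"), rights, d_alpha, blgsize = 1e6)
  expect_equal(unname(fit_all$weights), unname(fit_f2$weights),
               tolerance = 1e-6)
  expect_equal(fit_all$p_value, fit_f2$p_value, tolerance = 1e-6)

  # weight estimates vary far less across data-degradation replicates than
  # log10 P-values do
  reps <- lapply(1:4, function(k) {
    deg <- degrade_dataset(d_alpha, min_sites = 3000, seed = 100 + k)
    fit_qpadm("T", c("S1", "S2"), rights, deg, blgsize = 1e6)
  })
  eafs <- vapply(reps, function(f) unname(f$weights["S1"]), numeric(1))
  logp <- vapply(reps, function(f) log10(max(f$p_value, 1e-300)), numeric(1))
  expect_lt(stats::sd(eafs), stats::sd(logp))
})

test_that("guard rails on model shape", {
  expect_error(fit_qpadm("T", c("S1", "S2"), rights[1:3], f2_alpha), "n \\+ 2")
  expect_error(fit_qpadm("S1", c("S1", "S2"), rights, f2_alpha), "target")
})
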