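test_that("one-group t matches the textbook formula", {
  res <- one_group_t(c(-1, 1, -1, 1))
  expect_equal(res$mean, 0)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # hand computation: mean 0.7, sd = sqrt(0.08/3), t = 0.7/(sd/2)
  res <- one_group_t(c(0.5, 0.7, 0.9, 0.7))
  expect_equal(res$mean, 0.7)
  expect_equal(res$t, 0.7 / (sqrt(0.08 / 3) / 2), tolerance = 1e-12)
  expect_equal(res$t, 8.5732141, tolerance = 1e-6)
  expect_equal(res$p, 2 * pt(-res$t, 3))

  expect_warning(res <- one_group_t(c(0.3, 0.3, 0.3)), "zero spread")
  expect_true(is.na(res$t))
  expect_error(one_group_t(c(1, 2)), ">= 3")
})

test_that("the four comparisons behave on constructed matrices", {
  d <- canonical_design()
  # all-zero matrix -> all means 0
  m0 <- ratio_matrix(matrix(0, 5, 16, dimnames = list(letters[1:5],
                                                      d$chip_id)),
                     d, stage = "dye_corrected_oriented")
  suppressWarnings(de0 <- run_comparisons(m0, n_perm = 100, seed = 1))
  expect_true(all(de0$all16$mean_log2_C_over_B6a == 0))
  expect_true(all(de0$m4$mean_log2_C_over_B6a == 0))

  # identical values at both ages -> age-dependency t = 0
  set.seed(20)
  row <- rnorm(8)
  v <- matrix(NA_real_, 1, 16, dimnames = list("g1", d$chip_id))
  v[1, d$age_months == 4] <- row
  v[1, d$age_months == 8] <- row
  m <- ratio_matrix(v, d, stage = "dye_corrected_oriented")
  suppressWarnings(de <- run_comparisons(m, n_perm = 100, seed = 1))
  expect_equal(de$age_dependency$t_stat, 0)
  expect_equal(de$age_dependency$mean_log2_C_over_B6a, 0)
})

test_that("a planted 8-month-only effect lands in the right comparison", {
  sim <- gen_two_color_experiment(n_genes = 200, effect_frac = 0.15,
                                  effect_size = 1, effect_age = "8m",
                                  sigma = 0.2, missing_rate = 0, seed = 21)
  suppressMessages(nr <- normalize_chips(sim$chips, sim$design))
  de <- run_comparisons(nr$matrix, n_perm = 200, seed = 3)
  eff <- sim$truth$gene_id[sim$truth$strain_effect_8m != 0]
  sgn <- sign(sim$truth$strain_effect_8m[sim$truth$strain_effect_8m != 0])
  m8 <- de$m8[match(eff, de$m8$gene_id), ]
  m4 <- de$m4[match(eff, de$m4$gene_id), ]
  # per-gene SE at n = 8, sigma = 0.2 is ~0.07; allow extra room for the
  # slight shrinkage the lowess and rescaling steps introduce
  se <- 0.2 / sqrt(8)
  dev8 <- m8$mean_log2_C_over_B6a - sgn
  expect_true(all(abs(dev8) < 4.5 * se))
  expect_lt(abs(mean(dev8)), 3 * se / sqrt(length(dev8)) + 0.02)
  expect_true(all(abs(m4$mean_log2_C_over_B6a) < 3.5 * se))
  # FC identity for one-group comparisons
  expect_equal(de$all16$FC, 2^de$all16$mean_log2_C_over_B6a)
})

test_that("comparison 1 mean equals the average of the per-age means", {
  sim <- gen_two_color_experiment(n_genes = 100, missing_rate = 0, seed = 22)
  suppressMessages(nr <- normalize_chips(sim$chips, sim$design))
  de <- run_comparisons(nr$matrix, n_perm = 100, seed = 2)
  expect_equal(de$all16$mean_log2_C_over_B6a,
               (de$m4$mean_log2_C_over_B6a + de$m8$mean_log2_C_over_B6a) / 2,
               tolerance = 1e-10)
})

test_that("permutation FDR separates planted signal from null genes", {
  # 20 strong genes among 500: all called, few false positives
  d <- canonical_design()
  set.seed(23)
  v <- matrix(rnorm(500 * 16, 0, 0.1), 500, 16,
              dimnames = list(sprintf("g%03d", 1:500), d$chip_id))
  v[1:20, ] <- v[1:20, ] + 2   # |t| >> 10
  m <- ratio_matrix(v, d, stage = "dye_corrected_oriented")
  st <- apply(v, 1, function(x) one_group_t(x)$t)
  q <- permutation_fdr(st, m, "all16", n_perm = 200, seed = 5)
  expect_true(all(q[1:20] < 0.05))
  expect_lte(sum(q[-(1:20)] < 0.05), 3)

  # q monotone non-increasing in |t|
  ord <- order(abs(st))
  expect_true(all(diff(q[ord]) <= 1e-12))
})

test_that("null data yields large q values and a single zero-t gene caps at 1", {
  d <- canonical_design()
  set.seed(24)
  v <- matrix(rnorm(300 * 16, 0, 0.2), 300, 16,
              dimnames = list(sprintf("g%03d", 1:300), d$chip_id))
  m <- ratio_matrix(v, d, stage = "dye_corrected_oriented")
  st <- apply(v, 1, function(x) one_group_t(x)$t)
  q <- permutation_fdr(st, m, "all16", n_perm = 200, seed = 6)
  expect_gt(median(q), 0.5)

  v1 <- matrix(c(-1, 1, -1, 1, -1, 1, -1, 1, -1, 1, -1, 1, -1, 1, -1, 1),
               1, 16, dimnames = list("g1", d$chip_id))
  m1 <- ratio_matrix(v1, d, stage = "dye_corrected_oriented")
  q1 <- permutation_fdr(0, m1, "all16", n_perm = 100, seed = 1)
  expect_equal(q1, 1)

  expect_error(permutation_fdr(st, m, "all16", n_perm = 50), ">= 100")
})

test_that("the regulated call uses inclusive fold thresholds and the FDR gate", {
  expect_true(call_regulated(0.8, 0.04))    # inclusive down boundary
  expect_true(call_regulated(1.2, 0.04))    # inclusive up boundary
  expect_false(call_regulated(1.1, 0.001))
  expect_false(call_regulated(2.0, 0.2))
  expect_false(call_regulated(NA, 0.01))
  expect_equal(call_regulated(c(1.5, 0.5, 1), c(0.01, 0.2, 0.01)),
               c(TRUE, FALSE, FALSE))
})
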