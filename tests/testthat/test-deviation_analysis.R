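test_that("deviation at the fixed-fixed node reflects the all-tied null edge case", {
  # both marginal vectors preserved => every null has exactly the observed
  # partition (the multiple-site indices are marginal-determined), so
  # delta = 0, strict p = 0, midrank p = 0.5
  set.seed(40)
  m <- random_pa(10, 14, fill = 0.35)
  set.seed(41)
  d_ref <- discrepancy_reference(m, "both", n_ref = 500)
  set.seed(42)
  dev <- beta_deviation(m, 0, 0, n_null = 10, d_ref = d_ref)
  expect_equal(dev$delta, rep(0, 3))
  expect_equal(dev$p_value, rep(0, 3))
  set.seed(42)
  devm <- beta_deviation(m, 0, 0, n_null = 10, d_ref = d_ref, ties = "midrank")
  expect_equal(devm$p_value, rep(0.5, 3))
})

test_that("deviation and p-value arithmetic follow their definitions", {
  # at the equiprobable corner the nulls vary; check internal consistency
  set.seed(43)
  m <- random_pa(8, 12, fill = 0.4)
  set.seed(44)
  d_ref <- discrepancy_reference(m, "both", n_ref = 500)
  set.seed(45)
  dev <- beta_deviation(m, 1, 1, n_null = 25, d_ref = d_ref)
  expect_equal(dev$delta, dev$beta_obs - dev$beta_null_mean, tolerance = 1e-12)
  expect_true(all(dev$p_value >= 0 & dev$p_value <= 1))
  expect_equal(dev$delta[dev$index == "beta_sor"],
               dev$delta[dev$index == "beta_sim"] +
                 dev$delta[dev$index == "beta_sne"], tolerance = 1e-12)
})

test_that("landscapes cover the grid, are additive and bit-reproducible", {
  set.seed(50)
  m <- random_pa(10, 14, fill = 0.35)
  grid <- null_space_grid(3)
  l1 <- beta_landscape(m, grid, n_null = 8, seed = 99,
                       params = tp_params(n_ref = 200))
  expect_equal(nrow(l1), 9 * 3)
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(l1), "row_level", "col_level",
                  "index", "delta"),
    names_from = "index", values_from = "delta"
  )
  expect_equal(wide$beta_sor, wide$beta_sim + wide$beta_sne, tolerance = 1e-12)

  l2 <- beta_landscape(m, grid, n_null = 8, seed = 99,
                       params = tp_params(n_ref = 200))
  expect_identical(tibble::as_tibble(l1), tibble::as_tibble(l2))
})

test_that("significance uses the two-tailed rule with strict boundaries", {
  fake <- new_fake_landscape(p = c(0.5, 0.96, 0.05, 0.951, 0.04))
  mask <- significance_mask(fake)
  expect_equal(mask$significant, c(FALSE, TRUE, FALSE, TRUE, TRUE))
})

test_that("conservativeness quarters have the documented sizes", {
  fake <- new_fake_landscape_grid(11, indices = "beta_sne")
  expect_equal(nrow(conservativeness_subset(fake, "conservative")), 25)
  expect_equal(nrow(conservativeness_subset(fake, "liberal")), 25)
  expect_equal(nrow(conservativeness_subset(fake, "moderate")), 121)
})

test_that("rank-sum test matches exact enumeration and handles degeneracy", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(wilcoxon_rank_sum(c(2, 2), c(2, 2))$p_value, 1)

  set.seed(60)
  for (k in 1:20) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    x <- stats::rnorm(nx)
    y <- stats::rnorm(ny)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("large-sample rank-sum p agrees with a permutation oracle", {
  set.seed(61)
  x <- stats::rnorm(40)
  y <- stats::rnorm(45, mean = 0.4)
  p <- wilcoxon_rank_sum(x, y)$p_value
  pooled <- c(x, y)
  w_obs <- sum(rank(pooled)[seq_along(x)])
  mu <- length(x) * (length(pooled) + 1) / 2
  perm <- replicate(20000, {
    idx <- sample(length(pooled), length(x))
    sum(rank(pooled)[idx])
  })
  p_perm <- mean(abs(perm - mu) >= abs(w_obs - mu))
  expect_lt(abs(p - p_perm), 4 * sqrt(p_perm * (1 - p_perm) / 20000) + 0.005)
})

test_that("Holm adjustment reproduces the step-down procedure", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  p <- c(0.002, 0.2, 0.04, 0.9)
  expect_true(all(holm_adjust(p) >= p))
  perm <- c(3, 1, 4, 2)
  expect_equal(holm_adjust(p)[perm], holm_adjust(p[perm]))
})

test_that("significance symbols follow the star bands", {
  expect_equal(significance_symbol(c(0.5, 0.05, 0.009, 0.0009, 0.00005)),
               c("ns", "*", "**", "***", "****"))
})

test_that("stage comparison tests every pair with a per-family Holm correction", {
  set.seed(70)
  lands <- list(
    warm = new_fake_landscape_grid(5, delta_shift = 0),
    mid1 = new_fake_landscape_grid(5, delta_shift = 0.05),
    mid2 = new_fake_landscape_grid(5, delta_shift = 0.10),
    cold = new_fake_landscape_grid(5, delta_shift = 0.15)
  )
  cmp <- compare_stages(lands, levels = "moderate", indices = "beta_sne")
  expect_equal(nrow(cmp), choose(4, 2))
  expect_true(all(cmp$p_holm >= cmp$p_value))
  expect_equal(sum(cmp$consecutive), 3)

  same <- compare_stages(list(a = lands$warm, b = lands$warm),
                         levels = "moderate", indices = "beta_sne")
  expect_equal(same$symbol, "ns")

  cons <- compare_stages(lands, levels = "moderate", indices = "beta_sne",
                         family = "consecutive")
  expect_equal(nrow(cons), 3)
})
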