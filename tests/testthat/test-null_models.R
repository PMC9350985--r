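test_that("curveball trades preserve both marginal vectors and fill", {
  set.seed(3)
  m <- random_pa(6, 10)
  t1 <- curveball_trade(m, 500)
  expect_equal(marginals(t1), marginals(m))
  expect_equal(sum(t1), sum(m))

  # 2x2 checkerboard: only two states share these marginals
  cb <- pa_matrix(matrix(c(1, 0, 0, 1), 2, 2,
                         dimnames = list(c("a", "b"), c("t1", "t2"))))
  seen <- character()
  for (k in 1:50) seen <- union(seen, matrix_key(curveball_trade(cb, 1)))
  expect_true(all(seen %in% c("1001", "0110")))
  expect_length(seen, 2) # both states reachable

  # identical rows have no exclusive taxa: always a no-op
  same <- pa_matrix(rbind(a = c(1, 1, 0), b = c(1, 1, 0)))
  expect_equal(unclass(curveball_trade(same, 20)), unclass(same))
})

test_that("repeated trades visit the whole fixed-fixed space", {
  space <- enumerate_fixed_fixed(c(2, 1, 1), c(2, 1, 1))
  keys <- vapply(space, matrix_key, character(1))
  m <- pa_matrix(space[[1]] + 0)
  set.seed(9)
  visited <- character()
  for (k in 1:400) {
    m <- curveball_trade(m, 1)
    visited <- union(visited, matrix_key(m))
  }
  expect_setequal(visited, keys)
})

test_that("relocate moves one occurrence respecting its mode's invariant", {
  # a null-model intermediate may hold an empty site; build it unchecked
  one <- betanull:::new_pa(matrix(c(1L, 0L), 2, 1,
                                  dimnames = list(c("a", "b"), "t")))
  set.seed(1)
  moved <- relocate(one, "within_column")
  expect_equal(unname(unclass(moved)[, 1]), c(0, 1))

  ones <- pa_matrix(matrix(1, 2, 2, dimnames = list(c("a", "b"), c("t1", "t2"))))
  expect_message(noop <- relocate(ones, "free"), "no admissible")
  expect_equal(unclass(noop), unclass(ones))

  set.seed(2)
  m <- random_pa(5, 8)
  wc <- relocate(m, "within_column")
  expect_equal(marginals(wc)$col_totals, marginals(m)$col_totals)
  expect_equal(sum(wc), sum(m))
  wr <- relocate(m, "within_row")
  expect_equal(marginals(wr)$row_totals, marginals(m)$row_totals)
  fr <- relocate(m, "free")
  expect_equal(sum(fr), sum(m))
})

test_that("free relocation converges to uniform cell occupancy", {
  set.seed(4)
  m <- random_pa(4, 5, fill = 0.3)
  f <- sum(m)
  counts <- matrix(0, 4, 5)
  cur <- m
  for (k in 1:5000) {
    cur <- suppressMessages(relocate(cur, "free"))
    counts <- counts + unclass(cur)
  }
  expected <- 5000 * f / 20
  chi <- sum((counts - expected)^2 / expected)
  # crude df: 19; occupancy autocorrelated between successive moves, so
  # compare against a generous quantile
  expect_lt(chi, stats::qchisq(1 - 1e-6, df = 19) * 10)
  expect_gt(min(counts), 0)
})

test_that("raw discrepancy is the Bray-Curtis distance between marginals", {
  a <- list(row_totals = c(2, 0), col_totals = c(1, 1))
  b <- list(row_totals = c(0, 2), col_totals = c(1, 1))
  expect_equal(marginal_discrepancy(a, a, "rows"), 0)
  expect_equal(marginal_discrepancy(a, b, "rows"), 1)
  expect_equal(marginal_discrepancy(
    list(row_totals = c(3, 2, 1), col_totals = c(3, 2, 1)),
    list(row_totals = c(2, 2, 2), col_totals = c(3, 2, 1)), "rows"
  ), 2 / 12)
  empty <- list(row_totals = c(0, 0), col_totals = c(0, 0))
  expect_error(marginal_discrepancy(empty, empty, "rows"), "F = 0")
})

test_that("discrepancy reference is reproducible and self-consistent", {
  set.seed(10)
  m <- random_pa(10, 15, fill = 0.33)
  set.seed(99)
  d1 <- discrepancy_reference(m, "rows", n_ref = 500)
  set.seed(99)
  d2 <- discrepancy_reference(m, "rows", n_ref = 500)
  expect_identical(d1, d2)

  # independent R-level re-estimate with a Monte-Carlo error band
  set.seed(123)
  draws <- replicate(500, {
    x <- unclass(m) * 0L
    x[sample.int(length(x), sum(m))] <- 1L
    marginal_discrepancy(m, list(row_totals = rowSums(x),
                                 col_totals = colSums(x)), "rows")
  })
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(d1 - mean(draws)), 3 * sqrt(2) * se)

  ones <- pa_matrix(matrix(1, 3, 3, dimnames = list(paste0("s", 1:3),
                                                    paste0("t", 1:3))))
  expect_error(discrepancy_reference(ones, "rows"), "collapses")
})

test_that("the null-space grid is a regular Cartesian lattice", {
  g <- null_space_grid(11)
  expect_equal(nrow(g), 121)
  expect_equal(nrow(null_space_grid(2)), 4)
  expect_equal(sum(g$d_row_target == 0 & g$d_col_target == 0), 1)
  expect_setequal(unique(g$d_row_target), seq(0, 1, by = 0.1))
  expect_equal(nrow(null_model_presets()), 9)
})

test_that("tp_randomize honours each node's constraint contract", {
  set.seed(20)
  m <- random_pa(24, 40, fill = 0.33)
  set.seed(21)
  d_ref <- discrepancy_reference(m, "both", n_ref = 500)

  s00 <- tp_randomize(m, 0, 0, d_ref = d_ref)
  expect_identical(marginals(s00$matrix), marginals(m))
  expect_equal(s00$d_row_achieved, 0)

  s50 <- tp_randomize(m, 0.5, 0, d_ref = d_ref)
  expect_identical(marginals(s50$matrix)$col_totals, marginals(m)$col_totals)
  expect_true(s50$converged)
  expect_lt(abs(s50$d_row_achieved - 0.5), 0.02 + 1e-12)

  s05 <- tp_randomize(m, 0, 0.5, d_ref = d_ref)
  expect_identical(marginals(s05$matrix)$row_totals, marginals(m)$row_totals)
  expect_lt(abs(s05$d_col_achieved - 0.5), 0.02 + 1e-12)

  s11 <- tp_randomize(m, 1, 1, d_ref = d_ref)
  expect_equal(sum(s11$matrix), sum(m))

  # reproducibility: identical seeds give identical samples
  set.seed(77)
  a <- tp_randomize(m, 0.3, 0.7, d_ref = d_ref)
  set.seed(77)
  b <- tp_randomize(m, 0.3, 0.7, d_ref = d_ref)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
})

test_that("achieved raw discrepancy rises monotonically with the target level", {
  set.seed(30)
  m <- random_pa(12, 16, fill = 0.33)
  set.seed(31)
  d_ref <- discrepancy_reference(m, "both", n_ref = 500)
  mean_raw <- vapply(seq(0, 1, by = 0.25), function(tgt) {
    mean(replicate(10, {
      s <- tp_randomize(m, tgt, 0, d_ref = d_ref)
      marginal_discrepancy(m, s$matrix, "rows")
    }))
  }, numeric(1))
  expect_true(all(diff(mean_raw) >= -1e-9))
})
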