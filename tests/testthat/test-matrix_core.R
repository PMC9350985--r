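test_that("pa_matrix validates and coerces input", {
  m <- pa_matrix(matrix(c(1, 0, 0, 1), 2, 2,
                        dimnames = list(c("s1", "s2"), c("t1", "t2"))))
  expect_s3_class(m, "pa_matrix")
  expect_equal(sum(m), 2)

  # abundance-style cells coerce to presence with a warning
  ab <- matrix(c(3, 0, 0, 2), 2, 2,
               dimnames = list(c("s1", "s2"), c("t1", "t2")))
  expect_warning(m2 <- pa_matrix(ab), "coerced")
  expect_equal(unclass(m2)[1, 1], 1L)
  expect_equal(sum(m2), 2)

  dup <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("t1", "t2")))
  expect_error(pa_matrix(dup), "duplicated site")
  neg <- matrix(c(-1, 1, 1, 1), 2, 2,
                dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_error(pa_matrix(neg), "negative")
  expect_error(pa_matrix(matrix(numeric(0), 0, 0)), "empty")
  zero_row <- matrix(c(1, 0, 1, 0), 2, 2,
                     dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_error(pa_matrix(zero_row), "all-zero site")
})

test_that("wide and long CSV round-trip bit-identically", {
  set.seed(42)
  m <- random_pa(6, 9)
  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".csv")
  write_incidence(m, wide)
  expect_equal(unclass(read_incidence(wide)), unclass(m))
  write_incidence_long(m, long)
  m2 <- read_incidence_long(long)
  # long format preserves content up to site/taxon order
  expect_equal(unclass(m2)[rownames(m), colnames(m)[colSums(m) > 0]],
               unclass(trim_empty_taxa(m)))
})

test_that("fill, gamma and marginals follow their definitions", {
  m <- pa_matrix(matrix(c(1, 0, 0, 1), 2, 2,
                        dimnames = list(c("a", "b"), c("t1", "t2"))))
  expect_equal(matrix_fill(m), 0.5)
  expect_equal(gamma_diversity(m), 2)
  expect_equal(marginals(m)$row_totals, c(a = 1, b = 1))

  ones <- pa_matrix(matrix(1, 3, 4,
                           dimnames = list(paste0("s", 1:3), paste0("t", 1:4))))
  expect_equal(matrix_fill(ones), 1)

  tri <- pa_matrix(matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE,
                          dimnames = list(paste0("s", 1:3), paste0("t", 1:3))))
  expect_equal(unname(marginals(tri)$row_totals), c(3, 2, 1))
  expect_equal(unname(marginals(tri)$col_totals), c(3, 2, 1))

  # a taxon absent everywhere does not count toward gamma
  five <- unclass(random_pa(4, 5))
  five[, 3] <- 0L
  five <- pa_matrix(five)
  expect_equal(gamma_diversity(five), sum(colSums(five) > 0))
})

test_that("fill and gamma are invariant under row/column permutation", {
  set.seed(7)
  for (k in 1:20) {
    m <- random_pa(sample(3:8, 1), sample(3:10, 1))
    p <- unclass(m)[sample(nrow(m)), sample(ncol(m))]
    expect_equal(matrix_fill(pa_matrix(p)), matrix_fill(m))
    expect_equal(gamma_diversity(pa_matrix(p)), gamma_diversity(m))
  }
})

test_that("trim_empty_taxa drops only empty columns and conserves F", {
  x <- matrix(c(1, 0, 0, 0, 0, 1, 1, 1), 2, 4,
              dimnames = list(c("a", "b"), paste0("t", 1:4)))
  m <- pa_matrix(x)
  tr <- trim_empty_taxa(m)
  expect_equal(colnames(tr), c("t1", "t3", "t4"))
  expect_equal(sum(tr), sum(m))
  expect_equal(marginals(tr)$row_totals, marginals(m)$row_totals)

  full <- random_pa(4, 5, fill = 0.8)
  expect_equal(unclass(trim_empty_taxa(full)), unclass(full))
})

test_that("subsampled matrices keep exactly the taxa observed in the subsample", {
  set.seed(11)
  g <- toy_gradient(40)
  set.seed(12)
  mats <- subsample_equal(g$matrix, g$metadata, 32)
  for (sm in mats) {
    sites <- rownames(sm)
    expect_equal(ncol(sm),
                 sum(colSums(unclass(g$matrix)[sites, ]) > 0))
    expect_true(all(colSums(sm) > 0))
  }
})

test_that("site metadata reader derives stages from temperature", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    site_id = c("a", "b", "c", "d"),
    temperature = c(9, 5, 2, -1),
    elevation = c(400, 1200, 1900, 2400)
  ), path)
  md <- read_site_metadata(path)
  expect_equal(as.character(md$stage),
               c("foothill", "montane", "subalpine", "alpine"))
})

test_that("taxon frequency tables count occurrences per group", {
  m <- pa_matrix(matrix(c(1, 1, 0, 1, 1, 0, 1, 0), 4, 2,
                        dimnames = list(paste0("s", 1:4), c("t1", "t2"))))
  tf <- taxon_frequencies(m, groups = c("g1", "g1", "g2", "g2"))
  expect_equal(nrow(tf), 4)
  expect_equal(tf$frequency[tf$group == "g1" & tf$taxon_id == "t1"], 1)
})
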