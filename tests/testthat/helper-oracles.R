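# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized implementation paths.

# brute-force multiple-site partition by explicit double loop over pairs
oracle_beta_multi <- function(m) {
  x <- unclass(m)
  r <- nrow(x)
  s_i <- rowSums(x)
  s_t <- sum(colSums(x) > 0)
  sum_min <- 0
  sum_max <- 0
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      a <- sum(x[i, ] == 1 & x[j, ] == 1)
      b_ij <- sum(x[i, ] == 1 & x[j, ] == 0)
      b_ji <- sum(x[i, ] == 0 & x[j, ] == 1)
      stopifnot(a + b_ij == s_i[i], a + b_ji == s_i[j])
      sum_min <- sum_min + min(b_ij, b_ji)
      sum_max <- sum_max + max(b_ij, b_ji)
    }
  }
  core <- sum(s_i) - s_t
  sim <- if (core + sum_min == 0) 0 else sum_min / (core + sum_min)
  sor_den <- 2 * core + sum_min + sum_max
  sor <- if (sor_den == 0) 0 else (sum_min + sum_max) / sor_den
  c(beta_sor = sor, beta_sim = sim, beta_sne = sor - sim)
}

# random valid incidence matrix (no empty rows)
random_pa <- function(n_sites, n_taxa, fill = 0.4) {
  repeat {
    x <- matrix(as.integer(stats::runif(n_sites * n_taxa) < fill),
                n_sites, n_taxa)
    if (all(rowSums(x) > 0)) {
      dimnames(x) <- list(paste0("s", seq_len(n_sites)),
                          paste0("t", seq_len(n_taxa)))
      return(pa_matrix(x))
    }
  }
}

# every binary matrix with the given marginal totals (tiny cases only)
enumerate_fixed_fixed <- function(row_totals, col_totals) {
  r <- length(row_totals)
  s <- length(col_totals)
  f <- sum(row_totals)
  stopifnot(f == sum(col_totals), r * s <= 16)
  out <- list()
  for (cells in utils::combn(r * s, f, simplify = FALSE)) {
    x <- matrix(0L, r, s)
    x[cells] <- 1L
    if (all(rowSums(x) == row_totals) && all(colSums(x) == col_totals)) {
      out[[length(out) + 1L]] <- x
    }
  }
  out
}

matrix_key <- function(x) paste(as.integer(unclass(x)), collapse = "")

# exact two-sided rank-sum p-value by full enumeration of label assignments
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  ws <- vapply(
    utils::combn(length(pooled), nx, simplify = FALSE),
    function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2,
    numeric(1)
  )
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# small gradient study shared by pipeline tests (kept cheap)
toy_gradient <- function(sites_per_stage = 12) {
  make_gradient(gradient_spec(
    n_sites_per_stage = stats::setNames(rep(sites_per_stage, 4),
                                        c("foothill", "montane",
                                          "subalpine", "alpine")),
    n_taxa = 30
  ))
}

# minimal landscape-shaped tibbles for unit tests of the summary operations
new_fake_landscape <- function(p) {
  betanull:::new_beta_landscape(
    tibble::tibble(
      row_level = seq_along(p) - 1L, col_level = 0L,
      index = "beta_sne", p_value = p, delta = 0
    ),
    levels = length(p)
  )
}

new_fake_landscape_grid <- function(levels, delta_shift = 0,
                                    indices = c("beta_sor", "beta_sim",
                                                "beta_sne")) {
  g <- null_space_grid(levels)
  cells <- tidyr::expand_grid(g, index = indices)
  cells$delta <- stats::rnorm(nrow(cells), mean = delta_shift, sd = 0.02)
  cells$p_value <- stats::runif(nrow(cells))
  betanull:::new_beta_landscape(cells, levels = levels)
}

# split a gradient draw into per-stage matrices without subsampling
split_by_stage <- function(g) {
  ids <- split(g$metadata$site_id, g$metadata$stage)
  lapply(ids, function(s) {
    trim_empty_taxa(pa_matrix(unclass(g$matrix)[s, , drop = FALSE]))
  })
}
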