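# beta partition on a raw (possibly empty-row) null matrix, skipping the
# user-input validation path
beta_multi_raw <- function(x) {
  a <- tcrossprod(x)
  s <- rowSums(x)
  b <- s - a
  bt <- t(b)
  up <- upper.tri(a)
  sum_min <- sum(pmin(b[up], bt[up]))
  sum_max <- sum(pmax(b[up], bt[up]))
  core <- sum(s) - sum(colSums(x) > 0)
  sim_den <- core + sum_min
  sor_den <- 2 * core + sum_min + sum_max
  beta_sim <- if (sim_den == 0) 0 else sum_min / sim_den
  beta_sor <- if (sor_den == 0) 0 else (sum_min + sum_max) / sor_den
  c(beta_sor = beta_sor, beta_sim = beta_sim, beta_sne = beta_sor - beta_sim)
}

#' Beta-deviation at one null-space node
#'
#' Generates `n_null` randomized matrices at the node, computes the
#' multiple-site partition of each, and returns for every index the raw
#' deviation `delta = beta_obs - mean(beta_null)` together with a p-value
#' computed as the fraction of null matrices with a strictly higher score
#' than observed. Positive and negative deltas indicate respectively higher
#' and lower beta-diversity than expected by chance. The raw (not
#' standardized) deviation keeps the three indices on their common `[0, 1]`
#' scale and preserves additivity, so `delta_sor = delta_sim + delta_sne`.
#'
#' With `ties = "strict"` a null score exactly equal to the observed does
#' not count (the default); `ties = "midrank"` counts ties as 1/2, which
#' avoids p = 0 for degenerate all-tied null distributions.
#'
#' @param m Observed presence-absence matrix.
#' @param d_row,d_col Node targets in `[0, 1]`.
#' @param n_null Number of null matrices (>= 1).
#' @param params A [tp_params()] list.
#' @param d_ref Optional precomputed [discrepancy_reference()] list.
#' @param ties `"strict"` or `"midrank"`.
#' @return A tibble with one row per index: `index`, `beta_obs`,
#'   `beta_null_mean`, `delta`, `p_value`, `n_null`, plus the node targets
#'   and mean achieved discrepancies.
#' @export
beta_deviation <- function(m, d_row, d_col, n_null = 100,
                           params = tp_params(), d_ref = NULL,
                           ties = c("strict", "midrank")) {
  ties <- match.arg(ties)
  m <- assert_pa(m)
  stopifnot(n_null >= 1)
  if (is.null(d_ref)) d_ref <- discrepancy_reference(m, "both", params$n_ref)
  obs <- beta_multi_raw(unclass(m))
  nulls <- matrix(NA_real_, n_null, 3,
                  dimnames = list(NULL, c("beta_sor", "beta_sim", "beta_sne")))
  ach <- matrix(NA_real_, n_null, 2)
  for (k in seq_len(n_null)) {
    smp <- tp_randomize(m, d_row, d_col, params = params, d_ref = d_ref)
    if (!smp$converged) {
      stop(
        sprintf("node (%.2f, %.2f): null sample failed to converge", d_row, d_col),
        call. = FALSE
      )
    }
    nulls[k, ] <- beta_multi_raw(unclass(smp$matrix))
    ach[k, ] <- c(smp$d_row_achieved, smp$d_col_achieved)
  }
  p_fun <- switch(ties,
    strict = function(idx) mean(nulls[, idx] > obs[[idx]]),
    midrank = function(idx) {
      mean(nulls[, idx] > obs[[idx]]) + 0.5 * mean(nulls[, idx] == obs[[idx]])
    }
  )
  tibble::tibble(
    d_row_target = d_row,
    d_col_target = d_col,
    index = c("beta_sor", "beta_sim", "beta_sne"),
    beta_obs = as.numeric(obs),
    beta_null_mean = unname(colMeans(nulls)),
    delta = as.numeric(obs) - unname(colMeans(nulls)),
    p_value = vapply(c("beta_sor", "beta_sim", "beta_sne"), p_fun, numeric(1),
                     USE.NAMES = FALSE),
    n_null = as.integer(n_null),
    d_row_achieved = mean(ach[, 1]),
    d_col_achieved = mean(ach[, 2])
  )
}

#' Beta-deviation landscape over the null space
#'
#' Applies [beta_deviation()] at every node of the grid, yielding per-index
#' landscapes of deviation and significance over the bidimensional null
#' space. Deterministic for a given `seed`: each node gets its own derived
#' RNG stream (see [derive_seed()]), so results do not depend on node
#' evaluation order.
#'
#' @param m Observed presence-absence matrix.
#' @param grid A [null_space_grid()] tibble.
#' @param n_null Null matrices per node.
#' @param params A [tp_params()] list.
#' @param seed Optional integer root seed.
#' @param ties Passed to [beta_deviation()].
#' @return A tibble of class `beta_landscape`: one row per (node, index)
#'   with the [beta_deviation()] columns plus `row_level`, `col_level`.
#' @export
beta_landscape <- function(m, grid = null_space_grid(), n_null = 100,
                           params = tp_params(), seed = NULL,
                           ties = c("strict", "midrank")) {
  ties <- match.arg(ties)
  m <- assert_pa(m)
  if (!is.null(seed)) set.seed(derive_seed(seed, -1))
  d_ref <- discrepancy_reference(m, "both", params$n_ref)
  cells <- purrr::pmap_dfr(
    grid,
    function(row_level, col_level, d_row_target, d_col_target) {
      if (!is.null(seed)) set.seed(derive_seed(seed, row_level, col_level))
      dplyr::mutate(
        beta_deviation(m, d_row_target, d_col_target, n_null = n_null,
                       params = params, d_ref = d_ref, ties = ties),
        row_level = row_level, col_level = col_level,
        .before = 1
      )
    }
  )
  new_beta_landscape(cells, levels = max(grid$row_level) + 1L,
                     d_ref = d_ref, n_null = n_null, seed = seed)
}

new_beta_landscape <- function(cells, levels, d_ref = NULL, n_null = NULL,
                               seed = NULL) {
  structure(
    cells,
    levels = levels,
    d_ref = d_ref,
    n_null = n_null,
    seed = seed,
    class = c("beta_landscape", class(tibble::tibble()))
  )
}

#' Significance mask of a deviation landscape
#'
#' A deviation is significant at level `alpha` when its p-value (fraction
#' of null scores strictly above the observed) is below `alpha` or above
#' `1 - alpha` — a two-tailed rule on a one-sided p. Boundary values are
#' not significant (strict inequalities).
#'
#' @param landscape A [beta_landscape()].
#' @param alpha Significance level (default 0.05).
#' @return A tibble `row_level`, `col_level`, `index`, `p_value`,
#'   `significant`.
#' @export
significance_mask <- function(landscape, alpha = 0.05) {
  dplyr::transmute(
    tibble::as_tibble(landscape),
    .data$row_level, .data$col_level, .data$index, .data$p_value,
    significant = .data$p_value < alpha | .data$p_value > 1 - alpha
  )
}

#' Deviations at a conservativeness level
#'
#' The bottom-left quarter of the null space (low discrepancy on both axes)
#' holds the conservative null models, the top-right quarter (high
#' discrepancy) the liberal ones; the full landscape is read as moderately
#' conservative. On the default 11-level grid the quarters are the strict
#' 5x5 halves (grid indices 0-4 and 6-10), excluding the middle row and
#' column.
#'
#' @param landscape A [beta_landscape()] (or averaged landscape tibble with
#'   a `levels` attribute).
#' @param level `"conservative"`, `"moderate"`, or `"liberal"`.
#' @return A tibble of the landscape rows in the selected quarter.
#' @export
conservativeness_subset <- function(landscape,
                                    level = c("moderate", "conservative",
                                              "liberal")) {
  level <- match.arg(level)
  lv <- attr(landscape, "levels")
  if (is.null(lv)) lv <- max(landscape$row_level) + 1L
  mid <- (lv - 1) / 2
  tb <- tibble::as_tibble(landscape)
  switch(level,
    moderate = tb,
    conservative = dplyr::filter(tb, .data$row_level < mid, .data$col_level < mid),
    liberal = dplyr::filter(tb, .data$row_level > mid, .data$col_level > mid)
  )
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()]: exact enumeration for small
#' untied samples, normal approximation with tie and continuity correction
#' otherwise. Two groups with all values identical give p = 1.
#'
#' @param x,y Numeric value vectors (non-empty).
#' @return A one-row tibble `statistic` (rank-sum W), `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  p <- ht$p.value
  if (is.na(p)) p <- 1  # zero-variance degenerate case: no evidence either way
  tibble::tibble(statistic = unname(ht$statistic), p_value = p)
}

#' Holm step-down adjustment
#'
#' Family-wise error rate control: sort p ascending, multiply the k-th by
#' `m - k + 1`, enforce monotonicity, cap at 1 (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Significance symbols
#'
#' Conventional star bands: `****` p <= 1e-4, `***` p <= 1e-3, `**`
#' p <= 0.01, `*` p <= 0.05, otherwise `ns`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of symbols.
#' @export
significance_symbol <- function(p) {
  dplyr::case_when(
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 5e-2 ~ "*",
    .default = "ns"
  )
}

#' Compare beta-deviations between site groups
#'
#' For every unordered pair of groups, a two-sided Wilcoxon rank-sum test
#' on the per-node deviation values within the chosen conservativeness
#' quarter, for each index, with Holm correction applied per (index,
#' conservativeness) family. Group order (for the `consecutive` flag)
#' follows the order of the input list.
#'
#' @param landscapes Named list (>= 2) of [beta_landscape()] objects or
#'   averaged landscape tibbles, one per group, on identical grids.
#' @param levels Conservativeness levels to evaluate.
#' @param indices Which indices to compare.
#' @param family Holm family: `"all_pairs"` (default) adjusts over all
#'   group pairs; `"consecutive"` adjusts only over adjacent pairs in the
#'   given group order.
#' @param paired If `TRUE`, a paired signed-rank test matching cells across
#'   groups (same node order) instead of the unpaired rank-sum.
#' @return A tibble of class `stage_comparison`: `group_a`, `group_b`,
#'   `index`, `conservativeness`, `n_a`, `n_b`, `statistic`, `p_value`,
#'   `p_holm`, `symbol`, `consecutive`.
#' @export
compare_stages <- function(landscapes,
                           levels = c("conservative", "moderate", "liberal"),
                           indices = c("beta_sor", "beta_sim", "beta_sne"),
                           family = c("all_pairs", "consecutive"),
                           paired = FALSE) {
  family <- match.arg(family)
  stopifnot(length(landscapes) >= 2, !is.null(names(landscapes)))
  groups <- names(landscapes)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  if (family == "consecutive") {
    pairs <- purrr::map(seq_len(length(groups) - 1),
                        function(i) groups[c(i, i + 1)])
  }
  res <- purrr::map_dfr(levels, function(lvl) {
    subs <- purrr::map(landscapes, conservativeness_subset, level = lvl)
    purrr::map_dfr(indices, function(idx) {
      vals <- purrr::map(subs, function(s) {
        v <- dplyr::filter(s, .data$index == idx)$delta
        if (length(v) == 0) {
          stop("empty conservativeness subset for index ", idx, call. = FALSE)
        }
        v
      })
      one <- purrr::map_dfr(pairs, function(pr) {
        x <- vals[[pr[1]]]
        y <- vals[[pr[2]]]
        ht <- if (paired) {
          suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
        } else {
          suppressWarnings(stats::wilcox.test(x, y))
        }
        p <- ht$p.value
        if (is.na(p)) p <- 1  # zero-variance degenerate groups
        tibble::tibble(
          group_a = pr[1], group_b = pr[2], index = idx,
          conservativeness = lvl,
          n_a = length(x), n_b = length(y),
          statistic = unname(ht$statistic), p_value = p
        )
      })
      one$p_holm <- holm_adjust(one$p_value)
      one
    })
  })
  res$symbol <- significance_symbol(res$p_holm)
  res$consecutive <- purrr::map2_lgl(res$group_a, res$group_b, function(a, b) {
    abs(match(a, groups) - match(b, groups)) == 1
  })
  class(res) <- c("stage_comparison", class(res))
  res
}
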