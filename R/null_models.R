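#' Control parameters for the null-space randomizer
#'
#' @param eps Steering tolerance on the normalized discrepancy scale
#'   (one-fifth of a default grid step). A sample converged when its
#'   achieved discrepancy is within `eps` of the node target on both axes.
#' @param mix_factor Number of curveball trades in the mixing and re-mixing
#'   phases, as a multiple of F (the occurrence count).
#' @param budget_factor Steering proposal budget per axis, as a multiple of F.
#' @param n_ref Number of equiprobable refills used to estimate the
#'   discrepancy normalization constant per axis.
#' @param max_retries How many times an unconverged sample is regenerated
#'   before erroring.
#' @return A list of class `tp_params`.
#' @export
tp_params <- function(eps = 0.02, mix_factor = 10, budget_factor = 50,
                      n_ref = 1000, max_retries = 1) {
  stopifnot(eps > 0, mix_factor >= 0, budget_factor > 0, n_ref >= 100,
            max_retries >= 0)
  structure(
    list(eps = eps, mix_factor = mix_factor, budget_factor = budget_factor,
         n_ref = n_ref, max_retries = max_retries),
    class = "tp_params"
  )
}

# internal constructor: trusted 0/1 integer matrix -> pa_matrix without
# validation (null-model samples may legitimately contain empty sites)
new_pa <- function(x, template = NULL) {
  if (!is.null(template)) dimnames(x) <- dimnames(template)
  class(x) <- c("pa_matrix", "matrix", "array")
  x
}

#' Single curveball trade
#'
#' Picks two distinct random rows and exchanges a random subset of the taxa
#' exclusive to one with an equal-sized subset exclusive to the other. Both
#' marginal vectors are invariant, so repeated trades sample the fixed-fixed
#' ensemble (both marginal vectors preserved exactly). If the chosen rows
#' share no exclusive taxa the matrix is returned unchanged.
#'
#' @param m A presence-absence matrix.
#' @param n_trades Number of successive trades to apply.
#' @return The traded matrix.
#' @export
curveball_trade <- function(m, n_trades = 1) {
  m <- assert_pa(m)
  if (nrow(m) < 2L) stop("curveball needs at least 2 sites", call. = FALSE)
  new_pa(cpp_curveball(unclass(m), as.integer(n_trades)), template = m)
}

#' Single occurrence relocation
#'
#' Moves one uniformly chosen occurrence to a uniformly chosen empty cell.
#' `within_column` keeps column totals fixed (row totals change),
#' `within_row` the converse, `free` moves anywhere. F is invariant in all
#' modes. If no admissible move exists (full column/row/matrix) the matrix
#' is returned unchanged with a message.
#'
#' @param m A presence-absence matrix.
#' @param mode One of `"within_column"`, `"within_row"`, `"free"`.
#' @return The matrix after one move (possibly a no-op).
#' @export
relocate <- function(m, mode = c("within_column", "within_row", "free")) {
  mode <- match.arg(mode)
  m <- assert_pa(m)
  x <- unclass(m)
  occ <- which(x == 1L)
  if (length(occ) == 0L) stop("matrix has no occurrences", call. = FALSE)
  from <- occ[sample.int(length(occ), 1L)]
  r <- (from - 1L) %% nrow(x) + 1L
  c <- (from - 1L) %/% nrow(x) + 1L
  empty <- switch(mode,
    within_column = which(x[, c] == 0L),
    within_row = which(x[r, ] == 0L),
    free = which(x == 0L)
  )
  if (length(empty) == 0L) {
    message("relocate: no admissible move (", mode, "); matrix unchanged")
    return(m)
  }
  to <- empty[sample.int(length(empty), 1L)]
  switch(mode,
    within_column = {
      x[from] <- 0L
      x[to, c] <- 1L
    },
    within_row = {
      x[from] <- 0L
      x[r, to] <- 1L
    },
    free = {
      x[from] <- 0L
      x[to] <- 1L
    }
  )
  new_pa(x, template = m)
}

#' Raw marginal-total discrepancy
#'
#' Bray-Curtis distance between one axis's marginal totals of the original
#' and a randomized matrix: `sum(|m_i - m'_i|) / (2F)`. Zero when the axis
#' is preserved exactly; grows toward the equiprobable extreme.
#'
#' @param orig,null Marginal-vector lists as returned by [marginals()], or
#'   presence-absence matrices.
#' @param axis `"rows"` (site richness) or `"cols"` (taxon frequencies).
#' @return A non-negative number.
#' @export
marginal_discrepancy <- function(orig, null, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (is.matrix(orig)) orig <- marginals(orig)
  if (is.matrix(null)) null <- marginals(null)
  f <- sum(orig$row_totals)
  if (f == 0) stop("F = 0: discrepancy undefined", call. = FALSE)
  a <- if (axis == "rows") orig$row_totals else orig$col_totals
  b <- if (axis == "rows") null$row_totals else null$col_totals
  if (length(a) != length(b)) stop("marginal vectors differ in length", call. = FALSE)
  sum(abs(a - b)) / (2 * f)
}

#' Discrepancy normalization constants
#'
#' The raw discrepancy scale depends on the matrix, so each axis is
#' normalized by the Monte-Carlo mean raw discrepancy under full
#' equiprobable randomization (F occurrences placed uniformly without
#' collision). This anchors the fixed-fixed ensemble at 0 and the
#' equiprobable ensemble at 1, the two extremes of the null space.
#'
#' @param m A presence-absence matrix.
#' @param axis `"rows"`, `"cols"`, or `"both"`.
#' @param n_ref Number of equiprobable refills (>= 100).
#' @return For one axis, a positive number; for `"both"`, a named list
#'   `list(rows = , cols = )`.
#' @export
discrepancy_reference <- function(m, axis = c("both", "rows", "cols"),
                                  n_ref = 1000) {
  axis <- match.arg(axis)
  m <- assert_pa(m)
  stopifnot(n_ref >= 100)
  one <- function(rows_axis) {
    d <- cpp_discrepancy_reference(unclass(m), rows_axis, as.integer(n_ref))
    if (d == 0) {
      stop(
        "degenerate matrix: equiprobable refills preserve the ",
        if (rows_axis) "row" else "column",
        " marginals exactly; the null space collapses",
        call. = FALSE
      )
    }
    d
  }
  switch(axis,
    rows = one(TRUE),
    cols = one(FALSE),
    both = list(rows = one(TRUE), cols = one(FALSE))
  )
}

#' The bidimensional null-space grid
#'
#' A regular grid of target normalized discrepancies for the two marginal
#' axes, from the fixed-fixed corner (0, 0) to the equiprobable corner
#' (1, 1). The default 11 levels per axis give the complete 121-node null
#' space.
#'
#' @param levels Number of equally spaced levels per axis (>= 2).
#' @return A tibble with columns `row_level`, `col_level` (0-based grid
#'   indices) and `d_row_target`, `d_col_target` (targets in `[0, 1]`).
#' @export
null_space_grid <- function(levels = 11) {
  stopifnot(levels >= 2)
  targets <- seq(0, 1, length.out = levels)
  tidyr::expand_grid(row_level = seq_len(levels) - 1L,
                     col_level = seq_len(levels) - 1L) |>
    dplyr::mutate(
      d_row_target = targets[.data$row_level + 1L],
      d_col_target = targets[.data$col_level + 1L]
    )
}

#' Named classical null-model presets
#'
#' The classical algorithms for presence-absence null models arise from
#' fixing, proportionally constraining, or freeing each marginal axis. On
#' the discrepancy grid they map onto corners, mid-edges and the centre:
#' fixed = 0, proportional = 0.5, equiprobable = 1 on the relevant axis.
#'
#' @return A tibble with columns `preset`, `d_row_target`, `d_col_target`.
#' @export
null_model_presets <- function() {
  lv <- c(fixed = 0, proportional = 0.5, equiprobable = 1)
  tidyr::expand_grid(rows = names(lv), cols = names(lv)) |>
    dplyr::mutate(
      preset = paste0(.data$rows, "-", .data$cols),
      d_row_target = lv[.data$rows],
      d_col_target = lv[.data$cols]
    ) |>
    dplyr::select("preset", "d_row_target", "d_col_target")
}

# equiprobable draw: F occurrences placed uniformly without collision
equiprobable_draw <- function(m) {
  x <- unclass(m)
  out <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  out[sample.int(length(out), sum(x))] <- 1L
  new_pa(out)
}

#' Randomize a matrix to one node of the null space
#'
#' Generates one null matrix whose marginal-total discrepancies from the
#' original sit at the node's targets, with matrix fill always conserved.
#' Three phases: (1) mixing by curveball trades (a node with both targets 0
#' stops here, preserving both marginal vectors exactly); (2) steering, in
#' which single-occurrence relocations within columns raise the row-axis
#' discrepancy and relocations within rows raise the column-axis
#' discrepancy, each move accepted only if it brings that axis's normalized
#' discrepancy closer to target without exceeding target + eps; (3)
#' re-mixing by curveball trades, which preserve the achieved marginals
#' (hence the achieved discrepancies) while randomizing structure. The
#' equiprobable corner (both targets 1) is drawn directly from the
#' equiprobable ensemble, where achieved discrepancies scatter around 1 by
#' construction and the tolerance contract is waived.
#'
#' @param m The observed presence-absence matrix.
#' @param d_row,d_col Target normalized discrepancies in `[0, 1]`.
#' @param params A [tp_params()] list.
#' @param d_ref Optional precomputed [discrepancy_reference()] list
#'   (`rows`, `cols`); computed on the fly if missing.
#' @return A list of class `tp_sample`: `matrix`, `d_row_achieved`,
#'   `d_col_achieved`, `d_row_target`, `d_col_target`, `converged`.
#' @export
tp_randomize <- function(m, d_row, d_col, params = tp_params(), d_ref = NULL) {
  m <- assert_pa(m)
  stopifnot(d_row >= 0, d_row <= 1, d_col >= 0, d_col <= 1)
  if (is.null(d_ref)) d_ref <- discrepancy_reference(m, "both", params$n_ref)
  f <- sum(m)
  n_mix <- as.integer(ceiling(params$mix_factor * f))
  budget <- as.integer(ceiling(params$budget_factor * f))
  marg <- marginals(m)
  corner <- (d_row == 1 && d_col == 1)

  draw_once <- function() {
    if (corner) {
      x <- equiprobable_draw(m)
      return(list(matrix = x, converged = TRUE))
    }
    x <- cpp_curveball(unclass(m), n_mix)
    ok <- TRUE
    if (d_row > 0) {
      st <- cpp_steer(x, as.numeric(marg$row_totals), d_ref$rows,
                      d_row, params$eps, budget, TRUE)
      x <- st$matrix
      ok <- ok && st$converged
    }
    if (d_col > 0) {
      st <- cpp_steer(x, as.numeric(marg$col_totals), d_ref$cols,
                      d_col, params$eps, budget, FALSE)
      x <- st$matrix
      ok <- ok && st$converged
    }
    if (d_row > 0 || d_col > 0) x <- cpp_curveball(x, n_mix)
    list(matrix = new_pa(x, template = m), converged = ok)
  }

  res <- draw_once()
  tries <- 0L
  while (!res$converged && tries < params$max_retries) {
    res <- draw_once()
    tries <- tries + 1L
  }
  nm <- marginals(res$matrix)
  ach_row <- min(marginal_discrepancy(marg_list(marg), marg_list(nm), "rows") /
                   d_ref$rows, 1)
  ach_col <- min(marginal_discrepancy(marg_list(marg), marg_list(nm), "cols") /
                   d_ref$cols, 1)
  structure(
    list(
      matrix = res$matrix,
      d_row_achieved = ach_row,
      d_col_achieved = ach_col,
      d_row_target = d_row,
      d_col_target = d_col,
      converged = res$converged
    ),
    class = "tp_sample"
  )
}

marg_list <- function(m) list(row_totals = m$row_totals, col_totals = m$col_totals)

#' Derive a reproducible child seed from a root seed
#'
#' Deterministic integer stream-splitting: the root seed and any number of
#' integer indices (repetition, grid node, replicate, ...) are folded
#' through a multiplicative congruential step modulo 2^31 - 1. Used so that
#' every (repetition x node) task in a study has its own reproducible RNG
#' stream regardless of execution order.
#'
#' @param root Integer root seed.
#' @param ... Integer indices identifying the task.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, ...) {
  idx <- c(root, ...)
  s <- 1
  for (k in idx) s <- (s * 48271 + abs(k) + 1) %% 2147483647
  as.integer(s %% 2147483645 + 1)
}
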