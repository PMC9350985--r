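#' Construct and validate a presence-absence matrix
#'
#' The package's central object is a binary site-by-taxon incidence matrix:
#' rows are sites, columns are taxa, cells are 0/1. `pa_matrix()` validates
#' (and lightly coerces) a matrix or data frame into this form.
#'
#' Any strictly positive cell value is coerced to 1 with a warning, so
#' abundance tables can be used directly as incidence data. All-zero site
#' rows are rejected: a sampled site with no taxa indicates corrupt input.
#' All-zero taxon columns are permitted here (they arise naturally when a
#' set of sites is subsampled from a larger study) and are removed by
#' [trim_empty_taxa()] before any beta-diversity or null-model computation.
#'
#' @param x A numeric matrix or data frame with row names = site ids and
#'   column names = taxon ids. A data frame may carry the site ids in its
#'   first column instead of row names.
#' @return An integer 0/1 matrix with unique dimnames, of class
#'   `c("pa_matrix", "matrix", "array")`.
#' @examples
#' m <- pa_matrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("t1", "t2"))))
#' matrix_fill(m)
#' @export
pa_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (!is.numeric(x[[1]])) {
      ids <- as.character(x[[1]])
      x <- as.matrix(x[, -1, drop = FALSE])
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix or data frame", call. = FALSE)
  }
  if (nrow(x) == 0L || ncol(x) == 0L) stop("incidence table is empty", call. = FALSE)
  if (anyNA(x)) stop("incidence table contains missing values", call. = FALSE)
  if (any(x < 0)) stop("incidence table contains negative values", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("site_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("taxon_", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicated site ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicated taxon ids", call. = FALSE)
  if (any(x > 0 & x != 1)) {
    warning("cell values > 1 coerced to presence (1)", call. = FALSE)
  }
  m <- matrix(as.integer(x > 0), nrow(x), ncol(x), dimnames = dimnames(x))
  if (any(rowSums(m) == 0L)) {
    stop(
      "all-zero site rows: ",
      paste(rownames(m)[rowSums(m) == 0L], collapse = ", "),
      call. = FALSE
    )
  }
  class(m) <- c("pa_matrix", "matrix", "array")
  m
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(
    "<pa_matrix> ", nrow(x), " sites x ", ncol(x), " taxa, F = ",
    sum(x), " (fill ", signif(matrix_fill(x), 3), ")\n",
    sep = ""
  )
  invisible(x)
}

assert_pa <- function(m) {
  if (!inherits(m, "pa_matrix")) m <- pa_matrix(unclass(m))
  m
}

#' Read / write incidence matrices
#'
#' Wide format: one CSV with the site id in the first column and one 0/1
#' column per taxon. Long format: two columns `site_id,taxon_id`, one row
#' per occurrence. Both round-trip losslessly for valid matrices (in long
#' format, empty taxon columns are necessarily dropped).
#'
#' @param path Path to a CSV file.
#' @return A [pa_matrix()].
#' @export
read_incidence <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tb) < 2L) stop("incidence CSV needs a site-id column plus taxon columns", call. = FALSE)
  pa_matrix(as.data.frame(tb))
}

#' @rdname read_incidence
#' @param m A presence-absence matrix.
#' @export
write_incidence <- function(m, path) {
  m <- assert_pa(m)
  tb <- tibble::as_tibble(as.data.frame(unclass(m)), rownames = "site_id")
  readr::write_csv(tb, path)
  invisible(path)
}

#' @rdname read_incidence
#' @export
read_incidence_long <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("site_id", "taxon_id") %in% names(tb))) {
    stop("long incidence CSV needs columns site_id, taxon_id", call. = FALSE)
  }
  sites <- unique(tb$site_id)
  taxa <- unique(tb$taxon_id)
  m <- matrix(0L, length(sites), length(taxa), dimnames = list(sites, taxa))
  m[cbind(match(tb$site_id, sites), match(tb$taxon_id, taxa))] <- 1L
  pa_matrix(m)
}

#' @rdname read_incidence
#' @export
write_incidence_long <- function(m, path) {
  m <- assert_pa(m)
  occ <- which(unclass(m) == 1L, arr.ind = TRUE)
  tb <- tibble::tibble(
    site_id = rownames(m)[occ[, 1]],
    taxon_id = colnames(m)[occ[, 2]]
  )
  readr::write_csv(dplyr::arrange(tb, .data$site_id, .data$taxon_id), path)
  invisible(path)
}

#' Read a site metadata table
#'
#' Expects columns `site_id`, `temperature` (mean annual temperature, deg C)
#' and `elevation` (m a.s.l.); optional `x`/`y` coordinates are carried
#' through. A `stage` column is derived from temperature via [assign_stage()].
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per site, including a `stage` factor.
#' @export
read_site_metadata <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("site_id", "temperature", "elevation")
  if (!all(need %in% names(tb))) {
    stop("metadata CSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tb$site_id)) stop("duplicated site_id in metadata", call. = FALSE)
  tb$site_id <- as.character(tb$site_id)
  tb$stage <- assign_stage(tb$temperature)
  tb
}

#' Matrix fill
#'
#' The ratio of the total number of occurrences F to the number of matrix
#' cells (sites x taxa). Together with gamma-diversity this is the matrix
#' parameter the null models hold fixed.
#'
#' @param m A presence-absence matrix.
#' @return A fraction in `[0, 1]`.
#' @export
matrix_fill <- function(m) {
  m <- assert_pa(m)
  sum(m) / (nrow(m) * ncol(m))
}

#' Gamma-diversity
#'
#' Number of taxa actually present in the pooled set of sites, i.e. the
#' count of columns with at least one occurrence.
#'
#' @param m A presence-absence matrix.
#' @return An integer count.
#' @export
gamma_diversity <- function(m) {
  m <- assert_pa(m)
  sum(colSums(m) > 0L)
}

#' Row and column marginal totals
#'
#' Row totals are per-site richness; column totals are per-taxon
#' frequencies. Both sum to F.
#'
#' @param m A presence-absence matrix.
#' @return A list with named integer vectors `row_totals` and `col_totals`.
#' @export
marginals <- function(m) {
  m <- assert_pa(m)
  list(
    row_totals = rowSums(unclass(m)),
    col_totals = colSums(unclass(m))
  )
}

#' Drop taxa absent from every site
#'
#' Removes all-zero columns (taxa never observed in the current site set),
#' preserving the order of the remaining columns and leaving F, the row
#' totals, and the fill over occupied columns unchanged. Subsampled site
#' sets are trimmed this way before any beta-diversity or null-model
#' computation, so gamma counts only present taxa.
#'
#' @param m A presence-absence matrix.
#' @return A [pa_matrix()] with no empty columns.
#' @export
trim_empty_taxa <- function(m) {
  m <- assert_pa(m)
  keep <- colSums(unclass(m)) > 0L
  if (!any(keep)) stop("no taxa present after trimming", call. = FALSE)
  out <- unclass(m)[, keep, drop = FALSE]
  class(out) <- class(m)
  out
}

#' Tidy taxon frequency table
#'
#' Per-taxon occurrence frequencies, optionally within site groups: the
#' tabular counterpart of a taxon-frequency heatmap.
#'
#' @param m A presence-absence matrix.
#' @param groups Optional factor/character vector of site group labels
#'   (one per row of `m`).
#' @return A tibble with columns `taxon_id`, `group` (if given),
#'   `n_sites`, `frequency`.
#' @export
taxon_frequencies <- function(m, groups = NULL) {
  m <- assert_pa(m)
  if (is.null(groups)) {
    tibble::tibble(
      taxon_id = colnames(m),
      n_sites = unname(colSums(unclass(m))),
      frequency = unname(colSums(unclass(m))) / nrow(m)
    )
  } else {
    stopifnot(length(groups) == nrow(m))
    purrr::map_dfr(split(seq_len(nrow(m)), groups), function(idx) {
      sub <- unclass(m)[idx, , drop = FALSE]
      tibble::tibble(
        taxon_id = colnames(m),
        n_sites = unname(colSums(sub)),
        frequency = unname(colSums(sub)) / length(idx)
      )
    }, .id = "group")
  }
}
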