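#' Pairwise occurrence components for two sites
#'
#' Counts the taxa shared by two sites (`a`) and the taxa exclusive to each
#' (`b_ij`, `b_ji`). These are the building blocks of the Sorensen/Simpson
#' dissimilarity family.
#'
#' @param m A presence-absence matrix.
#' @param i,j Site indices or site ids; must differ.
#' @return A one-row tibble with columns `site_i`, `site_j`, `a`, `b_ij`,
#'   `b_ji`.
#' @export
pairwise_components <- function(m, i, j) {
  m <- assert_pa(m)
  i <- site_index(m, i)
  j <- site_index(m, j)
  if (i == j) stop("`i` and `j` must be different sites", call. = FALSE)
  ri <- unclass(m)[i, ]
  rj <- unclass(m)[j, ]
  tibble::tibble(
    site_i = rownames(m)[i],
    site_j = rownames(m)[j],
    a = sum(ri == 1L & rj == 1L),
    b_ij = sum(ri == 1L & rj == 0L),
    b_ji = sum(ri == 0L & rj == 1L)
  )
}

site_index <- function(m, i) {
  if (is.character(i)) {
    k <- match(i, rownames(m))
    if (is.na(k)) stop("unknown site id: ", i, call. = FALSE)
    return(k)
  }
  if (i < 1L || i > nrow(m)) stop("site index out of range", call. = FALSE)
  as.integer(i)
}

# Shared-taxon counts and exclusive counts for every unordered pair, via one
# cross-product; returns the accumulated sums of pair minima and maxima.
pair_sums <- function(m) {
  x <- unclass(m)
  a <- tcrossprod(x)              # a[i,j] = taxa shared by sites i and j
  s <- rowSums(x)
  b <- s - a                      # b[i,j] = taxa in i but not j
  bt <- t(b)
  up <- upper.tri(a)
  list(
    sum_min = sum(pmin(b[up], bt[up])),
    sum_max = sum(pmax(b[up], bt[up])),
    sum_s = sum(s),
    a = a, b = b
  )
}

#' Multiple-site beta-diversity partition
#'
#' Partitions total multiple-site dissimilarity (Sorensen-family, `beta_sor`)
#' into its spatial turnover (Simpson-family, `beta_sim`) and nestedness
#' (`beta_sne`) components, with `beta_sor = beta_sim + beta_sne`:
#'
#' \deqn{\beta_{SIM} = \frac{\sum\min(b_{ij}, b_{ji})}
#'   {\sum_i S_i - S_T + \sum\min(b_{ij}, b_{ji})}}
#' \deqn{\beta_{SOR} = \frac{\sum\min + \sum\max}
#'   {2(\sum_i S_i - S_T) + \sum\min + \sum\max}}
#'
#' where sums over `min`/`max` run over unordered site pairs, `S_i` is the
#' richness of site i and `S_T` the pooled (gamma) richness. Unlike mean
#' pairwise dissimilarities, these indices account for co-occurrence
#' patterns across more than two sites.
#'
#' Degenerate 0/0 denominators (e.g. all sites identical) return 0 for the
#' affected index, read as "no heterogeneity".
#'
#' @param m A presence-absence matrix with at least 2 sites and one
#'   occurrence.
#' @return A one-row tibble with columns `beta_sor`, `beta_sim`, `beta_sne`.
#' @examples
#' m <- make_nested(3, 4)
#' beta_multi(m) # perfectly nested: beta_sim = 0
#' @export
beta_multi <- function(m) {
  m <- assert_pa(m)
  if (nrow(m) < 2L) stop("multiple-site indices need at least 2 sites", call. = FALSE)
  if (sum(m) == 0L) stop("matrix has no occurrences", call. = FALSE)
  ps <- pair_sums(m)
  s_t <- gamma_diversity(m)
  core <- ps$sum_s - s_t                      # sum over pairs of shared structure
  sim_den <- core + ps$sum_min
  sor_den <- 2 * core + ps$sum_min + ps$sum_max
  beta_sim <- if (sim_den == 0) 0 else ps$sum_min / sim_den
  beta_sor <- if (sor_den == 0) 0 else (ps$sum_min + ps$sum_max) / sor_den
  tibble::tibble(
    beta_sor = beta_sor,
    beta_sim = beta_sim,
    beta_sne = beta_sor - beta_sim
  )
}

#' Pairwise beta-diversity partition
#'
#' The pairwise counterpart of [beta_multi()]: for each unordered site pair,
#' `beta_sor = (b_ij + b_ji) / (2a + b_ij + b_ji)`,
#' `beta_sim = min(b_ij, b_ji) / (a + min(b_ij, b_ji))`, and
#' `beta_sne = beta_sor - beta_sim`. For exactly two sites the pairwise and
#' multiple-site partitions coincide.
#'
#' @param m A presence-absence matrix with at least 2 sites.
#' @return A tibble with one row per unordered pair (`site_i`, `site_j`,
#'   `a`, `b_ij`, `b_ji`, `beta_sor`, `beta_sim`, `beta_sne`).
#' @seealso [beta_pairwise_mean()] for the unweighted means over pairs.
#' @export
beta_pairwise <- function(m) {
  m <- assert_pa(m)
  if (nrow(m) < 2L) stop("pairwise indices need at least 2 sites", call. = FALSE)
  ps <- pair_sums(m)
  idx <- which(upper.tri(ps$a), arr.ind = TRUE)
  a <- ps$a[idx]
  b_ij <- ps$b[idx]
  b_ji <- t(ps$b)[idx]
  bmin <- pmin(b_ij, b_ji)
  sor_den <- 2 * a + b_ij + b_ji
  sim_den <- a + bmin
  beta_sor <- ifelse(sor_den == 0, 0, (b_ij + b_ji) / sor_den)
  beta_sim <- ifelse(sim_den == 0, 0, bmin / sim_den)
  tibble::tibble(
    site_i = rownames(m)[idx[, 1]],
    site_j = rownames(m)[idx[, 2]],
    a = a, b_ij = b_ij, b_ji = b_ji,
    beta_sor = beta_sor,
    beta_sim = beta_sim,
    beta_sne = beta_sor - beta_sim
  )
}

#' @rdname beta_pairwise
#' @return `beta_pairwise_mean()`: a one-row tibble of unweighted arithmetic
#'   means of the three indices over the `R(R-1)/2` pairs.
#' @export
beta_pairwise_mean <- function(m) {
  pw <- if (is.data.frame(m)) m else beta_pairwise(m)
  dplyr::summarise(
    pw,
    beta_sor = mean(.data$beta_sor),
    beta_sim = mean(.data$beta_sim),
    beta_sne = mean(.data$beta_sne)
  )
}
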