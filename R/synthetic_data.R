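#' Perfectly nested incidence matrix
#'
#' Site k holds exactly the first `richness[k]` taxa, with strictly
#' decreasing richness, so every poorer site's assemblage is a strict
#' subset of every richer one's. Such matrices have zero turnover
#' (`beta_sim = 0`): all dissimilarity is nestedness.
#'
#' @param n_sites,n_taxa Matrix dimensions (`n_sites <= n_taxa` so a strict
#'   subset chain exists).
#' @param richness Optional strictly decreasing positive richness vector;
#'   by default evenly spread from `n_taxa` down to 1.
#' @return A [pa_matrix()].
#' @export
make_nested <- function(n_sites, n_taxa, richness = NULL) {
  if (is.null(richness)) {
    richness <- round(seq(n_taxa, 1, length.out = n_sites))
    for (i in seq_len(n_sites)[-1]) {
      richness[i] <- min(richness[i], richness[i - 1] - 1)
    }
  }
  stopifnot(length(richness) == n_sites, all(diff(richness) < 0) || n_sites == 1,
            all(richness >= 1), max(richness) <= n_taxa)
  m <- matrix(0L, n_sites, n_taxa,
              dimnames = list(paste0("site_", seq_len(n_sites)),
                              paste0("taxon_", seq_len(n_taxa))))
  for (i in seq_len(n_sites)) m[i, seq_len(richness[i])] <- 1L
  pa_matrix(m)
}

#' Incidence matrix with complete turnover
#'
#' Each site holds its own disjoint block of taxa, so no taxon is shared:
#' `beta_sor = beta_sim = 1` and the nestedness component is zero.
#'
#' @param n_sites Number of sites.
#' @param taxa_per_site Block size; the matrix has
#'   `n_sites * taxa_per_site` taxa, each present at exactly one site.
#' @return A [pa_matrix()].
#' @export
make_turnover <- function(n_sites, taxa_per_site) {
  stopifnot(n_sites >= 1, taxa_per_site >= 1)
  n_taxa <- n_sites * taxa_per_site
  m <- matrix(0L, n_sites, n_taxa,
              dimnames = list(paste0("site_", seq_len(n_sites)),
                              paste0("taxon_", seq_len(n_taxa))))
  for (i in seq_len(n_sites)) {
    m[i, ((i - 1) * taxa_per_site + 1):(i * taxa_per_site)] <- 1L
  }
  pa_matrix(m)
}

#' Equiprobable random incidence matrix
#'
#' Places exactly `round(fill * n_sites * n_taxa)` occurrences uniformly
#' over the cells without collision. Draws containing an empty site are
#' rejected and redrawn (valid study matrices have no empty sites), with a
#' message; structurally these matrices carry no co-occurrence signal, so
#' their deviation landscapes are centred on zero.
#'
#' @param n_sites,n_taxa Matrix dimensions.
#' @param fill Target matrix fill in (0, 1).
#' @param max_redraws Redraw attempts before giving up.
#' @return A [pa_matrix()].
#' @export
make_random <- function(n_sites, n_taxa, fill, max_redraws = 100) {
  stopifnot(fill > 0, fill < 1)
  f <- round(fill * n_sites * n_taxa)
  if (f < n_sites) {
    stop("fill too low: fewer occurrences than sites, empty sites unavoidable",
         call. = FALSE)
  }
  for (k in seq_len(max_redraws)) {
    m <- matrix(0L, n_sites, n_taxa,
                dimnames = list(paste0("site_", seq_len(n_sites)),
                                paste0("taxon_", seq_len(n_taxa))))
    m[sample.int(n_sites * n_taxa, f)] <- 1L
    if (all(rowSums(m) > 0L)) {
      if (k > 1) message("make_random: redrew ", k - 1, " matrices with empty sites")
      return(pa_matrix(m))
    }
  }
  stop("make_random: could not draw a matrix without empty sites", call. = FALSE)
}

#' Specification for the elevational-gradient generator
#'
#' Describes a synthetic metacommunity emulating a temperature-structured
#' incidence data set: four bioclimatic stages spanning the mean-annual-
#' temperature bands of an Alpine gradient (foothill > 8, montane 4-8,
#' subalpine 0-4, alpine < 0 deg C), with regional richness declining from
#' warm to cold and a tunable mix of nested and turnover structure.
#'
#' A fraction `lambda` of the taxa are "core" taxa with a Gaussian thermal
#' response centred at the warm end of the gradient, so their occupancy
#' decays monotonically toward the cold stages at a taxon-specific rate —
#' ordered species loss, the nestedness driver. The remaining taxa have
#' staggered narrow Gaussian thermal optima, drawn with a warm skew so
#' replacement is concentrated at the warm stages and regional richness
#' declines toward the cold end — the turnover driver. Occupancy
#' probabilities are rescaled once so the expected matrix fill matches
#' `target_fill`.
#'
#' @param n_sites_per_stage Named integer vector of site counts for
#'   foothill, montane, subalpine, alpine. The default (84, 110, 83, 32)
#'   gives 309 sites peaking at mid elevation with a 32-site minimum stage.
#' @param n_taxa Number of taxa (default 78).
#' @param target_fill Target matrix fill (default 0.33).
#' @param lambda Fraction of core (nested-structure) taxa in `[0, 1]`.
#' @param core_sigma_range Range of decay widths (deg C) for core taxa:
#'   small widths lose the taxon just below the warm end, large widths keep
#'   it across most of the gradient.
#' @param sigma_range Range of niche widths (deg C) for turnover taxa.
#' @param warm_skew Exponent `< 1` skewing turnover-taxon optima toward the
#'   warm end (optima are `Tmin + range * U^warm_skew`); 1 = uniform.
#' @param p_max_range Range of maximal occupancy probabilities.
#' @param determinism Sharpness of community assembly at the cold end
#'   (`>= 1`). Occupancy probabilities are tempered through
#'   `p^s / (p^s + (1-p)^s)` with the exponent `s` rising linearly from 1
#'   at the warm end to `determinism` at the cold end: cold-stage
#'   assemblages become increasingly deterministic (environmental
#'   filtering), warm-stage ones stay stochastic. `Inf` disables
#'   stochasticity entirely at the cold end (occupancy = probability above
#'   one half).
#' @param temperature_limits Overall gradient span in deg C.
#' @return A list of class `gradient_spec`.
#' @export
gradient_spec <- function(n_sites_per_stage = c(foothill = 84, montane = 110,
                                                subalpine = 83, alpine = 32),
                          n_taxa = 78,
                          target_fill = 0.33,
                          lambda = 0.5,
                          core_sigma_range = c(3, 10),
                          sigma_range = c(0.8, 2.5),
                          warm_skew = 0.5,
                          p_max_range = c(0.4, 1),
                          determinism = 3,
                          temperature_limits = c(-4, 12)) {
  stopifnot(
    length(n_sites_per_stage) == 4,
    all(n_sites_per_stage >= 1),
    n_taxa >= 1,
    target_fill > 0, target_fill < 1,
    lambda >= 0, lambda <= 1,
    all(core_sigma_range > 0),
    all(sigma_range > 0),
    warm_skew > 0, warm_skew <= 1,
    determinism >= 1,
    all(p_max_range > 0), all(p_max_range <= 1),
    temperature_limits[1] < 0, temperature_limits[2] > 8
  )
  if (is.null(names(n_sites_per_stage))) {
    names(n_sites_per_stage) <- c("foothill", "montane", "subalpine", "alpine")
  }
  structure(
    list(
      n_sites_per_stage = n_sites_per_stage, n_taxa = n_taxa,
      target_fill = target_fill, lambda = lambda,
      core_sigma_range = core_sigma_range, sigma_range = sigma_range,
      warm_skew = warm_skew,
      p_max_range = p_max_range, determinism = determinism,
      temperature_limits = temperature_limits
    ),
    class = "gradient_spec"
  )
}

stage_temperature_bands <- function(limits) {
  tibble::tibble(
    stage = c("foothill", "montane", "subalpine", "alpine"),
    t_min = c(8, 4, 0, limits[1]),
    t_max = c(limits[2], 8, 4, 0)
  )
}

#' Generate a synthetic elevational-gradient metacommunity
#'
#' Draws site temperatures uniformly within each stage's band, computes
#' per-site, per-taxon occupancy probabilities from the niche model in
#' [gradient_spec()], rescales them to the target fill, and samples
#' independent Bernoulli occurrences. Sites are exchangeable within a
#' stage (no spatial autocorrelation), matching the exchangeability
#' assumption of the downstream analysis. Elevation is a noisy linear
#' lapse-rate transform of temperature, reported for realism only.
#'
#' @param spec A [gradient_spec()].
#' @param max_redraws Per-site redraw attempts for empty assemblages.
#' @return A list with elements `matrix` (a [pa_matrix()]) and `metadata`
#'   (tibble: `site_id`, `temperature`, `elevation`, `stage`).
#' @export
make_gradient <- function(spec = gradient_spec(), max_redraws = 100) {
  stopifnot(inherits(spec, "gradient_spec"))
  bands <- stage_temperature_bands(spec$temperature_limits)
  n_stage <- spec$n_sites_per_stage
  stage <- rep(bands$stage, times = n_stage[bands$stage])
  temperature <- unlist(purrr::map(bands$stage, function(s) {
    b <- bands[bands$stage == s, ]
    stats::runif(n_stage[[s]], b$t_min, b$t_max)
  }))
  n_sites <- length(stage)
  n_core <- round(spec$lambda * spec$n_taxa)
  t_cold <- spec$temperature_limits[1]
  t_warm <- spec$temperature_limits[2]
  t_range <- t_warm - t_cold

  p_max <- stats::runif(spec$n_taxa, spec$p_max_range[1], spec$p_max_range[2])
  core_sigma <- stats::runif(spec$n_taxa, spec$core_sigma_range[1],
                             spec$core_sigma_range[2])
  mu <- t_cold + t_range * stats::runif(spec$n_taxa)^spec$warm_skew
  sigma <- stats::runif(spec$n_taxa, spec$sigma_range[1], spec$sigma_range[2])
  is_core <- seq_len(spec$n_taxa) <= n_core

  # occupancy probability matrix: sites x taxa
  prob <- matrix(0, n_sites, spec$n_taxa)
  for (t in seq_len(spec$n_taxa)) {
    prob[, t] <- if (is_core[t]) {
      p_max[t] * exp(-(temperature - t_warm)^2 / (2 * core_sigma[t]^2))
    } else {
      p_max[t] * exp(-(temperature - mu[t])^2 / (2 * sigma[t]^2))
    }
  }
  # temper toward determinism at the cold end: exponent 1 (warm) ->
  # `determinism` (cold), fixed point at p = 0.5
  sharp <- if (is.infinite(spec$determinism)) {
    1 + 1e6 * (t_warm - temperature) / t_range
  } else {
    1 + (spec$determinism - 1) * (t_warm - temperature) / t_range
  }
  temper <- function(p, s) {
    ps <- p^s
    qs <- (1 - p)^s
    out <- ps / (ps + qs)
    out[p >= 1] <- 1
    out[p <= 0] <- 0
    out
  }
  # calibrate a single pre-tempering scale so the expected fill hits target
  fill_at <- function(log_scale) {
    p <- pmin(prob * exp(log_scale), 0.995)
    mean(temper(p, sharp)) - spec$target_fill
  }
  lo <- -3
  hi <- 5
  if (fill_at(hi) < 0) {
    warning("make_gradient: target fill unreachable; using maximal occupancy",
            call. = FALSE)
    scale <- exp(hi)
  } else {
    scale <- exp(stats::uniroot(fill_at, c(lo, hi), tol = 1e-4)$root)
  }
  prob <- temper(pmin(prob * scale, 0.995), sharp)

  m <- matrix(0L, n_sites, spec$n_taxa,
              dimnames = list(paste0("site_", seq_len(n_sites)),
                              paste0("taxon_", seq_len(spec$n_taxa))))
  for (i in seq_len(n_sites)) {
    for (k in seq_len(max_redraws)) {
      row <- as.integer(stats::runif(spec$n_taxa) < prob[i, ])
      if (sum(row) > 0L) break
      if (k == max_redraws) {
        stop("make_gradient: site ", i, " empty after ", max_redraws,
             " redraws; increase target_fill or p_max", call. = FALSE)
      }
    }
    m[i, ] <- row
  }
  elevation <- pmax(2250 - 160 * temperature + stats::rnorm(n_sites, 0, 130), 150)
  list(
    matrix = pa_matrix(m),
    metadata = tibble::tibble(
      site_id = rownames(m),
      temperature = temperature,
      elevation = elevation,
      stage = factor(stage, levels = bands$stage)
    )
  )
}
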