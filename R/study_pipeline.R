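#' Assign bioclimatic stages from mean annual temperature
#'
#' Four temperature-defined elevation bands: foothill above 8 deg C,
#' montane 4-8 deg C (closed range), subalpine 0 to below 4 deg C, alpine
#' below 0 deg C.
#'
#' @param temperature Numeric vector of mean annual temperatures (deg C).
#' @return A factor with levels foothill, montane, subalpine, alpine
#'   (warm to cold).
#' @examples
#' assign_stage(c(9, 5, 2, -1))
#' @export
assign_stage <- function(temperature) {
  if (any(!is.finite(temperature))) {
    stop("non-finite temperature", call. = FALSE)
  }
  out <- dplyr::case_when(
    temperature > 8 ~ "foothill",
    temperature >= 4 ~ "montane",
    temperature >= 0 ~ "subalpine",
    .default = "alpine"
  )
  factor(out, levels = c("foothill", "montane", "subalpine", "alpine"))
}

#' Study configuration
#'
#' Bundles every tunable of the end-to-end analysis: equal-n subsampling,
#' repetition counts, null-space grid resolution, per-node null-sample
#' counts, randomizer controls and the significance level.
#'
#' @param n_subsample Sites drawn per stage (the study design uses the
#'   minimum stage size).
#' @param n_repetitions Number of independent subsampling repetitions whose
#'   results are averaged.
#' @param grid_levels Null-space grid resolution per axis (11 gives the
#'   full 121-node space).
#' @param n_null Null matrices per grid node.
#' @param alpha Significance level for the deviation rule and the stage
#'   comparisons.
#' @param params A [tp_params()] list for the randomizer.
#' @param ties,family,paired Passed to [beta_deviation()] /
#'   [compare_stages()].
#' @param seed Integer root seed; every repetition x node task derives its
#'   own stream from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_subsample = 32, n_repetitions = 100,
                         grid_levels = 11, n_null = 100, alpha = 0.05,
                         params = tp_params(), ties = "strict",
                         family = "all_pairs", paired = FALSE, seed = NULL) {
  stopifnot(n_subsample >= 2, n_repetitions >= 1, grid_levels >= 2,
            n_null >= 1, alpha > 0, alpha < 0.5)
  structure(
    list(n_subsample = n_subsample, n_repetitions = n_repetitions,
         grid_levels = grid_levels, n_null = n_null, alpha = alpha,
         params = params, ties = ties, family = family, paired = paired,
         seed = seed),
    class = "study_config"
  )
}

#' Equal-n subsample of sites per stage
#'
#' Uniform sampling without replacement of `n` sites within each stage,
#' each stage submatrix trimmed of taxa unobserved in the drawn sites.
#' Equalizing site numbers across stages removes the sampling-effort bias
#' that would otherwise confound between-stage comparisons.
#'
#' @param m Full presence-absence matrix.
#' @param metadata Site metadata tibble with `site_id` and `stage`.
#' @param n Sites per stage; must not exceed any stage's size.
#' @return A named list of per-stage [pa_matrix()] objects, ordered warm to
#'   cold.
#' @export
subsample_equal <- function(m, metadata, n) {
  m <- assert_pa(m)
  stopifnot(all(c("site_id", "stage") %in% names(metadata)))
  missing <- setdiff(rownames(m), metadata$site_id)
  if (length(missing)) {
    stop("sites without metadata: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  stages <- levels(factor(metadata$stage))
  by_stage <- split(as.character(metadata$site_id), metadata$stage)
  out <- purrr::imap(by_stage[stages], function(ids, stage_name) {
    ids <- intersect(ids, rownames(m))
    if (length(ids) < n) {
      stop("stage '", stage_name, "' has fewer than ", n, " sites",
           call. = FALSE)
    }
    pick <- sample(ids, n)
    trim_empty_taxa(new_pa(unclass(m)[pick, , drop = FALSE]))
  })
  out
}

#' Per-stage raw diversity profile
#'
#' The three multiple-site indices plus the two matrix parameters the null
#' models hold fixed: gamma-diversity and matrix fill.
#'
#' @param stage_matrices Named list of per-stage presence-absence matrices.
#' @return A tibble: `stage`, `beta_sor`, `beta_sim`, `beta_sne`, `gamma`,
#'   `fill`, `n_sites`.
#' @export
raw_profile <- function(stage_matrices) {
  purrr::imap_dfr(stage_matrices, function(m, s) {
    dplyr::bind_cols(
      tibble::tibble(stage = s),
      beta_multi(m),
      tibble::tibble(
        gamma = gamma_diversity(m),
        fill = matrix_fill(m),
        n_sites = nrow(m)
      )
    )
  })
}

#' Run the full study pipeline
#'
#' For each repetition: subsample equal numbers of sites per stage, compute
#' the per-stage raw profile, and the per-stage deviation landscape over
#' the null-space grid. Profiles and landscapes are then averaged per stage
#' across repetitions (deviations and p-values averaged per node; the mean
#' p is a descriptive, not inferential, summary), and stage pairs are
#' compared with Wilcoxon rank-sum tests on the per-node averaged
#' deviations at each conservativeness level, Holm-corrected.
#'
#' Deterministic for a fixed `config$seed`: each (repetition, stage, node)
#' task draws from its own derived RNG stream.
#'
#' @param m Full presence-absence matrix.
#' @param metadata Site metadata with `site_id` and `stage`.
#' @param config A [study_config()].
#' @return A list of class `study_result`: `profile` (mean over
#'   repetitions), `profile_by_rep`, `landscape` (averaged per stage),
#'   `comparisons`, `config`.
#' @export
run_study <- function(m, metadata, config = study_config()) {
  m <- assert_pa(m)
  stopifnot(inherits(config, "study_config"))
  grid <- null_space_grid(config$grid_levels)
  stages <- levels(factor(metadata$stage))

  rep_results <- purrr::map(seq_len(config$n_repetitions), function(rep) {
    if (!is.null(config$seed)) set.seed(derive_seed(config$seed, rep))
    mats <- subsample_equal(m, metadata, config$n_subsample)
    prof <- dplyr::mutate(raw_profile(mats), repetition = rep)
    land <- purrr::imap_dfr(mats, function(sm, stage_name) {
      seed_s <- if (is.null(config$seed)) NULL else {
        derive_seed(config$seed, rep, match(stage_name, stages))
      }
      dplyr::mutate(
        tibble::as_tibble(
          beta_landscape(sm, grid = grid, n_null = config$n_null,
                         params = config$params, seed = seed_s,
                         ties = config$ties)
        ),
        stage = stage_name, repetition = rep
      )
    })
    list(profile = prof, landscape = land)
  })

  profile_by_rep <- purrr::map_dfr(rep_results, "profile")
  profile <- profile_by_rep |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(dplyr::across(
      c("beta_sor", "beta_sim", "beta_sne", "gamma", "fill"), mean
    ), n_sites = config$n_subsample, .groups = "drop") |>
    dplyr::arrange(match(.data$stage, stages))

  landscape <- purrr::map_dfr(rep_results, "landscape") |>
    dplyr::group_by(.data$stage, .data$row_level, .data$col_level,
                    .data$d_row_target, .data$d_col_target, .data$index) |>
    dplyr::summarise(
      beta_obs = mean(.data$beta_obs),
      beta_null_mean = mean(.data$beta_null_mean),
      delta = mean(.data$delta),
      p_value = mean(.data$p_value),
      n_null = sum(.data$n_null),
      d_row_achieved = mean(.data$d_row_achieved),
      d_col_achieved = mean(.data$d_col_achieved),
      .groups = "drop"
    )

  per_stage <- purrr::map(stages, function(s) {
    new_beta_landscape(
      dplyr::filter(landscape, .data$stage == s),
      levels = config$grid_levels
    )
  })
  names(per_stage) <- stages
  comparisons <- compare_stages(
    per_stage,
    family = config$family, paired = config$paired
  )

  structure(
    list(
      profile = profile,
      profile_by_rep = profile_by_rep,
      landscape = new_beta_landscape(landscape, levels = config$grid_levels),
      comparisons = comparisons,
      config = config
    ),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result> ", x$config$n_repetitions, " repetition(s), ",
      x$config$grid_levels, "x", x$config$grid_levels, " null space, ",
      x$config$n_null, " nulls/node\n\n", sep = "")
  cat("Per-stage profile (averaged over repetitions):\n")
  print(x$profile)
  invisible(x)
}
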