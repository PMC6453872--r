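#' Per-subject density and texture feature table
#'
#' For each subject: the image's own step wedge is fitted
#' ([fit_wedge_curve()]), every ROI gets its mean grayscale (GV) and
#' calibrated density (GV_mmAl, NA when out of calibration range), and
#' directional fractal signature analysis yields FD_Ver and FD_Hor at
#' the four local scales plus the global fit. One wide row per subject:
#' 18 ROIs x (gv, gv_mmal, 4 FD_Ver, 4 FD_Hor) plus the two global FDs
#' per ROI.
#'
#' @param cohort A [generate_cohort()] result (or a compatible list with
#'   `subjects`, `rois`, `config`).
#' @param pp Which image to measure: `"minimal"` or `"clinical"`.
#' @return Tibble: `subject_id`, then the named feature columns, e.g.
#'   `gv_mmal_medial_SB`, `fd_ver_0.30_ROI7`, `fd_hor_global_ROI3`.
#' @export
extract_features <- function(cohort, pp = c("minimal", "clinical")) {
  pp <- match.arg(pp)
  stopifnot(inherits(cohort, "radbone_cohort"))
  purrr::map_dfr(cohort$subjects, function(sub) {
    rg <- sub[[pp]]
    curve <- fit_wedge_curve(rg$pixels, cohort$config$wedge)
    row <- list(subject_id = rg$subject_id)
    for (i in seq_len(nrow(cohort$rois))) {
      roi <- cohort$rois$roi_name[i]
      px <- extract_roi(rg, cohort$rois[i, ])
      dens <- gv_to_mmal(curve, mean_gv(px))
      row[[paste0("gv_", roi)]] <- dens$gv
      row[[paste0("gv_mmal_", roi)]] <- dens$gv_mmal
      sig <- fsa_roi(px, rg$pixel_size_mm, roi)
      for (orient in c("ver", "hor")) {
        s <- sig[[if (orient == "ver") "vertical" else "horizontal"]]
        for (sc in names(s$fd_local_by_scale_mm)) {
          row[[paste0("fd_", orient, "_", sc, "_", roi)]] <-
            unname(s$fd_local_by_scale_mm[[sc]])
        }
        row[[paste0("fd_", orient, "_global_", roi)]] <- s$fd_global
      }
    }
    as_tibble(row)
  })
}

feature_matrix <- function(features, prefixes = c("gv_mmal_", "fd_ver_", "fd_hor_")) {
  cols <- names(features)[Reduce(`|`, lapply(prefixes, startsWith, x = names(features)))]
  as.matrix(features[, cols])
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulation, ROI extraction, calibration and texture analysis, group
#' statistics, processing-mode agreement, and the two classification
#' tasks (radiographic OA vs control; medial BML vs no BML), each fit
#' with bone features only and with covariates (age, sex, BMI) added.
#' Deterministic given the config seed.
#'
#' @param config A [cohort_config()] (its `seed` drives everything).
#' @param enet An [enet_config()] for the classification stage.
#' @param tasks Character subset of `c("oa", "bml")`.
#' @param with_covariates Also fit the covariate-augmented models.
#' @param out_dir Optional directory: when given, writes `features.csv`
#'   (minimal PP), `features_clinical.csv`, `group_stats.csv`,
#'   `pp_agreement.csv`, `truth.csv` and one `model_<task>*.json` per
#'   fitted model.
#' @return A `radbone_run` list: `cohort`, `features_minimal`,
#'   `features_clinical`, `group_stats`, `pp_agreement`, and `models`
#'   (per task: `features` and optionally `with_covariates`
#'   [loocv_grid_search()] results).
#' @export
run_pipeline <- function(config = cohort_config(), enet = enet_config(),
                         tasks = c("oa", "bml"), with_covariates = TRUE,
                         out_dir = NULL) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  cohort <- generate_cohort(config)
  feat_min <- extract_features(cohort, "minimal")
  feat_cli <- extract_features(cohort, "clinical")
  subjects <- dplyr::distinct(cohort$truth[, c("subject_id", "group",
                                               "age", "sex", "bmi")])
  feat_g <- dplyr::left_join(feat_min, subjects, by = "subject_id")

  stat_cols <- names(feat_min)[startsWith(names(feat_min), "gv_mmal_") |
                                 startsWith(names(feat_min), "fd_")]
  group_stats <- group_table(feat_g, stat_cols)
  agreement <- pp_agreement(feat_min, feat_cli)

  X <- feature_matrix(feat_min)
  Xcov <- cbind(X, age = feat_g$age, sex = as.integer(feat_g$sex == "M"),
                bmi = feat_g$bmi)
  models <- list()
  for (task in tasks) {
    y <- if (task == "oa") as.integer(feat_g$group > 0) else
      as.integer(feat_g$group == 2)
    models[[task]] <- list(features = loocv_grid_search(X, y, enet))
    if (with_covariates) {
      models[[task]]$with_covariates <- loocv_grid_search(Xcov, y, enet)
    }
  }
  run <- structure(
    list(cohort = cohort, features_minimal = feat_min,
         features_clinical = feat_cli, group_stats = group_stats,
         pp_agreement = agreement, models = models,
         seed = config$seed),
    class = "radbone_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @method print radbone_run
#' @export
print.radbone_run <- function(x, ...) {
  cat(sprintf("<radbone_run> seed %d, %d subjects\n", x$seed,
              length(x$cohort$subjects)))
  for (task in names(x$models)) {
    for (variant in names(x$models[[task]])) {
      m <- x$models[[task]][[variant]]
      cat(sprintf("  %s (%s): AUC %.3f (%.3f-%.3f), alpha %g lambda %g\n",
                  task, variant, m$roc$auc, m$roc$ci_low, m$roc$ci_high,
                  m$best_alpha, m$best_lambda))
    }
  }
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$features_minimal, file.path(out_dir, "features.csv"))
  readr::write_csv(run$features_clinical,
                   file.path(out_dir, "features_clinical.csv"))
  readr::write_csv(run$group_stats, file.path(out_dir, "group_stats.csv"))
  readr::write_csv(run$pp_agreement, file.path(out_dir, "pp_agreement.csv"))
  readr::write_csv(run$cohort$truth, file.path(out_dir, "truth.csv"))
  for (task in names(run$models)) {
    for (variant in names(run$models[[task]])) {
      m <- run$models[[task]][[variant]]
      jsonlite::write_json(
        list(task = task, variant = variant,
             alpha = m$best_alpha, lambda = m$best_lambda,
             auc = m$roc$auc, ci = c(m$roc$ci_low, m$roc$ci_high),
             coefficients = as.list(tidy(m$fit) |>
                                      tibble::deframe())),
        file.path(out_dir, sprintf("model_%s_%s.json", task, variant)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(out_dir)
}
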