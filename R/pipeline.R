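#' Write a simulated cohort to disk
#'
#' Materialises a [make_cohort()] result as the on-disk layout the pipeline
#' consumes: NIfTI masks, midplane text files (center + normal), a
#' covariate CSV and a ground-truth CSV.
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$phantoms)) {
    id <- cohort$covariates$subject_id[i]
    ph <- cohort$phantoms[[i]]
    write_volume(ph$mask, file.path(dir, paste0(id, "_mask.nii.gz")))
    writeLines(paste(c(ph$plane$center, ph$plane$normal), collapse = " "),
               file.path(dir, paste0(id, "_plane.txt")))
  }
  write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

read_plane_file <- function(path) {
  v <- scan(path, quiet = TRUE)
  stopifnot(length(v) == 6)
  midplane(v[1:3], v[4:6])
}

#' Run the full cohort pipeline
#'
#' Orchestrates the whole framework over a cohort: determine each subject's
#' midsagittal plane (explicit plane file, rigid transform, or built-in
#' symmetry estimation), build the symmetric template from all masks, fit
#' every subject, compute similarity metrics and shape measures, and (when
#' covariates are available) the scalar and vertex-wise robust regressions.
#' Writes per-subject fitted meshes (PLY with the deformity map), cohort
#' CSV tables and a JSON manifest of parameters; deterministic given
#' identical inputs.
#'
#' @param config configuration list or path to a YAML file with fields:
#'   `masks` (character vector of NIfTI paths), optional `planes` (plane
#'   text files), optional `transforms` (4x4 native-to-standard matrices),
#'   optional `covariates` (CSV path), `output_dir`, optional
#'   `template` (list: `target_vertices`), optional `fit` (list of
#'   [deformation_params()] arguments), optional `predictors` (character,
#'   default `c("gender", "btv", "fi")`), optional `icv_reference`.
#' @return the cohort report (list), invisibly; artifacts under
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$masks), !is.null(config$output_dir))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(config$masks)
  missing <- !file.exists(config$masks)
  if (any(missing))
    stop("missing mask file(s): ", paste(config$masks[missing],
                                         collapse = ", "))
  ids <- sub("(_mask)?\\.nii(\\.gz)?$", "", basename(config$masks))
  masks <- lapply(config$masks, read_mask)
  planes <- vector("list", n)
  for (i in seq_len(n)) {
    planes[[i]] <- if (!is.null(config$planes)) {
      read_plane_file(config$planes[[i]])
    } else if (!is.null(config$transforms)) {
      plane_from_transform(read_transform(config$transforms[[i]]))
    } else {
      estimate_msp_by_symmetry(masks[[i]])
    }
  }
  tpl_args <- config$template
  target_vertices <- if (is.null(tpl_args$target_vertices)) 2500
                     else tpl_args$target_vertices
  mean_mask <- build_symmetric_shape(masks, planes)
  template <- build_template(mean_mask, target_vertices)
  write_template(template, file.path(out_dir, "template"))
  params <- do.call(deformation_params,
                    if (is.null(config$fit)) list() else config$fit)
  covs <- if (!is.null(config$covariates)) read.csv(config$covariates)
  icv_ref <- if (!is.null(config$icv_reference)) config$icv_reference
             else if (!is.null(covs$icv)) mean(covs$icv) else NA
  sim_rows <- list()
  meas_rows <- list()
  deform <- matrix(NA_real_, n, nrow(template$mesh$vertices))
  for (i in seq_len(n)) {
    fitted <- fit_template(template, masks[[i]], planes[[i]], params)
    cmp <- compare_fit(fitted, masks[[i]])
    sim_rows[[i]] <- data.frame(subject_id = ids[i], as.data.frame(cmp))
    sf <- if (!is.null(covs$icv) && is.finite(icv_ref))
      (covs$icv[i] / icv_ref)^(1 / 3) else 1
    ms <- shape_measures(fitted, template, masks[[i]], planes[[i]], sf)
    deform[i, ] <- ms$deformity
    meas_rows[[i]] <- data.frame(
      subject_id = ids[i], volume_mm3 = ms$volume_mm3,
      average_tvw = ms$average_tvw, anterior_tvw = ms$anterior_tvw,
      posterior_tvw = ms$posterior_tvw, max_tva = ms$max_tva,
      mean_tva = ms$mean_tva)
    write_ply(fitted, file.path(out_dir, paste0(ids[i], "_fit.ply")),
              scalars = data.frame(deformity = ms$deformity))
  }
  similarity <- do.call(rbind, sim_rows)
  measures <- do.call(rbind, meas_rows)
  write.csv(similarity, file.path(out_dir, "similarity.csv"),
            row.names = FALSE)
  write.csv(measures, file.path(out_dir, "measures.csv"), row.names = FALSE)
  ba <- bland_altman(similarity$mesh_volume_mm3, similarity$mask_volume_mm3)
  report <- list(n_subjects = n, subject_ids = ids,
                 similarity = similarity, measures = measures,
                 volume_bland_altman = ba[c("bias", "loa", "sd")])
  stats_tables <- NULL
  if (!is.null(covs)) {
    predictors <- if (is.null(config$predictors)) {
      intersect(c("gender", "btv", "fi"), names(covs))
    } else {
      config$predictors
    }
    adjust <- intersect(c("age_days", "gender"), names(covs))
    outcomes <- measures[c("volume_mm3", "average_tvw", "anterior_tvw",
                           "posterior_tvw", "max_tva")]
    stats_tables <- list()
    for (pr in predictors) {
      cv <- setdiff(adjust, pr)
      if (n < length(cv) + 2 + 5) {
        warning("too few subjects for regression on '", pr, "'; skipped")
        next
      }
      tab <- measure_regressions(outcomes, covs, pr, cv)
      vw <- vertexwise_regression(deform, covs[c(pr, cv)], pr, cv)
      stats_tables[[pr]] <- list(scalar = tab, vertexwise = vw)
      write.csv(tab, file.path(out_dir, paste0("regression_", pr, ".csv")),
                row.names = FALSE)
      write_ply(template$mesh,
                file.path(out_dir, paste0("map_", pr, ".ply")),
                scalars = vw[c("beta", "p", "q")])
    }
  } else {
    message("no covariates supplied; statistics stage skipped")
  }
  report$stats <- stats_tables
  manifest <- list(package_version = as.character(
                     utils::packageVersion("ventricle3d")),
                   n_subjects = n, subject_ids = ids,
                   target_vertices = target_vertices,
                   fit_params = unclass(params),
                   icv_reference = icv_ref)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
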