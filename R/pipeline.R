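## Orchestration: reproducible end-to-end runs and file-level stage wrappers.
## Every run writes a JSON sidecar with the resolved configuration, seed,
## package version and input checksums. All computations are voxel-space;
## CSVs are UTF-8, comma-separated, '.' decimal, with a header row.

write_sidecar <- function(path, stage, config, inputs = character()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(stage = stage, config = config,
         package = "wmhbullseye",
         version = as.character(utils::packageVersion("wmhbullseye")),
         input_md5 = sums),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

require_file <- function(path, stage) {
  if (!file.exists(path))
    stop("[", stage, "] missing input file: ", path, call. = FALSE)
  path
}

#' File-level parcellation stage
#'
#' Reads ventricle/cortex/white-matter masks and a lobar label volume
#' (NIfTI-1), runs [bullseye_parcellation()], and writes the bullseye label
#' volume, the code table CSV and a JSON sidecar.
#'
#' @param ventricles,cortex,wm,lobar input NIfTI paths.
#' @param out output NIfTI path for the parcel label volume.
#' @param code_table optional CSV path for the code table.
#' @return the `bullseye_map`, invisibly.
#' @export
pipeline_parcellate <- function(ventricles, cortex, wm, lobar, out,
                                code_table = NULL) {
  for (p in c(ventricles, cortex, wm, lobar)) require_file(p, "parcellate")
  v <- nifti_read(ventricles)
  cx <- nifti_read(cortex)
  w <- nifti_read(wm)
  lb <- nifti_read(lobar)
  spacing <- attr(v, "spacing")
  bm <- bullseye_parcellation(v != 0, cx != 0, w != 0, array(as.integer(lb), dim(lb)),
                              spacing)
  nifti_write(bm$values, out, spacing = spacing, datatype = "int16")
  if (!is.null(code_table))
    write.csv(bm$code_table, code_table, row.names = FALSE)
  write_sidecar(paste0(out, ".json"), "parcellate",
                list(ventricles = ventricles, cortex = cortex, wm = wm,
                     lobar = lobar, out = out),
                inputs = c(ventricles, cortex, wm, lobar))
  invisible(bm)
}

#' File-level quantification stage
#'
#' Reads a bullseye label volume and a binary WMH mask, computes per-parcel
#' volumes, and writes one CSV row (columns `subject_id`, `eTIV`,
#' `p11..p94`, `unassigned_mm3`).
#'
#' @param parcels,wmh input NIfTI paths.
#' @param out_csv output CSV path.
#' @param subject_id subject identifier written to the CSV.
#' @param etiv_mm3 optional eTIV to record (NA if unknown).
#' @return the per-parcel volume list, invisibly.
#' @export
pipeline_quantify <- function(parcels, wmh, out_csv, subject_id = "subject",
                              etiv_mm3 = NA_real_) {
  require_file(parcels, "quantify"); require_file(wmh, "quantify")
  pv <- nifti_read(parcels)
  lesion <- nifti_read(wmh)
  res <- parcel_volumes(array(as.integer(pv), dim(pv)), lesion != 0,
                        attr(pv, "spacing"))
  row <- data.frame(subject_id = subject_id, eTIV = etiv_mm3,
                    t(res$per_parcel_mm3), unassigned_mm3 = res$unassigned_mm3,
                    check.names = FALSE)
  names(row)[3:38] <- paste0("p", parcel_codes())
  write.csv(row, out_csv, row.names = FALSE)
  write_sidecar(paste0(out_csv, ".json"), "quantify",
                list(parcels = parcels, wmh = wmh, out_csv = out_csv),
                inputs = c(parcels, wmh))
  invisible(res)
}

#' Full synthetic end-to-end run
#'
#' Generates a phantom brain and a synthetic cohort, then runs every
#' downstream stage: bullseye parcellation, lesion seeding + round-trip
#' volumetry for one exemplar subject, eTIV adjustment and log transform,
#' parallel analysis, component fitting, mass-univariate parcel models,
#' component-cognition models with bootstrap CIs, demographic associations
#' and age-tertile gamma GLM contrasts. All artifacts are written under
#' `out_dir`; identical `seed` gives byte-identical CSV/JSON outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed global integer seed.
#' @param n cohort size (default 108).
#' @param shape phantom grid (default 64^3 for speed; 96^3 matches the
#'   documentation examples).
#' @param n_sim parallel-analysis null simulations.
#' @param B bootstrap resamples for the component models.
#' @param write_nifti also write phantom masks and the parcel volume as
#'   NIfTI (default TRUE).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_demo_pipeline <- function(out_dir, seed = 1L, n = 108L,
                              shape = c(64L, 64L, 64L), n_sim = 500L,
                              B = 1000L, write_nifti = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, paste0(...))

  # 1. phantom + parcellation
  pb <- make_phantom_brain(shape = shape, seed = seed)
  bm <- parcellate_phantom(pb)
  if (write_nifti) {
    nifti_write(pb$ventricle_mask, pth("phantom_ventricles.nii.gz"), pb$spacing, "uint8")
    nifti_write(pb$cortex_mask, pth("phantom_cortex.nii.gz"), pb$spacing, "uint8")
    nifti_write(pb$wm_mask, pth("phantom_wm.nii.gz"), pb$spacing, "uint8")
    nifti_write(pb$lobar_labels, pth("phantom_lobar.nii.gz"), pb$spacing, "int16")
    nifti_write(bm$values, pth("phantom_bullseye.nii.gz"), pb$spacing, "int16")
  }
  write.csv(bm$code_table, pth("code_table.csv"), row.names = FALSE)

  # 2. exemplar lesion round-trip
  targets <- setNames(rep(50, 36), as.character(parcel_codes()))
  gt <- seed_wmh_lesions(bm, targets, seed = seed)
  qv <- parcel_volumes(bm, gt$lesion_mask)
  stopifnot(all(qv$per_parcel_mm3 == gt$per_parcel_mm3))
  write.csv(data.frame(parcel = parcel_codes(),
                       target_mm3 = unname(targets),
                       recovered_mm3 = unname(qv$per_parcel_mm3)),
            pth("lesion_roundtrip.csv"), row.names = FALSE)

  # 3. cohort + quantification table
  cohort <- simulate_cohort(n = n, seed = seed)
  write.csv(cohort, pth("cohort.csv"), row.names = FALSE)
  tab <- log_transform(adjust_etiv(parcel_table(cohort)))
  write.csv(as.data.frame(tab), pth("parcels_log.csv"), row.names = FALSE)
  summ <- summarize_distribution(parcel_table(cohort))
  write.csv(data.frame(region = rownames(summ$layer_proportions),
                       summ$layer_proportions),
            pth("layer_proportions.csv"), row.names = FALSE)
  write.csv(data.frame(parcel = parcel_codes(),
                       median_mm3 = unname(summ$parcel_medians),
                       skewness = unname(summ$parcel_skewness)),
            pth("parcel_medians.csv"), row.names = FALSE)

  # 4. components
  logmat <- as.matrix(as.data.frame(tab)[, paste0("p", parcel_codes())])
  pa <- parallel_analysis(logmat, n_sim = n_sim, seed = seed)
  k <- max(pa$n_retained, 1L)
  cm <- fit_components(logmat, k = k)
  write.csv(data.frame(parcel = rownames(cm$pattern), cm$pattern,
                       structure = cm$structure,
                       communality = unname(cm$communalities)),
            pth("loadings.csv"), row.names = FALSE)
  write.csv(data.frame(subject_id = cohort$subject_id, cm$scores),
            pth("component_scores.csv"), row.names = FALSE)
  write.csv(as.data.frame(cm$phi), pth("component_correlations.csv"),
            row.names = FALSE)
  write.csv(data.frame(position = seq_along(pa$observed),
                       observed = pa$observed, null_quantile = pa$simulated),
            pth("eigenvalues.csv"), row.names = FALSE)

  # 5. associations
  scores <- cohort[, c("subject_id", "memory", "speed", "reasoning", "vocabulary")]
  covariates <- cohort[, c("subject_id", "age", "sex", "education", "bpf",
                           "hypertension")]
  parc_assoc <- fit_parcel_models(tab, scores, covariates)
  write.csv(parc_assoc, pth("parcel_associations.csv"), row.names = FALSE)
  comp_scores <- data.frame(subject_id = cohort$subject_id, cm$scores)
  comp_assoc <- fit_component_models(scores, comp_scores, covariates,
                                     B = B, seed = seed)
  write.csv(comp_assoc, pth("component_associations.csv"), row.names = FALSE)
  demo <- demographic_associations(cm$scores, cohort$age, cohort$sex)
  write.csv(demo, pth("component_demographics.csv"), row.names = FALSE)

  total_wmh <- rowSums(cohort[, paste0("p", parcel_codes())])
  tert <- age_tertiles(cohort$age)
  gam <- gamma_glm_compare(total_wmh + 1, tert)
  write.csv(gam, pth("age_tertile_contrasts.csv"), row.names = FALSE)

  write_sidecar(pth("run.json"), "demo",
                list(seed = seed, n = n, shape = shape, n_sim = n_sim, B = B,
                     n_retained = pa$n_retained,
                     total_var_explained = cm$total_var_explained))
  invisible(list(phantom = pb, bullseye = bm, cohort = cohort, table = tab,
                 parallel = pa, components = cm, parcel_assoc = parc_assoc,
                 component_assoc = comp_assoc, demographics = demo,
                 age_contrasts = gam))
}

#' Run a pipeline stage from a configuration list
#'
#' Thin dispatcher used by the command-line entry point
#' (`inst/cli/wmh_bullseye.R`). `config$subcommand` selects the stage; the
#' remaining entries are stage arguments. Configurations may be loaded from a
#' JSON file via [jsonlite::read_json()].
#'
#' @param config named list (or path to a JSON file) with at least
#'   `subcommand` plus the stage's arguments.
#' @return the stage's return value, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    require_file(config, "config")
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  sub <- config$subcommand
  if (is.null(sub)) stop("config$subcommand is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  switch(sub,
    demo = run_demo_pipeline(
      out_dir = config$out %||% "wmh_demo", seed = seed,
      n = as.integer(config$n %||% 108L),
      shape = as.integer(config$shape %||% c(64L, 64L, 64L)),
      n_sim = as.integer(config$n_sim %||% 500L),
      B = as.integer(config$bootstrap %||% 1000L)),
    phantom = {
      pb <- make_phantom_brain(shape = as.integer(config$shape %||% c(96L, 96L, 96L)),
                               seed = seed)
      out <- config$out %||% "phantom"
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      nifti_write(pb$ventricle_mask, file.path(out, "ventricles.nii.gz"), pb$spacing, "uint8")
      nifti_write(pb$cortex_mask, file.path(out, "cortex.nii.gz"), pb$spacing, "uint8")
      nifti_write(pb$wm_mask, file.path(out, "wm.nii.gz"), pb$spacing, "uint8")
      nifti_write(pb$lobar_labels, file.path(out, "lobar.nii.gz"), pb$spacing, "int16")
      write_sidecar(file.path(out, "phantom.json"), "phantom",
                    list(seed = seed, shape = dim(pb$wm_mask)))
      invisible(pb)
    },
    parcellate = pipeline_parcellate(config$ventricles, config$cortex,
                                     config$wm, config$lobar, config$out,
                                     config$code_table),
    quantify = pipeline_quantify(config$parcels, config$wmh, config$out,
                                 subject_id = config$subject_id %||% "subject"),
    `simulate-cohort` = {
      co <- simulate_cohort(n = as.integer(config$n %||% 108L), seed = seed)
      write.csv(co, config$out %||% "cohort.csv", row.names = FALSE)
      write_sidecar(paste0(config$out %||% "cohort.csv", ".json"),
                    "simulate-cohort", list(seed = seed, n = nrow(co)))
      invisible(co)
    },
    stop("unknown subcommand: ", sub)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
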