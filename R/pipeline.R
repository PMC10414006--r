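# Pipeline orchestration: synth -> Patlak -> masks -> hotspots ->
# colocalization -> statistics, as a configured, seeded, logged run with
# NIfTI/CSV/JSON outputs and a manifest of content hashes.

#' Default pipeline configuration
#'
#' The defaults reproduce the analysis constants of the method: top decile
#' (`fraction = 0.10`), minimum cluster size 5 voxels, 26-connectivity
#' contiguity, one-voxel cubic erosion kernel, one-voxel contact band, NAWM
#' fraction threshold 0.10 for the WMH subgroup, and regional load cut-offs
#' 1/3/6.
#'
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    stages = c("synth", "patlak", "masks", "hotspots", "colocalize", "stats"),
    n_patients = 10L,
    shape = c(48L, 48L, 48L),
    voxel_mm = c(2, 2, 2),
    noise_sd = 0.002,
    fraction = 0.10,
    min_size = 5L,
    connectivity = 26L,
    erosion_kernel = "cube",
    band_radius = 1L,
    nawm_fraction_threshold = 0.10,
    load_cutoffs = c(1L, 3L, 6L),
    include_cerebellum = TRUE,
    seed = 1L,
    out_dir = "bbb_pipeline_output",
    gzip = TRUE
  )
}

#' Validate a raw pipeline configuration
#'
#' Merges a raw config list over [default_config()], rejecting unknown keys
#' and out-of-range values. All problems are reported together in one error,
#' not one at a time.
#'
#' @param raw Named list of configuration overrides.
#' @return The validated, completed configuration list.
#' @export
#' @examples
#' cfg <- validate_config(list(n_patients = 3))
#' cfg$fraction
validate_config <- function(raw = list()) {
  defaults <- default_config()
  errors <- character()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    errors <- c(errors, paste("unknown config keys:",
                              paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, raw[intersect(names(raw), names(defaults))])
  check <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  check(is.numeric(cfg$fraction) && length(cfg$fraction) == 1L &&
          cfg$fraction > 0 && cfg$fraction < 1,
        "`fraction` must be in (0, 1)")
  check(is.numeric(cfg$min_size) && cfg$min_size >= 1,
        "`min_size` must be >= 1")
  check(cfg$connectivity %in% c(6, 26), "`connectivity` must be 6 or 26")
  check(cfg$erosion_kernel %in% c("cube", "cross"),
        "`erosion_kernel` must be 'cube' or 'cross'")
  check(is.numeric(cfg$band_radius) && cfg$band_radius >= 1,
        "`band_radius` must be >= 1")
  check(is.numeric(cfg$nawm_fraction_threshold) &&
          cfg$nawm_fraction_threshold >= 0 && cfg$nawm_fraction_threshold <= 1,
        "`nawm_fraction_threshold` must be in [0, 1]")
  check(length(cfg$load_cutoffs) == 3L && all(diff(cfg$load_cutoffs) > 0),
        "`load_cutoffs` must be 3 increasing counts")
  check(is.numeric(cfg$n_patients) && cfg$n_patients >= 0,
        "`n_patients` must be >= 0")
  check(is.numeric(cfg$noise_sd) && cfg$noise_sd >= 0,
        "`noise_sd` must be >= 0")
  check(all(cfg$stages %in% defaults$stages),
        paste("`stages` must be among:", paste(defaults$stages, collapse = ", ")))
  if (length(errors)) {
    stop("invalid configuration:\n- ", paste(errors, collapse = "\n- "),
         call. = FALSE)
  }
  cfg
}

#' Analyze one patient's imaging bundle
#'
#' The per-patient analysis chain applied to a truth bundle (or real data in
#' the same shape): Patlak mapping over the eroded WM mask, ROI means,
#' volume metrics, hotspot detection, lesion colocalization and subgroup
#' eligibility. Returns tables ready for the statistics layer.
#'
#' @param bundle A [simulate_patient_imaging()] result (list with `phantom`,
#'   `dce`, `vif`, `patient`).
#' @param config A validated configuration (see [validate_config()]).
#' @return List with `maps`, `masks`, `hotspots`, `classification`,
#'   `regional_load`, and `record` — the patient's one-row summary tibble
#'   combining covariates, imaging metrics and colocalization outcomes.
#' @export
analyze_patient <- function(bundle, config = validate_config()) {
  phantom <- bundle$phantom
  masks <- build_analysis_masks(phantom$labels, kernel = config$erosion_kernel,
                                atlas = phantom$atlas,
                                include_cerebellum = config$include_cerebellum)
  maps <- map_patlak(bundle$dce, bundle$vif, masks$wm_eroded)
  roi <- roi_means(maps, masks$nawm, masks$wmh)
  vols <- volume_metrics(phantom$labels, phantom$voxel_mm,
                         log10_transform = any(masks$wmh))
  hs <- detect_hotspots(maps$ps, masks$wm_eroded, atlas = phantom$atlas,
                        voxel_mm = phantom$voxel_mm,
                        fraction = config$fraction,
                        min_size = config$min_size,
                        connectivity = config$connectivity)
  lesions <- lesion_set(phantom, band_radius = config$band_radius)
  cls <- classify_hotspots(hs, lesions)
  elig <- subgroup_eligibility(
    masks, lesions,
    fazekas_dwmh = bundle$patient$fazekas_dwmh,
    fazekas_pvh = bundle$patient$fazekas_pvh,
    nawm_fraction_threshold = config$nawm_fraction_threshold)
  coloc <- colocalization_summary(cls, lesions)
  load <- regional_load(hs, cut_offs = config$load_cutoffs)

  patient_cols <- dplyr::select(
    tibble::as_tibble(bundle$patient),
    -dplyr::any_of(c("lacune_subgroup", "wmh_subgroup", "cmb_subgroup",
                     "nawm_fraction", "n_hotspots",
                     "ps_nawm", "ps_wmh", "vp_nawm", "vp_wmh",
                     grep("_presence$|^n_(lacune_edge|within_wmh|wmh_edge|cmb_edge)$",
                          names(bundle$patient), value = TRUE))))
  record <- dplyr::bind_cols(
    patient_cols,
    tibble::tibble(
      ps_nawm = roi$ps_mean_nawm_x1e4, ps_wmh = roi$ps_mean_wmh_x1e4,
      vp_nawm = roi$vp_mean_nawm_x1e4, vp_wmh = roi$vp_mean_wmh_x1e4,
      icv_ml_imaging = vols$icv_ml, wmh_ml_imaging = vols$wmh_ml,
      hotspot_threshold = hs$threshold_value
    ),
    coloc, elig
  )
  list(maps = maps, masks = masks, hotspots = hs, classification = cls,
       regional_load = load, record = record,
       lesions = lesions, volumes = vols, roi = roi)
}

write_nifti_vol <- function(x, path, voxel_mm, gzip = TRUE) {
  if (gzip && !grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  img <- RNifti::asNifti(x * 1, pixdim = voxel_mm)
  RNifti::writeNifti(img, path)
  path
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes the configured stages in dependency order for each patient of a
#' synthetic cohort, writing per-patient NIfTI volumes and CSV tables plus
#' cohort-level summaries, and returns (and writes) a run manifest listing
#' every artifact with its MD5 content hash, per-stage counts and aggregated
#' warnings. Identical configuration and seed give byte-identical outputs.
#'
#' @param config Raw or validated configuration; see [validate_config()].
#' @param design Optional [cohort_design()]; defaults to a design matching
#'   the config's `n_patients`, `shape`, `noise_sd` and `seed`.
#' @return The manifest (list), invisibly; written as `manifest.json` in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = list(), design = NULL) {
  cfg <- validate_config(config)
  if (is.null(design)) {
    design <- cohort_design(n_patients = cfg$n_patients, shape = cfg$shape,
                            voxel_mm = cfg$voxel_mm, noise_sd = cfg$noise_sd,
                            seed = cfg$seed)
  }
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  warnings_log <- character()
  stage_counts <- list()
  note <- function(path) artifacts <<- c(artifacts, path)

  cohort <- sample_cohort(design, simulate_outcomes = FALSE)
  cov_path <- file.path(out_dir, "cohort_covariates.csv")
  readr::write_csv(cohort$covariates, cov_path)
  note(cov_path)
  vif <- generate_vif(times = design$dce_times)
  vif_path <- file.path(out_dir, "vif.csv")
  readr::write_csv(tibble::as_tibble(vif), vif_path)
  note(vif_path)
  stage_counts$synth <- nrow(cohort$covariates)

  run_analysis <- any(c("patlak", "masks", "hotspots", "colocalize",
                        "stats") %in% cfg$stages)
  records <- list()
  loads <- list()
  if (nrow(cohort$covariates) > 0) {
    for (i in seq_len(nrow(cohort$covariates))) {
      patient <- cohort$covariates[i, ]
      pdir <- file.path(out_dir, patient$id)
      dir.create(pdir, showWarnings = FALSE)
      bundle <- simulate_patient_imaging(patient, design, vif = vif)
      if ("synth" %in% cfg$stages) {
        note(write_nifti_vol(bundle$phantom$labels,
                             file.path(pdir, "labels.nii"),
                             design$voxel_mm, cfg$gzip))
        note(write_nifti_vol(bundle$phantom$atlas,
                             file.path(pdir, "atlas.nii"),
                             design$voxel_mm, cfg$gzip))
        note(write_nifti_vol(bundle$truth$ps_true,
                             file.path(pdir, "ps_true.nii"),
                             design$voxel_mm, cfg$gzip))
        note(write_nifti_vol(bundle$truth$vp_true,
                             file.path(pdir, "vp_true.nii"),
                             design$voxel_mm, cfg$gzip))
        note(write_nifti_vol(bundle$dce$conc, file.path(pdir, "dce.nii"),
                             design$voxel_mm, cfg$gzip))
        truth_manifest <- list(
          imaging_seed = patient$imaging_seed,
          noise_sd = bundle$dce$noise_sd,
          foci = dplyr::select(bundle$truth$focus_index, -"voxels"),
          lesions = dplyr::select(bundle$phantom$lesion_index,
                                  -"voxels", -"centre")
        )
        tm_path <- file.path(pdir, "truth.json")
        jsonlite::write_json(truth_manifest, tm_path, auto_unbox = TRUE,
                             digits = NA)
        note(tm_path)
      }
      if (!run_analysis) next
      res <- analyze_patient(bundle, cfg)
      if (res$maps$n_dropped > 0) {
        warnings_log <- c(warnings_log,
                          sprintf("%s: %d voxels dropped from Patlak fit",
                                  patient$id, res$maps$n_dropped))
      }
      if (res$hotspots$ties_at_threshold > 0) {
        warnings_log <- c(warnings_log,
                          sprintf("%s: %d ties at the decile threshold",
                                  patient$id, res$hotspots$ties_at_threshold))
      }
      if ("patlak" %in% cfg$stages) {
        ps_out <- res$maps$ps; ps_out[is.na(ps_out)] <- 0
        vp_out <- res$maps$vp; vp_out[is.na(vp_out)] <- 0
        note(write_nifti_vol(ps_out, file.path(pdir, "ps.nii"),
                             design$voxel_mm, cfg$gzip))
        note(write_nifti_vol(vp_out, file.path(pdir, "vp.nii"),
                             design$voxel_mm, cfg$gzip))
        note(write_nifti_vol(res$maps$fit_mask, file.path(pdir, "fit_mask.nii"),
                             design$voxel_mm, cfg$gzip))
      }
      if ("hotspots" %in% cfg$stages) {
        note(write_nifti_vol(res$hotspots$hotspot_labels,
                             file.path(pdir, "hotspot_labels.nii"),
                             design$voxel_mm, cfg$gzip))
        hp <- file.path(pdir, "hotspots.csv")
        readr::write_csv(tidy(res$hotspots), hp); note(hp)
      }
      if ("colocalize" %in% cfg$stages) {
        cp <- file.path(pdir, "colocalization.csv")
        readr::write_csv(
          dplyr::select(res$classification, -"lacune_ids", -"cmb_ids"), cp)
        note(cp)
      }
      records[[i]] <- res$record
      loads[[i]] <- dplyr::mutate(res$regional_load, id = patient$id)
    }
    if (!run_analysis) records <- list()
  }
  if (length(records)) {
    stage_counts$patlak <- length(records)
    record_tbl <- dplyr::bind_rows(records)
    rec_path <- file.path(out_dir, "patient_records.csv")
    readr::write_csv(record_tbl, rec_path); note(rec_path)
    load_path <- file.path(out_dir, "regional_loads.csv")
    readr::write_csv(dplyr::bind_rows(loads), load_path); note(load_path)

    if ("stats" %in% cfg$stages) {
      coloc <- summarize_colocalization(record_tbl)
      cs_path <- file.path(out_dir, "colocalization_summary.csv")
      readr::write_csv(coloc$patient_summary, cs_path); note(cs_path)
      ls_path <- file.path(out_dir, "lesion_summary.csv")
      readr::write_csv(coloc$lesion_summary, ls_path); note(ls_path)
      desc_vars <- c("age", "female", "hypertension", "n_lacunes", "n_cmb",
                     "fazekas_pvh", "fazekas_dwmh", "svd_score", "wmh_ml",
                     "ps_nawm", "ps_wmh", "vp_nawm", "vp_wmh")
      if (length(unique(record_tbl$svd_type)) == 2L) {
        tbl1 <- cohort_table(record_tbl, desc_vars, grouping = "svd_type")
        t1_path <- file.path(out_dir, "cohort_table.csv")
        readr::write_csv(tbl1, t1_path); note(t1_path)
      }
      stage_counts$stats <- nrow(coloc$patient_summary)
    }
  }

  cfg_path <- file.path(out_dir, "resolved_config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  note(cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("bbbhotspots")),
    seed = cfg$seed,
    stages = cfg$stages,
    stage_counts = stage_counts,
    warnings = warnings_log,
    artifacts = lapply(sort(artifacts), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
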