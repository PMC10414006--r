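# Two-arm synthetic cohort (sporadic SVD vs CADASIL) with arm-dependent
# covariate and lesion-count distributions and planted effect structure.
# Defaults emulate the published two-arm cohort profile: 69 patients (42
# sporadic, 27 CADASIL), CADASIL younger with fewer vascular risk factors but
# heavier lesion load, lower NAWM PS/vP, and lower WMH CVR. Planted effects
# act on standardized covariates through logistic (presence) and log-linear
# (count) links, and in imaging mode are realised as planted high-PS foci.

#' Design of a synthetic two-arm SVD cohort
#'
#' All distributions are configurable; the defaults are the package's
#' emulation of a sporadic-SVD/CADASIL cohort profile. `effects` gives the
#' planted associations on standardized covariates: each element is a named
#' list with an `intercept` (log-odds of outcome presence) and per-covariate
#' log-odds slopes, plus `count_intercept`/count slopes on the log scale for
#' the number of colocalized hotspots.
#'
#' @param n_patients Cohort size (>= 0).
#' @param prop_cadasil Proportion in the CADASIL arm, in `[0, 1]`.
#' @param age_mean,age_sd Named numeric `c(sporadic = , cadasil = )`.
#' @param risk_prevalence Named list of per-arm prevalences for the binary
#'   risk factors.
#' @param lacune_mu,lacune_size,cmb_mu,cmb_size Negative-binomial lesion-count
#'   parameters per arm.
#' @param wmh_meanlog,wmh_sdlog Log-normal WMH volume (mL) parameters per arm.
#' @param roi_params Per-arm normal parameters for the displayed-scale ROI
#'   metrics (`ps_nawm`, `ps_wmh`, `vp_nawm`, `vp_wmh` x 1e4; `cvr_nawm`,
#'   `cvr_wmh` x 1e2).
#' @param cvr_missing_prob Probability a patient lacks CVR data.
#' @param effects Planted effect structure (see Details in the vignette).
#' @param standardization Named list of `c(mean, sd)` used to standardize
#'   covariates inside the effect linear predictors (fixed constants, not
#'   sample estimates, so planted log-odds are exact).
#' @param shape,voxel_mm,noise_sd,dce_times Imaging-mode phantom and DCE
#'   parameters.
#' @param seed Integer seed.
#' @return A list of class `bbb_cohort_design`.
#' @export
cohort_design <- function(
    n_patients = 69L,
    prop_cadasil = 27 / 69,
    age_mean = c(sporadic = 63.9, cadasil = 52.9),
    age_sd = c(sporadic = 10.7, cadasil = 11.4),
    risk_prevalence = list(
      female = c(sporadic = 0.429, cadasil = 0.482),
      hypertension = c(sporadic = 0.810, cadasil = 0.370),
      diabetes = c(sporadic = 0.214, cadasil = 0.037),
      hyperlipidaemia = c(sporadic = 0.738, cadasil = 0.370),
      ihd = c(sporadic = 0.167, cadasil = 0.037),
      smoking = c(sporadic = 0.500, cadasil = 0.519),
      alcohol = c(sporadic = 0.691, cadasil = 0.741),
      antiplatelet = c(sporadic = 0.952, cadasil = 0.593)
    ),
    lacune_mu = c(sporadic = 2.5, cadasil = 6),
    lacune_size = c(sporadic = 1, cadasil = 1.5),
    cmb_mu = c(sporadic = 1.2, cadasil = 3.5),
    cmb_size = c(sporadic = 0.4, cadasil = 0.5),
    wmh_meanlog = c(sporadic = log(8.2), cadasil = log(76.5)),
    wmh_sdlog = c(sporadic = 0.85, cadasil = 0.9),
    roi_params = list(
      ps_nawm = list(sporadic = c(0.93, 0.94), cadasil = c(-0.33, 0.99)),
      ps_wmh = list(sporadic = c(1.09, 1.20), cadasil = c(0.65, 1.11)),
      vp_nawm = list(sporadic = c(47.06, 13.98), cadasil = c(32.74, 11.26)),
      vp_wmh = list(sporadic = c(72.04, 23.46), cadasil = c(47.33, 27.23)),
      cvr_nawm = list(sporadic = c(3.59, 3.19), cadasil = c(3.55, 3.58)),
      cvr_wmh = list(sporadic = c(7.52, 6.25), cadasil = c(3.64, 6.47))
    ),
    cvr_missing_prob = 6 / 69,
    effects = list(
      lacune_edge = list(intercept = 0.6, cvr_wmh = -0.8,
                         count_intercept = log(1.5), count_cvr_wmh = -0.4),
      within_wmh = list(intercept = -0.4, log10_wmh_norm = 1.2,
                        count_intercept = log(1.2),
                        count_log10_wmh_norm = 0.6),
      wmh_edge = list(intercept = 0.3, log10_wmh_norm = 1.0,
                      count_intercept = log(1.5),
                      count_log10_wmh_norm = 0.5),
      cmb_edge = list(intercept = -0.6, count_intercept = log(0.8))
    ),
    standardization = list(cvr_wmh = c(5.83, 6.59),
                           log10_wmh_norm = c(-1.85, 0.6)),
    shape = c(48L, 48L, 48L),
    voxel_mm = c(2, 2, 2),
    noise_sd = 0.002,
    dce_times = seq(0, 1230, by = 24),
    seed = 1L) {
  stopifnot_scalar_number(n_patients, "n_patients", lower = 0)
  stopifnot_scalar_number(prop_cadasil, "prop_cadasil", 0, 1)
  for (p in risk_prevalence) {
    if (any(p < 0 | p > 1)) stop("prevalences must be in [0, 1]", call. = FALSE)
  }
  stopifnot_scalar_number(cvr_missing_prob, "cvr_missing_prob", 0, 1)
  structure(
    list(n_patients = as.integer(n_patients), prop_cadasil = prop_cadasil,
         age_mean = age_mean, age_sd = age_sd,
         risk_prevalence = risk_prevalence,
         lacune_mu = lacune_mu, lacune_size = lacune_size,
         cmb_mu = cmb_mu, cmb_size = cmb_size,
         wmh_meanlog = wmh_meanlog, wmh_sdlog = wmh_sdlog,
         roi_params = roi_params, cvr_missing_prob = cvr_missing_prob,
         effects = effects, standardization = standardization,
         shape = shape, voxel_mm = voxel_mm, noise_sd = noise_sd,
         dce_times = dce_times, seed = as.integer(seed)),
    class = "bbb_cohort_design"
  )
}

standardize_covariate <- function(x, name, standardization) {
  s <- standardization[[name]]
  if (is.null(s)) c(scale(x)) else (x - s[1L]) / s[2L]
}

effect_linpred <- function(effects_one, covariates, standardization,
                           prefix = "") {
  nm <- names(effects_one)
  if (prefix == "") {
    terms <- nm[!startsWith(nm, "count_") & nm != "intercept"]
    eta <- rep(effects_one$intercept %||% 0, nrow(covariates))
  } else {
    terms <- nm[startsWith(nm, "count_") & nm != "count_intercept"]
    eta <- rep(effects_one$count_intercept %||% 0, nrow(covariates))
  }
  for (tm in terms) {
    cov_name <- sub(paste0("^", prefix), "", tm)
    if (is.null(standardization[[cov_name]]) && nrow(covariates) < 2L) {
      stop(sprintf("no standardization constants for effect covariate '%s'",
                   cov_name), call. = FALSE)
    }
    z <- standardize_covariate(covariates[[cov_name]], cov_name, standardization)
    z[is.na(z)] <- 0  # missing covariates contribute no planted effect
    eta <- eta + effects_one[[tm]] * z
  }
  eta
}

# map WMH volume monotonically to Fazekas grades
fazekas_from_wmh <- function(wmh_ml) {
  list(dwmh = findInterval(wmh_ml, c(2, 20, 60)),
       pvh = findInterval(wmh_ml, c(1, 10, 40)))
}

#' Sample a synthetic SVD cohort
#'
#' Draws per-patient covariates, lesion counts, volumes, grades, ROI metrics
#' and (when `simulate_outcomes = TRUE`) the colocalization outcomes implied
#' by the design's planted effects: presence per category from a logistic
#' model and counts from a Poisson log-linear model on standardized
#' covariates, applied only to patients eligible for the category's subgroup.
#' Every patient also receives an imaging seed so the voxel-level bundle can
#' be materialized later with [simulate_patient_imaging()].
#'
#' @param design A [cohort_design()].
#' @param simulate_outcomes Draw tabular outcome columns from the planted
#'   effect structure (default `TRUE`).
#' @return Object of class `bbb_cohort`: list with `covariates` (tibble, one
#'   row per patient) and the `design`.
#' @export
#' @examples
#' coh <- sample_cohort(cohort_design(n_patients = 10, seed = 7))
#' dplyr::count(coh$covariates, svd_type)
sample_cohort <- function(design, simulate_outcomes = TRUE) {
  stopifnot(inherits(design, "bbb_cohort_design"))
  n <- design$n_patients
  if (n == 0L) {
    return(structure(list(covariates = tibble::tibble(), design = design),
                     class = "bbb_cohort"))
  }
  cov <- with_seed(design$seed, {
    arm <- ifelse(stats::runif(n) < design$prop_cadasil, "cadasil", "sporadic")
    draw_norm <- function(mean_by_arm, sd_by_arm) {
      stats::rnorm(n, mean_by_arm[arm], sd_by_arm[arm])
    }
    draw_bin <- function(prev) stats::runif(n) < prev[arm]
    draw_nbinom <- function(mu, size) {
      stats::rnbinom(n, mu = mu[arm], size = size[arm])
    }
    roi <- lapply(design$roi_params, function(p) {
      m <- vapply(p, `[`, numeric(1), 1L)[arm]
      s <- vapply(p, `[`, numeric(1), 2L)[arm]
      stats::rnorm(n, m, s)
    })
    wmh_ml <- stats::rlnorm(n, design$wmh_meanlog[arm], design$wmh_sdlog[arm])
    icv_ml <- stats::rnorm(n, 1450, 130)
    fz <- fazekas_from_wmh(wmh_ml)
    pvs_probs <- list(
      sporadic = c(0.25, 0.35, 0.30, 0.10),
      cadasil = c(0.08, 0.22, 0.40, 0.30)
    )
    draw_pvs <- function() {
      vapply(arm, function(a) sample.int(4L, 1L, prob = pvs_probs[[a]]),
             integer(1))
    }
    cvr_missing <- stats::runif(n) < design$cvr_missing_prob

    out <- tibble::tibble(
      id = sprintf("P%03d", seq_len(n)),
      svd_type = arm,
      age = draw_norm(design$age_mean, design$age_sd),
      female = draw_bin(design$risk_prevalence$female),
      hypertension = draw_bin(design$risk_prevalence$hypertension),
      diabetes = draw_bin(design$risk_prevalence$diabetes),
      hyperlipidaemia = draw_bin(design$risk_prevalence$hyperlipidaemia),
      ihd = draw_bin(design$risk_prevalence$ihd),
      smoking = draw_bin(design$risk_prevalence$smoking),
      alcohol = draw_bin(design$risk_prevalence$alcohol),
      antiplatelet = draw_bin(design$risk_prevalence$antiplatelet),
      n_lacunes = draw_nbinom(design$lacune_mu, design$lacune_size),
      n_cmb = draw_nbinom(design$cmb_mu, design$cmb_size),
      wmh_ml = wmh_ml,
      icv_ml = icv_ml,
      wmh_normalized = wmh_ml / icv_ml,
      log10_wmh_norm = log10(wmh_ml / icv_ml),
      fazekas_dwmh = fz$dwmh,
      fazekas_pvh = fz$pvh,
      pvs_bg = draw_pvs(),
      pvs_cso = draw_pvs(),
      ps_nawm = roi$ps_nawm, ps_wmh = roi$ps_wmh,
      vp_nawm = roi$vp_nawm, vp_wmh = roi$vp_wmh,
      cvr_nawm = ifelse(cvr_missing, NA_real_, roi$cvr_nawm),
      cvr_wmh = ifelse(cvr_missing, NA_real_, roi$cvr_wmh),
      imaging_seed = sample.int(.Machine$integer.max %/% 2L, n)
    )
    out$svd_score <- total_svd_score(out$n_lacunes, out$n_cmb,
                                     out$fazekas_dwmh, out$fazekas_pvh,
                                     out$pvs_bg)
    out$lacune_subgroup <- out$n_lacunes >= 1L
    out$cmb_subgroup <- out$n_cmb >= 1L
    # tabular stand-in for the voxel-level minimal-NAWM exclusion: assume
    # roughly 450 mL of analysis WM
    out$nawm_fraction <- pmax(0, 1 - out$wmh_ml / 450)
    out$wmh_subgroup <- (out$fazekas_dwmh > 0 | out$fazekas_pvh > 1) &
      out$nawm_fraction >= 0.10

    if (simulate_outcomes) {
      subgroup_of <- c(lacune_edge = "lacune_subgroup",
                       within_wmh = "wmh_subgroup",
                       wmh_edge = "wmh_subgroup",
                       cmb_edge = "cmb_subgroup")
      arm_mu <- ifelse(arm == "cadasil", 86.0, 58.2)
      arm_sd <- ifelse(arm == "cadasil", 29.7, 17.6)
      out$n_hotspots <- pmax(0L, as.integer(round(stats::rnorm(n, arm_mu, arm_sd))))
      for (cat in names(subgroup_of)) {
        eff <- design$effects[[cat]]
        if (is.null(eff)) next
        eta <- effect_linpred(eff, out, design$standardization)
        eta_cnt <- effect_linpred(eff, out, design$standardization,
                                  prefix = "count_")
        elig <- out[[subgroup_of[[cat]]]]
        presence <- ifelse(elig, stats::rbinom(n, 1L, stats::plogis(eta)),
                           NA_integer_)
        count <- ifelse(presence %in% 1L,
                        1L + stats::rpois(n, exp(eta_cnt)), 0L)
        count[is.na(presence)] <- NA_integer_
        out[[paste0(cat, "_presence")]] <- presence
        out[[paste0("n_", cat)]] <- count
      }
    }
    out
  })
  structure(list(covariates = cov, design = design), class = "bbb_cohort")
}

#' @export
print.bbb_cohort <- function(x, ...) {
  n <- nrow(x$covariates)
  cat(sprintf("<bbb_cohort> %d patients (%d CADASIL), seed %d\n", n,
              if (n) sum(x$covariates$svd_type == "cadasil") else 0L,
              x$design$seed))
  invisible(x)
}

#' @export
tidy.bbb_cohort <- function(x, ...) x$covariates

#' Materialize the imaging bundle for one synthetic patient
#'
#' Builds the phantom, ground-truth PS/vP maps with planted foci and the
#' noisy DCE series for one cohort row, reproducibly from the row's
#' `imaging_seed`. Focus counts per attachment follow the design's planted
#' count models (e.g. lower WMH CVR drives more lacune-rim foci), on top of
#' a baseline of random-WM foci.
#'
#' @param patient One row of a [sample_cohort()] covariate tibble.
#' @param design The matching [cohort_design()].
#' @param vif A shared [generate_vif()] object (defaults to the design grid).
#' @param focus_override Optional [focus_spec()] replacing the effect-driven
#'   focus placement (used for planted-structure experiments).
#' @return List with `phantom`, `truth`, `dce`, `vif` and the `patient` row.
#' @export
simulate_patient_imaging <- function(patient, design, vif = NULL,
                                     focus_override = NULL) {
  stopifnot(inherits(design, "bbb_cohort_design"))
  if (is.null(vif)) vif <- generate_vif(times = design$dce_times)
  seed <- patient$imaging_seed
  n_lac <- min(patient$n_lacunes, 4L)
  n_cmb <- min(patient$n_cmb, 2L)
  n_wmh <- 1L + patient$fazekas_dwmh + (patient$fazekas_pvh >= 2L)
  spec <- lesion_spec(n_lacunes = n_lac, n_wmh_blobs = n_wmh, n_cmb = n_cmb)
  phantom <- generate_phantom(shape = design$shape, voxel_mm = design$voxel_mm,
                              lesion_spec = spec, seed = seed)
  fspec <- if (!is.null(focus_override)) focus_override else {
    with_seed(seed + 1L, {
      draw_count <- function(cat) {
        eff <- design$effects[[cat]]
        if (is.null(eff)) return(0L)
        eta <- effect_linpred(eff, patient, design$standardization,
                              prefix = "count_")
        stats::rpois(1L, exp(eta))
      }
      focus_spec(
        at_lacune_rim = if (n_lac > 0L) draw_count("lacune_edge") else 0L,
        inside_wmh = if (n_wmh > 0L) draw_count("within_wmh") else 0L,
        at_wmh_rim = if (n_wmh > 0L) draw_count("wmh_edge") else 0L,
        at_cmb_rim = if (n_cmb > 0L) draw_count("cmb_edge") else 0L,
        random_wm = 4L + stats::rpois(1L, 4)
      )
    })
  }
  truth <- generate_truth_maps(phantom, focus_spec = fspec, seed = seed + 2L)
  dce <- synthesize_dce(truth, vif, noise_sd = design$noise_sd,
                        seed = seed + 3L)
  list(phantom = phantom, truth = truth, dce = dce, vif = vif,
       patient = patient)
}
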