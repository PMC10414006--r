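# Spatial relation of hotspots to SVD lesions. "Contact" with a focal lesion
# (lacune, microbleed) means overlap with the lesion or its one-voxel
# 26-neighbourhood outer band; "within WMH" requires every hotspot voxel
# inside the WMH mask, and "at WMH edge" is any contact that is not full
# containment, so the two WMH categories are mutually exclusive per hotspot.
# Flags are independent across lesion classes: a hotspot can be at a lacune
# edge and within a WMH at the same time.

#' Bundle lesion masks with their contact bands
#'
#' Builds per-lesion masks and one-voxel outer boundary bands for lacunes and
#' microbleeds, plus the WMH mask and its band, from a phantom's lesion
#' inventory (or explicit arguments).
#'
#' @param phantom A [generate_phantom()] result, or `NULL` when masks are
#'   given explicitly.
#' @param lacunes,cmbs Optional list of flat-index vectors, one per lesion.
#' @param wmh Optional logical 3D WMH mask.
#' @param dim3 Volume dimensions (required when `phantom` is `NULL`).
#' @param band_radius WMH contact band thickness in voxels (default 1).
#' @param contact_radius Contact band thickness for focal lesions (lacunes,
#'   microbleeds). Defaults to `band_radius + 1`: hotspots live inside the
#'   one-voxel-eroded WM mask, which by construction excludes the voxel shell
#'   immediately adjacent to a carved-out cavity, so direct contact across
#'   the eroded margin spans two voxels.
#' @param connectivity Dilation neighbourhood for the bands (default 26).
#' @return Object of class `bbb_lesions`: list with `lacunes`, `lacune_bands`,
#'   `cmbs`, `cmb_bands` (lists of flat-index vectors), `wmh`, `wmh_band`
#'   (logical arrays), `dim`.
#' @export
lesion_set <- function(phantom = NULL, lacunes = NULL, cmbs = NULL, wmh = NULL,
                       dim3 = NULL, band_radius = 1L,
                       contact_radius = band_radius + 1L,
                       connectivity = 26L) {
  if (!is.null(phantom)) {
    stopifnot(inherits(phantom, "bbb_phantom"))
    dim3 <- phantom$shape
    li <- phantom$lesion_index
    lacunes <- li$voxels[li$class == "lacune"]
    cmbs <- li$voxels[li$class == "cmb"]
    wmh <- phantom$labels == label_codes()[["wmh"]]
  }
  if (is.null(dim3)) stop("`dim3` is required without a phantom", call. = FALSE)
  if (is.null(wmh)) wmh <- array(FALSE, dim = dim3)
  band_of <- function(vox) {
    m <- array(FALSE, dim = dim3)
    m[vox] <- TRUE
    which(outer_band(m, radius = contact_radius, connectivity = connectivity))
  }
  structure(
    list(lacunes = lacunes %||% list(),
         lacune_bands = lapply(lacunes %||% list(), band_of),
         cmbs = cmbs %||% list(),
         cmb_bands = lapply(cmbs %||% list(), band_of),
         wmh = wmh,
         wmh_band = outer_band(wmh, radius = band_radius,
                               connectivity = connectivity),
         dim = dim3, band_radius = band_radius,
         contact_radius = contact_radius),
    class = "bbb_lesions"
  )
}

#' Classify hotspots against SVD lesions
#'
#' Per hotspot: `at_lacune_edge` if it overlaps any lacune or its contact
#' band; `at_cmb_edge` likewise for microbleeds; `within_wmh` if every voxel
#' is a WMH voxel; `at_wmh_edge` if it is not within WMH but touches the WMH
#' mask or its band. Touched lesion ids are recorded for per-lesion summaries.
#'
#' @param hotspots A `bbb_hotspots` object or hotspot tibble with a `voxels`
#'   list-column.
#' @param lesions A [lesion_set()] result.
#' @return A tibble, one row per hotspot: `hotspot_id`, the four logical
#'   flags, and list-columns `lacune_ids`, `cmb_ids` of touched lesion
#'   indices.
#' @export
classify_hotspots <- function(hotspots, lesions) {
  stopifnot(inherits(lesions, "bbb_lesions"))
  if (inherits(hotspots, "bbb_hotspots")) hotspots <- hotspots$hotspots
  if (nrow(hotspots) == 0L) {
    return(tibble::tibble(hotspot_id = integer(), at_lacune_edge = logical(),
                          within_wmh = logical(), at_wmh_edge = logical(),
                          at_cmb_edge = logical(), lacune_ids = list(),
                          cmb_ids = list()))
  }
  wmh_or_band <- lesions$wmh | lesions$wmh_band
  touch_set <- function(vox, interiors, bands) {
    which(vapply(seq_along(interiors), function(i) {
      any(vox %in% interiors[[i]]) || any(vox %in% bands[[i]])
    }, logical(1)))
  }
  purrr::map_dfr(seq_len(nrow(hotspots)), function(i) {
    vox <- hotspots$voxels[[i]]
    lac <- touch_set(vox, lesions$lacunes, lesions$lacune_bands)
    cmb <- touch_set(vox, lesions$cmbs, lesions$cmb_bands)
    within <- all(lesions$wmh[vox])
    tibble::tibble(
      hotspot_id = hotspots$hotspot_id[i],
      at_lacune_edge = length(lac) > 0L,
      within_wmh = within,
      at_wmh_edge = !within && any(wmh_or_band[vox]),
      at_cmb_edge = length(cmb) > 0L,
      lacune_ids = list(lac),
      cmb_ids = list(cmb)
    )
  })
}

#' Subgroup eligibility for the colocalization analyses
#'
#' A patient enters the lacune (or microbleed) subgroup when at least one
#' lacune (microbleed) lies in the deep white matter, operationalized as the
#' lesion centroid falling inside the one-voxel erosion of the analysis white
#' matter with lesion interiors filled in (the lesions themselves are carved
#' out of the WM mask, so the unfilled mask could never contain their
#' centroids). The WMH subgroup requires more than minimal WMH load (deep WMH
#' Fazekas > 0 or periventricular Fazekas > 1) and excludes patients with
#' large confluent WMH leaving minimal NAWM (NAWM below
#' `nawm_fraction_threshold` of the analysis WM).
#'
#' @param masks A [build_analysis_masks()] result.
#' @param lesions A [lesion_set()] result.
#' @param fazekas_dwmh,fazekas_pvh Fazekas grades 0-3.
#' @param nawm_fraction_threshold Minimum NAWM fraction of WM (default 0.10).
#' @return One-row tibble of logicals: `lacune_subgroup`, `wmh_subgroup`,
#'   `cmb_subgroup`, plus `nawm_fraction`.
#' @export
subgroup_eligibility <- function(masks, lesions, fazekas_dwmh, fazekas_pvh,
                                 nawm_fraction_threshold = 0.10) {
  stopifnot(inherits(masks, "bbb_masks"), inherits(lesions, "bbb_lesions"))
  for (g in c(fazekas_dwmh, fazekas_pvh)) {
    if (!g %in% 0:3) stop("Fazekas grades must be integers 0-3", call. = FALSE)
  }
  dim3 <- dim(masks$wm_all)
  filled <- masks$wm_all
  for (vox in c(lesions$lacunes, lesions$cmbs)) filled[vox] <- TRUE
  deep_wm <- erode_one_voxel(filled)
  centroid_in_deep_wm <- function(vox) {
    cc <- round(colMeans(flat_to_coord(vox, dim3)))
    deep_wm[cc[1L], cc[2L], cc[3L]]
  }
  nawm_fraction <- sum(masks$nawm) / sum(masks$wm_all)
  tibble::tibble(
    lacune_subgroup = any(vapply(lesions$lacunes, centroid_in_deep_wm, logical(1))),
    wmh_subgroup = (fazekas_dwmh > 0 || fazekas_pvh > 1) &&
      nawm_fraction >= nawm_fraction_threshold,
    cmb_subgroup = any(vapply(lesions$cmbs, centroid_in_deep_wm, logical(1))),
    nawm_fraction = nawm_fraction
  )
}

#' Per-patient colocalization summary
#'
#' Collapses a per-hotspot classification to one patient row: presence (0/1)
#' and hotspot count per category, and the number of lacunes/microbleeds
#' touched by at least one hotspot.
#'
#' @param classification A [classify_hotspots()] tibble.
#' @param lesions The matching [lesion_set()] (for lesion totals).
#' @return One-row tibble of counts and presence flags.
#' @export
colocalization_summary <- function(classification, lesions) {
  lac_touched <- unique(unlist(classification$lacune_ids))
  cmb_touched <- unique(unlist(classification$cmb_ids))
  tibble::tibble(
    n_hotspots = nrow(classification),
    n_lacune_edge = sum(classification$at_lacune_edge),
    n_within_wmh = sum(classification$within_wmh),
    n_wmh_edge = sum(classification$at_wmh_edge),
    n_cmb_edge = sum(classification$at_cmb_edge),
    lacune_edge_presence = as.integer(any(classification$at_lacune_edge)),
    within_wmh_presence = as.integer(any(classification$within_wmh)),
    wmh_edge_presence = as.integer(any(classification$at_wmh_edge)),
    cmb_edge_presence = as.integer(any(classification$at_cmb_edge)),
    n_lacunes_total = length(lesions$lacunes),
    n_lacunes_with_hotspot = length(lac_touched),
    n_cmbs_total = length(lesions$cmbs),
    n_cmbs_with_hotspot = length(cmb_touched)
  )
}

#' Cohort-level colocalization summary
#'
#' For each colocalization category, the number and fraction of eligible
#' patients with at least one flagged hotspot, and the fraction of evaluated
#' lesions (lacunes, microbleeds) touched by a hotspot.
#'
#' @param patients A tibble with one row per patient containing the
#'   [colocalization_summary()] columns plus the `*_subgroup` eligibility
#'   flags from [subgroup_eligibility()].
#' @return A list with `patient_summary` (per category: `n_eligible`,
#'   `n_with_hotspot`, `fraction`) and `lesion_summary` (per lesion class:
#'   totals and fraction with a hotspot). When a category has no eligible
#'   patients its row carries `n_eligible = 0` and `NA` fractions, and the
#'   list gains a `no_eligible` character vector naming those categories.
#' @export
summarize_colocalization <- function(patients) {
  cats <- tibble::tibble(
    category = c("lacune_edge", "within_wmh", "wmh_edge", "cmb_edge"),
    subgroup = c("lacune_subgroup", "wmh_subgroup", "wmh_subgroup",
                 "cmb_subgroup"),
    presence = c("lacune_edge_presence", "within_wmh_presence",
                 "wmh_edge_presence", "cmb_edge_presence")
  )
  patient_summary <- purrr::pmap_dfr(cats, function(category, subgroup, presence) {
    elig <- patients[patients[[subgroup]], , drop = FALSE]
    n_elig <- nrow(elig)
    n_with <- if (n_elig) sum(elig[[presence]] > 0L) else 0L
    tibble::tibble(category = category, n_eligible = n_elig,
                   n_with_hotspot = n_with,
                   fraction = if (n_elig) n_with / n_elig else NA_real_)
  })
  lesion_rows <- list(
    lacune = patients[patients$lacune_subgroup, , drop = FALSE],
    cmb = patients[patients$cmb_subgroup, , drop = FALSE]
  )
  lesion_summary <- purrr::imap_dfr(lesion_rows, function(df, cls) {
    tot <- sum(df[[paste0("n_", cls, "s_total")]])
    hit <- sum(df[[paste0("n_", cls, "s_with_hotspot")]])
    tibble::tibble(lesion_class = cls, n_lesions = tot,
                   n_with_hotspot = hit,
                   fraction = if (tot > 0L) hit / tot else NA_real_)
  })
  out <- list(patient_summary = patient_summary, lesion_summary = lesion_summary)
  no_elig <- patient_summary$category[patient_summary$n_eligible == 0L]
  if (length(no_elig)) out$no_eligible <- no_elig
  out
}
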