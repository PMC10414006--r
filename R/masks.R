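#' Build the eroded white-matter analysis masks
#'
#' The permeability analysis is restricted to the white matter excluding the
#' brainstem, after a one-voxel-kernel erosion of the combined WM mask.
#' Erosion is applied to WM plus WMH so that hotspots occurring inside WMH
#' stay within the analysis mask; normal-appearing white matter (NAWM) is the
#' combined mask minus WMH.
#'
#' @param labels Integer 3D label volume using [label_codes()].
#' @param kernel Erosion structuring element, `"cube"` (3x3x3, default) or
#'   `"cross"` (6-neighbourhood); passed to [erode_one_voxel()].
#' @param atlas Optional integer 3D region atlas (see [atlas_regions()]); only
#'   needed when `include_cerebellum = FALSE`.
#' @param include_cerebellum Keep cerebellar white matter in the analysis mask
#'   (default `TRUE`); excluding it requires `atlas`.
#' @return Object of class `bbb_masks`: list of logical 3D arrays `wm_all`
#'   (NAWM plus WMH, brainstem excluded), `wm_eroded`, `nawm`, `wmh`.
#' @export
#' @examples
#' ph <- generate_phantom(shape = c(36, 36, 36))
#' m <- build_analysis_masks(ph$labels)
#' c(all = sum(m$wm_all), eroded = sum(m$wm_eroded))
build_analysis_masks <- function(labels, kernel = c("cube", "cross"),
                                 atlas = NULL, include_cerebellum = TRUE) {
  kernel <- match.arg(kernel)
  codes <- label_codes()
  wmh <- labels == codes[["wmh"]]
  wm_all <- (labels == codes[["wm"]] | wmh) & labels != codes[["brainstem"]]
  if (!include_cerebellum) {
    if (is.null(atlas)) {
      stop("excluding cerebellar white matter requires the region `atlas`",
           call. = FALSE)
    }
    wm_all <- wm_all & (atlas %/% 10L) != 1L
  }
  if (!any(wm_all)) stop("label volume contains no white matter", call. = FALSE)
  structure(
    list(wm_all = wm_all,
         wm_eroded = erode_one_voxel(wm_all, kernel = kernel),
         nawm = wm_all & !wmh,
         wmh = wmh & wm_all),
    class = "bbb_masks"
  )
}

#' @export
print.bbb_masks <- function(x, ...) {
  cat(sprintf("<bbb_masks> wm_all %d, wm_eroded %d, nawm %d, wmh %d voxels\n",
              sum(x$wm_all), sum(x$wm_eroded), sum(x$nawm), sum(x$wmh)))
  invisible(x)
}

#' Intracranial and WMH volume metrics
#'
#' Volumes in mL from voxel counts times voxel volume. The intracranial
#' volume (ICV) counts every non-background label including CSF; WMH volume
#' is normalized to ICV to limit inter-individual variability, and the
#' normalized volume is log10-transformed for use in regression models.
#'
#' @param labels Integer 3D label volume using [label_codes()].
#' @param voxel_mm Per-axis voxel size in mm.
#' @param log10_transform Compute `log10_wmh_normalized` (default `TRUE`);
#'   requesting it with zero WMH volume is an error.
#' @return One-row tibble: `icv_ml`, `wmh_ml`, `wmh_normalized`,
#'   `log10_wmh_normalized` (`NA` if not requested).
#' @export
#' @examples
#' ph <- generate_phantom(shape = c(36, 36, 36))
#' volume_metrics(ph$labels, ph$voxel_mm)
volume_metrics <- function(labels, voxel_mm, log10_transform = TRUE) {
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (any(voxel_mm <= 0)) stop("`voxel_mm` must be > 0", call. = FALSE)
  codes <- label_codes()
  vox_ml <- prod(voxel_mm) / 1000
  icv_ml <- sum(labels != codes[["background"]]) * vox_ml
  wmh_ml <- sum(labels == codes[["wmh"]]) * vox_ml
  if (icv_ml <= 0) stop("label volume contains no intracranial voxels", call. = FALSE)
  wmh_normalized <- wmh_ml / icv_ml
  log10_wmh <- NA_real_
  if (log10_transform) {
    if (wmh_ml <= 0) {
      stop("log10 of normalized WMH volume is undefined: WMH volume is zero",
           call. = FALSE)
    }
    log10_wmh <- log10(wmh_normalized)
  }
  tibble::tibble(icv_ml = icv_ml, wmh_ml = wmh_ml,
                 wmh_normalized = wmh_normalized,
                 log10_wmh_normalized = log10_wmh)
}
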