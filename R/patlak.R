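# Patlak graphical model: tissue concentration regressed, without intercept,
# on the two-column design [C_p(t), integral of C_p]. The slope on the
# integral is PS (1/min), the coefficient on C_p is the plasma volume
# fraction vP. No backflux term and no clamping: negative PS estimates are a
# real outcome of the linear fit under noise and are preserved.

patlak_design <- function(vif, frame_window = NULL) {
  cumint <- cumulative_vif_integral(vif)
  if (is.null(frame_window)) {
    # all post-arrival frames; pre-arrival rows are all-zero and carry no
    # information either way
    frame_window <- which(vif$times >= vif$arrival_time)
  }
  frame_window <- as.integer(frame_window)
  if (length(frame_window) < 3L) {
    stop("the Patlak fit needs at least 3 frames in the window", call. = FALSE)
  }
  if (any(frame_window < 1L) || any(frame_window > length(vif$times))) {
    stop("`frame_window` indexes outside the time axis", call. = FALSE)
  }
  X <- cbind(cp = vif$cp[frame_window], cumint = cumint[frame_window])
  if (all(X[, "cp"] == 0)) {
    stop("degenerate VIF: cp is zero throughout the fit window", call. = FALSE)
  }
  list(X = X, frame_window = frame_window)
}

#' Fit the Patlak model at a single voxel
#'
#' Ordinary least squares of the tissue concentration curve on
#' `[cp(t), integral cp]` with no intercept. Negative estimates are returned
#' unmodified.
#'
#' @param ct_curve Tissue concentration (mM), one value per time point of the
#'   VIF time axis.
#' @param vif A [generate_vif()]-style object.
#' @param frame_window Optional integer frame indices to fit over; default is
#'   all post-arrival frames.
#' @return Named numeric `c(ps = , vp = )`, PS in 1/min, vP a fraction.
#' @export
#' @examples
#' vif <- generate_vif(times = seq(0, 600, 30))
#' ct <- 0.01 * vif$cp + 2e-4 * cumulative_vif_integral(vif)
#' fit_patlak_voxel(ct, vif)
fit_patlak_voxel <- function(ct_curve, vif, frame_window = NULL) {
  d <- patlak_design(vif, frame_window)
  y <- ct_curve[d$frame_window]
  if (length(y) != nrow(d$X)) {
    stop("`ct_curve` length must match the VIF time axis", call. = FALSE)
  }
  xtx <- crossprod(d$X)
  if (rcond(xtx) < .Machine$double.eps) {
    stop("singular Patlak design: cp and its integral are collinear in the window",
         call. = FALSE)
  }
  beta <- solve(xtx, crossprod(d$X, y))
  c(ps = beta[2L], vp = beta[1L])  # design columns are [cp, cumint]
}

#' Map PS and vP voxelwise over an analysis mask
#'
#' Applies the Patlak fit at every voxel of `analysis_mask`. All voxels share
#' the same design matrix, so the map is computed by one normal-equations
#' solve. Voxels with non-finite concentration values are excluded from
#' `fit_mask` and counted in the QC attributes rather than imputed.
#'
#' @param dce A [synthesize_dce()]-style object (list with `times` and 4D
#'   `conc`).
#' @param vif The vascular input function, same time axis as `dce`.
#' @param analysis_mask Logical 3D array of voxels to fit (e.g. eroded WM).
#' @param frame_window Optional frame indices; default all post-arrival frames.
#' @return Object of class `bbb_permeability`: list with `ps`, `vp` (3D arrays,
#'   `NA` off the fit mask), `fit_mask`, `n_frames_used` and `n_dropped`
#'   (voxels excluded for non-finite data).
#' @export
map_patlak <- function(dce, vif, analysis_mask, frame_window = NULL) {
  check_mask3d(analysis_mask)
  if (!isTRUE(all.equal(dce$times, vif$times))) {
    stop("DCE and VIF time axes differ", call. = FALSE)
  }
  if (!any(analysis_mask)) stop("empty analysis mask", call. = FALSE)
  shape <- dim(dce$conc)[1:3]
  if (!all(dim(analysis_mask) == shape)) {
    stop("analysis mask dimensions do not match the DCE volume", call. = FALSE)
  }
  d <- patlak_design(vif, frame_window)
  idx <- which(analysis_mask)
  nvox <- prod(shape)
  conc <- matrix(dce$conc, nrow = nvox)[idx, d$frame_window, drop = FALSE]

  finite <- rowSums(!is.finite(conc)) == 0L
  n_dropped <- sum(!finite)
  fit_idx <- idx[finite]

  xtx <- crossprod(d$X)
  if (rcond(xtx) < .Machine$double.eps) {
    stop("singular Patlak design: cp and its integral are collinear in the window",
         call. = FALSE)
  }
  beta <- solve(xtx, crossprod(d$X, t(conc[finite, , drop = FALSE])))

  ps <- array(NA_real_, dim = shape)
  vp <- array(NA_real_, dim = shape)
  ps[fit_idx] <- beta[2L, ]
  vp[fit_idx] <- beta[1L, ]
  fit_mask <- array(FALSE, dim = shape)
  fit_mask[fit_idx] <- TRUE

  structure(list(ps = ps, vp = vp, fit_mask = fit_mask,
                 n_frames_used = length(d$frame_window),
                 n_dropped = n_dropped),
            class = "bbb_permeability")
}

#' @export
print.bbb_permeability <- function(x, ...) {
  cat(sprintf(
    "<bbb_permeability> %d fitted voxels (%d frames, %d dropped); PS x 1e4: mean %.2f, range [%.2f, %.2f]\n",
    sum(x$fit_mask), x$n_frames_used, x$n_dropped,
    mean(x$ps[x$fit_mask]) * 1e4,
    min(x$ps[x$fit_mask]) * 1e4, max(x$ps[x$fit_mask]) * 1e4))
  invisible(x)
}

#' ROI mean permeability metrics
#'
#' Arithmetic means of PS and vP over the fitted voxels of each region of
#' interest. Values are stored in native units (1/min, fraction); the `*_x1e4`
#' columns carry the x 1e4 display convention used when reporting white-matter
#' permeability.
#'
#' @param maps A [map_patlak()] result.
#' @param nawm_mask,wmh_mask Logical 3D ROI masks.
#' @return A one-row tibble: `ps_mean_nawm`, `ps_mean_wmh`, `vp_mean_nawm`,
#'   `vp_mean_wmh`, their `_x1e4` versions, and voxel counts `n_nawm`, `n_wmh`.
#' @export
roi_means <- function(maps, nawm_mask, wmh_mask) {
  stopifnot(inherits(maps, "bbb_permeability"))
  check_mask3d(nawm_mask)
  check_mask3d(wmh_mask)
  roi_mean_one <- function(map, roi, name) {
    sel <- maps$fit_mask & roi
    if (!any(sel)) stop(sprintf("empty ROI: %s", name), call. = FALSE)
    mean(map[sel])
  }
  out <- tibble::tibble(
    ps_mean_nawm = roi_mean_one(maps$ps, nawm_mask, "NAWM"),
    ps_mean_wmh = roi_mean_one(maps$ps, wmh_mask, "WMH"),
    vp_mean_nawm = roi_mean_one(maps$vp, nawm_mask, "NAWM"),
    vp_mean_wmh = roi_mean_one(maps$vp, wmh_mask, "WMH"),
    n_nawm = sum(maps$fit_mask & nawm_mask),
    n_wmh = sum(maps$fit_mask & wmh_mask)
  )
  dplyr::mutate(out,
                ps_mean_nawm_x1e4 = .data$ps_mean_nawm * 1e4,
                ps_mean_wmh_x1e4 = .data$ps_mean_wmh * 1e4,
                vp_mean_nawm_x1e4 = .data$vp_mean_nawm * 1e4,
                vp_mean_wmh_x1e4 = .data$vp_mean_wmh * 1e4)
}
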