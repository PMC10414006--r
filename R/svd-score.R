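#' Total SVD score (0-4)
#'
#' Ordinal composite of small-vessel-disease burden: one point each for the
#' presence of one or more lacunes; one or more microbleeds; confluent deep
#' WMH (deep Fazekas 2 or 3) or periventricular WMH extending into the deep
#' white matter (periventricular Fazekas 3); and moderate to severe
#' perivascular spaces in the basal ganglia (grade 2-4).
#'
#' @param lacune_count,cmb_count Non-negative lesion counts.
#' @param fazekas_dwmh,fazekas_pvh Fazekas grades 0-3.
#' @param pvs_bg Basal-ganglia perivascular-space grade 0-4.
#' @return Integer score(s) in 0-4; inputs are recycled vectorwise.
#' @export
#' @examples
#' total_svd_score(2, 1, 3, 1, 3)  # 4
#' total_svd_score(0, 0, 2, 1, 1)  # 1
total_svd_score <- function(lacune_count, cmb_count, fazekas_dwmh,
                            fazekas_pvh, pvs_bg) {
  n <- max(lengths(list(lacune_count, cmb_count, fazekas_dwmh, fazekas_pvh,
                        pvs_bg)))
  args <- lapply(list(lacune_count = lacune_count, cmb_count = cmb_count,
                      fazekas_dwmh = fazekas_dwmh, fazekas_pvh = fazekas_pvh,
                      pvs_bg = pvs_bg), rep_len, n)
  with(args, {
    if (any(lacune_count < 0) || any(cmb_count < 0)) {
      stop("lesion counts must be >= 0", call. = FALSE)
    }
    if (any(!fazekas_dwmh %in% 0:3) || any(!fazekas_pvh %in% 0:3)) {
      stop("Fazekas grades must be integers 0-3", call. = FALSE)
    }
    if (any(!pvs_bg %in% 0:4)) {
      stop("basal-ganglia PVS grade must be an integer 0-4", call. = FALSE)
    }
    as.integer(
      (lacune_count >= 1) +
        (cmb_count >= 1) +
        (fazekas_dwmh %in% 2:3 | fazekas_pvh == 3) +
        (pvs_bg %in% 2:4)
    )
  })
}

#' Weighted Cohen's kappa for ordinal agreement
#'
#' Chance-corrected agreement between two ratings of the same items on a
#' shared ordinal scale, with linear disagreement weights
#' \eqn{w_{ij} = |i - j| / (k - 1)} (or squared for quadratic weighting):
#' \deqn{\kappa = 1 - \frac{\sum w_{ij} o_{ij}}{\sum w_{ij} e_{ij}},}
#' where \eqn{o} are observed cell proportions and \eqn{e} the products of
#' the marginals.
#'
#' @param ratings_a,ratings_b Equal-length vectors of ordinal ratings.
#' @param weighting `"linear"` (default) or `"quadratic"`.
#' @param categories Optional full category set (so levels unobserved in this
#'   sample still define the scale); default is the sorted union of observed
#'   values.
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' weighted_kappa(c(1, 2, 3, 2), c(1, 2, 3, 2))  # 1: perfect agreement
weighted_kappa <- function(ratings_a, ratings_b,
                           weighting = c("linear", "quadratic"),
                           categories = NULL) {
  weighting <- match.arg(weighting)
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating vectors must have equal length", call. = FALSE)
  }
  if (anyNA(ratings_a) || anyNA(ratings_b)) {
    stop("ratings must not contain missing values", call. = FALSE)
  }
  if (is.null(categories)) {
    categories <- sort(unique(c(ratings_a, ratings_b)))
  }
  k <- length(categories)
  if (k < 2L) {
    stop("kappa is undefined with fewer than 2 distinct categories", call. = FALSE)
  }
  fa <- factor(ratings_a, levels = categories)
  fb <- factor(ratings_b, levels = categories)
  o <- table(fa, fb) / length(ratings_a)
  e <- outer(rowSums(o), colSums(o))
  w <- abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  if (weighting == "quadratic") w <- w^2
  denom <- sum(w * e)
  if (denom == 0) {
    stop("kappa is undefined: no chance-expected disagreement", call. = FALSE)
  }
  1 - sum(w * o) / denom
}
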